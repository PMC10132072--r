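#' ORF search configuration
#'
#' Parameters controlling hit-anchored ORF calling. Defaults follow the
#' published workflow: a window extending 500 nt before and after the hit, six
#' accepted start codons (ATG, CTG, GTG, TTG, ATT, ATC), a minimum ORF length
#' of 300 nt and a requirement that the ORF cover at least 50 % of the hit
#' with an identical translated sequence.
#'
#' @param flank_nt Window extension on each side of the hit, in nt.
#' @param start_codons Accepted start codons.
#' @param stop_codons Stop codons (translation table 11).
#' @param min_orf_nt Minimum ORF length in nt, measured on the interval
#'   including the terminal stop codon when present.
#' @param min_hit_coverage Minimum fraction of hit residues the ORF must cover
#'   with identical translation (boundary inclusive).
#' @param window_bounded If `TRUE` (default) the search window edge delimits
#'   ORFs like a sequence edge; if `FALSE`, ORF enumeration extends over the
#'   whole record so ORFs may run past the window.
#' @param edge_orfs Retain ORFs truncated at a sequence/window edge that lack
#'   a start codon (`has_start_codon = FALSE`)?
#' @return A list of class `orf_config`.
#' @export
orf_config <- function(flank_nt = 500L,
                       start_codons = DEFAULT_START_CODONS,
                       stop_codons = DEFAULT_STOP_CODONS,
                       min_orf_nt = 300L,
                       min_hit_coverage = 0.5,
                       window_bounded = TRUE,
                       edge_orfs = TRUE) {
  stopifnot(flank_nt >= 0, min_orf_nt >= 3,
            min_hit_coverage > 0, min_hit_coverage <= 1,
            all(nchar(start_codons) == 3), all(nchar(stop_codons) == 3))
  structure(
    list(flank_nt = as.integer(flank_nt),
         start_codons = toupper(start_codons),
         stop_codons = toupper(stop_codons),
         min_orf_nt = as.integer(min_orf_nt),
         min_hit_coverage = min_hit_coverage,
         window_bounded = isTRUE(window_bounded),
         edge_orfs = isTRUE(edge_orfs)),
    class = "orf_config"
  )
}

empty_orf_tbl <- function() {
  tibble(record_id = character(), start = integer(), end = integer(),
         strand = character(), start_codon = character(),
         has_start_codon = logical(), has_stop_codon = logical(),
         length_nt = integer(), protein = character())
}

#' Enumerate ORFs in one frame of a window
#'
#' Scans the codons of a single reading frame on the working strand of a
#' window (for the minus strand, the reverse complement of the window).
#' Segments are delimited by in-frame stop codons and by the window edges.
#' Within each segment the ORF begins at the first accepted start codon; a
#' segment flush with the left (5') edge that contains no start codon yields
#' an edge-truncated ORF with `has_start_codon = FALSE` when
#' `config$edge_orfs` is set. The ORF runs to the delimiting stop codon
#' (included in the interval) or the edge. ORFs within one frame never
#' overlap.
#'
#' @param record_seq DNA string of the full record.
#' @param window_start,window_end Window as a 0-based half-open interval on
#'   the forward strand.
#' @param frame_offset Frame offset 0, 1 or 2 on the working strand.
#' @param strand `"+"` or `"-"`.
#' @param config An [orf_config()].
#' @param record_id Record id stamped on the output rows.
#' @return Tibble of ORFs with forward-strand 0-based half-open coordinates.
#' @export
enumerate_orfs_in_window <- function(record_seq, window_start, window_end,
                                     frame_offset, strand,
                                     config = orf_config(),
                                     record_id = NA_character_) {
  stopifnot(length(record_seq) == 1, frame_offset %in% 0:2,
            strand %in% c("+", "-"))
  len <- nchar(record_seq)
  if (window_start < 0 || window_end > len || window_start >= window_end) {
    abort(sprintf("Window [%d, %d) outside record bounds [0, %d).",
                  window_start, window_end, len))
  }
  working <- substr(record_seq, window_start + 1, window_end)
  if (strand == "-") working <- reverse_complement(working)
  wlen <- nchar(working)
  n_codons <- (wlen - frame_offset) %/% 3
  if (n_codons <= 0) return(empty_orf_tbl())
  codon_starts <- frame_offset + 3L * (seq_len(n_codons) - 1L) # 0-based
  codons <- substring(working, codon_starts + 1L, codon_starts + 3L)
  is_stop <- codons %in% config$stop_codons
  is_start <- codons %in% config$start_codons

  stop_idx <- which(is_stop)
  seg_start <- c(1L, stop_idx + 1L)
  seg_end <- c(stop_idx - 1L, n_codons) # last non-stop codon of each segment

  rows <- list()
  for (s in seq_along(seg_start)) {
    a <- seg_start[s]
    b <- seg_end[s]
    if (a > b) next
    starts_here <- which(is_start[a:b])
    at_edge <- (s == 1L)
    if (length(starts_here) > 0) {
      begin <- a + starts_here[1] - 1L
      has_start <- TRUE
    } else if (at_edge && config$edge_orfs) {
      begin <- a
      has_start <- FALSE
    } else {
      next
    }
    has_stop <- s <= length(stop_idx)
    last <- if (has_stop) stop_idx[s] else b
    coding_last <- if (has_stop) last - 1L else last
    prot <- if (coding_last >= begin) {
      paste(translate_codons(codons[begin:coding_last],
                             start_as_met = TRUE,
                             start_codons = config$start_codons),
            collapse = "")
    } else {
      ""
    }
    ws <- codon_starts[begin]
    we <- codon_starts[last] + 3L
    if (strand == "+") {
      fstart <- window_start + ws
      fend <- window_start + we
    } else {
      fstart <- window_end - we
      fend <- window_end - ws
    }
    rows[[length(rows) + 1L]] <- tibble(
      record_id = record_id,
      start = as.integer(fstart), end = as.integer(fend), strand = strand,
      start_codon = if (has_start) codons[begin] else NA_character_,
      has_start_codon = has_start, has_stop_codon = has_stop,
      length_nt = as.integer(we - ws), protein = prot
    )
  }
  if (length(rows) == 0) return(empty_orf_tbl())
  bind_rows(rows)
}

# translation-frame phase of a feature: position (mod 3) of its first
# translated base on the working strand
feature_phase <- function(start, end, strand) {
  if (strand == "+") start %% 3L else end %% 3L
}

#' Identical-translation coverage of a hit by an ORF
#'
#' Returns the fraction of hit residues that fall inside the ORF interval, lie
#' in the ORF's reading frame and strand, and whose (degapped) aligned subject
#' residue equals the genomic translation at that codon. Residues translating
#' to `X` (ambiguous) or `*` (stop) never count as identical. Hits with an
#' empty aligned subject string fall back to the plain in-frame
#' nucleotide-overlap fraction.
#'
#' @param orf One ORF row (tibble or list with `start`, `end`, `strand`).
#' @param hit One hit row with `start`, `end`, `strand`, `sseq` (see
#'   [hit_intervals()]).
#' @param record_seq DNA string of the record both features live on.
#' @return Coverage fraction in `[0, 1]`.
#' @export
hit_coverage_identity <- function(orf, hit, record_seq) {
  if (orf$strand != hit$strand) return(0)
  res <- gsub("-", "", hit$sseq, fixed = TRUE)
  nres <- nchar(res)
  same_frame <- feature_phase(orf$start, orf$end, orf$strand) ==
    feature_phase(hit$start, hit$end, hit$strand)
  if (nres == 0) {
    # no aligned subject sequence: in-frame nucleotide overlap fraction
    if (!same_frame) return(0)
    ov <- interval_gap(orf$start, orf$end, hit$start, hit$end) == 0
    if (!ov) return(0)
    overlap <- min(orf$end, hit$end) - max(orf$start, hit$start)
    return(max(0, overlap) / (hit$end - hit$start))
  }
  if (!same_frame) return(0)
  r <- seq_len(nres) - 1L
  if (hit$strand == "+") {
    cod_start <- hit$start + 3L * r
  } else {
    cod_start <- hit$end - 3L * (r + 1L)
  }
  inside <- cod_start >= orf$start & (cod_start + 3L) <= orf$end
  if (!any(inside)) return(0)
  idx <- which(inside)
  cods <- substring(record_seq, cod_start[idx] + 1L, cod_start[idx] + 3L)
  if (hit$strand == "-") cods <- vapply(cods, reverse_complement, character(1))
  aa <- translate_codons(cods)
  subject_res <- substring(res, idx, idx)
  ok <- aa == subject_res & !(aa %in% c("X", "*"))
  sum(ok) / nres
}

#' Longest ORF containing a hit
#'
#' Builds a window extending `config$flank_nt` on each side of the hit
#' (clipped to the record), enumerates ORFs in the hit's frame and strand, and
#' returns the longest ORF that covers at least `config$min_hit_coverage` of
#' the hit with an identical translated sequence and is at least
#' `config$min_orf_nt` long. Absence of a qualifying ORF is a value, not an
#' error: a zero-row tibble is returned.
#'
#' Only the hit's own frame and strand are searched: the identical-translation
#' requirement means ORFs in any other frame score zero coverage.
#'
#' @param record_seq DNA string of the record.
#' @param hit One hit row with `start`, `end`, `strand`, `sseq`.
#' @param config An [orf_config()].
#' @param record_id Record id stamped on the output.
#' @return One-row ORF tibble with a `hit_coverage` column, or a zero-row
#'   tibble.
#' @export
find_longest_containing_orf <- function(record_seq, hit,
                                        config = orf_config(),
                                        record_id = NA_character_) {
  len <- nchar(record_seq)
  if (config$window_bounded) {
    w0 <- max(0L, as.integer(hit$start) - config$flank_nt)
    w1 <- min(len, as.integer(hit$end) + config$flank_nt)
  } else {
    w0 <- 0L
    w1 <- len
  }
  fo <- if (hit$strand == "+") (hit$start - w0) %% 3L else (w1 - hit$end) %% 3L
  orfs <- enumerate_orfs_in_window(record_seq, w0, w1, fo, hit$strand,
                                   config, record_id = record_id)
  out <- empty_orf_tbl()
  out$hit_coverage <- numeric(0)
  if (nrow(orfs) == 0) return(out)
  orfs$hit_coverage <- vapply(
    seq_len(nrow(orfs)),
    function(i) hit_coverage_identity(orfs[i, ], hit, record_seq),
    numeric(1)
  )
  ok <- orfs$hit_coverage >= config$min_hit_coverage &
    orfs$length_nt >= config$min_orf_nt
  if (!any(ok)) return(out)
  cand <- orfs[ok, ]
  cand <- cand[order(-cand$length_nt, cand$start), ]
  cand[1, ]
}

#' Call ORFs for every hit
#'
#' Runs [find_longest_containing_orf()] for each hit against its subject
#' record and stacks the results, carrying the source hit's query id, e-value
#' and row index.
#'
#' @param records Record tibble from [read_fasta()].
#' @param hits Hit tibble; forward-strand intervals are derived with
#'   [hit_intervals()] if not already present.
#' @param config An [orf_config()].
#' @return ORF tibble, one row per hit with a qualifying ORF.
#' @export
call_orfs <- function(records, hits, config = orf_config()) {
  if (!all(c("start", "end", "strand") %in% names(hits))) {
    hits <- hit_intervals(hits)
  }
  missing <- setdiff(unique(hits$sseqid), records$id)
  if (length(missing) > 0) {
    abort(paste0("Hits reference records absent from `records`: ",
                 paste(head(missing, 3), collapse = ", ")))
  }
  seq_by_id <- setNames(records$seq, records$id)
  rows <- map(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    orf <- find_longest_containing_orf(seq_by_id[[h$sseqid]], h, config,
                                       record_id = h$sseqid)
    if (nrow(orf) == 0) return(NULL)
    orf$source_hit_index <- i
    orf$query_id <- h$qseqid
    orf$evalue <- h$evalue
    orf
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    out <- empty_orf_tbl()
    out$hit_coverage <- numeric(0)
    out$source_hit_index <- integer(0)
    out$query_id <- character(0)
    out$evalue <- numeric(0)
    return(out)
  }
  bind_rows(rows)
}

#' Collapse duplicate ORFs
#'
#' Multiple query proteins commonly hit the same gene; ORFs identical in
#' (record, interval, strand) are merged into one, keeping the source hit with
#' the lowest e-value. Output is sorted by record then start.
#'
#' @param orfs ORF tibble from [call_orfs()].
#' @return Deduplicated ORF tibble.
#' @export
dedupe_orfs <- function(orfs) {
  if (nrow(orfs) == 0) return(orfs)
  orfs |>
    group_by(.data$record_id, .data$start, .data$end, .data$strand) |>
    slice_min(.data$evalue, n = 1, with_ties = FALSE) |>
    ungroup() |>
    arrange(.data$record_id, .data$start, .data$strand)
}
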