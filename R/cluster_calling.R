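#' Pairing configuration
#'
#' Defaults follow the published workflow: pairs with more than 2 kb between
#' the genes are removed (overlapping genes pass with gap 0) and only genes
#' shorter than 6 kb are retained.
#'
#' @param max_gap_nt Maximum intergenic distance retained (inclusive).
#' @param max_gene_nt Exclusive upper bound on gene length.
#' @return A list of class `pairing_config`.
#' @export
pairing_config <- function(max_gap_nt = 2000L, max_gene_nt = 6000L) {
  stopifnot(max_gap_nt >= 0, max_gene_nt > 0)
  structure(list(max_gap_nt = as.integer(max_gap_nt),
                 max_gene_nt = as.integer(max_gene_nt)),
            class = "pairing_config")
}

#' Intergenic distance between two intervals
#'
#' Distance is measured between the closest interval ends: 0 when the
#' intervals overlap or abut, otherwise the number of nucleotides strictly
#' between them.
#'
#' @param start1,end1,start2,end2 0-based half-open interval coordinates
#'   (vectorized).
#' @param record_id1,record_id2 Optional record ids; supplying different ids
#'   is an error, distances across records are undefined.
#' @return Integer vector of gaps.
#' @examples
#' intergenic_gap(100, 400, 2500, 3000) # 2100
#' intergenic_gap(100, 400, 300, 600)   # overlap -> 0
#' @export
intergenic_gap <- function(start1, end1, start2, end2,
                           record_id1 = NULL, record_id2 = NULL) {
  if (!is.null(record_id1) && !is.null(record_id2) &&
      any(record_id1 != record_id2)) {
    abort("Intergenic distance is undefined across different records.")
  }
  as.integer(interval_gap(start1, end1, start2, end2))
}

#' Pair KS and CLF genes by genomic proximity
#'
#' Emits every (KS, CLF) combination on the same record whose intergenic gap
#' is at most `max_gap_nt` and whose gene lengths are both below
#' `max_gene_nt`. An ORF may appear in several pairs (one KS near two CLFs
#' yields two pairs). Strand concordance is not required; orientations are
#' recorded for inspection. Output order is deterministic: record, KS start,
#' CLF start.
#'
#' @param orfs Classified ORF tibble (columns `record_id`, `start`, `end`,
#'   `strand`, `label`, optionally `ks_bits`/`clf_bits`).
#' @param config A [pairing_config()].
#' @return Pair tibble with one row per retained KS-CLF pair.
#' @export
pair_genes <- function(orfs, config = pairing_config()) {
  need <- c("record_id", "start", "end", "strand", "label")
  stopifnot(all(need %in% names(orfs)))
  short <- dplyr::filter(orfs, .data$end - .data$start < config$max_gene_nt)
  ks <- dplyr::filter(short, .data$label == "KS")
  clf <- dplyr::filter(short, .data$label == "CLF")
  empty <- tibble(record_id = character(),
                  ks_start = integer(), ks_end = integer(),
                  ks_strand = character(),
                  clf_start = integer(), clf_end = integer(),
                  clf_strand = character(),
                  gap_nt = integer(),
                  ks_bits = numeric(), clf_bits = numeric())
  if (nrow(ks) == 0 || nrow(clf) == 0) return(empty)
  ksb <- if ("ks_bits" %in% names(ks)) ks$ks_bits else NA_real_
  clfb <- if ("clf_bits" %in% names(clf)) clf$clf_bits else NA_real_
  kst <- tibble(record_id = ks$record_id, ks_start = ks$start,
                ks_end = ks$end, ks_strand = ks$strand, ks_bits = ksb)
  clt <- tibble(record_id = clf$record_id, clf_start = clf$start,
                clf_end = clf$end, clf_strand = clf$strand, clf_bits = clfb)
  inner_join(kst, clt, by = "record_id", relationship = "many-to-many") |>
    mutate(gap_nt = intergenic_gap(.data$ks_start, .data$ks_end,
                                   .data$clf_start, .data$clf_end)) |>
    dplyr::filter(.data$gap_nt <= config$max_gap_nt) |>
    select("record_id", "ks_start", "ks_end", "ks_strand",
           "clf_start", "clf_end", "clf_strand", "gap_nt",
           "ks_bits", "clf_bits") |>
    arrange(.data$record_id, .data$ks_start, .data$clf_start)
}

#' Extract merged cluster regions around gene pairs
#'
#' Each pair's bounding interval is extended by `flank_nt` on both sides and
#' clipped to the record; overlapping extended intervals on one record are
#' merged, partitioning the pairs among the resulting regions. With
#' `merge_rule = "pair_gap"`, regions are instead kept separate whenever the
#' pair bounding intervals themselves are more than `flank_nt` apart (so two
#' pairs 30-60 kb apart, whose extensions overlap, stay distinct).
#'
#' @param pairs Pair tibble from [pair_genes()].
#' @param records Record tibble (`id`, `seq`) or a tibble with `id` and
#'   `length` columns.
#' @param flank_nt Extension on each side, default 30 kb.
#' @param merge_rule `"extension"` (merge when extended intervals overlap) or
#'   `"pair_gap"` (merge when pair bounding intervals are within `flank_nt`).
#' @return Region tibble: `record_id`, `start`, `end`, `n_pairs`,
#'   `pair_rows` (list column of row indices into `pairs`).
#' @export
extract_regions <- function(pairs, records, flank_nt = 30000L,
                            merge_rule = c("extension", "pair_gap")) {
  merge_rule <- match.arg(merge_rule)
  empty <- tibble(record_id = character(), start = integer(), end = integer(),
                  n_pairs = integer(), pair_rows = list())
  if (nrow(pairs) == 0) return(empty)
  rec_len <- if ("length" %in% names(records)) {
    setNames(as.integer(records$length), records$id)
  } else {
    setNames(nchar(records$seq), records$id)
  }
  missing <- setdiff(unique(pairs$record_id), names(rec_len))
  if (length(missing) > 0) {
    abort(paste0("Pairs reference records absent from `records`: ",
                 paste(head(missing, 3), collapse = ", ")))
  }
  b <- tibble(
    row = seq_len(nrow(pairs)),
    record_id = pairs$record_id,
    lo = pmin(pairs$ks_start, pairs$clf_start),
    hi = pmax(pairs$ks_end, pairs$clf_end)
  )
  b$ext_lo <- pmax(0L, b$lo - as.integer(flank_nt))
  b$ext_hi <- pmin(rec_len[b$record_id], b$hi + as.integer(flank_nt))
  b <- arrange(b, .data$record_id, .data$lo, .data$hi)

  out <- list()
  for (rid in unique(b$record_id)) {
    d <- b[b$record_id == rid, ]
    grp <- integer(nrow(d))
    grp[1] <- 1L
    cur_ext_hi <- d$ext_hi[1]
    cur_hi <- d$hi[1]
    if (nrow(d) > 1) {
      for (i in 2:nrow(d)) {
        same <- if (merge_rule == "extension") {
          d$ext_lo[i] < cur_ext_hi
        } else {
          d$lo[i] - cur_hi <= flank_nt
        }
        grp[i] <- if (same) grp[i - 1] else grp[i - 1] + 1L
        cur_ext_hi <- if (same) max(cur_ext_hi, d$ext_hi[i]) else d$ext_hi[i]
        cur_hi <- if (same) max(cur_hi, d$hi[i]) else d$hi[i]
      }
    }
    for (g in unique(grp)) {
      dd <- d[grp == g, ]
      out[[length(out) + 1L]] <- tibble(
        record_id = rid,
        start = as.integer(min(dd$ext_lo)),
        end = as.integer(max(dd$ext_hi)),
        n_pairs = nrow(dd),
        pair_rows = list(sort(dd$row))
      )
    }
  }
  bind_rows(out) |> arrange(.data$record_id, .data$start)
}

#' Categorize condensation-domain content of a region
#'
#' Given the multiset of annotation tokens found in a region (`t2ks`,
#' `t2clf`, `t2fas`), reports which pairings are present: `KS_CLF` needs at
#' least one `t2ks` and one `t2clf`; `KS_FAS` at least one `t2ks` and one
#' `t2fas`; `FAS_FAS` at least two `t2fas`. The categories are not mutually
#' exclusive and the empty set is possible. Unknown tokens are ignored with a
#' warning.
#'
#' @param labels Character vector of tokens (repeats meaningful).
#' @return Character vector, subset of `c("KS_CLF", "KS_FAS", "FAS_FAS")`.
#' @examples
#' categorize_region(c("t2ks", "t2clf"))
#' categorize_region(c("t2fas", "t2fas"))
#' @export
categorize_region <- function(labels) {
  known <- c("t2ks", "t2clf", "t2fas")
  unknown <- setdiff(unique(labels), known)
  if (length(unknown) > 0) {
    warn(paste0("Ignoring unknown gene-function tokens: ",
                paste(unknown, collapse = ", ")))
    labels <- labels[labels %in% known]
  }
  n_ks <- sum(labels == "t2ks")
  n_clf <- sum(labels == "t2clf")
  n_fas <- sum(labels == "t2fas")
  out <- character(0)
  if (n_ks >= 1 && n_clf >= 1) out <- c(out, "KS_CLF")
  if (n_ks >= 1 && n_fas >= 1) out <- c(out, "KS_FAS")
  if (n_fas >= 2) out <- c(out, "FAS_FAS")
  out
}

#' @rdname categorize_region
#' @param label_table Tibble with columns `region_id` and `gene_function`
#'   (one row per annotated gene).
#' @return For `categorize_regions()`: tibble with `region_id` and
#'   `categories` (semicolon-joined, empty string for none).
#' @export
categorize_regions <- function(label_table) {
  stopifnot(all(c("region_id", "gene_function") %in% names(label_table)))
  label_table |>
    group_by(.data$region_id) |>
    summarise(categories = paste(categorize_region(.data$gene_function),
                                 collapse = ";"),
              .groups = "drop")
}
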