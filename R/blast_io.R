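#' Default column specification for tabular homology hits
#'
#' The pipeline consumes tblastn-style tabular output (outfmt-6 family) with a
#' custom column list: the standard six leading fields plus subject
#' coordinates, subject frame and the aligned subject protein. The field order
#' is configurable because it varies with the search invocation.
#'
#' @return Character vector of column names in file order.
#' @export
blast_columns <- function() {
  c("qseqid", "sseqid", "pident", "length", "evalue", "bitscore",
    "sstart", "send", "sframe", "sseq")
}

BLAST_NUMERIC_COLS <- c("pident", "length", "evalue", "bitscore",
                        "sstart", "send", "sframe")

#' Parse tabular translated-homology hits
#'
#' Reads a tab-separated hit table (lines starting with `#` are comments) into
#' a tibble, one row per hit. No filtering is applied; numeric fields are
#' parsed strictly and a malformed line is reported with its line number.
#'
#' @param source Path to a TSV file, or a character vector of lines.
#' @param columns Ordered field names covering all hit fields; see
#'   [blast_columns()].
#' @return Tibble with one row per hit and the columns of `columns`.
#' @export
read_blast_hits <- function(source, columns = blast_columns()) {
  missing_cols <- setdiff(blast_columns(), columns)
  if (length(missing_cols) > 0) {
    abort(paste0("`columns` must cover all hit fields; missing: ",
                 paste(missing_cols, collapse = ", ")))
  }
  lines <- if (length(source) == 1 && file.exists(source)) {
    readLines(source)
  } else {
    as.character(source)
  }
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    out <- map(columns, function(x) character(0))
    names(out) <- columns
    out <- as_tibble(out)
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != length(columns))) {
      bad <- which(nf != length(columns))[1]
      abort(sprintf("Line %d has %d fields; expected %d.",
                    lineno[bad], nf[bad], length(columns)))
    }
    mat <- do.call(rbind, fields)
    colnames(mat) <- columns
    out <- as_tibble(as.data.frame(mat, stringsAsFactors = FALSE))
  }
  for (col in intersect(BLAST_NUMERIC_COLS, columns)) {
    val <- suppressWarnings(as.numeric(out[[col]]))
    bad <- is.na(val) & !is.na(out[[col]])
    if (any(bad)) {
      abort(sprintf("Line %d: cannot parse '%s' as numeric in column '%s'.",
                    lineno[which(bad)[1]], out[[col]][which(bad)[1]], col))
    }
    out[[col]] <- val
  }
  for (col in c("length", "sstart", "send", "sframe")) {
    if (col %in% names(out)) out[[col]] <- as.integer(out[[col]])
  }
  validate_hits(out)
  out
}

validate_hits <- function(hits) {
  if (nrow(hits) == 0) return(invisible(hits))
  if (!all(hits$sframe %in% c(-3L, -2L, -1L, 1L, 2L, 3L))) {
    abort("`sframe` must lie in {-3,-2,-1,1,2,3}.")
  }
  plus <- hits$sframe > 0
  bad <- (plus & hits$sstart >= hits$send) | (!plus & hits$sstart <= hits$send)
  if (any(bad)) {
    abort(sprintf(
      "Hit %d: subject coordinate order inconsistent with frame sign.",
      which(bad)[1]
    ))
  }
  if (any(hits$evalue < 0)) abort("Negative e-value.")
  invisible(hits)
}

#' Filter hits by e-value
#'
#' Retains hits with `evalue <= max_evalue` (boundary inclusive), preserving
#' order. The permissive default of 1 keeps distantly related matches; the
#' downstream ORF, profile-HMM and proximity stages remove spurious
#' alignments.
#'
#' @param hits Hit tibble from [read_blast_hits()].
#' @param max_evalue Maximum e-value retained; must be positive.
#' @return Filtered hit tibble.
#' @export
filter_hits <- function(hits, max_evalue = 1) {
  stopifnot(is.numeric(max_evalue), length(max_evalue) == 1, max_evalue > 0)
  dplyr::filter(hits, .data$evalue <= max_evalue)
}

#' Convert hit subject coordinates to forward-strand intervals
#'
#' Adds 0-based half-open forward-strand columns `start`, `end` and a `strand`
#' column derived from the frame sign. For minus-frame hits (printed with
#' `sstart > send`) the interval is `[send - 1, sstart)`.
#'
#' @param hits Hit tibble.
#' @return `hits` with `start`, `end`, `strand` columns added.
#' @examples
#' h <- read_blast_hits("q1\ts1\t95\t120\t1e-50\t250\t101\t460\t1\tMK")
#' hit_intervals(h)[, c("start", "end", "strand")]
#' @export
hit_intervals <- function(hits) {
  validate_hits(hits)
  mutate(
    hits,
    strand = ifelse(.data$sframe > 0, "+", "-"),
    start = ifelse(.data$sframe > 0, .data$sstart - 1L, .data$send - 1L),
    end = ifelse(.data$sframe > 0, .data$send, .data$sstart),
    start = as.integer(.data$start),
    end = as.integer(.data$end)
  )
}
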