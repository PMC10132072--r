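#' Pipeline configuration
#'
#' Aggregates the per-stage configurations with the published defaults:
#' e-value at most 1, a 500 nt ORF search flank, six start codons, 300 nt
#' minimum ORF length, 50 % identical hit coverage, a 2 kb pairing distance,
#' genes under 6 kb, and 30 kb cluster-region flanks.
#'
#' @param max_evalue Hit e-value cutoff (inclusive).
#' @param orf An [orf_config()].
#' @param pairing A [pairing_config()].
#' @param region_flank_nt Cluster-region extension, nt.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(max_evalue = 1,
                            orf = orf_config(),
                            pairing = pairing_config(),
                            region_flank_nt = 30000L) {
  structure(list(max_evalue = max_evalue, orf = orf, pairing = pairing,
                 region_flank_nt = as.integer(region_flank_nt)),
            class = "pipeline_config")
}

#' Serialize and reload a pipeline configuration
#'
#' Configurations are written as plain JSON at full precision; a write/read
#' round trip reproduces an equal object.
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `write_pipeline_config()`: `path`, invisibly;
#'   `read_pipeline_config()`: a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  payload <- list(
    format = "ksclf-config-1",
    max_evalue = config$max_evalue,
    orf = unclass(config$orf),
    pairing = unclass(config$pairing),
    region_flank_nt = config$region_flank_nt
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "ksclf-config-1")) {
    abort("Not a ksclf pipeline configuration file.")
  }
  pipeline_config(
    max_evalue = p$max_evalue,
    orf = orf_config(flank_nt = p$orf$flank_nt,
                     start_codons = p$orf$start_codons,
                     stop_codons = p$orf$stop_codons,
                     min_orf_nt = p$orf$min_orf_nt,
                     min_hit_coverage = p$orf$min_hit_coverage,
                     window_bounded = p$orf$window_bounded,
                     edge_orfs = p$orf$edge_orfs),
    pairing = pairing_config(max_gap_nt = p$pairing$max_gap_nt,
                             max_gene_nt = p$pairing$max_gene_nt),
    region_flank_nt = p$region_flank_nt
  )
}

#' Run the KS-CLF discovery pipeline end to end
#'
#' Executes hit filtering, hit-anchored ORF calling, deduplication,
#' profile-HMM classification, proximity pairing and cluster-region
#' extraction, collecting per-stage counts along the way. Zero pairs is a
#' valid outcome, not an error.
#'
#' @param records Record tibble from [read_fasta()].
#' @param hits Hit tibble from [read_blast_hits()].
#' @param ks_model,clf_model `profile_hmm` objects.
#' @param classifier A [classifier_config()] carrying the calibrated
#'   retention thresholds.
#' @param config A [pipeline_config()].
#' @return A `ksclf_run` object: list with tibbles `orfs` (deduplicated,
#'   classified), `pairs`, `regions`, and `stages` (the stage report).
#' @export
run_scan <- function(records, hits, ks_model, clf_model, classifier,
                     config = pipeline_config()) {
  stopifnot(inherits(classifier, "classifier_config"),
            inherits(config, "pipeline_config"))
  stages <- list()
  note <- function(stage, n_in, n_out, reasons = integer(0)) {
    dropped <- n_in - n_out
    stages[[length(stages) + 1L]] <<- tibble(
      stage = stage, n_in = n_in, n_out = n_out,
      n_dropped = max(0L, dropped),
      reasons = list(reasons)
    )
  }

  kept <- filter_hits(hits, config$max_evalue)
  note("hit_filter", nrow(hits), nrow(kept),
       c(evalue_above_cutoff = nrow(hits) - nrow(kept)))

  orfs_raw <- call_orfs(records, kept, config$orf)
  note("orf_calling", nrow(kept), nrow(orfs_raw),
       c(no_qualifying_orf = nrow(kept) - nrow(orfs_raw)))

  orfs <- dedupe_orfs(orfs_raw)
  note("orf_dedup", nrow(orfs_raw), nrow(orfs),
       c(duplicate_interval = nrow(orfs_raw) - nrow(orfs)))

  orfs <- classify_orfs(orfs, ks_model, clf_model, classifier)
  labelled <- dplyr::filter(orfs, .data$label != "none")
  note("classification", nrow(orfs), nrow(labelled),
       c(below_both_thresholds = nrow(orfs) - nrow(labelled)))

  pairs <- pair_genes(labelled, config$pairing)
  in_pair <- 0L
  if (nrow(labelled) > 0) {
    key <- function(r, s, e, st) paste(r, s, e, st)
    pk <- c(key(pairs$record_id, pairs$ks_start, pairs$ks_end, pairs$ks_strand),
            key(pairs$record_id, pairs$clf_start, pairs$clf_end,
                pairs$clf_strand))
    in_pair <- sum(key(labelled$record_id, labelled$start, labelled$end,
                       labelled$strand) %in% pk)
  }
  note("pairing", nrow(labelled), nrow(pairs),
       c(orf_in_no_pair = nrow(labelled) - in_pair))

  regions <- extract_regions(pairs, records, config$region_flank_nt)
  note("regions", nrow(pairs), nrow(regions), integer(0))

  structure(list(orfs = orfs, pairs = pairs, regions = regions,
                 stages = bind_rows(stages), config = config),
            class = "ksclf_run")
}

#' Per-stage funnel report of a pipeline run
#'
#' One row per stage with items in, items out, items dropped and a named
#' drop-reason histogram (list column). Successive stages telescope: each
#' stage's output count is the next stage's input count.
#'
#' @param run A `ksclf_run` from [run_scan()].
#' @return Tibble with columns `stage`, `n_in`, `n_out`, `n_dropped`,
#'   `reasons`.
#' @export
stage_report <- function(run) {
  stopifnot(inherits(run, "ksclf_run"))
  run$stages
}

#' @export
print.ksclf_run <- function(x, ...) {
  cat("<ksclf_run>\n")
  s <- x$stages
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-14s %5d -> %5d\n", s$stage[i], s$n_in[i], s$n_out[i]))
  }
  invisible(x)
}

#' One-row summary of a pipeline run
#'
#' @param x A `ksclf_run`.
#' @param ... Unused.
#' @return One-row tibble with hit, ORF, labelled-ORF, pair and region counts.
#' @export
glance.ksclf_run <- function(x, ...) {
  s <- x$stages
  tibble(
    n_hits = s$n_in[s$stage == "hit_filter"],
    n_hits_kept = s$n_out[s$stage == "hit_filter"],
    n_orfs = s$n_out[s$stage == "orf_dedup"],
    n_labelled = s$n_out[s$stage == "classification"],
    n_ks = sum(x$orfs$label == "KS"),
    n_clf = sum(x$orfs$label == "CLF"),
    n_pairs = nrow(x$pairs),
    n_regions = nrow(x$regions)
  )
}

#' Tidy the pair table of a run
#'
#' @param x A `ksclf_run`.
#' @param ... Unused.
#' @return The pair tibble.
#' @export
tidy.ksclf_run <- function(x, ...) {
  x$pairs
}

#' Stage-funnel plot for a pipeline run
#'
#' @param object A `ksclf_run`.
#' @param ... Unused.
#' @return A ggplot showing items entering and surviving each stage.
#' @export
autoplot.ksclf_run <- function(object, ...) {
  s <- object$stages |>
    mutate(stage = factor(.data$stage, levels = .data$stage)) |>
    tidyr::pivot_longer(c("n_in", "n_out"), names_to = "side",
                        values_to = "count") |>
    mutate(side = ifelse(.data$side == "n_in", "in", "out"))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$stage, y = .data$count,
                                  fill = .data$side)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "items", fill = NULL,
                  title = "Pipeline stage funnel") +
    ggplot2::theme_minimal()
}

#' Score distribution plot for classified ORFs
#'
#' @param orfs Classified ORF tibble (from [classify_orfs()] or
#'   `run$orfs`).
#' @param ks_threshold,clf_threshold Optional threshold lines.
#' @return A ggplot of KS vs CLF bit scores coloured by label.
#' @export
plot_scores <- function(orfs, ks_threshold = NULL, clf_threshold = NULL) {
  p <- ggplot2::ggplot(orfs, ggplot2::aes(x = .data$ks_bits,
                                          y = .data$clf_bits,
                                          colour = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "KS model score (bits)", y = "CLF model score (bits)",
                  colour = "label") +
    ggplot2::theme_minimal()
  if (!is.null(ks_threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = ks_threshold, linetype = 2)
  }
  if (!is.null(clf_threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = clf_threshold, linetype = 2)
  }
  p
}

write_tsv_base <- function(x, path) {
  x <- as.data.frame(x)
  list_cols <- vapply(x, is.list, logical(1))
  x[list_cols] <- lapply(x[list_cols], function(col) {
    vapply(col, function(v) paste(v, collapse = ","), character(1))
  })
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write pipeline tables to disk
#'
#' `write_orfs_tsv()` and `write_pairs_tsv()` emit tab-separated tables with
#' 0-based half-open coordinates; `write_regions_bed()` emits BED3 (already
#' 0-based half-open); `write_orf_proteins()` emits a protein FASTA with ids
#' `record_id:start-end:strand`.
#'
#' @param orfs,pairs,regions Pipeline tibbles.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_orfs_tsv <- function(orfs, path) write_tsv_base(orfs, path)

#' @rdname write_orfs_tsv
#' @export
write_pairs_tsv <- function(pairs, path) write_tsv_base(pairs, path)

#' @rdname write_orfs_tsv
#' @export
write_regions_bed <- function(regions, path) {
  bed <- regions[, c("record_id", "start", "end")]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_orfs_tsv
#' @export
write_orfs_bed <- function(orfs, path) {
  bed <- data.frame(
    chrom = orfs$record_id, start = orfs$start, end = orfs$end,
    name = sprintf("%s:%d-%d:%s", orfs$record_id, orfs$start, orfs$end,
                   orfs$strand),
    score = 0L, strand = orfs$strand
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_orfs_tsv
#' @param records Record tibble supplying the sequences sliced per region.
#' @export
write_region_fasta <- function(regions, records, path) {
  seq_by_id <- setNames(records$seq, records$id)
  slices <- tibble(
    id = sprintf("%s:%d-%d", regions$record_id, regions$start, regions$end),
    seq = substring(seq_by_id[regions$record_id], regions$start + 1,
                    regions$end)
  )
  write_fasta(slices, path)
}

#' Scan annotation text for condensing-enzyme gene-function tokens
#'
#' A minimal text-scan helper over annotation files (for example GenBank-style
#' flat files produced by a cluster annotator): every occurrence of the tokens
#' `t2ks`, `t2clf` or `t2fas` on a line containing `gene_functions` is
#' collected, yielding the label multiset that [categorize_region()] consumes.
#'
#' @param path Text file to scan.
#' @return Character vector of tokens, one per occurrence.
#' @export
scan_gene_functions <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[grepl("gene_functions", lines, fixed = TRUE)]
  hits <- regmatches(lines, gregexpr("t2(ks|clf|fas)", lines))
  unlist(hits, use.names = FALSE)
}

#' @rdname write_orfs_tsv
#' @export
write_orf_proteins <- function(orfs, path) {
  ids <- sprintf("%s:%d-%d:%s", orfs$record_id, orfs$start, orfs$end,
                 orfs$strand)
  writeLines(as.vector(rbind(paste0(">", ids),
                             sub("\\*+$", "", orfs$protein))), path)
  invisible(path)
}
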