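#' Synthetic contigs with planted KS/CLF-like genes
#'
#' The generator plants genes (a start codon, a reverse-translated protein
#' body, a stop codon; reverse-complemented on the minus strand) into random
#' background sequence at a chosen GC fraction, and emits a ground-truth
#' coordinate table plus a simulated translated-homology hit table, so the
#' whole pipeline can be exercised without any database download. Background
#' sequence may contain incidental ORFs: the pipeline has to reject them via
#' the coverage and classification stages, not via generator tricks.
#'
#' All randomness flows from a single spec seed through named substreams
#' (background, codons, stops, strands, proteins), so fixtures are stable.
#'
#' @name synthetic-fixtures
NULL

# deterministic substream seed, kept below 2^31
sub_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.double(seed) * 10007 + h * 97) %% 2147483561) + 1L
}

# synonymous codon sets, translation table 11, stops excluded
codons_by_aa <- local({
  tbl <- NULL
  function() {
    if (is.null(tbl)) {
      gc <- codon_table_11()
      tbl <<- split(names(gc), unname(gc))
      tbl[["*"]] <<- NULL
    }
    tbl
  }
})

#' Reverse-translate a protein into DNA
#'
#' Each residue is encoded by a synonymous codon drawn uniformly (translation
#' table 11), so the result has no internal stop codons and translates back to
#' the input exactly. Deterministic per seed.
#'
#' @param protein Protein string without `*`.
#' @param seed Integer seed.
#' @return DNA string of length `3 * nchar(protein)`.
#' @export
reverse_translate <- function(protein, seed) {
  stopifnot(length(protein) == 1)
  if (grepl("*", protein, fixed = TRUE)) {
    abort("Cannot reverse-translate a stop ('*').")
  }
  aa <- strsplit(toupper(protein), "", fixed = TRUE)[[1]]
  tbl <- codons_by_aa()
  bad <- !(aa %in% names(tbl))
  if (any(bad)) {
    abort(sprintf("Residue '%s' has no codon in translation table 11.",
                  aa[which(bad)[1]]))
  }
  withr::local_seed(as.integer(seed))
  cods <- vapply(aa, function(a) {
    opts <- tbl[[a]]
    opts[sample.int(length(opts), 1)]
  }, character(1), USE.NAMES = FALSE)
  paste(cods, collapse = "")
}

#' Specification for a synthetic contig
#'
#' @param record_id Record id.
#' @param record_length Contig length in nt.
#' @param plants Tibble with columns `protein` (no `*`; the first residue is
#'   encoded by `start_codon` and reported as `M`), `start_codon`, `position`
#'   (0-based forward-strand start of the gene), `strand` and
#'   `role` (`"KS"`, `"CLF"` or `"decoy"`).
#' @param gc_fraction Background GC content.
#' @param seed Master seed for all substreams.
#' @return A list of class `plant_spec`.
#' @export
plant_spec <- function(record_id, record_length, plants, gc_fraction = 0.5,
                       seed = 1L) {
  stopifnot(is.data.frame(plants),
            all(c("protein", "start_codon", "position", "strand", "role")
                %in% names(plants)),
            gc_fraction >= 0, gc_fraction <= 1, record_length >= 1)
  structure(list(record_id = record_id,
                 record_length = as.integer(record_length),
                 plants = as_tibble(plants),
                 gc_fraction = gc_fraction,
                 seed = as.integer(seed)),
            class = "plant_spec")
}

#' Generate a synthetic contig and its ground truth
#'
#' @param spec A [plant_spec()].
#' @return List with `record` (one-row tibble: `id`, `description`, `seq`) and
#'   `truth` (tibble: `record_id`, `start`, `end`, `strand`, `role`,
#'   `protein`; 0-based half-open gene intervals including the stop codon).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  plants <- spec$plants
  len <- spec$record_length

  withr::local_seed(sub_seed(spec$seed, "background"))
  gcp <- spec$gc_fraction / 2
  atp <- (1 - spec$gc_fraction) / 2
  bg <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c(atp, gcp, gcp, atp))

  withr::local_seed(sub_seed(spec$seed, "stops"))
  stops <- sample(DEFAULT_STOP_CODONS, nrow(plants), replace = TRUE)

  truth_rows <- list()
  occupied <- cbind(start = integer(0), end = integer(0))
  for (i in seq_len(nrow(plants))) {
    p <- plants[i, ]
    body <- reverse_translate(substring(p$protein, 2),
                              sub_seed(spec$seed, paste0("codons", i)))
    gene <- paste0(p$start_codon, body, stops[i])
    glen <- nchar(gene)
    s <- as.integer(p$position)
    e <- s + glen
    if (s < 0 || e > len) {
      abort(sprintf("Plant %d [%d, %d) outside record bounds [0, %d).",
                    i, s, e, len))
    }
    if (any(interval_gap(occupied[, "start"], occupied[, "end"], s, e) == 0 &
            pmin(occupied[, "end"], e) - pmax(occupied[, "start"], s) > 0)) {
      abort(sprintf("Plant %d overlaps an earlier plant.", i))
    }
    occupied <- rbind(occupied, c(s, e))
    ins <- if (p$strand == "-") reverse_complement(gene) else gene
    bg[(s + 1):e] <- strsplit(ins, "", fixed = TRUE)[[1]]
    truth_rows[[i]] <- tibble(
      record_id = spec$record_id, start = s, end = e,
      strand = p$strand, role = p$role,
      protein = paste0("M", substring(p$protein, 2))
    )
  }
  seq <- paste(bg, collapse = "")
  truth <- if (length(truth_rows) > 0) {
    bind_rows(truth_rows)
  } else {
    tibble(record_id = character(), start = integer(), end = integer(),
           strand = character(), role = character(), protein = character())
  }
  record <- tibble(id = spec$record_id,
                   description = sprintf("synthetic contig seed=%d", spec$seed),
                   seq = seq)
  check_truth_consistency(record, truth)
  list(record = record, truth = truth)
}

# every truth row must re-translate to its stated protein plus a stop
check_truth_consistency <- function(record, truth) {
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    g <- substr(record$seq, tr$start + 1, tr$end)
    if (tr$strand == "-") g <- reverse_complement(g)
    got <- translate_dna(g, start_as_met = TRUE)
    if (!identical(got, paste0(tr$protein, "*"))) {
      abort(sprintf("Truth row %d does not re-translate to its protein.", i))
    }
  }
  invisible(truth)
}

#' Simulate translated-homology hits for planted genes
#'
#' Emits, per planted gene, one hit covering the central `coverage_fraction`
#' of its coding codons (the stop codon is never covered), with subject
#' coordinates, frame and aligned subject protein exactly consistent with the
#' gene's strand and phase; the subject protein is the genomic translation of
#' the covered span, so the identity coverage downstream is 1. Decoy genes
#' receive hits too: rejecting them is the classifier's job, not the search
#' stage's.
#'
#' @param truth Truth table from [generate_genome()].
#' @param record Record tibble holding the contig.
#' @param coverage_fraction Fraction of coding codons covered, centrally.
#' @param evalue E-value stamped on each hit.
#' @return Hit tibble in the [blast_columns()] layout.
#' @export
simulate_blast_hits <- function(truth, record, coverage_fraction = 0.8,
                                evalue = 1e-50) {
  stopifnot(coverage_fraction > 0, coverage_fraction <= 1)
  len <- nchar(record$seq)
  rows <- map(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    n_cod <- (tr$end - tr$start) %/% 3L # includes the stop codon
    n_coding <- n_cod - 1L
    m <- max(1L, as.integer(round(coverage_fraction * n_coding)))
    c0 <- (n_coding - m) %/% 2L
    if (tr$strand == "+") {
      s0 <- tr$start + 3L * c0
      e0 <- s0 + 3L * m
      span <- substr(record$seq, s0 + 1, e0)
      sseq <- translate_dna(span)
      frame <- (s0 %% 3L) + 1L
      sstart <- s0 + 1L
      send <- e0
    } else {
      e0 <- tr$end - 3L * c0
      s0 <- e0 - 3L * m
      span <- reverse_complement(substr(record$seq, s0 + 1, e0))
      sseq <- translate_dna(span)
      frame <- -(((len - e0) %% 3L) + 1L)
      sstart <- e0
      send <- s0 + 1L
    }
    tibble(qseqid = paste0("query_", tr$role), sseqid = tr$record_id,
           pident = 100, length = m, evalue = evalue, bitscore = 2 * m,
           sstart = as.integer(sstart), send = as.integer(send),
           sframe = as.integer(frame), sseq = sseq)
  })
  out <- bind_rows(rows)
  if (nrow(out) > 0) validate_hits(out)
  out
}

#' Toy condensing-enzyme profile families
#'
#' Three mutually divergent toy protein families standing in for the KS, CLF
#' and FAS condensing enzymes: each is built from a fixed 140-column consensus
#' with six seed sequences at 90 % consensus identity. Also returns, per KS
#' and CLF model, a distant reference protein (55 % of consensus positions
#' mutated -- clearly diverged from the family, yet far above the score of an
#' unrelated sequence) playing the role of the distantly related cluster used
#' to calibrate inclusive retention thresholds. The construction is fixed
#' (internal seed), so the models are reproducible reference objects.
#'
#' @param profile_length Number of consensus columns.
#' @param n_seed_seqs Seed sequences per family alignment.
#' @param seed_identity Consensus identity of each seed sequence.
#' @param cutoff_divergence Fraction of consensus positions mutated in the
#'   calibration reference protein.
#' @return List with elements `ks`, `clf`, `fas` (`profile_hmm`),
#'   `ks_cutoff`, `clf_cutoff` (proteins).
#' @export
toy_profiles <- function(profile_length = 140L, n_seed_seqs = 6L,
                         seed_identity = 0.9, cutoff_divergence = 0.55) {
  withr::local_seed(987654321L)
  make_family <- function(name) {
    consensus <- sample(AA_ALPHABET, profile_length, replace = TRUE)
    seqs <- vapply(seq_len(n_seed_seqs), function(s) {
      x <- consensus
      mut <- runif(profile_length) > seed_identity
      x[mut] <- sample(AA_ALPHABET, sum(mut), replace = TRUE)
      paste(x, collapse = "")
    }, character(1))
    model <- build_profile(tibble(id = paste0(name, "_", seq_len(n_seed_seqs)),
                                  seq = seqs),
                           name = name)
    cut <- consensus
    mut <- runif(profile_length) < cutoff_divergence
    cut[mut] <- sample(AA_ALPHABET, sum(mut), replace = TRUE)
    list(model = model, cutoff = paste(cut, collapse = ""))
  }
  ks <- make_family("KS")
  clf <- make_family("CLF")
  fas <- make_family("FAS")
  list(ks = ks$model, clf = clf$model, fas = fas$model,
       ks_cutoff = ks$cutoff, clf_cutoff = clf$cutoff)
}

#' Standard synthetic study fixture
#'
#' Builds one 20 kb contig holding `n_pairs` planted KS-CLF gene pairs at the
#' given intergenic gaps plus `n_decoys` FAS-like decoy genes, together with
#' the simulated hit table, the toy profile models and thresholds calibrated
#' on the distant reference proteins. Pairs are separated by more than the
#' 2 kb pairing distance so no cross-pair combinations are eligible; decoys
#' carry hits and must be rejected by classification.
#'
#' @param seed Master seed.
#' @param n_pairs Number of planted KS-CLF pairs.
#' @param n_decoys Number of FAS-like decoy genes.
#' @param record_length Contig length in nt.
#' @param pair_gaps Intended intergenic gaps (recycled over pairs).
#' @param gc_fraction Background GC content.
#' @return List with `record`, `truth`, `hits`, `models` (from
#'   [toy_profiles()]), `ks_threshold`, `clf_threshold`, `spec`.
#' @export
synthetic_study <- function(seed = 1L, n_pairs = 3L, n_decoys = 2L,
                            record_length = 20000L,
                            pair_gaps = c(50L, 800L, 1900L),
                            gc_fraction = 0.5) {
  models <- toy_profiles()
  gaps <- rep_len(as.integer(pair_gaps), n_pairs)
  withr::local_seed(sub_seed(seed, "strands"))
  strands <- sample(c("+", "-"), 2L * n_pairs + n_decoys, replace = TRUE)

  plants <- list()
  cursor <- 600L
  k <- 0L
  for (i in seq_len(n_pairs)) {
    ksp <- sample_sequence(models$ks, sub_seed(seed, paste0("ksprot", i)))
    clfp <- sample_sequence(models$clf, sub_seed(seed, paste0("clfprot", i)))
    ks_len <- 3L * (nchar(ksp) + 1L)
    k <- k + 1L
    plants[[length(plants) + 1L]] <- tibble(
      protein = ksp, start_codon = "ATG", position = cursor,
      strand = strands[k], role = "KS")
    cursor <- cursor + ks_len + gaps[i]
    k <- k + 1L
    plants[[length(plants) + 1L]] <- tibble(
      protein = clfp, start_codon = c("ATG", "GTG", "TTG")[1 + (i %% 3)],
      position = cursor, strand = strands[k], role = "CLF")
    cursor <- cursor + 3L * (nchar(clfp) + 1L) + 3000L
  }
  for (d in seq_len(n_decoys)) {
    dp <- sample_sequence(models$fas, sub_seed(seed, paste0("decoy", d)))
    k <- k + 1L
    plants[[length(plants) + 1L]] <- tibble(
      protein = dp, start_codon = "ATG", position = cursor,
      strand = strands[k], role = "decoy")
    cursor <- cursor + 3L * (nchar(dp) + 1L) + 800L
  }
  spec <- plant_spec(record_id = sprintf("synth_%d", seed),
                     record_length = record_length,
                     plants = bind_rows(plants),
                     gc_fraction = gc_fraction, seed = seed)
  g <- generate_genome(spec)
  hits <- simulate_blast_hits(g$truth, g$record)
  list(
    record = g$record, truth = g$truth, hits = hits, models = models,
    ks_threshold = calibrate_threshold(models$ks, models$ks_cutoff),
    clf_threshold = calibrate_threshold(models$clf, models$clf_cutoff),
    spec = spec
  )
}
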