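#' Calibrate a retention threshold from a distant reference protein
#'
#' The retention threshold for a model is the score of a distantly related
#' reference sequence (in the published workflow, the aurachin cluster's KS
#' and CLF): any candidate scoring greater than or equal to this value is
#' retained, so the reference itself is always kept (boundary inclusive).
#'
#' @param model A `profile_hmm`.
#' @param cutoff_protein The reference protein string.
#' @param mode Scoring mode, see [score_sequence()].
#' @return Threshold in bits (a single number).
#' @export
calibrate_threshold <- function(model, cutoff_protein,
                                mode = c("forward", "viterbi")) {
  mode <- match.arg(mode)
  score_bits(model, cutoff_protein, mode)
}

#' Classifier configuration
#'
#' With `scorer = "builtin"` the package's own profile scorer is used and
#' thresholds must be calibrated with [calibrate_threshold()] on reference
#' cutoff sequences. With `scorer = "external"` the thresholds are taken as
#' printed by the external scoring tool that produced them (the published
#' workflow used HMMER with KS = 352 and CLF = 66); builtin scores are not
#' bit-compatible with external ones, so external thresholds only make sense
#' together with externally computed scores supplied via `score_fun`.
#'
#' @param ks_threshold,clf_threshold Retention thresholds in bits.
#' @param scorer `"builtin"` or `"external"`.
#' @param score_fun For `scorer = "external"`: a function
#'   `(model, protein) -> bits` wrapping the external tool's scores.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(ks_threshold = NULL, clf_threshold = NULL,
                              scorer = c("builtin", "external"),
                              score_fun = NULL) {
  scorer <- match.arg(scorer)
  if (scorer == "external") {
    ks_threshold <- ks_threshold %||% 352
    clf_threshold <- clf_threshold %||% 66
    if (is.null(score_fun)) {
      abort("External-scorer mode needs `score_fun` wrapping the external tool.")
    }
  }
  if (is.null(ks_threshold) || is.null(clf_threshold)) {
    abort(paste0("Builtin-scorer mode needs thresholds calibrated with ",
                 "calibrate_threshold() on cutoff sequences."))
  }
  stopifnot(is.finite(ks_threshold), is.finite(clf_threshold))
  structure(list(ks_threshold = ks_threshold, clf_threshold = clf_threshold,
                 scorer = scorer, score_fun = score_fun),
            class = "classifier_config")
}

#' Classify a protein as KS, CLF or neither
#'
#' Scores the protein against both models. Models whose threshold is met
#' (score >= threshold) are candidates: none gives `"none"`, one gives its
#' label, both gives the label with the higher bit score (an exact tie is
#' resolved to `"KS"`, deterministically).
#'
#' @param protein Protein string.
#' @param ks_model,clf_model `profile_hmm` objects.
#' @param config A [classifier_config()].
#' @return Single label in `c("KS", "CLF", "none")`.
#' @export
classify_protein <- function(protein, ks_model, clf_model, config) {
  sf <- if (config$scorer == "external") config$score_fun else
    function(m, p) score_bits(m, p, "forward")
  ks <- sf(ks_model, protein)
  clf <- sf(clf_model, protein)
  label_from_scores(ks, clf, config$ks_threshold, config$clf_threshold)
}

label_from_scores <- function(ks_bits, clf_bits, ks_thr, clf_thr) {
  ks_ok <- ks_bits >= ks_thr
  clf_ok <- clf_bits >= clf_thr
  dplyr::case_when(
    ks_ok & clf_ok & clf_bits > ks_bits ~ "CLF",
    ks_ok & clf_ok ~ "KS", # includes the exact tie, resolved to KS
    ks_ok ~ "KS",
    clf_ok ~ "CLF",
    .default = "none"
  )
}

#' Classify every ORF in a table
#'
#' Adds `ks_bits`, `clf_bits` and `label` columns to an ORF tibble.
#'
#' @param orfs ORF tibble with a `protein` column.
#' @param ks_model,clf_model `profile_hmm` objects.
#' @param config A [classifier_config()].
#' @return `orfs` with score and label columns added.
#' @export
classify_orfs <- function(orfs, ks_model, clf_model, config) {
  if (nrow(orfs) == 0) {
    orfs$ks_bits <- numeric(0)
    orfs$clf_bits <- numeric(0)
    orfs$label <- character(0)
    return(orfs)
  }
  sf <- if (config$scorer == "external") config$score_fun else
    function(m, p) score_bits(m, p, "forward")
  prot <- sub("\\*+$", "", orfs$protein) # terminal stops are not residues
  orfs$ks_bits <- vapply(prot, function(p) sf(ks_model, p), numeric(1),
                         USE.NAMES = FALSE)
  orfs$clf_bits <- vapply(prot, function(p) sf(clf_model, p), numeric(1),
                          USE.NAMES = FALSE)
  orfs$label <- label_from_scores(orfs$ks_bits, orfs$clf_bits,
                                  config$ks_threshold, config$clf_threshold)
  orfs
}

#' Sample a protein from a profile HMM
#'
#' Draws a full core-domain state path -- from the first to the last match
#' column, with insertions and deletions per the model's transition
#' probabilities -- and emissions from the corresponding distributions. The
#' uniform entry/exit used by the local scorer is an alignment device, not
#' part of the generative core, so samples span the whole profile: a model
#' with all emission mass on its consensus (and no insert/delete mass)
#' yields exactly the consensus string. Deterministic for a fixed seed.
#'
#' @param model A `profile_hmm`.
#' @param seed Integer seed.
#' @return Protein string.
#' @export
sample_sequence <- function(model, seed) {
  withr::local_seed(as.integer(seed))
  tr <- model$transitions
  L <- model$L
  out <- character(0)
  j <- 1L
  state <- "M"
  repeat {
    if (state == "M") {
      out <- c(out, sample(model$alphabet, 1, prob = model$match_emissions[j, ]))
      if (j == L) break
      # core transitions, exit mass excluded
      probs <- c(mm = tr$mm[j], mi = tr$mi[j], md = tr$md[j])
      mv <- sample(names(probs), 1, prob = probs)
      if (mv == "mm") { j <- j + 1L; state <- "M" }
      if (mv == "mi") state <- "I"
      if (mv == "md") { j <- j + 1L; state <- "D" }
    } else if (state == "I") {
      out <- c(out, sample(model$alphabet, 1, prob = model$insert_emissions))
      if (runif(1) < tr$im[j]) { j <- j + 1L; state <- "M" }
    } else { # D_j: dm -> M_{j+1}, dd -> D_{j+1}
      state <- if (runif(1) < tr$dm[j]) "M" else "D"
      j <- j + 1L
    }
  }
  paste(out, collapse = "")
}

#' Serialize a profile HMM to plain text
#'
#' Models are written as a JSON document holding the name, number of match
#' states, alphabet order and all emission/transition probabilities at full
#' precision, so a read/write round trip reproduces every probability.
#'
#' @param model A `profile_hmm`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(model, path) {
  payload <- list(
    format = "ksclf-profile-1",
    name = model$name, L = model$L, alphabet = model$alphabet,
    match_emissions = unclass(model$match_emissions),
    insert_emissions = model$insert_emissions,
    background = model$background,
    transitions = model$transitions
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "ksclf-profile-1")) {
    abort("Not a ksclf profile file.")
  }
  me <- if (is.matrix(p$match_emissions)) {
    p$match_emissions
  } else {
    matrix(as.numeric(unlist(p$match_emissions)), nrow = p$L, byrow = TRUE)
  }
  colnames(me) <- p$alphabet
  new_profile_hmm(
    name = p$name, alphabet = p$alphabet,
    match_emissions = me,
    insert_emissions = as.numeric(p$insert_emissions),
    background = as.numeric(p$background),
    transitions = lapply(p$transitions, as.numeric)
  )
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("<profile_hmm '%s': %d match states, %d-letter alphabet>\n",
              x$name, x$L, length(x$alphabet)))
  invisible(x)
}

#' Tidy a profile HMM into per-state emission rows
#'
#' @param x A `profile_hmm`.
#' @param ... Unused.
#' @return Tibble with columns `state`, `residue`, `probability`,
#'   `log_odds_bits`.
#' @export
tidy.profile_hmm <- function(x, ...) {
  prob <- as.numeric(t(x$match_emissions))
  bg <- rep(x$background, times = x$L)
  tibble(
    state = rep(seq_len(x$L), each = length(x$alphabet)),
    residue = rep(x$alphabet, times = x$L),
    probability = prob,
    log_odds_bits = log2(prob / bg)
  )
}

#' One-row summary of a profile HMM
#'
#' @param x A `profile_hmm`.
#' @param ... Unused.
#' @return One-row tibble with `name`, `n_match_states`, `alphabet_size`,
#'   `max_consensus_bits` (score of the consensus residue path).
#' @export
glance.profile_hmm <- function(x, ...) {
  consensus <- paste(x$alphabet[apply(x$match_emissions, 1, which.max)],
                     collapse = "")
  tibble(name = x$name, n_match_states = x$L,
         alphabet_size = length(x$alphabet),
         consensus = consensus,
         consensus_bits = score_bits(x, consensus, "viterbi"))
}
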