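#' Profile hidden Markov models for condensing-enzyme classification
#'
#' A `profile_hmm` is a local-alignment profile over the 20-letter amino-acid
#' alphabet with one match (M), insert (I) and delete (D) state per column.
#' Entry is uniform over match states (probability `1/L` each) and exit is
#' permitted from every match state, so residues outside the aligned core are
#' emitted by the background null and cancel out of the log-odds score.
#' Scores are reported in bits (log2 odds against the background null).
#'
#' @name profile_hmm
NULL

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

log2_sum <- function(x) {
  # log2(sum(2^x)), safe against -Inf
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log2(sum(2^(x - m)))
}

new_profile_hmm <- function(name, alphabet, match_emissions, insert_emissions,
                            background, transitions) {
  m <- structure(
    list(name = name, L = nrow(match_emissions), alphabet = alphabet,
         match_emissions = match_emissions,
         insert_emissions = insert_emissions,
         background = background, transitions = transitions),
    class = "profile_hmm"
  )
  validate_profile_hmm(m)
}

validate_profile_hmm <- function(m, tol = 1e-9) {
  stopifnot(inherits(m, "profile_hmm"))
  L <- m$L
  if (L < 1) abort("Profile must have at least one match state.")
  rows_ok <- abs(rowSums(m$match_emissions) - 1) <= tol
  if (!all(rows_ok)) abort("Match emission rows must each sum to 1.")
  if (abs(sum(m$insert_emissions) - 1) > tol) {
    abort("Insert emissions must sum to 1.")
  }
  if (abs(sum(m$background) - 1) > tol) abort("Background must sum to 1.")
  tr <- m$transitions
  if (abs(sum(tr$entry) - 1) > tol) abort("Entry distribution must sum to 1.")
  m_out <- tr$exit + tr$mm + tr$mi + tr$md
  if (!all(abs(m_out - 1) <= tol)) {
    abort("Match-state outgoing transitions must sum to 1.")
  }
  if (L > 1) {
    if (!all(abs(tr$im + tr$ii - 1) <= tol)) {
      abort("Insert-state outgoing transitions must sum to 1.")
    }
    if (!all(abs(tr$dm + tr$dd - 1) <= tol)) {
      abort("Delete-state outgoing transitions must sum to 1.")
    }
  }
  m
}

#' Build a profile HMM from a seed alignment
#'
#' Columns whose gap fraction is below `match_gap_threshold` become match
#' states. Match emissions are maximum-likelihood counts regularized by
#' background-proportional pseudocounts of total weight `pseudocount_weight`.
#' Transitions among match/insert/delete states are estimated from the
#' observed alignment paths with +1 smoothing. Insert states emit the
#' background distribution. Entry is uniform over match states; the exit
#' probability from match state `j` is `1/(L - j + 1)`, so exit is certain at
#' the last column and the remaining mass scales the estimated M transitions.
#' The build is deterministic: identical alignments give identical models.
#'
#' @param aln Alignment tibble with columns `id` and `seq` (equal-length
#'   gapped protein strings, `-` for gaps), or a named character vector.
#' @param name Model name.
#' @param match_gap_threshold Columns with gap fraction `<` this value become
#'   match states.
#' @param pseudocount_weight Total weight of the background-proportional
#'   pseudocount added to each match-emission column.
#' @param background Background amino-acid distribution (default uniform).
#' @return A `profile_hmm` object.
#' @export
build_profile <- function(aln, name = "profile", match_gap_threshold = 0.5,
                          pseudocount_weight = 1,
                          background = NULL) {
  if (is.character(aln)) aln <- tibble(id = names(aln) %||%
                                         paste0("s", seq_along(aln)),
                                       seq = unname(aln))
  stopifnot(is.data.frame(aln), all(c("id", "seq") %in% names(aln)))
  seqs <- toupper(aln$seq)
  if (length(seqs) < 2) abort("Need at least 2 aligned sequences.")
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1) {
    abort("Aligned sequences must have equal length.")
  }
  W <- widths[1]
  K <- length(AA_ALPHABET)
  if (is.null(background)) background <- rep(1 / K, K)
  background <- background / sum(background)
  chars <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  is_gap <- chars == "-" | chars == "."
  gap_frac <- colMeans(is_gap)
  match_cols <- which(gap_frac < match_gap_threshold)
  L <- length(match_cols)
  if (L == 0) abort("Degenerate model: no column qualifies as a match state.")

  # match emissions: counts + background-proportional pseudocounts
  match_emissions <- matrix(0, nrow = L, ncol = K,
                            dimnames = list(NULL, AA_ALPHABET))
  for (j in seq_len(L)) {
    col <- chars[, match_cols[j]]
    col <- col[col %in% AA_ALPHABET]
    cnt <- table(factor(col, levels = AA_ALPHABET))
    e <- as.numeric(cnt) + pseudocount_weight * background
    match_emissions[j, ] <- e / sum(e)
  }

  # transition counts from observed paths; architecture allows
  # M->{M,I,D,exit}, I->{M,I}, D->{M,D}; other observed moves are dropped
  cm <- matrix(1, nrow = max(L - 1, 1), ncol = 3,
               dimnames = list(NULL, c("mm", "mi", "md"))) # +1 smoothing
  ci <- matrix(1, nrow = max(L - 1, 1), ncol = 2,
               dimnames = list(NULL, c("im", "ii")))
  cd <- matrix(1, nrow = max(L - 1, 1), ncol = 2,
               dimnames = list(NULL, c("dm", "dd")))
  if (L > 1) {
    col_state <- rep(NA_integer_, W) # match column index or NA (insert col)
    col_state[match_cols] <- seq_len(L)
    for (s in seq_len(nrow(chars))) {
      prev <- NULL # list(kind, j)
      for (c in seq_len(W)) {
        j <- col_state[c]
        if (!is.na(j)) {
          kind <- if (is_gap[s, c]) "D" else "M"
          if (!is.null(prev) && prev$j >= 1 && prev$j < L) {
            jj <- prev$j
            if (prev$kind == "M") {
              cm[jj, if (kind == "M") "mm" else "md"] <-
                cm[jj, if (kind == "M") "mm" else "md"] + 1
            } else if (prev$kind == "I" && kind == "M") {
              ci[jj, "im"] <- ci[jj, "im"] + 1
            } else if (prev$kind == "D") {
              cd[jj, if (kind == "M") "dm" else "dd"] <-
                cd[jj, if (kind == "M") "dm" else "dd"] + 1
            }
          }
          prev <- list(kind = kind, j = j)
        } else if (!is_gap[s, c]) {
          # residue in an insert column
          if (!is.null(prev) && prev$j >= 1 && prev$j < L) {
            jj <- prev$j
            if (prev$kind == "M") cm[jj, "mi"] <- cm[jj, "mi"] + 1
            if (prev$kind == "I") ci[jj, "ii"] <- ci[jj, "ii"] + 1
            prev <- list(kind = "I", j = jj)
          }
        }
      }
    }
  }

  exit <- 1 / (L - seq_len(L) + 1)
  mm <- mi <- md <- rep(0, L)
  if (L > 1) {
    sub <- cm / rowSums(cm)
    mm[seq_len(L - 1)] <- (1 - exit[seq_len(L - 1)]) * sub[, "mm"]
    mi[seq_len(L - 1)] <- (1 - exit[seq_len(L - 1)]) * sub[, "mi"]
    md[seq_len(L - 1)] <- (1 - exit[seq_len(L - 1)]) * sub[, "md"]
    # the last delete state must rejoin the match track before the profile
    # ends, so M_{L-1} cannot open a delete and D_{L-1} must go to M_L
    k <- L - 1
    keep <- mm[k] + mi[k]
    if (keep > 0) {
      mm[k] <- (1 - exit[k]) * mm[k] / keep
      mi[k] <- (1 - exit[k]) * mi[k] / keep
    } else {
      mm[k] <- 1 - exit[k]
    }
    md[k] <- 0
    im <- ci[, "im"] / rowSums(ci)
    ii <- ci[, "ii"] / rowSums(ci)
    dm <- cd[, "dm"] / rowSums(cd)
    dd <- cd[, "dd"] / rowSums(cd)
    dm[k] <- 1
    dd[k] <- 0
  } else {
    im <- ii <- dm <- dd <- numeric(0)
  }

  new_profile_hmm(
    name = name, alphabet = AA_ALPHABET,
    match_emissions = match_emissions,
    insert_emissions = background,
    background = background,
    transitions = list(entry = rep(1 / L, L), exit = exit,
                       mm = mm, mi = mi, md = md,
                       im = im, ii = ii, dm = dm, dd = dd)
  )
}

encode_protein <- function(model, protein) {
  stopifnot(length(protein) == 1, is.character(protein))
  if (nchar(protein) == 0) abort("Cannot score an empty protein.")
  ch <- strsplit(toupper(protein), "", fixed = TRUE)[[1]]
  bad <- !(ch %in% c(model$alphabet, "X"))
  if (any(bad)) {
    abort(sprintf("Residue '%s' not in the model alphabet (X allowed).",
                  ch[which(bad)[1]]))
  }
  match(ch, model$alphabet) # NA for X
}

#' Score a protein against a profile HMM
#'
#' Computes the local-alignment log-odds score in bits: the log2 ratio of the
#' sequence probability under the profile (uniform entry over match states,
#' exit from any match state, residues outside the aligned core emitted by the
#' null) to the probability of the whole sequence under the background null.
#' `mode = "forward"` sums over all alignments; `mode = "viterbi"` takes the
#' best single alignment, so forward >= viterbi always. `X` residues are
#' emitted with background probability in every state (log-odds contribution
#' zero).
#'
#' @param model A `profile_hmm`.
#' @param protein Protein string (20-letter alphabet, `X` allowed).
#' @param mode `"forward"` or `"viterbi"`.
#' @param sequence_id Optional id stamped on the report.
#' @return One-row tibble with columns `sequence_id`, `model_name`, `bits`,
#'   `mode`.
#' @export
score_sequence <- function(model, protein, mode = c("forward", "viterbi"),
                           sequence_id = NA_character_) {
  mode <- match.arg(mode)
  tibble(sequence_id = sequence_id, model_name = model$name,
         bits = score_bits(model, protein, mode), mode = mode)
}

#' @rdname score_sequence
#' @param proteins Tibble with columns `id` and `protein`.
#' @export
score_proteins <- function(model, proteins, mode = c("forward", "viterbi")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(proteins),
            all(c("id", "protein") %in% names(proteins)))
  tibble(
    sequence_id = proteins$id, model_name = model$name,
    bits = vapply(proteins$protein, function(p) score_bits(model, p, mode),
                  numeric(1), USE.NAMES = FALSE),
    mode = mode
  )
}

# log2-space local forward/viterbi over the M/I/D lattice; emissions enter
# as log-odds ratios so null-emitted flanking residues cancel exactly
score_bits <- function(model, protein, mode = "forward") {
  x <- encode_protein(model, protein)
  n <- length(x)
  L <- model$L
  tr <- model$transitions
  # log-odds emission matrix over the whole sequence; X (NA) scores 0
  lrM <- log2(model$match_emissions) -
    matrix(log2(model$background), nrow = L, ncol = length(model$background),
           byrow = TRUE)
  lrI <- log2(model$insert_emissions) - log2(model$background)
  E <- matrix(0, nrow = L, ncol = n)
  ok <- !is.na(x)
  E[, ok] <- lrM[, x[ok], drop = FALSE]
  eI <- ifelse(ok, lrI[ifelse(ok, x, 1L)], 0)
  l_entry <- log2(tr$entry)
  l_exit <- log2(tr$exit)
  lmm <- log2(tr$mm); lmi <- log2(tr$mi); lmd <- log2(tr$md)
  lim <- log2(tr$im); lii <- log2(tr$ii)
  ldm <- log2(tr$dm); ldd <- log2(tr$dd)
  forward <- mode == "forward"
  # vectorized combine: log2(2^a + 2^b) for forward, max for viterbi
  comb <- function(a, b) {
    m <- a
    s <- which(b > a | is.na(a))
    m[s] <- b[s]
    if (!forward) return(m)
    out <- m + log2(2^(a - m) + 2^(b - m))
    out[m == -Inf] <- -Inf
    out
  }

  NEG <- -Inf
  Mprev <- rep(NEG, L); Iprev <- rep(NEG, L)
  ends <- rep(NEG, n) # best/total score of alignments ending at position i
  jj <- if (L > 1) 2:L else integer(0)
  ji <- if (L > 1) seq_len(L - 1) else integer(0)
  for (i in seq_len(n)) {
    inc <- l_entry # incoming log-mass per column, before emission
    if (L > 1) {
      from_m <- Mprev[ji] + lmm[ji]
      from_i <- Iprev[ji] + lim[ji]
      inc[jj] <- comb(inc[jj], comb(from_m, from_i))
      # delete chain fed by row i-1: D_j after consuming i-1 residues
      if (any(Mprev > NEG)) {
        Drow <- rep(NEG, L)
        d <- NEG
        for (j in jj) {
          a <- Mprev[j - 1] + lmd[j - 1]
          if (j > 2) {
            b <- d + ldd[j - 1]
            if (forward) {
              a <- if (a >= b) {
                if (a == NEG) NEG else a + log2(1 + 2^(b - a))
              } else {
                b + log2(1 + 2^(a - b))
              }
            } else if (b > a) {
              a <- b
            }
          }
          d <- a
          Drow[j] <- d
        }
        inc[jj] <- comb(inc[jj], Drow[ji] + ldm[ji])
      }
    }
    Mcur <- E[, i] + inc
    Icur <- rep(NEG, L)
    if (L > 1) {
      Icur[ji] <- eI[i] + comb(Mprev[ji] + lmi[ji], Iprev[ji] + lii[ji])
    }
    ends[i] <- if (forward) log2_sum(Mcur + l_exit) else max(Mcur + l_exit)
    Mprev <- Mcur
    Iprev <- Icur
  }
  if (forward) log2_sum(ends) else max(ends)
}
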