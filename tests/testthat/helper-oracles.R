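# Independent oracles used by the property and acceptance tests. These are
# deliberately naive re-derivations from first principles; they share no code
# with the package internals they check.

# per-base reverse complement
oracle_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  paste(rev(unname(comp[ch])), collapse = "")
}

oracle_translate1 <- function(codon) {
  gc <- Biostrings::getGeneticCode("11")
  aa <- unname(gc[codon])
  if (is.na(aa)) "X" else aa
}

# naive coverage: fraction of hit residues whose codon lies inside the ORF,
# in the ORF frame/strand, and whose genomic translation equals the subject
# residue (never '*' or 'X')
oracle_coverage <- function(orf_start, orf_end, orf_strand,
                            hit, record_seq) {
  res <- gsub("-", "", hit$sseq, fixed = TRUE)
  nres <- nchar(res)
  if (nres == 0) return(NA_real_)
  good <- 0
  for (r in 0:(nres - 1)) {
    if (hit$strand == "+") {
      cs <- hit$start + 3 * r
    } else {
      cs <- hit$end - 3 * (r + 1)
    }
    if (hit$strand != orf_strand) next
    if (cs < orf_start || cs + 3 > orf_end) next
    in_frame <- if (orf_strand == "+") {
      (cs - orf_start) %% 3 == 0
    } else {
      (orf_end - (cs + 3)) %% 3 == 0
    }
    if (!in_frame) next
    codon <- substr(record_seq, cs + 1, cs + 3)
    if (orf_strand == "-") codon <- oracle_revcomp(codon)
    aa <- oracle_translate1(codon)
    if (aa %in% c("*", "X")) next
    if (aa == substr(res, r + 1, r + 1)) good <- good + 1
  }
  good / nres
}

# brute-force longest-containing-ORF: enumerates every candidate (begin, end)
# codon pair in the hit frame of the window and applies the length/coverage
# rules directly
oracle_find_orf <- function(record_seq, hit, config) {
  len <- nchar(record_seq)
  w0 <- max(0, hit$start - config$flank_nt)
  w1 <- min(len, hit$end + config$flank_nt)
  working <- substr(record_seq, w0 + 1, w1)
  if (hit$strand == "-") working <- oracle_revcomp(working)
  fo <- if (hit$strand == "+") (hit$start - w0) %% 3 else (w1 - hit$end) %% 3
  wlen <- nchar(working)
  ncod <- (wlen - fo) %/% 3
  if (ncod <= 0) return(NULL)
  cs <- fo + 3 * (seq_len(ncod) - 1)
  codons <- substring(working, cs + 1, cs + 3)
  is_stop <- codons %in% config$stop_codons
  is_start <- codons %in% config$start_codons

  # candidate begins: every start codon; plus the very first codon when no
  # start codon precedes the first stop (edge-truncated ORF)
  begins <- which(is_start)
  first_stop <- if (any(is_stop)) which(is_stop)[1] else ncod + 1
  if (config$edge_orfs && !any(is_start[seq_len(min(first_stop - 1, ncod))])) {
    begins <- c(1, begins)
  }
  best <- NULL
  for (b in begins) {
    if (is_stop[b]) next
    later_stops <- which(is_stop & seq_len(ncod) > b - 1)
    later_stops <- later_stops[later_stops >= b]
    last <- if (length(later_stops) > 0) later_stops[1] else ncod
    # skip candidates whose begin is not the segment's canonical begin:
    # an earlier start codon (or the edge) in the same segment dominates
    prev_stop <- later_stops_before <- which(is_stop & seq_len(ncod) < b)
    seg_first <- if (length(prev_stop) > 0) max(prev_stop) + 1 else 1
    if (any(is_start[seq(seg_first, b)]) &&
        which(is_start[seg_first:b])[1] + seg_first - 1 < b) next
    ws <- cs[b]
    we <- cs[last] + 3
    if (hit$strand == "+") {
      fs <- w0 + ws
      fe <- w0 + we
    } else {
      fs <- w1 - we
      fe <- w1 - ws
    }
    if (fe - fs < config$min_orf_nt) next
    cov <- oracle_coverage(fs, fe, hit$strand, hit, record_seq)
    if (is.na(cov) || cov < config$min_hit_coverage) next
    if (is.null(best) || (fe - fs) > best$len ||
        ((fe - fs) == best$len && fs < best$start)) {
      best <- list(start = fs, end = fe, len = fe - fs)
    }
  }
  best
}

# exhaustive path-sum forward/viterbi for tiny models: enumerates every
# complete state path (entry at some match column, M/I/D moves, exit from a
# match column) with at most n emissions, then sums/maximizes the log-odds
# contributions over all placements in the sequence
oracle_paths <- function(model, max_emissions) {
  tr <- model$transitions
  L <- model$L
  paths <- list()
  walk <- function(state, j, emits, logp) {
    # emits: integer vector of match columns, 0 for insert emissions
    if (length(emits) > max_emissions) return()
    if (state == "M") {
      emits <- c(emits, j)
      if (length(emits) > max_emissions) return()
      # exit here
      if (tr$exit[j] > 0) {
        paths[[length(paths) + 1]] <<-
          list(emits = emits, logp = logp + log2(tr$exit[j]))
      }
      if (j < L) {
        if (tr$mm[j] > 0) walk("M", j + 1, emits, logp + log2(tr$mm[j]))
        if (tr$mi[j] > 0) walk("I", j, emits, logp + log2(tr$mi[j]))
        if (tr$md[j] > 0) walk("D", j + 1, emits, logp + log2(tr$md[j]))
      }
    } else if (state == "I") {
      emits <- c(emits, 0)
      if (length(emits) > max_emissions) return()
      if (tr$im[j] > 0) walk("M", j + 1, emits, logp + log2(tr$im[j]))
      if (tr$ii[j] > 0) walk("I", j, emits, logp + log2(tr$ii[j]))
    } else { # D
      if (j > L) return()
      if (j < L && tr$dd[j] > 0) walk("D", j + 1, emits, logp + log2(tr$dd[j]))
      if (tr$dm[j] > 0 && j + 1 <= L) walk("M", j + 1, emits, logp + log2(tr$dm[j]))
    }
  }
  for (j0 in seq_len(L)) {
    if (tr$entry[j0] > 0) {
      walk("M", j0, integer(0), log2(tr$entry[j0]))
    }
  }
  paths
}

oracle_score <- function(model, protein, paths, mode = "forward") {
  x <- match(strsplit(protein, "", fixed = TRUE)[[1]], model$alphabet)
  n <- length(x)
  lrM <- log2(model$match_emissions) -
    matrix(log2(model$background), nrow = model$L,
           ncol = length(model$background), byrow = TRUE)
  lrI <- log2(model$insert_emissions) - log2(model$background)
  terms <- c()
  for (p in paths) {
    e <- length(p$emits)
    if (e > n) next
    for (i0 in 0:(n - e)) {
      s <- p$logp
      for (t in seq_len(e)) {
        xi <- x[i0 + t]
        s <- s + if (p$emits[t] == 0) lrI[xi] else lrM[p$emits[t], xi]
      }
      terms <- c(terms, s)
    }
  }
  if (length(terms) == 0) return(-Inf)
  if (mode == "forward") {
    m <- max(terms)
    m + log2(sum(2^(terms - m)))
  } else {
    max(terms)
  }
}

# random DNA
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# build a random window + in-frame hit whose subject protein is the genomic
# translation of the hit span (identity hit), for oracle comparisons
random_orf_case <- function(max_len = 3000) {
  len <- 3 * sample(100:(max_len %/% 3), 1)
  seqs <- random_dna(len)
  strand <- sample(c("+", "-"), 1)
  nres <- sample(30:100, 1)
  max_start <- len - 3 * nres
  s0 <- sample(0:max_start, 1)
  e0 <- s0 + 3 * nres
  span <- substr(seqs, s0 + 1, e0)
  if (strand == "-") span <- oracle_revcomp(span)
  sseq <- paste(vapply(seq_len(nres), function(r) {
    oracle_translate1(substr(span, 3 * r - 2, 3 * r))
  }, character(1)), collapse = "")
  hit <- tibble::tibble(qseqid = "q", sseqid = "rec", start = s0, end = e0,
                        strand = strand, sseq = sseq, evalue = 1e-10)
  list(record_seq = seqs, hit = hit)
}

# map a recovered pair back to planted truth rows by anchored 3' ends: the
# called ORF may extend 5' of the planted start codon but its stop-codon end
# is exact
match_orf_to_truth <- function(orf_start, orf_end, orf_strand, truth) {
  hit3 <- if (orf_strand == "+") {
    truth$strand == "+" & truth$end == orf_end
  } else {
    truth$strand == "-" & truth$start == orf_start
  }
  which(hit3 & truth$start >= orf_start & truth$end <= orf_end)
}

# a tiny hand-made profile for exact-score tests
single_state_model <- function(p_match = 0.9, letter = "A") {
  AA <- ksclf:::AA_ALPHABET
  em <- rep((1 - p_match) / 19, 20)
  em[match(letter, AA)] <- p_match
  ksclf:::new_profile_hmm(
    "single", AA, matrix(em, nrow = 1, dimnames = list(NULL, AA)),
    rep(1 / 20, 20), rep(1 / 20, 20),
    list(entry = 1, exit = 1, mm = 0, mi = 0, md = 0,
         im = numeric(0), ii = numeric(0), dm = numeric(0), dd = numeric(0))
  )
}

# random valid tiny model over the full alphabet for oracle sweeps
random_tiny_model <- function(L) {
  AA <- ksclf:::AA_ALPHABET
  me <- matrix(stats::rgamma(L * 20, shape = 0.8), nrow = L)
  me <- me / rowSums(me)
  colnames(me) <- AA
  exit <- 1 / (L - seq_len(L) + 1)
  if (L > 1) {
    raw <- matrix(stats::runif(3 * (L - 1), 0.05, 1), ncol = 3)
    raw <- raw / rowSums(raw)
    mm <- mi <- md <- rep(0, L)
    mm[1:(L - 1)] <- (1 - exit[1:(L - 1)]) * raw[, 1]
    mi[1:(L - 1)] <- (1 - exit[1:(L - 1)]) * raw[, 2]
    md[1:(L - 1)] <- (1 - exit[1:(L - 1)]) * raw[, 3]
    im <- stats::runif(L - 1, 0.3, 0.9)
    ii <- 1 - im
    dm <- stats::runif(L - 1, 0.3, 0.9)
    dd <- 1 - dm
  } else {
    mm <- mi <- md <- 0
    im <- ii <- dm <- dd <- numeric(0)
  }
  ksclf:::new_profile_hmm(
    paste0("tiny", L), AA, me, rep(1 / 20, 20), rep(1 / 20, 20),
    list(entry = rep(1 / L, L), exit = exit, mm = mm, mi = mi, md = md,
         im = im, ii = ii, dm = dm, dd = dd)
  )
}

# build a record whose in-frame neighbourhood is stop-saturated TAA repeats,
# so ORF boundaries are fully determined by the planted gene
taa_padded_gene <- function(n_coding_codons, pad_codons = 220,
                            start_codon = "ATG", seed = 9) {
  protein <- paste0("M", paste(
    withr::with_seed(seed, sample(setdiff(ksclf:::AA_ALPHABET, "M"),
                                  n_coding_codons - 1, replace = TRUE)),
    collapse = ""))
  body <- reverse_translate(substring(protein, 2), seed = seed + 1)
  gene <- paste0(start_codon, body, "TAA")
  pad <- strrep("TAA", pad_codons)
  list(
    seq = paste0(pad, gene, pad),
    gene_start = nchar(pad),
    gene_end = nchar(pad) + nchar(gene),
    protein = protein
  )
}

# an identity hit over coding codons [from, to) of a plus-strand gene
identity_hit <- function(record_seq, gene_start, from, to,
                         evalue = 1e-30) {
  s0 <- gene_start + 3 * from
  e0 <- gene_start + 3 * to
  tibble::tibble(
    qseqid = "q", sseqid = "rec",
    start = s0, end = e0, strand = "+",
    sseq = translate_dna(substr(record_seq, s0 + 1, e0)),
    evalue = evalue
  )
}
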