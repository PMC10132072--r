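test_that("a single-state model scores by hand-computable log odds", {
  m <- single_state_model(p_match = 0.9, letter = "A")
  got <- score_sequence(m, "A")
  expect_equal(got$bits, log2(0.9 / 0.05), tolerance = 1e-12)
  expect_identical(got$model_name, "single")
  expect_error(score_sequence(m, ""), "empty")
})

test_that("profile building follows the match-column and determinism rules", {
  aln <- tibble::tibble(id = c("a", "b", "c"), seq = c("MK", "MK", "MR"))
  m <- build_profile(aln, name = "w2")
  expect_equal(m$L, 2)
  expect_equal(rowSums(m$match_emissions), c(1, 1), tolerance = 1e-12)
  # M column: 3 observations of M + uniform pseudocount of weight 1
  expect_equal(unname(m$match_emissions[1, "M"]), (3 + 0.05) / 4,
               tolerance = 1e-12)

  # a column with 60 % gaps is not a match state
  gappy <- tibble::tibble(id = letters[1:5],
                          seq = c("M-K", "M-K", "MAK", "MAK", "M--"))
  expect_equal(build_profile(gappy)$L, 2) # middle column has 3/5 gaps

  expect_error(build_profile(tibble::tibble(id = c("a", "b"),
                                            seq = c("--", "--"))),
               "Degenerate")

  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_profile(build_profile(aln), f1)
  write_profile(build_profile(aln), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("forward equals the exhaustive path sum on tiny models", {
  letters4 <- c("A", "C", "D", "E")
  withr::with_seed(404, {
    for (L in 1:3) {
      m <- random_tiny_model(L)
      paths <- oracle_paths(m, max_emissions = 4)
      seqs <- c(letters4,
                apply(expand.grid(letters4, letters4), 1, paste, collapse = ""),
                replicate(15, paste(sample(letters4, 4, replace = TRUE),
                                    collapse = "")))
      for (s in unique(seqs)) {
        expect_equal(ksclf:::score_bits(m, s, "forward"),
                     oracle_score(m, s, paths, "forward"),
                     tolerance = 1e-6)
        expect_equal(ksclf:::score_bits(m, s, "viterbi"),
                     oracle_score(m, s, paths, "viterbi"),
                     tolerance = 1e-6)
      }
    }
  })
})

test_that("forward dominates viterbi and flanking null residues cancel", {
  tp <- toy_profiles()
  withr::with_seed(55, {
    for (i in 1:10) {
      s <- sample_sequence(tp$ks, seed = 100 + i)
      fw <- ksclf:::score_bits(tp$ks, s, "forward")
      vi <- ksclf:::score_bits(tp$ks, s, "viterbi")
      expect_gte(fw, vi)
      # X is emitted with background probability in every state, so the
      # flank cancels exactly out of the best alignment's log odds; the
      # forward sum can only grow, and only marginally, because the flank
      # residues open additional low-mass entry paths
      padded <- paste0(strrep("X", 30), s, strrep("X", 30))
      expect_equal(ksclf:::score_bits(tp$ks, padded, "viterbi"), vi,
                   tolerance = 1e-9)
      fw_pad <- ksclf:::score_bits(tp$ks, padded, "forward")
      expect_gte(fw_pad, fw - 1e-9)
      expect_lt(fw_pad - fw, 0.5)
    }
  })
})

test_that("model serialization round-trips probabilities exactly", {
  tp <- toy_profiles()
  path <- withr::local_tempfile(fileext = ".json")
  write_profile(tp$clf, path)
  back <- read_profile(path)
  expect_equal(back$match_emissions, tp$clf$match_emissions,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$transitions, tp$clf$transitions, tolerance = 1e-12)
  expect_identical(back$name, tp$clf$name)
  expect_equal(ksclf:::score_bits(back, sample_sequence(tp$clf, 3)),
               ksclf:::score_bits(tp$clf, sample_sequence(tp$clf, 3)),
               tolerance = 1e-9)
})

test_that("threshold calibration retains the cutoff sequence itself", {
  tp <- toy_profiles()
  thr <- calibrate_threshold(tp$ks, tp$ks_cutoff)
  expect_true(is.finite(thr))
  # boundary inclusive: the calibration sequence scores exactly the threshold
  expect_gte(ksclf:::score_bits(tp$ks, tp$ks_cutoff), thr)
  cfg <- classifier_config(ks_threshold = thr,
                           clf_threshold = calibrate_threshold(tp$clf,
                                                               tp$clf_cutoff))
  expect_identical(classify_protein(tp$ks_cutoff, tp$ks, tp$clf, cfg), "KS")
})

test_that("classification resolves candidates by threshold then score", {
  expect_identical(ksclf:::label_from_scores(100, 10, 50, 50), "KS")
  expect_identical(ksclf:::label_from_scores(10, 100, 50, 50), "CLF")
  expect_identical(ksclf:::label_from_scores(10, 10, 50, 50), "none")
  expect_identical(ksclf:::label_from_scores(80, 90, 50, 50), "CLF")
  expect_identical(ksclf:::label_from_scores(90, 90, 50, 50), "KS") # tie
  expect_error(classifier_config(), "calibrated")
  expect_error(classifier_config(scorer = "external"), "score_fun")
})

test_that("sampling is seed-deterministic and model-faithful", {
  tp <- toy_profiles()
  expect_identical(sample_sequence(tp$ks, 7), sample_sequence(tp$ks, 7))
  expect_false(identical(sample_sequence(tp$ks, 7), sample_sequence(tp$ks, 8)))

  # all emission mass on one residue per column and no indel mass:
  # the sample is exactly the consensus
  AA <- ksclf:::AA_ALPHABET
  em <- matrix(0, nrow = 3, ncol = 20, dimnames = list(NULL, AA))
  em[1, "M"] <- 1; em[2, "K"] <- 1; em[3, "W"] <- 1
  degenerate <- ksclf:::new_profile_hmm(
    "cons", AA, em, rep(1 / 20, 20), rep(1 / 20, 20),
    list(entry = c(1, 0, 0), exit = c(1 / 3, 1 / 2, 1),
         mm = c(2 / 3, 1 / 2, 0), mi = c(0, 0, 0), md = c(0, 0, 0),
         im = c(1, 1), ii = c(0, 0), dm = c(1, 1), dd = c(0, 0))
  )
  expect_identical(sample_sequence(degenerate, 1), "MKW")

  # self-model scores beat shuffled versions on average
  withr::with_seed(606, {
    self <- vapply(1:25, function(i) {
      ksclf:::score_bits(tp$ks, sample_sequence(tp$ks, 300 + i))
    }, numeric(1))
    shuf <- vapply(1:25, function(i) {
      s <- strsplit(sample_sequence(tp$ks, 300 + i), "")[[1]]
      ksclf:::score_bits(tp$ks, paste(sample(s), collapse = ""))
    }, numeric(1))
  })
  expect_gt(mean(self), mean(shuf))
})
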