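test_that("segment scanning finds start-to-stop ORFs in one frame", {
  orfs <- enumerate_orfs_in_window("TAAATGAAATGA", 0, 12, 0, "+",
                                   record_id = "r")
  expect_equal(nrow(orfs), 1)
  expect_equal(orfs$start, 3L)
  expect_equal(orfs$end, 12L)
  expect_true(orfs$has_start_codon)
  expect_true(orfs$has_stop_codon)
  expect_identical(orfs$protein, "MK")

  # interior segment without a start codon yields nothing
  none <- enumerate_orfs_in_window("TAAAAAAAATGA", 0, 12, 0, "+")
  expect_equal(nrow(none), 0)

  # an alternative start codon ahead of ATG wins: first of the six starts
  alt <- enumerate_orfs_in_window("TAACTGAAAATGAAATGA", 0, 18, 0, "+")
  expect_equal(nrow(alt), 1)
  expect_identical(alt$start_codon, "CTG")
  expect_equal(alt$start, 3L)

  # edge-truncated segment with no start codon is retained, flagged
  edge <- enumerate_orfs_in_window("AAAAAAAAATGA", 0, 12, 0, "+")
  expect_equal(nrow(edge), 1)
  expect_false(edge$has_start_codon)
  expect_equal(edge$start, 0L)

  no_edge <- enumerate_orfs_in_window("AAAAAAAAATGA", 0, 12, 0, "+",
                                      config = orf_config(edge_orfs = FALSE))
  expect_equal(nrow(no_edge), 0)
})

test_that("identity coverage counts in-frame identical residues only", {
  g <- taa_padded_gene(120)
  orf <- tibble::tibble(start = g$gene_start, end = g$gene_end, strand = "+")

  full <- identity_hit(g$seq, g$gene_start, 10, 60)
  expect_equal(hit_coverage_identity(orf, full, g$seq), 1.0)
  expect_equal(oracle_coverage(orf$start, orf$end, "+", full, g$seq), 1.0)

  # hit runs past the stop into TAA-land: only the in-gene half counts
  half <- identity_hit(g$seq, g$gene_start, 90, 152)
  # residues 90..119 inside (30 coding), stop + pure-stop padding never count
  expect_equal(hit_coverage_identity(orf, half, g$seq), 30 / 62)
  expect_equal(oracle_coverage(orf$start, orf$end, "+", half, g$seq), 30 / 62)

  shifted <- dplyr::mutate(full, start = start + 1, end = end + 1)
  expect_equal(hit_coverage_identity(orf, shifted, g$seq), 0)
})

test_that("the longest containing ORF obeys the length and coverage rules", {
  cfg <- orf_config()

  g330 <- taa_padded_gene(109) # 110 codons with stop = 330 nt
  hit <- identity_hit(g330$seq, g330$gene_start, 30, 80)
  orf <- find_longest_containing_orf(g330$seq, hit, cfg, record_id = "rec")
  expect_equal(nrow(orf), 1)
  expect_equal(orf$start, g330$gene_start)
  expect_equal(orf$end, g330$gene_end)
  expect_equal(orf$hit_coverage, 1.0)

  g297 <- taa_padded_gene(98) # 99 codons with stop = 297 nt: too short
  hit297 <- identity_hit(g297$seq, g297$gene_start, 20, 70)
  expect_equal(nrow(find_longest_containing_orf(g297$seq, hit297, cfg)), 0)

  # ORF overlapping under half the hit residues is rejected
  g <- taa_padded_gene(120)
  low <- identity_hit(g$seq, g$gene_start, 80, 180) # 40 of 100 inside
  expect_equal(nrow(find_longest_containing_orf(g$seq, low, cfg)), 0)
})

test_that("ORF calling agrees with the brute-force enumeration oracle", {
  cfg <- orf_config()
  withr::with_seed(1234, {
    for (i in 1:80) {
      cs <- random_orf_case(2000)
      got <- find_longest_containing_orf(cs$record_seq, cs$hit, cfg)
      want <- oracle_find_orf(cs$record_seq, cs$hit, cfg)
      if (is.null(want)) {
        expect_equal(nrow(got), 0)
      } else {
        expect_equal(nrow(got), 1)
        expect_equal(got$start, want$start)
        expect_equal(got$end, want$end)
        expect_gte(got$hit_coverage, cfg$min_hit_coverage)
        expect_gte(got$length_nt, cfg$min_orf_nt)
      }
    }
  })
})

test_that("reverse-complementing the record mirrors the called ORF", {
  cfg <- orf_config()
  withr::with_seed(77, {
    for (i in 1:20) {
      cs <- random_orf_case(1500)
      len <- nchar(cs$record_seq)
      mirror_seq <- reverse_complement(cs$record_seq)
      mirror_hit <- dplyr::mutate(
        cs$hit,
        start = len - cs$hit$end, end = len - cs$hit$start,
        strand = ifelse(cs$hit$strand == "+", "-", "+")
      )
      a <- find_longest_containing_orf(cs$record_seq, cs$hit, cfg)
      b <- find_longest_containing_orf(mirror_seq, mirror_hit, cfg)
      expect_equal(nrow(a), nrow(b))
      if (nrow(a) == 1) {
        expect_equal(b$start, len - a$end)
        expect_equal(b$end, len - a$start)
        expect_identical(b$protein, a$protein)
      }
    }
  })
})

test_that("duplicate ORFs collapse to the best-evidence hit", {
  orfs <- tibble::tibble(
    record_id = c("r", "r", "r"),
    start = c(10L, 10L, 10L), end = c(100L, 100L, 100L),
    strand = c("+", "+", "-"),
    protein = "M", evalue = c(1e-5, 1e-20, 1e-3), query_id = c("a", "b", "c")
  )
  d <- dedupe_orfs(orfs)
  expect_equal(nrow(d), 2) # opposite strands stay distinct
  expect_equal(d$evalue[d$strand == "+"], 1e-20)
  expect_equal(nrow(dedupe_orfs(orfs[0, ])), 0)
})
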