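mk_orf <- function(record_id, start, end, strand = "+", label = "KS",
                   bits = 100) {
  tibble::tibble(record_id = record_id, start = as.integer(start),
                 end = as.integer(end), strand = strand, label = label,
                 ks_bits = bits, clf_bits = bits)
}

test_that("intergenic distance is closest-ends with overlap collapsing to 0", {
  expect_equal(intergenic_gap(100, 400, 400, 700), 0L) # abutting
  expect_equal(intergenic_gap(100, 400, 300, 600), 0L) # overlapping
  expect_equal(intergenic_gap(100, 400, 2500, 3000), 2100L)
  expect_equal(intergenic_gap(2500, 3000, 100, 400), 2100L) # symmetric
  expect_error(intergenic_gap(0, 1, 0, 1, "a", "b"), "records")
})

test_that("pairing applies the distance and gene-length bounds exactly", {
  cfg <- pairing_config()
  ks <- mk_orf("r", 1000, 2000, label = "KS")
  mk_case <- function(clf_start, clf_end) {
    pair_genes(dplyr::bind_rows(ks, mk_orf("r", clf_start, clf_end,
                                           label = "CLF")), cfg)
  }
  expect_equal(nrow(mk_case(2000, 3000)), 1) # gap 0
  expect_equal(mk_case(3999, 4999)$gap_nt, 1999L)
  expect_equal(mk_case(4000, 5000)$gap_nt, 2000L) # boundary retained
  expect_equal(nrow(mk_case(4001, 5001)), 0) # over 2 kb removed
  expect_equal(nrow(mk_case(7000, 8000)), 0) # gap 5000
  expect_equal(nrow(mk_case(1500, 2500)), 1) # overlap passes

  expect_equal(nrow(mk_case(2100, 8099)), 1) # CLF length 5999 retained
  expect_equal(nrow(mk_case(2100, 8100)), 0) # CLF length 6000 excluded

  # many-to-many: one KS within 2 kb of two CLFs gives two pairs
  both <- pair_genes(dplyr::bind_rows(
    ks,
    mk_orf("r", 2500, 3400, label = "CLF"),
    mk_orf("r", 3600, 3990, strand = "-", label = "CLF")
  ), cfg)
  expect_equal(nrow(both), 2)
  expect_gte(nrow(both), max(length(unique(both$ks_start)),
                             length(unique(both$clf_start))))

  # different records never pair
  apart <- pair_genes(dplyr::bind_rows(
    ks, mk_orf("other", 2100, 3000, label = "CLF")), cfg)
  expect_equal(nrow(apart), 0)

  # every emitted pair satisfies its config bounds
  withr::with_seed(88, {
    rand <- dplyr::bind_rows(lapply(1:60, function(i) {
      s <- sample(0:50000, 1)
      mk_orf("r", s, s + sample(300:7000, 1),
             label = sample(c("KS", "CLF"), 1))
    }))
  })
  got <- pair_genes(rand, cfg)
  expect_true(all(got$gap_nt <= cfg$max_gap_nt))
  expect_true(all(got$ks_end - got$ks_start < cfg$max_gene_nt))
  expect_true(all(got$clf_end - got$clf_start < cfg$max_gene_nt))
})

test_that("region extraction extends, clips and merges per record", {
  recs <- tibble::tibble(id = c("r1", "r2"), length = c(100000L, 100000L))
  p <- function(record_id, lo, hi) {
    tibble::tibble(record_id = record_id,
                   ks_start = as.integer(lo), ks_end = as.integer(lo + 1000),
                   ks_strand = "+",
                   clf_start = as.integer(hi - 1000), clf_end = as.integer(hi),
                   clf_strand = "+", gap_nt = 0L,
                   ks_bits = 1, clf_bits = 1)
  }
  one <- extract_regions(p("r1", 10000, 13000), recs)
  expect_equal(one$start, 0L) # clipped at the record edge
  expect_equal(one$end, 43000L)

  close_pair <- dplyr::bind_rows(p("r1", 10000, 13000), p("r1", 23000, 26000))
  expect_equal(nrow(extract_regions(close_pair, recs)), 1)

  far <- dplyr::bind_rows(p("r1", 10000, 13000), p("r1", 83000, 86000))
  two <- extract_regions(far, recs)
  expect_equal(nrow(two), 2)
  # regions on one record are pairwise disjoint
  expect_true(two$end[1] <= two$start[2])

  # merging is order-independent
  withr::with_seed(14, {
    many <- dplyr::bind_rows(lapply(1:12, function(i) {
      lo <- sample(0:90000, 1)
      p(sample(c("r1", "r2"), 1), lo, lo + 5000)
    }))
    shuffled <- many[sample(nrow(many)), ]
  })
  a <- extract_regions(many, recs)
  b <- extract_regions(shuffled, recs)
  expect_equal(a[, c("record_id", "start", "end", "n_pairs")],
               b[, c("record_id", "start", "end", "n_pairs")])

  expect_error(extract_regions(p("missing", 1000, 2000), recs), "absent")
  expect_equal(nrow(extract_regions(p("r1", 1, 2)[0, ], recs)), 0)
})

test_that("region categorization implements the pairing truth table", {
  expect_identical(categorize_region(c("t2ks", "t2clf")), "KS_CLF")
  expect_identical(categorize_region(c("t2ks", "t2fas")), "KS_FAS")
  expect_identical(categorize_region(c("t2fas", "t2fas")), "FAS_FAS")
  expect_setequal(categorize_region(c("t2ks", "t2fas", "t2clf")),
                  c("KS_CLF", "KS_FAS"))
  expect_identical(categorize_region(c("t2ks")), character(0))
  expect_identical(categorize_region(c("t2fas")), character(0))
  expect_setequal(categorize_region(c("t2ks", "t2clf", "t2fas", "t2fas")),
                  c("KS_CLF", "KS_FAS", "FAS_FAS"))
  expect_identical(categorize_region(character(0)), character(0))
  expect_warning(out <- categorize_region(c("t2ks", "t2clf", "mystery")),
                 "mystery")
  expect_identical(out, "KS_CLF")

  tbl <- tibble::tibble(
    region_id = c("A", "A", "B", "B", "C"),
    gene_function = c("t2ks", "t2clf", "t2fas", "t2fas", "t2ks")
  )
  got <- categorize_regions(tbl)
  expect_identical(got$categories[got$region_id == "A"], "KS_CLF")
  expect_identical(got$categories[got$region_id == "B"], "FAS_FAS")
  expect_identical(got$categories[got$region_id == "C"], "")
})
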