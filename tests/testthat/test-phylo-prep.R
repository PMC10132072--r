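test_that("gap-column trimming keeps the 5 % boundary and maps columns", {
  withr::with_seed(40, {
    base <- replicate(40, paste(sample(c("A", "R", "N", "D"), 10,
                                       replace = TRUE), collapse = ""))
  })
  chars <- do.call(rbind, strsplit(base, ""))
  chars[1:2, 3] <- "-" # 2/40 = 5.0 %: kept
  chars[1:3, 7] <- "-" # 3/40 = 7.5 %: removed
  aln <- tibble::tibble(id = paste0("s", 1:40),
                        seq = apply(chars, 1, paste, collapse = ""))
  out <- trim_gap_columns(aln, max_gap_fraction = 0.05)
  expect_equal(attr(out, "column_map"), setdiff(1:10, 7))
  expect_equal(nchar(out$seq[1]), 9)
  # closed-form width: columns with gap count <= floor(0.05 * 40)
  gap_counts <- colSums(chars == "-")
  expect_equal(nchar(out$seq[1]), sum(gap_counts <= floor(0.05 * 40)))

  clean <- tibble::tibble(id = c("a", "b"), seq = c("MK", "MR"))
  expect_identical(trim_gap_columns(clean)$seq, clean$seq)

  allgap <- tibble::tibble(id = c("a", "b"), seq = c("M-", "M-"))
  expect_equal(nchar(trim_gap_columns(allgap)$seq[1]), 1)
  expect_warning(trim_gap_columns(tibble::tibble(id = c("a", "b"),
                                                 seq = c("-", "-"))),
                 "width-0")
})

test_that("newick parsing reads FastTree-style supports and round-trips", {
  tr <- read_newick("((A:1,B:1)0.95:0.5,C:2);")
  expect_identical(tr$node.label, c("", "0.95"))
  expect_error(read_newick("((A:1,B:1);"), "Unbalanced")

  # bracketed support comments after a closing parenthesis are tolerated
  trb <- read_newick("((A:1,B:1)[0.87]:0.5,C:2);")
  expect_identical(trb$node.label[2], "0.87")

  withr::with_seed(60, {
    for (i in 1:50) {
      t0 <- ape::rtree(sample(4:30, 1))
      t0$node.label <- sprintf("%.3f", stats::runif(t0$Nnode))
      back <- read_newick(write_newick(t0))
      expect_true(isTRUE(ape::all.equal.phylo(back, t0,
                                              use.edge.length = FALSE)))
      expect_setequal(back$tip.label, t0$tip.label)
      expect_setequal(back$node.label, t0$node.label)
      expect_equal(sum(back$edge.length), sum(t0$edge.length),
                   tolerance = 1e-9)
    }
  })
})

support_tree <- function() {
  read_newick(paste0("(((A:1,B:2)0.69:0.5,(C:1,D:1)0.70:0.4)0.71:0.3,",
                     "(E:1,F:1)0.95:1,G:2);"))
}

test_that("collapse contracts exactly the nodes under the support threshold", {
  tr <- support_tree()
  depths0 <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
  col <- collapse_low_support(tr, min_support = 0.70)
  expect_equal(col$Nnode, tr$Nnode - 1) # only the 0.69 node went
  expect_false("0.69" %in% col$node.label)
  expect_true(all(c("0.70", "0.71", "0.95") %in% col$node.label))
  expect_setequal(col$tip.label, tr$tip.label)
  depths1 <- ape::node.depth.edgelength(col)[seq_along(col$tip.label)]
  expect_equal(depths1[match(tr$tip.label, col$tip.label)], depths0,
               tolerance = 1e-9)
  # idempotent
  again <- collapse_low_support(col, min_support = 0.70)
  expect_equal(again$Nnode, col$Nnode)

  # percent-scale supports are auto-detected
  trp <- support_tree()
  trp$node.label <- ifelse(nzchar(trp$node.label),
                           sprintf("%g", as.numeric(trp$node.label) * 100),
                           "")
  colp <- collapse_low_support(trp, min_support = 0.70)
  expect_equal(colp$Nnode, trp$Nnode - 1)

  untouched <- read_newick("(((A:1,B:2)1.0:0.5,C:1)1.0:0.3,D:2);")
  expect_equal(collapse_low_support(untouched, 0.70)$Nnode, untouched$Nnode)
})

test_that("missing support values follow the configured policy", {
  tr <- read_newick("(((A:1,B:2):0.5,C:1)0.9:0.3,D:2);")
  expect_warning(kept <- collapse_low_support(tr, 0.70,
                                              missing_support = "keep"),
                 "kept")
  expect_equal(kept$Nnode, tr$Nnode)
  zeroed <- collapse_low_support(tr, 0.70, missing_support = "zero")
  expect_equal(zeroed$Nnode, tr$Nnode - 1)
  expect_error(collapse_low_support(tr, 0.70, missing_support = "error"),
               "support")
})

test_that("outgroup rooting splits the subtending edge and conserves length", {
  tr <- read_newick("((A:1,B:1)0.9:0.5,(C:2,(D:1,FabF:3)0.8:1)0.7:0.5);")
  total0 <- sum(tr$edge.length)
  rooted <- root_with_outgroup(tr, "FabF")
  root <- length(rooted$tip.label) + 1L
  root_children <- rooted$edge[rooted$edge[, 1] == root, 2]
  expect_true(match("FabF", rooted$tip.label) %in% root_children)
  expect_equal(sum(rooted$edge.length), total0, tolerance = 1e-9)
  # the outgroup edge was split at its midpoint
  og_edge <- rooted$edge.length[rooted$edge[, 2] ==
                                  match("FabF", rooted$tip.label)]
  expect_equal(og_edge, 1.5, tolerance = 1e-9)
  # rerooting on the same leaf again is the identity
  expect_identical(write_newick(root_with_outgroup(rooted, "FabF")),
                   write_newick(rooted))
  expect_error(root_with_outgroup(tr, "nope"), "not found")
})
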