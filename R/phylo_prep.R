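#' Read and write aligned protein FASTA
#'
#' Alignments are tibbles with columns `id` and `seq` (equal-length gapped
#' protein strings, `-` for gaps).
#'
#' @param path File path.
#' @param aln Alignment tibble.
#' @return `read_alignment()`: alignment tibble; `write_alignment()`: `path`,
#'   invisibly.
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  id <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(id)) abort("Duplicate ids in alignment.")
  out <- tibble(id = id, seq = toupper(unname(as.character(set))))
  if (length(unique(nchar(out$seq))) > 1) {
    abort("Aligned sequences must have equal length.")
  }
  out
}

#' @rdname read_alignment
#' @export
write_alignment <- function(aln, path) {
  writeLines(as.vector(rbind(paste0(">", aln$id), aln$seq)), path)
  invisible(path)
}

#' Remove high-gap alignment columns
#'
#' A column is kept iff its gap fraction is at most `max_gap_fraction`
#' (strictly more than the threshold is removed, so a column at exactly the
#' boundary survives). The gap fraction is computed over all rows. The indices
#' of the surviving columns in the input alignment are attached as the
#' `column_map` attribute for traceability.
#'
#' @param aln Alignment tibble (`id`, `seq`).
#' @param max_gap_fraction Maximum tolerated gap fraction per column,
#'   default 0.05.
#' @return Trimmed alignment tibble with attribute `column_map`.
#' @export
trim_gap_columns <- function(aln, max_gap_fraction = 0.05) {
  stopifnot(max_gap_fraction >= 0, max_gap_fraction < 1)
  if (nrow(aln) == 0) abort("Empty alignment.")
  chars <- do.call(rbind, strsplit(aln$seq, "", fixed = TRUE))
  gap_frac <- colMeans(chars == "-" | chars == ".")
  keep <- which(gap_frac <= max_gap_fraction)
  if (length(keep) == 0) {
    warn("All columns exceeded the gap threshold; returning width-0 alignment.")
  }
  out <- tibble(
    id = aln$id,
    seq = apply(chars[, keep, drop = FALSE], 1, paste, collapse = "")
  )
  attr(out, "column_map") <- keep
  out
}

#' Read and write Newick trees
#'
#' Thin wrappers over \pkg{ape} that tolerate the FastTree dialect (support
#' values stored as internal node labels) and bracketed support comments of
#' the form `)[0.95]` on read.
#'
#' @param source Path to a Newick file or a Newick string.
#' @param tree An \pkg{ape} `phylo` object.
#' @param path Output path for `write_newick()`; `NULL` returns the string.
#' @return `read_newick()`: a `phylo`; `write_newick()`: the Newick string,
#'   invisibly when written to a file.
#' @export
read_newick <- function(source) {
  text <- if (length(source) == 1 && file.exists(source)) {
    paste(readLines(source), collapse = "")
  } else {
    paste(as.character(source), collapse = "")
  }
  if (!grepl(";", text)) abort("Newick text must end with ';'.")
  ch <- strsplit(text, "", fixed = TRUE)[[1]]
  open <- sum(ch == "(")
  close <- sum(ch == ")")
  if (open != close) {
    abort(sprintf("Unbalanced parentheses in Newick (%d '(' vs %d ')').",
                  open, close))
  }
  # bracketed support comment after a closing parenthesis -> node label
  text <- gsub("\\)\\[([0-9.eE+-]+)\\]", ")\\1", text)
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) abort("Failed to parse Newick text.")
  tree
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

# numeric support values per internal node (NA where absent), plus the scale
# actually used for the threshold
node_supports <- function(tree) {
  lab <- tree$node.label
  if (is.null(lab)) return(rep(NA_real_, tree$Nnode))
  sup <- suppressWarnings(as.numeric(lab))
  sup[!nzchar(lab %||% "")] <- NA_real_
  sup
}

resolve_support_scale <- function(sup, support_scale) {
  if (support_scale == "auto") {
    if (any(is.finite(sup) & sup > 1)) "percent" else "unit"
  } else {
    support_scale
  }
}

#' Collapse weakly supported internal edges into polytomies
#'
#' Every internal edge whose child node's support is strictly below
#' `min_support` is contracted: the child's children reattach to its parent
#' and each reattached branch length is incremented by the contracted edge's
#' length, so root-to-leaf path lengths are preserved. The leaf set never
#' changes and the operation is idempotent. The root is exempt.
#'
#' Support values may be fractions (FastTree local support, 0-1) or
#' percentages; `support_scale = "auto"` detects percentages from values
#' above 1 and rescales the threshold accordingly.
#'
#' @param tree A `phylo` with support values as internal node labels.
#' @param min_support Threshold; nodes with support `<` this collapse.
#'   Interpreted on the unit scale (0.70 means 70 %).
#' @param support_scale `"unit"`, `"percent"` or `"auto"`.
#' @param missing_support Treatment of internal nodes without a support
#'   value: `"keep"` (default, with a warning), `"zero"` (collapse) or
#'   `"error"`.
#' @return The collapsed `phylo`.
#' @export
collapse_low_support <- function(tree, min_support = 0.70,
                                 support_scale = c("auto", "unit", "percent"),
                                 missing_support = c("keep", "zero", "error")) {
  support_scale <- match.arg(support_scale)
  missing_support <- match.arg(missing_support)
  warned <- FALSE
  repeat {
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    sup <- node_supports(tree)
    scale <- resolve_support_scale(sup, support_scale)
    thr <- if (scale == "percent") min_support * 100 else min_support
    internal <- seq_len(tree$Nnode) + ntip
    missing <- is.na(sup) & internal != root
    if (any(missing)) {
      if (missing_support == "error") {
        abort("Internal node without a support value.")
      }
      if (missing_support == "keep" && !warned) {
        warn("Internal nodes without support values were kept.")
        warned <- TRUE
      }
      sup[missing] <- if (missing_support == "zero") -Inf else Inf
    }
    low <- internal[internal != root & sup < thr]
    if (length(low) == 0) break
    tree <- contract_internal_node(tree, low[1])
  }
  tree
}

# contract the edge above internal node v, reattaching its children to its
# parent; node numbering is compacted afterwards
contract_internal_node <- function(tree, v) {
  ntip <- length(tree$tip.label)
  e <- tree$edge
  pe <- which(e[, 2] == v)
  stopifnot(length(pe) == 1, v > ntip)
  p <- e[pe, 1]
  len <- if (!is.null(tree$edge.length)) tree$edge.length[pe] else 0
  ce <- which(e[, 1] == v)
  e[ce, 1] <- p
  if (!is.null(tree$edge.length)) {
    tree$edge.length[ce] <- tree$edge.length[ce] + len
    tree$edge.length <- tree$edge.length[-pe]
  }
  e <- e[-pe, , drop = FALSE]
  e[e > v] <- e[e > v] - 1L
  tree$edge <- e
  if (!is.null(tree$node.label)) {
    tree$node.label <- tree$node.label[-(v - ntip)]
  }
  tree$Nnode <- tree$Nnode - 1L
  tree
}

#' Root a tree on a named outgroup leaf
#'
#' Reroots the tree on the edge subtending the outgroup leaf, splitting that
#' edge at its midpoint, so the outgroup becomes one child of the new root and
#' the total branch length is conserved.
#'
#' @param tree A `phylo`.
#' @param leaf_label Tip label of the outgroup.
#' @return The rerooted `phylo`.
#' @export
root_with_outgroup <- function(tree, leaf_label) {
  tip <- match(leaf_label, tree$tip.label)
  if (is.na(tip)) {
    abort(sprintf("Outgroup leaf '%s' not found in the tree.", leaf_label))
  }
  edge <- which(tree$edge[, 2] == tip)
  root <- length(tree$tip.label) + 1L
  # already rooted on this leaf's edge: rerooting is the identity
  if (tree$edge[edge, 1] == root && sum(tree$edge[, 1] == root) == 2) {
    return(tree)
  }
  pos <- if (!is.null(tree$edge.length)) tree$edge.length[edge] / 2 else 0
  phytools::reroot(tree, node.number = tip, position = pos)
}
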