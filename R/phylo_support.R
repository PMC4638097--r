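#' Non-trivial bipartitions of a tree as canonical keys
#'
#' Each internal edge of a tree splits the leaves in two; the split is
#' represented by the side not containing the alphabetically first leaf,
#' sorted and joined with `"|"`. Keys are therefore invariant to rooting,
#' sample order and edge direction. Trivial splits (one leaf on a side) are
#' omitted.
#'
#' @param tree a `phylo` tree.
#' @return character vector of split keys (possibly empty).
#' @export
tree_splits <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  labels <- sort(tree$tip.label)
  anchor <- labels[1L]
  n <- length(labels)
  pp <- ape::prop.part(tree)
  tips <- attr(pp, "labels")
  keys <- vapply(pp, function(p) {
    side <- tips[p]
    if (anchor %in% side) side <- setdiff(tree$tip.label, side)
    if (length(side) < 2L || length(side) > n - 2L) return(NA_character_)
    paste(sort(side), collapse = "|")
  }, character(1))
  unique(keys[!is.na(keys)])
}

#' @noRd
split_key <- function(leaves, all_leaves) {
  anchor <- sort(all_leaves)[1L]
  if (anchor %in% leaves) leaves <- setdiff(all_leaves, leaves)
  paste(sort(leaves), collapse = "|")
}

#' Column-bootstrap support for the BioNJ tree
#'
#' Builds the point-estimate BioNJ tree from the full binary matrix, then
#' resamples marker columns with replacement (same width), rebuilding the
#' distance matrix and BioNJ tree for each replicate. The support of each
#' internal edge of the point tree is the percentage of replicate trees that
#' contain the same bipartition. All matrix columns take part in the
#' resampling, including germline-shared markers. Deterministic given `seed`.
#'
#' @param mmat a `marker_matrix` with the reference row added and >= 1 marker.
#' @param reps number of bootstrap replicates (default 10000).
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @return an object of class `bootstrap_phylo`: list with `tree` (the
#'   unrooted point tree), `splits` (data.frame: split key, size, support in
#'   percent), `reps`.
#' @export
bootstrap_support <- function(mmat, reps = 10000L, seed = NULL) {
  stopifnot(inherits(mmat, "marker_matrix"))
  if (reps < 1L) stop("`reps` must be >= 1")
  if (ncol(mmat$mat) < 1L) stop("matrix has no markers")
  mat <- mmat$mat
  point <- bionj_tree(as.matrix(stats::dist(mat)))
  keys <- tree_splits(point)
  hits <- integer(length(keys))
  names(hits) <- keys
  with_seed(seed, {
    for (b in seq_len(reps)) {
      idx <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
      rep_tree <- bionj_tree(as.matrix(stats::dist(mat[, idx, drop = FALSE])))
      rep_keys <- tree_splits(rep_tree)
      hit <- keys %in% rep_keys
      hits[hit] <- hits[hit] + 1L
    }
  })
  splits <- data.frame(
    split = keys,
    size = vapply(strsplit(keys, "|", fixed = TRUE), length, integer(1)),
    support = 100 * hits / reps,
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(tree = point, splits = splits, reps = reps),
            class = "bootstrap_phylo")
}

#' @export
print.bootstrap_phylo <- function(x, ...) {
  cat("BioNJ tree with bipartition bootstrap support (", x$reps,
      " replicates)\n", sep = "")
  print(x$splits)
  invisible(x)
}

#' Write bootstrap supports onto a tree's node labels
#'
#' Matches each internal node of `tree` (which may have been re-rooted since
#' the supports were computed) to the bootstrap split table by bipartition
#' key and sets `node.label` to the rounded support; nodes without a matching
#' non-trivial split get an empty label.
#'
#' @param tree a `phylo` tree over the same leaf set.
#' @param splits the `splits` data.frame of a [bootstrap_support()] result.
#' @return the tree with `node.label` set.
#' @export
annotate_supports <- function(tree, splits) {
  pp <- ape::prop.part(tree)
  tips <- attr(pp, "labels")
  labs <- vapply(pp, function(p) {
    key <- split_key(tips[p], tree$tip.label)
    i <- match(key, splits$split)
    if (is.na(i)) "" else sprintf("%d", round(splits$support[i]))
  }, character(1))
  tree$node.label <- labs
  tree
}

#' Tumour monophyly verdict
#'
#' Tests whether the tumour samples form a clade excluding the normal sample
#' and the reference pseudo-sample in the rooted tree. When they do, the
#' clade's bootstrap support is returned; otherwise the support of the
#' smallest clade containing all tumours is returned and the result is
#' flagged.
#'
#' @param tree a rooted `phylo` tree.
#' @param roles named role vector (may include the reference).
#' @param splits optional split table from [bootstrap_support()] for support
#'   lookup.
#' @return list with `monophyletic` (logical), `support` (percent or NA),
#'   `clade` (leaf labels of the clade examined) and `flagged` (TRUE when the
#'   support refers to a larger, non-tumour-only clade).
#' @export
tumour_monophyly <- function(tree, roles, splits = NULL) {
  stopifnot(inherits(tree, "phylo"))
  tumours <- sort(names(roles)[roles == "tumour"])
  if (!all(tumours %in% tree$tip.label))
    stop("tree lacks tumour tip(s): ",
         paste(setdiff(tumours, tree$tip.label), collapse = ", "))
  pp <- ape::prop.part(tree)
  tips <- attr(pp, "labels")
  clades <- lapply(pp, function(p) sort(tips[p]))
  exact <- vapply(clades, function(cl) identical(cl, tumours), logical(1))
  mono <- any(exact) || length(tumours) == 1L
  if (mono) {
    clade <- tumours
  } else {
    containing <- clades[vapply(clades, function(cl) all(tumours %in% cl),
                                logical(1))]
    clade <- containing[[which.min(lengths(containing))]]
  }
  support <- NA_real_
  if (!is.null(splits)) {
    i <- match(split_key(clade, tree$tip.label), splits$split)
    if (!is.na(i)) support <- splits$support[i]
  }
  list(monophyletic = mono, support = support, clade = clade,
       flagged = !mono)
}

#' Flag probable neoplastic contamination of the normal sample
#'
#' A "normal" mucosa sample contaminated with tumour cells shows up in three
#' ways, any of which raises the flag: (a) the normal leaf falls inside the
#' smallest clade containing all tumour samples; (b) the normal terminal
#' branch is at least as long as the shortest tumour terminal branch (a clean
#' normal accumulates far fewer lineage-specific variants than any tumour);
#' (c) the tumour-associated fraction of markers drops below `ta_threshold`
#' (default 0.20) because leaked trunk variants are reclassified as germline.
#'
#' For criterion (b) to mean "lineage-specific variant load", pass a tree
#' whose branch lengths are additive in marker counts — i.e. one built from
#' squared-Euclidean (Hamming) distances, where each discordant marker
#' contributes one unit to the path. On the display scale (square-root
#' distances) branch lengths are not additive and the comparison is
#' distorted. [run_pipeline()] evaluates this flag on such a companion tree.
#'
#' @param tree rooted `phylo` tree.
#' @param pcounts result of [partition_counts()].
#' @param roles named role vector.
#' @param ta_threshold tumour-associated-fraction threshold (default 0.20).
#' @return list with `flagged` and a named logical `criteria`
#'   (`normal_in_tumour_clade`, `normal_branch_long`, `low_tumour_fraction`),
#'   plus the measured branch lengths and fraction.
#' @export
flag_normal_contamination <- function(tree, pcounts, roles,
                                      ta_threshold = 0.20) {
  stopifnot(inherits(tree, "phylo"))
  normal <- names(roles)[roles == "normal"]
  tumours <- names(roles)[roles == "tumour"]
  pp <- ape::prop.part(tree)
  tips <- attr(pp, "labels")
  clades <- lapply(pp, function(p) tips[p])
  containing <- clades[vapply(clades, function(cl) all(tumours %in% cl),
                              logical(1))]
  tumour_clade <- containing[[which.min(lengths(containing))]]
  in_clade <- normal %in% tumour_clade

  tip_len <- function(lab) {
    i <- match(lab, tree$tip.label)
    tree$edge.length[tree$edge[, 2L] == i]
  }
  nlen <- tip_len(normal)
  tlens <- vapply(tumours, tip_len, numeric(1))
  branch_long <- nlen >= min(tlens)

  ta <- pcounts$tumour_associated_fraction
  low_ta <- !is.na(ta) && ta < ta_threshold

  criteria <- c(normal_in_tumour_clade = in_clade,
                normal_branch_long = branch_long,
                low_tumour_fraction = low_ta)
  list(flagged = any(criteria), criteria = criteria,
       normal_branch = nlen, tumour_branches = tlens,
       tumour_associated_fraction = ta, ta_threshold = ta_threshold)
}
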