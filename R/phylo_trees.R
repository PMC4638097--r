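#' Euclidean distance matrix on binary markers
#'
#' For binary rows the Euclidean distance between two samples is the square
#' root of the number of markers at which they differ (the square root of the
#' Hamming distance), so shared markers contribute nothing and each
#' discordant marker contributes one unit under the root.
#'
#' @param mmat a `marker_matrix` (usually after [add_reference_row()]).
#' @return symmetric numeric matrix with zero diagonal, labelled by sample.
#' @export
binary_distance <- function(mmat) {
  stopifnot(inherits(mmat, "marker_matrix"))
  if (nrow(mmat$mat) < 2L) stop("need at least 2 samples")
  as.matrix(stats::dist(mmat$mat, method = "euclidean"))
}

#' BioNJ distance tree
#'
#' Builds an unrooted tree by the BioNJ agglomeration (Gascuel 1997), a
#' variance-weighted variant of neighbour joining that performs well when
#' branch lengths are heterogeneous, as they are between tumour and normal
#' lineages. Variances are initialised to the distances; at each step the
#' pair (i, j) minimising \eqn{Q(i,j) = (r-2) d_{ij} - S_i - S_j} is joined
#' (r = current taxa, \eqn{S_i = \sum_k d_{ik}}), pendant lengths are
#' \eqn{b_i = d_{ij}/2 + (S_i - S_j)/(2(r-2))}, \eqn{b_j = d_{ij} - b_i}, and
#' distances/variances to the new node u are reduced with the weight
#' \eqn{\lambda = 1/2 + \sum_k (v_{jk} - v_{ik}) / (2 (r-2) v_{ij})} clamped
#' to \[0, 1\]:
#' \eqn{d_{uk} = \lambda d_{ik} + (1-\lambda) d_{jk} - \lambda b_i -
#' (1-\lambda) b_j} and
#' \eqn{v_{uk} = \lambda v_{ik} + (1-\lambda) v_{jk} -
#' \lambda (1-\lambda) v_{ij}}. The last three taxa are joined exactly.
#' Q ties are broken on the lowest (i, j) index pair, so the output is
#' deterministic. Negative branch lengths are retained.
#'
#' @param d symmetric non-negative distance matrix with labels, >= 3 taxa.
#' @return an unrooted `phylo` tree.
#' @export
bionj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("BioNJ needs at least 3 taxa")
  if (is.null(rownames(d))) stop("distance matrix must be labelled")
  if (any(d < 0) || max(abs(d - t(d))) > 1e-8)
    stop("distance matrix must be symmetric and non-negative")
  v <- d
  frag <- rownames(d)        # growing newick fragments, one per active node
  while (nrow(d) > 3L) {
    r <- nrow(d)
    S <- rowSums(d)
    best_i <- 1L; best_j <- 2L; best_q <- Inf
    for (i in 1:(r - 1L)) for (j in (i + 1L):r) {
      q <- (r - 2) * d[i, j] - S[i] - S[j]
      if (q < best_q) { best_q <- q; best_i <- i; best_j <- j }
    }
    i <- best_i; j <- best_j
    bi <- d[i, j] / 2 + (S[i] - S[j]) / (2 * (r - 2))
    bj <- d[i, j] - bi
    lam <- 0.5
    if (v[i, j] > 0) {
      k <- setdiff(seq_len(r), c(i, j))
      lam <- 0.5 + sum(v[j, k] - v[i, k]) / (2 * (r - 2) * v[i, j])
      lam <- min(max(lam, 0), 1)
    }
    k <- setdiff(seq_len(r), c(i, j))
    du <- lam * d[i, k] + (1 - lam) * d[j, k] - lam * bi - (1 - lam) * bj
    vu <- lam * v[i, k] + (1 - lam) * v[j, k] - lam * (1 - lam) * v[i, j]
    new_frag <- sprintf("(%s:%.17g,%s:%.17g)", frag[i], bi, frag[j], bj)
    d <- rbind(cbind(d[k, k, drop = FALSE], du), c(du, 0))
    v <- rbind(cbind(v[k, k, drop = FALSE], vu), c(vu, 0))
    frag <- c(frag[k], new_frag)
  }
  # exact join of the final three taxa around one internal node
  b1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b2 <- d[1, 2] - b1
  b3 <- d[1, 3] - b1
  txt <- sprintf("(%s:%.17g,%s:%.17g,%s:%.17g);",
                 frag[1], b1, frag[2], b2, frag[3], b3)
  ape::read.tree(text = txt)
}

#' UPGMA tree (average-linkage, ultrametric)
#'
#' Concordance check for the BioNJ tree: average-linkage hierarchical
#' clustering on the same distances, which assumes a molecular clock. On
#' clean clonal data it recovers the same tumour clade as BioNJ.
#'
#' @param d symmetric distance matrix with labels, >= 2 taxa.
#' @return a rooted ultrametric `phylo` tree.
#' @export
upgma_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 2L) stop("UPGMA needs at least 2 taxa")
  if (any(d < 0) || max(abs(d - t(d))) > 1e-8)
    stop("distance matrix must be symmetric and non-negative")
  phangorn::upgma(stats::as.dist(d))
}

#' Root a tree on the reference pseudo-sample
#'
#' Roots the tree on the edge leading to the `"reference"` leaf (the all-zero
#' pseudo-sample representing the reference genome), so ancestral states are
#' polarised: edges point away from the unmutated reference. Idempotent.
#'
#' @param tree a `phylo` tree containing a `"reference"` tip.
#' @return the rooted `phylo` tree.
#' @export
root_with_reference <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!"reference" %in% tree$tip.label)
    stop("tree has no 'reference' tip to root on")
  ape::root(tree, outgroup = "reference", resolve.root = TRUE)
}
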