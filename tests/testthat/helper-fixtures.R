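# Fixture builders shared across the test files. All fixtures are built in
# code at test time; nothing binary is stored.

# Write a small multi-sample VCF. `rows` is a data.frame with columns chrom,
# pos, ref, alt, filter, info, and one column per sample holding the full
# GT:AD:DP string.
write_test_vcf <- function(path, rows, samples,
                           format = "GT:AD:DP") {
  header <- c("##fileformat=VCFv4.2",
              "##INFO=<ID=ANN,Number=.,Type=String,Description=\"ann\">",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
              "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(rows)), function(i) {
    paste(c(rows$chrom[i], rows$pos[i], ".", rows$ref[i], rows$alt[i], "99",
            rows$filter[i], rows$info[i], format,
            unlist(rows[i, samples])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# A GT:AD:DP sample field with the given genotype and per-allele depths.
gtf <- function(gt, ref_reads = 20, alt_reads = 10) {
  sprintf("%s:%d,%d:%d", gt, ref_reads, alt_reads, ref_reads + alt_reads)
}

# Four-sample roles used throughout: one normal, three tumours.
test_roles <- c(N = "normal", T1 = "tumour", T2 = "tumour", T3 = "tumour")

# Build a marker_matrix directly from a samples x markers 0/1 matrix.
make_mmat <- function(mat, roles = test_roles[rownames(mat)]) {
  k <- ncol(mat)
  info <- data.frame(chrom = rep("chr1", k), pos = seq_len(k),
                     ref = rep("A", k), alt = rep("T", k),
                     ann = rep(NA_character_, k), stringsAsFactors = FALSE)
  if (k > 0) colnames(mat) <- paste0("chr1:", info$pos, "_A>T")
  structure(list(mat = mat, info = info, roles = roles),
            class = "marker_matrix")
}

# Random unrooted tree with strictly positive branch lengths plus its exact
# leaf-to-leaf (patristic) distance matrix: an additive matrix by
# construction.
random_additive <- function(n, min_len = 0.1, max_len = 2) {
  tr <- ape::rtree(n, rooted = FALSE,
                   br = function(k) stats::runif(k, min_len, max_len))
  tr$tip.label <- paste0("s", seq_len(n))
  d <- ape::cophenetic.phylo(tr)
  d <- d[tr$tip.label, tr$tip.label]
  list(tree = tr, d = d)
}

# Same unrooted topology? (Robinson-Foulds distance zero.)
same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}

# Exhaustive hypergeometric enumeration oracle for the two-sided Fisher
# p-value of a 2x2 table, computed from binomial coefficients directly
# (independent of the dhyper-based implementation path).
fisher_enum_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  xs <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, xs) + lchoose(r2, c1 - xs) - lchoose(n, c1)
  probs <- exp(logp)
  p_obs <- probs[xs == tab[1, 1]]
  min(sum(probs[probs <= p_obs * (1 + 1e-7)]), 1)
}

# Ordinary-least-squares branch lengths of a fixed topology against a
# distance matrix; returns the fitted tree and residual sum of squares.
ls_fit_topology <- function(topo, d) {
  labs <- rownames(d)
  tips <- match(topo$tip.label, labs)
  ne <- nrow(topo$edge)
  pairs <- utils::combn(length(labs), 2)
  A <- matrix(0, ncol(pairs), ne)
  for (e in seq_len(ne)) {
    side <- unlist(phangorn::Descendants(topo, topo$edge[e, 2], "tips"))
    side_labs <- topo$tip.label[side]
    in_side <- labs %in% side_labs
    A[, e] <- xor(in_side[pairs[1, ]], in_side[pairs[2, ]])
  }
  y <- d[cbind(pairs[1, ], pairs[2, ])]
  fit <- stats::lm.fit(A, y)
  topo$edge.length <- fit$coefficients
  topo$edge.length[is.na(topo$edge.length)] <- 0
  list(tree = topo, rss = sum(fit$residuals^2))
}

# Topology-enumeration + OLS oracle: the best-fitting tree over all unrooted
# topologies on the taxa of `d`.
ls_enum_oracle <- function(d) {
  labs <- rownames(d)
  topos <- phangorn::allTrees(length(labs), rooted = FALSE, tip.label = labs)
  fits <- lapply(topos, ls_fit_topology, d = d)
  fits[[which.min(vapply(fits, `[[`, numeric(1), "rss"))]]
}
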