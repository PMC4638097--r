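test_that("binary distances are sqrt of discordant marker counts and metric", {
  mat <- rbind(N = c(0L, 0L, 0L), T1 = c(1L, 1L, 0L), T2 = c(1L, 0L, 1L),
               T3 = c(0L, 1L, 1L))
  d <- binary_distance(make_mmat(mat))
  expect_equal(d["N", "T1"], sqrt(2))
  expect_equal(diag(d), rep(0, 4), ignore_attr = TRUE)
  expect_equal(d, t(d))
  # triangle inequality over all triples
  for (i in 1:4) for (j in 1:4) for (k in 1:4)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
  # reference row distance is sqrt of the sample's row sum
  mm <- add_reference_row(make_mmat(mat))
  dr <- binary_distance(mm)
  expect_equal(dr["reference", "T1"], sqrt(sum(mat["T1", ])))
  expect_error(binary_distance(make_mmat(mat[1, , drop = FALSE],
                                         roles = c(N = "normal"))))
})

test_that("BioNJ reproduces the additive quartet ((A:1,B:2):1,(C:3,D:4))", {
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- bionj_tree(d)
  truth <- ape::read.tree(text = "((A:1,B:2):1,C:3,D:4);")
  expect_true(same_topology(tr, truth))
  # patristic distances reproduce the input exactly (additive recovery)
  co <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
  expect_equal(co, d, tolerance = 1e-12)
  # pendant branch lengths
  len <- function(t, lab) t$edge.length[t$edge[, 2] == match(lab, t$tip.label)]
  expect_equal(len(tr, "A"), 1, tolerance = 1e-12)
  expect_equal(len(tr, "D"), 4, tolerance = 1e-12)
})

test_that("a fully symmetric 3-taxon matrix gives a star with unit branches", {
  d <- matrix(2, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  diag(d) <- 0
  tr <- bionj_tree(d)
  expect_equal(sort(tr$edge.length), c(1, 1, 1))
})

test_that("BioNJ agrees with independent NJ/BioNJ implementations on random matrices", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    ad <- random_additive(n)
    # noisy, generic matrix: ties have measure zero
    d <- ad$d + matrix(stats::runif(n * n, 0, 0.01), n, n)
    d <- (d + t(d)) / 2; diag(d) <- 0
    mine <- bionj_tree(d)
    # ape's compiled BioNJ is the independent cross-check for the topology;
    # branch lengths on non-additive input differ at the 1e-4 level between
    # BioNJ implementations (negative-length handling), so exact length
    # checks live in the additive-recovery tests
    theirs <- ape::bionj(as.dist(d))
    expect_true(same_topology(mine, theirs))
    # classical NJ recovers the same topology on near-additive data
    expect_true(same_topology(mine, ape::nj(as.dist(d))))
  }
})

test_that("UPGMA recovers ultrametric data and handles two taxa", {
  # ultrametric: ((a:1,b:1):1,(c:1.5,d:1.5):0.5) root height 2
  d <- matrix(c(0, 2, 4, 4,
                2, 0, 4, 4,
                4, 4, 0, 3,
                4, 4, 3, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- upgma_tree(d)
  co <- ape::cophenetic.phylo(tr)[letters[1:4], letters[1:4]]
  expect_equal(co, d, tolerance = 1e-12)
  d2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  t2 <- upgma_tree(d2)
  expect_equal(sort(t2$edge.length), c(1.5, 1.5))
})

test_that("reference rooting is idempotent, keeps the leaf set, and demands the leaf", {
  set.seed(11)
  mat <- rbind(N = rbinom(40, 1, .3), T1 = rbinom(40, 1, .5),
               T2 = rbinom(40, 1, .5), T3 = rbinom(40, 1, .5))
  storage.mode(mat) <- "integer"
  mat <- mat[, colSums(mat) > 0]
  mm <- add_reference_row(make_mmat(mat))
  tr <- bionj_tree(binary_distance(mm))
  r1 <- root_with_reference(tr)
  expect_true(ape::is.rooted(r1))
  expect_setequal(r1$tip.label, tr$tip.label)
  r2 <- root_with_reference(r1)
  expect_true(same_topology(r1, r2))
  tr2 <- tr; tr2$tip.label[tr2$tip.label == "reference"] <- "ref"
  expect_error(root_with_reference(tr2), "reference")
})

test_that("bootstrap support is deterministic under a fixed seed and order-invariant", {
  set.seed(3)
  mat <- rbind(N = rbinom(30, 1, .2), T1 = rbinom(30, 1, .6),
               T2 = rbinom(30, 1, .6), T3 = rbinom(30, 1, .6))
  storage.mode(mat) <- "integer"
  mat <- mat[, colSums(mat) > 0]
  mm <- add_reference_row(make_mmat(mat))
  b1 <- bootstrap_support(mm, reps = 50, seed = 99)
  b2 <- bootstrap_support(mm, reps = 50, seed = 99)
  expect_identical(b1$splits, b2$splits)
  # column order must not matter beyond resampling noise
  perm <- mm
  set.seed(1); idx <- sample(ncol(mm$mat))
  perm$mat <- perm$mat[, idx]
  perm$info <- perm$info[idx, ]
  b4 <- bootstrap_support(mm, reps = 600, seed = 99)
  b3 <- bootstrap_support(perm, reps = 600, seed = 99)
  m <- match(b4$splits$split, b3$splits$split)
  expect_false(any(is.na(m)))
  expect_true(all(abs(b4$splits$support - b3$splits$support[m]) <= 7))
  expect_error(bootstrap_support(mm, reps = 0), "reps")
})

test_that("trunk-only signal gives 100% tumour-clade support; a single repeated column gives 0/100 supports", {
  # every variable column supports tumours vs (normal, reference)
  trunk <- matrix(1L, 3, 20)
  mat <- rbind(N = rep(0L, 20), trunk)
  rownames(mat) <- c("N", "T1", "T2", "T3")
  mm <- add_reference_row(make_mmat(mat))
  bs <- bootstrap_support(mm, reps = 200, seed = 5)
  rooted <- root_with_reference(bs$tree)
  mono <- tumour_monophyly(rooted, mm$roles, bs$splits)
  expect_true(mono$monophyletic)
  expect_equal(mono$support, 100)

  one <- mat[, 1, drop = FALSE][, rep(1, 5)]
  mm1 <- add_reference_row(make_mmat(one))
  bs1 <- bootstrap_support(mm1, reps = 50, seed = 5)
  expect_true(all(bs1$splits$support %in% c(0, 100)))
})

test_that("monophyly verdicts and clade supports follow the tree", {
  roles <- c(test_roles, reference = "reference")
  tr <- ape::read.tree(text = "(((T1:1,T2:1):1,T3:2):3,N:1,reference:5);")
  rooted <- root_with_reference(tr)
  mono <- tumour_monophyly(rooted, roles)
  expect_true(mono$monophyletic)
  tr2 <- ape::read.tree(text = "(((T1:1,N:1):1,T2:2,T3:2):3,reference:5);")
  mono2 <- tumour_monophyly(root_with_reference(tr2), roles)
  expect_false(mono2$monophyletic)
  expect_true(mono2$flagged)
  expect_true(all(c("T1", "T2", "T3", "N") %in% mono2$clade))
  # two sister tumours are monophyletic
  roles2 <- c(N = "normal", T1 = "tumour", T2 = "tumour",
              reference = "reference")
  tr3 <- ape::read.tree(text = "((T1:1,T2:1):2,N:1,reference:4);")
  expect_true(tumour_monophyly(root_with_reference(tr3), roles2)$monophyletic)
})

test_that("contamination criteria fire on nested normals, long normal branches and low tumour fractions", {
  pc_clean <- list(tumour_associated_fraction = 0.38)
  pc_low <- list(tumour_associated_fraction = 0.15)
  clean <- root_with_reference(ape::read.tree(
    text = "(((T1:4,T2:4):1,T3:5):3,N:1,reference:9);"))
  flag <- flag_normal_contamination(clean, pc_clean, test_roles)
  expect_false(flag$flagged)

  # (a) normal nested inside the tumour clade
  nested <- root_with_reference(ape::read.tree(
    text = "(((T1:4,N:1):1,T2:4,T3:5):3,reference:9);"))
  f_a <- flag_normal_contamination(nested, pc_clean, test_roles)
  expect_true(f_a$criteria[["normal_in_tumour_clade"]])

  # (b) boundary: normal branch exactly equals the shortest tumour branch
  boundary <- root_with_reference(ape::read.tree(
    text = "(((T1:4,T2:4):1,T3:5):3,N:4,reference:9);"))
  f_b <- flag_normal_contamination(boundary, pc_clean, test_roles)
  expect_true(f_b$criteria[["normal_branch_long"]])
  expect_true(f_b$flagged)

  # (c) low tumour-associated fraction
  f_c <- flag_normal_contamination(clean, pc_low, test_roles)
  expect_true(f_c$criteria[["low_tumour_fraction"]])
})

test_that("patient-3-like contaminated simulations are flagged; clean ones are not", {
  cfg_dirty <- sim_config("clonal", seed = 13, contamination = 0.85)
  ds_dirty <- simulate_dataset(cfg_dirty)
  mm_dirty <- add_reference_row(truth_marker_matrix(ds_dirty$sim))
  pc_dirty <- partition_counts(truth_marker_matrix(ds_dirty$sim))
  tr_dirty <- root_with_reference(bionj_tree(binary_distance(mm_dirty)^2))
  f_dirty <- flag_normal_contamination(tr_dirty, pc_dirty, cfg_dirty$roles)
  expect_true(f_dirty$flagged)
  expect_lt(pc_dirty$tumour_associated_fraction, 0.20)

  cfg_clean <- sim_config("clonal", seed = 13)
  ds_clean <- simulate_dataset(cfg_clean)
  mm_clean <- add_reference_row(truth_marker_matrix(ds_clean$sim))
  pc_clean <- partition_counts(truth_marker_matrix(ds_clean$sim))
  tr_clean <- root_with_reference(bionj_tree(binary_distance(mm_clean)^2))
  f_clean <- flag_normal_contamination(tr_clean, pc_clean, cfg_clean$roles)
  expect_false(f_clean$flagged)
})
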