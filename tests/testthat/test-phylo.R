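test_that("phylogenetic covariance matrix follows shared path lengths", {
  t2 <- ape::read.tree(text = "(A:1,B:1);")
  t2$root.edge <- NULL
  # two tips joined at the root: independent, unit variance
  C2 <- ape::vcv(t2)
  expect_equal(unname(C2), diag(2), ignore_attr = TRUE)
  C3 <- phylo_vcv(three_tip_tree())
  expect_equal(diag(C3), c(A = 2, B = 2, C = 2))
  expect_equal(C3["A", "B"], 1)
  expect_equal(C3["A", "C"], 0)
  # brute-force path enumeration oracle on a random tree
  tr <- gen_tree(20L, seed = 13)
  C <- phylo_vcv(tr)
  depth <- ape::node.depth.edgelength(tr)
  d <- ape::dist.nodes(tr)
  n <- length(tr$tip.label)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      shared <- (depth[i] + depth[j] - d[i, j]) / 2
      expect_equal(C[i, j], shared, tolerance = 1e-10)
    }
  }
  bad <- tr; bad$edge.length <- NULL
  expect_error(phylo_vcv(bad), "branch lengths")
})

test_that("BM ancestral states match closed forms on two-tip trees", {
  # equal branches: the root is the midpoint
  t_eq <- ape::read.tree(text = "(A:1,B:1);")
  y <- matrix(c(0, 2), 2L, 1L, dimnames = list(c("A", "B"), "x"))
  expect_equal(unname(asr_bm(t_eq, y)["3", "x"]), 1)
  # branches (1, 3), tips (0, 4): inverse-branch-length weighting
  # (0/1 + 4/3) / (1 + 1/3) = 1
  t_uneq <- ape::read.tree(text = "(A:1,B:3);")
  y2 <- matrix(c(0, 4), 2L, 1L, dimnames = list(c("A", "B"), "x"))
  expect_equal(unname(asr_bm(t_uneq, y2)["3", "x"]), 1)
  # constant traits reconstruct as that constant everywhere
  tr <- ape::read.tree(text = "((A:1,B:3):10,C:13);")
  Yc <- matrix(5, 3L, 1L, dimnames = list(c("A", "B", "C"), "x"))
  expect_true(all(abs(asr_bm(tr, Yc) - 5) < 1e-10))
  # unmatched tips error
  expect_error(asr_bm(tr, Yc[1:2, , drop = FALSE]), "missing")
})

test_that("ancestral states agree with an independent implementation", {
  skip_if_not_installed("phytools")
  tr <- gen_tree(25L, seed = 21)
  Y <- simulate_bm(tr, n_traits = 3L, rate = 1, seed = 22)
  anc <- asr_bm(tr, Y)
  for (k in 1:3) {
    ref <- phytools::fastAnc(tr, Y[, k])
    expect_equal(unname(anc[, k]), unname(ref), tolerance = 1e-6)
  }
  # per-trait reconstruction equals the multivariate call column-by-column
  expect_equal(asr_bm(tr, Y[, 1L, drop = FALSE])[, 1L], anc[, 1L])
})

test_that("phylomorphospace projects tips, ancestors and unplaced taxa", {
  cfg <- sim_config(n_taxa = 20L, seed = 30L)
  ws <- gen_wing_set(cfg)
  cm <- t(vapply(ws$outlines, function(o) {
    efa_as_vector(efa_normalize(efa_forward(resample_equal_arclength(o, 150L), 9L)))
  }, numeric(36L)))
  sp <- fit_shape_space(cm)
  tr <- gen_tree(12L, seed = 31) # tips t001..t012: subset of the 20 taxa
  pm <- phylomorphospace(tr, cm, sp)
  expect_equal(nrow(pm$edges), nrow(tr$edge))
  expect_equal(sum(pm$points$type == "tip"), 12L)
  expect_equal(sum(pm$points$type == "internal"), tr$Nnode)
  expect_equal(sum(pm$points$type == "unplaced"), 8L)
  # linearity: projecting reconstructed coefficients equals reconstructing
  # in score space (both maps are affine/linear)
  anc_scores <- project(asr_bm(tr, cm[tr$tip.label, ]), sp)
  direct <- asr_bm(tr, project(cm[tr$tip.label, ], sp)[, 1:2])
  expect_equal(unname(anc_scores[, 1:2]), unname(direct), tolerance = 1e-8)
})

test_that("a star tree with equal depths projects its root to the trait mean", {
  tr <- star_tree(10L, depth = 1)
  cfg <- sim_config(n_taxa = 10L, seed = 33L)
  ws <- gen_wing_set(cfg)
  cm <- t(vapply(ws$outlines, function(o) {
    efa_as_vector(efa_normalize(efa_forward(resample_equal_arclength(o, 150L), 9L)))
  }, numeric(36L)))
  sp <- fit_shape_space(cm)
  pm <- phylomorphospace(tr, cm, sp)
  root <- pm$points[pm$points$node_id == 11L & pm$points$type == "internal", ]
  # scores are centred, so the root (= plain mean on a star tree) sits at 0
  expect_equal(c(root$pc1, root$pc2), colMeans(sp$scores[, 1:2]),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("K_mult is exactly 1 on equal-depth star trees", {
  tr <- star_tree(16L, depth = 2)
  set.seed(40)
  Y <- matrix(stats::rnorm(16L * 5L), 16L,
              dimnames = list(tr$tip.label, NULL))
  ks <- kmult(tr, Y, n_iterations = 0L)
  expect_equal(ks$K, 1, tolerance = 1e-10)
})

test_that("K_mult calibrates to 1 under BM and detects destroyed signal", {
  tr <- gen_tree(48L, seed = 41)
  K_bm <- vapply(1:40, function(i) {
    kmult(tr, simulate_bm(tr, 4L, 1, seed = 100 + i), n_iterations = 0L)$K
  }, numeric(1L))
  expect_equal(mean(K_bm), 1, tolerance = 0.12)
  # shuffling tips destroys signal: K drops and p becomes non-significant
  Y <- simulate_bm(tr, 4L, 1, seed = 999)
  Yshuf <- Y[wingscape:::.with_seed(7, sample.int(nrow(Y))), , drop = FALSE]
  rownames(Yshuf) <- rownames(Y)
  ks <- kmult(tr, Yshuf, n_iterations = 499L, seed = 8)
  expect_lt(ks$K, 1)
  expect_gt(ks$p_value, 0.05)
  # structured data on the true tree is significant at the permutation floor
  ks2 <- kmult(tr, Y, n_iterations = 499L, seed = 8)
  expect_gte(ks2$p_value, 1 / 500)
  expect_lt(ks2$p_value, 0.05)
})

test_that("K_mult is invariant to branch scaling and trait rotation; deterministic by seed", {
  tr <- gen_tree(20L, seed = 50)
  Y <- simulate_bm(tr, 3L, 1, seed = 51)
  k1 <- kmult(tr, Y, n_iterations = 99L, seed = 5)
  tr2 <- tr; tr2$edge.length <- tr$edge.length * 7.3
  k2 <- kmult(tr2, Y, n_iterations = 99L, seed = 5)
  expect_equal(k2$K, k1$K, tolerance = 1e-10)
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3L)))
  YQ <- Y %*% Q
  rownames(YQ) <- rownames(Y)
  k3 <- kmult(tr, YQ, n_iterations = 99L, seed = 5)
  expect_equal(k3$K, k1$K, tolerance = 1e-10)
  expect_identical(k1$p_value, kmult(tr, Y, n_iterations = 99L, seed = 5)$p_value)
  expect_error(kmult(tr, Y * 0), "zero")
})
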