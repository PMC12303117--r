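test_that("wing parameter bounds are enforced with the field named", {
  expect_error(wing_params(span = -1), "span")
  expect_error(wing_params(base_width_frac = 1.2), "base_width_frac")
  expect_error(wing_params(tip_roundness = 0), "tip_roundness")
  expect_error(wing_params(camber_asym = 0.7), "camber_asym")
  expect_error(gen_wing_outline(wing_params(), n_points = 16L), "n_points")
})

test_that("generated outlines are simple, smooth, reproducible and oriented", {
  set.seed(3)
  for (i in 1:20) {
    p <- wing_params(base_width_frac = stats::runif(1, 0.08, 0.6),
                     tip_width_frac = stats::runif(1, 0.08, 0.6),
                     tip_roundness = stats::runif(1, 0.4, 2.5),
                     camber_asym = stats::runif(1, -0.3, 0.3))
    o <- gen_wing_outline(p, 200L, seed = i, noise_sd = 0.01)
    expect_false(is_self_intersecting(o))
    expect_equal(which.min(o$vertices[, 1L]), 1L) # base at min x, first vertex
    expect_gt(wingscape:::signed_area(o$vertices), 0)
  }
  a <- gen_wing_outline(wing_params(), 200L, seed = 7, noise_sd = 0.02)
  b <- gen_wing_outline(wing_params(), 200L, seed = 7, noise_sd = 0.02)
  expect_identical(a$vertices, b$vertices)
  c2 <- gen_wing_outline(wing_params(), 200L, seed = 8, noise_sd = 0.02)
  expect_false(isTRUE(all.equal(a$vertices, c2$vertices)))
})

test_that("equal base and tip widths with no camber give a symmetric planform", {
  o <- gen_wing_outline(wing_params(base_width_frac = 0.3, tip_width_frac = 0.3,
                                    camber_asym = 0), 200L)
  v <- o$vertices
  mid <- (min(v[, 1L]) + max(v[, 1L])) / 2
  mirrored <- outline(cbind(2 * mid - v[, 1L], v[, 2L]))
  r1 <- resample_equal_arclength(o, 200L)
  r2 <- resample_equal_arclength(mirrored, 200L)
  # same shape after mirroring about the mid-span vertical axis
  expect_equal(sort(r1$vertices[, 2L]), sort(r2$vertices[, 2L]), tolerance = 1e-6)
  expect_equal(polygon_area(r1), polygon_area(r2), tolerance = 1e-9)
})

test_that("tip-heavy wings have a larger radius of second moment than base-heavy ones", {
  tipheavy <- gen_wing_outline(wing_params(base_width_frac = 0.12,
                                           tip_width_frac = 0.5), 200L)
  baseheavy <- gen_wing_outline(wing_params(base_width_frac = 0.5,
                                            tip_width_frac = 0.12), 200L)
  expect_gt(radius_second_moment(tipheavy), radius_second_moment(baseheavy))
})

test_that("gen_wing_set returns ground truth that downstream OLS recovers", {
  expect_error(sim_config(n_taxa = 2L), "n_taxa")
  cfg <- sim_config(n_taxa = 200L, seed = 5,
                    covariate_effects = list(mat = list(axis = 1L, slope = 1.0)),
                    noise_sd = 0.05)
  ws <- gen_wing_set(cfg)
  expect_length(ws$outlines, 200L)
  expect_equal(ws$covariates$taxon, ws$truth$taxon)
  # configured slope 1.0 on latent axis 1 is recovered within 10%
  fit <- ols(ws$covariates$mat, ws$truth$latent1)
  expect_equal(fit$slope, 1.0, tolerance = 0.1)
  # zero slope and zero noise gives a zero covariate
  cfg0 <- sim_config(n_taxa = 50L, seed = 6,
                     covariate_effects = list(mar = list(axis = 2L, slope = 0)),
                     noise_sd = 0)
  ws0 <- gen_wing_set(cfg0)
  expect_true(all(ws0$covariates$mar == 0))
})

test_that("generator latent axes are recoverable by the pipeline's own PCA", {
  cfg <- sim_config(n_taxa = 100L, seed = 9, noise_sd = 0)
  ws <- gen_wing_set(cfg)
  cm <- t(vapply(ws$outlines, function(o) {
    efa_as_vector(efa_normalize(efa_forward(resample_equal_arclength(o, 150L), 9L)))
  }, numeric(36L)))
  sp <- fit_shape_space(cm)
  r <- stats::cor(sp$scores[, 1:2], cbind(ws$truth$latent1, ws$truth$latent2))
  # each latent axis loads strongly on one of the first two PCs
  expect_gt(max(abs(r[, 1L])), 0.9)
  expect_gt(max(abs(r[, 2L])), 0.9)
})

test_that("pure-birth trees have the right shape and round-trip through Newick", {
  expect_error(gen_tree(2L), "n_tips")
  t3 <- gen_tree(3L, seed = 1)
  expect_equal(t3$Nnode, 2L)
  expect_equal(nrow(t3$edge), 4L)
  t64 <- gen_tree(64L, seed = 2)
  expect_equal(t64$Nnode, 63L)
  expect_true(all(t64$edge.length > 0))
  expect_identical(ape::write.tree(gen_tree(10L, 3)), ape::write.tree(gen_tree(10L, 3)))
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(t64, f)
  back <- read_newick(f)
  expect_true(ape::all.equal.phylo(back, t64, use.edge.length = FALSE))
  expect_equal(sort(back$edge.length), sort(t64$edge.length), tolerance = 1e-8)
})

test_that("Brownian simulation has the BM variance structure", {
  expect_error(simulate_bm(star_tree(8L), rate = -1), "rate")
  tr <- star_tree(8L, depth = 2)
  z <- simulate_bm(tr, n_traits = 3L, rate = 0, seed = 1)
  expect_true(all(z == 0))
  # star tree: tip states iid N(0, rate * depth); variance grows linearly
  # with depth
  vars <- vapply(c(0.5, 1, 2, 4), function(d) {
    y <- simulate_bm(star_tree(300L, depth = d), n_traits = 4L, rate = 1.5,
                     seed = round(10 * d))
    mean(apply(y, 2L, stats::var))
  }, numeric(1L))
  expect_equal(vars, 1.5 * c(0.5, 1, 2, 4), tolerance = 0.2)
  # reproducible
  expect_identical(simulate_bm(tr, 2L, 1, seed = 4), simulate_bm(tr, 2L, 1, seed = 4))
})
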