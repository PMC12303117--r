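spec3 <- objective_spec(c("AR", "r2hat", "vms"),
                        c("maximize", "maximize", "minimize"))

test_that("dominance follows the at-least-as-good / strictly-better rule", {
  expect_true(dominates(c(5, 0.7, 0.01), c(4, 0.6, 0.02), spec3))
  expect_false(dominates(c(4, 0.6, 0.02), c(5, 0.7, 0.01), spec3))
  expect_false(dominates(c(5, 0.7, 0.01), c(5, 0.7, 0.01), spec3)) # no strict gain
  expect_false(dominates(c(5, 0.5, 0.01), c(4, 0.6, 0.02), spec3)) # mixed
  expect_error(dominates(c(1, NA, 2), c(1, 1, 1), spec3), "missing")
  expect_error(objective_spec(c("a", "b"), "maximize"), "direction")
})

test_that("Goldberg ranks peel fronts and share ranks on ties", {
  chain <- rbind(c(3, 3, 1), c(2, 2, 2), c(1, 1, 3)) # strict dominance chain
  expect_equal(goldberg_ranks(chain, spec3), c(1L, 2L, 3L))
  two <- rbind(c(1, 0, 0), c(0, 1, 0)) # mutually non-dominating
  expect_equal(goldberg_ranks(two, spec3), c(1L, 1L))
  ties <- rbind(c(2, 2, 1), c(2, 2, 1), c(1, 1, 2))
  expect_equal(goldberg_ranks(ties, spec3), c(1L, 1L, 2L))
})

test_that("rank ratios give 1 on the front, 0 when dominated by all, 0.5 mid-chain", {
  chain <- rbind(c(3, 3, 1), c(2, 2, 2), c(1, 1, 3))
  rr <- pareto_rank_ratio(chain, spec3)
  expect_equal(rr$forward_rank, c(1L, 2L, 3L))
  expect_equal(rr$reverse_rank, c(3L, 2L, 1L))
  expect_equal(rr$ratio, c(1, 0.5, 0))
  # single solution and all-identical sets sit on the front
  expect_equal(pareto_rank_ratio(matrix(c(1, 1, 1), 1L), spec3)$ratio, 1)
  same <- matrix(1, 4L, 3L)
  expect_equal(pareto_rank_ratio(same, spec3)$ratio, rep(1, 4L))
})

test_that("ranks match a brute-force peeling oracle on random instances", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(5:40, 1L)
    m <- matrix(stats::rnorm(3L * n), n, 3L)
    m[sample(n, 2L), ] <- m[1L, ] # inject ties
    expect_identical(goldberg_ranks(m, spec3),
                     brute_force_ranks(m, c(TRUE, TRUE, FALSE)),
                     info = sprintf("3-metric instance %d", i))
  }
  spec2 <- objective_spec(c("x", "y"), c("maximize", "minimize"))
  for (i in 1:100) {
    n <- sample(5:40, 1L)
    m <- matrix(stats::rnorm(2L * n), n, 2L)
    expect_identical(goldberg_ranks(m, spec2),
                     brute_force_ranks(m, c(TRUE, FALSE)),
                     info = sprintf("2-metric instance %d", i))
  }
})

test_that("ratios are invariant to monotone transforms of a single metric", {
  set.seed(5)
  m <- matrix(stats::runif(60, 0.1, 2), 20L, 3L)
  base <- pareto_rank_ratio(m, spec3)
  m2 <- m
  m2[, 1L] <- exp(m2[, 1L])       # monotone on a maximized metric
  m2[, 3L] <- log(m2[, 3L] + 1)   # monotone on a minimized metric
  expect_equal(pareto_rank_ratio(m2, spec3), base)
})

test_that("adding or removing dominated solutions preserves structure", {
  set.seed(6)
  m <- matrix(stats::runif(30), 10L, 3L)
  f <- goldberg_ranks(m, spec3)
  # removing a maximally-dominated solution never decreases remaining ranks
  worst <- which.max(f)
  f2 <- goldberg_ranks(m[-worst, , drop = FALSE], spec3)
  expect_true(all(f2 <= f[-worst]))
  # appending a universally dominated solution keeps the existing order
  sink <- c(min(m[, 1L]) - 1, min(m[, 2L]) - 1, max(m[, 3L]) + 1)
  r_before <- pareto_rank_ratio(m, spec3)$ratio
  r_after <- pareto_rank_ratio(rbind(m, sink), spec3)$ratio
  expect_equal(order(r_before), order(r_after[1:10]))
  expect_equal(r_after[11L], 0)
})

test_that("optimality landscape scores viable cells and supports pairwise specs", {
  set.seed(31)
  n <- 60L
  records <- data.frame(cell_id = seq_len(n), pc1 = stats::rnorm(n),
                        pc2 = stats::rnorm(n), viable = rep(c(TRUE, FALSE), c(50L, 10L)))
  records$AR <- NA_real_; records$r2hat <- NA_real_; records$median_vms <- NA_real_
  ok <- records$viable
  records$AR[ok] <- stats::runif(50L, 1, 10)
  records$r2hat[ok] <- stats::runif(50L, 0.4, 0.8)
  records$median_vms[ok] <- stats::runif(50L, 0.01, 0.05)
  opt <- optimality_landscape(records)
  expect_true(all(is.na(opt$cells$ratio[!ok])))
  expect_true(all(opt$cells$ratio[ok] >= 0 & opt$cells$ratio[ok] <= 1))
  expect_true(any(opt$cells$ratio[ok] == 1))
  expect_true(any(opt$cells$ratio[ok] == 0))
  pw <- optimality_landscape(records, pairwise = c("AR", "median_vms"))
  expect_equal(sum(!is.na(pw$cells$ratio)), 50L)
  expect_error(optimality_landscape(records, pairwise = c("AR", "nope")), "not found")
  # when r2hat is collinear with AR the pairwise (AR, vms) trade-off ranks
  # nearly like the three-way one
  rec2 <- records
  rec2$r2hat[ok] <- 0.1 * rec2$AR[ok]
  full <- optimality_landscape(rec2)$cells$ratio[ok]
  pair <- optimality_landscape(rec2, pairwise = c("AR", "median_vms"))$cells$ratio[ok]
  expect_gt(stats::cor(full, pair, method = "spearman"), 0.8)
})
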