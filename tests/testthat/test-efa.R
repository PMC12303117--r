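test_that("a circle is described by its first harmonic alone", {
  r <- resample_equal_arclength(circle_outline(2, 1000L), 150L)
  co <- efa_forward(r, 9L)
  h1 <- co$harmonics[1L, ]
  # first harmonic is a circle of radius ~2 up to phase
  expect_equal(sqrt(h1["a"]^2 + h1["b"]^2), 2, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(sqrt(h1["c"]^2 + h1["d"]^2), 2, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_lt(max(abs(co$harmonics[-1L, ])), 1e-3 * 2)
  cn <- efa_normalize(co)
  expect_equal(abs(cn$harmonics[1L, "d"]), 1, tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(harmonic_power(co)[1L], 1, tolerance = 1e-6)
})

test_that("an ellipse is recovered by the decomposition with a dominant first harmonic", {
  # under the chord-length parameterisation an ellipse is not a single
  # harmonic (that holds only for the elliptic-angle parameterisation), but
  # the first harmonic carries almost all power and the full reconstruction
  # recovers the analytic semi-axes
  r <- resample_equal_arclength(ellipse_outline(2, 1, 2000L), 300L)
  co <- efa_forward(r, 9L)
  expect_gt(harmonic_power(co)[1L], 0.99)
  rec <- efa_inverse(co, 720L)$vertices
  expect_equal(diff(range(rec[, 1L])) / 2, 2, tolerance = 0.01)
  expect_equal(diff(range(rec[, 2L])) / 2, 1, tolerance = 0.01)
  # even harmonics vanish for a centrally symmetric outline
  expect_lt(max(abs(co$harmonics[c(2L, 4L, 6L, 8L), ])), 1e-3)
})

test_that("normalization pins a1, b1, c1 exactly and H out of range errors", {
  w <- resample_equal_arclength(std_wing(), 150L)
  cn <- efa_normalize(efa_forward(w, 9L))
  expect_identical(unname(cn$harmonics[1L, 1:3]), c(1, 0, 0))
  # 4H - 3 free coefficients: 33 at H = 9
  expect_equal(4L * 9L - 3L, 33L)
  expect_error(efa_forward(w, 150L), "out of range")
  expect_error(efa_forward(w, 0L), "H")
})

test_that("normalized coefficients are invariant to similarity transforms and start vertex", {
  w <- resample_equal_arclength(std_wing(tip_width_frac = 0.4), 150L)
  ref <- efa_normalize(efa_forward(w, 9L))
  v <- w$vertices
  set.seed(11)
  for (i in 1:5) {
    th <- stats::runif(1, 0, 2 * pi)
    sc <- stats::runif(1, 0.2, 5)
    shift <- stats::rnorm(2, 0, 10)
    start <- sample(nrow(v), 1L)
    v2 <- sc * v %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
    v2 <- sweep(v2, 2L, shift, "+")
    v2 <- v2[c(start:nrow(v2), seq_len(start - 1L)), ]
    cn2 <- efa_normalize(efa_forward(resample_equal_arclength(outline(v2), 150L), 9L))
    # agreement up to the documented 180-degree branch ambiguity, under which
    # every even harmonic changes sign
    flip <- cn2$harmonics
    flip[c(2L, 4L, 6L, 8L), ] <- -flip[c(2L, 4L, 6L, 8L), ]
    err <- min(max(abs(cn2$harmonics - ref$harmonics)),
               max(abs(flip - ref$harmonics)))
    expect_lt(err, 1e-4)
  }
})

test_that("forward and inverse transforms round-trip", {
  # the truncated series is re-parameterised by chord length on each forward
  # pass, so coefficients drift slightly at each round trip; the drift is
  # small relative to the coefficients and contracts with further trips
  w <- resample_equal_arclength(std_wing(camber_asym = 0.15), 150L)
  cn <- efa_normalize(efa_forward(w, 9L))
  rec <- efa_inverse(cn, 150L)
  rt <- efa_normalize(efa_forward(rec, 9L))
  d1 <- max(abs(rt$harmonics - cn$harmonics))
  expect_lt(d1, 5e-3)
  # pointwise shape error of the raw reconstruction is below 0.5% of span
  raw <- efa_inverse(efa_forward(w, 9L), 150L)
  span <- diff(range(w$vertices[, 1L]))
  gap <- mean(sqrt(rowSums((raw$vertices - w$vertices)^2))) / span
  expect_lt(gap, 0.005)
  rt2 <- efa_normalize(efa_forward(efa_inverse(rt, 150L), 9L))
  d2 <- max(abs(rt2$harmonics - rt$harmonics))
  expect_lt(d2, d1)
})

test_that("reconstruction error shrinks as harmonics are added", {
  w <- resample_equal_arclength(std_wing(tip_roundness = 0.6, camber_asym = 0.2), 200L)
  err <- vapply(c(2L, 4L, 8L, 16L), function(H) {
    rec <- efa_inverse(efa_forward(w, H), 200L)
    span <- diff(range(w$vertices[, 1L]))
    mean(sqrt(rowSums((rec$vertices - w$vertices)^2))) / span
  }, numeric(1L))
  expect_true(all(diff(err) <= 1e-12))
  expect_lt(err[3L], 0.005) # < 0.5% of span at H >= 8
})

test_that("harmonic power fractions are non-decreasing and smooth wings need few harmonics", {
  w <- resample_equal_arclength(std_wing(), 150L)
  pow <- harmonic_power(efa_forward(w, 20L))
  expect_true(all(diff(pow) >= 0))
  expect_equal(pow[length(pow)], 1)
  expect_gt(harmonic_sufficiency(std_wing(), 9L), 0.995)
})

test_that("coefficient vectors round-trip through the flat layout", {
  cn <- efa_normalize(efa_forward(resample_equal_arclength(std_wing(), 150L), 9L))
  v <- efa_as_vector(cn)
  expect_length(v, 36L)
  expect_named(v[1:4], c("a1", "b1", "c1", "d1"))
  back <- efa_from_vector(v)
  expect_equal(back$harmonics, cn$harmonics, ignore_attr = TRUE)
})
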