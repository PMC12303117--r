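#' Elliptical Fourier decomposition of a closed outline
#'
#' Decomposes a closed outline, parameterised by cumulative chord length, into
#' `H` elliptical harmonics. Each harmonic is an ellipse described by four
#' coefficients (a, b for x; c, d for y); the constant offset terms hold the
#' curve centroid. Coefficients are exact for the piecewise-linear curve
#' through the input vertices.
#'
#' @param x An [outline], normally resampled to equal arc length
#'   (see [resample_equal_arclength]).
#' @param H Number of harmonics (1 <= H <= floor(P/2) - 1 for P vertices).
#' @return An object of class `"efa_coefficients"`: list with `harmonics`
#'   (H x 4 matrix, columns a, b, c, d), `offset` (A0, C0), `perimeter`,
#'   and `normalized = FALSE`.
#' @export
efa_forward <- function(x, H = 9L) {
  v <- as_outline(x)$vertices
  P <- nrow(v)
  if (H < 1L) stop("H must be at least 1")
  if (H > floor(P / 2) - 1L) {
    stop(sprintf("H = %d out of range for %d points (max %d)", H, P,
                 floor(P / 2) - 1L))
  }
  vc <- rbind(v, v[1L, ])
  dx <- diff(vc[, 1L]); dy <- diff(vc[, 2L])
  dt <- sqrt(dx^2 + dy^2)
  t1 <- cumsum(dt)
  t0 <- c(0, t1[-P])
  Tt <- t1[P]
  harm <- matrix(0, H, 4L, dimnames = list(NULL, c("a", "b", "c", "d")))
  for (n in seq_len(H)) {
    w <- Tt / (2 * n^2 * pi^2)
    cs <- cos(2 * pi * n * t1 / Tt) - cos(2 * pi * n * t0 / Tt)
    sn <- sin(2 * pi * n * t1 / Tt) - sin(2 * pi * n * t0 / Tt)
    harm[n, ] <- w * c(sum(dx / dt * cs), sum(dx / dt * sn),
                       sum(dy / dt * cs), sum(dy / dt * sn))
  }
  # offsets = arc-length mean of the piecewise-linear curve
  A0 <- sum(dt * (vc[-(P + 1L), 1L] + vc[-1L, 1L]) / 2) / Tt
  C0 <- sum(dt * (vc[-(P + 1L), 2L] + vc[-1L, 2L]) / 2) / Tt
  structure(list(harmonics = harm, offset = c(A0 = A0, C0 = C0),
                 perimeter = Tt, normalized = FALSE),
            class = "efa_coefficients")
}

#' @export
print.efa_coefficients <- function(x, ...) {
  cat(sprintf("EFA coefficients: %d harmonics, %s\n", nrow(x$harmonics),
              if (isTRUE(x$normalized)) "normalized" else "raw"))
  invisible(x)
}

# rotate the per-harmonic coefficient matrices for a starting-phase shift
# theta and a spatial rotation psi; scale by 1/E.
.efa_transform <- function(harm, theta, psi, E) {
  H <- nrow(harm)
  out <- harm
  Rpsi <- matrix(c(cos(psi), -sin(psi), sin(psi), cos(psi)), 2L, 2L,
                 byrow = TRUE)
  for (n in seq_len(H)) {
    M <- matrix(harm[n, ], 2L, 2L, byrow = TRUE) # [a b; c d]
    Pn <- matrix(c(cos(n * theta), -sin(n * theta),
                   sin(n * theta), cos(n * theta)), 2L, 2L, byrow = TRUE)
    out[n, ] <- t(Rpsi %*% M %*% Pn) / E
  }
  out
}

#' Normalise elliptical Fourier coefficients
#'
#' Removes size, rotation, translation and starting-point phase using the
#' first-harmonic ellipse: size is divided out by the semi-major axis length,
#' the starting phase is shifted to the semi-major axis, and the shape is
#' rotated so the semi-major axis lies along +x. The result satisfies
#' a1 = 1, b1 = 0, c1 = 0 exactly, leaving 4H - 3 free values (33 at H = 9);
#' the offset is zeroed.
#'
#' The 180-degree ambiguity of the first-harmonic axes is resolved by keeping
#' the input's starting vertex nearest parameter 0: outlines prepared by
#' [resample_equal_arclength] start at the wing base (minimum-x extreme), so
#' the base consistently maps to parameter 0 across a data set. Selecting the
#' opposite branch would flip the sign of every even harmonic. Orientation
#' (counter-clockwise input) is preserved, so d1 keeps its sign.
#'
#' @param coeffs An unnormalised `"efa_coefficients"` object.
#' @return A normalised `"efa_coefficients"` object.
#' @export
efa_normalize <- function(coeffs) {
  if (!inherits(coeffs, "efa_coefficients")) stop("not efa_coefficients")
  if (isTRUE(coeffs$normalized)) return(coeffs)
  h1 <- coeffs$harmonics[1L, ]
  a1 <- h1[1L]; b1 <- h1[2L]; c1 <- h1[3L]; d1 <- h1[4L]
  if (sqrt(a1^2 + b1^2 + c1^2 + d1^2) < 1e-12) {
    stop("degenerate first harmonic: cannot normalize")
  }
  theta0 <- 0.5 * atan2(2 * (a1 * b1 + c1 * d1),
                        a1^2 + c1^2 - b1^2 - d1^2)
  # the two candidate phase shifts differ by pi (opposite ends of the
  # first-harmonic major axis); keep the one that moves the starting material
  # point -- the wing base under the standard orientation convention -- the
  # least, so the base stays at parameter 0. The rejected branch would flip
  # the sign of every even harmonic.
  dist0 <- function(th) abs(((th + pi) %% (2 * pi)) - pi)
  cands <- c(theta0, theta0 + pi)
  theta <- cands[which.min(vapply(cands, dist0, numeric(1L)))]
  ast <- a1 * cos(theta) + b1 * sin(theta)
  cst <- c1 * cos(theta) + d1 * sin(theta)
  E <- sqrt(ast^2 + cst^2)
  if (E < 1e-12) stop("degenerate first harmonic: zero semi-major axis")
  psi <- atan2(cst, ast)
  harm <- .efa_transform(coeffs$harmonics, theta, -psi, E)
  best <- structure(list(harmonics = harm, offset = c(A0 = 0, C0 = 0),
                         perimeter = 1, normalized = TRUE),
                    class = "efa_coefficients")
  # pin the constrained coefficients exactly (they are zero/one up to
  # floating-point noise by construction)
  stopifnot(max(abs(best$harmonics[1L, 1:3] - c(1, 0, 0))) < 1e-8)
  best$harmonics[1L, 1:3] <- c(1, 0, 0)
  best
}

#' Reconstruct an outline from elliptical Fourier coefficients
#'
#' Evaluates the truncated Fourier series at `P` uniform parameter steps.
#'
#' @param coeffs An `"efa_coefficients"` object (raw or normalised).
#' @param P Number of points (>= 8; default 150).
#' @return A resampled [outline] with `P` vertices (not re-oriented: the
#'   series is evaluated as-is so coefficients round-trip).
#' @export
efa_inverse <- function(coeffs, P = 150L) {
  if (!inherits(coeffs, "efa_coefficients")) stop("not efa_coefficients")
  if (P < 8L) stop("P must be at least 8")
  H <- nrow(coeffs$harmonics)
  s <- (seq_len(P) - 1L) / P
  xs <- rep(coeffs$offset[1L], P)
  ys <- rep(coeffs$offset[2L], P)
  for (n in seq_len(H)) {
    cn <- cos(2 * pi * n * s); sn <- sin(2 * pi * n * s)
    xs <- xs + coeffs$harmonics[n, 1L] * cn + coeffs$harmonics[n, 2L] * sn
    ys <- ys + coeffs$harmonics[n, 3L] * cn + coeffs$harmonics[n, 4L] * sn
  }
  res <- outline(xs, ys)
  class(res) <- c("resampled_outline", "outline")
  res
}

#' Harmonic power spectrum
#'
#' Power of harmonic n is (a_n^2 + b_n^2 + c_n^2 + d_n^2) / 2. Returns the
#' cumulative fraction of total power per harmonic; by default the total is
#' over the coefficients supplied (so the last entry is 1). Supply
#' `total_power` to express the fractions relative to a richer reference
#' decomposition.
#'
#' @param coeffs An `"efa_coefficients"` object.
#' @param total_power Optional denominator overriding the object's own total.
#' @return Numeric vector of cumulative power fractions, one per harmonic.
#' @export
harmonic_power <- function(coeffs, total_power = NULL) {
  if (!inherits(coeffs, "efa_coefficients")) stop("not efa_coefficients")
  p <- rowSums(coeffs$harmonics^2) / 2
  if (is.null(total_power)) total_power <- sum(p)
  cumsum(p) / total_power
}

#' Harmonic sufficiency of a truncated decomposition
#'
#' Fraction of the power of a high-order reference decomposition
#' (H_ref = floor(P/2) - 1) captured by the first `H` harmonics of an outline.
#' Used to validate that a chosen harmonic count (default 9) describes smooth
#' wing outlines essentially completely.
#'
#' @param x An [outline]; resampled internally to `P` points.
#' @param H Harmonic count under validation (default 9).
#' @param P Resampling point count (default 150).
#' @return Scalar in (0, 1]: cumulative power fraction of harmonics 1..H
#'   relative to the reference decomposition.
#' @export
harmonic_sufficiency <- function(x, H = 9L, P = 150L) {
  r <- resample_equal_arclength(as_outline(x), P)
  H_ref <- floor(P / 2) - 1L
  ref <- efa_forward(r, H_ref)
  harmonic_power(ref)[H]
}

#' Flatten coefficients to a named vector
#'
#' Row-major order a1, b1, c1, d1, ..., aH, bH, cH, dH; the layout used by the
#' morphospace PCA and the coefficient CSV writers.
#'
#' @param coeffs An `"efa_coefficients"` object.
#' @return Named numeric vector of length 4H.
#' @export
efa_as_vector <- function(coeffs) {
  H <- nrow(coeffs$harmonics)
  v <- as.vector(t(coeffs$harmonics))
  names(v) <- paste0(rep(c("a", "b", "c", "d"), H),
                     rep(seq_len(H), each = 4L))
  v
}

#' Rebuild a coefficient object from a flat vector
#'
#' Inverse of [efa_as_vector]. The vector is assumed normalised unless stated.
#'
#' @param v Numeric vector of length 4H in a1, b1, c1, d1, ... order.
#' @param normalized Flag recorded on the result (default `TRUE`).
#' @return An `"efa_coefficients"` object with zero offset.
#' @export
efa_from_vector <- function(v, normalized = TRUE) {
  if (length(v) %% 4L != 0L) stop("coefficient vector length must be 4H")
  H <- length(v) / 4L
  harm <- matrix(v, H, 4L, byrow = TRUE,
                 dimnames = list(NULL, c("a", "b", "c", "d")))
  structure(list(harmonics = harm, offset = c(A0 = 0, C0 = 0),
                 perimeter = 1, normalized = normalized),
            class = "efa_coefficients")
}
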