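#' Fit a PCA shape space over normalised EFA coefficients
#'
#' Centred, covariance-based PCA (no per-column rescaling, the standard choice
#' in outline morphometrics) over a shapes x coefficients matrix. Pinned
#' coefficient columns (a1, b1, c1 after normalisation) are constant and
#' contribute zero variance; they are carried through so back-projection
#' returns full-length coefficient vectors.
#'
#' @param coef_matrix Numeric matrix, one row per shape, columns in
#'   [efa_as_vector] order (or a list of `"efa_coefficients"` objects).
#' @return A `"shape_space"` object: `mean_vector`, `components` (orthonormal
#'   loadings in columns), `explained_variance`, `scores`, `sdev`.
#' @export
fit_shape_space <- function(coef_matrix) {
  if (is.list(coef_matrix) && !is.matrix(coef_matrix)) {
    coef_matrix <- do.call(rbind, lapply(coef_matrix, efa_as_vector))
  }
  if (nrow(coef_matrix) < 3L) stop("need at least 3 shapes to fit a shape space")
  pc <- stats::prcomp(coef_matrix, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  structure(list(mean_vector = pc$center,
                 components = pc$rotation,
                 explained_variance = ev / sum(ev),
                 sdev = pc$sdev,
                 scores = pc$x),
            class = "shape_space")
}

#' @export
print.shape_space <- function(x, ...) {
  cat(sprintf("Shape space: %d shapes x %d coefficients; PC1 %.1f%%, PC2 %.1f%% variance\n",
              nrow(x$scores), length(x$mean_vector),
              100 * x$explained_variance[1L], 100 * x$explained_variance[2L]))
  invisible(x)
}

#' Project coefficient vectors into a shape space
#'
#' @param coeffs A coefficient vector, matrix (rows = shapes), or
#'   `"efa_coefficients"` object.
#' @param space A fitted `"shape_space"`.
#' @return Score matrix (shapes x components).
#' @export
project <- function(coeffs, space) {
  if (inherits(coeffs, "efa_coefficients")) coeffs <- efa_as_vector(coeffs)
  if (is.null(dim(coeffs))) coeffs <- matrix(coeffs, nrow = 1L)
  if (ncol(coeffs) != length(space$mean_vector)) {
    stop("coefficient dimension does not match the shape space")
  }
  sweep(coeffs, 2L, space$mean_vector) %*% space$components
}

#' Back-project scores to coefficient vectors
#'
#' Scores on omitted trailing components are taken as zero, so a (PC1, PC2)
#' pair maps to `mean + pc1 * v1 + pc2 * v2`. The pinned normalisation
#' constraints (a1 = 1, b1 = 0, c1 = 0) are re-imposed exactly on the result.
#'
#' @param scores Numeric vector or matrix (rows = shapes) of leading component
#'   scores.
#' @param space A fitted `"shape_space"`.
#' @return Coefficient matrix (shapes x coefficients).
#' @export
backproject <- function(scores, space) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  k <- ncol(scores)
  if (k > ncol(space$components)) stop("more scores than components in the space")
  out <- scores %*% t(space$components[, seq_len(k), drop = FALSE])
  out <- sweep(out, 2L, space$mean_vector, "+")
  pin <- match(c("a1", "b1", "c1"), colnames(out))
  if (!anyNA(pin)) out[, pin] <- rep(c(1, 0, 0), each = nrow(out))
  out
}

#' Build a theoretical morphospace grid
#'
#' Lays a regular `n_cols` x `n_rows` lattice over the empirical (PC1, PC2)
#' score range extended by `border_frac` of each axis's range on each side,
#' back-projects every lattice point to a coefficient vector (all other
#' components zero), reconstructs the outline by inverse EFA at `P` points,
#' and flags geometric viability (absence of self-intersection). Non-viable
#' cells keep their reconstruction for plotting but are excluded from all
#' performance and optimality computations downstream.
#'
#' @param space A fitted `"shape_space"`.
#' @param n_cols,n_rows Lattice size (defaults 26 x 19, i.e. 494 shapes).
#' @param border_frac Border fraction per side (default 0.2).
#' @param P Points per reconstructed outline (default 150).
#' @return A `"theoretical_grid"`: `cells` data.frame (cell_id, col, row, pc1,
#'   pc2, viable), `outlines` list, plus the axis values and parameters.
#' @export
build_theoretical_grid <- function(space, n_cols = 26L, n_rows = 19L,
                                   border_frac = 0.2, P = 150L) {
  if (border_frac < 0) stop("border_frac must be non-negative")
  sc <- space$scores
  r1 <- range(sc[, 1L]); r2 <- range(sc[, 2L])
  if (diff(r1) == 0 || diff(r2) == 0) {
    stop("degenerate (zero-range) empirical axis: cannot build a grid")
  }
  pc1 <- seq(r1[1L] - border_frac * diff(r1), r1[2L] + border_frac * diff(r1),
             length.out = n_cols)
  pc2 <- seq(r2[1L] - border_frac * diff(r2), r2[2L] + border_frac * diff(r2),
             length.out = n_rows)
  cells <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  cells <- data.frame(cell_id = seq_len(nrow(cells)), cells,
                      pc1 = pc1[cells$col], pc2 = pc2[cells$row])
  coefs <- backproject(as.matrix(cells[, c("pc1", "pc2")]), space)
  outlines <- vector("list", nrow(cells))
  viable <- logical(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    o <- efa_inverse(efa_from_vector(coefs[i, ]), P)
    outlines[[i]] <- o
    viable[i] <- !is_self_intersecting(o)
  }
  cells$viable <- viable
  structure(list(cells = cells, outlines = outlines, coefficients = coefs,
                 pc1_values = pc1, pc2_values = pc2,
                 n_cols = n_cols, n_rows = n_rows, border_frac = border_frac,
                 P = P),
            class = "theoretical_grid")
}

#' @export
print.theoretical_grid <- function(x, ...) {
  cat(sprintf("Theoretical grid: %d x %d = %d cells, %d viable (%.1f%%)\n",
              x$n_cols, x$n_rows, nrow(x$cells), sum(x$cells$viable),
              100 * mean(x$cells$viable)))
  invisible(x)
}

#' Morphospace occupation statistics
#'
#' Fraction of grid cells whose cell region (the Voronoi rectangle around the
#' lattice point) contains at least one empirical score, plus the convex-hull
#' area of the scores as a fraction of the total gridded area, optionally per
#' group.
#'
#' @param grid A `"theoretical_grid"`.
#' @param scores Empirical score matrix (columns PC1, PC2) or a
#'   `"shape_space"` (its own scores are used).
#' @param groups Optional factor, one entry per score row, for per-group
#'   convex-hull fractions.
#' @return List with `cell_fraction`, `hull_fraction`, and (if `groups`)
#'   `hull_fraction_by_group`.
#' @export
occupation <- function(grid, scores, groups = NULL) {
  if (inherits(scores, "shape_space")) scores <- scores$scores
  s <- as.matrix(scores[, 1:2, drop = FALSE])
  d1 <- diff(grid$pc1_values[1:2]); d2 <- diff(grid$pc2_values[1:2])
  col <- round((s[, 1L] - grid$pc1_values[1L]) / d1) + 1L
  row <- round((s[, 2L] - grid$pc2_values[1L]) / d2) + 1L
  inside <- col >= 1L & col <= grid$n_cols & row >= 1L & row <= grid$n_rows
  occupied <- unique(paste(col[inside], row[inside]))
  hull_area <- function(p) {
    if (nrow(p) < 3L) return(0)
    h <- grDevices::chull(p)
    abs(signed_area(p[h, , drop = FALSE]))
  }
  total <- diff(range(grid$pc1_values)) * diff(range(grid$pc2_values))
  out <- list(cell_fraction = length(occupied) / nrow(grid$cells),
              hull_fraction = hull_area(s) / total)
  if (!is.null(groups)) {
    out$hull_fraction_by_group <- vapply(split(seq_len(nrow(s)), groups),
                                         function(i) hull_area(s[i, , drop = FALSE]) / total,
                                         numeric(1L))
  }
  out
}

#' Export a theoretical grid to CSV
#'
#' Writes one row per cell: cell_id, col, row, pc1, pc2, viable.
#'
#' @param grid A `"theoretical_grid"`.
#' @param path Output CSV path.
#' @export
write_grid_csv <- function(grid, path) {
  utils::write.csv(grid$cells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
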