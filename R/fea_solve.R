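# --- discrete Kirchhoff triangle (DKT) plate bending --------------------------
#
# Batoz's explicit 9-DOF thin-plate bending element: per node (w, thx, thy)
# with thx = dw/dy and thy = -dw/dx. The H-function derivative arrays below
# are the standard explicit formulation; curvatures are linear within each
# element and integrated with the 3-point mid-side Gauss rule, which is exact
# for the element stiffness.

.dkt_hderiv <- function(xi, eta, P, q, t, r) {
  # returns list(Hx_xi, Hy_xi, Hx_eta, Hy_eta), each length-9
  P4 <- P[1L]; P5 <- P[2L]; P6 <- P[3L]
  q4 <- q[1L]; q5 <- q[2L]; q6 <- q[3L]
  t4 <- t[1L]; t5 <- t[2L]; t6 <- t[3L]
  r4 <- r[1L]; r5 <- r[2L]; r6 <- r[3L]
  Hx_xi <- c(
    P6 * (1 - 2 * xi) + (P5 - P6) * eta,
    q6 * (1 - 2 * xi) - (q5 + q6) * eta,
    -4 + 6 * (xi + eta) + r6 * (1 - 2 * xi) - eta * (r5 + r6),
    -P6 * (1 - 2 * xi) + eta * (P4 + P6),
    q6 * (1 - 2 * xi) - eta * (q6 - q4),
    -2 + 6 * xi + r6 * (1 - 2 * xi) + eta * (r4 - r6),
    -eta * (P5 + P4),
    eta * (q4 - q5),
    -eta * (r5 - r4))
  Hy_xi <- c(
    t6 * (1 - 2 * xi) + eta * (t5 - t6),
    1 + r6 * (1 - 2 * xi) - eta * (r5 + r6),
    -q6 * (1 - 2 * xi) + eta * (q5 + q6),
    -t6 * (1 - 2 * xi) + eta * (t4 + t6),
    -1 + r6 * (1 - 2 * xi) + eta * (r4 - r6),
    -q6 * (1 - 2 * xi) - eta * (q4 - q6),
    -eta * (t4 + t5),
    eta * (r4 - r5),
    -eta * (q4 - q5))
  Hx_eta <- c(
    -P5 * (1 - 2 * eta) - xi * (P6 - P5),
    q5 * (1 - 2 * eta) - xi * (q5 + q6),
    -4 + 6 * (xi + eta) + r5 * (1 - 2 * eta) - xi * (r5 + r6),
    xi * (P4 + P6),
    xi * (q4 - q6),
    -xi * (r6 - r4),
    P5 * (1 - 2 * eta) - xi * (P4 + P5),
    q5 * (1 - 2 * eta) + xi * (q4 - q5),
    -2 + 6 * eta + r5 * (1 - 2 * eta) + xi * (r4 - r5))
  Hy_eta <- c(
    -t5 * (1 - 2 * eta) - xi * (t6 - t5),
    1 + r5 * (1 - 2 * eta) - xi * (r5 + r6),
    -q5 * (1 - 2 * eta) + xi * (q5 + q6),
    xi * (t4 + t6),
    xi * (r4 - r6),
    -xi * (q4 - q6),
    t5 * (1 - 2 * eta) - xi * (t4 + t5),
    -1 + r5 * (1 - 2 * eta) + xi * (r4 - r5),
    -q5 * (1 - 2 * eta) - xi * (q4 - q5))
  list(Hx_xi = Hx_xi, Hy_xi = Hy_xi, Hx_eta = Hx_eta, Hy_eta = Hy_eta)
}

# strain-displacement matrix (3 x 9) at a parametric point of one element
.dkt_B <- function(xi, eta, geom) {
  h <- .dkt_hderiv(xi, eta, geom$P, geom$q, geom$t, geom$r)
  rbind(geom$y31 * h$Hx_xi + geom$y12 * h$Hx_eta,
        -geom$x31 * h$Hy_xi - geom$x12 * h$Hy_eta,
        -geom$x31 * h$Hx_xi - geom$x12 * h$Hx_eta +
          geom$y31 * h$Hy_xi + geom$y12 * h$Hy_eta) / (2 * geom$A)
}

.dkt_geom <- function(xy) {
  x23 <- xy[2L, 1L] - xy[3L, 1L]; y23 <- xy[2L, 2L] - xy[3L, 2L]
  x31 <- xy[3L, 1L] - xy[1L, 1L]; y31 <- xy[3L, 2L] - xy[1L, 2L]
  x12 <- xy[1L, 1L] - xy[2L, 1L]; y12 <- xy[1L, 2L] - xy[2L, 2L]
  A <- (x31 * y12 - x12 * y31) / 2
  L2 <- c(x23^2 + y23^2, x31^2 + y31^2, x12^2 + y12^2) # sides 4, 5, 6
  xs <- c(x23, x31, x12); ys <- c(y23, y31, y12)
  list(x23 = x23, x31 = x31, x12 = x12, y23 = y23, y31 = y31, y12 = y12,
       A = A,
       P = -6 * xs / L2, q = 3 * xs * ys / L2,
       t = -6 * ys / L2, r = 3 * ys^2 / L2)
}

#' Solve thin-plate bending on a wing mesh
#'
#' Linear Kirchhoff plate bending with discrete Kirchhoff triangles: the mesh
#' is clamped (all three DOF zero) at its four base nodes and loaded by a
#' single transverse point force at the tip node. Element top-surface bending
#' stresses are recovered at element centroids and condensed to the von Mises
#' equivalent stress `sqrt(sx^2 + sy^2 - sx*sy + 3*txy^2)`.
#'
#' @param mesh A `"wing_mesh"` from [mesh_outline].
#' @param E Young's modulus (default 1e9, i.e. 1 GPa in SI units).
#' @param nu Poisson's ratio (0 < nu < 0.5; default 0.49).
#' @param thickness Plate thickness (> 0), same length unit as the mesh.
#' @param load Transverse point load at the tip node (default 0.003).
#' @return An `"fea_result"`: `displacement` (n x 3: w, thx, thy),
#'   `element_vms` (per element), `median_vms`, `mean_vms`, `tip_deflection`.
#' @export
solve_plate <- function(mesh, E = 1e9, nu = 0.49, thickness = 0.01,
                        load = 0.003) {
  if (nu <= 0 || nu >= 0.5) stop("nu must lie in (0, 0.5)")
  if (thickness <= 0) stop("thickness must be positive")
  nodes <- mesh$nodes
  tris <- mesh$triangles
  nn <- nrow(nodes)
  ne <- nrow(tris)
  D0 <- E * thickness^3 / (12 * (1 - nu^2))
  Db <- D0 * matrix(c(1, nu, 0, nu, 1, 0, 0, 0, (1 - nu) / 2), 3L, 3L)
  gauss <- list(c(0.5, 0), c(0, 0.5), c(0.5, 0.5))
  ii <- integer(81L * ne); jj <- integer(81L * ne); vv <- numeric(81L * ne)
  geoms <- vector("list", ne)
  pos <- 0L
  for (e in seq_len(ne)) {
    tri <- tris[e, ]
    geom <- .dkt_geom(nodes[tri, , drop = FALSE])
    geoms[[e]] <- geom
    Ke <- matrix(0, 9L, 9L)
    for (g in gauss) {
      B <- .dkt_B(g[1L], g[2L], geom)
      Ke <- Ke + (2 * geom$A / 6) * crossprod(B, Db %*% B)
    }
    dof <- as.vector(rbind(3L * tri - 2L, 3L * tri - 1L, 3L * tri))
    idx <- pos + seq_len(81L)
    ii[idx] <- rep(dof, times = 9L)
    jj[idx] <- rep(dof, each = 9L)
    vv[idx] <- Ke
    pos <- pos + 81L
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(3L * nn, 3L * nn))
  Fv <- numeric(3L * nn)
  Fv[3L * mesh$tip_node - 2L] <- load
  fixed <- as.vector(rbind(3L * mesh$base_nodes - 2L,
                           3L * mesh$base_nodes - 1L,
                           3L * mesh$base_nodes))
  free <- setdiff(seq_len(3L * nn), fixed)
  u <- numeric(3L * nn)
  if (any(Fv != 0)) {
    u[free] <- as.numeric(Matrix::solve(K[free, free], Fv[free]))
  }
  vms <- numeric(ne)
  for (e in seq_len(ne)) {
    dof <- as.vector(rbind(3L * tris[e, ] - 2L, 3L * tris[e, ] - 1L,
                           3L * tris[e, ]))
    kappa <- .dkt_B(1 / 3, 1 / 3, geoms[[e]]) %*% u[dof]
    M <- Db %*% kappa
    s <- 6 * M / thickness^2 # top-surface bending stresses (sx, sy, txy)
    vms[e] <- sqrt(s[1L]^2 + s[2L]^2 - s[1L] * s[2L] + 3 * s[3L]^2)
  }
  disp <- matrix(u, ncol = 3L, byrow = TRUE,
                 dimnames = list(NULL, c("w", "thx", "thy")))
  structure(list(displacement = disp, element_vms = vms,
                 median_vms = stats::median(vms), mean_vms = mean(vms),
                 tip_deflection = unname(disp[mesh$tip_node, "w"]),
                 E = E, nu = nu, thickness = thickness, load = load),
            class = "fea_result")
}

#' @export
print.fea_result <- function(x, ...) {
  cat(sprintf("Plate FEA: %d elements, tip deflection %.4g, median VMS %.4g\n",
              length(x$element_vms), x$tip_deflection, x$median_vms))
  invisible(x)
}

#' Median von Mises stress of a solved model
#'
#' Median over the per-element von Mises stresses (for an even element count,
#' the mean of the two central values).
#'
#' @param result An `"fea_result"` (or a numeric vector of element stresses).
#' @return Scalar median stress.
#' @export
median_vms <- function(result) {
  v <- if (inherits(result, "fea_result")) result$element_vms else result
  stats::median(v)
}

#' Median von Mises stress of a wing outline
#'
#' Convenience wrapper running the full structural scoring of one planform:
#' the shape is rescaled to unit area (all shapes are compared at equal area
#' and thickness, so stress values are relative, not absolute), meshed at
#' `n_target` elements, and solved as a clamped thin plate under a transverse
#' tip load.
#'
#' @param x An [outline].
#' @param n_target Element count (default 2500).
#' @param E,nu,load Material and loading constants (defaults 1 GPa, 0.49,
#'   0.003).
#' @param thickness Plate thickness after unit-area scaling (default 0.01).
#' @param statistic `"median"` (default) or `"mean"` element stress.
#' @return Scalar stress score (solver units).
#' @export
fea_median_vms <- function(x, n_target = 2500L, E = 1e9, nu = 0.49,
                           load = 0.003, thickness = 0.01,
                           statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  x <- as_outline(x)
  v <- x$vertices / sqrt(polygon_area(x)) # unit area
  mesh <- mesh_outline(outline(v), n_target)
  res <- solve_plate(mesh, E = E, nu = nu, thickness = thickness, load = load)
  if (statistic == "median") res$median_vms else res$mean_vms
}
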