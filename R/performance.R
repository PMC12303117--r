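# rotate vertices so the major principal axis of the vertex scatter lies
# along x. The rotation angle is taken in (-pi/2, pi/2], so conventionally
# oriented wings (span along +x) keep their base/tip assignment; shapes with
# degenerate (equal) principal moments are left untouched.
.align_major_axis <- function(v) {
  vc <- sweep(v, 2L, colMeans(v))
  cv <- stats::cov(vc)
  if ((cv[1L, 1L] - cv[2L, 2L])^2 + 4 * cv[1L, 2L]^2 <
      1e-12 * (cv[1L, 1L] + cv[2L, 2L])^2) {
    return(v) # isotropic scatter: no preferred axis
  }
  phi <- 0.5 * atan2(2 * cv[1L, 2L], cv[1L, 1L] - cv[2L, 2L])
  vc %*% matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2L)
}

#' Wing aspect ratio
#'
#' AR = R^2 / S for a single wing planform, with span R the extent along the
#' major principal axis (the x-extent once the planform is aligned span-along-
#' x; small rotations away from the standard orientation are corrected
#' internally) and S the polygon area. A proxy for induced-drag reduction:
#' slender wings score higher.
#'
#' @param x An [outline].
#' @return Aspect ratio (dimensionless, > 0).
#' @export
aspect_ratio <- function(x) {
  x <- orient_standard(as_outline(x))
  v <- .align_major_axis(x$vertices)
  diff(range(v[, 1L]))^2 / polygon_area(x)
}

#' Normalised spanwise chord distribution
#'
#' Slices the oriented planform with vertical lines at the midpoints of
#' `n_stations` equal spanwise intervals. The chord at a station is the total
#' y-extent of the polygon's intersection with the line (summed over pieces if
#' the slice is multiply connected). Chords are normalised as
#' `c_hat = c * R / S`, so the integral of `c_hat` over the non-dimensional
#' span is 1.
#'
#' @param x An [outline].
#' @param n_stations Number of spanwise stations (>= 20; default 200).
#' @return Data frame with `r_hat` (station position, fraction of span) and
#'   `c_hat` (normalised chord).
#' @export
chord_distribution <- function(x, n_stations = 200L) {
  if (n_stations < 20L) stop("n_stations must be at least 20")
  x <- orient_standard(as_outline(x))
  v <- .align_major_axis(x$vertices)
  R <- diff(range(v[, 1L]))
  S <- polygon_area(x)
  x0 <- min(v[, 1L])
  r_hat <- (seq_len(n_stations) - 0.5) / n_stations
  vc <- rbind(v, v[1L, ])
  xa <- vc[-nrow(vc), 1L]; ya <- vc[-nrow(vc), 2L]
  xb <- vc[-1L, 1L]; yb <- vc[-1L, 2L]
  chord <- vapply(r_hat, function(r) {
    xs <- x0 + r * R
    hit <- (xa < xs & xb >= xs) | (xb < xs & xa >= xs)
    if (!any(hit)) {
      warning("station line misses the polygon; chord set to 0")
      return(0)
    }
    ys <- ya[hit] + (xs - xa[hit]) / (xb[hit] - xa[hit]) * (yb[hit] - ya[hit])
    ys <- sort(ys)
    # interior intervals alternate inside/outside for a simple polygon
    sum(ys[seq(2L, length(ys), by = 2L)] - ys[seq(1L, length(ys) - 1L, by = 2L)])
  }, numeric(1L))
  data.frame(r_hat = r_hat, c_hat = chord * R / S)
}

#' Non-dimensional radius of the second moment of area
#'
#' `r2_hat = sqrt( integral of c_hat(r_hat) * r_hat^2 dr_hat )`, integrated by
#' the midpoint rule over the stations of [chord_distribution]. A proxy for
#' aerodynamic lift production in flapping flight: wings with more area in the
#' distal (apical) portion score higher. For any simple planform the value
#' lies strictly between 0 and 1.
#'
#' @inheritParams chord_distribution
#' @return `r2_hat` (dimensionless, in (0, 1)).
#' @export
radius_second_moment <- function(x, n_stations = 200L) {
  cd <- chord_distribution(x, n_stations)
  sqrt(sum(cd$c_hat * cd$r_hat^2) / n_stations)
}

#' Performance landscape over a theoretical grid
#'
#' Evaluates a metric on every viable cell of a theoretical grid and bins the
#' values into 10 equal-interval contour bands between the observed minimum
#' and maximum. Non-viable cells carry `NA`.
#'
#' @param grid A `"theoretical_grid"`.
#' @param metric `"AR"`, `"r2hat"`, or `"median_vms"`; alternatively a numeric
#'   vector of pre-computed per-cell values (NA for non-viable cells).
#' @param n_bands Number of contour bands (default 10).
#' @param n_stations Stations for the chord-based metric (default 200).
#' @param fea_args List of arguments passed to [fea_median_vms] when
#'   `metric = "median_vms"`.
#' @return A `"performance_landscape"`: the grid's `cells` data.frame with
#'   `value` and `band` columns, plus metric metadata.
#' @export
performance_landscape <- function(grid, metric = c("AR", "r2hat", "median_vms"),
                                  n_bands = 10L, n_stations = 200L,
                                  fea_args = list()) {
  cells <- grid$cells
  if (!any(cells$viable)) stop("all grid cells are non-viable")
  if (is.numeric(metric)) {
    value <- metric
    metric_name <- "custom"
    if (length(value) != nrow(cells)) stop("value vector length must equal cell count")
  } else {
    metric_name <- match.arg(metric)
    value <- rep(NA_real_, nrow(cells))
    for (i in which(cells$viable)) {
      o <- grid$outlines[[i]]
      value[i] <- switch(metric_name,
        AR = aspect_ratio(o),
        r2hat = radius_second_moment(o, n_stations),
        median_vms = do.call(fea_median_vms, c(list(o), fea_args)))
    }
  }
  cells$value <- value
  cells$band <- band_assign(value, n_bands)
  structure(list(cells = cells, metric = metric_name, n_bands = n_bands),
            class = "performance_landscape")
}

#' Equal-interval contour band assignment
#'
#' Bins values into `n_bands` equal intervals between their minimum and
#' maximum; the minimum falls in band 1 and the maximum in band `n_bands`.
#' Constant input collapses to a single band.
#'
#' @param value Numeric vector (NA allowed).
#' @param n_bands Number of bands (default 10).
#' @return Integer vector of band indices (NA preserved).
#' @export
band_assign <- function(value, n_bands = 10L) {
  rng <- range(value, na.rm = TRUE)
  if (diff(rng) == 0) {
    return(ifelse(is.na(value), NA_integer_, 1L))
  }
  b <- floor((value - rng[1L]) / diff(rng) * n_bands) + 1L
  pmin(b, n_bands)
}

#' @export
print.performance_landscape <- function(x, ...) {
  ok <- !is.na(x$cells$value)
  cat(sprintf("Performance landscape (%s): %d viable cells, range [%.4g, %.4g]\n",
              x$metric, sum(ok), min(x$cells$value[ok]), max(x$cells$value[ok])))
  invisible(x)
}
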