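#' Parameters of a synthetic wing outline
#'
#' Describes a smooth, closed, wing-like planform: span, the widths of the
#' humeral (base) and apical (tip) regions as fractions of span, a tip
#' roundness exponent, and a leading/trailing-edge asymmetry.
#'
#' @param span Wing length, arbitrary units (> 0).
#' @param base_width_frac Width near the humeral base as a fraction of span,
#'   in (0, 1).
#' @param tip_width_frac Width near the apical tip as a fraction of span,
#'   in (0, 1).
#' @param tip_roundness Shape exponent (> 0); larger values give blunter,
#'   rounder tips, smaller values a more pointed lens.
#' @param camber_asym Leading/trailing asymmetry in [-0.5, 0.5]; 0 gives a
#'   planform symmetric about the chord line.
#' @return A `"wing_params"` list.
#' @export
wing_params <- function(span = 1, base_width_frac = 0.25,
                        tip_width_frac = 0.35, tip_roundness = 1,
                        camber_asym = 0) {
  chk <- function(val, name, lo, hi) {
    if (!is.finite(val) || val <= lo || val >= hi) {
      stop(sprintf("wing parameter '%s' = %g out of bounds (%g, %g)",
                   name, val, lo, hi))
    }
  }
  chk(span, "span", 0, Inf)
  chk(base_width_frac, "base_width_frac", 0, 1)
  chk(tip_width_frac, "tip_width_frac", 0, 1)
  chk(tip_roundness, "tip_roundness", 0, Inf)
  if (!is.finite(camber_asym) || abs(camber_asym) > 0.5) {
    stop("wing parameter 'camber_asym' must lie in [-0.5, 0.5]")
  }
  structure(list(span = span, base_width_frac = base_width_frac,
                 tip_width_frac = tip_width_frac,
                 tip_roundness = tip_roundness, camber_asym = camber_asym),
            class = "wing_params")
}

# smoothstep between base and tip width fractions
.smoothstep <- function(u) u * u * (3 - 2 * u)

#' Generate a smooth wing-like closed outline
#'
#' Builds leading and trailing edges as smooth single-valued curves over the
#' span and joins them at the (closed) base and tip, guaranteeing a simple
#' closed polygon for parameters within the documented bounds. The half-width
#' profile blends the base and tip widths through a smoothstep and is shaped by
#' a lens envelope `(4u(1-u))^r` with `r = 1/(2 * tip_roundness)`, so width
#' vanishes smoothly at both ends. An optional smooth random perturbation
#' (low-order sinusoids, seeded) roughens the edges without breaking
#' simplicity.
#'
#' @param params A [wing_params] object.
#' @param n_points Number of polygon vertices (>= 32; default 200).
#' @param seed Integer seed controlling the perturbation draw.
#' @param noise_sd Amplitude of the smooth edge perturbation as a fraction of
#'   span (default 0: fully deterministic shape).
#' @return An [outline], base at minimum x, span along +x, counter-clockwise.
#' @export
gen_wing_outline <- function(params, n_points = 200L, seed = 1L,
                             noise_sd = 0) {
  if (!inherits(params, "wing_params")) params <- do.call(wing_params, params)
  if (n_points < 32L) stop("n_points must be at least 32")
  m <- ceiling(n_points / 2) + 1L
  # cosine-spaced stations cluster vertices at base and tip where curvature
  # concentrates
  u <- (1 - cos(pi * (seq_len(m) - 1L) / (m - 1L))) / 2
  s <- .smoothstep(u)
  width <- params$base_width_frac * (1 - s) + params$tip_width_frac * s
  r <- 1 / (2 * params$tip_roundness)
  env <- (4 * u * (1 - u))^r
  h <- params$span / 2 * width * env
  asym <- params$camber_asym * sin(pi * u)
  y_up <- h * (1 + asym)
  y_lo <- -h * (1 - asym)
  if (noise_sd > 0) {
    rng <- .with_seed(seed, {
      list(amp = stats::rnorm(6L, 0, noise_sd), ph = stats::runif(6L, 0, 2 * pi))
    })
    bump <- rep(0, m)
    for (k in 1:3) {
      bump <- bump + rng$amp[k] * sin((k + 1) * pi * u + rng$ph[k])
    }
    bump2 <- rep(0, m)
    for (k in 4:6) {
      bump2 <- bump2 + rng$amp[k] * sin((k - 2) * pi * u + rng$ph[k])
    }
    # taper perturbations with the envelope so closure and simplicity hold
    y_up <- y_up + params$span * env * bump
    y_lo <- y_lo + params$span * env * bump2
    inner <- seq_len(m)[-c(1L, m)] # edges coincide at the closed ends
    if (any(y_up[inner] <= y_lo[inner])) { # extreme draw: use clean profile
      y_up <- h * (1 + asym); y_lo <- -h * (1 - asym)
    }
  }
  xs <- params$span * u
  # traverse trailing (lower) edge base -> tip, then leading edge tip -> base;
  # endpoints coincide so drop duplicates at the joins
  px <- c(xs, rev(xs[-c(1L, m)]))
  py <- c(y_lo, rev(y_up[-c(1L, m)]))
  orient_standard(outline(px, py))
}

# evaluate an expression with a local RNG state, restoring the caller's
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Simulation configuration for a synthetic wing study
#'
#' @param n_taxa Number of taxa (>= 3).
#' @param seed Master integer seed; all draws derive from it.
#' @param bm_rate Brownian-motion variance per unit branch length (>= 0).
#' @param covariate_effects Named list mapping a covariate name to
#'   `list(axis = 1 or 2, slope = numeric)`: the covariate equals
#'   `slope * latent_axis + noise`.
#' @param noise_sd Non-phylogenetic residual standard deviation (>= 0).
#' @return A `"sim_config"` list.
#' @export
sim_config <- function(n_taxa = 60L, seed = 1L, bm_rate = 1,
                       covariate_effects = list(
                         mat = list(axis = 1L, slope = 0.5),
                         mar = list(axis = 2L, slope = 0)),
                       noise_sd = 0.1) {
  if (n_taxa < 3L) stop("n_taxa must be at least 3")
  if (bm_rate < 0) stop("bm_rate must be non-negative")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(n_taxa = as.integer(n_taxa), seed = as.integer(seed),
                 bm_rate = bm_rate, covariate_effects = covariate_effects,
                 noise_sd = noise_sd),
            class = "sim_config")
}

# map latent axes to wing parameters. Axis 1 = overall breadth, axis 2 =
# apical-tip size relative to the humeral base; both on roughly unit scale.
.latent_to_params <- function(l1, l2, span = 1) {
  scale <- exp(0.20 * pmax(pmin(l1, 2.5), -2.5))
  ratio <- exp(0.35 * pmax(pmin(l2, 2.5), -2.5))
  base <- pmin(pmax(0.28 * scale / sqrt(ratio), 0.04), 0.9)
  tip <- pmin(pmax(0.34 * scale * sqrt(ratio), 0.04), 0.9)
  wing_params(span = span, base_width_frac = base, tip_width_frac = tip,
              tip_roundness = 1, camber_asym = 0.1)
}

#' Generate a set of synthetic wings with covariates and ground truth
#'
#' Draws two independent standard-normal latent axes per taxon (axis 1:
#' overall breadth; axis 2: apical-tip size relative to the humeral base),
#' builds one wing outline per taxon, and generates covariates linearly
#' related to the latent axes through the configured slopes plus Gaussian
#' noise. Spans are log-normal so centroid size varies across taxa.
#'
#' @param config A [sim_config].
#' @param n_points Vertices per outline (default 200).
#' @return List with `outlines` (list of [outline]), `covariates` (data.frame:
#'   taxon, span, centroid_size, one column per configured covariate) and
#'   `truth` (data.frame of the latent axis values per taxon).
#' @export
gen_wing_set <- function(config, n_points = 200L) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  n <- config$n_taxa
  draws <- .with_seed(config$seed, {
    list(l1 = stats::rnorm(n), l2 = stats::rnorm(n),
         logspan = stats::rnorm(n, 0, 0.25),
         cov_noise = matrix(stats::rnorm(n * max(1L, length(config$covariate_effects)),
                                         0, config$noise_sd), nrow = n))
  })
  taxa <- sprintf("t%03d", seq_len(n))
  outlines <- vector("list", n)
  csize <- numeric(n)
  for (i in seq_len(n)) {
    p <- .latent_to_params(draws$l1[i], draws$l2[i], span = exp(draws$logspan[i]))
    outlines[[i]] <- gen_wing_outline(p, n_points = n_points,
                                      seed = config$seed + i)
    csize[i] <- centroid_size(resample_equal_arclength(outlines[[i]], 150L))
  }
  names(outlines) <- taxa
  covs <- data.frame(taxon = taxa, span = exp(draws$logspan),
                     centroid_size = csize)
  latent <- cbind(draws$l1, draws$l2)
  j <- 0L
  for (nm in names(config$covariate_effects)) {
    j <- j + 1L
    eff <- config$covariate_effects[[nm]]
    covs[[nm]] <- eff$slope * latent[, eff$axis] + draws$cov_noise[, j]
  }
  truth <- data.frame(taxon = taxa, latent1 = draws$l1, latent2 = draws$l2)
  list(outlines = outlines, covariates = covs, truth = truth)
}

#' Simulate a pure-birth phylogeny
#'
#' A rooted binary Yule tree with unit speciation rate; branch lengths are in
#' arbitrary time units and strictly positive. Deterministic given `seed`.
#'
#' @param n_tips Number of tips (>= 3).
#' @param seed Integer seed.
#' @return An [ape::phylo] tree with tip labels `t001`, `t002`, ...
#' @export
gen_tree <- function(n_tips, seed = 1L) {
  if (n_tips < 3L) stop("n_tips must be at least 3")
  tr <- .with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  tr$tip.label <- sprintf("t%03d", seq_len(n_tips))
  tr
}

#' Simulate traits under Brownian motion on a tree
#'
#' Tip values for each trait are drawn from a multivariate normal with mean
#' zero (root state) and covariance `rate * C`, where `C` is the shared
#' path-length matrix of the tree; traits are independent of each other.
#'
#' @param tree An [ape::phylo] tree with positive branch lengths.
#' @param n_traits Number of independent traits.
#' @param rate Variance accrued per unit branch length (>= 0).
#' @param seed Integer seed.
#' @return Matrix (tips x traits) with the tree's tip labels as row names.
#' @export
simulate_bm <- function(tree, n_traits = 1L, rate = 1, seed = 1L) {
  if (rate < 0) stop("rate must be non-negative")
  C <- ape::vcv(tree)
  n <- nrow(C)
  Y <- if (rate == 0) {
    matrix(0, n, n_traits)
  } else {
    L <- t(chol(C))
    Z <- .with_seed(seed, matrix(stats::rnorm(n * n_traits), n, n_traits))
    sqrt(rate) * (L %*% Z)
  }
  rownames(Y) <- rownames(C)
  colnames(Y) <- paste0("trait", seq_len(n_traits))
  Y
}
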