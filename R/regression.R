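#' Simple linear regression (OLS) with the summary used in the result tables
#'
#' Fits `response ~ predictor` by least squares with an intercept and reports
#' the slope, multiple and adjusted R-squared, F statistic, degrees of
#' freedom, and p-value. Typical pairings are shape PC1 against log centroid
#' size (allometry) and shape or size against environmental covariates; taxa
#' with missing values in either variable are dropped and the effective n is
#' reported.
#'
#' @param response Named (or plain) numeric vector.
#' @param predictor Numeric vector, same taxa/order as `response`.
#' @param log_predictor Log-transform the predictor first (used for centroid
#'   size; default `FALSE`).
#' @return A `"regression_result"` list: slope, intercept, multiple_r2,
#'   adjusted_r2, F, df (numerator, denominator), p_value, n, method.
#' @export
ols <- function(response, predictor, log_predictor = FALSE) {
  ok <- is.finite(response) & is.finite(predictor)
  y <- response[ok]; x <- predictor[ok]
  if (length(y) < 3L) stop("need at least 3 complete observations")
  if (log_predictor) {
    if (any(x <= 0)) stop("log transform requires positive predictor values")
    x <- log(x)
  }
  if (stats::var(x) == 0) stop("predictor has zero variance")
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 multiple_r2 = s$r.squared,
                 adjusted_r2 = s$adj.r.squared,
                 F = unname(s$fstatistic[1L]),
                 df = unname(s$fstatistic[2:3]),
                 p_value = unname(stats::pf(s$fstatistic[1L], s$fstatistic[2L],
                                            s$fstatistic[3L], lower.tail = FALSE)),
                 n = length(y), method = "OLS"),
            class = "regression_result")
}

#' Phylogenetic generalised least squares regression
#'
#' GLS with the Brownian-motion correlation structure `C` from [phylo_vcv]:
#' `beta = (X' C^-1 X)^-1 X' C^-1 y`. The fit is computed on the whitened
#' model (premultiplied by the inverse Cholesky factor of `C`), and R-squared,
#' F and p are those of the whitened regression against its whitened
#' intercept-only null. On a star phylogeny with equal depths, C is
#' proportional to the identity and PGLS reproduces OLS exactly.
#'
#' @param response Named numeric vector (names = taxa).
#' @param predictor Named numeric vector (names = taxa).
#' @param tree An [ape::phylo] tree. Taxa missing from any of the three inputs
#'   are dropped with a warning.
#' @param log_predictor Log-transform the predictor first (default `FALSE`).
#' @return A `"regression_result"` (method `"PGLS"`).
#' @export
pgls <- function(response, predictor, tree, log_predictor = FALSE) {
  validate_tree(tree)
  if (is.null(names(response)) || is.null(names(predictor))) {
    stop("response and predictor must be named by taxon")
  }
  taxa <- Reduce(intersect, list(names(response)[is.finite(response)],
                                 names(predictor)[is.finite(predictor)],
                                 tree$tip.label))
  if (length(taxa) < 3L) stop("fewer than 3 taxa shared across inputs")
  dropped <- setdiff(union(names(response), names(predictor)), taxa)
  if (length(dropped)) {
    warning(length(dropped), " taxa dropped (unmatched or missing values)")
  }
  tr <- ape::keep.tip(tree, taxa)
  y <- response[tr$tip.label]
  x <- predictor[tr$tip.label]
  if (log_predictor) {
    if (any(x <= 0)) stop("log transform requires positive predictor values")
    x <- log(x)
  }
  C <- phylo_vcv(tr)
  L <- t(chol(C))
  yw <- solve(L, y)
  Xw <- solve(L, cbind(intercept = 1, slope = x))
  fit <- stats::lm.fit(Xw, yw)
  rss1 <- sum(fit$residuals^2)
  fit0 <- stats::lm.fit(Xw[, 1L, drop = FALSE], yw)
  rss0 <- sum(fit0$residuals^2)
  n <- length(y)
  df <- c(1L, n - 2L)
  Fstat <- (rss0 - rss1) / (rss1 / df[2L])
  r2 <- 1 - rss1 / rss0
  structure(list(slope = unname(fit$coefficients["slope"]),
                 intercept = unname(fit$coefficients["intercept"]),
                 multiple_r2 = r2,
                 adjusted_r2 = 1 - (1 - r2) * (n - 1) / (n - 2),
                 F = Fstat, df = df,
                 p_value = stats::pf(Fstat, df[1L], df[2L], lower.tail = FALSE),
                 n = n, method = "PGLS"),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "%s (n = %d): slope %.5g, R2 %.4f (adj %.4f), F(%d, %d) = %.4g, p = %.4g\n",
    x$method, x$n, x$slope, x$multiple_r2, x$adjusted_r2,
    x$df[1L], x$df[2L], x$F, x$p_value))
  invisible(x)
}

#' Standard regression battery over shape, size and environment
#'
#' Runs the five pairings used throughout the package's analyses --
#' size to shape PC1 (log size), temperature to size, temperature to shape
#' PC1, rainfall to shape PC1, rainfall to PC2 -- as OLS and, when a tree is
#' supplied, as PGLS, and assembles the results into one table.
#'
#' @param scores Score matrix with taxon row names (PC1, PC2 in columns 1-2).
#' @param covariates Data frame with columns `taxon`, `centroid_size`, and the
#'   environmental covariates named in `mat`/`mar`.
#' @param tree Optional [ape::phylo] tree for the PGLS pass.
#' @param mat,mar Covariate column names (defaults `"mat"`, `"mar"`).
#' @param holm Apply a Holm correction across each method's p-values
#'   (default `FALSE`, matching a raw per-test presentation).
#' @return Data frame: test, method, n, multiple_r2, adjusted_r2, df1, df2,
#'   F, p, slope.
#' @export
regression_battery <- function(scores, covariates, tree = NULL,
                               mat = "mat", mar = "mar", holm = FALSE) {
  cv <- covariates
  rn <- cv$taxon
  named <- function(col) stats::setNames(cv[[col]], rn)
  idx <- match(rn, rownames(scores))
  pc1 <- stats::setNames(scores[idx, 1L], rn)
  pc2 <- stats::setNames(scores[idx, 2L], rn)
  size <- named("centroid_size")
  tests <- list(
    list(name = "size_vs_shapePC1", y = pc1, x = size, log = TRUE),
    list(name = "mat_vs_size", y = size, x = named(mat), log = FALSE),
    list(name = "mat_vs_shapePC1", y = pc1, x = named(mat), log = FALSE),
    list(name = "mar_vs_shapePC1", y = pc1, x = named(mar), log = FALSE),
    list(name = "mar_vs_shapePC2", y = pc2, x = named(mar), log = FALSE))
  rows <- list()
  for (t in tests) {
    r <- ols(t$y, t$x, log_predictor = t$log)
    rows[[length(rows) + 1L]] <- data.frame(
      test = t$name, method = "OLS", n = r$n, multiple_r2 = r$multiple_r2,
      adjusted_r2 = r$adjusted_r2, df1 = r$df[1L], df2 = r$df[2L],
      F = r$F, p = r$p_value, slope = r$slope)
    if (!is.null(tree)) {
      rp <- pgls(t$y, t$x, tree, log_predictor = t$log)
      rows[[length(rows) + 1L]] <- data.frame(
        test = t$name, method = "PGLS", n = rp$n,
        multiple_r2 = rp$multiple_r2, adjusted_r2 = rp$adjusted_r2,
        df1 = rp$df[1L], df2 = rp$df[2L], F = rp$F, p = rp$p_value,
        slope = rp$slope)
    }
  }
  out <- do.call(rbind, rows)
  if (holm) {
    for (m in unique(out$method)) {
      sel <- out$method == m
      out$p_holm[sel] <- stats::p.adjust(out$p[sel], method = "holm")
    }
  }
  out
}
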