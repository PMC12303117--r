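#' Objective specification for multi-objective ranking
#'
#' @param names Metric names, in column order of the solution matrix.
#' @param directions One of `"maximize"`/`"minimize"` per metric. The default
#'   three-way trade-off maximises aspect ratio and the radius of the second
#'   moment of area and minimises median von Mises stress (lower stress means
#'   higher breakage resistance).
#' @return An `"objective_spec"` list.
#' @export
objective_spec <- function(names = c("AR", "r2hat", "median_vms"),
                           directions = c("maximize", "maximize", "minimize")) {
  directions <- match.arg(directions, c("maximize", "minimize"),
                          several.ok = TRUE)
  if (length(names) != length(directions)) {
    stop("one direction is required per metric")
  }
  if (length(names) < 1L) stop("at least one metric is required")
  structure(list(names = names, directions = directions),
            class = "objective_spec")
}

# orient a solution matrix so larger is always better
.orient_solutions <- function(solutions, spec) {
  m <- as.matrix(solutions)
  if (ncol(m) != length(spec$names)) {
    stop("solution columns do not match the objective spec")
  }
  if (anyNA(m)) stop("missing value in solution matrix")
  sgn <- ifelse(spec$directions == "maximize", 1, -1)
  sweep(m, 2L, sgn, "*")
}

#' Pareto dominance between two solutions
#'
#' `a` dominates `b` iff it is at least as good in every metric (per the
#' spec's directions) and strictly better in at least one.
#'
#' @param a,b Numeric metric vectors of equal length.
#' @param spec An [objective_spec].
#' @return Logical scalar.
#' @export
dominates <- function(a, b, spec = objective_spec()) {
  m <- .orient_solutions(rbind(a, b), spec)
  all(m[1L, ] >= m[2L, ]) && any(m[1L, ] > m[2L, ])
}

#' Goldberg Pareto ranking
#'
#' Iterative front peeling: the non-dominated subset receives rank 1 and is
#' removed; the non-dominated subset of the remainder receives rank 2; and so
#' on until every solution is ranked. Identical solutions share a rank.
#'
#' @param solutions Matrix (solutions x metrics) or data.frame.
#' @param spec An [objective_spec].
#' @return Integer vector of ranks (1 = Pareto front).
#' @export
goldberg_ranks <- function(solutions, spec = objective_spec()) {
  m <- .orient_solutions(solutions, spec)
  n <- nrow(m)
  ranks <- rep(NA_integer_, n)
  remaining <- seq_len(n)
  r <- 0L
  while (length(remaining)) {
    r <- r + 1L
    sub <- m[remaining, , drop = FALSE]
    nd <- vapply(seq_along(remaining), function(i) {
      ai <- sub[i, ]
      for (j in seq_along(remaining)) {
        if (j == i) next
        aj <- sub[j, ]
        if (all(aj >= ai) && any(aj > ai)) return(FALSE)
      }
      TRUE
    }, logical(1L))
    ranks[remaining[nd]] <- r
    remaining <- remaining[!nd]
  }
  ranks
}

#' Pareto rank ratio
#'
#' Combines the forward Goldberg rank `f` (1 = the Pareto-optimal front) with
#' the reverse rank `b` obtained by inverting every objective direction
#' (1 = the anti-optimal front) into a single 0-1 optimality score:
#' solutions on the Pareto front score 1, solutions dominated by every other
#' solution score 0, and interior solutions score `(b - 1) / (f + b - 2)`.
#' Considering both directions corrects for uneven occupation of performance
#' space. A single solution scores 1.
#'
#' @inheritParams goldberg_ranks
#' @return Data frame with `forward_rank`, `reverse_rank`, `ratio`.
#' @export
pareto_rank_ratio <- function(solutions, spec = objective_spec()) {
  f <- goldberg_ranks(solutions, spec)
  rev_spec <- spec
  rev_spec$directions <- ifelse(spec$directions == "maximize",
                                "minimize", "maximize")
  b <- goldberg_ranks(solutions, rev_spec)
  ratio <- ifelse(f == 1L, 1, ifelse(b == 1L, 0, (b - 1) / (f + b - 2)))
  data.frame(forward_rank = f, reverse_rank = b, ratio = ratio)
}

#' Pareto optimality landscape over a theoretical grid
#'
#' Scores every viable cell by the Pareto rank ratio over the requested
#' metrics (the three-way default, or any pairwise subset) and attaches
#' 10-band equal-interval contours.
#'
#' @param records Data frame of per-cell metric values: must contain
#'   `cell_id`, `viable`, and one column per metric in `spec$names`
#'   (the output of [assemble_performance_records]).
#' @param spec An [objective_spec]; defaults to the three-way trade-off.
#' @param pairwise Optional character vector of two metric names: restrict the
#'   trade-off to that pair (directions inherited from `spec`).
#' @param n_bands Contour band count (default 10).
#' @return An `"optimality_landscape"`: `cells` data.frame with
#'   `forward_rank`, `reverse_rank`, `ratio`, `band` (NA on non-viable rows),
#'   plus `n_fronts`.
#' @export
optimality_landscape <- function(records, spec = objective_spec(),
                                 pairwise = NULL, n_bands = 10L) {
  if (!is.null(pairwise)) {
    idx <- match(pairwise, spec$names)
    if (anyNA(idx)) stop("pairwise metrics not found in the objective spec")
    spec <- objective_spec(spec$names[idx], spec$directions[idx])
  }
  missing_m <- setdiff(spec$names, colnames(records))
  if (length(missing_m)) {
    stop("metric columns missing from records: ",
         paste(missing_m, collapse = ", "))
  }
  ok <- records$viable & stats::complete.cases(records[, spec$names, drop = FALSE])
  if (sum(ok) < 2L) stop("need at least 2 viable scored cells")
  rr <- pareto_rank_ratio(as.matrix(records[ok, spec$names, drop = FALSE]), spec)
  cells <- records
  cells$forward_rank <- cells$reverse_rank <- cells$ratio <- NA_real_
  cells$forward_rank[ok] <- rr$forward_rank
  cells$reverse_rank[ok] <- rr$reverse_rank
  cells$ratio[ok] <- rr$ratio
  cells$band <- band_assign(cells$ratio, n_bands)
  structure(list(cells = cells, spec = spec,
                 n_fronts = max(rr$forward_rank), n_bands = n_bands),
            class = "optimality_landscape")
}

#' @export
print.optimality_landscape <- function(x, ...) {
  cat(sprintf("Optimality landscape (%s): %d scored cells, %d fronts\n",
              paste(x$spec$names, collapse = ", "),
              sum(!is.na(x$cells$ratio)), x$n_fronts))
  invisible(x)
}

#' Assemble per-cell performance records
#'
#' Joins per-metric landscape values into the single records table consumed by
#' [optimality_landscape].
#'
#' @param grid A `"theoretical_grid"`.
#' @param ... Named numeric vectors of per-cell values (length = cell count),
#'   or `"performance_landscape"` objects whose metric name is used.
#' @return Data frame: cell_id, pc1, pc2, viable, one column per metric.
#' @export
assemble_performance_records <- function(grid, ...) {
  out <- grid$cells[, c("cell_id", "pc1", "pc2", "viable")]
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (inherits(v, "performance_landscape")) v <- v$cells$value
    if (length(v) != nrow(out)) stop("metric vector length must equal cell count")
    out[[nm]] <- v
  }
  out
}
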