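#' Default pipeline configuration
#'
#' All analysis defaults are the package's standard settings: 150 outline
#' points, 9 harmonics, a 26 x 19 theoretical grid with a 20% border, 2500
#' triangular elements per plate model with E = 1 GPa, nu = 0.49 and a 0.003
#' transverse tip load, a three-way maximise-AR / maximise-r2hat /
#' minimise-stress trade-off, and 9999 permutations for the phylogenetic
#' signal test. Any entry can be overridden through `run_pipeline(config =
#' list(...))` or a YAML/JSON file with the same keys.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    outline_dir = NULL,        # directory of per-taxon outline CSVs
    tree_file = NULL,          # Newick tree
    covariates_file = NULL,    # CSV keyed by taxon
    out_dir = "wingscape_run",
    n_taxa = 60L,              # synthetic mode: taxa to simulate
    seed = 1L,
    P = 150L,
    H = 9L,
    grid_cols = 26L,
    grid_rows = 19L,
    border_frac = 0.2,
    n_stations = 200L,
    n_elements = 2500L,
    E = 1e9,
    nu = 0.49,
    load = 0.003,
    thickness = 0.01,
    kmult_iterations = 9999L,
    run_fea = TRUE,
    make_plots = TRUE
  )
}

.load_config <- function(config) {
  base <- default_config()
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config) &&
                  requireNamespace("yaml", quietly = TRUE)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  unknown <- setdiff(names(config), names(base))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  utils::modifyList(base, config)
}

.stage <- function(name, expr) {
  t0 <- proc.time()[3L]
  message(sprintf("[wingscape] stage %s ...", name))
  res <- tryCatch(force(expr), error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  message(sprintf("[wingscape] stage %s done (%.1f s)", name,
                  proc.time()[3L] - t0))
  res
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: data input (or synthetic generation), EFA
#' quantification, shape-space PCA, theoretical grid construction with
#' viability screening, performance landscapes (aspect ratio, radius of the
#' second moment of area and -- optionally, it is the slow stage -- median
#' von Mises stress), the Pareto optimality landscape (three-way and all
#' pairwise trade-offs), phylomorphospace and multivariate phylogenetic
#' signal, and the regression battery. All artifacts are written under
#' `config$out_dir` as plain CSV/JSON (plus PNG contour maps when ggplot2 is
#' available); the run is deterministic given `config$seed` and the resolved
#' configuration is saved alongside the outputs.
#'
#' @param config Named list, or path to a YAML/JSON file; see
#'   [default_config] for keys. Omitted keys take their defaults. With no
#'   input paths a fully synthetic study is generated.
#' @return Invisibly, a list with every intermediate object (`data`,
#'   `coefficients`, `space`, `grid`, `records`, `optimality`, `phylo`,
#'   `regressions`, paths).
#' @export
run_pipeline <- function(config = list()) {
  cfg <- .load_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  savecfg <- cfg[!vapply(cfg, is.null, logical(1L))]
  jsonlite::write_json(savecfg, file.path(cfg$out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  dat <- .stage("input", {
    if (is.null(cfg$outline_dir)) {
      sim <- gen_wing_set(sim_config(n_taxa = cfg$n_taxa, seed = cfg$seed))
      tree <- gen_tree(max(3L, round(cfg$n_taxa / 2)), seed = cfg$seed + 1L)
      jsonlite::write_json(sim$truth, file.path(cfg$out_dir, "ground_truth.json"),
                           digits = NA)
      list(outlines = sim$outlines, covariates = sim$covariates, tree = tree)
    } else {
      files <- list.files(cfg$outline_dir, pattern = "\\.(csv|tps)$",
                          full.names = TRUE)
      if (length(files) < 3L) stop("need at least 3 outline files")
      outl <- lapply(files, read_outline)
      names(outl) <- sub("\\.(csv|tps)$", "", basename(files))
      covs <- if (!is.null(cfg$covariates_file)) {
        utils::read.csv(cfg$covariates_file)
      } else NULL
      tree <- if (!is.null(cfg$tree_file)) read_newick(cfg$tree_file) else NULL
      list(outlines = outl, covariates = covs, tree = tree)
    }
  })

  coefs <- .stage("efa", {
    cm <- t(vapply(dat$outlines, function(o) {
      efa_as_vector(efa_normalize(efa_forward(
        resample_equal_arclength(o, cfg$P), cfg$H)))
    }, numeric(4L * cfg$H)))
    utils::write.csv(data.frame(taxon = rownames(cm), cm),
                     file.path(cfg$out_dir, "coefficients.csv"),
                     row.names = FALSE, quote = FALSE)
    cm
  })

  space <- .stage("shape_space", fit_shape_space(coefs))
  utils::write.csv(
    data.frame(taxon = rownames(space$scores), space$scores[, 1:2]),
    file.path(cfg$out_dir, "scores.csv"), row.names = FALSE, quote = FALSE)

  grid <- .stage("grid", build_theoretical_grid(
    space, cfg$grid_cols, cfg$grid_rows, cfg$border_frac, cfg$P))
  write_grid_csv(grid, file.path(cfg$out_dir, "grid.csv"))

  perf <- .stage("performance", {
    ar <- performance_landscape(grid, "AR", n_stations = cfg$n_stations)
    r2 <- performance_landscape(grid, "r2hat", n_stations = cfg$n_stations)
    vms <- if (isTRUE(cfg$run_fea)) {
      performance_landscape(grid, "median_vms",
                            fea_args = list(n_target = cfg$n_elements,
                                            E = cfg$E, nu = cfg$nu,
                                            load = cfg$load,
                                            thickness = cfg$thickness))
    } else NULL
    list(AR = ar, r2hat = r2, median_vms = vms)
  })
  for (nm in names(perf)) {
    if (is.null(perf[[nm]])) next
    utils::write.csv(cbind(metric = nm, perf[[nm]]$cells),
                     file.path(cfg$out_dir, paste0("landscape_", nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }

  opt <- .stage("pareto", {
    args <- list(grid = grid, AR = perf$AR, r2hat = perf$r2hat)
    if (!is.null(perf$median_vms)) args$median_vms <- perf$median_vms
    records <- do.call(assemble_performance_records, args)
    metrics <- setdiff(colnames(records), c("cell_id", "pc1", "pc2", "viable"))
    dirs <- ifelse(metrics == "median_vms", "minimize", "maximize")
    spec <- objective_spec(metrics, dirs)
    main <- optimality_landscape(records, spec)
    pairs <- if (length(metrics) >= 3L) {
      cmb <- utils::combn(metrics, 2L, simplify = FALSE)
      stats::setNames(lapply(cmb, function(p)
        optimality_landscape(records, spec, pairwise = p)),
        vapply(cmb, paste, "", collapse = "_"))
    } else list()
    utils::write.csv(main$cells, file.path(cfg$out_dir, "optimality.csv"),
                     row.names = FALSE, quote = FALSE)
    list(records = records, main = main, pairwise = pairs)
  })

  phy <- .stage("phylo", {
    if (is.null(dat$tree)) return(NULL)
    shared <- intersect(rownames(coefs), dat$tree$tip.label)
    if (length(shared) < 4L) return(NULL)
    tr <- ape::keep.tip(dat$tree, shared)
    pm <- phylomorphospace(tr, coefs, space)
    utils::write.csv(pm$points, file.path(cfg$out_dir, "phylomorphospace.csv"),
                     row.names = FALSE, quote = FALSE)
    ks <- kmult(tr, coefs[shared, , drop = FALSE],
                n_iterations = cfg$kmult_iterations, seed = cfg$seed + 2L)
    jsonlite::write_json(list(K = ks$K, p_value = ks$p_value,
                              n_iterations = ks$n_iterations),
                         file.path(cfg$out_dir, "kmult.json"),
                         auto_unbox = TRUE, digits = NA)
    list(phylomorphospace = pm, kmult = ks, tree = tr)
  })

  reg <- .stage("regression", {
    if (is.null(dat$covariates)) return(NULL)
    tab <- regression_battery(space$scores, dat$covariates,
                              tree = phy$tree)
    utils::write.csv(tab, file.path(cfg$out_dir, "regressions.csv"),
                     row.names = FALSE, quote = FALSE)
    tab
  })

  if (isTRUE(cfg$make_plots)) {
    .stage("plots", {
      tryCatch({
        .plot_landscapes(perf, opt, cfg$out_dir)
      }, error = function(e) {
        message("[wingscape] plotting skipped: ", conditionMessage(e))
      })
      NULL
    })
  }

  invisible(list(config = cfg, data = dat, coefficients = coefs,
                 space = space, grid = grid, performance = perf,
                 optimality = opt, phylo = phy, regressions = reg,
                 out_dir = cfg$out_dir))
}

# 10-band filled contour maps, white (lowest) to dark blue (highest)
.plot_landscapes <- function(perf, opt, out_dir) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 not available")
  }
  panels <- c(perf[!vapply(perf, is.null, logical(1L))],
              list(optimality = opt$main))
  for (nm in names(panels)) {
    cells <- panels[[nm]]$cells
    fill <- if (nm == "optimality") cells$ratio else cells$value
    df <- data.frame(pc1 = cells$pc1, pc2 = cells$pc2,
                     band = factor(cells$band))
    g <- ggplot2::ggplot(df, ggplot2::aes(x = pc1, y = pc2, fill = band)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_manual(
        values = grDevices::colorRampPalette(c("white", "#08306B"))(10),
        na.value = "grey70", drop = FALSE) +
      ggplot2::labs(title = nm, fill = "band") +
      ggplot2::theme_minimal()
    ggplot2::ggsave(file.path(out_dir, paste0("landscape_", nm, ".png")),
                    g, width = 7, height = 5, dpi = 150)
  }
  invisible(NULL)
}
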