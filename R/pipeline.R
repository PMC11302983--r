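#' Experiment configuration
#'
#' A fully serialisable description of one figure-level experiment. The
#' `"ci"` scale runs a reduced task (4 classes, 100 features, 4000 samples,
#' widths 100-32-32-4) sized for desk-scale reproduction; `"paper"` scale
#' uses the full-size architecture (784-100-100-10, 50 epochs, base rate
#' 5e-4). At the reduced scale the schedule has far fewer gradient steps,
#' so the base learning rate is raised and the epoch count set so that the
#' noise parameters reach their stationary values (see the package
#' vignette).
#'
#' @param experiment one of `"costs"`, `"tradeoff"`, `"variability"`,
#'   `"bayes"`.
#' @param seed integer master seed.
#' @param out_dir output directory for tables, reports and the manifest.
#' @param scale `"ci"` or `"paper"`.
#' @param overrides named list merged over the scale defaults; recognised
#'   groups: `data` (n_classes, n_features, n_samples, rate_heterogeneity),
#'   `network` (widths), `train` (epochs, eta_base, batch_size, sigma_init),
#'   `cost` (c, rho, lambda, s), `sweep` (c_grid, rho_grid),
#'   `bayes` (s, rho_grid, c_grid, n_H, H_range).
#' @return object of class `experiment_config` (a nested list).
#' @export
experiment_config <- function(experiment = c("costs", "tradeoff",
                                             "variability", "bayes"),
                              seed = 1, out_dir = tempdir(),
                              scale = c("ci", "paper"),
                              overrides = list()) {
  experiment <- match.arg(experiment)
  scale <- match.arg(scale)
  base <- if (scale == "ci") {
    list(
      data = list(n_classes = 4, n_features = 100, n_samples = 4000,
                  rate_heterogeneity = 3),
      network = list(widths = c(100, 32, 32, 4)),
      train = list(epochs = 30, eta_base = 5e-3, batch_size = 20,
                   sigma_init = 1e-4, beta2 = 0.99),
      cost = list(c = 0, rho = 2, lambda = 1e-4, s = 0.001),
      sweep = list(c_grid = c(0, 1e-5, 1e-3, 1e-1),
                   rho_grid = c(1 / 2, 2 / 3, 4 / 3, 2)),
      bayes = list(s = 0.01, rho_grid = c(1 / 2, 2 / 3, 4 / 3, 2),
                   c_grid = c(0.112, 0.2, 0.356), n_H = 20,
                   H_range = c(0.1, 100))
    )
  } else {
    list(
      data = list(n_classes = 10, n_features = 784, n_samples = 60000,
                  rate_heterogeneity = 3),
      network = list(widths = c(784, 100, 100, 10)),
      train = list(epochs = 50, eta_base = 5e-4, batch_size = 20,
                   sigma_init = 1e-4, beta2 = 0.999),
      cost = list(c = 0, rho = 2, lambda = 1e-4, s = 0.001),
      sweep = list(c_grid = c(0, 1e-5, 1e-3, 1e-1),
                   rho_grid = c(1 / 2, 2 / 3, 4 / 3, 2)),
      bayes = list(s = 0.01, rho_grid = c(1 / 2, 2 / 3, 4 / 3, 2),
                   c_grid = c(0.112, 0.2, 0.356), n_H = 20,
                   H_range = c(0.1, 100))
    )
  }
  for (grp in names(overrides)) {
    for (key in names(overrides[[grp]])) {
      base[[grp]][[key]] <- overrides[[grp]][[key]]
    }
  }
  cfg <- c(list(experiment = experiment, seed = as.integer(seed),
                out_dir = out_dir, scale = scale), base)
  class(cfg) <- "experiment_config"
  cfg
}

#' Write / read an experiment configuration as YAML
#'
#' Round-trips exactly: `read_experiment_config(write_experiment_config(x))`
#' reproduces `x`.
#'
#' @param config an `experiment_config`.
#' @param path YAML file path.
#' @return `path` (write) / the config (read).
#' @export
write_experiment_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  cfg <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) stop_arg("malformed YAML config: ", conditionMessage(e))
  )
  for (grp in c("network")) {
    if (!is.null(cfg[[grp]]$widths)) cfg[[grp]]$widths <- as.numeric(cfg[[grp]]$widths)
  }
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "experiment_config"
  cfg
}

write_manifest <- function(config, out_dir) {
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(config), tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  manifest <- list(
    experiment = config$experiment,
    config_md5 = hash,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("effsyn"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

pipeline_dataset <- function(config) {
  d <- config$data
  make_classification_task(d$n_classes, d$n_features, d$n_samples,
                           rate_heterogeneity = d$rate_heterogeneity,
                           seed = config$seed)
}

pipeline_train_config <- function(config, ...) {
  tr <- config$train
  train_config(eta_base = tr$eta_base, batch_size = tr$batch_size,
               epochs = tr$epochs, sigma_init = tr$sigma_init,
               beta2 = if (is.null(tr$beta2)) 0.999 else tr$beta2,
               seed = config$seed, ...)
}

#' Biophysical cost-curve experiment
#'
#' Computes the cost-versus-reliability curve for each of the four
#' mechanisms, fits the power-law exponent of each, writes per-mechanism
#' CSVs plus a fitted-exponent report, and returns the report.
#'
#' @param config an [experiment_config()].
#' @return data.frame with columns `mechanism`, `slope`, `rho_hat`,
#'   `expected_slope`.
#' @export
run_costs <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  expected <- c(calcium = -1 / 2, surface = -2 / 3, actin = -4 / 3,
                trafficking = -2)
  rows <- lapply(names(expected), function(mech) {
    curve <- tryCatch(
      cost_curve(mech),
      error = function(e) stop("cost curve failed for mechanism ", mech, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    write_cost_curve(curve, file.path(config$out_dir,
                                      paste0("cost_curve_", mech, ".csv")))
    fit <- fit_power_exponent(curve)
    data.frame(mechanism = mech, slope = fit$slope, rho_hat = fit$rho_hat,
               expected_slope = expected[[mech]])
  })
  report <- do.call(rbind, rows)
  utils::write.csv(report, file.path(config$out_dir, "cost_exponents.csv"),
                   row.names = FALSE)
  write_manifest(config, config$out_dir)
  report
}

#' Performance-reliability tradeoff experiment
#'
#' Wraps [sweep_c()] over the exponent grid and both noise modes, emitting
#' one long-format table (c, mode, accuracy, mean sigma, reliability cost,
#' rho). Completed (rho, mode) combinations are checkpointed as CSV and
#' skipped on rerun, so an interrupted sweep resumes where it stopped.
#'
#' @param config an [experiment_config()].
#' @return the long-format data.frame.
#' @export
run_tradeoff <- function(config) {
  dir.create(file.path(config$out_dir, "checkpoints"),
             showWarnings = FALSE, recursive = TRUE)
  dataset <- pipeline_dataset(config)
  tcfg <- pipeline_train_config(config)
  net_cfg <- network_config(widths = config$network$widths)
  parts <- list()
  for (rho in config$sweep$rho_grid) {
    for (mode in c("heterogeneous", "homogeneous")) {
      ckpt <- file.path(config$out_dir, "checkpoints",
                        sprintf("tradeoff_rho%.4g_%s.csv", rho, mode))
      if (file.exists(ckpt)) {
        parts[[length(parts) + 1L]] <- utils::read.csv(ckpt)
        next
      }
      tab <- sweep_c(config$sweep$c_grid, rho, dataset, tcfg, net_cfg,
                     modes = mode, lambda = config$cost$lambda)
      utils::write.csv(tab, ckpt, row.names = FALSE)
      parts[[length(parts) + 1L]] <- tab
    }
  }
  out <- do.call(rbind, parts)
  utils::write.csv(out, file.path(config$out_dir, "tradeoff.csv"),
                   row.names = FALSE)
  write_manifest(config, config$out_dir)
  out
}

#' Synapse-variability diagnostics experiment
#'
#' Trains one heterogeneous-noise network with the reliability multiplier
#' set by the tangency convention (`c = s^rho/rho`), computes the
#' per-synapse report for the layer between the two hidden layers, the
#' three importance-variability rank correlations, and writes both (report
#' CSV, correlations JSON).
#'
#' @param config an [experiment_config()].
#' @return list with `report` (a `diagnostics_report`), `correlations`, and
#'   the trained `net`.
#' @export
run_variability <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  dataset <- pipeline_dataset(config)
  tcfg <- pipeline_train_config(config)
  net_cfg <- network_config(widths = config$network$widths)
  spec <- cost_spec(c = c_from_scale(config$cost$rho, config$cost$s),
                    rho = config$cost$rho, lambda = config$cost$lambda,
                    s = config$cost$s)
  net <- init_network(net_cfg, "heterogeneous", sigma_init = tcfg$sigma_init,
                      seed = config$seed)
  fit <- train(net, dataset, spec, tcfg)
  report <- diagnostics_report(fit$net, dataset, layer = 2,
                               eta_base = tcfg$eta_base, seed = config$seed)
  cors <- variability_correlations(report)
  write_diagnostics_report(report, file.path(config$out_dir, "variability.csv"))
  jsonlite::write_json(
    lapply(cors, function(x) list(coefficient = x$coefficient,
                                  slope = x$slope, n = x$n,
                                  n_dropped = x$n_dropped)),
    file.path(config$out_dir, "correlations.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  write_manifest(config, config$out_dir)
  list(report = report, correlations = cors, net = fit$net)
}

#' Validate a correlations JSON file against the shipped schema
#'
#' Checks that every correlation object carries the fields (and scalar
#' types) listed in the schema shipped at
#' `inst/extdata/correlation_schema.json`.
#'
#' @param path JSON file written by [run_variability()].
#' @return `TRUE` (invisibly) or an error describing the first violation.
#' @export
validate_correlations_json <- function(path) {
  schema <- jsonlite::read_json(
    system.file("extdata", "correlation_schema.json", package = "effsyn"))
  obj <- jsonlite::read_json(path)
  for (name in unlist(schema$required_objects)) {
    if (is.null(obj[[name]])) stop_arg("missing correlation object: ", name)
    for (fld in unlist(schema$required_fields)) {
      v <- obj[[name]][[fld]]
      if (is.null(v) || length(v) != 1L || !is.numeric(v)) {
        stop_arg("field ", fld, " of ", name, " missing or non-scalar")
      }
    }
  }
  invisible(TRUE)
}

#' Posterior-comparison experiment
#'
#' Computes the slope of log efficient noise against log Laplace posterior
#' spread over a grid of curvatures: once across the exponent grid with the
#' tangency multiplier `c = s^rho/rho`, and once across a multiplier grid
#' at fixed `rho = 1/2`. All slopes are below one and decrease with the
#' exponent.
#'
#' @param config an [experiment_config()].
#' @return data.frame with columns `sweep`, `rho`, `c`, `slope`,
#'   `theoretical`.
#' @export
run_bayes <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  b <- config$bayes
  H <- 10^seq(log10(b$H_range[1]), log10(b$H_range[2]), length.out = b$n_H)
  rows <- list()
  for (rho in b$rho_grid) {
    sa <- sigma_vs_posterior_slope(H, c_from_scale(rho, b$s), rho)
    rows[[length(rows) + 1L]] <- data.frame(
      sweep = "rho", rho = rho, c = sa$c, slope = sa$slope,
      theoretical = sa$theoretical)
  }
  for (cc in b$c_grid) {
    sa <- sigma_vs_posterior_slope(H, cc, 1 / 2)
    rows[[length(rows) + 1L]] <- data.frame(
      sweep = "c", rho = 1 / 2, c = cc, slope = sa$slope,
      theoretical = sa$theoretical)
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, file.path(config$out_dir, "bayes_slopes.csv"),
                   row.names = FALSE)
  jsonlite::write_json(out, file.path(config$out_dir, "bayes_slopes.json"),
                       dataframe = "rows", pretty = TRUE, digits = NA)
  write_manifest(config, config$out_dir)
  out
}

#' Run every experiment in sequence
#'
#' @param config an [experiment_config()]; its `experiment` field is
#'   ignored.
#' @return named list of the four experiment results.
#' @export
run_all <- function(config) {
  list(
    costs = run_costs(config),
    tradeoff = run_tradeoff(config),
    variability = run_variability(config),
    bayes = run_bayes(config)
  )
}
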