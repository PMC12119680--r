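#' Run configuration for the end-to-end pipeline
#'
#' @param out_dir output directory for the report bundle.
#' @param landscape a [landscape_config()] for the synthetic region.
#' @param n_admissions number of admission records to generate.
#' @param seed master seed; stage seeds derive deterministically.
#' @param truth a [synthetic_truth()] driving the generator.
#' @param speeds a [speed_table()].
#' @param spec a [model_spec()] for the spatial fit (`blocks` may be
#'   `"screen"` to take the univariate-screen selection).
#' @param decay_tau attendance distance-decay scale in minutes.
#' @param p_not_anaemic,p_excluded_cause,p_missing_hb generator
#'   fractions exercising the exclusion cascade.
#' @param make_figures write PNG figures (band rates).
#' @param verbose print stage progress.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir = NULL,
                       landscape = landscape_config(nx = 80, ny = 80,
                                                    pixel_size = 400,
                                                    n_eas = 60, seed = 1),
                       n_admissions = 2500,
                       seed = 1,
                       truth = synthetic_truth(),
                       speeds = default_speed_table(),
                       spec = model_spec(),
                       decay_tau = 25,
                       p_not_anaemic = 0.36,
                       p_excluded_cause = 0.15,
                       p_missing_hb = 0.06,
                       make_figures = TRUE,
                       verbose = TRUE) {
  structure(list(out_dir = out_dir, landscape = landscape,
                 n_admissions = n_admissions, seed = seed, truth = truth,
                 speeds = speeds, spec = spec, decay_tau = decay_tau,
                 p_not_anaemic = p_not_anaemic,
                 p_excluded_cause = p_excluded_cause,
                 p_missing_hb = p_missing_hb,
                 make_figures = make_figures, verbose = verbose),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; nested sections
#' `landscape`, `truth.matern` and `spec` override the corresponding
#' defaults field by field. Referenced paths are checked at validation
#' time, before any computation.
#'
#' @param file YAML path.
#' @param out_dir output directory, overriding any `out_dir` in the
#'   file (a config template may leave it unset).
#' @return A [run_config()].
#' @export
read_run_config <- function(file, out_dir = NULL) {
  if (!file.exists(file)) stop("config file not found: ", file)
  y <- yaml::read_yaml(file)
  if (!is.null(out_dir)) y$out_dir <- out_dir
  ls_args <- y$landscape %||% list()
  truth_args <- y$truth %||% list()
  if (!is.null(truth_args$matern))
    truth_args$matern <- do.call(matern_params, truth_args$matern)
  if (!is.null(truth_args$beta_cov))
    truth_args$beta_cov <- unlist(truth_args$beta_cov)
  spec_args <- y$spec %||% list()
  top <- y[setdiff(names(y), c("landscape", "truth", "spec"))]
  do.call(run_config, c(top, list(
    landscape = do.call(landscape_config, ls_args),
    truth = do.call(synthetic_truth, truth_args),
    spec = do.call(model_spec, spec_args))))
}

validate_run_config <- function(config) {
  if (!inherits(config, "run_config")) stop("not a run_config")
  if (is.null(config$out_dir) || !nzchar(config$out_dir))
    stop("validation error: out_dir is required")
  parent <- dirname(config$out_dir)
  if (!dir.exists(parent))
    stop("validation error: parent of out_dir does not exist: ", parent)
  if (config$n_admissions < 1)
    stop("validation error: n_admissions must be >= 1")
  invisible(config)
}

stage <- function(name, verbose, expr) {
  if (verbose) message(sprintf("[%s] running...", name))
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  if (verbose) message(sprintf("[%s] done", name))
  res
}

#' Run the full pipeline: simulate, travel time, cohort, describe, fit
#'
#' Orchestrates an end-to-end run on a synthetic region: generates the
#' landscape and admissions, builds the friction surface and travel
#' times, applies the exclusion cascade, produces descriptive tables
#' and band rates, fits the spatial logit, and writes a report bundle
#' (CSV tables, JSON fit and ledger, figures, and a manifest with MD5
#' checksums of every output). Reruns with the same config and seed
#' are bit-identical for the deterministic stages. On a stage failure
#' the partial outputs are moved under a `failed/` prefix and the error
#' names the stage.
#'
#' @param config a [run_config()] (or a YAML path accepted by
#'   [read_run_config()]).
#' @return Invisibly, a list with the main in-memory artefacts
#'   (`landscape`, `zonal`, `cohort`, `ledger`, `table1`, `or_table`,
#'   `fit`, `manifest`) and the output directory.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  verbose <- isTRUE(config$verbose)
  result <- tryCatch({
    config$landscape$seed <- config$seed
    land <- stage("simulate", verbose, {
      l <- generate_landscape(config$landscape)
      write_landscape(l, file.path(out, "landscape"))
      write_truth_json(config$truth, file.path(out, "truth.json"))
      l
    })
    zonal <- stage("traveltime", verbose, {
      fr <- build_friction_surface(land$layers, config$speeds)
      tt <- least_cost_travel_time(fr, land$hospital)
      write_ascii_grid(tt$grid, file.path(out, "travel_time.asc"))
      z <- zonal_mean_travel_time(tt, land$eas)
      utils::write.csv(z, file.path(out, "ea_travel_time.csv"),
                       row.names = FALSE)
      z
    })
    eas <- attach_travel_time(land$eas, zonal)
    keep <- !is.na(eas$table$mean_travel_min)
    eas$table <- eas$table[keep, , drop = FALSE]
    write_ea_geojson(eas, file.path(out, "eas.geojson"))
    cohort_res <- stage("cohort", verbose, {
      sim <- simulate_admissions(
        eas, tt_class = stats::setNames(eas$table$tt_class, eas$table$ea_id),
        truth = config$truth, n_admissions = config$n_admissions,
        seed = config$seed + 1L, decay_tau = config$decay_tau,
        p_not_anaemic = config$p_not_anaemic,
        p_excluded_cause = config$p_excluded_cause,
        p_missing_hb = config$p_missing_hb)
      utils::write.csv(sim$admissions, file.path(out, "admissions.csv"),
                       row.names = FALSE)
      alt <- eas$table$altitude_m[match(sim$admissions$ea_id,
                                        eas$table$ea_id)]
      res <- apply_exclusions(sim$admissions, altitude_m = alt)
      utils::write.csv(res$cohort, file.path(out, "cohort.csv"),
                       row.names = FALSE)
      write_ledger_json(res$ledger, file.path(out, "ledger.json"))
      res
    })
    cohort <- cohort_res$cohort
    tabs <- stage("describe", verbose, {
      t1 <- summarize_table1(cohort, seed = config$seed)
      utils::write.csv(t1, file.path(out, "table1.csv"), row.names = FALSE)
      rates <- band_admission_rates(cohort, eas)
      utils::write.csv(rates, file.path(out, "band_rates.csv"),
                       row.names = FALSE)
      if (isTRUE(config$make_figures))
        plot_band_rates(rates, file.path(out, "band_rates.png"))
      list(table1 = t1, rates = rates)
    })
    fit_res <- stage("fit", verbose, {
      spec <- config$spec
      if (identical(spec$blocks, "screen")) {
        sc <- univariate_screen(cohort)
        spec$blocks <- sc$block[sc$selected]
      }
      fit <- fit_spatial_logit(cohort, spec, eas)
      or_tab <- adjusted_or_table(fit, cohort)
      utils::write.csv(or_tab, file.path(out, "table2.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(coefficients = fit$coefficients, hyper = fit$hyper,
             logml = fit$logml, convergence = fit$convergence,
             grid = fit$grid),
        file.path(out, "fit.json"), auto_unbox = TRUE, digits = NA,
        na = "null")
      list(fit = fit, or_table = or_tab)
    })
    manifest <- stage("report", verbose, {
      files <- setdiff(list.files(out, recursive = TRUE), "manifest.json")
      paths <- file.path(out, files)
      man <- list(
        seed = config$seed,
        n_admissions = config$n_admissions,
        r_version = as.character(getRversion()),
        created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        files = stats::setNames(as.list(unname(tools::md5sum(paths))), files)
      )
      jsonlite::write_json(man, file.path(out, "manifest.json"),
                           auto_unbox = TRUE)
      man
    })
    list(out_dir = out, landscape = land, zonal = zonal, cohort = cohort,
         ledger = cohort_res$ledger, table1 = tabs$table1,
         band_rates = tabs$rates, fit = fit_res$fit,
         or_table = fit_res$or_table, manifest = manifest)
  }, error = function(e) {
    failed <- file.path(out, "failed")
    dir.create(failed, showWarnings = FALSE)
    produced <- setdiff(list.files(out), "failed")
    file.rename(file.path(out, produced), file.path(failed, produced))
    stop(e)
  })
  invisible(result)
}
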