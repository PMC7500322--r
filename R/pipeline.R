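# End-to-end analysis pipeline and run configuration: conditions ->
# simulated choices -> Bradley-Terry preferences -> Bayesian model
# comparison, with all artifacts and provenance written to disk.

default_config <- function() {
  list(
    trajectory = list(x_i = 161.4, x_f = 96.9, d = 0.4, rate = 120),
    noise = list(sd_grid = c(0, seq(0.5, 4, by = 0.5)), fwhm = 0.05,
                 taper_tau = NULL, target_jerk_at_half = 0.5e5,
                 n_draws = 200),
    experiment = list(n_subjects = 20, observer_model = "C",
                      observer_coef = NULL, beta = 2),
    analysis = list(sd_max = 3.0, transition_sd_max = 1.5,
                    prior_scale = 10, ml_draws = 1e5, refine = TRUE),
    seed = 1L,
    outdir = NULL)
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (path == "") key else paste(path, key, sep = ".")
    if (!key %in% names(defaults)) {
      stopf("unknown configuration key '%s'", full)
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]])) stopf("configuration key '%s' must be a mapping", full)
      defaults[key] <- list(merge_config(defaults[[key]], user[[key]], full))
    } else {
      # [key] <- list(...) so explicit NULLs survive the assignment
      defaults[key] <- list(user[[key]])
    }
  }
  defaults
}

validate_config <- function(cfg) {
  tr <- cfg$trajectory
  if (tr$d <= 0) stopf("trajectory.d must be positive")
  if (tr$rate <= 0) stopf("trajectory.rate must be positive")
  if (cfg$noise$sd_grid[1] != 0) stopf("noise.sd_grid must start at 0")
  if (any(diff(cfg$noise$sd_grid) <= 0)) {
    stopf("noise.sd_grid must be strictly increasing")
  }
  if (cfg$experiment$n_subjects < 1) {
    stopf("experiment.n_subjects must be at least 1")
  }
  if (!cfg$experiment$observer_model %in% c("A", "B", "C", "strengths")) {
    stopf("experiment.observer_model must be A, B, C or 'strengths'")
  }
  if (cfg$analysis$sd_max <= 0) stopf("analysis.sd_max must be positive")
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

#' Build or load a pipeline run configuration
#'
#' `run_config()` assembles a validated configuration from defaults plus
#' overrides; `load_config()` reads one from a YAML (or JSON) file.
#' Unknown keys are rejected by name; every random stage has an explicit
#' seed derived from `seed`.
#'
#' @param ... Named overrides of the default configuration sections
#'   (`trajectory`, `noise`, `experiment`, `analysis`, `seed`, `outdir`).
#' @return An object of class `run_config` (a nested list).
#' @examples
#' cfg <- run_config(experiment = list(n_subjects = 5), seed = 42)
#' cfg$experiment$n_subjects
#' @export
run_config <- function(...) {
  user <- list(...)
  validate_config(merge_config(default_config(), user))
}

#' @rdname run_config
#' @param path Path to a YAML or JSON configuration file.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stopf("configuration file not found: %s", path)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(user)) user <- list()
  validate_config(merge_config(default_config(), user))
}

#' @rdname run_config
#' @param cfg A `run_config`.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Pipeline run configuration\n")
  utils::str(unclass(x), give.attr = FALSE)
  invisible(x)
}

default_observer_coef <- function(kind, jerks, trans_hi) {
  # Latent preference curves with unit range over the realized jerk scale,
  # emulating the qualitative profiles under study: A falls linearly from
  # 1 to 0.2 across the jerk range; B drops by 0.3 then flattens; C peaks
  # just above the smoothest condition and falls to 0.2 at the jerkiest.
  # Transitions sit at the second condition's jerk, inside the allowed
  # low-jerk region.
  x0 <- min(jerks)
  xmax <- max(jerks)
  span <- xmax - x0
  trans <- min(jerks[2], trans_hi * 0.99)
  switch(kind,
         A = c(1 + 0.8 * x0 / span, -0.8 / span),
         B = {
           b1 <- -0.3 / (trans - x0)
           c(1 - b1 * x0, b1, trans)
         },
         C = {
           c1 <- 0.8 / (xmax - trans)
           c(1 - c1 * trans, c1, trans)
         })
}

#' Run the full jerk-preference pipeline
#'
#' Chains every stage of the analysis: generate the jerk-graded condition
#' set (with noise calibration), simulate the paired-comparison game for a
#' group of synthetic observers, pool their choices, fit Bradley-Terry
#' preference strengths, assemble the jerk-preference dataset within the
#' analysis range, and compare the three preference models by Bayes
#' factors.  When `cfg$outdir` is set, all artifacts are written there:
#' `conditions/` (per-condition CSVs + manifest), `choices.csv`,
#' `preference.json`, `comparison.json` and `provenance.json` (config
#' hash, seeds, package version).
#'
#' @param cfg A [run_config].
#' @return A list of class `pipeline_report` with elements `conditions`,
#'   `choices`, `bt`, `dataset`, `comparison`, `config`.
#' @examples
#' \donttest{
#' cfg <- run_config(experiment = list(n_subjects = 5),
#'                   noise = list(n_draws = 50),
#'                   analysis = list(ml_draws = 2e4), seed = 3)
#' rep <- run_full_pipeline(cfg)
#' rep$comparison
#' }
#' @export
run_full_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  seeds <- derive_seeds(cfg$seed, 4L)

  cs <- tryCatch(
    generate_condition_set(
      x_i = cfg$trajectory$x_i, x_f = cfg$trajectory$x_f,
      d = cfg$trajectory$d, rate = cfg$trajectory$rate,
      sd_grid = cfg$noise$sd_grid, fwhm = cfg$noise$fwhm,
      taper_tau = cfg$noise$taper_tau,
      target_jerk_at_half = cfg$noise$target_jerk_at_half,
      n_draws = cfg$noise$n_draws, seed = seeds[1]),
    error = function(e) stopf("condition generation failed: %s",
                              conditionMessage(e)))

  k <- nrow(cs$conditions)
  jerks <- cs$conditions$realized_jerk
  trans_hi <- stats::approx(cs$conditions$sd, jerks,
                            xout = cfg$analysis$transition_sd_max,
                            rule = 2)$y
  obs <- if (cfg$experiment$observer_model == "strengths") {
    observer_spec(strengths = cfg$experiment$observer_coef)
  } else {
    coefs <- cfg$experiment$observer_coef
    if (is.null(coefs)) {
      coefs <- default_observer_coef(cfg$experiment$observer_model,
                                     jerks, trans_hi)
    }
    observer_spec(model = pref_model(cfg$experiment$observer_model, coefs),
                  beta = cfg$experiment$beta)
  }
  choices <- tryCatch(
    simulate_group(k, obs, jerks, n_subjects = cfg$experiment$n_subjects,
                   seed = seeds[2]),
    error = function(e) stopf("choice simulation failed: %s",
                              conditionMessage(e)))

  bt <- tryCatch(bt_fit(tabulate_choices(choices, k)),
                 error = function(e) stopf("Bradley-Terry fit failed: %s",
                                           conditionMessage(e)))

  dataset <- fit_dataset(jerks, unname(bt$p), sd = cs$conditions$sd,
                         sd_max = cfg$analysis$sd_max)
  comparison <- tryCatch(
    compare_pref_models(dataset,
                        transition_bounds = c(min(jerks), trans_hi),
                        n_draws = cfg$analysis$ml_draws,
                        refine = cfg$analysis$refine, seed = seeds[3]),
    error = function(e) stopf("model comparison failed: %s",
                              conditionMessage(e)))

  report <- structure(list(conditions = cs, choices = choices, bt = bt,
                           dataset = dataset, comparison = comparison,
                           config = cfg),
                      class = "pipeline_report")
  if (!is.null(cfg$outdir)) write_pipeline_artifacts(report, cfg$outdir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Jerk-preference pipeline report\n")
  cat(sprintf("  %d conditions, %d pooled choices from %d subjects\n",
              nrow(x$conditions$conditions), nrow(x$choices),
              length(unique(x$choices$subject))))
  print(x$bt)
  print(x$comparison)
  invisible(x)
}

write_pipeline_artifacts <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_condition_set(report$conditions, file.path(outdir, "conditions"))
  write_choices(report$choices, file.path(outdir, "choices.csv"))
  jsonlite::write_json(
    list(p = as.list(report$bt$p), loglik = report$bt$loglik,
         iterations = report$bt$iterations,
         converged = report$bt$converged,
         regularized = report$bt$regularized),
    file.path(outdir, "preference.json"), auto_unbox = TRUE, digits = NA)
  cmp <- report$comparison
  jsonlite::write_json(
    list(logml = as.list(cmp$logml), bf = cmp$bf, labels = cmp$labels),
    file.path(outdir, "comparison.json"), auto_unbox = TRUE, digits = NA,
    matrix = "rowmajor")
  cfg_file <- tempfile(fileext = ".yaml")
  save_config(report$config, cfg_file)
  jsonlite::write_json(
    list(config = unclass(report$config),
         config_md5 = unname(tools::md5sum(cfg_file)),
         package_version = as.character(utils::packageVersion("jerkpref")),
         r_version = R.version.string),
    file.path(outdir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  unlink(cfg_file)
  invisible(outdir)
}
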