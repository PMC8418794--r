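#' Run configuration for the end-to-end pipeline
#'
#' A single YAML file drives all pipeline stages so a published analysis is
#' one artifact. Top-level keys:
#' \describe{
#'   \item{seed}{Integer seed for all randomness.}
#'   \item{outdir}{Run directory; every stage writes only here.}
#'   \item{simulate}{Optional: `profile` to generate inputs with
#'     [make_fixtures()].}
#'   \item{data}{Paths to `segments`, `observations`, `platforms`, `grid`
#'     (defaults to files under `outdir/data`).}
#'   \item{detection}{Per-platform detection settings: `key`, `formula`,
#'     and for double-observer platforms `g0_formula`.}
#'   \item{dsm}{`variant`, `family`, and `terms` (list of
#'     `{covariates, k, bs}`).}
#'   \item{uncertainty}{`B` and `sampler`.}
#' }
#'
#' @param path YAML config path.
#' @return A validated config list with a recorded `config_hash`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop_mdsm(sprintf("Config file '%s' not found.", path), "mdsm_io_error")
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$outdir)) {
    stop_mdsm("Config must set `outdir`.", "mdsm_config_error")
  }
  cfg$seed <- cfg$seed %||% 1
  cfg$config_hash <- unname(tools::md5sum(path))
  cfg
}

cfg_data_paths <- function(cfg) {
  base <- file.path(cfg$outdir, "data")
  list(
    segments = cfg$data$segments %||% file.path(base, "segments.csv"),
    observations = cfg$data$observations %||%
      file.path(base, "observations.csv"),
    platforms = cfg$data$platforms %||% file.path(base, "platforms.yaml"),
    grid = cfg$data$grid %||% file.path(base, "grid.csv"))
}

stage_path <- function(cfg, stage) file.path(cfg$outdir, paste0(stage, ".rds"))

require_stage <- function(cfg, stage) {
  p <- stage_path(cfg, stage)
  if (!file.exists(p)) {
    stop_mdsm(sprintf(
      "Stage '%s' has not been run yet (expected %s). Run it first.",
      stage, p), "mdsm_stage_error")
  }
  readRDS(p)
}

log_stage <- function(cfg, stage, ...) {
  msg <- sprintf("[%s] stage=%s seed=%d hash=%s %s",
                 format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage,
                 as.integer(cfg$seed), cfg$config_hash,
                 paste(sprintf("%s", c(...)), collapse = " "))
  cat(msg, "\n", file = stderr())
  cat(msg, "\n", file = file.path(cfg$outdir, "run.log"), append = TRUE)
}

#' Pipeline stages
#'
#' Config-driven stages tying the package together:
#' `run_simulate()` generates fixture inputs, `run_fit_detection()` fits one
#' detection model per platform, `run_fit_dsm()` fits the count model and
#' propagates detection uncertainty, `run_predict()` computes abundance over
#' the grid, and `run_report()` writes a model-comparison table (AIC,
#' observed-vs-expected chi-squared by platform, and per-platform prediction
#' difference summaries). Each stage writes its outputs (state as `.rds`,
#' reports as CSV/YAML) under the config's `outdir` and never mutates its
#' inputs; running a stage before its predecessor raises a stage-order
#' error. `run_pipeline()` runs all stages in order.
#'
#' @param cfg A config list from [read_run_config()] (or a path to one).
#' @return Each stage returns its main object invisibly.
#' @export
run_simulate <- function(cfg) {
  cfg <- ensure_cfg(cfg)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  profile <- cfg$simulate$profile %||% "minimal"
  make_fixtures(profile, dir = file.path(cfg$outdir, "data"),
                seed = as.integer(cfg$seed))
  log_stage(cfg, "simulate", sprintf("profile=%s", profile))
  invisible(cfg)
}

ensure_cfg <- function(cfg) {
  if (is.character(cfg)) read_run_config(cfg) else cfg
}

#' @rdname run_simulate
#' @export
run_fit_detection <- function(cfg) {
  cfg <- ensure_cfg(cfg)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- cfg_data_paths(cfg)
  survey <- read_survey(paths$segments, paths$observations, paths$platforms)
  fits <- purrr::map(seq_len(nrow(survey$platforms)), function(i) {
    pl <- survey$platforms[i, ]
    det_cfg <- cfg$detection[[pl$platform_id]] %||% list()
    key <- det_cfg$key %||% "half_normal"
    form <- as.formula(det_cfg$formula %||% "~1")
    if (pl$protocol == "strip") {
      fit_detection(survey$observations, pl, segments = survey$segments)
    } else if (pl$protocol == "mrds_io") {
      fit_mrds(survey$observations, pl, ds_formula = form,
               g0_formula = as.formula(det_cfg$g0_formula %||% "~distance"),
               segments = survey$segments, key = key)
    } else {
      fit_detection(survey$observations, pl, formula = form,
                    segments = survey$segments, key = key)
    }
  })
  fits <- name_fits(fits)
  state <- list(survey = survey, detection_fits = fits)
  saveRDS(state, stage_path(cfg, "detection"))
  report <- purrr::map_dfr(fits, glance)
  readr::write_csv(report, file.path(cfg$outdir, "detection_report.csv"),
                   progress = FALSE)
  log_stage(cfg, "fit-detection",
            sprintf("platforms=%d", length(fits)))
  invisible(fits)
}

cfg_terms <- function(cfg) {
  purrr::map(cfg$dsm$terms %||% list(list(covariates = c("x", "y"), k = 20)),
             function(t) sm(unlist(t$covariates), k = t$k %||% 10,
                            bs = t$bs %||% "ts"))
}

#' @rdname run_simulate
#' @export
run_fit_dsm <- function(cfg) {
  cfg <- ensure_cfg(cfg)
  state <- require_stage(cfg, "detection")
  fit <- fit_dsm(state$survey$segments, state$detection_fits,
                 terms = cfg_terms(cfg),
                 variant = cfg$dsm$variant %||% "A",
                 family = cfg$dsm$family %||% "tweedie")
  fit <- propagate_variance(fit)
  saveRDS(fit, stage_path(cfg, "dsm"))
  readr::write_csv(tidy(fit), file.path(cfg$outdir, "dsm_report.csv"),
                   progress = FALSE)
  log_stage(cfg, "fit-dsm", sprintf("variant=%s aic=%.4f",
                                    fit$variant, model_aic(fit)))
  invisible(fit)
}

#' @rdname run_simulate
#' @export
run_predict <- function(cfg) {
  cfg <- ensure_cfg(cfg)
  fit <- require_stage(cfg, "dsm")
  grid <- readr::read_csv(cfg_data_paths(cfg)$grid, show_col_types = FALSE,
                          progress = FALSE)
  est <- abundance(fit, grid,
                   B = cfg$uncertainty$B %||% 1000,
                   sampler = cfg$uncertainty$sampler %||% "mvn",
                   seed = as.integer(cfg$seed))
  saveRDS(est, stage_path(cfg, "abundance"))
  readr::write_csv(dplyr::left_join(grid, est$cells, by = "cell_id"),
                   file.path(cfg$outdir, "grid_predictions.csv"),
                   progress = FALSE)
  yaml::write_yaml(list(N_hat = est$N_hat, cv_posterior = est$cv_posterior,
                        cv_total = est$cv_total,
                        extra_cv = as.list(est$extra_cv),
                        B = est$B, sampler = est$sampler,
                        seed = as.integer(cfg$seed),
                        config_hash = cfg$config_hash),
                  file.path(cfg$outdir, "abundance_report.yaml"))
  log_stage(cfg, "predict", sprintf("N_hat=%.6f cv=%.6f",
                                    est$N_hat, est$cv_total))
  invisible(est)
}

#' @rdname run_simulate
#' @export
run_report <- function(cfg) {
  cfg <- ensure_cfg(cfg)
  state <- require_stage(cfg, "detection")
  variants <- cfg$report$variants %||% c("A", "B", "C")
  if (length(state$detection_fits) < 2) variants <- "A"
  rows <- purrr::map_dfr(variants, function(v) {
    fit <- fit_dsm(state$survey$segments, state$detection_fits,
                   terms = cfg_terms(cfg), variant = v,
                   family = cfg$dsm$family %||% "tweedie")
    oe <- observed_expected(fit, "platform_id")
    row <- tibble::tibble(variant = v, aic = model_aic(fit),
                          chisq = attr(oe, "chisq"))
    if (v != "A") {
      grid <- readr::read_csv(cfg_data_paths(cfg)$grid,
                              show_col_types = FALSE, progress = FALSE)
      diffs <- platform_difference(fit, grid)
      row$mean_abs_difference <- mean(abs(diffs$difference))
    } else {
      row$mean_abs_difference <- 0
    }
    row
  })
  rows$delta_aic <- rows$aic - min(rows$aic)
  readr::write_csv(rows, file.path(cfg$outdir, "model_comparison.csv"),
                   progress = FALSE)
  log_stage(cfg, "report", sprintf("variants=%s",
                                   paste(variants, collapse = "")))
  invisible(rows)
}

#' @rdname run_simulate
#' @export
run_pipeline <- function(cfg) {
  cfg <- ensure_cfg(cfg)
  run_simulate(cfg)
  run_fit_detection(cfg)
  run_fit_dsm(cfg)
  est <- run_predict(cfg)
  run_report(cfg)
  invisible(est)
}
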