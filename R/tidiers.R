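#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a detection-function fit
#'
#' @param x A `"detection_fit"`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `std.error`. Scale
#'   parameters are on the log-sigma scale; the hazard shape is on the
#'   log(shape - 1) scale.
#' @method tidy detection_fit
#' @export
tidy.detection_fit <- function(x, ...) {
  tibble::tibble(term = names(x$theta), estimate = unname(x$theta),
                 std.error = sqrt(diag(x$V_theta)))
}

#' @rdname tidy.detection_fit
#' @method glance detection_fit
#' @export
glance.detection_fit <- function(x, ...) {
  tibble::tibble(platform_id = x$platform_id, key = x$key,
                 logLik = x$loglik, AIC = x$aic, df = x$n_par,
                 nobs = x$n_obs)
}

#' @rdname tidy.detection_fit
#' @method tidy conditional_fit
#' @export
tidy.conditional_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coef), estimate = unname(x$coef),
                 std.error = sqrt(diag(x$vcov)))
}

#' Tidy a fitted density surface model
#'
#' @param x A `"dsm_fit"`.
#' @param ... Unused.
#' @return One row per model term: parametric terms with estimates and
#'   standard errors, smooth terms with effective degrees of freedom.
#' @method tidy dsm_fit
#' @export
tidy.dsm_fit <- function(x, ...) {
  s <- summary(x$gam)
  param <- tibble::tibble(
    term = rownames(s$p.table), type = "parametric",
    estimate = s$p.table[, 1], std.error = s$p.table[, 2],
    edf = NA_real_, p.value = s$p.table[, 4])
  if (!is.null(s$s.table) && nrow(s$s.table) > 0) {
    smooth <- tibble::tibble(
      term = rownames(s$s.table), type = "smooth",
      estimate = NA_real_, std.error = NA_real_,
      edf = s$s.table[, "edf"], p.value = s$s.table[, ncol(s$s.table)])
  } else smooth <- NULL
  dplyr::bind_rows(param, smooth)
}

#' @rdname tidy.dsm_fit
#' @method glance dsm_fit
#' @export
glance.dsm_fit <- function(x, ...) {
  s <- summary(x$gam)
  tibble::tibble(variant = x$variant, family = x$family,
                 deviance.explained = s$dev.expl,
                 reml = as.numeric(x$gam$gcv.ubre),
                 AIC = stats::AIC(x$gam),
                 edf = sum(x$gam$edf), nobs = nrow(x$segments),
                 propagated = isTRUE(x$propagated))
}

#' Tidy an abundance estimate
#'
#' @param x An `"abundance_estimate"`.
#' @param ... Unused.
#' @return `tidy()` gives the per-cell table; `glance()` a one-row summary.
#' @method tidy abundance_estimate
#' @export
tidy.abundance_estimate <- function(x, ...) x$cells

#' @rdname tidy.abundance_estimate
#' @method glance abundance_estimate
#' @export
glance.abundance_estimate <- function(x, ...) {
  tibble::tibble(N_hat = x$N_hat, cv_posterior = x$cv_posterior,
                 cv_total = x$cv_total, B = x$B, sampler = x$sampler)
}
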