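#' Detection function forms
#'
#' Probability of detecting an object at distance `x` from the line or point.
#' Two standard key functions are supported: half-normal,
#' \eqn{g(x) = \exp(-x^2 / (2\sigma^2))}, and hazard-rate,
#' \eqn{g(x) = 1 - \exp(-(x/\sigma)^{-b})} with shape \eqn{b > 1}. Both give
#' certain detection on the line, \eqn{g(0) = 1}, and are non-increasing in
#' distance.
#'
#' @param x Distance(s), non-negative.
#' @param key `"half_normal"` or `"hazard_rate"`.
#' @param sigma Scale parameter(s), positive (recycled against `x`).
#' @param shape Hazard-rate shape \eqn{b > 1}; ignored for half-normal.
#' @return Detection probabilities in (0, 1].
#' @examples
#' detection_g(1, "half_normal", sigma = 1)       # exp(-0.5)
#' detection_g(2, "hazard_rate", sigma = 2, shape = 3)  # 1 - exp(-1)
#' @export
detection_g <- function(x, key = c("half_normal", "hazard_rate"),
                        sigma, shape = NULL) {
  key <- match.arg(key)
  if (any(x < 0)) stop_mdsm("Distances must be >= 0.", "mdsm_domain_error")
  if (any(sigma <= 0)) stop_mdsm("`sigma` must be > 0.", "mdsm_domain_error")
  if (key == "half_normal") {
    exp(-x^2 / (2 * sigma^2))
  } else {
    if (is.null(shape) || any(shape <= 1)) {
      stop_mdsm("Hazard-rate `shape` must be > 1.", "mdsm_domain_error")
    }
    ifelse(x == 0, 1, 1 - exp(-(x / sigma)^(-shape)))
  }
}

# integral of g over [lo, hi]; closed form for half-normal, else Gauss-Kronrod
# style adaptive quadrature at tight tolerance
integral_g_line <- function(key, sigma, shape, lo, hi,
                            method = c("auto", "closed", "quadrature")) {
  method <- match.arg(method)
  if (key == "half_normal" && method != "quadrature") {
    return(sigma * sqrt(2 * pi) * (pnorm(hi / sigma) - pnorm(lo / sigma)))
  }
  out <- tryCatch(
    integrate(function(x) detection_g(x, key, sigma, shape), lo, hi,
              abs.tol = 1e-10, rel.tol = 1e-10),
    error = function(e) NULL)
  if (is.null(out) || out$message != "OK") {
    stop_mdsm(sprintf(
      "Quadrature failed for key=%s sigma=%g on [%g, %g].",
      key, sigma, lo, hi), "mdsm_numeric_error")
  }
  out$value
}

integral_rg_point <- function(key, sigma, shape, lo, hi,
                              method = c("auto", "closed", "quadrature")) {
  method <- match.arg(method)
  if (key == "half_normal" && method != "quadrature") {
    # stable for w << sigma: avoids 1 - exp(-t) cancellation
    return(-sigma^2 * exp(-lo^2 / (2 * sigma^2)) *
             expm1(-(hi^2 - lo^2) / (2 * sigma^2)))
  }
  out <- tryCatch(
    integrate(function(r) r * detection_g(r, key, sigma, shape), lo, hi,
              abs.tol = 1e-10, rel.tol = 1e-10),
    error = function(e) NULL)
  if (is.null(out) || out$message != "OK") {
    stop_mdsm("Quadrature failed for the point-transect integral.",
              "mdsm_numeric_error")
  }
  out$value
}

#' Average detection probability within the covered strip
#'
#' Integrates distance out of the detection function. For line transects
#' perpendicular distances are uniform over the half-width, so
#' \eqn{p = w^{-1} \int_0^w g(x)\,dx}; for point transects radial distances
#' have a triangular density, so \eqn{p = 2 w^{-2} \int_0^w r\,g(r)\,dr}.
#' Half-normal uses the closed form; hazard-rate uses adaptive quadrature at
#' absolute tolerance 1e-10. `average_p_line(key = "strip")` is exactly 1.
#'
#' @inheritParams detection_g
#' @param w Truncation distance, positive.
#' @param method `"auto"` (closed form where available), `"closed"`, or
#'   `"quadrature"`.
#' @return Average detection probability(ies) in (0, 1].
#' @examples
#' average_p_line("half_normal", sigma = 1, w = 1)   # 0.855624
#' average_p_point("half_normal", sigma = 1, w = 1)  # 0.786939
#' @export
average_p_line <- function(key = c("half_normal", "hazard_rate", "strip"),
                           sigma = NULL, w, shape = NULL,
                           method = c("auto", "closed", "quadrature")) {
  key <- match.arg(key)
  method <- match.arg(method)
  if (any(w <= 0)) stop_mdsm("`w` must be > 0.", "mdsm_domain_error")
  if (key == "strip") return(rep(1, max(length(sigma), 1L)))
  vapply(seq_along(sigma), function(i) {
    integral_g_line(key, sigma[i], shape, 0, w, method) / w
  }, numeric(1))
}

#' @rdname average_p_line
#' @export
average_p_point <- function(key = c("half_normal", "hazard_rate", "strip"),
                            sigma = NULL, w, shape = NULL,
                            method = c("auto", "closed", "quadrature")) {
  key <- match.arg(key)
  method <- match.arg(method)
  if (any(w <= 0)) stop_mdsm("`w` must be > 0.", "mdsm_domain_error")
  if (key == "strip") return(rep(1, max(length(sigma), 1L)))
  vapply(seq_along(sigma), function(i) {
    2 * integral_rg_point(key, sigma[i], shape, 0, w, method) / w^2
  }, numeric(1))
}

# ---- maximum likelihood fitting ------------------------------------------

# split theta into scale coefficients and (for hazard) the shape transform;
# shape b = 1 + exp(phi) enforces b > 1
theta_parts <- function(theta, key, q) {
  list(theta_sigma = theta[seq_len(q)],
       shape = if (key == "hazard_rate") 1 + exp(theta[q + 1L]) else NULL)
}

# negative log-likelihood for exact or binned distances, line or point
detection_negloglik <- function(theta, key, X, w, transect,
                                distance = NULL, bin = NULL,
                                cutpoints = NULL) {
  q <- ncol(X)
  parts <- theta_parts(theta, key, q)
  sigma <- exp(drop(X %*% parts$theta_sigma))
  if (any(!is.finite(sigma)) || any(sigma <= 0)) return(1e10)
  shape <- parts$shape
  ll <- tryCatch({
    if (transect == "line") {
      denom <- vapply(sigma, function(s)
        integral_g_line(key, s, shape, 0, w), numeric(1))
      if (is.null(bin)) {
        sum(log(detection_g(distance, key, sigma, shape)) - log(denom))
      } else {
        num <- vapply(seq_along(sigma), function(i)
          integral_g_line(key, sigma[i], shape,
                          cutpoints[bin[i]], cutpoints[bin[i] + 1L]),
          numeric(1))
        sum(log(num) - log(denom))
      }
    } else {
      denom <- vapply(sigma, function(s)
        integral_rg_point(key, s, shape, 0, w), numeric(1))
      if (is.null(bin)) {
        sum(log(distance * detection_g(distance, key, sigma, shape)) -
              log(denom))
      } else {
        num <- vapply(seq_along(sigma), function(i)
          integral_rg_point(key, sigma[i], shape,
                            cutpoints[bin[i]], cutpoints[bin[i] + 1L]),
          numeric(1))
        sum(log(num) - log(denom))
      }
    }
  }, error = function(e) -Inf)
  if (!is.finite(ll)) return(1e10)
  -ll
}

# average p per row of a covariate design matrix
average_p_design <- function(theta, key, X, w, transect) {
  q <- ncol(X)
  parts <- theta_parts(theta, key, q)
  sigma <- exp(drop(X %*% parts$theta_sigma))
  if (transect == "line") {
    average_p_line(key, sigma, w, parts$shape)
  } else {
    average_p_point(key, sigma, w, parts$shape)
  }
}

# central finite differences of log p w.r.t. theta, step 1e-5 * (1 + |theta|)
dlogp_dtheta <- function(theta, key, X, w, transect) {
  base <- log(average_p_design(theta, key, X, w, transect))
  out <- matrix(0, nrow(X), length(theta))
  for (j in seq_along(theta)) {
    h <- 1e-5 * (1 + abs(theta[j]))
    up <- dn <- theta
    up[j] <- theta[j] + h
    dn[j] <- theta[j] - h
    out[, j] <- (log(average_p_design(up, key, X, w, transect)) -
                   log(average_p_design(dn, key, X, w, transect))) / (2 * h)
  }
  colnames(out) <- names(theta)
  out
}

#' Fit a single-platform detection function by maximum likelihood
#'
#' Fits a half-normal or hazard-rate detection function to the platform's
#' (already truncated) observations, with optional covariates on the scale
#' parameter via a log link, \eqn{\sigma = \exp(z^\top \theta_\sigma)}. Exact
#' distances use the conditional density \eqn{g(x)/\int_0^w g} (line) or
#' \eqn{r g(r)/\int_0^w r g} (point); binned distances use the multinomial
#' bin-probability likelihood conditioned on detection. Detection covariates
#' must be segment-level (vary between but not within segments), because they
#' re-enter the count model through the per-segment offset.
#'
#' @param observations Observation tibble (rows for this platform are
#'   selected automatically when a `platform_id` column is present).
#' @param platform One-row platform tibble from [platform()] (or a registry
#'   containing it, in which case the observations' platform is used).
#' @param formula Scale-covariate formula, e.g. `~ 1` or `~ beaufort`;
#'   covariate columns must exist in both `observations` and `segments`.
#' @param segments Optional segment tibble for this platform; when supplied,
#'   per-segment average detection probabilities and the gradient of
#'   \eqn{\log p} with respect to \eqn{\theta} are stored on the fit (needed
#'   for offsets and variance propagation).
#' @param key `"half_normal"` (default) or `"hazard_rate"`.
#' @return An object of class `"detection_fit"`: estimates `theta`, covariance
#'   `V_theta` (inverse observed information), `loglik`, `aic`, and — when
#'   `segments` was given — `p_by_segment` and `dlogp_dtheta`.
#' @export
fit_detection <- function(observations, platform, formula = ~1,
                          segments = NULL,
                          key = c("half_normal", "hazard_rate")) {
  key <- match.arg(key)
  if (nrow(platform) > 1L) {
    ids <- unique(observations$platform_id)
    if (length(ids) != 1L) {
      stop_mdsm("Pass a single platform or single-platform observations.",
                "mdsm_validation_error")
    }
    platform <- platform_row(platform, ids)
  }
  if (platform$protocol == "strip") {
    return(strip_detection_fit(platform, segments))
  }
  if ("platform_id" %in% names(observations)) {
    observations <- observations[
      observations$platform_id == platform$platform_id, , drop = FALSE]
  }
  if (nrow(observations) == 0L) {
    stop_mdsm(sprintf("No observations within truncation for platform '%s'.",
                      platform$platform_id), "mdsm_validation_error")
  }
  transect <- if (platform$protocol == "point") "point" else "line"
  w <- platform$truncation_w
  cutpoints <- platform$bin_cutpoints[[1]]
  binned <- !is.null(cutpoints)

  covars <- all.vars(formula)
  required_cols(observations, covars, "observations (detection covariates)")
  # detection covariates must be constant within segment (count-model offset
  # is per-segment); observation-level variation is rejected, the workaround
  # being to bin the covariate into per-segment classes
  if (length(covars) > 0) {
    chk <- observations |>
      dplyr::group_by(.data$segment_id) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(covars),
                                     ~ dplyr::n_distinct(.x)),
                       .groups = "drop")
    if (any(as.matrix(chk[, covars]) > 1)) {
      stop_mdsm(paste(
        "Detection covariates must be segment-level.",
        "Aggregate observation-level covariates to segment classes first."),
        "mdsm_validation_error")
    }
  }
  X <- model.matrix(formula, observations)
  if (any(observations$distance < 0, na.rm = TRUE)) {
    stop_mdsm("Negative distances are not allowed.", "mdsm_validation_error")
  }
  bin <- NULL
  distance <- observations$distance %||% NULL
  if (binned) {
    bin <- observations$bin
    if (is.null(bin) || any(is.na(bin))) {
      if (is.null(distance) || any(is.na(distance))) {
        stop_mdsm("Binned platform needs `bin` or exact `distance`.",
                  "mdsm_validation_error")
      }
      bin <- assign_bins(distance, cutpoints)
    }
    if (any(bin < 1 | bin > length(cutpoints) - 1L)) {
      stop_mdsm("Bin indices out of range.", "mdsm_validation_error")
    }
    distance <- NULL
  }

  # starting values: sigma at ~60% of truncation, hazard shape b = 2
  start <- c(log(0.6 * w), rep(0, ncol(X) - 1L))
  names(start) <- paste0("sigma:", colnames(X))
  if (key == "hazard_rate") start <- c(start, `shape:phi` = 0)

  fn <- function(th) detection_negloglik(th, key, X, w, transect,
                                         distance, bin, cutpoints)
  opt <- optim(start, fn, method = "BFGS", hessian = TRUE,
               control = list(maxit = 500, reltol = 1e-12))
  if (opt$convergence != 0) {
    stop_mdsm(sprintf(
      "Detection optimizer did not converge (code %d): %s",
      opt$convergence, opt$message %||% ""), "mdsm_numeric_error")
  }
  theta <- opt$par
  H <- opt$hessian
  ev <- eigen((H + t(H)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10 * max(abs(ev))) {
    rlang::warn("Detection Hessian not positive definite; using pseudo-inverse.")
    V <- MASS::ginv((H + t(H)) / 2)
    dimnames(V) <- list(names(theta), names(theta))
  } else {
    V <- solve(H)
  }

  fit <- structure(list(
    platform_id = platform$platform_id,
    key = key, transect = transect, binned = binned,
    formula = formula, w = w, cutpoints = cutpoints,
    theta = theta, V_theta = V,
    loglik = -opt$value, n_par = length(theta),
    aic = 2 * opt$value + 2 * length(theta),
    n_obs = nrow(observations),
    data_digest = digest_distances(observations, binned),
    distances = if (binned) {
      (cutpoints[bin] + cutpoints[bin + 1L]) / 2
    } else distance
  ), class = "detection_fit")
  if (!is.null(segments)) {
    fit <- add_segment_detectability(fit, segments)
  }
  fit
}

digest_distances <- function(observations, binned) {
  v <- if (binned && "bin" %in% names(observations)) {
    observations$bin
  } else observations$distance
  c(n = nrow(observations), sum = sum(v, na.rm = TRUE))
}

# populate p_by_segment / dlogp_dtheta for a platform's segments
add_segment_detectability <- function(fit, segments) {
  if ("platform_id" %in% names(segments)) {
    segments <- segments[segments$platform_id == fit$platform_id, ,
                         drop = FALSE]
  }
  covars <- all.vars(fit$formula)
  required_cols(segments, covars, "segments (detection covariates)")
  X <- model.matrix(fit$formula, segments)
  p <- average_p_design(fit$theta, fit$key, X, fit$w, fit$transect)
  fit$p_by_segment <- tibble::tibble(segment_id = segments$segment_id, p = p)
  D <- dlogp_dtheta(fit$theta, fit$key, X, fit$w, fit$transect)
  rownames(D) <- segments$segment_id
  fit$dlogp_dtheta <- D
  fit
}

#' @rdname fit_detection
#' @param object,newdata Used by the `predict` method: a fitted
#'   `"detection_fit"` and a tibble of segments with the detection covariates.
#' @param ... Unused.
#' @export
predict.detection_fit <- function(object, newdata, ...) {
  X <- model.matrix(object$formula, newdata)
  average_p_design(object$theta, object$key, X, object$w, object$transect)
}

# a strip/plot "fit": certain detection, no parameters, no uncertainty
strip_detection_fit <- function(platform, segments = NULL) {
  fit <- structure(list(
    platform_id = platform$platform_id,
    key = "strip", transect = "line", binned = FALSE,
    formula = ~1, w = platform$truncation_w, cutpoints = NULL,
    theta = setNames(numeric(0), character(0)),
    V_theta = matrix(0, 0, 0),
    loglik = NA_real_, n_par = 0L, aic = NA_real_,
    n_obs = 0L, data_digest = c(n = 0, sum = 0)
  ), class = "detection_fit")
  if (!is.null(segments)) {
    if ("platform_id" %in% names(segments)) {
      segments <- segments[segments$platform_id == platform$platform_id, ,
                           drop = FALSE]
    }
    fit$p_by_segment <- tibble::tibble(segment_id = segments$segment_id, p = 1)
    fit$dlogp_dtheta <- matrix(0, nrow(segments), 0,
                               dimnames = list(segments$segment_id, NULL))
  }
  fit
}

#' Compare detection-function fits by AIC
#'
#' @param ... Fitted `"detection_fit"` objects (or a single list of them) on
#'   the same data and truncation. Strip "fits" carry no likelihood and are
#'   excluded with a message.
#' @return A tibble sorted by AIC with a `delta_aic` column.
#' @export
detection_aic <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && !inherits(fits[[1]], "detection_fit")) {
    fits <- fits[[1]]
  }
  is_strip <- vapply(fits, function(f) f$key == "strip", logical(1))
  if (any(is_strip)) {
    rlang::inform(sprintf(
      "Excluding %d strip fit(s): certain detection has no likelihood.",
      sum(is_strip)))
    fits <- fits[!is_strip]
  }
  if (length(fits) == 0L) {
    stop_mdsm("No likelihood-based fits to compare.", "mdsm_validation_error")
  }
  digests <- t(vapply(fits, function(f) f$data_digest, numeric(2)))
  if (nrow(unique(round(digests, 8))) > 1L) {
    stop_mdsm("AIC comparison requires fits on identical data/truncation.",
              "mdsm_validation_error")
  }
  out <- purrr::map_dfr(fits, function(f) tibble::tibble(
    platform_id = f$platform_id, key = f$key,
    formula = deparse(f$formula), n_par = f$n_par,
    loglik = f$loglik, aic = f$aic))
  out <- dplyr::arrange(out, .data$aic)
  dplyr::mutate(out, delta_aic = .data$aic - min(.data$aic))
}

#' @export
print.detection_fit <- function(x, ...) {
  cat(sprintf("<detection_fit> platform '%s' (%s, %s%s)\n", x$platform_id,
              x$key, x$transect, if (x$binned) ", binned" else ""))
  if (x$key != "strip") {
    est <- tibble::tibble(term = names(x$theta), estimate = x$theta,
                          std.error = sqrt(diag(x$V_theta)))
    print(est)
    cat(sprintf("logLik %.3f  AIC %.3f  n %d\n", x$loglik, x$aic, x$n_obs))
  } else {
    cat("certain detection: p = 1\n")
  }
  invisible(x)
}
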