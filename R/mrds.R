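#' Build conditional detection trials from double-observer data
#'
#' Under the independent-observer protocol each observer's detections set up
#' binary trials for the other: every object seen by observer 2 is a trial for
#' observer 1 (success if observer 1 also saw it, i.e. a duplicate), and vice
#' versa. The stacked trials drive a logistic model for the conditional
#' detection probability.
#'
#' @param observations Observation tibble with `detected_by_1` and
#'   `detected_by_2` 0/1 columns (duplicates have both equal to 1) and a
#'   `distance` column.
#' @return A tibble of trials with columns `observer`, `success`, `distance`
#'   and any other observation columns.
#' @export
mrds_trials <- function(observations) {
  required_cols(observations, c("detected_by_1", "detected_by_2", "distance"),
                "observations")
  tot <- observations$detected_by_1 + observations$detected_by_2
  if (any(tot < 1)) {
    stop_mdsm("Every MRDS observation needs at least one detector.",
              "mdsm_validation_error")
  }
  base <- dplyr::select(observations,
                        -dplyr::any_of(c("detected_by_1", "detected_by_2")))
  t1 <- dplyr::mutate(base[observations$detected_by_2 == 1, , drop = FALSE],
                      observer = 1L)
  t1$success <- observations$detected_by_1[observations$detected_by_2 == 1]
  t2 <- dplyr::mutate(base[observations$detected_by_1 == 1, , drop = FALSE],
                      observer = 2L)
  t2$success <- observations$detected_by_2[observations$detected_by_1 == 1]
  dplyr::bind_rows(t1, t2)
}

#' Fit the conditional (mark-recapture) detection model
#'
#' Logistic regression of trial success on distance (and optional covariates),
#' pooled across the two observers by default; include `observer` in the
#' formula for per-observer intercepts/slopes. Complete separation triggers a
#' warning and a weakly ridge-penalized refit.
#'
#' @param observations Double-observer observation tibble (see
#'   [mrds_trials()]).
#' @param formula Right-hand-side formula over `distance`, `observer` and
#'   covariates, e.g. `~ distance`.
#' @return An object of class `"conditional_fit"` with elements `coef`,
#'   `vcov`, `loglik`, `trials`.
#' @export
fit_conditional <- function(observations, formula = ~distance) {
  trials <- mrds_trials(observations)
  n_dup <- sum(observations$detected_by_1 == 1 &
                 observations$detected_by_2 == 1)
  if (n_dup == 0L) {
    stop_mdsm("No duplicate detections: g(0) is inestimable.",
              "mdsm_validation_error")
  }
  f <- stats::update(formula, success ~ .)
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(f, family = binomial(), data = trials),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  X <- model.matrix(fit)
  if (separation || any(abs(coef(fit)) > 15)) {
    rlang::warn(paste("Possible complete separation in the conditional model;",
                      "refitting with a weak ridge penalty."))
    y <- trials$success
    ridge <- 1e-2
    nll <- function(b) {
      eta <- drop(X %*% b)
      -sum(y * eta - log1p(exp(eta))) + ridge * sum(b^2) / 2
    }
    opt <- optim(rep(0, ncol(X)), nll, method = "BFGS", hessian = TRUE)
    cf <- setNames(opt$par, colnames(X))
    V <- solve(opt$hessian)
    ll <- -(opt$value - ridge * sum(cf^2) / 2)
  } else {
    cf <- coef(fit)
    V <- vcov(fit)
    ll <- as.numeric(stats::logLik(fit))
  }
  structure(list(coef = cf, vcov = V, loglik = ll, formula = formula,
                 trials = trials, n_trials = nrow(trials),
                 n_duplicates = n_dup, X_names = colnames(X)),
            class = "conditional_fit")
}

# design row(s) at distance 0 for each observer
g0_design <- function(fit, newdata = NULL) {
  nd <- newdata %||% tibble::tibble(distance = 0)
  nd <- nd[rep(1, 2), , drop = FALSE]
  nd$distance <- 0
  nd$observer <- c(1L, 2L)
  f <- stats::update(fit$formula, NULL ~ .)
  model.matrix(f, nd)
}

#' Combined probability of detection on the trackline
#'
#' Under full independence of the two observers, the probability that an
#' object on the line is seen by at least one of them is
#' \eqn{g(0) = p_1(0) + p_2(0) - p_1(0) p_2(0)}, where \eqn{p_j(0)} is
#' observer j's conditional detection probability evaluated at distance 0.
#' The gradient of \eqn{\log g(0)} with respect to the logistic coefficients
#' is retained for variance propagation.
#'
#' @param fit A `"conditional_fit"`.
#' @param newdata Optional one-row tibble giving covariate values at which to
#'   evaluate g(0) (distance is forced to 0).
#' @return A list with `g0`, per-observer `p0`, `grad_log_g0` and the
#'   coefficient covariance `V_theta`.
#' @export
combined_g0 <- function(fit, newdata = NULL) {
  X0 <- g0_design(fit, newdata)
  eta <- drop(X0 %*% fit$coef)
  p0 <- unname(plogis(eta))
  g0 <- p0[1] + p0[2] - p0[1] * p0[2]
  # d g0 / d theta = (1-p2) p1' + (1-p1) p2', with p_j' = p_j (1-p_j) x_j
  d1 <- p0[1] * (1 - p0[1]) * X0[1, ]
  d2 <- p0[2] * (1 - p0[2]) * X0[2, ]
  grad <- (1 - p0[2]) * d1 + (1 - p0[1]) * d2
  list(g0 = g0, p0 = p0, grad_log_g0 = grad / g0, V_theta = fit$vcov)
}

#' Fit an independent-observer MRDS detection model
#'
#' Two-part model for a double-platform line transect: a distance-sampling
#' detection function fitted to the pooled unique detections, and a
#' conditional logistic model for trackline detection fitted to the
#' duplicate trials. The platform's per-segment detectability is the product
#' \eqn{g(0)\, p(\hat\theta; z)}; the parameter vector stacks the two parts
#' and their covariance is block-diagonal, so detection and g(0) uncertainty
#' both feed the variance propagation.
#'
#' @inheritParams fit_detection
#' @param ds_formula Scale-covariate formula for the distance model.
#' @param g0_formula Formula for the conditional model (distance, observer,
#'   covariates).
#' @return An object of classes `"mrds_fit"` and `"detection_fit"`.
#' @export
fit_mrds <- function(observations, platform, ds_formula = ~1,
                     g0_formula = ~distance, segments = NULL,
                     key = c("half_normal", "hazard_rate")) {
  key <- match.arg(key)
  if (nrow(platform) > 1L) {
    platform <- platform_row(platform, unique(observations$platform_id))
  }
  if ("platform_id" %in% names(observations)) {
    observations <- observations[
      observations$platform_id == platform$platform_id, , drop = FALSE]
  }
  ds <- fit_detection(observations, platform, formula = ds_formula,
                      segments = segments, key = key)
  cond <- fit_conditional(observations, g0_formula)
  g0c <- combined_g0(cond)

  theta <- c(ds$theta, setNames(cond$coef, paste0("g0:", names(cond$coef))))
  V <- block_diag(list(ds$V_theta, cond$vcov))
  dimnames(V) <- list(names(theta), names(theta))

  fit <- ds
  fit$theta <- theta
  fit$V_theta <- V
  fit$g0 <- g0c$g0
  fit$conditional <- cond
  fit$loglik <- ds$loglik + cond$loglik
  fit$n_par <- length(theta)
  fit$aic <- -2 * fit$loglik + 2 * fit$n_par
  if (!is.null(fit$p_by_segment)) {
    fit$p_by_segment$p <- fit$p_by_segment$p * g0c$g0
    D <- fit$dlogp_dtheta
    Dg <- matrix(rep(g0c$grad_log_g0, each = nrow(D)), nrow = nrow(D))
    fit$dlogp_dtheta <- cbind(D, Dg)
    colnames(fit$dlogp_dtheta) <- names(theta)
    rownames(fit$dlogp_dtheta) <- rownames(D)
  }
  class(fit) <- c("mrds_fit", "detection_fit")
  fit
}

#' Apply fixed detectability multipliers to segments
#'
#' Attaches a fixed trackline detection probability `g0` and availability `u`
#' (each with a CV) to segments, e.g. an aerial platform's externally
#' estimated g(0) = 0.67 and availability 0.37. The product `g0 * u`
#' multiplies the detection probability in the count-model offset; the CVs
#' never enter the model refit and are combined into the final abundance CV
#' by squared addition.
#'
#' @param segments Segment tibble.
#' @param g0,u Multipliers in (0, 1].
#' @param g0_cv,u_cv Non-negative CVs.
#' @param platform_id Optional platform to restrict the assignment to; other
#'   rows keep their existing (or default 1) multipliers.
#' @return `segments` with `g0`, `g0_cv`, `u`, `u_cv` and `multiplier`
#'   columns.
#' @export
apply_fixed_multipliers <- function(segments, g0 = 1, g0_cv = 0, u = 1,
                                    u_cv = 0, platform_id = NULL) {
  for (p in c(g0, u)) {
    if (p <= 0 || p > 1) {
      stop_mdsm("Multipliers must lie in (0, 1].", "mdsm_validation_error")
    }
  }
  if (g0_cv < 0 || u_cv < 0) {
    stop_mdsm("Multiplier CVs must be non-negative.", "mdsm_validation_error")
  }
  for (col in c("g0", "u")) {
    if (!(col %in% names(segments))) segments[[col]] <- 1
  }
  for (col in c("g0_cv", "u_cv")) {
    if (!(col %in% names(segments))) segments[[col]] <- 0
  }
  rows <- if (is.null(platform_id)) {
    rep(TRUE, nrow(segments))
  } else segments$platform_id %in% platform_id
  segments$g0[rows] <- g0
  segments$g0_cv[rows] <- g0_cv
  segments$u[rows] <- u
  segments$u_cv[rows] <- u_cv
  dplyr::mutate(segments, multiplier = .data$g0 * .data$u)
}
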