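#' Joint covariance of all detection-function parameters
#'
#' Assuming independence between the platforms' detection fits, their
#' parameter covariances stack into a block-diagonal matrix, one block per
#' platform in fit order. Strip platforms have no detection parameters and
#' contribute no block.
#'
#' @param detection_fits List of `"detection_fit"` objects.
#' @return A block-diagonal matrix with attribute `"blocks"`, a named list of
#'   column indices per platform (possibly 0 x 0).
#' @export
assemble_v_theta <- function(detection_fits) {
  detection_fits <- name_fits(detection_fits)
  keep <- purrr::keep(detection_fits, function(f) length(f$theta) > 0)
  for (f in keep) {
    ev <- eigen((f$V_theta + t(f$V_theta)) / 2, symmetric = TRUE,
                only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1)) {
      stop_mdsm(sprintf("V_theta block for platform '%s' is not PSD.",
                        f$platform_id), "mdsm_numeric_error")
    }
  }
  V <- block_diag(purrr::map(keep, "V_theta"))
  blocks <- list()
  at <- 0L
  for (f in keep) {
    blocks[[f$platform_id]] <- at + seq_along(f$theta)
    at <- at + length(f$theta)
  }
  attr(V, "blocks") <- blocks
  V
}

# derivative-of-log-p design matrix: one column per detection parameter,
# rows are segments (zero for other platforms' rows)
derivative_columns <- function(fit, v_theta) {
  blocks <- attr(v_theta, "blocks")
  segs <- fit$segments
  D <- matrix(0, nrow(segs), nrow(v_theta))
  colnames(D) <- colnames(v_theta)
  for (id in names(blocks)) {
    det <- fit$detection_fits[[id]]
    if (is.null(det$dlogp_dtheta)) {
      stop_mdsm(sprintf(
        "Detection fit for '%s' lacks per-segment gradients; refit with `segments`.",
        id), "mdsm_validation_error")
    }
    rows <- which(segs$platform_id == id)
    idx <- match(segs$segment_id[rows], rownames(det$dlogp_dtheta))
    D[rows, blocks[[id]]] <- det$dlogp_dtheta[idx, , drop = FALSE]
  }
  D
}

# family object with nuisance parameters frozen at their estimates, so the
# propagation refit does not re-estimate them
frozen_family <- function(gam_fit) {
  fam <- gam_fit$family
  if (grepl("^Tweedie", fam$family) && !is.null(fam$getTheta)) {
    mgcv::Tweedie(p = fam$getTheta(TRUE), link = "log")
  } else if (grepl("Negative Binomial", fam$family) && !is.null(fam$getTheta)) {
    mgcv::negbin(theta = fam$getTheta(TRUE), link = "log")
  } else {
    fam
  }
}

#' Propagate detection uncertainty into the spatial model
#'
#' Refits the count model with, for each platform, extra columns holding the
#' derivative of the log average detection probability with respect to that
#' platform's detection parameters, evaluated at the estimates (zero in other
#' platforms' rows). The coefficients on these columns are treated as a
#' random effect with mean zero and *fixed* prior covariance `v_theta` — a
#' quadratic approximation to how the offset would change if the detection
#' parameters moved. Because the prior is fixed at the detection fits'
#' covariance (its precision enters as a ridge penalty with smoothing
#' parameter pinned at 1, and the original smoothing and family parameters
#' are also held fixed), this propagates first-stage uncertainty rather than
#' re-estimating it. The refit's posterior covariance covers spline
#' coefficients and detection parameters jointly, including their
#' off-diagonal covariance.
#'
#' @param fit A `"dsm_fit"`.
#' @param v_theta Optional joint detection covariance from
#'   [assemble_v_theta()] (assembled from the fit's detection functions by
#'   default). A zero or empty matrix makes propagation a no-op.
#' @return The fit with elements `gam_vp` (refit), `V_combined` (joint
#'   posterior covariance) and `propagated = TRUE`. If the refit fails, the
#'   original fit is returned with `propagation_failed = TRUE` and a
#'   prominent warning suggesting the delta-method combination.
#' @export
propagate_variance <- function(fit, v_theta = NULL) {
  stopifnot(inherits(fit, "dsm_fit"))
  v_theta <- v_theta %||% assemble_v_theta(fit$detection_fits)
  if (nrow(v_theta) == 0L || all(abs(v_theta) < 1e-14)) {
    # no detection uncertainty: the posterior covariance is the spatial one
    fit$gam_vp <- fit$gam
    fit$V_combined <- fit$gam$Vp
    fit$beta_index <- rep(TRUE, length(coef(fit$gam)))
    fit$propagated <- TRUE
    fit$v_theta <- v_theta
    return(fit)
  }
  D <- derivative_columns(fit, v_theta)
  precision <- psd_inverse(v_theta, "V_theta")
  df <- as.data.frame(fit$segments)
  df$XD <- D
  f2 <- stats::update(fit$formula, . ~ . + XD)
  # fix every smoothing parameter: the ridge penalty on the derivative
  # columns at sp = 1 (so the prior precision is exactly solve(v_theta)),
  # and the original smooths at their estimates
  refit <- tryCatch(
    if (length(fit$gam$sp) > 0) {
      mgcv::gam(f2, family = frozen_family(fit$gam), data = df,
                method = "REML", sp = c(1, fit$gam$sp),
                paraPen = list(XD = list(precision)))
    } else {
      mgcv::gam(f2, family = frozen_family(fit$gam), data = df,
                method = "REML",
                paraPen = list(XD = list(precision, sp = 1)))
    },
    error = function(e) e)
  if (inherits(refit, "error")) {
    rlang::warn(paste(
      "PROPAGATION REFIT FAILED:", conditionMessage(refit),
      "-- falling back to the unpropagated fit; combine detection CV",
      "via delta_detection_cv() instead."))
    fit$propagation_failed <- TRUE
    fit$V_combined <- fit$gam$Vp
    return(fit)
  }
  fit$gam_vp <- refit
  fit$V_combined <- refit$Vp
  dimnames(fit$V_combined) <- list(names(coef(refit)), names(coef(refit)))
  fit$beta_index <- !grepl("^XD", names(coef(refit)))
  fit$propagated <- TRUE
  fit$v_theta <- v_theta
  fit
}

#' Delta-method CV of detectability, per platform
#'
#' An alternative to [propagate_variance()] that assumes independence between
#' the detection fits and the spatial model. Each platform's contribution is
#' the CV of the fitted-count-weighted mean log detectability,
#' \eqn{\sqrt{g^\top V_{\theta k} g}} with
#' \eqn{g = \sum_j w_j\, \partial \log p_{jk} / \partial \theta_k} and
#' weights \eqn{w_j = \hat\mu_j / \sum \hat\mu_j} over that platform's
#' segments.
#'
#' @param fit A `"dsm_fit"` whose detection fits carry per-segment gradients.
#' @return Named numeric vector of per-platform detectability CVs (strip
#'   platforms contribute nothing).
#' @export
delta_detection_cv <- function(fit) {
  mu <- as.numeric(predict(fit$gam, type = "response"))
  out <- numeric(0)
  for (det in fit$detection_fits) {
    if (length(det$theta) == 0L) next
    rows <- which(fit$segments$platform_id == det$platform_id)
    idx <- match(fit$segments$segment_id[rows], rownames(det$dlogp_dtheta))
    w <- mu[rows] / sum(mu[rows])
    g <- drop(w %*% det$dlogp_dtheta[idx, , drop = FALSE])
    out[det$platform_id] <- sqrt(drop(t(g) %*% det$V_theta %*% g))
  }
  out
}

# total quadratic penalty matrix recovered from the posterior covariance
# identity Vp = (X'WX + S)^-1 * scale; symmetrized and clipped to PSD
penalty_from_fit <- function(model) {
  X <- stats::model.matrix(model)
  W <- model$weights
  XWX <- crossprod(X * sqrt(pmax(W, 0)))
  scale <- model$sig2 %||% 1
  St <- scale * solve(model$Vp) - XWX
  St <- (St + t(St)) / 2
  e <- eigen(St, symmetric = TRUE)
  e$values[e$values < 0] <- 0
  e$vectors %*% (e$values * t(e$vectors))
}

# penalized log-likelihood at beta for the supported families (log link)
gam_logpost <- function(model, St) {
  X <- stats::model.matrix(model)
  y <- model$y
  off <- model$offset %||% rep(0, nrow(X))
  fam <- model$family$family
  scale <- model$sig2 %||% 1
  loglik <- if (fam == "poisson") {
    function(mu) sum(dpois(y, mu, log = TRUE))
  } else if (grepl("Negative Binomial", fam)) {
    theta <- model$family$getTheta(TRUE)
    function(mu) sum(dnbinom(y, size = theta, mu = mu, log = TRUE))
  } else if (grepl("^Tweedie", fam)) {
    p <- if (!is.null(model$family$getTheta)) {
      model$family$getTheta(TRUE)
    } else get("p", envir = environment(model$family$variance))
    function(mu) sum(mgcv::ldTweedie(y, mu, p = p, phi = scale)[, 1])
  } else {
    stop_mdsm(sprintf("MH sampling not supported for family '%s'.", fam),
              "mdsm_config_error")
  }
  function(beta) {
    mu <- exp(off + drop(X %*% beta))
    if (any(!is.finite(mu))) return(-Inf)
    loglik(mu) / scale - drop(t(beta) %*% St %*% beta) / (2 * scale)
  }
}

#' Sample model coefficients from their posterior
#'
#' Generates `B` coefficient vectors from the (approximate) posterior of the
#' count model — the propagated model when [propagate_variance()] has been
#' run, so the draws carry detection uncertainty too. Two samplers:
#' `"mvn"` draws directly from the multivariate normal approximation
#' \eqn{N(\hat\beta, V_{\beta,\theta})}; `"mh"` runs an adaptive random-walk
#' Metropolis–Hastings chain on the penalized-likelihood posterior (proposal
#' covariance \eqn{c\,V_{\beta,\theta}}, `c` tuned towards 0.2–0.4 acceptance
#' during a burn-in of `B/5`, thinning 1).
#'
#' @param fit A `"dsm_fit"`.
#' @param B Number of draws (>= 100).
#' @param sampler `"mvn"` or `"mh"`.
#' @param seed Optional integer seed; the same seed reproduces the draws
#'   exactly.
#' @return A `B x p` matrix of coefficient draws with attributes `sampler`
#'   and (for MH) `accept_rate`.
#' @export
posterior_sample <- function(fit, B = 1000, sampler = c("mvn", "mh"),
                             seed = NULL) {
  sampler <- match.arg(sampler)
  if (B < 100) stop_mdsm("`B` must be at least 100.", "mdsm_validation_error")
  model <- fit$gam_vp %||% fit$gam
  mu <- coef(model)
  V <- model$Vp
  if (!is.null(seed)) set.seed(seed)
  if (sampler == "mvn") {
    draws <- mgcv::rmvn(B, mu, V)
    if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1)
    colnames(draws) <- names(mu)
    attr(draws, "sampler") <- "mvn"
    return(draws)
  }
  St <- penalty_from_fit(model)
  logpost <- gam_logpost(model, St)
  p <- length(mu)
  L <- t(chol(V + diag(1e-10 * max(diag(V)), p)))
  cs <- 2.4 / sqrt(p)
  beta <- mu
  lp <- logpost(beta)
  burn <- max(ceiling(B / 5), 50)
  acc_window <- 0L
  for (i in seq_len(burn)) {
    prop <- beta + cs * drop(L %*% rnorm(p))
    lp_new <- logpost(prop)
    if (log(runif(1)) < lp_new - lp) {
      beta <- prop; lp <- lp_new; acc_window <- acc_window + 1L
    }
    if (i %% 50 == 0) {  # tune towards 0.2-0.4 acceptance
      rate <- acc_window / 50
      if (rate < 0.2) cs <- cs * 0.7
      if (rate > 0.4) cs <- cs * 1.4
      acc_window <- 0L
    }
  }
  draws <- matrix(NA_real_, B, p, dimnames = list(NULL, names(mu)))
  acc <- 0L
  for (b in seq_len(B)) {
    prop <- beta + cs * drop(L %*% rnorm(p))
    lp_new <- logpost(prop)
    if (log(runif(1)) < lp_new - lp) {
      beta <- prop; lp <- lp_new; acc <- acc + 1L
    }
    draws[b, ] <- beta
  }
  rate <- acc / B
  if (rate < 0.1 || rate > 0.6) {
    rlang::warn(sprintf("MH acceptance rate %.2f outside [0.1, 0.6].", rate))
  }
  attr(draws, "sampler") <- "mh"
  attr(draws, "accept_rate") <- rate
  draws
}

# build prediction data (replicated per platform for variants B/C) and the
# linear-predictor matrix
prediction_matrix <- function(fit, grid) {
  model <- fit$gam_vp %||% fit$gam
  if (!("cell_id" %in% names(grid))) grid$cell_id <- seq_len(nrow(grid))
  required_cols(grid, "area", "grid")
  if (any(grid$area <= 0)) {
    stop_mdsm("Grid cell areas must be positive.", "mdsm_validation_error")
  }
  covars <- setdiff(all.vars(fit$formula),
                    c("n", ".mdsm_offset", "platform", "platform_ord", "XD"))
  miss <- setdiff(covars, names(grid))
  if (length(miss) > 0) {
    stop_mdsm(sprintf("Grid lacks model covariate(s): %s",
                      paste(miss, collapse = ", ")), "mdsm_schema_error")
  }
  if (any(is.na(grid[covars]))) {
    stop_mdsm("Grid covariates contain missing values.",
              "mdsm_validation_error")
  }
  # extrapolation warning: fraction of cells outside the training range
  out_frac <- 0
  for (v in covars) {
    if (!is.numeric(grid[[v]])) next
    rng <- range(fit$segments[[v]])
    out_frac <- max(out_frac, mean(grid[[v]] < rng[1] | grid[[v]] > rng[2]))
  }
  if (out_frac > 0) {
    rlang::warn(sprintf(
      "%.1f%% of grid cells lie outside the training covariate range.",
      100 * out_frac))
  }
  replicate_platforms <- !("platform_id" %in% names(grid)) &&
    (fit$variant %in% c("B", "C") || isTRUE(fit$simultaneous))
  nd <- if (replicate_platforms) {
    purrr::map_dfr(fit$platforms,
                   function(id) dplyr::mutate(grid, platform_id = id))
  } else grid
  if (!("platform_id" %in% names(nd)) && fit$variant != "A") {
    nd$platform_id <- fit$platforms[1]
  }
  if (fit$variant == "A" && !("platform_id" %in% names(nd))) {
    nd$platform_id <- fit$platforms[1]  # unused by the A design
  }
  nd$platform <- factor(nd$platform_id, levels = fit$platforms)
  nd$platform_ord <- factor(nd$platform_id, levels = fit$platforms,
                            ordered = TRUE)
  df <- as.data.frame(nd)
  cf <- names(coef(model))
  if (any(grepl("^XD", cf))) {
    df$XD <- matrix(0, nrow(df), sum(grepl("^XD", cf)))
  }
  df$.mdsm_offset <- 0
  Xp <- predict(model, newdata = df, type = "lpmatrix")
  list(Xp = Xp, cell_id = nd$cell_id, area = nd$area,
       platform_id = nd$platform_id, model = model)
}

#' Abundance and its uncertainty over a prediction grid
#'
#' Computes the abundance estimate \eqn{\hat N = a \exp(X_p \hat\beta)}
#' (a row vector of cell areas times predicted densities). For variants B
#' and C — and for any model fitted to duplicated segments from simultaneous
#' protocols, where each platform records a disjoint behavioural subset —
#' the grid is predicted once per platform and the per-platform abundances
#' are summed. Uncertainty comes from posterior simulation: for each
#' coefficient draw \eqn{\beta^*_b} the abundance \eqn{\hat N^*_b} is
#' recomputed, and empirical means, variances and CVs are taken over the `B`
#' draws, per cell and in total. CVs of fixed multipliers (aerial g(0),
#' availability) are combined with the posterior CV by adding squared CVs.
#'
#' @param fit A `"dsm_fit"`, ideally after [propagate_variance()].
#' @param grid Prediction grid tibble: `area`, model covariates, optional
#'   `cell_id` and `platform_id`.
#' @param B,sampler,seed Passed to [posterior_sample()] when `draws` is NULL.
#' @param draws Optional precomputed coefficient draw matrix.
#' @param extra_cv Optional named vector of additional CV components; by
#'   default the fixed-multiplier CVs found on the fitted segments.
#' @return An object of class `"abundance_estimate"`: `N_hat`, `cells`
#'   (per-cell abundance, density and CV), `draws` (the \eqn{\hat N^*_b}),
#'   `by_platform`, `cv_posterior`, `extra_cv`, `cv_total`.
#' @export
abundance <- function(fit, grid, B = 1000, sampler = "mvn", seed = NULL,
                      draws = NULL, extra_cv = NULL) {
  pm <- prediction_matrix(fit, grid)
  beta_hat <- coef(pm$model)
  eta <- drop(pm$Xp %*% beta_hat)
  cell_ab <- pm$area * exp(eta)
  by_platform <- tibble::tibble(cell_id = pm$cell_id,
                                platform_id = pm$platform_id,
                                abundance = cell_ab)
  cells <- by_platform |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(abundance = sum(.data$abundance), .groups = "drop")
  cells$area <- pm$area[match(cells$cell_id, pm$cell_id)]
  cells$density <- cells$abundance / cells$area
  N_hat <- sum(cells$abundance)

  if (is.null(draws)) {
    draws <- posterior_sample(fit, B = B, sampler = sampler, seed = seed)
  }
  cf <- names(beta_hat)
  draws_use <- draws[, cf, drop = FALSE]
  Eta <- pm$Xp %*% t(draws_use)               # (cells*K) x B
  Ab <- pm$area * exp(Eta)
  cell_draws <- rowsum(Ab, group = pm$cell_id, reorder = FALSE)
  ord <- match(cells$cell_id, rownames(cell_draws))
  cell_draws <- cell_draws[ord, , drop = FALSE]
  N_b <- colSums(cell_draws)
  cells$cv <- apply(cell_draws, 1, sd) / rowMeans(cell_draws)
  cv_posterior <- sd(N_b) / mean(N_b)

  extra_cv <- extra_cv %||% fixed_multiplier_cvs(fit)
  cv_total <- combine_cv(c(posterior = cv_posterior, extra_cv))

  structure(list(
    N_hat = N_hat, cells = cells, by_platform = by_platform,
    draws = N_b, cv_posterior = cv_posterior, extra_cv = extra_cv,
    cv_total = cv_total, B = ncol(cell_draws),
    sampler = attr(draws, "sampler") %||% "supplied"
  ), class = "abundance_estimate")
}

# CVs of fixed multipliers present on the fitted segments, one component per
# platform and multiplier type
fixed_multiplier_cvs <- function(fit) {
  segs <- fit$segments
  out <- numeric(0)
  for (id in fit$platforms) {
    rows <- segs$platform_id == id
    for (col in c("g0_cv", "u_cv")) {
      if (!(col %in% names(segs))) next
      v <- max(segs[[col]][rows], 0)
      if (v > 0) out[paste0(sub("_cv", "", col), "_", id)] <- v
    }
  }
  out
}

#' Combine independent CV components
#'
#' Independent coefficients of variation combine as the square root of the
#' sum of squared CVs.
#'
#' @param ... Non-negative CVs (scalars or named vectors).
#' @return The total CV.
#' @examples
#' combine_cv(0.3, 0.4)  # 0.5
#' @export
combine_cv <- function(...) {
  cvs <- unlist(list(...))
  if (length(cvs) == 0L) return(0)
  if (any(cvs < 0)) {
    stop_mdsm("CV components must be non-negative.", "mdsm_validation_error")
  }
  sqrt(sum(cvs^2))
}

#' Per-platform prediction differences
#'
#' For variants B and C, predicts the density surface separately for each
#' pair of platforms and returns cell-wise differences — if the extra
#' platform structure is unnecessary, the difference surface should be near
#' zero.
#'
#' @param fit A `"dsm_fit"` of variant B or C.
#' @param grid Prediction grid.
#' @return Tibble with `cell_id`, the two platform densities and their
#'   difference (second minus first level).
#' @export
platform_difference <- function(fit, grid) {
  if (fit$variant == "A") {
    stop_mdsm("Variant A has a single shared surface.", "mdsm_config_error")
  }
  pm <- prediction_matrix(fit, grid)
  dens <- exp(drop(pm$Xp %*% coef(pm$model)))
  tibble::tibble(cell_id = pm$cell_id, platform_id = pm$platform_id,
                 density = dens) |>
    tidyr::pivot_wider(names_from = "platform_id", values_from = "density") |>
    dplyr::mutate(difference = .data[[fit$platforms[2]]] -
                    .data[[fit$platforms[1]]])
}

#' @export
print.abundance_estimate <- function(x, ...) {
  cat(sprintf("<abundance_estimate> N_hat = %.1f (posterior CV %.3f, total CV %.3f)\n",
              x$N_hat, x$cv_posterior, x$cv_total))
  cat(sprintf("%d cells, %d posterior draws (%s sampler)\n",
              nrow(x$cells), x$B, x$sampler))
  if (length(x$extra_cv) > 0) {
    cat("extra CV components:",
        paste(sprintf("%s=%.3f", names(x$extra_cv), x$extra_cv),
              collapse = ", "), "\n")
  }
  invisible(x)
}
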