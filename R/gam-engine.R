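#' Declare a smooth term for the count model
#'
#' Smooth terms are penalized spline basis expansions
#' \eqn{f(x) = \sum_j \beta_j b_j(x)} with a quadratic wiggliness penalty;
#' smoothing parameters are chosen by REML. The default basis is a
#' thin-plate regression spline with shrinkage (`bs = "ts"`), whose penalty
#' also shrinks the null space so that a large smoothing parameter removes
#' the whole term — useful for model selection. Factor-smooth terms
#' (`by = <factor>`) add per-level deviation smooths around the reference
#' smooth, each with its own penalty.
#'
#' @param covariates Character vector of one or two covariate names.
#' @param k Maximum basis size (>= 3).
#' @param bs Basis code: `"ts"` (thin-plate with shrinkage, default), `"tp"`,
#'   `"cs"` (cubic with shrinkage), `"cr"` (cubic).
#' @param by Optional factor name for a factor-smooth interaction.
#' @return A `"smooth_spec"` list.
#' @examples
#' sm("depth", k = 5)
#' sm(c("x", "y"), k = 30, by = "platform_id")
#' @export
sm <- function(covariates, k = 10, bs = c("ts", "tp", "cs", "cr"),
               by = NULL) {
  bs <- match.arg(bs)
  if (!is.character(covariates) || !(length(covariates) %in% 1:2)) {
    stop_mdsm("`covariates` must name one or two columns.",
              "mdsm_validation_error")
  }
  if (k < 3) stop_mdsm("`k` must be >= 3.", "mdsm_validation_error")
  structure(list(covariates = covariates, k = k, bs = bs, by = by),
            class = "smooth_spec")
}

# mgcv s(...) call text for one smooth spec; `by` overridden per variant
# (pass by = NA to force a plain smooth regardless of spec$by)
smooth_term_string <- function(spec, by = NULL) {
  by <- if (length(by) == 1 && is.na(by)) NULL else by %||% spec$by
  sprintf("s(%s, k = %d, bs = \"%s\"%s)",
          paste(spec$covariates, collapse = ", "), spec$k, spec$bs,
          if (is.null(by)) "" else paste0(", by = ", by))
}

#' Construct a penalized spline basis
#'
#' Evaluates the design matrix and penalty matrices for one smooth term, with
#' the sum-to-zero identifiability constraint absorbed. For factor-smooth
#' terms the result contains a reference-level smooth block plus one deviation
#' block per non-reference factor level, each with its own penalty.
#'
#' @param spec A [sm()] smooth specification.
#' @param data Data frame holding the covariate(s) (and `by` factor).
#' @return A list with `X` (design matrix), `S` (list of penalty matrices,
#'   expanded to `ncol(X)`), and `blocks` (column index list per sub-smooth).
#' @export
build_basis <- function(spec, data) {
  make_con <- function(term) {
    mgcv::smoothCon(eval(str2lang(term)), data = as.data.frame(data),
                    absorb.cons = TRUE)
  }
  cons <- make_con(smooth_term_string(spec, by = NA))
  if (!is.null(spec$by)) {
    df <- as.data.frame(data)
    df[[spec$by]] <- factor(df[[spec$by]], ordered = TRUE)
    dev <- mgcv::smoothCon(
      eval(str2lang(smooth_term_string(spec))), data = df,
      absorb.cons = TRUE)
    cons <- c(cons, dev)
  }
  X <- do.call(cbind, purrr::map(cons, "X"))
  S <- list()
  blocks <- list()
  at <- 0L
  for (sc in cons) {
    idx <- at + seq_len(ncol(sc$X))
    blocks[[length(blocks) + 1L]] <- idx
    for (Sk in sc$S) {
      full <- matrix(0, ncol(X), ncol(X))
      full[idx, idx] <- Sk
      S[[length(S) + 1L]] <- full
    }
    at <- at + ncol(sc$X)
  }
  list(X = X, S = S, blocks = blocks, smooths = cons)
}

#' Log-likelihood of the count families
#'
#' Exact log-densities for the Poisson and negative binomial families, and the
#' Tweedie log-density for power \eqn{p \in (1, 2)} evaluated by series
#' expansion.
#'
#' @param family `"poisson"`, `"negbin"` or `"tweedie"`.
#' @param y Non-negative response vector.
#' @param mu Positive mean vector.
#' @param scale Dispersion \eqn{\phi} (Tweedie).
#' @param power Tweedie power in (1, 2).
#' @param theta Negative-binomial size parameter.
#' @return Scalar log-likelihood.
#' @export
family_loglik <- function(family = c("poisson", "negbin", "tweedie"),
                          y, mu, scale = 1, power = NULL, theta = NULL) {
  family <- match.arg(family)
  if (any(y < 0)) stop_mdsm("`y` must be non-negative.", "mdsm_domain_error")
  if (any(mu <= 0)) stop_mdsm("`mu` must be positive.", "mdsm_domain_error")
  switch(family,
    poisson = sum(dpois(y, mu, log = TRUE)),
    negbin = {
      if (is.null(theta)) {
        stop_mdsm("`theta` required for negbin.", "mdsm_validation_error")
      }
      sum(dnbinom(y, size = theta, mu = mu, log = TRUE))
    },
    tweedie = {
      if (is.null(power) || power <= 1 || power >= 2) {
        stop_mdsm("Tweedie `power` must lie in (1, 2).",
                  "mdsm_validation_error")
      }
      sum(mgcv::ldTweedie(y, mu, p = power, phi = scale)[, 1])
    })
}

# map a family name (or family object) to the mgcv family used for fitting
mdsm_family <- function(family) {
  if (inherits(family, "family")) return(family)
  switch(match.arg(family, c("poisson", "quasipoisson", "negbin", "tweedie")),
         poisson = poisson(link = "log"),
         quasipoisson = quasipoisson(link = "log"),
         negbin = mgcv::nb(link = "log"),
         tweedie = mgcv::tw(link = "log"))
}

#' Fit a penalized-spline count model by REML
#'
#' Thin interface to the penalized IRLS / REML machinery: coefficients are
#' estimated by penalized IRLS given smoothing parameters, and smoothing
#' parameters (plus any negative-binomial or Tweedie nuisance parameters) by
#' optimizing the Laplace-approximate restricted marginal likelihood. With no
#' smooth terms (or `sp` fixed at 0) this reduces to an ordinary GLM.
#'
#' @param formula Model formula in mgcv syntax (may include `s(...)` terms
#'   and `offset(...)`).
#' @param data Data frame.
#' @param family `"poisson"`, `"quasipoisson"`, `"negbin"`, `"tweedie"`, or a
#'   family object.
#' @param sp Optional fixed smoothing parameters (passed to the fitter;
#'   positive entries are fixed, -1 entries estimated).
#' @param ... Further arguments passed to the fitter (e.g. `paraPen`).
#' @return A fitted `"gam"` object: coefficients `coef()`, Bayesian posterior
#'   covariance `vcov()`, smoothing parameters `$sp`, per-term effective
#'   degrees of freedom `$edf`.
#' @export
fit_penalized <- function(formula, data, family = "poisson", sp = NULL, ...) {
  mgcv::gam(formula, family = mdsm_family(family),
            data = as.data.frame(data), method = "REML", sp = sp, ...)
}

#' AIC for penalized count models
#'
#' \eqn{-2\ell(\hat\beta) + 2\,\mathrm{edf}} with the effective degrees of
#' freedom accounting for penalization; reduces to the usual
#' \eqn{-2\ell + 2p} for unpenalized fits.
#'
#' @param fit A fitted model from [fit_penalized()] or [fit_dsm()].
#' @return Scalar AIC.
#' @export
model_aic <- function(fit) {
  if (inherits(fit, "dsm_fit")) fit <- fit$gam
  stats::AIC(fit)
}
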