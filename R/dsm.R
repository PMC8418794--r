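#' Build the detectability offset for the count model
#'
#' Each segment's expected count is modelled as effective area times density,
#' where the effective area is `area * p * g0 * u`: the segment area, the
#' platform's average detection probability for that segment, the trackline
#' detection probability and the availability probability. The log of this
#' product is the count-model offset. Strip platforms have `p = 1`, so their
#' offset is `log(area)` (times any fixed multipliers).
#'
#' @param segments Segment tibble with `segment_id`, `platform_id`, `area`,
#'   and optional `g0`/`u` multiplier columns (default 1).
#' @param detection_fits List of `"detection_fit"` objects, one per platform,
#'   each with `p_by_segment` populated.
#' @return `segments` with columns `p` and `.mdsm_offset`.
#' @export
build_offset <- function(segments, detection_fits) {
  detection_fits <- name_fits(detection_fits)
  needed <- unique(segments$platform_id)
  missing <- setdiff(needed, names(detection_fits))
  if (length(missing) > 0) {
    stop_mdsm(sprintf("No detection fit for platform(s): %s",
                      paste(missing, collapse = ", ")),
              "mdsm_reference_error")
  }
  for (col in c("g0", "u")) {
    if (!(col %in% names(segments))) segments[[col]] <- 1
  }
  p <- rep(NA_real_, nrow(segments))
  for (id in needed) {
    fit <- detection_fits[[id]]
    if (is.null(fit$p_by_segment)) {
      fit <- add_segment_detectability(fit, segments)
      detection_fits[[id]] <- fit
    }
    rows <- segments$platform_id == id
    idx <- match(segments$segment_id[rows], fit$p_by_segment$segment_id)
    p[rows] <- fit$p_by_segment$p[idx]
  }
  bad <- which(is.na(p) | p <= 0)
  if (length(bad) > 0) {
    stop_mdsm(sprintf(
      "Missing or zero detection probability for segment(s): %s",
      paste(head(segments$segment_id[bad], 5), collapse = ", ")),
      "mdsm_validation_error")
  }
  segments$p <- p
  segments$.mdsm_offset <- log(segments$area * p * segments$g0 * segments$u)
  if (any(!is.finite(segments$.mdsm_offset))) {
    stop_mdsm("Non-finite offset; check areas and multipliers.",
              "mdsm_validation_error")
  }
  attr(segments, "detection_fits") <- detection_fits
  segments
}

name_fits <- function(detection_fits) {
  if (inherits(detection_fits, "detection_fit")) {
    detection_fits <- list(detection_fits)
  }
  names(detection_fits) <- vapply(detection_fits, function(f) f$platform_id,
                                  character(1))
  detection_fits
}

# assemble the mgcv formula for a model variant; the deviation smooths of
# variant C use an ordered platform factor so the reference level keeps the
# shared smooth only
dsm_formula <- function(terms, variant) {
  smooths <- vapply(terms, smooth_term_string, character(1))
  rhs <- switch(variant,
    A = smooths,
    B = c("platform - 1", smooths),
    # common intercept: the factor-smooth deviations are centred, so C
    # collapses exactly to A when their penalties grow
    C = c(smooths,
          vapply(terms, smooth_term_string, character(1),
                 by = "platform_ord")))
  as.formula(paste("n ~", paste(rhs, collapse = " + "),
                   "+ offset(.mdsm_offset)"))
}

#' Fit a multi-platform density surface model
#'
#' Fits a penalized-spline model of per-segment individual counts with a
#' per-segment effective-area offset built from the platform detection fits.
#' Three variants are supported:
#' * `"A"`: one shared density surface — common intercept and shared smooths;
#'   differences between platforms are attributed to detectability alone.
#' * `"B"`: per-platform intercepts — platform densities differ by a
#'   constant multiplicative factor.
#' * `"C"`: factor-smooth interactions — per-platform intercepts plus
#'   per-platform deviation smooths around a reference smooth, so the shape
#'   of the surface may differ by platform. Deviation smooths use shrinkage
#'   bases with their own penalties, so variant C collapses towards variant A
#'   as the deviation penalties grow.
#'
#' Smoothing parameters (and any Tweedie/negative-binomial nuisance
#' parameters) are estimated by REML.
#'
#' @param segments Segment tibble (e.g. from [assemble_survey()]), with
#'   counts `n`, areas, multiplier columns and model covariates.
#' @param detection_fits List of per-platform `"detection_fit"` objects.
#' @param terms List of [sm()] smooth specifications (and/or character
#'   strings of parametric terms).
#' @param variant `"A"`, `"B"` or `"C"`.
#' @param family `"tweedie"` (default), `"negbin"`, `"poisson"` or
#'   `"quasipoisson"`.
#' @param formula Optional right-hand-side formula overriding `terms` (the
#'   offset is appended automatically).
#' @param sp Optional fixed smoothing parameters.
#' @return An object of class `"dsm_fit"` wrapping the fitted penalized model
#'   (`$gam`), the offset provenance (`$segments`) and the detection fits.
#' @export
fit_dsm <- function(segments, detection_fits, terms, variant = c("A", "B", "C"),
                    family = "tweedie", formula = NULL, sp = NULL) {
  variant <- match.arg(variant)
  detection_fits <- name_fits(detection_fits)
  segments <- build_offset(segments, detection_fits)
  detection_fits <- attr(segments, "detection_fits")
  platforms <- sort(unique(segments$platform_id))
  if (variant %in% c("B", "C") && length(platforms) < 2L) {
    stop_mdsm(sprintf("Variant %s requires at least two platforms.", variant),
              "mdsm_config_error")
  }
  segments$platform <- factor(segments$platform_id, levels = platforms)
  segments$platform_ord <- factor(segments$platform_id, levels = platforms,
                                  ordered = TRUE)
  if (is.null(formula)) {
    if (missing(terms) || length(terms) == 0L) {
      terms <- list()
      f <- switch(variant, A = n ~ 1 + offset(.mdsm_offset),
                  B = , C = n ~ platform - 1 + offset(.mdsm_offset))
    } else {
      if (inherits(terms, "smooth_spec")) terms <- list(terms)
      f <- dsm_formula(terms, variant)
    }
  } else {
    rhs <- paste(deparse(formula[[length(formula)]]), collapse = " ")
    f <- as.formula(paste("n ~", rhs, "+ offset(.mdsm_offset)"))
    terms <- list()
  }
  gam_fit <- fit_penalized(f, segments, family = family, sp = sp)
  # duplicated segment ids across platforms indicate simultaneous protocols:
  # predictions must then be made per platform and summed
  simultaneous <- anyDuplicated(segments$segment_id) > 0 &&
    length(platforms) > 1L
  structure(list(
    gam = gam_fit, formula = f, segments = segments,
    detection_fits = detection_fits, platforms = platforms,
    variant = variant, family = family, terms = terms,
    simultaneous = simultaneous,
    propagated = FALSE
  ), class = "dsm_fit")
}

#' Observed vs expected counts by a grouping covariate
#'
#' Aggregates observed counts and fitted expected counts
#' (\eqn{E_g = \sum_{i \in g} \hat\mu_i}) over the levels of a grouping
#' covariate — which need not be in the model — and reports the Pearson
#' chi-squared statistic \eqn{\sum_g (O_g - E_g)^2 / E_g}. Aggregation matters
#' because a smooth model predicts small positive values where exact zeros
#' were observed; grouping (e.g. by platform) gives an interpretable
#' goodness-of-fit check.
#'
#' @param fit A `"dsm_fit"`.
#' @param group_by Name of a column of the fitted segments to aggregate by.
#' @return A tibble with columns `group`, `observed`, `expected`, carrying
#'   the chi-squared statistic as attribute `"chisq"`.
#' @export
observed_expected <- function(fit, group_by = "platform_id") {
  segs <- fit$segments
  required_cols(segs, group_by, "segments")
  mu <- as.numeric(predict(fit$gam, type = "response"))
  tab <- tibble::tibble(group = as.character(segs[[group_by]]),
                        observed = segs$n, expected = mu) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(observed = sum(.data$observed),
                     expected = sum(.data$expected), .groups = "drop")
  empty <- tab$expected <= 0
  if (any(empty)) {
    rlang::warn(sprintf("Excluding %d empty group(s).", sum(empty)))
    tab <- tab[!empty, , drop = FALSE]
  }
  attr(tab, "chisq") <- pearson_chisq(tab$observed, tab$expected)
  class(tab) <- c("mdsm_oe", class(tab))
  tab
}

#' @export
print.mdsm_oe <- function(x, ...) {
  NextMethod()
  cat(sprintf("Pearson chi-squared: %.4g\n", attr(x, "chisq")))
  invisible(x)
}

#' @export
print.dsm_fit <- function(x, ...) {
  cat(sprintf("<dsm_fit> variant %s, family %s, %d platform(s), %d segments\n",
              x$variant, x$family, length(x$platforms), nrow(x$segments)))
  cat("formula:", deparse(x$formula), "\n")
  if (x$propagated) cat("detection uncertainty propagated\n")
  print(summary(x$gam)$s.table)
  invisible(x)
}
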