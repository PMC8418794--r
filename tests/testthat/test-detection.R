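test_that("detection key functions match their closed forms", {
  expect_equal(detection_g(0, "half_normal", sigma = 1), 1)
  expect_equal(detection_g(1, "half_normal", sigma = 1), exp(-0.5))
  # hazard-rate at x = sigma is 1 - exp(-1) for any shape
  for (b in c(1.5, 2, 5)) {
    expect_equal(detection_g(2, "hazard_rate", sigma = 2, shape = b),
                 1 - exp(-1))
  }
  expect_error(detection_g(1, "half_normal", sigma = -1),
               class = "mdsm_domain_error")
  expect_error(detection_g(1, "hazard_rate", sigma = 1, shape = 0.5),
               class = "mdsm_domain_error")
})

test_that("average detection probability matches quadrature and closed forms", {
  # line, half-normal sigma = 1, w = 1
  expect_equal(average_p_line("half_normal", 1, 1), 0.855624, tolerance = 1e-6)
  # point, half-normal sigma = 1, w = 1: 2 (1 - exp(-1/2))
  expect_equal(average_p_point("half_normal", 1, 1), 2 * (1 - exp(-0.5)),
               tolerance = 1e-9)
  # closed form vs quadrature agreement to 1e-8 across parameter grid
  for (sigma in c(0.3, 1, 2.5)) {
    for (w in c(0.5, 1, 4)) {
      expect_equal(average_p_line("half_normal", sigma, w, method = "closed"),
                   average_p_line("half_normal", sigma, w,
                                  method = "quadrature"),
                   tolerance = 1e-8)
      expect_equal(average_p_point("half_normal", sigma, w, method = "closed"),
                   average_p_point("half_normal", sigma, w,
                                   method = "quadrature"),
                   tolerance = 1e-8)
    }
  }
  # independent quadrature oracle
  expect_equal(average_p_line("hazard_rate", 1, 2, shape = 2.5),
               quad(function(x) 1 - exp(-(x / 1)^(-2.5)), 1e-12, 2) / 2,
               tolerance = 1e-7)
})

test_that("average p behaves at the limits", {
  expect_equal(average_p_line("half_normal", 1, 1e-6), 1, tolerance = 1e-9)
  expect_equal(average_p_point("half_normal", 1, 1e-6), 1, tolerance = 1e-9)
  expect_equal(average_p_point("half_normal", 1e8, 1), 1, tolerance = 1e-9)
  expect_equal(average_p_line("strip", w = 1), 1)
})

test_that("average p never increases with truncation distance", {
  ws <- seq(0.2, 5, by = 0.2)
  for (key in c("half_normal", "hazard_rate")) {
    shape <- if (key == "hazard_rate") 2.5 else NULL
    p <- vapply(ws, function(w) average_p_line(key, 1, w, shape), numeric(1))
    expect_true(all(diff(p) <= 1e-10))
    pp <- vapply(ws, function(w) average_p_point(key, 1, w, shape), numeric(1))
    expect_true(all(diff(pp) <= 1e-10))
  }
})

test_that("maximum likelihood recovers the half-normal scale", {
  obs <- sim_detection_data(n = 500, sigma = 1, w = 3, seed = 11)
  pl <- platform("p1", "line_cds", truncation_w = 3)
  fit <- fit_detection(obs, pl)
  sigma_hat <- exp(fit$theta[["sigma:(Intercept)"]])
  # independent oracle: grid search over sigma on the truncated likelihood
  grid <- seq(0.7, 1.4, by = 5e-4)
  ll <- vapply(grid, function(s) {
    sum(-obs$distance^2 / (2 * s^2)) -
      nrow(obs) * log(quad(function(x) exp(-x^2 / (2 * s^2)), 0, 3))
  }, numeric(1))
  sigma_oracle <- grid[which.max(ll)]
  expect_equal(sigma_hat, sigma_oracle, tolerance = 2e-3)
  se <- sqrt(diag(fit$V_theta))[1]
  expect_lt(abs(log(sigma_hat) - log(1)), 3 * se)
  expect_equal(fit$aic, -2 * fit$loglik + 2, tolerance = 1e-10)
})

test_that("rescaling distances and truncation rescales sigma, not p", {
  obs <- sim_detection_data(n = 300, sigma = 0.8, w = 2.4, seed = 5)
  segs <- tibble::tibble(segment_id = "S0001", platform_id = "p1")
  pl1 <- platform("p1", "line_cds", truncation_w = 2.4)
  fit1 <- fit_detection(obs, pl1, segments = segs)
  c_scale <- 1000  # e.g. km -> m
  obs2 <- dplyr::mutate(obs, distance = distance * c_scale)
  pl2 <- platform("p1", "line_cds", truncation_w = 2.4 * c_scale)
  fit2 <- fit_detection(obs2, pl2, segments = segs)
  expect_equal(exp(fit2$theta[[1]]), c_scale * exp(fit1$theta[[1]]),
               tolerance = 1e-4)
  expect_equal(fit2$p_by_segment$p, fit1$p_by_segment$p, tolerance = 1e-6)
})

test_that("binned likelihood uses the right bin probabilities", {
  # expected share of bin 1 under half-normal sigma = 1, cutpoints (0, 1, 2)
  pi1 <- quad(function(x) exp(-x^2 / 2), 0, 1) /
    quad(function(x) exp(-x^2 / 2), 0, 2)
  expect_equal(pi1, 0.71524, tolerance = 1e-4)
  set.seed(21)
  n <- 800
  bins <- rbinom(n, 1, 1 - pi1) + 1L
  obs <- tibble::tibble(object_id = seq_len(n),
                        segment_id = sprintf("S%04d", seq_len(n)),
                        platform_id = "p1", bin = bins,
                        distance = NA_real_, size = 1)
  pl <- platform("p1", "line_cds", truncation_w = 2,
                 bin_cutpoints = c(0, 1, 2))
  fit <- fit_detection(obs, pl)
  sigma_hat <- exp(fit$theta[[1]])
  pi1_hat <- quad(function(x) exp(-x^2 / (2 * sigma_hat^2)), 0, 1) /
    quad(function(x) exp(-x^2 / (2 * sigma_hat^2)), 0, 2)
  # fitted bin share reproduces the empirical share (binomial ML)
  expect_equal(pi1_hat, mean(bins == 1), tolerance = 0.01)
})

test_that("a four-bin seabird design is accepted and fitted", {
  pl <- platform("water", "line_cds", truncation_w = 300, sides = "one",
                 bin_cutpoints = c(0, 50, 100, 200, 300))
  set.seed(3)
  d <- rtrunc_halfnormal(400, sigma = 150, w = 300)
  obs <- tibble::tibble(object_id = seq_along(d),
                        segment_id = sprintf("S%03d", seq_along(d) %% 20),
                        platform_id = "water", distance = d, size = 1)
  obs$bin <- mdsm:::assign_bins(obs$distance, pl$bin_cutpoints[[1]])
  obs$distance <- NA_real_
  fit <- fit_detection(obs, pl)
  expect_s3_class(fit, "detection_fit")
  expect_true(fit$binned)
  expect_equal(exp(fit$theta[[1]]), 150, tolerance = 0.2)
})

test_that("covariates on the scale must be segment-level", {
  obs <- sim_detection_data(n = 50, sigma = 1, w = 3, seed = 2)
  obs$beaufort <- runif(50)          # varies within (trivial) segments
  obs$segment_id <- "S1"             # force one segment
  pl <- platform("p1", "line_cds", truncation_w = 3)
  expect_error(fit_detection(obs, pl, formula = ~beaufort),
               "segment-level", class = "mdsm_validation_error")
})

test_that("scale covariates shift sigma on the log scale", {
  set.seed(7)
  n_half <- 400
  d_lo <- rtrunc_halfnormal(n_half, sigma = 0.6, w = 3)
  d_hi <- rtrunc_halfnormal(n_half, sigma = 1.2, w = 3)
  obs <- tibble::tibble(
    object_id = seq_len(2 * n_half),
    segment_id = rep(c("calm", "rough"), each = n_half),
    platform_id = "p1",
    distance = c(d_lo, d_hi), size = 1,
    sea = rep(c(0, 1), each = n_half))
  pl <- platform("p1", "line_cds", truncation_w = 3)
  fit <- fit_detection(obs, pl, formula = ~sea)
  expect_equal(exp(fit$theta[["sigma:(Intercept)"]]), 0.6, tolerance = 0.1)
  expect_equal(fit$theta[["sigma:sea"]], log(2), tolerance = 0.2)
})

test_that("detection AIC comparison orders fits and rejects mismatches", {
  obs <- sim_detection_data(n = 300, sigma = 1, w = 3, seed = 9)
  pl <- platform("p1", "line_cds", truncation_w = 3)
  fit_hn <- fit_detection(obs, pl)
  expect_equal(detection_aic(fit_hn)$delta_aic, 0)
  fit_hr <- fit_detection(obs, pl, key = "hazard_rate")
  tab <- detection_aic(fit_hn, fit_hr)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$delta_aic[1], 0)
  expect_true(all(diff(tab$aic) >= 0))
  # a useless covariate costs about two AIC units
  obs$noise <- rep(c(0, 1), length.out = nrow(obs))
  # make the covariate segment-level by regrouping
  obs$segment_id <- paste0(obs$segment_id, "_", obs$noise)
  fit_noise <- fit_detection(obs, pl, formula = ~noise)
  expect_gt(fit_noise$aic - fit_hn$aic, -0.5)
  expect_lt(fit_noise$aic - fit_hn$aic, 2.5)
  # strip fits carry no likelihood
  strip <- fit_detection(obs, platform("s", "strip", 1))
  expect_message(tab2 <- detection_aic(list(fit_hn, strip)), "strip")
  expect_equal(nrow(tab2), 1)
  # different data refuse to be compared
  other <- fit_detection(sim_detection_data(200, 1, 3, seed = 10), pl)
  expect_error(detection_aic(fit_hn, other),
               class = "mdsm_validation_error")
})

test_that("per-segment detectability and gradients are populated", {
  obs <- sim_detection_data(n = 200, sigma = 1, w = 3, seed = 4)
  segs <- tibble::tibble(segment_id = c("S0001", "S0002"),
                         platform_id = "p1")
  pl <- platform("p1", "line_cds", truncation_w = 3)
  fit <- fit_detection(obs, pl, segments = segs)
  expect_equal(nrow(fit$p_by_segment), 2)
  expect_true(all(fit$p_by_segment$p > 0 & fit$p_by_segment$p <= 1))
  # finite-difference gradient of log p matches the closed-form derivative
  # d log p / d log sigma for the half-normal line case
  s <- exp(fit$theta[[1]])
  w <- 3
  eps <- 1e-6
  p_fun <- function(sg) average_p_line("half_normal", sg, w)
  d_closed <- (log(p_fun(s * exp(eps))) - log(p_fun(s * exp(-eps)))) /
    (2 * eps)
  expect_equal(unname(fit$dlogp_dtheta[1, 1]), d_closed, tolerance = 1e-5)
})
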