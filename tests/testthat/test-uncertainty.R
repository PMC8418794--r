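# single-platform fitted model with enough segments for stable propagation
fit_single <- function(seed = 1, family = "poisson", n_lines = 4, k = 10) {
  design <- sim_design(
    region = c(10, 10), density = sim_density("logsmooth", 5, 0.8),
    platforms = platform_registry(
      platform("main", "line_cds", truncation_w = 0.6)),
    det_params = list(main = list(key = "half_normal", sigma = 0.3)),
    n_lines = n_lines, seg_len = 1)
  sim <- simulate_survey(design, seed = seed)
  det <- fit_detection(sim$survey$observations, sim$survey$platforms,
                       segments = sim$survey$segments)
  fit <- fit_dsm(sim$survey$segments, list(det),
                 terms = list(sm(c("x", "y"), k = k)),
                 variant = "A", family = family)
  list(fit = fit, det = det, sim = sim, design = design)
}

# delta-method CV of total N from a model's coefficient covariance
cv_N_from_V <- function(fit, grid, model = fit$gam) {
  pm <- mdsm:::prediction_matrix(fit, grid)
  keep <- colnames(pm$Xp)
  beta <- coef(model)[keep]
  V <- vcov(model)[keep, keep]
  w <- pm$area * exp(drop(pm$Xp %*% beta))
  g <- drop(t(w) %*% pm$Xp)
  sqrt(drop(t(g) %*% V %*% g)) / sum(w)
}

test_that("the joint detection covariance stacks block-diagonally", {
  mk <- function(id, V) structure(
    list(platform_id = id, theta = setNames(rep(0, nrow(V)),
                                            paste0(id, seq_len(nrow(V)))),
         V_theta = V, key = "half_normal"),
    class = "detection_fit")
  V <- assemble_v_theta(list(mk("a", diag(2) * 0.1), mk("b", diag(3) * 0.2)))
  expect_equal(dim(V), c(5, 5))
  expect_equal(V[1:2, 3:5], matrix(0, 2, 3), ignore_attr = TRUE)
  expect_equal(attr(V, "blocks"), list(a = 1:2, b = 3:5))
  # a strip platform contributes no block
  strip <- mdsm:::strip_detection_fit(platform("s", "strip", 1))
  V2 <- assemble_v_theta(list(mk("a", diag(2) * 0.1), strip))
  expect_equal(dim(V2), c(2, 2))
  # empty list: zero-dimensional matrix
  expect_equal(dim(assemble_v_theta(list(strip))), c(0, 0))
  # non-PSD block is refused with the platform named
  bad <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(assemble_v_theta(list(mk("bad", bad))), "bad",
               class = "mdsm_numeric_error")
})

test_that("zero detection covariance leaves the posterior unchanged", {
  fs <- fit_single()
  v0 <- assemble_v_theta(list(fs$det))
  v0[] <- 0
  prop <- propagate_variance(fs$fit, v0)
  expect_true(prop$propagated)
  expect_equal(prop$V_combined, fs$fit$gam$Vp, tolerance = 1e-6)
})

test_that("propagation never shrinks the abundance variance", {
  grid <- NULL
  for (seed in 1:5) {
    fs <- fit_single(seed = seed)
    grid <- make_grid(fs$design, nx = 8, ny = 8)
    prop <- propagate_variance(fs$fit)
    expect_true(prop$propagated)
    cv_plain <- suppressWarnings(cv_N_from_V(fs$fit, grid))
    cv_prop <- suppressWarnings(cv_N_from_V(prop, grid, prop$gam_vp))
    expect_gte(cv_prop, cv_plain - 1e-8)
  }
})

test_that("propagated CV matches the delta-method combination", {
  # detection covariates are spatially constant, so the independence
  # assumption behind the delta method holds and the two routes must agree
  fs <- fit_single(seed = 3, n_lines = 6)
  grid <- make_grid(fs$design, nx = 8, ny = 8)
  prop <- propagate_variance(fs$fit)
  cv_prop <- suppressWarnings(cv_N_from_V(prop, grid, prop$gam_vp))
  cv_gam <- suppressWarnings(cv_N_from_V(fs$fit, grid))
  cv_p <- unname(delta_detection_cv(fs$fit))
  cv_delta <- combine_cv(cv_gam, cv_p)
  expect_lt(abs(cv_prop - cv_delta) / cv_delta, 0.15)
})

test_that("MVN posterior draws reproduce the target covariance", {
  d <- data.frame(n = rpois(60, 5), area = 1,
                  segment_id = as.character(1:60), platform_id = "p",
                  x = runif(60))
  # three-parameter parametric fit via the dsm surface
  det <- mdsm:::strip_detection_fit(platform("p", "strip", 1), d)
  fit <- fit_dsm(d, list(det), formula = ~x + I(x^2), variant = "A",
                 family = "poisson")
  fit <- propagate_variance(fit)
  draws <- posterior_sample(fit, B = 20000, sampler = "mvn", seed = 99)
  V <- fit$V_combined
  emp <- var(draws)
  expect_lt(norm(emp - V, "F") / norm(V, "F"), 0.05)
  # determinism
  draws2 <- posterior_sample(fit, B = 20000, sampler = "mvn", seed = 99)
  expect_identical(draws, draws2)
})

test_that("Metropolis-Hastings matches the MVN answer on a normal-limit posterior", {
  set.seed(2)
  d <- data.frame(n = rpois(400, 8), area = 1,
                  segment_id = as.character(1:400), platform_id = "p",
                  x = runif(400))
  det <- mdsm:::strip_detection_fit(platform("p", "strip", 1), d)
  fit <- fit_dsm(d, list(det), formula = ~x, variant = "A",
                 family = "poisson")
  grid <- tibble::tibble(cell_id = c("a", "b"), area = c(3, 7),
                         x = c(0.3, 0.7))
  est_mvn <- abundance(fit, grid, B = 4000, sampler = "mvn", seed = 5)
  est_mh <- abundance(fit, grid, B = 4000, sampler = "mh", seed = 5)
  mc_se <- sd(est_mvn$draws) / sqrt(4000)
  # large-count Poisson GLM: posterior is very nearly Gaussian
  expect_lt(abs(mean(est_mh$draws) - mean(est_mvn$draws)), 10 * mc_se)
  expect_lt(abs(est_mh$cv_posterior / est_mvn$cv_posterior - 1), 0.15)
  # seeded determinism of the chain
  d1 <- posterior_sample(fit, B = 500, sampler = "mh", seed = 11)
  d2 <- posterior_sample(fit, B = 500, sampler = "mh", seed = 11)
  expect_identical(d1, d2)
  expect_gte(attr(d1, "accept_rate"), 0.1)
  expect_lte(attr(d1, "accept_rate"), 0.6)
})

test_that("intercept-only abundance has the closed form a * exp(beta0)", {
  d <- data.frame(n = c(1, 3, 2, 2), area = 1,
                  segment_id = as.character(1:4), platform_id = "p")
  det <- mdsm:::strip_detection_fit(platform("p", "strip", 1), d)
  fit <- fit_dsm(d, list(det), variant = "A", family = "poisson")
  expect_equal(unname(coef(fit$gam)[1]), log(2), tolerance = 1e-8)
  grid <- tibble::tibble(cell_id = c("a", "b"), area = c(3, 7))
  est <- abundance(fit, grid, B = 2000, seed = 1)
  expect_equal(est$N_hat, 20, tolerance = 1e-6)
  # CV from draws matches the analytic delta-method SE of beta0:
  # cv(N) = sd(exp(b0)) / E exp(b0) ~ se(b0) for small se
  se_b0 <- sqrt(vcov(fit$gam)[1, 1])
  expect_equal(est$cv_posterior, sqrt(exp(se_b0^2) - 1), tolerance = 0.1)
  # posterior mean of N*_b is close to the plug-in estimate
  mc_se <- sd(est$draws) / sqrt(length(est$draws))
  expect_lt(abs(mean(est$draws) - est$N_hat * exp(se_b0^2 / 2)), 3 * mc_se)
})

test_that("per-cell CV is invariant to cell ordering", {
  fs <- fit_single(seed = 4)
  grid <- make_grid(fs$design, nx = 5, ny = 5)
  est1 <- suppressWarnings(abundance(fs$fit, grid, B = 500, seed = 3))
  perm <- sample(nrow(grid))
  est2 <- suppressWarnings(abundance(fs$fit, grid[perm, ], B = 500, seed = 3))
  j1 <- dplyr::arrange(est1$cells, cell_id)
  j2 <- dplyr::arrange(est2$cells, cell_id)
  expect_equal(j1$cv, j2$cv, tolerance = 1e-12)
  expect_equal(j1$abundance, j2$abundance, tolerance = 1e-12)
})

test_that("independent CVs combine by squared addition", {
  expect_equal(combine_cv(0.3, 0.4), 0.5)
  expect_equal(combine_cv(0.42), 0.42)
  expect_equal(combine_cv(), 0)
  expect_error(combine_cv(-0.1), class = "mdsm_validation_error")
})

test_that("fixed-multiplier CVs are folded into the total abundance CV", {
  design <- sim_design(
    region = c(10, 10), density = sim_density("constant", 6),
    platforms = platform_registry(
      platform("aerial", "line_mcds", truncation_w = 0.6,
               g0 = 0.67, g0_cv = 0.1,
               availability = 0.37, availability_cv = 0.07)),
    det_params = list(aerial = list(key = "half_normal", sigma = 0.3)),
    n_lines = 4, seg_len = 1)
  sim <- simulate_survey(design, seed = 21)
  segs <- apply_fixed_multipliers(sim$survey$segments, g0 = 0.67,
                                  g0_cv = 0.1, u = 0.37, u_cv = 0.07,
                                  platform_id = "aerial")
  det <- fit_detection(sim$survey$observations, sim$survey$platforms,
                       segments = segs)
  fit <- fit_dsm(segs, list(det), variant = "A", family = "poisson")
  fit <- propagate_variance(fit)
  grid <- make_grid(design, nx = 4, ny = 4)
  est <- abundance(fit, grid, B = 1000, seed = 2)
  expect_setequal(names(est$extra_cv), c("g0_aerial", "u_aerial"))
  expect_equal(est$cv_total,
               sqrt(est$cv_posterior^2 + 0.1^2 + 0.07^2), tolerance = 1e-10)
})
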