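# a small fitted two-platform survey reused across tests
fit_fulmar_like <- function(seed = 2, variant = "A", family = "poisson",
                            k = 15, sp = NULL) {
  design <- sim_profile("fulmar_like")
  sim <- simulate_survey(design, seed = seed)
  water <- fit_detection(sim$survey$observations,
                         mdsm:::platform_row(sim$survey$platforms, "water"),
                         segments = sim$survey$segments)
  flying <- fit_detection(sim$survey$observations,
                          mdsm:::platform_row(sim$survey$platforms, "flying"),
                          segments = sim$survey$segments)
  fit <- fit_dsm(sim$survey$segments, list(water, flying),
                 terms = list(sm(c("x", "y"), k = k)),
                 variant = variant, family = family, sp = sp)
  list(fit = fit, sim = sim, design = design)
}

test_that("the log offset is the log effective area", {
  segs <- tibble::tibble(segment_id = c("s1", "s2"),
                         platform_id = c("aerial", "aerial"),
                         area = c(1, 10), g0 = c(1, 0.67), u = c(1, 0.37))
  det <- structure(list(
    platform_id = "aerial", key = "half_normal", formula = ~1,
    theta = c("sigma:(Intercept)" = 0), V_theta = matrix(0.1, 1, 1),
    p_by_segment = tibble::tibble(segment_id = c("s1", "s2"),
                                  p = c(1, 0.5)),
    dlogp_dtheta = matrix(0, 2, 1, dimnames = list(c("s1", "s2"), NULL))),
    class = "detection_fit")
  out <- build_offset(segs, list(det))
  expect_equal(out$.mdsm_offset[1], 0)
  expect_equal(out$.mdsm_offset[2], log(10 * 0.5 * 0.67 * 0.37))
  expect_equal(out$.mdsm_offset[2], log(1.2395), tolerance = 1e-10)
  expect_equal(out$.mdsm_offset[2], 0.2147, tolerance = 1e-4)
})

test_that("strip platforms contribute offset = log(area)", {
  segs <- tibble::tibble(segment_id = c("a", "b"), platform_id = "flying",
                         area = c(2, 5))
  strip <- mdsm:::strip_detection_fit(
    platform("flying", "strip", truncation_w = 0.3), segs)
  out <- build_offset(segs, list(strip))
  expect_equal(out$.mdsm_offset, log(c(2, 5)))
})

test_that("missing detectability is a named error", {
  segs <- tibble::tibble(segment_id = "a", platform_id = "boat", area = 1)
  expect_error(build_offset(segs, list()), "boat",
               class = "mdsm_reference_error")
})

test_that("Pearson aggregation reproduces the published worked example", {
  # platform-blind model for the seabird data: observed (501, 533) vs
  # expected (405, 632)
  expect_equal(pearson_chisq(c(501, 533), c(405, 632)), 38.26,
               tolerance = 1e-3)
  expect_equal(pearson_chisq(c(501, 533), c(501, 533)), 0)
  expect_equal(pearson_chisq(c(501, 533), c(490, 517)),
               121 / 490 + 256 / 517, tolerance = 1e-10)
  expect_equal(pearson_chisq(c(501, 533), c(490, 517)), 0.742,
               tolerance = 1e-3)
})

test_that("observed vs expected totals come from the fitted means", {
  ff <- fit_fulmar_like()
  oe <- observed_expected(ff$fit, "platform_id")
  expect_equal(sort(oe$group), c("flying", "water"))
  segs <- ff$fit$segments
  mu <- predict(ff$fit$gam, type = "response")
  for (g in oe$group) {
    expect_equal(oe$observed[oe$group == g],
                 sum(segs$n[segs$platform_id == g]))
    expect_equal(oe$expected[oe$group == g],
                 sum(mu[segs$platform_id == g]), tolerance = 1e-8)
  }
  expect_equal(attr(oe, "chisq"),
               pearson_chisq(oe$observed, oe$expected))
})

test_that("doubling all areas shifts the intercept by -log(2) only", {
  ff <- fit_fulmar_like(family = "poisson")
  sp_hat <- ff$fit$gam$sp
  fit1 <- fit_dsm(ff$fit$segments, ff$fit$detection_fits,
                  terms = list(sm(c("x", "y"), k = 15)),
                  variant = "A", family = "poisson", sp = sp_hat)
  segs2 <- dplyr::mutate(ff$fit$segments, area = 2 * area)
  fit2 <- fit_dsm(segs2, ff$fit$detection_fits,
                  terms = list(sm(c("x", "y"), k = 15)),
                  variant = "A", family = "poisson", sp = sp_hat)
  cf1 <- coef(fit1$gam)
  cf2 <- coef(fit2$gam)
  expect_equal(cf2[["(Intercept)"]], cf1[["(Intercept)"]] - log(2),
               tolerance = 1e-6)
  expect_equal(cf2[-1], cf1[-1], tolerance = 1e-6)
})

test_that("variant B with Poisson matches per-platform totals exactly", {
  ff <- fit_fulmar_like(variant = "B", family = "poisson")
  segs <- ff$fit$segments
  mu <- predict(ff$fit$gam, type = "response")
  for (id in ff$fit$platforms) {
    rows <- segs$platform_id == id
    expect_equal(sum(mu[rows]), sum(segs$n[rows]), tolerance = 1e-6)
  }
})

test_that("variant B recovers a between-platform density ratio of 2", {
  design <- sim_profile("fulmar_like")
  design$density_mult <- c(water = 1, flying = 2)
  sim <- simulate_survey(design, seed = 7)
  water <- fit_detection(sim$survey$observations,
                         mdsm:::platform_row(sim$survey$platforms, "water"),
                         segments = sim$survey$segments)
  flying <- fit_detection(sim$survey$observations,
                          mdsm:::platform_row(sim$survey$platforms, "flying"),
                          segments = sim$survey$segments)
  fit <- fit_dsm(sim$survey$segments, list(water, flying),
                 terms = list(sm(c("x", "y"), k = 15)),
                 variant = "B", family = "poisson")
  cf <- coef(fit$gam)
  delta <- cf[["platformflying"]] - cf[["platformwater"]]
  V <- vcov(fit$gam)[1:2, 1:2]
  se <- sqrt(V[1, 1] + V[2, 2] - 2 * V[1, 2])
  expect_lt(abs(delta - log(2)), 3 * se)
})

test_that("variants B and C require at least two platforms", {
  design <- sim_profile("minimal")
  sim <- simulate_survey(design, seed = 3)
  det <- fit_detection(sim$survey$observations, sim$survey$platforms,
                       segments = sim$survey$segments)
  expect_error(
    fit_dsm(sim$survey$segments, list(det), terms = list(sm(c("x", "y"))),
            variant = "B"),
    class = "mdsm_config_error")
})

test_that("a four-smooth Tweedie specification assembles as declared", {
  design <- sim_design(
    region = c(10, 10), density = sim_density("logsmooth", 4, 0.8),
    platforms = platform_registry(
      platform("aerial", "line_mcds", truncation_w = 0.6)),
    det_params = list(aerial = list(key = "half_normal", sigma = 0.3)),
    n_lines = 5, seg_len = 1)
  sim <- simulate_survey(design, seed = 12)
  segs <- sim$survey$segments
  # derived environmental covariates standing in for depth-like fields
  segs$dist125 <- abs(segs$y - 4)
  segs$depth <- 100 - 5 * segs$y + segs$x
  segs$dist2shore <- 10 - segs$y
  segs$sst <- 15 + sin(segs$y) + 0.2 * segs$x
  segs <- apply_fixed_multipliers(segs, g0 = 0.67, g0_cv = 0.1,
                                  u = 0.37, u_cv = 0.1)
  det <- fit_detection(sim$survey$observations, sim$survey$platforms,
                       segments = segs)
  fit <- fit_dsm(segs, list(det),
                 terms = list(sm("dist125", k = 5), sm("depth", k = 5),
                              sm("dist2shore", k = 5), sm("sst", k = 5)),
                 variant = "A", family = "tweedie")
  expect_equal(length(fit$gam$smooth), 4)
  expect_true(all(vapply(fit$gam$smooth,
                         function(s) s$bs.dim, numeric(1)) == 5))
  expect_match(fit$gam$family$family, "Tweedie")
  # offsets include the fixed multipliers
  expect_equal(fit$segments$.mdsm_offset,
               log(segs$area * fit$segments$p * 0.67 * 0.37))
})

test_that("predictions on duplicated designs sum the per-platform surfaces", {
  ffB <- fit_fulmar_like(variant = "B", family = "poisson")
  grid <- make_grid(ffB$design, nx = 6, ny = 6)
  est <- suppressWarnings(abundance(ffB$fit, grid, B = 200, seed = 1))
  wide <- tidyr::pivot_wider(est$by_platform, names_from = "platform_id",
                             values_from = "abundance")
  joined <- dplyr::left_join(est$cells, wide, by = "cell_id")
  expect_equal(joined$abundance, unname(joined$water + joined$flying),
               tolerance = 1e-10)
  # variant A on the same duplicated design also sums (identical surfaces)
  ffA <- fit_fulmar_like(variant = "A", family = "poisson")
  estA <- suppressWarnings(abundance(ffA$fit, grid, B = 200, seed = 1))
  wideA <- tidyr::pivot_wider(estA$by_platform, names_from = "platform_id",
                              values_from = "abundance")
  expect_equal(wideA$water, wideA$flying, tolerance = 1e-10)
})

test_that("factor-smooth variant C collapses to variant A as its deviation penalties grow", {
  ffA <- fit_fulmar_like(variant = "A", family = "poisson")
  spA <- ffA$fit$gam$sp
  n_dev <- length(ffA$fit$platforms) - 1
  fitC <- fit_dsm(ffA$fit$segments, ffA$fit$detection_fits,
                  terms = list(sm(c("x", "y"), k = 15)),
                  variant = "C", family = "poisson",
                  sp = c(spA, rep(1e8, n_dev)))
  muA <- predict(ffA$fit$gam, type = "response")
  muC <- predict(fitC$gam, type = "response")
  expect_lt(max(abs(muA - muC)), 1e-3)
})
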