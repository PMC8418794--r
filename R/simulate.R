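#' Intensity surfaces for the survey simulator
#'
#' Named density (animals per unit area) surfaces over a rectangular region:
#' `"constant"`; `"loglinear"`, an exponential east-west trend; and
#' `"logsmooth"`, a smooth bump pattern. All are strictly positive.
#'
#' @param type Surface type.
#' @param mean_density Approximate mean animals per unit area.
#' @param coef Trend/amplitude coefficient on the log scale.
#' @return A `"sim_density"` list with a `fn(x, y)` element.
#' @export
sim_density <- function(type = c("constant", "loglinear", "logsmooth"),
                        mean_density = 1, coef = 1) {
  type <- match.arg(type)
  force(mean_density); force(coef)
  fn <- switch(type,
    constant = function(x, y, region) rep(mean_density, length(x)),
    loglinear = function(x, y, region) {
      mean_density * exp(coef * (x / region[1] - 0.5)) /
        (sinh(coef / 2) * 2 / coef)  # normalized to mean_density on average
    },
    logsmooth = function(x, y, region) {
      mean_density * exp(coef * sin(2 * pi * x / region[1]) *
                           cos(pi * y / region[2])) /
        mean(exp(coef * sin(2 * pi * seq(0, 1, len = 101)) %o%
                   cos(pi * seq(0, 1, len = 101))))
    })
  structure(list(type = type, mean_density = mean_density, coef = coef,
                 fn = fn), class = "sim_density")
}

#' Describe a synthetic multi-platform survey
#'
#' Defines the study conditions for the simulator: a rectangular region
#' surveyed by parallel north-south transect lines split into equal-length
#' segments, one or more platforms (each with its own protocol, truncation
#' and true detection parameters), and a true density surface. The same
#' object drives data generation and truth bookkeeping, so every stage of
#' the pipeline can be tested against known values.
#'
#' @param region `c(width, height)` of the rectangle (distance units).
#' @param density A [sim_density()] surface.
#' @param platforms Platform registry ([platform_registry()]); each
#'   platform's `availability` and `g0` are treated as the *true* thinning
#'   probabilities as well as the analyst's fixed multipliers.
#' @param det_params Named list (by platform id) of true detection
#'   parameters: `key` (`"half_normal"`/`"hazard_rate"`), `sigma`, `shape`;
#'   for `mrds_io` platforms also `p0_1`, `p0_2`, the per-observer trackline
#'   detection probabilities (observer j detects an available animal at
#'   distance x with probability `p0_j * g(x)`). Strip platforms need no
#'   entry.
#' @param n_lines Transect lines per platform.
#' @param seg_len Segment length.
#' @param family Count mechanism: `"poisson"` or `"negbin"` (gamma-mixed
#'   Poisson with size `nb_theta`).
#' @param nb_theta Negative-binomial size parameter.
#' @param density_mult Optional named vector of per-platform multipliers on
#'   the density surface (e.g. different densities of swimming vs flying
#'   birds); default 1 for every platform.
#' @param group_lambda Group sizes are `1 + rpois(group_lambda)`; 0 (the
#'   default) simulates individuals.
#' @return A `"sim_design"` list.
#' @export
sim_design <- function(region = c(10, 10), density = sim_density("constant", 2),
                       platforms, det_params = list(),
                       n_lines = 5, seg_len = 1,
                       family = c("poisson", "negbin"), nb_theta = 5,
                       group_lambda = 0, density_mult = NULL) {
  family <- match.arg(family)
  structure(list(region = region, density = density, platforms = platforms,
                 det_params = det_params, n_lines = n_lines,
                 seg_len = seg_len, family = family, nb_theta = nb_theta,
                 group_lambda = group_lambda, density_mult = density_mult),
            class = "sim_design")
}

true_abundance <- function(design, nx = 200, ny = 200) {
  gx <- (seq_len(nx) - 0.5) * design$region[1] / nx
  gy <- (seq_len(ny) - 0.5) * design$region[2] / ny
  g <- expand.grid(x = gx, y = gy)
  cell_area <- prod(design$region) / (nx * ny)
  sum(design$density$fn(g$x, g$y, design$region) * cell_area)
}

# simulate one platform's segments + observations; called under that
# platform's own RNG substream
simulate_platform <- function(design, pl, line_offset = 0) {
  W <- design$region[1]; H <- design$region[2]
  spacing <- W / design$n_lines
  xs <- spacing * (seq_len(design$n_lines) - 0.5) + line_offset
  xs <- ((xs - spacing / 2) %% W) + spacing / 2  # wrap offsets into region
  n_seg <- max(1L, floor(H / design$seg_len))
  ys <- design$seg_len * (seq_len(n_seg) - 0.5)
  segs <- tidyr::expand_grid(line = seq_along(xs), seg = seq_len(n_seg))
  segs$x <- xs[segs$line]
  segs$y <- ys[segs$seg]
  segs$segment_id <- sprintf("L%02dS%02d", segs$line, segs$seg)
  segs$platform_id <- pl$platform_id
  segs$effort_length <- design$seg_len
  segs <- compute_areas(segs, pl)

  dp <- design$det_params[[pl$platform_id]]
  u_true <- pl$availability
  g0_fixed <- pl$g0
  dens <- design$density$fn(segs$x, segs$y, design$region)
  mult <- design$density_mult[[pl$platform_id]] %||% 1
  mu_present <- mult * dens * segs$area
  if (design$family == "negbin") {
    mu_present <- mu_present *
      rgamma(length(mu_present), shape = design$nb_theta,
             rate = design$nb_theta)
  }
  n_present <- rpois(nrow(segs), mu_present)
  total <- sum(n_present)
  obs <- tibble::tibble(
    segment_id = rep(segs$segment_id, n_present),
    platform_id = pl$platform_id,
    distance = runif(total, 0, pl$truncation_w)
  )
  # availability thinning
  obs <- obs[runif(total) < u_true, , drop = FALSE]
  if (pl$protocol == "strip") {
    obs$detected <- TRUE
  } else if (pl$protocol == "mrds_io") {
    g <- detection_g(obs$distance, dp$key, dp$sigma, dp$shape)
    d1 <- runif(nrow(obs)) < dp$p0_1 * g
    d2 <- runif(nrow(obs)) < dp$p0_2 * g
    obs$detected_by_1 <- as.integer(d1)
    obs$detected_by_2 <- as.integer(d2)
    obs$detected <- d1 | d2
  } else {
    g <- detection_g(obs$distance, dp$key, dp$sigma, dp$shape)
    obs$detected <- runif(nrow(obs)) < g0_fixed * g
  }
  obs <- obs[obs$detected, , drop = FALSE]
  obs$detected <- NULL
  obs$size <- if (design$group_lambda > 0) {
    1 + rpois(nrow(obs), design$group_lambda)
  } else rep(1L, nrow(obs))
  cp <- pl$bin_cutpoints[[1]]
  if (!is.null(cp)) {
    obs$bin <- assign_bins(obs$distance, cp)
    obs$distance <- NA_real_  # binned protocols record the bin only
  }
  list(segments = segs, observations = obs)
}

#' Simulate a multi-platform survey with known truth
#'
#' Animals are placed by an inhomogeneous Poisson process over the region
#' (segment intensity evaluated at the segment centre), thinned by
#' availability, assigned uniform perpendicular distances within the covered
#' strip, and detected according to the platform's true detection curve
#' (certain detection for strips; independent per-observer Bernoulli
#' detections with duplicates for double-observer platforms; a fixed
#' trackline multiplier otherwise). Binned platforms record the bin only.
#' Each platform is generated under its own RNG substream (seed + platform
#' index in registry order), so results are reproducible at the table level.
#'
#' @param design A [sim_design()].
#' @param seed Integer seed.
#' @return A list with `survey` (an `"mdsm_survey"`) and `truth` (total
#'   abundance, density surface, design).
#' @export
simulate_survey <- function(design, seed = 1) {
  all_segs <- list()
  all_obs <- list()
  for (i in seq_len(nrow(design$platforms))) {
    pl <- design$platforms[i, ]
    set.seed(seed + i)
    sim <- simulate_platform(design, pl,
                             line_offset = (i - 1) * design$region[1] /
                               (2 * design$n_lines * nrow(design$platforms)))
    all_segs[[i]] <- sim$segments
    all_obs[[i]] <- sim$observations
  }
  segments <- dplyr::bind_rows(all_segs)
  observations <- dplyr::bind_rows(all_obs)
  expected <- nrow(observations)
  if (expected < 5) {
    rlang::warn(sprintf(
      "Only %d detections simulated; fits will be unstable.", expected))
  }
  survey <- assemble_survey(segments, observations, design$platforms)
  base_N <- true_abundance(design)
  mults <- vapply(design$platforms$platform_id,
                  function(id) design$density_mult[[id]] %||% 1, numeric(1))
  by_platform <- setNames(base_N * mults, design$platforms$platform_id)
  # simultaneous protocols record disjoint subsets of one population, so
  # their per-platform totals add; separate surveys each census the same
  # population, so the total is the shared surface's integral
  simultaneous <- any(!is.na(design$platforms$simultaneous_with))
  total_N <- if (simultaneous) sum(by_platform) else base_N
  list(survey = survey,
       truth = list(total_N = total_N, by_platform = by_platform,
                    simultaneous = simultaneous,
                    mean_density = design$density$mean_density,
                    density_type = design$density$type,
                    region = design$region, seed = seed))
}

#' Prediction grid over a simulated region
#'
#' @param design A [sim_design()] (or a list with a `region` element).
#' @param nx,ny Grid resolution.
#' @return Tibble with `cell_id`, `x`, `y`, `area`.
#' @export
make_grid <- function(design, nx = 20, ny = 20) {
  W <- design$region[1]; H <- design$region[2]
  g <- tidyr::expand_grid(ix = seq_len(nx), iy = seq_len(ny))
  tibble::tibble(cell_id = sprintf("C%04d", seq_len(nrow(g))),
                 x = (g$ix - 0.5) * W / nx,
                 y = (g$iy - 0.5) * H / ny,
                 area = (W / nx) * (H / ny))
}

#' Built-in simulation profiles
#'
#' Three ready-made designs exercising the main survey configurations:
#' * `"minimal"` — one half-normal line-transect platform, 20 segments; a
#'   fast smoke-test design.
#' * `"fulmar_like"` — a seabirds-at-sea design: one-sided binned line
#'   transect (cutpoints 0/0.05/0.1/0.2/0.3 km) for birds on the water plus
#'   a simultaneous one-sided 0.3 km strip for flying birds, duplicated
#'   segments.
#' * `"finwhale_like"` — two separate surveys: a shipboard double-observer
#'   (independent observer) hazard-rate platform truncated at 6 km, and an
#'   aerial hazard-rate platform truncated at 0.9 km with fixed g(0) = 0.67
#'   and availability 0.37 multipliers.
#'
#' @param profile Profile name.
#' @return A `"sim_design"`.
#' @export
sim_profile <- function(profile = c("minimal", "fulmar_like",
                                    "finwhale_like")) {
  profile <- match.arg(profile)
  switch(profile,
    minimal = sim_design(
      region = c(10, 10),
      density = sim_density("logsmooth", mean_density = 4, coef = 0.8),
      platforms = platform_registry(
        platform("main", "line_cds", truncation_w = 0.6)),
      det_params = list(main = list(key = "half_normal", sigma = 0.3)),
      n_lines = 2, seg_len = 1),
    fulmar_like = sim_design(
      region = c(30, 30),
      density = sim_density("logsmooth", mean_density = 3, coef = 0.8),
      platforms = platform_registry(
        platform("water", "line_cds", truncation_w = 0.3,
                 bin_cutpoints = c(0, 0.05, 0.1, 0.2, 0.3), sides = "one",
                 simultaneous_with = "flying"),
        platform("flying", "strip", truncation_w = 0.3, sides = "one",
                 simultaneous_with = "water")),
      det_params = list(water = list(key = "half_normal", sigma = 0.15)),
      # behavioural split: 60% of birds on the water, 40% flying
      density_mult = c(water = 0.6, flying = 0.4),
      n_lines = 5, seg_len = 2),
    finwhale_like = sim_design(
      region = c(60, 60),
      density = sim_density("logsmooth", mean_density = 0.6, coef = 0.8),
      platforms = platform_registry(
        platform("ship", "mrds_io", truncation_w = 6),
        platform("aerial", "line_mcds", truncation_w = 0.9,
                 g0 = 0.67, g0_cv = 0.1,
                 availability = 0.37, availability_cv = 0.1)),
      det_params = list(
        ship = list(key = "hazard_rate", sigma = 2.5, shape = 2.5,
                    p0_1 = 0.8, p0_2 = 0.8),
        aerial = list(key = "hazard_rate", sigma = 0.4, shape = 2.5)),
      n_lines = 6, seg_len = 5))
}

#' Write simulated fixture files
#'
#' Simulates a profile and writes the survey CSVs, the platform YAML, a
#' prediction grid and a structured truth record to `dir`. Deterministic
#' given `profile` and `seed`.
#'
#' @param profile See [sim_profile()].
#' @param dir Output directory.
#' @param seed Integer seed.
#' @return The directory, invisibly.
#' @export
make_fixtures <- function(profile = "minimal", dir = tempfile("mdsm"),
                          seed = 1) {
  design <- sim_profile(profile)
  sim <- simulate_survey(design, seed = seed)
  write_survey(sim$survey, dir)
  readr::write_csv(make_grid(design), file.path(dir, "grid.csv"),
                   progress = FALSE)
  yaml::write_yaml(list(profile = profile, seed = seed,
                        total_N = sim$truth$total_N,
                        region = as.numeric(design$region)),
                   file.path(dir, "truth.yaml"))
  invisible(dir)
}
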