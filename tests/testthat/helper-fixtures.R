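# shared fixtures and independent oracles, built in code at test time

# rejection sampler for half-normal detected distances on [0, w]
# (independent of the package's likelihood code)
rtrunc_halfnormal <- function(n, sigma, w) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- runif(2 * n, 0, w)
    keep <- runif(2 * n) < exp(-x^2 / (2 * sigma^2))
    out <- c(out, x[keep])
  }
  out[seq_len(n)]
}

# quadrature oracle
quad <- function(f, lo, hi) {
  integrate(f, lo, hi, abs.tol = 1e-12, rel.tol = 1e-12)$value
}

# a simple two-segment toy survey for one line platform
toy_survey <- function(w = 6) {
  platforms <- platform_registry(
    platform("boat", "line_cds", truncation_w = w))
  segments <- tibble::tibble(
    segment_id = c("A", "B"), platform_id = "boat",
    effort_length = c(2, 2), x = c(1, 2), y = c(1, 1))
  observations <- tibble::tibble(
    object_id = 1:3, segment_id = "A", platform_id = "boat",
    distance = c(0.5, 1.2, 3.0), size = c(1, 2, 1))
  list(platforms = platforms, segments = segments,
       observations = observations)
}

# exact-distance observations attached to single-segment-per-obs segments,
# for detection fitting at a given sample size
sim_detection_data <- function(n, sigma, w, seed) {
  set.seed(seed)
  tibble::tibble(
    object_id = seq_len(n),
    segment_id = sprintf("S%04d", seq_len(n)),
    platform_id = "p1",
    distance = rtrunc_halfnormal(n, sigma, w),
    size = 1)
}

# double-observer trials simulated directly from a logistic law
# logit p_j(x) = b0 + b1 * x, independent observers
sim_mrds_obs <- function(n_objects, b0, b1, w, seed) {
  set.seed(seed)
  x <- runif(n_objects, 0, w)
  p <- plogis(b0 + b1 * x)
  d1 <- rbinom(n_objects, 1, p)
  d2 <- rbinom(n_objects, 1, p)
  keep <- d1 + d2 >= 1
  tibble::tibble(
    object_id = seq_len(sum(keep)),
    segment_id = "S1", platform_id = "ship",
    distance = x[keep], size = 1,
    detected_by_1 = d1[keep], detected_by_2 = d2[keep])
}
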