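#' Declare a survey platform
#'
#' A platform is a survey/protocol combination with its own detection process:
#' a shipboard line transect, an aerial survey, the "birds in flight" strip of
#' a seabirds-at-sea protocol, and so on. Each platform carries its protocol,
#' truncation distance, optional distance-bin cutpoints, and any fixed
#' detectability multipliers (a trackline detection probability g(0) and an
#' availability probability, each with a CV that is folded into the final
#' abundance CV by squared addition).
#'
#' @param platform_id Short identifier, unique within a registry.
#' @param protocol One of `"line_cds"`, `"line_mcds"`, `"point"`, `"strip"`,
#'   `"mrds_io"` (independent-observer double-platform line transect).
#' @param truncation_w Truncation distance (same length unit as all distances;
#'   must be positive).
#' @param bin_cutpoints Optional ascending vector of bin cutpoints, starting at
#'   0 and ending at `truncation_w`. Bins are half-open `[c_j, c_{j+1})` with
#'   the last bin closed at `truncation_w`.
#' @param sides `"two"` if the transect covers both sides of the line (the
#'   default), `"one"` for a one-sided strip.
#' @param simultaneous_with Optional `platform_id` of a platform operating
#'   simultaneously on the same physical segments (see
#'   [duplicate_segments()]).
#' @param g0 Fixed trackline detection probability multiplier in (0, 1]
#'   (default 1). Leave at 1 for platforms whose g(0) is estimated from
#'   double-observer data.
#' @param g0_cv,availability_cv Coefficients of variation of the fixed
#'   multipliers; enter only the combined abundance CV.
#' @param availability Fixed availability probability in (0, 1] (default 1).
#' @return A one-row tibble; bind several with [platform_registry()].
#' @examples
#' platform("aerial", "line_mcds", truncation_w = 0.9,
#'          g0 = 0.67, g0_cv = 0.1, availability = 0.37, availability_cv = 0.1)
#' @export
platform <- function(platform_id, protocol, truncation_w,
                     bin_cutpoints = NULL,
                     sides = c("two", "one"),
                     simultaneous_with = NA_character_,
                     g0 = 1, g0_cv = 0,
                     availability = 1, availability_cv = 0) {
  protocol <- match.arg(protocol,
                        c("line_cds", "line_mcds", "point", "strip", "mrds_io"))
  sides <- match.arg(sides)
  if (!is_scalar_number(truncation_w) || truncation_w <= 0) {
    stop_mdsm("`truncation_w` must be a positive number.",
              "mdsm_validation_error")
  }
  if (!is.null(bin_cutpoints)) {
    bc <- as.numeric(bin_cutpoints)
    if (length(bc) < 2L || any(diff(bc) <= 0)) {
      stop_mdsm("`bin_cutpoints` must be strictly ascending.",
                "mdsm_validation_error")
    }
    if (bc[1] != 0 || abs(bc[length(bc)] - truncation_w) > 1e-9) {
      stop_mdsm(
        "`bin_cutpoints` must start at 0 and end at `truncation_w`.",
        "mdsm_validation_error")
    }
    bin_cutpoints <- bc
  }
  for (p in list(g0 = g0, availability = availability)) {
    if (!is_scalar_number(p) || p <= 0 || p > 1) {
      stop_mdsm("Fixed multipliers must lie in (0, 1].",
                "mdsm_validation_error")
    }
  }
  if (g0_cv < 0 || availability_cv < 0) {
    stop_mdsm("Multiplier CVs must be non-negative.", "mdsm_validation_error")
  }
  tibble::tibble(
    platform_id = as.character(platform_id),
    protocol = protocol,
    truncation_w = truncation_w,
    bin_cutpoints = list(bin_cutpoints),
    sides = sides,
    simultaneous_with = as.character(simultaneous_with),
    g0 = g0, g0_cv = g0_cv,
    availability = availability, availability_cv = availability_cv
  )
}

#' Combine platforms into a registry
#'
#' @param ... One-row tibbles from [platform()] (or tibbles of several rows).
#' @return A tibble with one row per platform.
#' @export
platform_registry <- function(...) {
  reg <- dplyr::bind_rows(...)
  if (anyDuplicated(reg$platform_id)) {
    stop_mdsm("Duplicate platform_id in registry.", "mdsm_validation_error")
  }
  bad <- setdiff(stats::na.omit(reg$simultaneous_with), reg$platform_id)
  if (length(bad) > 0) {
    stop_mdsm(sprintf("simultaneous_with refers to unknown platform(s): %s",
                      paste(bad, collapse = ", ")),
              "mdsm_reference_error")
  }
  reg
}

platform_row <- function(platforms, platform_id) {
  row <- platforms[platforms$platform_id == platform_id, ]
  if (nrow(row) != 1L) {
    stop_mdsm(sprintf("Unknown platform_id '%s'.", platform_id),
              "mdsm_reference_error")
  }
  row
}

#' Read / write a platform registry as YAML
#'
#' The registry file maps each platform id to its protocol, truncation,
#' optional cutpoints, sides, simultaneous partner and fixed multipliers.
#'
#' @param path File path.
#' @param platforms A registry tibble from [platform_registry()].
#' @return `read_platforms()` returns a registry tibble; `write_platforms()`
#'   returns `path` invisibly.
#' @export
read_platforms <- function(path) {
  if (!file.exists(path)) {
    stop_mdsm(sprintf("Platform file '%s' does not exist.", path),
              "mdsm_io_error")
  }
  raw <- yaml::read_yaml(path)
  rows <- purrr::imap(raw, function(spec, id) {
    platform(
      platform_id = id,
      protocol = spec$protocol,
      truncation_w = spec$truncation,
      bin_cutpoints = spec$cutpoints,
      sides = spec$sides %||% "two",
      simultaneous_with = spec$simultaneous_with %||% NA_character_,
      g0 = spec$g0 %||% 1, g0_cv = spec$g0_cv %||% 0,
      availability = spec$availability %||% 1,
      availability_cv = spec$availability_cv %||% 0
    )
  })
  platform_registry(rows)
}

#' @rdname read_platforms
#' @export
write_platforms <- function(platforms, path) {
  out <- purrr::map(seq_len(nrow(platforms)), function(i) {
    row <- platforms[i, ]
    spec <- list(
      protocol = row$protocol,
      truncation = row$truncation_w,
      sides = row$sides,
      g0 = row$g0, g0_cv = row$g0_cv,
      availability = row$availability,
      availability_cv = row$availability_cv
    )
    if (!is.null(row$bin_cutpoints[[1]])) {
      spec$cutpoints <- as.numeric(row$bin_cutpoints[[1]])
    }
    if (!is.na(row$simultaneous_with)) {
      spec$simultaneous_with <- row$simultaneous_with
    }
    spec
  })
  names(out) <- platforms$platform_id
  yaml::write_yaml(out, path)
  invisible(path)
}

required_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_mdsm(sprintf("%s is missing required column(s): %s",
                      what, paste(missing, collapse = ", ")),
              "mdsm_schema_error")
  }
}

#' Derive segment areas from effort
#'
#' When no `area` column is supplied, segment areas are computed from effort
#' and the platform geometry: `sides * truncation_w * effort_length` for line
#' and strip transects (`sides` is 1 or 2), and
#' `point_count * pi * truncation_w^2` for point transects. Areas are in the
#' square of the distance unit used throughout.
#'
#' @param segments Segment tibble with `platform_id` and `effort_length` (or
#'   `point_count` for point platforms).
#' @param platforms Platform registry.
#' @return `segments` with an `area` column.
#' @export
compute_areas <- function(segments, platforms) {
  required_cols(segments, "platform_id", "segments")
  areas <- purrr::map_dbl(seq_len(nrow(segments)), function(i) {
    pl <- platform_row(platforms, segments$platform_id[i])
    if (pl$protocol == "point") {
      required_cols(segments, "point_count", "segments (point platform)")
      segments$point_count[i] * pi * pl$truncation_w^2
    } else {
      required_cols(segments, "effort_length", "segments (line platform)")
      nsides <- if (pl$sides == "two") 2 else 1
      nsides * pl$truncation_w * segments$effort_length[i]
    }
  })
  dplyr::mutate(segments, area = areas)
}

#' Truncate observations at each platform's truncation distance
#'
#' Rows with distances beyond their platform's truncation are dropped (a
#' message reports how many). Bin-coded rows are left unchanged, since bin
#' cutpoints already respect the truncation. Negative distances are a
#' validation error.
#'
#' @param observations Observation tibble with `platform_id` and `distance`
#'   (and/or `bin`).
#' @param platforms Platform registry (a single-platform registry is fine).
#' @return The truncated observation tibble.
#' @export
truncate_observations <- function(observations, platforms) {
  if (nrow(observations) == 0L) return(observations)
  required_cols(observations, "platform_id", "observations")
  has_distance <- "distance" %in% names(observations)
  if (has_distance && any(observations$distance < 0, na.rm = TRUE)) {
    stop_mdsm("Negative distances are not allowed.", "mdsm_validation_error")
  }
  keep <- purrr::map_lgl(seq_len(nrow(observations)), function(i) {
    pl <- platform_row(platforms, observations$platform_id[i])
    if (pl$protocol == "strip") return(TRUE)
    d <- if (has_distance) observations$distance[i] else NA_real_
    if (is.na(d)) {
      if ("bin" %in% names(observations) && !is.na(observations$bin[i])) {
        return(TRUE)
      }
      stop_mdsm(sprintf(
        "Observation %s on non-strip platform '%s' has no distance or bin.",
        observations$object_id[i] %||% i, pl$platform_id),
        "mdsm_validation_error")
    }
    d <= pl$truncation_w + 1e-12
  })
  dropped <- sum(!keep)
  if (dropped > 0) {
    rlang::inform(sprintf(
      "Dropped %d observation(s) beyond the truncation distance.", dropped))
  }
  observations[keep, , drop = FALSE]
}

# assign bin index from exact distances for a binned platform;
# bins are [c_j, c_{j+1}) except the last, closed at w
assign_bins <- function(distance, cutpoints) {
  idx <- findInterval(distance, cutpoints, rightmost.closed = TRUE,
                      left.open = FALSE)
  idx[idx > length(cutpoints) - 1L] <- length(cutpoints) - 1L
  idx
}

#' Recompute segment counts from observations
#'
#' Sets each segment's count `n` to the sum of group sizes of its attached
#' (already truncated) observations; segments with no observations get 0.
#'
#' @param segments Segment tibble with `segment_id` and `platform_id`.
#' @param observations Observation tibble with `segment_id`, `platform_id` and
#'   `size`.
#' @return `segments` with an updated integer-valued `n` column.
#' @export
recount_segments <- function(segments, observations) {
  if (nrow(observations) > 0L) {
    required_cols(observations, c("segment_id", "platform_id", "size"),
                  "observations")
    counts <- observations |>
      dplyr::group_by(.data$segment_id, .data$platform_id) |>
      dplyr::summarise(n = sum(.data$size), .groups = "drop")
  } else {
    counts <- tibble::tibble(segment_id = character(0),
                             platform_id = character(0), n = numeric(0))
  }
  segments$n <- NULL
  segments |>
    dplyr::left_join(counts, by = c("segment_id", "platform_id")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0))
}

#' Duplicate segments for simultaneous protocols
#'
#' When two protocols run simultaneously over the same physical effort (e.g.
#' birds on the water recorded by line transect while birds in flight are
#' recorded by strip transect), each physical segment is analysed once per
#' platform: `n1` physical segments become `2 * n1` analysis rows. Each copy
#' carries its own `platform_id`, its own area (recomputed from effort when
#' `effort_length` is present, since truncation and sides may differ between
#' the protocols) and its own count `n`, while shared environmental covariates
#' are identical across copies.
#'
#' @param segments One physical set of segments (any `platform_id` column is
#'   ignored).
#' @param platforms Registry containing exactly the two platforms, marked as
#'   simultaneous via `simultaneous_with`.
#' @param observations Optional observations (with `platform_id`) used to
#'   recompute per-copy counts.
#' @return A segment tibble with `2 * nrow(segments)` rows.
#' @export
duplicate_segments <- function(segments, platforms, observations = NULL) {
  if (nrow(platforms) != 2L) {
    stop_mdsm("`platforms` must contain exactly two platforms.",
              "mdsm_validation_error")
  }
  ok <- identical(platforms$simultaneous_with[1], platforms$platform_id[2]) ||
    identical(platforms$simultaneous_with[2], platforms$platform_id[1])
  if (!ok) {
    stop_mdsm("The two platforms are not marked as simultaneous.",
              "mdsm_validation_error")
  }
  segments$platform_id <- NULL
  out <- purrr::map_dfr(platforms$platform_id, function(id) {
    dplyr::mutate(segments, platform_id = id)
  })
  if ("effort_length" %in% names(out)) {
    out <- compute_areas(out, platforms)
  }
  if (!is.null(observations)) {
    out <- recount_segments(out, observations)
  }
  out
}

#' Read a multi-platform survey from delimited text
#'
#' Reads the three comma-separated survey tables (segments, observations,
#' platform registry as YAML), validates them against the registry, truncates
#' observations at each platform's truncation distance, derives segment areas
#' from effort where no `area` column is given, assigns bin indices for binned
#' platforms, and recomputes segment counts from the surviving observations.
#' Missing model covariates are rejected, not imputed.
#'
#' @param segments_path,observations_path Paths to CSV files.
#' @param platforms_path Path to the YAML platform registry.
#' @return A list of class `"mdsm_survey"` with elements `segments`,
#'   `observations` and `platforms`.
#' @export
read_survey <- function(segments_path, observations_path, platforms_path) {
  for (p in c(segments_path, observations_path, platforms_path)) {
    if (!file.exists(p)) {
      stop_mdsm(sprintf("Input file '%s' does not exist.", p), "mdsm_io_error")
    }
  }
  platforms <- read_platforms(platforms_path)
  segments <- readr::read_csv(segments_path, show_col_types = FALSE,
                              progress = FALSE)
  observations <- readr::read_csv(observations_path, show_col_types = FALSE,
                                  progress = FALSE)
  assemble_survey(segments, observations, platforms)
}

#' Assemble and validate a survey from in-memory tables
#'
#' The programmatic counterpart of [read_survey()]; applies the same
#' validation, truncation, area derivation, binning and recounting.
#'
#' @param segments,observations Tibbles (see [read_survey()] for schemas).
#' @param platforms Platform registry tibble.
#' @return A list of class `"mdsm_survey"`.
#' @export
assemble_survey <- function(segments, observations, platforms) {
  required_cols(segments, c("segment_id", "platform_id"), "segments")
  required_cols(observations, c("segment_id", "platform_id", "size"),
                "observations")
  segments$segment_id <- as.character(segments$segment_id)
  observations$segment_id <- as.character(observations$segment_id)

  bad <- setdiff(unique(c(segments$platform_id, observations$platform_id)),
                 platforms$platform_id)
  if (length(bad) > 0) {
    stop_mdsm(sprintf("Unknown platform_id(s): %s",
                      paste(bad, collapse = ", ")), "mdsm_reference_error")
  }
  key_seg <- paste(segments$segment_id, segments$platform_id)
  if (anyDuplicated(key_seg)) {
    stop_mdsm("Duplicate (segment_id, platform_id) rows in segments.",
              "mdsm_validation_error")
  }
  key_obs <- paste(observations$segment_id, observations$platform_id)
  orphan <- !(key_obs %in% key_seg)
  if (any(orphan)) {
    stop_mdsm(sprintf("%d observation(s) refer to unknown segments.",
                      sum(orphan)), "mdsm_reference_error")
  }
  if (any(observations$size < 1, na.rm = TRUE)) {
    stop_mdsm("Group sizes must be >= 1.", "mdsm_validation_error")
  }

  if (!("area" %in% names(segments))) {
    segments <- compute_areas(segments, platforms)
  }
  if (any(!is.finite(segments$area) | segments$area <= 0)) {
    stop_mdsm("All segment areas must be positive.", "mdsm_validation_error")
  }
  if (!("u" %in% names(segments))) {
    segments$u <- platforms$availability[
      match(segments$platform_id, platforms$platform_id)]
  }
  if (any(segments$u <= 0 | segments$u > 1)) {
    stop_mdsm("Availability u must lie in (0, 1].", "mdsm_validation_error")
  }
  if (!("g0" %in% names(segments))) {
    segments$g0 <- platforms$g0[
      match(segments$platform_id, platforms$platform_id)]
  }

  observations <- truncate_observations(observations, platforms)
  # bin assignment for binned platforms with exact distances
  if (nrow(observations) > 0L) {
    if (!("bin" %in% names(observations))) observations$bin <- NA_integer_
    observations$bin <- as.integer(observations$bin)
    for (i in seq_len(nrow(platforms))) {
      cp <- platforms$bin_cutpoints[[i]]
      if (is.null(cp)) next
      rows <- observations$platform_id == platforms$platform_id[i] &
        is.na(observations$bin) & !is.na(observations$distance %||% NA)
      if (any(rows)) {
        observations$bin[rows] <- assign_bins(observations$distance[rows], cp)
      }
    }
    # MRDS flags
    if (all(c("detected_by_1", "detected_by_2") %in% names(observations))) {
      mrds_ids <- platforms$platform_id[platforms$protocol == "mrds_io"]
      mr <- observations$platform_id %in% mrds_ids
      if (any(mr)) {
        tot <- observations$detected_by_1[mr] + observations$detected_by_2[mr]
        if (any(is.na(tot)) || any(tot < 1)) {
          stop_mdsm(
            "MRDS observations need detected_by_1 + detected_by_2 >= 1.",
            "mdsm_validation_error")
        }
      }
    }
  }
  segments <- recount_segments(segments, observations)

  structure(list(segments = segments, observations = observations,
                 platforms = platforms),
            class = "mdsm_survey")
}

#' Write a survey back to delimited text
#'
#' Round-trips losslessly with [read_survey()] (counts and bins are
#' recomputed deterministically on read).
#'
#' @param survey An `"mdsm_survey"` list.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_survey <- function(survey, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(survey$segments, file.path(dir, "segments.csv"),
                   progress = FALSE)
  readr::write_csv(survey$observations, file.path(dir, "observations.csv"),
                   progress = FALSE)
  write_platforms(survey$platforms, file.path(dir, "platforms.yaml"))
  invisible(dir)
}

#' @export
print.mdsm_survey <- function(x, ...) {
  cat(sprintf("<mdsm_survey> %d segments, %d observations, %d platform(s)\n",
              nrow(x$segments), nrow(x$observations), nrow(x$platforms)))
  cat("platforms:", paste(sprintf("%s [%s]", x$platforms$platform_id,
                                  x$platforms$protocol), collapse = ", "), "\n")
  invisible(x)
}
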