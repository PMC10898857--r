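# Profile ingestion and geometry: calibration, resampling, smoothing,
# mirroring into closed outlines, vessel dimensions, and trial timing.

COMMUNITIES <- c("PR", "MK", "FR")
VESSEL_TYPES <- c("cylinder", "bowl", "sphere", "vase")

TRIAL_COLUMNS <- c(
  "potter_id", "community", "vessel_type", "clay_mass_kg", "trial",
  "gesture_index", "elapsed_time_s", "point_index", "x", "y"
)

#' Construct a trial record
#'
#' A trial record holds the ordered sequence of digitized half-profiles (one
#' per fashioning gesture, the first being the preform) for one vessel thrown
#' by one potter, together with its design keys and timing.
#'
#' @param potter_id potter identifier (character).
#' @param community community code, one of `"PR"`, `"MK"`, `"FR"`.
#' @param vessel_type one of `"cylinder"`, `"bowl"`, `"sphere"`, `"vase"`.
#' @param clay_mass clay mass in kg (the study used 0.75 and 2.25).
#' @param trial trial number in 1..5.
#' @param profiles list of two-column (x, y) matrices, right half-profiles in
#'   cm, ordered by gesture; element 1 is the preform (gesture 0).
#' @param elapsed_time numeric vector of seconds from forming-phase onset,
#'   strictly increasing, one per profile.
#' @return an object of class `trial_record`.
#' @export
trial_record <- function(potter_id, community, vessel_type, clay_mass,
                         trial, profiles, elapsed_time) {
  assert(length(profiles) >= 2, "a trial needs at least a preform and a final profile")
  assert(length(elapsed_time) == length(profiles),
         "one elapsed time per profile is required")
  assert(all(diff(elapsed_time) > 0),
         "elapsed_time must be strictly increasing within a trial")
  assert(community %in% COMMUNITIES,
         "unknown community '", community, "'")
  profiles <- lapply(profiles, function(p) {
    p <- as.matrix(p)
    assert(ncol(p) == 2 && nrow(p) >= 3, "each profile needs >= 3 (x, y) points")
    assert(all(p[, 1] >= 0), "half-profiles must have x >= 0 (right half only)")
    colnames(p) <- c("x", "y")
    p
  })
  structure(
    list(
      potter_id = as.character(potter_id), community = community,
      vessel_type = as.character(vessel_type), clay_mass = as.numeric(clay_mass),
      trial = as.integer(trial), profiles = profiles,
      elapsed_time = as.numeric(elapsed_time),
      duration = as.numeric(elapsed_time[length(elapsed_time)])
    ),
    class = "trial_record"
  )
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf(
    "Trial: potter %s (%s), %s %.2f kg, trial %d, %d outlines, %.1f s\n",
    x$potter_id, x$community, x$vessel_type, x$clay_mass, x$trial,
    length(x$profiles), x$duration
  ))
  invisible(x)
}

trial_key <- function(trial) {
  paste(trial$potter_id, trial$vessel_type, trial$clay_mass, trial$trial, sep = "|")
}

#' Flatten trials to the long table schema
#'
#' @param trials list of `trial_record` objects.
#' @return a data frame with one row per digitized point.
#' @export
trials_to_table <- function(trials) {
  rows <- lapply(trials, function(tr) {
    per_gesture <- lapply(seq_along(tr$profiles), function(g) {
      p <- tr$profiles[[g]]
      data.frame(
        potter_id = tr$potter_id, community = tr$community,
        vessel_type = tr$vessel_type, clay_mass_kg = tr$clay_mass,
        trial = tr$trial, gesture_index = g - 1L,
        elapsed_time_s = tr$elapsed_time[g],
        point_index = seq_len(nrow(p)) - 1L,
        x = p[, 1], y = p[, 2]
      )
    })
    do.call(rbind, per_gesture)
  })
  do.call(rbind, rows)
}

#' Write trials to CSV or JSON
#'
#' @param trials list of `trial_record` objects.
#' @param path output file; format inferred from the extension unless given.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  tab <- trials_to_table(trials)
  if (format == "csv") {
    utils::write.csv(tab, path, row.names = FALSE)
  } else {
    jsonlite::write_json(tab, path, digits = NA)
  }
  invisible(path)
}

#' Read digitized trials from a long-format CSV or JSON table
#'
#' The schema has one row per digitized profile point, keyed by
#' potter / community / vessel type / clay mass / trial / gesture:
#' columns `potter_id, community, vessel_type, clay_mass_kg, trial,
#' gesture_index, elapsed_time_s, point_index, x, y`.
#'
#' @param path input file.
#' @param format `"csv"` or `"json"` (`"auto"` infers from the extension).
#' @return a list of [trial_record()] objects, ordered by potter, vessel type,
#'   clay mass and trial number.
#' @export
read_trials <- function(path, format = c("auto", "csv", "json")) {
  assert(file.exists(path), "input file not found: ", path)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  tab <- if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
  missing_cols <- setdiff(TRIAL_COLUMNS, names(tab))
  assert(length(missing_cols) == 0,
         "malformed file: missing column(s) ", paste(missing_cols, collapse = ", "))
  key_cols <- c("potter_id", "community", "vessel_type", "clay_mass_kg", "trial",
                "gesture_index", "elapsed_time_s", "point_index")
  bad <- which(!stats::complete.cases(tab[key_cols]))
  assert(length(bad) == 0,
         "malformed file: missing key values at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))

  key <- paste(tab$potter_id, tab$vessel_type, tab$clay_mass_kg, tab$trial, sep = "|")
  trials <- lapply(split(seq_len(nrow(tab)), key), function(idx) {
    sub <- tab[idx, ]
    sub <- sub[order(sub$gesture_index, sub$point_index), ]
    gestures <- split(sub, sub$gesture_index)
    times <- vapply(gestures, function(g) g$elapsed_time_s[1], numeric(1))
    if (any(diff(times) <= 0)) {
      stop_pm("validation error: elapsed_time not strictly increasing for trial ",
              "potter ", sub$potter_id[1], " ", sub$vessel_type[1],
              " ", sub$clay_mass_kg[1], " kg trial ", sub$trial[1])
    }
    trial_record(
      potter_id = sub$potter_id[1], community = sub$community[1],
      vessel_type = sub$vessel_type[1], clay_mass = sub$clay_mass_kg[1],
      trial = sub$trial[1],
      profiles = lapply(gestures, function(g) cbind(x = g$x, y = g$y)),
      elapsed_time = unname(times)
    )
  })
  ord <- order(vapply(trials, function(tr) {
    sprintf("%s|%s|%06.2f|%02d", tr$potter_id, tr$vessel_type, tr$clay_mass, tr$trial)
  }, character(1)))
  unname(trials[ord])
}

#' Convert a profile from pixels to centimeters
#'
#' @param profile two-column (x, y) matrix.
#' @param factor cm-per-pixel calibration factor (> 0), obtained from the
#'   digitized calibration object.
#' @return the profile scaled to cm.
#' @export
calibrate_profile <- function(profile, factor) {
  assert(is.numeric(factor) && length(factor) == 1 && factor > 0,
         "calibration factor must be a single positive number")
  p <- as.matrix(profile)
  p[] <- p * factor
  p
}

profile_height <- function(profile) diff(range(profile[, 2]))

#' Resample a half-profile to a regular grid
#'
#' Profiles are resampled to `n` points at regular intervals along the
#' vertical (y) axis when x is a single-valued function of y. Profiles that
#' overhang (x multivalued in y, e.g. necked vases digitized past the rim
#' lip) are resampled at equal arc-length steps instead and flagged with
#' `attr(, "parameterization") == "arc"`.
#'
#' @param profile two-column (x, y) matrix in cm.
#' @param n number of output points (default 256).
#' @return an `n` x 2 matrix ordered base to rim (ascending y).
#' @export
resample_profile <- function(profile, n = 256) {
  p <- as.matrix(profile)
  assert(nrow(p) >= 3, "profile needs >= 3 points")
  assert(profile_height(p) > 0, "degenerate profile: zero height")
  # normalize traversal to base -> rim
  if (p[1, 2] > p[nrow(p), 2]) p <- p[rev(seq_len(nrow(p))), ]
  dy <- diff(p[, 2])
  if (all(dy > 0)) {
    grid <- seq(min(p[, 2]), max(p[, 2]), length.out = n)
    x <- stats::approx(p[, 2], p[, 1], xout = grid, ties = "ordered")$y
    out <- cbind(x = x, y = grid)
    attr(out, "parameterization") <- "y"
  } else {
    seg <- sqrt(diff(p[, 1])^2 + dy^2)
    s <- c(0, cumsum(seg))
    assert(s[length(s)] > 0, "degenerate profile: zero length")
    grid <- seq(0, s[length(s)], length.out = n)
    out <- cbind(
      x = stats::approx(s, p[, 1], xout = grid, ties = "ordered")$y,
      y = stats::approx(s, p[, 2], xout = grid, ties = "ordered")$y
    )
    attr(out, "parameterization") <- "arc"
  }
  out
}

#' Low-pass smooth the x-coordinates of a profile
#'
#' Applies a zero-phase (forward-backward) second-order Butterworth low-pass
#' to the x series, with odd-reflective end padding so endpoints are
#' preserved. The y grid is untouched.
#'
#' @param profile resampled two-column (x, y) matrix.
#' @param cutoff normalized cutoff frequency as a fraction of the point-index
#'   sampling rate, in (0, 0.5). Default 0.1.
#' @return the smoothed profile.
#' @export
smooth_profile <- function(profile, cutoff = 0.1) {
  assert(is.numeric(cutoff) && length(cutoff) == 1 && cutoff > 0 && cutoff < 0.5,
         "cutoff must lie in (0, 0.5) as a fraction of the sampling rate")
  p <- as.matrix(profile)
  n <- nrow(p)
  bf <- signal::butter(2, 2 * cutoff)   # signal normalizes to Nyquist
  # pad long enough for the zero-state filter transient to decay below 1e-9
  pad <- min(n - 1L, max(24L, ceiling(7 / cutoff)))
  x <- p[, 1]
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  fwd <- signal::filter(bf, xp)
  bwd <- rev(signal::filter(bf, rev(fwd)))
  out <- p
  out[, 1] <- as.numeric(bwd)[(pad + 1):(pad + n)]
  attr(out, "parameterization") <- attr(profile, "parameterization")
  out
}

#' Mirror a half-profile into a closed outline
#'
#' Wheel-thrown vessels are axisymmetric, so the full cross-sectional outline
#' is obtained by reflecting the right half-profile about the rotation axis
#' (x = 0). The contour starts at the on-axis rim point, traverses the right
#' edge downwards (clockwise), returns along the mirrored left edge, and is
#' closed exactly; axis closure points are inserted when the profile
#' endpoints are off-axis, and duplicate on-axis points are merged.
#'
#' @param profile resampled (and usually smoothed) half-profile, x >= 0.
#' @param tol tolerance below which an x-coordinate counts as on-axis.
#' @return a closed outline: an (m+1) x 2 matrix whose first and last rows
#'   coincide, of class `outline`.
#' @export
close_outline <- function(profile, tol = 1e-9) {
  p <- as.matrix(profile)
  assert(all(p[, 1] >= -tol), "invalid half-profile: negative x coordinates")
  p[, 1] <- pmax(p[, 1], 0)
  if (p[1, 2] < p[nrow(p), 2]) p <- p[rev(seq_len(nrow(p))), ]  # rim first
  n <- nrow(p)
  right <- p
  if (right[1, 1] > tol) right <- rbind(c(0, right[1, 2]), right)
  if (right[nrow(right), 1] > tol) right <- rbind(right, c(0, right[nrow(right), 2]))
  right[c(1, nrow(right)), 1] <- 0   # snap on-axis endpoints exactly
  # both ends of `right` are now on the axis; the mirrored left edge shares
  # them, so it contributes rows m-1 .. 2 only (base to rim)
  left <- right[(nrow(right) - 1):2, , drop = FALSE]
  left[, 1] <- -left[, 1]
  out <- rbind(right, left, right[1, , drop = FALSE])
  colnames(out) <- c("x", "y")
  structure(out, class = c("outline", "matrix", "array"),
            start = "rim-axis", orientation = "clockwise")
}

#' @export
print.outline <- function(x, ...) {
  cat(sprintf("Closed outline: %d points, height %.3f cm, max diameter %.3f cm\n",
              nrow(x) - 1L, diff(range(x[, 2])), 2 * max(x[, 1])))
  invisible(x)
}

#' Signed area of a closed outline (shoelace)
#' @param outline a closed outline matrix.
#' @return signed area in cm^2 (negative for clockwise traversal).
#' @export
outline_area <- function(outline) {
  o <- unclass(outline)
  n <- nrow(o)
  sum(o[-n, 1] * o[-1, 2] - o[-1, 1] * o[-n, 2]) / 2
}

#' Vessel height and maximum diameter
#'
#' @param profile a calibrated half-profile (or closed outline).
#' @return named numeric vector `c(height, max_diameter)` in cm:
#'   height = y range, max_diameter = 2 x max(x).
#' @export
vessel_dimensions <- function(profile) {
  p <- as.matrix(profile)
  c(height = diff(range(p[, 2])), max_diameter = 2 * max(p[, 1]))
}

#' Percent time of each outline in a trial
#'
#' Rescales elapsed time so the start of the shaping phase (the preform) is 0
#' and the end (the final form) is 100, linear in elapsed seconds.
#'
#' @param trial a `trial_record`.
#' @return numeric vector of percent-time stamps, one per outline.
#' @export
percent_time <- function(trial) {
  t <- trial$elapsed_time
  assert(length(t) >= 2, "percent time needs >= 2 outlines")
  span <- t[length(t)] - t[1]
  assert(span > 0, "degenerate trial: zero duration")
  (t - t[1]) / span * 100
}

#' Closed outlines for every gesture of a trial
#'
#' Convenience composition of [resample_profile()], [smooth_profile()] and
#' [close_outline()] over a trial's profile sequence.
#'
#' @param trial a `trial_record`.
#' @param n resampling resolution (default 256 points).
#' @param cutoff smoothing cutoff; `NULL` skips smoothing.
#' @return list of `outline` objects, one per gesture.
#' @export
trial_outlines <- function(trial, n = 256, cutoff = 0.1) {
  lapply(trial$profiles, function(p) {
    r <- resample_profile(p, n = n)
    if (!is.null(cutoff)) r <- smooth_profile(r, cutoff = cutoff)
    close_outline(r)
  })
}
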