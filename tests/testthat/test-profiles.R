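# Profile ingestion, calibration, resampling, smoothing, mirroring, timing.

make_mini_trials <- function(seed = 11) {
  cfg <- small_config(seed, potters = c(2, 2, 2), trials = 2,
                      gestures = c(3, 5), n_points = 40)
  generate_study(cfg)
}

test_that("write/read round-trip reproduces the dataset and orders trials", {
  trials <- make_mini_trials()
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(trials, path)
  back <- read_trials(path)
  expect_length(back, length(trials))   # 3 communities x 2 potters x 2 trials
  expect_length(back, 12)
  key <- function(tr) paste(tr$potter_id, tr$vessel_type, tr$clay_mass, tr$trial)
  ord <- match(vapply(back, key, ""), vapply(trials, key, ""))
  for (i in seq_along(back)) {
    orig <- trials[[ord[i]]]
    expect_identical(back[[i]]$community, orig$community)
    expect_equal(back[[i]]$elapsed_time, orig$elapsed_time)
    for (g in seq_along(orig$profiles)) {
      expect_equal(unname(back[[i]]$profiles[[g]]), unname(orig$profiles[[g]]))
    }
  }
  # JSON route round-trips too
  jpath <- withr::local_tempfile(fileext = ".json")
  write_trials(trials[1:2], jpath)
  expect_length(read_trials(jpath), 2)
})

test_that("malformed tables are rejected with informative errors", {
  trials <- make_mini_trials()
  tab <- trials_to_table(trials[1:2])
  path <- withr::local_tempfile(fileext = ".csv")

  bad <- tab
  bad$elapsed_time_s[bad$gesture_index == 2] <- -1   # decreasing within trial
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_trials(path), "elapsed_time not strictly increasing")

  bad2 <- tab[, setdiff(names(tab), "community")]
  write.csv(bad2, path, row.names = FALSE)
  expect_error(read_trials(path), "missing column")

  bad3 <- tab
  bad3$trial[5] <- NA
  write.csv(bad3, path, row.names = FALSE)
  expect_error(read_trials(path), "missing key")

  expect_error(read_trials("no/such/file.csv"), "not found")
})

test_that("calibration scales coordinates and validates its factor", {
  p <- cbind(x = c(100, 120, 80), y = c(200, 100, 0))
  expect_equal(calibrate_profile(p, 1.0), p)
  expect_equal(calibrate_profile(p, 0.05)[1, ], c(x = 5.0, y = 10.0))
  expect_error(calibrate_profile(p, -1), "positive")
  expect_error(calibrate_profile(p, 0), "positive")
})

test_that("resampling yields a regular y grid and interpolates x linearly", {
  line <- cbind(x = rep(3, 11), y = seq(0, 10, 1))
  r <- resample_profile(line, n = 5)
  expect_equal(r[, "x"], rep(3, 5))
  expect_equal(r[, "y"], c(0, 2.5, 5, 7.5, 10))

  r256 <- resample_profile(make_vase_profile(1000), n = 256)
  expect_identical(nrow(r256), 256L)
  expect_equal(diff(r256[, "y"]), rep(diff(r256[1:2, "y"]), 255))

  expect_error(resample_profile(cbind(x = 1:3, y = rep(2, 3))), "zero height")
})

test_that("resampling a semicircular bowl tracks the analytic arc", {
  R <- 7
  y <- seq(0, R, length.out = 1000)
  half <- cbind(x = sqrt(pmax(R^2 - y^2, 0)), y = y)   # dome of radius 7
  r <- resample_profile(half, n = 256)
  expect_lt(max(abs(r[, "x"] - sqrt(pmax(R^2 - r[, "y"]^2, 0)))), 0.001 * R)
})

test_that("resampling is idempotent and flags overhanging profiles", {
  p <- make_vase_profile(333)
  r1 <- resample_profile(p, n = 128)
  r2 <- resample_profile(r1, n = 128)
  expect_lt(max(abs(r1 - r2)), 1e-12)
  expect_identical(attr(r1, "parameterization"), "y")

  # necked profile that folds back in y -> arc-length parameterization
  th <- seq(-pi / 2, pi / 2, length.out = 101)
  hook <- cbind(x = 2 + cos(th), y = 5 + sin(th))
  overhang <- rbind(cbind(x = rep(3, 20), y = seq(0, 4, length.out = 20)), hook)
  ro <- resample_profile(overhang, n = 64)
  expect_identical(attr(ro, "parameterization"), "arc")
  expect_identical(nrow(ro), 64L)
})

test_that("smoothing is low-pass, zero-phase and preserves constants", {
  y <- seq(0, 10, length.out = 256)
  const <- cbind(x = rep(4, 256), y = y)
  expect_lt(max(abs(smooth_profile(const, 0.1)[, "x"] - 4)), 1e-6)

  # smooth curve + high-frequency sinusoid far above the cutoff
  base <- 5 + sin(seq(0, pi, length.out = 256))
  noise <- 0.5 * sin(2 * pi * 0.35 * seq_len(256))
  prof <- cbind(x = base + noise, y = y)
  sm <- smooth_profile(prof, cutoff = 0.1)
  resid <- sm[, "x"] - base
  inner <- 20:236   # away from the reflective pads
  expect_lt(max(abs(resid[inner])), 0.1 * 0.5)  # > 90% attenuation

  expect_error(smooth_profile(prof, 0.6), "cutoff")
  expect_error(smooth_profile(prof, 0), "cutoff")
})

test_that("smoothing leaves dimensions of a band-limited profile intact", {
  p <- resample_profile(make_vase_profile(1000), n = 256)
  dim_raw <- vessel_dimensions(p)
  dim_sm <- vessel_dimensions(smooth_profile(p, 0.1))
  expect_lt(abs(dim_sm["height"] - dim_raw["height"]), 0.005 * dim_raw["height"])
  expect_lt(abs(dim_sm["max_diameter"] - dim_raw["max_diameter"]),
            0.005 * dim_raw["height"])
})

test_that("close_outline mirrors, closes, merges axis points and is symmetric", {
  prof <- make_vase_profile(256, axis_ends = TRUE)
  out <- close_outline(prof)
  n <- nrow(out)
  expect_equal(out[1, ], out[n, ])          # closed exactly
  expect_identical(n - 1L, 510L)            # 256 + 254 distinct points

  # reflecting about x = 0 maps the outline onto itself
  mirrored <- cbind(-out[, 1], out[, 2])
  match_dist <- vapply(seq_len(n - 1), function(i) {
    min(sqrt((mirrored[, 1] - out[i, 1])^2 + (mirrored[, 2] - out[i, 2])^2))
  }, numeric(1))
  expect_lt(max(match_dist), 1e-9)

  # area doubles the area between half-profile and axis (trapezoid rule)
  half_area <- sum(diff(prof[, 2]) * (prof[-1, 1] + prof[-256, 1]) / 2)
  expect_equal(abs(outline_area(out)), 2 * half_area, tolerance = 1e-10)

  # off-axis endpoints get closure points inserted
  out2 <- close_outline(make_vase_profile(256, axis_ends = FALSE))
  expect_identical(nrow(out2) - 1L, 514L)
  expect_equal(unname(out2[1, 1]), 0)

  bad <- make_vase_profile(64); bad[10, 1] <- -0.5
  expect_error(close_outline(bad), "invalid half-profile")
})

test_that("vessel dimensions follow the height / max-diameter definitions", {
  rect <- cbind(x = rep(5, 50), y = seq(0, 10, length.out = 50))
  expect_equal(vessel_dimensions(rect), c(height = 10, max_diameter = 10))

  y <- seq(0, 7, length.out = 500)
  dome <- cbind(x = sqrt(pmax(49 - y^2, 0)), y = y)
  expect_equal(vessel_dimensions(dome), c(height = 7, max_diameter = 14),
               tolerance = 1e-6)

  # generator ground truth: rendered profile matches its template dimensions
  cfg <- small_config(3, potters = c(2, 2, 2), trials = 1, gestures = c(3, 3),
                      sigma_community = 0, sigma_potter = 0, sigma_trial = 0,
                      sigma_measurement = 0)
  tr <- generate_study(cfg)[[1]]
  fin <- tr$profiles[[length(tr$profiles)]]
  dims <- vessel_dimensions(resample_profile(fin, 256))
  expect_lt(abs(dims["height"] - 15), 0.05)          # vase template H
  expect_lt(abs(dims["max_diameter"] - 22), 1.0)     # ~2 x max spline radius
})

test_that("percent time maps elapsed seconds linearly onto 0-100", {
  mk <- function(times) {
    p <- make_vase_profile(16)
    trial_record("P1", "PR", "vase", 2.25, 1,
                 rep(list(p), length(times)), times)
  }
  expect_equal(percent_time(mk(c(0, 5, 10))), c(0, 50, 100))
  expect_equal(percent_time(mk(c(3, 9))), c(0, 100))
  expect_equal(percent_time(mk(c(2, 4, 8))), c(0, 100 / 3, 100))
  expect_error(mk(c(2, 2, 2)), "strictly increasing")
})
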