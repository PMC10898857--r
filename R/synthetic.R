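# Seeded synthetic morphogenesis generator. Vessel shapes are monotone-height
# radius profiles controlled by 6 control points; a trial interpolates control
# points from a community-styled preform to a vessel-type template along a
# potter-specific schedule with a mid-path waypoint, plus trial- and
# measurement-level noise. Community and potter structure scale with
# sigma_community / sigma_potter, so setting either to zero removes that
# level of structure entirely (null data).

CONTROL_FRACS <- c(0, 0.2, 0.4, 0.6, 0.8, 1)

# final-form templates at 2.25 kg (radii in cm at the 6 control heights)
FINAL_TEMPLATES <- list(
  cylinder = list(radii = c(5.5, 5.6, 5.6, 5.6, 5.5, 5.3), height = 27),
  bowl     = list(radii = c(4.0, 9.0, 12.0, 14.0, 15.0, 15.5), height = 11),
  sphere   = list(radii = c(4.0, 9.0, 10.5, 10.0, 8.0, 5.0), height = 18),
  vase     = list(radii = c(4.0, 8.0, 11.0, 10.0, 6.0, 7.5), height = 15)
)

# shared preform base: a squat dome right after centering and opening
BASE_PREFORM <- list(radii = c(5.5, 7.0, 7.2, 7.0, 6.5, 6.8), height = 8)

# fixed community style directions (unit-scale patterns, multiplied by
# sigma_community): PR/MK wide-rimmed taller preforms with an overshooting
# (PR) or gradual (MK) path; FR flat disk-like preforms and wide bottoms
COMMUNITY_STYLES <- list(
  PR = list(pre_radii = c(-0.5, 0.0, 0.3, 0.5, 1.0, 2.0), pre_height = 2.5,
            way_radii = c(-1.0, -0.8, -0.5, -0.5, -0.8, -1.0), way_height = 6.0),
  MK = list(pre_radii = c(-0.3, 0.2, 0.4, 0.3, 0.8, 1.6), pre_height = 1.2,
            way_radii = c(-0.3, -0.2, -0.2, -0.3, -0.4, -0.5), way_height = 1.5),
  FR = list(pre_radii = c(1.5, 1.8, 1.5, 0.8, -0.5, -1.5), pre_height = -2.5,
            way_radii = c(2.0, 1.0, 0.2, -0.3, -0.5, -0.8), way_height = -1.0)
)

#' Configuration for the synthetic morphogenesis generator
#'
#' Defaults emulate the field-study design: 3 communities with 9/6/6 potters,
#' 5 trials per potter and vessel type, and 6-14 outlines per trial from
#' preform to final form. Effect scales are in control-point units (cm):
#' `sigma_community` scales all community-level structure (preform style,
#' path style, final-shape offsets), `sigma_potter` the potter-level random
#' offsets, `sigma_trial` the trial-to-trial noise, and
#' `sigma_measurement` the per-point digitization noise on x. `stage_scale`
#' multiplies effect and noise magnitudes at the preform, middle and final
#' stage (linearly interpolated over the path), defaulting to a decreasing
#' schedule so morphological variation narrows toward the final shape.
#'
#' @param n_communities number of communities (max 3: PR, MK, FR).
#' @param potters_per_community integer vector of potters per community.
#' @param trials_per_potter trials per potter and vessel type (default 5).
#' @param gestures_range inclusive range of outlines per trial.
#' @param vessel_types subset of cylinder/bowl/sphere/vase.
#' @param clay_masses subset of c(0.75, 2.25) kg.
#' @param n_points points per rendered half-profile (default 256).
#' @param sigma_community,sigma_potter,sigma_trial,sigma_measurement effect
#'   scales in cm; all must be >= 0.
#' @param stage_scale length-3 positive multipliers (preform, middle, final).
#' @param seed mandatory integer seed.
#' @return a `generator_config` list with validated fields.
#' @export
generator_config <- function(n_communities = 3,
                             potters_per_community = c(9, 6, 6),
                             trials_per_potter = 5,
                             gestures_range = c(6, 14),
                             vessel_types = "vase",
                             clay_masses = 2.25,
                             n_points = 256,
                             sigma_community = 0.6,
                             sigma_potter = 0.35,
                             sigma_trial = 0.15,
                             sigma_measurement = 0.02,
                             stage_scale = c(2, 1, 0.6),
                             seed = NULL) {
  assert(!is.null(seed), "a seed is mandatory")
  assert(n_communities >= 1 && n_communities <= 3, "1-3 communities supported")
  assert(length(potters_per_community) == n_communities &&
           all(potters_per_community >= 1), "invalid potters_per_community")
  assert(trials_per_potter >= 1, "trials_per_potter must be >= 1")
  assert(length(gestures_range) == 2 && gestures_range[1] >= 2 &&
           gestures_range[2] >= gestures_range[1], "invalid gestures_range")
  assert(all(vessel_types %in% VESSEL_TYPES), "unknown vessel type")
  sig <- c(sigma_community, sigma_potter, sigma_trial, sigma_measurement)
  assert(all(sig >= 0), "all sigma must be >= 0")
  assert(length(stage_scale) == 3 && all(stage_scale > 0), "invalid stage_scale")
  structure(
    list(
      n_communities = as.integer(n_communities),
      potters_per_community = as.integer(potters_per_community),
      trials_per_potter = as.integer(trials_per_potter),
      gestures_range = as.integer(gestures_range),
      vessel_types = vessel_types, clay_masses = clay_masses,
      n_points = as.integer(n_points),
      sigma_community = sigma_community, sigma_potter = sigma_potter,
      sigma_trial = sigma_trial, sigma_measurement = sigma_measurement,
      stage_scale = stage_scale, seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

stage_scale_at <- function(config, s) {
  ss <- config$stage_scale
  ifelse(s <= 0.5, ss[1] + (ss[2] - ss[1]) * s / 0.5,
         ss[2] + (ss[3] - ss[2]) * (s - 0.5) / 0.5)
}

validate_template <- function(radii, height) {
  assert(all(radii > 0), "config error: non-positive template radii")
  assert(height > 0, "config error: non-positive template height")
}

# deterministic effect ledger for one config: community offsets per
# (community, vessel type, mass) and potter offsets, all seeded sub-streams
draw_effects <- function(config) {
  comms <- COMMUNITIES[seq_len(config$n_communities)]
  eff <- list()
  for (ci in seq_along(comms)) {
    cm <- comms[ci]
    style <- COMMUNITY_STYLES[[cm]]
    potters <- lapply(seq_len(config$potters_per_community[ci]), function(pi) {
      with_seed(sub_seed(config$seed, 1L, ci, pi), {
        list(
          id = paste0(substr(cm, 1, 1), pi),
          pre_radii = stats::rnorm(6, 0, config$sigma_potter),
          pre_height = stats::rnorm(1, 0, config$sigma_potter),
          way_radii = stats::rnorm(6, 0, config$sigma_potter),
          way_height = stats::rnorm(1, 0, 2 * config$sigma_potter),
          final_radii = stats::rnorm(6, 0, config$sigma_potter),
          # potter-specific monotone time schedule; a potter-level effect,
          # so its spread also scales with sigma_potter
          speed = exp(stats::rnorm(1, 0, 0.7 * config$sigma_potter))
        )
      })
    })
    type_offsets <- list()
    for (vt in config$vessel_types) {
      for (mass in config$clay_masses) {
        key <- paste(vt, mass, sep = "|")
        type_offsets[[key]] <- with_seed(
          sub_seed(config$seed, 2L, ci, match(vt, VESSEL_TYPES),
                   round(mass * 100)),
          list(final_radii = stats::rnorm(6, 0, config$sigma_community),
               final_height = stats::rnorm(1, 0, config$sigma_community))
        )
      }
    }
    eff[[cm]] <- list(community = cm, style = style, potters = potters,
                      type_offsets = type_offsets)
  }
  eff
}

#' Exact effect ledger underlying a synthetic study
#'
#' Returns the community- and potter-level offsets and styles the generator
#' uses for a given configuration, for parameter-recovery tests. The ledger
#' is a pure function of the config (including its seed): regenerating the
#' study from the same config reproduces the same dataset.
#'
#' @param config a [generator_config()].
#' @return a list with the seed, config, and per-community effect entries.
#' @export
ground_truth <- function(config) {
  list(seed = config$seed, config = config, effects = draw_effects(config))
}

render_profile <- function(radii, height, config, sigma_meas) {
  validate_template(radii, height)
  ygrid <- seq(0, height, length.out = config$n_points)
  r <- stats::spline(CONTROL_FRACS * height, radii, xout = ygrid,
                     method = "natural")$y
  r <- pmax(r, 0.05)
  if (sigma_meas > 0) r <- pmax(r + stats::rnorm(length(r), 0, sigma_meas), 0.01)
  cbind(x = r, y = ygrid)
}

render_trial <- function(config, eff_c, potter, vt, mass, trial) {
  msc <- (mass / 2.25)^(1 / 3)   # linear dimension scaling with clay mass
  sc <- config$sigma_community
  style <- eff_c$style
  toff <- eff_c$type_offsets[[paste(vt, mass, sep = "|")]]
  fin <- FINAL_TEMPLATES[[vt]]

  # stage multipliers dial community/potter effect magnitudes by stage, so a
  # decreasing schedule narrows morphological variation toward the final form
  ss <- config$stage_scale
  pre_radii <- (BASE_PREFORM$radii +
                  ss[1] * (sc * style$pre_radii + potter$pre_radii)) * msc
  pre_height <- (BASE_PREFORM$height +
                   ss[1] * (sc * style$pre_height + potter$pre_height)) * msc
  fin_radii <- (fin$radii + ss[3] * (toff$final_radii + potter$final_radii)) * msc
  fin_height <- (fin$height + ss[3] * toff$final_height) * msc
  way_radii <- ss[2] * (sc * style$way_radii + potter$way_radii) * msc
  way_height <- ss[2] * (sc * style$way_height + potter$way_height) * msc

  with_seed(sub_seed(config$seed, 3L, match(eff_c$community, COMMUNITIES),
                     match(potter$id, vapply(eff_c$potters, `[[`, "", "id")),
                     match(vt, VESSEL_TYPES), round(mass * 100), trial), {
    g <- if (config$gestures_range[1] == config$gestures_range[2]) {
      config$gestures_range[1]
    } else {
      sample(config$gestures_range[1]:config$gestures_range[2], 1)
    }
    trial_radii <- stats::rnorm(6, 0, config$sigma_trial)
    trial_height <- stats::rnorm(1, 0, config$sigma_trial)
    profiles <- vector("list", g)
    for (k in seq_len(g)) {
      s <- (k - 1) / (g - 1)
      sw <- s^potter$speed          # potter-specific monotone schedule
      w <- sin(pi * sw)
      scale_s <- stage_scale_at(config, sw)
      jit <- stats::rnorm(6, 0, config$sigma_trial / 2)
      radii <- (1 - sw) * pre_radii + sw * fin_radii + w * way_radii +
        scale_s * (trial_radii + jit) * msc
      height <- (1 - sw) * pre_height + sw * fin_height + w * way_height +
        scale_s * trial_height * msc
      radii <- pmax(radii, 0.3)
      height <- max(height, 1)
      profiles[[k]] <- render_profile(radii, height, config,
                                      config$sigma_measurement)
    }
    base <- stats::rlnorm(1, log(140), 0.25)
    times <- cumsum(c(0, stats::rgamma(g - 1, shape = 2, scale = base / (2 * g))))
    times <- times + c(0, cumsum(rep(1e-3, g - 1)))   # guard strict increase
    trial_record(potter$id, eff_c$community, vt, mass, trial, profiles, times)
  })
}

#' Generate a synthetic morphogenesis study
#'
#' Produces seeded trial records for every potter x vessel type x clay mass
#' x trial combination of the configuration. Community structure (preform
#' styles, path styles, final-shape offsets) scales with `sigma_community`,
#' potter idiosyncrasies with `sigma_potter`; trial and measurement noise
#' are always present. Identical configs (same seed) give identical data.
#'
#' @param config a [generator_config()].
#' @return a list of `trial_record` objects with the effect ledger attached
#'   as attribute `ground_truth`.
#' @export
generate_study <- function(config) {
  eff <- draw_effects(config)
  trials <- list()
  for (cm in names(eff)) {
    for (potter in eff[[cm]]$potters) {
      for (vt in config$vessel_types) {
        for (mass in config$clay_masses) {
          for (tr in seq_len(config$trials_per_potter)) {
            trials[[length(trials) + 1L]] <-
              render_trial(config, eff[[cm]], potter, vt, mass, tr)
          }
        }
      }
    }
  }
  attr(trials, "ground_truth") <- list(seed = config$seed, config = config,
                                       effects = eff)
  trials
}

#' Generate null synthetic data
#'
#' `null = "community"` removes all community- and potter-level structure
#' (sigma_community = sigma_potter = 0), the exchangeable null for the
#' community-level permutation test; `null = "potter"` removes potter-level
#' structure only, the null for the individual-level test.
#'
#' @param config a [generator_config()].
#' @param null which null to generate.
#' @return as [generate_study()].
#' @export
generate_null <- function(config, null = c("community", "potter")) {
  null <- match.arg(null)
  config$sigma_potter <- 0
  if (null == "community") config$sigma_community <- 0
  generate_study(config)
}
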