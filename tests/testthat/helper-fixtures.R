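# Fixture builders and independent oracles used across the suite.

# closed contour of a circle: start at the top (on-axis) point, clockwise
make_circle <- function(r = 2, n = 400, center = c(0, 0)) {
  th <- seq(pi / 2, pi / 2 - 2 * pi, length.out = n + 1)[-(n + 1)]
  o <- cbind(x = center[1] + r * cos(th), y = center[2] + r * sin(th))
  rbind(o, o[1, ])
}

# axis-aligned ellipse, semi-axis a along x, b along y; start at top
make_ellipse <- function(a = 3, b = 1, n = 400) {
  th <- seq(pi / 2, pi / 2 - 2 * pi, length.out = n + 1)[-(n + 1)]
  o <- cbind(x = a * cos(th), y = b * sin(th))
  rbind(o, o[1, ])
}

# random smooth star-shaped closed contour (not symmetric)
make_random_contour <- function(n = 300, n_bumps = 4, amp = 0.15) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- 1
  for (k in seq_len(n_bumps)) {
    r <- r + amp * stats::rnorm(1) * cos((k + 1) * th + stats::runif(1, 0, 2 * pi))
  }
  o <- cbind(x = r * cos(th), y = r * sin(th))
  rbind(o, o[1, ])
}

# vase-like half-profile (on-axis endpoints optional)
make_vase_profile <- function(n = 256, height = 15, axis_ends = FALSE) {
  y <- seq(0, height, length.out = n)
  s <- y / height
  x <- 4 + 7 * sin(pi * s)^1.5 - 3 * exp(-((s - 0.85) / 0.12)^2)
  if (axis_ends) x[c(1, n)] <- 0
  cbind(x = pmax(x, 0), y = y)
}

small_config <- function(seed, potters = c(3, 2, 2), trials = 4,
                         gestures = c(5, 8), ...) {
  generator_config(potters_per_community = potters, trials_per_potter = trials,
                   gestures_range = gestures, seed = seed, ...)
}

# ---- independent EFA oracle ------------------------------------------------
# Fourier coefficients of the piecewise-linear coordinate functions x(t),
# y(t) under chord-length parameterization, by exact per-segment integration
# of (alpha + beta t) cos(w t) and (alpha + beta t) sin(w t). Independent of
# the Kuhl derivative-based formulas used by the implementation.
oracle_efa <- function(outline, n_harmonics = 30) {
  o <- unclass(as.matrix(outline))
  p <- o[-nrow(o), , drop = FALSE]
  np <- nrow(p)
  nxt <- c(2:np, 1L)
  dx <- p[nxt, 1] - p[, 1]; dy <- p[nxt, 2] - p[, 2]
  dt <- sqrt(dx^2 + dy^2)
  keep <- dt > 0
  t1 <- cumsum(dt[keep]); t0 <- c(0, t1[-length(t1)])
  total <- t1[length(t1)]
  x0 <- p[keep, 1]; y0 <- p[keep, 2]
  sx <- dx[keep] / dt[keep]; sy <- dy[keep] / dt[keep]
  res <- list(an = numeric(n_harmonics), bn = numeric(n_harmonics),
              cn = numeric(n_harmonics), dn = numeric(n_harmonics))
  for (n in seq_len(n_harmonics)) {
    w <- 2 * pi * n / total
    Fc <- function(t) sin(w * t) / w
    Ftc <- function(t) cos(w * t) / w^2 + t * sin(w * t) / w
    Fs <- function(t) -cos(w * t) / w
    Fts <- function(t) sin(w * t) / w^2 - t * cos(w * t) / w
    ax <- x0 - sx * t0; ay <- y0 - sy * t0
    res$an[n] <- 2 / total * sum(ax * (Fc(t1) - Fc(t0)) + sx * (Ftc(t1) - Ftc(t0)))
    res$bn[n] <- 2 / total * sum(ax * (Fs(t1) - Fs(t0)) + sx * (Fts(t1) - Fts(t0)))
    res$cn[n] <- 2 / total * sum(ay * (Fc(t1) - Fc(t0)) + sy * (Ftc(t1) - Ftc(t0)))
    res$dn[n] <- 2 / total * sum(ay * (Fs(t1) - Fs(t0)) + sy * (Fts(t1) - Fts(t0)))
  }
  res
}

# ---- brute-force distance-based ANOVA oracle -------------------------------
# sums of squares from pairwise squared distances (sum over within-group
# pairs divided by group size), independent of the trace/Gower-centering
# route used by the implementation
oracle_ss_within <- function(d, f) {
  f <- factor(f)
  s <- 0
  for (lev in levels(f)) {
    idx <- which(f == lev)
    if (length(idx) > 1) {
      s <- s + sum(d[idx, idx]^2) / 2 / length(idx)
    }
  }
  s
}

oracle_oneway_pseudo_f <- function(d, f) {
  f <- factor(f)
  n <- nrow(d)
  a <- nlevels(f)
  ss_total <- sum(d^2) / 2 / n
  ss_w <- oracle_ss_within(d, f)
  ss_b <- ss_total - ss_w
  (ss_b / (a - 1)) / (ss_w / (n - a))
}

oracle_nested_f <- function(d, community, potter) {
  n <- nrow(d)
  a <- nlevels(factor(community)); p <- nlevels(factor(potter))
  ss_total <- sum(d^2) / 2 / n
  ss_w_comm <- oracle_ss_within(d, community)
  ss_w_pot <- oracle_ss_within(d, potter)
  ss_comm <- ss_total - ss_w_comm
  ss_pot <- ss_w_comm - ss_w_pot
  ss_res <- ss_w_pot
  c(community = (ss_comm / (a - 1)) / (ss_pot / (p - a)),
    individual = (ss_pot / (p - a)) / (ss_res / (n - p)))
}

# cophenetic distance matrix implied by an upgma merge table (brute force
# over the hclust tree), on the height-of-merge scale (not /2)
oracle_cophenetic <- function(hc) {
  n <- length(hc$labels)
  members <- vector("list", nrow(hc$merge))
  cd <- matrix(0, n, n)
  for (k in seq_len(nrow(hc$merge))) {
    grab <- function(i) if (i < 0) -i else members[[i]]
    l <- grab(hc$merge[k, 1]); r <- grab(hc$merge[k, 2])
    cd[l, r] <- hc$height[k]; cd[r, l] <- hc$height[k]
    members[[k]] <- c(l, r)
  }
  dimnames(cd) <- list(hc$labels, hc$labels)
  cd
}

# final-shape coefficient vectors + labels for a generated trial set,
# running only the last outline of each trial through the pipeline
final_shape_vectors <- function(trials, n = 256) {
  vecs <- t(vapply(trials, function(tr) {
    p <- tr$profiles[[length(tr$profiles)]]
    efa_vector(close_outline(smooth_profile(resample_profile(p, n = n))))
  }, numeric(60)))
  list(
    vectors = vecs,
    community = vapply(trials, function(tr) tr$community, character(1)),
    potter = vapply(trials, function(tr) paste0(tr$community, "_", tr$potter_id),
                    character(1))
  )
}
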