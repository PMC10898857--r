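# Pooled PCA shape space, morphogenetic trajectories, and stage snapshots.

#' Fit the pooled PCA shape space
#'
#' Centered principal component analysis (covariance, not correlation: the
#' size-normalized coefficients share a common scale) of pooled 60-D
#' coefficient vectors. Axis signs follow a deterministic convention (the
#' largest-magnitude loading element of each axis is positive) so scores are
#' reproducible across runs and platforms.
#'
#' @param x numeric matrix (rows = outlines, columns = coefficients) or a
#'   data frame from [efa_table()] (coefficient columns are auto-detected).
#' @return an object of class `shape_space`: `mean`, orthonormal `loadings`,
#'   per-axis `explained_variance` fractions, `sdev`, `n_samples`.
#' @export
fit_shape_space <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[coef_columns(x)])
  assert(nrow(x) >= 4, "need >= 4 vectors to fit a shape space")
  assert(all(is.finite(x)), "missing or non-finite values in coefficients")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  ev <- pc$sdev^2
  frac <- if (sum(ev) > 0) ev / sum(ev) else ev
  if (sum(ev > max(ev) * 1e-12) < 3) {
    warning("shape space has rank < 3", call. = FALSE)
  }
  structure(
    list(mean = pc$center, loadings = loadings, sdev = pc$sdev,
         explained_variance = frac, n_samples = nrow(x)),
    class = "shape_space"
  )
}

#' @export
print.shape_space <- function(x, ...) {
  cat(sprintf("Shape space: %d samples, %d axes\n", x$n_samples,
              ncol(x$loadings)))
  cat(sprintf("  PC1-3 variance: %.1f%%, %.1f%%, %.1f%% (cumulative %.1f%%)\n",
              100 * x$explained_variance[1], 100 * x$explained_variance[2],
              100 * x$explained_variance[3],
              100 * sum(x$explained_variance[1:3])))
  invisible(x)
}

#' @export
summary.shape_space <- function(object, k = 5, ...) {
  k <- min(k, length(object$explained_variance))
  data.frame(
    axis = paste0("PC", seq_len(k)),
    variance_fraction = object$explained_variance[seq_len(k)],
    cumulative = cumsum(object$explained_variance)[seq_len(k)]
  )
}

#' Project coefficient vectors into a shape space
#'
#' @param space a `shape_space`.
#' @param x a vector or matrix of coefficient vectors (rows).
#' @param k number of leading axes (default 3).
#' @return a matrix of k-D scores (one row per input vector).
#' @export
project_shapes <- function(space, x, k = 3) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (is.data.frame(x)) x <- as.matrix(x[coef_columns(x)])
  assert(ncol(x) == nrow(space$loadings),
         "contract violation: dimension mismatch (", ncol(x), " vs ",
         nrow(space$loadings), ")")
  assert(k >= 1 && k <= ncol(space$loadings), "k exceeds available axes")
  sweep(x, 2, space$mean) %*% space$loadings[, seq_len(k), drop = FALSE]
}

#' Morphogenetic trajectory of one trial in shape space
#'
#' @param trial a `trial_record`.
#' @param coeffs matrix of the trial's coefficient vectors, one row per
#'   outline (in gesture order).
#' @param space a `shape_space`.
#' @param k number of axes (default 3).
#' @return an object of class `trajectory`: design keys, ordered k-D
#'   `points`, and matching `percent_times`.
#' @export
make_trajectory <- function(trial, coeffs, space, k = 3) {
  coeffs <- as.matrix(coeffs)
  assert(nrow(coeffs) == length(trial$profiles),
         "gap error: ", nrow(coeffs), " coefficient rows for ",
         length(trial$profiles), " outlines")
  assert(all(is.finite(coeffs)), "gap error: non-finite coefficients")
  structure(
    list(potter_id = trial$potter_id, community = trial$community,
         vessel_type = trial$vessel_type, clay_mass = trial$clay_mass,
         trial = trial$trial,
         points = project_shapes(space, coeffs, k = k),
         percent_times = percent_time(trial)),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: potter %s (%s), %s, trial %d, %d points in %d-D\n",
              x$potter_id, x$community, x$vessel_type, x$trial,
              nrow(x$points), ncol(x$points)))
  invisible(x)
}

#' Index of the outline representing a morphogenetic stage
#'
#' Preform is gesture 0 (the first outline), final the last; the middle is
#' the gesture-count midpoint `round((n - 1) / 2)` with half-up rounding
#' (0-based), robust to irregular gesture timing.
#'
#' @param n_outlines number of outlines in the trial (>= 2).
#' @param stage `"preform"`, `"middle"`, or `"final"`.
#' @return 1-based outline index.
#' @export
stage_index <- function(n_outlines, stage = c("preform", "middle", "final")) {
  stage <- match.arg(stage)
  assert(n_outlines >= 2, "a trial needs >= 2 outlines")
  switch(stage,
    preform = 1L,
    final = as.integer(n_outlines),
    middle = {
      if (n_outlines == 2) {
        warning("degenerate middle stage: trial has only 2 outlines",
                call. = FALSE)
        2L
      } else {
        as.integer(floor((n_outlines - 1) / 2 + 0.5)) + 1L
      }
    }
  )
}

#' Extract the stage snapshot rows of an EFA table
#'
#' One row per trial: the coefficient vector of the outline representing the
#' requested stage of each morphogenetic trajectory.
#'
#' @param tab a data frame from [efa_table()].
#' @param stage `"preform"`, `"middle"`, or `"final"`.
#' @return a data frame with the same columns as `tab` plus `stage`.
#' @export
stage_table <- function(tab, stage = c("preform", "middle", "final")) {
  stage <- match.arg(stage)
  key <- interaction(tab$potter_id, tab$vessel_type, tab$clay_mass, tab$trial,
                     drop = TRUE)
  rows <- unlist(lapply(split(seq_len(nrow(tab)), key), function(idx) {
    idx[order(tab$gesture[idx])][stage_index(length(idx), stage)]
  }))
  out <- tab[sort(rows), , drop = FALSE]
  out$stage <- stage
  rownames(out) <- NULL
  out
}

#' Per-stage shape space
#'
#' Independent PCA of the snapshots of a single stage (e.g. all preforms, or
#' all final forms), used for two-axis stage maps. No basis is shared with
#' the pooled space or with other stages.
#'
#' @param x snapshot coefficient matrix or [stage_table()] data frame.
#' @return a `shape_space`.
#' @export
fit_stage_space <- function(x) fit_shape_space(x)
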