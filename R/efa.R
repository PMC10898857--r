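# Elliptical Fourier analysis of closed vessel outlines: Kuhl-Giardina
# coefficients under chord-length parameterization, bilateral-symmetry
# reduction to 30 coefficient pairs, and size normalization by the first pair.

#' Elliptical Fourier coefficients of a closed outline
#'
#' Computes Kuhl-Giardina elliptical Fourier coefficients from the
#' chord-length parameterization of a closed contour. For each harmonic n the
#' four coefficients (a_n, b_n) describe the x series and (c_n, d_n) the y
#' series: x(t) = A0 + sum a_n cos(2 pi n t / T) + b_n sin(2 pi n t / T), and
#' likewise for y.
#'
#' @param outline a closed outline (first and last points coincide), e.g.
#'   from [close_outline()].
#' @param n_harmonics number of harmonics (default 30).
#' @param param contour parameterization: `"chord"` (default; cumulative
#'   chord length, robust to uneven point spacing) or `"uniform"` (equal
#'   parameter steps per point, under which an ellipse sampled at equal
#'   angles is exactly a single-harmonic shape).
#' @return an object of class `efa`: lists of per-harmonic coefficients
#'   `an`, `bn`, `cn`, `dn`, DC terms `A0`, `C0`, and the perimeter `T`.
#' @export
elliptic_fourier <- function(outline, n_harmonics = 30,
                             param = c("chord", "uniform")) {
  param <- match.arg(param)
  o <- unclass(as.matrix(outline))
  k <- nrow(o)
  assert(k >= 4, "outline too small")
  assert(all(abs(o[1, ] - o[k, ]) < 1e-9),
         "contract violation: outline is not closed")
  p <- o[-k, , drop = FALSE]
  np <- nrow(p)
  assert(np >= 2 * n_harmonics + 1,
         "undersampled outline: need >= ", 2 * n_harmonics + 1, " distinct points")
  nxt <- c(2:np, 1L)
  dx <- p[nxt, 1] - p[, 1]
  dy <- p[nxt, 2] - p[, 2]
  dt <- if (param == "chord") sqrt(dx^2 + dy^2) else rep(1, length(dx))
  keep <- dt > 0
  dx <- dx[keep]; dy <- dy[keep]; dt <- dt[keep]
  tcum <- cumsum(dt)
  total <- tcum[length(tcum)]
  t0 <- c(0, tcum[-length(tcum)])

  n <- seq_len(n_harmonics)
  omega <- 2 * pi * n / total                     # length N
  ct1 <- cos(outer(tcum, omega)); ct0 <- cos(outer(t0, omega))
  st1 <- sin(outer(tcum, omega)); st0 <- sin(outer(t0, omega))
  fac <- total / (2 * pi^2 * n^2)
  vx <- dx / dt
  vy <- dy / dt
  an <- fac * colSums(vx * (ct1 - ct0))
  bn <- fac * colSums(vx * (st1 - st0))
  cn <- fac * colSums(vy * (ct1 - ct0))
  dn <- fac * colSums(vy * (st1 - st0))

  # exact means of the piecewise-linear coordinate functions
  xs <- p[keep, 1]; ys <- p[keep, 2]
  a0 <- sum(dt * (xs + xs + dx) / 2) / total
  c0 <- sum(dt * (ys + ys + dy) / 2) / total

  structure(
    list(an = an, bn = bn, cn = cn, dn = dn, A0 = a0, C0 = c0,
         n_harmonics = n_harmonics, perimeter = total),
    class = "efa"
  )
}

#' @export
print.efa <- function(x, ...) {
  cat(sprintf("EFA: %d harmonics, perimeter %.3f, first-harmonic magnitude %.4f\n",
              x$n_harmonics, x$perimeter, harmonic_magnitude(x)[1]))
  invisible(x)
}

#' Per-harmonic ellipse magnitudes
#'
#' The semi-major axis length of each harmonic ellipse (largest singular
#' value of the 2x2 coefficient matrix of the harmonic).
#'
#' @param coeffs an `efa` object.
#' @return numeric vector of length `n_harmonics`.
#' @export
harmonic_magnitude <- function(coeffs) {
  vapply(seq_len(coeffs$n_harmonics), function(n) {
    m <- matrix(c(coeffs$an[n], coeffs$bn[n], coeffs$cn[n], coeffs$dn[n]),
                2, 2, byrow = TRUE)
    svd(m, nu = 0, nv = 0)$d[1]
  }, numeric(1))
}

#' Reduce coefficients of a bilaterally symmetric outline to pairs
#'
#' With the fixed start-point convention (on-axis rim point, clockwise
#' traversal of the right edge), x(t) is an odd and y(t) an even function of
#' the contour parameter, so the x-cosine (a_n) and y-sine (d_n) coefficients
#' vanish for a symmetric outline. This retains the two surviving
#' coefficients (b_n, c_n) per harmonic and records the largest suppressed
#' magnitude, relative to the first harmonic, as a QC metric.
#'
#' @param coeffs an `efa` object.
#' @param warn_tol relative magnitude of a discarded coefficient above which
#'   a symmetry-violation warning is raised (default 1e-3).
#' @return an `n_harmonics` x 2 matrix with columns `b` (x-sine) and `c`
#'   (y-cosine) and attribute `qc` (max suppressed relative magnitude).
#' @export
symmetry_reduce <- function(coeffs, warn_tol = 1e-3) {
  mag1 <- sqrt(coeffs$bn[1]^2 + coeffs$cn[1]^2)
  assert(mag1 > 0, "degenerate shape: vanishing first harmonic")
  qc <- max(abs(c(coeffs$an, coeffs$dn))) / mag1
  if (qc > warn_tol) {
    warning("symmetry violation: suppressed coefficient magnitude ",
            signif(qc, 3), " x first harmonic", call. = FALSE)
  }
  out <- cbind(b = coeffs$bn, c = coeffs$cn)
  attr(out, "qc") <- qc
  out
}

#' Size-normalize coefficient pairs into a 60-D shape vector
#'
#' Divides all retained coefficients by the size of the first harmonic so
#' that pure shape, independent of vessel size, is analyzed. The default
#' convention divides by the Euclidean norm of the first retained pair;
#' `"semi_major"` divides by the semi-major axis length of the first
#' harmonic ellipse instead. Both are strictly scale-invariant.
#'
#' @param pairs matrix from [symmetry_reduce()].
#' @param convention `"pair_norm"` (default) or `"semi_major"`.
#' @return numeric vector of length 2 x nrow(pairs) (interleaved b1, c1,
#'   b2, c2, ...), with the `qc` attribute carried over.
#' @export
size_normalize <- function(pairs, convention = c("pair_norm", "semi_major")) {
  convention <- match.arg(convention)
  size <- switch(convention,
    pair_norm = sqrt(pairs[1, 1]^2 + pairs[1, 2]^2),
    semi_major = max(abs(pairs[1, ]))
  )
  assert(is.finite(size) && size > 0, "degenerate shape: zero first harmonic")
  v <- as.numeric(t(pairs)) / size
  names(v) <- paste0(rep(c("b", "c"), nrow(pairs)),
                     rep(seq_len(nrow(pairs)), each = 2))
  attr(v, "qc") <- attr(pairs, "qc")
  v
}

#' Size-normalized 60-D coefficient vector of an outline
#'
#' Composition of [elliptic_fourier()], [symmetry_reduce()] and
#' [size_normalize()].
#'
#' @inheritParams elliptic_fourier
#' @inheritParams size_normalize
#' @return numeric vector of length `2 * n_harmonics`.
#' @export
efa_vector <- function(outline, n_harmonics = 30,
                       convention = c("pair_norm", "semi_major")) {
  size_normalize(symmetry_reduce(elliptic_fourier(outline, n_harmonics)),
                 convention = match.arg(convention))
}

#' Reconstruct an outline from elliptical Fourier coefficients
#'
#' @param coeffs an `efa` object.
#' @param n_points number of points to sample at equal parameter steps
#'   (>= 8).
#' @param n_harmonics number of harmonics to use (default: all).
#' @return a closed outline matrix (`n_points + 1` rows).
#' @export
reconstruct_outline <- function(coeffs, n_points = 256,
                                n_harmonics = coeffs$n_harmonics) {
  assert(n_points >= 8, "n_points must be >= 8")
  assert(n_harmonics >= 1 && n_harmonics <= coeffs$n_harmonics,
         "invalid harmonic count")
  t <- seq(0, 1, length.out = n_points + 1)[-(n_points + 1)]
  n <- seq_len(n_harmonics)
  cosm <- cos(outer(t, 2 * pi * n))
  sinm <- sin(outer(t, 2 * pi * n))
  x <- coeffs$A0 + cosm %*% coeffs$an[n] + sinm %*% coeffs$bn[n]
  y <- coeffs$C0 + cosm %*% coeffs$cn[n] + sinm %*% coeffs$dn[n]
  out <- cbind(x = as.numeric(x), y = as.numeric(y))
  out <- rbind(out, out[1, ])
  structure(out, class = c("outline", "matrix", "array"))
}

#' Coefficient table for a set of trials
#'
#' Runs the outline pipeline and EFA over every gesture of every trial and
#' returns one row per outline: design keys, gesture index, percent time,
#' the 60 size-normalized coefficients and the symmetry QC metric.
#'
#' @param trials list of `trial_record` objects.
#' @param n_harmonics harmonics to retain (default 30).
#' @param n resampling resolution per profile.
#' @param cutoff smoothing cutoff (`NULL` to skip smoothing).
#' @param convention size-normalization convention, see [size_normalize()].
#' @return a data frame with columns `potter_id, community, vessel_type,
#'   clay_mass, trial, gesture, percent_time, qc, b1, c1, ..., b30, c30`.
#' @export
efa_table <- function(trials, n_harmonics = 30, n = 256, cutoff = 0.1,
                      convention = "pair_norm") {
  rows <- lapply(trials, function(tr) {
    outs <- trial_outlines(tr, n = n, cutoff = cutoff)
    pt <- percent_time(tr)
    vecs <- lapply(outs, efa_vector, n_harmonics = n_harmonics,
                   convention = convention)
    coef_mat <- do.call(rbind, vecs)
    data.frame(
      potter_id = tr$potter_id, community = tr$community,
      vessel_type = tr$vessel_type, clay_mass = tr$clay_mass,
      trial = tr$trial, gesture = seq_along(outs) - 1L,
      percent_time = pt,
      qc = vapply(vecs, function(v) attr(v, "qc"), numeric(1)),
      coef_mat
    )
  })
  do.call(rbind, rows)
}

#' Coefficient-column names of an EFA table
#' @param tab a data frame from [efa_table()].
#' @return character vector of the 60 coefficient column names.
#' @export
coef_columns <- function(tab) {
  grep("^[bc][0-9]+$", names(tab), value = TRUE)
}
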