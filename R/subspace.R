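# Cross-projection subspace similarity between morphogenetic paths.
# Each trial's 60-D coefficient sequence is analyzed by its own PCA; the
# variance of one trial's data captured by another trial's top-3 axes,
# relative to that captured by its own (V2/V1), averaged over both
# directions, is the subspace similarity S; D = 1 - S.

#' Per-trial PCA subspace
#'
#' PCA of one trial's own outline sequence in coefficient space. Variances
#' use the population convention (divide by n) throughout so cross-trial
#' ratios are sample-size-free.
#'
#' @param x matrix of the trial's coefficient vectors (>= 4 rows).
#' @param k subspace dimension (default 3).
#' @param label optional trial label.
#' @return an object of class `trial_subspace`: orthonormal `basis` (p x k),
#'   `mean`, `V1` (variance captured by the top-k axes), `total_var`,
#'   centered `data`, `n`, `label`.
#' @export
trial_subspace <- function(x, k = 3, label = NULL) {
  x <- as.matrix(x)
  assert(nrow(x) >= k + 1,
         "insufficient rank: trial ", label %||% "", " has ", nrow(x),
         " outlines (need >= ", k + 1, ")")
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sv <- svd(xc, nu = 0)
  ev <- sv$d^2 / nrow(x)
  v1 <- sum(ev[seq_len(min(k, length(ev)))])
  assert(v1 > 0, "degenerate trial: no shape variation")
  structure(
    list(basis = sv$v[, seq_len(k), drop = FALSE], mean = mu, V1 = v1,
         total_var = sum(ev), data = xc, n = nrow(x), k = k,
         label = label),
    class = "trial_subspace"
  )
}

#' @export
print.trial_subspace <- function(x, ...) {
  cat(sprintf("Trial subspace%s: %d outlines, top-%d variance %.3g of %.3g (%.1f%%)\n",
              if (is.null(x$label)) "" else paste0(" ", x$label),
              x$n, x$k, x$V1, x$total_var, 100 * x$V1 / x$total_var))
  invisible(x)
}

#' Cross-projection variance ratio V2/V1
#'
#' Projects trial A's coefficient data (centered by A's own mean; B
#' contributes directions only) onto trial B's top-k axes, and returns the
#' captured variance V2 relative to the variance V1 captured by A's own
#' axes. By PCA optimality V2 <= V1, so the ratio lies in [0, 1]; it reaches
#' 1 when B's subspace captures A's scatter as well as A's own.
#'
#' @param a a `trial_subspace` (projected data).
#' @param b a `trial_subspace` (projecting basis).
#' @return the ratio V2/V1.
#' @export
cross_projection <- function(a, b) {
  assert(inherits(a, "trial_subspace") && inherits(b, "trial_subspace"),
         "cross_projection expects trial_subspace objects")
  assert(nrow(a$basis) == nrow(b$basis),
         "contract violation: coefficient dimensionality differs")
  # self-projection is 1 by definition; short-circuit so it is exact
  if (identical(a$data, b$data) && identical(a$basis, b$basis)) return(1)
  scores <- a$data %*% b$basis
  v2 <- sum(scores^2) / a$n
  ratio <- v2 / a$V1
  # guard against roundoff just above 1 on rank-deficient trials
  min(ratio, 1)
}

#' Subspace similarity S between two trials
#'
#' The average of the cross-projection ratio in both directions; symmetric,
#' in [0, 1], and exactly 1 for a trial against itself.
#'
#' @param a,b `trial_subspace` objects.
#' @return the similarity index S.
#' @export
subspace_similarity <- function(a, b) {
  (cross_projection(a, b) + cross_projection(b, a)) / 2
}

#' Trial-by-trial subspace dissimilarity matrix (1 - S)
#'
#' Builds per-trial subspaces from an EFA table and returns the symmetric
#' matrix of subspace dissimilarities D = 1 - S. Trials with fewer than
#' `k + 1` outlines cannot support a rank-k subspace and are excluded with a
#' warning (listed in attribute `excluded`).
#'
#' @param tab a data frame from [efa_table()].
#' @param k subspace dimension (default 3).
#' @return a labeled symmetric matrix with zero diagonal; attribute `meta`
#'   holds one row of design keys per retained trial.
#' @export
subspace_dissimilarity <- function(tab, k = 3) {
  key <- interaction(tab$potter_id, tab$vessel_type, tab$clay_mass, tab$trial,
                     sep = "|", drop = TRUE)
  groups <- split(seq_len(nrow(tab)), key)
  cols <- coef_columns(tab)
  usable <- vapply(groups, length, integer(1)) >= k + 1
  if (any(!usable)) {
    warning("excluding ", sum(!usable), " trial(s) with < ", k + 1,
            " outlines: ", paste(names(groups)[!usable], collapse = ", "),
            call. = FALSE)
  }
  groups <- groups[usable]
  assert(length(groups) >= 2, "empty input: fewer than 2 usable trials")
  subs <- lapply(names(groups), function(nm) {
    idx <- groups[[nm]]
    trial_subspace(as.matrix(tab[idx[order(tab$gesture[idx])], cols]),
                   k = k, label = nm)
  })
  n <- length(subs)
  d <- matrix(0, n, n, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- 1 - subspace_similarity(subs[[i]], subs[[j]])
    }
  }
  meta <- do.call(rbind, lapply(groups, function(idx) {
    tab[idx[1], c("potter_id", "community", "vessel_type", "clay_mass", "trial")]
  }))
  rownames(meta) <- NULL
  attr(d, "meta") <- meta
  attr(d, "excluded") <- names(usable)[!usable]
  d
}
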