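# Distance-based statistics: alternative-Gower distances, two-level nested
# permutation MANOVA (potters within communities), multivariate dispersion
# at morphogenetic stages, and UPGMA dendrograms with Newick export.

#' Alternative-Gower distance between two vectors
#'
#' The modified Gower distance for continuous data: the mean absolute
#' difference over variables that are not zero in both observations (no
#' range standardization). If every variable is doubly zero the distance is
#' 0. For signed Fourier coefficients double zeros are virtually absent, so
#' this behaves as a scaled city-block distance.
#'
#' @param x,y numeric vectors of equal length with finite values.
#' @return the distance.
#' @export
alt_gower <- function(x, y) {
  assert(length(x) == length(y), "contract violation: length mismatch")
  assert(all(is.finite(x)) && all(is.finite(y)), "non-finite values")
  keep <- x != 0 | y != 0
  nz <- sum(keep)
  if (nz == 0) return(0)
  sum(abs(x[keep] - y[keep])) / nz
}

#' Pairwise distance matrix
#'
#' @param x numeric matrix (rows = observations) or an [efa_table()] data
#'   frame.
#' @param metric `"altGower"` (default, used for the permutation and
#'   dispersion tests) or `"euclidean"`.
#' @return symmetric matrix with zero diagonal.
#' @export
distance_matrix <- function(x, metric = c("altGower", "euclidean")) {
  metric <- match.arg(metric)
  if (is.data.frame(x)) x <- as.matrix(x[coef_columns(x)])
  assert(nrow(x) >= 2, "need >= 2 observations")
  assert(all(is.finite(x)), "validation error: non-finite input")
  if (metric == "euclidean") {
    d <- as.matrix(stats::dist(x))
  } else {
    n <- nrow(x)
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      xi <- x[i, ]
      for (j in (i + 1):n) {
        d[i, j] <- d[j, i] <- alt_gower(xi, x[j, ])
      }
    }
    dimnames(d) <- list(rownames(x), rownames(x))
  }
  d
}

# Gower-centered inner-product matrix G = -1/2 J D^2 J
gower_center <- function(d) {
  a <- -0.5 * d^2
  rm <- rowMeans(a)
  sweep(sweep(a, 1, rm), 2, rm) + mean(a)
}

# sum of squares explained by a grouping: tr(H G) for the hat matrix of the
# group dummies (G is doubly centered so the intercept term vanishes)
ss_groups <- function(g, f) {
  f <- factor(f)
  m <- rowsum(g, f)
  b <- rowsum(t(m), f)
  sum(diag(as.matrix(b)) / as.numeric(table(f)))
}

as_square <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- unclass(d)
  assert(is.matrix(d) && nrow(d) == ncol(d), "need a square dissimilarity matrix")
  assert(max(abs(d - t(d))) < 1e-12, "matrix is not symmetric")
  d
}

# all assignments of potters to community slots preserving community sizes
enumerate_assignments <- function(n_potters, sizes) {
  rec <- function(remaining, sizes) {
    if (length(sizes) == 0) return(list(integer(0)))
    if (length(sizes) == 1) return(list(remaining))
    picks <- utils::combn(remaining, sizes[1], simplify = FALSE)
    out <- list()
    for (p in picks) {
      rest <- rec(setdiff(remaining, p), sizes[-1])
      out <- c(out, lapply(rest, function(r) c(p, r)))
    }
    out
  }
  rec(seq_len(n_potters), sizes)
}

#' Nested permutation MANOVA on a dissimilarity matrix
#'
#' Two-level distance-based MANOVA with individual potters nested within
#' communities. Sums of squares are partitioned from the Gower-centered
#' matrix of -D^2/2: SS(community), SS(potter within community), and
#' residual, conserving the total. The community pseudo-F uses the
#' potter-within-community mean square as its denominator
#' (F = MS_community / MS_potter); the individual pseudo-F uses the residual
#' (F = MS_potter / MS_residual). Community p-values come from permuting
#' whole potters across communities preserving community sizes (potters are
#' the exchangeable units under that null); individual p-values from
#' permuting observations among potters within the same community. P-values
#' use the (exceedances + 1) / (n_perm + 1) estimator, so the observed
#' statistic is always a member of its own null.
#'
#' @param d square dissimilarity matrix (or `dist`).
#' @param community community label per observation.
#' @param potter potter label per observation; each potter must map to
#'   exactly one community.
#' @param n_perm number of randomizations (default 10000).
#' @param seed integer seed for the permutation stream.
#' @param exhaustive if `TRUE`, the community test enumerates all potter
#'   assignments instead of sampling (exact p; small designs only).
#' @return an object of class `nested_permanova` with an ANOVA-style table
#'   and per-factor permutation results.
#' @export
nested_permanova <- function(d, community, potter, n_perm = 10000, seed = 1,
                             exhaustive = FALSE) {
  d <- as_square(d)
  n <- nrow(d)
  assert(length(community) == n && length(potter) == n,
         "labels must match the matrix dimension")
  community <- factor(as.character(community))
  potter <- factor(as.character(potter))
  map <- tapply(as.character(community), potter, unique)
  assert(all(lengths(map) == 1),
         "design error: a potter maps to more than one community")
  potters_of <- split(names(map), unlist(map))
  assert(all(table(potter) >= 2),
         "design error: singleton potter (>= 2 observations per potter needed)")
  # the community test needs >= 2 communities, each with >= 2 potters
  # (whole potters are its exchangeable units); otherwise it is skipped and
  # only the individual test is run
  comm_feasible <- nlevels(community) >= 2 && all(lengths(potters_of) >= 2)
  if (!comm_feasible) {
    message("nested_permanova: community test skipped (needs >= 2 ",
            "communities with >= 2 potters each)")
  }

  g <- gower_center(d)
  ss_total <- sum(diag(g))
  ss_comm <- ss_groups(g, community)
  ss_cells <- ss_groups(g, potter)
  ss_pot <- ss_cells - ss_comm
  ss_res <- ss_total - ss_cells
  a <- nlevels(community)
  p <- nlevels(potter)
  df <- c(community = a - 1L, individual = p - a, residual = n - p)
  ms <- unname(c(ss_comm, ss_pot, ss_res) / df)
  f_comm <- if (comm_feasible) ms[1] / ms[2] else NA_real_
  f_ind <- ms[2] / ms[3]

  potter_chr <- as.character(potter)
  comm_of_potter <- unlist(map)
  potter_ids <- names(map)
  sizes <- table(factor(comm_of_potter, levels = levels(community)))

  f_comm_perm <- function(assign_comm) {
    # assign_comm: community level per potter (aligned with potter_ids)
    new_comm <- assign_comm[match(potter_chr, potter_ids)]
    ssc <- ss_groups(g, new_comm)
    (ssc / df[1]) / ((ss_cells - ssc) / df[2])
  }

  set.seed(seed)
  if (!comm_feasible) {
    p_comm <- NA_real_
    n_perm_comm <- 0L
  } else if (exhaustive) {
    slots <- rep(levels(community), sizes)
    assigns <- enumerate_assignments(p, as.integer(sizes))
    f_null <- vapply(assigns, function(ord) {
      ac <- character(p)
      ac[ord] <- slots
      f_comm_perm(ac)
    }, numeric(1))
    p_comm <- mean(f_null >= f_comm - 1e-12)
    n_perm_comm <- length(f_null)
  } else {
    slots <- rep(levels(community), sizes)
    f_null <- vapply(seq_len(n_perm), function(i) {
      ac <- character(p)
      ac[sample.int(p)] <- slots
      f_comm_perm(ac)
    }, numeric(1))
    p_comm <- (sum(f_null >= f_comm - 1e-12) + 1) / (n_perm + 1)
    n_perm_comm <- n_perm
  }

  idx_by_comm <- split(seq_len(n), community)
  f_ind_null <- vapply(seq_len(n_perm), function(i) {
    new_potter <- potter_chr
    for (idx in idx_by_comm) {
      new_potter[idx] <- potter_chr[idx][sample.int(length(idx))]
    }
    ssc <- ss_groups(g, new_potter)
    ((ssc - ss_comm) / df[2]) / ((ss_total - ssc) / df[3])
  }, numeric(1))
  p_ind <- (sum(f_ind_null >= f_ind - 1e-12) + 1) / (n_perm + 1)

  structure(
    list(
      table = data.frame(
        factor = c("community", "individual", "residual"),
        df = as.integer(df),
        SS = c(ss_comm, ss_pot, ss_res),
        MS = ms,
        F = c(f_comm, f_ind, NA),
        p = c(p_comm, p_ind, NA)
      ),
      community = list(factor = "community", df = df[[1]], F = f_comm,
                       p = p_comm, n_perm = n_perm_comm, seed = seed),
      individual = list(factor = "individual", df = df[[2]], F = f_ind,
                        p = p_ind, n_perm = n_perm, seed = seed),
      ss_total = ss_total, n = n, seed = seed,
      exhaustive = exhaustive
    ),
    class = "nested_permanova"
  )
}

#' @export
print.nested_permanova <- function(x, ...) {
  cat("Nested permutation MANOVA (potters within communities)\n")
  cat(sprintf("  n = %d observations, %s community permutations, %d individual permutations, seed %d\n",
              x$n, if (x$exhaustive) "exhaustive" else
                format(x$community$n_perm), x$individual$n_perm, x$seed))
  tab <- x$table
  tab$SS <- signif(tab$SS, 5); tab$MS <- signif(tab$MS, 5)
  tab$F <- signif(tab$F, 4); tab$p <- signif(tab$p, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Multivariate dispersion across groups (betadisper-style)
#'
#' Embeds the dissimilarity matrix by principal coordinates (double
#' centering of -D^2/2, keeping axes with negative eigenvalues), computes
#' each observation's distance to its group centroid (real-axis contribution
#' minus imaginary-axis contribution; negative squared distances are clipped
#' to zero and counted), and tests homogeneity of dispersion with a one-way
#' F on the distances whose p-value comes from permuting group labels.
#'
#' @param x observation matrix / [efa_table()] data frame, or a precomputed
#'   square dissimilarity matrix (or `dist`).
#' @param groups group label per observation (e.g. morphogenetic stage).
#' @param metric distance metric when `x` holds observations;
#'   `"euclidean"` matches direct distance-to-mean in coefficient space.
#' @param n_perm permutations for the homogeneity test (default 999).
#' @param seed permutation seed.
#' @return an object of class `dispersion_analysis`: per-observation
#'   `distances`, `group`, group `medians` and `means`, `F`, `p`, and the
#'   count of clipped negative squared distances.
#' @export
dispersion_analysis <- function(x, groups, metric = c("altGower", "euclidean"),
                                n_perm = 999, seed = 1) {
  metric <- match.arg(metric)
  if (inherits(x, "dist") ||
      (is.matrix(x) && nrow(x) == ncol(x) && max(abs(unclass(x) - t(unclass(x)))) < 1e-12 &&
         all(abs(diag(unclass(x))) < 1e-12))) {
    d <- as_square(x)
  } else {
    d <- distance_matrix(x, metric = metric)
  }
  groups <- factor(groups)
  assert(length(groups) == nrow(d), "labels must match the matrix dimension")
  assert(nlevels(groups) >= 2, "need >= 2 groups")
  assert(all(table(groups) >= 2), "need >= 2 observations per group")

  g <- gower_center(d)
  e <- eigen(g, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-8
  pos <- e$values > tol
  neg <- e$values < -tol
  upos <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]), sum(pos))
  uneg <- e$vectors[, neg, drop = FALSE] %*% diag(sqrt(-e$values[neg]), sum(neg))

  dist_to_centroid <- function(grp) {
    d2 <- numeric(nrow(d))
    for (lev in levels(grp)) {
      idx <- which(grp == lev)
      cp <- colMeans(upos[idx, , drop = FALSE])
      d2p <- rowSums(sweep(upos[idx, , drop = FALSE], 2, cp)^2)
      d2n <- 0
      if (ncol(uneg) > 0) {
        cn <- colMeans(uneg[idx, , drop = FALSE])
        d2n <- rowSums(sweep(uneg[idx, , drop = FALSE], 2, cn)^2)
      }
      d2[idx] <- d2p - d2n
    }
    d2
  }
  one_way_f <- function(z, grp) {
    gm <- tapply(z, grp, mean)
    ng <- as.numeric(table(grp))
    ssb <- sum(ng * (gm - mean(z))^2)
    ssw <- sum((z - gm[as.integer(grp)])^2)
    (ssb / (nlevels(grp) - 1)) / (ssw / (length(z) - nlevels(grp)))
  }

  d2 <- dist_to_centroid(groups)
  n_clip <- sum(d2 < 0)
  if (n_clip > 0) {
    message("dispersion_analysis: clipped ", n_clip,
            " negative squared distance(s) to 0")
  }
  z <- sqrt(pmax(d2, 0))
  f_obs <- one_way_f(z, groups)
  set.seed(seed)
  f_null <- vapply(seq_len(n_perm), function(i) {
    gp <- groups[sample.int(length(groups))]
    zp <- sqrt(pmax(dist_to_centroid(gp), 0))
    one_way_f(zp, gp)
  }, numeric(1))
  p <- (sum(f_null >= f_obs - 1e-12) + 1) / (n_perm + 1)

  structure(
    list(distances = z, group = groups,
         medians = tapply(z, groups, stats::median),
         means = tapply(z, groups, mean),
         F = f_obs, p = p, n_perm = n_perm, seed = seed,
         n_clipped = n_clip, metric = metric),
    class = "dispersion_analysis"
  )
}

#' @export
print.dispersion_analysis <- function(x, ...) {
  cat("Multivariate dispersion (distance to group centroid)\n")
  cat(sprintf("  F = %.4g, permutation p = %.4g (%d permutations, seed %d)\n",
              x$F, x$p, x$n_perm, x$seed))
  cat("  group medians:\n")
  print(signif(x$medians, 4))
  invisible(x)
}

#' Aggregate a trial-level dissimilarity matrix to potter level
#'
#' The potter-to-potter dissimilarity is the arithmetic mean over all cross
#' pairs of their trials; the diagonal is zero.
#'
#' @param d square trial-level dissimilarity matrix.
#' @param potter potter label per trial (defaults to the matrix's `meta`
#'   attribute when present).
#' @param mode aggregation rule (only `"mean_pairwise"`).
#' @return a potter-level symmetric matrix with zero diagonal.
#' @export
potter_aggregate <- function(d, potter = NULL, mode = "mean_pairwise") {
  mode <- match.arg(mode, "mean_pairwise")
  if (is.null(potter)) {
    meta <- attr(d, "meta")
    assert(!is.null(meta), "supply potter labels or a matrix with meta attribute")
    potter <- meta$potter_id
  }
  d <- as_square(d)
  potter <- factor(as.character(potter))
  assert(nlevels(potter) >= 2, "need >= 2 potters")
  levs <- levels(potter)
  out <- matrix(0, nlevels(potter), nlevels(potter), dimnames = list(levs, levs))
  for (i in seq_along(levs)[-1]) {
    for (j in seq_len(i - 1)) {
      block <- d[potter == levs[i], potter == levs[j], drop = FALSE]
      out[i, j] <- out[j, i] <- mean(block)
    }
  }
  out
}

#' UPGMA dendrogram with Newick export
#'
#' Average-linkage agglomeration weighted by cluster sizes (UPGMA) via
#' [stats::hclust()]; merge heights are reported on the cophenetic/2 scale,
#' so leaf-to-ancestor branch lengths sum to half the cophenetic distance
#' (the tree is ultrametric). Ties are resolved by hclust's deterministic
#' smallest-index rule.
#'
#' @param d square dissimilarity matrix (or `dist`) with labels.
#' @return an object of class `upgma_dendrogram`: the `hclust` object,
#'   `merges` table (pair, height), labels, and a `newick` string with
#'   branch lengths.
#' @export
upgma <- function(d) {
  dm <- as_square(d)
  assert(nrow(dm) >= 2, "need >= 2 leaves")
  if (is.null(rownames(dm))) {
    dimnames(dm) <- list(paste0("L", seq_len(nrow(dm))),
                         paste0("L", seq_len(nrow(dm))))
  }
  hc <- stats::hclust(stats::as.dist(dm), method = "average")
  heights <- hc$height / 2
  node_label <- function(i) {
    if (i < 0) hc$labels[-i] else sprintf("node%d", i)
  }
  merges <- data.frame(
    left = vapply(seq_len(nrow(hc$merge)), function(k) node_label(hc$merge[k, 1]),
                  character(1)),
    right = vapply(seq_len(nrow(hc$merge)), function(k) node_label(hc$merge[k, 2]),
                   character(1)),
    height = heights
  )
  # recursive ultrametric Newick with branch lengths on the height/2 scale
  subtree <- function(k) {
    child <- function(i) {
      if (i < 0) {
        sprintf("%s:%.10g", hc$labels[-i], heights[k])
      } else {
        sprintf("%s:%.10g", subtree(i), heights[k] - heights[i])
      }
    }
    sprintf("(%s,%s)", child(hc$merge[k, 1]), child(hc$merge[k, 2]))
  }
  newick <- paste0(subtree(nrow(hc$merge)), ";")
  structure(
    list(hclust = hc, merges = merges, labels = hc$labels, newick = newick),
    class = "upgma_dendrogram"
  )
}

#' @export
print.upgma_dendrogram <- function(x, ...) {
  cat(sprintf("UPGMA dendrogram: %d leaves\n", length(x$labels)))
  print(x$merges, row.names = FALSE)
  invisible(x)
}

#' Write a dendrogram to a Newick file
#' @param dend an `upgma_dendrogram`.
#' @param path output path (.nwk).
#' @return `path`, invisibly.
#' @export
write_newick <- function(dend, path) {
  writeLines(dend$newick, path)
  invisible(path)
}
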