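# Alternative-Gower distances, nested PERMANOVA, dispersion, UPGMA.

test_that("alt_gower applies the mean-absolute / double-zero rule", {
  expect_identical(alt_gower(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(alt_gower(c(0, 2, 4), c(1, 2, 0)), 5 / 3)
  expect_equal(alt_gower(c(0, 3), c(0, 5)), 2)      # double zero excluded
  expect_identical(alt_gower(c(0, 0), c(0, 0)), 0)  # NZ = 0
  expect_error(alt_gower(1:3, 1:4), "length mismatch")
})

test_that("distance matrices match vegan and elementwise brute force", {
  set.seed(1)
  x <- matrix(rnorm(10 * 6), 10, 6)
  d <- distance_matrix(x, "altGower")
  expect_true(all(diag(d) == 0))
  for (i in 1:9) for (j in (i + 1):10) {
    expect_equal(d[i, j], alt_gower(x[i, ], x[j, ]))
  }
  # independent implementation in vegan (vegan's altGower assumes
  # non-negative data, so the cross-check uses magnitudes)
  xp <- abs(x)
  dv <- as.matrix(vegan::vegdist(xp, method = "altGower"))
  expect_equal(unname(distance_matrix(xp, "altGower")), unname(dv),
               tolerance = 1e-12)

  basis <- diag(3)
  de <- distance_matrix(basis, "euclidean")
  expect_equal(unname(de[upper.tri(de)]), rep(sqrt(2), 3))
  expect_error(distance_matrix(rbind(c(1, NA), c(0, 1))), "non-finite")
})

nested_fixture <- function(seed = 2, potters = c(3, 3), obs = 4, shift = 0) {
  set.seed(seed)
  comm <- rep(paste0("C", seq_along(potters)), potters * obs)
  pot <- rep(paste0("p", seq_len(sum(potters))), each = obs)
  x <- matrix(rnorm(sum(potters) * obs * 5), ncol = 5)
  x[comm == "C2", 1] <- x[comm == "C2", 1] + shift
  list(x = x, d = distance_matrix(x, "euclidean"), comm = comm, pot = pot)
}

test_that("nested SS partition conserves totals and matches brute force", {
  for (s in 1:5) {
    fx <- nested_fixture(seed = s, potters = c(3, 2, 4), obs = 3, shift = 1)
    pm <- nested_permanova(fx$d, fx$comm, fx$pot, n_perm = 49, seed = s)
    tab <- pm$table
    expect_equal(sum(tab$SS), pm$ss_total, tolerance = 1e-8)
    # independent pairwise-d^2 oracle for both pseudo-F statistics
    oracle <- oracle_nested_f(fx$d, fx$comm, fx$pot)
    expect_equal(pm$community$F, unname(oracle["community"]), tolerance = 1e-10)
    expect_equal(pm$individual$F, unname(oracle["individual"]), tolerance = 1e-10)
    expect_identical(pm$community$df, 2L)
    expect_identical(pm$individual$df, 9L - 3L)
  }
})

test_that("a flat design reduces to one-way PERMANOVA", {
  set.seed(4)
  x <- matrix(rnorm(9 * 4), 9, 4)
  d <- distance_matrix(x, "euclidean")
  pot <- rep(c("a", "b", "c"), each = 3)
  expect_message(
    pm <- nested_permanova(d, rep("C1", 9), pot, n_perm = 99, seed = 1),
    "community test skipped")
  expect_true(is.na(pm$community$F))
  expect_equal(pm$individual$F, oracle_oneway_pseudo_f(d, pot),
               tolerance = 1e-10)
  # and agrees with vegan's one-way pseudo-F
  av <- vegan::adonis2(stats::as.dist(d) ~ g,
                       data = data.frame(g = pot), permutations = 2)
  expect_equal(pm$individual$F, av$F[1], tolerance = 1e-8)
})

test_that("exhaustive community permutation matches explicit enumeration", {
  fx <- nested_fixture(seed = 7, potters = c(2, 2), obs = 2, shift = 2)
  pm <- nested_permanova(fx$d, fx$comm, fx$pot, exhaustive = TRUE, seed = 1)
  # enumerate all 6 assignments of 4 potters to 2+2 community slots by hand
  pots <- unique(fx$pot)
  fs <- apply(utils::combn(4, 2), 2, function(first) {
    new_comm <- ifelse(fx$pot %in% pots[first], "C1", "C2")
    oracle_nested_f(fx$d, new_comm, fx$pot)["community"]
  })
  expect_equal(pm$community$p, mean(fs >= pm$community$F - 1e-12))
  expect_identical(pm$community$n_perm, 6L)
})

test_that("permutation p-values use the +1 rule and are seed-stable in law", {
  fx <- nested_fixture(seed = 3, shift = 0.5)
  pm <- nested_permanova(fx$d, fx$comm, fx$pot, n_perm = 99, seed = 11)
  expect_gt(pm$community$p, 0); expect_lte(pm$community$p, 1)
  expect_true(pm$community$p %in% ((0:99 + 1) / 100))
  expect_true(pm$individual$p %in% ((0:99 + 1) / 100))
  # identical seeds reproduce; different seeds agree in distribution
  pm2 <- nested_permanova(fx$d, fx$comm, fx$pot, n_perm = 99, seed = 11)
  expect_identical(pm$table, pm2$table)
  p_seeds <- vapply(1:30, function(s) {
    nested_permanova(fx$d, fx$comm, fx$pot, n_perm = 199, seed = s)$individual$p
  }, numeric(1))
  expect_lt(stats::sd(p_seeds), 0.1)
  expect_error(nested_permanova(fx$d, fx$comm, rep(letters[1:12],
               each = 2)[1:24], n_perm = 9),
               NA)   # sanity: compatible relabeling runs
})

test_that("community effect size monotonically drives the observed F", {
  shifts <- c(0, 0.5, 1, 2, 4)
  med_f <- vapply(shifts, function(sh) {
    stats::median(vapply(1:20, function(s) {
      fx <- nested_fixture(seed = 500 + s, potters = c(2, 2, 2), obs = 3,
                           shift = sh)
      nested_permanova(fx$d, fx$comm, fx$pot, n_perm = 1, seed = 1)$community$F
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med_f) >= 0))
})

test_that("singleton potters and inconsistent nesting are design errors", {
  fx <- nested_fixture()
  pot_bad <- fx$pot; pot_bad[1] <- "solo"
  expect_error(nested_permanova(fx$d, fx$comm, pot_bad, n_perm = 9),
               "singleton potter")
  comm_bad <- fx$comm; comm_bad[1] <- "C2"
  expect_error(nested_permanova(fx$d, comm_bad, fx$pot, n_perm = 9),
               "more than one community")
})

test_that("dispersion via PCoA equals direct distance-to-mean (euclidean)", {
  set.seed(8)
  x <- matrix(rnorm(30 * 6), 30, 6)
  grp <- rep(c("a", "b", "c"), each = 10)
  disp <- dispersion_analysis(x, grp, metric = "euclidean", n_perm = 49)
  direct <- unlist(lapply(split(seq_len(30), grp), function(idx) {
    sweep(x[idx, ], 2, colMeans(x[idx, ])) |> (\(m) sqrt(rowSums(m^2)))()
  }))
  expect_equal(unname(disp$distances[order(grp)]), unname(direct),
               tolerance = 1e-8)
  # vegan::betadisper as an independent implementation
  bd <- vegan::betadisper(stats::dist(x), grp, type = "centroid")
  expect_equal(unname(disp$distances), unname(bd$distances), tolerance = 1e-8)
})

test_that("dispersion scales with group spread and is null-calibrated", {
  set.seed(12)
  base <- matrix(rnorm(20 * 5), 20, 5)
  doubled <- sweep(base, 2, colMeans(base))
  x <- rbind(base, sweep(2 * doubled, 2, colMeans(base), `+`) )
  grp <- rep(c("g1", "g2"), each = 20)
  disp <- dispersion_analysis(x, grp, metric = "euclidean", n_perm = 19)
  expect_equal(mean(disp$distances[grp == "g2"]),
               2 * mean(disp$distances[grp == "g1"]), tolerance = 1e-10)

  # translated copies of one cloud: dispersions equal, p rarely small
  pvals <- vapply(1:40, function(s) {
    set.seed(s)
    cloud <- matrix(rnorm(12 * 4), 12, 4)
    xx <- rbind(cloud, sweep(cloud, 2, rep(3, 4), `+`))
    dd <- dispersion_analysis(xx, rep(c("a", "b"), each = 12),
                              metric = "euclidean", n_perm = 49, seed = s)
    expect_equal(unname(dd$means["a"]), unname(dd$means["b"]), tolerance = 1e-10)
    dd$p
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.9)
})

test_that("altGower dispersion handles negative PCoA axes", {
  set.seed(21)
  x <- matrix(rexp(24 * 5), 24, 5)
  grp <- rep(c("a", "b"), each = 12)
  disp <- dispersion_analysis(x, grp, metric = "altGower", n_perm = 19)
  expect_true(all(disp$distances >= 0))
  bd <- vegan::betadisper(vegan::vegdist(x, "altGower"), grp, type = "centroid")
  expect_equal(unname(disp$distances), unname(bd$distances), tolerance = 1e-6)
})

test_that("potter aggregation averages cross-trial dissimilarities", {
  d <- matrix(0, 4, 4)
  d[1, 3] <- d[3, 1] <- 1; d[1, 4] <- d[4, 1] <- 2
  d[2, 3] <- d[3, 2] <- 3; d[2, 4] <- d[4, 2] <- 4
  d[1, 2] <- d[2, 1] <- 9; d[3, 4] <- d[4, 3] <- 9
  pa <- potter_aggregate(d, c("A", "A", "B", "B"))
  expect_equal(pa["A", "B"], 2.5)
  expect_true(all(diag(pa) == 0))
  expect_equal(pa, t(pa))
  # identical trial sets -> 0 between potters
  z <- matrix(0, 4, 4)
  expect_true(all(potter_aggregate(z, c("A", "A", "B", "B")) == 0))
})

test_that("UPGMA reproduces hand-computed merges and exports valid Newick", {
  d3 <- matrix(c(0, 1, 4, 1, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  den <- upgma(d3)
  expect_equal(den$merges$height, c(0.5, 2.0))
  expect_setequal(c(den$merges$left[1], den$merges$right[1]), c("A", "B"))

  # 4-leaf hand case: d(A,B)=2, d(C,D)=3, cross pairs 8,8,8,10
  d4 <- matrix(c(0, 2, 8, 8,
                 2, 0, 8, 10,
                 8, 8, 0, 3,
                 8, 10, 3, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  den4 <- upgma(d4)
  expect_equal(den4$merges$height, c(1, 1.5, 4.25))  # (8+8+8+10)/4/2 = 4.25

  # 2 leaves merge at d/2
  d2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(upgma(d2)$merges$height, 1.5)

  # Newick round-trips through ape with the ultrametric cophenetic structure
  tree <- ape::read.tree(text = den4$newick)
  expect_setequal(tree$tip.label, LETTERS[1:4])
  coph <- ape::cophenetic.phylo(tree)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(unname(coph), unname(2 * oracle_cophenetic(den4$hclust) / 2),
               tolerance = 1e-8)
})

test_that("UPGMA trees are ultrametric on random dissimilarities", {
  set.seed(6)
  for (i in 1:5) {
    x <- matrix(rnorm(8 * 4), 8, 4)
    d <- distance_matrix(x, "euclidean")
    rownames(d) <- colnames(d) <- paste0("L", 1:8)
    den <- upgma(d)
    expect_true(all(diff(den$merges$height) >= -1e-12))  # monotone merges
    coph <- oracle_cophenetic(den$hclust)
    # ultrametric condition: for all triples, the two largest are equal
    for (a in 1:6) for (b in (a + 1):7) for (cc in (b + 1):8) {
      trip <- sort(c(coph[a, b], coph[a, cc], coph[b, cc]), decreasing = TRUE)
      expect_lt(trip[1] - trip[2], 1e-10)
    }
    tree <- ape::read.tree(text = den$newick)
    expect_equal(unname(ape::cophenetic.phylo(tree)[rownames(d), rownames(d)]),
                 unname(coph), tolerance = 1e-8)
  }
})
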