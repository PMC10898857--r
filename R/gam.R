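# Hierarchical smooth-trajectory models for shape-space coordinates as
# functions of percent time: a single global smoother (G), community-specific
# smoothers with a shared penalty (S), and community smoothers plus
# potter-level factor smoothers and intercepts (SI). Fitting is delegated to
# mgcv (cubic P-splines, second-order difference penalty, REML).

#' Odd/even train-test split of trials
#'
#' Odd-numbered trials (1, 3, 5) form the training set and even-numbered
#' trials (2, 4) the test set, so out-of-sample predictions are assessed on
#' held-out repetitions of the same potters.
#'
#' @param x a data frame with a `trial` column, or a list of `trial_record`s.
#' @return list with `train` and `test` subsets of the same type as `x`.
#' @export
split_trials <- function(x) {
  trial_no <- if (is.data.frame(x)) x$trial else
    vapply(x, function(tr) tr$trial, integer(1))
  assert(all(trial_no %in% 1:5), "trial numbers must lie in 1..5")
  missing_no <- setdiff(1:5, unique(trial_no))
  if (length(missing_no) > 0) {
    warning("missing trial number(s): ", paste(missing_no, collapse = ", "),
            call. = FALSE)
  }
  odd <- trial_no %% 2 == 1
  if (is.data.frame(x)) {
    list(train = x[odd, , drop = FALSE], test = x[!odd, , drop = FALSE])
  } else {
    list(train = x[odd], test = x[!odd])
  }
}

#' Trajectory table: shape-space scores against percent time
#'
#' @param tab an [efa_table()] data frame.
#' @param space a `shape_space`.
#' @param k number of axes (default 3).
#' @return data frame with design keys, `percent_time`, and `PC1..PCk`.
#' @export
trajectory_table <- function(tab, space, k = 3) {
  scores <- project_shapes(space, tab, k = k)
  colnames(scores) <- paste0("PC", seq_len(k))
  cbind(tab[c("potter_id", "community", "vessel_type", "clay_mass",
              "trial", "gesture", "percent_time")], as.data.frame(scores))
}

model_formula <- function(model, response, k, k_fs) {
  switch(model,
    G = stats::as.formula(sprintf(
      "%s ~ s(percent_time, bs = 'ps', k = %d, m = c(2, 2))", response, k)),
    S = stats::as.formula(sprintf(
      "%s ~ community + s(percent_time, by = community, bs = 'ps', k = %d, m = c(2, 2), id = 1)",
      response, k)),
    SI = stats::as.formula(sprintf(
      paste0("%s ~ community + s(percent_time, by = community, bs = 'ps', ",
             "k = %d, m = c(2, 2), id = 1) + s(percent_time, potter_id, ",
             "bs = 'fs', k = %d, m = 1)"), response, k, k_fs))
  )
}

#' Fit a hierarchical smooth trajectory model
#'
#' @param data data frame with columns `percent_time` (0-100), the response,
#'   and `community` / `potter_id` factors as required by the model.
#' @param model `"G"` (one global smoother), `"S"` (community smoothers,
#'   shared penalty), or `"SI"` (community smoothers plus potter-level
#'   factor smoothers, which carry potter intercepts in their penalized
#'   null space).
#' @param response response column name (default `"PC1"`).
#' @param k basis dimension per smoother (default 10).
#' @param k_fs basis dimension of the potter factor smoothers (default 6).
#' @param sp optional fixed smoothing parameters (passed to [mgcv::gam()];
#'   0 gives an unpenalized regression-spline fit).
#' @return an object of class `smooth_fit` wrapping the mgcv fit with its
#'   AIC, effective degrees of freedom, scale, and training fingerprint.
#' @export
fit_smooth_model <- function(data, model = c("G", "S", "SI"),
                             response = "PC1", k = 10, k_fs = 6, sp = NULL) {
  model <- match.arg(model)
  assert(response %in% names(data), "response column '", response, "' not found")
  assert(all(data$percent_time >= 0 & data$percent_time <= 100),
         "percent_time must lie in [0, 100]")
  assert(nrow(data) >= k + 2, "too few observations for the basis dimension")
  # declared factor levels are preserved so absent design levels are caught
  if (!is.factor(data$community)) data$community <- factor(data$community)
  if (!is.factor(data$potter_id)) data$potter_id <- factor(data$potter_id)
  if (model %in% c("S", "SI")) {
    empty <- levels(data$community)[table(data$community) == 0]
    assert(length(empty) == 0,
           "design error: community level(s) absent: ",
           paste(empty, collapse = ", "))
  }
  fit <- mgcv::gam(model_formula(model, response, k, k_fs),
                   data = data, method = "REML", sp = sp)
  structure(
    list(gam = fit, model = model, response = response, k = k,
         aic = stats::AIC(fit), edf = sum(fit$edf),
         loglik = as.numeric(stats::logLik(fit)), scale = fit$sig2,
         rss = sum(stats::residuals(fit, type = "response")^2),
         n_train = nrow(data),
         train_fingerprint = sum(data[[response]]) + nrow(data)),
    class = "smooth_fit"
  )
}

#' @export
print.smooth_fit <- function(x, ...) {
  cat(sprintf("Smooth trajectory model %s for %s: n = %d, edf = %.2f, AIC = %.2f\n",
              x$model, x$response, x$n_train, x$edf, x$aic))
  invisible(x)
}

#' AIC comparison of trajectory models
#'
#' @param fits list of `smooth_fit` objects sharing the same training data.
#' @return data frame with model, response, AIC, edf, and delta AIC relative
#'   to the best model, sorted by AIC.
#' @export
aic_compare <- function(fits) {
  fp <- vapply(fits, function(f) f$train_fingerprint, numeric(1))
  resp <- vapply(fits, function(f) f$response, character(1))
  for (r in unique(resp)) {
    assert(length(unique(fp[resp == r])) == 1,
           "contract violation: fits for ", r, " use different training data")
  }
  out <- data.frame(
    model = vapply(fits, function(f) f$model, character(1)),
    response = resp,
    AIC = vapply(fits, function(f) f$aic, numeric(1)),
    edf = vapply(fits, function(f) f$edf, numeric(1))
  )
  out$delta_AIC <- out$AIC - ave(out$AIC, out$response, FUN = min)
  out[order(out$response, out$AIC), ]
}

#' Out-of-sample Gaussian deviance
#'
#' Deviance of held-out data under the fitted mean: twice the difference
#' between the saturated and the model log-likelihood, which for the
#' Gaussian family is the sum of squared prediction errors (the same
#' convention mgcv's `deviance()` uses, so models with different residual
#' scales are compared on a common footing). Lower is better; exact
#' predictions give 0.
#'
#' @param fit a `smooth_fit`.
#' @param test data frame of held-out rows (same columns as training).
#' @return one-row data frame with model, response, n_test and deviance.
#' @export
oos_deviance <- function(fit, test) {
  assert(nrow(test) > 0, "contract violation: empty test set")
  test$community <- factor(test$community)
  test$potter_id <- factor(test$potter_id)
  mu <- as.numeric(mgcv::predict.gam(fit$gam, newdata = test))
  y <- test[[fit$response]]
  data.frame(model = fit$model, response = fit$response, n_test = nrow(test),
             deviance = sum((y - mu)^2))
}

#' Fit and compare trajectory models G, S, SI over shape-space axes
#'
#' Fits each requested model to the training rows for each response axis,
#' and evaluates AIC on the training fit and Gaussian deviance on the test
#' rows, mirroring an odd/even trial split comparison table.
#'
#' @param train,test data frames (e.g. from [split_trials()] applied to a
#'   [trajectory_table()]).
#' @param models subset of `c("G", "S", "SI")`.
#' @param responses response columns (default `PC1..PC3`).
#' @param k,k_fs basis dimensions, see [fit_smooth_model()].
#' @return an object of class `smooth_comparison`: the per-model-per-axis
#'   `table`, per-model `totals` (summed AIC and OOS deviance), and the
#'   fitted objects.
#' @export
compare_models <- function(train, test, models = c("G", "S", "SI"),
                           responses = c("PC1", "PC2", "PC3"),
                           k = 10, k_fs = 6) {
  fits <- list()
  rows <- list()
  for (resp in responses) {
    for (m in models) {
      f <- fit_smooth_model(train, model = m, response = resp, k = k,
                            k_fs = k_fs)
      oos <- oos_deviance(f, test)
      fits[[paste(m, resp, sep = ".")]] <- f
      rows[[paste(m, resp, sep = ".")]] <- data.frame(
        model = m, response = resp, AIC = f$aic, edf = f$edf, rss = f$rss,
        oos_deviance = oos$deviance
      )
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  totals <- stats::aggregate(cbind(AIC, oos_deviance) ~ model, tab, sum)
  structure(list(table = tab, totals = totals, fits = fits,
                 models = models, responses = responses),
            class = "smooth_comparison")
}

#' @export
print.smooth_comparison <- function(x, ...) {
  cat("Trajectory model comparison (training AIC, out-of-sample deviance)\n")
  tab <- x$table
  tab$AIC <- round(tab$AIC, 2); tab$edf <- round(tab$edf, 2)
  tab$rss <- signif(tab$rss, 4); tab$oos_deviance <- signif(tab$oos_deviance, 4)
  print(tab, row.names = FALSE)
  cat("Totals over axes:\n")
  tot <- x$totals
  tot$AIC <- round(tot$AIC, 2); tot$oos_deviance <- signif(tot$oos_deviance, 4)
  print(tot, row.names = FALSE)
  invisible(x)
}

#' Simulate trajectory data with known group structure
#'
#' Direct simulation of shape-space trajectories (one response) for model
#' comparison studies: community-specific smooth mean curves, potter-level
#' smooth deviations and intercepts, and observation noise. With
#' `community_effect = 0` all communities share one global curve.
#'
#' @param potters_per_community integer vector (default c(3, 3, 3)).
#' @param trials trials per potter (default 5, numbered 1..5).
#' @param points_per_trial observations per trial along percent time.
#' @param community_effect amplitude of community curve differences.
#' @param potter_effect amplitude of potter deviations.
#' @param sigma observation noise SD.
#' @param seed integer seed.
#' @return data frame with `potter_id, community, trial, percent_time, PC1`.
#' @export
simulate_trajectories <- function(potters_per_community = c(3, 3, 3),
                                  trials = 5, points_per_trial = 10,
                                  community_effect = 1, potter_effect = 0.5,
                                  sigma = 0.3, seed = 1) {
  set.seed(seed)
  comms <- COMMUNITIES[seq_along(potters_per_community)]
  base_curve <- function(t) 2 * sin(pi * t / 100) - t / 60
  rows <- list()
  for (ci in seq_along(comms)) {
    # community-specific smooth deviation from the shared base curve
    cdev <- function(t, a = stats::rnorm(2)) {
      community_effect * (a[1] * cos(pi * t / 100) + a[2] * sin(2 * pi * t / 100))
    }
    camp <- stats::rnorm(2)
    camp <- camp / sqrt(sum(camp^2))   # unit direction: community_effect is the magnitude
    for (pi_ in seq_len(potters_per_community[ci])) {
      pamp <- stats::rnorm(3)
      for (tr in seq_len(trials)) {
        t <- sort(stats::runif(points_per_trial, 0, 100))
        t[1] <- 0; t[length(t)] <- 100
        y <- base_curve(t) + cdev(t, camp) +
          potter_effect * (pamp[1] + pamp[2] * sin(3 * pi * t / 100) +
                             pamp[3] * t / 100) +
          stats::rnorm(points_per_trial, 0, sigma)
        rows[[length(rows) + 1]] <- data.frame(
          potter_id = paste0(substr(comms[ci], 1, 1), pi_),
          community = comms[ci], trial = tr, percent_time = t, PC1 = y
        )
      }
    }
  }
  do.call(rbind, rows)
}
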