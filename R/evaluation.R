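#' ROC and AUC against background pseudo-absences
#'
#' AUC is the probability that a random presence score outranks a random
#' background score, with ties counted one half (the rank-sum estimator,
#' identical to exhaustive pairwise comparison). The ROC reports
#' sensitivity against the fraction of background predicted present at each
#' candidate threshold.
#'
#' @param presence_scores numeric scores of (test) presences.
#' @param background_scores numeric scores of background points.
#' @return list `auc` and `roc` (data.frame `threshold`, `sensitivity`,
#'   `fpr`).
#' @export
roc_auc <- function(presence_scores, background_scores) {
  m <- length(presence_scores); n <- length(background_scores)
  if (m < 1 || n < 2)
    stop("need at least 1 presence and 2 background scores")
  all_scores <- c(presence_scores, background_scores)
  if (length(unique(all_scores)) == 1L) {
    warning("all scores identical; AUC undefined, returning 0.5")
    auc <- 0.5
  } else {
    r <- rank(all_scores)
    auc <- (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  }
  th <- sort(unique(all_scores))
  roc <- data.frame(
    threshold = th,
    sensitivity = vapply(th, function(t) mean(presence_scores >= t), 0),
    fpr = vapply(th, function(t) mean(background_scores >= t), 0))
  list(auc = auc, roc = roc)
}

#' Equal sensitivity-specificity threshold
#'
#' Scans all distinct observed scores as candidate thresholds and returns
#' the one minimizing |sensitivity - specificity|, where specificity is the
#' fraction of background scored below the threshold. Ties break toward the
#' lower threshold, favouring sensitivity (false presences are tolerated in
#' preference to false absences).
#'
#' @param presence_scores,background_scores numeric score vectors.
#' @return the threshold (numeric scalar) with attributes `sensitivity` and
#'   `specificity`.
#' @export
equal_ss_threshold <- function(presence_scores, background_scores) {
  all_scores <- c(presence_scores, background_scores)
  if (length(unique(all_scores)) == 1L) {
    warning("degenerate scores; threshold equals the common value")
    th <- all_scores[1]
    attr(th, "sensitivity") <- 1
    attr(th, "specificity") <- 0
    return(th)
  }
  cand <- sort(unique(all_scores))
  sens <- vapply(cand, function(t) mean(presence_scores >= t), 0)
  spec <- vapply(cand, function(t) mean(background_scores < t), 0)
  gap <- abs(sens - spec)
  best <- which(gap <= min(gap) + 1e-12)[1]  # candidates ascending: first = lowest
  th <- cand[best]
  attr(th, "sensitivity") <- sens[best]
  attr(th, "specificity") <- spec[best]
  th
}

#' One-sided binomial test of omission
#'
#' Tests the null hypothesis that held-out presences are predicted no
#' better than random given the fraction of the study area predicted
#' present: `p = P(X >= n_test - n_omitted)` for
#' `X ~ Binomial(n_test, fractional_predicted_area)`.
#'
#' @param n_test number of test presences.
#' @param n_omitted number scored below the threshold.
#' @param fractional_predicted_area share of background predicted present,
#'   in (0, 1).
#' @return one-sided p-value.
#' @export
binomial_omission_test <- function(n_test, n_omitted, fractional_predicted_area) {
  stopifnot(n_omitted >= 0, n_omitted <= n_test)
  a <- fractional_predicted_area
  if (a <= 0 || a >= 1) {
    warning("degenerate fractional predicted area; p-value is an indicator")
    hits <- n_test - n_omitted
    return(if (a <= 0) as.numeric(hits == 0) else 1)
  }
  hits <- n_test - n_omitted
  stats::pbinom(hits - 1, n_test, a, lower.tail = FALSE)
}

#' K-fold cross-validation of the maximum-entropy model
#'
#' Presences are partitioned at random into K near-equal parts; each fold
#' fits on the remaining K-1 parts with the full background (background
#' points are shared across folds) and is tested on the held-out presences
#' against that background.
#'
#' @param samples a `sample_matrix`.
#' @param K number of folds (default 10; must not exceed the presence
#'   count).
#' @param seed integer seed for the partition.
#' @param ... fitting arguments passed to [maxent_fit()].
#' @return list with `stats` (per-fold data.frame: `fold`, `train_auc`,
#'   `test_auc`, `n_test`), `test_scores` (pooled held-out logistic
#'   scores), `bg_scores` (background logistic scores from the last fold's
#'   model — used only for reporting), and `assignments` (fold id per
#'   presence).
#' @export
kfold_cv <- function(samples, K = 10, seed = 1, ...) {
  pres_idx <- which(samples$label == 1)
  bg_idx <- which(samples$label == 0)
  m <- length(pres_idx)
  if (K < 2) stop("K must be at least 2")
  if (K > m) stop(sprintf("K = %d exceeds the presence count %d", K, m))
  fold <- with_seed(split_seed(seed, "kfold"),
                    sample(rep(seq_len(K), length.out = m)))
  stats_l <- list(); test_scores <- list(); test_fold <- list()
  bg_scores <- NULL
  for (k in seq_len(K)) {
    tr <- c(pres_idx[fold != k], bg_idx)
    te <- pres_idx[fold == k]
    sub <- list(x = samples$x[tr, , drop = FALSE], label = samples$label[tr])
    fit <- maxent_fit(sub, ...)
    s_tr <- predict(fit, samples$x[pres_idx[fold != k], , drop = FALSE])
    s_bg <- predict(fit, samples$x[bg_idx, , drop = FALSE])
    s_te <- predict(fit, samples$x[te, , drop = FALSE])
    stats_l[[k]] <- data.frame(
      fold = k,
      train_auc = roc_auc(s_tr, s_bg)$auc,
      test_auc = roc_auc(s_te, s_bg)$auc,
      n_test = length(te))
    test_scores[[k]] <- s_te
    test_fold[[k]] <- rep(k, length(te))
    bg_scores <- s_bg
  }
  list(stats = do.call(rbind, stats_l),
       test_scores = unlist(test_scores),
       test_fold = unlist(test_fold),
       bg_scores = bg_scores,
       assignments = fold)
}

#' Permutation importance of each covariate
#'
#' For each covariate, permutes its column jointly across presence and
#' background rows (all features derived from the covariate see the
#' permuted values), recomputes the AUC and records the drop from the
#' unpermuted AUC. Drops are floored at zero and normalized to sum to 100.
#'
#' @param model a fitted `maxent_model`.
#' @param samples the `sample_matrix` it was fitted on.
#' @param seed integer seed for the permutations.
#' @return named numeric vector of percentages summing to 100 (all zero,
#'   with a warning, if no permutation lowers the AUC).
#' @export
permutation_importance <- function(model, samples, seed = 1) {
  x <- as.data.frame(samples$x)
  pres <- samples$label == 1
  base_scores <- predict(model, x)
  base_auc <- roc_auc(base_scores[pres], base_scores[!pres])$auc
  covs <- model$features$covariates
  drops <- stats::setNames(numeric(length(covs)), covs)
  with_seed(split_seed(seed, "perm_importance"), {
    for (cv in covs) {
      xp <- x
      xp[[cv]] <- sample(xp[[cv]])
      s <- predict(model, xp)
      drops[cv] <- base_auc - roc_auc(s[pres], s[!pres])$auc
    }
  })
  drops <- pmax(drops, 0)
  tot <- sum(drops)
  if (tot <= 0) {
    warning("no covariate permutation lowered the AUC; importances all zero")
    return(drops)
  }
  100 * drops / tot
}

#' Jackknife gain per covariate
#'
#' Gain is the penalized average log-likelihood of the presences under the
#' fitted Gibbs density minus its value under the uniform null (which is
#' exactly 0), i.e. the fitted objective of [maxent_fit()]. Computed for
#' the full model, for each model with one covariate removed, and for each
#' single-covariate model.
#'
#' @param samples a `sample_matrix`.
#' @param ... fitting arguments passed to [maxent_fit()] (feature classes,
#'   regularization, ...).
#' @return list with `full_gain` and `table` (data.frame `covariate`,
#'   `gain_without`, `gain_alone`, `converged_without`, `converged_alone`).
#' @export
jackknife_gain <- function(samples, ...) {
  x <- as.data.frame(samples$x)
  covs <- names(x)
  if (length(covs) < 2) stop("need at least 2 covariates")
  gain_of <- function(cols) {
    sub <- list(x = x[, cols, drop = FALSE], label = samples$label)
    fit <- maxent_fit(sub, ...)
    list(gain = fit$convergence$objective, conv = fit$convergence$converged)
  }
  full <- gain_of(covs)
  tab <- do.call(rbind, lapply(covs, function(cv) {
    wo <- gain_of(setdiff(covs, cv))
    al <- gain_of(cv)
    data.frame(covariate = cv, gain_without = wo$gain, gain_alone = al$gain,
               converged_without = wo$conv, converged_alone = al$conv,
               stringsAsFactors = FALSE)
  }))
  list(full_gain = full$gain, full_converged = full$conv, table = tab)
}

#' Median test for divergence among groups
#'
#' Nonparametric k-sample comparison via a contingency table: counts above
#' versus at-or-below the pooled median per group, tested with a chi-square
#' statistic on G-1 degrees of freedom (no continuity correction by
#' default; Yates correction optional for two groups).
#'
#' @param groups named list of numeric vectors (each n >= 5), e.g. presence
#'   values and per-season background values of one covariate.
#' @param correct apply Yates continuity correction (2 groups only).
#' @return list `statistic`, `df`, `p_value`, `grand_median`, `table`.
#' @export
median_test <- function(groups, correct = FALSE) {
  if (length(groups) < 2) stop("need at least 2 groups")
  ns <- vapply(groups, length, 0L)
  if (any(ns < 5)) stop("each group needs at least 5 values")
  all_v <- unlist(groups, use.names = FALSE)
  med <- stats::median(all_v)
  if (length(unique(all_v)) == 1L) {
    warning("all values equal; median test undefined, returning p = 1")
    return(list(statistic = 0, df = length(groups) - 1L, p_value = 1,
                grand_median = med, table = NULL))
  }
  above <- vapply(groups, function(v) sum(v > med), 0L)
  below <- ns - above
  tab <- rbind(above = above, at_or_below = below)
  G <- length(groups)
  exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp_tab == 0)) {
    warning("degenerate contingency table; returning p = 1")
    return(list(statistic = 0, df = G - 1L, p_value = 1,
                grand_median = med, table = tab))
  }
  dev <- abs(tab - exp_tab)
  if (correct && G == 2) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / exp_tab)
  list(statistic = stat, df = G - 1L,
       p_value = stats::pchisq(stat, G - 1L, lower.tail = FALSE),
       grand_median = med, table = tab)
}

#' Full evaluation battery for one season's model
#'
#' Runs K-fold cross-validation, pools the held-out presence scores to set
#' the equal sensitivity-specificity threshold and the test-site omission
#' rate, performs the binomial omission test against the fractional
#' predicted area (share of background above the threshold), fits the full
#' model for prevalence (mean logistic output over background) and
#' permutation importance, and applies the median test to each seasonally
#' varying covariate (presence values vs background values).
#'
#' @param samples a `sample_matrix` for the season.
#' @param K folds (default 10).
#' @param seed integer seed.
#' @param median_covariates covariates to median-test (default the four
#'   seasonally varying ones present in the samples).
#' @param ... fitting arguments passed to [maxent_fit()].
#' @return an `evaluation_report` list.
#' @export
evaluate_season <- function(samples, K = 10, seed = 1,
                            median_covariates = NULL, ...) {
  cv <- kfold_cv(samples, K = K, seed = seed, ...)
  full <- maxent_fit(samples, ...)
  bg_scores <- predict(full, samples$x[samples$label == 0, , drop = FALSE])
  th <- equal_ss_threshold(cv$test_scores, bg_scores)
  omission <- mean(cv$test_scores < as.numeric(th))
  fpa <- mean(bg_scores >= as.numeric(th))
  n_test <- length(cv$test_scores)
  pbin <- binomial_omission_test(n_test, round(omission * n_test), fpa)
  imp <- permutation_importance(full, samples, seed = seed)
  if (is.null(median_covariates))
    median_covariates <- intersect(c("temp", "oxygen", "u_east", "v_north"),
                                   names(samples$x))
  med <- lapply(median_covariates, function(cv_name) {
    median_test(list(presence = samples$x[[cv_name]][samples$label == 1],
                     background = samples$x[[cv_name]][samples$label == 0]))
  })
  names(med) <- median_covariates
  structure(list(
    season = samples$season,
    folds = cv$stats,
    mean_train_auc = mean(cv$stats$train_auc),
    sd_train_auc = stats::sd(cv$stats$train_auc),
    mean_test_auc = mean(cv$stats$test_auc),
    sd_test_auc = stats::sd(cv$stats$test_auc),
    threshold = as.numeric(th),
    omission_rate = omission,
    fractional_predicted_area = fpa,
    binomial_p = pbin,
    prevalence = mean(predict(full, samples$x[samples$label == 0, , drop = FALSE],
                              type = "logistic")),
    importance = imp,
    median_tests = med,
    model = full), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> season %s\n", x$season))
  cat(sprintf("  AUC train %.3f (sd %.3f), test %.3f (sd %.3f) over %d folds\n",
              x$mean_train_auc, x$sd_train_auc, x$mean_test_auc, x$sd_test_auc,
              nrow(x$folds)))
  cat(sprintf("  threshold %.3f, omission %.3f, prevalence %.3f, binomial p %.3g\n",
              x$threshold, x$omission_rate, x$prevalence, x$binomial_p))
  cat("  importance (%):\n")
  print(round(x$importance, 1))
  invisible(x)
}

#' Assemble a Table-1-shaped report across seasons
#'
#' Rows are the evaluation statistics (training/test AUC, prevalence,
#' logistic threshold, omission rate, binomial p, per-covariate
#' importances); columns are seasons.
#'
#' @param reports named list of `evaluation_report`s (one per season).
#' @return data.frame with a `statistic` column and one column per season.
#' @export
report_table <- function(reports) {
  covs <- unique(unlist(lapply(reports, function(r) names(r$importance))))
  rows <- c("Average Training AUC", "Average Test AUC", "Prevalence",
            "Logistic Threshold", "Test Site Omission Rate",
            "Binomial Omission p",
            paste(covs, "Importance"))
  out <- data.frame(statistic = rows, stringsAsFactors = FALSE)
  for (sn in names(reports)) {
    r <- reports[[sn]]
    imp <- stats::setNames(rep(NA_real_, length(covs)), covs)
    imp[names(r$importance)] <- r$importance
    out[[sn]] <- c(round(r$mean_train_auc, 3), round(r$mean_test_auc, 3),
                   round(r$prevalence, 3), round(r$threshold, 3),
                   round(r$omission_rate, 3), signif(r$binomial_p, 3),
                   round(unname(imp), 1))
  }
  out
}

#' Serialize evaluation reports
#'
#' @param reports named list of `evaluation_report`s.
#' @param json_path,csv_path output paths (either may be NULL).
#' @export
write_report <- function(reports, json_path = NULL, csv_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(report_table(reports), csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    slim <- lapply(reports, function(r) {
      r$model <- NULL
      r$median_tests <- lapply(r$median_tests, function(m) {
        m$table <- NULL
        m
      })
      unclass(r)
    })
    jsonlite::write_json(slim, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  }
  invisible(reports)
}
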