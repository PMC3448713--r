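#' Feature expansion for the maximum-entropy model
#'
#' Expands raw covariates into the model's feature space: linear and
#' quadratic terms per covariate, pairwise products, and threshold plus
#' forward/reverse hinge features at empirical-quantile knots. Every feature
#' is then min-max scaled to [0, 1] using the combined presence+background
#' sample, and the raw covariate ranges are retained for clamping during
#' projection. Constant covariates are dropped with a warning.
#'
#' @param x data.frame of covariate columns (presence rows then background
#'   rows), or a `sample_matrix`.
#' @param classes feature classes to build, subset of
#'   `c("linear", "quadratic", "product", "hinge", "threshold")`.
#'   (Categorical features are accepted in the type system but no covariate
#'   here is categorical.)
#' @param hinge_knots number of empirical-quantile knots per covariate for
#'   hinge and threshold features.
#' @return a `feature_set`: feature definitions, scaling constants and raw
#'   covariate ranges.
#' @export
expand_features <- function(x, classes = c("linear", "quadratic", "product",
                                           "hinge", "threshold"),
                            hinge_knots = 5) {
  if (inherits(x, "sample_matrix")) x <- x$x
  x <- as.data.frame(x)
  classes <- match.arg(classes, several.ok = TRUE)
  keep <- vapply(x, function(v) length(unique(v)) >= 2, TRUE)
  if (any(!keep)) {
    warning(sprintf("dropping constant covariate(s): %s",
                    paste(names(x)[!keep], collapse = ", ")))
    x <- x[, keep, drop = FALSE]
  }
  covs <- names(x)
  if (!length(covs)) stop("no usable covariates")
  rng <- data.frame(cov = covs,
                    min = vapply(x, min, 0), max = vapply(x, max, 0),
                    stringsAsFactors = FALSE)
  defs <- list()
  add <- function(type, cov1, cov2 = NA_character_, knot = NA_real_)
    defs[[length(defs) + 1L]] <<- data.frame(
      type = type, cov1 = cov1, cov2 = cov2, knot = knot,
      stringsAsFactors = FALSE)
  if ("linear" %in% classes) for (cv in covs) add("linear", cv)
  if ("quadratic" %in% classes) for (cv in covs) add("quadratic", cv)
  if ("product" %in% classes && length(covs) >= 2) {
    cmb <- utils::combn(covs, 2)
    for (k in seq_len(ncol(cmb))) add("product", cmb[1, k], cmb[2, k])
  }
  probs <- seq_len(hinge_knots) / (hinge_knots + 1)
  if ("threshold" %in% classes)
    for (cv in covs)
      for (k in unique(stats::quantile(x[[cv]], probs, names = FALSE)))
        add("threshold", cv, knot = k)
  if ("hinge" %in% classes)
    for (cv in covs)
      for (k in unique(stats::quantile(x[[cv]], probs, names = FALSE))) {
        add("hinge", cv, knot = k)
        add("reverse_hinge", cv, knot = k)
      }
  defs <- do.call(rbind, defs)
  raw <- .raw_features(defs, x)
  defs$fmin <- apply(raw, 2, min)
  defs$fmax <- apply(raw, 2, max)
  const <- defs$fmax - defs$fmin <= 0
  defs <- defs[!const, , drop = FALSE]
  rownames(defs) <- NULL
  defs$name <- .feature_names(defs)
  structure(list(defs = defs, cov_range = rng, covariates = covs),
            class = "feature_set")
}

.feature_names <- function(defs) {
  vapply(seq_len(nrow(defs)), function(i) {
    d <- defs[i, ]
    switch(d$type,
           linear = d$cov1,
           quadratic = paste0(d$cov1, "^2"),
           product = paste0(d$cov1, "*", d$cov2),
           threshold = sprintf("(%s>%.6g)", d$cov1, d$knot),
           hinge = sprintf("h(%s-%.6g)", d$cov1, d$knot),
           reverse_hinge = sprintf("h(%.6g-%s)", d$knot, d$cov1))
  }, "")
}

.raw_features <- function(defs, x) {
  out <- matrix(0, nrow(x), nrow(defs))
  for (i in seq_len(nrow(defs))) {
    d <- defs[i, ]
    v <- x[[d$cov1]]
    out[, i] <- switch(d$type,
                       linear = v,
                       quadratic = v^2,
                       product = v * x[[d$cov2]],
                       threshold = as.numeric(v > d$knot),
                       hinge = pmax(0, v - d$knot),
                       reverse_hinge = pmax(0, d$knot - v))
  }
  out
}

#' Evaluate a feature set on covariate rows
#'
#' @param fs a `feature_set`.
#' @param x data.frame of covariates.
#' @param clamp truncate covariates (and scaled features) to the training
#'   range; the number of clamped covariate values is attached as attribute
#'   `"n_clamped"`.
#' @return numeric matrix, one scaled feature per column.
#' @export
feature_matrix <- function(fs, x, clamp = FALSE) {
  x <- as.data.frame(x)
  missing_cov <- setdiff(fs$covariates, names(x))
  if (length(missing_cov))
    stop(sprintf("covariate(s) missing from data: %s",
                 paste(missing_cov, collapse = ", ")))
  n_clamped <- 0L
  if (clamp) {
    for (i in seq_len(nrow(fs$cov_range))) {
      cv <- fs$cov_range$cov[i]
      lo <- fs$cov_range$min[i]; hi <- fs$cov_range$max[i]
      out_of <- sum(x[[cv]] < lo | x[[cv]] > hi, na.rm = TRUE)
      n_clamped <- n_clamped + out_of
      x[[cv]] <- pmin(pmax(x[[cv]], lo), hi)
    }
  }
  raw <- .raw_features(fs$defs, x)
  scaled <- sweep(sweep(raw, 2, fs$defs$fmin), 2, fs$defs$fmax - fs$defs$fmin, "/")
  if (clamp) scaled <- pmin(pmax(scaled, 0), 1)
  colnames(scaled) <- fs$defs$name
  attr(scaled, "n_clamped") <- n_clamped
  scaled
}

# Published per-class base regularization, interpolated in the presence
# count m (the reference software's defaults).
.base_penalty <- function(type, m) {
  interp <- function(xs, ys) stats::approx(xs, ys, xout = m, rule = 2)$y
  switch(type,
         linear = , quadratic = , product =
           interp(c(0, 10, 30, 100), c(1, 1, 0.2, 0.05)),
         threshold = interp(c(0, 100), c(2, 1)),
         hinge = , reverse_hinge = 0.5,
         categorical = interp(c(0, 10, 17), c(0.65, 0.5, 0.25)),
         stop(sprintf("unknown feature type '%s'", type)))
}

.logsumexp <- function(v) {
  mx <- max(v)
  mx + log(sum(exp(v - mx)))
}

#' Fit the presence-only maximum-entropy model
#'
#' Maximizes the L1-penalized log-likelihood of the presence sample under
#' the Gibbs density `exp(sum lambda * f) / Z` relative to the background
#' sample:
#' `ll = mean_presence(eta) - log(mean_background(exp(eta))) - sum(beta * |lambda|)`,
#' where `eta = F lambda` on scaled features, by proximal Newton ascent:
#' each iteration reweights the background under the current Gibbs density,
#' solves the L1-penalized quadratic model (gradient and full feature
#' covariance under the weighted background) by inner coordinate descent
#' with soft-threshold updates, and backtracks the resulting step with a
#' halving line search on the true penalized objective, which is therefore
#' non-decreasing across iterations by construction. The
#' per-feature penalty is `beta_j = r * base(class, m) * sd_j / sqrt(m)`
#' with `m` the presence count, `sd_j` the feature's standard deviation
#' over the presence rows (combined rows when degenerate) and `base` the
#' published per-class constant. Fitting stops when an iteration gains less
#' than `tol` log-likelihood or after `max_iter` iterations; an unconverged
#' fit is returned flagged, not rejected.
#'
#' @param samples a `sample_matrix`, or any list with `x` (covariate
#'   data.frame) and `label` (1 presence / 0 background).
#' @param features optional pre-built [expand_features()] result.
#' @param classes,hinge_knots passed to [expand_features()] when `features`
#'   is NULL.
#' @param reg_multiplier regularization multiplier `r` (default 3).
#' @param tol convergence threshold on log-likelihood gain per pass
#'   (default 1e-5).
#' @param max_iter maximum coordinate updates (default 10000).
#' @param min_background minimum background rows (default 100).
#' @return a `maxent_model`.
#' @export
maxent_fit <- function(samples, features = NULL,
                       classes = c("linear", "quadratic", "product",
                                   "hinge", "threshold"),
                       hinge_knots = 5, reg_multiplier = 3,
                       tol = 1e-5, max_iter = 10000, min_background = 100) {
  x <- as.data.frame(samples$x)
  label <- samples$label
  bad <- which(!vapply(x, function(v) all(is.finite(v)), TRUE))
  if (length(bad)) {
    j <- bad[1]
    i <- which(!is.finite(x[[j]]))[1]
    stop(sprintf("non-finite covariate value at row %d, column '%s'",
                 i, names(x)[j]))
  }
  m <- sum(label == 1); nb <- sum(label == 0)
  if (m < 1) stop("need at least one presence row")
  if (nb < min_background)
    stop(sprintf("need at least %d background rows, got %d", min_background, nb))
  if (is.null(features)) features <- expand_features(x, classes, hinge_knots)
  F_all <- feature_matrix(features, x)
  Fp <- F_all[label == 1, , drop = FALSE]
  Fb <- F_all[label == 0, , drop = FALSE]
  p <- ncol(F_all)
  mean_p <- colMeans(Fp)

  sd_pres <- apply(Fp, 2, stats::sd)
  sd_all <- apply(F_all, 2, stats::sd)
  sd_j <- ifelse(is.na(sd_pres) | sd_pres <= 0, sd_all, sd_pres)
  base <- vapply(features$defs$type, .base_penalty, 0, m = m)
  beta <- reg_multiplier * base * sd_j / sqrt(m)

  lambda <- numeric(p)
  eta_b <- numeric(nb)
  pen_obj <- function(lam, eta)
    sum(lam * mean_p) - (.logsumexp(eta) - log(nb)) - sum(beta * abs(lam))
  obj <- 0    # objective at lambda = 0
  obj_trace <- obj
  iter <- 0L
  converged <- FALSE
  last_gain <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    w <- exp(eta_b - max(eta_b))
    w <- w / sum(w)
    Ef <- as.numeric(crossprod(Fb, w))
    g <- mean_p - Ef
    # weighted feature covariance = Hessian of the log-partition term
    Fw <- Fb * sqrt(w)
    H <- crossprod(Fw) - tcrossprod(Ef)
    diag(H) <- diag(H) + 1e-9
    # inner coordinate descent on the L1-penalized quadratic model
    u <- lambda
    for (sweep in 1:20) {
      u_old <- u
      for (j in seq_len(p)) {
        r_j <- g[j] - sum(H[j, ] * (u - lambda)) + H[j, j] * (u[j] - lambda[j])
        z <- lambda[j] + r_j / H[j, j]
        u[j] <- sign(z) * max(abs(z) - beta[j] / H[j, j], 0)
      }
      if (max(abs(u - u_old)) < 1e-9) break
    }
    d <- u - lambda
    if (max(abs(d)) < 1e-12) { converged <- TRUE; last_gain <- 0; break }
    step <- 1
    accepted <- FALSE
    for (ls in 1:40) {
      cand <- lambda + step * d
      eta_c <- eta_b + as.numeric(Fb %*% (cand - lambda))
      cand_obj <- pen_obj(cand, eta_c)
      if (is.finite(cand_obj) && cand_obj >= obj - 1e-12) { accepted <- TRUE; break }
      step <- step / 2
    }
    if (!accepted) { last_gain <- 0; converged <- TRUE; break }
    last_gain <- cand_obj - obj
    lambda <- cand
    eta_b <- eta_c
    obj <- cand_obj
    obj_trace <- c(obj_trace, obj)
    if (last_gain < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("maxent fit not converged after %d iterations (last gain %.3g)",
                    iter, last_gain))

  logZ <- .logsumexp(eta_b)           # Z = sum over background of exp(eta)
  pbg <- exp(eta_b - logZ)
  H <- -sum(pbg * log(pmax(pbg, 1e-300)))
  structure(list(
    lambda = stats::setNames(lambda, features$defs$name),
    beta = beta, features = features,
    tau = 0.5, reg_multiplier = reg_multiplier,
    m = m, n_bg = nb, logZ = logZ, H = H,
    raw_bg = pbg,
    sample_means = colMeans(x),
    convergence = list(iterations = iter, converged = converged,
                       final_gain = last_gain,
                       objective = obj, trace = obj_trace)),
    class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  nz <- sum(abs(x$lambda) > 1e-10)
  cat(sprintf(
    "<maxent_model> %d features (%d active), m = %d presences, %d background\n",
    length(x$lambda), nz, x$m, x$n_bg))
  cat(sprintf("  reg multiplier %.3g; %sconverged in %d iterations; gain %.4f\n",
              x$reg_multiplier, if (x$convergence$converged) "" else "NOT ",
              x$convergence$iterations, x$convergence$objective))
  invisible(x)
}

#' Model predictions on covariate rows
#'
#' Raw output is the Gibbs density normalized over the training background
#' (raw values over the background rows sum to 1). The logistic output is
#' `tau * exp(eta') / (1 - tau + tau * exp(eta'))` with
#' `eta' = eta - log Z + H` and assumed prevalence `tau` (0.5 by default),
#' so a cell with the background-average score maps to `tau`. Cumulative
#' output is the percentile (0-100) of the raw value within the background
#' raw distribution. Projection clamps covariates to the training range;
#' the clamped-value count is attached as attribute `"n_clamped"`.
#'
#' @param object a `maxent_model`.
#' @param newdata data.frame of covariates or a `sample_matrix`.
#' @param type one of `"logistic"`, `"raw"`, `"cumulative"`, `"link"`.
#' @param clamp clamp covariates to the training range (default TRUE).
#' @param ... unused.
#' @export
predict.maxent_model <- function(object, newdata, type = c("logistic", "raw",
                                                           "cumulative", "link"),
                                 clamp = TRUE, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "sample_matrix")) newdata <- newdata$x
  Fm <- feature_matrix(object$features, newdata, clamp = clamp)
  eta <- as.numeric(Fm %*% object$lambda)
  out <- switch(type,
                link = eta,
                raw = exp(eta - object$logZ),
                logistic = {
                  e <- exp(eta - object$logZ + object$H)
                  object$tau * e / (1 - object$tau + object$tau * e)
                },
                cumulative = {
                  raw <- exp(eta - object$logZ)
                  ec <- stats::ecdf(object$raw_bg)
                  100 * ec(raw)
                })
  attr(out, "n_clamped") <- attr(Fm, "n_clamped")
  out
}

#' Marginal response curve of one covariate
#'
#' Logistic output along a grid of one covariate with every other covariate
#' held at its mean value over the training sample (presences plus
#' background).
#'
#' @param model a `maxent_model`.
#' @param covariate covariate name.
#' @param grid values at which to evaluate; defaults to 100 points over the
#'   training range.
#' @param n grid length when `grid` is NULL.
#' @return data.frame with `value` and `logistic`.
#' @export
response_curve <- function(model, covariate, grid = NULL, n = 100) {
  rng <- model$features$cov_range
  if (!covariate %in% rng$cov)
    stop(sprintf("unknown covariate '%s'; model covariates: %s",
                 covariate, paste(rng$cov, collapse = ", ")))
  if (is.null(grid)) {
    i <- match(covariate, rng$cov)
    grid <- seq(rng$min[i], rng$max[i], length.out = n)
  }
  means <- model$sample_means
  df <- as.data.frame(lapply(means[rng$cov], rep, length(grid)))
  names(df) <- rng$cov
  df[[covariate]] <- grid
  data.frame(value = grid,
             logistic = as.numeric(predict(model, df, type = "logistic")))
}

#' Serialize a fitted model as a plain-text lambdas file
#'
#' A diffable key-value format: scalar header lines (`tau`, `logZ`, `H`,
#' counts, convergence), the raw covariate ranges, quantiles of the
#' background raw distribution (so cumulative output survives the
#' round-trip approximately), the sample means used by response curves, and
#' one line per feature with its definition, scaling constants and lambda.
#'
#' @param model a `maxent_model`.
#' @param path file path.
#' @export
write_lambdas <- function(model, path) {
  con <- file(path, "w"); on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("seaway_lambdas 1")
  for (k in c("tau", "reg_multiplier", "m", "n_bg", "logZ", "H"))
    wl("%s %.17g", k, model[[k]])
  wl("iterations %d", model$convergence$iterations)
  wl("converged %d", as.integer(model$convergence$converged))
  q <- stats::quantile(model$raw_bg, seq(0, 1, 0.01), names = FALSE)
  wl("raw_bg_quantiles %s", paste(sprintf("%.17g", q), collapse = ","))
  rng <- model$features$cov_range
  for (i in seq_len(nrow(rng)))
    wl("range %s %.17g %.17g %.17g", rng$cov[i], rng$min[i], rng$max[i],
       model$sample_means[[rng$cov[i]]])
  d <- model$features$defs
  for (i in seq_len(nrow(d)))
    wl("feature %s %s %s %.17g %.17g %.17g %.17g", d$type[i], d$cov1[i],
       d$cov2[i], d$knot[i], d$fmin[i], d$fmax[i], model$lambda[i])
  invisible(path)
}

#' @rdname write_lambdas
#' @export
read_lambdas <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "seaway_lambdas")) stop("not a seaway lambdas file")
  kv <- strsplit(lines[-1], " ")
  get1 <- function(key) {
    for (t in kv) if (t[1] == key) return(t[2])
    stop(sprintf("missing key '%s'", key))
  }
  rngs <- Filter(function(t) t[1] == "range", kv)
  feats <- Filter(function(t) t[1] == "feature", kv)
  cov_range <- data.frame(
    cov = vapply(rngs, `[`, "", 2),
    min = as.numeric(vapply(rngs, `[`, "", 3)),
    max = as.numeric(vapply(rngs, `[`, "", 4)),
    stringsAsFactors = FALSE)
  sample_means <- stats::setNames(as.numeric(vapply(rngs, `[`, "", 5)),
                                  cov_range$cov)
  num <- function(v) suppressWarnings(as.numeric(v))  # "NA" -> NA silently
  defs <- data.frame(
    type = vapply(feats, `[`, "", 2),
    cov1 = vapply(feats, `[`, "", 3),
    cov2 = vapply(feats, `[`, "", 4),
    knot = num(vapply(feats, `[`, "", 5)),
    fmin = as.numeric(vapply(feats, `[`, "", 6)),
    fmax = as.numeric(vapply(feats, `[`, "", 7)),
    stringsAsFactors = FALSE)
  defs$cov2[defs$cov2 == "NA"] <- NA_character_
  defs$name <- .feature_names(defs)
  lambda <- as.numeric(vapply(feats, `[`, "", 8))
  fs <- structure(list(defs = defs, cov_range = cov_range,
                       covariates = cov_range$cov),
                  class = "feature_set")
  q <- as.numeric(strsplit(get1("raw_bg_quantiles"), ",")[[1]])
  structure(list(
    lambda = stats::setNames(lambda, defs$name),
    beta = NULL, features = fs,
    tau = as.numeric(get1("tau")),
    reg_multiplier = as.numeric(get1("reg_multiplier")),
    m = as.integer(get1("m")), n_bg = as.integer(get1("n_bg")),
    logZ = as.numeric(get1("logZ")), H = as.numeric(get1("H")),
    raw_bg = q,
    sample_means = sample_means,
    convergence = list(iterations = as.integer(get1("iterations")),
                       converged = as.logical(as.integer(get1("converged"))),
                       final_gain = NA_real_, objective = NA_real_,
                       trace = NULL)),
    class = "maxent_model")
}
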