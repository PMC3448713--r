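test_that("feature expansion: counts, knots, scaling, constant covariates", {
  set.seed(1)
  x <- as.data.frame(matrix(runif(120 * 6), 120, 6,
                            dimnames = list(NULL, letters[1:6])))
  fs <- expand_features(x, classes = c("linear", "quadratic", "product"))
  # 6 linear + 6 quadratic + choose(6, 2) products
  expect_equal(nrow(fs$defs), 6 + 6 + 15)
  Fm <- feature_matrix(fs, x)
  expect_equal(unname(apply(Fm, 2, min)), rep(0, ncol(Fm)))
  expect_equal(unname(apply(Fm, 2, max)), rep(1, ncol(Fm)))

  # forward hinge is zero at its knot
  fs_h <- expand_features(x["a"], classes = "hinge", hinge_knots = 3)
  k <- fs_h$defs$knot[fs_h$defs$type == "hinge"][1]
  Fh <- feature_matrix(fs_h, data.frame(a = k))
  expect_equal(unname(Fh[1, fs_h$defs$type == "hinge"][1]), 0)

  x$g <- 1  # constant covariate dropped with a warning
  expect_warning(fs2 <- expand_features(x, classes = "linear"), "constant")
  expect_false("g" %in% fs2$covariates)
})

test_that("single binary feature at r = 0 matches the moment-matching root", {
  # presence mean 0.8, background mean 0.5
  set.seed(2)
  xp <- data.frame(f = rbinom(200, 1, 0.8))
  xb <- data.frame(f = rbinom(2000, 1, 0.5))
  sm <- as_samples(xp, xb)
  fit <- maxent_fit(sm, classes = "linear", reg_multiplier = 0, tol = 1e-10)
  # independent oracle: solve d/d(lambda) [ mean_p f - log mean_b e^(l f) ] = 0
  fb <- xb$f; mp <- mean(xp$f)
  root <- stats::uniroot(function(l) mp - sum(fb * exp(l * fb)) / sum(exp(l * fb)),
                         c(-20, 20), tol = 1e-12)$root
  expect_equal(unname(fit$lambda), root, tolerance = 1e-4)
})

test_that("moment matching holds for linear features at r = 0", {
  set.seed(3)
  xb <- data.frame(u = rnorm(3000), v = rnorm(3000))
  keep <- with_seed(4, sample(3000, 150, prob = exp(0.7 * xb$u - 0.4 * xb$v)))
  sm <- as_samples(xb[keep, ], xb)
  fit <- maxent_fit(sm, classes = "linear", reg_multiplier = 0, tol = 1e-9)
  Fm <- feature_matrix(fit$features, sm$x)
  w <- predict(fit, sm$x[sm$label == 0, ], type = "raw")
  fitted_means <- as.numeric(crossprod(Fm[sm$label == 0, ], w))
  pres_means <- colMeans(Fm[sm$label == 1, , drop = FALSE])
  expect_equal(fitted_means, unname(pres_means), tolerance = 1e-4)
})

test_that("penalty limits: huge r kills all weights; null data fits near zero", {
  set.seed(5)
  xb <- data.frame(u = rnorm(1000), v = runif(1000))
  sm <- as_samples(xb[1:80, ], xb)
  fit_inf <- maxent_fit(sm, classes = c("linear", "quadratic"),
                        reg_multiplier = 1e8)
  expect_equal(max(abs(fit_inf$lambda)), 0)
  # raw output is then uniform over the background
  raw <- predict(fit_inf, xb, type = "raw")
  expect_equal(range(raw), rep(1 / 1000, 2), tolerance = 1e-12)
  # presences drawn identically to background: lambda stays small at r = 3
  null_fit <- maxent_fit(as_samples(xb[with_seed(6, sample(1000, 100)), ], xb),
                         classes = "linear", reg_multiplier = 3)
  expect_lt(max(abs(null_fit$lambda)), 1)
  expect_lt(null_fit$convergence$objective, 0.05)
})

test_that("penalized objective is non-decreasing and convergence is recorded", {
  w <- tiny_stack(1)
  sp <- default_virtual_species()
  rec <- draw_presences(sp, w$built$stack, "summer", 60, seed = 9)
  sm <- make_samples(rec, w$built$stack, "summer", n_background = 400, seed = 9)
  fit <- maxent_fit(sm, reg_multiplier = 3)
  expect_false(is.unsorted(fit$convergence$trace))
  expect_true(is.finite(fit$convergence$final_gain))
  expect_true(fit$convergence$iterations >= 1)
})

test_that("agreement with L1-penalized logistic discrimination in the rare limit", {
  # with abundant background and a rare presence class, the maxent density
  # ratio and the logistic discriminant share the same slope
  set.seed(10)
  xb <- data.frame(u = rnorm(20000))
  keep <- sample(20000, 150, prob = exp(0.8 * xb$u))
  sm <- as_samples(xb[keep, , drop = FALSE], xb)
  fit <- maxent_fit(sm, classes = "linear", reg_multiplier = 0, tol = 1e-9)
  glm_fit <- stats::glm(c(rep(1, 150), rep(0, 20000)) ~ c(xb$u[keep], xb$u),
                        family = stats::binomial())
  # undo the feature min-max scaling to compare on the covariate scale
  span <- fit$features$defs$fmax - fit$features$defs$fmin
  expect_equal(unname(fit$lambda) / span, unname(stats::coef(glm_fit)[2]),
               tolerance = 0.05)
})

test_that("predictions: normalization, logistic transform algebra, clamping", {
  set.seed(11)
  xb <- data.frame(u = rnorm(500), v = rnorm(500))
  sm <- as_samples(xb[sample(500, 60, prob = exp(xb$u)), ], xb)
  fit <- maxent_fit(sm, classes = "linear", reg_multiplier = 1)
  raw <- predict(fit, xb, type = "raw")
  expect_equal(sum(raw), 1, tolerance = 1e-12)
  # eta = logZ - H  =>  logistic = tau = 0.5; solve for the u value that
  # brings the row to that score (linear features, so eta is affine in u)
  d <- fit$features$defs
  iu <- which(d$cov1 == "u")
  lam_u <- unname(fit$lambda[iu])
  expect_gt(lam_u, 0)
  target_eta <- fit$logZ - fit$H
  eta0 <- as.numeric(predict(fit, data.frame(u = d$fmin[iu], v = 0),
                             type = "link", clamp = FALSE))
  f_needed <- (target_eta - eta0) / lam_u
  u_val <- d$fmin[iu] + f_needed * (d$fmax[iu] - d$fmin[iu])
  expect_equal(as.numeric(predict(fit, data.frame(u = u_val, v = 0),
                                  clamp = FALSE)), 0.5, tolerance = 1e-9)
  # clamping reports how many covariate values were truncated
  far <- data.frame(u = c(100, 0), v = c(0, -100))
  p <- predict(fit, far)
  expect_equal(attr(p, "n_clamped"), 2L)
  expect_true(all(p > 0 & p < 1))
  # cumulative output is a background percentile
  cum <- predict(fit, xb, type = "cumulative")
  expect_true(all(cum >= 0 & cum <= 100))
  expect_error(predict(fit, data.frame(u = 1)), "missing")
})

test_that("non-finite covariates are reported by row and column", {
  xb <- data.frame(u = c(1, NA, 3), v = 1:3)
  # combined rows: 1 presence + 3 background; the NA sits at combined row 3
  expect_error(maxent_fit(as_samples(xb[1, , drop = FALSE], xb),
                          min_background = 1),
               "row 3, column 'u'")
})

test_that("response curves: monotone for a positive linear model, in (0,1)", {
  set.seed(12)
  xb <- data.frame(u = rnorm(800), v = rnorm(800))
  sm <- as_samples(xb[sample(800, 100, prob = exp(1.2 * xb$u)), ], xb)
  fit <- maxent_fit(sm, classes = "linear", reg_multiplier = 1)
  expect_gt(fit$lambda[["u"]], 0)
  rc <- response_curve(fit, "u")
  expect_true(all(diff(rc$logistic) > 0))
  expect_true(all(rc$logistic > 0 & rc$logistic < 1))
  expect_error(response_curve(fit, "temp"), "unknown covariate")
})

test_that("lambdas files round-trip predictions", {
  w <- tiny_stack(1)
  sp <- default_virtual_species()
  rec <- draw_presences(sp, w$built$stack, "winter", 40, seed = 13)
  sm <- make_samples(rec, w$built$stack, "winter", n_background = 300, seed = 13)
  fit <- maxent_fit(sm, reg_multiplier = 3)
  f <- withr::local_tempfile(fileext = ".lambdas")
  write_lambdas(fit, f)
  fit2 <- read_lambdas(f)
  expect_equal(unname(fit2$lambda), unname(fit$lambda), tolerance = 1e-12)
  p1 <- as.numeric(predict(fit, sm$x))
  p2 <- as.numeric(predict(fit2, sm$x))
  expect_equal(p2, p1, tolerance = 1e-10)
  rc1 <- response_curve(fit, "temp")
  rc2 <- response_curve(fit2, "temp")
  expect_equal(rc2$logistic, rc1$logistic, tolerance = 1e-10)
})
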