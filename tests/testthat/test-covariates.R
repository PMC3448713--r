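test_that("cost reclassification maps the three depth bands", {
  depth <- sea_raster(matrix(c(5, 50, 300, 150), 2, 2), 1, c(0, 2))
  cost <- reclassify_cost(depth)
  expect_equal(cost$values[1, 1], 5)    # 0-10 m
  expect_equal(cost$values[2, 1], 1)    # 10-200 m
  expect_equal(cost$values[1, 2], 10)   # > 200 m
  expect_equal(cost$values[2, 2], 1)
  # total on valid cells and deterministic (idempotent by construction)
  expect_identical(reclassify_cost(depth)$values, cost$values)
  expect_true(all(valid_values(cost) %in% c(1, 5, 10)))
  # land inside the valid mask is a mask inconsistency
  bad <- sea_raster(matrix(c(-3, 50), 1, 2), 1, c(0, 1))
  expect_error(reclassify_cost(bad), "mask inconsistency")
})

test_that("cost_distance: uniform strip geodesic and source condition", {
  cost <- sea_raster(matrix(1, 1, 11), cell_size = 2, origin = c(0, 1))
  d <- cost_distance(cost, c(1, 1))
  expect_equal(d$values[1, 1], 0)
  expect_equal(d$values[1, 11], 10 * 2)  # 10 rook steps at cost 1, cell 2 km
  expect_true(all(valid_values(d) >= 0))
})

test_that("cost_distance matches the relaxation oracle around a wall", {
  vals <- matrix(1, 5, 5)
  vals[, 3] <- 10                       # a high-cost wall
  cost <- sea_raster(vals, 1, c(0, 5))
  d <- cost_distance(cost, c(3, 1))
  expect_equal(d$values, relaxation_cost_distance(cost, c(3, 1)),
               tolerance = 1e-12)
})

test_that("cost_distance satisfies the triangle inequality on a toy grid", {
  cost <- random_cost_grid(6, 6, seed = 21)
  cells <- which(cost$valid, arr.ind = TRUE)
  picks <- cells[c(1, 10, 20), , drop = FALSE]
  fields <- lapply(seq_len(3), function(i)
    suppressWarnings(cost_distance(cost, picks[i, ])))
  dab <- fields[[1]]$values[picks[2, 1], picks[2, 2]]
  for (i in seq_len(nrow(cells))) {
    dac <- fields[[1]]$values[cells[i, 1], cells[i, 2]]
    dbc <- fields[[2]]$values[cells[i, 1], cells[i, 2]]
    if (is.finite(dac) && is.finite(dbc) && is.finite(dab))
      expect_lte(dac, dab + dbc + 1e-9)
  }
})

test_that("cost_distance flags invalid attractors and unreachable cells", {
  vals <- matrix(1, 3, 5)
  valid <- matrix(TRUE, 3, 5)
  valid[, 3] <- FALSE                   # split the strip in two
  cost <- sea_raster(vals, 1, c(0, 3), valid)
  expect_error(cost_distance(cost, c(1, 3)), "not on a valid cell")
  expect_warning(d <- cost_distance(cost, c(1, 1)), "unreachable")
  expect_true(all(is.infinite(d$values[, 4:5][valid[, 4:5]])))
})

test_that("ordinary kriging: exactness, constants, and the two-point system", {
  target <- flat_raster(8, 8)
  vg <- list(nugget = 0, psill = 2, range = 6, model = "spherical")
  pts <- data.frame(x = c(1.5, 6.5, 3.5), y = c(1.5, 6.5, 6.5),
                    value = c(3, 7, 5))
  kr <- krige_field(pts, target, variogram = vg)
  # zero nugget: prediction at a datum equals the datum
  for (i in seq_len(3)) {
    ri <- round(8 - pts$y[i] + 0.5); ci <- round(pts$x[i] + 0.5)
    expect_equal(kr$values[ri, ci], pts$value[i], tolerance = 1e-9)
  }
  # constant data: field identically that constant
  ptc <- transform(pts, value = 4.2)
  krc <- krige_field(ptc, target, variogram = vg)
  expect_equal(range(valid_values(krc)), c(4.2, 4.2), tolerance = 1e-10)

  # two points with a known variogram: closed-form ordinary kriging
  p2 <- data.frame(x = c(2.5, 5.5), y = c(4.5, 4.5), value = c(10, 20))
  gamma_sph <- function(h) ifelse(h <= 0, 0, ifelse(h < vg$range,
    vg$psill * (1.5 * h / vg$range - 0.5 * (h / vg$range)^3), vg$psill))
  kr2 <- krige_field(p2, target, variogram = vg)
  # target cell (4, 4) has centre (3.5, 4.5): solve the 3x3 system by hand
  d1 <- 1; d2 <- 2
  # with two points the OK weights are w1 = (g2 - g1)/(2*g12) + 1/2
  g12 <- gamma_sph(3)
  w1 <- (gamma_sph(d2) - gamma_sph(d1)) / (2 * g12) + 0.5
  expect_equal(kr2$values[4, 4], w1 * 10 + (1 - w1) * 20, tolerance = 1e-9)

  expect_error(krige_field(p2, target), "at least 3")
  coll <- data.frame(x = c(1, 2, 3), y = c(1, 2, 3), value = c(1, 2, 3))
  expect_error(krige_field(coll, target), "collinear")
})

test_that("variogram fitting recovers structure on dense synthetic data", {
  dom <- tiny_domain(8)
  layer <- make_seasonal_fields(dom$bathymetry, dom$latitude, "summer", 8)$temp
  pts <- coarse_points(layer, step = 3)
  vg <- fit_variogram(pts)
  expect_gt(vg$range, 0)
  expect_gte(vg$nugget, 0)
  kr <- krige_field(pts, layer, variogram = NULL)
  # interpolation from a dense subsample tracks the field
  both <- !is.na(kr$values) & !is.na(layer$values)
  expect_gt(stats::cor(kr$values[both], layer$values[both]), 0.8)
})

test_that("sample_background: counts, determinism, uniformity", {
  w <- tiny_stack(1)
  bg <- sample_background(w$built$stack, "summer", n = 300, seed = 5)
  expect_equal(nrow(bg$cells), 300)
  expect_equal(anyDuplicated(paste(bg$cells$row, bg$cells$col)), 0)
  expect_false(any(is.na(bg$covariates)))
  bg2 <- sample_background(w$built$stack, "summer", n = 300, seed = 5)
  expect_identical(bg$cells, bg2$cells)
  expect_error(sample_background(w$built$stack, "summer", n = 1e6, seed = 1),
               "valid cells")
  # empirical selection frequencies uniform on a 100-cell toy domain
  toy_depth <- sea_raster(matrix(50, 10, 10), 1, c(0, 10))
  toy_attr <- raster_like(toy_depth, matrix(1, 10, 10))
  lyr <- list(temp = toy_attr, oxygen = toy_attr, u_east = toy_attr,
              v_north = toy_attr)
  toy <- covariate_stack(toy_depth, toy_attr, toy_attr,
                         list(summer = list(avg = lyr)))
  hits <- numeric(100)
  for (s in 1:200) {
    b <- sample_background(toy, "summer", n = 20, seed = s)
    hits[(b$cells$col - 1) * 10 + b$cells$row] <-
      hits[(b$cells$col - 1) * 10 + b$cells$row] + 1
  }
  expect_gt(stats::chisq.test(hits)$p.value, 0.01)
})

test_that("match_covariates: window rule and season-restricted attraction", {
  w <- tiny_stack(1)
  stack <- w$built$stack
  vr <- which(stack$static$depth$valid, arr.ind = TRUE)
  rec <- data.frame(row = vr[1:4, 1], col = vr[1:4, 2], season = "summer",
                    year = c(2004L, 2005L, 1959L, NA))
  m <- match_covariates(rec, stack, "summer", window_years = c(2004, 2006))
  expect_named(m, c("depth", "spawn_attr", "temp", "oxygen", "u_east",
                    "v_north"))
  # in-window records take their own year's layer; the 1959 and NA records
  # take the multi-year average
  t04 <- stack$seasonal$summer[["2004"]]$temp$values[vr[1, 1], vr[1, 2]]
  tavg3 <- stack$seasonal$summer$avg$temp$values[vr[3, 1], vr[3, 2]]
  expect_equal(m$temp[1], t04)
  expect_equal(m$temp[3], tavg3)
  expect_false(isTRUE(all.equal(
    m$temp[2], stack$seasonal$summer$avg$temp$values[vr[2, 1], vr[2, 2]])))

  # winter rows carry the overwintering attraction, never the spawning one
  recw <- transform(rec, season = "winter")
  mw <- match_covariates(recw, stack, "winter")
  expect_true("winter_attr" %in% names(mw))
  expect_false("spawn_attr" %in% names(mw))
  expect_error(match_covariates(rec, stack, "winter"),
               "season being modelled")
})

test_that("make_samples assembles labelled complete rows under the season rule", {
  w <- tiny_stack(1)
  sp <- default_virtual_species()
  for (sn in c("summer", "winter")) {
    rec <- draw_presences(sp, w$built$stack, sn, 25, seed = 7)
    sm <- make_samples(rec, w$built$stack, sn, n_background = 200, seed = 7)
    expect_s3_class(sm, "sample_matrix")
    expect_equal(sum(sm$label == 1), 25)
    expect_equal(sum(sm$label == 0), 200)
    expect_false(any(is.na(sm$x)))
    an <- attraction_for_season(sn)
    expect_true(an %in% names(sm$x))
    expect_false(setdiff(c("spawn_attr", "winter_attr"), an) %in% names(sm$x))
  }
  f <- withr::local_tempfile(fileext = ".csv")
  rec <- draw_presences(sp, w$built$stack, "summer", 25, seed = 7)
  sm <- make_samples(rec, w$built$stack, "summer", n_background = 200, seed = 7)
  write_samples_csv(sm, f)
  sm2 <- read_samples_csv(f)
  expect_equal(sm2$label, sm$label)
  expect_equal(sm2$x$temp, sm$x$temp)
  expect_equal(sm2$season, "summer")
})
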