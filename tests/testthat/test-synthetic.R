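test_that("make_domain: shelf width, determinism, latitude mapping, masks", {
  cfg <- domain_config(n_rows = 200, n_cols = 60, shelf_width_km = 30, seed = 9)
  dom <- make_domain(cfg)
  # valid corridor about shelf_width cells wide per row (plus fringe/land
  # variation), within +-20% on average
  per_row <- rowSums(dom$bathymetry$valid)
  expect_gt(mean(per_row), 30 * 0.8)
  expect_lt(mean(per_row), 30 * 1.2)
  # same config twice -> bit-identical rasters
  dom2 <- make_domain(cfg)
  expect_identical(dom$bathymetry$values, dom2$bathymetry$values)
  expect_identical(dom$latitude$values, dom2$latitude$values)
  # latitude linear in row: top row = north bound, bottom = south bound
  top <- dom$latitude$values[1, dom$latitude$valid[1, ]]
  bottom <- dom$latitude$values[200, dom$latitude$valid[200, ]]
  expect_true(all(top == cfg$latitude_range[2]))
  expect_true(all(bottom == cfg$latitude_range[1]))
  # bathymetry positive-down, valid = (0, 200] plus a deeper fringe
  vv <- valid_values(dom$bathymetry)
  expect_true(all(vv > 0))
  expect_true(any(vv > 200))            # the cost-10 fringe exists
  expect_true(mean(vv <= 200) > 0.9)
  # attractors sit on valid cells
  for (a in dom$attractors)
    expect_true(dom$bathymetry$valid[a[1], a[2]])
})

test_that("make_domain rejects an attractor off the valid mask", {
  cfg <- tiny_config(1)
  cfg$attractors <- list(spawning = c(1, 1), overwintering = c(5, 20))
  expect_error(make_domain(cfg), "spawning attractor")
})

test_that("seasonal fields: latitude structure, clamps, season and year streams", {
  dom <- tiny_domain(4)
  f_w <- make_seasonal_fields(dom$bathymetry, dom$latitude, "winter", seed = 4)
  f_s <- make_seasonal_fields(dom$bathymetry, dom$latitude, "summer", seed = 4)
  # winter: northernmost 10% of rows colder than southernmost 10%
  nr <- nrow(dom$bathymetry$values)
  north <- f_w$temp$values[1:ceiling(nr / 10), ]
  south <- f_w$temp$values[(nr - ceiling(nr / 10) + 1):nr, ]
  expect_lt(mean(north, na.rm = TRUE), mean(south, na.rm = TRUE))
  # oxygen clamped to [0, 120] % saturation
  expect_true(all(valid_values(f_w$oxygen) >= 0))
  expect_true(all(valid_values(f_w$oxygen) <= 120))
  # currents small-magnitude
  expect_true(all(abs(valid_values(f_w$u_east)) <= 0.2))
  expect_true(all(abs(valid_values(f_w$v_north)) <= 0.2))
  # season enters the stream: same seed, different layers
  expect_false(identical(f_w$temp$values, f_s$temp$values))
  # year enters the stream too, but the persistent part is shared
  f04 <- make_seasonal_fields(dom$bathymetry, dom$latitude, "winter", 4, year = 2004)
  f05 <- make_seasonal_fields(dom$bathymetry, dom$latitude, "winter", 4, year = 2005)
  expect_false(identical(f04$temp$values, f05$temp$values))
  expect_gt(stats::cor(valid_values(f04$temp), valid_values(f05$temp)), 0.1)
  # determinism
  expect_identical(
    make_seasonal_fields(dom$bathymetry, dom$latitude, "winter", seed = 4)$temp$values,
    f_w$temp$values)
  expect_error(make_seasonal_fields(dom$bathymetry, dom$latitude, "monsoon", 1),
               "summer, autumn, winter, spring")
})

test_that("virtual species suitability stays in [0, 1] and respects season weights", {
  w <- tiny_stack(1)
  sp <- virtual_species(list(temp = c(1, -0.05), spawn_attr = c(-0.1, 0)),
                        season_weights = c(summer = 1, autumn = 1, winter = 1,
                                           spring = 0),
                        intercept = -2)
  suit <- suitability_by_season(sp, w$built$stack)
  for (sn in names(suit)) {
    vv <- valid_values(suit[[sn]])
    expect_true(all(vv >= 0 & vv <= 1))
  }
  # spring weight 0 turns the attraction term off: spring suitability is a
  # function of temperature only, so it differs from summer's
  expect_false(identical(suit$spring$values, suit$summer$values))
})

test_that("telemetry: uniform occupancy under a flat species", {
  w <- tiny_stack(1)
  suit <- suitability_by_season(virtual_species(), w$built$stack)  # all 0.5
  sites <- make_hydrophone_array(w$domain, 12, seed = 1)
  ev <- simulate_telemetry(virtual_species(detection_rate = 1), suit, sites,
                          months = sprintf("2004-%02d", 1:12),
                          n_tags = 100, seed = 5)
  # occupancy (distinct tag-months per site), not raw detection counts,
  # is the multinomial quantity under the flat species
  occ <- unique(data.frame(tag = ev$tag_id,
                           month = format(ev$timestamp, "%Y-%m"),
                           site = ev$hydrophone_id))
  counts <- table(factor(occ$site, levels = sites$hydrophone_id))
  expect_gt(stats::chisq.test(as.vector(counts))$p.value, 0.01)
})

test_that("telemetry degenerate cases and errors", {
  w <- tiny_stack(1)
  suit <- suitability_by_season(virtual_species(), w$built$stack)
  sites <- make_hydrophone_array(w$domain, 10, seed = 1)
  # detection_rate 0 -> no events
  ev0 <- simulate_telemetry(virtual_species(detection_rate = 0), suit, sites,
                            months = "2004-06", n_tags = 20, seed = 1)
  expect_equal(nrow(ev0), 0)
  # a site of true suitability 0 receives no events
  sp0 <- virtual_species(list(temp = c(0, 0)), intercept = -Inf)
  zero <- suitability_by_season(sp0, w$built$stack)
  expect_true(all(valid_values(zero$summer) == 0))
  ev <- simulate_telemetry(virtual_species(detection_rate = 2), zero, sites,
                           months = "2004-06", n_tags = 20, seed = 1)
  expect_equal(nrow(ev), 0)
  # hydrophone off the valid mask is named
  bad <- rbind(sites, data.frame(hydrophone_id = "HBAD", row = 1, col = 1,
                                 lon = NA, lat = NA))
  expect_error(
    simulate_telemetry(virtual_species(), suit, bad, "2004-06", 10, 1),
    "HBAD")
  # determinism
  ev1 <- simulate_telemetry(virtual_species(detection_rate = 1), suit, sites,
                            months = "2004-06", n_tags = 30, seed = 9)
  ev2 <- simulate_telemetry(virtual_species(detection_rate = 1), suit, sites,
                            months = "2004-06", n_tags = 30, seed = 9)
  expect_identical(ev1, ev2)
})

test_that("recoverability by construction: a loaded covariate separates presences", {
  # a monotone loading on one covariate must shift the presence median
  # (a symmetric niche centred at the background median would not)
  w <- tiny_stack(1)
  sp <- virtual_species(list(temp = c(1.5, 0)), intercept = -1.5 * 9)
  rec <- draw_presences(sp, w$built$stack, "summer", 150, seed = 3)
  sm <- make_samples(rec, w$built$stack, "summer", n_background = 600, seed = 3)
  mt <- median_test(list(presence = sm$x$temp[sm$label == 1],
                         background = sm$x$temp[sm$label == 0]))
  expect_lt(mt$p_value, 0.01)
})

test_that("telemetry tables round-trip through CSV", {
  w <- tiny_stack(1)
  suit <- suitability_by_season(virtual_species(), w$built$stack)
  sites <- make_hydrophone_array(w$domain, 10, seed = 1)
  ev <- simulate_telemetry(virtual_species(detection_rate = 0.5), suit, sites,
                           months = "2004-07", n_tags = 10, seed = 2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_detections_csv(ev, f1); write_sites_csv(sites, f2)
  ev2 <- read_detections_csv(f1)
  expect_equal(nrow(ev2), nrow(ev))
  expect_equal(as.numeric(ev2$timestamp), floor(as.numeric(ev$timestamp)))
  expect_equal(read_sites_csv(f2)$hydrophone_id, sites$hydrophone_id)
})
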