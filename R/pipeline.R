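#' Build the full synthetic covariate stack
#'
#' From a domain: reclassifies bathymetry into the cost surface, computes
#' the two least-cost attraction fields, generates seasonal oceanographic
#' fields per year plus their multi-year seasonal averages, and (optionally)
#' regrids each layer through ordinary kriging from a coarse point grid --
#' emulating interpolation of coarse ocean-model output onto the 1 km
#' analysis grid.
#'
#' @param domain output of [make_domain()].
#' @param seed integer master seed for the fields.
#' @param years calendar years of per-year layers (default 2004:2006).
#' @param krige_step if not NULL, stride (in cells) of the coarse point grid
#'   each layer is sampled at and kriged back from; NULL uses the generated
#'   fields directly.
#' @return list with the `covariate_stack` (`stack`), the `cost` surface and
#'   the two attraction fields.
#' @export
build_synthetic_stack <- function(domain, seed = 1, years = 2004:2006,
                                  krige_step = NULL) {
  cost <- reclassify_cost(domain$bathymetry)
  spawn_attr <- cost_distance(cost, domain$attractors$spawning)
  winter_attr <- cost_distance(cost, domain$attractors$overwintering)
  regrid <- function(r) {
    if (is.null(krige_step)) return(r)
    krige_field(coarse_points(r, krige_step), r)
  }
  seasonal <- list()
  for (sn in .SEASONS) {
    per_year <- lapply(years, function(yr)
      lapply(make_seasonal_fields(domain$bathymetry, domain$latitude, sn,
                                  seed, year = yr), regrid))
    names(per_year) <- as.character(years)
    lnames <- names(per_year[[1]])
    avg <- lapply(lnames, function(ln) {
      vals <- Reduce(`+`, lapply(per_year, function(y) y[[ln]]$values)) /
        length(per_year)
      raster_like(domain$bathymetry, vals)
    })
    names(avg) <- lnames
    seasonal[[sn]] <- c(per_year, list(avg = avg))
  }
  list(stack = covariate_stack(domain$bathymetry, spawn_attr, winter_attr,
                               seasonal),
       cost = cost, spawn_attr = spawn_attr, winter_attr = winter_attr)
}

#' A default sturgeon-like virtual species
#'
#' Thermal niche with a quadratic optimum at 9 deg C and attraction to the
#' spawning and overwintering grounds (negative linear response to
#' least-cost distance), weighted down in spring when real migrants
#' disperse from the spawning grounds. Used by [run_pipeline()] and the
#' recovery experiments.
#'
#' @param temp_opt thermal optimum, deg C.
#' @param temp_width quadratic coefficient magnitude (logit per deg C^2).
#' @param attr_slope logit decrease per cost unit of attraction distance.
#' @param detection_rate detections per day at an occupied site.
#' @param seed integer seed.
#' @export
default_virtual_species <- function(temp_opt = 9, temp_width = 1,
                                    attr_slope = 0.05, detection_rate = 2,
                                    seed = 1) {
  virtual_species(
    response_coefficients = list(
      temp = c(2 * temp_width * temp_opt, -temp_width),
      spawn_attr = c(-attr_slope, 0),
      winter_attr = c(-attr_slope, 0)),
    season_weights = c(summer = 1, autumn = 1, winter = 1, spring = 0.3),
    detection_rate = detection_rate,
    intercept = 1 - temp_width * temp_opt^2,
    seed = seed)
}

#' Per-season true-suitability layers for a species on a stack
#'
#' Builds each season's layer list from the stack's multi-year averages
#' plus depth and only that season's attraction covariate (the season rule),
#' then evaluates [true_suitability()].
#'
#' @param species a [virtual_species()].
#' @param stack a `covariate_stack`.
#' @return named list season -> suitability `sea_raster`.
#' @export
suitability_by_season <- function(species, stack) {
  out <- lapply(.SEASONS, function(sn) {
    avg <- .seasonal_layers(stack, sn, "avg")
    an <- attraction_for_season(sn)
    layers <- c(avg, list(depth = stack$static$depth))
    layers[[an]] <- stack$static[[an]]
    true_suitability(species, layers, sn)
  })
  names(out) <- .SEASONS
  out
}

#' Run the whole pipeline on a synthetic world
#'
#' Generates a domain, covariate stack, virtual species and telemetry;
#' converts detections to seasonal presence records; assembles per-season
#' presence/background sample matrices (the attraction covariate follows
#' the season rule in every row); fits and evaluates a model per season;
#' and produces the seasonal and season-averaged probability surfaces,
#' threshold maps and latitudinal profiles. Everything is a pure function
#' of `seed` and the configuration.
#'
#' @param seed master integer seed.
#' @param config a [domain_config()].
#' @param species a [virtual_species()]; default [default_virtual_species()].
#' @param months telemetry months (`"YYYY-MM"`), default Jun 2004 - May 2005.
#' @param n_tags simulated tags.
#' @param n_hydrophones array size.
#' @param n_background requested background points; capped at the valid-cell
#'   count with a message.
#' @param K cross-validation folds; reduced per season (with a message) when
#'   a season has fewer presences.
#' @param classes,hinge_knots,reg_multiplier,tol,max_iter model settings
#'   (defaults: all feature classes, regularization multiplier 3,
#'   convergence 1e-5, 10000 iterations).
#' @param years years of per-year oceanographic layers.
#' @param krige_step coarse-grid stride for kriging regrid (NULL = off).
#' @param outdir if not NULL, writes the report (CSV + JSON), presence
#'   records, per-season samples and lambdas files, surfaces (ESRI ASCII)
#'   and profiles there.
#' @return list: `domain`, `stack`, `records`, `samples`, `reports`,
#'   `table` (Table-1-shaped data.frame), `surfaces`, `thresholds`,
#'   `profiles`.
#' @export
run_pipeline <- function(seed = 1, config = domain_config(seed = seed),
                         species = default_virtual_species(seed = seed),
                         months = sprintf("%04d-%02d",
                                          rep(c(2004, 2005), c(7, 5)),
                                          c(6:12, 1:5)),
                         n_tags = 100, n_hydrophones = 80,
                         n_background = 8000, K = 10,
                         classes = c("linear", "quadratic", "product",
                                     "hinge", "threshold"),
                         hinge_knots = 5, reg_multiplier = 3,
                         tol = 1e-5, max_iter = 10000,
                         years = 2004:2006, krige_step = NULL,
                         outdir = NULL) {
  domain <- make_domain(config)
  built <- build_synthetic_stack(domain, seed = seed, years = years,
                                 krige_step = krige_step)
  stack <- built$stack
  suit <- suitability_by_season(species, stack)
  sites <- make_hydrophone_array(domain, n_hydrophones, seed = seed)
  events <- simulate_telemetry(species, suit, sites, months,
                               n_tags = n_tags, seed = seed)
  days <- detection_days(events)
  records <- aggregate_seasonal(days, sites)

  n_valid <- sum(stack$static$depth$valid)
  if (n_background > n_valid) {
    message(sprintf("capping background at the %d valid cells (requested %d)",
                    n_valid, n_background))
    n_background <- n_valid
  }

  samples <- list(); reports <- list()
  for (sn in .SEASONS) {
    rec <- records[records$season == sn, , drop = FALSE]
    if (nrow(rec) < 2) {
      warning(sprintf("season '%s' has %d presence record(s); skipped",
                      sn, nrow(rec)))
      next
    }
    sm <- make_samples(rec, stack, sn, n_background = n_background,
                       seed = seed, window_years = range(years))
    # the season rule, asserted on the emitted sample rows
    an <- attraction_for_season(sn)
    other <- setdiff(c("spawn_attr", "winter_attr"), an)
    stopifnot(an %in% names(sm$x), !other %in% names(sm$x))
    samples[[sn]] <- sm
    K_eff <- min(K, nrow(rec))
    if (K_eff < K)
      message(sprintf("season '%s': reducing K from %d to %d (presence count)",
                      sn, K, K_eff))
    reports[[sn]] <- evaluate_season(sm, K = K_eff, seed = seed,
                                     classes = classes,
                                     hinge_knots = hinge_knots,
                                     reg_multiplier = reg_multiplier,
                                     tol = tol, max_iter = max_iter)
  }
  if (!length(reports)) stop("no season had enough presences to model")

  models <- lapply(reports, function(r) r$model)
  surf <- seasonal_surface(models, stack)
  thresholds <- lapply(reports, function(r) r$threshold)
  tmap <- lapply(names(models), function(sn)
    threshold_map(surf$seasonal[[sn]], reports[[sn]]$threshold))
  names(tmap) <- names(models)
  profiles <- lapply(names(models), function(sn)
    latitudinal_profile(surf$seasonal[[sn]], domain$latitude))
  names(profiles) <- names(models)
  tab <- report_table(reports)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_report(reports, file.path(outdir, "evaluation.json"),
                 file.path(outdir, "table1.csv"))
    write_presence_csv(records, file.path(outdir, "presences.csv"))
    write_sites_csv(sites, file.path(outdir, "sites.csv"))
    write_ascii_grid(surf$average, file.path(outdir, "surface_average.asc"))
    for (sn in names(models)) {
      write_samples_csv(samples[[sn]], file.path(outdir, sprintf("samples_%s.csv", sn)))
      write_lambdas(models[[sn]], file.path(outdir, sprintf("model_%s.lambdas", sn)))
      write_ascii_grid(surf$seasonal[[sn]],
                       file.path(outdir, sprintf("surface_%s.asc", sn)))
      write_ascii_grid(tmap[[sn]], file.path(outdir, sprintf("binary_%s.asc", sn)))
    }
    write_profiles_csv(profiles, file.path(outdir, "profiles.csv"))
  }
  list(domain = domain, stack = stack, records = records, samples = samples,
       reports = reports, table = tab, surfaces = surf,
       threshold_maps = tmap, thresholds = thresholds, profiles = profiles,
       events = events, sites = sites)
}
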