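#' Configuration for a synthetic coastal domain
#'
#' Describes an idealised continental-shelf study area: a band of ocean no
#' deeper than 200 m running along one edge of the grid, with latitude mapped
#' linearly onto rows and two behavioural attractors (a spawning-river mouth
#' and an overwintering ground) placed on the shelf. This emulates the
#' geometry of a west-coast shelf corridor bounded by the 200 m isobath,
#' with the spawning attractor near 40.6 degrees N and the overwintering
#' attractor near 51 degrees N by default.
#'
#' @param n_rows,n_cols grid extent in cells (at least 50 x 20).
#' @param cell_size cell edge in km (default 1, the analysis convention).
#' @param coast which edge is land: `"east"` or `"west"`.
#' @param shelf_width_km mean cross-shore width of the 0-200 m zone.
#' @param latitude_range `(south, north)` in degrees N, mapped linearly to
#'   rows (row 1 = north).
#' @param spawn_lat,winter_lat latitudes at which the two attractors are
#'   auto-placed mid-shelf when `attractors` is NULL.
#' @param attractors optional list with elements `spawning` and
#'   `overwintering`, each `c(row, col)`; both must fall on valid cells.
#' @param correlation_length spatial correlation length of generator noise,
#'   in cells.
#' @param seed master integer seed for the domain.
#' @return a `domain_config` list.
#' @export
domain_config <- function(n_rows = 200, n_cols = 60, cell_size = 1,
                          coast = c("east", "west"),
                          shelf_width_km = 30,
                          latitude_range = c(36, 52),
                          spawn_lat = 40.6, winter_lat = 51,
                          attractors = NULL,
                          correlation_length = 10, seed = 1) {
  coast <- match.arg(coast)
  if (n_rows < 50 || n_cols < 20)
    stop("domain extent must be at least 50 x 20 cells")
  if (latitude_range[1] >= latitude_range[2])
    stop("latitude_range must be (south, north) with south < north")
  structure(list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    cell_size = cell_size, coast = coast, shelf_width_km = shelf_width_km,
    latitude_range = latitude_range, spawn_lat = spawn_lat,
    winter_lat = winter_lat, attractors = attractors,
    correlation_length = correlation_length, seed = as.integer(seed)),
    class = "domain_config")
}

#' Generate a synthetic shelf domain
#'
#' Builds bathymetry (positive-down metres, increasing smoothly offshore)
#' and a latitude raster from a [domain_config()]. The validity mask is true
#' exactly where 0 < depth <= 200 m, plus a one-cell offshore fringe deeper
#' than 200 m so that the highest-avoidance cost class is represented.
#' Output is a pure function of the configuration (including its seed).
#'
#' @param config a [domain_config()].
#' @return list with `bathymetry` and `latitude` (`sea_raster`s sharing one
#'   geometry/mask), `attractors` (list of `spawning`, `overwintering` cell
#'   coordinates), and the `config`.
#' @export
make_domain <- function(config) {
  nr <- config$n_rows; nc <- config$n_cols; cs <- config$cell_size
  # alongshore variation of shoreline position and shelf width
  shore_noise <- smooth_noise(nr, 1, config$correlation_length * 2,
                              split_seed(config$seed, "domain/shore"))[, 1]
  width_noise <- smooth_noise(nr, 1, config$correlation_length * 2,
                              split_seed(config$seed, "domain/width"))[, 1]
  land_cells <- pmax(1L, pmin(4L, 2L + round(shore_noise)))
  width_km <- pmax(5 * cs, config$shelf_width_km * (1 + 0.15 * width_noise))

  depth <- matrix(NA_real_, nr, nc)
  valid <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    shore <- nc - land_cells[i]              # last ocean column (coast east)
    if (shore < 1) next
    cols <- seq_len(shore)
    d_off <- (shore - cols + 0.5) * cs       # offshore distance, km
    z <- 200 * (d_off / width_km[i])^1.2     # depth, m (200 m at shelf edge)
    depth[i, cols] <- z
    ok <- z > 0 & z <= 200
    valid[i, cols] <- ok
    inner <- which(ok)
    if (length(inner)) {                     # one-cell fringe beyond 200 m
      fr <- min(inner) - 1L
      if (fr >= 1L && is.finite(depth[i, fr]) && depth[i, fr] > 200)
        valid[i, fr] <- TRUE
    }
  }
  if (config$coast == "west") {
    depth <- depth[, rev(seq_len(nc)), drop = FALSE]
    valid <- valid[, rev(seq_len(nc)), drop = FALSE]
  }
  bathy <- sea_raster(depth, cs, c(0, nr * cs), valid)

  lat_rng <- config$latitude_range
  lat_row <- lat_rng[2] + (seq_len(nr) - 1) / (nr - 1) * (lat_rng[1] - lat_rng[2])
  latitude <- sea_raster(matrix(lat_row, nr, nc), cs, c(0, nr * cs), valid)

  attractors <- config$attractors
  if (is.null(attractors)) {
    attractors <- list(
      spawning = .place_on_shelf(valid, lat_row, config$spawn_lat),
      overwintering = .place_on_shelf(valid, lat_row, config$winter_lat))
  }
  for (nm in c("spawning", "overwintering")) {
    a <- attractors[[nm]]
    if (is.null(a) || length(a) != 2L)
      stop(sprintf("configuration error: %s attractor missing or malformed", nm))
    if (a[1] < 1 || a[1] > nr || a[2] < 1 || a[2] > nc || !valid[a[1], a[2]])
      stop(sprintf("configuration error: %s attractor at (%d, %d) is not on a valid cell",
                   nm, a[1], a[2]))
  }
  list(bathymetry = bathy, latitude = latitude, attractors = attractors,
       config = config)
}

.place_on_shelf <- function(valid, lat_row, target_lat) {
  row <- which.min(abs(lat_row - target_lat))
  cols <- which(valid[row, ])
  if (!length(cols)) stop("no valid cells at attractor latitude")
  c(row, cols[ceiling(length(cols) / 2)])
}

.SEASONS <- c("summer", "autumn", "winter", "spring")

#' Season of a calendar month
#'
#' Seasons follow the meteorological calendar used throughout the pipeline:
#' summer = Jun-Aug, autumn = Sep-Nov, winter = Dec-Feb, spring = Mar-May.
#' The season year is the year of the season's first month, so December 2004,
#' January 2005 and February 2005 all belong to winter 2004.
#'
#' @param month integer 1-12.
#' @param year calendar year (only needed for `season_year`).
#' @return `month_season`: season label; `season_year`: integer year.
#' @export
month_season <- function(month) {
  month <- as.integer(month)
  if (any(is.na(month) | month < 1 | month > 12)) stop("month must be 1-12")
  c("winter", "winter", "spring", "spring", "spring", "summer", "summer",
    "summer", "autumn", "autumn", "autumn", "winter")[month]
}

#' @rdname month_season
#' @export
season_year <- function(month, year) {
  ifelse(as.integer(month) <= 2L, as.integer(year) - 1L, as.integer(year))
}

#' Generate seasonal near-bottom oceanographic fields
#'
#' Produces temperature (deg C), dissolved oxygen (% saturation) and
#' eastward/northward near-bottom currents (m/s) on the domain grid, with
#' the qualitative structure of a shelf circulation model: temperature
#' decreases with latitude (9-10 deg C in the south falling below 8 in the
#' north) and, in winter and spring, drops sharply north of `temp_break_lat`;
#' oxygen sits near saturation with a low-oxygen pocket at the southern
#' extreme; currents are small-magnitude with spatially correlated noise.
#' All fields are reproducible from the seed; the season label and optional
#' year enter the stream so different seasons/years differ.
#'
#' @param bathymetry,latitude rasters from [make_domain()].
#' @param season one of summer, autumn, winter, spring.
#' @param seed integer master seed.
#' @param year optional calendar year (adds inter-annual variation).
#' @param correlation_length noise correlation length in cells.
#' @param temp_break_lat latitude of the cold-water break used in winter and
#'   spring (deg N).
#' @return named list of `sea_raster`s: `temp`, `oxygen`, `u_east`,
#'   `v_north`.
#' @export
make_seasonal_fields <- function(bathymetry, latitude, season, seed,
                                 year = NULL, correlation_length = 10,
                                 temp_break_lat = 48) {
  if (!season %in% .SEASONS)
    stop(sprintf("unknown season '%s'; valid labels: %s",
                 season, paste(.SEASONS, collapse = ", ")))
  stopifnot_same_geometry(bathymetry, latitude, "bathymetry and latitude")
  nr <- nrow(bathymetry$values); nc <- ncol(bathymetry$values)
  stream <- function(what, with_year = FALSE)
    split_seed(seed, paste0("fields/", season, "/", what,
                            if (with_year) paste0("/", if (is.null(year)) "t" else year)))
  # persistent part (standing eddies, topographic steering) is shared across
  # years of one season; the transient part is re-drawn per year, so
  # multi-year seasonal averages keep most of the mesoscale structure
  noise <- function(what, sd = 1)
    sd * (0.75 * smooth_noise(nr, nc, correlation_length, stream(what)) +
          0.66 * smooth_noise(nr, nc, correlation_length, stream(what, TRUE)))

  lat <- latitude$values
  depth <- bathymetry$values
  south <- min(lat, na.rm = TRUE)

  base_t <- c(summer = 10, autumn = 9.5, winter = 9, spring = 9.5)[[season]]
  # gradients at observed magnitudes: ~2 deg C per 18 deg latitude and a
  # mild cross-shelf stratification; mesoscale noise carries the rest of
  # the variance so each covariate keeps identifiable independent variation
  temp <- base_t - 0.11 * (lat - south) - 0.003 * ifelse(is.na(depth), 0, depth)
  if (season %in% c("winter", "spring"))
    temp <- temp - 2.5 * stats::plogis((lat - temp_break_lat) / 0.6)
  # mesoscale variability (eddies, upwelling filaments) dominates the
  # deterministic gradients so each covariate keeps identifiable
  # independent variation
  temp <- temp + noise("temp", 1.0)

  oxy <- 96 - 35 * exp(-((lat - south) / 1.2)^2) + noise("oxygen", 4)
  oxy <- pmin(pmax(oxy, 0), 120)

  u_mean <- c(summer = -0.02, autumn = 0.0, winter = 0.03, spring = 0.0)[[season]]
  v_mean <- c(summer = -0.03, autumn = 0.01, winter = 0.04, spring = 0.01)[[season]]
  u <- pmin(pmax(u_mean + noise("u_east", 0.05), -0.2), 0.2)
  v <- pmin(pmax(v_mean + noise("v_north", 0.05), -0.2), 0.2)

  lapply(list(temp = temp, oxygen = oxy, u_east = u, v_north = v),
         function(m) raster_like(bathymetry, m))
}

#' Define a virtual species
#'
#' The true species-environment relationship used to simulate telemetry and
#' to score parameter recovery. Suitability at a cell is the logistic
#' transform of `intercept + sum_k w_s * (b1_k * x_k + b2_k * x_k^2)` over
#' the covariates named in `response_coefficients`; `w_s` is the
#' season-specific multiplier for attraction covariates (`spawn_attr`,
#' `winter_attr`) and 1 otherwise. The logistic keeps true suitability in
#' [0, 1] at every cell by construction.
#'
#' @param response_coefficients named list, covariate -> `c(linear, quadratic)`.
#' @param season_weights named numeric, per-season multiplier on attractor
#'   terms (default 1 for all seasons).
#' @param detection_rate expected detections per day at an occupied
#'   hydrophone.
#' @param intercept logit-scale intercept.
#' @param seed integer seed carried with the species.
#' @export
virtual_species <- function(response_coefficients = list(),
                            season_weights = c(summer = 1, autumn = 1,
                                               winter = 1, spring = 1),
                            detection_rate = 2, intercept = 0, seed = 1) {
  stopifnot(detection_rate >= 0)
  structure(list(response_coefficients = response_coefficients,
                 season_weights = season_weights,
                 detection_rate = detection_rate,
                 intercept = intercept, seed = as.integer(seed)),
            class = "virtual_species")
}

#' True suitability surface of a virtual species
#'
#' @param species a [virtual_species()].
#' @param layers named list of covariate `sea_raster`s.
#' @param season season label (selects the attractor weight).
#' @return a `sea_raster` of suitabilities in [0, 1].
#' @export
true_suitability <- function(species, layers, season = "summer") {
  template <- layers[[1]]
  logit <- matrix(species$intercept, nrow(template$values), ncol(template$values))
  for (cov in names(species$response_coefficients)) {
    if (!cov %in% names(layers)) next
    b <- species$response_coefficients[[cov]]
    b2 <- if (length(b) >= 2) b[2] else 0
    w <- if (cov %in% c("spawn_attr", "winter_attr"))
      unname(species$season_weights[season]) else 1
    if (is.na(w)) w <- 1
    x <- layers[[cov]]$values
    logit <- logit + w * (b[1] * x + b2 * x^2)
  }
  raster_like(template, stats::plogis(logit))
}

#' Lay out a synthetic hydrophone array
#'
#' Evenly spaced alongshore sites (the real array geometry is unknown, so
#' alongshore spacing is the simplest regular design); the cross-shore
#' position of each site is drawn at random over the shelf so the array
#' spans the depth range rather than pinning every site to one isobath.
#'
#' @param domain output of [make_domain()].
#' @param n number of hydrophones (>= 10).
#' @param seed integer seed for the cross-shore draw.
#' @return data.frame `hydrophone_id`, `row`, `col`, `lon`, `lat`.
#' @export
make_hydrophone_array <- function(domain, n = 40, seed = 1) {
  if (n < 10) stop("need at least 10 hydrophones")
  valid <- domain$bathymetry$valid
  rows_with <- which(rowSums(valid) > 0)
  rows <- rows_with[round(seq(1, length(rows_with), length.out = n))]
  col <- with_seed(split_seed(seed, "array"), vapply(rows, function(r) {
    cc <- which(valid[r, ])
    cc[sample.int(length(cc), 1L)]
  }, 1L))
  ll <- grid_lonlat(domain, rows, col)
  data.frame(hydrophone_id = sprintf("H%03d", seq_len(n)),
             row = rows, col = col, lon = ll$lon, lat = ll$lat,
             stringsAsFactors = FALSE)
}

#' Nominal longitude/latitude of grid cells
#'
#' Latitude comes from the domain's latitude raster; longitude is a nominal
#' affine mapping of the x coordinate at a reference meridian (the synthetic
#' world carries no projection).
#'
#' @param domain output of [make_domain()].
#' @param rows,cols cell coordinates.
#' @param lon_ref reference meridian for column 0 (deg E).
#' @export
grid_lonlat <- function(domain, rows, cols, lon_ref = -128) {
  lat <- domain$latitude$values[cbind(rows, cols)]
  x <- (cols - 0.5) * domain$latitude$cell_size
  lon <- lon_ref + x / (111.32 * cos(lat * pi / 180))
  data.frame(lon = lon, lat = lat)
}

#' Simulate acoustic telemetry from a virtual species
#'
#' Each simulated tag, in each month, occupies one hydrophone site chosen
#' with probability proportional to the true suitability at the site for
#' that month's season (or is absent when all suitabilities are zero).
#' Occupied site-months emit Poisson-distributed detection events at the
#' species' `detection_rate` per day, with timestamps uniform over the
#' month. Tags move between site-months independently: the downstream
#' pipeline consumes season-aggregated presences, not tracks, so no movement
#' kernel is modelled.
#'
#' @param species a [virtual_species()].
#' @param suitability named list: season -> `sea_raster` of true
#'   suitability (e.g. from [true_suitability()]).
#' @param hydrophones site table from [make_hydrophone_array()] (>= 10 sites
#'   on valid cells).
#' @param months character vector of months `"YYYY-MM"`.
#' @param n_tags number of simulated tags.
#' @param seed integer seed.
#' @return data.frame `tag_id`, `hydrophone_id`, `timestamp` (POSIXct, UTC).
#' @export
simulate_telemetry <- function(species, suitability, hydrophones, months,
                               n_tags = 148, seed = 1) {
  if (nrow(hydrophones) < 10) stop("need at least 10 hydrophones")
  template <- suitability[[1]]
  bad <- which(!template$valid[cbind(hydrophones$row, hydrophones$col)])
  if (length(bad))
    stop(sprintf("hydrophone(s) off the valid mask: %s",
                 paste(hydrophones$hydrophone_id[bad], collapse = ", ")))
  out <- list()
  with_seed(split_seed(seed, "telemetry"), {
    for (mo in months) {
      yr <- as.integer(substr(mo, 1, 4)); mn <- as.integer(substr(mo, 6, 7))
      sn <- month_season(mn)
      if (!sn %in% names(suitability))
        stop(sprintf("no suitability layer for season '%s'", sn))
      s <- suitability[[sn]]$values[cbind(hydrophones$row, hydrophones$col)]
      s[is.na(s)] <- 0
      t0 <- as.POSIXct(sprintf("%04d-%02d-01 00:00:00", yr, mn), tz = "UTC")
      t1 <- seq(t0, by = "1 month", length.out = 2)[2]
      span <- as.numeric(difftime(t1, t0, units = "secs"))
      ndays <- span / 86400
      if (sum(s) <= 0) next
      for (tag in seq_len(n_tags)) {
        site <- sample.int(nrow(hydrophones), 1L, prob = s)
        n_det <- stats::rpois(1L, species$detection_rate * ndays)
        if (n_det < 1) next
        ts <- t0 + sort(stats::runif(n_det, 0, span - 1))
        out[[length(out) + 1L]] <- data.frame(
          tag_id = sprintf("T%03d", tag),
          hydrophone_id = hydrophones$hydrophone_id[site],
          timestamp = ts, stringsAsFactors = FALSE)
      }
    }
  })
  if (!length(out))
    return(data.frame(tag_id = character(), hydrophone_id = character(),
                      timestamp = as.POSIXct(character(), tz = "UTC"),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Read and write telemetry tables
#'
#' Detections CSV has columns `tag_id`, `hydrophone_id`, `timestamp`
#' (ISO 8601, UTC); the site table has `hydrophone_id`, `row`, `col`,
#' `lon`, `lat`.
#'
#' @param events,sites data.frames as produced by [simulate_telemetry()] and
#'   [make_hydrophone_array()].
#' @param path file path.
#' @export
write_detections_csv <- function(events, path) {
  ev <- events
  ev$timestamp <- format(ev$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(ev, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections_csv
#' @export
read_detections_csv <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  ev$timestamp <- as.POSIXct(ev$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                             tz = "UTC")
  ev
}

#' @rdname write_detections_csv
#' @export
write_sites_csv <- function(sites, path) {
  utils::write.csv(sites, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections_csv
#' @export
read_sites_csv <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)
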