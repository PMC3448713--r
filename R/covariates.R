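#' Reclassify bathymetry into a migration cost surface
#'
#' Depths in the typical migration band (10-200 m) get the lowest traversal
#' cost 1; very shallow water (0-10 m) an intermediate avoidance cost 5;
#' water deeper than 200 m the greatest avoidance cost 10. The mapping is
#' total on valid cells and idempotent in the sense that reclassifying the
#' same bathymetry always yields the same surface.
#'
#' @param bathymetry `sea_raster`, positive-down depth in metres.
#' @return a `sea_raster` of costs in \{1, 5, 10\}.
#' @export
reclassify_cost <- function(bathymetry) {
  z <- bathymetry$values
  if (any(z[bathymetry$valid] <= 0))
    stop("valid mask inconsistency: non-positive depth inside valid mask")
  cost <- matrix(NA_real_, nrow(z), ncol(z))
  cost[bathymetry$valid & z > 0 & z <= 10] <- 5
  cost[bathymetry$valid & z > 10 & z <= 200] <- 1
  cost[bathymetry$valid & z > 200] <- 10
  raster_like(bathymetry, cost)
}

#' Accumulated least-cost distance to an attractor
#'
#' Single-source shortest accumulated cost from the attractor cell over the
#' 8-connected grid of valid cells. A step between adjacent cells costs the
#' mean of the two cells' costs times the step length (`cell_size` for
#' rook moves, `cell_size * sqrt(2)` diagonally), so the result is in cost
#' units (cost x km). The field is 0 at the attractor, non-negative
#' everywhere, and finite at every valid cell connected to it; unreachable
#' valid cells are left `Inf` and reported with a warning.
#'
#' @param cost a cost `sea_raster` from [reclassify_cost()].
#' @param attractor `c(row, col)` of the source cell (must be valid).
#' @return a `sea_raster` of accumulated costs.
#' @export
cost_distance <- function(cost, attractor) {
  nr <- nrow(cost$values); nc <- ncol(cost$values)
  if (attractor[1] < 1 || attractor[1] > nr || attractor[2] < 1 ||
      attractor[2] > nc || !cost$valid[attractor[1], attractor[2]])
    stop(sprintf("attractor at (%d, %d) is not on a valid cell",
                 attractor[1], attractor[2]))
  id <- matrix(seq_len(nr * nc), nr, nc)        # column-major cell ids
  valid <- cost$valid
  cs <- cost$cell_size

  edges <- list(); weights <- list()
  # offsets to east, south, south-east, south-west cover all 8-neighbour
  # pairs once
  offs <- list(c(0L, 1L, 1), c(1L, 0L, 1), c(1L, 1L, sqrt(2)),
               c(1L, -1L, sqrt(2)))
  for (o in offs) {
    dr <- o[1]; dc <- o[2]; len <- o[3] * cs
    r1 <- seq_len(nr - dr); c1 <- if (dc >= 0) seq_len(nc - dc) else seq(1 - dc, nc)
    a <- as.vector(id[r1, c1, drop = FALSE])
    b <- as.vector(id[r1 + dr, c1 + dc, drop = FALSE])
    ok <- valid[a] & valid[b]
    if (!any(ok)) next
    edges[[length(edges) + 1L]] <- rbind(a[ok], b[ok])
    weights[[length(weights) + 1L]] <-
      (cost$values[a[ok]] + cost$values[b[ok]]) / 2 * len
  }
  dvec <- rep(Inf, nr * nc)
  src <- id[attractor[1], attractor[2]]
  if (length(edges)) {
    el <- do.call(cbind, edges)
    g <- igraph::make_empty_graph(n = nr * nc, directed = FALSE)
    g <- igraph::add_edges(g, as.vector(el))
    igraph::E(g)$weight <- unlist(weights)
    dvec <- as.numeric(igraph::distances(g, v = src, algorithm = "dijkstra"))
  }
  dvec[src] <- 0
  d <- matrix(dvec, nr, nc)
  d[!valid] <- NA_real_
  unreach <- sum(is.infinite(d[valid]))
  if (unreach > 0)
    warning(sprintf("%d valid cell(s) unreachable from the attractor", unreach))
  raster_like(cost, d)
}

#' Fit a spherical variogram to point data
#'
#' Empirical semivariogram binned over pairwise distances (15 bins to half
#' the maximum distance), then a weighted least-squares fit of an isotropic
#' spherical model (nugget, partial sill, range) with bin pair-counts as
#' weights.
#'
#' @param points data.frame with `x`, `y`, `value`.
#' @param n_bins number of distance bins.
#' @return list `nugget`, `psill`, `range`, plus the binned empirical
#'   variogram.
#' @export
fit_variogram <- function(points, n_bins = 15) {
  n <- nrow(points)
  if (n < 3) stop("need at least 3 points to fit a variogram")
  dx <- outer(points$x, points$x, "-"); dy <- outer(points$y, points$y, "-")
  h <- sqrt(dx^2 + dy^2)[lower.tri(dx)]
  g <- (outer(points$value, points$value, "-")^2 / 2)[lower.tri(dx)]
  hmax <- max(h) / 2
  breaks <- seq(0, hmax, length.out = n_bins + 1)
  bin <- cut(h, breaks, include.lowest = TRUE)
  emp <- data.frame(
    dist = tapply(h, bin, mean),
    gamma = tapply(g, bin, mean),
    n = as.integer(table(bin)))
  emp <- emp[!is.na(emp$gamma) & emp$n > 0, ]
  if (nrow(emp) < 3) stop("too few non-empty variogram bins")
  sph <- function(h, nug, psill, rng) {
    ifelse(h <= 0, 0,
           ifelse(h < rng, nug + psill * (1.5 * h / rng - 0.5 * (h / rng)^3),
                  nug + psill))
  }
  obj <- function(par) {
    m <- sph(emp$dist, par[1], par[2], par[3])
    sum(emp$n * (emp$gamma - m)^2)
  }
  s0 <- stats::var(points$value)
  fit <- stats::optim(c(0, max(s0, 1e-8), hmax / 2), obj, method = "L-BFGS-B",
                      lower = c(0, 1e-10, max(hmax * 0.05, 1e-6)),
                      upper = c(s0 * 2 + 1e-8, s0 * 4 + 1e-6, hmax * 4))
  list(nugget = fit$par[1], psill = fit$par[2], range = fit$par[3],
       empirical = emp, model = "spherical")
}

.vgm_gamma <- function(h, vg) {
  ifelse(h <= 0, 0,
         ifelse(h < vg$range,
                vg$nugget + vg$psill * (1.5 * h / vg$range - 0.5 * (h / vg$range)^3),
                vg$nugget + vg$psill))
}

#' Ordinary kriging of scattered points onto the analysis grid
#'
#' Ordinary kriging with an isotropic spherical variogram. When `variogram`
#' is NULL the model is fitted automatically with [fit_variogram()] (which
#' requires at least 3 non-collinear points); supplying a variogram allows
#' prediction from as few as 2 points. With a zero nugget the predictor
#' interpolates the data exactly. A singular kriging system falls back to
#' inverse-distance weighting with a warning.
#'
#' @param points data.frame with `x`, `y`, `value` (km coordinates).
#' @param target a `sea_raster` supplying the prediction geometry/mask.
#' @param variogram optional list `nugget`, `psill`, `range`.
#' @return a `sea_raster` of predictions at every valid cell, with the
#'   variogram attached as attribute `"variogram"`.
#' @export
krige_field <- function(points, target, variogram = NULL) {
  points <- points[is.finite(points$value), , drop = FALSE]
  n <- nrow(points)
  if (is.null(variogram)) {
    if (n < 3) stop("need at least 3 points with finite values")
    if (qr(cbind(1, points$x, points$y))$rank < 3)
      stop("points are collinear; cannot fit a variogram")
    variogram <- fit_variogram(points)
  } else if (n < 2) stop("need at least 2 points")

  dx <- outer(points$x, points$x, "-"); dy <- outer(points$y, points$y, "-")
  G <- .vgm_gamma(sqrt(dx^2 + dy^2), variogram)
  K <- rbind(cbind(G, 1), c(rep(1, n), 0))

  vr <- which(target$valid, arr.ind = TRUE)
  cc <- cell_centers(target, vr[, 1], vr[, 2])
  D <- sqrt(outer(points$x, cc$x, "-")^2 + outer(points$y, cc$y, "-")^2)
  RHS <- rbind(.vgm_gamma(D, variogram), 1)

  pred <- tryCatch({
    W <- solve(K, RHS)
    wneg <- sum(W[seq_len(n), ] < -1e-8)
    if (wneg > 0)
      message(sprintf("kriging: %d negative weight(s) across %d predictions",
                      wneg, ncol(W)))
    as.numeric(crossprod(W[seq_len(n), , drop = FALSE], points$value))
  }, error = function(e) {
    warning("singular kriging system; falling back to inverse-distance weighting")
    w <- 1 / pmax(D, 1e-9)^2
    as.numeric(crossprod(w, points$value) / colSums(w))
  })
  vals <- matrix(NA_real_, nrow(target$values), ncol(target$values))
  vals[cbind(vr[, 1], vr[, 2])] <- pred
  out <- raster_like(target, vals)
  attr(out, "variogram") <- variogram
  out
}

#' Sample a raster at a coarse point grid
#'
#' Emulates coarse ocean-model output: picks every `step`-th valid cell and
#' returns its centre coordinates and value, ready for [krige_field()].
#'
#' @param r a `sea_raster`.
#' @param step subsampling stride in cells.
#' @export
coarse_points <- function(r, step = 8) {
  rows <- seq(1, nrow(r$values), by = step)
  cols <- seq(1, ncol(r$values), by = step)
  idx <- as.matrix(expand.grid(row = rows, col = cols))
  keep <- r$valid[idx]
  idx <- idx[keep, , drop = FALSE]
  cc <- cell_centers(r, idx[, 1], idx[, 2])
  data.frame(x = cc$x, y = cc$y, value = r$values[idx])
}

#' Assemble a covariate stack
#'
#' Aligned named layers on one grid geometry: static depth and the two
#' least-cost attraction fields, plus seasonal oceanographic layers per
#' (season, year) and multi-year seasonal averages under year key `"avg"`.
#'
#' @param depth bathymetry `sea_raster`.
#' @param spawn_attr,winter_attr attraction `sea_raster`s from
#'   [cost_distance()].
#' @param seasonal nested list: `seasonal[[season]][[year or "avg"]]` is a
#'   named list with `temp`, `oxygen`, `u_east`, `v_north`.
#' @return a `covariate_stack`.
#' @export
covariate_stack <- function(depth, spawn_attr, winter_attr, seasonal) {
  stopifnot_same_geometry(depth, spawn_attr, "depth and spawn_attr")
  stopifnot_same_geometry(depth, winter_attr, "depth and winter_attr")
  for (sn in names(seasonal))
    for (yr in names(seasonal[[sn]]))
      for (lname in names(seasonal[[sn]][[yr]]))
        stopifnot_same_geometry(depth, seasonal[[sn]][[yr]][[lname]],
                                sprintf("depth and %s/%s/%s", sn, yr, lname))
  structure(list(static = list(depth = depth, spawn_attr = spawn_attr,
                               winter_attr = winter_attr),
                 seasonal = seasonal),
            class = "covariate_stack")
}

#' Season-appropriate attraction covariate name
#'
#' The overwintering attraction is used only in the autumn and winter
#' models; the spawning attraction only in spring and summer.
#'
#' @param season season label.
#' @export
attraction_for_season <- function(season) {
  if (!season %in% .SEASONS)
    stop(sprintf("unknown season '%s'; valid labels: %s",
                 season, paste(.SEASONS, collapse = ", ")))
  if (season %in% c("autumn", "winter")) "winter_attr" else "spawn_attr"
}

.seasonal_layers <- function(stack, season, year) {
  sl <- stack$seasonal[[season]]
  if (is.null(sl)) stop(sprintf("stack has no seasonal layers for '%s'", season))
  key <- as.character(year)
  if (!is.null(sl[[key]])) return(sl[[key]])
  NULL
}

#' Match covariate values to presence records
#'
#' Records whose season-year falls inside `window_years` (and for which the
#' stack holds that year's layers) receive that season-and-year's
#' oceanographic values; records outside the window receive the multi-year
#' seasonal averages (year key `"avg"`). Depth is always attached, along
#' with exactly one attraction covariate according to the season rule
#' (overwintering for autumn/winter, spawning for spring/summer).
#'
#' @param records presence-record data.frame (needs `row`, `col`, `season`,
#'   `year`).
#' @param stack a [covariate_stack()].
#' @param season the season being modelled; all records must carry it.
#' @param window_years `c(first, last)` calendar years of the matching
#'   window.
#' @return data.frame of covariate rows, one per record, with columns
#'   `depth`, the season's attraction covariate, `temp`, `oxygen`,
#'   `u_east`, `v_north`.
#' @export
match_covariates <- function(records, stack, season,
                             window_years = c(2004, 2006)) {
  if (any(records$season != season))
    stop("all records must belong to the season being modelled")
  attr_name <- attraction_for_season(season)
  idx <- cbind(records$row, records$col)
  depth <- stack$static$depth$values[idx]
  attr_v <- stack$static[[attr_name]]$values[idx]
  n <- nrow(records)
  ocean <- matrix(NA_real_, n, 4,
                  dimnames = list(NULL, c("temp", "oxygen", "u_east", "v_north")))
  for (i in seq_len(n)) {
    yr <- records$year[i]
    use <- NULL
    if (!is.na(yr) && yr >= window_years[1] && yr <= window_years[2])
      use <- .seasonal_layers(stack, season, yr)
    if (is.null(use)) use <- .seasonal_layers(stack, season, "avg")
    if (is.null(use))
      stop(sprintf("stack has no layers for season '%s', year %s or average",
                   season, records$year[i]))
    for (lname in colnames(ocean))
      ocean[i, lname] <- use[[lname]]$values[records$row[i], records$col[i]]
  }
  out <- data.frame(depth = depth, attr_v, ocean, check.names = FALSE)
  names(out)[2] <- attr_name
  if (any(!stats::complete.cases(out)))
    stop("missing covariate values in matched rows (record off the valid mask?)")
  out
}

#' Draw background pseudo-absence cells
#'
#' A uniform random draw of valid cells without replacement, with covariates
#' attached from the multi-year seasonal averages plus the static layers and
#' the season's attraction covariate.
#'
#' @param stack a [covariate_stack()].
#' @param season season label (selects average layers and attraction).
#' @param n number of background points (default 8000).
#' @param seed integer seed.
#' @return list with `cells` (data.frame `row`, `col`) and `covariates`
#'   (data.frame as in [match_covariates()]).
#' @export
sample_background <- function(stack, season, n = 8000, seed = 1) {
  valid <- stack$static$depth$valid
  vr <- which(valid, arr.ind = TRUE)
  if (n > nrow(vr))
    stop(sprintf("requested %d background points but only %d valid cells",
                 n, nrow(vr)))
  pick <- with_seed(split_seed(seed, paste0("background/", season)),
                    sample.int(nrow(vr), n))
  cells <- data.frame(row = vr[pick, 1], col = vr[pick, 2])
  avg <- .seasonal_layers(stack, season, "avg")
  if (is.null(avg)) stop(sprintf("stack has no average layers for '%s'", season))
  attr_name <- attraction_for_season(season)
  idx <- cbind(cells$row, cells$col)
  cov <- data.frame(
    depth = stack$static$depth$values[idx],
    a = stack$static[[attr_name]]$values[idx],
    temp = avg$temp$values[idx], oxygen = avg$oxygen$values[idx],
    u_east = avg$u_east$values[idx], v_north = avg$v_north$values[idx],
    check.names = FALSE)
  names(cov)[2] <- attr_name
  list(cells = cells, covariates = cov)
}

#' Build the presence/background sample matrix for one season
#'
#' Stacks matched presence rows on top of background rows, with a presence
#' label, ready for feature expansion and model fitting. Every retained row
#' is complete; the attraction covariate follows the season rule.
#'
#' @param records presence records for the season.
#' @param stack a [covariate_stack()].
#' @param season season label.
#' @param n_background background count (default 8000).
#' @param seed integer seed for the background draw.
#' @param window_years matching window passed to [match_covariates()].
#' @return a `sample_matrix`: list with `x` (covariate data.frame),
#'   `label` (1 = presence, 0 = background), `season`, `cells`.
#' @export
make_samples <- function(records, stack, season, n_background = 8000,
                         seed = 1, window_years = c(2004, 2006)) {
  records <- records[records$season == season, , drop = FALSE]
  if (!nrow(records)) stop(sprintf("no presence records for season '%s'", season))
  pres <- match_covariates(records, stack, season, window_years)
  bg <- sample_background(stack, season, n_background, seed)
  stopifnot(identical(names(pres), names(bg$covariates)))
  x <- rbind(pres, bg$covariates)
  structure(list(
    x = x,
    label = c(rep(1L, nrow(pres)), rep(0L, nrow(bg$covariates))),
    season = season,
    cells = rbind(data.frame(row = records$row, col = records$col), bg$cells)),
    class = "sample_matrix")
}

#' @export
print.sample_matrix <- function(x, ...) {
  cat(sprintf("<sample_matrix> season %s: %d presences, %d background, covariates: %s\n",
              x$season, sum(x$label == 1), sum(x$label == 0),
              paste(names(x$x), collapse = ", ")))
  invisible(x)
}

#' Read and write sample matrices as CSV
#'
#' Header row names the covariates; a `label` column distinguishes presence
#' (1) from background (0) rows and a `season` column carries the season.
#'
#' @param samples a `sample_matrix`.
#' @param path file path.
#' @export
write_samples_csv <- function(samples, path) {
  df <- cbind(label = samples$label, season = samples$season, samples$x)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_samples_csv
#' @export
read_samples_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(list(x = df[, setdiff(names(df), c("label", "season")), drop = FALSE],
                 label = as.integer(df$label), season = df$season[1],
                 cells = NULL),
            class = "sample_matrix")
}
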