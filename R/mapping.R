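#' Project a fitted model onto the analysis grid
#'
#' Builds the covariate row of every valid cell from the stack's multi-year
#' seasonal averages, the static depth and the season's attraction layer,
#' and evaluates the model's logistic output there (clamped to the training
#' range).
#'
#' @param model a `maxent_model`.
#' @param stack a `covariate_stack`.
#' @param season season label.
#' @return a `sea_raster` of logistic probabilities of presence.
#' @export
predict_surface <- function(model, stack, season) {
  depth <- stack$static$depth
  vr <- which(depth$valid, arr.ind = TRUE)
  avg <- .seasonal_layers(stack, season, "avg")
  if (is.null(avg)) stop(sprintf("stack has no average layers for '%s'", season))
  attr_name <- attraction_for_season(season)
  idx <- cbind(vr[, 1], vr[, 2])
  df <- data.frame(
    depth = depth$values[idx],
    a = stack$static[[attr_name]]$values[idx],
    temp = avg$temp$values[idx], oxygen = avg$oxygen$values[idx],
    u_east = avg$u_east$values[idx], v_north = avg$v_north$values[idx],
    check.names = FALSE)
  names(df)[2] <- attr_name
  df <- df[, intersect(c(model$features$covariates,
                         setdiff(names(df), model$features$covariates)),
                       names(df)), drop = FALSE]
  p <- predict(model, df, type = "logistic")
  vals <- matrix(NA_real_, nrow(depth$values), ncol(depth$values))
  vals[idx] <- p
  raster_like(depth, vals)
}

#' Seasonal probability surfaces and their all-season average
#'
#' One logistic surface per season model (each season's stack view carries
#' its own attraction covariate), plus the unweighted cellwise arithmetic
#' mean across seasons.
#'
#' @param models named list of `maxent_model`s, one per season.
#' @param stack a `covariate_stack` (or named list of per-season stacks).
#' @return list with `seasonal` (named list of `sea_raster`s) and `average`.
#' @export
seasonal_surface <- function(models, stack) {
  seasons <- names(models)
  surfaces <- lapply(seasons, function(sn) {
    st <- if (inherits(stack, "covariate_stack")) stack else stack[[sn]]
    predict_surface(models[[sn]], st, sn)
  })
  names(surfaces) <- seasons
  for (sn in seasons[-1])
    stopifnot_same_geometry(surfaces[[1]], surfaces[[sn]], "seasonal surfaces")
  avg_vals <- Reduce(`+`, lapply(surfaces, function(s) s$values)) / length(surfaces)
  list(seasonal = surfaces, average = raster_like(surfaces[[1]], avg_vals))
}

#' Threshold a probability surface into a binary presence map
#'
#' @param surface logistic `sea_raster`.
#' @param threshold presence threshold in (0, 1); the boundary values 0 and
#'   1 are accepted with a message (they mark everything or nothing
#'   present).
#' @return a `sea_raster` of 0/1 (invalid cells stay invalid).
#' @export
threshold_map <- function(surface, threshold) {
  if (threshold <= 0 || threshold >= 1)
    message("boundary threshold: the map is all-present or all-absent")
  vals <- ifelse(surface$values >= threshold, 1, 0)
  raster_like(surface, vals)
}

#' Latitudinal profile of a surface or covariate layer
#'
#' Bins valid-cell values by latitude, keeps bins with at least
#' `min_cells` cells, and smooths the bin means with degree-1 locally
#' weighted regression (tricube kernel) over latitude. Constant layers are
#' preserved exactly.
#'
#' @param layer `sea_raster` of the quantity (probability or covariate).
#' @param latitude latitude `sea_raster` on the same geometry.
#' @param span loess span as a fraction of points (default 0.3).
#' @param bin_width latitude bin width in degrees (default 0.1).
#' @param min_cells minimum cells per retained bin (default 10).
#' @return data.frame `latitude`, `value` (smoothed), `raw` (bin mean),
#'   `n` (cells per bin); class `latitudinal_profile`.
#' @export
latitudinal_profile <- function(layer, latitude, span = 0.3, bin_width = 0.1,
                                min_cells = 10) {
  stopifnot_same_geometry(layer, latitude, "layer and latitude")
  ok <- layer$valid & !is.na(layer$values)
  v <- layer$values[ok]; lat <- latitude$values[ok]
  bins <- round(lat / bin_width) * bin_width
  agg <- stats::aggregate(list(raw = v), list(latitude = bins), mean)
  cnt <- stats::aggregate(list(n = v), list(latitude = bins), length)
  agg <- merge(agg, cnt, by = "latitude")
  dropped <- sum(agg$n < min_cells)
  if (dropped > 0)
    message(sprintf("latitudinal_profile: %d bin(s) below %d cells dropped",
                    dropped, min_cells))
  agg <- agg[agg$n >= min_cells, , drop = FALSE]
  agg <- agg[order(agg$latitude), , drop = FALSE]
  if (nrow(agg) >= 10 && stats::sd(agg$raw) > 0) {
    fit <- stats::loess(raw ~ latitude, data = agg, span = span, degree = 1,
                        family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    agg$value <- stats::predict(fit, agg$latitude)
  } else {
    agg$value <- agg$raw
  }
  structure(agg[, c("latitude", "value", "raw", "n")],
            class = c("latitudinal_profile", "data.frame"))
}

#' Write latitudinal profiles as CSV
#'
#' Columns `latitude`, `season`, `value`.
#'
#' @param profiles named list of `latitudinal_profile`s (name = season).
#' @param path file path.
#' @export
write_profiles_csv <- function(profiles, path) {
  df <- do.call(rbind, lapply(names(profiles), function(sn) {
    data.frame(latitude = profiles[[sn]]$latitude, season = sn,
               value = profiles[[sn]]$value)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
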