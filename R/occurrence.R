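#' Detection-days per tag, hydrophone and month
#'
#' Quantifies residence by summing the time elapsed between acoustic
#' detections in which at least two sequential detections occur at the same
#' hydrophone without an intervening detection at another hydrophone. Each
#' qualifying interval is attributed wholly to the hydrophone and to the
#' calendar month containing the interval's start; a single isolated
#' detection contributes zero time. Exact duplicate rows (same tag,
#' hydrophone and timestamp) are removed with a warning. The result is
#' invariant to input row order.
#'
#' @param events data.frame with `tag_id`, `hydrophone_id`, `timestamp`
#'   (POSIXct or ISO 8601 character).
#' @return data.frame `tag_id`, `hydrophone_id`, `month` ("YYYY-MM"),
#'   `days_present` (summed seconds / 86400).
#' @export
detection_days <- function(events) {
  empty <- data.frame(tag_id = character(), hydrophone_id = character(),
                      month = character(), days_present = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(events)) return(empty)
  ev <- events[, c("tag_id", "hydrophone_id", "timestamp")]
  if (!inherits(ev$timestamp, "POSIXct"))
    ev$timestamp <- as.POSIXct(ev$timestamp, tz = "UTC")
  dup <- duplicated(ev)
  if (any(dup)) {
    warning(sprintf("removed %d duplicate detection row(s)", sum(dup)))
    ev <- ev[!dup, ]
  }
  ev <- ev[order(ev$tag_id, ev$timestamp, ev$hydrophone_id), ]

  tag <- ev$tag_id; hyd <- ev$hydrophone_id; ts <- as.numeric(ev$timestamp)
  n <- nrow(ev)
  if (n < 2) return(empty)
  i <- seq_len(n - 1L)
  pair <- tag[i] == tag[i + 1L] & hyd[i] == hyd[i + 1L]
  if (!any(pair)) return(empty)
  start <- ev$timestamp[i][pair]
  acc <- data.frame(
    tag_id = tag[i][pair],
    hydrophone_id = hyd[i][pair],
    month = format(start, "%Y-%m", tz = "UTC"),
    secs = ts[i + 1L][pair] - ts[i][pair],
    stringsAsFactors = FALSE)
  out <- stats::aggregate(secs ~ tag_id + hydrophone_id + month, acc, sum)
  out$days_present <- out$secs / 86400
  out$secs <- NULL
  out[order(out$tag_id, out$hydrophone_id, out$month), , drop = FALSE]
}

#' Aggregate detection-days into seasonal presence records
#'
#' A hydrophone contributes one presence record per (season, year) when any
#' single tag accumulated at least `threshold_days` of residence there
#' within the season (set `per_tag = FALSE` to pool residence across tags
#' instead). Duplicates collapse: there is never more than one record per
#' hydrophone within a season. Winter spans the year boundary and is
#' labelled with the year of its December.
#'
#' @param day_table output of [detection_days()].
#' @param sites site table with `hydrophone_id`, `row`, `col`, `lon`, `lat`.
#' @param threshold_days minimum summed days of presence (default 1).
#' @param per_tag apply the threshold per tag (default) or pooled over tags.
#' @return data.frame of presence records: `hydrophone_id`, `row`, `col`,
#'   `lon`, `lat`, `season`, `year`, `month` (NA for acoustic records),
#'   `source = "acoustic"`.
#' @export
aggregate_seasonal <- function(day_table, sites, threshold_days = 1,
                               per_tag = TRUE) {
  empty <- data.frame(hydrophone_id = character(), row = integer(),
                      col = integer(), lon = numeric(), lat = numeric(),
                      season = character(), year = integer(),
                      month = integer(), source = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(day_table)) return(empty)
  missing_h <- setdiff(unique(day_table$hydrophone_id), sites$hydrophone_id)
  if (length(missing_h))
    stop(sprintf("hydrophone id(s) missing from site table: %s",
                 paste(missing_h, collapse = ", ")))
  yr <- as.integer(substr(day_table$month, 1, 4))
  mn <- as.integer(substr(day_table$month, 6, 7))
  dt <- data.frame(tag_id = day_table$tag_id,
                   hydrophone_id = day_table$hydrophone_id,
                   season = month_season(mn),
                   year = season_year(mn, yr),
                   days = day_table$days_present,
                   stringsAsFactors = FALSE)
  if (per_tag) {
    agg <- stats::aggregate(days ~ tag_id + hydrophone_id + season + year, dt, sum)
  } else {
    agg <- stats::aggregate(days ~ hydrophone_id + season + year, dt, sum)
  }
  keep <- agg[agg$days >= threshold_days,
              c("hydrophone_id", "season", "year"), drop = FALSE]
  keep <- unique(keep)
  if (!nrow(keep)) return(empty)
  idx <- match(keep$hydrophone_id, sites$hydrophone_id)
  out <- data.frame(hydrophone_id = keep$hydrophone_id,
                    row = sites$row[idx], col = sites$col[idx],
                    lon = sites$lon[idx], lat = sites$lat[idx],
                    season = keep$season, year = as.integer(keep$year),
                    month = NA_integer_, source = "acoustic",
                    stringsAsFactors = FALSE)
  out[order(out$year, out$season, out$hydrophone_id), , drop = FALSE]
}

#' Merge supplementary presence reports into the acoustic record set
#'
#' Reports from other sources carry a collection month and a location in
#' domain coordinates; each is snapped to the nearest valid cell centre
#' within `snap_radius_km` (rejected with a warning beyond it), assigned the
#' season containing its month, and appended. A report falling on a
#' (cell, season, year) already occupied by an acoustic record collapses
#' into the existing record.
#'
#' @param acoustic presence records from [aggregate_seasonal()].
#' @param reports data.frame with `x`, `y` (km, domain coordinates),
#'   `month` (1-12), `year`.
#' @param domain_raster any `sea_raster` on the analysis grid (supplies the
#'   valid mask).
#' @param snap_radius_km maximum snap distance (default 10).
#' @param lonlat optional function `(rows, cols) -> data.frame(lon, lat)`
#'   used to fill report coordinates; defaults to NA lon/lat.
#' @return combined presence-record data.frame.
#' @export
merge_reports <- function(acoustic, reports, domain_raster,
                          snap_radius_km = 10, lonlat = NULL) {
  if (is.null(reports) || !nrow(reports)) return(acoustic)
  vr <- which(domain_raster$valid, arr.ind = TRUE)
  cc <- cell_centers(domain_raster, vr[, 1], vr[, 2])
  rows <- list()
  for (i in seq_len(nrow(reports))) {
    d2 <- (cc$x - reports$x[i])^2 + (cc$y - reports$y[i])^2
    j <- which.min(d2)
    if (sqrt(d2[j]) > snap_radius_km) {
      warning(sprintf("report %d is %.1f km from the nearest valid cell; rejected",
                      i, sqrt(d2[j])))
      next
    }
    mn <- as.integer(reports$month[i])
    ll <- if (is.null(lonlat)) data.frame(lon = NA_real_, lat = NA_real_)
          else lonlat(vr[j, 1], vr[j, 2])
    rows[[length(rows) + 1L]] <- data.frame(
      hydrophone_id = NA_character_, row = vr[j, 1], col = vr[j, 2],
      lon = ll$lon, lat = ll$lat,
      season = month_season(mn),
      year = season_year(mn, reports$year[i]),
      month = mn, source = "report", stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(acoustic)
  rep_df <- do.call(rbind, rows)
  combined <- rbind(acoustic, rep_df)
  key <- paste(combined$row, combined$col, combined$season, combined$year)
  combined[!duplicated(key), , drop = FALSE]
}

#' Read and write presence-record CSVs
#'
#' Columns: `lon`, `lat`, `row`, `col`, `season`, `year`, `month`, `source`.
#'
#' @param records presence-record data.frame.
#' @param path file path.
#' @export
write_presence_csv <- function(records, path) {
  cols <- c("lon", "lat", "row", "col", "season", "year", "month", "source")
  utils::write.csv(records[, intersect(cols, names(records)), drop = FALSE],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_presence_csv
#' @export
read_presence_csv <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)
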