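# Shared fixtures: all synthetic, generated in code at test time.

tiny_config <- function(seed = 1, n_rows = 60, n_cols = 24)
  domain_config(n_rows = n_rows, n_cols = n_cols, shelf_width_km = 12,
                latitude_range = c(40, 48), spawn_lat = 42, winter_lat = 47,
                seed = seed)

tiny_domain <- function(seed = 1, ...) make_domain(tiny_config(seed = seed, ...))

# cached tiny stack (built once per test run)
.world_cache <- new.env(parent = emptyenv())
tiny_stack <- function(seed = 1) {
  key <- paste0("stack", seed)
  if (is.null(.world_cache[[key]])) {
    dom <- tiny_domain(seed)
    .world_cache[[key]] <- list(domain = dom,
                                built = build_synthetic_stack(dom, seed = seed,
                                                              years = 2004:2006))
  }
  .world_cache[[key]]
}

# presence records drawn in proportion to a species' true suitability
draw_presences <- function(species, stack, season, m, seed) {
  valid <- which(stack$static$depth$valid, arr.ind = TRUE)
  s <- suitability_by_season(species, stack)[[season]]$values[valid]
  pick <- with_seed(seed, sample(nrow(valid), m, prob = s, replace = TRUE))
  data.frame(row = valid[pick, 1], col = valid[pick, 2],
             season = season, year = NA_integer_)
}

# a small raster with every cell valid, for kriging / background tests
flat_raster <- function(n_rows = 10, n_cols = 10, cell_size = 1)
  sea_raster(matrix(1, n_rows, n_cols), cell_size, c(0, n_rows * cell_size))

# sample matrix straight from data frames
as_samples <- function(x_pres, x_bg, season = "summer") {
  structure(list(x = rbind(x_pres, x_bg),
                 label = c(rep(1L, nrow(x_pres)), rep(0L, nrow(x_bg))),
                 season = season, cells = NULL),
            class = "sample_matrix")
}

# independent single-source least-cost oracle: Bellman-Ford style value
# iteration over the 8-connected grid, run to a fixed point
relaxation_cost_distance <- function(cost, attractor) {
  nr <- nrow(cost$values); nc <- ncol(cost$values)
  d <- matrix(Inf, nr, nc)
  d[attractor[1], attractor[2]] <- 0
  cs <- cost$cell_size
  repeat {
    changed <- FALSE
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (!cost$valid[i, j]) next
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > nr || jj < 1 || jj > nc || !cost$valid[ii, jj]) next
        len <- cs * sqrt(di^2 + dj^2)
        step <- (cost$values[i, j] + cost$values[ii, jj]) / 2 * len
        if (d[ii, jj] + step < d[i, j] - 1e-12) {
          d[i, j] <- d[ii, jj] + step
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  d[!cost$valid] <- NA_real_
  d
}

# random small cost grid with a connected valid mask
random_cost_grid <- function(nr, nc, seed) {
  with_seed(seed, {
    vals <- matrix(sample(c(1, 5, 10), nr * nc, replace = TRUE,
                          prob = c(0.6, 0.2, 0.2)), nr, nc)
    valid <- matrix(stats::runif(nr * nc) < 0.85, nr, nc)
    valid[1, ] <- TRUE  # keep a connected spine along the top row
    sea_raster(vals, 1, c(0, nr), valid)
  })
}
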