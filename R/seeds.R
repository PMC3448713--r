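#' Derive a per-module random stream from a master seed
#'
#' Every stochastic generator in the package draws its seed from one master
#' integer through this splitting rule, so a whole synthetic world is a pure
#' function of a single seed. The rule hashes the stream name with a 31-ary
#' polynomial modulo the Mersenne prime 2^31 - 1 and folds in the master
#' seed; results stay inside R's 32-bit integer range.
#'
#' @param seed master integer seed.
#' @param name character stream label, e.g. `"fields/winter/2005"`.
#' @return a positive integer seed.
#' @export
split_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  p <- 2147483647
  h <- 0
  for (ch in utf8ToInt(as.character(name))) h <- (h * 31 + ch) %% p
  out <- (abs(as.numeric(seed)) %% p * 48271 + h) %% p
  as.integer(out %% (p - 2) + 1)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state, so
#' seeded draws never perturb surrounding randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Spatially correlated noise: seeded white noise blurred with a separable
# Gaussian kernel (sd = correlation_length / 2 cells), rescaled to unit sd.
smooth_noise <- function(n_rows, n_cols, correlation_length = 10, seed = 1) {
  z <- with_seed(seed, matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols))
  sigma <- max(correlation_length / 2, 0.5)
  half <- ceiling(3 * sigma)
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    idx <- c(rep(1L, half), seq_len(n), rep(n, half))  # replicate edges
    stats::filter(v[idx], k, sides = 2)[(half + 1):(half + n)]
  }
  for (j in seq_len(ncol(z))) z[, j] <- pad_conv(z[, j])
  for (i in seq_len(nrow(z))) z[i, ] <- pad_conv(z[i, ])
  s <- stats::sd(z)
  if (s > 0) z <- z / s
  z
}
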