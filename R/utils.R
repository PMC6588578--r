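# Internal helpers shared across modules.

# Validate that `x` is a single finite numeric; `what` names the field in errors.
check_scalar <- function(x, what, min = -Inf, max = Inf, allow_inf = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) ||
      (!allow_inf && !is.finite(x))) {
    stop("`", what, "` must be a single finite number", call. = FALSE)
  }
  if (x < min) stop("`", what, "` must be >= ", min, call. = FALSE)
  if (x > max) stop("`", what, "` must be <= ", max, call. = FALSE)
  invisible(x)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG stream.
# seed = NULL leaves the global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  check_scalar(seed, "rng_seed")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Wilson score confidence interval for a binomial proportion
#'
#' Closed-form Wilson score interval, the small-sample-robust interval used for
#' per-bin S-layer presence fractions across a cell population.
#'
#' @param k Number of successes (vectorized).
#' @param n Number of trials (scalar or same length as `k`).
#' @param conf Confidence level, default 0.95.
#'
#' @return A data.frame with columns `fraction` (k/n), `low`, `high`.
#'   Both bounds lie in \[0, 1\] and always bracket `fraction`.
#' @examples
#' wilson_interval(162, 162)
#' wilson_interval(1, 2)
#' @export
wilson_interval <- function(k, n, conf = 0.95) {
  if (any(n < 1) || any(k < 0) || any(k > n)) {
    stop("need 0 <= k <= n with n >= 1", call. = FALSE)
  }
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  # analytically the interval always contains p; enforce it against the
  # floating-point residual at k = 0 or k = n
  data.frame(
    fraction = p,
    low = pmin(pmax(0, centre - half), p),
    high = pmax(pmin(1, centre + half), p)
  )
}

# Otsu threshold on a numeric vector (maximizes between-class variance over a
# 256-level histogram of the value range). Returns a threshold on the original
# scale; values strictly above it are foreground.
otsu_threshold <- function(values, n_levels = 256L) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite values for thresholding", call. = FALSE)
  rng <- range(values)
  if (rng[1] == rng[2]) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_levels + 1L)
  h <- tabulate(findInterval(values, breaks, all.inside = TRUE), n_levels)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w <- cumsum(h)
  mu <- cumsum(h * mids)
  tot_w <- w[n_levels]
  tot_mu <- mu[n_levels]
  w1 <- w[-n_levels]
  w2 <- tot_w - w1
  valid <- w1 > 0 & w2 > 0
  m1 <- mu[-n_levels] / w1
  m2 <- (tot_mu - mu[-n_levels]) / w2
  bcv <- w1 * w2 * (m1 - m2)^2
  bcv[!valid] <- -Inf
  mids[which.max(bcv)]
}

# Euclidean distance from points (n x d matrix) to the segment set described by
# a polyline (m x d); returns per-point min distance and index of nearest
# polyline vertex. Used for cell-geometry rendering and axis projection.
nearest_polyline_point <- function(points, polyline) {
  np <- nrow(points)
  m <- nrow(polyline)
  best_d2 <- rep(Inf, np)
  best_i <- rep(1L, np)
  # chunk over polyline vertices to bound memory
  step <- max(1L, floor(5e6 / np))
  for (start in seq(1L, m, by = step)) {
    idx <- start:min(m, start + step - 1L)
    d2 <- outer(points[, 1], polyline[idx, 1], "-")^2
    for (d in 2:ncol(points)) {
      d2 <- d2 + outer(points[, d], polyline[idx, d], "-")^2
    }
    j <- max.col(-d2, ties.method = "first")
    v <- d2[cbind(seq_len(np), j)]
    upd <- v < best_d2
    best_d2[upd] <- v[upd]
    best_i[upd] <- idx[j[upd]]
  }
  list(dist = sqrt(best_d2), index = best_i)
}
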