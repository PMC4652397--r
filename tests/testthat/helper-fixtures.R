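# Shared fixtures: small generator configurations and hand-built datasets.

# A desk-scale study: ~250 units, a handful of measured units per class.
small_config <- function(seed = 101, ...) {
  args <- utils::modifyList(
    list(n_parent_areas = 100, mean_units_per_parent = 2.5,
         deaths_per_unit_year = 2, n_health_areas = 10, seed = seed),
    list(...))
  do.call(generator_config, args)
}

# Binary classification data with one informative continuous covariate.
# `flip` is the label noise rate; `prevalence` the high-class fraction.
make_separable <- function(n, prevalence = 0.5, flip = 0, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  cut <- quantile(x, 1 - prevalence)
  y <- ifelse(x >= cut, "high", "low")
  if (flip > 0) {
    swap <- runif(n) < flip
    y[swap] <- ifelse(y[swap] == "high", "low", "high")
  }
  list(x = data.frame(x1 = x, x2 = rnorm(n)), y = y)
}

# Brute-force 95th percentile: sort and interpolate at h = (n-1)p + 1.
oracle_p95 <- function(values, p = 0.95) {
  s <- sort(values)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(s[n])
  s[lo] + (h - lo) * (s[lo + 1] - s[lo])
}

# Brute-force Geary's c by explicit double loop.
oracle_geary <- function(x, w) {
  n <- length(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + w[i, j] * (x[i] - x[j])^2
  (n - 1) * num / (2 * sum(w) * sum((x - mean(x))^2))
}

# Brute-force tricube local polynomial fit at each x, solving the normal
# equations directly.
oracle_loess <- function(x, y, span, degree) {
  n <- length(x)
  q0 <- max(ceiling(span * n), degree + 1)
  sapply(x, function(x0) {
    d <- abs(x - x0)
    ord <- order(d)
    q <- q0
    repeat {
      nb <- ord[seq_len(q)]
      dmax <- max(d[nb])
      w <- if (dmax == 0) rep(1, q) else (1 - pmin(1, d[nb] / dmax)^3)^3
      if (sum(w > 0) >= degree + 1 || q >= n) break
      q <- q + 1
    }
    X <- outer(x[nb] - x0, 0:degree, `^`)
    beta <- solve(t(X) %*% (w * X), t(X) %*% (w * y[nb]))
    beta[1]
  })
}
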