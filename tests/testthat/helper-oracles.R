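# Independent oracles and small fixture builders used across test files.
# Each oracle is a deliberately naive implementation kept independent of
# the package code path it checks.

# Closed-form normal equations for simple linear regression y ~ x.
oracle_normal_equations <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  c(slope = slope, intercept = intercept)
}

# Brute-force lagged Pearson: direct sums at each lag on the overlap.
oracle_lagged_pearson <- function(x, y, fs, max_lag_s) {
  n <- length(x)
  L <- round(max_lag_s * fs)
  best_r <- 0; best_lag <- 0
  r_by_lag <- numeric(0)
  for (k in -L:L) {
    if (k >= 0) { xs <- x[1:(n - k)]; ys <- y[(1 + k):n] }
    else { xs <- x[(1 - k):n]; ys <- y[1:(n + k)] }
    m <- length(xs)
    mx <- sum(xs) / m; my <- sum(ys) / m
    num <- sum((xs - mx) * (ys - my))
    den <- sqrt(sum((xs - mx)^2) * sum((ys - my)^2))
    r <- num / den
    r_by_lag <- c(r_by_lag, r)
    if (abs(r) > abs(best_r)) { best_r <- r; best_lag <- k }
  }
  list(r_by_lag = r_by_lag, best_r = best_r, best_lag_s = best_lag / fs)
}

# Two-sided Fisher exact p by enumeration of all 2x2 tables with the
# observed margins, summing hypergeometric probabilities <= observed.
oracle_fisher_2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- c_ + d; k <- a + c_
  probs <- vapply(max(0, k - n):min(k, m), function(x) {
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k))
  }, numeric(1))
  p_obs <- exp(lchoose(m, a) + lchoose(n, k - a) - lchoose(m + n, k))
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# A session whose 465 channel is an exact affine map of the 405 plus an
# optional added signal, for isosbestic-fit checks.
make_affine_session <- function(n = 2000, fs = 100, slope = 3, intercept = 2,
                                signal = 0, noise = 0, seed = 1) {
  set.seed(seed)
  t <- (seq_len(n) - 1) / fs
  f405 <- 50 + 5 * sin(2 * pi * 0.01 * t) + rnorm(n, sd = noise)
  f465 <- slope * f405 + intercept + signal + rnorm(n, sd = noise)
  photometry_session(t, f465, f405, fs = fs)
}

# Trapezoidal speed profile evaluated on a grid: rises from `base` at
# `onset`, plateau of `peak` until `offset`, falls back over `ramp`.
trapezoid_speed <- function(t, onset, offset, peak, base = 0.5, ramp = 1) {
  v <- rep(base, length(t))
  ris <- t >= onset & t < onset + ramp
  v[ris] <- base + (peak - base) * (t[ris] - onset) / ramp
  v[t >= onset + ramp & t <= offset] <- peak
  fal <- t > offset & t < offset + ramp
  v[fal] <- peak - (peak - base) * (t[fal] - offset) / ramp
  v
}

# Bandlimited broadband noise (smoothed white noise) for surrogate tests.
broadband <- function(n, fs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  moving_average(rnorm(n), fs, 0.25)
}
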