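# Event alignment, peri-event metrics, lagged correlation and the
# phase-randomized surrogate machinery.

make_trace <- function(x, fs = 100, t0 = 0) {
  structure(list(time_s = t0 + (seq_along(x) - 1) / fs, z = x, fs = fs),
            class = "dff_trace")
}

test_that("alignment slices, baselines and drops edge events correctly", {
  fs <- 100
  x <- sin(2 * pi * 0.2 * (0:5999) / fs)
  tr <- make_trace(x, fs)
  m <- align_to_events(tr, events = 30, pre_s = 2, post_s = 3)
  i0 <- 30 * fs + 1
  expect_equal(as.numeric(m$mat[1, ]), x[(i0 - 200):(i0 + 300)])

  tr2 <- make_trace(rep(4, 2000), fs)
  m2 <- align_to_events(tr2, events = c(5, 10), pre_s = 2, post_s = 2,
                        baseline_window = c(-2, -1))
  expect_true(all(m2$mat == 0))

  m3 <- align_to_events(tr, events = c(1, 30, 59.9), pre_s = 2, post_s = 3)
  expect_equal(nrow(m3$mat), 1)
  expect_equal(m3$dropped, c(1, 59.9))

  # baseline-normalized rows have exactly zero mean over the baseline span
  set.seed(1)
  tr3 <- make_trace(rnorm(4000), fs)
  m4 <- align_to_events(tr3, events = c(10, 20), pre_s = 5, post_s = 5,
                        baseline_window = c(-5, -1))
  bsel <- m4$t_rel >= -5 & m4$t_rel <= -1
  expect_equal(rowMeans(m4$mat[, bsel]), c(0, 0), tolerance = 1e-13)

  expect_error(align_to_events(tr, events = -100, pre_s = 2, post_s = 2),
               class = "empty_matrix")
})

test_that("post-event extremum finds the nearest interior extremum", {
  fs <- 100
  t <- (0:1099) / fs
  row <- exp(-((t - 6)^2) / 0.1)   # event at 5 s, bump peaks at +1 s
  tr <- make_trace(row, fs)
  m <- align_to_events(tr, events = 5, pre_s = 2, post_s = 5)
  ex <- post_event_extremum(m, c(0, 5), mode = "max")
  expect_equal(ex$latency_s, 1, tolerance = 2 / fs)
  expect_false(ex$boundary)

  trm <- make_trace(-row, fs)
  mm <- align_to_events(trm, events = 5, pre_s = 2, post_s = 5)
  exm <- post_event_extremum(mm, c(0, 5), mode = "min")
  expect_equal(exm$value, -ex$value)
  expect_equal(exm$latency_s, ex$latency_s)

  mono <- make_trace(seq(0, 1, length.out = 1100), fs)
  mo <- align_to_events(mono, events = 5, pre_s = 1, post_s = 3)
  exo <- post_event_extremum(mo, c(0, 3), mode = "max")
  expect_true(exo$boundary)
})

test_that("amplitude change under the bout and opto rules", {
  fs <- 100
  flat <- make_trace(rep(2, 3000), fs)
  expect_equal(amplitude_change(flat, 5, 15, rule = "opto")$delta, 0)
  expect_equal(amplitude_change(flat, 5, 15, rule = "bout")$delta, 0)

  ramp <- make_trace(seq(0, 6, length.out = 3001), fs)  # +2 z per 10 s
  d <- amplitude_change(ramp, 10, 20, rule = "opto")
  expect_equal(d$delta, 2, tolerance = 1e-6)

  # constructed onset-dip / offset-peak transients: bout delta ~ amplitude
  t <- (0:2999) / fs
  sig <- -1.5 * exp(-((t - 10.5)^2) / 0.2) + 2.5 * exp(-((t - 20.5)^2) / 0.2)
  tr <- make_trace(sig, fs)
  db <- amplitude_change(tr, 10, 20, rule = "bout")
  expect_equal(db$delta, 4, tolerance = 0.05 * 4)

  out <- amplitude_change(ramp, c(10, -50), c(20, -40), rule = "opto")
  expect_equal(attr(out, "dropped"), 2L)
})

test_that("duration correlation: perfect, independent and insufficient cases", {
  d <- duration_correlation(c(1, 2, 3.5, 5), c(1, 2, 3.5, 5))
  expect_equal(d$r, 1)
  set.seed(2)
  di <- duration_correlation(runif(1001, 1, 3), runif(1001, 1, 3),
                             as_durations = TRUE)
  expect_lt(abs(di$r), 0.1)
  expect_error(duration_correlation(c(1, 2), c(1, 2)),
               class = "insufficient_data")
})

test_that("lagged Pearson: identity, known delay, oracle equivalence, antisymmetry", {
  set.seed(3)
  fs <- 50
  x <- broadband(800, fs)
  self <- lagged_pearson(x, x, fs, max_lag_s = 1)
  expect_equal(self$best_r, 1)
  expect_equal(self$best_lag_s, 0)

  k <- 12
  y <- c(rep(0, k), x[1:(length(x) - k)])  # y lags x by k samples
  del <- lagged_pearson(x, y, fs, max_lag_s = 1)
  expect_equal(del$best_lag_s, k / fs)
  expect_gt(del$best_r, 0.999)

  xn <- rnorm(400); yn <- rnorm(400)
  mine <- lagged_pearson(xn, yn, fs, max_lag_s = 0.8)
  oracle <- oracle_lagged_pearson(xn, yn, fs, max_lag_s = 0.8)
  expect_equal(mine$r_by_lag, oracle$r_by_lag, tolerance = 1e-12)
  expect_equal(mine$best_r, oracle$best_r, tolerance = 1e-12)
  expect_equal(mine$best_lag_s, oracle$best_lag_s)

  swap <- lagged_pearson(yn, xn, fs, max_lag_s = 0.8)
  expect_equal(swap$best_lag_s, -mine$best_lag_s)
  expect_error(lagged_pearson(rep(1, 100), rnorm(100), fs, 0.2),
               class = "undefined_correlation")
})

test_that("phase shuffling preserves spectrum, mean, power and autocorrelation", {
  for (n in c(256, 255)) {   # even and odd lengths
    set.seed(10 + n)
    x <- as.numeric(arima.sim(list(ar = 0.9), n))
    set.seed(99)
    s <- phase_shuffle(x)
    expect_equal(Mod(fft(s)), Mod(fft(x)), tolerance = 1e-9)
    expect_equal(mean(s), mean(x), tolerance = 1e-12)
    expect_equal(sum(s^2), sum(x^2), tolerance = 1e-9 * sum(x^2))
    # Wiener-Khinchin: circular autocorrelation depends only on |FFT|^2
    ac <- function(v) Re(fft(Mod(fft(v))^2, inverse = TRUE)) / length(v)
    expect_equal(ac(s), ac(x), tolerance = 1e-9 * max(abs(ac(x))))
    expect_false(isTRUE(all.equal(s, x)))
  }
  expect_error(phase_shuffle(c(1, 2)), class = "invalid_config")
})

test_that("surrogate test separates identical pairs and is seed-deterministic", {
  fs <- 20
  set.seed(4)
  xs <- lapply(1:4, function(i) broadband(400, fs))
  res <- shuffle_correlation_test(xs, xs, fs, n_shuffle = 40, max_lag_s = 1)
  expect_true(all(res$real_values == 1))
  expect_true(all(res$real_values >= max(res$surrogate_values)))
  expect_lt(res$p_value, 0.01)
  expect_length(res$surrogate_values, 40)

  set.seed(7)
  a <- shuffle_correlation_test(xs, xs, fs, n_shuffle = 20)
  set.seed(7)
  b <- shuffle_correlation_test(xs, xs, fs, n_shuffle = 20)
  expect_identical(a$p_value, b$p_value)
  expect_identical(a$surrogate_values, b$surrogate_values)
  expect_error(shuffle_correlation_test(xs, xs, fs, n_shuffle = 0),
               class = "invalid_config")
})

test_that("epoch correlation recovers noise-dependent ordering and skips degenerate epochs", {
  fs <- 25
  n <- 3000
  epochs <- list(pre = c(0, 40), during = c(40, 80), post = c(80, 120))
  ord_ok <- vapply(1:20, function(s) {
    set.seed(s)
    src <- broadband(n, fs)
    t_idx <- (seq_len(n) - 1) / fs
    noise_sd <- ifelse(t_idx >= 40 & t_idx < 80, 1.5, 0.2)
    x <- make_trace(src + rnorm(n, sd = noise_sd), fs)
    y <- make_trace(src + rnorm(n, sd = noise_sd), fs)
    r <- epoch_correlation(x, y, epochs, max_lag_s = 1)
    r$best_r[r$epoch == "during"] < min(r$best_r[r$epoch != "during"])
  }, logical(1))
  expect_true(all(ord_ok))

  x2 <- make_trace(c(rep(1, 500), broadband(500, fs)), fs)
  y2 <- make_trace(c(rep(1, 500), broadband(500, fs, seed = 1)), fs)
  suppressMessages(
    r2 <- epoch_correlation(x2, y2, list(flat = c(0, 19.9), ok = c(20, 39)),
                            max_lag_s = 0.5))
  expect_false("flat" %in% r2$epoch)
  expect_true("ok" %in% r2$epoch)

  ident <- make_trace(broadband(1000, fs, seed = 2), fs)
  r3 <- epoch_correlation(ident, ident, list(a = c(0, 20), b = c(20, 39)))
  expect_equal(r3$best_r, c(1, 1))
})
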