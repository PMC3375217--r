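test_that("first-spike histogram normalises by trial count", {
  # 10 trials, 7 with the first spike in [50, 60), 3 spikeless
  trials <- data.frame(trial_id = 1:10, orientation = 0, stim_onset = 0,
                       stim_duration = 300, trial_length = 800)
  spikes <- data.frame(trial_id = 1:7, unit_id = 1,
                       t_ms = seq(50, 59, length.out = 7))
  rec <- latwta:::new_recording(spikes, trials,
                                data.frame(unit_id = 1))
  d <- estimate_nth_spike_distribution(rec, 1)
  b <- findInterval(50, d$edges)
  expect_equal(unname(d$f[1, b]), 0.7)
  expect_equal(sum(d$f), 0.7)
  expect_equal(max(d$F), 0.7)
  # all spikeless
  rec$spikes <- spikes[0, ]
  d0 <- estimate_nth_spike_distribution(rec, 1)
  expect_true(all(d0$f == 0) && all(d0$F == 0))
  expect_true(is.na(level_curve(d0)[1]))
})

test_that("cumulative of Poisson first spikes matches the exponential law", {
  lam <- 20
  units <- unit_row(1, A = 0, B = 0, phi = 0, rmax = 0, kappa = 0,
                    lam = lam)
  cfg <- generator_config(n_units = 1, orientations = 0,
                          repetitions = 1000, stim_duration = 300,
                          units = units, seed = 21)
  rec <- generate_population(cfg)
  d <- estimate_nth_spike_distribution(rec, 1)
  analytic <- 1 - exp(-lam / 1000 * d$edges[-1])
  se <- sqrt(analytic * (1 - analytic) / 1000)
  expect_true(all(abs(d$F[1, ] - analytic) < 3 * pmax(se, 1e-3)))
  # median of the exponential
  expect_lt(abs(level_curve(d)[1] - log(2) / (lam / 1000)), 3)
})

test_that("level curve interpolates linearly inside the crossing bin", {
  f <- matrix(0, 1, 40)
  f[1, 7] <- 1  # all mass in [60, 70)
  d <- structure(list(n = 1, bin_ms = 10, edges = seq(0, 400, 10),
                      orientations = 0, f = f,
                      F = t(apply(f, 1, cumsum)), K = 10),
                 class = "nth_spike_distribution")
  expect_equal(unname(level_curve(d, 0.5)[1]), 65)
  # level above total mass -> undefined
  d$f[1, 7] <- 0.4
  d$F <- t(apply(d$f, 1, cumsum))
  expect_true(is.na(level_curve(d, 0.5)[1]))
})

test_that("SEM bounds bracket the level curve and use sqrt(F(1-F)/K)", {
  f <- matrix(0, 1, 40)
  f[1, 5] <- 0.5; f[1, 9] <- 0.5
  d <- structure(list(n = 1, bin_ms = 10, edges = seq(0, 400, 10),
                      orientations = 0, f = f,
                      F = t(apply(f, 1, cumsum)), K = 100),
                 class = "nth_spike_distribution")
  # F = 0.5 at the crossing bin: SEM = sqrt(0.25/100) = 0.05 exactly there
  Fv <- d$F[1, ]
  b <- latwta:::level_cross(pmin(Fv + sqrt(Fv * (1 - Fv) / 100), 1),
                            d$edges, 0.5)
  bounds <- latency_sem_bounds(d)
  expect_equal(bounds$lower[1], b)
  expect_true(bounds$lower[1] <= bounds$latency[1])
  expect_true(bounds$latency[1] <= bounds$upper[1])
  # degenerate 0/1 cumulative: bounds collapse onto the point estimate
  f2 <- matrix(0, 1, 40); f2[1, 7] <- 1
  d2 <- d; d2$f <- f2; d2$F <- t(apply(f2, 1, cumsum))
  b2 <- latency_sem_bounds(d2)
  expect_equal(b2$lower[1], b2$latency[1])
  expect_equal(b2$upper[1], b2$latency[1])
})

test_that("cosine fit recovers exact in-span samples and flags constants", {
  th <- seq(0, 157.5, by = 22.5)
  y <- 80 - 20 * cos(2 * (th - 45) * pi / 180)
  fit <- fit_cosine(th, y)
  expect_equal(fit$A, 80, tolerance = 1e-10)
  expect_equal(fit$B, 20, tolerance = 1e-10)
  expect_equal(fit$phi, 45, tolerance = 1e-8)
  flat <- fit_cosine(th, rep(70, 8))
  expect_equal(flat$A, 70, tolerance = 1e-10)
  expect_equal(flat$B, 0, tolerance = 1e-10)
  expect_true(is.na(flat$phi))
  expect_false(fit_cosine(th[1:2], y[1:2])$ok)
  # NA latencies are dropped, not imputed
  y2 <- y; y2[3] <- NA
  expect_equal(fit_cosine(th, y2)$B, 20, tolerance = 1e-8)
})

test_that("noisy cosine fit agrees with a dense grid-search oracle", {
  set.seed(99)
  th <- seq(0, 157.5, by = 22.5)
  truth <- list(A = 75, B = 18, phi = 110)
  y <- truth$A - truth$B * cos(2 * (th - truth$phi) * pi / 180) +
    rnorm(8, 0, 3)
  fit <- fit_cosine(th, y)
  # oracle: exhaustive search over phi with closed-form A, B per phi;
  # a negative amplitude means the true optimum sits at phi + 90
  grid <- seq(0, 179.9, by = 0.1)
  fits <- vapply(grid, function(p) {
    x <- -cos(2 * (th - p) * pi / 180)
    cf <- coef(lm(y ~ x))
    c(sum((y - cf[1] - cf[2] * x)^2), cf[2])
  }, numeric(2))
  k <- which.min(fits[1, ])
  best <- if (fits[2, k] >= 0) grid[k] else (grid[k] + 90) %% 180
  d <- abs(((fit$phi - best + 90) %% 180) - 90)
  expect_lt(d, 1)  # same optimum up to grid resolution
})

test_that("von-Mises fit recovers parameters and flags flat curves", {
  th <- seq(0, 175, by = 5)
  truth <- c(base = 4, amp = 30, kappa = 2, phi = 60)
  r <- truth["base"] + truth["amp"] *
    exp(truth["kappa"] * (cos(2 * (th - truth["phi"]) * pi / 180) - 1))
  fit <- fit_von_mises(th, r)
  expect_equal(fit$base, 4, tolerance = 1e-3)
  expect_equal(fit$amp, 30, tolerance = 1e-3)
  expect_equal(fit$kappa, 2, tolerance = 1e-3)
  expect_equal(fit$phi, 60, tolerance = 0.1)
  flat <- fit_von_mises(seq(0, 157.5, 22.5), rep(12, 8))
  expect_true(flat$degenerate)
})

test_that("von-Mises preferred orientation matches a grid oracle", {
  set.seed(4)
  th <- seq(0, 157.5, by = 22.5)
  r <- 5 + 25 * exp(1.5 * (cos(2 * (th - 93) * pi / 180) - 1)) +
    rnorm(8, 0, 1)
  fit <- fit_von_mises(th, r)
  d <- abs(((fit$phi - 93 + 90) %% 180) - 90)
  expect_lt(d, 22.5)  # within one orientation step
})

test_that("PSTH half-max latency follows the interpolation contract", {
  # 0 until 60 ms then constant 50 spikes/s
  p <- data.frame(time = seq(5, 395, 10),
                  rate = ifelse(seq(5, 395, 10) > 60, 50, 0))
  expect_equal(halfmax_latency(p, spont_rate = 2), 60)
  # peak below twice the spontaneous rate -> undefined
  p2 <- p; p2$rate <- p2$rate / 50 * 8
  expect_true(is.na(halfmax_latency(p2, spont_rate = 5)))
  # linear ramp 0 -> 100 over [50, 150]: half peak near 100 ms
  tt <- seq(0.5, 399.5, 1)
  ramp <- pmax(0, pmin(tt - 50, 100))
  p3 <- data.frame(time = tt, rate = ramp)
  expect_lt(abs(halfmax_latency(p3, 0) - 100), 1.1)
})

test_that("unit classification applies both thresholds", {
  units <- rbind(
    unit_row(1, A = 60, B = 10, phi = 30, rmax = 60, kappa = 0, lam = 2),
    unit_row(2, A = 80, B = 28, phi = 30, rmax = 60, kappa = 1.5, lam = 2),
    unit_row(3, A = 60, B = 10, phi = 30, rmax = 60, kappa = 0, lam = 9))
  cfg <- generator_config(n_units = 3, repetitions = 150,
                          shared_shift_sd = 0, onset_jitter_sd = 4,
                          units = units, seed = 14)
  rec <- generate_population(cfg)
  cl <- classify_units(rec)
  expect_equal(cl$label, c("onset_detector", "tuned", "other"))
  expect_lt(abs(cl$spont_rate[3] - 9), 2)
})

test_that("latency at the preferred orientation shortens with evoked rate", {
  lat <- vapply(c(20, 60, 150), function(R) {
    units <- unit_row(1, A = 70, B = 20, phi = 0, rmax = R, kappa = 1,
                      lam = 0)
    cfg <- generator_config(n_units = 1, repetitions = 300,
                            shared_shift_sd = 0, onset_jitter_sd = 3,
                            units = units, seed = 31)
    rec <- generate_population(cfg)
    d <- estimate_nth_spike_distribution(rec, 1)
    unname(level_curve(d)["0"])
  }, numeric(1))
  expect_true(all(diff(lat) < 0))
})

test_that("latency- and rate-based preferred orientations agree", {
  units <- unit_row(1, A = 80, B = 25, phi = 72, rmax = 50, kappa = 1.5,
                    lam = 1)
  cfg <- generator_config(n_units = 1, repetitions = 250,
                          shared_shift_sd = 0, onset_jitter_sd = 5,
                          units = units, seed = 8)
  rec <- generate_population(cfg)
  d <- estimate_nth_spike_distribution(rec, 1)
  fit_lat <- fit_cosine(d$orientations, level_curve(d))
  rt <- rate_tuning(rec, 1)
  fit_rate <- fit_von_mises(rt$orientation, rt$rate)
  d_pp <- abs(((fit_lat$phi - fit_rate$phi + 90) %% 180) - 90)
  expect_lt(d_pp, 22.5)
})
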