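test_that("first crossing detection: censoring, immediate crossing, boundary", {
  n_grid <- 1200
  quiet <- list(rep(0, n_grid))                    # never crosses
  ev <- first_crossing_times(quiet)
  expect_true(ev$censored)
  expect_true(is.na(ev$time_ns))

  hot <- list(c(60, rep(0, 5)))                    # crosses at the first sample
  ev2 <- first_crossing_times(hot)
  expect_false(ev2$censored)
  expect_equal(ev2$time_ns, 2.5e-3)

  # |phi| >= threshold: boundary value and negative crossing both count
  expect_equal(first_crossing_times(list(c(0, 50, 0, 0, 0, 0)))$time_ns, 5e-3)
  expect_equal(first_crossing_times(list(c(0, 0, -55, 0, 0, 0)))$time_ns, 7.5e-3)

  expect_error(first_crossing_times(list()), "empty")
  # short trace without a crossing has no defined censoring time
  expect_error(first_crossing_times(list(rep(0, 10))), "ends before")
})

test_that("generator bookkeeping matches first_crossing_times exactly", {
  s <- gen_twist_trajectories(k_per_ns = log(2) / 1.73, n_traj = 101, seed = 7)
  ev <- first_crossing_times(s$traces)
  expect_equal(ev$time_ns, s$events$time_ns)
  expect_equal(ev$censored, s$events$censored)
})

test_that("survival curve: trivial limits, closed form, order invariance", {
  s0 <- gen_twist_trajectories(k_per_ns = 0, n_traj = 20, seed = 1)
  cv0 <- survival_curve(s0$events)
  expect_true(all(cv0$A == 1))
  expect_equal(cv0$A[1], 1)

  # all cross at the first step
  ev <- first_crossing_times(lapply(1:5, function(i) c(80, rep(0, 5))))
  cv1 <- survival_curve(ev)
  expect_equal(cv1$A[1], 1)          # A(0)
  expect_true(all(cv1$A[-1] == 0))

  # Exp(k) events: A(t_j) within binomial CI of exp(-k t_j)
  k <- log(2) / 1.2
  s <- gen_twist_trajectories(k_per_ns = k, n_traj = 400,
                              emit_traces = FALSE, seed = 5)
  cv <- survival_curve(s$events)
  idx <- seq(1, length(cv$time_ns), by = 60)
  for (i in idx) {
    p <- exp(-k * cv$time_ns[i])
    ci <- qbinom(c(0.0005, 0.9995), 400, p) / 400
    expect_gte(cv$A[i], ci[1]); expect_lte(cv$A[i], ci[2])
  }
  expect_true(all(diff(cv$A) <= 0))

  # order invariance
  ev_shuf <- s$events[sample(nrow(s$events)), ]
  attr(ev_shuf, "t_max_ns") <- attr(s$events, "t_max_ns")
  attr(ev_shuf, "dt_ps") <- attr(s$events, "dt_ps")
  expect_equal(survival_curve(ev_shuf)$A, cv$A)

  ev_bad <- s$events
  attr(ev_bad, "dt_ps") <- NULL
  expect_error(survival_curve(ev_bad), "grid")
})

test_that("first-order fit recovers noiseless decay exactly and flags no-decay", {
  k <- log(2) / 5.92
  times <- c(0, seq_len(1200) * 2.5 / 1000)
  curve <- structure(list(time_ns = times, A = exp(-k * times),
                          n_total = 101, t_max_ns = 3, dt_ps = 2.5),
                     class = "survival_curve")
  fit <- fit_first_order(curve)
  expect_equal(fit$half_life_ns, 5.92, tolerance = 1e-9)
  expect_equal(fit$flag, "ok")
  expect_equal(fit$k_free_intercept, k, tolerance = 1e-9)

  flat <- structure(list(time_ns = times, A = rep(1, length(times)),
                         n_total = 101, t_max_ns = 3, dt_ps = 2.5),
                    class = "survival_curve")
  f0 <- fit_first_order(flat)
  expect_equal(f0$k_per_ns, 0)
  expect_equal(f0$flag, "no-decay")
  expect_true(is.infinite(f0$half_life_ns))
})

test_that("rate estimator is consistent: 2% relative error at n = 10^4", {
  s <- gen_twist_trajectories(k_per_ns = log(2) / 1.73, n_traj = 1e4,
                              emit_traces = FALSE, seed = 31)
  fit <- fit_first_order(survival_curve(s$events))
  expect_lt(abs(fit$half_life_ns - 1.73) / 1.73, 0.02)
})

test_that("heavily censored regime: fit unbiased within the Monte-Carlo band, with widened spread", {
  # true half-life 10.8 ns against a 3 ns window: ~83% of trajectories censored
  set.seed(17)
  est <- replicate(60, {
    s <- gen_twist_trajectories(k_per_ns = log(2) / 10.8, n_traj = 101,
                                emit_traces = FALSE)
    fit_first_order(survival_curve(s$events))$half_life_ns
  })
  band <- quantile(est, c(0.025, 0.975))
  expect_gte(10.8, band[[1]])
  expect_lte(10.8, band[[2]])
  # uncertainty is wide in this regime (documents the censoring cost)
  expect_gt(diff(band) / 10.8, 0.3)
  # a mildly censored rate is far tighter under the same protocol
  est2 <- replicate(60, {
    s <- gen_twist_trajectories(k_per_ns = log(2) / 0.25, n_traj = 101,
                                emit_traces = FALSE)
    fit_first_order(survival_curve(s$events))$half_life_ns
  })
  expect_lt(diff(quantile(est2, c(0.025, 0.975))) / 0.25,
            diff(band) / 10.8)
})

test_that("bootstrap CI brackets the point estimate and scales sensibly", {
  s <- gen_twist_trajectories(k_per_ns = log(2) / 1.73, n_traj = 101,
                              emit_traces = FALSE, seed = 23)
  fit <- fit_first_order(survival_curve(s$events))
  ci <- bootstrap_rate_ci(s$events, n_boot = 500, seed = 24)
  expect_gte(fit$half_life_ns, ci$half_life_ci[1])
  expect_lte(fit$half_life_ns, ci$half_life_ci[2])
  expect_lt(ci$half_life_ci[1], ci$half_life_ci[2])
})

test_that("rate ratios between proteins behave like the half-life inverses", {
  mk <- function(tau) {
    times <- c(0, seq_len(1200) * 2.5 / 1000)
    fit_first_order(structure(list(time_ns = times,
                                   A = exp(-log(2) / tau * times),
                                   n_total = 101, t_max_ns = 3, dt_ps = 2.5),
                              class = "survival_curve"))
  }
  # halide binding accelerates twisting ~3x (1.73 vs 0.57 ns half-lives)
  expect_equal(halide_rate_ratio(mk(0.57), mk(1.73)), 1.73 / 0.57,
               tolerance = 1e-9)
  expect_equal(halide_rate_ratio(mk(5.92), mk(5.92)), 1, tolerance = 1e-12)
  # 23-fold contrast between slow and fast twisting chromophores
  expect_equal(halide_rate_ratio(mk(0.25), mk(5.92)), 23.68, tolerance = 1e-3)
  f0 <- structure(list(k_per_ns = 0), class = "rate_fit")
  expect_error(halide_rate_ratio(mk(1), f0), "zero rate")
})
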