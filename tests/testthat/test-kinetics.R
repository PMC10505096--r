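# build a rate_series object directly from a k(t) curve (test device)
rate_series_from_k <- function(times, k, events_per_cp = NULL) {
  cum <- if (is.null(events_per_cp)) round(k * times) else
    cumsum(events_per_cp)
  structure(list(checkpoint_times = times, cumulative_events = cum,
                 k = k, dk_dt = c(NA, diff(k) / diff(times))),
            class = "rate_series")
}

test_that("constant rate: plateau from the first checkpoint", {
  tt <- seq(10, 200, by = 10)
  rs <- rate_series_from_k(tt, rep(0.5, length(tt)))
  ss <- steady_state_rate(rs)
  expect_equal(ss$k_ss, 0.5)
  expect_equal(ss$plateau_onset, 10)
  # window (10, 200]: sigma = sqrt(events inside) / duration
  expect_equal(ss$k_sigma,
               sqrt(rs$cumulative_events[20] - rs$cumulative_events[1]) /
                 190)
})

test_that("saturating k(t) = 1 - exp(-t/50): onset follows the threshold", {
  tt <- seq(10, 1000, by = 10)
  k <- 1 - exp(-tt / 50)
  cum <- k * tt                       # exact cumulative count
  rs <- structure(list(checkpoint_times = tt, cumulative_events = cum,
                       k = k, dk_dt = c(NA, diff(k) / diff(tt))),
                  class = "rate_series")
  ss <- steady_state_rate(rs, threshold = 0.004)
  # analytic onset: the derivative over the interval ending at checkpoint
  # t is exp(-(t-10)/50)(1-exp(-0.2))/10, first below 0.004 when the
  # interval starts at 80; the plateau therefore begins at checkpoint 80
  t_first_ok <- tt[min(which(exp(-tt / 50) * (1 - exp(-0.2)) / 10 < 0.004))]
  expect_equal(ss$plateau_onset, t_first_ok)
  # steady-state rate: events in the window (onset, end] over its duration
  i0 <- which(tt == t_first_ok)
  expect_equal(ss$k_ss, (cum[100] - cum[i0]) / (1000 - tt[i0]))
  expect_lt(abs(ss$k_ss - 1), 0.02)
})

test_that("persistently drifting rate raises a non-convergence error", {
  tt <- seq(10, 300, by = 10)
  rs <- rate_series_from_k(tt, 0.01 + 0.005 * tt)  # dk/dt = 0.005 always
  expect_error(steady_state_rate(rs),
               class = "permcount_nonconvergence")
  # too few checkpoints is also non-convergence
  rs2 <- rate_series_from_k(seq(10, 40, 10), rep(1, 4))
  expect_error(steady_state_rate(rs2),
               class = "permcount_nonconvergence")
})

test_that("appending plateau-consistent checkpoints leaves k_ss stable", {
  tt <- seq(10, 500, by = 10)
  k <- c(seq(0.1, 0.5, length.out = 10), rep(0.5, 40))
  rs <- rate_series_from_k(tt, k)
  ss <- steady_state_rate(rs)
  tt2 <- seq(10, 800, by = 10)
  k2 <- c(k, rep(0.5, 30))
  ss2 <- steady_state_rate(rate_series_from_k(tt2, k2))
  expect_equal(ss2$plateau_onset, ss$plateau_onset)
  expect_equal(ss2$k_ss, ss$k_ss)
})

test_that("block-averaged sigma is available as an alternative", {
  tt <- seq(10, 600, by = 10)
  set.seed(12)
  ev <- rpois(length(tt), 5)
  rs <- rate_series_from_k(tt, cumsum(ev) / tt, events_per_cp = ev)
  ss <- steady_state_rate(rs, sigma_method = "block")
  expect_gt(ss$k_sigma, 0)
})

test_that("rate-to-permeability conversion: dimensional anchor and scaling", {
  # 20 solutes in a 300 nm^3 box; k = 1/ns over A = 25 nm^2 gives
  # P = k L_z / (2 N) = 1e9 * 12e-7 cm / 40 = 30 cm/s
  C <- solute_concentration(20, 300)
  expect_equal(permeability_from_rate(1, 25, C), 30, tolerance = 1e-12)
  expect_equal(permeability_from_rate(0, 25, C), 0)
  # linear in k, inverse in A and C
  set.seed(3)
  for (i in 1:10) {
    k <- runif(1, 0, 2); a <- runif(1, 10, 50); cc <- runif(1, 1e-5, 1e-3)
    s <- runif(1, 0.5, 3)
    base <- permeability_from_rate(k, a, cc)
    expect_equal(permeability_from_rate(s * k, a, cc), s * base)
    expect_equal(permeability_from_rate(k, s * a, cc), base / s)
    expect_equal(permeability_from_rate(k, a, s * cc), base / s)
  }
  expect_error(permeability_from_rate(1, -1, C),
               class = "permcount_input_error")
  expect_error(permeability_from_rate(1, 25, 0),
               class = "permcount_input_error")
})

test_that("apparent permeability is half the single-bilayer value", {
  expect_equal(apparent_permeability(2), 1)
  expect_equal(apparent_permeability(0), 0)
  expect_equal(apparent_permeability(8.99), 4.495)
  expect_error(apparent_permeability(-1), class = "permcount_input_error")
})

test_that("permeability estimate propagates the relative rate error", {
  ss <- list(k_ss = 0.4, k_sigma = 0.04, plateau_onset = 100)
  est <- permeability_estimate(ss, temperature = 440, label = "x")
  expect_equal(est$P_sigma / est$P_sim, ss$k_sigma / ss$k_ss)
  expect_equal(est$P_sim,
               permeability_from_rate(est$k_ss, est$area_A,
                                      est$concentration_C))
  f <- tempfile(fileext = ".tsv")
  write_estimate_tsv(est, f)
  expect_equal(read.delim(f)$k_ss, 0.4)
})

test_that("steady-state estimator covers the true rate on Poisson streams", {
  set.seed(99)
  hits <- 0L
  n_rep <- 200
  rate <- 0.5; horizon <- 1000
  for (r in seq_len(n_rep)) {
    times <- cumsum(rexp(2 * rate * horizon, rate))
    times <- times[times <= horizon]
    rs <- rate_series(data.frame(end_time = times), total_time = horizon)
    ss <- steady_state_rate(rs)
    if (abs(ss$k_ss - rate) <= 2 * ss$k_sigma) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})
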