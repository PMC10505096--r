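geom_pm2 <- membrane_geometry(-1, 1, crossing_offset = 1)

test_that("membrane geometry from the lipid reference", {
  zs <- zseries(1:10, matrix(0, 10, 1), 12, 440,
                lipid_ref_z = matrix(c(-2, 2), 1))
  g <- estimate_membrane_geometry(zs)
  expect_equal(g$lower_boundary, -2)
  expect_equal(g$upper_boundary, 2)
  expect_equal(g$lower_plane, -3)

  # noisy leaflets: time-averaged boundaries within the standard error
  set.seed(4)
  n <- 400
  lip <- cbind(rnorm(n, -2, 0.05), rnorm(n, 2, 0.05))
  zs2 <- zseries(1:n, matrix(0, n, 1), 12, 440, lipid_ref_z = lip)
  g2 <- estimate_membrane_geometry(zs2)
  se <- 0.05 / sqrt(n)
  expect_lt(abs(g2$lower_boundary + 2), 4 * se)
  expect_lt(abs(g2$upper_boundary - 2), 4 * se)

  # collapsed bilayer refused
  zs3 <- zseries(1:5, matrix(0, 5, 1), 12, 440,
                 lipid_ref_z = matrix(c(-0.2, 0.2), 1))
  expect_error(estimate_membrane_geometry(zs3),
               class = "permcount_degenerate_membrane")
  zs4 <- zseries(1:5, matrix(0, 5, 1), 12, 440)
  expect_error(estimate_membrane_geometry(zs4),
               class = "permcount_geometry_error")
})

test_that("no transit is counted for a solute oscillating in one bulk", {
  z <- rep(c(-4, -3.5, -5, -2.5), 10)   # stays below the lower plane z=-2
  zs <- zseries(seq_along(z), z, 12, 440)
  ev <- detect_crossings(zs, geom_pm2)
  expect_equal(nrow(ev), 0L)
})

test_that("crafted path: five transits, three aborted entries, count = 5", {
  # each full transit goes bulk -> opposite bulk; aborted entries dip into
  # the membrane region and return to the source bulk
  transit <- function(t0, from) {
    s <- if (from < 0) 1 else -1
    data.frame(time = t0 + 0:2, z = c(from, 0, -from) * 1)
  }
  abort <- function(t0, from) {
    data.frame(time = t0 + 0:1, z = c(from, sign(from) * 0.5))
  }
  wp <- rbind(
    transit(0, -4), abort(3, 4), transit(5, 4), transit(8, -4),
    abort(11, 4), transit(13, 4), abort(16, -4), transit(18, -4),
    data.frame(time = 21, z = 4))
  traj <- crafted_trajectory(wp, box_z = 12, membrane_edge = 1, dt = 0.05)
  expect_equal(attr(traj, "true_events"), 5L)
  ev <- detect_crossings(traj, attr(traj, "geometry"))
  expect_equal(nrow(ev), 5L)
  expect_equal(brute_force_crossings(traj, attr(traj, "geometry")), 5L)
})

test_that("a transit via the periodic boundary alone is not an event", {
  wp <- data.frame(time = c(0, 1, 2, 3),
                   z = c(-4, -5.5, -6.5, -8))  # around the back of the box
                                               # (unwrapped: exits at -6)
  traj <- crafted_trajectory(wp, box_z = 12, membrane_edge = 1, dt = 0.05)
  expect_equal(attr(traj, "true_events"), 0L)
  ev <- detect_crossings(traj, attr(traj, "geometry"))
  expect_equal(nrow(ev), 0L)
})

test_that("event timestamps and directions are the scripted ones", {
  z <- c(-4, -4, -1.5, 0, 1.5, 4, 4, 1.5, -4)
  zs <- zseries(0:8, z, 12, 440)
  ev <- detect_crossings(zs, geom_pm2)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$direction, c("up", "down"))
  # up event: last in bulk at t=1, first beyond far plane at t=5
  expect_equal(ev$start_time[1], 1)
  expect_equal(ev$end_time[1], 5)
  # a solute exactly on the far plane counts as arrived (closed boundary)
  z2 <- c(-4, 0, 2, -4)
  ev2 <- detect_crossings(zseries(0:3, z2, 12, 440), geom_pm2)
  expect_equal(ev2$direction, c("up", "down"))
})

test_that("time reversal swaps directions but preserves the count", {
  set.seed(42)
  for (i in 1:20) {
    zs <- random_walk_series(n = 80, k = 2)
    ev <- detect_crossings(zs, geom_pm2)
    rev_zs <- zseries(zs$times, zs$z[rev(seq_len(n_frames(zs))), ,
                                     drop = FALSE],
                      zs$box_z, zs$temperature)
    ev_r <- detect_crossings(rev_zs, geom_pm2)
    expect_equal(nrow(ev_r), nrow(ev))
    expect_equal(sum(ev_r$direction == "up"), sum(ev$direction == "down"))
  }
})

test_that("refining the sampling stride never loses transits", {
  wp <- rbind(data.frame(time = 0:6, z = c(-4, 4, -4, 2.5, -4, 4, -4)))
  counts <- vapply(c(0.5, 0.1, 0.02), function(dt) {
    traj <- crafted_trajectory(wp, box_z = 12, membrane_edge = 1, dt = dt)
    nrow(detect_crossings(traj, attr(traj, "geometry")))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[3], attr(
    crafted_trajectory(wp, 12, 1, dt = 0.02), "true_events"))
})

test_that("detector refuses an un-recentred series", {
  lip <- matrix(c(2, 6), 1)   # midplane at 4, far from 0
  zs <- zseries(1:5, matrix(5, 5, 1), 16, 440, lipid_ref_z = lip)
  expect_error(detect_crossings(zs, membrane_geometry(-2, 2)),
               class = "permcount_input_error")
})

test_that("rate series arithmetic and invariants", {
  # no events
  rs0 <- rate_series(data.frame(end_time = numeric(0)), total_time = 100)
  expect_true(all(rs0$k == 0))

  # 100 uniform events over 100 ns -> k = 1 at the final checkpoint
  ev <- data.frame(end_time = seq(1, 100, by = 1))
  rs <- rate_series(ev, total_time = 100, checkpoint_interval = 10)
  expect_equal(rs$checkpoint_times, seq(10, 100, by = 10))
  expect_equal(rs$k[10], 1.0)
  expect_equal(rs$k, rs$cumulative_events / rs$checkpoint_times)
  expect_true(all(diff(rs$cumulative_events) >= 0))

  expect_error(rate_series(data.frame(end_time = 150), total_time = 100),
               class = "permcount_inconsistency")
  expect_error(rate_series(ev, total_time = -1),
               class = "permcount_input_error")
})

test_that("Poisson event stream recovers its rate within 3 sigma", {
  set.seed(7)
  rate <- 0.5; horizon <- 2000
  times <- cumsum(rexp(3000, rate))
  times <- times[times <= horizon]
  rs <- rate_series(data.frame(end_time = times), total_time = horizon)
  sigma <- sqrt(length(times)) / horizon
  expect_lt(abs(rs$k[length(rs$k)] - rate), 3 * sigma)
})

test_that("events export as a TSV table", {
  z <- c(-4, 0, 4)
  ev <- detect_crossings(zseries(0:2, z, 12, 440), geom_pm2)
  f <- tempfile(fileext = ".tsv")
  write_events_tsv(ev, f)
  back <- read.delim(f)
  expect_equal(names(back), c("solute_index", "start_ns", "end_ns",
                              "direction"))
  expect_equal(nrow(back), 1L)
})
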