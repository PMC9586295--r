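test_that("wrap_angle maps onto (-pi, pi] and matches the brute-force oracle", {
  expect_identical(wrap_angle(0), 0)
  expect_equal(wrap_angle(pi + 0.1), -pi + 0.1)
  expect_equal(wrap_angle(-3 * pi), wrap_brute(-3 * pi))
  expect_equal(wrap_angle(pi), pi)
  expect_equal(wrap_angle(-pi), pi)
  set.seed(7)
  a <- runif(300, -30, 30)
  w <- wrap_angle(a)
  expect_equal(w, wrap_brute(a))
  expect_true(all(w > -pi & w <= pi))
  expect_true(all(abs((w - a) %% (2 * pi)) < 1e-9 |
                    abs((w - a) %% (2 * pi) - 2 * pi) < 1e-9))
  expect_error(wrap_angle(NaN), "finite")
  expect_error(wrap_angle(Inf), "finite")
})

test_that("trajectory constructor enforces its invariants", {
  expect_error(trajectory("a", 0, 0, 0), "2 samples")
  expect_error(trajectory("a", c(0, 0.1, 0.15), rep(0, 3), rep(0, 3)),
               "uniform")
  expect_error(trajectory("a", c(0.1, 0), c(0, 0), c(0, 0)), "increasing")
  expect_error(trajectory("a", c(0, 0.1), c(0, NA), c(0, 0)))
  t <- trajectory("a", c(0, 0.1, 0.2), 1:3, 4:6)
  expect_s3_class(t, "trajectory")
  expect_equal(t$dt, 0.1)
})

test_that("track tables round-trip bit-exactly and tolerate format variants", {
  set.seed(11)
  tracks <- lapply(1:5, function(i) {
    n <- sample(5:30, 1)
    trajectory(paste0("trk", i), (0:(n - 1)) * 0.1,
               cumsum(rnorm(n)) * 17.3, 500 + cumsum(rnorm(n)) * 9.1)
  })
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tracks(tracks, path)
  back <- read_tracks(path)
  expect_length(back, 5)
  for (i in 1:5) {
    expect_identical(back[[i]]$x, tracks[[i]]$x)
    expect_identical(back[[i]]$y, tracks[[i]]$y)
    expect_identical(back[[i]]$times, tracks[[i]]$times)
  }
  # comma-delimited with extra columns
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "TRACK_ID,POSITION_T,POSITION_X,POSITION_Y,QUALITY",
    "t1,0.0,1.0,2.0,9",
    "t1,0.1,1.5,2.5,9",
    "t2,0.0,0.0,0.0,9"   # single-sample track: dropped with warning
  ), path2)
  expect_warning(got <- read_tracks(path2), "dropped 1")
  expect_length(got, 1)
  expect_equal(attr(got, "n_dropped"), 1L)
  # malformed rows are reported
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "TRACK_ID,POSITION_T,POSITION_X,POSITION_Y",
    "t1,0.0,1.0,2.0",
    "t1,0.1,oops,2.5"
  ), path3)
  expect_error(suppressWarnings(read_tracks(path3)), "line")
})

test_that("smoothing matches the direct convolution oracle", {
  # constant track is a fixed point
  tc <- trajectory("c", (0:40) * 0.1, rep(3.5, 41), rep(7.25, 41))
  sc <- smooth_trajectory(tc)
  expect_equal(sc$x, tc$x)
  expect_equal(sc$y, tc$y)
  # linear ramp: interior samples unchanged (symmetric window)
  x <- 3.0 * (0:59)
  tr <- trajectory("r", (0:59) * 0.1, x, rev(x))
  sr <- smooth_trajectory(tr, window = 10, passes = 1)
  expect_equal(sr$x[7:54], x[7:54], tolerance = 1e-12)
  # unit spike: centre value becomes 1/window after one pass
  xs <- rep(0, 50); xs[25] <- 1
  ts <- trajectory("s", (0:49) * 0.1, xs, rep(0, 50))
  ss <- smooth_trajectory(ts, window = 10, passes = 1)
  expect_equal(ss$x[25], 1 / 10)
  expect_equal(ss$x, smooth_brute(xs, 10, 1))
  # random tracks, several windows and passes, full oracle equivalence
  set.seed(3)
  for (w in c(3, 5, 10)) {
    for (p in c(1, 5)) {
      xr <- cumsum(rnorm(35))
      tt <- trajectory("z", (0:34) * 0.1, xr, rev(xr))
      st <- smooth_trajectory(tt, window = w, passes = p)
      expect_equal(st$x, smooth_brute(xr, w, p), tolerance = 1e-12)
    }
  }
  expect_error(smooth_trajectory(tc, window = 0), "window")
})

test_that("kinematics of straight and two-sample tracks are exact", {
  tt <- (0:20) * 0.1
  t1 <- trajectory("s", tt, 10 * (0:20), rep(500, 21))  # 10 um per frame
  k1 <- compute_kinematics(t1)
  expect_equal(k1$speed, rep(100, 21))
  expect_equal(k1$omega, rep(0, 21))
  expect_equal(k1$heading, rep(0, 21))
  t2 <- trajectory("p", c(0, 0.1), c(0, 1), c(0, -2))
  k2 <- compute_kinematics(t2)
  expect_equal(k2$speed, rep(sqrt(1 + 4) / 0.1, 2))
  expect_equal(k2$heading[1], k2$heading[2])
})

test_that("heading sign convention: moving toward wall 0 gives positive heading", {
  # wall-normal velocity is -speed*sin(heading): y decreasing => heading in (0, pi)
  tt <- (0:10) * 0.1
  toward0 <- compute_kinematics(trajectory("a", tt, rep(0, 11), 500 - 20 * (0:10)))
  expect_true(all(toward0$heading > 0 & toward0$heading < pi))
  away0 <- compute_kinematics(trajectory("b", tt, rep(0, 11), 500 + 20 * (0:10)))
  expect_true(all(away0$heading < 0 & away0$heading > -pi))
})

test_that("circle kinematics match the analytic oracle and converge in dt", {
  R <- 50; om <- 0.5
  k <- compute_kinematics(circle_track(R, om, dt = 0.1))
  int <- 5:150
  expect_lt(max(abs(abs(k$omega[int]) - om)) / om, 0.01)
  expect_lt(max(abs(k$speed[int] - R * om)) / (R * om), 0.01)
  # on an exact circle the chord direction equals the midpoint tangent, so
  # omega is exact at any dt; the speed carries the (om*dt)^2/6 chord error
  # and must converge as dt is refined
  err <- vapply(c(0.1, 0.05, 0.025), function(dt) {
    kk <- compute_kinematics(circle_track(R, om, dt = dt))
    ii <- seq(5, length(kk$omega) - 5)
    max(abs(kk$speed[ii] - R * om))
  }, numeric(1))
  expect_true(all(diff(err) < 0))  # monotone improvement as dt halves
  expect_equal(err[1] / err[2], 4, tolerance = 0.1)  # quadratic order
})

test_that("rigid rotation shifts headings by alpha and preserves speed and omega", {
  set.seed(5)
  n <- 80
  x <- cumsum(rnorm(n, 1, 2)); y <- 500 + cumsum(rnorm(n, 0, 2))
  t0 <- trajectory("r0", (0:(n - 1)) * 0.1, x, y)
  k0 <- compute_kinematics(t0)
  for (alpha in c(0.3, -1.2, 2.9)) {
    # rotating coordinates by alpha rotates velocities; in the (x, -y) heading
    # frame this shifts headings by -alpha... verify via direct construction
    xr <- cos(alpha) * x - sin(alpha) * y
    yr <- sin(alpha) * x + cos(alpha) * y
    kr <- compute_kinematics(trajectory("rr", (0:(n - 1)) * 0.1, xr, yr))
    expect_equal(kr$speed, k0$speed, tolerance = 1e-9)
    expect_equal(kr$omega, k0$omega, tolerance = 1e-9)
    dh <- wrap_angle(kr$heading - k0$heading)
    expect_lt(max(abs(dh - dh[1])), 1e-9)  # uniform shift
    expect_equal(abs(dh[1]), abs(wrap_angle(alpha)), tolerance = 1e-9)
  }
})

test_that("zero-velocity samples carry the previous heading and are flagged", {
  tt <- (0:6) * 0.1
  x <- c(0, 1, 2, 2, 2, 3, 4)  # stationary plateau in the middle
  k <- compute_kinematics(trajectory("z", tt, x, rep(0, 7)))
  expect_true(any(k$heading_imputed))
  expect_true(all(is.finite(k$heading)))
  expect_true(all(k$heading[k$heading_imputed] == 0))  # carried from motion along +x
})

test_that("filter_tracks keeps exactly the tracks above the speed threshold", {
  tt <- (0:20) * 0.1
  mk <- function(v, id) trajectory(id, tt, v * tt, rep(500, 21))
  expect_length(filter_tracks(list(mk(0, "still"))), 0)
  expect_length(filter_tracks(list(mk(100, "fast"))), 1)
  speeds <- c(0.5, 2, 4.9, 5.1, 7, 20, 3, 80, 5.0001, 4.9999)
  tracks <- lapply(seq_along(speeds), function(i) mk(speeds[i], paste0("t", i)))
  kept <- filter_tracks(tracks, min_mean_speed = 5)
  expect_equal(sort(vapply(kept, `[[`, character(1), "track_id")),
               sort(paste0("t", which(speeds > 5))))
})
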