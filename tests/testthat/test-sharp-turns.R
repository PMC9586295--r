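make_kin_with_omega <- function(omega, dt = 0.1, y = NULL, speed = NULL,
                                id = "k") {
  n <- length(omega)
  kinematics(id, times = (0:(n - 1)) * dt,
             y = if (is.null(y)) rep(500, n) else y,
             speed = if (is.null(speed)) rep(50, n) else speed,
             heading = rep(0, n), omega = omega, dt = dt)
}

test_that("constant-heading tracks yield no sharp turns", {
  tr <- trajectory("s", (0:50) * 0.1, 5 * (0:50), rep(500, 51))
  ev <- detect_sharp_turns(compute_kinematics(tr), pi / 8)
  expect_equal(nrow(ev), 0)
})

test_that("injected threshold-crossing runs are detected with correct extent and peak", {
  crit <- pi / 8
  om <- rep(0, 60)
  om[21:28] <- c(0.5, 0.8, 1.0, 3 * crit, 1.0, 0.9, 0.7, 0.5)  # 8 samples
  k <- make_kin_with_omega(om)
  ev <- detect_sharp_turns(k, crit)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_index, 21)
  expect_equal(ev$end_index, 28)
  expect_equal(ev$duration, 8 * 0.1)
  expect_equal(ev$t0_index, 24)
  expect_equal(ev$peak_abs_omega, 3 * crit)
  expect_gte(ev$peak_abs_omega, crit)
  expect_true(ev$start_index <= ev$t0_index && ev$t0_index <= ev$end_index)
  # earliest sample wins on ties
  om2 <- rep(0, 30); om2[10:12] <- c(1, 1, 1)
  ev2 <- detect_sharp_turns(make_kin_with_omega(om2), crit)
  expect_equal(ev2$t0_index, 10)
})

test_that("a sub-threshold gap of one sample separates two events", {
  crit <- pi / 8
  om <- rep(0, 40)
  om[10:13] <- 1; om[14] <- 0.1; om[15:17] <- -1  # sign does not matter
  ev <- detect_sharp_turns(make_kin_with_omega(om), crit)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$start_index, c(10, 15))
  expect_equal(ev$end_index, c(13, 17))
})

test_that("detector is equivalent to the brute-force scan on random tracks", {
  set.seed(42)
  for (rep in 1:60) {
    k <- random_kinematics(n = sample(20:150, 1), seed = NULL)
    crit <- runif(1, 0.1, 1)
    ev <- detect_sharp_turns(k, crit)
    br <- turns_brute(k$omega, crit)
    if (is.null(br)) {
      expect_equal(nrow(ev), 0)
    } else {
      expect_equal(nrow(ev), nrow(br))
      expect_equal(ev$start_index, unname(br[, "start"]))
      expect_equal(ev$end_index, unname(br[, "end"]))
      expect_equal(ev$t0_index, unname(br[, "t0"]))
    }
    # the union of event samples is exactly the super-threshold sample set
    inev <- rep(FALSE, length(k$omega))
    for (j in seq_len(nrow(ev))) inev[ev$start_index[j]:ev$end_index[j]] <- TRUE
    expect_equal(inev, abs(k$omega) >= crit)
  }
})

test_that("event count is non-increasing in the threshold", {
  set.seed(9)
  k <- random_kinematics(n = 600)
  crits <- seq(0.05, 1.5, by = 0.05)
  counts <- vapply(crits, function(cc) nrow(detect_sharp_turns(k, cc)),
                   numeric(1))
  # counts can rise locally when events split, but the super-threshold sample
  # count is strictly monotone; check that and the endpoint behaviour
  samples <- vapply(crits, function(cc) sum(abs(k$omega) >= cc), numeric(1))
  expect_true(all(diff(samples) <= 0))
  expect_true(counts[length(counts)] <= counts[1] || counts[1] == 0)
})

test_that("turn_statistics bins events and tracks correctly", {
  W <- 1000
  # one event at channel centre
  om <- rep(0, 50); om[25] <- 2
  k <- make_kin_with_omega(om, y = rep(500, 50))
  ev <- detect_sharp_turns(k, pi / 8)
  st <- turn_statistics(ev, list(k), W)
  ctr_bin <- findInterval(500, seq(0, W, by = 50), rightmost.closed = TRUE)
  expect_equal(st$per_bin$n_turns[ctr_bin], 1)
  expect_equal(sum(st$per_bin$n_turns), 1)
  expect_equal(st$per_bin$n_traj[ctr_bin], 1)
  expect_true(all(st$per_bin$n_turns[-ctr_bin] == 0))
  expect_true(all(is.na(st$per_bin$turns_per_traj[st$per_bin$n_traj == 0])))
})

test_that("fixed-duration turns give flat mean duration across bins", {
  set.seed(13)
  W <- 1000; dt <- 0.1
  kins <- list(); evs <- list()
  for (i in 1:30) {
    n <- 200
    om <- rep(0, n)
    # two injected 10-sample (1.0 s) turns, well separated so runs never merge
    for (s in c(sample(10:70, 1), sample(110:170, 1))) om[s:(s + 9)] <- 1.5
    y <- runif(1, 0, W) + cumsum(rnorm(n, 0, 2))
    y <- pmin(pmax(y, 0), W)
    k <- make_kin_with_omega(om, y = y, id = paste0("t", i))
    kins[[i]] <- k
    evs[[i]] <- detect_sharp_turns(k, pi / 8)
  }
  ev <- do.call(rbind, evs)
  expect_true(all(ev$duration == 1.0))
  st <- turn_statistics(ev, kins, W)
  occupied <- !is.na(st$per_bin$mean_duration)
  expect_true(all(abs(st$per_bin$mean_duration[occupied] - 1.0) < 1e-12))
})

test_that("near-wall turn-rate elevation is recovered from a Poisson construction", {
  # identifiable construction: quiet headings, strong turns, known rates
  spec <- synthetic_spec(D_rb = 0.005, turn_rate_bulk = 0.03,
                         turn_wall_mult = 3, turn_omega_range = c(1.2, 1.8),
                         seed = 99)
  f <- constant_fields(spec$W, spec$V_sb, spec$D_rb)
  out <- generate_tracks(f, spec, n_tracks = 150, duration = 60)
  kins <- lapply(out$tracks, function(t) {
    compute_kinematics(smooth_trajectory(t, 10, 5))
  })
  ev_all <- lapply(kins, detect_sharp_turns, omega_crit = pi / 8)
  ev <- do.call(rbind, ev_all)
  st <- turn_statistics(ev, kins, spec$W)
  pb <- st$per_bin
  wall <- pb$bin_lo < spec$turn_zone | pb$bin_hi > spec$W - spec$turn_zone
  rate_wall <- sum(pb$n_turns[wall]) / sum(pb$n_traj[wall])
  rate_bulk <- sum(pb$n_turns[!wall]) / sum(pb$n_traj[!wall])
  # wall rate elevated by roughly the configured multiplier
  expect_gt(rate_wall / rate_bulk, 1.5)

  # Poisson count check on the injected process. Specular wall bounces also
  # exceed the angular-velocity threshold (they are genuine sharp direction
  # changes), so both the detected events and the expected count are
  # restricted to frames away from labelled reflections; the smoothing
  # window spreads a bounce over ~7 frames, hence the dilation.
  truth_by_id <- split(out$truth, out$truth$track_id)
  dilate7 <- function(x) {
    n <- length(x)
    out <- x
    for (s in 1:7) out <- out | c(x[-(1:s)], rep(FALSE, s)) |
        c(rep(FALSE, s), x[seq_len(n - s)])
    out
  }
  n_det <- 0
  lam <- 0
  for (j in seq_along(kins)) {
    tr <- truth_by_id[[kins[[j]]$track_id]]
    refl <- dilate7(tr$reflected)
    evj <- ev_all[[j]]
    if (nrow(evj)) {
      clean <- vapply(seq_len(nrow(evj)), function(i) {
        !any(refl[evj$start_index[i]:evj$end_index[i]])
      }, logical(1))
      n_det <- n_det + sum(clean)
    }
    h <- pmin(tr$y, spec$W - tr$y)
    rate <- spec$turn_rate_bulk *
      ifelse(h < spec$turn_zone, spec$turn_wall_mult, 1)
    lam <- lam + sum(rate[!refl] * 0.1)
  }
  expect_gt(n_det, lam - 4 * sqrt(lam))
  expect_lt(n_det, lam + 4 * sqrt(lam))
})

test_that("time-aligned |omega| profiles peak at t - t0 = 0", {
  set.seed(31)
  kins <- list(); evs <- list()
  for (i in 1:20) {
    n <- 150
    om <- rnorm(n, 0, 0.02)
    s <- sample(seq(20, n - 20), 1)
    om[s:(s + 8)] <- 1.2 * exp(-abs(seq(-4, 4)) / 3)  # peaked bump
    k <- make_kin_with_omega(om, y = rep(500, n), id = paste0("a", i))
    kins[[i]] <- k
    evs[[i]] <- detect_sharp_turns(k, pi / 8)
  }
  st <- turn_statistics(do.call(rbind, evs), kins, 1000)
  rb <- st$aligned[st$aligned$region == "RB", ]
  expect_equal(rb$t_rel[which.max(rb$mean_abs_omega)], 0)
})
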