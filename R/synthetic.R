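#' Specification of the synthetic study conditions
#'
#' Collects the parameters of the synthetic stand-in for the measured
#' wall-behaviour fields and track sets: a channel of width `W = 50 * Lc`
#' (1000 um for `Lc = 20` um), bulk rotational diffusivity
#' `D_rb = 0.025` rad^2/s, wall layers in which the speed is attenuated
#' (decay length 100 um for wall-normal headings, 70 um for wall-parallel),
#' a wall torque of amplitude ~1 rad/s peaking at tilted headings
#' (`|phi| = pi/4` modulo the parallel/normal sign structure), rotational
#' diffusivity enhanced by an order of magnitude at wall-normal headings
#' within ~50 um of the wall, and sharp-turn episodes of mean duration ~1 s
#' occurring as a Poisson process whose rate is elevated within `2.5 * Lc`
#' of the walls. Tracks are sampled at 10 frames per second.
#'
#' @param V_sb bulk swimming speed (um/s); default 80, typical of a fast
#'   raphidophyte alga.
#' @param D_rb bulk rotational diffusivity (rad^2/s); default 0.025.
#' @param W channel width (um); default 1000.
#' @param Lc characteristic cell length (um); default 20.
#' @param lambda_perp,lambda_par speed-attenuation decay lengths (um) for
#'   wall-normal and wall-parallel headings; defaults 100 and 70.
#' @param speed_deficit fractional speed reduction at contact; default 0.6.
#' @param torque_amp wall-torque amplitude (rad/s); default 1.
#' @param lambda_torque wall-torque decay length (um); default 50.
#' @param dr_factor rotational-diffusivity enhancement factor at the wall for
#'   wall-normal headings; default 10.
#' @param lambda_dr diffusivity-layer decay length (um); default 50.
#' @param turn_rate_bulk sharp-turn rate in the bulk (1/s); default 0.02.
#' @param turn_wall_mult rate multiplier within `turn_zone` of a wall;
#'   default 3.
#' @param turn_zone width of the elevated-rate zone (um); default `2.5 * Lc`.
#' @param turn_duration_mean mean turn duration (s); default 1.
#' @param turn_omega_range range (rad/s) of the uniformly drawn extra
#'   angular-velocity magnitude during a turn; default `c(0.5, 1.5)`, well
#'   above the detection threshold `pi/8`.
#' @param frame_interval frame interval (s); default 0.1.
#' @param dt_internal internal integration step (s); default 0.01, subsampled
#'   x10 to frames.
#' @param seed optional RNG seed applied by the generators.
#' @return an object of class `synthetic_spec` (a named list).
#' @export
synthetic_spec <- function(V_sb = 80, D_rb = 0.025, W = 1000, Lc = 20,
                           lambda_perp = 100, lambda_par = 70,
                           speed_deficit = 0.6,
                           torque_amp = 1, lambda_torque = 50,
                           dr_factor = 10, lambda_dr = 50,
                           turn_rate_bulk = 0.02, turn_wall_mult = 3,
                           turn_zone = 2.5 * Lc,
                           turn_duration_mean = 1,
                           turn_omega_range = c(0.5, 1.5),
                           frame_interval = 0.1, dt_internal = 0.01,
                           seed = NULL) {
  spec <- list(
    V_sb = V_sb, D_rb = D_rb, W = W, Lc = Lc,
    lambda_perp = lambda_perp, lambda_par = lambda_par,
    speed_deficit = speed_deficit,
    torque_amp = torque_amp, lambda_torque = lambda_torque,
    dr_factor = dr_factor, lambda_dr = lambda_dr,
    turn_rate_bulk = turn_rate_bulk, turn_wall_mult = turn_wall_mult,
    turn_zone = turn_zone, turn_duration_mean = turn_duration_mean,
    turn_omega_range = turn_omega_range,
    frame_interval = frame_interval, dt_internal = dt_internal,
    seed = seed
  )
  with(spec, stopifnot(
    V_sb > 0, D_rb > 0, W > 0, Lc > 0,
    lambda_perp > 0, lambda_par > 0, speed_deficit >= 0, speed_deficit < 1,
    torque_amp >= 0, lambda_torque > 0, dr_factor >= 1, lambda_dr > 0,
    turn_rate_bulk >= 0, turn_wall_mult >= 1, turn_duration_mean > 0,
    frame_interval > 0, dt_internal > 0
  ))
  structure(spec, class = "synthetic_spec")
}

#' Build smooth ground-truth wall fields from a synthetic spec
#'
#' Parametric emulations of measured wall-behaviour maps (they are stand-ins
#' constrained by observed magnitudes and peak locations, not measurements):
#'
#' * speed: `Vs = V_sb * (1 - a * (exp(-h0/lambda(phi)) + exp(-h1/lambda(phi))))`
#'   with `h0 = y`, `h1 = W - y` and the decay length interpolating from
#'   `lambda_par` (wall-parallel) to `lambda_perp` (wall-normal) via
#'   `sin^2(phi)`;
#' * wall torque: `omega_w = -2 A |sin(phi)| cos(phi) *
#'   (exp(-h0/lambda_t) - exp(-h1/lambda_t))`, which rotates incoming cells
#'   toward wall-parallel and outgoing cells toward wall-normal headings,
#'   with extreme magnitude `A` at tilted headings (`|phi|, pi - |phi| = pi/4`);
#' * diffusivity: `Dr = D_rb * (1 + (F - 1) * sin^2(phi) *
#'   (exp(-h0/lambda_D) + exp(-h1/lambda_D)))`, maximal (`F * D_rb`) for
#'   wall-normal headings at contact.
#'
#' All three are smooth, periodic in heading, and revert to the bulk values
#' away from the walls.
#'
#' @param spec a [synthetic_spec].
#' @return a [wall_fields] object.
#' @export
make_fields <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  W <- spec$W
  Vs <- function(y, phi) {
    lam <- spec$lambda_par + (spec$lambda_perp - spec$lambda_par) * sin(phi)^2
    v <- spec$V_sb * (1 - spec$speed_deficit * (exp(-y / lam) + exp(-(W - y) / lam)))
    pmax(v, 0.05 * spec$V_sb)
  }
  omega_w <- function(y, phi) {
    -2 * spec$torque_amp * abs(sin(phi)) * cos(phi) *
      (exp(-y / spec$lambda_torque) - exp(-(W - y) / spec$lambda_torque))
  }
  Dr <- function(y, phi) {
    spec$D_rb * (1 + (spec$dr_factor - 1) * sin(phi)^2 *
                   (exp(-y / spec$lambda_dr) + exp(-(W - y) / spec$lambda_dr)))
  }
  wall_fields(Vs, omega_w, Dr, W = W, V_sb = spec$V_sb, D_rb = spec$D_rb)
}

#' Generate synthetic tracks by forward simulation of the planar model
#'
#' Integrates the planar Langevin dynamics
#' `dy = -Vs sin(phi) dt`, `dx = Vs cos(phi) dt`,
#' `dphi = (omega_w [+ omega_g] + omega_turn) dt + sqrt(2 Dr dt) dW`
#' with an Euler-Maruyama step of `spec$dt_internal` (coefficients at the
#' pre-point), specular reflection at the walls, and subsamples the state to
#' the experimental frame interval. Sharp-turn episodes are optionally
#' superposed as a position-dependent Poisson process: while a turn is
#' active an extra angular velocity of random sign and uniformly drawn
#' magnitude is added to the drift for a gamma-distributed duration (shape 4,
#' mean `spec$turn_duration_mean`).
#'
#' Ground truth is returned alongside each track: the local true
#' coefficients at each frame and the turn labels, so estimators can be
#' validated by parameter recovery.
#'
#' @param fields a [wall_fields] (e.g. [make_fields()] output).
#' @param spec the [synthetic_spec] (turn process, frame rate, seed).
#' @param n_tracks number of tracks.
#' @param duration track duration (s).
#' @param gyro_B optional gyrotactic timescale (s); when set, the gyrotactic
#'   drift `-cos(heading)/(2 gyro_B)` is added (vertical-plane scenario).
#' @param inject_turns superpose the sharp-turn process? Default `TRUE`.
#' @param bounded apply reflecting walls at 0 and `W`? Default `TRUE`.
#' @param seed RNG seed; defaults to `spec$seed`.
#' @return list with `tracks` (list of [trajectory]) and `truth`, a
#'   data.frame with one row per frame: `track_id`, `time`, `y`, `heading`,
#'   `true_speed`, `true_omega` (deterministic drift incl. gyrotaxis, excl.
#'   turn), `true_Dr`, `in_turn`, `turn_omega`, and `reflected` (`TRUE` when
#'   a wall reflection occurred during the frame ending at this sample;
#'   displacement-based headings are undefined across a specular bounce).
#' @export
generate_tracks <- function(fields, spec, n_tracks, duration,
                            gyro_B = NULL, inject_turns = TRUE,
                            bounded = TRUE, seed = spec$seed) {
  stopifnot(inherits(fields, "wall_fields"), inherits(spec, "synthetic_spec"))
  if (!is.null(seed)) set.seed(seed)
  dt <- spec$dt_internal
  thin <- round(spec$frame_interval / dt)
  stopifnot(abs(thin * dt - spec$frame_interval) < 1e-9, thin >= 1)
  n_steps <- ceiling(duration / dt)
  n_frames <- floor(n_steps / thin) + 1L
  W <- fields$W

  y <- runif(n_tracks, 0, W)
  x <- numeric(n_tracks)
  phi <- runif(n_tracks, -pi, pi)
  turn_left <- numeric(n_tracks)   # seconds remaining in the active turn
  turn_om <- numeric(n_tracks)

  rec_y <- matrix(NA_real_, n_frames, n_tracks)
  rec_x <- matrix(NA_real_, n_frames, n_tracks)
  rec_phi <- matrix(NA_real_, n_frames, n_tracks)
  rec_vs <- matrix(NA_real_, n_frames, n_tracks)
  rec_om <- matrix(NA_real_, n_frames, n_tracks)
  rec_dr <- matrix(NA_real_, n_frames, n_tracks)
  rec_turn <- matrix(FALSE, n_frames, n_tracks)
  rec_turnom <- matrix(0, n_frames, n_tracks)
  rec_refl <- matrix(FALSE, n_frames, n_tracks)
  refl_acc <- rep(FALSE, n_tracks)   # any reflection since the last frame

  record <- function(frame) {
    vs <- fields$Vs(y, phi)
    om <- fields$omega_w(y, phi)
    if (!is.null(gyro_B)) om <- om + gyro_omega(phi, gyro_B)
    rec_y[frame, ] <<- y; rec_x[frame, ] <<- x; rec_phi[frame, ] <<- phi
    rec_vs[frame, ] <<- vs; rec_om[frame, ] <<- om
    rec_dr[frame, ] <<- fields$Dr(y, phi)
    rec_turn[frame, ] <<- turn_left > 0
    rec_turnom[frame, ] <<- ifelse(turn_left > 0, turn_om, 0)
  }
  record(1L)
  frame <- 1L
  for (s in seq_len(n_steps)) {
    vs <- fields$Vs(y, phi)
    om <- fields$omega_w(y, phi)
    if (!is.null(gyro_B)) om <- om + gyro_omega(phi, gyro_B)
    dr <- fields$Dr(y, phi)
    if (inject_turns) {
      active <- turn_left > 0
      idle <- !active
      if (any(idle)) {
        h <- pmin(y, W - y)
        rate <- spec$turn_rate_bulk *
          ifelse(h < spec$turn_zone, spec$turn_wall_mult, 1)
        start <- idle & (runif(n_tracks) < rate * dt)
        ns <- sum(start)
        if (ns > 0L) {
          turn_left[start] <- rgamma(ns, shape = 4, scale = spec$turn_duration_mean / 4)
          turn_om[start] <- sample(c(-1, 1), ns, replace = TRUE) *
            runif(ns, spec$turn_omega_range[1], spec$turn_omega_range[2])
        }
      }
      om_eff <- om + ifelse(turn_left > 0, turn_om, 0)
      turn_left <- pmax(turn_left - dt, 0)
    } else {
      om_eff <- om
    }
    y <- y - vs * sin(phi) * dt
    x <- x + vs * cos(phi) * dt
    phi <- phi + om_eff * dt + sqrt(2 * dr * dt) * rnorm(n_tracks)
    if (bounded) {
      lo <- y < 0
      y[lo] <- -y[lo]; phi[lo] <- -phi[lo]
      hi <- y > W
      y[hi] <- 2 * W - y[hi]; phi[hi] <- -phi[hi]
      refl_acc <- refl_acc | lo | hi
    }
    phi <- wrap_angle(phi)
    if (s %% thin == 0L) {
      frame <- frame + 1L
      record(frame)
      rec_refl[frame, ] <- refl_acc
      refl_acc[] <- FALSE
    }
  }

  times <- (seq_len(n_frames) - 1L) * spec$frame_interval
  ids <- sprintf("synth%04d", seq_len(n_tracks))
  tracks <- lapply(seq_len(n_tracks), function(j) {
    trajectory(ids[j], times, rec_x[, j], rec_y[, j],
               frame_interval = spec$frame_interval)
  })
  truth <- data.frame(
    track_id = rep(ids, each = n_frames),
    time = rep(times, times = n_tracks),
    y = as.vector(rec_y),
    heading = as.vector(rec_phi),
    true_speed = as.vector(rec_vs),
    true_omega = as.vector(rec_om),
    true_Dr = as.vector(rec_dr),
    in_turn = as.vector(rec_turn),
    turn_omega = as.vector(rec_turnom),
    reflected = as.vector(rec_refl)
  )
  list(tracks = tracks, truth = truth)
}

#' Vertical-plane gyrotactic scenario
#'
#' Convenience wrapper: builds the wall fields from `spec` and generates
#' vertical-plane tracks with the gyrotactic drift `-cos(theta)/(2B)` added
#' to the heading equation. The returned ground truth includes `B`.
#'
#' @param spec a [synthetic_spec].
#' @param B gyrotactic timescale (s), > 0.
#' @param n_tracks,duration as in [generate_tracks()].
#' @param ... further arguments passed to [generate_tracks()] (e.g.
#'   `inject_turns`, `bounded`, `seed`).
#' @return list with `fields`, `tracks`, `truth`, `B`.
#' @export
gyrotactic_scenario <- function(spec, B, n_tracks, duration, ...) {
  stopifnot(B > 0)
  fields <- make_fields(spec)
  out <- generate_tracks(fields, spec, n_tracks, duration, gyro_B = B, ...)
  list(fields = fields, tracks = out$tracks, truth = out$truth, B = B)
}

#' Simulate pure heading random walks at the frame rate
#'
#' Heading-only trajectories with zero deterministic torque:
#' `phi_{i+1} = phi_i + N(0, 2 D_r dt)`, the bulk-condition null model used
#' to validate the moment estimator of rotational diffusivity. Positions are
#' pinned at mid-channel so the series can be pooled through the binned
#' estimators.
#'
#' @param n number of walks.
#' @param steps increments per walk.
#' @param D_r rotational diffusivity (rad^2/s).
#' @param dt frame interval (s), default 0.1.
#' @param W nominal channel width (um), default 1000.
#' @param seed optional RNG seed.
#' @return list of [kinematics] objects.
#' @export
heading_random_walks <- function(n, steps, D_r, dt = 0.1, W = 1000,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  times <- (0:steps) * dt
  lapply(seq_len(n), function(j) {
    phi <- cumsum(c(runif(1, -pi, pi), rnorm(steps, 0, sqrt(2 * D_r * dt))))
    kinematics(
      track_id = sprintf("walk%04d", j), times = times,
      y = rep(W / 2, steps + 1L), speed = rep(0, steps + 1L),
      heading = wrap_angle(phi), omega = c(diff(phi) / dt, 0), dt = dt
    )
  })
}
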