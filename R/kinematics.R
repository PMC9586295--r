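#' Construct a kinematics object directly
#'
#' Per-sample speed, heading and angular velocity for one track. Normally
#' produced by [compute_kinematics()]; the constructor is exported so that
#' heading-only series (e.g. simulated heading random walks) can be fed to the
#' binned estimators without a positional track.
#'
#' Heading convention: the heading `phi` is measured so that the wall-normal
#' velocity component is `-speed * sin(phi)`; `0 < phi < pi` therefore means
#' the cell is moving toward the wall at coordinate 0, and `-pi < phi < 0`
#' toward the far wall.
#'
#' @param track_id identifier.
#' @param times sample times (s).
#' @param y wall-normal coordinate per sample (um).
#' @param speed per-sample speed (um/s), >= 0.
#' @param heading per-sample heading (rad), wrapped into `(-pi, pi]`.
#' @param omega per-sample angular velocity (rad/s).
#' @param dt frame interval (s).
#' @param x optional streamwise coordinate per sample (um).
#' @param heading_imputed logical per sample: `TRUE` where the heading was
#'   undefined (zero velocity) and carried forward from the last defined value.
#' @return an object of class `kinematics`.
#' @export
kinematics <- function(track_id, times, y, speed, heading, omega, dt,
                       x = NULL, heading_imputed = NULL) {
  n <- length(times)
  stopifnot(length(y) == n, length(speed) == n, length(heading) == n,
            length(omega) == n)
  if (any(speed < 0)) stop("kinematics(): speed must be >= 0")
  if (is.null(heading_imputed)) heading_imputed <- rep(FALSE, n)
  structure(
    list(track_id = as.character(track_id)[1], times = times, x = x, y = y,
         speed = speed, heading = wrap_angle(heading), omega = omega,
         dt = dt, heading_imputed = heading_imputed),
    class = "kinematics"
  )
}

#' @export
print.kinematics <- function(x, ...) {
  cat(sprintf("<kinematics %s: %d samples, mean speed %.2f um/s>\n",
              x$track_id, length(x$times), mean(x$speed)))
  invisible(x)
}

#' Convert a trajectory to speed, heading and angular velocity
#'
#' Velocity components are computed by central differences at interior
#' samples, with forward/backward differences at the first/last sample. Speed
#' is the velocity norm; the heading is `atan2(-vy, vx)` so that the
#' wall-normal velocity is `-speed * sin(heading)` (positive headings point
#' toward the wall at 0). The angular velocity at interior samples is the sum
#' of the two adjacent single-step wrapped heading increments divided by
#' `2 * dt` (a central estimate built from minimal signed increments, so a
#' heading passing through +/-pi does not produce a spurious 2*pi jump); at
#' the ends the single wrapped increment over `dt` is used.
#'
#' Samples with zero velocity have no defined heading; the previous defined
#' heading is carried forward (or the first defined heading carried backward)
#' and flagged in `heading_imputed`.
#'
#' @param t a [trajectory] (optionally pre-smoothed with
#'   [smooth_trajectory()]).
#' @return a [kinematics] object.
#' @export
compute_kinematics <- function(t) {
  stopifnot(inherits(t, "trajectory"))
  n <- length(t$times)
  dt <- t$dt
  vx <- numeric(n); vy <- numeric(n)
  if (n == 2L) {
    vx[] <- (t$x[2] - t$x[1]) / dt
    vy[] <- (t$y[2] - t$y[1]) / dt
  } else {
    i <- 2:(n - 1L)
    vx[i] <- (t$x[i + 1L] - t$x[i - 1L]) / (2 * dt)
    vy[i] <- (t$y[i + 1L] - t$y[i - 1L]) / (2 * dt)
    vx[1] <- (t$x[2] - t$x[1]) / dt
    vy[1] <- (t$y[2] - t$y[1]) / dt
    vx[n] <- (t$x[n] - t$x[n - 1L]) / dt
    vy[n] <- (t$y[n] - t$y[n - 1L]) / dt
  }
  speed <- sqrt(vx^2 + vy^2)
  zero <- speed == 0
  heading <- numeric(n)
  heading[!zero] <- wrap_angle(atan2(-vy[!zero], vx[!zero]))
  if (any(zero)) {
    if (all(zero)) {
      heading[] <- 0
    } else {
      # carry forward the last defined heading; backfill the leading run
      idx <- ifelse(zero, NA_integer_, seq_len(n))
      filled <- cummax_na(idx)
      first_def <- which(!zero)[1]
      filled[seq_len(first_def - 1L)] <- first_def
      heading <- heading[filled]
    }
  }
  dphi <- wrap_angle_diff(heading)
  omega <- numeric(n)
  if (n == 2L) {
    omega[] <- dphi[1] / dt
  } else {
    i <- 2:(n - 1L)
    omega[i] <- (dphi[i - 1L] + dphi[i]) / (2 * dt)
    omega[1] <- dphi[1] / dt
    omega[n] <- dphi[n - 1L] / dt
  }
  kinematics(t$track_id, t$times, t$y, speed, heading, omega, dt,
             x = t$x, heading_imputed = zero)
}

# wrapped single-step heading increments (length n-1)
wrap_angle_diff <- function(heading) {
  wrap_angle(diff(heading))
}

# last-observation-carried-forward on an index vector with NAs
cummax_na <- function(idx) {
  notna <- !is.na(idx)
  filled <- idx
  filled[!notna] <- NA_integer_
  last <- NA_integer_
  for (i in seq_along(filled)) {
    if (notna[i]) last <- filled[i] else filled[i] <- last
  }
  filled
}

#' Filter tracks by mean swimming speed
#'
#' Keeps tracks whose mean per-sample speed strictly exceeds
#' `min_mean_speed`, the standard exclusion of non-motile cells and debris
#' from particle-tracking data.
#'
#' @param tracks list of [trajectory] or [kinematics] objects.
#' @param min_mean_speed threshold (um/s), default 5.
#' @return the subset of `tracks` passing the filter.
#' @export
filter_tracks <- function(tracks, min_mean_speed = 5) {
  keep <- vapply(tracks, function(t) {
    k <- if (inherits(t, "kinematics")) t else compute_kinematics(t)
    mean(k$speed) > min_mean_speed
  }, logical(1))
  tracks[keep]
}
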