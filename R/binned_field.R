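#' Create an empty position-by-orientation binned field
#'
#' The standard grid for ensemble behaviour maps: `n_pos` equal position bins
#' over `[0, W]` crossed with `n_ang` equal orientation bins over
#' `(-pi, pi]`. Each bin accumulates the sample count, the speed sum, and the
#' first and second moments of the one-frame heading increment `dphi`, from
#' which drift (mean angular velocity) and rotational diffusivity are
#' estimated by [estimate_drift_diffusion()].
#'
#' @param W channel width (um).
#' @param n_pos number of position bins (default 51).
#' @param n_ang number of orientation bins (default 80).
#' @return an object of class `binned_field`.
#' @export
binned_field <- function(W, n_pos = 51L, n_ang = 80L) {
  n_pos <- as.integer(n_pos); n_ang <- as.integer(n_ang)
  stopifnot(W > 0, n_pos >= 1L, n_ang >= 1L)
  z <- matrix(0, n_pos, n_ang)
  structure(
    list(
      W = W,
      pos_edges = seq(0, W, length.out = n_pos + 1L),
      ang_edges = seq(-pi, pi, length.out = n_ang + 1L),
      count = z, sum_speed = z, sum_dphi = z, sumsq_dphi = z,
      n_rejected = 0L, dt = NA_real_
    ),
    class = "binned_field"
  )
}

#' @export
print.binned_field <- function(x, ...) {
  cat(sprintf("<binned_field: %d x %d bins over [0, %g] um x (-pi, pi], %g samples>\n",
              nrow(x$count), ncol(x$count), x$W, sum(x$count)))
  invisible(x)
}

#' Bin centres of a binned field
#' @param grid a [binned_field].
#' @return list with numeric vectors `pos` (um) and `ang` (rad).
#' @export
bin_centers <- function(grid) {
  list(
    pos = (grid$pos_edges[-1] + grid$pos_edges[-length(grid$pos_edges)]) / 2,
    ang = (grid$ang_edges[-1] + grid$ang_edges[-length(grid$ang_edges)]) / 2
  )
}

#' Accumulate track samples into a binned field
#'
#' Every sample `i` that has a successor contributes its position `y_i`,
#' heading `phi_i`, speed and heading increment
#' `dphi_i = wrap(phi_{i+1} - phi_i)` to the bin of the *starting* sample
#' (the pre-point convention matching an Ito-interpreted model). Samples
#' outside `[0, W]` are rejected and counted in `n_rejected`. The grid may be
#' filled incrementally over several calls.
#'
#' @param grid a [binned_field].
#' @param kins list of [kinematics] objects (uniform, equal `dt`).
#' @param exclude optional named list (by `track_id`) of logical vectors, one
#'   element per sample, marking increments whose *starting* sample should be
#'   skipped (e.g. frames inside labelled sharp-turn episodes).
#' @return the updated `binned_field`.
#' @export
accumulate_tracks <- function(grid, kins, exclude = NULL) {
  stopifnot(inherits(grid, "binned_field"))
  if (inherits(kins, "kinematics")) kins <- list(kins)
  n_pos <- nrow(grid$count); n_ang <- ncol(grid$count)
  ys <- list(); phis <- list(); sps <- list(); dphis <- list()
  for (k in kins) {
    stopifnot(inherits(k, "kinematics"))
    if (is.na(grid$dt)) grid$dt <- k$dt
    if (abs(k$dt - grid$dt) > 1e-9) {
      stop("accumulate_tracks(): all tracks must share the grid frame interval")
    }
    n <- length(k$times)
    if (n < 2L) next
    i <- seq_len(n - 1L)
    keep <- rep(TRUE, n - 1L)
    if (!is.null(exclude) && !is.null(exclude[[k$track_id]])) {
      keep <- !exclude[[k$track_id]][i]
    }
    ys[[length(ys) + 1L]] <- k$y[i][keep]
    phis[[length(phis) + 1L]] <- wrap_angle(k$heading[i][keep])
    sps[[length(sps) + 1L]] <- k$speed[i][keep]
    dphis[[length(dphis) + 1L]] <- wrap_angle(k$heading[i + 1L] - k$heading[i])[keep]
  }
  if (!length(ys)) return(grid)
  y <- unlist(ys); phi <- unlist(phis); sp <- unlist(sps); dphi <- unlist(dphis)
  pb <- findInterval(y, grid$pos_edges, rightmost.closed = TRUE)
  inside <- pb >= 1L & pb <= n_pos
  grid$n_rejected <- grid$n_rejected + sum(!inside)
  if (!all(inside)) {
    y <- y[inside]; phi <- phi[inside]; sp <- sp[inside]; dphi <- dphi[inside]
    pb <- pb[inside]
  }
  ab <- findInterval(phi, grid$ang_edges, rightmost.closed = TRUE)
  cell <- (ab - 1L) * n_pos + pb
  grid$count <- grid$count + matrix(tabulate(cell, nbins = n_pos * n_ang), n_pos, n_ang)
  sums <- rowsum(cbind(sp, dphi, dphi^2), cell)
  at <- as.integer(rownames(sums))
  grid$sum_speed[at] <- grid$sum_speed[at] + sums[, 1]
  grid$sum_dphi[at] <- grid$sum_dphi[at] + sums[, 2]
  grid$sumsq_dphi[at] <- grid$sumsq_dphi[at] + sums[, 3]
  grid
}

#' Moment estimates of drift and rotational diffusivity per bin
#'
#' Under the planar Langevin model the one-frame heading increment in a bin
#' is `dphi ~ omega * dt + N(0, 2 * D_r * dt)`, so the per-bin moment
#' estimators are `omega = mean(dphi) / dt` and `D_r = var(dphi) / (2 * dt)`
#' (unbiased n-1 variance). Bins with fewer than `min_count` increments are
#' flagged undefined (`NA`), never filled with zeros.
#'
#' @param grid an accumulated [binned_field].
#' @param dt frame interval (s); defaults to the interval recorded during
#'   accumulation.
#' @param min_count minimum increments for a defined estimate (default 10).
#' @return the `binned_field` with matrices `mean_speed` (um/s), `omega`
#'   (rad/s), `D_r` (rad^2/s) and the logical matrix `defined` added.
#' @export
estimate_drift_diffusion <- function(grid, dt = grid$dt, min_count = 10L) {
  stopifnot(inherits(grid, "binned_field"))
  if (is.na(dt) || dt <= 0) stop("estimate_drift_diffusion(): dt must be > 0")
  n <- grid$count
  defined <- n >= min_count
  mean_dphi <- ifelse(defined, grid$sum_dphi / pmax(n, 1), NA_real_)
  varh <- ifelse(n >= 2,
                 (grid$sumsq_dphi - grid$sum_dphi^2 / pmax(n, 1)) / pmax(n - 1, 1),
                 NA_real_)
  varh <- pmax(varh, 0)  # guard tiny negative round-off
  grid$mean_speed <- ifelse(defined, grid$sum_speed / pmax(n, 1), NA_real_)
  grid$omega <- ifelse(defined, mean_dphi / dt, NA_real_)
  grid$D_r <- ifelse(defined, varh / (2 * dt), NA_real_)
  grid$defined <- defined
  grid$dt <- dt
  grid
}

#' Joint PDF and normalized concentration profile from a binned field
#'
#' The joint probability density `P(y, phi)` is the bin count divided by the
#' total count and the bin area, so that `sum(P) * bin_area = 1`. The
#' orientation-integrated density `N*(y)` is then normalized by its width
#' average, giving the dimensionless concentration `N(y)` with width average
#' 1 -- the concentration measure a continuum model would predict.
#'
#' @param grid an accumulated [binned_field].
#' @return list with `P` (n_pos x n_ang density matrix, 1/(um rad)) and
#'   `profile`, a data.frame of class `concentration_profile` with columns
#'   `position` (bin centre, um) and `N`.
#' @export
estimate_pdf_and_concentration <- function(grid) {
  stopifnot(inherits(grid, "binned_field"))
  total <- sum(grid$count)
  if (total <= 0) stop("estimate_pdf_and_concentration(): empty grid")
  dpos <- diff(grid$pos_edges)[1]
  dang <- diff(grid$ang_edges)[1]
  P <- grid$count / (total * dpos * dang)
  Nstar <- rowSums(P) * dang            # integral of P over orientation
  N <- Nstar / mean(Nstar)
  profile <- data.frame(position = bin_centers(grid)$pos, N = N)
  class(profile) <- c("concentration_profile", "data.frame")
  attr(profile, "W") <- grid$W
  list(P = P, profile = profile)
}

#' Export a binned field as a flat table
#'
#' One row per bin with bin centres and all defined layers, suitable for
#' plotting or delimited export.
#'
#' @param grid a [binned_field], typically after [estimate_drift_diffusion()].
#' @return a data.frame with columns `position`, `heading`, `count` and any of
#'   `mean_speed`, `omega`, `D_r` present in the grid.
#' @export
field_table <- function(grid) {
  ctr <- bin_centers(grid)
  out <- data.frame(
    position = rep(ctr$pos, times = length(ctr$ang)),
    heading = rep(ctr$ang, each = length(ctr$pos)),
    count = as.vector(grid$count)
  )
  for (layer in c("mean_speed", "omega", "D_r")) {
    if (!is.null(grid[[layer]])) out[[layer]] <- as.vector(grid[[layer]])
  }
  out
}

#' Fit the gyrotactic reorientation timescale from a binned field
#'
#' In the vertical plane the bulk drift follows the gyrotactic law
#' `omega(theta) = -cos(theta) / (2B)`. Pooling increments over the bulk
#' position range and regressing the pooled per-heading-bin drift on
#' `-cos(theta)` through the origin (weighted by bin counts) yields
#' `1 / (2B)` and hence the reorientation timescale `B`.
#'
#' @param grid an accumulated [binned_field] of vertical-plane tracks.
#' @param dt frame interval (s); defaults to the recorded interval.
#' @param pos_range position interval (um) regarded as bulk. The default
#'   excludes 250 um from each wall: the gyrotactic drift (order
#'   `1/(2B)` ~ 0.05 rad/s) is much weaker than wall torques (order 1
#'   rad/s), so the fit region must leave several torque decay lengths
#'   (~50 um each) for the wall contribution to become negligible.
#' @param min_count minimum pooled increments per heading bin (default 50).
#' @return list with `B` (s), `slope` (`1/(2B)`, 1/s), and the pooled
#'   per-heading drift table `by_heading`.
#' @export
fit_gyrotaxis_B <- function(grid, dt = grid$dt,
                            pos_range = c(250, grid$W - 250),
                            min_count = 50L) {
  stopifnot(inherits(grid, "binned_field"))
  ctr <- bin_centers(grid)
  rows <- ctr$pos >= pos_range[1] & ctr$pos <= pos_range[2]
  cnt <- colSums(grid$count[rows, , drop = FALSE])
  sdp <- colSums(grid$sum_dphi[rows, , drop = FALSE])
  ok <- cnt >= min_count
  if (sum(ok) < 3L) stop("fit_gyrotaxis_B(): too few populated heading bins in the bulk")
  omega <- sdp[ok] / cnt[ok] / dt
  xv <- -cos(ctr$ang[ok])
  fit <- stats::lm(omega ~ 0 + xv, weights = cnt[ok])
  slope <- unname(coef(fit)[1])
  if (slope <= 0) stop("fit_gyrotaxis_B(): fitted slope is not positive; no gyrotactic signal")
  list(
    B = 1 / (2 * slope), slope = slope,
    by_heading = data.frame(heading = ctr$ang[ok], omega = omega, count = cnt[ok])
  )
}
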