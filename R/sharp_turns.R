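#' Detect sharp-turn events by angular-velocity threshold
#'
#' A sharp turn is a maximal contiguous run of samples whose angular-velocity
#' magnitude is at or above the critical value `omega_crit`. The canonical
#' thresholds are `pi/8` rad/s for horizontal-plane tracks and `pi/2` rad/s in
#' the vertical plane, both far above the bulk mean angular velocity. Within
#' each event `t0` marks the sample of maximum `|omega|` (the earliest such
#' sample on ties).
#'
#' @param k a [kinematics] object.
#' @param omega_crit critical angular velocity (rad/s), > 0. Default `pi/8`.
#' @return a `data.frame` with one row per event: `track_id`, `start_index`,
#'   `end_index` (inclusive sample indices), `t0_index`, `duration` (s,
#'   `(end - start + 1) * dt`), `peak_abs_omega` (rad/s), `mean_speed_during`
#'   (um/s), `mean_abs_omega_during` (rad/s) and `location` (wall-normal
#'   coordinate at `t0`, um). Zero rows when no sample crosses the threshold.
#' @export
detect_sharp_turns <- function(k, omega_crit = pi / 8) {
  stopifnot(inherits(k, "kinematics"))
  if (!is.numeric(omega_crit) || omega_crit <= 0) {
    stop("detect_sharp_turns(): omega_crit must be > 0")
  }
  above <- abs(k$omega) >= omega_crit
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- which(r$values)
  out <- lapply(sel, function(j) {
    s <- starts[j]; e <- ends[j]
    aw <- abs(k$omega[s:e])
    t0 <- s + which.max(aw) - 1L
    data.frame(
      track_id = k$track_id,
      start_index = s, end_index = e, t0_index = t0,
      duration = (e - s + 1L) * k$dt,
      peak_abs_omega = max(aw),
      mean_speed_during = mean(k$speed[s:e]),
      mean_abs_omega_during = mean(aw),
      location = k$y[t0],
      stringsAsFactors = FALSE
    )
  })
  if (!length(out)) {
    return(data.frame(
      track_id = character(), start_index = integer(), end_index = integer(),
      t0_index = integer(), duration = numeric(), peak_abs_omega = numeric(),
      mean_speed_during = numeric(), mean_abs_omega_during = numeric(),
      location = numeric(), stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, out)
}

#' Default near-wall and bulk regions for a channel of width W
#'
#' Wall regions cover the first and last `2.5 * Lc` of the channel; the bulk
#' region is the central band of the same width.
#'
#' @param W channel width (um).
#' @param Lc characteristic cell length (um), default 20.
#' @return a named list of `c(lo, hi)` intervals (um).
#' @export
default_regions <- function(W, Lc = 20) {
  list(
    RW1 = c(0, 2.5 * Lc),
    RW2 = c(W - 2.5 * Lc, W),
    RB = c(W / 2 - 1.25 * Lc, W / 2 + 1.25 * Lc)
  )
}

#' Spatially binned and time-aligned sharp-turn statistics
#'
#' Bins the channel into intervals of `bin_width` and reports, per bin, the
#' number of sharp-turn events `N_t` located there, the number of distinct
#' tracks entering the bin `N_traj`, their ratio, and the mean event duration.
#' In addition, for each named region the speed and `|omega|` series of all
#' events located in the region are aligned on the time of peak angular
#' velocity (`t - t0 = 0`) and averaged across events.
#'
#' @param events event table from [detect_sharp_turns()] (rows from several
#'   tracks may be concatenated with `rbind`).
#' @param kins list of [kinematics] objects the events were detected on.
#' @param W channel width (um).
#' @param bin_width spatial bin width (um); default `2.5 * Lc` with
#'   `Lc = 20` um.
#' @param regions named list of `c(lo, hi)` position intervals for the
#'   aligned profiles; default [default_regions()].
#' @param align_window half-width of the alignment window (s), default 2.
#' @return a list with elements `per_bin` (data.frame: `bin_lo`, `bin_hi`,
#'   `n_turns`, `n_traj`, `turns_per_traj`, `mean_duration`; ratio and mean
#'   duration are `NA` for unvisited bins) and `aligned` (data.frame:
#'   `region`, `t_rel`, `mean_speed`, `mean_abs_omega`, `n_events`).
#' @export
turn_statistics <- function(events, kins, W, bin_width = 2.5 * 20,
                            regions = default_regions(W),
                            align_window = 2) {
  edges <- seq(0, W, by = bin_width)
  if (edges[length(edges)] < W) edges <- c(edges, W)
  nb <- length(edges) - 1L
  dt <- kins[[1]]$dt
  # tracks entering each bin
  n_traj <- integer(nb)
  for (k in kins) {
    b <- findInterval(k$y, edges, rightmost.closed = TRUE)
    b <- unique(b[b >= 1L & b <= nb])
    n_traj[b] <- n_traj[b] + 1L
  }
  ev_bin <- findInterval(events$location, edges, rightmost.closed = TRUE)
  n_turns <- tabulate(ev_bin[ev_bin >= 1L & ev_bin <= nb], nbins = nb)
  mean_dur <- vapply(seq_len(nb), function(b) {
    d <- events$duration[ev_bin == b]
    if (length(d)) mean(d) else NA_real_
  }, numeric(1))
  per_bin <- data.frame(
    bin_lo = edges[-length(edges)], bin_hi = edges[-1],
    n_turns = n_turns, n_traj = n_traj,
    turns_per_traj = ifelse(n_traj > 0L, n_turns / n_traj, NA_real_),
    mean_duration = mean_dur
  )

  # time-aligned ensemble profiles per region
  kin_by_id <- stats::setNames(kins, vapply(kins, `[[`, character(1), "track_id"))
  half <- round(align_window / dt)
  offsets <- -half:half
  aligned <- list()
  for (rn in names(regions)) {
    rg <- regions[[rn]]
    evr <- events[events$location >= rg[1] & events$location <= rg[2], , drop = FALSE]
    sp_sum <- numeric(length(offsets)); om_sum <- numeric(length(offsets))
    cnt <- integer(length(offsets))
    for (ii in seq_len(nrow(evr))) {
      k <- kin_by_id[[evr$track_id[ii]]]
      if (is.null(k)) next
      j <- evr$t0_index[ii] + offsets
      ok <- j >= 1L & j <= length(k$times)
      sp_sum[ok] <- sp_sum[ok] + k$speed[j[ok]]
      om_sum[ok] <- om_sum[ok] + abs(k$omega[j[ok]])
      cnt[ok] <- cnt[ok] + 1L
    }
    aligned[[rn]] <- data.frame(
      region = rn, t_rel = offsets * dt,
      mean_speed = ifelse(cnt > 0L, sp_sum / cnt, NA_real_),
      mean_abs_omega = ifelse(cnt > 0L, om_sum / cnt, NA_real_),
      n_events = cnt
    )
  }
  list(per_bin = per_bin, aligned = do.call(rbind, aligned))
}
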