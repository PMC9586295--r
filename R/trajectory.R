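#' Construct a planar cell trajectory
#'
#' A trajectory is one cell's uniformly sampled planar track in the
#' (streamwise, wall-normal) frame: the `x` coordinate runs along the channel
#' and the `y` coordinate runs from the wall at 0 to the wall at `W`
#' (positions in micrometres, times in seconds).
#'
#' @param track_id identifier (coerced to character).
#' @param times numeric vector of sample times (s), strictly increasing and
#'   uniformly spaced.
#' @param x,y numeric position coordinates (um), same length as `times`.
#' @param frame_interval optional sampling interval Delta-t (s); inferred from
#'   `times` when `NULL`. Sampling must be uniform to within 1e-6 s.
#' @return an object of class `trajectory`: a list with elements `track_id`,
#'   `times`, `x`, `y`, `dt`.
#' @export
trajectory <- function(track_id, times, x, y, frame_interval = NULL) {
  times <- as.numeric(times); x <- as.numeric(x); y <- as.numeric(y)
  n <- length(times)
  if (n < 2L) stop("trajectory(): at least 2 samples are required")
  if (length(x) != n || length(y) != n) {
    stop("trajectory(): times, x and y must have the same length")
  }
  if (any(!is.finite(times)) || any(!is.finite(x)) || any(!is.finite(y))) {
    stop("trajectory(): times and positions must be finite")
  }
  dtimes <- diff(times)
  if (any(dtimes <= 0)) stop("trajectory(): times must be strictly increasing")
  dt <- if (is.null(frame_interval)) stats::median(dtimes) else as.numeric(frame_interval)
  if (any(abs(dtimes - dt) > 1e-6)) {
    stop("trajectory(): sampling is not uniform (|diff(times) - dt| > 1e-6 s)")
  }
  structure(
    list(track_id = as.character(track_id)[1], times = times, x = x, y = y, dt = dt),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory %s: %d samples, dt = %g s, duration = %g s>\n",
              x$track_id, length(x$times), x$dt,
              x$times[length(x$times)] - x$times[1]))
  invisible(x)
}

#' Read a delimited track table
#'
#' Reads particle-tracking exports with columns `TRACK_ID`, `POSITION_T` (s),
#' `POSITION_X` (um), `POSITION_Y` (um) -- the column set written by common
#' tracking tools. Extra columns are ignored and the delimiter (comma or tab)
#' is detected automatically. Tracks with fewer than 2 samples cannot carry
#' kinematics and are dropped with a warning.
#'
#' @param path path to a delimited text file.
#' @return a list of [trajectory] objects, one per track id, each ordered by
#'   time. The number of dropped single-sample tracks is attached as attribute
#'   `n_dropped`.
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop("read_tracks(): file not found: ", path)
  tab <- data.table::fread(path, header = TRUE, data.table = TRUE)
  need <- c("TRACK_ID", "POSITION_T", "POSITION_X", "POSITION_Y")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("read_tracks(): missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("POSITION_T", "POSITION_X", "POSITION_Y")) {
    tab[[col]] <- suppressWarnings(as.numeric(tab[[col]]))
  }
  bad <- !stats::complete.cases(tab[, need, with = FALSE])
  if (any(bad)) {
    stop("read_tracks(): malformed rows (non-numeric or missing fields) at line(s): ",
         paste(utils::head(which(bad) + 1L, 10L), collapse = ", "))
  }
  split_tab <- split(tab, by = "TRACK_ID", sorted = TRUE)
  n_dropped <- 0L
  out <- list()
  for (tb in split_tab) {
    if (nrow(tb) < 2L) {
      n_dropped <- n_dropped + 1L
      next
    }
    o <- order(tb$POSITION_T)
    out[[length(out) + 1L]] <- trajectory(
      track_id = tb$TRACK_ID[1],
      times = tb$POSITION_T[o], x = tb$POSITION_X[o], y = tb$POSITION_Y[o]
    )
  }
  if (n_dropped > 0L) {
    warning(sprintf("read_tracks(): dropped %d track(s) with < 2 samples", n_dropped))
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write trajectories as a delimited track table
#'
#' Inverse of [read_tracks()]: writes one row per sample with columns
#' `TRACK_ID`, `POSITION_T`, `POSITION_X`, `POSITION_Y`.
#'
#' @param tracks list of [trajectory] objects.
#' @param path output path.
#' @param sep field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path, sep = "\t") {
  # %.17g guarantees doubles survive the text round trip bit-exactly
  tab <- data.table::rbindlist(lapply(tracks, function(t) {
    data.table::data.table(
      TRACK_ID = t$track_id, POSITION_T = sprintf("%.17g", t$times),
      POSITION_X = sprintf("%.17g", t$x), POSITION_Y = sprintf("%.17g", t$y)
    )
  }))
  data.table::fwrite(tab, path, sep = sep)
  invisible(path)
}

# Symmetric moving-average kernel for an integer window.
# Even windows use span window+1 with half weights at the extremes, so the
# filter is symmetric (zero phase shift) while still averaging `window`
# samples' worth of weight; odd windows are the plain centred mean.
smoothing_kernel <- function(window) {
  if (window %% 2L == 0L) {
    c(0.5, rep(1, window - 1L), 0.5) / window
  } else {
    rep(1, window) / window
  }
}

smooth_series <- function(x, kern) {
  n <- length(x)
  half <- (length(kern) - 1L) %/% 2L
  if (half == 0L || n == 1L) return(x)
  out <- as.numeric(stats::filter(x, kern, sides = 2))
  # truncated, renormalized window at the track ends
  edge <- which(is.na(out))
  for (i in edge) {
    j <- max(1L, i - half):min(n, i + half)
    kk <- kern[j - i + half + 1L]
    out[i] <- sum(kk * x[j]) / sum(kk)
  }
  out
}

#' Smooth a trajectory with a repeated moving average
#'
#' Applies `passes` sequential passes of a centred moving-average of `window`
#' points to each coordinate, the standard pre-processing that removes
#' frame-to-frame zigzag (helical swimming, localization noise) before
#' kinematic quantities are computed. For an even `window` the filter is the
#' symmetric even-length moving average (half weights on the two extreme
#' samples, total span `window + 1`), which preserves linear trends exactly;
#' at the track ends the window is truncated and renormalized.
#'
#' @param t a [trajectory].
#' @param window integer window size (samples), >= 1. Default 10.
#' @param passes number of passes, >= 0. Default 5.
#' @return a [trajectory] with identical times and smoothed coordinates.
#' @export
smooth_trajectory <- function(t, window = 10L, passes = 5L) {
  stopifnot(inherits(t, "trajectory"))
  window <- as.integer(window); passes <- as.integer(passes)
  if (window < 1L) stop("smooth_trajectory(): window must be >= 1")
  if (passes < 0L) stop("smooth_trajectory(): passes must be >= 0")
  if (passes == 0L || window == 1L) return(t)
  kern <- smoothing_kernel(window)
  x <- t$x; y <- t$y
  for (p in seq_len(passes)) {
    x <- smooth_series(x, kern)
    y <- smooth_series(y, kern)
  }
  trajectory(t$track_id, t$times, x, y, frame_interval = t$dt)
}
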