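# Independent brute-force oracles used across the suite.

# wrap by repeated +/- 2*pi shifts
wrap_brute <- function(a) {
  vapply(a, function(x) {
    while (x > pi) x <- x - 2 * pi
    while (x <= -pi) x <- x + 2 * pi
    x
  }, numeric(1))
}

# direct truncated-window convolution with the package's symmetric kernel
smooth_brute <- function(x, window, passes) {
  kern <- if (window %% 2 == 0) c(0.5, rep(1, window - 1), 0.5) / window
          else rep(1, window) / window
  half <- (length(kern) - 1) %/% 2
  n <- length(x)
  for (p in seq_len(passes)) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      j <- max(1, i - half):min(n, i + half)
      kk <- kern[j - i + half + 1]
      out[i] <- sum(kk * x[j]) / sum(kk)
    }
    x <- out
  }
  x
}

# brute-force threshold scan: returns start/end/t0 per maximal run
turns_brute <- function(omega, crit) {
  above <- abs(omega) >= crit
  out <- NULL
  i <- 1
  n <- length(above)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1]) j <- j + 1
      aw <- abs(omega[i:j])
      out <- rbind(out, c(start = i, end = j, t0 = i + which.max(aw) - 1))
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  out
}

# circular track sampled at dt: radius R, angular rate om, centred at (0, yc)
circle_track <- function(R = 50, om = 0.5, dt = 0.1, t_end = 20, yc = 500,
                         id = "circle") {
  tt <- seq(0, t_end, by = dt)
  trajectory(id, tt, R * cos(om * tt), yc + R * sin(om * tt))
}

# a random synthetic kinematics object (heading random walk with drifts)
random_kinematics <- function(n = 200, dt = 0.1, seed = NULL, id = "rk") {
  if (!is.null(seed)) set.seed(seed)
  phi <- cumsum(rnorm(n, 0, 0.3))
  kinematics(id, times = (0:(n - 1)) * dt, y = runif(n, 0, 1000),
             speed = runif(n, 10, 100), heading = wrap_angle(phi),
             omega = rnorm(n, 0, 0.4), dt = dt)
}

# triangle-wave fold of an unbounded coordinate into [0, W] (specular walls)
fold_position <- function(y, W) {
  m <- y %% (2 * W)
  ifelse(m > W, 2 * W - m, m)
}
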