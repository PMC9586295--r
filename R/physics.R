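#' Gyrotactic reorientation rate in the vertical plane
#'
#' A bottom-heavy cell displaced from vertical experiences a gravitational
#' torque balanced by viscous resistance, rotating it back toward upward
#' swimming at rate `omega_g = -cos(theta) / (2B)`, where `B` (s) is the
#' gyrotactic reorientation timescale and `theta` is the heading in the
#' vertical plane (`theta = -pi/2` is upward swimming and is the stable fixed
#' point). This is the planar reduction of the three-dimensional law
#' `dp/dt = [k - (k.p) p] / (2B)` with `k` the unit upward vector.
#'
#' @param theta heading angle(s) in the vertical plane (rad).
#' @param B gyrotactic timescale (s), > 0.
#' @return angular velocity (rad/s), same length as `theta`.
#' @export
gyro_omega <- function(theta, B) {
  if (!is.numeric(B) || length(B) != 1L || !is.finite(B) || B <= 0) {
    stop("gyro_omega(): B must be a positive scalar")
  }
  -cos(theta) / (2 * B)
}

# theta-component of the 3-D gyrotactic law [k - (k.p)p]/(2B) with the planar
# parameterization p = (cos(theta), -sin(theta)) and k = (0, 1); used as an
# independent consistency check of gyro_omega() in the tests.
gyro_omega_from_3d <- function(theta, B) {
  px <- cos(theta); pz <- -sin(theta)
  kdotp <- pz
  # dp/dt components
  dpx <- (0 - kdotp * px) / (2 * B)
  dpz <- (1 - kdotp * pz) / (2 * B)
  # theta from p: theta = atan2(-pz, px); dtheta = (-px*dpz + ... ) chain rule:
  # theta_dot = (pz*dpx - px*dpz) / (px^2 + pz^2) derived from
  # d/dt atan2(-pz, px)
  (-px * dpz + pz * dpx) / (px^2 + pz^2)
}

#' Far-field image-dipole angular velocity near a plane wall
#'
#' The far-field hydrodynamic prediction for the wall-induced angular
#' velocity of a tilted force-dipole swimmer at distance `h` from a plane
#' wall:
#' `omega(h, phi) = (p / (8 pi mu)) * 3 sin(2 phi) / (16 h^3) *
#'  [1 + (Gamma / 2) * (1 + sin^2(phi))]`,
#' with dipole strength `p` (< 0 for a puller), dynamic viscosity `mu` and
#' shape factor `Gamma = (r^2 - 1) / (r^2 + 1)` for aspect ratio `r`
#' (`Gamma ~ 0` for a nearly spherical cell). The bracket carries the even
#' `sin^2(phi)` term, so the whole expression is odd in `phi` and decays as
#' `h^-3`. The function is a diagnostic for comparison with measured fields;
#' it is never used inside the simulator.
#'
#' @param h distance from the wall (um), > 0.
#' @param phi heading relative to the wall (rad).
#' @param p_strength dipole strength (N um); negative for a puller.
#' @param mu dynamic viscosity (consistent units), > 0.
#' @param Gamma shape factor in `[-1, 1]`; default 0 (spherical).
#' @return angular velocity, vectorized over `h` and `phi`.
#' @export
dipole_wall_omega <- function(h, phi, p_strength, mu, Gamma = 0) {
  if (any(h <= 0)) stop("dipole_wall_omega(): h must be > 0")
  if (mu <= 0) stop("dipole_wall_omega(): mu must be > 0")
  if (Gamma < -1 || Gamma > 1) stop("dipole_wall_omega(): Gamma must be in [-1, 1]")
  (p_strength / (8 * pi * mu)) * (3 * sin(2 * phi)) / (16 * h^3) *
    (1 + (Gamma / 2) * (1 + sin(phi)^2))
}

#' Wall-induced velocity diagnostic
#'
#' The quantity `-(V_s - V_sb) * sin(phi)` is the wall-induced wall-normal
#' velocity implied by a measured speed field: a positive value at distance
#' `h` means effective attraction toward the wall for a cell at heading
#' `phi`. A far-field image dipole would make this decay as `h^-2` and change
#' sign at `phi = +/- pi/2 +/- arccos(1/3)`. The diagnostic computes the
#' quantity from a binned speed field near the wall at position 0, fits a
#' power law in `h` per heading bin, and locates the sign changes of the
#' h-averaged profile.
#'
#' @param grid a [binned_field] with `mean_speed` filled (see
#'   [estimate_drift_diffusion()]).
#' @param V_sb bulk swimming speed (um/s).
#' @param h_range distance range (um) used for the power-law fit; default
#'   `c(10, 200)`.
#' @param min_bins minimum defined h-bins per heading for a fitted exponent
#'   (default 4).
#' @return list with `table` (long data.frame `h`, `phi`, `Q`),
#'   `exponents` (data.frame `phi`, `exponent`), `median_exponent`, and
#'   `sign_changes` (headings, rad, where the h-averaged diagnostic crosses
#'   zero). `median_exponent` is `NA` when no heading has enough defined
#'   bins.
#' @export
wall_induced_velocity_diagnostic <- function(grid, V_sb, h_range = c(10, 200),
                                             min_bins = 4L) {
  stopifnot(inherits(grid, "binned_field"))
  if (is.null(grid$mean_speed)) {
    stop("wall_induced_velocity_diagnostic(): run estimate_drift_diffusion() first")
  }
  ctr <- bin_centers(grid)
  rows <- which(ctr$pos >= h_range[1] & ctr$pos <= h_range[2])
  if (!length(rows)) stop("wall_induced_velocity_diagnostic(): empty h range")
  h <- ctr$pos[rows]
  Q <- -(grid$mean_speed[rows, , drop = FALSE] - V_sb) *
    matrix(sin(ctr$ang), length(rows), length(ctr$ang), byrow = TRUE)
  tab <- data.frame(
    h = rep(h, times = length(ctr$ang)),
    phi = rep(ctr$ang, each = length(h)),
    Q = as.vector(Q)
  )
  exponents <- vapply(seq_along(ctr$ang), function(j) {
    q <- Q[, j]
    ok <- is.finite(q) & abs(q) > 0
    if (sum(ok) < min_bins) return(NA_real_)
    unname(coef(stats::lm(log(abs(q[ok])) ~ log(h[ok])))[2])
  }, numeric(1))
  # sign changes of the h-averaged diagnostic across adjacent heading bins
  qbar <- colMeans(Q, na.rm = TRUE)
  sign_changes <- numeric(0)
  for (j in seq_len(length(qbar) - 1L)) {
    a <- qbar[j]; b <- qbar[j + 1L]
    if (is.finite(a) && is.finite(b) && a * b < 0) {
      frac <- a / (a - b)
      sign_changes <- c(sign_changes,
                        ctr$ang[j] + frac * (ctr$ang[j + 1L] - ctr$ang[j]))
    }
  }
  expo_ok <- is.finite(exponents) & abs(sin(ctr$ang)) > 0.2
  list(
    table = tab,
    exponents = data.frame(phi = ctr$ang, exponent = exponents),
    median_exponent = if (any(expo_ok)) stats::median(exponents[expo_ok]) else NA_real_,
    sign_changes = sign_changes
  )
}

#' Fit the exponential vertical concentration law
#'
#' Outside the wall layers the steady vertical concentration of a dilute
#' gyrotactic suspension follows `N(z) = N0 * exp(sigma * z / H)` with the
#' dimensionless slope `sigma = V_z * H / D_T` (an effective Peclet number
#' built from the mean vertical swimming velocity `V_z` and the effective
#' translational diffusivity `D_T`). The fit is ordinary least squares on
#' `log N` against `z / H` over the requested position range.
#'
#' @param profile a `concentration_profile` (or data.frame with columns
#'   `position`, `N`).
#' @param H channel height (um).
#' @param fit_range position interval (um) to fit over; default excludes
#'   `5 * Lc = 100` um from each wall.
#' @return list with `N0`, `sigma`, `r_squared`, `n_bins`.
#' @export
fit_exponential_profile <- function(profile, H, fit_range = c(100, H - 100)) {
  stopifnot(all(c("position", "N") %in% names(profile)))
  sel <- profile$position >= fit_range[1] & profile$position <= fit_range[2] &
    is.finite(profile$N)
  z <- profile$position[sel]; N <- profile$N[sel]
  if (length(z) < 3L) stop("fit_exponential_profile(): need >= 3 bins in fit range")
  if (any(N <= 0)) stop("fit_exponential_profile(): nonpositive N in fit range")
  zh <- z / H
  fit <- stats::lm(log(N) ~ zh)
  tss <- sum((log(N) - mean(log(N)))^2)
  rss <- sum(stats::residuals(fit)^2)
  list(
    N0 = exp(unname(coef(fit)[1])),
    sigma = unname(coef(fit)[2]),
    r_squared = if (tss > 0) 1 - rss / tss else 1,
    n_bins = length(z)
  )
}

#' Stationary heading density of the free gyrotactic orientation process
#'
#' The orientation equation `dtheta = -cos(theta)/(2B) dt + sqrt(2 D_r) dW`
#' on the circle has stationary density proportional to
#' `exp(-sin(theta) / (2 B D_r))` -- a von Mises density centred on upward
#' swimming (`theta = -pi/2`) with concentration `kappa = 1 / (2 B D_r)`.
#'
#' @param theta heading (rad), vectorized.
#' @param B gyrotactic timescale (s), > 0.
#' @param D_r rotational diffusivity (rad^2/s), > 0.
#' @return normalized density values (1/rad).
#' @export
stationary_heading_density <- function(theta, B, D_r) {
  stopifnot(B > 0, D_r > 0)
  kappa <- 1 / (2 * B * D_r)
  f <- function(th) exp(-kappa * sin(th))
  Z <- stats::integrate(f, -pi, pi, rel.tol = 1e-10)$value
  f(theta) / Z
}
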