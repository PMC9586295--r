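#' Coefficient fields for the individual-based model
#'
#' Bundles the three coefficient maps of the planar Langevin model --
#' swimming speed `Vs(y, phi)`, wall-induced angular velocity
#' `omega_w(y, phi)` and rotational diffusivity `Dr(y, phi)` -- as vectorized
#' closures over `[0, W] x (-pi, pi]`, periodic in heading.
#'
#' @param Vs,omega_w,Dr functions of `(y, phi)` returning um/s, rad/s and
#'   rad^2/s respectively, vectorized over both arguments.
#' @param W channel width (um).
#' @param V_sb bulk swimming speed (um/s).
#' @param D_rb bulk rotational diffusivity (rad^2/s).
#' @return an object of class `wall_fields`.
#' @export
wall_fields <- function(Vs, omega_w, Dr, W, V_sb, D_rb) {
  stopifnot(is.function(Vs), is.function(omega_w), is.function(Dr),
            W > 0, V_sb >= 0, D_rb >= 0)
  structure(list(Vs = Vs, omega_w = omega_w, Dr = Dr,
                 W = W, V_sb = V_sb, D_rb = D_rb),
            class = "wall_fields")
}

#' Constant (bulk-valued) coefficient fields
#'
#' The no-wall-effect limit: `Vs = V_sb`, `omega_w = 0`, `Dr = D_rb`
#' everywhere. Under these fields the bounded model has a uniform stationary
#' distribution in both position and orientation.
#'
#' @inheritParams wall_fields
#' @return a [wall_fields] object.
#' @export
constant_fields <- function(W, V_sb, D_rb) {
  wall_fields(
    Vs = function(y, phi) rep_len(V_sb, max(length(y), length(phi))),
    omega_w = function(y, phi) rep_len(0, max(length(y), length(phi))),
    Dr = function(y, phi) rep_len(D_rb, max(length(y), length(phi))),
    W = W, V_sb = V_sb, D_rb = D_rb
  )
}

#' Evaluate wall fields on a regular grid
#'
#' Samples the closures at the bin centres of an `n_pos x n_ang` grid, the
#' representation interpolated linearly by the simulator (mirroring how
#' measured fields enter the model).
#'
#' @param fields a [wall_fields].
#' @param n_pos,n_ang grid size (defaults 51 x 80).
#' @return list with `pos` and `ang` centre vectors and matrices `Vs`,
#'   `omega_w`, `Dr` (`n_pos x n_ang`).
#' @export
fields_to_grids <- function(fields, n_pos = 51L, n_ang = 80L) {
  stopifnot(inherits(fields, "wall_fields"))
  g <- binned_field(fields$W, n_pos, n_ang)
  ctr <- bin_centers(g)
  yy <- matrix(ctr$pos, n_pos, n_ang)
  pp <- matrix(ctr$ang, n_pos, n_ang, byrow = TRUE)
  list(
    pos = ctr$pos, ang = ctr$ang,
    Vs = matrix(fields$Vs(yy, pp), n_pos, n_ang),
    omega_w = matrix(fields$omega_w(yy, pp), n_pos, n_ang),
    Dr = matrix(fields$Dr(yy, pp), n_pos, n_ang)
  )
}
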