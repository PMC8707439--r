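# Per-particle stress tensors and the pair pressure that feeds the
# multi-contact correction.

#' Per-particle average (Love-Weber) stress tensor
#'
#' `sigma_i = -(1/V_i) sum_c sym(l_c (x) F_c)` over the particle's
#' contacts, with `l_c` the branch vector from the particle centre to the
#' contact point and `F_c` the total force exerted *on* the particle
#' there; `V_i` is the sphere volume. The sign convention is
#' compression-positive: inward (squeezing) forces give a positive trace,
#' so that under compaction the multi-contact correction is repulsive.
#'
#' @param radius Particle radius (m), or `volume` given directly.
#' @param branches n x 3 matrix of branch vectors (m).
#' @param forces n x 3 matrix of contact forces on the particle (N).
#' @param volume Particle volume (m^3); computed from `radius` if omitted.
#' @return List of class `mcdem_particle_stress`: `tensor` (3 x 3,
#'   symmetric, Pa) and `volume` (m^3).
#' @export
particle_stress <- function(radius = NULL, branches, forces, volume = NULL) {
  if (is.null(volume)) {
    stopifnot(!is.null(radius), radius > 0)
    volume <- 4 / 3 * pi * radius^3
  }
  if (volume <= 0) stop("particle volume must be > 0")
  branches <- rbind(branches); forces <- rbind(forces)
  stopifnot(ncol(branches) == 3, ncol(forces) == 3,
            nrow(branches) == nrow(forces))
  s <- matrix(0, 3, 3)
  for (k in seq_len(nrow(branches)))
    s <- s - outer(branches[k, ], forces[k, ])
  s <- (s + t(s)) / 2 / volume
  structure(list(tensor = s, volume = volume),
            class = "mcdem_particle_stress")
}

#' Hertzian contact area
#'
#' `A = pi a^2` with contact radius `a^2 = R* delta_n`, i.e.
#' `A = pi R* delta_n` — linear in the overlap.
#'
#' @param delta_n Normal overlap (m).
#' @param pair [effective_properties()] result.
#' @return Contact area (m^2); zero for non-positive overlap.
#' @export
contact_area <- function(delta_n, pair) {
  if (delta_n <= 0) return(0)
  pi * pair$Rstar * delta_n
}

#' Pair pressure entering the multi-contact correction
#'
#' `P_ij = (1/3) (tr(sigma_i) + tr(sigma_j))` — the sum of the two
#' particles' traces over three, exactly as the model states (note this is
#' the sum of the two mean pressures, not their average). With the
#' compression-positive convention of [particle_stress()], compaction
#' yields a positive `P_ij` and therefore extra repulsion.
#'
#' @param s_i,s_j [particle_stress()] results (or plain 3 x 3 matrices).
#' @return Pressure (Pa).
#' @export
pair_pressure <- function(s_i, s_j) {
  tr <- function(s) {
    if (inherits(s, "mcdem_particle_stress")) s <- s$tensor
    sum(diag(s))
  }
  (tr(s_i) + tr(s_j)) / 3
}
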