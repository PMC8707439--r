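# Strain-driven uniaxial compaction: protocol and control containers,
# time-step estimation, and the main simulation driver.

#' Uniaxial loading protocol
#'
#' Displacement-controlled compression along z: the top plate moves down
#' at constant speed until the target engineering strain (referenced to
#' the initial plate gap) or the axial stress stop is reached, then —
#' if `decompress` — reverses at the same speed until the plate force
#' vanishes.
#'
#' @param max_strain Target engineering strain, in (0, 1).
#' @param max_stress Optional stop condition on the measured axial plate
#'   stress (Pa); `Inf` to disable.
#' @param plate_speed Plate speed (m/s); `NULL` derives it from the
#'   step budget in [sim_control()].
#' @param decompress Run the unloading leg?
#' @return A list of class `mcdem_protocol`.
#' @export
loading_protocol <- function(max_strain, max_stress = Inf,
                             plate_speed = NULL, decompress = FALSE) {
  stopifnot(max_strain > 0, max_strain < 1, max_stress > 0)
  structure(list(max_strain = max_strain, max_stress = max_stress,
                 plate_speed = plate_speed, decompress = decompress),
            class = "mcdem_protocol")
}

#' Numerical control settings for a compaction run
#'
#' @param dt Time step (s); `NULL` chooses 0.2 of the contact period of
#'   the smallest pair evaluated at the unloading stiffness (worst case)
#'   and 10\% reference overlap, times `sqrt(mass_scaling)`.
#' @param n_steps Integration steps budgeted for the loading leg; sets
#'   the plate speed when the protocol does not fix it. More steps means
#'   slower, more quasi-static loading.
#' @param record_every Steps between curve samples; `NULL` gives ~400
#'   samples per leg. Stress samples are window averages between records.
#' @param mass_scaling Factor multiplying all particle masses (raises the
#'   stable time step by its square root). Quasi-staticity must be judged
#'   from the kinetic/elastic energy ratio when used.
#' @param dashpot,friction,rolling Switches for the restitution-matched
#'   viscous dashpots, tangential friction, and rolling torque.
#' @param gravity Gravitational acceleration (m/s^2), default 0: sub-mm
#'   beds loaded to MPa stresses are gravity-insensitive.
#' @param max_steps Hard cap on total steps (both legs).
#' @return A list of class `mcdem_control`.
#' @export
sim_control <- function(dt = NULL, n_steps = 2e5, record_every = NULL,
                        mass_scaling = 1, dashpot = TRUE, friction = TRUE,
                        rolling = TRUE, gravity = 0, max_steps = NULL) {
  stopifnot(n_steps >= 1, mass_scaling > 0)
  structure(list(dt = dt, n_steps = as.integer(n_steps),
                 record_every = record_every, mass_scaling = mass_scaling,
                 dashpot = dashpot, friction = friction, rolling = rolling,
                 gravity = gravity, max_steps = max_steps),
            class = "mcdem_control")
}

#' Critical (stable) time step estimate
#'
#' Rayleigh-type estimate from the smallest particle mass and the largest
#' contact stiffness: `dt = safety * sqrt(m_min / k_lin)` with
#' `k_lin = (3/2) k_max sqrt(ref_overlap * r_min)` the linearized slope of
#' the force law at the reference overlap and `k_max` the unloading
#' stiffness `k2` of the smallest pair (worst case).
#'
#' @param packing An `mcdem_packing`.
#' @param material [material_params()]; defaults to the packing's.
#' @param params [contact_model_params()] supplying `k2_over_k1`.
#' @param ref_overlap Reference overlap as a fraction of the smallest
#'   radius (default 0.01).
#' @param safety Safety factor (default 0.2).
#' @return Time step (s).
#' @export
critical_time_step <- function(packing, material = packing$material,
                               params = contact_model_params(),
                               ref_overlap = 0.01, safety = 0.2) {
  if (!length(packing$radius)) stop("empty packing")
  rmin <- min(packing$radius)
  m_min <- 4 / 3 * pi * rmin^3 * material$density
  pair <- effective_properties(material, rmin, material, rmin, params)
  k_lin <- 1.5 * pair$k2 * sqrt(ref_overlap * rmin)
  safety * sqrt(m_min / k_lin)
}

#' Run a strain-driven uniaxial compaction
#'
#' Compresses the packing between its plates along z and records the
#' stress-strain response. The axial stress is the top-plate normal
#' reaction divided by the plate area, window-averaged between curve
#' samples; strain is plate displacement over the initial gap.
#'
#' @param packing An `mcdem_packing` from [generate_packing()].
#' @param params [contact_model_params()]; `beta > 0` activates the
#'   multi-contact correction (particle-particle contacts only).
#' @param protocol [loading_protocol()].
#' @param control [sim_control()].
#' @param material Override for the packing's material.
#' @return An object of class `mcdem_compaction`: `curve` (data.frame
#'   with strain, stress (Pa), relative_density, kinetic_energy,
#'   elastic_energy, n_contacts), `packing` (final state), and
#'   `diagnostics` (dt, plate_speed, steps, max overlap ratio, mean
#'   kinetic/elastic energy ratio over the loaded part of the run).
#' @export
run_uniaxial <- function(packing, params, protocol,
                         control = sim_control(),
                         material = packing$material) {
  stopifnot(inherits(packing, "mcdem_packing"),
            inherits(params, "mcdem_contact_params"),
            inherits(protocol, "mcdem_protocol"),
            inherits(control, "mcdem_control"))
  if (is.null(material)) stop("no material attached to the packing")
  gap <- packing$z_hi - packing$z_lo
  dt <- control$dt
  if (is.null(dt))
    dt <- critical_time_step(packing, material, params, ref_overlap = 0.1) *
      sqrt(control$mass_scaling)
  speed <- protocol$plate_speed
  n_load <- control$n_steps
  if (is.null(speed)) {
    speed <- protocol$max_strain * gap / (n_load * dt)
  } else {
    n_load <- ceiling(protocol$max_strain * gap / (speed * dt))
  }
  record_every <- control$record_every
  if (is.null(record_every)) record_every <- max(1L, n_load %/% 400L)
  max_steps <- control$max_steps
  if (is.null(max_steps))
    max_steps <- ceiling(n_load * (if (protocol$decompress) 2.6 else 1.3))

  cpar <- c(unclass(params),
            list(dashpot = control$dashpot, friction = control$friction,
                 rolling = control$rolling))
  res <- cpp_compress(
    packing$position, packing$radius,
    packing$box[1], packing$box[2], packing$z_lo, packing$z_hi,
    unclass(material), cpar,
    list(plate_speed = speed, max_strain = protocol$max_strain,
         max_stress = protocol$max_stress, decompress = protocol$decompress),
    list(dt = dt, record_every = as.integer(record_every),
         max_steps = as.integer(max_steps),
         mass_scaling = control$mass_scaling, gravity = control$gravity))
  if (isTRUE(res$unstable))
    stop("simulation went unstable (non-finite kinetic energy); ",
         "reduce dt or the plate speed")

  curve <- data.frame(
    strain = res$strain, stress = res$stress,
    relative_density = res$relative_density,
    kinetic_energy = res$kinetic_energy,
    elastic_energy = res$elastic_energy,
    n_contacts = res$n_contacts)
  loaded <- curve$elastic_energy > 0
  ke_ratio <- if (any(loaded))
    mean(curve$kinetic_energy[loaded] / curve$elastic_energy[loaded])
  else NA_real_

  final <- packing
  final$position <- res$state$position
  final$z_hi <- res$state$z_hi
  final$stress_tensors <- res$state$stress
  final$fraction <- packing_fraction(final)
  structure(list(
    curve = curve, packing = final,
    diagnostics = list(dt = res$dt, plate_speed = res$plate_speed,
                       steps = res$steps,
                       max_overlap_ratio = res$max_overlap_ratio,
                       ke_ratio = ke_ratio)
  ), class = "mcdem_compaction")
}

#' @export
print.mcdem_compaction <- function(x, ...) {
  pk <- max(x$curve$stress)
  cat(sprintf(paste0("<mcdem_compaction> %d samples, peak stress %.3g MPa ",
                     "at strain %.3f (%d steps, dt = %.3g s)\n"),
              nrow(x$curve), pk / 1e6,
              x$curve$strain[which.max(x$curve$stress)],
              x$diagnostics$steps, x$diagnostics$dt))
  invisible(x)
}

#' Relative density at a compaction state
#'
#' Solid particle volume over the current bed volume — the packing
#' fraction at the current plate gap. At zero strain this is the initial
#' fraction; at engineering strain `e` it is `fraction0 / (1 - e)`
#' (rigid-particle bookkeeping; overlap volume is not subtracted).
#'
#' @param packing An `mcdem_packing`.
#' @param strain Engineering strain(s) relative to the packing's gap.
#' @return Relative density (dimensionless).
#' @export
relative_density <- function(packing, strain = 0) {
  packing_fraction(packing) / (1 - strain)
}

# Internal: free dynamics without moving plates, used by the collision,
# momentum-conservation and restitution tests.
free_run <- function(position, radius, velocity, angvel = NULL,
                     box, z_lo = 0, z_hi = box[3], material, params,
                     dt, n_steps, record_every = n_steps,
                     walls = TRUE, dashpot = TRUE, friction = TRUE,
                     rolling = TRUE) {
  position <- rbind(position); velocity <- rbind(velocity)
  if (is.null(angvel)) angvel <- matrix(0, nrow(position), 3)
  if (length(box) == 1) box <- rep(box, 3)
  cpar <- c(unclass(params), list(dashpot = dashpot, friction = friction,
                                  rolling = rolling))
  cpp_free_run(position, radius, velocity, rbind(angvel),
               box[1], box[2], z_lo, z_hi,
               unclass(material), cpar, dt, as.integer(n_steps),
               as.integer(record_every), walls)
}
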