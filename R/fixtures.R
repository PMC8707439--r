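# Deterministic test rigs: scripted overlap paths evaluated directly
# against the contact laws (no time integration), and synthetic reference
# compression curves with known generating parameters.

#' Scripted overlap path
#'
#' A piecewise-linear load/unload/reload program over the normal overlap,
#' starting from zero: waypoints are interpolated with `n_per_segment`
#' points each, producing the overlap sequence that drives a contact-law
#' sweep.
#'
#' @param waypoints Numeric vector of overlap waypoints (m); a leading 0
#'   is prepended if absent.
#' @param n_per_segment Samples per segment.
#' @return Numeric vector of overlaps, class `mcdem_scripted_path`.
#' @export
scripted_path <- function(waypoints, n_per_segment = 200) {
  if (waypoints[1] != 0) waypoints <- c(0, waypoints)
  out <- unlist(lapply(seq_len(length(waypoints) - 1), function(k) {
    seq(waypoints[k], waypoints[k + 1], length.out = n_per_segment + 1)[-1]
  }))
  structure(c(0, out), class = "mcdem_scripted_path")
}

#' Two-particle rig: contact-law sweep along a scripted path
#'
#' Evaluates the configured normal law exactly along an overlap path,
#' bypassing time integration — the direct probe of the hysteretic
#' force-displacement loop (loading branch, unloading through the plastic
#' overlap, adhesive minimum, reloading).
#'
#' @param material [material_params()].
#' @param radius Radius of both spheres (m), or a length-2 vector.
#' @param path [scripted_path()] (or numeric overlap vector, m).
#' @param params [contact_model_params()].
#' @param multicontact_area,multicontact_pressure Optional constant
#'   `A_ij` (m^2) and `P_ij` (Pa) switching the sweep to the
#'   multi-contact law.
#' @return Data.frame with `overlap`, `force` (N) and `branch`.
#' @export
two_particle_rig <- function(material, radius, path,
                             params = contact_model_params(),
                             multicontact_area = NULL,
                             multicontact_pressure = NULL) {
  if (length(radius) == 1) radius <- c(radius, radius)
  pair <- effective_properties(material, radius[1], material, radius[2], params)
  st <- contact_state()
  mc <- !is.null(multicontact_area)
  if (mc && is.null(multicontact_pressure)) multicontact_pressure <- 0
  n <- length(path)
  force <- numeric(n); branch <- character(n)
  for (k in seq_len(n)) {
    res <- if (mc)
      multicontact_normal_force(st, path[k], pair, params,
                                multicontact_area, multicontact_pressure)
    else hysteretic_normal_force(st, path[k], pair, params)
    st <- res$state
    force[k] <- res$force; branch[k] <- st$branch
  }
  data.frame(overlap = as.numeric(path), force = force, branch = branch)
}

#' Synthetic reference compressibility curve
#'
#' Runs the simulator itself at known generating parameters and returns
#' the loading-leg stress-strain curve, optionally perturbed by
#' multiplicative Gaussian noise — a stand-in for digitized experimental
#' compression profiles in calibration tests, with the generating truth
#' available for parameter-recovery checks.
#'
#' @param packing An `mcdem_packing`.
#' @param params Generating [contact_model_params()] (e.g. the true
#'   `beta`).
#' @param protocol [loading_protocol()].
#' @param control [sim_control()].
#' @param noise_sd Multiplicative noise standard deviation (0 = exact).
#' @param seed Seed for the noise draw.
#' @return Data.frame `strain`, `stress` with attributes
#'   `provenance = "synthetic"` and `generating_params`.
#' @export
make_synthetic_reference <- function(packing, params, protocol,
                                     control = sim_control(),
                                     noise_sd = 0, seed = NULL) {
  sim <- run_uniaxial(packing, params, protocol, control)
  cv <- sim$curve[seq_len(which.max(sim$curve$stress)), c("strain", "stress")]
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    cv$stress <- cv$stress * (1 + stats::rnorm(nrow(cv), 0, noise_sd))
  }
  attr(cv, "provenance") <- "synthetic"
  attr(cv, "generating_params") <- params
  cv
}
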