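# Pure force-displacement laws. These scalar/vector functions are the
# reference formulation of the contact model; the compiled engine applies
# the same expressions inside the time integration, and the test suite
# pins the two against each other along scripted overlap paths.

#' Multi-contact model parameters
#'
#' The knobs of the hysteretic adhesive elastic-plastic law and its
#' multi-contact extension. `k2_over_k1` sets the (saturated) unloading
#' stiffness relative to the Hertzian loading stiffness, `kc_over_k1` the
#' adhesive branch stiffness, `phi_f` the dimensionless plasticity depth
#' that fixes the overlap at which the unloading stiffness saturates, and
#' `beta` scales the stress-coupled multi-contact correction
#' `(beta * nu * A_ij) * P_ij` (`beta = 0` switches the correction off,
#' recovering conventional DEM). `F0` is a constant pull-off force,
#' zero by default.
#'
#' @param k2_over_k1 Unloading/loading stiffness ratio (>= 1).
#' @param kc_over_k1 Adhesion/loading stiffness ratio (>= 0).
#' @param phi_f Plasticity depth, in (0, 1].
#' @param beta Multi-contact prefactor (>= 0).
#' @param F0 Pull-off force (N).
#' @return An object of class `mcdem_contact_params`.
#' @export
contact_model_params <- function(k2_over_k1 = 120, kc_over_k1 = 0.5,
                                 phi_f = 0.99, beta = 0, F0 = 0) {
  if (k2_over_k1 < 1) stop("k2_over_k1 must be >= 1")
  if (kc_over_k1 < 0) stop("kc_over_k1 must be >= 0")
  if (phi_f <= 0 || phi_f > 1) stop("phi_f must lie in (0, 1]")
  if (beta < 0) stop("beta must be >= 0")
  structure(list(k2_over_k1 = k2_over_k1, kc_over_k1 = kc_over_k1,
                 phi_f = phi_f, beta = beta, F0 = F0),
            class = "mcdem_contact_params")
}

#' Effective pair properties of two contacting bodies
#'
#' Standard Hertz-Mindlin effective quantities:
#' `1/E* = (1-nu_i^2)/E_i + (1-nu_j^2)/E_j`,
#' `1/G* = (2-nu_i)/G_i + (2-nu_j)/G_j` with `G = E/(2(1+nu))`, and
#' `R* = R_i R_j / (R_i + R_j)`. A wall is treated as a particle of
#' infinite radius (`R* = R_i`) made of the material's wall properties.
#' The loading stiffness is Hertzian, `k1 = (4/3) E* sqrt(R*)`, and
#' `kt = 8 G* sqrt(R*)`; `k2` and `kc` follow from the `params` ratios.
#'
#' @param mat_i Material of particle i ([material_params()]).
#' @param r_i Radius of particle i (m).
#' @param mat_j Material of particle j; `NULL` for a wall contact.
#' @param r_j Radius of particle j (m); ignored for a wall.
#' @param params Optional [contact_model_params()] supplying k2/kc ratios
#'   (defaults to the elastic special case k2 = k1, kc = 0).
#' @return A list of class `mcdem_pair`: `Rstar`, `Estar`, `Gstar`,
#'   `k1`, `k2`, `kc`, `kt`, `phi_f`, `F0`, `mu`, `mu_r`, `Rr`
#'   (rolling radius, taken equal to `R*`), `nu_pair` (pair-mean Poisson
#'   ratio entering the multi-contact term) and `restitution`.
#' @export
effective_properties <- function(mat_i, r_i, mat_j = NULL, r_j = NULL,
                                 params = contact_model_params(k2_over_k1 = 1,
                                                               kc_over_k1 = 0)) {
  stopifnot(inherits(mat_i, "mcdem_material"), r_i > 0)
  wall <- is.null(mat_j)
  if (wall) {
    Ej <- mat_i$wall_young; nuj <- mat_i$wall_poisson
    Rstar <- r_i
    mu <- mat_i$sliding_friction_pw; mur <- mat_i$rolling_friction_pw
    e <- mat_i$restitution_pw
  } else {
    stopifnot(inherits(mat_j, "mcdem_material"), r_j > 0)
    Ej <- mat_j$young_modulus; nuj <- mat_j$poisson_ratio
    Rstar <- r_i * r_j / (r_i + r_j)
    mu <- mat_i$sliding_friction_pp; mur <- mat_i$rolling_friction_pp
    e <- mat_i$restitution_pp
  }
  Ei <- mat_i$young_modulus; nui <- mat_i$poisson_ratio
  Estar <- 1 / ((1 - nui^2) / Ei + (1 - nuj^2) / Ej)
  Gi <- Ei / (2 * (1 + nui)); Gj <- Ej / (2 * (1 + nuj))
  Gstar <- 1 / ((2 - nui) / Gi + (2 - nuj) / Gj)
  k1 <- 4 / 3 * Estar * sqrt(Rstar)
  structure(list(
    Rstar = Rstar, Estar = Estar, Gstar = Gstar,
    k1 = k1, k2 = params$k2_over_k1 * k1, kc = params$kc_over_k1 * k1,
    kt = 8 * Gstar * sqrt(Rstar),
    phi_f = params$phi_f, F0 = params$F0,
    mu = mu, mu_r = mur, Rr = Rstar,
    nu_pair = if (wall) nui else (nui + nuj) / 2,
    restitution = e
  ), class = "mcdem_pair")
}

#' Fresh per-contact history state
#'
#' A contact's hysteretic memory: the maximum overlap `delta_max` reached
#' while the contact persists, the accumulated tangential spring, and the
#' branch of the law last taken.
#'
#' @return An object of class `mcdem_contact_state`.
#' @export
contact_state <- function() {
  structure(list(delta_max = 0, delta_t = c(0, 0, 0), branch = "broken"),
            class = "mcdem_contact_state")
}

#' Hertzian elastic normal force
#'
#' `F = k_n delta^{3/2} + gamma_n ddelta` with `k_n = (4/3) E* sqrt(R*)`.
#' The damping contribution is clipped so the total never turns attractive
#' (this elastic law has no adhesion). Negative overlap returns zero.
#'
#' @param delta_n Normal overlap (m).
#' @param ddelta_n Overlap rate (m/s); positive while approaching.
#' @param pair [effective_properties()] result.
#' @param gamma_n Normal dashpot coefficient (N s/m); default 0.
#' @return Normal force (N), repulsive positive.
#' @export
hertz_normal_force <- function(delta_n, ddelta_n = 0, pair, gamma_n = 0) {
  if (delta_n <= 0) return(0)
  max(pair$k1 * delta_n^1.5 + gamma_n * ddelta_n, 0)
}

#' Plastic (residual) overlap of the hysteretic law
#'
#' `delta_0 = (1 - k1/k2*)^{2/3} delta_max`: the overlap at which the
#' unloading branch crosses zero force. `k1 = k2` gives zero residual
#' overlap (non-linear elasticity); `k2 -> Inf` gives `delta_0 -> delta_max`
#' (perfectly plastic contact).
#'
#' @param delta_max Maximum overlap reached (m).
#' @param k1,k2_star Loading and (current) unloading stiffnesses.
#' @return Residual overlap (m).
#' @export
plastic_overlap <- function(delta_max, k1, k2_star) {
  if (k2_star < k1) stop("invalid stiffness: k2_star < k1")
  (1 - k1 / k2_star)^(2 / 3) * delta_max
}

#' History-dependent unloading stiffness
#'
#' The unloading stiffness interpolates linearly in `delta_max` between
#' `k1` (undamaged contact) and `k2` (fully developed plastic contact),
#' saturating at the plastic-flow overlap
#' `delta*_max = k2/(k2 - k1) * phi_f * 2 R*`.
#'
#' @param delta_max Maximum overlap reached (m).
#' @param pair [effective_properties()] result (uses `k1`, `k2`, `Rstar`).
#' @param params [contact_model_params()] (uses `phi_f`).
#' @return `k2*` in N m^-3/2.
#' @export
unloading_stiffness <- function(delta_max, pair, params) {
  k1 <- pair$k1; k2 <- params$k2_over_k1 * k1
  if (k2 == k1) return(k1)
  dstar <- k2 / (k2 - k1) * params$phi_f * 2 * pair$Rstar
  if (delta_max >= dstar) k2 else k1 + (k2 - k1) * delta_max / dstar
}

#' Hysteretic adhesive elastic-plastic normal force
#'
#' The three-branch law. With `f1 = k1 d^{3/2}`,
#' `f2 = k2*(d^{3/2} - delta_0^{3/2})` and `f3 = -kc d^{3/2}`:
#' virgin loading `F = F0 + f1` while `f2 >= f1`; unloading/reloading
#' `F = F0 + f2` in between; adhesive branch `F = F0 + f3` once
#' `f3 >= f2`. `delta_max`, `delta_0` and `k2*` are refreshed from the
#' running maximum overlap, which makes the law history dependent; the
#' force is continuous across branch switches, and at exact equality the
#' virgin branch wins.
#'
#' @param state [contact_state()] carrying `delta_max`.
#' @param delta_n Current overlap (m).
#' @param pair [effective_properties()] result.
#' @param params [contact_model_params()].
#' @return List with `force` (N) and the updated `state` (branch recorded).
#' @export
hysteretic_normal_force <- function(state, delta_n, pair, params) {
  stopifnot(inherits(state, "mcdem_contact_state"))
  if (delta_n <= 0) {
    state$delta_max <- 0; state$delta_t <- c(0, 0, 0); state$branch <- "broken"
    return(list(force = 0, state = state))
  }
  state$delta_max <- max(state$delta_max, delta_n)
  k1 <- pair$k1
  k2s <- unloading_stiffness(state$delta_max, pair, params)
  d0 <- plastic_overlap(state$delta_max, k1, k2s)
  kc <- params$kc_over_k1 * k1
  f1 <- k1 * delta_n^1.5
  f2 <- k2s * (delta_n^1.5 - d0^1.5)
  f3 <- -kc * delta_n^1.5
  # ties go to the virgin branch, with a 1e-12 relative slack absorbing the
  # rounding of ((1 - k1/k2*)^(2/3))^(3/2) during monotone loading
  if (f2 >= f1 - 1e-12 * abs(f1)) {
    state$branch <- "loading"; F <- params$F0 + f1
  } else if (f2 > f3) {
    state$branch <- "unload_reload"; F <- params$F0 + f2
  } else {
    state$branch <- "adhesive"; F <- params$F0 + f3
  }
  list(force = F, state = state)
}

#' Hysteretic law with the multi-contact correction
#'
#' Adds the stress-coupled term `(beta * nu * A_ij) * P_ij` to whichever
#' branch of [hysteretic_normal_force()] is active; `nu` is the pair-mean
#' Poisson ratio, `A_ij` the contact area and `P_ij` the pair pressure
#' from [pair_pressure()]. With `beta = 0` the result is identical to the
#' plain hysteretic law.
#'
#' @inheritParams hysteretic_normal_force
#' @param area Contact area `A_ij` (m^2, >= 0).
#' @param pressure Pair pressure `P_ij` (Pa, compression positive).
#' @return List with `force` (N) and updated `state`.
#' @export
multicontact_normal_force <- function(state, delta_n, pair, params,
                                      area, pressure) {
  if (area < 0) stop("contact area must be >= 0")
  base <- hysteretic_normal_force(state, delta_n, pair, params)
  if (base$state$branch == "broken") return(base)
  base$force <- base$force + params$beta * pair$nu_pair * area * pressure
  base
}

#' Mindlin-type tangential force with Coulomb cap
#'
#' The tangential spring accumulates the integrated surface-tangential
#' velocity, `delta_t += v_t dt`; the force is
#' `F_t = -kt |delta_t|^{1/2} delta_t - gamma_t v_t`, capped at
#' `mu * F_n` with the spring rescaled onto the cap when sliding.
#' A non-positive normal force releases the contact (zero force, spring
#' reset).
#'
#' @param state [contact_state()] carrying the spring `delta_t`.
#' @param v_t Tangential relative surface velocity (3-vector, m/s).
#' @param dt Time step (s).
#' @param Fn Current total normal force (N).
#' @param pair [effective_properties()] result.
#' @param gamma_t Tangential dashpot coefficient; default 0.
#' @return List with `force` (3-vector, N) and updated `state`.
#' @export
tangential_force <- function(state, v_t, dt, Fn, pair, gamma_t = 0) {
  stopifnot(inherits(state, "mcdem_contact_state"), dt > 0)
  if (Fn <= 0) {
    state$delta_t <- c(0, 0, 0)
    return(list(force = c(0, 0, 0), state = state))
  }
  s <- state$delta_t + v_t * dt
  smag <- sqrt(sum(s^2))
  Ft <- -pair$kt * sqrt(smag) * s - gamma_t * v_t
  fmag <- sqrt(sum(Ft^2))
  cap <- pair$mu * Fn
  if (fmag > cap) {
    Ft <- Ft * (cap / fmag)
    s <- if (smag > 0) s * ((cap / pair$kt)^(2 / 3) / smag) else s
  }
  state$delta_t <- s
  list(force = Ft, state = state)
}

#' Constant-directional rolling torque
#'
#' `tau = -omega_rel/|omega_rel| * mu_r * R_r * |F_n|`, opposing the
#' relative rotation; zero when the relative angular velocity vanishes.
#' The rolling radius `R_r` is the effective radius `R*`.
#'
#' @param omega_rel Relative angular velocity (3-vector, 1/s).
#' @param Fn Normal force (N).
#' @param pair [effective_properties()] result.
#' @return Torque (3-vector, N m).
#' @export
rolling_torque <- function(omega_rel, Fn, pair) {
  om <- sqrt(sum(omega_rel^2))
  if (om < 1e-300) return(c(0, 0, 0))
  -omega_rel / om * pair$mu_r * pair$Rr * abs(Fn)
}
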