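#' Single-particle and wall material parameters
#'
#' Bundles the particle-scale mechanical properties a simulation needs:
#' Young's modulus, Poisson ratio and true density of the particle
#' material, the elastic properties of the die walls/plates, and the
#' restitution, sliding-friction and rolling-friction coefficients for
#' particle-particle (pp) and particle-wall (pw) contacts.
#'
#' @param young_modulus Particle Young's modulus (Pa).
#' @param poisson_ratio Particle Poisson ratio (dimensionless, in [0, 0.5)).
#' @param density Particle true density (kg m^-3).
#' @param restitution_pp,restitution_pw Coefficients of restitution in (0, 1].
#' @param sliding_friction_pp,sliding_friction_pw Sliding friction
#'   coefficients (>= 0); static and dynamic friction are taken equal.
#' @param rolling_friction_pp,rolling_friction_pw Rolling friction
#'   coefficients (>= 0) of the constant-directional-torque model.
#' @param wall_young,wall_poisson Elastic properties of the wall material.
#' @return An object of class `mcdem_material`.
#' @seealso [mcc_a()], [mcc_p()] for the two built-in microcrystalline
#'   cellulose parameter sets.
#' @export
material_params <- function(young_modulus, poisson_ratio, density,
                            restitution_pp = 0.5, restitution_pw = restitution_pp,
                            sliding_friction_pp = 0.5,
                            sliding_friction_pw = sliding_friction_pp,
                            rolling_friction_pp = 0, rolling_friction_pw = 0,
                            wall_young = 7.62e10, wall_poisson = 0.31) {
  stopifnot(young_modulus > 0, density > 0, wall_young > 0)
  if (poisson_ratio < 0 || poisson_ratio >= 0.5)
    stop("poisson_ratio must lie in [0, 0.5)")
  if (restitution_pp <= 0 || restitution_pp > 1 ||
      restitution_pw <= 0 || restitution_pw > 1)
    stop("restitution coefficients must lie in (0, 1]")
  fr <- c(sliding_friction_pp, sliding_friction_pw,
          rolling_friction_pp, rolling_friction_pw)
  if (any(fr < 0)) stop("friction coefficients must be >= 0")
  structure(list(
    young_modulus = young_modulus, poisson_ratio = poisson_ratio,
    density = density,
    restitution_pp = restitution_pp, restitution_pw = restitution_pw,
    sliding_friction_pp = sliding_friction_pp,
    sliding_friction_pw = sliding_friction_pw,
    rolling_friction_pp = rolling_friction_pp,
    rolling_friction_pw = rolling_friction_pw,
    wall_young = wall_young, wall_poisson = wall_poisson
  ), class = "mcdem_material")
}

#' Built-in material: coarse microcrystalline cellulose grade (MCC-A)
#'
#' Particle and wall parameters for a coarse MCC tableting grade
#' (Avicel PH 200 type), with its volume-weighted size-distribution
#' quantiles. The particle Young's modulus stems from nano-indentation
#' scale calibration, the friction set from shear-cell/wall/drum tests.
#'
#' @return A list with elements `material` ([material_params()]) and
#'   `psd` ([psd_spec()]).
#' @export
mcc_a <- function() {
  list(
    material = material_params(
      young_modulus = 2.58e8, poisson_ratio = 0.30, density = 1541.1,
      restitution_pp = 0.352, restitution_pw = 0.352,
      sliding_friction_pp = 0.561, sliding_friction_pw = 0.707,
      rolling_friction_pp = 0.3, rolling_friction_pw = 0.01,
      wall_young = 7.62e10, wall_poisson = 0.31),
    psd = psd_spec(x10 = 82.9, x50 = 224.6, x90 = 379.3)
  )
}

#' Built-in material: fine microcrystalline cellulose grade (MCC-P)
#'
#' Particle and wall parameters for a fine MCC grade (Pharmacel 102 type).
#'
#' @return A list with elements `material` and `psd`; see [mcc_a()].
#' @export
mcc_p <- function() {
  list(
    material = material_params(
      young_modulus = 1.34e9, poisson_ratio = 0.30, density = 1533.7,
      restitution_pp = 0.346, restitution_pw = 0.346,
      sliding_friction_pp = 0.548, sliding_friction_pw = 0.715,
      rolling_friction_pp = 0.3, rolling_friction_pw = 0.01,
      wall_young = 7.62e10, wall_poisson = 0.31),
    psd = psd_spec(x10 = 28.3, x50 = 86.5, x90 = 173.8)
  )
}

#' Particle size distribution quantile specification
#'
#' Volume-weighted (Q3) diameter quantiles as reported by laser
#' diffraction, plus optional hard truncation bounds for sampling.
#' Default truncation is `[x10/2, 1.2 * x90]`, which keeps contact
#' stiffness and the stable time step bounded when sampling from the
#' fitted distribution's tails.
#'
#' @param x10,x50,x90 Diameters (micrometres) below which 10/50/90 percent
#'   of the particle volume lies; must be strictly increasing.
#' @param lower_cut,upper_cut Truncation diameters (micrometres).
#' @return An object of class `mcdem_psd` (diameters stored in metres).
#' @export
psd_spec <- function(x10, x50, x90,
                     lower_cut = x10 / 2, upper_cut = 1.2 * x90) {
  if (!(x10 > 0 && x10 < x50 && x50 < x90))
    stop("invalid PSD: need 0 < x10 < x50 < x90")
  structure(list(
    x10 = x10 * 1e-6, x50 = x50 * 1e-6, x90 = x90 * 1e-6,
    lower_cut = lower_cut * 1e-6, upper_cut = upper_cut * 1e-6,
    span = (x90 - x10) / x50
  ), class = "mcdem_psd")
}

#' Fit a volume-weighted log-normal distribution to Q3 quantiles
#'
#' Three quantiles over-determine the two log-normal parameters, so the
#' median is pinned to `x50` and the log-sd is the least-squares solution
#' over the two log-symmetric quantile ratios,
#' `sigma = ln(x90/x10) / (2 z_0.9)` with `z_0.9 = qnorm(0.9)`. The fit
#' reproduces `x50` and the `x90/x10` ratio exactly; for strongly
#' asymmetric quantile triples the individual `x10`/`x90` values are
#' reproduced only approximately (the relative misfit is returned).
#'
#' @param psd An [psd_spec()] object, or the `x10` diameter (micrometres)
#'   when `x50` and `x90` are given.
#' @param x50,x90 Optional quantiles (micrometres) when `psd` is numeric.
#' @return An object of class `mcdem_psd_fit`: `median` (m), `sdlog`,
#'   `meanlog_number` (log-median of the number-weighted distribution),
#'   truncation bounds (m), and `quantile_rel_error` for x10/x50/x90.
#' @examples
#' f <- fit_psd(psd_spec(82.9, 224.6, 379.3))
#' f$sdlog    # about 0.5933
#' @export
fit_psd <- function(psd, x50 = NULL, x90 = NULL) {
  if (is.numeric(psd)) psd <- psd_spec(psd, x50, x90)
  stopifnot(inherits(psd, "mcdem_psd"))
  z <- qnorm(0.9)
  sdlog <- log(psd$x90 / psd$x10) / (2 * z)
  median <- psd$x50
  fitted <- median * exp(c(-z, 0, z) * sdlog)
  rel <- fitted / c(psd$x10, psd$x50, psd$x90) - 1
  structure(list(
    median = median, sdlog = sdlog,
    meanlog_number = log(median) - 3 * sdlog^2,
    lower_cut = psd$lower_cut, upper_cut = psd$upper_cut,
    quantile_rel_error = stats::setNames(rel, c("x10", "x50", "x90")),
    psd = psd
  ), class = "mcdem_psd_fit")
}

#' Sample particle radii from a fitted size distribution
#'
#' Radii are drawn so that the *volume-weighted* quantiles of a large
#' sample converge to the fitted Q3 distribution; i.e. diameters are
#' sampled from the number-weighted density proportional to
#' `f_volume(d) / d^3` (a log-normal with the same log-sd and log-median
#' shifted by `-3 sdlog^2`), truncated to the specification's cut bounds
#' by inverse-CDF sampling. Deterministic under `set.seed()`.
#'
#' @param fit An [fit_psd()] result.
#' @param n Number of radii to draw (ignored if `target_volume` given).
#' @param target_volume Stop rule: draw until the cumulative particle
#'   volume (m^3) reaches this value.
#' @return Numeric vector of radii in metres.
#' @export
sample_radii <- function(fit, n = NULL, target_volume = NULL) {
  stopifnot(inherits(fit, "mcdem_psd_fit"))
  if (is.null(n) && is.null(target_volume))
    stop("give either n or target_volume")
  ml <- fit$meanlog_number; sl <- fit$sdlog
  if (sl <= 0) {                      # monodisperse degenerate case
    d1 <- fit$median
    if (!is.null(n)) return(rep(d1 / 2, n))
    nn <- ceiling(target_volume / (pi / 6 * d1^3))
    return(rep(d1 / 2, nn))
  }
  plo <- plnorm(fit$lower_cut, ml, sl)
  phi <- plnorm(fit$upper_cut, ml, sl)
  draw <- function(k) {
    u <- runif(k, plo, phi)
    qlnorm(u, ml, sl) / 2             # diameter -> radius
  }
  if (!is.null(n)) return(draw(n))
  rad <- numeric(0); vol <- 0
  while (vol < target_volume) {
    k <- max(16L, ceiling((target_volume - vol) /
                            (pi / 6 * exp(3 * ml + 4.5 * sl^2))))
    nr <- draw(k)
    cv <- vol + cumsum(4 / 3 * pi * nr^3)
    take <- which(cv >= target_volume)
    if (length(take)) {
      rad <- c(rad, nr[seq_len(take[1])])
      vol <- cv[take[1]]
    } else {
      rad <- c(rad, nr)
      vol <- cv[k]
    }
  }
  rad
}

#' @export
print.mcdem_material <- function(x, ...) {
  cat("<mcdem_material> E =", format(x$young_modulus, digits = 4),
      "Pa, nu =", x$poisson_ratio, ", rho =", x$density, "kg/m^3\n")
  invisible(x)
}

#' @export
print.mcdem_psd_fit <- function(x, ...) {
  cat("<mcdem_psd_fit> volume-weighted log-normal: median =",
      format(x$median * 1e6, digits = 4), "um, sdlog =",
      format(x$sdlog, digits = 4), "\n")
  invisible(x)
}
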