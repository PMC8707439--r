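# Shared fixtures: small, fast rigs built in code.

# coarse MCC-like test material (soft particles, stiff walls)
test_material <- function() {
  material_params(
    young_modulus = 2.58e8, poisson_ratio = 0.30, density = 1541.1,
    restitution_pp = 0.352, restitution_pw = 0.352,
    sliding_friction_pp = 0.561, sliding_friction_pw = 0.707,
    rolling_friction_pp = 0.3, rolling_friction_pw = 0.01,
    wall_young = 7.62e10, wall_poisson = 0.31)
}

# near-monodisperse PSD whose samples are effectively one size
narrow_fit <- function(d50_um = 60) {
  fit_psd(psd_spec(0.95 * d50_um, d50_um, 1.05 * d50_um))
}

# small packing reused across dynamic tests (cached per session)
tiny_packing <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressWarnings(
        generate_packing(0.35e-3, narrow_fit(), 0.58, test_material(),
                         seed = 7))
    cache
  }
})

# reference pair for contact-law examples: two x50-sized coarse spheres
x50_pair <- function(params = contact_model_params()) {
  effective_properties(test_material(), 112.3e-6, test_material(), 112.3e-6,
                       params)
}

expect_rel_equal <- function(object, expected, tol) {
  expect_true(abs(object / expected - 1) < tol,
              label = sprintf("%.10g vs expected %.10g (rel err %.2g > %.2g)",
                              object, expected,
                              abs(object / expected - 1), tol))
}
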