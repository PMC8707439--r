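# Pure contact-law operations: effective properties, the hysteretic
# adhesive elastic-plastic normal law, tangential/rolling laws, and the
# multi-contact correction.

test_that("effective properties follow the reciprocal Hertz-Mindlin forms", {
  m <- test_material()
  r <- 1e-4
  p <- effective_properties(m, r, m, r)
  expect_equal(p$Rstar, r / 2)
  # oracle: direct evaluation of 1/E* = 2 (1 - nu^2)/E
  expect_equal(p$Estar, 2.58e8 / (2 * (1 - 0.3^2)), tolerance = 1e-12)
  expect_equal(p$Estar, 1.4176e8, tolerance = 1e-4)
  G <- 2.58e8 / (2 * 1.3)
  expect_equal(p$Gstar, 1 / (2 * (2 - 0.3) / G), tolerance = 1e-12)
  expect_equal(p$k1, 4 / 3 * p$Estar * sqrt(p$Rstar), tolerance = 1e-12)

  # wall contact: infinite-radius partner with wall elastic constants
  pw <- effective_properties(m, r)
  expect_equal(pw$Rstar, r)
  Ew <- 1 / ((1 - 0.3^2) / 2.58e8 + (1 - 0.31^2) / 7.62e10)
  expect_equal(pw$Estar, Ew, tolerance = 1e-12)
  expect_lt(abs(pw$Estar / 2.83e8 - 1), 0.01)  # dominated by the soft side
  expect_equal(pw$mu, m$sliding_friction_pw)
})

test_that("Hertzian normal force matches closed-form arithmetic", {
  p <- x50_pair()
  expect_identical(hertz_normal_force(0, 10, p), 0)
  expect_identical(hertz_normal_force(-1e-6, 0, p), 0)
  # two x50 coarse spheres at 1 um overlap: F = (4/3) E* sqrt(R*) d^1.5
  FF <- hertz_normal_force(1e-6, 0, p)
  expect_equal(FF, 4 / 3 * 1.4175824e8 * sqrt(56.15e-6) * (1e-6)^1.5,
               tolerance = 1e-6)
  expect_rel_equal(FF, 1.416e-3, 1e-3)
  expect_equal(hertz_normal_force(2e-6, 0, p) / FF, 2^1.5, tolerance = 1e-12)
  # damping never makes the elastic law attractive
  expect_identical(hertz_normal_force(1e-6, -1e9, p, gamma_n = 1), 0)
})

test_that("plastic overlap reproduces its limits and the table ratio", {
  expect_equal(plastic_overlap(1e-5, 1e6, 1e6), 0)
  expect_equal(plastic_overlap(1e-5, 1e6, 120e6) / 1e-5,
               (119 / 120)^(2 / 3), tolerance = 1e-12)
  expect_equal(plastic_overlap(1e-5, 1e6, 1e18) / 1e-5, 1, tolerance = 1e-9)
  expect_error(plastic_overlap(1e-5, 2e6, 1e6), "invalid stiffness")
})

test_that("unloading stiffness interpolates between k1 and k2", {
  pr <- x50_pair()
  pm <- contact_model_params(k2_over_k1 = 120, phi_f = 0.99)
  k1 <- pr$k1
  expect_equal(unloading_stiffness(0, pr, pm), k1)
  dstar <- 120 / 119 * 0.99 * 2 * pr$Rstar
  expect_rel_equal(dstar, 1.1214e-4, 1e-3)
  expect_equal(unloading_stiffness(dstar, pr, pm), 120 * k1)
  expect_equal(unloading_stiffness(2 * dstar, pr, pm), 120 * k1)
  expect_equal(unloading_stiffness(dstar / 2, pr, pm), 60.5 * k1,
               tolerance = 1e-12)
  # continuous and non-decreasing
  ks <- vapply(seq(0, 2 * dstar, length.out = 400),
               unloading_stiffness, 0, pair = pr, params = pm)
  expect_true(all(diff(ks) >= -1e-9 * k1))
})

test_that("virgin loading follows k1 d^1.5 and reduces to Hertz when k1 = k2", {
  pm0 <- contact_model_params(k2_over_k1 = 1, kc_over_k1 = 0)
  pr <- x50_pair(pm0)
  path <- scripted_path(c(2e-5, 5e-6, 1.5e-5, 0), n_per_segment = 150)
  sweep <- two_particle_rig(test_material(), 112.3e-6, path, pm0)
  hertz <- vapply(sweep$overlap, hertz_normal_force, 0, ddelta_n = 0, pair = pr)
  expect_equal(sweep$force, hertz, tolerance = 1e-14)

  pm <- contact_model_params()
  mono <- scripted_path(2e-5, n_per_segment = 300)
  up <- two_particle_rig(test_material(), 112.3e-6, mono, pm)
  expect_equal(up$force, pr$k1 * as.numeric(mono)^1.5, tolerance = 1e-14)
  expect_true(all(up$branch[-1] == "loading"))
})

test_that("unloading crosses zero at the plastic overlap and bottoms at the adhesive minimum", {
  pm <- contact_model_params(k2_over_k1 = 120, kc_over_k1 = 0.5, phi_f = 0.99)
  pr <- x50_pair(pm)
  dmax <- 3e-5
  k2s <- unloading_stiffness(dmax, pr, pm)
  d0 <- plastic_overlap(dmax, pr$k1, k2s)
  path <- scripted_path(c(dmax, 1e-9), n_per_segment = 6000)
  sw <- two_particle_rig(test_material(), 112.3e-6, path, pm)
  un <- sw[seq(6002, 12001), ]          # the unloading segment
  # sign change brackets d0
  i <- which(diff(sign(un$force)) < 0)[1]
  expect_true(un$overlap[i + 1] <= d0 && d0 <= un$overlap[i])
  # the adhesive branch takes over where -kc d^1.5 meets the unloading
  # branch: dmin = ((k2* - k1)/(k2* + kc))^(2/3) dmax (brute-force sweep
  # confirms this intersection of the three-branch law), and the minimum
  # force is -kc dmin^1.5 there
  kc <- pm$kc_over_k1 * pr$k1
  dmin <- ((k2s - pr$k1) / (k2s + kc))^(2 / 3) * dmax
  expect_rel_equal(min(un$force), -kc * dmin^1.5, 1e-3)
  imin <- which.min(un$force)
  expect_rel_equal(un$overlap[imin], dmin, 1e-3)
  k2s_sat <- unloading_stiffness(2 * 120 / 119 * 0.99 * 2 * pr$Rstar, pr, pm)
  expect_equal(k2s_sat, 120 * pr$k1)    # saturated beyond the plastic-flow limit
})

test_that("force is continuous along load/unload/reload paths", {
  pm <- contact_model_params(k2_over_k1 = 120, kc_over_k1 = 0.5, phi_f = 0.99)
  wp <- c(2.5e-5, 8e-6, 1.8e-5, 2e-6, 3e-5)
  coarse <- two_particle_rig(test_material(), 112.3e-6,
                             scripted_path(wp, 400), pm)
  fine <- two_particle_rig(test_material(), 112.3e-6,
                           scripted_path(wp, 4000), pm)
  fmax <- max(abs(fine$force))
  ref <- approx(fine$overlap * 0 + seq_along(fine$overlap), fine$force,
                xout = seq(1, nrow(fine), length.out = nrow(coarse)))$y
  # refined path agrees with the coarse one pointwise: no branch jumps
  expect_lt(max(abs(coarse$force - ref)) / fmax, 1e-3)
  # force increments bounded by the steepest branch slope (Lipschitz):
  # |dF| <= 1.5 k2 sqrt(dmax) |d delta|
  pr <- x50_pair(pm)
  lip <- 1.5 * 120 * pr$k1 * sqrt(max(fine$overlap))
  expect_lt(max(abs(diff(fine$force))),
            lip * max(abs(diff(fine$overlap))) * (1 + 1e-9))
})

test_that("reloading retraces the unloading branch and rejoins virgin loading", {
  pm <- contact_model_params(k2_over_k1 = 120, kc_over_k1 = 0.5, phi_f = 0.99)
  pr <- x50_pair(pm)
  dmax <- 2e-5; dlow <- 1.6e-5
  n <- 500
  up <- two_particle_rig(test_material(), 112.3e-6,
                         scripted_path(c(dmax, dlow, dmax, 2.4e-5), n), pm)
  # segment rows: 1 leading zero, then n points per segment
  seg <- function(k) up[(1 + (k - 1) * n + 1):(1 + k * n), ]
  unload <- seg(2); reload <- seg(3)
  # retrace: at fixed delta_max the law is a function of overlap, so the
  # reload forces reproduce the unload forces at the same overlaps
  expect_equal(approx(reload$overlap, reload$force, xout = 1.8e-5)$y,
               approx(unload$overlap, unload$force, xout = 1.8e-5)$y,
               tolerance = 1e-9)
  # past dmax the virgin branch resumes
  tail_f <- up[up$overlap > dmax, ]
  expect_equal(tail_f$force, pr$k1 * tail_f$overlap^1.5, tolerance = 1e-12)
})

test_that("hysteresis dissipates energy iff k2 > k1 or adhesion is present", {
  loop <- function(pm) {
    path <- scripted_path(c(2e-5, 1e-9), 4000)
    sw <- two_particle_rig(test_material(), 112.3e-6, path, pm)
    sum(diff(sw$overlap) * (sw$force[-1] + sw$force[-nrow(sw)]) / 2)
  }
  w_el <- loop(contact_model_params(k2_over_k1 = 1, kc_over_k1 = 0))
  w_pl <- loop(contact_model_params(k2_over_k1 = 120, kc_over_k1 = 0.5))
  expect_lt(abs(w_el) / w_pl, 1e-9)   # quadrature noise only
  expect_gt(w_pl, 0)
})

test_that("tangential spring obeys the Coulomb cap and unwinds elastically", {
  pr <- x50_pair()
  st <- contact_state()
  # large accumulated spring saturates exactly at mu |Fn|
  res <- tangential_force(st, c(1, 0, 0), 1e-3, Fn = 1e-3, pr)
  expect_equal(sqrt(sum(res$force^2)), 0.561 * 1e-3, tolerance = 1e-12)
  # spring rescaled onto the cap
  expect_equal(pr$kt * sqrt(sum(res$state$delta_t^2))^1.5, 0.561e-3,
               tolerance = 1e-9)
  # zero velocity, zero spring -> zero force
  expect_equal(tangential_force(contact_state(), c(0, 0, 0), 1e-6, 1, pr)$force,
               c(0, 0, 0))
  # elastic unwind: equal and opposite displacement returns spring to zero
  st <- contact_state()
  for (k in 1:10) st <- tangential_force(st, c(1e-4, 0, 0), 1e-6, 1, pr)$state
  for (k in 1:10) st <- tangential_force(st, c(-1e-4, 0, 0), 1e-6, 1, pr)$state
  expect_equal(max(abs(st$delta_t)), 0, tolerance = 1e-18)
  # lost contact resets the spring
  res <- tangential_force(st, c(1, 0, 0), 1e-6, Fn = -1, pr)
  expect_equal(res$force, c(0, 0, 0))
  expect_equal(res$state$delta_t, c(0, 0, 0))
})

test_that("rolling torque opposes relative rotation with CDT magnitude", {
  pr <- x50_pair()
  expect_equal(rolling_torque(c(0, 0, 0), 1, pr), c(0, 0, 0))
  tq <- rolling_torque(c(0, 0, 2), 1e-3, pr)
  expect_rel_equal(sqrt(sum(tq^2)), 0.3 * 56.15e-6 * 1e-3, 1e-3)
  expect_equal(tq, -rolling_torque(c(0, 0, -2), 1e-3, pr))
  expect_lt(sum(tq * c(0, 0, 1)), 0)  # opposes the rotation
})

test_that("multi-contact correction is additive and vanishes with beta or area", {
  pm0 <- contact_model_params(beta = 0)
  pmb <- contact_model_params(beta = 1.3)
  pr <- x50_pair(pmb)
  path <- scripted_path(c(2e-5, 5e-6, 2.5e-5), 100)
  plain <- two_particle_rig(test_material(), 112.3e-6, path, pm0)
  mc0 <- two_particle_rig(test_material(), 112.3e-6, path, pm0,
                          multicontact_area = 1e-9,
                          multicontact_pressure = 1e7)
  expect_equal(mc0$force, plain$force, tolerance = 1e-15)   # beta = 0
  mcb <- two_particle_rig(test_material(), 112.3e-6, path, pmb,
                          multicontact_area = 1e-9,
                          multicontact_pressure = 1e7)
  on <- mcb$overlap > 0
  # oracle: arithmetic, 1.3 * 0.3 * 1e-9 * 1e7 = 3.9e-3 N
  expect_equal(mcb$force[on] - plain$force[on],
               rep(3.9e-3, sum(on)), tolerance = 1e-12)
  mca <- two_particle_rig(test_material(), 112.3e-6, path, pmb,
                          multicontact_area = 0,
                          multicontact_pressure = 1e7)
  expect_equal(mca$force, plain$force, tolerance = 1e-15)   # point contact
  st <- contact_state()
  expect_error(
    multicontact_normal_force(st, 1e-6, pr, pmb, area = -1, pressure = 0),
    "area")
})

test_that("parameter validation rejects unphysical inputs", {
  expect_error(contact_model_params(k2_over_k1 = 0.5), "k2_over_k1")
  expect_error(contact_model_params(phi_f = 0), "phi_f")
  expect_error(contact_model_params(beta = -1), "beta")
  expect_error(material_params(1e8, 0.6, 1000), "poisson")
  expect_error(material_params(1e8, 0.3, 1000, restitution_pp = 0), "restitution")
})
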