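test_that("Debye screening length follows the square-root salt law", {
  expect_equal(debye_kappa(0), 0)
  expect_identical(debye_kappa(0.4) / debye_kappa(0.1), 2)
  expect_equal(debye_kappa(0.15), 0.329 * sqrt(0.15))
  expect_error(debye_kappa(-0.1), ">= 0")
})

test_that("DH prefactor limits and monotonicity", {
  expect_equal(dh_prefactor(0), 1)
  expect_equal(dh_prefactor(2, a = 0), 1)
  grid <- dh_prefactor(seq(0, 2, by = 0.05))
  expect_true(all(diff(grid) > 0))
})

test_that("calibration pins the reference pair energy to one energy unit", {
  K <- calibrate_kcoulomb(r_ref = 5, C_ref = 0.15)
  ep <- electrostatics_params(C = 0.15, K_coulomb = K)
  expect_equal(abs(dh_pair_energy(5, 1, -1, ep)), 1, tolerance = 1e-12)
})

test_that("DH energy obeys Coulomb limit, screening monotonicity and neutrality", {
  xyz <- rbind(c(0, 0, 0), c(0, 0, 6))
  b <- bead_df(xyz, kind = "SC", res = c("LYS", "GLU"))
  topo <- new_topology(assign_charges(b))
  K <- calibrate_kcoulomb()
  e0 <- total_energy(xyz, topo, electrostatics_params(C = 0, K_coulomb = K),
                     no_pairs)
  expect_equal(e0$electrostatic, -K / (80 * 6), tolerance = 1e-12)
  es <- total_energy(xyz, topo, electrostatics_params(C = 0.3, K_coulomb = K),
                     no_pairs)
  expect_lt(abs(es$electrostatic), abs(e0$electrostatic))
  # no charges -> exactly zero electrostatics
  b0 <- b; b0$charge <- 0
  eq <- total_energy(xyz, new_topology(b0),
                     electrostatics_params(C = 0.15), no_pairs)
  expect_identical(eq$electrostatic, 0)
  # overlapping charged beads are rejected
  expect_error(total_energy(rbind(c(0, 0, 0), c(0, 0, 0.005)), topo,
                            electrostatics_params(C = 0.15), no_pairs),
               "overlapping charged")
})

test_that("12-10 contact potential: analytic minimum, zero crossing, decay", {
  xyz <- rbind(c(0, 0, 0), c(5, 0, 0))
  topo <- new_topology(bead_df(xyz), contacts = {
    ct <- data.frame(i = 1, j = 2, pair_kind = "SCSC", span = "inter",
                     r_native = 5, epsilon = 2, salt_bridge = FALSE,
                     dh_comp = 0)
    ct
  })
  at <- function(r) total_energy(rbind(c(0, 0, 0), c(r, 0, 0)), topo,
                                 no_elec, no_pairs)$native_contact
  expect_equal(at(5), -2, tolerance = 1e-12)
  expect_lt(abs(at(500)), 1e-10)
  # root of 5 s^12 - 6 s^10 at s = sqrt(5/6)
  r0 <- 5 * sqrt(5 / 6)
  expect_equal(at(r0), 0, tolerance = 1e-10)
  # minimum: energy rises on either side
  expect_gt(at(4.8), at(5))
  expect_gt(at(5.2), at(5))
})

test_that("excluded volume: value at sigma, truncation, native pairs exempt", {
  xyz <- rbind(c(0, 0, 0), c(4, 0, 0))
  topo <- new_topology(bead_df(xyz))
  ctl <- ff_control(ev_sigma = 4, ev_epsilon = 1)
  e_sig <- total_energy(xyz, topo, no_elec, ctl)$excluded_volume
  expect_equal(e_sig, 1, tolerance = 1e-6)
  far <- total_energy(rbind(c(0, 0, 0), c(17, 0, 0)), topo, no_elec, ctl)
  expect_identical(far$excluded_volume, 0)
  # a native-contact pair never contributes excluded volume
  topo2 <- topo
  topo2$contacts <- data.frame(i = 1, j = 2, pair_kind = "SCSC",
                               span = "inter", r_native = 5, epsilon = 1,
                               salt_bridge = FALSE, dh_comp = 0)
  e2 <- total_energy(xyz, topo2, no_elec, ctl)
  expect_identical(e2$excluded_volume, 0)
})

test_that("energy decomposition closes and matches the brute-force oracle", {
  ctl <- ff_control(wall_radius = 40)
  ep <- electrostatics_params(C = 0.1)
  for (s in 1:6) {
    fr <- random_frame(fx_fifty_topo, seed = 100 + s)
    e <- total_energy(fr, fx_fifty_topo, ep, ctl)
    expect_equal(e$total,
                 e$bond + e$angle + e$dihedral + e$chirality +
                   e$native_contact + e$excluded_volume + e$electrostatic +
                   e$wall, tolerance = 1e-9)
    o <- oracle_energy(fr, fx_fifty_topo, ep, ctl)
    for (nm in names(o))
      expect_equal(e[[nm]], o[[nm]], tolerance = 1e-9,
                   label = paste("component", nm, "seed", s))
  }
})

test_that("analytic forces agree with central finite differences", {
  ep <- electrostatics_params(C = 0.15)
  for (s in 1:3) {
    fr <- random_frame(fx_mixed_topo, seed = 200 + s, sd = 0.1, min_dist = 2.8)
    err <- fd_force_error(fx_mixed_topo, fr, ep, ff_control())
    expect_lt(err, 1e-6)
  }
})

test_that("every term is invariant under rigid translations and rotations", {
  fr <- random_frame(fx_dimer_topo, seed = 55)
  ep <- electrostatics_params(C = 0.15)
  e0 <- unlist(total_energy(fr, fx_dimer_topo, ep, no_pairs))
  shifted <- sweep(fr, 2, c(3.2, -7.1, 11.0), "+")
  th <- 0.83
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rotated <- fr %*% t(R)
  for (tr in list(shifted, rotated)) {
    e1 <- unlist(total_energy(tr, fx_dimer_topo, ep, no_pairs))
    expect_equal(e1, e0, tolerance = 1e-9)
  }
})

test_that("uncharging every bead reproduces the plain structure-based model", {
  fr <- random_frame(fx_salt_topo, seed = 77)
  plain <- fx_salt_topo
  plain$beads$charge <- 0
  e_off <- total_energy(fr, fx_salt_topo, no_elec, ff_control())
  e_plain <- total_energy(fr, plain, electrostatics_params(C = 0.15),
                          ff_control())
  expect_equal(e_plain$total, e_off$total, tolerance = 1e-12)
})

test_that("kelvin labels map linearly into reduced temperature", {
  expect_equal(reduced_temperature(55), 55 * 0.00831451)
  expect_equal(reduced_temperature(0), 0)
})
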