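# Metropolis sampler: determinism, constraints, Boltzmann statistics,
# enforced rotation and topology switching.

test_that("identical configurations give bit-identical ensembles", {
  top <- toy_motor_topology()
  cfg <- sampler_config(n_steps = 20000, stride = 20, seed = 33)
  a <- sample_cg(top, cfg)
  b <- sample_cg(top, cfg)
  expect_identical(a$frames, b$frames)
  c <- sample_cg(top, sampler_config(n_steps = 20000, stride = 20, seed = 34))
  expect_false(identical(a$frames, c$frames))
})

test_that("constrained bonds are held at exactly r0 in every frame", {
  top <- two_bead_top(r0 = 0.35, constrained = TRUE)
  ens <- sample_cg(top, sampler_config(n_steps = 5000, stride = 10, seed = 35))
  lens <- vapply(ens$frames, function(f) sqrt(sum((f[1, ] - f[2, ])^2)),
                 numeric(1))
  expect_lt(max(abs(lens - 0.35)), 1e-12)
})

test_that("constraint chains are rejected with a clear error", {
  top <- cg_topology("chain", bead_table(c("A", "B", "C"), "TC5"),
                     bond_table(c(1, 2), c(2, 3), 0.35, 0,
                                constrained = TRUE))
  expect_error(sample_cg(top, sampler_config(n_steps = 1000, seed = 1)),
               "constraint chains")
})

test_that("bond-length statistics match the exact stationary density", {
  # moderate stiffness: compare against the radial-Jacobian quadrature oracle
  top <- two_bead_top(k = 1250, r0 = 0.35)
  ens <- sample_cg(top, sampler_config(n_steps = 2e6, stride = 20, seed = 36))
  lens <- vapply(ens$frames, function(f) sqrt(sum((f[1, ] - f[2, ])^2)),
                 numeric(1))
  oracle <- bond_length_moments(1250, 0.35)
  expect_equal(mean(lens), oracle$mean, tolerance = 0.003)
  expect_equal(var(lens), oracle$var, tolerance = 0.02)
  # Kolmogorov-Smirnov distance against the analytic CDF
  cdf <- bond_length_cdf(1250, 0.35)
  D <- max(abs(ecdf(lens)(sort(lens)) - cdf(sort(lens))))
  expect_lt(D, 0.02)
})

test_that("stiff bonds satisfy the equipartition closed form", {
  top <- two_bead_top(k = 8000, r0 = 0.35)
  ens <- sample_cg(top, sampler_config(n_steps = 1e6, stride = 20, seed = 37))
  lens <- vapply(ens$frames, function(f) sqrt(sum((f[1, ] - f[2, ])^2)),
                 numeric(1))
  expect_equal(var(lens), kB * 300 / 8000, tolerance = 0.03)
})

test_that("quartic bimodal angle sampling matches the quadrature density", {
  qc <- quartic_well_coeffs(6, 25)
  top <- three_bead_angle_top(theta0 = 105, form = "quartic", coeffs = qc)
  ens <- sample_cg(top, sampler_config(n_steps = 2e6, stride = 50, seed = 38))
  d <- extract_distributions(ens, top, bw_angle = 2)
  tm <- d$terms[["angle:1-2-3"]]
  ref_dens <- binned_angle_oracle(qc, 105, tm$centers, half_width = 1)
  sup <- max(abs(tm$density - ref_dens), na.rm = TRUE)
  expect_lt(sup, 0.05)                       # per-degree densities
  expect_lt(sup, 0.05 * max(ref_dens))       # and relative to the peak
})

test_that("move-size adaptation lands near the 40% acceptance target", {
  top <- toy_motor_topology()
  ens <- sample_cg(top, sampler_config(n_steps = 2e5, stride = 100, seed = 39))
  expect_gt(ens$metadata$acceptance, 0.30)
  expect_lt(ens$metadata$acceptance, 0.50)
})

test_that("a chain that can never accept reports itself as stuck", {
  top <- two_bead_top(k = 1e9, r0 = 0.35)
  cfg <- sampler_config(n_steps = 50000, stride = 10, seed = 40,
                        move_sigma = 50, burn_in = 0)  # no adaptation
  expect_error(sample_cg(top, cfg), "stuck chain")
})

test_that("the rotation reference completes a full turn on schedule", {
  top <- toy_motor_topology()
  drv <- rotation_driver(6:8, axis = c(4, 5), rate = 80, k_rot = 280)
  res <- enforced_rotation(top, drv, duration = 6,
                           cfg = sampler_config(n_steps = 2e4, seed = 41))
  expect_equal(turn_time(res$trace, 360, "reference"), 4.5, tolerance = 1e-9)
})

test_that("a null driver leaves the rotor where it was", {
  top <- toy_motor_topology()
  drv <- rotation_driver(6:8, axis = c(4, 5), rate = 0, k_rot = 280)
  res <- enforced_rotation(top, drv, duration = 6,
                           cfg = sampler_config(n_steps = 2e4, seed = 42))
  expect_lt(abs(mean(res$trace$rotor_angle)), 20)
  expect_lt(max(res$trace$ref_angle), 1e-12)
})

test_that("the restrained rotor follows the reference with a bounded lag", {
  top <- toy_motor_topology()
  drv <- rotation_driver(6:8, axis = c(4, 5), rate = 80, k_rot = 280)
  res <- enforced_rotation(top, drv, duration = 9,
                           cfg = sampler_config(n_steps = 2e4, seed = 43))
  lag <- res$trace$ref_angle - res$trace$rotor_angle
  late <- lag[res$trace$time_ps > 2]
  expect_lt(max(abs(late)), 90)                    # bounded
  expect_lt(sd(late), 30)                          # steady, not growing
  expect_gt(tail(res$trace$rotor_angle, 1), 600)   # keeps turning
})

test_that("degenerate axles are rejected", {
  top <- toy_motor_topology()
  expect_error(rotation_driver(6:8, axis = c(4, 4)), NA)  # same index allowed...
  drv <- rotation_driver(6:8, axis = c(4, 4))
  expect_error(enforced_rotation(top, drv, duration = 1,
                                 cfg = sampler_config(n_steps = 1000, seed = 2)),
               "degenerate axis")
})

test_that("switching to the other stereoisomer re-centres the torsion", {
  zt <- four_bead_dihedral_top(n = 1, phi0 = 180, kphi = 12)  # minimum at 0
  et <- four_bead_dihedral_top(n = 1, phi0 = 0, kphi = 12)    # minimum at 180
  st <- sample_cg(zt, sampler_config(n_steps = 4e5, stride = 40, seed = 44))
  d0 <- extract_distributions(st, zt)$terms[["dihedral:1-2-3-4:1"]]
  expect_lt(abs(d0$mean), 25)
  sw <- switch_topology(st, et, sampler_config(n_steps = 4e5, stride = 40,
                                               seed = 45))
  d1 <- extract_distributions(sw, et)$terms[["dihedral:1-2-3-4:1"]]
  expect_gt(abs(d1$mean), 155)
  expect_length(sw$metadata$energies, length(sw$frames))
  # switching back recovers the original equilibrium
  back <- switch_topology(sw, zt, sampler_config(n_steps = 4e5, stride = 40,
                                                 seed = 46))
  d2 <- extract_distributions(back, zt)$terms[["dihedral:1-2-3-4:1"]]
  expect_lt(abs(d2$mean), 25)
})

test_that("switching requires matching beads", {
  st <- sample_cg(two_bead_top(), sampler_config(n_steps = 2000, seed = 47))
  expect_error(switch_topology(st, three_bead_angle_top(),
                               sampler_config(n_steps = 1000, seed = 1)),
               "incompatibility error")
})
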