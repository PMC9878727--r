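# Boltzmann inversion, quartic/dihedral fits, iterative refinement.

test_that("harmonic inversion gives x0 = mean and k = kBT/sigma^2", {
  bond <- list(mean = 0.35, sd = 0.01, kind = "bond")
  inv <- invert_harmonic(bond, 300)
  expect_equal(inv$x0, 0.35)
  expect_equal(inv$k, kB * 300 / 0.01^2)        # 24943.5 kJ/mol/nm^2
  expect_equal(inv$k, 24943.5, tolerance = 1e-6)

  ang <- list(mean = 120, sd = 5, kind = "angle")
  inva <- invert_harmonic(ang, 300)
  expect_equal(inva$x0, 120)
  expect_equal(inva$k, kB * 300 / (5 * pi / 180)^2)  # ~327.5 kJ/mol/rad^2
  expect_equal(inva$k, 327.5, tolerance = 1e-3)

  frozen <- list(mean = 0.4, sd = 0, kind = "bond")
  expect_true(invert_harmonic(frozen)$constrained)
})

test_that("inversion of exact Gaussian statistics recovers the parameters", {
  set.seed(22)
  k_true <- 5000; x0_true <- 0.36
  sig <- sqrt(kB * 300 / k_true)
  x <- rnorm(1e5, x0_true, sig)
  inv <- invert_harmonic(list(mean = mean(x), sd = sd(x), kind = "bond"), 300)
  expect_equal(inv$x0, x0_true, tolerance = 0.001)
  expect_equal(inv$k, k_true, tolerance = 0.02)
})

test_that("quartic fit of a Gaussian histogram reduces to the harmonic limit", {
  sig <- 5; mu <- 110
  centers <- seq(mu - 20, mu + 20, by = 0.5)
  dens <- dnorm(centers, mu, sig)
  q <- fit_quartic_angle(list(centers = centers, density = dens), 300,
                         jacobian = "none")
  k_expected <- kB * 300 / (sig * pi / 180)^2
  expect_equal(q$theta0, mu, tolerance = 0.01)
  expect_equal(q$coeffs[3], k_expected / 2, tolerance = 0.02)
  expect_lt(abs(q$coeffs[4]), 0.02 * q$coeffs[3])
  expect_lt(abs(q$coeffs[5]), 0.02 * q$coeffs[3])
})

test_that("the density floor masks unoccupied bins out of the fit", {
  centers <- seq(60, 150, by = 1)
  dens <- dnorm(centers, 105, 5)
  dens[centers > 130] <- 0        # empty tail must not feed log(0)
  q <- fit_quartic_angle(list(centers = centers, density = dens), 300,
                         jacobian = "none")
  expect_true(all(is.finite(q$coeffs)))
})

test_that("a sampled double well refits to the planted quartic well positions", {
  qc <- quartic_well_coeffs(6, 25)
  top <- three_bead_angle_top(theta0 = 105, form = "quartic", coeffs = qc)
  ens <- sample_cg(top, sampler_config(n_steps = 1e6, stride = 50, seed = 23))
  d <- extract_distributions(ens, top)
  q <- fit_quartic_angle(d$terms[["angle:1-2-3"]], 300, jacobian = "sine")
  # wells of the fitted polynomial: roots of dV/dx away from the barrier
  x <- seq(-0.8, 0.8, length.out = 2001)
  v <- sapply(x, function(xi) sum(q$coeffs * xi^(0:4)))
  neg <- which(x < -0.05); pos <- which(x > 0.05)
  wells_deg <- q$theta0 +
    x[c(neg[which.min(v[neg])], pos[which.min(v[pos])])] * 180 / pi
  expect_equal(wells_deg[1], 80, tolerance = 0.04)
  expect_equal(wells_deg[2], 130, tolerance = 0.04)
})

test_that("dihedral fitting recovers a planted single-term torsion", {
  beta <- 1 / (kB * 300)
  centers <- seq(-179.5, 179.5, by = 1)
  vfun <- function(phi_deg) 5 * (1 + cos(2 * phi_deg * pi / 180 - pi))
  dens <- exp(-beta * vfun(centers)); dens <- dens / sum(dens)
  fit <- fit_dihedral(list(centers = centers, density = dens), 300,
                      multiplicities = 2)
  expect_equal(fit$kphi[1], 5, tolerance = 0.1)
  expect_equal(fit$phi0[1], 180)

  flat <- fit_dihedral(list(centers = centers,
                            density = rep(1 / 360, length(centers))), 300,
                       multiplicities = 1:3)
  expect_true(all(flat$kphi < 1e-8))
})

test_that("a two-term profile fits better with the matching basis", {
  beta <- 1 / (kB * 300)
  centers <- seq(-179.5, 179.5, by = 1)
  vfun <- function(p) 4 * (1 + cos(p * pi / 180)) + 2.5 * (1 + cos(2 * p * pi / 180))
  dens <- exp(-beta * vfun(centers)); dens <- dens / sum(dens)
  dist <- list(centers = centers, density = dens)
  one <- attr(fit_dihedral(dist, 300, multiplicities = 1), "residual")
  two <- attr(fit_dihedral(dist, 300, multiplicities = 1:2), "residual")
  expect_lt(two, one)
  expect_lt(two, 1e-6)
})

test_that("refine is a fixpoint when starting at the target parameters", {
  top <- toy_motor_topology()
  ref <- sample_cg(top, sampler_config(n_steps = 4e5, stride = 40, seed = 24))
  target <- extract_distributions(ref, top)
  res <- refine(top, target, fit_config(seed = 25, sampler_steps = 2e5,
                                        sampler_stride = 20))
  expect_true(res$report$converged)
  expect_equal(res$report$trace$iteration[1], 0)
  expect_equal(res$report$iterations, 1)
  expect_equal(res$topology$bonds$k, top$bonds$k)  # untouched
})

test_that("refinement converges to the same parameters under different damping", {
  top <- three_bead_angle_top(theta0 = 115, kf = 200)
  ref <- sample_cg(top, sampler_config(n_steps = 6e5, stride = 30, seed = 26))
  target <- extract_distributions(ref, top)
  start <- top
  start$bonds$k <- start$bonds$k * 1.3
  start$bonds$r0 <- start$bonds$r0 + 0.01
  start$angles$kf <- start$angles$kf * 1.3
  fit1 <- refine(start, target, fit_config(seed = 27, damping = 1,
                                           sampler_steps = 3e5,
                                           sampler_stride = 30))
  fit2 <- refine(start, target, fit_config(seed = 28, damping = 0.5,
                                           sampler_steps = 3e5,
                                           sampler_stride = 30,
                                           max_iterations = 30))
  expect_true(fit1$report$converged)
  expect_true(fit2$report$converged)
  expect_equal(fit1$topology$bonds$r0, fit2$topology$bonds$r0, tolerance = 0.01)
  expect_equal(fit1$topology$angles$theta0, fit2$topology$angles$theta0,
               tolerance = 0.02)
})

test_that("stiff-bond sample-and-refit recovers k despite the radial Jacobian", {
  k_true <- 8000; r0_true <- 0.35   # k r0^2 / kBT ~ 390
  top <- two_bead_top(k = k_true, r0 = r0_true)
  ens <- sample_cg(top, sampler_config(n_steps = 1e6, stride = 20, seed = 29))
  d <- extract_distributions(ens, top)
  inv <- invert_harmonic(d$terms[["bond:1-2"]], 300)
  expect_equal(inv$k, k_true, tolerance = 0.05)
})
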