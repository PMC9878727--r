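# Shared builders and independent quadrature oracles for the test suite.

kB <- 0.0083145

two_bead_top <- function(k = 1250, r0 = 0.35, constrained = FALSE) {
  cg_topology("dimer",
              bead_table(c("A", "B"), c("TC5", "TC5")),
              bond_table(1, 2, r0, k, constrained = constrained))
}

three_bead_angle_top <- function(theta0 = 105, kf = 150, form = "harmonic",
                                 coeffs = NULL) {
  cg_topology("trimer",
              bead_table(c("A", "B", "C"), "TC5"),
              bond_table(c(1, 2), c(2, 3), 0.35, 8000),
              angle_table(1, 2, 3, theta0, kf, form, coeffs))
}

four_bead_dihedral_top <- function(n = 2, phi0 = 180, kphi = 5) {
  cg_topology("tetramer",
              bead_table(c("A", "B", "C", "D"), "TC5"),
              bond_table(1:3, 2:4, 0.35, 8000),
              angle_table(c(1, 2), c(2, 3), c(3, 4), 115, 250),
              dihedral_table(1, 2, 3, 4, n, phi0, kphi))
}

# planted quartic double well used by the toy motor: wells at +/- 25 deg
quartic_well_coeffs <- function(barrier = 6, half_width_deg = 25) {
  D <- half_width_deg * pi / 180
  c(barrier, 0, -2 * barrier / D^2, 0, barrier / D^4)
}

# exact moments of the bond-length distribution p(r) ~ r^2 exp(-beta k/2 (r-r0)^2)
bond_length_moments <- function(k, r0, temperature = 300) {
  beta <- 1 / (kB * temperature)
  s <- sqrt(1 / (beta * k))
  r <- seq(max(1e-6, r0 - 8 * s), r0 + 8 * s, length.out = 20001)
  w <- r^2 * exp(-beta * 0.5 * k * (r - r0)^2)
  w <- w / sum(w)
  m <- sum(w * r)
  list(mean = m, var = sum(w * (r - m)^2))
}

# bin-averaged oracle for comparing an angle histogram (per-degree density,
# fixed-width bins) against the quadrature Boltzmann density
binned_angle_oracle <- function(coeffs, theta0_deg, centers, half_width,
                                temperature = 300) {
  beta <- 1 / (kB * temperature)
  fine <- seq(0.5, 179.5, by = 0.05)
  x <- fine * pi / 180 - theta0_deg * pi / 180
  v <- sapply(x, function(xi) sum(coeffs * xi^(0:4)))
  dens <- sin(fine * pi / 180) * exp(-beta * v)
  dens <- dens / (sum(dens) * 0.05)
  sapply(centers, function(c0) mean(dens[abs(fine - c0) <= half_width]))
}

# analytic CDF of the same distribution (for KS-style checks)
bond_length_cdf <- function(k, r0, temperature = 300) {
  beta <- 1 / (kB * temperature)
  s <- sqrt(1 / (beta * k))
  r <- seq(max(1e-6, r0 - 8 * s), r0 + 8 * s, length.out = 20001)
  w <- r^2 * exp(-beta * 0.5 * k * (r - r0)^2)
  cdf <- cumsum(w) / sum(w)
  function(x) approx(r, cdf, xout = x, yleft = 0, yright = 1)$y
}

# quick ensemble from explicit bond-length samples along x
frames_from_lengths <- function(lens) {
  lapply(lens, function(r) rbind(c(0, 0, 0), c(r, 0, 0)))
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}
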