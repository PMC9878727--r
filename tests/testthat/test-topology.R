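# Topology model: term energies, virtual sites, validation, .itp round trip.

test_that("harmonic bond energy matches the closed form", {
  top <- two_bead_top(k = 1250, r0 = 0.35)
  e <- bonded_energy(top, rbind(c(0, 0, 0), c(0.40, 0, 0)))
  expect_equal(e$bonds[1], 0.5 * 1250 * 0.05^2)  # 1.5625 kJ/mol
  expect_equal(e$total, 1.5625)
})

test_that("energy vanishes at the equilibrium geometry (quartic C0 = 0)", {
  qc <- c(0, 0, 60, 0, 170)
  top <- three_bead_angle_top(theta0 = 120, form = "quartic", coeffs = qc)
  th <- 120 * pi / 180
  coords <- rbind(c(0.35, 0, 0), c(0, 0, 0),
                  0.35 * c(cos(th), sin(th), 0))
  e <- bonded_energy(top, coords)
  expect_equal(e$total, 0, tolerance = 1e-12)
})

test_that("total energy equals an independent per-term hand evaluation", {
  set.seed(7)
  top <- toy_motor_topology()
  coords <- place_virtual_sites(top, matrix(rnorm(27, sd = 0.4), 9, 3))
  e <- bonded_energy(top, coords)
  # brute-force oracle: accumulate term by term from raw geometry
  dist <- function(i, j) sqrt(sum((coords[i, ] - coords[j, ])^2))
  ang <- function(i, j, k) {
    u <- coords[i, ] - coords[j, ]; v <- coords[k, ] - coords[j, ]
    acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
  }
  dih <- function(i, j, k, l) {
    b1 <- coords[j, ] - coords[i, ]; b2 <- coords[k, ] - coords[j, ]
    b3 <- coords[l, ] - coords[k, ]
    n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
    atan2(sum(pracma_cross(n1, b2 / sqrt(sum(b2^2))) * n2), sum(n1 * n2))
  }
  pracma_cross <- function(a, b)
    c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
  manual <- 0
  for (t in seq_len(nrow(top$bonds)))
    manual <- manual + 0.5 * top$bonds$k[t] *
      (dist(top$bonds$i[t], top$bonds$j[t]) - top$bonds$r0[t])^2
  for (t in seq_len(nrow(top$angles))) {
    a <- top$angles[t, ]
    dth <- ang(a$i, a$j, a$k) - a$theta0 * pi / 180
    manual <- manual + if (a$form == "harmonic") 0.5 * a$kf * dth^2
      else sum(unlist(a[paste0("c", 0:4)]) * dth^(0:4))
  }
  for (t in seq_len(nrow(top$dihedrals))) {
    d <- top$dihedrals[t, ]
    manual <- manual + d$kphi *
      (1 + cos(d$n * dih(d$i, d$j, d$k, d$l) - d$phi0 * pi / 180))
  }
  expect_equal(e$total, manual, tolerance = 1e-10)
})

test_that("bonded energy is invariant under rigid motions", {
  set.seed(21)
  top <- toy_motor_topology()
  for (rep in 1:5) {
    coords <- place_virtual_sites(top, matrix(rnorm(27, sd = 0.4), 9, 3))
    e0 <- bonded_energy(top, coords)$total
    R <- random_rotation()
    moved <- coords %*% t(R) + matrix(rnorm(3), 9, 3, byrow = TRUE)
    expect_equal(bonded_energy(top, moved)$total, e0, tolerance = 1e-9)
  }
})

test_that("quartic angle with C2 = kf/2 reproduces the harmonic energy", {
  kf <- 150
  harm <- three_bead_angle_top(theta0 = 105, kf = kf)
  quart <- three_bead_angle_top(theta0 = 105, form = "quartic",
                                coeffs = c(0, 0, kf / 2, 0, 0))
  for (th_deg in c(40, 80, 105, 140, 170)) {
    th <- th_deg * pi / 180
    coords <- rbind(c(0.35, 0, 0), c(0, 0, 0), 0.35 * c(cos(th), sin(th), 0))
    expect_equal(bonded_energy(quart, coords)$total,
                 bonded_energy(harm, coords)$total, tolerance = 1e-10)
  }
})

test_that("constrained bonds contribute no energy", {
  top <- two_bead_top(r0 = 0.35, constrained = TRUE)
  e <- bonded_energy(top, rbind(c(0, 0, 0), c(0.50, 0, 0)))
  expect_equal(e$total, 0)
})

test_that("coincident coordinates in an angle raise an undefined-geometry error", {
  top <- three_bead_angle_top()
  coords <- rbind(c(0, 0, 0), c(0, 0, 0), c(0.3, 0, 0))
  expect_error(bonded_energy(top, coords), "undefined geometry")
})

test_that("virtual-site placement follows cog and weighted rules", {
  beads <- bead_table(c("A", "B", "C", "V"), "TC5",
                      is_virtual = c(FALSE, FALSE, FALSE, TRUE))
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0), c(9, 9, 9))
  top <- cg_topology("tri", beads, bond_table(c(1, 2), c(2, 3), 0.4, 100),
                     virtual_sites = list(virtual_site(4, 1:3, "cog")))
  out <- place_virtual_sites(top, tri)
  expect_equal(out[4, ], colMeans(tri[1:3, ]))
  expect_equal(place_virtual_sites(top, out), out)  # idempotent

  topw <- cg_topology("triw", beads, bond_table(c(1, 2), c(2, 3), 0.4, 100),
                      virtual_sites = list(
                        virtual_site(4, c(1, 2), "weighted", c(0.5, 0.5))))
  expect_equal(place_virtual_sites(topw, tri)[4, ], (tri[1, ] + tri[2, ]) / 2)

  set.seed(3)
  beads5 <- bead_table(c("A", "B", "C", "D", "V"), "TC5",
                       is_virtual = c(rep(FALSE, 4), TRUE))
  top5 <- cg_topology("quad", beads5, bond_table(1:3, 2:4, 0.4, 100),
                      virtual_sites = list(virtual_site(5, 1:4, "cog")))
  r <- matrix(rnorm(15), 5, 3)
  expect_equal(place_virtual_sites(top5, r)[5, ], colMeans(r[1:4, ]))
})

test_that("virtual-site definitions are validated", {
  expect_error(virtual_site(3, integer(0)), "at least one constructor")
  expect_error(virtual_site(3, c(2, 3)), "construct itself")
  expect_error(virtual_site(3, c(1, 2), "weighted", c(0.7, 0.7)), "sum to 1")
})

test_that("topology validation catches out-of-range and virtual-only terms", {
  beads <- bead_table(paste0("B", 1:5), "TC5")
  expect_error(cg_topology("bad", beads, bond_table(1, 99, 0.3, 100)),
               "out of range")
  beads2 <- bead_table(c("A", "B", "V1", "V2"), "TC5",
                       is_virtual = c(FALSE, FALSE, TRUE, TRUE))
  expect_error(
    cg_topology("vv", beads2, bond_table(3, 4, 0.3, 100),
                virtual_sites = list(virtual_site(3, 1:2, "cog"),
                                     virtual_site(4, 1:2, "cog"))),
    "virtual sites only")
})

test_that(".itp round trip is an exact fixpoint", {
  top <- toy_motor_topology()
  # constrain the last bond so the [constraints] directive is exercised too
  top$bonds$constrained[7] <- TRUE
  top$bonds$k[7] <- 0
  f1 <- tempfile(fileext = ".itp")
  f2 <- tempfile(fileext = ".itp")
  write_itp(top, f1)
  r1 <- read_itp(f1)
  write_itp(r1, f2)
  r2 <- read_itp(f2)
  expect_equal(r1, r2)
  expect_equal(r1$bonds, top$bonds)
  expect_equal(r1$angles, top$angles)
  expect_equal(r1$dihedrals, top$dihedrals)
  expect_equal(r1$virtual_sites, top$virtual_sites)
  expect_identical(readLines(f1), readLines(f2))
})

test_that(".itp reader maps virtual_sitesn cog sites and reports bad input", {
  f <- tempfile(fileext = ".itp")
  writeLines(c("[ moleculetype ]", "toy 1",
               "[ atoms ]",
               "1 TC5 1 toy A 1 0.0 36",
               "2 TC5 1 toy B 2 0.0 36",
               "3 TC5 1 toy V 3 0.0 0",
               "[ bonds ]", "1 2 1 0.4 1200 ; axle",
               "[ virtual_sitesn ]", "3 1 1 2"), f)
  top <- read_itp(f)
  expect_equal(top$virtual_sites[[1]]$rule, "cog")
  expect_equal(top$virtual_sites[[1]]$constructors, c(1L, 2L))
  expect_true(top$beads$is_virtual[3])
  expect_equal(top$bonds$r0[1], 0.4)

  writeLines(c("[ moleculetype ]", "toy 1", "[ atoms ]",
               "1 TC5 1 toy A 1 0.0", "[ nonsense ]", "1 2 3"), f)
  expect_error(read_itp(f), "line 5.*nonsense")

  writeLines(c("[ moleculetype ]", "toy 1", "[ atoms ]",
               "1 TC5 1 toy A 1 0.0", "2 TC5 1 toy B 2 0.0",
               "[ bonds ]", "1 99 1 0.4 100"), f)
  expect_error(read_itp(f), "out of range")
})

test_that("default bead radii follow the size class and can be overridden", {
  b <- bead_table(c("r", "s", "t"), c("P4", "SP4", "TC5"))
  expect_equal(b$radius, c(0.264, 0.230, 0.191))
  b2 <- bead_table("x", "TC5", radius = 0.2)
  expect_equal(b2$radius, 0.2)
  expect_error(bead_table("x", "TC5", radius = -1), "positive")
})
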