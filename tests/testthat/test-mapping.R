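# Forward mapping, scheme I/O and scheme/topology cross-checks.

simple_scheme <- function(rule = "cog", masses = NULL) {
  mapping_scheme("toy",
                 list(list(bead = "B1", atoms = 1:2, rule = rule)),
                 atom_masses = masses)
}

test_that("cog and com place beads at the stated means", {
  aa <- conformer_ensemble(list(rbind(c(0, 0, 0), c(1, 0, 0))),
                           resolution = "AA")
  cg <- map_ensemble(simple_scheme(), aa)
  expect_equal(cg$frames[[1]][1, ], c(0.5, 0, 0))
  cgm <- map_ensemble(simple_scheme("com", masses = c(12, 1)), aa)
  expect_equal(cgm$frames[[1]][1, ], c(1 / 13, 0, 0))
})

test_that("multi-bead mapping equals explicit group means on every frame", {
  set.seed(11)
  frames <- replicate(50, matrix(rnorm(30), 10, 3), simplify = FALSE)
  aa <- conformer_ensemble(frames, resolution = "AA")
  groups <- list(1:3, 4:6, 7:10)
  scheme <- mapping_scheme("toy10",
                           lapply(seq_along(groups), function(g)
                             list(bead = paste0("B", g), atoms = groups[[g]],
                                  rule = "cog")))
  cg <- map_ensemble(scheme, aa)
  for (f in c(1, 25, 50))
    for (g in seq_along(groups))
      expect_equal(cg$frames[[f]][g, ],
                   colMeans(frames[[f]][groups[[g]], , drop = FALSE]))
})

test_that("mapping commutes with rigid motions", {
  set.seed(12)
  frames <- replicate(5, matrix(rnorm(30), 10, 3), simplify = FALSE)
  aa <- conformer_ensemble(frames, resolution = "AA")
  scheme <- mapping_scheme("toy10",
                           list(list(bead = "B1", atoms = 1:4, rule = "cog"),
                                list(bead = "B2", atoms = 5:10, rule = "cog")))
  R <- random_rotation(); tr <- rnorm(3)
  moved <- conformer_ensemble(lapply(frames, function(f)
    f %*% t(R) + matrix(tr, 10, 3, byrow = TRUE)), resolution = "AA")
  a <- map_ensemble(scheme, moved)
  b <- map_ensemble(scheme, aa)
  for (f in seq_along(frames))
    expect_equal(a$frames[[f]],
                 b$frames[[f]] %*% t(R) + matrix(tr, 2, 3, byrow = TRUE),
                 tolerance = 1e-9)
})

test_that("cog equals com when all masses are equal", {
  set.seed(13)
  aa <- conformer_ensemble(list(matrix(rnorm(12), 4, 3)), resolution = "AA")
  sc_cog <- mapping_scheme("m", list(list(bead = "B", atoms = 1:4, rule = "cog")))
  sc_com <- mapping_scheme("m", list(list(bead = "B", atoms = 1:4, rule = "com")),
                           atom_masses = rep(12, 4))
  expect_equal(map_ensemble(sc_cog, aa)$frames[[1]],
               map_ensemble(sc_com, aa)$frames[[1]])
})

test_that("out-of-range atom references raise a mapping error", {
  aa <- conformer_ensemble(list(matrix(0, 3, 3)), resolution = "AA")
  sc <- mapping_scheme("m", list(list(bead = "B", atoms = c(1, 7), rule = "cog")))
  expect_error(map_ensemble(sc, aa), "mapping error")
})

test_that("scheme JSON round trip preserves assignments", {
  sc <- mapping_scheme("mol",
                       list(list(bead = "B1", atoms = c(1L, 3L, 5L), rule = "cog"),
                            list(bead = "B2", atoms = c(2L, 4L), rule = "com"),
                            list(bead = "V", atoms = integer(0), rule = "cog")),
                       atom_masses = c(12, 1, 12, 1, 16))
  f <- tempfile(fileext = ".json")
  write_mapping(sc, f)
  back <- read_mapping(f)
  expect_equal(back$assignments, sc$assignments)
  expect_equal(back$atom_masses, sc$atom_masses)
})

test_that("check_scheme reports agreement and findings machine-readably", {
  ref <- gen_reference_ensemble(n_steps = 2000, stride = 100, seed = 2)
  ok <- check_scheme(ref$scheme, ref$topology)
  expect_true(ok$ok)
  expect_length(ok$findings, 0)

  # a topology with an extra virtual bead nothing constructs
  top2 <- ref$topology
  top2$beads <- rbind(top2$beads,
                      bead_table("V2", "TC5", is_virtual = TRUE))
  bad <- check_scheme(ref$scheme, top2)
  expect_false(bad$ok)
  expect_true(any(grepl("unconstructible v-site", bad$findings)))

  # atom 7 left out of a 10-atom molecule
  sc <- mapping_scheme("m", list(list(bead = "B1", atoms = c(1:6), rule = "cog"),
                                 list(bead = "B2", atoms = c(8:10), rule = "cog")))
  topm <- cg_topology("m", bead_table(c("B1", "B2"), "TC5"),
                      bond_table(1, 2, 0.4, 100))
  rep7 <- check_scheme(sc, topm, n_atoms = 10)
  expect_equal(rep7$unassigned_atoms, 7L)
  expect_true(any(grepl("unassigned atoms: 7", rep7$findings)))
})

test_that("decorated pseudo-AA ensembles map back to the CG frames bit-exactly", {
  ref <- gen_reference_ensemble(n_steps = 5000, stride = 50, seed = 31)
  cg <- map_ensemble(ref$scheme, ref$aa, ref$topology)
  expect_equal(length(cg$frames), length(ref$cg$frames))
  for (f in seq_along(cg$frames))
    expect_equal(cg$frames[[f]], ref$cg$frames[[f]], tolerance = 1e-12)
})
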