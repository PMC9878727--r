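# Seeded synthetic-fixture generators with planted ground truth: reference
# ensembles for the fitting loop, umbrella data from a known PMF, and
# Crooks-consistent work samples with a known dG.

#' Toy-motor topology with planted bonded parameters
#'
#' A minimal second-generation-motor caricature exhibiting every term type
#' the full models use: 8 real beads (a 4-bead "stator" chain and a 4-bead
#' "rotor" chain joined at the axle bond 4-5), one virtual pivot bead at
#' the centre of geometry of the stator, harmonic bonds and angles, one
#' bimodal angle carried by a quartic double-well potential (modes near 80
#' and 130 degrees), and one n = 2 dihedral running through the virtual
#' pivot (stator-rotor torsion).
#'
#' @param bimodal include the quartic double-well angle (TRUE) or use a
#'   harmonic angle there instead.
#' @return a `cg_topology` holding the planted ground truth.
#' @export
toy_motor_topology <- function(bimodal = TRUE) {
  beads <- bead_table(name = c(paste0("S", 1:4), paste0("R", 1:4), "VP"),
                      type_code = c("TC5", "TC5", "TC5", "TC5",
                                    "TC3", "TC3", "SP4", "TC5", "TC5"),
                      charge = 0,
                      is_virtual = c(rep(FALSE, 8), TRUE))
  bonds <- bond_table(i = 1:7, j = 2:8,
                      r0 = c(0.33, 0.36, 0.34, 0.40, 0.35, 0.37, 0.33),
                      k  = c(7000, 5500, 8000, 4500, 6000, 5000, 7500))
  # double well V(x) = B ((x/D)^2 - 1)^2, x = theta - theta0 in radians:
  # theta0 = 105 deg, wells at +/- 25 deg, barrier B = 6 kJ/mol
  D <- 25 * pi / 180; B <- 6
  qc <- c(B, 0, -2 * B / D^2, 0, B / D^4)
  forms <- c("harmonic", "harmonic", "harmonic",
             if (bimodal) "quartic" else "harmonic",
             "harmonic", "harmonic")
  angles <- angle_table(i = 1:6, j = 2:7, k = 3:8,
                        theta0 = c(120, 135, 110, 105, 125, 140),
                        kf = c(180, 140, 220, if (bimodal) 0 else 160, 150, 130),
                        form = forms,
                        coeffs = if (bimodal) qc else NULL)
  dihedrals <- dihedral_table(i = 2, j = 9, k = 5, l = 6, n = 2,
                              phi0 = 180, kphi = 5)
  vs <- list(virtual_site(9, 1:4, "cog"))
  cg_topology("toy-motor", beads, bonds, angles, dihedrals, vs)
}

#' Generate a planted-truth reference ensemble
#'
#' Samples the planted topology's Boltzmann distribution with
#' [sample_cg()], then decorates each bead with `atoms_per_bead`
#' pseudo-atoms whose centre of geometry reproduces the bead position
#' exactly (offsets are drawn once and re-centred to zero mean), yielding
#' a pseudo-atomistic ensemble, its mapping scheme, and the ground-truth
#' topology. Forward-mapping the decorated ensemble recovers the CG frames
#' bit-exactly, so mapping correctness and fitting correctness are
#' testable independently.
#'
#' @param top planted `cg_topology` (default [toy_motor_topology()]).
#' @param n_steps,stride,temperature,seed sampler settings.
#' @param atoms_per_bead pseudo-atoms decorating each real bead.
#' @param spread decoration spread, nm.
#' @param jitter if `TRUE`, offsets are redrawn per frame (still exactly
#'   cog-preserving); if `FALSE`, one rigid decoration is reused.
#' @return list with `aa` (pseudo-AA ensemble), `cg` (the CG reference
#'   frames), `scheme` (the matching [mapping_scheme()]), `topology`
#'   (planted truth).
#' @export
gen_reference_ensemble <- function(top = toy_motor_topology(),
                                   n_steps = 1e6, stride = 100,
                                   temperature = 300, seed = 1,
                                   atoms_per_bead = 3, spread = 0.08,
                                   jitter = TRUE) {
  cfg <- sampler_config(temperature = temperature, n_steps = n_steps,
                        stride = stride, seed = seed)
  cg <- sample_cg(top, cfg)
  real <- which(!top$beads$is_virtual)
  nb <- length(real)
  app <- atoms_per_bead
  centred_offsets <- function() {
    o <- matrix(stats::rnorm(app * 3, sd = spread), app, 3)
    sweep(o, 2, colMeans(o))
  }
  base <- lapply(seq_len(nb), function(b) centred_offsets())
  aa_frames <- lapply(cg$frames, function(f) {
    at <- matrix(NA_real_, nb * app, 3)
    for (bi in seq_len(nb)) {
      o <- if (jitter) centred_offsets() else base[[bi]]
      rows <- ((bi - 1) * app + 1):(bi * app)
      at[rows, ] <- o + matrix(f[real[bi], ], app, 3, byrow = TRUE)
    }
    at
  })
  aa <- conformer_ensemble(aa_frames, resolution = "AA",
                           metadata = list(generator = "gen_reference_ensemble",
                                           seed = seed,
                                           atoms_per_bead = app, spread = spread))
  assignments <- vector("list", nrow(top$beads))
  for (bi in seq_len(nb)) {
    assignments[[real[bi]]] <- list(bead = top$beads$name[real[bi]],
                                    atoms = ((bi - 1) * app + 1):(bi * app),
                                    rule = "cog")
  }
  for (v in which(top$beads$is_virtual))
    assignments[[v]] <- list(bead = top$beads$name[v], atoms = integer(0),
                             rule = "cog")
  scheme <- mapping_scheme(top$name, assignments)
  list(aa = aa, cg = cg, scheme = scheme, topology = top)
}

#' Double-well PMF for umbrella fixtures
#'
#' `F(xi) = barrier ((xi - centre)^2/half_width^2 - 1)^2` with minima at
#' `centre +/- half_width` — a closed-form profile whose barrier and well
#' positions are known exactly.
#'
#' @param barrier kJ/mol.
#' @param centre,half_width nm.
#' @return a vectorized function of xi (nm).
#' @export
double_well_pmf <- function(barrier = 10, centre = 0, half_width = 0.5) {
  function(xi) barrier * (((xi - centre)^2 / half_width^2) - 1)^2
}

#' Generate umbrella-window samples from a known PMF
#'
#' Each window's reaction-coordinate samples are drawn by inverse-CDF
#' sampling from the exact biased Boltzmann density
#' `exp(-beta (F(xi) + k/2 (xi - xi0)^2))` on a fine grid. The protocol
#' defaults follow the standard pulling setup: 0.1 nm window spacing and
#' k = 1500 kJ mol^-1 nm^-2.
#'
#' @param pmf function of xi returning kJ/mol (bounded on the range).
#' @param xi0 window centres, nm.
#' @param k spring constant, kJ mol^-1 nm^-2.
#' @param n_per_window samples per window.
#' @param temperature K.
#' @param seed RNG seed.
#' @param grid_n inverse-CDF grid resolution.
#' @return an [umbrella_set()]; attribute `"pmf"` carries the planted
#'   truth.
#' @export
gen_umbrella_data <- function(pmf, xi0, k = 1500, n_per_window = 10000,
                              temperature = 300, seed = 1, grid_n = 4000) {
  beta <- 1 / (KB * temperature)
  set.seed(seed)
  pad <- 4 * sqrt(1 / (beta * k))
  lo <- min(xi0) - pad; hi <- max(xi0) + pad
  grid <- seq(lo, hi, length.out = grid_n)
  Fg <- pmf(grid)
  if (any(!is.finite(Fg))) stop("PMF unbounded on the sampled range")
  windows <- lapply(xi0, function(x0) {
    logp <- -beta * (Fg + 0.5 * k * (grid - x0)^2)
    p <- exp(logp - max(logp))
    cdf <- cumsum(p); cdf <- cdf / cdf[length(cdf)]
    u <- stats::runif(n_per_window)
    keep <- !duplicated(cdf)
    xi <- stats::approx(cdf[keep], grid[keep], xout = u, rule = 2)$y
    list(xi0 = x0, k = k, xi = xi)
  })
  us <- umbrella_set(windows, temperature = temperature)
  attr(us, "pmf") <- pmf
  us
}

#' Generate Crooks-consistent Gaussian work samples
#'
#' Forward work ~ N(dG + sigma^2 beta / 2, sigma^2) and reverse work
#' ~ N(-dG + sigma^2 beta / 2, sigma^2), which satisfy the Gaussian
#' fluctuation relation exactly, so the planted `dG` is the true answer
#' for any bidirectional estimator.
#'
#' @param dG planted free-energy difference, kJ/mol.
#' @param sigma work standard deviation, kJ/mol (>= 0).
#' @param n samples per direction.
#' @param temperature K.
#' @param seed RNG seed.
#' @return a [work_samples()]; attribute `"dG"` carries the planted truth.
#' @export
gen_work_samples <- function(dG, sigma, n, temperature = 300, seed = 1) {
  stopifnot(sigma >= 0)
  beta <- 1 / (KB * temperature)
  set.seed(seed)
  w <- work_samples(forward = stats::rnorm(n, dG + sigma^2 * beta / 2, sigma),
                    reverse = stats::rnorm(n, -dG + sigma^2 * beta / 2, sigma),
                    temperature = temperature)
  attr(w, "dG") <- dG
  w
}

#' Planted-truth round-trip parameterization experiment
#'
#' The toolkit's self-validation: generate a reference ensemble from the
#' planted toy-motor truth, decorate it to pseudo-atoms and forward-map it
#' back; Boltzmann-invert the mapped distributions onto the term skeleton;
#' perturb the harmonic starting point (+20% force constants, +0.01 nm
#' equilibrium lengths); run the iterative distribution-matching loop; then
#' resample the fitted topology and score it against the reference with
#' [mae_between()]. The returned MAEs are the quantities the model-quality
#' thresholds (0.0025 nm, 5.5 deg, 11.4 deg) apply to.
#'
#' @param seed base RNG seed for every stochastic stage.
#' @param n_steps reference / resampling chain length (MC steps).
#' @param stride frame recording stride.
#' @param temperature K.
#' @param k_perturb,r0_perturb starting-point perturbations (factor on k,
#'   nm offset on r0).
#' @return list with `mae` (final [mae_between()] report of the resampled
#'   fit against the reference), `fit` (the [refine()] report), `topology`
#'   (fitted), `truth` (planted topology).
#' @export
roundtrip_experiment <- function(seed = 1, n_steps = 1e6, stride = 100,
                                 temperature = 300, k_perturb = 1.2,
                                 r0_perturb = 0.01) {
  ref <- gen_reference_ensemble(n_steps = n_steps, stride = stride,
                                temperature = temperature, seed = seed)
  mapped <- map_ensemble(ref$scheme, ref$aa, ref$topology)
  target <- extract_distributions(mapped, ref$topology)
  start <- boltzmann_invert(ref$topology, target, temperature)
  start$bonds$k <- start$bonds$k * k_perturb
  start$bonds$r0 <- start$bonds$r0 + r0_perturb
  fit <- refine(start, target,
                fit_config(temperature = temperature, seed = seed + 1000L))
  resampled <- sample_cg(fit$topology,
                         sampler_config(temperature = temperature,
                                        n_steps = n_steps, stride = stride,
                                        seed = seed + 2000L))
  model <- extract_distributions(resampled, fit$topology)
  list(mae = mae_between(target, model), fit = fit$report,
       topology = fit$topology, truth = ref$topology)
}
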