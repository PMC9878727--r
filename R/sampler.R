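# Metropolis Monte Carlo sampling of the bonded CG potential, plus the
# enforced-rotation and topology-switch toy drivers.

#' Sampler configuration
#'
#' Settings for the single-molecule Metropolis chain. One step is one
#' attempted move of one randomly chosen movable (non-virtual) bead. The
#' move size adapts toward 40% acceptance during burn-in only, then
#' freezes; burn-in frames are never recorded.
#'
#' @param temperature K.
#' @param n_steps production MC steps.
#' @param stride record one frame every `stride` steps.
#' @param move_sigma initial Gaussian move size, nm.
#' @param seed RNG seed (the chain is bit-reproducible for a given seed).
#' @param burn_in extra equilibration steps before recording
#'   (default `n_steps %/% 10`).
#' @return a `sampler_config` list.
#' @export
sampler_config <- function(temperature = 300, n_steps = 100000, stride = 10,
                           move_sigma = 0.05, seed = 1, burn_in = NULL) {
  stopifnot(temperature > 0, n_steps >= stride, stride >= 1)
  structure(list(temperature = temperature, n_steps = as.integer(n_steps),
                 stride = as.integer(stride), move_sigma = move_sigma,
                 seed = as.integer(seed),
                 burn_in = as.integer(burn_in %||% (n_steps %/% 10))),
            class = "sampler_config")
}

# pendant-constraint bookkeeping: partner index per bead (-1 if free);
# beads in more than one constrained bond are rejected.
constraint_partners <- function(top) {
  n <- nrow(top$beads)
  partner <- rep(-1L, n)
  r0 <- rep(0, n)
  cb <- top$bonds[top$bonds$constrained, , drop = FALSE]
  count <- integer(n)
  for (t in seq_len(nrow(cb))) {
    i <- cb$i[t]; j <- cb$j[t]
    count[c(i, j)] <- count[c(i, j)] + 1L
    partner[i] <- j - 1L; partner[j] <- i - 1L
    r0[c(i, j)] <- cb$r0[t]
  }
  if (any(count > 1))
    stop("constraint chains are not supported: bead(s) ",
         paste(which(count > 1), collapse = ", "),
         " participate in more than one constrained bond")
  list(partner = partner, r0 = r0)
}

# deterministic initial structure: breadth-first walk over the bond graph,
# each new bead placed at r0 from its parent in a pseudo-random direction
build_initial_coords <- function(top) {
  n <- nrow(top$beads)
  coords <- matrix(NA_real_, n, 3)
  real <- which(!top$beads$is_virtual)
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (t in seq_len(nrow(top$bonds))) {
    i <- top$bonds$i[t]; j <- top$bonds$j[t]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  r0_of <- function(i, j) {
    b <- top$bonds
    hit <- which((b$i == i & b$j == j) | (b$i == j & b$j == i))[1]
    b$r0[hit]
  }
  placed <- logical(n)
  for (root in real) {
    if (placed[root]) next
    coords[root, ] <- if (!any(placed)) c(0, 0, 0) else stats::rnorm(3, sd = 1)
    placed[root] <- TRUE
    queue <- root
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (nb in adj[[cur]]) {
        if (placed[nb] || top$beads$is_virtual[nb]) next
        dir <- stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        coords[nb, ] <- coords[cur, ] + r0_of(cur, nb) * dir
        placed[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
  }
  coords[top$beads$is_virtual, ] <- 0
  place_virtual_sites(top, coords)
}

#' Sample equilibrium configurations of a bonded CG model
#'
#' Runs a Metropolis Monte Carlo chain on the bead coordinates under
#' [bonded_energy()]. Constrained bonds are held at exactly their reference
#' length (moves of a constrained bead resample the bond direction at fixed
#' length); virtual sites are re-placed after every accepted move. The same
#' configuration always yields a bit-identical ensemble.
#'
#' @param top a `cg_topology` with at least one non-virtual bead.
#' @param cfg a [sampler_config()].
#' @param init optional initial coordinates (beads x 3, nm).
#' @return a CG `conformer_ensemble`; metadata records the seed, acceptance
#'   rate, final move size and final coordinates (used by
#'   [switch_topology()]), and per-frame energies are in
#'   `metadata$energies`.
#' @export
sample_cg <- function(top, cfg, init = NULL) {
  validate_topology(top)
  movable <- which(!top$beads$is_virtual) - 1L
  if (!length(movable)) stop("topology has no non-virtual beads to sample")
  cons <- constraint_partners(top)
  arr <- topology_arrays(top)
  set.seed(cfg$seed)
  coords0 <- init %||% build_initial_coords(top)
  res <- cpp_sample(as.matrix(coords0), arr$bonds, arr$angles, arr$dihedrals,
                    arr$vs_sites, arr$vs_cons, arr$vs_w, movable,
                    cons$partner, cons$r0,
                    cfg$n_steps, cfg$burn_in, cfg$stride,
                    1 / (KB * cfg$temperature), cfg$move_sigma,
                    matrix(0, 0, 3), 0.0, integer(0))
  conformer_ensemble(res$frames, resolution = "CG",
                     metadata = list(generator = "sample_cg",
                                     topology = top$name, seed = cfg$seed,
                                     temperature = cfg$temperature,
                                     n_steps = cfg$n_steps, stride = cfg$stride,
                                     acceptance = res$acceptance,
                                     move_sigma = res$sigma,
                                     bead_names = top$beads$name,
                                     energies = res$frame_energies,
                                     final_coords = res$final,
                                     final_energy = res$energy))
}

#' Enforced-rotation driver
#'
#' Defines the toy driver that mimics enforced rotation of a molecular
#' motor: reference positions of the rotor beads rotate rigidly about the
#' axle direction at a fixed rate, and an isotropic harmonic restraint
#' (pivot-free: centred on the rotor's instantaneous centroid, no mass
#' weighting) couples the beads to that rotating reference.
#'
#' @param rotation_group bead indices of the rotor.
#' @param axis two bead indices defining the axle direction.
#' @param rate rotation rate, degrees/ps (the protocol value is 80).
#' @param k_rot restraint force constant, kJ mol^-1 nm^-2 (protocol: 280).
#' @param timestep fictitious time advanced per MC sweep, ps.
#' @return a `rotation_driver` list.
#' @export
rotation_driver <- function(rotation_group, axis, rate = 80, k_rot = 280,
                            timestep = 0.002) {
  stopifnot(rate >= 0, k_rot >= 0, length(axis) == 2)
  if (any(axis %in% rotation_group))
    stop("axis beads must not belong to the rotation group")
  structure(list(rotation_group = as.integer(rotation_group),
                 axis = as.integer(axis), rate = rate, k_rot = k_rot,
                 timestep = timestep),
            class = "rotation_driver")
}

#' Run enforced rotation on a CG model
#'
#' Advances the Metropolis chain in sweeps (one attempted move per movable
#' bead), moving the rotating reference forward by `timestep` per sweep,
#' and records the cumulative rotor angle against time. At the protocol
#' rate of 80 deg/ps the reference completes a full 360 deg turn at 4.5 ps;
#' with a sufficiently stiff restraint the rotor follows with a bounded
#' steady-state lag.
#'
#' @param top a `cg_topology`.
#' @param drv a [rotation_driver()].
#' @param duration simulated time, ps.
#' @param cfg a [sampler_config()] (`move_sigma`, `temperature`, `seed`
#'   used; the chain is first equilibrated for `burn_in` steps without the
#'   driver).
#' @param stride record trace/frames every `stride` sweeps.
#' @return list with `ensemble`, `trace` (data.frame: `time_ps`,
#'   `ref_angle`, `rotor_angle`, cumulative degrees) and the driver.
#' @export
enforced_rotation <- function(top, drv, duration, cfg, stride = 1) {
  stopifnot(duration > 0)
  validate_topology(top)
  eq <- sample_cg(top, cfg)
  init <- eq$metadata$final_coords
  arr <- topology_arrays(top)
  cons <- constraint_partners(top)
  movable <- which(!top$beads$is_virtual) - 1L
  res <- cpp_enforced_rotation(init, arr$bonds, arr$angles, arr$dihedrals,
                               arr$vs_sites, arr$vs_cons, arr$vs_w, movable,
                               cons$partner, cons$r0,
                               drv$rotation_group - 1L,
                               drv$axis[1] - 1L, drv$axis[2] - 1L,
                               drv$rate, drv$k_rot, drv$timestep, duration,
                               1 / (KB * cfg$temperature),
                               eq$metadata$move_sigma, as.integer(stride))
  trace <- as.data.frame(res$trace)
  ens <- conformer_ensemble(res$frames, resolution = "CG",
                            metadata = list(generator = "enforced_rotation",
                                            seed = cfg$seed, rate = drv$rate,
                                            k_rot = drv$k_rot,
                                            timestep = drv$timestep))
  list(ensemble = ens, trace = trace, driver = drv)
}

#' Time at which the rotation trace completes a given turn
#'
#' Linear interpolation of the cumulative angle trace; with
#' `which = "reference"` this is the driver schedule (360 deg at
#' 360/rate ps), with `which = "rotor"` the restrained follower.
#'
#' @param trace the trace data.frame from [enforced_rotation()].
#' @param angle target cumulative angle, degrees.
#' @param which trace column to use.
#' @return time in ps (NA if the angle is never reached).
#' @export
turn_time <- function(trace, angle = 360, which = c("reference", "rotor")) {
  which <- match.arg(which)
  y <- if (which == "reference") trace$ref_angle else trace$rotor_angle
  if (max(y) < angle) return(NA_real_)
  stats::approx(y, trace$time_ps, xout = angle, ties = "ordered")$y
}

#' Continue a chain under a new topology (E/Z switch mimic)
#'
#' Mimics photo-switching by continuing a finished run from its last
#' coordinates with a different bonded topology (the other stereoisomer's
#' parameter set): same beads, new potential. The relaxation is recorded as
#' per-frame energies in the returned ensemble's metadata.
#'
#' @param state a `conformer_ensemble` produced by [sample_cg()] (its
#'   `metadata$final_coords` seeds the new chain).
#' @param new_top the replacement `cg_topology`; must have the same bead
#'   count and bead names.
#' @param cfg a [sampler_config()] for the continuation.
#' @return a CG `conformer_ensemble` under the new potential.
#' @export
switch_topology <- function(state, new_top, cfg) {
  init <- state$metadata$final_coords
  if (is.null(init)) stop("state carries no final coordinates; run sample_cg first")
  if (nrow(new_top$beads) != nrow(init))
    stop("incompatibility error: bead count differs between old state and new topology")
  old_names <- state$metadata$bead_names
  if (!is.null(old_names) && !identical(old_names, new_top$beads$name))
    stop("incompatibility error: bead names differ")
  out <- sample_cg(new_top, cfg, init = init)
  out$metadata$generator <- "switch_topology"
  out
}
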