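# Boltzmann inversion of target distributions and iterative refinement of
# bonded parameters against the Monte Carlo sampler.

#' Fit configuration
#'
#' Controls the iterative distribution-matching loop of [refine()]. The
#' default convergence thresholds are the mean-absolute-error levels at
#' which a model is accepted: 0.0025 nm for bond lengths, 5.5 degrees for
#' unimodal angles, 11.4 degrees for bimodal angles.
#'
#' @param temperature K.
#' @param max_iterations refinement iterations.
#' @param tol_bond,tol_angle,tol_bimodal MAE thresholds (nm, deg, deg).
#' @param damping update damping in (0, 1].
#' @param seed base RNG seed (each iteration derives its own).
#' @param sampler_steps,sampler_stride Monte Carlo settings used for the
#'   per-iteration model ensembles.
#' @return a `fit_config` list.
#' @export
fit_config <- function(temperature = 300, max_iterations = 20,
                       tol_bond = 0.0025, tol_angle = 5.5, tol_bimodal = 11.4,
                       damping = 0.7, seed = 1,
                       sampler_steps = 200000, sampler_stride = 20) {
  stopifnot(temperature > 0, tol_bond > 0, tol_angle > 0, tol_bimodal > 0,
            damping > 0, damping <= 1)
  structure(list(temperature = temperature,
                 max_iterations = as.integer(max_iterations),
                 tol_bond = tol_bond, tol_angle = tol_angle,
                 tol_bimodal = tol_bimodal, damping = damping,
                 seed = as.integer(seed),
                 sampler_steps = as.integer(sampler_steps),
                 sampler_stride = as.integer(sampler_stride)),
            class = "fit_config")
}

#' Direct Boltzmann inversion of a unimodal distribution
#'
#' For a harmonic term, the equilibrium value is the distribution mean and
#' the force constant is `kB T / sigma^2` (angle sigmas converted to
#' radians first). A vanishing sigma signals a constraint rather than a
#' stiff spring and is returned as a constrained recommendation.
#'
#' @param dist a distribution entry (fields `mean`, `sd`, `kind`) from
#'   [extract_distributions()], or a list with those fields.
#' @param temperature K.
#' @return list with `x0` (mean, native units), `k` (kJ mol^-1 nm^-2 for
#'   bonds, kJ mol^-1 rad^-2 for angles) and `constrained`.
#' @export
invert_harmonic <- function(dist, temperature = 300) {
  s <- dist$sd
  if (s < 1e-9)
    return(list(x0 = dist$mean, k = NA_real_, constrained = TRUE))
  if (identical(dist$kind, "angle")) s <- s * pi / 180
  list(x0 = dist$mean, k = KB * temperature / s^2, constrained = FALSE)
}

# -kB T ln(density) on occupied bins, min-anchored at zero.
# jacobian = "sine" divides angle densities by sin(theta) first, the
# standard correction for the angular volume element of 3-D sampling.
inverted_profile <- function(centers, density, temperature,
                             floor_frac = 1e-4, jacobian = "none") {
  keep <- density >= floor_frac * max(density)
  x <- centers[keep]
  p <- density[keep]
  if (jacobian == "sine") p <- p / sin(pmax(x, 1) * pi / 180)
  v <- -KB * temperature * log(p)
  list(x = x, v = v - min(v))
}

#' Fit a quartic angle potential to a (bimodal) angle distribution
#'
#' Inverts the observed density to a free-energy profile
#' `-kB T ln p(theta)` (min-anchored at zero, restricted to bins above a
#' density floor) and fits `sum_n Cn (theta - theta0)^n`, n = 0..4, by
#' linear least squares with `theta0` at the density-weighted mean. The
#' quartic form captures the double wells of bimodal angle distributions
#' that a harmonic angle cannot.
#'
#' @param dist an angle distribution entry (`centers`, `density` in
#'   degrees).
#' @param temperature K.
#' @param jacobian `"none"` inverts the raw density (the literal
#'   definition); `"sine"` removes the sin(theta) volume element first,
#'   appropriate when the input came from sampling in 3-D coordinates.
#' @param floor_frac density floor, as a fraction of the maximum, below
#'   which bins are excluded from the fit.
#' @return list with `theta0` (degrees) and `coeffs` (`C0..C4`,
#'   kJ mol^-1 rad^-n).
#' @export
fit_quartic_angle <- function(dist, temperature = 300,
                              jacobian = c("none", "sine"),
                              floor_frac = 1e-4) {
  jacobian <- match.arg(jacobian)
  if (sum(dist$density > 0) < 6)
    stop("degenerate fit: fewer than 6 occupied bins")
  prof <- inverted_profile(dist$centers, dist$density, temperature,
                           floor_frac, jacobian)
  w <- dist$density[dist$density >= floor_frac * max(dist$density)]
  theta0 <- sum(prof$x * w) / sum(w)
  dx <- (prof$x - theta0) * pi / 180
  fit <- stats::lm(prof$v ~ dx + I(dx^2) + I(dx^3) + I(dx^4))
  co <- unname(stats::coef(fit))
  co[is.na(co)] <- 0
  list(theta0 = theta0, coeffs = co)
}

#' Fit proper-dihedral cosine terms to a dihedral distribution
#'
#' Inverts the density to a torsional free-energy profile and fits the
#' basis `k_n (1 + cos(n phi - phi0_n))` by linear least squares; for each
#' multiplicity the phase is 0 or 180 degrees, chosen so the amplitude is
#' non-negative.
#'
#' @param dist a dihedral distribution entry (`centers`, `density` in
#'   degrees).
#' @param temperature K.
#' @param multiplicities integer vector of multiplicities to include.
#' @param floor_frac density floor (fraction of maximum).
#' @return data.frame with columns `n`, `phi0` (deg), `kphi` (kJ/mol);
#'   attribute `"residual"` holds the fit RMS residual.
#' @export
fit_dihedral <- function(dist, temperature = 300, multiplicities = 1:3,
                         floor_frac = 1e-4) {
  if (length(multiplicities) == 0) stop("multiplicities must be nonempty")
  if (!sum(dist$density > 0)) stop("empty histogram")
  prof <- inverted_profile(dist$centers, dist$density, temperature, floor_frac)
  phi <- prof$x * pi / 180
  X <- vapply(multiplicities, function(n) cos(n * phi),
              numeric(length(phi)))
  fit <- stats::lm(prof$v ~ X)
  a <- unname(stats::coef(fit))[-1]
  a[is.na(a)] <- 0
  out <- data.frame(n = as.integer(multiplicities),
                    phi0 = ifelse(a >= 0, 0, 180),
                    kphi = abs(a))
  attr(out, "residual") <- sqrt(mean(stats::residuals(fit)^2))
  out
}

#' Boltzmann-invert a full distribution set onto a topology skeleton
#'
#' Produces the initial guess of the iterative loop: every harmonic bond
#' and unimodal angle from [invert_harmonic()], every bimodal angle as a
#' quartic term from [fit_quartic_angle()], and every dihedral from
#' [fit_dihedral()]. Term structure (indices, constrained flags, dihedral
#' multiplicities) is taken from the template topology; only parameters are
#' replaced.
#'
#' @param template a `cg_topology` giving the term structure.
#' @param target a `distribution_set` extracted from the mapped reference.
#' @param temperature K.
#' @param jacobian angle-inversion convention passed to
#'   [fit_quartic_angle()]; `"sine"` (default) is appropriate for targets
#'   measured on 3-D ensembles.
#' @return a `cg_topology` with inverted parameters.
#' @export
boltzmann_invert <- function(template, target, temperature = 300,
                             jacobian = "sine") {
  top <- template
  for (t in seq_len(nrow(top$bonds))) {
    id <- sprintf("bond:%d-%d", top$bonds$i[t], top$bonds$j[t])
    if (top$bonds$constrained[t]) { top$bonds$r0[t] <- target$terms[[id]]$mean; next }
    inv <- invert_harmonic(target$terms[[id]], temperature)
    if (inv$constrained) { top$bonds$constrained[t] <- TRUE; top$bonds$k[t] <- 0 }
    else top$bonds$k[t] <- inv$k
    top$bonds$r0[t] <- inv$x0
  }
  for (t in seq_len(nrow(top$angles))) {
    a <- top$angles[t, ]
    id <- sprintf("angle:%d-%d-%d", a$i, a$j, a$k)
    tgt <- target$terms[[id]]
    if (tgt$modality == "bimodal" || a$form == "quartic") {
      q <- fit_quartic_angle(tgt, temperature, jacobian = jacobian)
      top$angles$form[t] <- "quartic"
      top$angles$theta0[t] <- q$theta0
      top$angles[t, paste0("c", 0:4)] <- as.list(q$coeffs)
      top$angles$kf[t] <- 0
    } else {
      inv <- invert_harmonic(tgt, temperature)
      top$angles$theta0[t] <- inv$x0
      top$angles$kf[t] <- inv$k
    }
  }
  for (t in seq_len(nrow(top$dihedrals))) {
    d <- top$dihedrals[t, ]
    id <- sprintf("dihedral:%d-%d-%d-%d:%d", d$i, d$j, d$k, d$l, d$n)
    fitted <- fit_dihedral(target$terms[[id]], temperature,
                           multiplicities = d$n)
    top$dihedrals$phi0[t] <- fitted$phi0[1]
    top$dihedrals$kphi[t] <- fitted$kphi[1]
  }
  validate_topology(top)
  top
}

#' Iterative distribution matching
#'
#' Refines a topology's harmonic bond and angle parameters against target
#' distributions by repeatedly sampling the current model with
#' [sample_cg()], extracting its distributions, and applying damped moment
#' updates: `x0 <- x0 + damping * (mean_target - mean_model)` and
#' `k <- k * (sigma_model^2 / sigma_target^2)^damping`. Quartic and
#' dihedral terms keep their direct Boltzmann-inversion fit. The loop stops
#' when all MAE thresholds of the configuration are met, or after
#' `max_iterations`, returning the best iterate seen.
#'
#' @param top0 starting `cg_topology` (term list must match the target's).
#' @param target a `distribution_set`.
#' @param cfg a [fit_config()].
#' @return list with `topology` (best iterate), `report` (a `fit_report`:
#'   `converged`, `iterations`, `trace` data.frame of per-iteration MAEs,
#'   `mae` of the best iterate).
#' @export
refine <- function(top0, target, cfg = fit_config()) {
  top <- top0
  trace <- list()
  best <- NULL
  score <- function(m) {
    s <- m$mae_bonds / cfg$tol_bond
    if (!is.na(m$mae_angles_unimodal)) s <- max(s, m$mae_angles_unimodal / cfg$tol_angle)
    if (!is.na(m$mae_angles_bimodal)) s <- max(s, m$mae_angles_bimodal / cfg$tol_bimodal)
    s
  }
  converged <- FALSE
  for (it in seq_len(cfg$max_iterations)) {
    scfg <- sampler_config(temperature = cfg$temperature,
                           n_steps = cfg$sampler_steps,
                           stride = cfg$sampler_stride,
                           seed = cfg$seed + 7919L * it)
    ens <- sample_cg(top, scfg)
    model <- extract_distributions(ens, top)
    mae <- mae_between(target, model)
    trace[[it]] <- data.frame(iteration = it - 1L,
                              mae_bonds = mae$mae_bonds,
                              mae_angles_unimodal = mae$mae_angles_unimodal,
                              mae_angles_bimodal = mae$mae_angles_bimodal)
    if (is.null(best) || score(mae) < score(best$mae))
      best <- list(topology = top, mae = mae)
    ok <- mae$mae_bonds <= cfg$tol_bond &&
      (is.na(mae$mae_angles_unimodal) || mae$mae_angles_unimodal <= cfg$tol_angle) &&
      (is.na(mae$mae_angles_bimodal) || mae$mae_angles_bimodal <= cfg$tol_bimodal)
    if (ok) { converged <- TRUE; break }
    # damped moment updates on harmonic terms
    for (t in seq_len(nrow(top$bonds))) {
      if (top$bonds$constrained[t]) next
      id <- sprintf("bond:%d-%d", top$bonds$i[t], top$bonds$j[t])
      tm <- target$terms[[id]]; mm <- model$terms[[id]]
      top$bonds$r0[t] <- top$bonds$r0[t] + cfg$damping * (tm$mean - mm$mean)
      if (tm$sd > 0 && mm$sd > 0)
        top$bonds$k[t] <- top$bonds$k[t] * (mm$sd^2 / tm$sd^2)^cfg$damping
    }
    for (t in seq_len(nrow(top$angles))) {
      if (top$angles$form[t] != "harmonic") next
      a <- top$angles[t, ]
      id <- sprintf("angle:%d-%d-%d", a$i, a$j, a$k)
      tm <- target$terms[[id]]; mm <- model$terms[[id]]
      top$angles$theta0[t] <- a$theta0 + cfg$damping * (tm$mean - mm$mean)
      if (tm$sd > 0 && mm$sd > 0)
        top$angles$kf[t] <- a$kf * (mm$sd^2 / tm$sd^2)^cfg$damping
    }
  }
  report <- structure(list(converged = converged,
                           iterations = length(trace),
                           trace = do.call(rbind, trace),
                           mae = best$mae),
                      class = "fit_report")
  list(topology = best$topology, report = report)
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("fit_report: %s after %d iteration(s)\n",
              if (x$converged) "converged" else "NOT converged", x$iterations))
  print(x$mae)
  invisible(x)
}
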