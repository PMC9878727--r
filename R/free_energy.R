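# Free-energy estimators: thermodynamic integration over lambda, Bennett's
# acceptance ratio, WHAM for umbrella windows with bootstrap errors, and
# octanol-water log P assembly.

#' Free-energy result container
#'
#' @param dG free-energy difference, kJ/mol.
#' @param uncertainty standard uncertainty, kJ/mol (>= 0).
#' @param method one of `"TI"`, `"BAR"`, `"WHAM-difference"`.
#' @param temperature K (optional; checked for consistency by [log_p()]).
#' @return a `free_energy_result`.
#' @export
free_energy_result <- function(dG, uncertainty, method, temperature = NULL) {
  stopifnot(uncertainty >= 0)
  structure(list(dG = dG, uncertainty = uncertainty, method = method,
                 temperature = temperature),
            class = "free_energy_result")
}

#' @export
print.free_energy_result <- function(x, ...) {
  cat(sprintf("dG = %.4f +/- %.4f kJ/mol [%s]\n", x$dG, x$uncertainty, x$method))
  invisible(x)
}

#' Lambda series for thermodynamic integration
#'
#' Per-lambda samples of dH/dlambda along an alchemical path; the
#' decoupling protocol uses 21 evenly spaced lambda steps from fully
#' coupled (0) to fully decoupled (1).
#'
#' @param lambda strictly increasing values in [0, 1], endpoints included.
#' @param samples list of numeric vectors (kJ/mol), one per lambda.
#' @return a `lambda_series`.
#' @export
lambda_series <- function(lambda, samples) {
  stopifnot(length(lambda) == length(samples))
  if (length(lambda) < 2) stop("TI needs at least 2 lambda points")
  if (any(diff(lambda) <= 0)) stop("lambda values must be strictly increasing")
  if (abs(lambda[1]) > 1e-12 || abs(lambda[length(lambda)] - 1) > 1e-12)
    stop("lambda endpoints 0 and 1 must be present")
  structure(list(lambda = lambda, samples = samples), class = "lambda_series")
}

#' Thermodynamic integration
#'
#' Trapezoidal quadrature of the per-lambda mean dH/dlambda; the
#' uncertainty propagates per-lambda standard errors through the
#' quadrature weights in quadrature.
#'
#' @param series a [lambda_series()].
#' @return a `free_energy_result` with method `"TI"`.
#' @export
ti_integrate <- function(series) {
  lam <- series$lambda
  n <- length(lam)
  means <- vapply(series$samples, mean, numeric(1))
  ses <- vapply(series$samples, function(x)
    if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0, numeric(1))
  w <- numeric(n)
  dl <- diff(lam)
  w[1] <- dl[1] / 2
  w[n] <- dl[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dl[-(n - 1)] + dl[-1]) / 2
  free_energy_result(sum(w * means), sqrt(sum((w * ses)^2)), "TI")
}

#' Forward/reverse work samples
#'
#' @param forward,reverse work values, kJ/mol (nonempty).
#' @param temperature K.
#' @return a `work_samples`.
#' @export
work_samples <- function(forward, reverse, temperature = 300) {
  if (!length(forward) || !length(reverse))
    stop("BAR needs samples in both directions")
  structure(list(forward = as.numeric(forward), reverse = as.numeric(reverse),
                 temperature = temperature),
            class = "work_samples")
}

#' Bennett acceptance ratio estimate
#'
#' Solves the Bennett self-consistency equation
#' `sum_F f(beta (W_F - dG + M)) = sum_R f(beta (W_R + dG - M))` with
#' `f(x) = 1/(1 + exp(x))` and `M = ln(n_F/n_R)/beta` by bracketed root
#' finding, and reports the asymptotic variance estimate. Statistically
#' optimal among estimators built from bidirectional work samples.
#'
#' @param w a [work_samples()].
#' @return a `free_energy_result` with method `"BAR"`.
#' @export
bar_estimate <- function(w) {
  beta <- 1 / (KB * w$temperature)
  nF <- length(w$forward); nR <- length(w$reverse)
  M <- log(nF / nR) / beta
  fermi <- function(x) 1 / (1 + exp(x))
  g <- function(dG)
    sum(fermi(beta * (w$forward - dG + M))) -
    sum(fermi(beta * (w$reverse + dG - M)))
  lo <- min(c(w$forward, -w$reverse)) - 1
  hi <- max(c(w$forward, -w$reverse)) + 1
  for (i in 1:60) {
    if (g(lo) * g(hi) < 0) break
    span <- hi - lo
    lo <- lo - span; hi <- hi + span
    if (i == 60)
      stop("estimation error: no BAR root in bracket; forward/reverse work ",
           "distributions likely do not overlap")
  }
  dG <- stats::uniroot(g, c(lo, hi), tol = 1e-10)$root
  fF <- fermi(beta * (w$forward - dG + M))
  fR <- fermi(beta * (w$reverse + dG - M))
  varb <- (mean(fF^2) / mean(fF)^2 - 1) / nF +
          (mean(fR^2) / mean(fR)^2 - 1) / nR
  free_energy_result(dG, sqrt(max(varb, 0)) / beta, "BAR",
                     temperature = w$temperature)
}

#' Umbrella-sampling window set
#'
#' Harmonic-bias windows along a 1-D reaction coordinate: the standard
#' protocol uses 0.1 nm window spacing and a spring constant of
#' 1500 kJ mol^-1 nm^-2. Adjacent windows whose sampled ranges do not
#' overlap trigger a warning (WHAM cannot tie them together reliably).
#'
#' @param windows list of entries `list(xi0 = <nm>, k = <kJ/mol/nm^2>,
#'   xi = <numeric time series, nm>)`.
#' @param temperature K.
#' @return an `umbrella_set`.
#' @export
umbrella_set <- function(windows, temperature = 300) {
  if (length(windows) < 2) stop("umbrella set needs at least 2 windows")
  ord <- order(vapply(windows, `[[`, numeric(1), "xi0"))
  windows <- windows[ord]
  for (i in seq_len(length(windows) - 1)) {
    a <- range(windows[[i]]$xi); b <- range(windows[[i + 1]]$xi)
    if (a[2] < b[1])
      warning(sprintf("windows %d and %d have disjoint sampled ranges", i, i + 1))
  }
  structure(list(windows = windows, temperature = temperature),
            class = "umbrella_set")
}

# one WHAM solve on fixed histograms; returns window free energies f and
# unnormalized bin probabilities P
wham_solve <- function(counts, N, bias, beta, tol, max_iter) {
  f <- numeric(ncol(counts))          # per-window free energies
  nb_tot <- rowSums(counts)           # bins x windows -> per-bin totals
  expU <- exp(-beta * bias)           # bins x windows
  for (it in seq_len(max_iter)) {
    denom <- expU %*% (N * exp(beta * f))
    P <- nb_tot / pmax(denom[, 1], .Machine$double.xmin)
    fn <- -log(pmax(crossprod(expU, P)[, 1], .Machine$double.xmin)) / beta
    fn <- fn - fn[1]
    if (max(abs(fn - f)) <= tol * max(1, max(abs(fn)))) { f <- fn; break }
    f <- fn
    if (it == max_iter)
      warning("WHAM did not reach tolerance within max_iter iterations")
  }
  list(f = f, P = P)
}

#' Weighted histogram analysis of umbrella windows
#'
#' Self-consistent WHAM on a fixed grid (default 300 bins over the sampled
#' range), iterated to relative tolerance 1e-7 on the window free
#' energies. Uncertainty comes from bootstrap resampling of each window's
#' time series (default 100 replicates); the profile and every replicate
#' are min-anchored at zero. Bins never visited are dropped; an internal
#' gap of empty bins between populated regions aborts with a gap report,
#' since disjoint windows cannot be tied into one profile.
#'
#' @param us an [umbrella_set()].
#' @param n_bins histogram bins.
#' @param n_bootstrap bootstrap replicates (0 disables).
#' @param seed RNG seed for the bootstrap.
#' @param tol relative tolerance on window free energies.
#' @param max_iter iteration cap.
#' @return a `pmf_profile`: data.frame with `xi` (bin centres, nm),
#'   `F` (kJ/mol, min 0), `se` (bootstrap standard errors).
#' @export
wham <- function(us, n_bins = 300, n_bootstrap = 100, seed = 1,
                 tol = 1e-7, max_iter = 50000) {
  beta <- 1 / (KB * us$temperature)
  xs <- unlist(lapply(us$windows, `[[`, "xi"))
  edges <- seq(min(xs), max(xs), length.out = n_bins + 1)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  nw <- length(us$windows)
  bias <- vapply(us$windows, function(wd) 0.5 * wd$k * (centers - wd$xi0)^2,
                 numeric(n_bins))
  histw <- function(windows) {
    vapply(windows, function(wd)
      tabulate(findInterval(wd$xi, edges, rightmost.closed = TRUE),
               nbins = n_bins), numeric(n_bins))
  }
  counts <- histw(us$windows)
  occupied <- rowSums(counts) > 0
  # the window chain must be connected: each window's sampled range has to
  # overlap the union of the ranges before it
  rng <- lapply(us$windows, function(wd) range(wd$xi))
  reach <- rng[[1]][2]
  for (i in seq_len(nw - 1)) {
    if (rng[[i + 1]][1] > reach)
      stop(sprintf("convergence failure: windows %d and %d are disjoint (gap %.3f..%.3f nm along xi)",
                   i, i + 1, reach, rng[[i + 1]][1]))
    reach <- max(reach, rng[[i + 1]][2])
  }
  N <- vapply(us$windows, function(wd) length(wd$xi), numeric(1))
  sol <- wham_solve(counts, N, bias, beta, tol, max_iter)
  Fv <- rep(NA_real_, n_bins)
  Fv[occupied] <- -log(sol$P[occupied]) / beta
  Fv <- Fv - min(Fv, na.rm = TRUE)
  se <- rep(NA_real_, n_bins)
  if (n_bootstrap > 0) {
    set.seed(seed)
    reps <- matrix(NA_real_, n_bins, n_bootstrap)
    for (b in seq_len(n_bootstrap)) {
      wins <- lapply(us$windows, function(wd) {
        wd$xi <- sample(wd$xi, length(wd$xi), replace = TRUE)
        wd
      })
      cb <- histw(wins)
      sb <- wham_solve(cb, N, bias, beta, tol, max_iter)
      fb <- rep(NA_real_, n_bins)
      occ_b <- rowSums(cb) > 0
      fb[occ_b] <- -log(sb$P[occ_b]) / beta
      reps[, b] <- fb - min(fb, na.rm = TRUE)
    }
    se <- apply(reps, 1, stats::sd, na.rm = TRUE)
  }
  structure(data.frame(xi = centers, F = Fv, se = se),
            class = c("pmf_profile", "data.frame"))
}

#' Octanol-water partition coefficient from solvation free energies
#'
#' Assembles `log P = (dG_water->vac - dG_octanol->vac) / (2.303 R T)` from
#' two decoupling free energies (R = 0.0083145 kJ mol^-1 K^-1, T defaults
#' to the 310 K of the TI protocol). A hydrophobic solute, easier to
#' remove from water than from octanol, gives a positive log P.
#' Uncertainties combine in quadrature before scaling.
#'
#' @param dG_water,dG_octanol `free_energy_result`s for removing the
#'   solute from water and from (hydrated) octanol.
#' @param temperature K.
#' @return list with `logP` and `uncertainty` (log10 units).
#' @export
log_p <- function(dG_water, dG_octanol, temperature = 310) {
  tw <- dG_water$temperature; to <- dG_octanol$temperature
  if (!is.null(tw) && !is.null(to) && abs(tw - to) > 1e-9)
    stop("temperature mismatch between free-energy inputs")
  denom <- 2.303 * KB * temperature
  list(logP = (dG_water$dG - dG_octanol$dG) / denom,
       uncertainty = sqrt(dG_water$uncertainty^2 + dG_octanol$uncertainty^2) / denom)
}
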