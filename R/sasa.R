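# Shrake-Rupley solvent-accessible surface area and the cross-resolution
# SASA comparison.

# Rowland & Taylor van der Waals radii, nm, for the common organic atoms
ATOMIC_RADII_NM <- c(H = 0.110, C = 0.177, N = 0.164, O = 0.158, S = 0.181)

#' Per-particle radii tables
#'
#' `atomic_radii()` looks up Rowland-Taylor van der Waals radii (nm) by
#' element symbol; `bead_radii()` takes the per-bead radii of a topology
#' (bead-class defaults unless overridden), optionally dropping virtual
#' sites, which are interaction constructs rather than volume.
#'
#' @param elements character vector of element symbols (H, C, N, O, S).
#' @return numeric radii in nm (named).
#' @export
atomic_radii <- function(elements) {
  r <- ATOMIC_RADII_NM[elements]
  if (anyNA(r))
    stop("no tabulated radius for element(s): ",
         paste(unique(elements[is.na(r)]), collapse = ", "))
  r
}

#' @rdname atomic_radii
#' @param top a `cg_topology`.
#' @param include_virtual include virtual beads.
#' @export
bead_radii <- function(top, include_virtual = FALSE) {
  keep <- if (include_virtual) rep(TRUE, nrow(top$beads)) else !top$beads$is_virtual
  stats::setNames(top$beads$radius[keep], top$beads$name[keep])
}

# deterministic, nearly uniform unit-sphere point set (Fibonacci lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' For each particle, a deterministic Fibonacci point set is placed on the
#' sphere of radius `r_i + probe`; the accessible fraction is the share of
#' points lying inside no other inflated sphere, scaled by
#' `4 pi (r_i + probe)^2`.
#'
#' @param coords particles x 3 matrix, nm.
#' @param radii per-particle radii, nm.
#' @param probe probe radius, nm (water-probe convention 0.14).
#' @param n_points sphere points per particle (>= 32).
#' @return a `sasa_result`: list with `total` (nm^2), `per_particle`,
#'   `probe`, `n_points`.
#' @export
sasa <- function(coords, radii, probe = 0.14, n_points = 960) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (length(radii) != n) stop("coords and radii must have the same length")
  if (n_points < 32) stop("accuracy error: n_points must be at least 32")
  pts <- fibonacci_sphere(n_points)
  inflated <- radii + probe
  per <- numeric(n)
  for (i in seq_len(n)) {
    ri <- inflated[i]
    sphere <- pts * ri + matrix(coords[i, ], n_points, 3, byrow = TRUE)
    free <- rep(TRUE, n_points)
    for (j in seq_len(n)) {
      if (j == i) next
      if (sum((coords[i, ] - coords[j, ])^2) >= (ri + inflated[j])^2) next
      d2 <- (sphere[, 1] - coords[j, 1])^2 + (sphere[, 2] - coords[j, 2])^2 +
            (sphere[, 3] - coords[j, 3])^2
      free <- free & (d2 >= inflated[j]^2)
      if (!any(free)) break
    }
    per[i] <- 4 * pi * ri^2 * mean(free)
  }
  structure(list(total = sum(per), per_particle = per, probe = probe,
                 n_points = as.integer(n_points)),
            class = "sasa_result")
}

#' Ensemble-averaged SASA
#'
#' Mean total SASA over the frames of an ensemble (optionally a thinned
#' subset for speed).
#'
#' @param ens a `conformer_ensemble`.
#' @param radii per-particle radii, nm (particles must match the frames).
#' @param probe,n_points passed to [sasa()].
#' @param max_frames evaluate at most this many evenly spaced frames.
#' @return list with `mean_total` (nm^2), `per_frame` totals, `probe`.
#' @export
sasa_ensemble <- function(ens, radii, probe = 0.14, n_points = 960,
                          max_frames = 50) {
  idx <- unique(round(seq(1, length(ens$frames),
                          length.out = min(max_frames, length(ens$frames)))))
  totals <- vapply(ens$frames[idx], function(f)
    sasa(f[seq_along(radii), , drop = FALSE], radii, probe, n_points)$total,
    numeric(1))
  list(mean_total = mean(totals), per_frame = totals, probe = probe)
}

#' Cross-resolution SASA comparison
#'
#' Per-molecule percent difference `100 |<A_CG> - <A_AA>| / <A_AA>` between
#' ensemble-mean areas at the two resolutions, with the average and the
#' maximum across molecules — the semiquantitative check that a chosen
#' mapping reproduces a reasonable molecular shape and size.
#'
#' @param aa,cg numeric vectors of per-molecule ensemble-mean areas (nm^2),
#'   in matching order.
#' @return list with `percent_diff` per molecule, `average`, `maximum`.
#' @export
sasa_compare <- function(aa, cg) {
  aa <- as.numeric(aa); cg <- as.numeric(cg)
  if (length(aa) != length(cg)) stop("area vectors must have equal length")
  if (any(aa <= 0)) stop("zero or negative reference (AA) area")
  pd <- 100 * abs(cg - aa) / aa
  list(percent_diff = pd, average = mean(pd), maximum = max(pd))
}
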