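#' @useDynLib cgmotor, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif sd setNames density approx optimize uniroot
#'   coef lm var quantile
#' @importFrom utils head tail modifyList
NULL

# Boltzmann constant, kJ mol^-1 K^-1 (equal to the molar gas constant R)
KB <- 0.0083145

# Martini-convention default bead radii by size class, nm
BEAD_CLASS_RADII <- c(regular = 0.264, small = 0.230, tiny = 0.191)
BEAD_CLASS_MASSES <- c(regular = 72, small = 54, tiny = 36)

#' Bead definitions for a coarse-grained topology
#'
#' Builds the bead table of a CG molecule. The size class (regular / small /
#' tiny) follows the Martini convention and is inferred from the leading
#' letter of the type code (`"S"` small, `"T"` tiny, otherwise regular)
#' unless given explicitly; it sets the default bead radius
#' (0.264 / 0.230 / 0.191 nm), which can be overridden per bead.
#'
#' @param name character vector of bead labels.
#' @param type_code Martini-style type codes (e.g. `"TC5"`, `"SP4"`, `"TQ4p"`).
#' @param charge charges in elementary units (recycled).
#' @param bead_class optional explicit classes, one of `"regular"`,
#'   `"small"`, `"tiny"`.
#' @param radius optional per-bead radii in nm (default by class).
#' @param is_virtual logical; virtual beads are massless interaction sites
#'   constructed from other beads each step.
#' @return a `data.frame` with one row per bead.
#' @export
bead_table <- function(name, type_code, charge = 0, bead_class = NULL,
                       radius = NULL, is_virtual = FALSE) {
  n <- length(name)
  if (is.null(bead_class)) {
    bead_class <- ifelse(startsWith(type_code, "T"), "tiny",
                  ifelse(startsWith(type_code, "S"), "small", "regular"))
  }
  bead_class <- rep_len(bead_class, n)
  if (!all(bead_class %in% names(BEAD_CLASS_RADII)))
    stop("bead_class must be one of: ", paste(names(BEAD_CLASS_RADII), collapse = ", "))
  if (is.null(radius)) radius <- unname(BEAD_CLASS_RADII[bead_class])
  radius <- rep_len(radius, n)
  if (any(radius <= 0)) stop("bead radii must be positive")
  data.frame(name = as.character(name),
             bead_class = bead_class,
             type_code = rep_len(as.character(type_code), n),
             charge = rep_len(as.numeric(charge), n),
             radius = as.numeric(radius),
             is_virtual = rep_len(as.logical(is_virtual), n),
             stringsAsFactors = FALSE)
}

#' Bonded term tables
#'
#' Constructors for the term tables of a [cg_topology()]. Indices are
#' 1-based bead indices; distances in nm, angles in degrees, force constants
#' in kJ mol^-1 nm^-2 (bonds) or kJ mol^-1 rad^-2 (angles). A quartic angle
#' carries polynomial coefficients `C0..C4` (kJ mol^-1 rad^-n) of
#' `sum_n Cn (theta - theta0)^n`, able to represent bimodal (double-well)
#' angle distributions. Dihedrals are proper cosine terms
#' `k_phi (1 + cos(n phi - phi0))`; several rows may share one quad.
#'
#' @param i,j,k,l bead indices.
#' @param r0 equilibrium length, nm.
#' @param k,kf force constants.
#' @param constrained logical; constrained bonds are held at fixed length
#'   and contribute no energy.
#' @param theta0 equilibrium / reference angle, degrees.
#' @param form `"harmonic"` or `"quartic"`.
#' @param coeffs for quartic angles, numeric length 5 (`C0..C4`) or a matrix
#'   with 5 columns (one row per term).
#' @param n dihedral multiplicity (integer >= 1).
#' @param phi0 dihedral phase, degrees.
#' @param kphi dihedral amplitude, kJ mol^-1.
#' @return a `data.frame` of terms.
#' @name term_tables
NULL

#' @rdname term_tables
#' @export
bond_table <- function(i, j, r0, k, constrained = FALSE) {
  d <- data.frame(i = as.integer(i), j = as.integer(j), r0 = as.numeric(r0),
                  k = as.numeric(k), constrained = rep_len(constrained, length(i)))
  if (any(d$i == d$j)) stop("bond endpoints must differ")
  if (any(d$r0 <= 0)) stop("bond r0 must be positive")
  if (any(d$k < 0)) stop("bond force constants must be non-negative")
  d
}

#' @rdname term_tables
#' @export
angle_table <- function(i, j, k, theta0, kf = 0, form = "harmonic", coeffs = NULL) {
  n <- length(i)
  form <- rep_len(form, n)
  cc <- matrix(0, n, 5, dimnames = list(NULL, paste0("c", 0:4)))
  if (!is.null(coeffs)) {
    coeffs <- if (is.matrix(coeffs)) coeffs else matrix(coeffs, ncol = 5, byrow = TRUE)
    if (ncol(coeffs) != 5) stop("quartic form requires 5 coefficients C0..C4")
    qrows <- which(form == "quartic")
    if (nrow(coeffs) == n) cc[qrows, ] <- coeffs[qrows, , drop = FALSE]
    else if (nrow(coeffs) == length(qrows)) cc[qrows, ] <- coeffs
    else if (nrow(coeffs) == 1) cc[qrows, ] <- coeffs[rep(1, length(qrows)), , drop = FALSE]
    else stop("coeffs must have one row per term or per quartic term")
  }
  if (any(form == "quartic") && is.null(coeffs))
    stop("quartic form requires 5 coefficients C0..C4")
  d <- data.frame(i = as.integer(i), j = as.integer(j), k = as.integer(k),
                  theta0 = as.numeric(theta0), kf = rep_len(as.numeric(kf), n),
                  form = form, stringsAsFactors = FALSE)
  harm <- d$form == "harmonic"
  if (any(harm & (d$theta0 <= 0 | d$theta0 >= 180)))
    stop("harmonic angle theta0 must lie in (0, 180) degrees")
  if (any(d$i == d$j | d$j == d$k | d$i == d$k)) stop("angle indices must be distinct")
  cbind(d, as.data.frame(cc))
}

#' @rdname term_tables
#' @export
dihedral_table <- function(i, j, k, l, n, phi0, kphi) {
  d <- data.frame(i = as.integer(i), j = as.integer(j), k = as.integer(k),
                  l = as.integer(l), n = as.integer(n), phi0 = as.numeric(phi0),
                  kphi = as.numeric(kphi))
  if (any(apply(d[, 1:4], 1, function(x) length(unique(x)) != 4)))
    stop("dihedral indices must be four distinct beads")
  if (any(d$n < 1)) stop("dihedral multiplicities must be positive")
  d
}

#' @rdname term_tables
#' @param site index of the virtual bead.
#' @param constructors indices of the beads the site is built from.
#' @param rule `"cog"` (unweighted mean) or `"weighted"`.
#' @param weights for `rule = "weighted"`, weights summing to 1.
#' @export
virtual_site <- function(site, constructors, rule = c("cog", "weighted"),
                         weights = NULL) {
  rule <- match.arg(rule)
  if (length(constructors) == 0) stop("virtual site needs at least one constructor bead")
  if (site %in% constructors) stop("virtual site cannot construct itself")
  if (rule == "weighted") {
    if (is.null(weights) || length(weights) != length(constructors))
      stop("weighted rule needs one weight per constructor")
    if (abs(sum(weights) - 1) > 1e-8) stop("virtual-site weights must sum to 1")
  } else {
    weights <- rep(1 / length(constructors), length(constructors))
  }
  structure(list(site = as.integer(site),
                 constructors = as.integer(constructors),
                 rule = rule, weights = as.numeric(weights)),
            class = "cg_virtual_site")
}

#' Coarse-grained molecular topology
#'
#' Assembles beads and bonded terms into a validated CG topology. Virtual
#' sites are geometric constructions (centre of geometry or weighted mean of
#' constructor beads); they carry no independent degrees of freedom and a
#' bonded term may involve only virtual beads when a virtual site acts as a
#' dihedral pivot (as when a site in a motor's stator defines the
#' stator-rotor dihedral).
#'
#' @param name molecule label.
#' @param beads a [bead_table()].
#' @param bonds,angles,dihedrals term tables (may be `NULL`).
#' @param virtual_sites list of [virtual_site()] definitions.
#' @return an object of class `cg_topology`.
#' @export
cg_topology <- function(name, beads, bonds = NULL, angles = NULL,
                        dihedrals = NULL, virtual_sites = list()) {
  top <- structure(list(name = name, beads = beads,
                        bonds = bonds %||% bond_table(integer(), integer(), numeric(), numeric()),
                        angles = angles %||% angle_table(integer(), integer(), integer(), numeric()),
                        dihedrals = dihedrals %||% dihedral_table(integer(), integer(), integer(), integer(), integer(), numeric(), numeric()),
                        virtual_sites = virtual_sites),
                   class = "cg_topology")
  validate_topology(top)
  top
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cg_topology <- function(x, ...) {
  cat(sprintf("cg_topology '%s': %d beads (%d virtual), %d bonds (%d constrained), %d angles, %d dihedral terms, %d virtual sites\n",
              x$name, nrow(x$beads), sum(x$beads$is_virtual),
              nrow(x$bonds), sum(x$bonds$constrained),
              nrow(x$angles), nrow(x$dihedrals), length(x$virtual_sites)))
  invisible(x)
}

#' Validate a CG topology
#'
#' Checks index ranges, virtual-site consistency and term invariants;
#' called by [cg_topology()] and after any programmatic edit.
#'
#' @param top a `cg_topology`.
#' @return `top`, invisibly; stops with a validation error otherwise.
#' @export
validate_topology <- function(top) {
  nb <- nrow(top$beads)
  idx <- c(top$bonds$i, top$bonds$j, top$angles$i, top$angles$j, top$angles$k,
           top$dihedrals$i, top$dihedrals$j, top$dihedrals$k, top$dihedrals$l,
           unlist(lapply(top$virtual_sites, function(v) c(v$site, v$constructors))))
  if (length(idx) && (min(idx) < 1 || max(idx) > nb))
    stop(sprintf("validation error: term index %d out of range (1..%d)",
                 if (min(idx) < 1) min(idx) else max(idx), nb))
  virt <- which(top$beads$is_virtual)
  both <- function(ii) all(ii %in% virt)
  if (nrow(top$bonds) && any(apply(top$bonds[, c("i", "j")], 1, both)))
    stop("validation error: bond between virtual sites only")
  if (nrow(top$angles) && any(apply(top$angles[, c("i", "j", "k")], 1, both)))
    stop("validation error: angle over virtual sites only")
  vs_sites <- vapply(top$virtual_sites, function(v) v$site, integer(1))
  if (anyDuplicated(vs_sites)) stop("validation error: duplicate virtual-site definitions")
  declared <- which(top$beads$is_virtual)
  if (!setequal(declared, vs_sites))
    stop("validation error: is_virtual beads and virtual_sites definitions disagree")
  if (any(top$beads$radius <= 0)) stop("validation error: non-positive bead radius")
  invisible(top)
}

# Pack a topology into the 0-based, radian-unit matrices the C++ kernels
# consume. Returns list(bonds, angles, dihedrals, vs_sites, vs_cons, vs_w).
topology_arrays <- function(top) {
  b <- top$bonds
  bonds <- cbind(b$i - 1, b$j - 1, b$r0, b$k, as.numeric(b$constrained))
  a <- top$angles
  angles <- cbind(a$i - 1, a$j - 1, a$k - 1,
                  as.numeric(a$form == "quartic"), a$theta0 * pi / 180, a$kf,
                  a$c0, a$c1, a$c2, a$c3, a$c4)
  d <- top$dihedrals
  dihedrals <- cbind(d$i - 1, d$j - 1, d$k - 1, d$l - 1, d$n,
                     d$phi0 * pi / 180, d$kphi)
  storage.mode(bonds) <- storage.mode(angles) <- storage.mode(dihedrals) <- "double"
  if (!nrow(bonds)) bonds <- matrix(0, 0, 5)
  if (!nrow(angles)) angles <- matrix(0, 0, 11)
  if (!nrow(dihedrals)) dihedrals <- matrix(0, 0, 7)
  list(bonds = bonds, angles = angles, dihedrals = dihedrals,
       vs_sites = vapply(top$virtual_sites, function(v) v$site - 1L, integer(1)),
       vs_cons = lapply(top$virtual_sites, function(v) v$constructors - 1L),
       vs_w = lapply(top$virtual_sites, function(v) v$weights))
}

#' Bonded energy of a configuration
#'
#' Evaluates the bonded potential of a CG topology on one coordinate frame:
#' harmonic bonds `1/2 k (r - r0)^2`, harmonic angles
#' `1/2 kf (theta - theta0)^2` or quartic angles
#' `sum_n Cn (theta - theta0)^n`, and proper dihedrals
#' `k_phi (1 + cos(n phi - phi0))`. Constrained bonds contribute zero.
#' Virtual sites must already be placed (see [place_virtual_sites()]).
#'
#' @param top a `cg_topology`.
#' @param coords numeric matrix, beads x 3, nm.
#' @return list with `total` (kJ/mol) and per-term breakdown vectors
#'   `bonds`, `angles`, `dihedrals`.
#' @export
bonded_energy <- function(top, coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(top$beads))
    stop("coords must have one row per bead")
  arr <- topology_arrays(top)
  cpp_bonded_energy(coords, arr$bonds, arr$angles, arr$dihedrals)
}

#' Place virtual sites in a coordinate frame
#'
#' Fills virtual-bead positions from their constructor beads: the `cog` rule
#' takes the unweighted mean, the `weighted` rule the weighted mean.
#' Idempotent, since constructor beads are never virtual sites themselves.
#'
#' @param top a `cg_topology`.
#' @param coords beads x 3 matrix (virtual rows may hold anything).
#' @return the coordinate matrix with virtual rows replaced.
#' @export
place_virtual_sites <- function(top, coords) {
  coords <- as.matrix(coords)
  arr <- topology_arrays(top)
  if (length(arr$vs_sites) == 0) return(coords)
  cpp_place_vsites(coords, arr$vs_sites, arr$vs_cons, arr$vs_w)
}

# ---------------------------------------------------------------------------
# GROMACS-dialect .itp subset reader / writer
# ---------------------------------------------------------------------------

# supported directives and the function types mapped to internal forms:
#   [bonds] funct 1 -> harmonic bond; [constraints] funct 1 -> constrained
#   [angles] funct 1 -> harmonic, funct 6 -> quartic (th0, C0..C4)
#   [dihedrals] funct 1 or 9 -> proper cosine terms
#   [virtual_sitesn] funct 1 -> cog, funct 3 -> weighted (index/weight pairs)

#' Read a CG topology from a GROMACS-dialect .itp file
#'
#' Parses the directive subset `[moleculetype]`, `[atoms]`, `[bonds]`,
#' `[constraints]`, `[angles]`, `[dihedrals]`, `[virtual_sitesn]`
#' (whitespace-separated fields, `;` comments). Harmonic angles use function
#' type 1, quartic angles function type 6 with coefficients `C0..C4`;
#' proper dihedrals accept function types 1 and 9; `virtual_sitesn` accepts
#' type 1 (centre of geometry) and type 3 (explicit index/weight pairs).
#' Beads named as virtual sites are flagged virtual. Writing with
#' [write_itp()] and re-reading reproduces an identical topology.
#'
#' @param path file path.
#' @return a `cg_topology`.
#' @export
read_itp <- function(path) {
  raw <- readLines(path, warn = FALSE)
  lines <- sub(";.*$", "", raw)
  section <- NA_character_
  atoms <- list(); bonds <- list(); constraints <- list()
  angles <- list(); dihedrals <- list(); vsites <- list()
  molname <- "molecule"
  known <- c("moleculetype", "atoms", "bonds", "constraints", "angles",
             "dihedrals", "virtual_sitesn")
  for (ln in seq_along(lines)) {
    s <- trimws(lines[ln])
    if (s == "") next
    if (grepl("^\\[", s)) {
      section <- trimws(gsub("\\[|\\]", "", s))
      if (!section %in% known)
        stop(sprintf("parse error at line %d: unknown directive [ %s ]", ln, section))
      next
    }
    if (is.na(section)) stop(sprintf("parse error at line %d: content before any directive", ln))
    f <- strsplit(s, "\\s+")[[1]]
    num <- suppressWarnings(as.numeric(f))
    switch(section,
      moleculetype = { molname <- f[1] },
      atoms = atoms[[length(atoms) + 1]] <-
        list(nr = as.integer(f[1]), type = f[2], name = f[5],
             charge = if (length(f) >= 7) num[7] else 0),
      bonds = {
        if (as.integer(f[3]) != 1)
          stop(sprintf("parse error at line %d: unsupported bond function type %s", ln, f[3]))
        bonds[[length(bonds) + 1]] <- list(i = num[1], j = num[2], r0 = num[4], k = num[5])
      },
      constraints = constraints[[length(constraints) + 1]] <-
        list(i = num[1], j = num[2], r0 = num[4]),
      angles = {
        ft <- as.integer(f[4])
        if (ft == 1) angles[[length(angles) + 1]] <-
            list(i = num[1], j = num[2], k = num[3], form = "harmonic",
                 theta0 = num[5], kf = num[6], cc = rep(0, 5))
        else if (ft == 6) angles[[length(angles) + 1]] <-
            list(i = num[1], j = num[2], k = num[3], form = "quartic",
                 theta0 = num[5], kf = 0, cc = num[6:10])
        else stop(sprintf("parse error at line %d: unsupported angle function type %d", ln, ft))
      },
      dihedrals = {
        ft <- as.integer(f[5])
        if (!ft %in% c(1L, 9L))
          stop(sprintf("parse error at line %d: unsupported dihedral function type %d", ln, ft))
        dihedrals[[length(dihedrals) + 1]] <-
          list(i = num[1], j = num[2], k = num[3], l = num[4],
               phi0 = num[6], kphi = num[7], n = as.integer(f[8]))
      },
      virtual_sitesn = {
        ft <- as.integer(f[2])
        if (ft == 1) vsites[[length(vsites) + 1]] <-
            virtual_site(as.integer(f[1]), as.integer(f[-(1:2)]), "cog")
        else if (ft == 3) {
          rest <- num[-(1:2)]
          vsites[[length(vsites) + 1]] <-
            virtual_site(as.integer(f[1]), as.integer(rest[c(TRUE, FALSE)]),
                         "weighted", rest[c(FALSE, TRUE)])
        } else stop(sprintf("parse error at line %d: unsupported virtual_sitesn type %d", ln, ft))
      })
  }
  if (!length(atoms)) stop("parse error: no [atoms] section")
  vs_idx <- vapply(vsites, function(v) v$site, integer(1))
  beads <- bead_table(name = vapply(atoms, `[[`, "", "name"),
                      type_code = vapply(atoms, `[[`, "", "type"),
                      charge = vapply(atoms, `[[`, 0, "charge"),
                      is_virtual = seq_along(atoms) %in% vs_idx)
  bl <- function(lst, fld) vapply(lst, `[[`, numeric(1), fld)
  bond_df <- NULL
  if (length(bonds) || length(constraints)) {
    bond_df <- bond_table(
      i = c(if (length(bonds)) bl(bonds, "i"), if (length(constraints)) bl(constraints, "i")),
      j = c(if (length(bonds)) bl(bonds, "j"), if (length(constraints)) bl(constraints, "j")),
      r0 = c(if (length(bonds)) bl(bonds, "r0"), if (length(constraints)) bl(constraints, "r0")),
      k = c(if (length(bonds)) bl(bonds, "k"), if (length(constraints)) rep(0, length(constraints))),
      constrained = c(rep(FALSE, length(bonds)), rep(TRUE, length(constraints))))
  }
  angle_df <- NULL
  if (length(angles)) {
    angle_df <- angle_table(
      i = bl(angles, "i"), j = bl(angles, "j"), k = bl(angles, "k"),
      theta0 = bl(angles, "theta0"), kf = bl(angles, "kf"),
      form = vapply(angles, `[[`, "", "form"),
      coeffs = do.call(rbind, lapply(angles, `[[`, "cc")))
  }
  dih_df <- NULL
  if (length(dihedrals)) {
    dih_df <- dihedral_table(
      i = bl(dihedrals, "i"), j = bl(dihedrals, "j"), k = bl(dihedrals, "k"),
      l = bl(dihedrals, "l"), n = vapply(dihedrals, `[[`, integer(1), "n"),
      phi0 = bl(dihedrals, "phi0"), kphi = bl(dihedrals, "kphi"))
  }
  cg_topology(molname, beads, bond_df, angle_df, dih_df, vsites)
}

fmt_num <- function(x) formatC(x, digits = 12, format = "g")

#' Write a CG topology as a GROMACS-dialect .itp file
#'
#' Inverse of [read_itp()] on the supported directive subset; the
#' round trip `read_itp(write_itp(top))` reproduces `top` exactly.
#'
#' @param top a `cg_topology`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_itp <- function(top, path) {
  out <- c("[ moleculetype ]", "; name  nrexcl", paste(top$name, 1), "",
           "[ atoms ]", "; nr type resnr residue atom cgnr charge mass")
  for (i in seq_len(nrow(top$beads))) {
    b <- top$beads[i, ]
    mass <- if (b$is_virtual) 0 else BEAD_CLASS_MASSES[[b$bead_class]]
    out <- c(out, paste(i, b$type_code, 1, top$name, b$name, i,
                        fmt_num(b$charge), fmt_num(mass)))
  }
  bonds <- top$bonds[!top$bonds$constrained, , drop = FALSE]
  cons <- top$bonds[top$bonds$constrained, , drop = FALSE]
  if (nrow(bonds)) {
    out <- c(out, "", "[ bonds ]", "; i j funct r0 k")
    for (i in seq_len(nrow(bonds)))
      out <- c(out, paste(bonds$i[i], bonds$j[i], 1,
                          fmt_num(bonds$r0[i]), fmt_num(bonds$k[i])))
  }
  if (nrow(cons)) {
    out <- c(out, "", "[ constraints ]", "; i j funct r0")
    for (i in seq_len(nrow(cons)))
      out <- c(out, paste(cons$i[i], cons$j[i], 1, fmt_num(cons$r0[i])))
  }
  if (nrow(top$angles)) {
    out <- c(out, "", "[ angles ]", "; i j k funct params")
    for (i in seq_len(nrow(top$angles))) {
      a <- top$angles[i, ]
      out <- c(out, if (a$form == "harmonic")
        paste(a$i, a$j, a$k, 1, fmt_num(a$theta0), fmt_num(a$kf))
        else paste(a$i, a$j, a$k, 6, fmt_num(a$theta0),
                   paste(fmt_num(unlist(a[paste0("c", 0:4)])), collapse = " ")))
    }
  }
  if (nrow(top$dihedrals)) {
    out <- c(out, "", "[ dihedrals ]", "; i j k l funct phi0 kphi n")
    for (i in seq_len(nrow(top$dihedrals))) {
      d <- top$dihedrals[i, ]
      out <- c(out, paste(d$i, d$j, d$k, d$l, 1, fmt_num(d$phi0),
                          fmt_num(d$kphi), d$n))
    }
  }
  if (length(top$virtual_sites)) {
    out <- c(out, "", "[ virtual_sitesn ]", "; site funct constructors")
    for (v in top$virtual_sites) {
      out <- c(out, if (v$rule == "cog")
        paste(v$site, 1, paste(v$constructors, collapse = " "))
        else paste(v$site, 3, paste(rbind(v$constructors, fmt_num(v$weights)),
                                    collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}
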