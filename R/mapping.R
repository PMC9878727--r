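#' Atomistic-to-CG mapping schemes
#'
#' A mapping scheme assigns groups of atoms to CG beads; forward mapping
#' places each real bead at the centre of geometry (`cog`, the Martini
#' convention for heavy atoms) or centre of mass (`com`) of its atoms.
#' Virtual beads carry no atom assignment: their positions are constructed
#' geometrically by the topology's virtual-site rules after mapping.
#'
#' @param molecule molecule label.
#' @param assignments list of entries `list(bead = <label>, atoms =
#'   <1-based atom indices>, rule = "cog"|"com")`; virtual beads use
#'   `atoms = integer(0)`. Entries are in CG bead order.
#' @param atom_masses atomic masses in amu, required for any `com` rule.
#' @return an object of class `mapping_scheme`.
#' @export
mapping_scheme <- function(molecule, assignments, atom_masses = NULL) {
  for (a in assignments) {
    if (is.null(a$bead)) stop("every assignment needs a bead label")
    a$atoms <- as.integer(a$atoms)
    if (length(a$atoms) && anyDuplicated(a$atoms))
      stop(sprintf("duplicate atom indices within bead '%s'", a$bead))
    rule <- a$rule %||% "cog"
    if (!rule %in% c("cog", "com")) stop("weight rule must be 'cog' or 'com'")
    if (rule == "com" && is.null(atom_masses))
      stop("com rule requires atom_masses")
  }
  assignments <- lapply(assignments, function(a) {
    list(bead = a$bead, atoms = as.integer(a$atoms), rule = a$rule %||% "cog")
  })
  structure(list(molecule = molecule, assignments = assignments,
                 atom_masses = atom_masses),
            class = "mapping_scheme")
}

#' @export
print.mapping_scheme <- function(x, ...) {
  nv <- sum(vapply(x$assignments, function(a) length(a$atoms) == 0, logical(1)))
  cat(sprintf("mapping_scheme '%s': %d beads (%d virtual), %d atoms assigned\n",
              x$molecule, length(x$assignments), nv,
              length(unlist(lapply(x$assignments, `[[`, "atoms")))))
  invisible(x)
}

#' Read / write mapping schemes as JSON
#'
#' Plain-text JSON with explicit 1-based atom indices matching the
#' coordinate file order.
#'
#' @param path file path.
#' @return [read_mapping()]: a `mapping_scheme`.
#' @export
read_mapping <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  mapping_scheme(j$molecule,
                 lapply(j$beads, function(b)
                   list(bead = b$name, atoms = unlist(b$atoms) %||% integer(0),
                        rule = b$rule %||% "cog")),
                 atom_masses = unlist(j$atom_masses))
}

#' @rdname read_mapping
#' @param scheme a `mapping_scheme`.
#' @export
write_mapping <- function(scheme, path) {
  obj <- list(molecule = scheme$molecule,
              beads = lapply(scheme$assignments, function(a)
                list(name = a$bead, atoms = a$atoms, rule = a$rule)))
  if (!is.null(scheme$atom_masses)) obj$atom_masses <- scheme$atom_masses
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Forward-map an atomistic ensemble to CG resolution
#'
#' Per frame, each real bead is placed at the unweighted (`cog`) or
#' mass-weighted (`com`) mean of its assigned atoms; virtual beads are then
#' filled by [place_virtual_sites()] when a topology is supplied. The frame
#' count is preserved. Mapping commutes with rigid motions of the input.
#'
#' @param scheme a `mapping_scheme`.
#' @param aa an atomistic `conformer_ensemble`.
#' @param top optional `cg_topology` supplying virtual-site rules.
#' @return a CG `conformer_ensemble`.
#' @export
map_ensemble <- function(scheme, aa, top = NULL) {
  max_idx <- max(c(0L, unlist(lapply(scheme$assignments, `[[`, "atoms"))))
  if (max_idx > aa$n_particles)
    stop(sprintf("mapping error: scheme references atom %d but frames have %d atoms",
                 max_idx, aa$n_particles))
  nb <- length(scheme$assignments)
  weights <- lapply(scheme$assignments, function(a) {
    if (!length(a$atoms)) return(numeric(0))
    if (a$rule == "com") {
      m <- scheme$atom_masses[a$atoms]
      m / sum(m)
    } else rep(1 / length(a$atoms), length(a$atoms))
  })
  frames <- lapply(aa$frames, function(f) {
    cg <- matrix(NA_real_, nb, 3)
    for (b in seq_len(nb)) {
      at <- scheme$assignments[[b]]$atoms
      if (length(at))
        cg[b, ] <- crossprod(f[at, , drop = FALSE], weights[[b]])[, 1]
    }
    if (!is.null(top)) cg <- place_virtual_sites(top, cg)
    cg
  })
  conformer_ensemble(frames, resolution = "CG",
                     metadata = c(aa$metadata,
                                  list(mapped_from = aa$resolution,
                                       molecule = scheme$molecule)))
}

#' Cross-check a mapping scheme against a CG topology
#'
#' Verifies bead-count and bead-name agreement, that every virtual bead in
#' the topology is constructible (has a virtual-site rule and no atom
#' assignment), and lists unassigned atoms. Findings are reported, never
#' raised.
#'
#' @param scheme a `mapping_scheme`.
#' @param top a `cg_topology`.
#' @param n_atoms total atom count of the molecule (for the unassigned-atom
#'   check); defaults to the largest index the scheme mentions.
#' @return list with `ok`, `findings` (character), and `unassigned_atoms`.
#' @export
check_scheme <- function(scheme, top, n_atoms = NULL) {
  findings <- character()
  nb_s <- length(scheme$assignments)
  nb_t <- nrow(top$beads)
  if (nb_s != nb_t)
    findings <- c(findings, sprintf("bead count mismatch: scheme %d vs topology %d",
                                    nb_s, nb_t))
  sn <- vapply(scheme$assignments, `[[`, "", "bead")
  if (nb_s == nb_t && any(sn != top$beads$name))
    findings <- c(findings, sprintf("bead name mismatch at positions: %s",
                                    paste(which(sn != top$beads$name), collapse = ", ")))
  vs_sites <- vapply(top$virtual_sites, function(v) v$site, integer(1))
  for (b in which(top$beads$is_virtual)) {
    if (!b %in% vs_sites)
      findings <- c(findings, sprintf("unconstructible v-site: bead %d has no construction rule", b))
    if (b <= nb_s && length(scheme$assignments[[b]]$atoms))
      findings <- c(findings, sprintf("virtual bead %d has a direct atom assignment", b))
  }
  for (b in setdiff(which(!top$beads$is_virtual), integer(0))) {
    if (b <= nb_s && !length(scheme$assignments[[b]]$atoms))
      findings <- c(findings, sprintf("real bead %d has no atoms assigned", b))
  }
  assigned <- sort(unique(unlist(lapply(scheme$assignments, `[[`, "atoms"))))
  n_atoms <- n_atoms %||% if (length(assigned)) max(assigned) else 0L
  unassigned <- setdiff(seq_len(n_atoms), assigned)
  if (length(unassigned))
    findings <- c(findings, sprintf("unassigned atoms: %s",
                                    paste(unassigned, collapse = ", ")))
  list(ok = length(findings) == 0, findings = findings,
       unassigned_atoms = unassigned)
}
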