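#' Conformer ensembles
#'
#' A `conformer_ensemble` is a list of coordinate frames (matrices,
#' particles x 3, nm) at one resolution (`"AA"` atomistic or `"CG"`
#' coarse-grained), with optional box lengths and provenance metadata
#' (seed, generator, sampler settings).
#'
#' @param frames list of numeric matrices with identical dimensions.
#' @param resolution `"AA"` or `"CG"`.
#' @param box optional numeric length-3 box vector, nm.
#' @param metadata named list of provenance fields.
#' @return an object of class `conformer_ensemble`.
#' @export
conformer_ensemble <- function(frames, resolution = c("CG", "AA"), box = NULL,
                               metadata = list()) {
  resolution <- match.arg(resolution)
  if (length(frames) < 1) stop("ensemble needs at least one frame")
  np <- nrow(frames[[1]])
  ok <- vapply(frames, function(f) is.matrix(f) && nrow(f) == np && ncol(f) == 3,
               logical(1))
  if (!all(ok)) stop("all frames must be matrices with the same particle count x 3")
  structure(list(frames = frames, n_particles = np, resolution = resolution,
                 box = box, metadata = metadata),
            class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf("conformer_ensemble [%s]: %d frames x %d particles\n",
              x$resolution, length(x$frames), x$n_particles))
  invisible(x)
}

#' @export
length.conformer_ensemble <- function(x) length(x$frames)

#' Read / write multi-frame XYZ coordinate files
#'
#' Plain XYZ blocks (`count`, comment, `name x y z` rows), with coordinates
#' in nm. This is the toolkit's lossless interchange format; [read_gro()] /
#' [write_gro()] cover the fixed-precision GROMACS dialect.
#'
#' @param path file path.
#' @param resolution resolution tag for the resulting ensemble.
#' @return [read_xyz()]: a `conformer_ensemble`; writers return `path`
#'   invisibly.
#' @export
read_xyz <- function(path, resolution = "CG") {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  pos <- 1
  while (pos <= length(lines)) {
    if (trimws(lines[pos]) == "") { pos <- pos + 1; next }
    n <- as.integer(trimws(lines[pos]))
    if (is.na(n)) stop(sprintf("XYZ parse error at line %d: expected atom count", pos))
    block <- lines[(pos + 2):(pos + 1 + n)]
    f <- t(vapply(strsplit(trimws(block), "\\s+"),
                  function(x) as.numeric(x[2:4]), numeric(3)))
    frames[[length(frames) + 1]] <- f
    pos <- pos + 2 + n
  }
  conformer_ensemble(frames, resolution = resolution,
                     metadata = list(source = path))
}

#' @rdname read_xyz
#' @param ens a `conformer_ensemble`.
#' @param names optional particle names (defaults to `P1..Pn`).
#' @export
write_xyz <- function(ens, path, names = NULL) {
  np <- ens$n_particles
  if (is.null(names)) names <- paste0("P", seq_len(np))
  con <- file(path, "w")
  on.exit(close(con))
  for (fi in seq_along(ens$frames)) {
    f <- ens$frames[[fi]]
    writeLines(c(as.character(np), sprintf("frame %d (nm)", fi),
                 sprintf("%s %.9f %.9f %.9f", names, f[, 1], f[, 2], f[, 3])),
               con)
  }
  invisible(path)
}

#' Read / write GROMACS-dialect .gro coordinate files
#'
#' Fixed-format `.gro` blocks (title, atom count, atom records with
#' positions in nm to three decimals, box line); multiple concatenated
#' blocks form a multi-frame trajectory.
#'
#' @param path file path.
#' @param resolution resolution tag.
#' @return [read_gro()]: a `conformer_ensemble`; writers return `path`
#'   invisibly.
#' @export
read_gro <- function(path, resolution = "CG") {
  lines <- readLines(path, warn = FALSE)
  frames <- list(); box <- NULL
  pos <- 1
  while (pos <= length(lines)) {
    if (trimws(lines[pos]) == "") { pos <- pos + 1; next }
    n <- as.integer(trimws(lines[pos + 1]))
    if (is.na(n)) stop(sprintf(".gro parse error at line %d: expected atom count", pos + 1))
    block <- lines[(pos + 2):(pos + 1 + n)]
    f <- t(vapply(block, function(s)
      c(as.numeric(substr(s, 21, 28)), as.numeric(substr(s, 29, 36)),
        as.numeric(substr(s, 37, 44))), numeric(3), USE.NAMES = FALSE))
    frames[[length(frames) + 1]] <- f
    box <- as.numeric(strsplit(trimws(lines[pos + 2 + n]), "\\s+")[[1]])[1:3]
    pos <- pos + 3 + n
  }
  conformer_ensemble(frames, resolution = resolution, box = box,
                     metadata = list(source = path))
}

#' @rdname read_gro
#' @param ens a `conformer_ensemble`.
#' @param names optional particle names.
#' @param resname residue name written on every record.
#' @export
write_gro <- function(ens, path, names = NULL, resname = "MOL") {
  np <- ens$n_particles
  if (is.null(names)) names <- paste0("P", seq_len(np))
  box <- ens$box %||% c(10, 10, 10)
  con <- file(path, "w")
  on.exit(close(con))
  for (fi in seq_along(ens$frames)) {
    f <- ens$frames[[fi]]
    writeLines(c(sprintf("frame %d", fi), sprintf("%5d", np),
                 sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1, resname,
                         substr(names, 1, 5), seq_len(np),
                         f[, 1], f[, 2], f[, 3]),
                 sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3])),
               con)
  }
  invisible(path)
}

#' Read a coordinate ensemble, dispatching on file extension
#'
#' `.gro` files go through [read_gro()], anything else through [read_xyz()].
#'
#' @inheritParams read_xyz
#' @return a `conformer_ensemble`.
#' @export
read_ensemble <- function(path, resolution = "CG") {
  if (grepl("\\.gro$", path)) read_gro(path, resolution)
  else read_xyz(path, resolution)
}
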