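#' Structure model: an atom table plus one or more coordinate frames
#'
#' Light container used by all geometry metrics.  `atoms` records chain,
#' author residue number, residue name and atom name; coordinates live in a
#' frames matrix (one row per frame, bio3d xyz layout `x1 y1 z1 x2 ...`) so
#' a single structure and a multi-model trajectory share one
#' representation.
#'
#' @param atoms Data frame with columns `chain`, `resno`, `resid`, `elety`,
#'   `x`, `y`, `z` (coordinates of the first frame, Angstrom).
#' @param frames Optional numeric matrix of coordinates, one row per frame,
#'   `3 * nrow(atoms)` columns.  Defaults to the single frame in `atoms`.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, frames = NULL) {
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("'atoms' must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  xyz1 <- as.numeric(t(as.matrix(atoms[, c("x", "y", "z")])))
  if (is.null(frames)) frames <- matrix(xyz1, nrow = 1L)
  frames <- unname(as.matrix(frames))
  if (ncol(frames) != 3L * nrow(atoms))
    stop("'frames' must have 3 * n_atoms columns", call. = FALSE)
  if (any(!is.finite(frames)))
    stop("coordinates must be finite", call. = FALSE)
  structure(list(atoms = atoms, frames = frames), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d atoms, %d residues, chains %s, %d frame(s)\n",
              nrow(x$atoms),
              nrow(unique(x$atoms[, c("chain", "resno")])),
              paste(unique(x$atoms$chain), collapse = ""),
              nrow(x$frames)))
  invisible(x)
}

#' Number of frames in a structure model
#' @param model A [structure_model()].
#' @export
n_frames <- function(model) nrow(model$frames)

# N x 3 coordinate matrix of one frame
frame_coords <- function(model, frame = 1L) {
  matrix(model$frames[frame, ], ncol = 3L, byrow = TRUE)
}

#' Read a structure (PDB or mmCIF), including multi-model trajectories
#'
#' Thin wrapper around bio3d's readers.  MODEL/ENDMDL blocks of a
#' multi-model PDB become frames.  Author residue numbering is kept as-is.
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @return A [structure_model()].
#' @export
read_structure <- function(path) {
  if (!file.exists(path))
    stop("structure file not found: ", path, call. = FALSE)
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE))
    bio3d::read.cif(path) else bio3d::read.pdb(path, multi = TRUE)
  atoms <- pdb$atom[, c("type", "chain", "resno", "resid", "elety",
                        "x", "y", "z")]
  atoms$chain[is.na(atoms$chain)] <- "A"
  frames <- pdb$xyz
  if (!is.matrix(frames)) frames <- matrix(frames, nrow = 1L)
  structure_model(atoms, frames)
}

#' Write a structure model as (multi-model) PDB
#'
#' @param model A [structure_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  bio3d::write.pdb(file = path, xyz = model$frames, type = "ATOM",
                   resno = a$resno, resid = a$resid, chain = a$chain,
                   elety = a$elety)
  invisible(path)
}

#' Site map: paper residue numbering to file chains and residues
#'
#' FRET tables address label sites as (subunit, residue) in the numbering
#' used by the experiments; deposited structures address atoms as
#' (chain, author residue number).  A site map records, per crystallographic
#' copy of the complex, which chain holds each subunit and an additive
#' residue-number offset.  The restraint atom defaults to the alpha carbon.
#'
#' @param copies List of named character vectors/lists, one per
#'   crystallographic copy, mapping subunit name to chain id.
#' @param offsets Named numeric vector of per-subunit residue offsets
#'   (file resno = table residue + offset); missing subunits get 0.
#' @param atom Atom name used for site resolution (default `"CA"`).
#' @return An object of class `site_map`.
#' @examples
#' site_map(copies = list(c(cTnC = "A", cTnI = "B", cTnT = "C")))
#' @export
site_map <- function(copies, offsets = NULL, atom = "CA") {
  if (!is.list(copies) || length(copies) == 0L)
    stop("'copies' must be a non-empty list of subunit -> chain maps",
         call. = FALSE)
  copies <- lapply(copies, function(cp) unlist(cp))
  structure(list(copies = copies, offsets = offsets %||% numeric(),
                 atom = atom), class = "site_map")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a site map from YAML
#'
#' Expected layout:
#' ```yaml
#' atom: CA
#' offsets: {cTnC: 0}
#' copies:
#'   - {cTnC: A, cTnI: B, cTnT: C}
#'   - {cTnC: D, cTnI: E, cTnT: F}
#' ```
#' @param path Path to the YAML file.
#' @return A [site_map()].
#' @export
read_site_map <- function(path) {
  if (!file.exists(path))
    stop("site map not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  site_map(copies = cfg$copies,
           offsets = unlist(cfg$offsets),
           atom = cfg$atom %||% "CA")
}

# "cTnC:13" or c(subunit, residue) or list(subunit=, residue=) -> list
parse_site <- function(site) {
  if (is.list(site)) return(list(subunit = site$subunit,
                                 residue = as.integer(site$residue)))
  if (length(site) == 1L && grepl(":", site)) {
    parts <- strsplit(site, ":", fixed = TRUE)[[1L]]
    return(list(subunit = parts[1L], residue = as.integer(parts[2L])))
  }
  if (length(site) == 2L)
    return(list(subunit = as.character(site[1L]),
                residue = as.integer(site[2L])))
  stop("cannot parse site specification", call. = FALSE)
}

# Resolve a (subunit, residue) site to an atom row index; mapping errors
# name the offender.
resolve_site <- function(model, map, site, copy = 1L) {
  stopifnot(inherits(model, "structure_model"), inherits(map, "site_map"))
  s <- parse_site(site)
  if (copy > length(map$copies))
    stop("site map has no copy ", copy, call. = FALSE)
  cp <- map$copies[[copy]]
  if (!s$subunit %in% names(cp))
    stop("site map does not cover subunit '", s$subunit, "'", call. = FALSE)
  off <- if (s$subunit %in% names(map$offsets))
    map$offsets[[s$subunit]] else 0
  resno <- s$residue + off
  ok_type <- if ("type" %in% names(model$atoms))
    model$atoms$type %in% "ATOM" else TRUE
  idx <- which(model$atoms$chain == cp[[s$subunit]] &
                 model$atoms$resno == resno &
                 model$atoms$elety == map$atom & ok_type)
  if (length(idx) == 0L)
    stop("site ", s$subunit, ":", s$residue, " (chain ", cp[[s$subunit]],
         ", resno ", resno, ", atom ", map$atom,
         ") is absent from the structure", call. = FALSE)
  idx[1L]
}

#' Number of crystallographic copies in a site map
#' @param map A [site_map()].
#' @export
n_copies <- function(map) length(map$copies)
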