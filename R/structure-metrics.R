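#' Alpha-carbon distance between two mapped sites
#'
#' Euclidean distance (Angstrom) between the alpha carbons of two label
#' sites, resolved through a [site_map()].  Symmetric in its arguments.
#'
#' @param model A [structure_model()].
#' @param site_a,site_b Sites, e.g. `"cTnC:13"` or `c("cTnC", 13)`.
#' @param map A [site_map()].
#' @param copy Crystallographic copy to use (index into the map's copies).
#' @param frame Frame index for trajectories.
#' @return Distance in Angstrom.
#' @export
ca_distance <- function(model, site_a, site_b, map, copy = 1L, frame = 1L) {
  i <- resolve_site(model, map, site_a, copy)
  j <- resolve_site(model, map, site_b, copy)
  xyz <- frame_coords(model, frame)
  sqrt(sum((xyz[i, ] - xyz[j, ])^2))
}

#' Openness of the TnC N-domain hydrophobic pocket
#'
#' The opening of the regulatory N-domain pocket of troponin C tracks the
#' alpha-carbon distance between residues 13 and 51: the pocket is called
#' open when that distance reaches `threshold` (default 24 Angstrom, the
#' midpoint between the closed-state and open-state skeletal crystal
#' anchors of 19.21 and 29.06 Angstrom).
#'
#' @param model A [structure_model()].
#' @param map A [site_map()] covering the TnC subunit.
#' @param threshold Open/closed decision distance in Angstrom.
#' @param subunit Subunit name carrying residues 13 and 51.
#' @param residues The two monitored residues (default `c(13, 51)`).
#' @param copy,frame Copy and frame selectors.
#' @return An object of class `pocket_state`: list with `d_13_51`, `state`
#'   (`"open"` iff the distance is >= threshold) and `threshold`.
#' @export
pocket_openness <- function(model, map, threshold = 24, subunit = "cTnC",
                            residues = c(13, 51), copy = 1L, frame = 1L) {
  d <- ca_distance(model, c(subunit, residues[1L]),
                   c(subunit, residues[2L]), map, copy, frame)
  structure(list(d_13_51 = d,
                 state = if (d >= threshold) "open" else "closed",
                 threshold = threshold),
            class = "pocket_state")
}

#' @export
print.pocket_state <- function(x, ...) {
  cat(sprintf("N-domain pocket: d(13-51) = %.2f A -> %s (threshold %.1f A)\n",
              x$d_13_51, x$state, x$threshold))
  invisible(x)
}

vnorm <- function(v) sqrt(sum(v^2))
unit <- function(v) v / vnorm(v)
angle_deg <- function(a, b, c) {
  # angle at b of the path a-b-c, degrees
  u <- unit(a - b)
  v <- unit(c - b)
  acos(min(1, max(-1, sum(u * v)))) * 180 / pi
}

# Side-chain heavy-atom donor/acceptor tables (protein N/O chemistry).
.SC_DONORS <- c("NE", "NH1", "NH2", "NZ", "ND1", "NE2", "ND2", "NE1",
                "OG", "OG1", "OH", "SG")
.SC_ACCEPTORS <- c("OD1", "OD2", "OE1", "OE2", "OG", "OG1", "OH",
                   "ND1", "NE2", "OXT")

#' Detect hydrogen bonds by geometric criteria
#'
#' Ligplot-style geometric detection on heavy atoms: a donor (N or O
#' carrying a polar hydrogen) and an acceptor (carbonyl or side-chain O,
#' His ring N) are reported as bonded when their heavy-atom distance is at
#' most `d_cut` and the angle criterion holds.  For backbone amides the
#' hydrogen position is inferred from the N, CA and preceding C atoms and
#' the D-H...A angle must reach `angle_cut`; for donors whose hydrogen
#' cannot be placed the antecedent-angle proxy C-D...A >= 90 degrees is
#' used instead.  Pairs within the same residue or between
#' sequence-adjacent backbones are skipped.  Output ordering is
#' deterministic (donor chain, residue, acceptor chain, residue).
#'
#' @param model A [structure_model()] with backbone atoms.
#' @param d_cut Heavy-atom donor-acceptor cutoff in Angstrom.
#' @param angle_cut D-H...A angle cutoff in degrees.
#' @param frame Frame index.
#' @return Data frame of class `hbond_list`: donor/acceptor chain, residue
#'   number, atom name, heavy-atom `distance` and the evaluated `angle`
#'   (D-H...A, or the donor-antecedent proxy when no H could be inferred).
#' @export
detect_hbonds <- function(model, d_cut = 3.5, angle_cut = 120, frame = 1L) {
  a <- model$atoms
  xyz <- frame_coords(model, frame)
  key <- paste(a$chain, a$resno, a$elety)
  row_of <- function(chain, resno, elety)
    match(paste(chain, resno, elety), key)

  is_bb_n <- a$elety == "N" & !(a$resid %in% "PRO")
  donors <- which(is_bb_n | a$elety %in% .SC_DONORS)
  acceptors <- which(a$elety %in% c("O", .SC_ACCEPTORS))
  if (!length(donors) || !length(acceptors))
    return(empty_hbonds())

  out <- vector("list", length(donors))
  for (di in seq_along(donors)) {
    d <- donors[di]
    dv <- xyz[d, ]
    dd <- sqrt(colSums((t(xyz[acceptors, , drop = FALSE]) - dv)^2))
    cand <- acceptors[dd <= d_cut]
    dist <- dd[dd <= d_cut]
    if (!length(cand)) next
    # never bond within a residue; skip adjacent backbone amide-carbonyl
    same_res <- a$chain[cand] == a$chain[d] & a$resno[cand] == a$resno[d]
    adj_bb <- a$chain[cand] == a$chain[d] &
      abs(a$resno[cand] - a$resno[d]) < 2L &
      a$elety[d] == "N" & a$elety[cand] == "O"
    keep <- !(same_res | adj_bb)
    cand <- cand[keep]
    dist <- dist[keep]
    if (!length(cand)) next

    # hydrogen inference for backbone N: H along the bisector opposite
    # the CA and preceding-C directions
    hpos <- NULL
    antecedent <- NULL
    if (a$elety[d] == "N") {
      ca <- row_of(a$chain[d], a$resno[d], "CA")
      cprev <- row_of(a$chain[d], a$resno[d] - 1L, "C")
      if (!is.na(ca) && !is.na(cprev)) {
        hdir <- unit(unit(dv - xyz[cprev, ]) + unit(dv - xyz[ca, ]))
        hpos <- dv + hdir  # N-H ~ 1.0 A
      } else if (!is.na(ca)) {
        antecedent <- xyz[ca, ]
      }
    }
    if (is.null(hpos) && is.null(antecedent)) {
      # side-chain donor: antecedent = nearest heavy atom in the residue
      res_atoms <- which(a$chain == a$chain[d] & a$resno == a$resno[d])
      res_atoms <- setdiff(res_atoms, d)
      if (length(res_atoms)) {
        dr <- sqrt(colSums((t(xyz[res_atoms, , drop = FALSE]) - dv)^2))
        antecedent <- xyz[res_atoms[which.min(dr)], ]
      }
    }

    ang <- vapply(seq_along(cand), function(k) {
      av <- xyz[cand[k], ]
      if (!is.null(hpos)) angle_deg(dv, hpos, av)
      else if (!is.null(antecedent)) angle_deg(antecedent, dv, av)
      else 180
    }, numeric(1))
    pass <- if (!is.null(hpos)) ang >= angle_cut else ang >= 90
    if (!any(pass)) next
    out[[di]] <- data.frame(
      donor_chain = a$chain[d], donor_resno = a$resno[d],
      donor_atom = a$elety[d],
      acceptor_chain = a$chain[cand[pass]],
      acceptor_resno = a$resno[cand[pass]],
      acceptor_atom = a$elety[cand[pass]],
      distance = dist[pass], angle = ang[pass],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) return(empty_hbonds())
  out <- out[order(out$donor_chain, out$donor_resno, out$acceptor_chain,
                   out$acceptor_resno, out$acceptor_atom), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hbond_list", "data.frame")
  out
}

empty_hbonds <- function() {
  out <- data.frame(donor_chain = character(), donor_resno = integer(),
                    donor_atom = character(), acceptor_chain = character(),
                    acceptor_resno = integer(), acceptor_atom = character(),
                    distance = numeric(), angle = numeric(),
                    stringsAsFactors = FALSE)
  class(out) <- c("hbond_list", "data.frame")
  out
}

#' Assign alpha-helical residues from the backbone hydrogen-bond pattern
#'
#' A residue is labelled helical when it lies inside the i -> i+4 backbone
#' hydrogen-bond ladder (carbonyl O of residue i accepting from amide N of
#' residue i+4, found with [detect_hbonds()]).  As in DSSP's alpha-helix
#' rule, a single isolated bond is not enough: two consecutive bonds
#' (i, i+4) and (i+1, i+5) mark residues i+1 .. i+5, so a genuine local
#' break in the ladder splits a helix.  Contiguous runs of at least
#' `min_run` residues are reported as segments; chain breaks split
#' segments.
#'
#' @param model A [structure_model()] with backbone N, CA, C, O atoms.
#' @param min_run Minimum helical run length (default 4).
#' @param d_cut,angle_cut Criteria forwarded to [detect_hbonds()].
#' @param frame Frame index.
#' @return List with `labels` (per-residue `"H"`/`"C"`, one entry per
#'   chain+residue in the atom table) and `segments` (data frame `chain`,
#'   `start`, `end`).
#' @export
assign_helices <- function(model, min_run = 4L, d_cut = 3.5,
                           angle_cut = 120, frame = 1L) {
  hb <- detect_hbonds(model, d_cut = d_cut, angle_cut = angle_cut,
                      frame = frame)
  res <- unique(model$atoms[, c("chain", "resno")])
  res <- res[order(res$chain, res$resno), ]
  lab <- setNames(rep("C", nrow(res)), paste(res$chain, res$resno))
  if (nrow(hb)) {
    i4 <- hb[hb$donor_atom == "N" & hb$acceptor_atom == "O" &
               hb$donor_chain == hb$acceptor_chain &
               hb$donor_resno - hb$acceptor_resno == 4L, , drop = FALSE]
    for (ch in unique(i4$acceptor_chain)) {
      istart <- sort(unique(i4$acceptor_resno[i4$acceptor_chain == ch]))
      for (i in istart[(istart + 1L) %in% istart]) {
        marked <- paste(ch, (i + 1L):(i + 5L))
        lab[intersect(marked, names(lab))] <- "H"
      }
    }
  }
  segs <- list()
  for (ch in unique(res$chain)) {
    rr <- res$resno[res$chain == ch]
    hh <- lab[paste(ch, rr)] == "H"
    # split runs at chain breaks (non-consecutive numbering)
    run_id <- cumsum(c(TRUE, diff(rr) != 1L | diff(hh) != 0L))
    for (g in split(seq_along(rr), run_id)) {
      if (hh[g[1L]] && length(g) >= min_run)
        segs[[length(segs) + 1L]] <- data.frame(
          chain = ch, start = rr[g[1L]], end = rr[g[length(g)]],
          stringsAsFactors = FALSE)
    }
  }
  segments <- if (length(segs)) do.call(rbind, segs) else
    data.frame(chain = character(), start = integer(), end = integer())
  list(labels = lab, segments = segments)
}

# least-squares axis of a run of CA atoms, oriented N- to C-terminal
helix_axis <- function(model, segment, frame = 1L) {
  seg <- as.list(segment)
  a <- model$atoms
  idx <- which(a$chain == seg$chain & a$resno >= seg$start &
                 a$resno <= seg$end & a$elety == "CA")
  if (length(idx) < 5L)
    stop("segment ", seg$chain, ":", seg$start, "-", seg$end,
         " has fewer than 5 CA atoms; axis is degenerate", call. = FALSE)
  xyz <- frame_coords(model, frame)[idx, , drop = FALSE]
  centred <- sweep(xyz, 2L, colMeans(xyz))
  ax <- svd(centred, nu = 0, nv = 1)$v[, 1L]
  if (sum(ax * (xyz[nrow(xyz), ] - xyz[1L, ])) < 0) ax <- -ax
  ax
}

#' Angle between two helix axes
#'
#' Each axis is the principal component of the centred CA coordinates of a
#' segment (at least 5 residues), oriented from N- to C-terminus; the
#' returned angle lies in \[0, 180\] degrees.  A reference direction can
#' stand in for the second segment.
#'
#' @param model A [structure_model()].
#' @param segment_1 List or one-row data frame with `chain`, `start`, `end`.
#' @param segment_2 Second segment, or `NULL` when `reference` is given.
#' @param reference Optional reference axis (length-3 vector).
#' @param frame Frame index.
#' @return Angle in degrees.
#' @export
helix_axis_angle <- function(model, segment_1, segment_2 = NULL,
                             reference = NULL, frame = 1L) {
  a1 <- helix_axis(model, segment_1, frame)
  a2 <- if (!is.null(segment_2)) helix_axis(model, segment_2, frame)
  else if (!is.null(reference)) unit(as.numeric(reference))
  else stop("supply 'segment_2' or 'reference'", call. = FALSE)
  acos(min(1, max(-1, sum(a1 * a2)))) * 180 / pi
}

#' Optimal-superposition RMSD per frame (Kabsch)
#'
#' RMSD of every frame against a reference after least-squares rigid
#' superposition, computed with bio3d's Kabsch-based fitting.
#'
#' @param model A [structure_model()] with frames, or a numeric matrix of
#'   frame coordinates (one row per frame, xyz layout).
#' @param reference Frame index into `model` (default 1) or an xyz vector.
#' @param selection Optional atom indices used both for fitting and for
#'   the RMSD (default: CA atoms when atom names are available, else all).
#' @return Numeric vector, RMSD in Angstrom per frame.
#' @export
kabsch_rmsd <- function(model, reference = 1L, selection = NULL) {
  frames <- if (inherits(model, "structure_model")) model$frames else
    as.matrix(model)
  if (is.null(selection) && inherits(model, "structure_model") &&
      any(model$atoms$elety == "CA"))
    selection <- which(model$atoms$elety == "CA")
  if (is.null(selection)) selection <- seq_len(ncol(frames) / 3L)
  if (length(selection) < 3L)
    stop("superposition needs at least 3 atoms", call. = FALSE)
  ref <- if (length(reference) == 1L) frames[reference, ] else
    as.numeric(reference)
  xyz_idx <- bio3d::atom2xyz(selection)
  fitted <- bio3d::fit.xyz(ref, frames, fixed.inds = xyz_idx,
                           mobile.inds = xyz_idx)
  if (!is.matrix(fitted)) fitted <- matrix(fitted, nrow = 1L)
  dev2 <- sweep(fitted[, xyz_idx, drop = FALSE], 2L, ref[xyz_idx])^2
  unname(sqrt(rowSums(dev2) / length(selection)))
}

#' Per-residue root mean square fluctuation
#'
#' \eqn{\sqrt{\langle |x - \langle x\rangle|^2 \rangle}} per selected atom
#' across the post-equilibration frames, reported per residue (the
#' default selection is one CA per residue).  Frames are assumed already
#' superposed; set `superpose = TRUE` to Kabsch-fit them onto the first
#' retained frame first.
#'
#' @param model A [structure_model()] with at least 2 frames after
#'   discarding `equilibration_frames`.
#' @param selection Atom indices (default: CA atoms).
#' @param equilibration_frames Leading frames to discard.
#' @param superpose Rigid-fit frames onto the first retained frame.
#' @return Named numeric vector of RMSF (Angstrom), named `chain:resno`.
#' @export
rmsf <- function(model, selection = NULL, equilibration_frames = 0L,
                 superpose = FALSE) {
  stopifnot(inherits(model, "structure_model"))
  frames <- model$frames
  if (equilibration_frames >= nrow(frames) - 1L)
    stop("need at least 2 frames after equilibration", call. = FALSE)
  if (equilibration_frames > 0L)
    frames <- frames[-seq_len(equilibration_frames), , drop = FALSE]
  if (is.null(selection)) {
    selection <- which(model$atoms$elety == "CA")
    if (!length(selection)) selection <- seq_len(nrow(model$atoms))
  }
  xyz_idx <- bio3d::atom2xyz(selection)
  if (superpose)
    frames <- bio3d::fit.xyz(frames[1L, ], frames,
                             fixed.inds = xyz_idx, mobile.inds = xyz_idx)
  sub <- frames[, xyz_idx, drop = FALSE]
  mu <- colMeans(sub)
  dev2 <- sweep(sub, 2L, mu)^2
  per_axis <- colMeans(dev2)
  per_atom <- sqrt(per_axis[c(TRUE, FALSE, FALSE)] +
                     per_axis[c(FALSE, TRUE, FALSE)] +
                     per_axis[c(FALSE, FALSE, TRUE)])
  setNames(per_atom, paste0(model$atoms$chain[selection], ":",
                            model$atoms$resno[selection]))
}

#' FRET-model distance agreement
#'
#' Core comparison rule: a model distance agrees with a FRET mean distance
#' when the absolute deviation is within `tolerance_frac` of the FRET
#' distance (the conventional +/-10 percent distance uncertainty from the
#' unknown orientation factor and probe size) plus a fixed
#' `linker_allowance` for the randomly folding probe linker (default 7
#' Angstrom).
#'
#' @param rbar FRET mean distances in Angstrom.
#' @param d_model Model distances in Angstrom (same length).
#' @param tolerance_frac Fractional tolerance (default 0.10).
#' @param linker_allowance Additive allowance in Angstrom (default 7).
#' @return Data frame with `deviation`, `fractional_deviation` and the
#'   `within_tolerance` flag.
#' @export
fret_agreement <- function(rbar, d_model, tolerance_frac = 0.10,
                           linker_allowance = 7) {
  dev <- d_model - rbar
  data.frame(deviation = dev,
             fractional_deviation = dev / rbar,
             within_tolerance =
               abs(dev) <= tolerance_frac * rbar + linker_allowance)
}

#' Compare a structure against a FRET distance table
#'
#' For every table row the mapped alpha-carbon distance in the structure is
#' measured and compared with the FRET mean distance under
#' [fret_agreement()]'s rule.  Rows whose sites cannot be resolved are
#' reported with `NA` distances rather than failing.
#'
#' @param table A FRET table (see [read_fret_table()]), already filtered
#'   to one state or carrying a `state` column plus the `state` argument.
#' @param model A [structure_model()].
#' @param map A [site_map()].
#' @param state Optional state filter (`"ca_free"` or `"ca_saturated"`).
#' @param tolerance_frac,linker_allowance See [fret_agreement()].
#' @param copy,frame Copy and frame selectors.
#' @return The table with `d_model`, `deviation`, `fractional_deviation`
#'   and `within_tolerance` columns appended; the fraction of resolvable
#'   rows within tolerance is attached as attribute `fraction_within`.
#' @export
compare_to_fret <- function(table, model, map, state = NULL,
                            tolerance_frac = 0.10, linker_allowance = 7,
                            copy = 1L, frame = 1L) {
  tab <- as.data.frame(table)
  if (!is.null(state)) tab <- tab[tab$state == state, , drop = FALSE]
  d_model <- vapply(seq_len(nrow(tab)), function(k) {
    tryCatch(ca_distance(model,
                         c(tab$subunit_d[k], tab$res_d[k]),
                         c(tab$subunit_a[k], tab$res_a[k]),
                         map, copy, frame),
             error = function(e) NA_real_)
  }, numeric(1))
  agr <- fret_agreement(tab$rbar_A, d_model, tolerance_frac,
                        linker_allowance)
  out <- cbind(tab, d_model = d_model, agr)
  rownames(out) <- NULL
  attr(out, "fraction_within") <-
    mean(agr$within_tolerance[!is.na(d_model)])
  out
}
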