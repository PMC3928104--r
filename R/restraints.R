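#' Read a FRET distance table
#'
#' Tab-separated table with one row per measured donor-acceptor pair and
#' state, columns `subunit_d`, `res_d`, `subunit_a`, `res_a`, `state`
#' (`ca_free` or `ca_saturated`), `rbar_A` and `hw_A`.  Extra columns
#' (reference crystal or model distances) pass through untouched.
#'
#' @param path Path to the TSV file.
#' @return Data frame of class `fret_table`.
#' @seealso [fret_table1()] for the packaged troponin table.
#' @export
read_fret_table <- function(path) {
  if (!file.exists(path))
    stop("FRET table not found: ", path, call. = FALSE)
  tab <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  need <- c("subunit_d", "res_d", "subunit_a", "res_a", "state",
            "rbar_A", "hw_A")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("FRET table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- tab$rbar_A <= 0 | tab$hw_A <= 0 | tab$res_d < 1 | tab$res_a < 1
  if (any(bad))
    stop("FRET table rows with non-positive distances/half-widths or ",
         "residues: ", paste(which(bad), collapse = ", "), call. = FALSE)
  if (!all(tab$state %in% c("ca_free", "ca_saturated")))
    stop("'state' must be 'ca_free' or 'ca_saturated'", call. = FALSE)
  class(tab) <- c("fret_table", "data.frame")
  tab
}

#' The packaged cardiac troponin FRET distance table
#'
#' Loads the package's bundled table of 45 measured intra-/inter-subunit
#' donor-acceptor distance distributions (mean distance and half-width in
#' Angstrom) for the reconstituted cardiac troponin complex in each of the
#' calcium-free and calcium-saturated states, together with the published
#' reference distances of the deposited crystal structure and the
#' restrained simulation models where available.
#'
#' @return A `fret_table` data frame (90 rows: 45 pairs x 2 states).
#' @export
fret_table1 <- function() {
  read_fret_table(system.file("extdata", "fret_distances_troponin.tsv",
                              package = "trfret", mustWork = TRUE))
}

#' Harmonic force constant from a FRET half-width
#'
#' Boltzmann-consistent mapping of the measured distance heterogeneity to
#' a restraint stiffness: a harmonic well whose equilibrium width matches
#' the distribution width at temperature T has
#' \deqn{k = k_B T / \sigma^2, \qquad \sigma = HW / 2.35}
#' with sigma converted to nm, giving k in kJ mol^-1 nm^-2.  Wide
#' (dynamic) distances therefore restrain weakly.
#'
#' @param hw Half-width in Angstrom, > 0 (vectorised).
#' @param temperature Temperature in K.
#' @return Force constant(s) in kJ mol^-1 nm^-2.
#' @examples
#' force_constant_from_hw(10.2, 300)
#' @export
force_constant_from_hw <- function(hw, temperature = 300) {
  hw <- as.numeric(hw)
  if (any(!is.finite(hw)) || any(hw <= 0))
    stop("'hw' must be positive", call. = FALSE)
  if (!is.finite(temperature) || temperature <= 0)
    stop("'temperature' must be positive", call. = FALSE)
  sigma_nm <- hw / HW_SIGMA_FACTOR / 10
  KB_KJ_PER_MOL_K * temperature / sigma_nm^2
}

#' Build flat-bottom distance restraints from a FRET table
#'
#' Turns each table row of the requested state into a flat-bottom
#' alpha-carbon distance restraint.  Under the default `"plus7"` scheme
#' the lower bound is the measured FRET distance and the upper bound is
#' the FRET distance plus 7 Angstrom (the allowance for the randomly
#' folding probe linker); `"sym7"` uses FRET -/+ 7 Angstrom and `"point"`
#' pins both bounds at the FRET distance.  A second upper bound `up2 =
#' up1 + 2` Angstrom marks the onset of the linear penalty regime required
#' by the GROMACS restraint dialect.  The force constant comes from
#' [force_constant_from_hw()].
#'
#' @param table A `fret_table` (see [read_fret_table()]).
#' @param state `"ca_free"` or `"ca_saturated"`.
#' @param site_map Optional [site_map()]: when given, every site must be
#'   resolvable in `structure` and the emitted records carry atom indices.
#' @param structure Optional [structure_model()] used with `site_map`.
#' @param scheme Bound scheme: `"plus7"` (default), `"sym7"` or `"point"`.
#' @param temperature Temperature (K) for the force constants.
#' @return Data frame of class `restraint_set`, one record per row of the
#'   selected state, with columns `ai`, `aj` (atom indices when resolved,
#'   otherwise sequential site ordinals), the site labels, `low`, `up1`,
#'   `up2` (Angstrom), `kfac` (kJ mol^-1 nm^-2) and a provenance `label`.
#' @export
build_restraints <- function(table, state = c("ca_free", "ca_saturated"),
                             site_map = NULL, structure = NULL,
                             scheme = c("plus7", "sym7", "point"),
                             temperature = 300) {
  state <- match.arg(state)
  scheme <- match.arg(scheme)
  tab <- as.data.frame(table)
  tab <- tab[tab$state == state, , drop = FALSE]
  if (!nrow(tab)) stop("no rows for state '", state, "'", call. = FALSE)

  low <- switch(scheme,
                plus7 = tab$rbar_A,
                sym7 = pmax(tab$rbar_A - 7, 0.1),
                point = tab$rbar_A)
  up1 <- switch(scheme,
                plus7 = tab$rbar_A + 7,
                sym7 = tab$rbar_A + 7,
                point = tab$rbar_A)
  up2 <- up1 + 2

  site_d <- paste0(tab$subunit_d, ":", tab$res_d)
  site_a <- paste0(tab$subunit_a, ":", tab$res_a)
  if (!is.null(site_map)) {
    if (is.null(structure))
      stop("'structure' is required to resolve sites through 'site_map'",
           call. = FALSE)
    ai <- vapply(site_d, function(s)
      resolve_site(structure, site_map, s), integer(1))
    aj <- vapply(site_a, function(s)
      resolve_site(structure, site_map, s), integer(1))
  } else {
    sites <- unique(c(site_d, site_a))
    ai <- match(site_d, sites)
    aj <- match(site_a, sites)
  }

  out <- data.frame(
    ai = as.integer(ai), aj = as.integer(aj),
    site_i = site_d, site_j = site_a,
    low = low, up1 = up1, up2 = up2,
    kfac = force_constant_from_hw(tab$hw_A, temperature),
    label = paste0(site_d, "--", site_a, "/", state),
    stringsAsFactors = FALSE)
  stopifnot(all(out$low > 0), all(out$low <= out$up1),
            all(out$up1 <= out$up2))
  rownames(out) <- NULL
  class(out) <- c("restraint_set", "data.frame")
  out
}

#' Write distance restraints in the GROMACS dialect
#'
#' Emits a deterministic `[ distance_restraints ]` block, one line per
#' record in stable index order: `ai aj funct index type low up1 up2 kfac`
#' with distances converted to nm and `funct = 1`, `type = 1`.  Duplicate
#' (ai, aj) pairs are both written, with a warning.
#'
#' @param records A `restraint_set` from [build_restraints()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_restraints <- function(records, path) {
  stopifnot(inherits(records, "data.frame"))
  if (nrow(records)) {
    dup <- duplicated(records[, c("ai", "aj")])
    if (any(dup))
      warning(sum(dup), " duplicate (ai, aj) pair(s); all written",
              call. = FALSE)
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("[ distance_restraints ]",
               ";  ai   aj funct index type       low       up1       up2         kfac  ; label"),
             con)
  for (k in seq_len(nrow(records))) {
    r <- records[k, ]
    writeLines(sprintf(
      "%5d %4d %5d %5d %4d %9.4f %9.4f %9.4f %12.6f  ; %s",
      r$ai, r$aj, 1L, k - 1L, 1L,
      r$low / 10, r$up1 / 10, r$up2 / 10, r$kfac, r$label), con)
  }
  invisible(path)
}

#' Read back a GROMACS-dialect distance-restraint file
#'
#' Inverse of [write_distance_restraints()]; nm fields are converted back
#' to Angstrom and the site labels are recovered from the trailing
#' comment.
#'
#' @param path Path to the restraint file.
#' @return A `restraint_set` data frame.
#' @export
read_distance_restraints <- function(path) {
  if (!file.exists(path))
    stop("restraint file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(\\[|;|$)", lines)]
  if (!length(lines)) {
    out <- data.frame(ai = integer(), aj = integer(), site_i = character(),
                      site_j = character(), low = numeric(),
                      up1 = numeric(), up2 = numeric(), kfac = numeric(),
                      label = character(), stringsAsFactors = FALSE)
    class(out) <- c("restraint_set", "data.frame")
    return(out)
  }
  parts <- strsplit(lines, ";", fixed = TRUE)
  label <- trimws(vapply(parts, function(p)
    if (length(p) > 1L) p[2L] else NA_character_, character(1)))
  num <- lapply(parts, function(p) scan(text = p[1L], quiet = TRUE))
  m <- do.call(rbind, num)
  sites <- strsplit(sub("/[^/]*$", "", label), "--", fixed = TRUE)
  out <- data.frame(
    ai = as.integer(m[, 1L]), aj = as.integer(m[, 2L]),
    site_i = vapply(sites, `[`, character(1), 1L),
    site_j = vapply(sites, `[`, character(1), 2L),
    low = m[, 6L] * 10, up1 = m[, 7L] * 10, up2 = m[, 8L] * 10,
    kfac = m[, 9L], label = label, stringsAsFactors = FALSE)
  class(out) <- c("restraint_set", "data.frame")
  out
}

#' Score restraint satisfaction on a structure
#'
#' Measures every restrained alpha-carbon distance in the structure and
#' reports the flat-bottom violation `max(0, low - d, d - up1)` per record
#' plus the overall fraction satisfied.
#'
#' @param structure A [structure_model()].
#' @param records A `restraint_set`.
#' @param site_map A [site_map()] to resolve the record sites; when `NULL`
#'   the records' `ai`/`aj` columns are taken as atom row indices into the
#'   structure.
#' @param copy,frame Copy and frame selectors.
#' @return The records with `d_actual` and `violation` columns appended;
#'   the fraction of satisfied records is attached as attribute
#'   `fraction_satisfied`.
#' @export
score_restraints <- function(structure, records, site_map = NULL,
                             copy = 1L, frame = 1L) {
  stopifnot(inherits(structure, "structure_model"))
  xyz <- frame_coords(structure, frame)
  d <- vapply(seq_len(nrow(records)), function(k) {
    if (!is.null(site_map)) {
      i <- resolve_site(structure, site_map, records$site_i[k], copy)
      j <- resolve_site(structure, site_map, records$site_j[k], copy)
    } else {
      i <- records$ai[k]
      j <- records$aj[k]
      if (i > nrow(xyz) || j > nrow(xyz))
        stop("restraint ", k, " references atom beyond the structure",
             call. = FALSE)
    }
    sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  }, numeric(1))
  out <- cbind(as.data.frame(records), d_actual = d,
               violation = pmax(0, records$low - d, d - records$up1))
  rownames(out) <- NULL
  attr(out, "fraction_satisfied") <- mean(out$violation == 0)
  out
}
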