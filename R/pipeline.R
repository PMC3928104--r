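# FNV-1a 32-bit hash of a string; used to stamp outputs with a config
# fingerprint (not cryptographic).
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# the destination directory is not part of the run's identity
config_hash <- function(config) {
  config$output_dir <- NULL
  fnv1a32(paste(deparse(config[order(names(config))]), collapse = "\n"))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[stage: ", name, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the decay -> distances -> restraints -> validation pipeline
#'
#' Orchestrates the package end to end from a single YAML (or list)
#' configuration: fits donor and donor-acceptor decay pairs into a FRET
#' distance table (or takes a ready table), converts the table into
#' flat-bottom distance restraints per state, writes the GROMACS-dialect
#' restraint files plus TSV reports, and, when a structure and site map
#' are configured, scores restraint satisfaction, FRET agreement and
#' pocket openness on the structure.  All outputs are deterministic for a
#' fixed configuration and seed and carry the configuration hash.
#'
#' Recognised configuration fields: `output_dir` (required), one of
#' `fret_table` or `decays` (a list of `donor`/`da`/`r0` file triples with
#' `donor_site`, `acceptor_site`, optional `n_components`, `state`);
#' `states` (default both), `scheme`, `temperature`, `seed`; optional
#' `structure`, `site_map`, `pocket_threshold`, `tolerance_frac`,
#' `linker_allowance`, `pocket_subunit`.
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @return Invisibly, the run report (also written as `report.json`):
#'   config hash, per-state restraint counts and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  out_dir <- config$output_dir %||% stop("'output_dir' is required",
                                         call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  seed <- config$seed %||% 1L

  # referenced inputs must exist before any work starts
  paths <- as.character(c(config$fret_table, config$structure,
                          config$site_map,
                          unlist(lapply(config$decays, function(d)
                            c(d$donor, d$da)))))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input path(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)

  report <- list(config_hash = hash, seed = seed, outputs = list())

  tab <- if (!is.null(config$fret_table)) {
    stage("read_table", read_fret_table(config$fret_table))
  } else if (!is.null(config$decays)) {
    stage("decay_fits", {
      rows <- lapply(config$decays, function(d) {
        don_fit <- fit_donor(read_decay(d$donor),
                             n_components = d$n_components %||% 2L)
        ff <- fit_fret(read_decay(d$da), don_fit, R0 = d$r0)
        sd_ <- parse_site(d$donor_site)
        sa_ <- parse_site(d$acceptor_site)
        data.frame(subunit_d = sd_$subunit, res_d = sd_$residue,
                   subunit_a = sa_$subunit, res_a = sa_$residue,
                   state = d$state %||% config$states[[1L]] %||% "ca_saturated",
                   rbar_A = ff$distribution$rbar,
                   hw_A = ff$distribution$hw,
                   chi2_red = ff$chi2_red,
                   se_rbar = ff$uncertainty[["rbar"]],
                   se_hw = ff$uncertainty[["hw"]],
                   stringsAsFactors = FALSE)
      })
      tab <- do.call(rbind, rows)
      class(tab) <- c("fret_table", "data.frame")
      tab
    })
  } else stop("config needs 'fret_table' or 'decays'", call. = FALSE)

  fits_path <- file.path(out_dir, "fret_distances.tsv")
  write_report_tsv(as.data.frame(tab), fits_path, hash)
  report$outputs$fret_distances <- fits_path

  struct <- NULL
  smap <- NULL
  if (!is.null(config$structure)) {
    struct <- stage("read_structure", read_structure(config$structure))
    if (is.null(config$site_map))
      stop("'site_map' is required with 'structure'", call. = FALSE)
    smap <- stage("read_site_map", read_site_map(config$site_map))
  }

  states <- config$states %||% intersect(c("ca_free", "ca_saturated"),
                                         unique(tab$state))
  report$restraints <- list()
  for (st in states) {
    recs <- stage(paste0("restraints_", st),
                  build_restraints(tab, state = st,
                                   scheme = config$scheme %||% "plus7",
                                   temperature = config$temperature %||% 300))
    itp <- file.path(out_dir, paste0("restraints_", st, ".itp"))
    write_distance_restraints(recs, itp)
    tsv <- file.path(out_dir, paste0("restraints_", st, ".tsv"))
    write_report_tsv(as.data.frame(recs), tsv, hash)
    report$restraints[[st]] <- list(n = nrow(recs), itp = itp, tsv = tsv)

    if (!is.null(struct)) {
      val <- stage(paste0("validate_", st), {
        cmp <- compare_to_fret(
          tab, struct, smap, state = st,
          tolerance_frac = config$tolerance_frac %||% 0.10,
          linker_allowance = config$linker_allowance %||% 7)
        sc <- score_restraints(struct, recs, site_map = smap)
        pk <- tryCatch(
          pocket_openness(struct, smap,
                          threshold = config$pocket_threshold %||% 24,
                          subunit = config$pocket_subunit %||% "cTnC"),
          error = function(e) NULL)
        list(cmp = cmp, sc = sc, pk = pk)
      })
      vpath <- file.path(out_dir, paste0("validation_", st, ".tsv"))
      write_report_tsv(val$cmp, vpath, hash)
      report$restraints[[st]]$validation <- vpath
      report$restraints[[st]]$fraction_within <-
        attr(val$cmp, "fraction_within")
      report$restraints[[st]]$fraction_satisfied <-
        attr(val$sc, "fraction_satisfied")
      if (!is.null(val$pk))
        report$restraints[[st]]$pocket <-
          list(d_13_51 = val$pk$d_13_51, state = val$pk$state)
    }
  }

  rpath <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, rpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  report$outputs$report <- rpath
  invisible(report)
}

# TSV with a config-hash header comment; fixed formatting so reruns are
# byte-identical.
write_report_tsv <- function(df, path, hash) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 6,
                                                 format = "g"))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
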