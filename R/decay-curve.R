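#' TCSPC decay curve
#'
#' A binned photon-count time trace as produced by a time-correlated single
#' photon counting (TCSPC) instrument: a uniformly spaced time axis in
#' nanoseconds and non-negative counts per channel (1024 channels is
#' typical).  An instrument response function sampled on the same axis may be
#' attached; it is carried along but only used when a fit explicitly
#' convolves with it.
#'
#' @param time Numeric vector of channel times in ns, strictly increasing
#'   with constant spacing.
#' @param counts Numeric vector of non-negative counts, one per channel.
#' @param irf Optional numeric vector of instrument-response counts on the
#'   same time axis.
#' @return An object of class `decay_curve`: a list with elements `time`,
#'   `counts`, `irf` (possibly `NULL`), `n_channels` and `channel_width`.
#' @examples
#' dc <- decay_curve(time = seq(0, 50, by = 0.05), counts = rep(1, 1001))
#' dc$channel_width
#' @export
decay_curve <- function(time, counts, irf = NULL) {
  time <- as.numeric(time)
  counts <- as.numeric(counts)
  if (length(time) < 2L)
    stop("a decay curve needs at least two channels", call. = FALSE)
  if (length(time) != length(counts))
    stop("'time' and 'counts' must have the same length", call. = FALSE)
  if (anyNA(time) || anyNA(counts) || any(!is.finite(time)) ||
      any(!is.finite(counts)))
    stop("'time' and 'counts' must be finite", call. = FALSE)
  dt <- diff(time)
  if (any(dt <= 0))
    stop("'time' must be strictly increasing", call. = FALSE)
  if (max(dt) - min(dt) > 1e-6 * mean(dt))
    stop("'time' must be uniformly spaced", call. = FALSE)
  if (any(counts < 0))
    stop("'counts' must be non-negative", call. = FALSE)
  if (!is.null(irf)) {
    irf <- as.numeric(irf)
    if (length(irf) != length(time))
      stop("'irf' must be sampled on the same time axis", call. = FALSE)
    if (any(!is.finite(irf)) || any(irf < 0))
      stop("'irf' must be finite and non-negative", call. = FALSE)
  }
  structure(
    list(time = time, counts = counts, irf = irf,
         n_channels = length(time), channel_width = mean(dt)),
    class = "decay_curve")
}

#' Read a decay curve from a text file
#'
#' Accepts the plain two-column time/counts layout (whitespace- or
#' comma-separated, `#` comments and an optional header line allowed); a
#' third column, when present, is taken as the instrument response function.
#'
#' @param path Path to the text file.
#' @return A [decay_curve()].
#' @export
read_decay <- function(path) {
  if (!file.exists(path))
    stop("decay file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 50L)
  first <- first[!grepl("^\\s*(#|$)", first)]
  sep <- if (any(grepl(",", first))) "," else ""
  header <- grepl("[A-Za-z]", first[1L])
  d <- read.table(path, sep = sep, header = header, comment.char = "#")
  if (ncol(d) < 2L)
    stop("decay file must have at least two columns (time, counts)",
         call. = FALSE)
  decay_curve(d[[1L]], d[[2L]], irf = if (ncol(d) >= 3L) d[[3L]])
}

#' Write a decay curve as two- (or three-) column text
#'
#' @param curve A [decay_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_decay <- function(curve, path) {
  stopifnot(inherits(curve, "decay_curve"))
  d <- data.frame(time_ns = curve$time, counts = curve$counts)
  if (!is.null(curve$irf)) d$irf <- curve$irf
  write.table(format(d, trim = TRUE, digits = 12), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.decay_curve <- function(x, ...) {
  cat(sprintf(
    "TCSPC decay: %d channels x %.4g ns, %.4g total counts%s\n",
    x$n_channels, x$channel_width, sum(x$counts),
    if (is.null(x$irf)) "" else ", IRF attached"))
  invisible(x)
}
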