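#' @export
print.donor_fit <- function(x, ...) {
  cat("Donor-only decay fit\n")
  print(x$model)
  cat(sprintf("chi2_red = %.4g over %d channels%s\n", x$chi2_red,
              length(x$window),
              if (x$overparameterized) " (over-parameterized)" else ""))
  invisible(x)
}

#' @export
summary.donor_fit <- function(object, ...) {
  cat("Donor-only decay fit\n")
  tab <- data.frame(amplitude = object$model$amplitudes,
                    lifetime_ns = object$model$lifetimes)
  print(tab, row.names = FALSE)
  cat(sprintf("baseline: %.4g counts/channel\n", object$model$baseline))
  cat(sprintf("fit window: channels %d-%d (%d points)\n",
              min(object$window), max(object$window), length(object$window)))
  cat(sprintf("chi2_red: %.4g\n", object$chi2_red))
  invisible(object)
}

#' @export
coef.donor_fit <- function(object, ...) {
  k <- length(object$model$lifetimes)
  setNames(c(object$model$amplitudes, object$model$lifetimes,
             object$model$baseline),
           c(paste0("alpha", seq_len(k)), paste0("tau", seq_len(k)),
             "baseline"))
}

#' @export
residuals.donor_fit <- function(object, ...) object$residuals

#' @export
predict.donor_fit <- function(object, time = NULL, ...) {
  if (is.null(time))
    return(stats::setNames(object$fitted, NULL))
  donor_intensity(time, object$model)
}

#' @export
plot.donor_fit <- function(x, ...) plot_decay_fit(x, main = "Donor fit", ...)

#' @export
print.fret_fit <- function(x, ...) {
  cat("FRET distance-distribution fit\n")
  print(x$distribution)
  cat(sprintf("chi2_red = %.4g over %d channels\n",
              x$chi2_red, length(x$window)))
  invisible(x)
}

#' @export
summary.fret_fit <- function(object, ...) {
  d <- object$distribution
  cat("FRET distance-distribution fit (donor frozen)\n")
  cat(sprintf("  rbar = %.2f +/- %.2f A\n", d$rbar, object$uncertainty[["rbar"]]))
  cat(sprintf("  HW   = %.2f +/- %.2f A (sigma = %.2f A)\n",
              d$hw, object$uncertainty[["hw"]], d$sigma))
  cat(sprintf("  R0   = %.2f A  => efficiency at rbar: %.3f\n",
              object$R0, transfer_efficiency(d$rbar, object$R0)))
  cat(sprintf("  scale = %.4g, baseline = %.4g\n", object$scale,
              object$baseline))
  cat(sprintf("  chi2_red = %.4g; converged: %s%s\n", object$chi2_red,
              object$converged,
              if (object$boundary) " (bound hit)" else ""))
  invisible(object)
}

#' @export
coef.fret_fit <- function(object, ...) {
  c(rbar = object$distribution$rbar, hw = object$distribution$hw,
    scale = object$scale, baseline = object$baseline)
}

#' @export
residuals.fret_fit <- function(object, ...) object$residuals

#' Predict the fitted donor-acceptor decay, or the recovered P(r)
#'
#' @param object A `fret_fit`.
#' @param time Times (ns) at which to evaluate the fitted model; defaults
#'   to the fitted window.
#' @param what `"decay"` (fitted counts) or `"pr"` (the recovered distance
#'   distribution evaluated on `r`).
#' @param r Distance grid in Angstrom for `what = "pr"`.
#' @param ... Unused.
#' @export
predict.fret_fit <- function(object, time = NULL, what = c("decay", "pr"),
                             r = NULL, ...) {
  what <- match.arg(what)
  if (what == "pr") {
    d <- object$distribution
    if (is.null(r)) r <- seq(max(0.01, d$rbar - 5 * d$sigma),
                             d$rbar + 5 * d$sigma, length.out = 201L)
    return(data.frame(r = r, density = dnorm(r, d$rbar, d$sigma)))
  }
  if (is.null(time)) return(stats::setNames(object$fitted, NULL))
  object$scale *
    ensemble_decay(time, object$donor, object$R0, object$distribution) +
    object$baseline
}

#' Simulate Poisson replicates of a fitted donor-acceptor decay
#'
#' Draws `nsim` Poisson realisations with the fitted expected counts on the
#' fitted window, the parametric-bootstrap primitive for this model.
#'
#' @param object A `fret_fit`.
#' @param nsim Number of replicates.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A matrix, one column per replicate.
#' @export
simulate.fret_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  mu <- pmax(object$fitted, 0)
  matrix(rpois(length(mu) * nsim, rep(mu, nsim)), ncol = nsim)
}

#' @export
plot.fret_fit <- function(x, ...) plot_decay_fit(x, main = "FRET fit", ...)

# shared decay + weighted-residual panel
plot_decay_fit <- function(x, main = "", ...) {
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  t <- x$curve$time[x$window]
  y <- x$curve$counts[x$window]
  plot(t, pmax(y, 0.5), log = "y", pch = ".", xlab = "time (ns)",
       ylab = "counts", main = main, ...)
  lines(t, pmax(x$fitted, 0.5), col = 2, lwd = 2)
  plot(t, x$residuals, type = "l", xlab = "time (ns)",
       ylab = "weighted residual")
  abline(h = 0, lty = 2)
  invisible(x)
}
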