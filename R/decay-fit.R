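#' Reduced chi-square goodness of fit
#'
#' \deqn{\chi^2_{red} = \frac{1}{N - p}\sum_k
#'   \frac{(y_k - m_k)^2}{\max(m_k, 1)}}
#' over the fitted channels, the usual Poisson-counting goodness-of-fit
#' statistic; values near 1 indicate a statistically adequate model.
#'
#' @param observed Observed counts.
#' @param model Model counts, same length.
#' @param n_params Number of fitted parameters p (< N).
#' @return The reduced chi-square.
#' @examples
#' reduced_chi_square(c(100, 50, 25), c(100, 50, 25), 1)  # 0
#' @export
reduced_chi_square <- function(observed, model, n_params) {
  observed <- as.numeric(observed)
  model <- as.numeric(model)
  if (length(observed) != length(model))
    stop("'observed' and 'model' must have the same length", call. = FALSE)
  n <- length(observed)
  if (n <= n_params)
    stop("degrees of freedom must be positive (N > n_params)", call. = FALSE)
  sum((observed - model)^2 / pmax(model, 1)) / (n - n_params)
}

# Fit window: channels strictly after the counts maximum (skipping any
# rise/IRF region the pure-decay model does not describe) through the last
# channel with >= 10 counts.  Falls back to the full tail when the curve
# never reaches 10 counts.
fit_window <- function(curve, min_tail_counts = 10) {
  peak <- which.max(curve$counts)
  start <- min(peak + 1L, curve$n_channels - 1L)
  last <- which(curve$counts >= min_tail_counts)
  end <- if (length(last)) max(last) else curve$n_channels
  if (end <= start + 8L) end <- curve$n_channels
  start:end
}

# Discrete convolution of a model decay with a (renormalised) IRF sampled
# on the same channel grid.
convolve_irf <- function(model, irf) {
  irf <- irf / sum(irf)
  n <- length(model)
  full <- stats::convolve(irf, rev(model), type = "open")
  full[seq_len(n)]
}

fit_failure <- function(msg, last = NULL) {
  stop(errorCondition(msg, last = last,
                      class = c("trfret_fit_failure", "error")))
}

#' Fit a multi-exponential model to a donor-only decay
#'
#' Weighted least-squares (Levenberg-Marquardt) fit of a 1-3 component
#' exponential model with additive baseline to a TCSPC donor decay, using
#' Poisson (Neyman) weights 1/max(counts, 1).  Only channels after the
#' counts maximum up to the last channel holding at least 10 counts enter
#' the fit.  Lifetimes are returned sorted ascending.
#'
#' @param curve A [decay_curve()] holding at least 1000 photons.
#' @param n_components Number of exponential components (1, 2 or 3).
#' @param irf Optional instrument response (a [decay_curve()] or numeric
#'   vector on the same channel grid); when supplied the model is convolved
#'   with it before comparison.
#' @param fit_baseline Fit an additive constant baseline (default) or pin
#'   it to zero.
#' @return An object of class `donor_fit` with elements `model` (a
#'   [donor_model()]), `chi2_red`, weighted `residuals`, `fitted`, `window`,
#'   `converged` and an `overparameterized` flag (set, with a warning,
#'   when a component's amplitude or intensity contribution collapses or
#'   two lifetimes coincide — the signature of one component too many).
#' @seealso [fit_fret()] for the donor-acceptor stage.
#' @export
fit_donor <- function(curve, n_components = 2L, irf = NULL,
                      fit_baseline = TRUE) {
  stopifnot(inherits(curve, "decay_curve"))
  n_components <- as.integer(n_components)
  if (!n_components %in% 1:3)
    stop("'n_components' must be 1, 2 or 3", call. = FALSE)
  if (sum(curve$counts) < 1000)
    stop("decay holds fewer than 1000 photons; not fittable", call. = FALSE)
  if (inherits(irf, "decay_curve")) irf <- irf$counts
  if (is.null(irf)) irf <- curve$irf

  win <- fit_window(curve)
  t <- curve$time[win] - curve$time[1L]
  y <- curve$counts[win]
  sw <- sqrt(1 / pmax(y, 1))

  k <- n_components
  eval_model <- function(par) {
    tau <- exp(par[seq_len(k)])
    amp <- par[k + seq_len(k)]
    base <- if (fit_baseline) par[2L * k + 1L] else 0
    m <- drop(exp(-outer(t, 1 / tau)) %*% amp)
    if (!is.null(irf)) m <- convolve_irf(m, irf[win])
    m + base
  }

  tbar <- sum(t * y) / sum(y)
  tau0 <- tbar * c(1, 0.4, 2.5)[seq_len(k)]
  par0 <- c(log(tau0), rep(max(y) / k, k),
            if (fit_baseline) max(min(y), 1e-2))
  lower <- c(rep(-Inf, k), rep(0, k), if (fit_baseline) 0)

  res <- minpack.lm::nls.lm(
    par = par0, lower = lower,
    fn = function(par) (eval_model(par) - y) * sw,
    control = minpack.lm::nls.lm.control(maxiter = 400))
  if (!res$info %in% 1:4)
    fit_failure(paste0("donor fit did not converge: ", res$message),
                last = res$par)

  tau <- exp(res$par[seq_len(k)])
  amp <- res$par[k + seq_len(k)]
  base <- if (fit_baseline) res$par[2L * k + 1L] else 0
  ord <- order(tau)
  tau <- tau[ord]
  amp <- amp[ord]
  # degeneracy: a component with negligible amplitude or intensity
  # contribution, or two lifetimes collapsing onto each other
  ifrac <- amp * tau / sum(amp * tau)
  overpar <- any(amp < 1e-4 * sum(amp)) || any(ifrac < 0.01) ||
    (k > 1L && any(diff(tau) < 0.02 * tau[-1L]))
  if (overpar)
    warning("over-parameterized donor model: a component amplitude is ",
            "negligible or two lifetimes coincide", call. = FALSE)
  # guard against an exactly-zero amplitude breaking the model invariant
  amp_model <- pmax(amp, .Machine$double.xmin)
  model <- donor_model(amp_model, tau, baseline = max(base, 0))
  fitted <- eval_model(res$par)
  n_par <- length(par0)
  structure(list(
    model = model, chi2_red = reduced_chi_square(y, fitted, n_par),
    residuals = (y - fitted) * sw, fitted = fitted, window = win,
    curve = curve, converged = TRUE, overparameterized = overpar,
    n_params = n_par),
    class = "donor_fit")
}

# Decay kernel on a fixed distance grid: K[t, r] = sum_i alpha_i
# exp(-(t/tau_i) (1 + (R0/r)^6)).  The Gaussian weights move during the
# fit but the kernel does not, so each model evaluation is one
# matrix-vector product.
fret_kernel <- function(t, donor, R0, r_min = 1, r_max = 180, n_r = 1201L) {
  r <- seq(r_min, r_max, length.out = n_r)
  boost <- 1 + (R0 / r)^6
  K <- matrix(0, length(t), n_r)
  for (i in seq_along(donor$amplitudes))
    K <- K + donor$amplitudes[i] *
      exp(-outer(t / donor$lifetimes[i], boost))
  list(r = r, K = K, simp = simpson_weights(n_r, r[2L] - r[1L]),
       dr = r[2L] - r[1L])
}

#' Recover a Gaussian distance distribution from a donor-acceptor decay
#'
#' Levenberg-Marquardt fit of the ensemble decay model (the Gaussian
#' P(r) integral over the distance-dependent donor decay) to a
#' donor-acceptor TCSPC curve, with Poisson weights 1/max(counts, 1).  The
#' donor photophysics are frozen at the values fitted from the donor-only
#' decay; only the distribution mean `rbar`, half-width `hw`, an intensity
#' scale and (optionally) a baseline are free.
#'
#' The mean distance is initialised from a mean-lifetime efficiency
#' estimate; if the fitted surface looks multimodal (poor chi-square or a
#' bound hit from the central start) the fit is restarted from
#' 0.8x and 1.2x that initial distance and the best solution kept.
#'
#' @param da_curve Donor-acceptor [decay_curve()].
#' @param donor A [donor_model()] or the result of [fit_donor()].
#' @param R0 Forster critical distance in Angstrom.
#' @param init Optional `c(rbar, hw)` starting values in Angstrom.
#' @param fit_baseline Fit an additive baseline (default `TRUE`).
#' @param multistart Allow restarts around the initial mean distance.
#' @param irf Optional instrument response for convolution.
#' @return An object of class `fret_fit` with the fitted
#'   [distance_distribution()] under `$distribution`, `chi2_red`, weighted
#'   `residuals`, standard errors under `$uncertainty`, `converged` and
#'   `boundary` flags, and the frozen donor/R0 for prediction.
#' @section Errors: a decay indistinguishable from the donor-only model
#'   (estimated transfer efficiency below 2\%) raises a condition of class
#'   `trfret_no_transfer`: the distance is not determinable.
#' @export
fit_fret <- function(da_curve, donor, R0, init = NULL, fit_baseline = TRUE,
                     multistart = TRUE, irf = NULL) {
  stopifnot(inherits(da_curve, "decay_curve"))
  if (inherits(donor, "donor_fit")) donor <- donor$model
  stopifnot(inherits(donor, "donor_model"))
  if (!is.finite(R0) || R0 <= 0) stop("'R0' must be positive", call. = FALSE)
  if (inherits(irf, "decay_curve")) irf <- irf$counts
  if (is.null(irf)) irf <- da_curve$irf

  win <- fit_window(da_curve)
  t <- da_curve$time[win] - da_curve$time[1L]
  y <- da_curve$counts[win]
  sw <- sqrt(1 / pmax(y, 1))

  # mean-lifetime efficiency estimate for initialisation and the
  # no-transfer guard; the donor mean arrival time is computed on the
  # same truncated window so the ratio is free of truncation bias
  base_guess <- stats::quantile(y, 0.02, names = FALSE)
  tbar_da <- sum(t * y) / sum(y)
  d0 <- donor_intensity(t, donor_model(donor$amplitudes, donor$lifetimes))
  tbar_d <- sum(t * d0) / sum(d0)
  e_est <- 1 - tbar_da / tbar_d
  if (is.null(init) && e_est < 0.02)
    stop(errorCondition(
      sprintf(paste0("donor-acceptor decay is indistinguishable from the ",
                     "donor-only decay (estimated efficiency %.2g%%); ",
                     "distance not determinable"), 100 * max(e_est, 0)),
      class = c("trfret_no_transfer", "error")))

  r_min <- 1
  r_max <- 180
  kern <- fret_kernel(t, donor, R0, r_min, r_max)

  eval_model <- function(par) {
    rbar <- par[1L]
    hw <- par[2L]
    scale <- par[3L]
    base <- if (fit_baseline) par[4L] else 0
    sigma <- hw / HW_SIGMA_FACTOR
    if (sigma >= 3 * kern$dr) {
      w <- dnorm(kern$r, rbar, sigma) * kern$simp
      m <- drop(kern$K %*% (w / sum(w)))
    } else {
      # distribution narrower than the kernel grid: integrate on a local
      # grid instead
      m <- ensemble_decay(t, donor_model(donor$amplitudes, donor$lifetimes),
                          R0, distance_distribution(rbar, hw))
    }
    if (!is.null(irf)) m <- convolve_irf(m, irf[win])
    scale * m + base
  }

  if (is.null(init)) {
    e0 <- min(max(e_est, 0.005), 0.995)
    r0 <- min(max(R0 * (1 / e0 - 1)^(1 / 6), 8), 150)
    hw0 <- 10
  } else {
    r0 <- init[1L]
    hw0 <- init[2L]
  }
  lower <- c(r_min + 1, 0.2, 0, if (fit_baseline) 0)
  upper <- c(r_max - 1, 80, Inf, if (fit_baseline) Inf)

  run_one <- function(r_start) {
    m1 <- eval_model(c(r_start, hw0, 1, 0))
    sc0 <- max(sum(pmax(y - base_guess, 0)) / sum(m1), 1e-6)
    par0 <- c(r_start, hw0, sc0, if (fit_baseline) max(base_guess, 1e-2))
    minpack.lm::nls.lm(
      par = par0, lower = lower, upper = upper,
      fn = function(par) (eval_model(par) - y) * sw,
      control = minpack.lm::nls.lm.control(maxiter = 400))
  }

  n_par <- 3L + as.integer(fit_baseline)
  res <- run_one(r0)
  needs_restart <- function(res) {
    chi2 <- res$deviance / (length(y) - n_par)
    !res$info %in% 1:4 || chi2 > 1.5 ||
      res$par[1L] < lower[1L] + 0.5 || res$par[1L] > upper[1L] - 0.5
  }
  if (multistart && needs_restart(res)) {
    for (f in c(0.8, 1.2)) {
      alt <- run_one(min(max(r0 * f, lower[1L] + 1), upper[1L] - 1))
      if (alt$deviance < res$deviance) res <- alt
    }
  }
  if (!res$info %in% 1:4)
    fit_failure(paste0("distance-distribution fit did not converge: ",
                       res$message), last = res$par)

  boundary <- res$par[1L] < lower[1L] + 0.5 || res$par[1L] > upper[1L] - 0.5
  if (boundary)
    warning("fitted mean distance sits at the distance-grid bound; ",
            "the distance is poorly determined", call. = FALSE)

  fitted <- eval_model(res$par)
  chi2 <- reduced_chi_square(y, fitted, n_par)
  se <- rep(NA_real_, n_par)
  cov <- try(solve(res$hessian) * res$deviance / (length(y) - n_par),
             silent = TRUE)
  if (!inherits(cov, "try-error") && all(diag(cov) >= 0))
    se <- sqrt(diag(cov))

  structure(list(
    distribution = distance_distribution(res$par[1L], res$par[2L]),
    chi2_red = chi2,
    residuals = (y - fitted) * sw,
    fitted = fitted,
    uncertainty = c(rbar = se[1L], hw = se[2L]),
    converged = TRUE, boundary = boundary,
    scale = res$par[3L],
    baseline = if (fit_baseline) res$par[4L] else 0,
    window = win, curve = da_curve, donor = donor, R0 = R0,
    n_params = n_par, efficiency_estimate = e_est),
    class = "fret_fit")
}
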