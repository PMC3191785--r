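#' Time-rescaled inter-spike intervals
#'
#' By the time-rescaling theorem, if the fitted conditional intensity is
#' correct then the integrated intensity between consecutive spikes is an
#' i.i.d. unit-exponential sequence; `u_j = 1 - exp(-tau_j)` is then i.i.d.
#' Uniform(0, 1).  Intervals are computed within trials and pooled across
#' them -- trials are independent, so partial intervals at trial edges are
#' discarded rather than spliced.
#'
#' Two constructions are offered.  `"exact"` (the default) is the
#' discrete-time rescaling: each non-spiking bin between two spikes
#' contributes `q_t = -log(1 - p_t)` with `p_t = lambda_t * Delta`, and the
#' spiking bin contributes a randomized residual
#' `-log(1 - u * p_s)`, `u ~ U(0, 1)`, which makes `tau` *exactly*
#' unit-exponential under the discrete Bernoulli model at any bin width
#' (draws come from R's RNG, so results are reproducible under
#' `set.seed()`).  `"none"` is the naive Riemann sum
#' `tau_j = sum lambda_t * Delta` up to and including the next spike bin;
#' it is the continuous-time formula, convenient for closed-form checks,
#' but at coarse bins its KS test is anticonservative because the
#' per-interval mass is quantized.
#'
#' @param fit a [fit_penalized()] result.
#' @param dm the design matrix the fit refers to (supplies the bins and the
#'   response used to locate spikes).
#' @param y response vector; defaults to the design's.
#' @param discrete_correction `"exact"` or `"none"`, see Details.
#' @return List with `tau` (rescaled intervals), `u` (uniform transforms)
#'   and `n_intervals`.  Fewer than two spikes anywhere gives empty vectors
#'   with a warning.
#' @export
time_rescale <- function(fit, dm, y = dm$y,
                         discrete_correction = c("exact", "none")) {
  discrete_correction <- match.arg(discrete_correction)
  mu <- exp(drop(dm$X %*% fit$alpha_hat) + log(dm$delta_s))
  tau <- numeric(0)
  for (j in unique(dm$trial)) {
    rows <- which(dm$trial == j)
    rows <- rows[order(dm$bin[rows])]
    p <- mu[rows]
    sp <- which(y[rows] == 1)
    if (length(sp) < 2) next
    if (discrete_correction == "none") {
      cum <- cumsum(p)
      tau <- c(tau, diff(cum[sp]))
    } else {
      p_clip <- pmin(p, 1 - 1e-12)
      q <- -log1p(-p_clip)
      cumq <- cumsum(q)
      # mass strictly between consecutive spike bins
      between <- cumq[sp[-1] - 1L] - cumq[sp[-length(sp)]]
      resid <- -log1p(-stats::runif(length(between)) * p_clip[sp[-1]])
      tau <- c(tau, between + resid)
    }
  }
  if (!length(tau)) {
    warning("fewer than 2 spikes in every trial; no rescaled intervals")
    return(list(tau = numeric(0), u = numeric(0), n_intervals = 0L))
  }
  list(tau = tau, u = 1 - exp(-tau), n_intervals = length(tau))
}

# Asymptotic simultaneous KS band constants.
.ks_const <- c("0.9" = 1.22, "0.95" = 1.36)

#' Kolmogorov-Smirnov uniformity band test
#'
#' Compares a sample of rescaled-interval transforms against Uniform(0, 1):
#' the KS statistic is the maximum distance between the empirical and the
#' uniform CDF, and the sample is "inside the band" when the statistic is
#' below `c(level) / sqrt(n)` with the asymptotic constants `c(0.95) = 1.36`
#' and `c(0.90) = 1.22`.  Note the 90% band is the *stricter* criterion:
#' inside-at-90% implies inside-at-95%.
#'
#' @param u numeric values in `[0, 1]`.
#' @param level 0.90 or 0.95.
#' @return List with `statistic`, `critical` and logical `inside_band`.
#' @export
ks_band_test <- function(u, level = 0.95) {
  if (!length(u)) stop("empty sample", call. = FALSE)
  if (any(u < 0 | u > 1)) stop("values outside [0, 1]", call. = FALSE)
  lev <- as.character(level)
  if (!lev %in% names(.ks_const))
    stop("level must be 0.90 or 0.95", call. = FALSE)
  n <- length(u)
  us <- sort(u)
  i <- seq_len(n)
  D <- max(pmax(i / n - us, us - (i - 1) / n))
  crit <- .ks_const[[lev]] / sqrt(n)
  list(statistic = D, critical = crit, inside_band = D < crit)
}

#' Goodness-of-fit report for one fitted cell
#'
#' Runs [time_rescale()] and [ks_band_test()] at the 95% and 90% bands.
#'
#' @param fit a [fit_penalized()] result.
#' @param dm its design matrix.
#' @param y response; defaults to the design's.
#' @param discrete_correction passed to [time_rescale()].
#' @return An object of class `gof_report` with fields `rescaled_intervals`,
#'   `ks_statistic`, `band_95`, `band_90`, `n_intervals`.
#' @export
gof_report <- function(fit, dm, y = dm$y,
                       discrete_correction = c("exact", "none")) {
  tr <- time_rescale(fit, dm, y, discrete_correction)
  if (tr$n_intervals == 0) {
    return(structure(list(rescaled_intervals = numeric(0),
                          ks_statistic = NA_real_, band_95 = NA,
                          band_90 = NA, n_intervals = 0L,
                          target_cell = fit$target_cell),
                     class = "gof_report"))
  }
  k95 <- ks_band_test(tr$u, 0.95)
  k90 <- ks_band_test(tr$u, 0.90)
  structure(list(rescaled_intervals = tr$tau, ks_statistic = k95$statistic,
                 band_95 = k95$inside_band, band_90 = k90$inside_band,
                 n_intervals = tr$n_intervals, target_cell = fit$target_cell),
            class = "gof_report")
}

#' @export
print.gof_report <- function(x, ...) {
  cat(sprintf("<gof_report> cell %s: KS = %.4f over %d intervals; inside 95%% band: %s, 90%%: %s\n",
              x$target_cell, x$ks_statistic, x$n_intervals,
              x$band_95, x$band_90))
  invisible(x)
}

#' Empirical-vs-model CDF of the rescaled intervals (KS plot data)
#'
#' @param report a [gof_report()].
#' @return data.frame with `model_cdf` (uniform quantiles) and
#'   `empirical_cdf`, suitable for a KS plot or CSV export.
#' @export
ks_plot_data <- function(report) {
  u <- sort(1 - exp(-report$rescaled_intervals))
  n <- length(u)
  data.frame(model_cdf = u, empirical_cdf = (seq_len(n) - 0.5) / n)
}
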