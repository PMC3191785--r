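#' Build the GLM design matrix for one target cell
#'
#' For every analysis bin `t`, the covariate vector is an intercept plus, for
#' each source cell `i` and history window `k`, the number of spikes of `i`
#' in the inclusive lag range `[t - hi_k, t - lo_k]` -- strictly before `t`,
#' so the current bin never contributes.  Columns are ordered source-cell
#' major: cell 1 windows `1..K`, cell 2 windows `1..K`, and so on; the
#' target's own history (`i == target`) is included like any other source.
#' Bins whose deepest lag would reach before the trial start are masked out
#' of the likelihood rather than zero-padded, which avoids biased low counts
#' at trial onsets.  History for early epoch bins is drawn from the
#' full-trial binning, so spikes preceding the epoch within the same trial
#' do count.
#'
#' @param binned a [bin_spikes()] result.
#' @param scheme a [window_scheme()].
#' @param target_cell integer cell index whose spiking is the response.
#' @param min_history_ms mask bins with less than this much history (ms)
#'   even if the scheme needs less; defaults to the scheme's deepest lag.
#'   Model-selection code uses it to score candidate schemes on a common
#'   set of bins.
#' @return An object of class `design_matrix`: list with the dense matrix
#'   `X` (first column the constant 1), response `y`, per-row `trial` and
#'   `bin` indices, `delta_s`, `C`, `K`, `d = C * K`, the scheme, the target,
#'   and `n_masked` (bins dropped for incomplete history).
#' @export
build_design <- function(binned, scheme, target_cell, min_history_ms = NULL) {
  stopifnot(inherits(binned, "binned_spikes"), inherits(scheme, "window_scheme"))
  C <- ncol(binned$trials[[1]])
  if (!(target_cell %in% seq_len(C)))
    stop("target_cell out of range", call. = FALSE)
  delta <- binned$delta_s
  ms <- 1e-3 / delta
  lo_b <- as.integer(round(scheme$lo * ms))
  hi_b <- as.integer(round(scheme$hi * ms))
  if (any(abs(scheme$lo * ms - lo_b) > 1e-8) ||
      any(abs(scheme$hi * ms - hi_b) > 1e-8))
    stop("window bounds must align to the bin grid", call. = FALSE)
  K <- scheme$K
  max_lag <- max(hi_b)
  if (!is.null(min_history_ms))
    max_lag <- max(max_lag, as.integer(round(min_history_ms * ms)))
  if (max_lag >= binned$n_bins)
    stop("scheme lag exceeds the trial length", call. = FALSE)
  d <- C * K
  Xs <- vector("list", length(binned$trials))
  ys <- trial_id <- bin_id <- vector("list", length(binned$trials))
  n_masked <- 0L
  for (j in seq_along(binned$trials)) {
    B <- binned$trials[[j]]
    bins <- binned$epoch_bins[[j]]
    keep <- bins - max_lag >= 1L
    n_masked <- n_masked + sum(!keep)
    t_ok <- bins[keep]
    if (!length(t_ok))
      stop("scheme lag exceeds the epoch length on trial ", j, call. = FALSE)
    # CS[t + 1, i] = number of spikes of cell i in bins 1..t
    CS <- rbind(0L, apply(B, 2, cumsum))
    Xj <- matrix(0, length(t_ok), d)
    for (i in seq_len(C)) {
      for (k in seq_len(K)) {
        Xj[, (i - 1L) * K + k] <-
          CS[t_ok - lo_b[k] + 1L, i] - CS[t_ok - hi_b[k], i]
      }
    }
    Xs[[j]] <- Xj
    ys[[j]] <- B[t_ok, target_cell]
    trial_id[[j]] <- rep.int(j, length(t_ok))
    bin_id[[j]] <- t_ok
  }
  X <- cbind(1, do.call(rbind, Xs))
  colnames(X) <- c("(intercept)",
                   sprintf("c%d.w%d", rep(seq_len(C), each = K),
                           rep(seq_len(K), C)))
  structure(list(X = X, y = as.numeric(unlist(ys)),
                 trial = unlist(trial_id), bin = unlist(bin_id),
                 delta_s = delta, C = C, K = K, d = d, scheme = scheme,
                 target_cell = target_cell, n_masked = n_masked),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> target cell %d: %d bins x %d covariates (+ intercept), %d masked\n",
              x$target_cell, nrow(x$X), x$d, x$n_masked))
  invisible(x)
}

# Row-subset a design matrix (used by cross-validation folds).
subset_design <- function(dm, rows) {
  out <- dm
  out$X <- dm$X[rows, , drop = FALSE]
  out$y <- dm$y[rows]
  out$trial <- dm$trial[rows]
  out$bin <- dm$bin[rows]
  out
}
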