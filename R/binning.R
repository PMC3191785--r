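#' Discretize an ensemble into 0/1 spike indicators
#'
#' Bins every trial of the ensemble into half-open bins `[t, t + Delta)` of
#' width `delta_s` over the full trial, and marks which bins fall inside the
#' requested analysis epoch.  The indicator is 1 iff at least one spike falls
#' in the bin; bins receiving more than one spike are saturated at 1 (the 0/1
#' coding of the point-process likelihood) and counted in `collisions` so the
#' user can shrink `delta_s` if they are frequent.  The full-trial binning is
#' kept so that history covariates of early epoch bins can draw on spikes
#' that precede the epoch within the same trial.
#'
#' @param ens a [spike_ensemble()].
#' @param epoch epoch name (must be defined on every trial), or `NULL` for
#'   the whole trial.
#' @param delta_s bin width in seconds; defaults to the ensemble's.
#' @return An object of class `binned_spikes`: per-trial integer matrices
#'   (`n_bins x C`) of 0/1 indicators, the epoch bin indices per trial, the
#'   bin width, collision count, outcomes and cell metadata.
#' @export
bin_spikes <- function(ens, epoch = NULL, delta_s = ens$bin_width_s) {
  stopifnot(inherits(ens, "spike_ensemble"))
  C <- n_cells(ens)
  n_bins <- as.integer(round(ens$trial_length_s / delta_s))
  if (abs(n_bins * delta_s - ens$trial_length_s) > delta_s)
    stop("bin width must divide the trial length to within one bin", call. = FALSE)
  collisions <- 0L
  trials <- vector("list", n_trials(ens))
  epoch_bins <- vector("list", n_trials(ens))
  for (j in seq_len(n_trials(ens))) {
    tr <- ens$trials[[j]]
    B <- matrix(0L, n_bins, C)
    for (c_i in seq_len(C)) {
      st <- tr$spikes[[c_i]]
      if (length(st)) {
        b <- pmin(floor(st / delta_s) + 1L, n_bins)
        counts <- tabulate(b, nbins = n_bins)
        collisions <- collisions + sum(pmax(counts - 1L, 0L))
        B[, c_i] <- as.integer(counts > 0L)
      }
    }
    if (is.null(epoch)) {
      epoch_bins[[j]] <- seq_len(n_bins)
    } else {
      if (!epoch %in% names(tr$epochs))
        stop(sprintf("epoch '%s' is not defined on trial %d", epoch, j),
             call. = FALSE)
      e <- tr$epochs[[epoch]]
      lo <- as.integer(round(e[1] / delta_s)) + 1L
      hi <- as.integer(round(e[2] / delta_s))
      epoch_bins[[j]] <- seq.int(lo, hi)
    }
    trials[[j]] <- B
  }
  structure(list(trials = trials, epoch_bins = epoch_bins,
                 epoch = if (is.null(epoch)) "full" else epoch,
                 delta_s = delta_s, n_bins = n_bins, collisions = collisions,
                 cells = ens$cells, outcomes = trial_outcomes(ens),
                 trial_length_s = ens$trial_length_s),
            class = "binned_spikes")
}

#' @export
print.binned_spikes <- function(x, ...) {
  cat(sprintf("<binned_spikes> %d cells, %d trials, epoch '%s' (%d bins/trial at %g s), %d multi-spike bins\n",
              ncol(x$trials[[1]]), length(x$trials), x$epoch,
              length(x$epoch_bins[[1]]), x$delta_s, x$collisions))
  invisible(x)
}

#' Baseline firing rate per cell
#'
#' Baseline rate is the average firing rate over a control recording (animal
#' sitting quietly): total spikes divided by total observed time, per cell.
#'
#' @param ens_control a [spike_ensemble()] of control-period data.
#' @return Named numeric vector of rates in spikes/s.
#' @export
baseline_rates <- function(ens_control) {
  stopifnot(inherits(ens_control, "spike_ensemble"))
  total_t <- n_trials(ens_control) * ens_control$trial_length_s
  if (total_t <= 0) stop("zero observed time", call. = FALSE)
  counts <- Reduce(`+`, lapply(ens_control$trials,
                               function(tr) lengths(tr$spikes)))
  stats::setNames(counts / total_t, ens_control$cells$cell_id)
}

# Published regime centroids (rate spikes/s, trough-to-trough duration ms)
# used only to orient cluster labels and to classify a lone cell.
.rs_centroid <- c(rate = 8.5, duration = 0.9)
.fs_centroid <- c(rate = 22.7, duration = 0.4)

#' Classify cells as regular-spiking (RS) or fast-spiking (FS)
#'
#' Partitions cells into two clusters on the standardized
#' (spike duration, baseline rate) plane with 2-means, seeded
#' deterministically from the two most separated points along the
#' rate-minus-duration axis.  The cluster with the lower mean rate (longer
#' mean duration on a rate tie) is labelled RS -- putative pyramidal cells
#' fire slower and have broader spikes than putative interneurons.  Exact
#' ties, and the degenerate case of identical cells, resolve to RS.
#'
#' @param baseline_rate numeric vector, spikes/s.
#' @param spike_duration numeric vector, trough-to-trough ms.
#' @return Character vector of `"RS"`/`"FS"` labels.
#' @export
classify_cell_types <- function(baseline_rate, spike_duration) {
  if (length(baseline_rate) != length(spike_duration))
    stop("rate and duration vectors must have equal length", call. = FALSE)
  if (anyNA(baseline_rate) || anyNA(spike_duration))
    stop("both features must be present for every cell", call. = FALSE)
  n <- length(baseline_rate)
  if (n == 1L) {
    warning("single cell: classified by nearest published regime centroid")
    d_rs <- sum(((c(baseline_rate, spike_duration) - .rs_centroid) /
                   .rs_centroid)^2)
    d_fs <- sum(((c(baseline_rate, spike_duration) - .fs_centroid) /
                   .fs_centroid)^2)
    return(if (d_rs <= d_fs) "RS" else "FS")
  }
  zs <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
  X <- cbind(duration = zs(spike_duration), rate = zs(baseline_rate))
  axis <- X[, "rate"] - X[, "duration"]   # FS direction: fast and brief
  if (diff(range(axis)) == 0) return(rep("RS", n))   # degenerate: all alike
  cluster <- if (n == 2) {
    1:2                                    # each cell is its own cluster
  } else {
    stats::kmeans(X, centers = X[c(which.min(axis), which.max(axis)), ,
                                 drop = FALSE])$cluster
  }
  mean_rate <- tapply(baseline_rate, cluster, mean)
  mean_dur <- tapply(spike_duration, cluster, mean)
  # RS cluster: lower rate; rate tie broken toward longer duration, then RS
  rs_pos <- if (mean_rate[1] != mean_rate[2]) {
    which.min(mean_rate)
  } else if (mean_dur[1] != mean_dur[2]) which.max(mean_dur) else 1L
  rs_id <- as.integer(names(mean_rate)[rs_pos])
  ifelse(cluster == rs_id, "RS", "FS")
}

#' Screen cells for task-related rate modulation
#'
#' A cell is task-related if its trial-wise mean firing rate in at least one
#' task stage differs significantly from the background stage (one-way ANOVA
#' per stage-versus-background contrast, as in standard PETH screening).
#'
#' @param ens a [spike_ensemble()] whose trials define all `stages` epochs.
#' @param stages character vector of epoch names, including `"background"`.
#' @param alpha significance level; `alpha >= 1` declares every cell
#'   task-related.
#' @return Logical vector, one element per cell.
#' @export
screen_task_related <- function(ens, stages = c("background", "reaching"),
                                alpha = 0.05) {
  stopifnot(inherits(ens, "spike_ensemble"))
  if (length(stages) < 2 || !"background" %in% stages)
    stop("need >= 2 stages including 'background'", call. = FALSE)
  C <- n_cells(ens)
  # per-trial, per-stage rates
  rates <- lapply(stages, function(s) {
    sapply(seq_len(n_trials(ens)), function(j) {
      tr <- ens$trials[[j]]
      if (!s %in% names(tr$epochs))
        stop(sprintf("stage '%s' missing on trial %d", s, j), call. = FALSE)
      e <- tr$epochs[[s]]
      vapply(tr$spikes, function(st) sum(st >= e[1] & st < e[2]), 0) /
        (e[2] - e[1])
    })
  })
  names(rates) <- stages
  if (any(vapply(rates, function(m) NROW(m) == 0, TRUE)))
    stop("a stage has zero trials", call. = FALSE)
  bg <- rates[["background"]]
  out <- logical(C)
  for (c_i in seq_len(C)) {
    if (alpha >= 1) { out[c_i] <- TRUE; next }
    for (s in setdiff(stages, "background")) {
      x <- if (C == 1) as.numeric(rates[[s]]) else rates[[s]][c_i, ]
      y <- if (C == 1) as.numeric(bg) else bg[c_i, ]
      p <- if (stats::var(c(x, y)) == 0) 1 else {
        fit <- stats::aov(r ~ g, data = data.frame(
          r = c(x, y), g = rep(c("stage", "bg"), c(length(x), length(y)))))
        summary(fit)[[1]][["Pr(>F)"]][1]
      }
      if (is.finite(p) && p < alpha) { out[c_i] <- TRUE; break }
    }
  }
  out
}
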