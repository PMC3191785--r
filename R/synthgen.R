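#' Ground-truth generative model for ensemble spike trains
#'
#' Draws a known point-process GLM over `n_rs + n_fs` cells: baseline
#' log-rates from the RS and FS firing regimes (log-normals moment-matched
#' to 8.5 +/- 3.6 and 22.7 +/- 9.6 spikes/s), spike durations from the two
#' waveform regimes, and a directed coupling map in which each ordered
#' off-diagonal pair is coupled with probability `density`.  A coupled pair
#' receives the same coefficient at every history window -- excitatory with
#' odds `ei_balance`, magnitude `coupling_scale` -- so that planted
#' structure is recoverable lag by lag.  An optional `self_coupling`
#' coefficient on the first window models short-range refractoriness or
#' burstiness.  Every downstream stage can use the returned object as its
#' recovery oracle.
#'
#' @param n_rs,n_fs numbers of regular-spiking and fast-spiking cells
#'   (`n_rs + n_fs >= 1`).
#' @param scheme a [window_scheme()].
#' @param density probability in `[0, 1]` that an ordered off-diagonal pair
#'   is coupled.
#' @param ei_balance odds that a coupled pair is excitatory rather than
#'   inhibitory (default 1.11, the E:I balance of the reference recordings).
#' @param coupling_scale magnitude of planted coefficients (dimensionless
#'   log-gain).  The default 0.5 (gain `exp(0.5) ~ 1.65` per spike) keeps
#'   `lambda * Delta` in a stable regime at the default rates.
#' @param self_coupling coefficient planted on each cell's own first
#'   window; 0 (none) by default.
#' @param seed integer RNG seed; the draw is fully reproducible from it.
#' @return An object of class `ground_truth` with fields `n_cells`,
#'   `cell_types`, `baseline_log_rates`, `spike_durations`, `coupling`
#'   (data.frame `target`, `source`, `window`, `coef`), `scheme`, `seed`.
#' @export
make_ground_truth <- function(n_rs, n_fs, scheme, density = 0.15,
                              ei_balance = 1.11, coupling_scale = 0.5,
                              self_coupling = 0, seed = 1L) {
  if (n_rs < 0 || n_fs < 0 || n_rs + n_fs < 1)
    stop("invalid-argument: need n_rs, n_fs >= 0 and n_rs + n_fs >= 1",
         call. = FALSE)
  if (density < 0 || density > 1)
    stop("invalid-argument: density must lie in [0, 1]", call. = FALSE)
  if (!is.finite(coupling_scale) || !is.finite(density) || ei_balance <= 0)
    stop("invalid-argument: non-finite or non-positive parameters", call. = FALSE)
  stopifnot(inherits(scheme, "window_scheme"))
  C <- n_rs + n_fs
  set.seed(seed)
  types <- rep(c("RS", "FS"), c(n_rs, n_fs))
  lnorm_pars <- function(m, s) {
    sdlog <- sqrt(log(1 + (s / m)^2))
    c(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
  }
  rs_p <- lnorm_pars(8.5, 3.6); fs_p <- lnorm_pars(22.7, 9.6)
  rates <- ifelse(types == "RS",
                  stats::rlnorm(C, rs_p[1], rs_p[2]),
                  stats::rlnorm(C, fs_p[1], fs_p[2]))
  durations <- ifelse(types == "RS",
                      stats::rnorm(C, 0.9, 0.08),
                      stats::rnorm(C, 0.4, 0.05))
  durations <- pmax(durations, 0.15)
  K <- scheme$K
  coup <- list()
  if (C >= 2 && density > 0) {
    p_exc <- ei_balance / (1 + ei_balance)
    for (tgt in seq_len(C)) for (src in seq_len(C)) {
      if (src == tgt) next
      if (stats::runif(1) < density) {
        sgn <- if (stats::runif(1) < p_exc) 1 else -1
        coup[[length(coup) + 1L]] <- data.frame(
          target = tgt, source = src, window = seq_len(K),
          coef = sgn * coupling_scale)
      }
    }
  }
  if (self_coupling != 0) {
    for (c_i in seq_len(C))
      coup[[length(coup) + 1L]] <- data.frame(
        target = c_i, source = c_i, window = 1L, coef = self_coupling)
  }
  coupling <- if (length(coup)) do.call(rbind, coup) else
    data.frame(target = integer(0), source = integer(0),
               window = integer(0), coef = numeric(0))
  .validate_coupling(coupling, C, K)
  structure(list(n_cells = C, cell_types = types,
                 baseline_log_rates = log(rates),
                 spike_durations = durations,
                 coupling = coupling, scheme = scheme, seed = seed),
            class = "ground_truth")
}

.validate_coupling <- function(coupling, C, K) {
  if (nrow(coupling)) {
    if (any(coupling$target < 1 | coupling$target > C |
            coupling$source < 1 | coupling$source > C))
      stop("coupling references an invalid cell index", call. = FALSE)
    if (any(coupling$window < 1 | coupling$window > K))
      stop("coupling references an invalid window index", call. = FALSE)
    if (any(!is.finite(coupling$coef)))
      stop("non-finite coupling coefficient", call. = FALSE)
  }
  invisible(TRUE)
}

#' Plant or overwrite a specific coupling
#'
#' Convenience editor for building exact generative models in tests and
#' simulation studies: sets `alpha[source, window] = coef` for the given
#' target, replacing any previous entries for that (target, source) pair at
#' the touched windows.
#'
#' @param gt a [make_ground_truth()] object.
#' @param target,source cell indices.
#' @param coef coefficient value(s), recycled over `windows`.
#' @param windows window indices; all K by default.
#' @return The modified `ground_truth`.
#' @export
set_coupling <- function(gt, target, source, coef,
                         windows = seq_len(gt$scheme$K)) {
  stopifnot(inherits(gt, "ground_truth"))
  keep <- !(gt$coupling$target == target & gt$coupling$source == source &
              gt$coupling$window %in% windows)
  add <- data.frame(target = target, source = source, window = windows,
                    coef = rep_len(coef, length(windows)))
  add <- add[add$coef != 0, ]
  gt$coupling <- rbind(gt$coupling[keep, ], add)
  .validate_coupling(gt$coupling, gt$n_cells, gt$scheme$K)
  gt
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d cells (%d RS / %d FS), K = %d, %d coupling entries, seed %d\n",
              x$n_cells, sum(x$cell_types == "RS"), sum(x$cell_types == "FS"),
              x$scheme$K, nrow(x$coupling), x$seed))
  invisible(x)
}

#' Trial protocol specification
#'
#' Describes the multi-trial recording protocol emulated by the simulator:
#' 3-second trials with the analogue trigger at 1.5 s, a pre-trigger
#' `background` epoch and a post-trigger `reaching` epoch, per-trial
#' outcome labels, and the 1 ms discretization bin.
#'
#' @param n_trials number of trials.
#' @param trial_length_s trial duration (default 3 s).
#' @param trigger_time_s trigger time (default 1.5 s).
#' @param epochs named list of `c(start, end)` intervals; defaults to
#'   `background = [0, trigger)`, `reaching = [trigger, trial_length)`.
#' @param outcomes per-trial labels (`"successful"`/`"unsuccessful"`),
#'   recycled; all successful by default.
#' @param bin_width_s Delta, default 0.001 s.
#' @return An object of class `trial_spec`.
#' @export
trial_spec <- function(n_trials, trial_length_s = 3, trigger_time_s = 1.5,
                       epochs = NULL, outcomes = "successful",
                       bin_width_s = 0.001) {
  if (n_trials < 1) stop("need at least one trial", call. = FALSE)
  if (is.null(epochs))
    epochs <- list(background = c(0, trigger_time_s),
                   reaching = c(trigger_time_s, trial_length_s))
  .validate_epochs(epochs, trial_length_s, 0L)
  n_bins <- round(trial_length_s / bin_width_s)
  if (abs(n_bins * bin_width_s - trial_length_s) > bin_width_s)
    stop("bin width must divide the trial length to within one bin",
         call. = FALSE)
  outcomes <- rep_len(outcomes, n_trials)
  if (!all(outcomes %in% c("successful", "unsuccessful")))
    stop("outcomes must be 'successful' or 'unsuccessful'", call. = FALSE)
  structure(list(n_trials = as.integer(n_trials),
                 trial_length_s = trial_length_s,
                 trigger_time_s = trigger_time_s, epochs = epochs,
                 outcomes = outcomes, bin_width_s = bin_width_s),
            class = "trial_spec")
}

# Coefficient matrix A (C x C*K, source-major columns) from the coupling map.
coupling_matrix <- function(gt) {
  K <- gt$scheme$K
  A <- matrix(0, gt$n_cells, gt$n_cells * K)
  cp <- gt$coupling
  if (nrow(cp))
    A[cbind(cp$target, (cp$source - 1L) * K + cp$window)] <- cp$coef
  A
}

#' Simulate an ensemble from a ground-truth model
#'
#' Forward-samples the discrete-time approximation of the point process:
#' bin by bin, each cell spikes with probability `lambda_c(t | H_t) * Delta`
#' computed from the ensemble's own sampled history through the log-linear
#' intensity, with independent Bernoulli draws across cells given the shared
#' history.  `lambda * Delta` is clipped at `1 - 1e-6`; clipping events are
#' counted and reported with a warning (they indicate explosive positive
#' feedback).  History is empty at each trial start and trials are
#' independent.  Spike times are placed at bin centres.
#'
#' @param gt a [make_ground_truth()] object.
#' @param spec a [trial_spec()].
#' @param seed RNG seed; defaults to the ground truth's own seed.
#' @return A [spike_ensemble()] whose cell metadata carry the generative
#'   types, rates and durations; the ground truth is attached as attribute
#'   `"ground_truth"`.
#' @export
simulate_ensemble <- function(gt, spec, seed = gt$seed) {
  stopifnot(inherits(gt, "ground_truth"), inherits(spec, "trial_spec"))
  delta <- spec$bin_width_s
  n_bins <- as.integer(round(spec$trial_length_s / delta))
  ms <- 1e-3 / delta
  win_lo <- as.integer(round(gt$scheme$lo * ms))
  win_hi <- as.integer(round(gt$scheme$hi * ms))
  A <- coupling_matrix(gt)
  set.seed(seed)
  sim <- simulate_trials_cpp(spec$n_trials, n_bins, delta,
                             gt$baseline_log_rates, A, win_lo, win_hi)
  if (sim$n_clipped > 0)
    warning(sprintf("lambda*Delta clipped at 1 - 1e-6 in %d bins; couplings may be explosive",
                    as.integer(sim$n_clipped)))
  trials <- vector("list", spec$n_trials)
  for (j in seq_len(spec$n_trials)) {
    trials[[j]] <- list(
      trial_id = j, outcome = spec$outcomes[j], epochs = spec$epochs,
      spikes = lapply(sim$trials[[j]], function(b) (b - 0.5) * delta))
  }
  cells <- data.frame(cell_id = seq_len(gt$n_cells),
                      putative_type = gt$cell_types,
                      baseline_rate = exp(gt$baseline_log_rates),
                      spike_duration = gt$spike_durations,
                      region_tag = NA_character_)
  ens <- spike_ensemble(trials, cells, spec$trial_length_s, delta)
  attr(ens, "ground_truth") <- gt
  ens
}

#' Simulate a two-condition ensemble from two generative models
#'
#' Builds one labelled ensemble in which successful trials are drawn from
#' `gt_succ` and unsuccessful trials from `gt_unsucc` -- e.g. sign-reversed
#' coupling traces between outcome conditions.  Both ground truths must
#' share the cell count and window scheme.
#'
#' @param gt_succ,gt_unsucc [make_ground_truth()] objects.
#' @param spec a [trial_spec()] whose `outcomes` contain both labels.
#' @param seed RNG seed.
#' @return A [spike_ensemble()] with per-trial outcome labels; attribute
#'   `"ground_truth"` holds both models.
#' @export
make_condition_pair <- function(gt_succ, gt_unsucc, spec,
                                seed = gt_succ$seed) {
  stopifnot(inherits(gt_succ, "ground_truth"),
            inherits(gt_unsucc, "ground_truth"))
  if (gt_succ$n_cells != gt_unsucc$n_cells)
    stop("invalid-argument: ground truths have different cell counts",
         call. = FALSE)
  if (!identical(unclass(gt_succ$scheme), unclass(gt_unsucc$scheme)))
    stop("invalid-argument: ground truths use different window schemes",
         call. = FALSE)
  is_succ <- spec$outcomes == "successful"
  spec_s <- spec; spec_s$n_trials <- sum(is_succ)
  spec_s$outcomes <- rep("successful", sum(is_succ))
  spec_u <- spec; spec_u$n_trials <- sum(!is_succ)
  spec_u$outcomes <- rep("unsuccessful", sum(!is_succ))
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, 2)
  ens_s <- if (sum(is_succ)) simulate_ensemble(gt_succ, spec_s, seeds[1])
  ens_u <- if (sum(!is_succ)) simulate_ensemble(gt_unsucc, spec_u, seeds[2])
  trials <- vector("list", spec$n_trials)
  i_s <- i_u <- 0L
  for (j in seq_len(spec$n_trials)) {
    if (is_succ[j]) {
      i_s <- i_s + 1L; trials[[j]] <- ens_s$trials[[i_s]]
    } else {
      i_u <- i_u + 1L; trials[[j]] <- ens_u$trials[[i_u]]
    }
    trials[[j]]$trial_id <- j
  }
  base <- if (sum(is_succ)) ens_s else ens_u
  ens <- spike_ensemble(trials, base$cells, spec$trial_length_s,
                        spec$bin_width_s)
  attr(ens, "ground_truth") <- list(successful = gt_succ,
                                    unsuccessful = gt_unsucc)
  ens
}

#' Write / read a ground truth as a JSON sidecar
#'
#' @param gt a [make_ground_truth()] object.
#' @param path file path.
#' @return `read_ground_truth` returns the restored object.
#' @export
write_ground_truth <- function(gt, path) {
  obj <- list(format = "spikeglm-groundtruth v1", n_cells = gt$n_cells,
              cell_types = gt$cell_types,
              baseline_log_rates = gt$baseline_log_rates,
              spike_durations = gt$spike_durations,
              coupling = gt$coupling,
              scheme = list(lo = gt$scheme$lo, hi = gt$scheme$hi),
              seed = gt$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(obj$format, "spikeglm-groundtruth v1"))
    stop("not a spikeglm ground-truth file: ", path, call. = FALSE)
  coupling <- if (length(obj$coupling)) as.data.frame(obj$coupling) else
    data.frame(target = integer(0), source = integer(0),
               window = integer(0), coef = numeric(0))
  structure(list(n_cells = obj$n_cells, cell_types = obj$cell_types,
                 baseline_log_rates = obj$baseline_log_rates,
                 spike_durations = obj$spike_durations,
                 coupling = coupling,
                 scheme = window_scheme(Map(c, obj$scheme$lo, obj$scheme$hi)),
                 seed = obj$seed),
            class = "ground_truth")
}
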