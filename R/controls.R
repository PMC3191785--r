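# Monte-Carlo sanity checks for condition differences in coefficient traces:
# split-half refits (overfitting control) and trial-label shuffles (chance
# control).  Both operate on one directed pair and report per-window
# coefficient traces with across-run mean and SEM.

# Fit the target cell of `pair` on one outcome's trials and return its
# K-vector coupling trace (source -> target) with Wald CIs.  With
# `restrict_to_pair` the model is reduced to the two cells of the pair,
# which is much faster and is the documented speed option; the default
# refits against the full ensemble history.
.pair_trace <- function(ens, pair, outcome, epoch, scheme, rho, Q_kind,
                        restrict_to_pair, trial_idx = NULL) {
  sub <- subset_trials(ens, trial_outcomes(ens) == outcome)
  if (!is.null(trial_idx)) sub <- subset_trials(sub, trial_idx)
  src <- pair[1]; tgt <- pair[2]
  if (restrict_to_pair) {
    keep <- sort(unique(c(src, tgt)))
    sub$cells <- sub$cells[keep, , drop = FALSE]
    for (j in seq_along(sub$trials))
      sub$trials[[j]]$spikes <- sub$trials[[j]]$spikes[keep]
    src <- match(pair[1], keep); tgt <- match(pair[2], keep)
  }
  binned <- bin_spikes(sub, epoch)
  dm <- build_design(binned, scheme, tgt)
  fit <- fit_penalized(dm, rho = rho, Q_kind = Q_kind)
  K <- scheme$K
  idx <- 1L + (src - 1L) * K + seq_len(K)
  est <- unname(fit$alpha_hat[idx])
  se <- sqrt(pmax(diag(fit$Sigma)[idx], 0))
  list(est = est, lo = est - 1.96 * se, hi = est + 1.96 * se)
}

.aggregate_runs <- function(run_mat) {
  # run_mat: n_runs x K
  m <- colMeans(run_mat)
  sem <- if (nrow(run_mat) >= 2)
    apply(run_mat, 2, stats::sd) / sqrt(nrow(run_mat)) else
    rep(NA_real_, ncol(run_mat))
  list(mean = m, sem = sem)
}

#' Split-half overfitting check for a coefficient trace
#'
#' Refits the directed pair's coupling trace on a random half of each
#' outcome group's trials, repeated over `n_runs` Monte-Carlo runs, and
#' compares the across-run mean trace with the full-sample trace.  If the
#' full-sample estimates reflect structure rather than overfitting, the
#' half-sample means correlate strongly and positively with them.
#'
#' @param ens a two-condition [spike_ensemble()] with `>= 4` trials per
#'   outcome.
#' @param pair `c(source, target)` cell indices.
#' @param n_runs Monte-Carlo runs (default 20).
#' @param seed master seed; per-run seeds are drawn from it.
#' @param epoch analysis epoch (default `"reaching"`).
#' @param scheme a [window_scheme()].
#' @param rho,Q_kind passed to [fit_penalized()].
#' @param restrict_to_pair refit only the two cells of the pair (speed
#'   option) instead of the full ensemble (default).
#' @return An object of class `control_trace` with per-condition full
#'   traces (est/lo/hi), per-run half-sample traces, their `mean` and
#'   `sem`, and the full-vs-half-mean `correlation` (per condition and
#'   pooled).  With `n_runs = 1` the SEM is reported absent (`NA`).
#' @export
split_half_check <- function(ens, pair, n_runs = 20, seed = 1L,
                             epoch = "reaching", scheme, rho = 0,
                             Q_kind = "ridge", restrict_to_pair = FALSE) {
  outcomes <- c("successful", "unsuccessful")
  n_by <- vapply(outcomes, function(o) sum(trial_outcomes(ens) == o), 0L)
  if (any(n_by < 4))
    stop("invalid-argument: need >= 4 trials per condition", call. = FALSE)
  full <- lapply(outcomes, function(o)
    .pair_trace(ens, pair, o, epoch, scheme, rho, Q_kind, restrict_to_pair))
  names(full) <- outcomes
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max, n_runs)
  runs <- lapply(outcomes, function(o) matrix(NA_real_, n_runs, scheme$K))
  names(runs) <- outcomes
  for (r in seq_len(n_runs)) {
    set.seed(run_seeds[r])
    for (o in outcomes) {
      half <- sample.int(n_by[[o]], floor(n_by[[o]] / 2))
      tr <- .pair_trace(ens, pair, o, epoch, scheme, rho, Q_kind,
                        restrict_to_pair, trial_idx = sort(half))
      runs[[o]][r, ] <- tr$est
    }
  }
  agg <- lapply(runs, .aggregate_runs)
  corr_by <- vapply(outcomes, function(o) {
    if (stats::sd(full[[o]]$est) == 0 || stats::sd(agg[[o]]$mean) == 0)
      NA_real_ else stats::cor(full[[o]]$est, agg[[o]]$mean)
  }, 0.0)
  pooled_full <- unlist(lapply(full, `[[`, "est"))
  pooled_half <- unlist(lapply(agg, `[[`, "mean"))
  structure(list(kind = "split_half", pair = pair, epoch = epoch,
                 scheme = scheme, n_runs = n_runs, seed = seed,
                 full = full, runs = runs,
                 mean = lapply(agg, `[[`, "mean"),
                 sem = lapply(agg, `[[`, "sem"),
                 correlation = c(as.list(corr_by),
                                 pooled = stats::cor(pooled_full, pooled_half))),
            class = "control_trace")
}

#' Trial-label shuffle (chance) check for a coefficient trace
#'
#' Permutes the successful/unsuccessful trial labels so that each shuffled
#' group contains (as nearly as possible) equal numbers of truly successful
#' and truly unsuccessful trials, refits both groups, and records the
#' per-window traces and their difference over `n_runs` Monte-Carlo runs.
#' Under the shuffle null any genuine outcome-specific coupling is mixed
#' away, so the across-run mean difference should not differ significantly
#' from zero (its `mean +/- 1.96 * SEM` band should cover 0 per window).
#'
#' @inheritParams split_half_check
#' @param n_runs Monte-Carlo runs (default 100).
#' @return An object of class `control_trace` with per-run shuffled traces
#'   per (relabelled) condition, the per-run `difference` traces, and their
#'   across-run `mean` / `sem`; `covers_zero` flags, per window, whether
#'   the mean difference's 1.96 SEM band covers zero.
#' @export
shuffle_label_check <- function(ens, pair, n_runs = 100, seed = 1L,
                                epoch = "reaching", scheme, rho = 0,
                                Q_kind = "ridge", restrict_to_pair = FALSE) {
  oc <- trial_outcomes(ens)
  ns <- sum(oc == "successful"); nu <- sum(oc == "unsuccessful")
  if (ns == 0 || nu == 0)
    stop("invalid-argument: both outcome groups must be non-empty", call. = FALSE)
  # exact equal mixture in both shuffled groups needs ns == nu, both even
  if (ns != nu || ns %% 2 == 1)
    warning("exact equal mixture unattainable; using nearest balanced split")
  idx_s <- which(oc == "successful"); idx_u <- which(oc == "unsuccessful")
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max, n_runs)
  K <- scheme$K
  runs_a <- runs_b <- diff_runs <- matrix(NA_real_, n_runs, K)
  for (r in seq_len(n_runs)) {
    set.seed(run_seeds[r])
    # true-succ count in group A; with odd ns the leftover trial goes to
    # either side at random so the null has no deterministic tilt
    take_s <- floor(ns / 2) + (ns %% 2) * stats::rbinom(1, 1, 0.5)
    take_u <- min(ns - take_s, nu)           # true-unsucc trials in group A
    a_idx <- c(sample(idx_s, take_s), sample(idx_u, take_u))
    b_idx <- setdiff(c(idx_s, idx_u), a_idx)
    shuf <- ens
    for (j in a_idx) shuf$trials[[j]]$outcome <- "successful"
    for (j in b_idx) shuf$trials[[j]]$outcome <- "unsuccessful"
    tr_a <- .pair_trace(shuf, pair, "successful", epoch, scheme, rho,
                        Q_kind, restrict_to_pair)
    tr_b <- .pair_trace(shuf, pair, "unsuccessful", epoch, scheme, rho,
                        Q_kind, restrict_to_pair)
    runs_a[r, ] <- tr_a$est
    runs_b[r, ] <- tr_b$est
    diff_runs[r, ] <- tr_a$est - tr_b$est
  }
  agg_a <- .aggregate_runs(runs_a)
  agg_b <- .aggregate_runs(runs_b)
  agg_d <- .aggregate_runs(diff_runs)
  covers <- abs(agg_d$mean) <= 1.96 * agg_d$sem
  structure(list(kind = "shuffle_label", pair = pair, epoch = epoch,
                 scheme = scheme, n_runs = n_runs, seed = seed,
                 runs = list(group_a = runs_a, group_b = runs_b),
                 difference = diff_runs,
                 mean = list(group_a = agg_a$mean, group_b = agg_b$mean,
                             difference = agg_d$mean),
                 sem = list(group_a = agg_a$sem, group_b = agg_b$sem,
                            difference = agg_d$sem),
                 covers_zero = covers),
            class = "control_trace")
}

#' @export
print.control_trace <- function(x, ...) {
  cat(sprintf("<control_trace> %s check, pair %d -> %d, %d windows, %d runs\n",
              x$kind, x$pair[1], x$pair[2], x$scheme$K, x$n_runs))
  if (x$kind == "split_half")
    cat(sprintf("  full-vs-half-mean correlation (pooled): %.3f\n",
                x$correlation$pooled))
  else
    cat(sprintf("  mean difference covers zero in %d / %d windows\n",
                sum(x$covers_zero), length(x$covers_zero)))
  invisible(x)
}

#' Export a control trace as a tidy table
#'
#' @param x a `control_trace` from [split_half_check()] or
#'   [shuffle_label_check()].
#' @return data.frame with one row per (condition, window): estimate and,
#'   where defined, CI bounds or run-aggregate mean/SEM.
#' @export
trace_table <- function(x) {
  stopifnot(inherits(x, "control_trace"))
  K <- x$scheme$K
  if (x$kind == "split_half") {
    full <- do.call(rbind, lapply(names(x$full), function(o)
      data.frame(condition = o, window = seq_len(K), kind = "full",
                 estimate = x$full[[o]]$est, lo = x$full[[o]]$lo,
                 hi = x$full[[o]]$hi, sem = NA_real_)))
    half <- do.call(rbind, lapply(names(x$mean), function(o)
      data.frame(condition = o, window = seq_len(K), kind = "half_mean",
                 estimate = x$mean[[o]], lo = NA_real_, hi = NA_real_,
                 sem = x$sem[[o]])))
    rbind(full, half)
  } else {
    do.call(rbind, lapply(names(x$mean), function(o)
      data.frame(condition = o, window = seq_len(K), kind = "shuffle_mean",
                 estimate = x$mean[[o]], lo = NA_real_, hi = NA_real_,
                 sem = x$sem[[o]])))
  }
}
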