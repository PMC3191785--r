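# Shared fixtures and independent oracles, built in code at test time.

sch3 <- function() window_scheme(list(c(1, 3), c(4, 6), c(7, 9)))
sch2 <- function() window_scheme(list(c(1, 3), c(4, 6)))

# hand-built ensemble: `trials` is a list of per-cell spike-time lists
make_ens <- function(trials, n_cells = length(trials[[1]]),
                     trial_length_s = 3, outcomes = "successful",
                     epochs = list(background = c(0, 1.5),
                                   reaching = c(1.5, 3))) {
  outcomes <- rep_len(outcomes, length(trials))
  spike_ensemble(
    lapply(seq_along(trials), function(j)
      list(outcome = outcomes[j], epochs = epochs, spikes = trials[[j]])),
    cells = data.frame(cell_id = seq_len(n_cells)),
    trial_length_s = trial_length_s)
}

# simulate with clipping warnings silenced (clipping is reported, not an error)
sim_quiet <- function(gt, spec, seed = gt$seed) {
  withCallingHandlers(simulate_ensemble(gt, spec, seed),
                      warning = function(w) {
                        if (grepl("clipped", conditionMessage(w)))
                          invokeRestart("muffleWarning")
                      })
}

# brute-force history-count oracle: spikes of cell `i` in [t-hi, t-lo] bins
brute_count <- function(spike_bins_i, t, lo, hi) {
  sum(spike_bins_i >= t - hi & spike_bins_i <= t - lo)
}

# minimal fitted-model stand-ins for connectivity unit tests
fake_fit <- function(est, se, target, C, K, scheme, delta_s = 0.001) {
  stopifnot(length(est) == C * K + 1, length(se) == C * K + 1)
  nm <- c("(intercept)", sprintf("c%d.w%d", rep(seq_len(C), each = K),
                                 rep(seq_len(K), C)))
  names(est) <- nm
  Sigma <- diag(se^2)
  dimnames(Sigma) <- list(nm, nm)
  structure(list(alpha_hat = est, Sigma = Sigma, rho = 0, Q_kind = "ridge",
                 loglik = 0, penalized_loglik = 0, bic = 0, l = 1,
                 converged = TRUE, scheme = scheme, target_cell = target,
                 delta_s = delta_s, C = C, K = K),
            class = "glm_fit")
}

fake_efit <- function(est_list, se_list, C, K, scheme,
                      cell_types = rep("RS", C), condition = "test") {
  fits <- lapply(seq_len(C), function(c_i)
    fake_fit(est_list[[c_i]], se_list[[c_i]], c_i, C, K, scheme))
  structure(list(fits = fits,
                 cells = data.frame(cell_id = seq_len(C),
                                    putative_type = cell_types),
                 C = C, K = K, scheme = scheme, condition = condition,
                 delta_s = 0.001),
            class = "ensemble_fit")
}
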