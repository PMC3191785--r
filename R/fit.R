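#' Penalty matrix for ridge / smoothing regularization
#'
#' Builds the positive-semidefinite matrix `Q` of the penalty
#' `-rho * t(alpha) %*% Q %*% alpha`.  The intercept (baseline log-rate) is
#' never penalized: shrinking it would bias every baseline toward one spike
#' per bin.  `"ridge"` is the identity on the coupling coordinates;
#' `"smooth"` penalizes first differences between adjacent windows of the
#' same source cell, encouraging smooth coefficient traces across lags.
#'
#' @param C,K cell and window counts.
#' @param Q_kind `"ridge"` or `"smooth"`.
#' @return A `(C*K + 1) x (C*K + 1)` matrix.
#' @export
penalty_matrix <- function(C, K, Q_kind = c("ridge", "smooth")) {
  Q_kind <- match.arg(Q_kind)
  d <- C * K
  if (Q_kind == "ridge") {
    Q <- diag(c(0, rep(1, d)), nrow = d + 1)
  } else {
    D <- matrix(0, C * max(K - 1, 0), d)
    r <- 0L
    for (i in seq_len(C)) for (k in seq_len(K - 1)) {
      r <- r + 1L
      D[r, (i - 1L) * K + k] <- -1
      D[r, (i - 1L) * K + k + 1L] <- 1
    }
    Q <- rbind(0, cbind(0, crossprod(D)))
  }
  Q
}

#' Discrete point-process log-likelihood
#'
#' The log-likelihood of the target cell's 0/1 spike indicators under the
#' log-linear conditional intensity `lambda_t = exp(alpha . x_t)` (spikes/s),
#' discretized at bin width Delta:
#' `sum_t [ y_t * log(lambda_t * Delta) - lambda_t * Delta ]`
#' over the unmasked bins -- the finite-sum form of the continuous-time
#' point-process likelihood.
#'
#' @param alpha coefficient vector (intercept first), length `d + 1`.
#' @param dm a [build_design()] result.
#' @param y response; defaults to the design's target indicators.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(alpha, dm, y = dm$y) {
  eta <- drop(dm$X %*% alpha) + log(dm$delta_s)
  mu <- exp(eta)
  if (any(!is.finite(mu)))
    stop("numerical-failure: non-finite conditional intensity", call. = FALSE)
  sum(y * eta - mu)
}

#' Fit the point-process GLM by penalized maximum likelihood
#'
#' Maximizes `L_p(alpha) = L(alpha) - rho * t(alpha) Q alpha` by damped
#' Newton iterations with step-halving line search.  `-L_p` is convex, so
#' the optimum is global; iterations stop when the penalized log-likelihood
#' changes by less than `tol` (default `1e-4`) between updates.  The
#' coefficient covariance is the inverse observed information of the
#' *unpenalized* likelihood, `solve(t(X) diag(lambda * Delta) X)` -- for the
#' log-linear intensity the residual second-derivative term vanishes -- from
#' which 95% Wald bounds `alpha_hat +/- 1.96 * sqrt(diag(Sigma))` follow.
#'
#' @param dm a [build_design()] result.
#' @param y response vector (defaults to the design's).
#' @param rho regularization strength, `>= 0`.
#' @param Q_kind penalty matrix choice, see [penalty_matrix()].
#' @param tol convergence tolerance on the penalized log-likelihood change.
#' @param max_iter Newton iteration cap.
#' @param compute_sigma set `FALSE` to skip the covariance (e.g. inside CV).
#' @param init optional starting coefficient vector; convexity makes the
#'   optimum independent of it (default: data-driven intercept start).
#' @return An object of class `glm_fit`: named coefficients `alpha_hat`,
#'   `rho`, `Q_kind`, `loglik`, `penalized_loglik`, covariance `Sigma`,
#'   `bic = -2 loglik + dim(alpha) log(l)`, sample count `l`, the scheme and
#'   target, convergence flag and trace.
#' @export
fit_penalized <- function(dm, y = dm$y, rho = 0, Q_kind = "ridge",
                          tol = 1e-4, max_iter = 500, compute_sigma = TRUE,
                          init = NULL) {
  stopifnot(rho >= 0)
  X <- dm$X
  l <- nrow(X)
  off <- log(dm$delta_s)
  Q <- penalty_matrix(dm$C, dm$K, Q_kind)
  p <- ncol(X)
  if (is.null(init)) {
    alpha <- numeric(p)
    alpha[1] <- log(max(sum(y), 0.5) / l) - off
  } else {
    stopifnot(length(init) == p)
    alpha <- as.numeric(init)
  }
  pen_ll <- function(a, mu_eta = NULL) {
    eta <- drop(X %*% a) + off
    mu <- exp(eta)
    list(lp = sum(y * eta - mu) - rho * drop(crossprod(a, Q %*% a)),
         ll = sum(y * eta - mu), mu = mu)
  }
  cur <- pen_ll(alpha)
  if (!is.finite(cur$lp)) stop("numerical-failure at initial point", call. = FALSE)
  trace <- cur$lp
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mu <- cur$mu
    g <- drop(crossprod(X, y - mu)) - 2 * rho * drop(Q %*% alpha)
    H <- crossprod(X, X * mu) + 2 * rho * Q
    step <- tryCatch(solve(H, g), error = function(e) {
      solve(H + diag(1e-8 * max(diag(H)), p), g)
    })
    s <- 1
    repeat {
      cand <- alpha + s * step
      new <- pen_ll(cand)
      if (is.finite(new$lp) && new$lp >= cur$lp - 1e-12) break
      s <- s / 2
      if (s < 1e-12) { new <- cur; cand <- alpha; break }
    }
    delta_lp <- new$lp - cur$lp
    alpha <- cand
    cur <- new
    trace <- c(trace, cur$lp)
    if (abs(delta_lp) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop(sprintf("fit did not converge in %d iterations (last |dLp| = %.3g)",
                 max_iter, abs(diff(utils::tail(trace, 2)))), call. = FALSE)
  names(alpha) <- colnames(X)
  fit <- structure(list(
    alpha_hat = alpha, rho = rho, Q_kind = Q_kind,
    loglik = cur$ll, penalized_loglik = cur$lp,
    Sigma = NULL, bic = -2 * cur$ll + p * log(l), l = l,
    n_iter = it, converged = converged, trace = trace,
    scheme = dm$scheme, target_cell = dm$target_cell,
    delta_s = dm$delta_s, C = dm$C, K = dm$K), class = "glm_fit")
  if (compute_sigma) fit$Sigma <- coefficient_covariance(fit, dm, y)
  fit
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit> target cell %d: %d coefficients, rho = %g (%s), loglik = %.2f, BIC = %.2f, %d bins\n",
              x$target_cell, length(x$alpha_hat), x$rho, x$Q_kind,
              x$loglik, x$bic, x$l))
  invisible(x)
}

#' Observed-information coefficient covariance
#'
#' Inverts the observed information `sum_t lambda_t Delta x_t t(x_t)` of the
#' unpenalized log-likelihood at the fitted coefficients (the Wald/sandwich
#' base for the log-linear intensity).  Symmetry is enforced; a singular
#' information matrix falls back to the Moore-Penrose pseudo-inverse with a
#' warning, flagging unidentifiable coefficients.
#'
#' @param fit a [fit_penalized()] result.
#' @param dm the design it was fitted on.
#' @param y response vector.
#' @return Symmetric PSD covariance matrix `Sigma`.
#' @export
coefficient_covariance <- function(fit, dm, y = dm$y) {
  mu <- exp(drop(dm$X %*% fit$alpha_hat) + log(dm$delta_s))
  info <- crossprod(dm$X, dm$X * mu)
  Sigma <- tryCatch(chol2inv(chol(info)), error = function(e) {
    warning("singular information matrix; using pseudo-inverse (some coefficients are unidentifiable)")
    MASS::ginv(info)
  })
  Sigma <- (Sigma + t(Sigma)) / 2
  dimnames(Sigma) <- list(names(fit$alpha_hat), names(fit$alpha_hat))
  Sigma
}

#' Select the regularization strength by cross-validation
#'
#' Leave-one-trial-out (the trial is the exchangeable unit) or k-fold
#' cross-validation over trials: for each candidate `rho` the model is
#' refitted with the held-out trial(s) removed and scored by the held-out
#' log-likelihood; the `rho` with the highest mean held-out score wins, the
#' smaller `rho` on a tie.
#'
#' @param dm a [build_design()] result covering `>= 2` trials.
#' @param rho_grid candidate strengths; default 8 log-spaced values in
#'   `[1e-4, 1e2]`.
#' @param folds `NULL` for leave-one-trial-out, or an integer k for k-fold
#'   (trials assigned to folds round-robin in order).
#' @param Q_kind,tol passed to [fit_penalized()].
#' @return List with the selected `rho` and the per-candidate mean held-out
#'   log-likelihood `cv_table`.
#' @export
select_rho <- function(dm, rho_grid = 10^seq(-4, 2, length.out = 8),
                       folds = NULL, Q_kind = "ridge", tol = 1e-4) {
  if (!length(rho_grid)) stop("empty rho grid", call. = FALSE)
  trials <- sort(unique(dm$trial))
  if (length(trials) < 2) stop("cross-validation needs >= 2 trials", call. = FALSE)
  fold_of <- if (is.null(folds)) {
    stats::setNames(seq_along(trials), trials)
  } else {
    stats::setNames(rep_len(seq_len(folds), length(trials)), trials)
  }
  fold_ids <- sort(unique(fold_of))
  scores <- matrix(NA_real_, length(rho_grid), length(fold_ids))
  for (fi in seq_along(fold_ids)) {
    held <- trials[fold_of == fold_ids[fi]]
    test_rows <- dm$trial %in% held
    dtrain <- subset_design(dm, !test_rows)
    dtest <- subset_design(dm, test_rows)
    for (ri in seq_along(rho_grid)) {
      f <- fit_penalized(dtrain, rho = rho_grid[ri], Q_kind = Q_kind,
                         tol = tol, compute_sigma = FALSE)
      scores[ri, fi] <- log_likelihood(f$alpha_hat, dtest)
    }
  }
  mean_score <- rowMeans(scores)
  best <- which(mean_score == max(mean_score))[1]
  list(rho = rho_grid[best],
       cv_table = data.frame(rho = rho_grid, heldout_loglik = mean_score))
}

#' Select the history-window scheme by BIC
#'
#' Fits each candidate scheme and returns the one minimizing
#' `BIC = -2 L(alpha) + dim(alpha) log(l)`.  Ties are broken toward fewer
#' windows (a compact model is preferred), then toward the earlier
#' candidate.  All candidates are scored on a common set of bins -- every
#' candidate masks up to the deepest lag of the whole candidate list -- so
#' their likelihoods are comparable.
#'
#' @param binned a [bin_spikes()] result.
#' @param candidate_schemes list of [window_scheme()]s.
#' @param target_cell response cell index.
#' @param rho,Q_kind,tol passed to [fit_penalized()].
#' @return List with the winning `scheme`, its `fit`, and a `bic_table`.
#' @export
select_windows <- function(binned, candidate_schemes, target_cell,
                           rho = 0, Q_kind = "ridge", tol = 1e-4) {
  if (!length(candidate_schemes)) stop("no candidate schemes", call. = FALSE)
  fits <- vector("list", length(candidate_schemes))
  bic <- k <- numeric(length(candidate_schemes))
  common_lag <- max(vapply(candidate_schemes, function(s) max(s$hi), 0L))
  for (s in seq_along(candidate_schemes)) {
    dm <- build_design(binned, candidate_schemes[[s]], target_cell,
                       min_history_ms = common_lag)
    fits[[s]] <- fit_penalized(dm, rho = rho, Q_kind = Q_kind, tol = tol)
    bic[s] <- fits[[s]]$bic
    k[s] <- candidate_schemes[[s]]$K
  }
  best <- order(bic, k, seq_along(bic))[1]
  list(scheme = candidate_schemes[[best]], fit = fits[[best]],
       bic_table = data.frame(candidate = seq_along(bic), K = k, bic = bic))
}

#' Fit the network model: one GLM per target cell
#'
#' The network log-likelihood factorizes over target cells (they are
#' conditionally independent given the shared ensemble history), so the
#' ensemble fit is the collection of `C` independent penalized fits sharing
#' one design apart from the response column.
#'
#' @param binned a [bin_spikes()] result.
#' @param scheme a [window_scheme()].
#' @param rho regularization strength, or `"cv"` to select per target with
#'   [select_rho()].
#' @param rho_grid,folds used when `rho = "cv"`.
#' @param Q_kind,tol passed to [fit_penalized()].
#' @param condition optional condition label (e.g. `"reaching/successful"`)
#'   carried into downstream reports.
#' @return An object of class `ensemble_fit`: list of `glm_fit`s plus cell
#'   metadata, `C`, `K`, scheme and condition.
#' @export
fit_ensemble <- function(binned, scheme, rho = 0,
                         rho_grid = 10^seq(-4, 2, length.out = 8),
                         folds = NULL, Q_kind = "ridge", tol = 1e-4,
                         condition = binned$epoch) {
  C <- ncol(binned$trials[[1]])
  fits <- vector("list", C)
  for (c_i in seq_len(C)) {
    dm <- build_design(binned, scheme, c_i)
    r <- if (identical(rho, "cv")) {
      select_rho(dm, rho_grid, folds = folds, Q_kind = Q_kind, tol = tol)$rho
    } else rho
    fits[[c_i]] <- fit_penalized(dm, rho = r, Q_kind = Q_kind, tol = tol)
  }
  structure(list(fits = fits, cells = binned$cells, C = C, K = scheme$K,
                 scheme = scheme, condition = condition,
                 delta_s = binned$delta_s),
            class = "ensemble_fit")
}

#' @export
print.ensemble_fit <- function(x, ...) {
  cat(sprintf("<ensemble_fit> %d cells, K = %d windows, condition '%s'\n",
              x$C, x$K, x$condition))
  invisible(x)
}

#' Serialize an ensemble fit to JSON
#'
#' Writes coefficients, the diagonal of the covariance (full matrix
#' optional), log-likelihoods, BIC, `rho` and the window scheme per target
#' cell, in a form [read_ensemble_fit()] restores for downstream
#' connectivity analysis.
#'
#' @param efit an [fit_ensemble()] result.
#' @param path output file.
#' @param full_sigma include the full covariance matrices?
#' @return `path`, invisibly.
#' @export
write_ensemble_fit <- function(efit, path, full_sigma = FALSE) {
  obj <- list(
    format = "spikeglm-fit v1",
    C = efit$C, K = efit$K, condition = efit$condition,
    delta_s = efit$delta_s,
    scheme = list(lo = efit$scheme$lo, hi = efit$scheme$hi),
    cells = as.list(efit$cells),
    fits = lapply(efit$fits, function(f) {
      out <- list(target_cell = f$target_cell,
                  alpha_hat = as.list(f$alpha_hat),      # keep names in JSON
                  sigma_diag = as.list(diag(f$Sigma)),
                  rho = f$rho, Q_kind = f$Q_kind,
                  loglik = f$loglik, penalized_loglik = f$penalized_loglik,
                  bic = f$bic, l = f$l, n_iter = f$n_iter)
      if (full_sigma) out$Sigma <- f$Sigma
      out
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ensemble_fit
#' @export
read_ensemble_fit <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  if (!identical(obj$format, "spikeglm-fit v1"))
    stop("not a spikeglm fit file: ", path, call. = FALSE)
  scheme <- window_scheme(Map(c, obj$scheme$lo, obj$scheme$hi))
  obj$cells <- as.data.frame(lapply(obj$cells, unlist),
                             stringsAsFactors = FALSE)
  fits <- lapply(obj$fits, function(f) {
    a <- unlist(f$alpha_hat)
    sd2 <- unlist(f$sigma_diag)
    Sigma <- if (!is.null(f$Sigma)) f$Sigma else diag(sd2, length(sd2))
    dimnames(Sigma) <- list(names(a), names(a))
    structure(list(alpha_hat = a, rho = f$rho, Q_kind = f$Q_kind,
                   loglik = f$loglik,
                   penalized_loglik = f$penalized_loglik,
                   Sigma = Sigma, bic = f$bic, l = f$l,
                   n_iter = f$n_iter, converged = TRUE,
                   scheme = scheme, target_cell = f$target_cell,
                   delta_s = obj$delta_s, C = obj$C, K = obj$K),
              class = "glm_fit")
  })
  structure(list(fits = fits, cells = obj$cells, C = obj$C, K = obj$K,
                 scheme = scheme, condition = obj$condition,
                 delta_s = obj$delta_s),
            class = "ensemble_fit")
}
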