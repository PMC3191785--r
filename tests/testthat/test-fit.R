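# An intercept-only design for closed-form checks.
intercept_dm <- function(y, delta_s = 0.001) {
  structure(list(X = matrix(1, length(y), 1,
                            dimnames = list(NULL, "(intercept)")),
                 y = y, trial = rep(1L, length(y)),
                 bin = seq_along(y), delta_s = delta_s, C = 1L, K = 0L,
                 d = 0L, scheme = NULL, target_cell = 1L, n_masked = 0L),
            class = "design_matrix")
}

test_that("log-likelihood matches closed form and a per-bin loop oracle", {
  # all-zero response, intercept only: L = -l * exp(a0) * Delta
  dm0 <- intercept_dm(rep(0, 500))
  a0 <- log(7)
  expect_equal(log_likelihood(a0, dm0), -500 * 7 * 0.001)
  # generic data against a naive per-bin summation
  gt <- make_ground_truth(1, 1, sch2(), density = 0.5, seed = 3)
  ens <- sim_quiet(gt, trial_spec(2))
  dm <- build_design(bin_spikes(ens), sch2(), 2)
  set.seed(4)
  alpha <- c(log(9), rnorm(4, 0, 0.3))
  loop <- 0
  for (t in seq_len(nrow(dm$X))) {
    lam_dt <- exp(sum(dm$X[t, ] * alpha)) * dm$delta_s
    loop <- loop + dm$y[t] * log(lam_dt) - lam_dt
  }
  expect_equal(log_likelihood(alpha, dm), loop, tolerance = 1e-10)
})

test_that("log-likelihood is concave along random segments", {
  gt <- make_ground_truth(1, 1, sch2(), density = 0.5, seed = 5)
  ens <- sim_quiet(gt, trial_spec(2))
  dm <- build_design(bin_spikes(ens), sch2(), 1)
  set.seed(6)
  for (r in 1:10) {
    a1 <- c(log(8), rnorm(4, 0, 0.5))
    a2 <- c(log(8), rnorm(4, 0, 0.5))
    mid <- (a1 + a2) / 2
    expect_gte(log_likelihood(mid, dm),
               min(log_likelihood(a1, dm), log_likelihood(a2, dm)))
  }
})

test_that("intercept-only MLE equals the empirical rate exactly", {
  set.seed(7)
  y <- as.numeric(runif(20000) < 0.012)
  dm <- intercept_dm(y)
  f <- fit_penalized(dm, tol = 1e-12)
  expect_equal(exp(f$alpha_hat[["(intercept)"]]) * dm$delta_s,
               sum(y) / length(y), tolerance = 1e-12)
  # covariance: Fisher information is the expected spike count
  expect_equal(f$Sigma[1, 1], 1 / sum(y), tolerance = 1e-8)
})

test_that("unpenalized fit agrees with an independent Poisson GLM", {
  gt <- make_ground_truth(1, 1, sch2(), density = 0, seed = 9)
  gt <- set_coupling(gt, 2, 1, coef = c(0.7, 0.3))
  ens <- sim_quiet(gt, trial_spec(25), seed = 10)
  dm <- build_design(bin_spikes(ens), sch2(), 2)
  f <- fit_penalized(dm, tol = 1e-10)
  ref <- suppressWarnings(
    stats::glm.fit(dm$X, dm$y, family = stats::poisson(),
                   offset = rep(log(dm$delta_s), nrow(dm$X))))
  expect_equal(unname(f$alpha_hat), unname(ref$coefficients),
               tolerance = 1e-6)
  # and with the covariance route: Wald SEs match summary.glm's
  W <- exp(drop(dm$X %*% ref$coefficients) + log(dm$delta_s))
  se_ref <- sqrt(diag(solve(crossprod(dm$X, dm$X * W))))
  expect_equal(unname(sqrt(diag(f$Sigma))), unname(se_ref),
               tolerance = 1e-6)
})

test_that("ridge path shrinks coupling coefficients monotonically", {
  gt <- make_ground_truth(1, 1, sch2(), density = 0.5, seed = 11)
  ens <- sim_quiet(gt, trial_spec(8), seed = 12)
  dm <- build_design(bin_spikes(ens), sch2(), 2)
  grid <- 10^seq(-2, 3, length.out = 8)
  norms <- vapply(grid, function(rho) {
    f <- fit_penalized(dm, rho = rho, tol = 1e-8)
    sqrt(sum(f$alpha_hat[-1]^2))
  }, 0.0)
  expect_true(all(diff(norms) <= 1e-8))
  # rho = 0 with Q = I equals the unpenalized optimum
  f0 <- fit_penalized(dm, rho = 0, tol = 1e-10)
  expect_equal(f0$loglik, f0$penalized_loglik)
})

test_that("the optimum is unique across random initializations", {
  gt <- make_ground_truth(1, 1, sch2(), density = 0.5, seed = 13)
  ens <- sim_quiet(gt, trial_spec(5), seed = 14)
  dm <- build_design(bin_spikes(ens), sch2(), 1)
  set.seed(15)
  lps <- vapply(1:5, function(i) {
    init <- c(log(10), rnorm(4, 0, 0.5))
    fit_penalized(dm, rho = 0.5, tol = 1e-9, init = init)$penalized_loglik
  }, 0.0)
  expect_lt(max(lps) - min(lps), 1e-6)
})

test_that("stored BIC equals its formula bit for bit", {
  gt <- make_ground_truth(1, 1, sch2(), density = 0, seed = 17)
  ens <- sim_quiet(gt, trial_spec(3))
  dm <- build_design(bin_spikes(ens), sch2(), 1)
  f <- fit_penalized(dm)
  expect_identical(f$bic,
                   -2 * f$loglik + length(f$alpha_hat) * log(f$l))
})

test_that("covariance matches a finite-difference Hessian", {
  gt <- make_ground_truth(1, 1, sch2(), density = 0.5, seed = 19)
  ens <- sim_quiet(gt, trial_spec(4), seed = 20)
  dm <- build_design(bin_spikes(ens), sch2(), 2)
  f <- fit_penalized(dm, tol = 1e-10)
  p <- length(f$alpha_hat)
  h <- 1e-4
  H <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    ei <- ej <- numeric(p); ei[i] <- h; ej[j] <- h
    H[i, j] <- (log_likelihood(f$alpha_hat + ei + ej, dm) -
                  log_likelihood(f$alpha_hat + ei - ej, dm) -
                  log_likelihood(f$alpha_hat - ei + ej, dm) +
                  log_likelihood(f$alpha_hat - ei - ej, dm)) / (4 * h^2)
  }
  expect_equal(unname(f$Sigma), unname(solve(-H)), tolerance = 1e-3)
})

test_that("cross-validation selects sensible regularization strengths", {
  # single candidate passes through
  gt <- make_ground_truth(1, 1, sch2(), density = 0, seed = 21)
  ens <- sim_quiet(gt, trial_spec(4), seed = 22)
  dm <- build_design(bin_spikes(ens), sch2(), 1)
  expect_equal(select_rho(dm, rho_grid = 3.3)$rho, 3.3)
  expect_error(select_rho(dm, rho_grid = numeric(0)), "empty")
  # sparse data with spurious covariates: shrinkage helps out of sample
  gt0 <- make_ground_truth(2, 1, sch3(), density = 0, seed = 23)
  gt0$baseline_log_rates <- rep(log(4), 3)
  ens0 <- sim_quiet(gt0, trial_spec(6), seed = 24)
  dm0 <- build_design(bin_spikes(ens0), sch3(), 1)
  sel <- select_rho(dm0, rho_grid = 10^seq(-4, 2, length.out = 8))
  expect_gt(sel$rho, 1e-4)
  # abundant data from a dense true model: rho = 0 is near-optimal
  gt1 <- make_ground_truth(1, 1, sch2(), density = 0, seed = 25)
  gt1 <- set_coupling(gt1, 2, 1, coef = c(0.8, 0.5))
  ens1 <- sim_quiet(gt1, trial_spec(30), seed = 26)
  dm1 <- build_design(bin_spikes(ens1), sch2(), 2)
  sel1 <- select_rho(dm1, rho_grid = c(1e-6, 1, 10), folds = 5)
  tab <- sel1$cv_table
  expect_lt(max(tab$heldout_loglik) - tab$heldout_loglik[1], 2)
})

test_that("BIC window selection prefers the generating scheme", {
  sch_big <- window_scheme(list(c(1, 3), c(4, 6), c(7, 9), c(10, 12)))
  gt <- make_ground_truth(1, 1, sch2(), density = 0, seed = 27)
  gt <- set_coupling(gt, 2, 1, coef = c(0.6, 0.4))
  ens <- sim_quiet(gt, trial_spec(30), seed = 28)
  b <- bin_spikes(ens)
  sel <- select_windows(b, list(sch2(), sch_big), 2)
  expect_equal(sel$scheme$K, 2)
  # identical candidates: tie broken toward the first
  sel2 <- select_windows(b, list(sch2(), sch2()), 2)
  expect_equal(sel2$bic_table$bic[1], sel2$bic_table$bic[2])
  expect_identical(unclass(sel2$scheme), unclass(sch2()))
})

test_that("planted couplings are recovered within their Wald intervals", {
  hits <- 0L
  for (r in 1:10) {
    gt <- make_ground_truth(1, 1, sch2(), density = 0, seed = 600 + r)
    gt <- set_coupling(gt, 2, 1, coef = 0.5, windows = 1)
    ens <- sim_quiet(gt, trial_spec(60), seed = 700 + r)
    dm <- build_design(bin_spikes(ens), sch2(), 2)
    f <- fit_penalized(dm)
    est <- f$alpha_hat["c1.w1"]
    se <- sqrt(f$Sigma["c1.w1", "c1.w1"])
    hits <- hits + (abs(est - 0.5) <= 1.96 * se)
  }
  expect_gte(hits, 8L)   # nominal ~9.5/10
})
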