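# Two-condition fixture with a sign-reversed, lag-decaying 1 -> 2 coupling.
reversal_ensemble <- function(seed = 99, n_per = 20) {
  gt_s <- make_ground_truth(1, 1, sch3(), density = 0, seed = 11)
  gt_u <- set_coupling(gt_s, 2, 1, coef = c(-1.2, -0.8, -0.4))
  gt_s <- set_coupling(gt_s, 2, 1, coef = c(1.2, 0.8, 0.4))
  spec <- trial_spec(2 * n_per,
                     outcomes = rep(c("successful", "unsuccessful"),
                                    each = n_per))
  list(ens = make_condition_pair(gt_s, gt_u, spec, seed = seed),
       gt_s = gt_s, gt_u = gt_u, spec = spec)
}

test_that("split-half refits track the full-sample coefficient traces", {
  fx <- reversal_ensemble()
  sh <- split_half_check(fx$ens, c(1, 2), n_runs = 8, seed = 5,
                         scheme = sch3())
  expect_gt(sh$correlation$pooled, 0.7)
  # mean half-sample traces carry the planted signs in the strong windows
  expect_true(all(sh$mean$successful[1:2] > 0))
  expect_true(all(sh$mean$unsuccessful[1:2] < 0))
  # single run: SEM undefined and reported absent
  sh1 <- split_half_check(fx$ens, c(1, 2), n_runs = 1, seed = 6,
                          scheme = sch3())
  expect_true(all(is.na(sh1$sem$successful)))
  # too few trials rejected
  few <- subset_trials(fx$ens, c(1, 2, 21, 22))
  expect_error(split_half_check(few, c(1, 2), scheme = sch3()),
               "invalid-argument")
})

test_that("label shuffles null out the planted condition difference", {
  fx <- reversal_ensemble()
  sf <- shuffle_label_check(fx$ens, c(1, 2), n_runs = 30, seed = 7,
                            scheme = sch3())
  K <- sch3()$K
  z_sim <- stats::qnorm(1 - 0.025 / K)   # simultaneous band across windows
  expect_true(all(abs(sf$mean$difference) <= z_sim * sf$sem$difference))
  # the unshuffled difference escapes the shuffle null in the strong windows
  sh <- split_half_check(fx$ens, c(1, 2), n_runs = 1, seed = 8,
                         scheme = sch3())
  d_full <- sh$full$successful$est - sh$full$unsuccessful$est
  null_sd <- sf$sem$difference * sqrt(sf$n_runs)
  expect_gt(max(abs(d_full - sf$mean$difference) / null_sd), 1.96)
  # reproducible from the master seed
  sf2 <- shuffle_label_check(fx$ens, c(1, 2), n_runs = 30, seed = 7,
                             scheme = sch3())
  expect_identical(sf$mean, sf2$mean)
})

test_that("identical generators produce no systematic condition difference", {
  gt <- make_ground_truth(1, 1, sch3(), density = 0, seed = 11)
  gt <- set_coupling(gt, 2, 1, coef = c(0.8, 0.5, 0.3))
  spec <- trial_spec(40, outcomes = rep(c("successful", "unsuccessful"),
                                        each = 20))
  ens <- make_condition_pair(gt, gt, spec, seed = 31)
  sh <- split_half_check(ens, c(1, 2), n_runs = 1, seed = 32,
                         scheme = sch3())
  d <- sh$full$successful$est - sh$full$unsuccessful$est
  se_s <- (sh$full$successful$hi - sh$full$successful$est) / 1.96
  se_u <- (sh$full$unsuccessful$hi - sh$full$unsuccessful$est) / 1.96
  z_sim <- stats::qnorm(1 - 0.025 / sch3()$K)
  expect_true(all(abs(d) <= z_sim * sqrt(se_s^2 + se_u^2)))
})

test_that("shuffle balance warns when an exact equal mixture is impossible", {
  fx <- reversal_ensemble(n_per = 21)   # odd group sizes
  expect_warning(
    shuffle_label_check(fx$ens, c(1, 2), n_runs = 2, seed = 9,
                        scheme = sch3()),
    "nearest balanced")
  one_sided <- subset_trials(fx$ens, "successful")
  expect_error(shuffle_label_check(one_sided, c(1, 2), scheme = sch3()),
               "invalid-argument")
})

test_that("trace tables expose per-window run aggregates", {
  fx <- reversal_ensemble(n_per = 4)
  sh <- split_half_check(fx$ens, c(1, 2), n_runs = 2, seed = 12,
                         scheme = sch3())
  tab <- trace_table(sh)
  expect_setequal(unique(tab$kind), c("full", "half_mean"))
  expect_equal(nrow(tab), 2 * 2 * sch3()$K)
  sf <- shuffle_label_check(fx$ens, c(1, 2), n_runs = 2, seed = 13,
                            scheme = sch3())
  tab2 <- trace_table(sf)
  expect_true("difference" %in% tab2$condition)
})
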