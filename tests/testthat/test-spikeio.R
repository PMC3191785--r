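test_that("spike-text round trip is lossless at microsecond precision", {
  gt <- make_ground_truth(2, 1, sch3(), density = 0.4, seed = 7)
  ens <- sim_quiet(gt, trial_spec(6, outcomes = c("successful",
                                                  "unsuccessful")))
  path <- withr::local_tempfile(fileext = ".spikes")
  write_ensemble(ens, path)
  ens2 <- read_ensemble(path)
  expect_equal(n_cells(ens2), 3)
  expect_equal(n_trials(ens2), 6)
  expect_identical(trial_outcomes(ens2), trial_outcomes(ens))
  for (j in seq_len(n_trials(ens)))
    expect_equal(ens2$trials[[j]]$spikes, ens$trials[[j]]$spikes,
                 tolerance = 1e-9)
  expect_equal(ens2$cells$baseline_rate, ens$cells$baseline_rate)
  expect_equal(ens2$trials[[1]]$epochs$reaching, c(1.5, 3))
})

test_that("readers reject malformed rows and boundary violations", {
  ens <- make_ens(list(list(c(0.5, 1.2), numeric(0))), n_cells = 2)
  path <- withr::local_tempfile(fileext = ".spikes")
  write_ensemble(ens, path)
  # CRLF tolerated
  txt <- readLines(path)
  writeLines(txt, path, sep = "\r\n")
  expect_silent(read_ensemble(path))
  # malformed row reported with its line number
  writeLines(c(txt, "1\t2"), path)
  expect_error(read_ensemble(path), "line 6")
  # spike at t == trial_length violates the half-open trial interval
  writeLines(c(txt, "1\t2\t3.000000"), path)
  expect_error(read_ensemble(path), "\\[0, 3\\)")
  expect_error(make_ens(list(list(3.0, numeric(0))), n_cells = 2),
               "\\[0, 3\\)")
})

test_that("binning saturates multi-spike bins and reports collisions", {
  ens <- make_ens(list(list(c(0.001, 0.0019), numeric(0))), n_cells = 2)
  b <- bin_spikes(ens)
  expect_equal(b$trials[[1]][2, 1], 1L)    # both spikes in bin [1, 2) ms
  expect_equal(sum(b$trials[[1]][, 1]), 1L)
  expect_equal(b$collisions, 1L)
  # empty cell: all-zero indicator of the epoch length
  expect_equal(sum(b$trials[[1]][, 2]), 0L)
  expect_equal(nrow(b$trials[[1]]), 3000)
  b_re <- bin_spikes(ens, "reaching")
  expect_equal(length(b_re$epoch_bins[[1]]), 1500)
})

test_that("indicator mean matches the Bernoulli rate (binomial oracle)", {
  gt <- make_ground_truth(1, 0, sch3(), density = 0, seed = 51)
  gt$baseline_log_rates <- log(20)
  ens <- sim_quiet(gt, trial_spec(20), seed = 52)
  b <- bin_spikes(ens)
  m <- mean(vapply(b$trials, function(B) mean(B[, 1]), 0.0))
  n <- 20 * 3000
  expect_lt(abs(m - 0.02), 3 * sqrt(0.02 * 0.98 / n))
})

test_that("baseline rates are total spikes over total time", {
  ens <- make_ens(list(list(seq(0.05, 2.95, length.out = 30))), n_cells = 1)
  expect_equal(unname(baseline_rates(ens)), 10)
  # simulated RS/FS regimes recover the published population means
  gt_rs <- make_ground_truth(12, 0, sch3(), density = 0, seed = 61)
  r_rs <- baseline_rates(sim_quiet(gt_rs, trial_spec(20), seed = 62))
  expect_lt(abs(mean(r_rs) - 8.5), 3 * 3.6 / sqrt(12) + 0.5)
  gt_fs <- make_ground_truth(0, 12, sch3(), density = 0, seed = 63)
  r_fs <- baseline_rates(sim_quiet(gt_fs, trial_spec(20), seed = 64))
  expect_lt(abs(mean(r_fs) - 22.7), 3 * 9.6 / sqrt(12) + 0.5)
})

test_that("RS/FS classification follows rate and spike width", {
  expect_equal(classify_cell_types(c(8, 25), c(0.9, 0.4)), c("RS", "FS"))
  # degenerate input: identical cells all resolve to RS
  expect_equal(classify_cell_types(rep(10, 4), rep(0.6, 4)), rep("RS", 4))
  # lone cell classified by nearest regime centroid, with a warning
  expect_warning(lab <- classify_cell_types(24, 0.38), "single cell")
  expect_equal(lab, "FS")
  # generator-label oracle: well-separated clusters recovered exactly
  agree <- 0L
  for (r in 1:50) {
    set.seed(200 + r)
    n_rs <- 6; n_fs <- 4
    rate <- c(rnorm(n_rs, 8.5, 1.5), rnorm(n_fs, 22.7, 2.5))
    dur <- c(rnorm(n_rs, 0.9, 0.05), rnorm(n_fs, 0.4, 0.05))
    truth <- rep(c("RS", "FS"), c(n_rs, n_fs))
    perm <- sample(n_rs + n_fs)   # order must not matter
    lab <- classify_cell_types(rate[perm], dur[perm])
    agree <- agree + all(lab == truth[perm])
  }
  expect_equal(agree, 50L)
})

test_that("task-relatedness screening has power and honours alpha", {
  # constant-rate cell: few false positives over seeded simulations
  gt <- make_ground_truth(1, 0, sch3(), density = 0, seed = 71)
  gt$baseline_log_rates <- log(12)
  fp <- 0L
  for (r in 1:100) {
    ens <- sim_quiet(gt, trial_spec(20), seed = 300 + r)
    fp <- fp + screen_task_related(ens, alpha = 0.05)[1]
  }
  expect_lte(fp, 10L)
  # 3x reach-stage rate: detected
  set.seed(81)
  trials <- lapply(1:15, function(j) {
    bg <- sort(runif(rpois(1, 5 * 1.5), 0, 1.5))
    re <- sort(runif(rpois(1, 15 * 1.5), 1.5, 3))
    list(c(bg, re))
  })
  ens3 <- make_ens(trials, n_cells = 1)
  expect_true(screen_task_related(ens3, alpha = 0.05)[1])
  # alpha = 1 declares everything task-related
  expect_true(all(screen_task_related(ens3, alpha = 1)))
  expect_error(screen_task_related(ens3, stages = c("reaching")), "background")
})
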