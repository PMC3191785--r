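test_that("Wald edge calls follow the confidence-interval rule", {
  K <- 3; C <- 2; sch <- sch3()
  # all CIs straddle zero: empty graph
  est0 <- lapply(1:C, function(i) c(log(10), rep(0.05, C * K)))
  se0 <- lapply(1:C, function(i) c(0.01, rep(0.1, C * K)))
  g0 <- significant_edges(fake_efit(est0, se0, C, K, sch))
  expect_equal(nrow(g0$edges), 0)
  expect_equal(mean_ei_ratio(g0), 0)
  # one forced edge: est 0.5, sd 0.1 -> CI approx [0.304, 0.696]
  est1 <- est0
  est1[[2]][1 + 1] <- 0.5   # source 1, window 1, target 2
  g1 <- significant_edges(fake_efit(est1, se0, C, K, sch))
  expect_equal(nrow(g1$edges), 1)
  expect_equal(g1$edges$source, 1)
  expect_equal(g1$edges$target, 2)
  expect_equal(g1$edges$sign, "E")
  expect_equal(g1$edges$lo, 0.304, tolerance = 1e-3)
  expect_equal(g1$edges$hi, 0.696, tolerance = 1e-3)
  # Bonferroni across lags is stricter
  gb <- significant_edges(fake_efit(est1, se0, C, K, sch), bonferroni = TRUE)
  expect_equal(nrow(gb$edges), 1)   # 0.5/0.1 survives even the corrected level
  est1[[2]][1 + 1] <- 0.21
  expect_equal(nrow(significant_edges(fake_efit(est1, se0, C, K, sch))$edges), 1)
  expect_equal(nrow(significant_edges(fake_efit(est1, se0, C, K, sch),
                                      bonferroni = TRUE)$edges), 0)
})

test_that("mean E+I ratio normalizes over lags and ordered pairs", {
  K <- 2; C <- 3; sch <- sch2()
  # every off-diagonal coefficient significant at every lag -> ratio 1
  est <- lapply(1:C, function(c_i) {
    v <- c(log(10), rep(1, C * K))
    v[1 + ((c_i - 1) * K + 1):((c_i - 1) * K + K)] <- 0   # mute self
    v
  })
  se <- lapply(1:C, function(i) c(0.01, rep(0.05, C * K)))
  g <- significant_edges(fake_efit(est, se, C, K, sch))
  expect_equal(mean_ei_ratio(g), 1)
  # invariant to relabelling the cells (permute targets and source blocks)
  perm <- c(2, 3, 1)
  est_p <- se_p <- vector("list", C)
  for (tgt in 1:C) {
    v <- c(est[[tgt]][1], rep(NA_real_, C * K))
    w <- c(se[[tgt]][1], rep(NA_real_, C * K))
    for (src in 1:C) {
      to <- 1 + (perm[src] - 1) * K + seq_len(K)
      from <- 1 + (src - 1) * K + seq_len(K)
      v[to] <- est[[tgt]][from]
      w[to] <- se[[tgt]][from]
    }
    est_p[[perm[tgt]]] <- v
    se_p[[perm[tgt]]] <- w
  }
  g_perm <- significant_edges(fake_efit(est_p, se_p, C, K, sch))
  expect_equal(mean_ei_ratio(g_perm), mean_ei_ratio(g))
  # C < 2 rejected
  g1 <- significant_edges(fake_efit(list(c(log(5), 1)), list(c(0.1, 0.1)),
                                    1, 1, window_scheme(list(c(1, 3)))))
  expect_error(mean_ei_ratio(g1), "2 cells")
})

test_that("E:I balance counts significant signs", {
  K <- 1; C <- 5; sch <- window_scheme(list(c(1, 3)))
  # plant 10 excitatory and 9 inhibitory off-diagonal coefficients
  est <- lapply(1:C, function(i) c(log(10), rep(0, C)))
  slots <- setdiff(seq_len(C * C), seq(1, C * C, by = C + 1))  # off-diag
  for (i in seq_along(slots)) {
    tgt <- (slots[i] - 1) %/% C + 1
    src <- (slots[i] - 1) %% C + 1
    if (i <= 19) est[[tgt]][1 + src] <- if (i <= 10) 1 else -1
  }
  se <- lapply(1:C, function(i) c(0.01, rep(0.05, C)))
  g <- significant_edges(fake_efit(est, se, C, K, sch))
  expect_equal(sum(g$edges$sign == "E"), 10)
  expect_equal(sum(g$edges$sign == "I"), 9)
  expect_equal(ei_balance(g), 10 / 9)   # 1.11
  # equal counts give exactly 1; no inhibition flags infinity
  g_eq <- g; g_eq$edges <- g$edges[c(1:9, 11:19), ]
  expect_equal(ei_balance(g_eq), 1)
  g_e <- g; g_e$edges <- g$edges[g$edges$sign == "E", ]
  expect_warning(b <- ei_balance(g_e), "infinite")
  expect_identical(b, Inf)
})

test_that("group fractions use the squared-count denominators", {
  K <- 1; sch <- window_scheme(list(c(1, 3)))
  # 8 RS + 5 FS: denominators 64 / 80 / 25 as in dataset 1
  C <- 13
  est <- lapply(1:C, function(i) c(log(10), rep(0, C)))
  est[[2]][1 + 1] <- 1     # RS(1) -> RS(2)
  est[[9]][1 + 1] <- 1     # RS(1) -> FS(9)
  est[[9]][1 + 9] <- -1    # FS self pair counts in FS-FS
  se <- lapply(1:C, function(i) c(0.01, rep(0.05, C)))
  types <- rep(c("RS", "FS"), c(8, 5))
  g <- significant_edges(fake_efit(est, se, C, K, sch, cell_types = types))
  gf <- group_fractions(g)
  expect_equal(unname(gf$denominators), c(64, 80, 25))
  expect_equal(unname(gf$counts), c(1, 1, 1))
  expect_equal(unname(gf$fractions), c(1 / 64, 1 / 80, 1 / 25))
  expect_equal(sum(gf$counts), gf$n_significant_pairs)
  expect_equal(sum(gf$denominators), C^2)
  # 6 RS + 6 FS: dataset-8 denominators
  C2 <- 12
  est2 <- lapply(1:C2, function(i) c(log(10), rep(0, C2)))
  se2 <- lapply(1:C2, function(i) c(0.01, rep(0.05, C2)))
  g2 <- significant_edges(fake_efit(est2, se2, C2, K, sch,
                                    cell_types = rep(c("RS", "FS"), each = 6)))
  gf2 <- group_fractions(g2)
  expect_equal(unname(gf2$denominators), c(36, 72, 36))
  expect_equal(unname(gf2$fractions), c(0, 0, 0))
  expect_error(group_fractions(g2, rep("RS", 5)), "typed")
})

test_that("strong planted couplings are recovered with high precision/recall", {
  prec <- rec <- numeric(0)
  for (r in 1:3) {
    gt <- make_ground_truth(2, 2, sch3(), density = 0.4, coupling_scale = 0.5,
                            seed = 40 + r)
    ens <- sim_quiet(gt, trial_spec(80), seed = 50 + r)
    ef <- fit_ensemble(bin_spikes(ens), sch3())
    e <- significant_edges(ef)$edges
    e <- e[!e$self, ]
    truth <- gt$coupling[gt$coupling$source != gt$coupling$target, ]
    key <- function(d) paste(d$source, d$target, d$window)
    tp <- sum(key(e) %in% key(truth))
    prec <- c(prec, if (nrow(e)) tp / nrow(e) else 1)
    rec <- c(rec, if (nrow(truth)) tp / nrow(truth) else 1)
  }
  expect_gte(mean(prec), 0.9)
  expect_gte(mean(rec), 0.9)
})

test_that("condition comparison tests behave under null and alternative", {
  # identical paired vectors: no rejection
  x <- c(0.2, 0.4, 0.3, 0.5)
  expect_gte(compare_conditions(x, x)$p.value, 0.05)
  expect_error(compare_conditions(x, x[1:3]), "equal-length")
  # denser condition detected across synthetic datasets
  set.seed(61)
  a <- pmin(pmax(rnorm(20, 0.2, 0.05), 0), 1)
  b <- pmin(pmax(rnorm(20, 0.5, 0.05), 0), 1)
  expect_lt(compare_conditions(a, b)$p.value, 0.05)
  # ANOVA: planted period effect, null outcome effect
  set.seed(62)
  df <- expand.grid(dataset = 1:8,
                    cell_group = c("rs_rs", "rs_fs", "fs_fs"),
                    outcome = c("succ", "unsucc"),
                    period = c("background", "reaching"))
  df$fraction <- 0.3 + 0.25 * (df$period == "reaching") +
    rnorm(nrow(df), 0, 0.05)
  tab <- anova_connectivity(df)[[1]]
  p <- tab[["Pr(>F)"]]
  names(p) <- rownames(tab)
  expect_lt(p[grep("period", names(p))], 0.05)
  expect_gt(p[grep("outcome", names(p))], 0.05)
})

test_that("graphs export to GraphML and DOT with edge attributes", {
  K <- 1; C <- 3; sch <- window_scheme(list(c(1, 3)))
  est <- lapply(1:C, function(i) c(log(10), rep(0, C)))
  est[[2]][1 + 1] <- 1; est[[3]][1 + 1] <- -1
  se <- lapply(1:C, function(i) c(0.01, rep(0.05, C)))
  g <- significant_edges(fake_efit(est, se, C, K, sch))
  p1 <- withr::local_tempfile(fileext = ".graphml")
  p2 <- withr::local_tempfile(fileext = ".dot")
  write_connectivity_graph(g, p1, "graphml")
  write_connectivity_graph(g, p2, "dot")
  expect_true(file.size(p1) > 0 && file.size(p2) > 0)
  ig <- igraph::read_graph(p1, format = "graphml")
  expect_equal(igraph::ecount(ig), 2)
  expect_setequal(igraph::E(ig)$sign, c("E", "I"))
})
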