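# Orchestration: simulate -> fit -> assess -> connect -> control from one
# declarative config, with logging and deterministic seed fan-out.

.config_keys <- c("out_dir", "seed", "delta_ms", "scheme", "dataset_id",
                  "candidates", "rho", "rho_grid", "cv_folds", "Q_kind",
                  "level", "epochs", "outcomes", "simulate", "input",
                  "controls", "dataset_label")

.simulate_keys <- c("n_rs", "n_fs", "density", "ei_balance",
                    "coupling_scale", "self_coupling", "n_trials", "n_succ",
                    "trial_length_s", "trigger_time_s")

.controls_keys <- c("pair", "split_runs", "shuffle_runs", "restrict_to_pair")

#' Validate a pipeline run configuration
#'
#' A run config is a named list (or a YAML file parsed into one) that fully
#' determines a pipeline run.  Recognized keys: `out_dir`, `seed`,
#' `delta_ms` (default 1), one of `scheme` (list of `(lo, hi)` ms ranges) /
#' `dataset_id` (use that dataset's published scheme) / `candidates`
#' (schemes for per-run BIC selection), `rho` (number or `"cv"`),
#' `rho_grid`, `cv_folds`, `Q_kind`, `level` (default 0.95), `epochs`
#' (default background + reaching), `outcomes` (default both), exactly one
#' of `simulate` (block with `n_rs`, `n_fs`, `density`, `ei_balance`,
#' `coupling_scale`, `self_coupling`, `n_trials`, `n_succ`,
#' `trial_length_s`, `trigger_time_s`) or `input` (spike-text path), an
#' optional `controls` block (`pair`, `split_runs`, `shuffle_runs`,
#' `restrict_to_pair`), and an optional `dataset_label`.  Unknown keys are
#' errors, not warnings.
#'
#' @param config named list, or path to a YAML file.
#' @return The validated config with defaults filled in, class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (inherits(config, "run_config")) return(config)
  if (!is.list(config)) stop("config must be a named list or a YAML path",
                             call. = FALSE)
  unknown <- setdiff(names(config), .config_keys)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(config$out_dir)) stop("config needs out_dir", call. = FALSE)
  if (is.null(config$seed)) stop("config needs an integer seed", call. = FALSE)
  config$seed <- as.integer(config$seed)
  config$delta_ms <- config$delta_ms %||% 1
  config$level <- config$level %||% 0.95
  config$rho <- config$rho %||% 0
  config$Q_kind <- config$Q_kind %||% "ridge"
  config$epochs <- config$epochs %||% c("background", "reaching")
  config$outcomes <- config$outcomes %||% c("successful", "unsuccessful")
  config$dataset_label <- config$dataset_label %||% "dataset"
  has_sim <- !is.null(config$simulate); has_inp <- !is.null(config$input)
  if (has_sim == has_inp)
    stop("config needs exactly one of 'simulate' or 'input'", call. = FALSE)
  if (has_sim) {
    unknown <- setdiff(names(config$simulate), .simulate_keys)
    if (length(unknown))
      stop("unknown simulate keys: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    s <- config$simulate
    s$density <- s$density %||% 0.15
    s$ei_balance <- s$ei_balance %||% 1.11
    s$coupling_scale <- s$coupling_scale %||% 0.5
    s$self_coupling <- s$self_coupling %||% 0
    s$trial_length_s <- s$trial_length_s %||% 3
    s$trigger_time_s <- s$trigger_time_s %||% 1.5
    if (is.null(s$n_trials) || s$n_trials < 1)
      stop("simulate block needs n_trials >= 1", call. = FALSE)
    s$n_succ <- s$n_succ %||% ceiling(s$n_trials / 2)
    if (is.null(s$n_rs) || is.null(s$n_fs))
      stop("simulate block needs n_rs and n_fs", call. = FALSE)
    config$simulate <- s
  }
  if (!is.null(config$controls)) {
    unknown <- setdiff(names(config$controls), .controls_keys)
    if (length(unknown))
      stop("unknown controls keys: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    ct <- config$controls
    if (is.null(ct$pair) || length(ct$pair) != 2)
      stop("controls block needs pair = c(source, target)", call. = FALSE)
    ct$split_runs <- ct$split_runs %||% 20
    ct$shuffle_runs <- ct$shuffle_runs %||% 100
    ct$restrict_to_pair <- ct$restrict_to_pair %||% FALSE
    config$controls <- ct
  }
  # scheme resolution
  if (!is.null(config$dataset_id)) {
    config$scheme <- dataset_scheme(config$dataset_id)
  } else if (!is.null(config$scheme) && !inherits(config$scheme, "window_scheme")) {
    config$scheme <- window_scheme(config$scheme)
  }
  if (!is.null(config$candidates))
    config$candidates <- lapply(config$candidates, function(s)
      if (inherits(s, "window_scheme")) s else window_scheme(s))
  if (is.null(config$scheme) && is.null(config$candidates))
    stop("config needs a scheme, a dataset_id, or candidate schemes",
         call. = FALSE)
  structure(config, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable fingerprint of a config: md5 of its canonical JSON serialization.
config_fingerprint <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  plain <- rapply(unclass(config), unclass, how = "replace")
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full connectivity pipeline from a config
#'
#' Executes, per behavioural condition (epoch x outcome), the four-step
#' analysis: (i) model fitting by penalized maximum likelihood (with
#' optional BIC scheme selection and cross-validated `rho`), (ii)
#' determination of significant GLM coefficients by Wald intervals, (iii)
#' repetition across conditions, and (iv) summary statistics ready for
#' between-condition tests.  Emits, under `out_dir`: the ensemble in
#' spike-text form (plus a ground-truth JSON sidecar when simulated),
#' per-condition fit and goodness-of-fit JSON, GraphML and DOT graphs, a
#' condition summary CSV, control trace CSVs when requested, and a run log
#' recording package version, seeds, resolved defaults and the config
#' fingerprint.
#'
#' @param config a [run_config()], a named list, or a YAML path.
#' @return A report list (config, per-condition summaries, file paths),
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  config <- run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    writeLines(msg, log_con)
    message(msg)
  }
  say("spikeglm %s | seed %d | config %s",
      as.character(utils::packageVersion("spikeglm")), config$seed,
      config_fingerprint(config))
  say("resolved config: %s",
      jsonlite::toJSON(rapply(unclass(config), unclass, how = "replace"),
                       auto_unbox = TRUE, force = TRUE))
  delta_s <- config$delta_ms * 1e-3

  # --- data: simulate or read -------------------------------------------
  if (!is.null(config$simulate)) {
    s <- config$simulate
    scheme_for_sim <- config$scheme %||% config$candidates[[1]]
    gt <- make_ground_truth(s$n_rs, s$n_fs, scheme_for_sim,
                            density = s$density, ei_balance = s$ei_balance,
                            coupling_scale = s$coupling_scale,
                            self_coupling = s$self_coupling,
                            seed = config$seed + 1L)
    spec <- trial_spec(s$n_trials, s$trial_length_s, s$trigger_time_s,
                       outcomes = rep(c("successful", "unsuccessful"),
                                      c(s$n_succ, s$n_trials - s$n_succ)),
                       bin_width_s = delta_s)
    ens <- simulate_ensemble(gt, spec, seed = config$seed + 2L)
    write_ground_truth(gt, file.path(config$out_dir, "ground_truth.json"))
    say("simulated %d trials x %d cells", n_trials(ens), n_cells(ens))
  } else {
    ens <- read_ensemble(config$input)
    say("read %s: %d trials x %d cells", config$input, n_trials(ens),
        n_cells(ens))
  }
  ens_path <- file.path(config$out_dir, "ensemble.spikes")
  write_ensemble(ens, ens_path)

  # --- per-condition fits ------------------------------------------------
  conditions <- expand.grid(epoch = config$epochs, outcome = config$outcomes,
                            stringsAsFactors = FALSE)
  summaries <- list()
  paths <- list(ensemble = ens_path, log = log_path)
  for (ci in seq_len(nrow(conditions))) {
    ep <- conditions$epoch[ci]; oc <- conditions$outcome[ci]
    label <- sprintf("%s_%s", ep, oc)
    keep <- trial_outcomes(ens) == oc
    if (!any(keep)) stop("no trials with outcome ", oc, call. = FALSE)
    binned <- bin_spikes(subset_trials(ens, keep), ep, delta_s)
    scheme <- config$scheme
    if (is.null(scheme)) {
      sel <- select_windows(binned, config$candidates, target_cell = 1,
                            rho = if (identical(config$rho, "cv")) 0 else config$rho,
                            Q_kind = config$Q_kind)
      scheme <- sel$scheme
      say("[%s] BIC selected scheme with K = %d", label, scheme$K)
    }
    efit <- fit_ensemble(binned, scheme, rho = config$rho,
                         rho_grid = config$rho_grid %||%
                           10^seq(-4, 2, length.out = 8),
                         folds = config$cv_folds, Q_kind = config$Q_kind,
                         condition = label)
    fit_path <- file.path(config$out_dir, sprintf("fits_%s.json", label))
    write_ensemble_fit(efit, fit_path)
    gofs <- lapply(seq_len(efit$C), function(c_i) {
      dm <- build_design(binned, scheme, c_i)
      gof_report(efit$fits[[c_i]], dm)
    })
    gof_path <- file.path(config$out_dir, sprintf("gof_%s.json", label))
    jsonlite::write_json(lapply(gofs, function(g)
      list(target_cell = g$target_cell, ks_statistic = g$ks_statistic,
           band_95 = g$band_95, band_90 = g$band_90,
           n_intervals = g$n_intervals)),
      gof_path, auto_unbox = TRUE, digits = NA)
    g <- significant_edges(efit, level = config$level)
    graph_path <- file.path(config$out_dir, sprintf("graph_%s.graphml", label))
    dot_path <- file.path(config$out_dir, sprintf("graph_%s.dot", label))
    if (nrow(g$edges[!g$edges$self, ])) {
      write_connectivity_graph(g, graph_path, "graphml")
      write_connectivity_graph(g, dot_path, "dot")
    }
    typed <- all(binned$cells$putative_type %in% c("RS", "FS"))
    sm <- connectivity_summary(g, if (typed) binned$cells$putative_type
                               else NULL)
    summaries[[label]] <- sm
    say("[%s] %d cells fitted; KS 95%% pass %d/%d; mean E+I ratio %.3f",
        label, efit$C, sum(vapply(gofs, `[[`, NA, "band_95"), na.rm = TRUE),
        efit$C, sm$mean_ei_ratio)
    paths[[label]] <- c(fits = fit_path, gof = gof_path)
  }

  # --- condition summary table ------------------------------------------
  sum_rows <- do.call(rbind, lapply(names(summaries), function(lbl) {
    sm <- summaries[[lbl]]
    gf <- sm$group_fractions
    data.frame(dataset = config$dataset_label, condition = lbl,
               mean_ei_ratio = sm$mean_ei_ratio,
               ei_balance = sm$ei_balance,
               n_excitatory = sm$n_excitatory,
               n_inhibitory = sm$n_inhibitory,
               frac_rs_rs = if (is.null(gf)) NA else gf$fractions[["rs_rs"]],
               frac_rs_fs = if (is.null(gf)) NA else gf$fractions[["rs_fs"]],
               frac_fs_fs = if (is.null(gf)) NA else gf$fractions[["fs_fs"]])
  }))
  summary_path <- file.path(config$out_dir, "summary.csv")
  utils::write.csv(format(sum_rows, digits = 15), summary_path,
                   row.names = FALSE)
  paths$summary <- summary_path

  # --- controls ----------------------------------------------------------
  if (!is.null(config$controls)) {
    ct <- config$controls
    scheme <- config$scheme %||% config$candidates[[1]]
    sh <- split_half_check(ens, ct$pair, n_runs = ct$split_runs,
                           seed = config$seed + 3L, scheme = scheme,
                           rho = if (identical(config$rho, "cv")) 0 else config$rho,
                           restrict_to_pair = ct$restrict_to_pair)
    utils::write.csv(trace_table(sh),
                     file.path(config$out_dir, "controls_split.csv"),
                     row.names = FALSE)
    sf <- shuffle_label_check(ens, ct$pair, n_runs = ct$shuffle_runs,
                              seed = config$seed + 4L, scheme = scheme,
                              rho = if (identical(config$rho, "cv")) 0 else config$rho,
                              restrict_to_pair = ct$restrict_to_pair)
    utils::write.csv(trace_table(sf),
                     file.path(config$out_dir, "controls_shuffle.csv"),
                     row.names = FALSE)
    say("controls: split-half pooled correlation %.3f; shuffle covers zero %d/%d windows",
        sh$correlation$pooled, sum(sf$covers_zero), length(sf$covers_zero))
    paths$controls <- c(split = file.path(config$out_dir, "controls_split.csv"),
                        shuffle = file.path(config$out_dir, "controls_shuffle.csv"))
  }
  say("done")
  invisible(list(config = config, summaries = summaries, paths = paths))
}

#' Aggregate per-run summaries into one study-level table
#'
#' Reads the `summary.csv` of several pipeline runs (one per dataset) and
#' binds them into a single table shaped like the study's per-dataset
#' connectivity summary: one row per (dataset, condition) with the mean E+I
#' ratio and the RS-RS / RS-FS / FS-FS interaction fractions.
#'
#' @param summary_paths character vector of `summary.csv` paths.
#' @param out optional output CSV path.
#' @return The combined data.frame (invisibly if `out` is given).
#' @export
aggregate_summaries <- function(summary_paths, out = NULL) {
  missing <- summary_paths[!file.exists(summary_paths)]
  if (length(missing))
    stop("missing summary file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  combined <- do.call(rbind, lapply(summary_paths, utils::read.csv))
  if (!is.null(out)) {
    utils::write.csv(combined, out, row.names = FALSE)
    return(invisible(combined))
  }
  combined
}
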