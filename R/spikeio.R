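#' Multi-trial ensemble spike-train container
#'
#' A `spike_ensemble` holds per-trial, per-cell spike time stamps for `C`
#' simultaneously recorded cells, together with trial epoch boundaries,
#' trial outcome labels and per-cell metadata.  It is the raw material of
#' every downstream stage: binning, GLM design, fitting, and connectivity.
#'
#' Times are seconds, zero-based within each trial, and must lie strictly
#' inside `[0, trial_length_s)`; within each (trial, cell) they must be
#' strictly increasing.  Trials are treated as independent realizations.
#'
#' @param trials a list; each element is a list with fields `outcome`
#'   (one of `"successful"`, `"unsuccessful"`, `"control"`), `epochs`
#'   (named list of `c(start, end)` second intervals), and `spikes`
#'   (list of length `C` of sorted numeric spike-time vectors).
#' @param cells a data.frame of per-cell metadata with at least `cell_id`;
#'   optional columns `putative_type` (`"RS"`, `"FS"`, `"unknown"`),
#'   `baseline_rate` (spikes/s), `spike_duration` (ms, trough-to-trough),
#'   `region_tag`.
#' @param trial_length_s trial duration in seconds.
#' @param bin_width_s default discretization bin width Delta (seconds).
#' @return An object of class `spike_ensemble`.
#' @export
spike_ensemble <- function(trials, cells, trial_length_s = 3,
                           bin_width_s = 0.001) {
  cells <- as.data.frame(cells)
  if (is.null(cells$cell_id)) cells$cell_id <- seq_len(nrow(cells))
  if (is.null(cells$putative_type)) cells$putative_type <- "unknown"
  if (is.null(cells$baseline_rate)) cells$baseline_rate <- NA_real_
  if (is.null(cells$spike_duration)) cells$spike_duration <- NA_real_
  if (is.null(cells$region_tag)) cells$region_tag <- NA_character_
  C <- nrow(cells)
  if (C < 1) stop("at least one cell is required", call. = FALSE)
  ok_outcomes <- c("successful", "unsuccessful", "control")
  for (j in seq_along(trials)) {
    tr <- trials[[j]]
    if (is.null(tr$outcome) || !tr$outcome %in% ok_outcomes)
      stop(sprintf("trial %d: outcome label must be one of %s", j,
                   paste(ok_outcomes, collapse = "/")), call. = FALSE)
    if (is.null(tr$epochs) || is.null(names(tr$epochs)))
      stop(sprintf("trial %d: named epoch boundaries are required", j),
           call. = FALSE)
    .validate_epochs(tr$epochs, trial_length_s, j)
    if (length(tr$spikes) != C)
      stop(sprintf("trial %d: expected spike lists for %d cells", j, C),
           call. = FALSE)
    for (c_i in seq_len(C)) {
      st <- tr$spikes[[c_i]]
      if (length(st)) {
        if (any(st < 0) || any(st >= trial_length_s))
          stop(sprintf("trial %d, cell %d: spike times must lie in [0, %g)",
                       j, c_i, trial_length_s), call. = FALSE)
        if (any(diff(st) <= 0))
          stop(sprintf("trial %d, cell %d: spike times must be strictly increasing",
                       j, c_i), call. = FALSE)
      }
    }
    if (is.null(tr$trial_id)) trials[[j]]$trial_id <- j
  }
  structure(list(cells = cells, trials = trials,
                 trial_length_s = trial_length_s, bin_width_s = bin_width_s),
            class = "spike_ensemble")
}

.validate_epochs <- function(epochs, trial_length_s, trial_idx) {
  b <- do.call(rbind, lapply(epochs, as.numeric))
  if (ncol(b) != 2 || any(b[, 1] >= b[, 2]))
    stop(sprintf("trial %d: epochs must be (start < end) intervals", trial_idx),
         call. = FALSE)
  if (any(b[, 1] < 0) || any(b[, 2] > trial_length_s))
    stop(sprintf("trial %d: epochs must lie within [0, %g]", trial_idx,
                 trial_length_s), call. = FALSE)
  o <- order(b[, 1])
  if (nrow(b) > 1 && any(b[o, 1][-1] < b[o, 2][-nrow(b)]))
    stop(sprintf("trial %d: epochs overlap", trial_idx), call. = FALSE)
  invisible(TRUE)
}

#' @export
print.spike_ensemble <- function(x, ...) {
  oc <- table(vapply(x$trials, `[[`, "", "outcome"))
  cat(sprintf("<spike_ensemble> %d cells, %d trials (%s), %g s trials, Delta = %g s\n",
              n_cells(x), n_trials(x),
              paste(sprintf("%d %s", oc, names(oc)), collapse = ", "),
              x$trial_length_s, x$bin_width_s))
  invisible(x)
}

#' Number of cells / trials in an ensemble
#' @param ens a [spike_ensemble()].
#' @return integer count.
#' @export
n_cells <- function(ens) nrow(ens$cells)

#' @rdname n_cells
#' @export
n_trials <- function(ens) length(ens$trials)

#' Outcome label of every trial
#' @param ens a [spike_ensemble()].
#' @return character vector of length `n_trials(ens)`.
#' @export
trial_outcomes <- function(ens) vapply(ens$trials, `[[`, "", "outcome")

#' Subset the trials of an ensemble
#'
#' @param ens a [spike_ensemble()].
#' @param idx integer/logical trial index, or an outcome label
#'   (`"successful"`/`"unsuccessful"`/`"control"`).
#' @return A [spike_ensemble()] with the selected trials, cells unchanged.
#' @export
subset_trials <- function(ens, idx) {
  if (is.character(idx)) idx <- trial_outcomes(ens) %in% idx
  out <- ens
  out$trials <- ens$trials[idx]
  if (!length(out$trials)) stop("trial subset is empty", call. = FALSE)
  out
}

# ---------------------------------------------------------------------------
# Spike-text I/O.  One row per spike (trial, cell, time_s) after a JSON
# metadata header carried on '#' comment lines.  Times are written at
# microsecond precision, matching the 40 us sampling of the acquisition
# hardware the format is meant to carry.

#' Write / read an ensemble in the spike-text format
#'
#' The format is a plain-text file: a first line `# spikeglm-spikes v1`,
#' a second line `# <JSON>` holding all metadata (cell table, per-trial
#' outcome labels and epoch boundaries, trial length, bin width), a
#' tab-separated header `trial\tcell\ttime_s`, then one row per spike.
#' Spike times are serialized at microsecond precision; the round trip is
#' lossless at that resolution.  Readers accept both LF and CRLF endings.
#'
#' @param ens a [spike_ensemble()].
#' @param path file path.
#' @return `read_ensemble` returns a [spike_ensemble()]; `write_ensemble`
#'   returns `path` invisibly.
#' @export
write_ensemble <- function(ens, path) {
  meta <- list(
    trial_length_s = ens$trial_length_s,
    bin_width_s = ens$bin_width_s,
    cells = as.list(ens$cells),   # column lists: stable JSON round trip
    trials = lapply(ens$trials, function(tr)
      list(trial_id = tr$trial_id, outcome = tr$outcome, epochs = tr$epochs))
  )
  rows <- character(0)
  for (j in seq_along(ens$trials)) {
    sp <- ens$trials[[j]]$spikes
    for (c_i in seq_along(sp)) {
      if (length(sp[[c_i]]))
        rows <- c(rows, sprintf("%d\t%d\t%.6f", j, c_i, sp[[c_i]]))
    }
  }
  con <- file(path, "wb")   # binary: stable LF endings on every platform
  on.exit(close(con))
  writeLines(c("# spikeglm-spikes v1",
               paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)),
               "trial\tcell\ttime_s", rows), con, sep = "\n")
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  if (length(lines) < 3 || !startsWith(lines[1], "# spikeglm-spikes"))
    stop("not a spikeglm spike-text file: ", path, call. = FALSE)
  meta <- jsonlite::fromJSON(sub("^# ", "", lines[2]), simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  meta$cells <- as.data.frame(lapply(meta$cells, unlist),
                              stringsAsFactors = FALSE)
  body <- lines[-(1:3)]
  body <- body[nzchar(body)]
  C <- nrow(meta$cells)
  n_tr <- length(meta$trials)
  spikes <- replicate(n_tr, replicate(C, numeric(0), simplify = FALSE),
                      simplify = FALSE)
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 3L)
    if (length(bad))
      stop(sprintf("malformed spike row at line %d of %s", bad[1] + 3L, path),
           call. = FALSE)
    m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 3, byrow = TRUE)
    if (anyNA(m))
      stop(sprintf("non-numeric spike row at line %d of %s",
                   which(rowSums(is.na(m)) > 0)[1] + 3L, path), call. = FALSE)
    if (any(m[, 1] < 1 | m[, 1] > n_tr | m[, 2] < 1 | m[, 2] > C))
      stop("spike row references an unknown trial or cell", call. = FALSE)
    for (r in seq_len(nrow(m)))
      spikes[[m[r, 1]]][[m[r, 2]]] <- c(spikes[[m[r, 1]]][[m[r, 2]]], m[r, 3])
  }
  trials <- vector("list", n_tr)
  for (j in seq_len(n_tr)) {
    tm <- meta$trials[[j]]
    trials[[j]] <- list(trial_id = tm$trial_id, outcome = tm$outcome,
                        epochs = lapply(tm$epochs, as.numeric),
                        spikes = spikes[[j]])
  }
  spike_ensemble(trials, cells = meta$cells,
                 trial_length_s = meta$trial_length_s,
                 bin_width_s = meta$bin_width_s)
}
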