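#' Spiking-history window schemes
#'
#' A window scheme partitions the recent firing history of every source cell
#' into `K` millisecond lag ranges.  The spike count of each cell inside each
#' range -- strictly before the current time bin -- is one covariate of the
#' point-process GLM, so a scheme with `K` windows over a `C`-cell ensemble
#' yields `C * K` history covariates per target cell (plus an intercept).
#'
#' Ranges are inclusive at both ends and expressed in whole milliseconds:
#' the range 1--3 means lags of 1, 2 and 3 bins at a 1 ms bin width.  Ranges
#' must be strictly increasing and non-overlapping; gaps are permitted.
#'
#' @param windows a list of length-2 numeric vectors `c(lo, hi)`, or a
#'   two-column matrix, giving inclusive lag ranges in ms.
#' @return An object of class `window_scheme`: a list with integer vectors
#'   `lo`, `hi` (ms) and the window count `K`.
#' @examples
#' window_scheme(list(c(1, 3), c(4, 6), c(7, 10)))
#' @export
window_scheme <- function(windows) {
  if (is.matrix(windows)) windows <- split(windows, row(windows))
  w <- do.call(rbind, lapply(windows, function(r) {
    if (length(r) != 2L) stop("each window must be a (lo, hi) pair", call. = FALSE)
    as.numeric(r)
  }))
  lo <- w[, 1]; hi <- w[, 2]
  if (any(lo != round(lo)) || any(hi != round(hi)))
    stop("window bounds must be whole milliseconds", call. = FALSE)
  if (any(lo < 1) || any(hi < lo))
    stop("windows must satisfy 1 <= lo <= hi", call. = FALSE)
  if (nrow(w) > 1 && any(lo[-1] <= hi[-nrow(w)]))
    stop("windows must be strictly increasing and non-overlapping", call. = FALSE)
  structure(list(lo = as.integer(lo), hi = as.integer(hi), K = nrow(w)),
            class = "window_scheme")
}

#' @export
print.window_scheme <- function(x, ...) {
  cat(sprintf("<window_scheme> K = %d: %s ms\n", x$K,
              paste(sprintf("%d~%d", x$lo, x$hi), collapse = ", ")))
  invisible(x)
}

#' @export
format.window_scheme <- function(x, ...) sprintf("%d~%d", x$lo, x$hi)

#' History-window schemes of the eight reference datasets
#'
#' Returns the BIC-selected history-window scheme used for each of the eight
#' ensemble recordings of the reference study design.  Datasets 1, 3, 4, 7
#' and 8 share a 9-window scheme reaching back 40 ms; dataset 2 extends it to
#' 50 ms (10 windows); datasets 5 and 6 use a finer 10-window tiling of the
#' 16--24 ms range.  Window widths grow with lag, reflecting the roughly
#' exponential decay of spiking dependence on preceding activity.
#'
#' @param dataset_id integer in 1..8.
#' @return A [window_scheme()].
#' @examples
#' dataset_scheme(1)   # 9 windows, up to 40 ms
#' @export
dataset_scheme <- function(dataset_id) {
  if (length(dataset_id) != 1L || !dataset_id %in% 1:8)
    stop("dataset_id must be a single integer in 1..8", call. = FALSE)
  base9 <- list(c(1, 3), c(4, 6), c(7, 9), c(10, 12), c(13, 15),
                c(16, 20), c(21, 25), c(26, 30), c(31, 40))
  fine10 <- list(c(1, 3), c(4, 6), c(7, 9), c(10, 12), c(13, 15),
                 c(16, 18), c(19, 21), c(22, 24), c(25, 30), c(31, 40))
  w <- switch(as.character(dataset_id),
    "2" = c(base9, list(c(41, 50))),
    "5" = fine10,
    "6" = fine10,
    base9)
  window_scheme(w)
}

#' Composition of the eight reference datasets
#'
#' Trial and cell counts of the eight simultaneously recorded MI ensembles
#' that define the reference study design: per-dataset numbers of successful
#' and unsuccessful reaching trials, of regular-spiking (RS, putative
#' pyramidal) and fast-spiking (FS, putative interneuron) cells, and of cells
#' recorded at forelimb- versus hindlimb-representation sites.  Useful for
#' setting up simulations that match the recorded ensembles, and for
#' bookkeeping (e.g. 95 cells in total, each fitted under 4 behavioural
#' conditions).
#'
#' @return A data.frame with one row per dataset and columns `dataset`,
#'   `animal`, `n_trials`, `n_succ`, `n_unsucc`, `n_cells`, `n_rs`, `n_fs`,
#'   `n_forelimb`, `n_hindlimb`.
#' @examples
#' sum(dataset_info()$n_cells)   # 95 task-related neurons
#' @export
dataset_info <- function() {
  data.frame(
    dataset    = 1:8,
    animal     = c(1, 1, 1, 1, 2, 2, 2, 2),
    n_trials   = c(42, 50, 31, 35, 37, 60, 42, 35),
    n_succ     = c(21, 26, 15, 16, 26, 32, 27, 24),
    n_unsucc   = c(21, 24, 16, 19, 11, 28, 15, 11),
    n_cells    = c(13, 15, 15, 11, 10, 10, 9, 12),
    n_rs       = c(8, 10, 7, 6, 6, 7, 8, 6),
    n_fs       = c(5, 5, 8, 5, 4, 3, 1, 6),
    n_forelimb = c(7, 9, 10, 6, 6, 7, 6, 6),
    n_hindlimb = c(6, 6, 5, 4, 4, 3, 3, 6)
  )
}
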