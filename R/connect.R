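#' Directed signed connectivity graph from significant coefficients
#'
#' A coupling coefficient `alpha[i, k]` of target `c` is a significant
#' connection `i -> c` at lag window `k` when its Wald confidence interval
#' `alpha_hat +/- z * sqrt(Sigma_ii)` excludes zero; the connection is
#' excitatory for a positive estimate and inhibitory for a negative one.
#' Following the source method, no multiplicity correction is applied by
#' default; `bonferroni = TRUE` divides the test level across the K lags of
#' each directed pair for conservative use.  Self-connections (`i == c`)
#' are retained in the edge table but flagged, and are excluded from the
#' pairwise summary statistics that are defined over distinct pairs.
#'
#' @param efit an [fit_ensemble()] result (each fit must carry `Sigma`).
#' @param level confidence level of the Wald intervals (default 0.95).
#' @param bonferroni correct the level across the K lags?
#' @return An object of class `connectivity_graph`: the edge data.frame
#'   (`source`, `target`, `window`, `coef`, `se`, `lo`, `hi`, `sign`,
#'   `self`), plus `n_cells`, `K`, `level` and the condition label.
#' @export
significant_edges <- function(efit, level = 0.95, bonferroni = FALSE) {
  stopifnot(inherits(efit, "ensemble_fit"))
  C <- efit$C; K <- efit$K
  alpha_level <- 1 - level
  if (bonferroni) alpha_level <- alpha_level / K
  z <- stats::qnorm(1 - alpha_level / 2)
  rows <- list()
  for (f in efit$fits) {
    if (is.null(f$Sigma)) stop("fit is missing its covariance", call. = FALSE)
    est <- f$alpha_hat[-1]
    se <- sqrt(pmax(diag(f$Sigma)[-1], 0))
    lo <- est - z * se
    hi <- est + z * se
    sig <- lo > 0 | hi < 0
    if (any(sig)) {
      idx <- which(sig)
      src <- (idx - 1L) %/% K + 1L
      win <- (idx - 1L) %% K + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        source = src, target = f$target_cell, window = win,
        coef = unname(est[idx]), se = unname(se[idx]),
        lo = unname(lo[idx]), hi = unname(hi[idx]),
        sign = ifelse(est[idx] > 0, "E", "I"),
        self = src == f$target_cell)
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source = integer(0), target = integer(0), window = integer(0),
               coef = numeric(0), se = numeric(0), lo = numeric(0),
               hi = numeric(0), sign = character(0), self = logical(0))
  structure(list(edges = edges, n_cells = C, K = K, level = level,
                 bonferroni = bonferroni, condition = efit$condition,
                 cell_types = efit$cells$putative_type),
            class = "connectivity_graph")
}

#' @export
print.connectivity_graph <- function(x, ...) {
  e <- x$edges[!x$edges$self, ]
  cat(sprintf("<connectivity_graph> %d cells x %d lags ('%s'): %d significant coefficients (%d E / %d I), %d self\n",
              x$n_cells, x$K, x$condition, nrow(e),
              sum(e$sign == "E"), sum(e$sign == "I"), sum(x$edges$self)))
  invisible(x)
}

#' Mean (E + I) connectivity ratio
#'
#' The number of significant nonzero coupling coefficients (excitatory plus
#' inhibitory) among the `C^2 - C` ordered cell pairs, averaged over the K
#' lag windows:
#' `ratio = (1/K) * sum_k #significant off-diagonal coefficients at lag k / (C^2 - C)`.
#' Self-connections are excluded from numerator and denominator.
#'
#' @param g a [significant_edges()] graph with `n_cells >= 2`.
#' @return Scalar in `[0, 1]`.
#' @export
mean_ei_ratio <- function(g) {
  stopifnot(inherits(g, "connectivity_graph"))
  C <- g$n_cells
  if (C < 2) stop("mean E+I ratio needs at least 2 cells", call. = FALSE)
  sum(!g$edges$self) / (g$K * C * (C - 1))
}

#' Excitatory-to-inhibitory (E : I) balance
#'
#' Total significant excitatory coefficients divided by total significant
#' inhibitory coefficients, over all distinct-pair (source, lag)
#' combinations.  With no inhibitory coefficient the ratio is reported as
#' `Inf` with a warning.
#'
#' @param g a [significant_edges()] graph.
#' @return Positive scalar (possibly `Inf`).
#' @export
ei_balance <- function(g) {
  stopifnot(inherits(g, "connectivity_graph"))
  e <- g$edges[!g$edges$self, ]
  n_e <- sum(e$sign == "E"); n_i <- sum(e$sign == "I")
  if (n_i == 0) {
    warning("no inhibitory connections; E:I balance is infinite")
    return(Inf)
  }
  n_e / n_i
}

#' Interaction fractions by cell-group pairing
#'
#' A directed pair `i -> c` interacts when at least one of its K lag
#' coefficients is significant.  Interacting pairs are tallied within the
#' RS-RS, RS-FS and FS-FS subgroups and divided by the total number of
#' ordered pairs in each subgroup *including self-pairs*: `n_RS^2`,
#' `2 * n_RS * n_FS` and `n_FS^2` respectively (so the three denominators
#' sum to `C^2`).
#'
#' @param g a [significant_edges()] graph.
#' @param cell_types per-cell `"RS"`/`"FS"` labels; defaults to the types
#'   carried by the graph.
#' @return List with `fractions`, `counts` and `denominators`, each a named
#'   numeric vector over `rs_rs`, `rs_fs`, `fs_fs`.
#' @export
group_fractions <- function(g, cell_types = g$cell_types) {
  stopifnot(inherits(g, "connectivity_graph"))
  if (is.null(cell_types) || length(cell_types) != g$n_cells ||
      !all(cell_types %in% c("RS", "FS")))
    stop("every cell must be typed RS or FS", call. = FALSE)
  n_rs <- sum(cell_types == "RS"); n_fs <- sum(cell_types == "FS")
  denom <- c(rs_rs = n_rs^2, rs_fs = 2 * n_rs * n_fs, fs_fs = n_fs^2)
  pairs <- unique(g$edges[, c("source", "target")])
  grp <- function(i, c_) {
    a <- cell_types[i]; b <- cell_types[c_]
    if (a == "RS" && b == "RS") "rs_rs" else if (a == "FS" && b == "FS")
      "fs_fs" else "rs_fs"
  }
  counts <- c(rs_rs = 0, rs_fs = 0, fs_fs = 0)
  if (nrow(pairs)) {
    tab <- table(mapply(grp, pairs$source, pairs$target))
    counts[names(tab)] <- as.numeric(tab)
  }
  frac <- ifelse(denom > 0, counts / denom, NA_real_)
  list(fractions = frac, counts = counts, denominators = denom,
       n_significant_pairs = nrow(pairs))
}

#' Condition summary of a connectivity graph
#'
#' @param g a [significant_edges()] graph.
#' @param cell_types optional RS/FS labels for the group fractions.
#' @return An object of class `connectivity_summary` collecting the mean
#'   E+I ratio, the E:I balance, group fractions and raw counts.
#' @export
connectivity_summary <- function(g, cell_types = g$cell_types) {
  gf <- if (!is.null(cell_types) && all(cell_types %in% c("RS", "FS")))
    group_fractions(g, cell_types) else NULL
  e <- g$edges[!g$edges$self, ]
  structure(list(condition = g$condition,
                 mean_ei_ratio = mean_ei_ratio(g),
                 ei_balance = if (sum(e$sign == "I") > 0)
                   sum(e$sign == "E") / sum(e$sign == "I") else Inf,
                 n_excitatory = sum(e$sign == "E"),
                 n_inhibitory = sum(e$sign == "I"),
                 group_fractions = gf),
            class = "connectivity_summary")
}

#' @export
print.connectivity_summary <- function(x, ...) {
  cat(sprintf("<connectivity_summary> '%s': mean E+I ratio %.3f, E:I %.2f (%d E, %d I)\n",
              x$condition, x$mean_ei_ratio, x$ei_balance,
              x$n_excitatory, x$n_inhibitory))
  if (!is.null(x$group_fractions))
    cat(sprintf("  fractions RS-RS %.2f [%d], RS-FS %.2f [%d], FS-FS %.2f [%d]\n",
                x$group_fractions$fractions[1], x$group_fractions$denominators[1],
                x$group_fractions$fractions[2], x$group_fractions$denominators[2],
                x$group_fractions$fractions[3], x$group_fractions$denominators[3]))
  invisible(x)
}

#' Compare connectivity between two conditions
#'
#' Paired (or unpaired) Wilcoxon rank-sum/signed-rank test on per-dataset
#' summary statistics -- typically the mean E+I connectivity ratios of the
#' two behavioural conditions.
#'
#' @param summaries_a,summaries_b numeric vectors of per-dataset statistics.
#' @param paired logical; vectors must be of equal length when `TRUE`.
#' @return The `htest` object from [stats::wilcox.test()].
#' @export
compare_conditions <- function(summaries_a, summaries_b, paired = TRUE) {
  if (paired && length(summaries_a) != length(summaries_b))
    stop("paired comparison needs equal-length vectors", call. = FALSE)
  if (paired && all(summaries_a == summaries_b)) {
    # all signed ranks vanish: no evidence against the null by construction
    return(structure(list(statistic = c(V = 0), p.value = 1,
                          method = "Wilcoxon signed rank test (degenerate: identical vectors)",
                          alternative = "two.sided",
                          data.name = "summaries_a and summaries_b"),
                     class = "htest"))
  }
  stats::wilcox.test(summaries_a, summaries_b, paired = paired, exact = FALSE)
}

#' Multiway ANOVA over connectivity fractions
#'
#' Three-factor analysis of variance of interaction fractions with main
#' effects of cell group (RS-RS / RS-FS / FS-FS), task outcome
#' (successful / unsuccessful) and period (background / reaching).
#'
#' @param df data.frame with columns `fraction`, `cell_group`, `outcome`,
#'   `period` (one row per dataset x group x outcome x period).
#' @return The ANOVA table (`summary.aov`).
#' @export
anova_connectivity <- function(df) {
  need <- c("fraction", "cell_group", "outcome", "period")
  if (!all(need %in% names(df)))
    stop("df must have columns ", paste(need, collapse = ", "), call. = FALSE)
  summary(stats::aov(fraction ~ cell_group + outcome + period, data = df))
}

#' Export a connectivity graph to GraphML or DOT
#'
#' Builds a directed [igraph::graph_from_data_frame()] with `window`,
#' `sign` and `coef` edge attributes (one edge per significant coefficient;
#' filter on `window` for per-lag panels) and writes it via
#' [igraph::write_graph()].
#'
#' @param g a [significant_edges()] graph.
#' @param path output file.
#' @param format `"graphml"` or `"dot"`.
#' @param include_self keep flagged self-connections?
#' @return `path`, invisibly.
#' @export
write_connectivity_graph <- function(g, path, format = c("graphml", "dot"),
                                     include_self = FALSE) {
  format <- match.arg(format)
  e <- g$edges
  if (!include_self) e <- e[!e$self, ]
  verts <- data.frame(name = as.character(seq_len(g$n_cells)),
                      type = if (!is.null(g$cell_types)) g$cell_types
                             else rep("unknown", g$n_cells))
  ig <- igraph::graph_from_data_frame(
    data.frame(from = as.character(e$source), to = as.character(e$target),
               window = e$window, sign = e$sign, coef = e$coef),
    directed = TRUE, vertices = verts)
  igraph::write_graph(ig, path, format = format)
  invisible(path)
}
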