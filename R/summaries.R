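#' Classify the outcome of an invasion
#'
#' Maps a finished invasion onto one of five outcome classes:
#'
#' * `EXTINCT`: minimum mean fitness fell below the extinction threshold
#'   (or the population collapsed reproductively);
#' * `TERMINATED_OVERFLOW`: the mean diploid copy number exceeded the cap;
#' * `LOST`: all TE copies were lost;
#' * `STABLE_CONTROLLED`: the TE persists but is under control -- every
#'   individual is silenced, or the mean copy number's relative change over
#'   the last `slope_window` generations is below `slope_tol` per generation
#'   (transposition-selection balance);
#' * `ACTIVE`: the invasion was still visibly ongoing at the last recorded
#'   generation.
#'
#' Precedence is EXTINCT > TERMINATED_OVERFLOW > LOST > (STABLE_CONTROLLED
#' vs ACTIVE). The STABLE/ACTIVE split is a heuristic with an explicit,
#' configurable rule; the defaults are a 500-generation window and a 0.1%
#' per-generation tolerance.
#'
#' @param invasion An [run_invasion()] result (or a list with a compatible
#'   `trajectory` tibble and `stop_reason`).
#' @param config The [simulation_config()] of the run.
#' @param slope_window,slope_tol STABLE/ACTIVE rule parameters.
#' @return A single status string.
#' @export
classify_outcome <- function(invasion, config,
                             slope_window = 500, slope_tol = 0.001) {
  traj <- invasion$trajectory
  stopifnot(nrow(traj) >= 1)
  reason <- invasion$stop_reason %||% ""
  if (min(traj$mean_fitness) < config$extinction_threshold ||
      reason == "collapse") {
    return("EXTINCT")
  }
  if (max(traj$mean_copies) > config$copy_cap) {
    return("TERMINATED_OVERFLOW")
  }
  last <- nrow(traj)
  if (traj$mean_copies[last] == 0) {
    return("LOST")
  }
  if (traj$frac_silenced[last] >= 1 || reason %in% c("plateau", "balance")) {
    return("STABLE_CONTROLLED")
  }
  w <- min(slope_window, last - 1)
  if (w >= 1) {
    n0 <- traj$mean_copies[last - w]
    n1 <- traj$mean_copies[last]
    if (n0 > 0 && abs(n1 - n0) / n0 / w < slope_tol) {
      return("STABLE_CONTROLLED")
    }
  }
  "ACTIVE"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Largest piRNA clusters among extinct populations
#'
#' Returns the k largest cluster sizes (percent of genome) among the rows of
#' a sweep classified EXTINCT, in descending order; if fewer than k extinct
#' rows exist, all of them are returned. The maximum of this list is the
#' headline "largest cluster of an extinct population" statistic.
#'
#' @param sweep A [run_sweep()] result (tibble with `status` and
#'   `cluster_percent` columns).
#' @param k Number of clusters to return (default 50).
#' @return Numeric vector, descending.
#' @export
largest_extinct_clusters <- function(sweep, k = 50) {
  stopifnot(k >= 1)
  cl <- sweep$cluster_percent[sweep$status == "EXTINCT"]
  utils::head(sort(cl, decreasing = TRUE), k)
}

#' Fraction of extinct populations per cluster-size bin
#'
#' @param sweep A [run_sweep()] result.
#' @param bin_edges Monotonically increasing edges of cluster-size bins
#'   (percent of genome); bins are left-open, right-closed.
#' @return A tibble with one row per bin: edges, run count, extinct count
#'   and the fraction extinct (`NA` for empty bins, which are undefined
#'   rather than zero).
#' @export
extinction_fraction_by_bin <- function(sweep, bin_edges) {
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop("bin_edges must be strictly increasing", call. = FALSE)
  }
  bins <- cut(sweep$cluster_percent, breaks = bin_edges)
  n <- as.integer(table(bins))
  ext <- as.integer(table(bins[sweep$status == "EXTINCT"]))
  tibble::tibble(
    bin_low = bin_edges[-length(bin_edges)],
    bin_high = bin_edges[-1],
    n_runs = n,
    n_extinct = ext,
    fraction_extinct = ifelse(n > 0, ext / n, NA_real_)
  )
}

#' Compare cluster-size distributions between scenarios
#'
#' Rank-based and parametric comparisons of outcome distributions across
#' scenarios, as used for the "largest clusters of extinct populations"
#' contrasts: a two-group Wilcoxon rank-sum test, a Kruskal-Wallis rank-sum
#' test for two or more groups, or a one-way ANOVA.
#'
#' @param ... Two or more numeric vectors (one per scenario), or a single
#'   list of such vectors.
#' @param test One of `"wilcoxon"`, `"kruskal"`, `"anova"`.
#' @return A list with `statistic` and `p_value`.
#' @examples
#' compare_scenarios(c(1, 2, 3), c(2, 3, 4), test = "kruskal")
#' @export
compare_scenarios <- function(..., test = c("wilcoxon", "kruskal", "anova")) {
  test <- match.arg(test)
  groups <- list(...)
  if (length(groups) == 1 && is.list(groups[[1]])) groups <- groups[[1]]
  if (length(groups) < 2 || any(lengths(groups) == 0)) {
    stop("need at least two non-empty groups", call. = FALSE)
  }
  if (test == "wilcoxon") {
    if (length(groups) != 2) {
      stop("the Wilcoxon rank-sum test compares exactly two groups", call. = FALSE)
    }
    fit <- suppressWarnings(wilcox.test(groups[[1]], groups[[2]]))
    return(list(statistic = unname(fit$statistic), p_value = fit$p.value))
  }
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(seq_along(groups), lengths(groups)))
  if (test == "kruskal") {
    fit <- kruskal.test(values, labels)
    list(statistic = unname(fit$statistic), p_value = fit$p.value)
  } else {
    fit <- summary(aov(values ~ labels))[[1]]
    list(statistic = fit[["F value"]][1], p_value = fit[["Pr(>F)"]][1])
  }
}

#' Percent of zero-fitness individuals when mean fitness first reaches 0.1
#'
#' At the first recorded generation in which mean population fitness is at
#' or below `threshold`, returns the percentage of individuals whose clamped
#' fitness is exactly zero -- the individuals that cannot contribute any
#' offspring. With a linear fitness function this is typically 16-23% at a
#' mean fitness of 0.1. Returns `NA` if the trajectory never reaches the
#' threshold.
#'
#' @param invasion An [run_invasion()] result.
#' @param threshold Mean-fitness threshold (default 0.1).
#' @return Percent of individuals with zero fitness, or `NA`.
#' @export
fraction_zero_fitness_at_threshold <- function(invasion, threshold = 0.1) {
  traj <- invasion$trajectory
  hit <- which(traj$mean_fitness <= threshold)
  if (length(hit) == 0) {
    return(NA_real_)
  }
  100 * traj$frac_zero_fitness[hit[1]]
}
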