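#' Select genes with changed expression
#'
#' Genes qualify when their M-value exceeds the fold threshold in the chosen
#' direction (strictly: `M > log2(fold_threshold)` for up,
#' `M < -log2(fold_threshold)` for down, either for both) and their p-value
#' is strictly below `p_threshold`.
#'
#' @param profile named numeric vector of M-values.
#' @param pvalues numeric vector of matching length (same gene order).
#' @param direction `"up"`, `"down"` or `"both"`.
#' @param fold_threshold fold-change cutoff (default 1.7).
#' @param p_threshold p-value cutoff (default 0.05).
#' @return Character vector of qualifying gene ids.
#' @export
select_changed_genes <- function(profile, pvalues,
                                 direction = c("up", "down", "both"),
                                 fold_threshold = 1.7, p_threshold = 0.05) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(profile), !is.null(names(profile)))
  if (length(profile) != length(pvalues)) {
    stop("profile and pvalues must have the same length", call. = FALSE)
  }
  thr <- log2(fold_threshold)
  hit <- switch(direction,
    up = profile > thr,
    down = profile < -thr,
    both = abs(profile) > thr
  )
  names(profile)[hit & pvalues < p_threshold]
}

#' Hypergeometric gene-set enrichment
#'
#' Tests whether `selected` genes over-represent `gene_set` within
#' `universe`: with N universe genes of which K belong to the set and n are
#' selected, the p-value is the upper tail
#' \eqn{P(X \ge k)} for \eqn{X \sim} Hypergeometric(N, K, n), where k is the
#' observed overlap. Genes outside the universe are dropped from both the
#' set and the selection before counting.
#'
#' @param universe character vector of all assayed gene ids.
#' @param gene_set character vector of set member ids.
#' @param selected character vector of selected gene ids.
#' @param set_name optional label for the output row.
#' @param n_sets_tested Bonferroni denominator (default 1).
#' @return A one-row tibble: `set_name`, `universe_size`, `set_size`,
#'   `selected_size`, `overlap`, `p_value`, `p_bonferroni`.
#' @export
hypergeometric_enrichment <- function(universe, gene_set, selected,
                                      set_name = "set", n_sets_tested = 1) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  K_ids <- intersect(unique(gene_set), universe)
  n_ids <- intersect(unique(selected), universe)
  dropped <- (length(unique(gene_set)) - length(K_ids)) +
    (length(unique(selected)) - length(n_ids))
  if (dropped > 0) {
    message(dropped, " gene(s) outside the universe dropped before counting")
  }
  N <- length(universe)
  K <- length(K_ids)
  n <- length(n_ids)
  k <- length(intersect(K_ids, n_ids))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  tibble::tibble(
    set_name = set_name,
    universe_size = N, set_size = K, selected_size = n, overlap = k,
    p_value = p,
    p_bonferroni = min(1, p * n_sets_tested)
  )
}

#' Enrichment of several gene sets against one selection
#'
#' Applies [hypergeometric_enrichment()] to every set in a GMT-style list,
#' Bonferroni-correcting over the number of sets tested.
#'
#' @param universe character vector of all assayed gene ids.
#' @param gene_sets named list of character vectors (see
#'   [read_gene_sets()]).
#' @param selected character vector of selected gene ids.
#' @return A tibble with one row per set, ordered as supplied.
#' @export
enrich_gene_sets <- function(universe, gene_sets, selected) {
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  m <- length(gene_sets)
  purrr::map_dfr(names(gene_sets), function(nm) {
    suppressMessages(
      hypergeometric_enrichment(universe, gene_sets[[nm]], selected,
                                set_name = nm, n_sets_tested = m)
    )
  })
}

#' Bonferroni correction
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param m_tests number of tests (defaults to `length(p_values)`).
#' @return `min(1, p * m_tests)` elementwise.
#' @export
bonferroni <- function(p_values, m_tests = length(p_values)) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE), m_tests >= 1)
  pmin(1, p_values * m_tests)
}

#' Estimate doubling time from an OD600 growth curve
#'
#' Fits a least-squares line to log2(OD600) versus time over the exponential
#' window (by default the trailing half of the supplied points, i.e. the
#' linear part just prior to harvest) and returns the reciprocal slope as
#' the doubling time.
#'
#' @param curve data frame with columns `time_min` and `od600`.
#' @param window optional `c(start, end)` time range in minutes overriding
#'   the default window.
#' @return A list of class `doubling_time_result`: `doubling_time_min`,
#'   `slope` (log2 OD per minute), `fit_window`, `r_squared`, `n_points`.
#' @export
doubling_time <- function(curve, window = NULL) {
  stopifnot(is.data.frame(curve), all(c("time_min", "od600") %in% names(curve)))
  if (any(curve$od600 <= 0)) stop("non-positive OD600 value", call. = FALSE)
  if (is.null(window)) {
    n <- nrow(curve)
    idx <- order(curve$time_min)
    keep <- idx[seq.int(n - ceiling(n / 2) + 1, n)]
  } else {
    keep <- which(curve$time_min >= window[1] & curve$time_min <= window[2])
  }
  if (length(keep) < 3) {
    stop("need at least 3 points in the fit window", call. = FALSE)
  }
  sub <- curve[keep, ]
  fit <- stats::lm(log2(od600) ~ time_min, data = sub)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope <= 1e-12) stop("no growth", call. = FALSE)
  structure(
    list(
      doubling_time_min = 1 / slope,
      slope = slope,
      fit_window = range(sub$time_min),
      r_squared = suppressWarnings(summary(fit)$r.squared),
      n_points = nrow(sub)
    ),
    class = "doubling_time_result"
  )
}

#' @export
print.doubling_time_result <- function(x, ...) {
  cat(sprintf(
    "<doubling_time_result> %.1f min (slope %.4g /min, R2 = %.3f, %d pts)\n",
    x$doubling_time_min, x$slope, x$r_squared, x$n_points
  ))
  invisible(x)
}

#' @method glance doubling_time_result
#' @export
glance.doubling_time_result <- function(x, ...) {
  tibble::tibble(
    doubling_time_min = x$doubling_time_min,
    slope = x$slope,
    r_squared = x$r_squared,
    window_start = x$fit_window[1],
    window_end = x$fit_window[2],
    n_points = x$n_points
  )
}

#' Relative doubling time versus a reference
#'
#' @param mutant,wildtype `doubling_time_result` objects (or numbers of
#'   minutes).
#' @return `log2(dt_mutant / dt_wildtype)`.
#' @export
relative_doubling_time <- function(mutant, wildtype) {
  dt <- function(x) {
    if (inherits(x, "doubling_time_result")) x$doubling_time_min else x
  }
  a <- dt(mutant)
  b <- dt(wildtype)
  stopifnot(a > 0, b > 0)
  log2(a / b)
}
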