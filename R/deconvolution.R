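#' Deconvolution configuration
#'
#' Settings for [fit_deconvolution()] and its controls. The weights across
#' the cycle timepoints are governed by a single cubic spline through
#' `n_control_points` control points whose x-positions sit at fixed fractions
#' of the cycle duration (defaults 0.2, 0.4, 0.6 and 0.8, i.e. 78, 156, 234
#' and 312 min for a 390-min cycle); only the ordinates are optimized.
#'
#' @param n_control_points number of spline control points (default 4).
#' @param control_x_fractions their x-positions as fractions of the cycle
#'   duration, strictly increasing in (0, 1).
#' @param min_restarts minimum number of random optimizer restarts
#'   (default 10).
#' @param max_restarts restart budget before giving up on convergence
#'   (default 100).
#' @param cv_threshold convergence requires the coefficient of variation of
#'   the best three correlations to be at most this (default 0.01).
#' @param weight_corr_threshold convergence also requires all pairwise
#'   correlations among the best three weight vectors to reach this
#'   (default 0.95).
#' @param spline_method end-condition rule for [stats::splinefun()]:
#'   `"fmm"` (default, Forsythe-Malcolm-Moler) or `"natural"`.
#' @param seed master seed; restart initializations are drawn from a stream
#'   seeded with it.
#' @return A list of class `deconvolution_config`.
#' @export
deconvolution_config <- function(n_control_points = 4,
                                 control_x_fractions = c(0.2, 0.4, 0.6, 0.8),
                                 min_restarts = 10,
                                 max_restarts = 100,
                                 cv_threshold = 0.01,
                                 weight_corr_threshold = 0.95,
                                 spline_method = c("fmm", "natural"),
                                 seed = 1L) {
  spline_method <- match.arg(spline_method)
  stopifnot(
    n_control_points == length(control_x_fractions),
    all(diff(control_x_fractions) > 0),
    all(control_x_fractions > 0), all(control_x_fractions < 1),
    min_restarts >= 3, max_restarts >= min_restarts,
    cv_threshold > 0, weight_corr_threshold > 0
  )
  structure(
    list(
      n_control_points = as.integer(n_control_points),
      control_x_fractions = control_x_fractions,
      min_restarts = as.integer(min_restarts),
      max_restarts = as.integer(max_restarts),
      cv_threshold = cv_threshold,
      weight_corr_threshold = weight_corr_threshold,
      spline_method = spline_method,
      seed = as.integer(seed)
    ),
    class = "deconvolution_config"
  )
}

#' Spline-governed population weights
#'
#' Evaluates the interpolating cubic spline through the control points at
#' each cycle timepoint (extrapolating outside the control range), clamps
#' negative values to zero and normalizes the result to sum to one, yielding
#' per-timepoint population fractions.
#'
#' @param control_x control-point x-positions in minutes (distinct).
#' @param control_y control-point ordinates (unconstrained).
#' @param timepoints evaluation grid in minutes.
#' @param method spline end condition, `"fmm"` or `"natural"`.
#' @return Numeric weight vector over `timepoints`, in `[0, 1]`, summing
#'   to 1.
#' @export
spline_weights <- function(control_x, control_y, timepoints,
                           method = c("fmm", "natural")) {
  method <- match.arg(method)
  if (anyDuplicated(control_x)) {
    stop("duplicate control-point x values", call. = FALSE)
  }
  stopifnot(length(control_x) == length(control_y), length(control_x) >= 4)
  f <- stats::splinefun(control_x, control_y, method = method)
  w <- pmax(f(timepoints), 0)
  s <- sum(w)
  if (s <= 0) stop("degenerate weights: spline non-positive everywhere",
                   call. = FALSE)
  w / s
}

#' Virtual expression profile of a weighted phase mixture
#'
#' The weighted sum of the cycle series' timepoint columns: the expression
#' profile an asynchronous population would show if its cells were
#' distributed over the cycle according to `weights`.
#'
#' @param series a [cycle_series].
#' @param weights length-T weight vector.
#' @return Named numeric vector of M-values, one per gene.
#' @export
virtual_profile <- function(series, weights) {
  stopifnot(inherits(series, "cycle_series"))
  if (length(weights) != ncol(series$values)) {
    stop("length(weights) must equal the number of timepoints", call. = FALSE)
  }
  drop(series$values %*% weights)
}

# correlation that tolerates zero-variance inputs (returns NA -> handled by
# callers as a failed fit rather than an error)
safe_cor <- function(a, b) {
  if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) return(NA_real_)
  stats::cor(a, b)
}

# pairwise weight-vector correlation used in the convergence check; two
# (near-)identical constant vectors count as perfectly correlated
weight_cor <- function(a, b) {
  if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) {
    return(if (max(abs(a - b)) < 1e-8) 1 else 0)
  }
  stats::cor(a, b)
}

align_target <- function(series, target, min_shared = 10) {
  stopifnot(is.numeric(target), !is.null(names(target)))
  shared <- intersect(rownames(series$values), names(target))
  if (length(shared) < min_shared) {
    stop("need at least ", min_shared, " genes shared between series and target",
         call. = FALSE)
  }
  list(values = series$values[shared, , drop = FALSE],
       target = target[shared])
}

#' Deconvolve a target profile into cell-cycle phase fractions
#'
#' Expresses `target` (a single expression profile, e.g. a stress response)
#' as a weighted mixture of the cycle series' timepoint profiles. The weights
#' are governed by a cubic spline through four control points; the control
#' ordinates are optimized by Nelder-Mead simplex search to maximize the
#' Pearson correlation between the virtual mixture profile and the target.
#'
#' The optimizer is restarted at least `min_restarts` times from ordinates
#' drawn uniformly in (0, 1). The fit is declared converged when the best
#' three restarts agree: coefficient of variation of their correlations at
#' most `cv_threshold` and all pairwise correlations among their weight
#' vectors at least `weight_corr_threshold`. Otherwise further restarts are
#' added up to `max_restarts`, after which the best fit is returned flagged
#' `converged = FALSE`.
#'
#' @param series a [cycle_series].
#' @param target named numeric vector of M-values; matched to the series by
#'   gene id (at least 10 shared genes).
#' @param config a [deconvolution_config()].
#' @return An object of class `deconvolution_fit` with the optimized control
#'   points, the weight vector (population fractions summing to 1), the
#'   achieved correlation and restart diagnostics.
#' @export
fit_deconvolution <- function(series, target, config = deconvolution_config()) {
  stopifnot(inherits(series, "cycle_series"),
            inherits(config, "deconvolution_config"))
  al <- align_target(series, target)
  vals <- al$values
  tgt <- al$target
  tp <- series$timepoints_min
  cx <- config$control_x_fractions * series$cycle_duration_min

  objective <- function(y) {
    f <- stats::splinefun(cx, y, method = config$spline_method)
    w <- pmax(f(tp), 0)
    s <- sum(w)
    if (s <= 0) return(2) # degenerate: worse than any correlation
    r <- safe_cor(drop(vals %*% (w / s)), tgt)
    if (is.na(r)) return(2)
    -r
  }

  restarts <- list()
  run_one <- function(init) {
    opt <- stats::optim(init, objective, method = "Nelder-Mead")
    r <- -opt$value
    w <- tryCatch(
      spline_weights(cx, opt$par, tp, method = config$spline_method),
      error = function(e) NULL
    )
    if (is.null(w) || r < -1) {
      return(list(r = -Inf, par = opt$par, weights = NULL))
    }
    list(r = r, par = opt$par, weights = w)
  }

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  converged <- FALSE
  top3 <- NULL
  n_used <- 0
  while (n_used < config$max_restarts) {
    batch <- if (n_used == 0) config$min_restarts else 1L
    for (b in seq_len(batch)) {
      init <- stats::runif(config$n_control_points)
      restarts[[length(restarts) + 1]] <- run_one(init)
    }
    n_used <- length(restarts)
    rs <- vapply(restarts, `[[`, numeric(1), "r")
    ok <- which(is.finite(rs))
    if (length(ok) >= 3) {
      top3 <- ok[order(-rs[ok], ok)][1:3]
      r3 <- rs[top3]
      cv <- stats::sd(r3) / abs(mean(r3))
      w3 <- lapply(restarts[top3], `[[`, "weights")
      pr <- c(weight_cor(w3[[1]], w3[[2]]),
              weight_cor(w3[[1]], w3[[3]]),
              weight_cor(w3[[2]], w3[[3]]))
      if (is.finite(cv) && cv <= config$cv_threshold &&
          all(pr >= config$weight_corr_threshold)) {
        converged <- TRUE
        break
      }
    }
  }

  rs <- vapply(restarts, `[[`, numeric(1), "r")
  if (!any(is.finite(rs))) {
    stop("degenerate weights on every restart", call. = FALSE)
  }
  best <- which(is.finite(rs))[order(-rs[is.finite(rs)],
                                     which(is.finite(rs)))][1]
  fit <- restarts[[best]]
  top3_r <- if (!is.null(top3)) rs[top3] else rep(NA_real_, 3)
  top3_min_pr <- if (!is.null(top3)) {
    w3 <- lapply(restarts[top3], `[[`, "weights")
    min(weight_cor(w3[[1]], w3[[2]]), weight_cor(w3[[1]], w3[[3]]),
        weight_cor(w3[[2]], w3[[3]]))
  } else NA_real_

  structure(
    list(
      control_x_min = cx,
      control_y = fit$par,
      weights = setNames(fit$weights, paste0("t", tp)),
      timepoints_min = tp,
      correlation = fit$r,
      n_restarts_used = n_used,
      converged = converged,
      top3_correlations = top3_r,
      top3_weight_min_pairwise_r = top3_min_pr,
      n_genes = length(tgt),
      config = config
    ),
    class = "deconvolution_fit"
  )
}

#' @export
print.deconvolution_fit <- function(x, ...) {
  cat(sprintf(
    "<deconvolution_fit> r = %.4f over %d genes; %d restarts, %s\n",
    x$correlation, x$n_genes, x$n_restarts_used,
    if (x$converged) "converged" else "NOT converged"
  ))
  invisible(x)
}

#' Tidy a deconvolution fit
#'
#' @param x a `deconvolution_fit`.
#' @param ... unused.
#' @return `tidy()`: a tibble of per-timepoint weights (`time_min`,
#'   `weight`), suitable for a circular histogram of the cycle population.
#' @method tidy deconvolution_fit
#' @export
tidy.deconvolution_fit <- function(x, ...) {
  tibble::tibble(time_min = x$timepoints_min, weight = unname(x$weights))
}

#' @rdname tidy.deconvolution_fit
#' @return `glance()`: one-row tibble of fit diagnostics.
#' @method glance deconvolution_fit
#' @export
glance.deconvolution_fit <- function(x, ...) {
  tibble::tibble(
    correlation = x$correlation,
    n_genes = x$n_genes,
    n_restarts_used = x$n_restarts_used,
    converged = x$converged,
    top3_cv = stats::sd(x$top3_correlations) / abs(mean(x$top3_correlations)),
    top3_weight_min_pairwise_r = x$top3_weight_min_pairwise_r
  )
}

new_control_summary <- function(correlations, kind) {
  structure(
    list(correlations = correlations, kind = kind,
         mean_abs_r = mean(abs(correlations)),
         max_abs_r = max(abs(correlations))),
    class = "deconvolution_control"
  )
}

#' @export
print.deconvolution_control <- function(x, ...) {
  cat(sprintf("<deconvolution_control: %s> n = %d, mean |r| = %.3f, max |r| = %.3f\n",
              x$kind, length(x$correlations), x$mean_abs_r, x$max_abs_r))
  invisible(x)
}

#' @method glance deconvolution_control
#' @export
glance.deconvolution_control <- function(x, ...) {
  tibble::tibble(kind = x$kind, n = length(x$correlations),
                 mean_abs_r = x$mean_abs_r, max_abs_r = x$max_abs_r)
}

#' Overfitting control: randomized gene labels
#'
#' Refits the deconvolution after permuting which gene each target value is
#' assigned to (a fresh permutation per randomization). If the original fit
#' reflects genuine shared structure rather than overfitting, the permuted
#' correlations should collapse towards zero.
#'
#' @inheritParams fit_deconvolution
#' @param n_randomizations number of permutations (default 100).
#' @return A `deconvolution_control` with the achieved correlations and
#'   their mean/max absolute value.
#' @export
randomize_gene_labels_control <- function(series, target,
                                          n_randomizations = 100,
                                          config = deconvolution_config()) {
  if (n_randomizations < 1) stop("n_randomizations must be >= 1", call. = FALSE)
  al <- align_target(series, target)
  rs <- vapply(seq_len(n_randomizations), function(i) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i
    set.seed(config$seed * 1000L + i)
    perm <- sample(length(al$target))
    tgt_i <- setNames(al$target[perm], names(al$target))
    fit_deconvolution(series, tgt_i, cfg_i)$correlation
  }, numeric(1))
  new_control_summary(rs, "gene_label_randomization")
}

#' Overfitting control: randomized cycle matrix
#'
#' Refits after independently permuting the gene order within every
#' timepoint column of the cycle series, destroying each gene's trajectory
#' while preserving the per-column value distributions.
#'
#' @inheritParams randomize_gene_labels_control
#' @return A `deconvolution_control`.
#' @export
randomize_matrix_control <- function(series, target,
                                     n_randomizations = 100,
                                     config = deconvolution_config()) {
  if (n_randomizations < 1) stop("n_randomizations must be >= 1", call. = FALSE)
  rs <- vapply(seq_len(n_randomizations), function(i) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i
    set.seed(config$seed * 2000L + i)
    vals <- apply(series$values, 2, sample)
    rownames(vals) <- rownames(series$values)
    series_i <- cycle_series(vals, series$timepoints_min,
                             series$cycle_duration_min)
    fit_deconvolution(series_i, target, cfg_i)$correlation
  }, numeric(1))
  new_control_summary(rs, "matrix_randomization")
}

#' Split-half cross-validation of a deconvolution
#'
#' For each split, half the shared genes (training set) are used to optimize
#' the spline control points; the resulting weights are then scored as the
#' correlation between the virtual profile and the target on the held-out
#' half.
#'
#' @inheritParams fit_deconvolution
#' @param n_splits number of random half-splits (default 100).
#' @return A tibble with one row per split (`split`, `train_r`, `test_r`)
#'   and attributes `mean_train_r`, `mean_test_r`.
#' @export
cross_validate <- function(series, target, n_splits = 100,
                           config = deconvolution_config()) {
  if (n_splits < 1) stop("n_splits must be >= 1", call. = FALSE)
  al <- align_target(series, target, min_shared = 20)
  n <- length(al$target)
  res <- purrr::map_dfr(seq_len(n_splits), function(i) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i
    set.seed(config$seed * 3000L + i)
    train <- sort(sample(n, floor(n / 2)))
    test <- setdiff(seq_len(n), train)
    fit <- fit_deconvolution(series, al$target[train], cfg_i)
    virt <- drop(al$values %*% fit$weights)
    tibble::tibble(
      split = i,
      train_r = fit$correlation,
      test_r = safe_cor(virt[test], al$target[test])
    )
  })
  attr(res, "mean_train_r") <- mean(res$train_r)
  attr(res, "mean_test_r") <- mean(res$test_r)
  res
}
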