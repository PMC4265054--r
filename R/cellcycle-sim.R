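#' Slot-model of a cycling cell population
#'
#' The population is a circular array of one-minute slots along the cell
#' cycle, each holding the relative number of cells at that point. The
#' default geometry is a 77-min cycle split into G1 (21), S (14), G2 (14),
#' M (21) and M.G1 (7) minutes, with the START checkpoint sitting between
#' slots 14 and 15 (i.e. within G1) and cells in slots 1-28 carrying 1N DNA
#' content. A stress such as heat shock erects a transient barrier at START;
#' cells pile up in front of it for `recovery_min` minutes and the slots
#' beyond it empty out.
#'
#' @param phase_lengths_min named vector of phase lengths in minutes;
#'   defaults `c(G1 = 21, S = 14, G2 = 14, M = 21, M.G1 = 7)`.
#' @param barrier_after_slot the barrier blocks the transition out of this
#'   slot (default 14).
#' @param recovery_min minutes cells need to recover before passing the
#'   barrier (default 25).
#' @param one_n_last_slot last slot counted as 1N DNA content (default 28).
#' @param coarse_bin_min width of the coarse-grained visualization bins in
#'   minutes; must divide the cycle length (default 7).
#' @param fold_threshold fold-change in bin occupancy below which expression
#'   consequences are ignored (default 1.7).
#' @param release_mode what happens when recovery completes: `"cohort"`
#'   (default) lifts the barrier so the accumulated mass advances as a single
#'   synchronized block; `"drain"` lets at most one steady-state slot-mass
#'   (1/n_slots) pass per minute until the pile has dissipated.
#' @return A list of class `population_model`.
#' @export
population_model <- function(phase_lengths_min = c(G1 = 21, S = 14, G2 = 14,
                                                   M = 21, M.G1 = 7),
                             barrier_after_slot = 14,
                             recovery_min = 25,
                             one_n_last_slot = 28,
                             coarse_bin_min = 7,
                             fold_threshold = 1.7,
                             release_mode = c("cohort", "drain")) {
  release_mode <- match.arg(release_mode)
  n_slots <- sum(phase_lengths_min)
  stopifnot(
    all(phase_lengths_min > 0),
    barrier_after_slot >= 1, barrier_after_slot < n_slots,
    one_n_last_slot >= 1, one_n_last_slot <= n_slots,
    recovery_min >= 1, fold_threshold > 1
  )
  if (n_slots %% coarse_bin_min != 0) {
    stop("coarse_bin_min must divide the cycle length (", n_slots, " min)",
         call. = FALSE)
  }
  structure(
    list(
      slot_minutes = 1L,
      phase_lengths_min = phase_lengths_min,
      n_slots = as.integer(n_slots),
      barrier_after_slot = as.integer(barrier_after_slot),
      recovery_min = as.integer(recovery_min),
      one_n_last_slot = as.integer(one_n_last_slot),
      coarse_bin_min = as.integer(coarse_bin_min),
      fold_threshold = fold_threshold,
      release_mode = release_mode
    ),
    class = "population_model"
  )
}

#' Steady-state (asynchronous) population
#'
#' The unsynchronized population is uniform over the cycle: every slot holds
#' 1/n_slots of the cells. Without a barrier this distribution is a fixed
#' point of the dynamics.
#'
#' @param model a [population_model()].
#' @return A list of class `population_state` with elements `time_min`,
#'   `density` (length n_slots, summing to 1), `barrier_active`, `draining`.
#' @export
init_steady_state <- function(model) {
  stopifnot(inherits(model, "population_model"))
  structure(
    list(
      time_min = 0L,
      density = rep(1 / model$n_slots, model$n_slots),
      barrier_active = FALSE,
      draining = FALSE
    ),
    class = "population_state"
  )
}

#' Advance the population by one minute
#'
#' Every slot's mass moves to the next slot (the last slot wraps to the
#' first; division transfers relative cell numbers unchanged). While the
#' barrier is active the transition out of the barrier slot is blocked, so
#' its mass piles up while upstream slots keep feeding it and the slots just
#' beyond it empty out. In drain-mode release (`draining = TRUE`) at most one
#' steady-state slot-mass passes the barrier per minute. Total mass is
#' conserved exactly.
#'
#' @param state a `population_state`.
#' @param model the matching [population_model()].
#' @return The state one minute later.
#' @export
step_population <- function(state, model) {
  stopifnot(inherits(state, "population_state"),
            inherits(model, "population_model"))
  n <- model$n_slots
  b <- model$barrier_after_slot
  d <- state$density
  new <- d[c(n, seq_len(n - 1))] # rotate forward by one slot
  if (state$barrier_active) {
    new[b + 1] <- 0                  # nothing crosses the barrier
    new[b] <- new[b] + d[b]          # blocked mass stays and piles up
  } else if (state$draining) {
    pass <- min(d[b], 1 / n)
    new[b + 1] <- pass
    new[b] <- new[b] + (d[b] - pass)
  }
  state$density <- new
  state$time_min <- state$time_min + 1L
  state
}

#' Fraction of cells with 1N DNA content
#'
#' Sum of the density over slots 1 to `one_n_last_slot` (cells that have not
#' yet replicated their DNA); the remainder is 2N.
#'
#' @inheritParams step_population
#' @return A fraction in `[0, 1]`.
#' @export
one_n_fraction <- function(state, model) {
  sum(state$density[seq_len(model$one_n_last_slot)])
}

#' Coarse-grain a population state for visualization
#'
#' Averages consecutive groups of `coarse_bin_min` one-minute slots.
#'
#' @inheritParams step_population
#' @return Numeric vector of length `n_slots / coarse_bin_min` of mean slot
#'   occupancies.
#' @export
coarse_grain <- function(state, model) {
  w <- model$coarse_bin_min
  if (model$n_slots %% w != 0) {
    stop("coarse bin width does not divide the cycle length", call. = FALSE)
  }
  colMeans(matrix(state$density, nrow = w))
}

#' Simulate a heat-shock arrest and release
#'
#' Runs the slot model from the uniform steady state for `t_end_min`
#' minutes. At `shock_at_min` a barrier is erected at the START checkpoint
#' (between slots `barrier_after_slot` and the next); it stays up for
#' `recovery_min` minutes, after which the accumulated cells are released
#' according to the model's `release_mode`. The trace records, for every
#' minute including t = 0, the full density, the 1N fraction, the
#' coarse-grained bins and the expression-magnitude curves.
#'
#' @param model a [population_model()].
#' @param t_end_min simulation horizon in minutes (>= 1).
#' @param shock_at_min minute at which the shock is applied (default 0);
#'   `NULL` simulates an undisturbed population (no barrier is ever
#'   erected).
#' @return An object of class `simulation_trace` with elements `times_min`,
#'   `densities` (matrix, one row per minute), `one_n_fractions`,
#'   `coarse_densities`, `magnitude_up`, `magnitude_down`, `model`.
#' @export
simulate_population <- function(model, t_end_min, shock_at_min = 0) {
  stopifnot(inherits(model, "population_model"), t_end_min >= 1)
  if (!is.null(shock_at_min) && t_end_min < shock_at_min) {
    stop("t_end_min must be at least shock_at_min", call. = FALSE)
  }
  state <- init_steady_state(model)
  n_steps <- as.integer(t_end_min)
  dens <- matrix(NA_real_, n_steps + 1, model$n_slots)
  dens[1, ] <- state$density
  release_at <- if (is.null(shock_at_min)) Inf else
    shock_at_min + model$recovery_min
  for (t in seq_len(n_steps)) {
    t0 <- t - 1 # the step covers minute t0 -> t0 + 1
    state$barrier_active <- !is.null(shock_at_min) && t0 >= shock_at_min &&
      t0 < release_at
    if (model$release_mode == "drain" && t0 >= release_at) {
      # keep draining while the barrier slot holds more than steady state
      state$draining <- state$density[model$barrier_after_slot] >
        1 / model$n_slots + 1e-12
    } else {
      state$draining <- FALSE
    }
    state <- step_population(state, model)
    dens[t + 1, ] <- state$density
  }
  trace <- structure(
    list(
      times_min = 0:n_steps,
      densities = dens,
      one_n_fractions = rowSums(
        dens[, seq_len(model$one_n_last_slot), drop = FALSE]
      ),
      coarse_densities = t(apply(dens, 1, function(d) {
        colMeans(matrix(d, nrow = model$coarse_bin_min))
      })),
      model = model
    ),
    class = "simulation_trace"
  )
  mag <- expression_magnitude(trace, model)
  trace$magnitude_up <- mag$magnitude_up
  trace$magnitude_down <- mag$magnitude_down
  trace
}

#' Predicted magnitude of population-driven expression changes
#'
#' Under the population-shift model, the apparent expression change of a
#' phase-specific gene is proportional to the change in the number of cells
#' in its phase. Per minute, each coarse bin's occupancy fold change
#' relative to t = 0 is computed (with a 1e-6 floor against empty bins);
#' bins changing more than `fold_threshold`-fold up (down) contribute their
#' log2 fold change to the up (down) magnitude, averaged over contributing
#' bins and finally normalized to the series' own maximum absolute value.
#' The output is a shape over time, not an absolute scale.
#'
#' @param trace a `simulation_trace` that includes t = 0.
#' @param model the matching [population_model()].
#' @return A list with numeric vectors `magnitude_up` and `magnitude_down`
#'   (one value per trace minute; `magnitude_down` is non-positive).
#' @export
expression_magnitude <- function(trace, model) {
  stopifnot(inherits(trace, "simulation_trace"))
  if (trace$times_min[1] != 0) {
    stop("trace must include the t = 0 pre-shock state", call. = FALSE)
  }
  eps <- 1e-6
  base <- pmax(trace$coarse_densities[1, ], eps)
  lf <- log2(pmax(t(trace$coarse_densities), eps) / base) # bins x time
  thr <- log2(model$fold_threshold)
  up <- apply(lf, 2, function(v) {
    hit <- v > thr
    if (any(hit)) mean(v[hit]) else 0
  })
  down <- apply(lf, 2, function(v) {
    hit <- v < -thr
    if (any(hit)) mean(v[hit]) else 0
  })
  if (max(abs(up)) > 0) up <- up / max(abs(up))
  if (max(abs(down)) > 0) down <- down / max(abs(down))
  list(magnitude_up = up, magnitude_down = down)
}

#' @export
print.simulation_trace <- function(x, ...) {
  cat(sprintf(
    "<simulation_trace> %d min, %d slots (%s release); 1N %.3f -> %.3f\n",
    max(x$times_min), x$model$n_slots, x$model$release_mode,
    x$one_n_fractions[1], x$one_n_fractions[length(x$one_n_fractions)]
  ))
  invisible(x)
}

#' Tidy a simulation trace
#'
#' @param x a `simulation_trace`.
#' @param ... unused.
#' @return A tibble with one row per minute: `time_min`, `one_n_fraction`,
#'   `magnitude_up`, `magnitude_down`, and one `bin_*` column per coarse
#'   bin.
#' @method tidy simulation_trace
#' @export
tidy.simulation_trace <- function(x, ...) {
  cb <- as.data.frame(x$coarse_densities)
  names(cb) <- paste0("bin_", seq_len(ncol(cb)))
  dplyr::bind_cols(
    tibble::tibble(
      time_min = x$times_min,
      one_n_fraction = x$one_n_fractions,
      magnitude_up = x$magnitude_up,
      magnitude_down = x$magnitude_down
    ),
    tibble::as_tibble(cb)
  )
}

#' Plot a simulation trace
#'
#' Shows the 1N fraction and the normalized up/down expression-magnitude
#' curves over time.
#'
#' @param object a `simulation_trace`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot simulation_trace
#' @export
autoplot.simulation_trace <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::select("time_min", "one_n_fraction", "magnitude_up",
                  "magnitude_down") |>
    tidyr::pivot_longer(-"time_min", names_to = "series", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_min, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time after shock (min)", y = NULL,
                  title = "Cell-cycle population shift after START arrest") +
    ggplot2::theme_minimal()
}

#' Plot deconvolved cycle-phase weights
#'
#' Bar chart of the per-timepoint population fractions of a
#' [fit_deconvolution()] result (the linear analogue of a circular
#' histogram around the cycle dial).
#'
#' @param object a `deconvolution_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot deconvolution_fit
#' @export
autoplot.deconvolution_fit <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$time_min, y = .data$weight)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "cycle time (min)", y = "population fraction",
                  title = sprintf("Phase mixture (r = %.2f)",
                                  object$correlation)) +
    ggplot2::theme_minimal()
}
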