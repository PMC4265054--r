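#' Synthetic deletion-strain compendium with a planted slow-growth signature
#'
#' Generates a genes-by-strains M-value matrix containing a planted rank-1
#' slow-growth signature: a fixed gene pattern (half induced, half
#' repressed) whose loading in each strain scales with that strain's planted
#' log2 relative doubling time, on top of strain-specific expression spikes
#' for a subset of strains and i.i.d. Gaussian noise. P-values are generated
#' from a two-sided z-test of each M-value against the known noise scale, so
#' threshold logic downstream behaves as it would on measured data.
#'
#' @param n_genes,n_strains matrix dimensions (defaults 2000 x 200).
#' @param n_signature_genes number of genes carrying the signature (default
#'   600; half up, half down).
#' @param signature_amplitude absolute M-value of signature genes at unit
#'   loading (default 1).
#' @param beta scaling between growth rate and signature loading
#'   (default 1).
#' @param specific_effect_strains number of strains given private effects
#'   (default 40).
#' @param specific_genes_per_strain genes spiked per such strain
#'   (default 20).
#' @param specific_amplitude absolute M-value of the private spikes
#'   (default 2).
#' @param noise_sd Gaussian noise standard deviation (default 0.25).
#' @param seed integer seed; the output is a pure function of the
#'   parameters and the seed.
#' @return A list with `matrix` (an [expression_matrix] with p-values) and
#'   `truth` (planted signature vector, per-strain growth rates, the spiked
#'   strains, the seed and a parameter echo).
#' @export
make_compendium <- function(n_genes = 2000, n_strains = 200,
                            n_signature_genes = 600,
                            signature_amplitude = 1.0, beta = 1.0,
                            specific_effect_strains = 40,
                            specific_genes_per_strain = 20,
                            specific_amplitude = 2.0,
                            noise_sd = 0.25, seed = 1L) {
  stopifnot(n_signature_genes <= n_genes,
            n_signature_genes %% 2 == 0,
            specific_effect_strains <= n_strains,
            specific_genes_per_strain <= n_genes,
            noise_sd >= 0)
  withr_seed(seed)
  gid <- sprintf("g%04d", seq_len(n_genes))
  sid <- sprintf("strain%03d", seq_len(n_strains))
  sigma <- numeric(n_genes)
  sig_genes <- sample(n_genes, n_signature_genes)
  half <- n_signature_genes / 2
  sigma[sig_genes[seq_len(half)]] <- signature_amplitude
  sigma[sig_genes[half + seq_len(half)]] <- -signature_amplitude
  growth <- stats::runif(n_strains, -0.1, 1.0) # log2 relative doubling times
  m <- outer(sigma, beta * growth)
  spiked <- sample(n_strains, specific_effect_strains)
  for (s in spiked) {
    g <- sample(n_genes, specific_genes_per_strain)
    m[g, s] <- m[g, s] +
      sample(c(-1, 1), specific_genes_per_strain, replace = TRUE) *
        specific_amplitude
  }
  if (noise_sd > 0) m <- m + matrix(stats::rnorm(n_genes * n_strains,
                                                 sd = noise_sd),
                                    n_genes, n_strains)
  dimnames(m) <- list(gid, sid)
  pv <- zscore_pvalues(m, noise_sd)
  list(
    matrix = expression_matrix(m, pvalues = pv),
    truth = list(
      planted_signature = setNames(sigma, gid),
      planted_growth_rates = setNames(growth, sid),
      specific_effect_strains = sid[spiked],
      seed = seed,
      generator_params = list(
        n_genes = n_genes, n_strains = n_strains,
        n_signature_genes = n_signature_genes,
        signature_amplitude = signature_amplitude, beta = beta,
        specific_effect_strains = specific_effect_strains,
        specific_genes_per_strain = specific_genes_per_strain,
        specific_amplitude = specific_amplitude, noise_sd = noise_sd
      )
    )
  )
}

# two-sided z-test of each cell against the generator's noise scale
zscore_pvalues <- function(m, noise_sd) {
  if (noise_sd > 0) {
    pv <- 2 * stats::pnorm(-abs(m) / noise_sd)
  } else {
    pv <- ifelse(m != 0, 0, 1)
  }
  dimnames(pv) <- dimnames(m)
  pv
}

# seed the RNG for the duration of the calling generator, restoring the
# caller's stream afterwards so generators are pure in (params, seed)
withr_seed <- function(seed, env = parent.frame()) {
  restore <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    bquote(assign(".Random.seed", .(get(".Random.seed", globalenv())),
                  globalenv()))
  } else {
    quote(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  do.call(on.exit, list(restore, add = TRUE), envir = env)
  set.seed(seed)
  invisible(seed)
}

#' Synthetic cell-cycle time course
#'
#' Sinusoidal per-gene trajectories sampled along one cycle and expressed as
#' M-values relative to t = 0: gene g with phase \eqn{\phi_g} and amplitude
#' \eqn{A_g} has value
#' \eqn{A_g [\cos(2\pi(t/D - \phi_g)) - \cos(2\pi \phi_g)]} at time t for
#' cycle duration D, so the first column is exactly zero in the noiseless
#' case. The default geometry mirrors a 14-point, 30-min-interval
#' elutriation series spanning 0-390 min.
#'
#' @param n_genes number of cycling genes (default 400).
#' @param n_timepoints number of samples (default 14).
#' @param interval_min sampling interval (default 30).
#' @param cycle_duration_min cycle length (default 390).
#' @param amplitude_range per-gene amplitudes drawn uniformly from this
#'   range (default 0.5-2).
#' @param noise_sd additive Gaussian noise (default 0).
#' @param n_harmonics number of cosine harmonics per gene trajectory
#'   (default 1, a pure sinusoid). Note that with a single harmonic the
#'   series matrix has rank 2 exactly, so mixture weights fitted against it
#'   are not identifiable beyond their two-dimensional projection;
#'   `n_harmonics >= 2` (amplitudes shrinking as 1/h, independent phases)
#'   gives a full-rank dictionary on which deconvolution recovers planted
#'   weights uniquely.
#' @param seed integer seed.
#' @return A list with `series` (a [cycle_series]) and `truth` (phases,
#'   amplitudes, seed, parameter echo).
#' @export
make_cycle_series <- function(n_genes = 400, n_timepoints = 14,
                              interval_min = 30, cycle_duration_min = 390,
                              amplitude_range = c(0.5, 2.0),
                              noise_sd = 0.0, n_harmonics = 1L, seed = 1L) {
  stopifnot(n_timepoints >= 4, interval_min > 0, noise_sd >= 0,
            n_harmonics >= 1)
  withr_seed(seed)
  tp <- seq(0, by = interval_min, length.out = n_timepoints)
  stopifnot(cycle_duration_min >= max(tp))
  gid <- sprintf("g%04d", seq_len(n_genes))
  phase <- stats::runif(n_genes)
  amp <- stats::runif(n_genes, amplitude_range[1], amplitude_range[2])
  extra <- if (n_harmonics > 1) {
    lapply(seq.int(2, n_harmonics), function(h) {
      list(h = h, phase = stats::runif(n_genes), amp = amp / h)
    })
  } else list()
  wave <- function(t) {
    v <- amp * (cos(2 * pi * (t / cycle_duration_min - phase)) -
                  cos(2 * pi * phase))
    for (e in extra) {
      v <- v + e$amp * (cos(2 * pi * (e$h * t / cycle_duration_min -
                                        e$phase)) -
                          cos(2 * pi * e$phase))
    }
    v
  }
  vals <- vapply(tp, wave, numeric(n_genes))
  if (noise_sd > 0) {
    vals <- vals + matrix(stats::rnorm(length(vals), sd = noise_sd),
                          nrow = n_genes)
  }
  rownames(vals) <- gid
  list(
    series = cycle_series(vals, tp, cycle_duration_min),
    truth = list(
      phases = setNames(phase, gid), amplitudes = setNames(amp, gid),
      seed = seed,
      generator_params = list(
        n_genes = n_genes, n_timepoints = n_timepoints,
        interval_min = interval_min,
        cycle_duration_min = cycle_duration_min,
        amplitude_range = amplitude_range, noise_sd = noise_sd,
        n_harmonics = n_harmonics
      )
    )
  )
}

#' Synthetic deconvolution target with known mixture weights
#'
#' Builds a target profile as the spline-weighted mixture of a cycle
#' series' timepoint profiles — the construction [fit_deconvolution()]
#' assumes — plus optional per-gene noise. The true control ordinates and
#' the implied weight vector are recorded as ground truth.
#'
#' @param series a [cycle_series].
#' @param control_y the four true spline ordinates.
#' @param control_x_fractions control-point positions as fractions of the
#'   cycle (default 0.2, 0.4, 0.6, 0.8).
#' @param noise_sd additive Gaussian noise per gene (default 0).
#' @param seed integer seed (used only for the noise).
#' @return A list with `target` (named gene vector) and `truth`
#'   (`control_y`, `weights`, seed, parameter echo).
#' @export
make_mixture_target <- function(series, control_y,
                                control_x_fractions = c(0.2, 0.4, 0.6, 0.8),
                                noise_sd = 0, seed = 1L) {
  stopifnot(inherits(series, "cycle_series"), noise_sd >= 0)
  cx <- control_x_fractions * series$cycle_duration_min
  w <- spline_weights(cx, control_y, series$timepoints_min)
  target <- virtual_profile(series, w)
  if (noise_sd > 0) {
    withr_seed(seed)
    target <- target + stats::rnorm(length(target), sd = noise_sd)
  }
  list(
    target = target,
    truth = list(
      control_y = control_y, weights = w, seed = seed,
      generator_params = list(control_x_fractions = control_x_fractions,
                              noise_sd = noise_sd)
    )
  )
}

#' Synthetic enrichment scenario with signature contamination
#'
#' Emulates the enrichment-improvement experiment: a single perturbation
#' profile combines (i) a direct effect on a planted target gene set,
#' (ii) contamination by the compendium's slow-growth signature at loading
#' `contamination`, and (iii) Gaussian noise. A small compendium sharing the
#' same planted signature is generated alongside so the signature can be
#' extracted and removed. The target set is drawn from genes outside the
#' signature support so direct and indirect effects are separable.
#'
#' @param n_genes universe size (default 1000).
#' @param target_set_size planted set size (default 50).
#' @param direct_effect M-value added to target-set genes (default 1.5).
#' @param contamination signature loading of the perturbation profile
#'   (default 0.8).
#' @param n_signature_genes,signature_amplitude,noise_sd,n_strains passed to
#'   the embedded compendium generator.
#' @param seed integer seed.
#' @return A list with `profile` (named M-value vector), `pvalues`,
#'   `gene_set` (the planted target ids), `compendium` (an
#'   [expression_matrix] for signature extraction) and `truth`.
#' @export
make_enrichment_scenario <- function(n_genes = 1000, target_set_size = 50,
                                     direct_effect = 1.5,
                                     contamination = 0.8,
                                     n_signature_genes = 300,
                                     signature_amplitude = 1.0,
                                     noise_sd = 0.25,
                                     n_strains = 100, seed = 1L) {
  stopifnot(target_set_size <= n_genes,
            n_signature_genes + target_set_size <= n_genes)
  comp <- make_compendium(
    n_genes = n_genes, n_strains = n_strains,
    n_signature_genes = n_signature_genes,
    signature_amplitude = signature_amplitude,
    specific_effect_strains = 0, specific_genes_per_strain = 1,
    noise_sd = noise_sd, seed = seed
  )
  sigma <- comp$truth$planted_signature
  gid <- names(sigma)
  withr_seed(seed + 10000L)
  candidates <- which(sigma == 0)
  target_set <- sort(sample(candidates, target_set_size))
  profile <- contamination * sigma
  profile[target_set] <- profile[target_set] + direct_effect
  profile <- profile + stats::rnorm(n_genes, sd = noise_sd)
  names(profile) <- gid
  pv <- drop(zscore_pvalues(matrix(profile, ncol = 1), noise_sd))
  names(pv) <- gid
  list(
    profile = profile,
    pvalues = pv,
    gene_set = gid[target_set],
    compendium = comp$matrix,
    truth = list(
      planted_target_set = gid[target_set],
      planted_signature = sigma,
      contamination = contamination, seed = seed,
      generator_params = list(
        n_genes = n_genes, target_set_size = target_set_size,
        direct_effect = direct_effect, contamination = contamination,
        n_signature_genes = n_signature_genes,
        signature_amplitude = signature_amplitude,
        noise_sd = noise_sd, n_strains = n_strains
      )
    )
  )
}

#' Synthetic exponential growth curve
#'
#' OD600 readings following
#' \eqn{OD(t) = 0.05 \cdot 2^{t/\mathrm{dt}} \cdot e^{\epsilon_t}} with
#' optional multiplicative log-normal noise.
#'
#' @param doubling_time_min true doubling time (default 90).
#' @param n_points number of readings (default 20).
#' @param interval_min time between readings (default 15).
#' @param noise_sd standard deviation of the multiplicative log-noise
#'   (default 0).
#' @param seed integer seed.
#' @return A tibble with columns `time_min`, `od600`.
#' @export
make_growth_curve <- function(doubling_time_min = 90, n_points = 20,
                              interval_min = 15, noise_sd = 0, seed = 1L) {
  stopifnot(doubling_time_min > 0, n_points >= 3, interval_min > 0,
            noise_sd >= 0)
  t <- seq(0, by = interval_min, length.out = n_points)
  od <- 0.05 * 2^(t / doubling_time_min)
  if (noise_sd > 0) {
    withr_seed(seed)
    od <- od * exp(stats::rnorm(n_points, sd = noise_sd))
  }
  tibble::tibble(time_min = t, od600 = od)
}
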