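#' Simulate a 500-cell GFAP trajectory ensemble for one signal
#'
#' Integrates the Ito SDEs of the chosen model variant with the
#' Euler-Maruyama scheme (default step 0.01 h, output saved every 0.1 h).
#' Every cell runs on an independent counter-derived RNG stream, so the
#' result is bit-reproducible for a given `(spec, signal, config)` and does
#' not depend on evaluation order. For the CLE family, extrinsic noise is
#' realized as a per-cell, trajectory-constant log-normal perturbation of all
#' 41 rate constants (standard deviation `sigma_ext` on the log scale), and
#' intrinsic noise as state-dependent white noise with amplitude
#' `sigma_int * w_s * sqrt(production_s + degradation_s)` per species. For
#' the AN model, additive Brownian terms with intensity `sigma_an` times each
#' state's dynamic scale are used. States are clamped to zero after every
#' step; any non-finite state aborts with a diagnostic naming the cell, time
#' and state. Before treatment is applied at t = 0, each cell is placed at
#' the untreated steady state of its own (possibly extrinsically perturbed)
#' parameters and run for a stochastic settling period at dose 0
#' (`config$burn_in`, default 10 h), so initial GFAP baselines carry the
#' cell-to-cell variability that the fold-change descriptor divides by.
#'
#' @param spec A [glioma_model()].
#' @param signal One row of [build_signal_grid()] (data frame or list with
#'   `ct_dose`, `noise_label` and the relevant sigma fields).
#' @param config A [sim_config()].
#' @param full_state Keep the full 10-state trajectory tensor (memory-heavy;
#'   default `FALSE` keeps GFAP only).
#' @return A `trajectory_ensemble`: list with `gfap` (n_cells x T matrix),
#'   `time` (hours, length T), `signal` (one-row tibble), `variant`,
#'   `seed_used`, and optionally `full_state` (n_cells x 10 x T array).
#' @export
#' @examples
#' m <- glioma_model("CLE")
#' sig <- build_signal_grid("CLE")[13, ]  # dose 10, LL
#' ens <- simulate_ensemble(m, sig, sim_config(n_cells = 20, seed = 1))
#' dim(ens$gfap)
simulate_ensemble <- function(spec, signal, config = sim_config(),
                              full_state = FALSE) {
  stopifnot(inherits(spec, "glioma_model"), inherits(config, "sim_config"))
  signal <- tibble::as_tibble(as.list(signal))
  if (!all(c("ct_dose", "noise_label") %in% names(signal))) {
    rlang::abort("`signal` must carry `ct_dose` and `noise_label`.")
  }
  an <- spec$variant == "AN"
  noise_kind <- if (an) 1L else 2L
  sigma_int <- if (an) 0 else signal$sigma_int
  sigma_ext <- if (an) 0 else signal$sigma_ext
  sigma_an <- if (an) signal$sigma_an else 0
  if (an && (is.null(sigma_an) || is.na(sigma_an))) {
    rlang::abort("AN signals must carry `sigma_an`.")
  }
  if (!an && (is.na(sigma_int) || is.na(sigma_ext))) {
    rlang::abort("CLE-family signals must carry `sigma_int` and `sigma_ext`.")
  }
  seed <- as.double(config$seed)
  out <- .cpp_simulate_ensemble(
    unname(spec$drift_params), unname(spec$init),
    signal$ct_dose, spec$feedback_scale, noise_kind,
    sigma_int, sigma_ext, sigma_an,
    unname(spec$noise_weights), unname(spec$an_scales),
    config$n_cells, config$t_end, config$dt, config$save_stride,
    seed %% 2^32, seed %/% 2^32, isTRUE(full_state),
    config$burn_in %||% 10
  )
  ens <- list(
    gfap = out$gfap, time = as.numeric(out$time), signal = signal,
    variant = spec$variant, seed_used = config$seed
  )
  if (isTRUE(full_state)) {
    fs <- array(out$full_state,
                dim = c(config$n_cells, 10L, length(ens$time)))
    dimnames(fs) <- list(NULL, spec$state_names, NULL)
    ens$full_state <- fs
  }
  structure(ens, class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf(
    "<trajectory_ensemble> %s, dose %g ng/ml, noise %s: %d cells x %d time points\n",
    x$variant, x$signal$ct_dose, x$signal$noise_label,
    nrow(x$gfap), ncol(x$gfap)
  ))
  invisible(x)
}

#' Simulate all 16 ensembles of a model variant
#'
#' Runs [simulate_ensemble()] over the full signal grid. Each signal uses a
#' seed derived from `config$seed` and the signal index through a
#' counter-based scheme, so the full grid is reproducible from one master
#' seed and individual ensembles can be regenerated in isolation.
#'
#' @inheritParams simulate_ensemble
#' @param grid Optional signal grid (defaults to
#'   `build_signal_grid(spec$variant)`).
#' @return A list of 16 `trajectory_ensemble` objects, names `s01`..`s16`.
#' @export
simulate_signal_grid <- function(spec, config = sim_config(), grid = NULL,
                                 full_state = FALSE) {
  if (is.null(grid)) grid <- build_signal_grid(spec$variant)
  purrr::map(seq_len(nrow(grid)), function(i) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, i)
    simulate_ensemble(spec, grid[i, ], cfg, full_state = full_state)
  }) |>
    rlang::set_names(sprintf("s%02d", seq_len(nrow(grid))))
}

#' Derive a child RNG seed from a parent seed and counter
#'
#' Deterministic 31-bit hash used to fan a master seed out to replicates,
#' signals and other subtasks without stream collisions.
#'
#' @param seed Parent integer seed.
#' @param ... One or more non-negative integer counters.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed) %% 2147483647
  for (i in idx) {
    h <- (h * 48271 + as.double(i) * 16807 + 12345) %% 2147483647
  }
  as.integer(h + 1)
}

#' Fraction of cells reaching the differentiation threshold
#'
#' The differentiation potential is the fraction of the simulated population
#' whose GFAP reaches `threshold` (default 0.8). Two criteria are exposed:
#' `"any"` counts a cell if it touches the threshold at any saved time point
#' (the potential metric); `"terminal"` counts it only if GFAP is at or above
#' threshold at the final time (the criterion used for the
#' terminally-differentiated subpopulation filter). With stochastic
#' trajectories the any-time count is inflated by transient noise excursions,
#' so noise-level comparisons are best made with the terminal criterion.
#'
#' @param ens A `trajectory_ensemble`.
#' @param threshold Positive GFAP threshold (default 0.8).
#' @param criterion `"any"` or `"terminal"`.
#' @return A fraction in `[0, 1]`.
#' @export
differentiation_potential <- function(ens, threshold = 0.8,
                                      criterion = c("any", "terminal")) {
  stopifnot(inherits(ens, "trajectory_ensemble"), threshold > 0)
  criterion <- match.arg(criterion)
  if (nrow(ens$gfap) == 0) rlang::abort("empty ensemble")
  hit <- switch(criterion,
    any = apply(ens$gfap, 1, max) >= threshold,
    terminal = ens$gfap[, ncol(ens$gfap)] >= threshold
  )
  mean(hit)
}

#' Write / read a trajectory ensemble as CSV with a JSON sidecar
#'
#' The CSV stores the time grid as its header row (hours) and one row per
#' cell; the sidecar (same path with extension `.json`) records the signal,
#' variant, seed, and a hash of the drift parameters for provenance.
#'
#' @param ens A `trajectory_ensemble`.
#' @param path CSV output path.
#' @param spec The `glioma_model` used (for the parameter hash).
#' @return `path`, invisibly.
#' @export
write_ensemble_csv <- function(ens, path, spec = NULL) {
  stopifnot(inherits(ens, "trajectory_ensemble"))
  m <- ens$gfap
  colnames(m) <- format(ens$time, trim = TRUE)
  utils::write.csv(m, path, row.names = FALSE)
  meta <- list(
    variant = ens$variant,
    signal = as.list(ens$signal),
    seed = ens$seed_used,
    n_cells = nrow(m),
    param_hash = if (!is.null(spec)) {
      sum(unname(spec$drift_params) * seq_along(spec$drift_params)) |>
        signif(12)
    } else NULL
  )
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ensemble_csv
#' @export
read_ensemble_csv <- function(path) {
  m <- as.matrix(utils::read.csv(path, check.names = FALSE))
  meta_path <- sub("\\.csv$", ".json", path)
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  sig <- if (!is.null(meta$signal)) tibble::as_tibble(meta$signal) else
    tibble::tibble(ct_dose = NA_real_, noise_label = NA_character_)
  structure(
    list(gfap = unname(m), time = as.numeric(colnames(m)), signal = sig,
         variant = meta$variant %||% NA_character_,
         seed_used = meta$seed %||% NA_integer_),
    class = "trajectory_ensemble"
  )
}
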