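#' Build the 16-signal grid for a model variant
#'
#' A composite signal is one cholera-toxin dose combined with one noise
#' setting; each model variant is driven by the Cartesian product of 4 doses
#' (0, 5, 7.5, 10 ng/ml) and 4 noise settings, giving 16 channel inputs. The
#' grid is returned dose-major: dose varies slowest, the noise level cycles
#' within each dose in table order (AN: 0.1%, 1%, 5%, 10%; CLE/CLE-: LL, HL,
#' LH, HH).
#'
#' @param variant `"AN"`, `"CLE"` or `"CLE-"`.
#' @return A tibble with 16 rows and columns `signal_id` (1..16), `variant`,
#'   `ct_dose` (ng/ml), `noise_label`, and the realized noise intensities:
#'   `sigma_int`/`sigma_ext` (CLE family; `NA` for AN) and `sigma_an`
#'   (AN; `NA` for CLE family).
#' @export
#' @examples
#' build_signal_grid("CLE")
build_signal_grid <- function(variant = c("AN", "CLE", "CLE-")) {
  variant <- match.arg(variant)
  raw <- .gliacap_params()$signals
  doses <- unlist(raw$ct_doses)
  if (variant == "AN") {
    noise <- tibble::tibble(
      noise_label = unlist(raw$an_noise$labels),
      sigma_int = NA_real_, sigma_ext = NA_real_,
      sigma_an = unlist(raw$an_noise$sigma)
    )
  } else {
    noise <- tibble::tibble(
      noise_label = unlist(raw$cle_noise$labels),
      sigma_int = unlist(raw$cle_noise$sigma_int),
      sigma_ext = unlist(raw$cle_noise$sigma_ext),
      sigma_an = NA_real_
    )
  }
  grid <- tidyr::expand_grid(ct_dose = doses, noise)
  grid |>
    dplyr::mutate(signal_id = dplyr::row_number(), variant = variant,
                  .before = 1) |>
    dplyr::relocate("signal_id", "variant", "ct_dose", "noise_label")
}

#' Simulation configuration
#'
#' @param n_cells Number of cells per ensemble (default 500).
#' @param t_end Simulated time horizon in hours (default 48).
#' @param dt Euler-Maruyama integration step in hours (default 0.01).
#' @param save_stride Output thinning: one saved point every `save_stride`
#'   integration steps (default 10, i.e. saved grid spacing 0.1 h, 481
#'   points over 48 h).
#' @param burn_in Stochastic settling period at dose 0 before treatment
#'   starts, in hours (default 10). Each cell rests at its own untreated
#'   steady state and accumulates its noise process during this window, so
#'   baselines at t = 0 carry cell-to-cell variability; 0 starts every cell
#'   exactly at its deterministic rest state.
#' @param seed Integer RNG seed for the ensemble.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 500, t_end = 48, dt = 0.01,
                       save_stride = 10, burn_in = 10, seed = 1) {
  stopifnot(n_cells >= 2, t_end > 0, dt > 0, save_stride >= 1, burn_in >= 0)
  n_steps <- round(t_end / dt)
  if (abs(n_steps * dt - t_end) > 1e-9) {
    rlang::abort("`t_end` must be an integral number of `dt` steps.")
  }
  if (n_steps %% save_stride != 0) {
    rlang::abort("`save_stride` must divide the number of integration steps.")
  }
  structure(
    list(n_cells = as.integer(n_cells), t_end = t_end, dt = dt,
         save_stride = as.integer(save_stride), burn_in = burn_in,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}
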