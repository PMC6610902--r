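#' Scalar trajectory descriptors
#'
#' Each cell's GFAP time course can be reduced to one of three summary
#' descriptors: the maximum GFAP level (`max_response`), the ratio of the
#' maximum to the initial level (`max_fold_change`), and the trapezoidal area
#' under the curve (`auc`). Descriptors are computed on the saved output
#' grid (default spacing 0.1 h), i.e. on what an observer of the simulation
#' would record, not on the internal integration grid.
#'
#' `max_fold_change` (and the fold transformation) require a positive initial
#' level: cells with initial GFAP at or below `eps_init` are excluded and
#' counted, never silently assigned infinite values.
#'
#' @param gfap_row Numeric vector: one cell's trajectory.
#' @param time_grid Time grid in hours (for `auc`).
#' @param eps_init Admissibility floor for the initial level (default 1e-8).
#' @return A scalar.
#' @name descriptors
NULL

#' @rdname descriptors
#' @export
max_response <- function(gfap_row) {
  if (length(gfap_row) == 0) rlang::abort("empty trajectory")
  if (!all(is.finite(gfap_row))) rlang::abort("non-finite trajectory values")
  max(gfap_row)
}

#' @rdname descriptors
#' @export
max_fold_change <- function(gfap_row, eps_init = 1e-8) {
  if (length(gfap_row) == 0) rlang::abort("empty trajectory")
  if (!all(is.finite(gfap_row))) rlang::abort("non-finite trajectory values")
  if (gfap_row[1] <= eps_init) return(NA_real_)
  max(gfap_row) / gfap_row[1]
}

#' @rdname descriptors
#' @export
auc <- function(gfap_row, time_grid) {
  if (length(gfap_row) != length(time_grid)) {
    rlang::abort("trajectory and time grid lengths differ")
  }
  if (is.unsorted(time_grid, strictly = TRUE)) {
    rlang::abort("time grid must be strictly increasing")
  }
  dt <- diff(time_grid)
  sum(dt * (gfap_row[-length(gfap_row)] + gfap_row[-1]) / 2)
}

#' Fold-transform an ensemble
#'
#' Divides every cell's time course pointwise by its own initial GFAP level,
#' so transformed trajectories start at 1. Cells whose initial level is at or
#' below `eps_init` are dropped, with the count recorded in the
#' `n_excluded` attribute.
#'
#' @param ens A `trajectory_ensemble`.
#' @param eps_init Admissibility floor (default 1e-8).
#' @return A `trajectory_ensemble` with transformed `gfap`.
#' @export
fold_transform <- function(ens, eps_init = 1e-8) {
  stopifnot(inherits(ens, "trajectory_ensemble"))
  init <- ens$gfap[, 1]
  keep <- init > eps_init
  out <- ens
  out$gfap <- ens$gfap[keep, , drop = FALSE] / init[keep]
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Tidy descriptor table for a set of ensembles
#'
#' Computes all three descriptors for every cell of every ensemble and
#' returns them in long form, ready for summarising or plotting. Cells
#' excluded from `max_fold_change` (initial level below the floor) appear as
#' `NA` for that descriptor only.
#'
#' @param ensembles A list of `trajectory_ensemble` objects (e.g. from
#'   [simulate_signal_grid()]).
#' @param eps_init Fold admissibility floor.
#' @return A tibble with columns `variant`, `signal_id` (list position),
#'   `ct_dose`, `noise_label`, `cell`, `descriptor`, `value`.
#' @export
describe_ensembles <- function(ensembles, eps_init = 1e-8) {
  if (inherits(ensembles, "trajectory_ensemble")) ensembles <- list(ensembles)
  purrr::imap(ensembles, function(ens, idx) {
    g <- ens$gfap
    mr <- apply(g, 1, max)
    fc <- ifelse(g[, 1] > eps_init, mr / g[, 1], NA_real_)
    dt <- diff(ens$time)
    area <- as.vector(((g[, -ncol(g), drop = FALSE] +
                          g[, -1, drop = FALSE]) / 2) %*% dt)
    tibble::tibble(
      variant = ens$variant,
      signal_id = if (is.character(idx)) match(idx, names(ensembles)) else idx,
      ct_dose = ens$signal$ct_dose,
      noise_label = ens$signal$noise_label,
      cell = rep(seq_len(nrow(g)), 3),
      descriptor = rep(c("max_response", "max_fold_change", "auc"),
                       each = nrow(g)),
      value = c(mr, fc, area)
    )
  }) |>
    purrr::list_rbind()
}
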