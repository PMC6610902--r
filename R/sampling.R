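#' Time-point sampling plans for multivariate response vectors
#'
#' A sampling plan selects `d` saved time-point indices from a trajectory;
#' each cell's GFAP values at those indices form its d-dimensional response
#' vector. Three strategies are provided:
#'
#' * `symmetric_plan()` — the default: `d` indices uniformly spaced around
#'   the middle time point, at fractional positions `j / (d + 1)` of the
#'   interval (interior spacing, symmetric about the midpoint).
#' * `balanced_plan()` — the interval is split into `d` contiguous
#'   equal-length index blocks (any remainder spread over the leading
#'   blocks); within each block the index with maximum pooled variance is
#'   chosen.
#' * `greedy_plan()` — the `d` indices with largest pooled variance over the
#'   whole interval, returned in time order.
#'
#' Ties are always broken toward the earlier time point, so plans are
#' deterministic functions of the variance profile.
#'
#' @param time_grid Saved time grid (hours), length `T`.
#' @param d Response vector dimension (default 6).
#' @param variance Per-time-point pooled variance (length `T`), from
#'   [pooled_timepoint_variance()].
#' @param endpoints For `symmetric_plan()`: if `TRUE`, span the full interval
#'   including both endpoints instead of the interior placement.
#' @return A `sampling_plan`: list with `strategy`, `d`, `indices` (strictly
#'   increasing, 1-based).
#' @name sampling_plans
NULL

new_sampling_plan <- function(strategy, d, indices) {
  stopifnot(length(indices) == d, !anyDuplicated(indices),
            !is.unsorted(indices, strictly = TRUE))
  structure(list(strategy = strategy, d = as.integer(d),
                 indices = as.integer(indices)),
            class = "sampling_plan")
}

#' @export
print.sampling_plan <- function(x, ...) {
  cat(sprintf("<sampling_plan> %s, d = %d: indices %s\n",
              x$strategy, x$d, paste(x$indices, collapse = ", ")))
  invisible(x)
}

#' @rdname sampling_plans
#' @export
symmetric_plan <- function(time_grid, d = 6, endpoints = FALSE) {
  T_len <- length(time_grid)
  if (d > T_len) rlang::abort("`d` cannot exceed the number of time points")
  if (d == T_len) return(new_sampling_plan("symmetric", d, seq_len(T_len)))
  idx <- if (endpoints) {
    round(seq(1, T_len, length.out = d))
  } else {
    round(1 + (T_len - 1) * seq_len(d) / (d + 1))
  }
  idx <- unique(as.integer(idx))
  # collision from rounding on tiny grids: fall back to distinct positions
  while (length(idx) < d) {
    cand <- setdiff(seq_len(T_len), idx)
    idx <- sort(c(idx, cand[ceiling(length(cand) / 2)]))
  }
  new_sampling_plan("symmetric", d, sort(idx))
}

#' Pooled per-time-point GFAP variance
#'
#' Variance of GFAP across all cells of all supplied ensembles, pooled into a
#' single profile per time point (the convention used to drive the
#' asymmetric plans: one plan per dataset).
#'
#' @param ensembles List of `trajectory_ensemble` objects on a shared grid.
#' @return Numeric vector of variances, one per time point.
#' @export
pooled_timepoint_variance <- function(ensembles) {
  if (inherits(ensembles, "trajectory_ensemble")) ensembles <- list(ensembles)
  grids <- purrr::map(ensembles, "time")
  if (!all(purrr::map_lgl(grids, identical, grids[[1]]))) {
    rlang::abort("ensembles must share one time grid")
  }
  g <- do.call(rbind, purrr::map(ensembles, "gfap"))
  apply(g, 2, stats::var)
}

#' @rdname sampling_plans
#' @export
balanced_plan <- function(variance, d = 6) {
  T_len <- length(variance)
  if (T_len < d) rlang::abort("need at least `d` time points")
  base <- T_len %/% d
  rem <- T_len %% d
  sizes <- rep(base, d) + c(rep(1L, rem), rep(0L, d - rem))
  stops <- cumsum(sizes)
  starts <- c(1L, utils::head(stops, -1) + 1L)
  idx <- purrr::map2_int(starts, stops, function(a, b) {
    block <- variance[a:b]
    a + which.max(block) - 1L    # which.max: first maximum = earliest tie
  })
  new_sampling_plan("balanced", d, idx)
}

#' @rdname sampling_plans
#' @export
greedy_plan <- function(variance, d = 6) {
  T_len <- length(variance)
  if (T_len < d) rlang::abort("need at least `d` time points")
  ord <- order(-variance, seq_len(T_len))  # ties -> earlier index
  new_sampling_plan("greedy", d, sort(ord[seq_len(d)]))
}

#' Assemble a response dataset from ensembles and a plan
#'
#' Stacks, for every cell of every ensemble, the GFAP values at the plan's
#' time indices into an `N x d` matrix with the ensemble index as the class
#' label — the input format of the capacity estimator. With
#' `transform = "fold"` each trajectory is first divided by its initial
#' value (inadmissible cells dropped and counted per signal). Scalar
#' descriptor datasets are built with [descriptor_dataset()] and share the
#' same container.
#'
#' @param ensembles List of `trajectory_ensemble` objects (the S signals).
#' @param plan A `sampling_plan`.
#' @param transform `"raw"` or `"fold"`.
#' @param eps_init Fold admissibility floor.
#' @return A `response_dataset`: list with `X` (N x d matrix), `labels`
#'   (integer class per row), `counts` (cells per class), `plan`,
#'   `transform`, `excluded` (per-class drop counts).
#' @export
assemble_response_dataset <- function(ensembles, plan,
                                      transform = c("raw", "fold"),
                                      eps_init = 1e-8) {
  transform <- match.arg(transform)
  stopifnot(inherits(plan, "sampling_plan"))
  if (inherits(ensembles, "trajectory_ensemble")) ensembles <- list(ensembles)
  T_len <- length(ensembles[[1]]$time)
  if (any(plan$indices < 1 | plan$indices > T_len)) {
    rlang::abort("plan indices fall outside the time grid")
  }
  excluded <- integer(length(ensembles))
  rows <- purrr::imap(ensembles, function(ens, idx) {
    g <- ens$gfap
    if (transform == "fold") {
      keep <- g[, 1] > eps_init
      i <- if (is.character(idx)) match(idx, names(ensembles)) else idx
      excluded[i] <<- sum(!keep)
      g <- g[keep, , drop = FALSE] / g[keep, 1]
    }
    g[, plan$indices, drop = FALSE]
  })
  X <- do.call(rbind, rows)
  if (!all(is.finite(X))) rlang::abort("non-finite response values")
  labels <- rep(seq_along(rows), vapply(rows, nrow, 0L))
  new_response_dataset(X, labels, plan, transform, excluded)
}

new_response_dataset <- function(X, labels, plan, transform = "raw",
                                 excluded = NULL) {
  stopifnot(nrow(X) == length(labels))
  counts <- tabulate(labels, nbins = max(labels))
  structure(
    list(X = unname(as.matrix(X)), labels = as.integer(labels),
         counts = counts, plan = plan, transform = transform,
         excluded = excluded),
    class = "response_dataset"
  )
}

#' @export
print.response_dataset <- function(x, ...) {
  cat(sprintf(
    "<response_dataset> %d vectors x %d dims, %d classes (n = %s)\n",
    nrow(x$X), ncol(x$X), length(x$counts),
    paste(range(x$counts), collapse = "-")
  ))
  invisible(x)
}

#' Build a scalar-descriptor response dataset
#'
#' Wraps one descriptor value per cell into a d = 1 `response_dataset`, so
#' static (descriptor) and dynamic (vector) channel capacities run through
#' the same estimator.
#'
#' @param ensembles List of `trajectory_ensemble` objects.
#' @param descriptor `"max_response"`, `"max_fold_change"` or `"auc"`.
#' @param eps_init Fold admissibility floor for `max_fold_change`.
#' @return A `response_dataset` with `d = 1`.
#' @export
descriptor_dataset <- function(ensembles,
                               descriptor = c("max_response",
                                              "max_fold_change", "auc"),
                               eps_init = 1e-8) {
  descriptor <- match.arg(descriptor)
  if (inherits(ensembles, "trajectory_ensemble")) ensembles <- list(ensembles)
  excluded <- integer(length(ensembles))
  vals <- purrr::imap(ensembles, function(ens, idx) {
    g <- ens$gfap
    v <- switch(descriptor,
      max_response = apply(g, 1, max),
      max_fold_change = {
        keep <- g[, 1] > eps_init
        i <- if (is.character(idx)) match(idx, names(ensembles)) else idx
        excluded[i] <<- sum(!keep)
        apply(g[keep, , drop = FALSE], 1, max) / g[keep, 1]
      },
      auc = {
        dt <- diff(ens$time)
        as.vector(((g[, -ncol(g), drop = FALSE] +
                      g[, -1, drop = FALSE]) / 2) %*% dt)
      }
    )
    matrix(v, ncol = 1)
  })
  X <- do.call(rbind, vals)
  labels <- rep(seq_along(vals), vapply(vals, nrow, 0L))
  plan <- new_sampling_plan("descriptor", 1L, 1L)
  plan$strategy <- paste0("descriptor:", descriptor)
  new_response_dataset(X, labels, plan, "raw", excluded)
}

#' Serialize a sampling plan to JSON
#'
#' @param plan A `sampling_plan`.
#' @param path Output path.
#' @param time_grid Optional grid whose hash is stored for provenance.
#' @return `path`, invisibly.
#' @export
write_plan_json <- function(plan, path, time_grid = NULL) {
  obj <- list(strategy = plan$strategy, d = plan$d, indices = plan$indices)
  if (!is.null(time_grid)) {
    obj$grid_hash <- signif(sum(time_grid * seq_along(time_grid)), 12)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
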