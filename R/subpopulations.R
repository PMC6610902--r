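#' Retain the terminally differentiated subpopulation
#'
#' Keeps the cells whose GFAP is at or above `threshold` at the final saved
#' time point — the criterion used when removing non-differentiated cells
#' before a capacity calculation. An ensemble left empty is returned with
#' zero rows and flagged via the `emptied` attribute.
#'
#' @param ens A `trajectory_ensemble`.
#' @param threshold GFAP threshold (default 0.8).
#' @return A `trajectory_ensemble` containing the retained cells; attribute
#'   `n_removed` records the cut.
#' @export
filter_terminal_differentiated <- function(ens, threshold = 0.8) {
  stopifnot(inherits(ens, "trajectory_ensemble"), threshold > 0)
  keep <- ens$gfap[, ncol(ens$gfap)] >= threshold
  out <- ens
  out$gfap <- ens$gfap[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "emptied") <- !any(keep)
  out
}

#' k-means clustering of response trajectories
#'
#' Clusters one signal's cells by their entire saved GFAP time course
#' (points in R^T, Euclidean distance): greedy kmeans++-style seeding from a
#' fixed RNG stream, 20 restarts of Lloyd iteration, best within-cluster sum
#' of squares kept (ties resolved toward the lowest restart index). Clusters
#' are then rank-labelled C1, C2, C3 by descending mean GFAP over all cells
#' and time points in the cluster, which makes labels comparable across
#' signals and invariant to input row order.
#'
#' @param ens A `trajectory_ensemble`.
#' @param n_clusters Number of clusters (default 3).
#' @param seed RNG seed for seeding and restarts.
#' @param n_restarts Number of seeded restarts (default 20).
#' @return A `cluster_assignment`: list with `labels` (factor `C1`..`Ck` per
#'   cell), `centroids` (k x T matrix, rank order), `mean_gfap` (per
#'   cluster, descending), `sizes`, `degenerate` flag.
#' @export
cluster_trajectories <- function(ens, n_clusters = 3, seed = 1,
                                 n_restarts = 20) {
  stopifnot(inherits(ens, "trajectory_ensemble"))
  X <- ens$gfap
  if (nrow(X) < n_clusters) {
    rlang::abort("fewer cells than requested clusters")
  }
  distinct_rows <- nrow(unique(X))
  if (distinct_rows < n_clusters) {
    labels <- factor(rep("C1", nrow(X)),
                     levels = paste0("C", seq_len(n_clusters)))
    return(structure(
      list(labels = labels,
           centroids = rbind(colMeans(X),
                             matrix(NA_real_, n_clusters - 1, ncol(X))),
           mean_gfap = c(mean(X), rep(NA_real_, n_clusters - 1)),
           sizes = c(nrow(X), rep(0L, n_clusters - 1)),
           degenerate = TRUE),
      class = "cluster_assignment"
    ))
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    centers <- .kmeanspp_centers(X, n_clusters, derive_seed(seed, r))
    fit <- suppressWarnings(
      stats::kmeans(X, centers = centers, iter.max = 100,
                    algorithm = "Lloyd")
    )
    if (is.null(best) || fit$tot.withinss < best$tot.withinss - 1e-12) {
      best <- fit
    }
  }
  mean_per_cluster <- vapply(
    seq_len(n_clusters),
    function(cl) mean(X[best$cluster == cl, , drop = FALSE]),
    0
  )
  rank_order <- order(-mean_per_cluster)
  relabel <- integer(n_clusters)
  relabel[rank_order] <- seq_len(n_clusters)
  labels <- factor(paste0("C", relabel[best$cluster]),
                   levels = paste0("C", seq_len(n_clusters)))
  structure(
    list(labels = labels,
         centroids = best$centers[rank_order, , drop = FALSE],
         mean_gfap = mean_per_cluster[rank_order],
         sizes = as.integer(table(labels)),
         degenerate = FALSE),
    class = "cluster_assignment"
  )
}

# Greedy kmeans++ seeding with a private RNG stream.
.kmeanspp_centers <- function(X, k, seed) {
  old <- .save_seed(seed)
  on.exit(.restore_seed(old))
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k - 1) + 1) {
    tot <- sum(d2)
    pick <- if (tot <= 0) sample.int(n, 1) else
      sample.int(n, 1, prob = d2 / tot)
    centers[j, ] <- X[pick, ]
    d2 <- pmin(d2, rowSums((X - matrix(centers[j, ], n, ncol(X),
                                       byrow = TRUE))^2))
  }
  centers
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf(
    "<cluster_assignment> %d clusters (sizes %s), mean GFAP %s%s\n",
    length(x$sizes), paste(x$sizes, collapse = "/"),
    paste(round(x$mean_gfap, 3), collapse = " > "),
    if (x$degenerate) " [degenerate]" else ""
  ))
  invisible(x)
}

#' Per-cluster channel capacities
#'
#' For every rank label (C1..Ck) assembles a response dataset from that
#' label's cells across all signals — matched by rank, the only link between
#' clusters of different signals — and estimates its channel capacity.
#' Signals whose block for a label has `k + 1` or fewer cells are dropped
#' from that label's dataset with a warning; the retained signal count is
#' recorded.
#'
#' @param ensembles List of S `trajectory_ensemble` objects.
#' @param assignments List of S `cluster_assignment` objects (same order).
#' @param plan A `sampling_plan` for the response vectors.
#' @param k Neighbour count for the estimator.
#' @param ... Passed to [estimate_capacity()].
#' @return A tibble with one row per cluster label: `cluster`,
#'   `capacity_bits`, `mi_at_uniform`, `n_signals`, `n_cells`, and the
#'   estimate object in `estimate`.
#' @export
per_cluster_capacity <- function(ensembles, assignments, plan, k = 5, ...) {
  stopifnot(length(ensembles) == length(assignments))
  n_clusters <- length(assignments[[1]]$sizes)
  labs <- paste0("C", seq_len(n_clusters))
  purrr::map(labs, function(lab) {
    subsets <- purrr::map2(ensembles, assignments, function(ens, asg) {
      out <- ens
      out$gfap <- ens$gfap[asg$labels == lab, , drop = FALSE]
      out
    })
    sizes <- purrr::map_int(subsets, ~ nrow(.x$gfap))
    ok <- sizes > k + 1
    if (!all(ok)) {
      rlang::warn(sprintf(
        "cluster %s: dropping %d signal(s) with <= k + 1 cells", lab,
        sum(!ok)
      ))
    }
    if (sum(ok) < 2) {
      return(tibble::tibble(cluster = lab, capacity_bits = NA_real_,
                            mi_at_uniform = NA_real_,
                            n_signals = sum(ok), n_cells = sum(sizes[ok]),
                            estimate = list(NULL)))
    }
    data <- assemble_response_dataset(subsets[ok], plan)
    est <- estimate_capacity(data, k = k, ...)
    tibble::tibble(cluster = lab, capacity_bits = est$capacity_bits,
                   mi_at_uniform = est$mi_at_uniform,
                   n_signals = sum(ok), n_cells = nrow(data$X),
                   estimate = list(est))
  }) |>
    purrr::list_rbind()
}
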