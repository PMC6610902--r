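#' Experiment configuration for replicated capacity runs
#'
#' Describes which conditions [run_replicates()] evaluates: model variants,
#' response representations (scalar descriptors, raw and fold-transformed
#' d-dimensional vectors), sampling strategies, and the subpopulation
#' analyses. Every replicate re-simulates all 16 ensembles of each model
#' from a replicate-specific seed derived from `master_seed`, so the
#' reported spread covers both simulation and estimation variability
#' (set `resimulate = FALSE` to re-run only the estimator on fixed data).
#'
#' @param models Character subset of `c("AN", "CLE", "CLE-")`.
#' @param descriptors Evaluate the three scalar descriptors (default TRUE).
#' @param strategies Sampling strategies for the vector representation,
#'   subset of `c("symmetric", "balanced", "greedy")`.
#' @param transforms Vector representations, subset of `c("raw", "fold")`.
#' @param subpopulations Run the terminal-differentiation filter and C1-C3
#'   cluster capacities (default FALSE).
#' @param strategy_models,subpop_models Models on which the asymmetric
#'   sampling strategies and the subpopulation analyses run (default
#'   `"CLE"`, the model they were designed around; symmetric sampling runs
#'   on every model).
#' @param n_replicates Number of replications (default 10; at least 2 for
#'   any significance test).
#' @param n_cells,t_end Simulation size per ensemble.
#' @param k,d Estimator neighbour count and vector dimension.
#' @param master_seed Master RNG seed.
#' @param resimulate Re-simulate ensembles each replicate (default TRUE).
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(models = c("AN", "CLE", "CLE-"),
                              descriptors = TRUE,
                              strategies = "symmetric",
                              transforms = c("raw", "fold"),
                              subpopulations = FALSE,
                              strategy_models = "CLE",
                              subpop_models = "CLE",
                              n_replicates = 10,
                              n_cells = 500, t_end = 48,
                              k = 5, d = 6,
                              master_seed = 1,
                              resimulate = TRUE) {
  models <- match.arg(models, c("AN", "CLE", "CLE-"), several.ok = TRUE)
  strategies <- match.arg(strategies, c("symmetric", "balanced", "greedy"),
                          several.ok = TRUE)
  transforms <- match.arg(transforms, c("raw", "fold"), several.ok = TRUE)
  stopifnot(n_replicates >= 1, n_cells >= 2, k >= 1, d >= 1)
  structure(
    list(models = models, descriptors = descriptors,
         strategies = strategies, transforms = transforms,
         subpopulations = subpopulations,
         strategy_models = strategy_models,
         subpop_models = subpop_models,
         n_replicates = as.integer(n_replicates),
         n_cells = as.integer(n_cells), t_end = t_end,
         k = as.integer(k), d = as.integer(d),
         master_seed = as.integer(master_seed),
         resimulate = isTRUE(resimulate)),
    class = "experiment_config"
  )
}

#' Run the replicated capacity experiment
#'
#' For every replicate and model: simulates the 16 signal ensembles,
#' assembles the configured representations, and estimates each one's
#' channel capacity. Output is a tidy table, one row per (model,
#' representation, strategy, subset, replicate).
#'
#' @param config An [experiment_config()].
#' @param progress Emit a message per replicate (default FALSE).
#' @return A tibble with columns `model`, `representation`
#'   (`max_response`, `max_fold_change`, `auc`, `vector_raw`,
#'   `vector_fold`), `strategy`, `subset` (`full`, `final_diff`,
#'   `C1`..`C3`), `replicate`, `capacity_bits`, `mi_at_uniform`,
#'   `converged`.
#' @export
run_replicates <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  specs <- purrr::map(config$models, glioma_model)
  names(specs) <- config$models
  base_ens <- NULL
  if (!config$resimulate) {
    base_ens <- purrr::map(specs, function(sp) {
      simulate_signal_grid(sp, sim_config(
        n_cells = config$n_cells, t_end = config$t_end,
        seed = derive_seed(config$master_seed, 0)
      ))
    })
  }
  rows <- purrr::map(seq_len(config$n_replicates), function(rep_i) {
    if (progress) message("replicate ", rep_i)
    purrr::imap(specs, function(sp, model) {
      ens <- if (config$resimulate) {
        simulate_signal_grid(sp, sim_config(
          n_cells = config$n_cells, t_end = config$t_end,
          seed = derive_seed(config$master_seed, rep_i,
                             match(model, config$models))
        ))
      } else base_ens[[model]]
      .replicate_rows(ens, model, rep_i, config)
    }) |>
      purrr::list_rbind()
  }) |>
    purrr::list_rbind()
  rows
}

.replicate_rows <- function(ens, model, rep_i, config) {
  out <- list()
  row_of <- function(est, representation, strategy, subset) {
    tibble::tibble(
      model = model, representation = representation, strategy = strategy,
      subset = subset, replicate = rep_i,
      capacity_bits = est$capacity_bits, mi_at_uniform = est$mi_at_uniform,
      converged = est$converged
    )
  }
  if (isTRUE(config$descriptors)) {
    for (desc in c("max_response", "max_fold_change", "auc")) {
      est <- estimate_capacity(descriptor_dataset(ens, desc), k = config$k)
      out <- c(out, list(row_of(est, desc, "static", "full")))
    }
  }
  time <- ens[[1]]$time
  variance <- NULL
  plans <- list()
  strategies <- config$strategies
  if (!model %in% (config$strategy_models %||% config$models)) {
    strategies <- intersect(strategies, "symmetric")
  }
  for (strat in strategies) {
    plans[[strat]] <- switch(strat,
      symmetric = symmetric_plan(time, config$d),
      balanced = {
        if (is.null(variance)) variance <- pooled_timepoint_variance(ens)
        balanced_plan(variance, config$d)
      },
      greedy = {
        if (is.null(variance)) variance <- pooled_timepoint_variance(ens)
        greedy_plan(variance, config$d)
      }
    )
  }
  for (strat in names(plans)) {
    for (tr in config$transforms) {
      # fold-transformed data only for the default plan (the Fig-4 contrast)
      if (tr == "fold" && strat != "symmetric") next
      est <- estimate_capacity(
        assemble_response_dataset(ens, plans[[strat]], transform = tr),
        k = config$k
      )
      out <- c(out, list(row_of(est, paste0("vector_", tr), strat, "full")))
    }
  }
  if (isTRUE(config$subpopulations) &&
      model %in% (config$subpop_models %||% config$models)) {
    plan <- plans[["symmetric"]] %||% symmetric_plan(time, config$d)
    filt <- purrr::map(ens, filter_terminal_differentiated)
    sizes <- purrr::map_int(filt, ~ nrow(.x$gfap))
    ok <- sizes > config$k + 1
    if (sum(ok) >= 2) {
      est <- estimate_capacity(
        assemble_response_dataset(filt[ok], plan), k = config$k
      )
      out <- c(out, list(row_of(est, "vector_raw", "symmetric",
                                "final_diff")))
    }
    asg <- purrr::imap(ens, function(e, i) {
      cluster_trajectories(e, seed = derive_seed(
        config$master_seed, rep_i, 100 +
          (if (is.character(i)) match(i, names(ens)) else i)
      ))
    })
    cl <- per_cluster_capacity(ens, asg, plan, k = config$k)
    for (j in seq_len(nrow(cl))) {
      if (is.na(cl$capacity_bits[j])) next
      est <- cl$estimate[[j]]
      out <- c(out, list(row_of(est, "vector_raw", "symmetric",
                                cl$cluster[j])))
    }
  }
  purrr::list_rbind(out)
}

#' Welch comparison of two conditions' replicate capacities
#'
#' Two-sample t test (unequal-variance Welch form, via [stats::t.test()])
#' on the replicate capacity values of two conditions selected from a
#' [run_replicates()] table.
#'
#' @param table A [run_replicates()] result.
#' @param condition_a,condition_b Named lists (or one-row data frames) of
#'   column filters, e.g. `list(model = "CLE", representation =
#'   "vector_raw", strategy = "symmetric", subset = "full")`.
#' @return A one-row tibble: `mean_a`, `mean_b`, `sd_a`, `sd_b`, `n_a`,
#'   `n_b`, `t_statistic`, `p_value`, `degenerate` (TRUE when both sides
#'   have zero variance and the test is decided by mean equality).
#' @export
compare_conditions <- function(table, condition_a, condition_b) {
  pick <- function(cond) {
    rows <- table
    for (nm in names(cond)) {
      rows <- rows[rows[[nm]] == cond[[nm]], , drop = FALSE]
    }
    rows$capacity_bits
  }
  a <- pick(condition_a); b <- pick(condition_b)
  if (length(a) < 2 || length(b) < 2) {
    rlang::abort("need at least 2 replicates per condition")
  }
  degenerate <- stats::sd(a) == 0 && stats::sd(b) == 0
  if (degenerate) {
    t_stat <- if (mean(a) == mean(b)) 0 else Inf * sign(mean(a) - mean(b))
    p <- if (mean(a) == mean(b)) 1 else 0
  } else {
    ht <- stats::t.test(a, b, var.equal = FALSE)
    t_stat <- unname(ht$statistic)
    p <- ht$p.value
  }
  tibble::tibble(
    mean_a = mean(a), mean_b = mean(b),
    sd_a = stats::sd(a), sd_b = stats::sd(b),
    n_a = length(a), n_b = length(b),
    t_statistic = t_stat, p_value = p, degenerate = degenerate
  )
}

#' Summarise a replicate table
#'
#' Mean and standard deviation of capacity per condition, the form in which
#' replicated capacities are reported.
#'
#' @param table A [run_replicates()] result.
#' @return A tibble grouped summary, one row per condition.
#' @export
summarize_replicates <- function(table) {
  table |>
    dplyr::group_by(.data$model, .data$representation, .data$strategy,
                    .data$subset) |>
    dplyr::summarise(
      mean_bits = mean(.data$capacity_bits),
      sd_bits = stats::sd(.data$capacity_bits),
      n = dplyr::n(), .groups = "drop"
    )
}
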