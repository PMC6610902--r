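#' Synthetic channels with known information content
#'
#' These generators produce `response_dataset` objects whose true mutual
#' information or channel capacity is computable independently of the kNN
#' estimator — by exact Blahut-Arimoto on a discrete transition matrix, by
#' quadrature for Gaussian mixtures, or by construction. They exist to
#' validate the estimator and the samplers without any signaling-model
#' parameters.
#'
#' @name fixtures
NULL

#' Exact capacity of a discrete memoryless channel
#'
#' Classical Blahut-Arimoto iteration on a true S x M transition matrix.
#' This is the fixtures' truth engine; it never sees estimated densities.
#'
#' @param transition Row-stochastic S x M matrix.
#' @param tol Convergence tolerance in bits (default 1e-10).
#' @param max_iter Iteration cap.
#' @return List with `capacity_bits` and `weights`.
#' @export
ba_discrete_capacity <- function(transition, tol = 1e-10, max_iter = 10000) {
  P <- as.matrix(transition)
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-9)) {
    rlang::abort("`transition` must be row-stochastic")
  }
  S <- nrow(P)
  w <- rep(1 / S, S)
  logP <- ifelse(P > 0, log2(P), 0)
  for (it in seq_len(max_iter)) {
    q <- as.vector(crossprod(w, P))
    D <- rowSums(P * (logP - rep(ifelse(q > 0, log2(q), 0),
                                 each = S) * (P > 0)))
    cap_lo <- sum(w * D)
    if (max(D) - cap_lo < tol) {
      return(list(capacity_bits = cap_lo, weights = w))
    }
    w <- w * 2^(D - max(D))
    w <- w / sum(w)
  }
  list(capacity_bits = sum(w * D), weights = w)
}

#' @describeIn fixtures Jittered-atom realization of a discrete channel:
#'   class `s` emits atom `m` (site coordinate `m - 1` on the line, embedded
#'   in `d` dimensions) with probability `confusion[s, m]`, plus Gaussian
#'   jitter much smaller than the unit site spacing. True capacity comes
#'   from [ba_discrete_capacity()] on the exact matrix.
#' @param confusion Row-stochastic S x M matrix.
#' @param n_per_signal Samples per class.
#' @param jitter Atom jitter standard deviation (default 1e-3).
#' @param d Embedding dimension (default 1; extra coordinates are jitter
#'   only).
#' @param seed RNG seed.
#' @return List with `data` (a `response_dataset`), `true_capacity_bits`,
#'   and `true_weights`.
#' @export
make_discrete_channel <- function(confusion, n_per_signal = 500, jitter = 1e-3,
                                  d = 1, seed = 1) {
  P <- as.matrix(confusion)
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-9)) {
    rlang::abort("`confusion` must be row-stochastic")
  }
  S <- nrow(P); M <- ncol(P)
  truth <- ba_discrete_capacity(P)
  old <- .save_seed(seed)
  on.exit(.restore_seed(old))
  X <- matrix(0, S * n_per_signal, d)
  labels <- rep(seq_len(S), each = n_per_signal)
  for (s in seq_len(S)) {
    sites <- sample.int(M, n_per_signal, replace = TRUE, prob = P[s, ])
    rows <- (s - 1) * n_per_signal + seq_len(n_per_signal)
    X[rows, 1] <- (sites - 1) + stats::rnorm(n_per_signal, sd = jitter)
    if (d > 1) {
      X[rows, -1] <- stats::rnorm(n_per_signal * (d - 1), sd = jitter)
    }
  }
  plan <- new_sampling_plan("fixture", d, seq_len(d))
  list(data = new_response_dataset(X, labels, plan),
       true_capacity_bits = truth$capacity_bits,
       true_weights = truth$weights)
}

#' @describeIn fixtures Class-conditional isotropic Gaussian channel. The
#'   true mutual information at uniform weights is
#'   `H(mixture) - (d/2) log2(2 pi e sigma^2)`, with the mixture entropy
#'   integrated numerically: adaptive quadrature in d = 1, tensor
#'   Gauss-Hermite in d = 2, and seeded Monte Carlo (error estimate
#'   reported) above.
#' @param means S x d matrix of class means.
#' @param sigma Common isotropic standard deviation.
#' @param mc_n Monte Carlo size for d > 2 truth integration.
#' @return List with `data`, `true_mi_uniform_bits`, `truth_se_bits`.
#' @export
make_gaussian_channel <- function(means, sigma, n_per_signal = 500, seed = 1,
                                  mc_n = 200000) {
  mu <- as.matrix(means)
  stopifnot(sigma > 0)
  S <- nrow(mu); d <- ncol(mu)
  old <- .save_seed(seed)
  on.exit(.restore_seed(old))
  X <- matrix(0, S * n_per_signal, d)
  labels <- rep(seq_len(S), each = n_per_signal)
  for (s in seq_len(S)) {
    rows <- (s - 1) * n_per_signal + seq_len(n_per_signal)
    X[rows, ] <- matrix(stats::rnorm(n_per_signal * d, sd = sigma),
                        ncol = d) +
      matrix(mu[s, ], n_per_signal, d, byrow = TRUE)
  }
  truth <- gaussian_mixture_mi(mu, sigma, mc_n = mc_n)
  plan <- new_sampling_plan("fixture", d, seq_len(d))
  list(data = new_response_dataset(X, labels, plan),
       true_mi_uniform_bits = truth$mi_bits,
       truth_se_bits = truth$se_bits)
}

#' True mutual information of a uniform isotropic Gaussian mixture
#'
#' Numerical integration of `H(Y) - H(Y | S)` for `Y | S = s` Gaussian with
#' mean `means[s, ]` and isotropic sd `sigma`, `S` uniform.
#'
#' @inheritParams make_gaussian_channel
#' @return List with `mi_bits` and `se_bits` (0 for deterministic
#'   quadrature).
#' @export
gaussian_mixture_mi <- function(means, sigma, mc_n = 200000) {
  mu <- as.matrix(means)
  S <- nrow(mu); d <- ncol(mu)
  cond_ent <- d / 2 * log2(2 * pi * exp(1) * sigma^2)
  mix_log_density <- function(Y) {
    # Y: n x d matrix -> log2 mixture density per row
    comps <- vapply(seq_len(S), function(s) {
      sq <- rowSums((Y - matrix(mu[s, ], nrow(Y), d, byrow = TRUE))^2)
      -sq / (2 * sigma^2)
    }, numeric(nrow(Y)))
    if (is.null(dim(comps))) comps <- matrix(comps, nrow = 1)
    mx <- apply(comps, 1, max)
    (mx + log(rowMeans(exp(comps - mx)))) / log(2) -
      d / 2 * log2(2 * pi * sigma^2)
  }
  if (d == 1) {
    # expectation of -log2 p_mix under each component, integrated where the
    # component actually lives; the component average is the mixture entropy
    H <- 0
    for (s in seq_len(S)) {
      integrand <- function(y) {
        ld <- mix_log_density(matrix(y, ncol = 1))
        -stats::dnorm(y, mu[s, 1], sigma) * ld
      }
      H <- H + stats::integrate(integrand, mu[s, 1] - 12 * sigma,
                                mu[s, 1] + 12 * sigma, rel.tol = 1e-10,
                                subdivisions = 2000L)$value / S
    }
    return(list(mi_bits = H - cond_ent, se_bits = 0))
  }
  if (d == 2) {
    gh <- .gauss_hermite(80)
    # integrate H(Y) = -E_Y[log2 p(Y)]; Y drawn per mixture component,
    # component average gives the mixture expectation exactly.
    nodes <- sqrt(2) * sigma * gh$nodes
    wts <- gh$weights / sqrt(pi)
    H <- 0
    for (s in seq_len(S)) {
      Y <- as.matrix(expand.grid(nodes + mu[s, 1], nodes + mu[s, 2]))
      W <- as.vector(outer(wts, wts))
      H <- H - sum(W * mix_log_density(Y)) / S
    }
    return(list(mi_bits = H - cond_ent, se_bits = 0))
  }
  old <- .save_seed(20231115L)
  on.exit(.restore_seed(old))
  comp <- sample.int(S, mc_n, replace = TRUE)
  Y <- matrix(stats::rnorm(mc_n * d, sd = sigma), ncol = d) + mu[comp, ]
  ld <- mix_log_density(Y)
  list(mi_bits = mean(-ld) - cond_ent, se_bits = stats::sd(ld) / sqrt(mc_n))
}

.gauss_hermite <- function(n) {
  # Golub-Welsch: eigen-decomposition of the Hermite Jacobi matrix
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

#' @describeIn fixtures Well-separated cluster fixture for subpopulation
#'   tests: each signal's population is a mixture of `n_clusters` levels with
#'   signal-dependent separation per cluster (cluster 1 strongly
#'   dose-separated, last cluster flat).
#' @param S Number of signals.
#' @param n_clusters Number of within-signal clusters.
#' @export
make_separated_clusters <- function(S = 4, n_per_signal = 120, n_clusters = 3,
                                    sigma = 0.02, seed = 1) {
  old <- .save_seed(seed)
  on.exit(.restore_seed(old))
  T_len <- 25
  time <- seq(0, 48, length.out = T_len)
  base_levels <- c(0.9, 0.5, 0.1)[seq_len(n_clusters)]
  sep <- c(0.5, 0.2, 0)[seq_len(n_clusters)]  # dose sensitivity per cluster
  sizes <- rep(n_per_signal %/% n_clusters, n_clusters)
  sizes[1] <- sizes[1] + n_per_signal %% n_clusters
  ens <- purrr::map(seq_len(S), function(s) {
    g <- do.call(rbind, purrr::map(seq_len(n_clusters), function(cl) {
      lvl <- base_levels[cl] * (1 + sep[cl] * (s - 1) / max(S - 1, 1))
      matrix(lvl, sizes[cl], T_len) +
        matrix(stats::rnorm(sizes[cl] * T_len, sd = sigma), sizes[cl])
    }))
    structure(
      list(gfap = pmax(g, 0), time = time,
           signal = tibble::tibble(ct_dose = s, noise_label = "fixture"),
           variant = "fixture", seed_used = seed),
      class = "trajectory_ensemble"
    )
  })
  list(ensembles = ens, cluster_sizes = sizes,
       cluster_levels = base_levels)
}

#' @describeIn fixtures Trajectory toy for the samplers: sigmoidal baseline
#'   trajectories identical across signals except inside short windows
#'   around `spike_times`, where the level is dose-dependent. Pooled
#'   variance therefore peaks at the spikes, so balanced/greedy plans pick
#'   them up while the symmetric plan can miss them entirely.
#' @param T_len Number of saved time points.
#' @param spike_times Time indices (1-based) carrying the dose information.
#' @param spike_gain Dose separation at the spikes.
#' @param noise_sd Within-class jitter.
#' @export
make_trajectory_toy <- function(S = 4, n_per_signal = 150, T_len = 101,
                                spike_times = c(11, 91), spike_gain = 1,
                                noise_sd = 0.05, seed = 1) {
  stopifnot(all(spike_times >= 1), all(spike_times <= T_len))
  old <- .save_seed(seed)
  on.exit(.restore_seed(old))
  time <- seq(0, 48, length.out = T_len)
  base <- 1 / (1 + exp(-(time - 24) / 6))   # shared sigmoid
  ens <- purrr::map(seq_len(S), function(s) {
    g <- matrix(base, n_per_signal, T_len, byrow = TRUE)
    for (tp in spike_times) {
      g[, tp] <- g[, tp] + spike_gain * (s - 1) / max(S - 1, 1)
    }
    g <- g + matrix(stats::rnorm(n_per_signal * T_len, sd = noise_sd),
                    n_per_signal)
    structure(
      list(gfap = g, time = time,
           signal = tibble::tibble(ct_dose = s, noise_label = "toy"),
           variant = "toy", seed_used = seed),
      class = "trajectory_ensemble"
    )
  })
  ens
}

# Seed hygiene: fixtures set the R RNG locally and restore it afterwards.
.save_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  old
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
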