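#' k-nearest-neighbour conditional likelihood matrix
#'
#' Estimates, for every response vector, its conditional density under each
#' signal with the classical kNN density estimator: for sample `i` and class
#' `s`,
#' \deqn{L[s, i] = k / (m_s \, c_d \, r^d),}
#' where `r` is the Euclidean distance from vector `i` to its k-th nearest
#' neighbour among the class-`s` samples (excluding `i` itself when it
#' belongs to `s`), `m_s` the number of eligible neighbours (`n_s` or
#' `n_s - 1`), and `c_d` the volume of the d-dimensional unit ball. Zero
#' neighbour distances (exact duplicates, which arise at vanishing noise)
#' are replaced by the floor `dist_floor` so densities stay finite.
#'
#' @param data A `response_dataset`.
#' @param k Neighbour count (default 5).
#' @param dist_floor Replacement for zero k-th-neighbour distances
#'   (default 1e-12 response units).
#' @return A `likelihood_matrix`: list with `L` (S x N, strictly positive),
#'   `counts`, `k`, `d`.
#' @export
knn_likelihoods <- function(data, k = 5, dist_floor = 1e-12) {
  stopifnot(inherits(data, "response_dataset"), k >= 1)
  S <- length(data$counts)
  if (any(data$counts <= k)) {
    bad <- which(data$counts <= k)
    rlang::abort(sprintf(
      "class%s %s ha%s too few members for k = %d (counts: %s)",
      if (length(bad) > 1) "es" else "", paste(bad, collapse = ", "),
      if (length(bad) > 1) "ve" else "s", k,
      paste(data$counts[bad], collapse = ", ")
    ))
  }
  d <- ncol(data$X)
  res <- .cpp_knn_class_dist(data$X, data$labels, S, as.integer(k))
  r <- pmax(res$kth_dist, dist_floor)
  m <- matrix(res$counts, S, nrow(data$X))
  own <- cbind(data$labels, seq_len(nrow(data$X)))  # [s(i), i] positions
  m[(own[, 2] - 1) * S + own[, 1]] <- m[(own[, 2] - 1) * S + own[, 1]] - 1
  c_d <- pi^(d / 2) / gamma(d / 2 + 1)
  L <- k / (m * c_d * r^d)
  out <- list(L = L, counts = res$counts, labels = data$labels,
              k = as.integer(k), d = as.integer(d))
  out$class_idx <- split(seq_along(out$labels), out$labels)
  out$log2_own <- lapply(seq_len(S), function(s)
    log2(L[cbind(s, out$class_idx[[s]])]))
  structure(out, class = "likelihood_matrix")
}

#' Construct a likelihood matrix by hand
#'
#' Mainly useful for testing [mutual_information()] and
#' [maximize_capacity()] against direct arithmetic on small instances.
#'
#' @param L S x N matrix of strictly positive conditional densities.
#' @param labels Own class (1..S) of each of the N samples.
#' @param k,d Metadata (neighbour count, dimension); defaults 1.
#' @return A `likelihood_matrix`.
#' @export
likelihood_matrix <- function(L, labels, k = 1L, d = 1L) {
  L <- as.matrix(L)
  stopifnot(all(L > 0), ncol(L) == length(labels),
            all(labels %in% seq_len(nrow(L))))
  structure(list(L = L, counts = tabulate(labels, nbins = nrow(L)),
                 labels = as.integer(labels),
                 k = as.integer(k), d = as.integer(d)),
            class = "likelihood_matrix")
}

#' Plug-in mutual information at a given input distribution
#'
#' Evaluates the estimator
#' \deqn{\hat I(w) = \sum_s w_s \frac{1}{n_s} \sum_{i \in s}
#'       \log_2 \frac{L[s, i]}{\sum_{s'} w_{s'} L[s', i]},}
#' the difference between the response entropy and the conditional response
#' entropy under the same plug-in densities. The returned value is clipped
#' below at 0; the raw (possibly slightly negative) value is attached as the
#' `"raw"` attribute.
#'
#' @param lik A `likelihood_matrix` from [knn_likelihoods()].
#' @param weights Input distribution over the S signals (non-negative,
#'   summing to 1 within 1e-9).
#' @return Mutual information in bits.
#' @export
mutual_information <- function(lik, weights) {
  stopifnot(inherits(lik, "likelihood_matrix"))
  w <- as.numeric(weights)
  if (length(w) != nrow(lik$L) || any(w < -1e-12) ||
      abs(sum(w) - 1) > 1e-9) {
    rlang::abort("`weights` must be a probability vector over the S signals")
  }
  w <- pmax(w, 0)
  per <- .per_class_divergence(lik, w)
  raw <- sum(w * per)
  structure(max(raw, 0), raw = raw)
}

# D_s(w) = (1/n_s) sum_{i in s} log2( L[s,i] / q_w(i) ), the per-class
# divergence whose w-average is the plug-in MI and whose maximum upper-bounds
# the capacity.
.per_class_divergence <- function(lik, w) {
  q <- as.vector(crossprod(w, lik$L))          # mixture density at each sample
  S <- nrow(lik$L)
  idx_of <- lik$class_idx %||% split(seq_along(lik$labels), lik$labels)
  own <- lik$log2_own
  per <- numeric(S)
  for (s in seq_len(S)) {
    idx <- idx_of[[s]]
    lo <- if (is.null(own)) log2(lik$L[cbind(s, idx)]) else own[[s]]
    per[s] <- mean(lo - log2(q[idx]))
  }
  per
}

#' Maximize mutual information over input distributions
#'
#' Runs a Blahut-Arimoto-style multiplicative fixed point on the empirical
#' likelihood matrix: starting from uniform weights, each iteration sets
#' \eqn{w_s \propto w_s 2^{D_s(w)}} where \eqn{D_s} is the per-class
#' divergence of [mutual_information()]. For a true channel this update is
#' globally convergent with a non-decreasing objective; the empirical
#' objective (sample-weighted divergences) can dip transiently on the way
#' to the optimum, so the iteration is run undamped and the best iterate
#' seen is returned. Iteration stops when the capacity gap
#' \eqn{\max_s D_s(w) - \hat I(w)} falls below `tol` (converged), when the
#' best objective has not improved by `tol / 1000` over 100 iterations
#' (plateau; reported as not converged), or at `max_iter`. A
#' projected-gradient ascent (`method = "gradient"`) is provided as a
#' cross-check; both agree with brute-force simplex search on small
#' instances.
#'
#' @param lik A `likelihood_matrix`.
#' @param tol Stopping tolerance in bits (default 1e-4).
#' @param max_iter Iteration cap (default 10000).
#' @param method `"ba"` (default) or `"gradient"`.
#' @return A `capacity_estimate`: list with `capacity_bits`, `weights_opt`,
#'   `mi_at_uniform`, `n_iterations`, `converged`, `k`, `d`.
#' @export
maximize_capacity <- function(lik, tol = 1e-4, max_iter = 10000,
                              method = c("ba", "gradient")) {
  stopifnot(inherits(lik, "likelihood_matrix"))
  method <- match.arg(method)
  S <- nrow(lik$L)
  w <- rep(1 / S, S)
  mi_u <- as.numeric(mutual_information(lik, w))
  if (method == "gradient") {
    est <- .maximize_gradient(lik, tol, max_iter)
    est$mi_at_uniform <- mi_u
    return(est)
  }
  converged <- FALSE
  it <- 0
  best_obj <- -Inf
  best_w <- w
  last_check <- -Inf
  while (it < max_iter) {
    it <- it + 1
    per <- .per_class_divergence(lik, w)
    obj <- sum(w * per)
    if (obj > best_obj) { best_obj <- obj; best_w <- w }
    gap <- max(per) - obj
    if (gap < tol) { converged <- TRUE; break }
    if (it %% 100 == 0) {                   # plateau detection
      if (best_obj - last_check < tol / 1000) break
      last_check <- best_obj
    }
    w <- w * 2^(per - max(per))
    w <- w / sum(w)
  }
  # gradient polish: the empirical objective is only approximately a true
  # channel MI, so the fixed point can park marginally below the optimum on
  # small samples; short ascents from the best iterate (and, on small
  # instances, a few biased restarts) remove that slack.
  starts <- list(best_w, rep(1 / S, S))
  if (S <= 6) {
    for (s in seq_len(S)) {
      v <- rep(0.1 / (S - 1), S); v[s] <- 0.9
      starts <- c(starts, list(v))
    }
  }
  for (w0 in starts) {
    pol <- .polish_weights(lik, w0)
    if (pol$obj > best_obj) { best_obj <- pol$obj; best_w <- pol$w }
  }
  per <- .per_class_divergence(lik, best_w)
  converged <- converged || (max(per) - sum(best_w * per) < tol)
  cap <- max(best_obj, 0)
  new_capacity_estimate(cap, best_w, mi_u, it, converged, lik)
}

# Euclidean gradient of the empirical MI objective at w:
# dI/dw_t = D_t(w) - (1/ln 2) * sum_i beta_i L[t,i] / q(i),
# beta_i = w_{s(i)} / n_{s(i)}.
.mi_gradient <- function(lik, w, per = NULL) {
  if (is.null(per)) per <- .per_class_divergence(lik, w)
  q <- as.vector(crossprod(w, lik$L))
  beta <- (w / lik$counts)[lik$labels]
  per - as.vector(lik$L %*% (beta / q)) / log(2)
}

# softmax-parametrized BFGS ascent with the analytic gradient
.polish_weights <- function(lik, w0, maxit = 200) {
  eps <- 1e-12
  eta0 <- log(pmax(w0, eps))
  obj_fn <- function(eta) {
    w <- exp(eta - max(eta)); w <- w / sum(w)
    -sum(w * .per_class_divergence(lik, w))
  }
  gr_fn <- function(eta) {
    w <- exp(eta - max(eta)); w <- w / sum(w)
    g <- .mi_gradient(lik, w)
    -(w * (g - sum(w * g)))            # chain rule through softmax
  }
  opt <- stats::optim(eta0, obj_fn, gr_fn, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-14))
  w <- exp(opt$par - max(opt$par)); w <- w / sum(w)
  list(w = w, obj = -opt$value)
}

.maximize_gradient <- function(lik, tol, max_iter) {
  S <- nrow(lik$L)
  pol <- .polish_weights(lik, rep(1 / S, S), maxit = max_iter)
  per <- .per_class_divergence(lik, pol$w)
  new_capacity_estimate(max(pol$obj, 0), pol$w,
                        as.numeric(mutual_information(lik, rep(1 / S, S))),
                        NA_integer_,
                        max(per) - sum(pol$w * per) < max(tol, 1e-3), lik)
}

new_capacity_estimate <- function(cap, w, mi_u, iter, converged, lik) {
  stopifnot(cap >= 0, cap <= log2(length(w)) + 1e-9)
  structure(
    list(capacity_bits = cap, weights_opt = w, mi_at_uniform = mi_u,
         n_iterations = as.integer(iter), converged = converged,
         k = lik$k, d = lik$d, n_per_class = lik$counts),
    class = "capacity_estimate"
  )
}

#' @export
print.capacity_estimate <- function(x, ...) {
  cat(sprintf(
    "<capacity_estimate> %.4f bits (MI at uniform %.4f), S = %d, k = %d, d = %d, %s after %d iterations\n",
    x$capacity_bits, x$mi_at_uniform, length(x$weights_opt), x$k, x$d,
    if (x$converged) "converged" else "NOT converged", x$n_iterations
  ))
  invisible(x)
}

#' Estimate the channel capacity of a response dataset
#'
#' Convenience composition of [knn_likelihoods()] and
#' [maximize_capacity()]: the full plug-in channel-capacity estimator. The
#' estimate is always within `[0, log2(S)]`; no finite-sample extrapolation
#' is performed.
#'
#' @param data A `response_dataset`.
#' @param k Neighbour count (default 5).
#' @param tol,max_iter,method Passed to [maximize_capacity()].
#' @param dist_floor Passed to [knn_likelihoods()].
#' @return A `capacity_estimate`.
#' @export
#' @examples
#' fx <- make_discrete_channel(diag(4), n_per_signal = 60, seed = 1)
#' estimate_capacity(fx$data, k = 5)
estimate_capacity <- function(data, k = 5, tol = 1e-4, max_iter = 10000,
                              method = c("ba", "gradient"),
                              dist_floor = 1e-12) {
  lik <- knn_likelihoods(data, k = k, dist_floor = dist_floor)
  est <- maximize_capacity(lik, tol = tol, max_iter = max_iter,
                           method = method)
  est$plan <- data$plan
  est$transform <- data$transform
  est
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an estimated capacity: one row per signal with its optimal weight
#' @param x A `capacity_estimate`.
#' @param ... Unused.
#' @return A tibble with columns `signal`, `weight`, `n`.
#' @export
tidy.capacity_estimate <- function(x, ...) {
  tibble::tibble(
    signal = seq_along(x$weights_opt),
    weight = x$weights_opt,
    n = x$n_per_class
  )
}

#' One-row summary of an estimated capacity
#' @param x A `capacity_estimate`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.capacity_estimate <- function(x, ...) {
  tibble::tibble(
    capacity_bits = x$capacity_bits,
    mi_at_uniform = x$mi_at_uniform,
    n_signals = length(x$weights_opt),
    k = x$k, d = x$d,
    n_iterations = x$n_iterations,
    converged = x$converged
  )
}
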