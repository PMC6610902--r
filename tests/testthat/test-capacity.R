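test_that("kNN densities match a hand computation", {
  # class 1 on a line at 0..4, class 2 far away; k = 1
  X <- matrix(c(0, 1, 2, 3, 4, 1e4, 1e4 + 1, 1e4 + 2, 1e4 + 3, 1e4 + 4), ncol = 1)
  ds <- gliacap:::new_response_dataset(X, rep(1:2, each = 5),
                                       gliacap:::new_sampling_plan("t", 1, 1))
  lik <- knn_likelihoods(ds, k = 1)
  # query = the point at 0 (own class): r = 1, m = 4, c_1 = 2 -> 1/(4*2*1)
  expect_equal(lik$L[1, 1], 0.125)
  # interior point at 2: r = 1 as well
  expect_equal(lik$L[1, 3], 0.125)
  # cross-class likelihoods are vastly smaller than own-class ones
  expect_lt(max(lik$L[2, 1:5]), 1e-3 * min(lik$L[1, 1:5]))

  # duplicates: the distance floor keeps densities finite
  Xd <- matrix(rep(c(0, 5), each = 6), ncol = 1)
  dsd <- gliacap:::new_response_dataset(Xd, rep(1:2, each = 6),
                                        gliacap:::new_sampling_plan("t", 1, 1))
  likd <- knn_likelihoods(dsd, k = 2)
  expect_true(all(is.finite(likd$L)))
  expect_true(all(likd$L > 0))

  # a class with too few members fails loudly, naming the class
  ds_bad <- gliacap:::new_response_dataset(X[1:8, , drop = FALSE],
                                           c(rep(1L, 6), 2L, 2L),
                                           gliacap:::new_sampling_plan("t", 1, 1))
  expect_error(knn_likelihoods(ds_bad, k = 5), "class 2")
})

test_that("mutual information matches the explicit double sum", {
  # indistinguishable signals -> 0 bits
  L_same <- matrix(rep(c(2, 1, 3, 1), each = 3), nrow = 3, byrow = FALSE)
  lik0 <- likelihood_matrix(L_same, labels = rep(1:3, length.out = 4))
  expect_equal(as.numeric(mutual_information(lik0, rep(1 / 3, 3))), 0)

  # two perfectly separated signals at uniform weights -> 1 bit
  L_sep <- rbind(c(1, 1, 1e-30, 1e-30), c(1e-30, 1e-30, 1, 1))
  lik1 <- likelihood_matrix(L_sep, labels = c(1, 1, 2, 2))
  expect_equal(as.numeric(mutual_information(lik1, c(0.5, 0.5))), 1,
               tolerance = 1e-9)

  # small hand-set instance vs brute-force arithmetic
  set.seed(42)
  S <- 3; N <- 12
  L <- matrix(rexp(S * N), S, N)
  labels <- rep(1:S, each = 4)
  w <- c(0.2, 0.5, 0.3)
  lik <- likelihood_matrix(L, labels)
  direct <- 0
  for (s in 1:S) {
    for (i in which(labels == s)) {
      direct <- direct + w[s] * (1 / 4) * log2(L[s, i] / sum(w * L[, i]))
    }
  }
  expect_equal(attr(mutual_information(lik, w), "raw"), direct,
               tolerance = 1e-12)
  expect_error(mutual_information(lik, c(0.5, 0.6, 0.2)), "probability")
})

test_that("capacity maximization agrees with brute-force simplex search", {
  # mirror-symmetric two-signal instance -> uniform optimum
  set.seed(7)
  x <- rnorm(20)
  X <- matrix(c(x, -x), ncol = 1)
  ds <- gliacap:::new_response_dataset(X, rep(1:2, each = 20),
                                       gliacap:::new_sampling_plan("t", 1, 1))
  est <- maximize_capacity(knn_likelihoods(ds, k = 3))
  expect_equal(est$weights_opt, c(0.5, 0.5), tolerance = 0.02)

  # random S = 3 instances: BA vs 0.01-resolution grid search within 1e-3
  for (seed in c(1, 2, 3)) {
    set.seed(seed)
    X <- matrix(c(rnorm(10, 0), rnorm(10, 1.5), rnorm(10, 4)), ncol = 1)
    ds <- gliacap:::new_response_dataset(X, rep(1:3, each = 10),
                                         gliacap:::new_sampling_plan("t", 1, 1))
    lik <- knn_likelihoods(ds, k = 3)
    est <- maximize_capacity(lik)
    oracle <- grid_search_capacity(lik, 0.01)
    expect_equal(est$capacity_bits, oracle, tolerance = 1e-3)
    expect_gte(est$capacity_bits, as.numeric(mutual_information(
      lik, rep(1 / 3, 3))) - 1e-9)
    # gradient cross-check route agrees with the fixed point
    grad <- maximize_capacity(lik, method = "gradient")
    expect_equal(grad$capacity_bits, est$capacity_bits, tolerance = 5e-3)
  }
})

test_that("duplicated signals leave capacity at the merged-channel value", {
  # signal 3 duplicates signal 2's distribution: capacity == 2-signal value
  set.seed(12)
  a <- rnorm(40, 0, 0.5); b <- rnorm(40, 5, 0.5); b2 <- rnorm(40, 5, 0.5)
  ds3 <- gliacap:::new_response_dataset(matrix(c(a, b, b2), ncol = 1),
                                        rep(1:3, each = 40),
                                        gliacap:::new_sampling_plan("t", 1, 1))
  ds2 <- gliacap:::new_response_dataset(matrix(c(a, b), ncol = 1),
                                        rep(1:2, each = 40),
                                        gliacap:::new_sampling_plan("t", 1, 1))
  c3 <- maximize_capacity(knn_likelihoods(ds3, k = 5))$capacity_bits
  c2 <- maximize_capacity(knn_likelihoods(ds2, k = 5))$capacity_bits
  oracle3 <- grid_search_capacity(knn_likelihoods(ds3, k = 5), 0.01)
  expect_equal(c3, oracle3, tolerance = 1e-3)
  expect_equal(c3, c2, tolerance = 0.05)
})

test_that("capacity respects its information-theoretic bounds", {
  # same distribution for every signal -> near zero; 16 copies -> <= 4 bits
  set.seed(3)
  X16 <- matrix(rnorm(16 * 60), ncol = 1)
  ds16 <- gliacap:::new_response_dataset(X16, rep(1:16, each = 60),
                                         gliacap:::new_sampling_plan("t", 1, 1))
  est16 <- estimate_capacity(ds16, k = 5)
  expect_gte(est16$capacity_bits, 0)
  expect_lte(est16$capacity_bits, 4)
  expect_lt(est16$capacity_bits, 0.4)   # sixteen identical-copy classes

  # well-separated 4-class Gaussian in d = 2 -> ~2 bits
  fx <- make_gaussian_channel(10 * cbind(c(0, 1, 0, 1), c(0, 0, 1, 1)),
                              sigma = 0.5, n_per_signal = 200, seed = 9)
  est4 <- estimate_capacity(fx$data, k = 5)
  expect_equal(est4$capacity_bits, 2, tolerance = 0.05)
})

test_that("capacity is invariant to permuting vector coordinates", {
  ens <- cle_grid_small()[c(1, 9, 13, 16)]
  plan <- symmetric_plan(ens[[1]]$time, 4)
  ds <- assemble_response_dataset(ens, plan)
  perm <- ds
  perm$X <- ds$X[, c(3, 1, 4, 2)]
  e1 <- estimate_capacity(ds, k = 5)
  e2 <- estimate_capacity(perm, k = 5)
  expect_equal(e1$capacity_bits, e2$capacity_bits, tolerance = 1e-9)
})

test_that("tidy and glance summarise capacity estimates", {
  fx <- make_discrete_channel(diag(3), n_per_signal = 50, seed = 4)
  est <- estimate_capacity(fx$data, k = 5)
  td <- tidy(est)
  expect_equal(nrow(td), 3L)
  expect_equal(sum(td$weight), 1, tolerance = 1e-9)
  gl <- glance(est)
  expect_equal(gl$n_signals, 3L)
  expect_true(gl$capacity_bits <= log2(3) + 1e-9)
})
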