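test_that("symmetric plans sit evenly around the midpoint", {
  tg <- seq(0, 48, by = 0.1)            # 481 points
  p1 <- symmetric_plan(tg, 1)
  expect_equal(p1$indices, 241L)        # the middle time point
  p6 <- symmetric_plan(tg, 6)
  gaps <- diff(p6$indices)
  expect_true(all(abs(gaps - gaps[1]) <= 1))          # even spacing
  expect_equal(p6$indices + rev(p6$indices), rep(482L, 6))  # symmetry
  pall <- symmetric_plan(tg, length(tg))
  expect_equal(pall$indices, seq_along(tg))
  expect_error(symmetric_plan(tg, length(tg) + 1), "exceed")
})

test_that("pooled variance pools cells across all signals", {
  e1 <- fake_ensemble(matrix(0.3, 10, 5), time = 0:4)
  e2 <- fake_ensemble(matrix(0.3, 10, 5), time = 0:4)
  expect_equal(pooled_timepoint_variance(list(e1, e2)), rep(0, 5))

  # two signals with means 0 and 1, no within-signal noise -> 0.25 pooled
  ea <- fake_ensemble(matrix(0, 8, 5), time = 0:4)
  eb <- fake_ensemble(matrix(1, 8, 5), time = 0:4)
  v <- pooled_timepoint_variance(list(ea, eb))
  expect_equal(v, rep(0.25 * 16 / 15, 5))   # sample variance, n = 16

  # variance concentrated at one time point
  g <- matrix(0.5, 6, 5); g[1:3, 3] <- 1
  expect_equal(which.max(pooled_timepoint_variance(list(fake_ensemble(g, time = 0:4)))), 3L)

  expect_error(pooled_timepoint_variance(list(e1, fake_ensemble(matrix(0, 2, 4), time = 0:3))),
               "time grid")
})

test_that("balanced plan takes the per-block argmax with earliest-tie rule", {
  v <- rep(1, 12)
  p <- balanced_plan(v, 6)
  expect_equal(p$indices, c(1L, 3L, 5L, 7L, 9L, 11L))  # block starts on ties
  v2 <- seq_len(12)
  p2 <- balanced_plan(v2, 3)
  expect_equal(p2$indices, c(4L, 8L, 12L))             # block ends, increasing v
  # one spike per block is found exactly
  v3 <- rep(0, 20); spikes <- c(2L, 7L, 13L, 19L); v3[spikes] <- 5
  expect_equal(balanced_plan(v3, 4)$indices, spikes)
  # remainder spread over leading blocks
  p4 <- balanced_plan(rep(1, 10), 3)
  expect_equal(p4$indices, c(1L, 5L, 8L))              # blocks 4/3/3
})

test_that("greedy plan takes the global top-d, ties to earlier times", {
  v <- c(9, 8, 7, 1, 1, 1)
  expect_equal(greedy_plan(v, 3)$indices, 1:3)
  expect_equal(greedy_plan(rep(2, 6), 3)$indices, 1:3)
  v2 <- rep(0, 30); v2[c(4, 11, 25)] <- c(3, 5, 4)
  expect_equal(greedy_plan(v2, 3)$indices, c(4L, 11L, 25L))
})

test_that("balanced and greedy coincide for one dominant peak per block", {
  v <- rep(0.1, 24)
  peaks <- c(3L, 10L, 15L, 22L)
  v[peaks] <- c(7, 9, 8, 6)
  expect_equal(balanced_plan(v, 4)$indices, greedy_plan(v, 4)$indices)
})

test_that("response datasets stack cells with signal labels", {
  ens <- cle_grid_small()
  plan <- symmetric_plan(ens[[1]]$time, 6)
  ds <- assemble_response_dataset(ens, plan)
  expect_equal(dim(ds$X), c(16 * 150, 6))
  expect_equal(ds$counts, rep(150L, 16))
  expect_equal(ds$labels, rep(1:16, each = 150))
  expect_true(all(is.finite(ds$X)))

  # scalar descriptor dataset shares the container
  dd <- descriptor_dataset(ens, "max_response")
  expect_equal(ncol(dd$X), 1L)
  expect_equal(nrow(dd$X), 16 * 150)

  # duplicate plan indices are rejected by construction
  expect_error(gliacap:::new_sampling_plan("x", 3, c(1, 1, 2)))
  # out-of-grid indices rejected
  bad <- plan; bad$indices[1] <- 9999L
  expect_error(assemble_response_dataset(ens, bad), "outside")
})

test_that("fold assembly drops and counts inadmissible cells", {
  g <- rbind(c(0, 0.5, 1), c(0.2, 0.4, 0.8), c(0.1, 0.2, 0.4))
  ens <- list(fake_ensemble(g, time = 0:2), fake_ensemble(g + 0.05, time = 0:2))
  plan <- symmetric_plan(0:2, 2)
  ds <- assemble_response_dataset(ens, plan, transform = "fold")
  expect_equal(ds$counts, c(2L, 3L))
  expect_equal(ds$excluded, c(1L, 0L))
})
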