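test_that("zero-noise simulation matches an adaptive ODE solve of the drift", {
  skip_if_not_installed("deSolve")
  m <- glioma_model("AN")
  g <- build_signal_grid("AN")
  sig <- g[g$ct_dose == 10 & g$noise_label == "0.1%", ]
  sig$sigma_an <- 0  # noise forced off
  ens <- simulate_ensemble(m, sig, sim_config(n_cells = 2, seed = 1,
                                              burn_in = 0))
  rhs <- function(t, x, parms) {
    list(model_propensities(pmax(x, 0), m, 10)$drift)
  }
  sol <- deSolve::ode(y = unname(m$init), times = ens$time, func = rhs,
                      parms = NULL, rtol = 1e-8, atol = 1e-10)
  gfap_ode <- sol[, 11]
  expect_equal(ens$gfap[1, ], gfap_ode, tolerance = 1e-3)
  # both cells identical without noise
  expect_equal(ens$gfap[1, ], ens$gfap[2, ])
})

test_that("CLE with zero intrinsic and extrinsic noise gives identical cells", {
  m <- glioma_model("CLE")
  sig <- build_signal_grid("CLE")[13, ]
  sig$sigma_int <- 0; sig$sigma_ext <- 0
  ens <- simulate_ensemble(m, sig, sim_config(n_cells = 5, seed = 3))
  for (i in 2:5) expect_identical(ens$gfap[i, ], ens$gfap[1, ])
})

test_that("ensembles are bit-reproducible and non-negative", {
  m <- glioma_model("CLE")
  sig <- build_signal_grid("CLE")[16, ]  # dose 10, HH
  e1 <- simulate_ensemble(m, sig, sim_config(n_cells = 50, seed = 99))
  e2 <- simulate_ensemble(m, sig, sim_config(n_cells = 50, seed = 99))
  expect_identical(e1$gfap, e2$gfap)
  expect_true(all(is.finite(e1$gfap)))
  expect_true(all(e1$gfap >= 0))
  e3 <- simulate_ensemble(m, sig, sim_config(n_cells = 50, seed = 100))
  expect_false(identical(e1$gfap, e3$gfap))
  # time grid contract
  expect_equal(e1$time[1], 0)
  expect_equal(e1$time[length(e1$time)], 48)
  expect_true(all(diff(e1$time) > 0))
})

test_that("terminal GFAP rises with CT dose (CLE, low noise)", {
  m <- glioma_model("CLE")
  g <- build_signal_grid("CLE")
  cfg <- sim_config(n_cells = 60, seed = 11)
  term <- vapply(which(g$noise_label == "LL"), function(i) {
    mean(simulate_ensemble(m, g[i, ], cfg)$gfap[, 481])
  }, 0)
  expect_true(all(diff(term) > -1e-3))           # non-decreasing in dose
  expect_gt(term[4], term[1] + 0.3)              # dose 10 well above dose 0
})

test_that("CLE- enhances differentiation relative to CLE", {
  cle <- glioma_model("CLE")
  clem <- make_cle_minus(cle)
  g <- build_signal_grid("CLE")
  cfg <- sim_config(n_cells = 60, seed = 21)
  term <- function(spec, i) mean(simulate_ensemble(spec, g[i, ], cfg)$gfap[, 481])
  # strict improvement at the sub-switch doses, where feedback keeps CLE dark
  for (i in which(g$ct_dose %in% c(0, 5) & g$noise_label == "LL")) {
    expect_gt(term(clem, i), term(cle, i) + 0.2)
  }
  # averaged over the grid the enhancement persists
  full_cle <- mean(vapply(1:16, term, 0, spec = cle))
  full_clem <- mean(vapply(1:16, term, 0, spec = clem))
  expect_gt(full_clem, full_cle)
})

test_that("halving dt changes the population-mean time course by < 2%", {
  m <- glioma_model("CLE")
  sig <- build_signal_grid("CLE")[13, ]  # dose 10, LL (default-noise row)
  base <- simulate_ensemble(m, sig, sim_config(n_cells = 100, seed = 5))
  fine <- simulate_ensemble(m, sig, sim_config(n_cells = 100, dt = 0.005,
                                               save_stride = 20, seed = 5))
  expect_equal(base$time, fine$time)
  m1 <- colMeans(base$gfap); m2 <- colMeans(fine$gfap)
  expect_lt(max(abs(m1 - m2)) / max(abs(m1)), 0.02)
})

test_that("differentiation potential counts threshold crossings", {
  flat0 <- fake_ensemble(matrix(0, 5, 10))
  expect_equal(differentiation_potential(flat0), 0)
  flat1 <- fake_ensemble(matrix(1, 5, 10))
  expect_equal(differentiation_potential(flat1), 1)
  g <- matrix(0.5, 5, 10)
  g[1, 4] <- 0.85; g[2, 10] <- 0.9; g[3, 2] <- 0.81   # 3 of 5 cross 0.8
  mix <- fake_ensemble(g)
  expect_equal(differentiation_potential(mix, criterion = "any"), 0.6)
  expect_equal(differentiation_potential(mix, criterion = "terminal"), 0.2)
  expect_error(differentiation_potential(fake_ensemble(matrix(0, 0, 10))),
               "empty")
})

test_that("ensemble CSV round-trips with its JSON sidecar", {
  m <- glioma_model("CLE")
  sig <- build_signal_grid("CLE")[13, ]
  ens <- simulate_ensemble(m, sig, sim_config(n_cells = 5, seed = 2))
  path <- file.path(withr::local_tempdir(), "ens.csv")
  write_ensemble_csv(ens, path, spec = m)
  back <- read_ensemble_csv(path)
  expect_equal(back$gfap, unname(ens$gfap), tolerance = 1e-12)
  expect_equal(back$time, ens$time)
  expect_equal(back$signal$ct_dose, 10)
  expect_equal(back$variant, "CLE")
})
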