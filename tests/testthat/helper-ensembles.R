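# Shared simulation fixtures, built once per test run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .cache)) assign(key, force(expr), .cache)
  get(key, .cache)
}

# moderate-size CLE grid for qualitative property tests
cle_grid_small <- function() {
  cached("cle_grid_small", {
    simulate_signal_grid(glioma_model("CLE"),
                         sim_config(n_cells = 150, seed = 424242))
  })
}

# hand-built ensemble from a gfap matrix
fake_ensemble <- function(gfap, time = seq(0, 48, length.out = ncol(gfap)),
                          dose = 0, noise = "LL", variant = "CLE") {
  structure(
    list(gfap = gfap, time = time,
         signal = tibble::tibble(ct_dose = dose, noise_label = noise),
         variant = variant, seed_used = 0L),
    class = "trajectory_ensemble"
  )
}

# brute-force simplex grid search for S <= 3 (independent capacity oracle)
grid_search_capacity <- function(lik, resolution = 0.01) {
  S <- nrow(lik$L)
  stopifnot(S <= 3)
  steps <- seq(0, 1, by = resolution)
  best <- -Inf
  if (S == 2) {
    for (w1 in steps) {
      v <- as.numeric(mutual_information(lik, c(w1, 1 - w1)))
      if (v > best) best <- v
    }
  } else {
    for (w1 in steps) {
      for (w2 in seq(0, 1 - w1, by = resolution)) {
        v <- as.numeric(mutual_information(lik, c(w1, w2, 1 - w1 - w2)))
        if (v > best) best <- v
      }
    }
  }
  best
}
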