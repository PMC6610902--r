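#' Glioma differentiation model specifications
#'
#' @description
#' `glioma_model()` builds a model specification for one of the three
#' stochastic variants of the glioma differentiation network:
#'
#' * `"AN"` — additive-noise model: constant-intensity Brownian terms on every
#'   state, scaled by each state's dynamic range.
#' * `"CLE"` — chemical-Langevin-equation model: state-dependent multiplicative
#'   noise (square-root of the summed production and degradation propensities)
#'   for intrinsic noise, plus per-cell log-normal perturbation of the rate
#'   constants for extrinsic noise.
#' * `"CLE-"` — the CLE model with the cyclin D1 positive-feedback term
#'   weakened by `feedback_scale` (0 removes it entirely).
#'
#' The network has 10 states (PKA, CREB, IL6, JAK2, STAT3, PI3K, AKT,
#' phospho-GSK3B, cyclin D1, GFAP) and 41 rate constants, stored in a
#' packaged parameter file. The parameterisation is synthetic: it was
#' calibrated to reproduce the qualitative behaviour of the published system
#' (see the package vignette), not fitted to measurements. Cholera toxin (CT)
#' acts through two arms: a PKA/CREB/IL6/JAK2/STAT3 arm that drives GFAP
#' synthesis, and a PI3K/AKT/GSK3B arm whose inhibition de-represses
#' GSK3-driven cyclin D1 degradation. Cyclin D1 represses GFAP through an
#' ultrasensitive gate, so its dose-driven collapse is what licenses
#' differentiation.
#'
#' @param variant `"AN"`, `"CLE"` or `"CLE-"`.
#' @param feedback_scale Dimensionless multiplier on the cyclin D1
#'   positive-feedback synthesis term. Must be 1 for AN/CLE; in `[0, 1)` for
#'   CLE- (default 0, i.e. feedback removed).
#' @param params Optional named numeric vector of the 41 drift parameters,
#'   overriding the packaged values (names must match exactly).
#'
#' @return An object of class `glioma_model`: a list with elements `variant`,
#'   `state_names` (10), `drift_params` (41 named rates), `noise_weights`
#'   (per-species CLE noise scales), `an_scales` (per-state AN dynamic
#'   scales), `init` (shared untreated steady state) and `feedback_scale`.
#' @export
#' @examples
#' m <- glioma_model("CLE")
#' m$state_names
#' length(m$drift_params)
glioma_model <- function(variant = c("AN", "CLE", "CLE-"),
                         feedback_scale = NULL, params = NULL) {
  variant <- match.arg(variant)
  raw <- .gliacap_params()
  drift <- unlist(raw$drift_parameters)
  if (!is.null(params)) {
    if (!setequal(names(params), names(drift))) {
      rlang::abort("`params` must supply exactly the 41 named drift parameters.")
    }
    drift[names(params)] <- params
  }
  if (is.null(feedback_scale)) {
    feedback_scale <- if (variant == "CLE-") 0 else 1
  }
  if (variant %in% c("AN", "CLE") && feedback_scale != 1) {
    rlang::abort("`feedback_scale` must be 1 for the AN and CLE variants.")
  }
  if (variant == "CLE-" && (feedback_scale < 0 || feedback_scale >= 1)) {
    rlang::abort("`feedback_scale` must lie in [0, 1) for the CLE- variant.")
  }
  spec <- list(
    variant = variant,
    state_names = unlist(raw$states),
    drift_params = drift,
    noise_weights = unlist(raw$noise$cle_species_weights),
    an_scales = unlist(raw$noise$an_dynamic_scales),
    init = unlist(raw$initial_conditions),
    feedback_scale = feedback_scale
  )
  stopifnot(length(spec$state_names) == 10L, length(spec$drift_params) == 41L)
  structure(spec, class = "glioma_model")
}

#' Derive a CLE- specification from a CLE model
#'
#' Returns the same network with the cyclin D1 positive-feedback synthesis
#' term multiplied by `feedback_scale` and the variant relabelled `"CLE-"`.
#' Only the feedback term changes: all other drift contributions are
#' identical.
#'
#' @param spec A `glioma_model` with variant `"CLE"`.
#' @param feedback_scale Multiplier in `[0, 1)`; 0 (default) removes the
#'   feedback loop entirely.
#' @return A `glioma_model` with variant `"CLE-"`.
#' @export
make_cle_minus <- function(spec, feedback_scale = 0) {
  stopifnot(inherits(spec, "glioma_model"))
  if (spec$variant != "CLE") {
    rlang::abort("`make_cle_minus()` expects a CLE base specification.")
  }
  if (!is.numeric(feedback_scale) || length(feedback_scale) != 1 ||
      feedback_scale < 0 || feedback_scale >= 1) {
    rlang::abort("`feedback_scale` must be a single value in [0, 1).")
  }
  spec$variant <- "CLE-"
  spec$feedback_scale <- feedback_scale
  spec
}

#' @export
print.glioma_model <- function(x, ...) {
  cat(sprintf(
    "<glioma_model> variant %s, %d states, %d drift parameters, feedback scale %g\n",
    x$variant, length(x$state_names), length(x$drift_params), x$feedback_scale
  ))
  invisible(x)
}

.gliacap_params <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "glioma_params_synthetic.yaml",
                          package = "gliacap", mustWork = TRUE)
      cache <<- yaml::read_yaml(path)
    }
    cache
  }
})

#' Production and degradation propensities of the network (reference)
#'
#' Plain-R evaluation of the per-state production and degradation rates at
#' one state vector. This is the reference implementation of the drift field
#' (the compiled integrator reproduces it exactly); it is also the building
#' block for ODE cross-checks. The drift is `production - degradation`.
#'
#' @param state Numeric vector of 10 state values (model order).
#' @param spec A `glioma_model`.
#' @param ct_dose CT dose in ng/ml.
#' @return A list with numeric vectors `production` and `degradation`
#'   (length 10), and `drift` (their difference).
#' @export
model_propensities <- function(state, spec, ct_dose) {
  stopifnot(inherits(spec, "glioma_model"), length(state) == 10L)
  p <- as.list(spec$drift_params)
  fs <- spec$feedback_scale
  hill <- function(x, K, n) if (x <= 0) 0 else x^n / (K^n + x^n)
  PKA <- state[1]; CREB <- state[2]; IL6 <- state[3]; JAK2 <- state[4]
  STAT3 <- state[5]; PI3K <- state[6]; AKT <- state[7]; GSK <- state[8]
  CYC <- state[9]; GFAP <- state[10]
  A <- min(max(1 - GSK, 0), 1)                      # active GSK3beta
  gate <- p$K_r^p$n_r / (p$K_r^p$n_r + CYC^p$n_r)   # cyclin D1 repression gate
  production <- c(
    (p$b_pka + p$k_pka * hill(ct_dose, p$K_ct1, p$n_ct1)) * (1 - PKA),
    p$k_creb * PKA / (p$K_creb + PKA) * (1 - CREB),
    p$b_il6 + p$k_il6 * CREB,
    p$k_jak * IL6 / (p$K_jak + IL6) * (1 - JAK2),
    p$k_stat * JAK2 / (p$K_stat + JAK2) * (1 - STAT3),
    p$b_pi3k * (1 - PI3K),
    p$k_akt * PI3K / (p$K_akt + PI3K) * (1 - AKT),
    p$k_gsk * AKT / (p$K_gsk + AKT) * (1 - GSK),
    p$b_cyc + fs * p$k_fb * hill(CYC, p$K_fb, p$n_fb),
    (p$b_g + (p$k_g1 * STAT3 + p$k_g2 * CREB) * gate) * (1 - GFAP)
  )
  degradation <- c(
    p$d_pka * PKA,
    p$d_creb * CREB,
    p$d_il6 * IL6,
    p$d_jak * JAK2,
    p$d_stat * STAT3,
    (p$d_pi3k + p$k_ipi * hill(ct_dose, p$K_ct2, p$n_ct2)) * PI3K,
    p$d_akt * AKT,
    p$d_gsk * GSK,
    (p$d_cyc + p$k_deg * A / (p$K_deg + A)) * CYC,
    p$d_g * GFAP
  )
  names(production) <- names(degradation) <- spec$state_names
  list(production = production, degradation = degradation,
       drift = production - degradation)
}
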