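# Synthetic parameterisation of the 10-state glioma differentiation network.
#
# This is the package's own reconstruction: rate constants were calibrated so
# that the deterministic and stochastic model variants reproduce the published
# qualitative behaviour of the system (dose-graded differentiation, a
# proliferative high-cyclin-D1 attractor for untreated cells, ultrasensitive
# GFAP de-repression, noise-level-dependent suppression and heterogeneity).
# They are not measured values. Units: rates per hour, concentrations are
# dimensionless activity/abundance levels, CT dose in ng/ml.
schema: gliacap-params-v1
states:
  - PKA        # cholera-toxin activated PKA (via cAMP)
  - CREB       # phospho-CREB
  - IL6        # interleukin-6
  - JAK2       # active JAK2
  - STAT3      # phospho-STAT3
  - PI3K       # active PI3K
  - AKT        # phospho-AKT
  - GSK3B      # phospho-GSK3beta (inactive form; 1 - GSK3B is active kinase)
  - CCND1      # cyclin D1
  - GFAP       # glial fibrillary acidic protein (differentiation marker)
initial_conditions:
  PKA:   0.0476190476
  CREB:  0.0271493213
  IL6:   0.0671493213
  JAK2:  0.2010840108
  STAT3: 0.4010810811
  PI3K:  0.7692307692
  AKT:   0.3333333333
  GSK3B: 0.8510638298
  CCND1: 5.0766465423
  GFAP:  0.1666666667
drift_parameters:
  b_pka:  0.02    # basal PKA activation
  k_pka:  1.5     # CT-induced PKA activation (PKA/CREB arm)
  K_ct1:  8.0     # CT half-saturation for PKA arm, ng/ml
  n_ct1:  1.5     # CT Hill coefficient, PKA arm
  d_pka:  0.4     # PKA deactivation
  k_creb: 1.2     # PKA-dependent CREB phosphorylation
  K_creb: 2.0     # PKA Michaelis constant for CREB
  d_creb: 1.0     # CREB dephosphorylation
  b_il6:  0.02    # basal IL6 production
  k_il6:  0.5     # CREB-driven IL6 production
  d_il6:  0.5     # IL6 turnover
  k_jak:  2.0     # IL6-dependent JAK2 activation
  K_jak:  1.0     # IL6 Michaelis constant for JAK2
  d_jak:  0.5     # JAK2 deactivation
  k_stat: 2.0     # JAK2-dependent STAT3 phosphorylation
  K_stat: 1.0     # JAK2 Michaelis constant for STAT3
  d_stat: 0.5     # STAT3 dephosphorylation
  b_pi3k: 1.0     # basal PI3K activation
  d_pi3k: 0.3     # PI3K deactivation
  k_ipi:  15.0    # CT-induced PI3K inhibition (dose-graded arm)
  K_ct2:  9.0     # CT half-saturation for PI3K inhibition, ng/ml
  n_ct2:  3.0     # CT Hill coefficient, PI3K arm
  k_akt:  6.2     # PI3K-dependent AKT phosphorylation
  K_akt:  4.0     # PI3K Michaelis constant for AKT
  d_akt:  2.0     # AKT dephosphorylation
  k_gsk:  6.0     # AKT-dependent GSK3beta phosphorylation (inactivation)
  K_gsk:  2.0     # AKT Michaelis constant for GSK3beta
  d_gsk:  0.15    # GSK3beta dephosphorylation (re-activation)
  b_cyc:  0.08    # basal cyclin D1 synthesis
  k_fb:   1.82    # cyclin D1 positive-feedback synthesis (ultrasensitive)
  n_fb:   4.0     # feedback Hill coefficient
  K_fb:   1.4     # feedback half-saturation
  d_cyc:  0.02    # basal cyclin D1 turnover
  k_deg:  24.0    # active-GSK3-driven cyclin D1 degradation
  K_deg:  10.0    # GSK3 activity Michaelis constant for degradation
  b_g:    0.006   # basal GFAP synthesis
  k_g1:   0.45    # STAT3-driven GFAP synthesis
  k_g2:   0.15    # CREB-driven GFAP synthesis
  K_r:    0.24    # cyclin D1 repression threshold for GFAP
  n_r:    10.0    # repression Hill coefficient (ultrasensitive gate)
  d_g:    0.03    # GFAP turnover
noise:
  # CLE intrinsic noise: amplitude sigma_int * w_i * sqrt(prod_i + deg_i),
  # w_i an inverse-square-root copy-number scale per species.
  cle_species_weights:
    PKA: 1.0
    CREB: 1.0
    IL6: 1.0
    JAK2: 1.0
    STAT3: 1.0
    PI3K: 1.0
    AKT: 1.0
    GSK3B: 1.0
    CCND1: 2.0
    GFAP: 3.0
  # AN additive noise: amplitude sigma_an * dynamic scale of each state.
  an_dynamic_scales:
    PKA: 1.0
    CREB: 1.0
    IL6: 1.0
    JAK2: 1.0
    STAT3: 1.0
    PI3K: 1.0
    AKT: 1.0
    GSK3B: 1.0
    CCND1: 3.0
    GFAP: 1.0
signals:
  ct_doses: [0.0, 5.0, 7.5, 10.0]
  an_noise:                  # AN model: Brownian intensity as percent of scale
    labels: ["0.1%", "1%", "5%", "10%"]
    sigma:  [0.001, 0.01, 0.05, 0.1]
  cle_noise:                 # CLE models: intrinsic/extrinsic std pairs
    labels:    ["LL", "HL", "LH", "HH"]
    sigma_int: [0.001, 0.1, 0.001, 0.1]
    sigma_ext: [0.001, 0.001, 0.1, 0.1]
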