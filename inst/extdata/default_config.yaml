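# endoxsim default study configuration.
#
# model: joint tamoxifen-endoxifen population PK model.
#   PLACEHOLDER ESTIMATES — source-model estimates (to be transcribed from
#   the cited model publication). The structure (parameters, covariate
#   models, IIV placement) is fixed; the numeric values below are clearly
#   labelled placeholders chosen once to give plausible exposures
#   (endoxifen steady-state trough ~5-15 ng/mL at 20 mg QD in gNM).
#   Transcribe the published final estimates here for exact reproduction.
model:
  ka: 0.5          # 1/h, first-order absorption rate
  tlag: 0.5        # h, absorption lag time
  V_TAM: 1000      # L, apparent tamoxifen central volume (V/F)
  CL20: 5.1        # L/h, tamoxifen clearance to other metabolites (CL/F)
  CL23: 0.21       # L/h, tamoxifen-to-endoxifen formation clearance (CL/F)
  V_ENDX: 300      # L, apparent endoxifen central volume (V/F)
  CL30: 2.5        # L/h, endoxifen elimination clearance (CL/F)
  theta_AS:        # fractional change on CL23 per CYP2D6 activity score
    "0": -0.75
    "0.5": -0.50
    "1": -0.35
    "1.5": -0.15
    "2": 0.0
  theta_age: -0.2  # power exponent, age on CL20
  theta_wt: 0.75   # power exponent, weight on CL20
  age_ref: 55      # y
  wt_ref: 70       # kg
  omega2_CL23: 0.25   # log-scale IIV variance on CL23
  omega2_CL20: 0.06   # log-scale IIV variance on CL20
  sigma_prop: 0.20    # proportional (log-scale) residual error SD for TDM

# population: synthetic virtual cohort. The phenotype mixture matches the
# development cohort; age/weight marginals are configurable stand-ins for
# the unavailable clinical covariate table.
population:
  n_patients: 10000
  phenotype_probs: {gNM: 0.566, gIM: 0.378, gPM: 0.056}
  as_gNM: {"2": 0.8, "1.5": 0.2}
  as_gIM: {"1": 0.5, "0.5": 0.5}
  age_mean: 55
  age_sd: 12
  age_min: 25
  age_max: 90
  weight_median: 70
  weight_cv: 0.20
  omega2_CL23: 0.25
  omega2_CL20: 0.06

# strategies: the five evaluated dosing strategies.
strategies:
  - {strategy: conventional,  label: conventional}
  - {strategy: cyp2d6_guided, label: cyp2d6_guided}
  - {strategy: mipd, target_trough: 5.97, label: mipd_597}
  - {strategy: mipd, target_trough: 5.97, dose_increment: 10, label: mipd_597_plus10}
  - {strategy: mipd, target_trough: 9.0,  label: mipd_9}

adherence:
  nonadherent_fraction: 0.40
  phase1_weeks: 26      # full adherence ("6 months")
  phase2_weeks: 26      # missed-dose pattern applies
  scenarios: [1, 2]     # missed doses per week (2 = consecutive days)

seed: 20210203
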