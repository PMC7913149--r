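# endoxsim

Stochastic simulation of endoxifen target attainment under tamoxifen
dosing strategies and non-adherence.

## The problem

Tamoxifen, a mainstay of ER-positive breast cancer therapy, acts largely
through its CYP2D6-formed metabolite endoxifen. Steady-state minimum
endoxifen concentrations (C<sub>ss,min</sub>) above a proposed threshold of
5.97 ng/mL have been associated with better outcomes, yet roughly a fifth
of patients stay below it at the conventional 20 mg once-daily dose, and
long-term non-adherence (defined as &lt;80% intake — 1.4 missed doses per
week for a once-daily drug) is common. Precision dosing that titrates each
patient to a target exposure is attractive, but a dose chosen to sit *just*
above a threshold has no reserve when doses are missed.

`endoxsim` is for pharmacometricians and clinical-pharmacology researchers
who want to quantify that trade-off in silico. It implements:

* a joint parent–metabolite population PK model — first-order absorption
  with lag time into a tamoxifen compartment (V<sub>TAM</sub>/F) with
  parallel formation (CL<sub>23</sub>/F) and other-route elimination
  (CL<sub>20</sub>/F) clearances, and an endoxifen compartment
  (V<sub>ENDX</sub>/F, CL<sub>30</sub>/F); CYP2D6 activity score as a
  fractional change on CL<sub>23</sub>, age/weight power models on
  CL<sub>20</sub>, log-normal IIV on both — solved in closed form
  (tri-exponential superposition), with a geometric-series closed form for
  the periodic steady state of weekly intake patterns;
* a virtual-population generator (56.6% gNM / 37.8% gIM / 5.6% gPM activity
  score mixture, configurable age/weight marginals, seeded etas);
* five dosing strategies: conventional 20 mg; CYP2D6-guided 20/30/60 mg;
  and MIPD — genotype-guided initial dose, trough TDM at weeks 2/3/4, MAP
  estimation of (η<sub>CL23</sub>, η<sub>CL20</sub>) by minimising
  `J(η) = Σ (ln y − ln f(η))²/σ² + η²/ω²`, and selection of the smallest
  grid dose (5–120 mg) forecast to reach the target (5.97 ng/mL; a +10 mg
  variant; a 9 ng/mL safeguard variant);
* adherence scenarios: 26 weeks full adherence, then a 60/40
  adherent/non-adherent split with 1 or 2 consecutive doses missed per week
  for 26 weeks, assessed at 12 months via the periodic steady state;
* risk summaries: percent below target per strategy × phenotype × scenario,
  relative risk increases over the full-adherence baseline, medians and CV%.

The shipped parameter values are clearly-labelled placeholders producing
plausible exposures (the published source-model estimates can be
transcribed into `inst/extdata/default_config.yaml` for quantitative
reproduction); see `vignette("endoxsim-methods")`.

## Worked example

```r
library(endoxsim)

# one patient: CYP2D6 normal metaboliser, reference covariates
ind <- individual_params(tam_model(), activity_score = 2, age = 55, weight = 70)
ss_min_endx(ind, 20)                     # 13.16 ng/mL, full adherence
ss_min_endx(ind, 20, weekly_pattern(2))  # 9.22 ng/mL, 2 missed doses/week

# the full study on a 500-patient cohort
cfg <- study_config(population = population_spec(n = 500), seed = 42)
res <- run_study(cfg, verbose = FALSE)
subset(res$adherent_summary, phenotype == "Overall")
```

```
        strategy   n percent_below median_css cv_pct
    conventional 318          20.4      10.54   65.1
   cyp2d6_guided 318          10.4      12.14   58.1
        mipd_597 318          11.0       7.99   25.9
 mipd_597_plus10 318           0.0      13.83   35.8
          mipd_9 318           0.0      11.58   22.0
```

Among the 318 strictly adherent patients, conventional dosing leaves 20.4%
below the 5.97 ng/mL target; MIPD to the 5.97 target brings exposures close
to the threshold (median 7.99 ng/mL, CV 26%), while the 9 ng/mL safeguard
target attains it for everyone at moderate variability. The flip side
appears in the non-adherent arm (2 consecutive missed doses/week):

```r
subset(res$relative_risk, phenotype == "Overall" & scenario == 2)
```

```
        strategy risk_pct baseline_pct  rri
    conventional    40.66         20.4 1.99
   cyp2d6_guided    25.82         10.4 2.49
        mipd_597    54.95         11.0 4.99
 mipd_597_plus10     6.59          0.0   NA
          mipd_9     8.79          0.0   NA
```

The *relative* risk increase due to missed doses grows with the degree of
individualisation (MIPD 5.0× vs conventional 2.0×) — threshold-targeted
precision dosing is the least forgiving strategy — whereas raising the MIPD
target to 9 ng/mL keeps absolute risk lowest even under non-adherence
(`NA` ratios flag a zero adherent baseline).

`run_study(cfg, outdir = "results")` additionally writes per-patient CSVs
(population, dose decisions, assessments), the four summary tables and a
JSON run manifest. A thin command-line wrapper with `generate-population`,
`validate-config`, `run-study` and `summarize` subcommands is installed at
`system.file("scripts", "endoxsim.R", package = "endoxsim")`.

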