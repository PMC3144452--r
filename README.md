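# svycoxsim

Longitudinal cohort studies often select participants by **non-proportional
stratified sampling** — over-representing small population subgroups to gain
power — and then lose participants to follow-up. Both features are routinely
ignored when Cox proportional-hazards models are fitted, and both can bias
hazard-ratio estimates. `svycoxsim` is a simulation laboratory for
quantifying that bias: it generates a synthetic occupational cohort with a
known hazard structure, draws samples under simple-random and stratified
designs, imposes random or stratum-differential attrition, fits weighted and
unweighted Cox models of three specifications, and summarises bias, variance
and mean squared error of the hazard-ratio estimates over Monte-Carlo
replicates. It is aimed at biostatisticians and epidemiologists who want to
demonstrate — or teach — when design weights matter in survival analysis.

## The model

The cohort contains three occupational strata (professionals, technicians,
administrative staff; population shares 50.5% / 28% / 21.5%) with smoking
prevalence 15.9% / 20.9% / 25.3%. Time to myocardial infarction follows a
Weibull proportional-hazards model

h(t | x) = h₀(t) · exp(x′β),  h₀(t) = (a/b)(t/b)^(a−1),

with shape a = 2, scale b calibrated so ~15% of professional non-smokers
have an event within the 40-year administrative censoring horizon. The
stratum main-effect hazard ratios are 1.5 (technicians) and 3.0
(administrative) versus professionals, and smoking acts **in interaction
with stratum**: HR 1.5 / 2.0 / 3.0 within professionals / technicians /
administrative.

Sampling attaches design weights w_i = N_h/n_h (inverse selection
probabilities). The weighted Cox estimator solves the design-weighted score
equation

U(β) = Σᵢ wᵢ δᵢ { xᵢ − S⁽¹⁾(tᵢ;β)/S⁽⁰⁾(tᵢ;β) } = 0,
S⁽ʳ⁾(t;β) = Σ_{j: tⱼ ≥ t} wⱼ e^{xⱼ′β} xⱼ^{⊗r},

by Newton–Raphson (Breslow ties), with the design-based sandwich covariance
I(β̂)⁻¹ M I(β̂)⁻¹, where M is the sum of outer products of per-individual
weighted score residuals. The solver and sandwich are implemented natively
in this package; `survival::coxph` is used only as an independent
cross-check in the test suite.

Three model specifications are compared: **full** (stratum indicators plus
stratum-by-smoking interactions — the generating structure), **marginal**
(stratum indicators plus a common smoking effect) and **smoke-only** (the
crude smoking effect).

## Worked example

```r
library(svycoxsim)

spec   <- population_spec()                       # N = 52,750, defaults above
cohort <- generate_population(spec, seed = 2011)

# Census ("true" population) fit of the generating model
population_reference_fit(cohort, "full") |> tidy()
#>   term          estimate    hr     se robust_se statistic  p.value
#> 1 tech             0.410  1.51 0.0264    0.0264      15.6 1.10e-54
#> 2 admin            1.08   2.95 0.0247    0.0247      43.7 0
#> 3 prof_smoking     0.422  1.53 0.0370    0.0371      11.4 4.35e-30
#> 4 tech_smoking     0.715  2.04 0.0351    0.0352      20.3 5.76e-92
#> 5 admin_smoking    1.10   3.02 0.0278    0.0276      40.0 0
```

The census fit recovers the generating hazard ratios (1.5, 3.0; 1.5, 2.0,
3.0) within sampling error. A stratified sample that oversamples the
high-hazard strata carries weights 8.88 / 3.28 / 1.51:

```r
alloc <- c(professionals = 3000, technicians = 4500, administrative = 7500)
design <- design_spec("stratified", allocation = alloc)
ref <- population_reference_fit(cohort, "marginal")   # smoking HR 2.23

run_sc <- function(wt) scenario_spec(design, model = "marginal",
                                     weighted = wt, replicates = 50)
sm_w <- summarize_replicates(run_replications(cohort, run_sc(TRUE),  seed = 2011), ref)
sm_u <- summarize_replicates(run_replications(cohort, run_sc(FALSE), seed = 2011), ref)
compare_scenarios(list(weighted = sm_w, unweighted = sm_u)) |>
  dplyr::filter(term == "smoking")
#>     scenario    term     bias  emp_var avg_est_var     mse mse_rank excludes_ref
#> 1   weighted smoking 0.000608 0.001118    0.001366 0.00112        1        FALSE
#> 2 unweighted smoking 0.167611 0.000376    0.000836 0.02847        2         TRUE
```

Read: the weighted fit of the (misspecified) marginal model is essentially
unbiased for the population smoking log-HR; dropping the weights shrinks the
variance but adds a bias of +0.17 on the log scale (HR 2.23 → ≈2.63), so its
MSE is 25× larger and the central 95% of its replicate estimates excludes
the population value — the classic precision-for-bias trade gone wrong.

`plot_hr_density()` draws the replicate HR distributions,
`plot_scenario_metric()` the MSE/variance bar charts, and `run_study()`
executes a whole YAML-configured scenario grid (bundled examples in
`inst/extdata/config-tiny.yaml` and `config-study.yaml`) and writes all
tables plus a manifest.

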