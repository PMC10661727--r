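# igsim

Model-based simulation of serum total IgG pharmacokinetics in patients with
primary immunodeficiency diseases (PIDD) who switch from stable intravenous
immunoglobulin (IVIG) to subcutaneous maintenance therapy: conventional SCIG
at 0.15 g/kg weekly, or hyaluronidase-facilitated fSCIG at 0.6 g/kg every
4 weeks. The package is aimed at pharmacometricians and clinical-pharmacology
analysts who want to ask: *if every patient receives the same dose per
kilogram of total body weight, how does steady-state IgG exposure differ
across BMI categories and age groups, and does everyone stay above a
protective trough?*

## The model

Serum IgG is described by a linear two-compartment disposition model
(CL, V_c, Q, V_p) with first-order subcutaneous absorption (k_a,
bioavailability F) and zero-order endogenous IgG synthesis k_syn into the
central compartment, so the endogenous baseline is C_endo = k_syn / CL. For
a repeated dose D the central concentration is assembled by superposition of
the tri-exponential single-dose solution,

    C(t) = C_endo + C_excess(t) + (F k_a D / V_c) * sum over past doses of
           [ A1 e^{-lambda1 (t - t_d)} + A2 e^{-lambda2 (t - t_d)} + A3 e^{-k_a (t - t_d)} ],

where C_excess(t) is the decaying part of the 7 g/L switch concentration in
excess of the baseline (central and peripheral compartments start in
pseudo-equilibrium). Clearances scale allometrically with fat-free mass
(Janmahasatian), FFM^theta_CL, volumes with FFM^theta_V, with lognormal
inter-individual variability on CL, V_c, k_a and k_syn — while doses are
computed on *total* body weight. That mismatch (dose ~ WT, elimination ~
FFM^0.9) is what makes troughs rise with BMI and fall in young children.

Steady-state metrics (C_min,ss, C_max,ss, AUC_ss, C_ave,ss = AUC/28) are
computed on the aligned final 28 days of the 20-week horizon, and stratified
summaries report means, SDs, trough ratios versus a reference stratum, the
percentage of subjects at or above 7 g/L, and median ribbons with 5th–95th
percentiles.

Because the underlying clinical model's estimates are not redistributable,
the packaged parameter set is produced by `calibrate_defaults()`: three
monotone 1-D solves that pin the healthy-BMI adult mean trough under SCIG
(12.1 g/L) and fSCIG (10.7 g/L) and the 2–<6 years/adult SCIG trough ratio
(0.78). Every other stratum contrast the package reports is an emergent
prediction. See the methods vignette (`vignettes/igsim-methods.Rmd`) for the
full account.

## Worked example

Simulate the BMI-stratified adult study arm (1000 subjects per stratum)
under weekly SCIG with the calibrated parameters:

```r
library(igsim)
params <- calibrate_defaults()          # or default_parameters()
pop    <- sample_population(population_spec("bmi", n_per_group = 1000, seed = 101))
scig   <- run_scenario(pop, regimen_scig(), params, seed = 11)
scig
#> <igsim_scenario> scig: 4000 subjects, horizon 140 d, window [112, 140] d
#>   mean C_min,ss 12.84 g/L; % >= 7 g/L: 98.8

s <- summarize_groups(scig)
s[, c("stratum", "n", "cmin_mean", "cmin_sd", "cmin_ratio", "pct_cmin_ge_threshold")]
#>       stratum    n cmin_mean cmin_sd cmin_ratio pct_cmin_ge_threshold
#> 1 underweight 1000      11.4    2.42       0.94                  97.6
#> 2     healthy 1000      12.1    2.56       1.00                  97.9
#> 3  overweight 1000      13.3    2.74       1.10                  99.7
#> 4       obese 1000      14.5    2.95       1.19                 100.0
```

Reading the table: the healthy-BMI stratum mean trough sits at the 12.1 g/L
anchor; the obese stratum runs 19% higher and the underweight stratum 6%
lower, because a g/kg dose over-delivers relative to lean mass as adiposity
rises. Nearly all subjects stay at or above the 7 g/L protective threshold,
with the shortfall concentrated in the variability tail of the leaner
strata.

Percentile ribbons for plotting (here at the switch, mid-horizon and end):

```r
rib <- percentile_ribbon(scig)
rib[rib$time %in% c(0, 70, 140), ]
#>     time   p5  p50  p95
#> 1      0 7.00  7.0  7.0
#> 281   70 8.15 11.5 15.5
#> 561  140 8.47 13.0 19.2
```

`write_report(s, rib_with_stratum, "results/")` writes `summary.csv`,
`ribbons.csv` and the two figures (concentration–time ribbons; trough bars
with SD whiskers and the dashed 7 g/L line). A thin command-line wrapper is
included: `Rscript inst/cli/igsim.R simulate --regimen scig --stratify bmi
--n 1000 --seed 42 --out results/`.

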