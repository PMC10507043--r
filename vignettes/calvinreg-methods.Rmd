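---
title: "Methods: ensemble kinetics, control analysis, and LiP-SMap statistics in calvinreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble kinetics, control analysis, and LiP-SMap statistics in calvinreg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calvinreg)
```

`calvinreg` bundles three analysis tracks that together probe metabolite-level
regulation of the bacterial Calvin cycle: (i) interaction calling from
limited-proteolysis (LiP-SMap) peptide quantification, with cross-species
comparison through ortholog binarization, PCA, and Ward-clustered
functional-category heatmaps; (ii) plate-reader enzyme kinetics (Malachite
Green phosphate detection, Hill fits, effector verdicts) and nanoDSF
thermal-shift analytics; and (iii) an ensemble kinetic model of cyanobacterial
central carbon metabolism that asks what a validated regulation — feed-forward
activation of fructose-1,6/sedoheptulose-1,7-bisphosphatase (F/SBPase) by
glyceraldehyde-3-phosphate (GAP) and its inhibition by NADPH — does to
steady-state stability and flux control.

This vignette records the models, the tunable parameters and their defaults,
the numerical choices, and the limitations, so that the test suite's meaning
is clear.

## The kinetic model and its rate laws

The packaged network (`build_calvin_model()`) is a **synthetic
reconstruction** of a *Synechocystis* central-carbon-metabolism model:
29 reactions connecting 36 metabolites, of which 22 are internal (dynamic)
and 14 are clamped externals (CO2, O2, solvent species, and the drains'
product pools). It carries the Calvin cycle proper, the photorespiratory
entry (Rubisco oxygenation and phosphoglycolate phosphatase), glycogen
synthesis, lower glycolysis with pyruvate dehydrogenase and PEP carboxylase
drains, biosynthetic drains from GAP, E4P and R5P, light-driven ATP and NADPH
supply, mass-action phosphate supply, and ATP/NADPH maintenance reactions.
Two conservation relations (ATP+ADP, NADPH+NADP) are detected structurally
and removed via the link matrix before any linearization. The reconstruction
is faithful in structure and size to the study system, but it is **not** the
original model: the original's exact concentration ranges, standard Gibbs
energies, and genome-scale flux distribution live in an external repository,
so the packaged ranges, Gibbs energies and fluxes are stand-ins chosen as
follows.

* The flux distribution satisfies `N v = 0` exactly (all values are binary
  fractions, so the residual is zero in floating point), with a
  carboxylation:oxygenation ratio of 18.5:1 and drains sized like a growing
  autotroph (glycogen, nucleotide, aromatic, lipid, acetyl-CoA).
* Internal concentration ranges span 5-fold either side of a literature-scale
  reference state (25-fold span), standing in for ranges from
  network-embedded thermodynamic (NET) analysis. At this width the
  feasibility rejection does real work: the acceptance rate of the
  concentration sampler is ~0.2-0.4 rather than ~1.
* Standard transformed Gibbs energies were fixed so the reference state
  dissipates -4 to -5 kJ/mol through the reversible steps and -15 to
  -25 kJ/mol through the irreversible ones, preserving the near/far from
  equilibrium structure of the cycle.

Three rate-law kinds cover the network. Irreversible steps are
(multi-substrate) irreversible Michaelis-Menten, with an optional Hill
exponent on a declared primary substrate; the F/SBPase reactions (FBPase and
SBPase) use the Hill form on FBP and SBP. Reversible steps use a
thermodynamically consistent law

\[ v = V_{max}\,\theta_S\,(1 - Q/K_{eq}) / D, \qquad
   K_{eq} = e^{-\Delta G^{0\prime}/RT}, \]

with \(\theta_S = \prod_s (c_s/K_{M,s})^{|n_s|}\) and
\(D = \prod_s (1 + c_s/K_{M,s})^{|n_s|} + \prod_p (1 + c_p/K_{M,p})^{n_p} - 1\).
The thermodynamic factor makes the rate vanish exactly at \(Q = K_{eq}\) and
gives it the sign of the driving force, which is what the feasibility-based
`Vmax` back-calculation relies on. Supply follows mass action. The cited
lineage of ensemble models does not print its rate-law algebra, so this
"separable thermodynamic factor" form is this package's choice; it is Haldane
consistent by construction.

Regulation terms come in two kinds. Noncompetitive inhibition multiplies a
rate by \(1/(1 + c/K_i)\). K_M activation scales the primary substrate's
Michaelis constant by \(1 - f_{max}\, c/(c + K_a)\) with a ceiling
\(f_{max} = 0.75\): a saturating activator reduces K_M by at most 75%, the
behaviour measured for GAP on F/SBPase. The `base` variant carries no
F/SBPase regulation; the `fsbpase` variant adds exactly one GAP activation
and one NADPH inhibition to each of the two F/SBPase reactions. The variants
share stoichiometry element for element, so any ensemble difference is
attributable to the regulation terms.

## Sampling and the ensemble

`sample_concentrations()` draws internal concentrations log-uniformly within
their ranges and rejects states in which any flux-carrying reaction would run
against its Gibbs energy (`dG * sign(v) >= 0`; the equilibrium boundary
counts as infeasible). Log-uniform-with-rejection is this package's reading
of "random sampling of the thermodynamically allowable space"; a hit-and-run
sampler could stand behind the same interface. `sample_parameters()` draws
each K_M log-uniformly between 0.1x and 10x the concentration of its
metabolite in the current state, each K_i/K_a log-uniformly between 0.5x and
2x the effector's enzyme-assay concentration (GAP 0.5 mM, NADPH 3 mM), and
the F/SBPase Hill exponent uniformly between 1 and 1.5.
`back_calculate_vmax()` then exploits linearity in `Vmax`: with all other
constants fixed, `Vmax = v_target / v(Vmax = 1)`, so every sampled model
reproduces the reference flux distribution exactly (the test suite asserts a
relative residual below 1e-9 over 10^4 models; observed ~1e-16). Zero-flux
reactions get `Vmax = 0`; a sign mismatch between the normalized rate and the
target flux is an error, and thermodynamic feasibility precludes it.

All randomness flows from one root seed; per-stage and per-model child seeds
are derived arithmetically, so ensembles are exactly reproducible.

## Stability and metabolic control analysis

`jacobian_matrix()` forms the reduced Jacobian `J = N_R (dv/dS) L` over the
independent internal species, with analytic derivatives for every rate law
(a central finite-difference evaluation is kept as a cross-check; the test
suite requires agreement to 1e-4 relative — this check caught a sign error
in the reversible law's thermodynamic term during development, which is why
it exists). A model is stable when the spectral abscissa is below
`-tol * ||J||` with `tol = 1e-9`; eigenvalues inside the tolerance band are
conservatively classified unstable and flagged, though with conservations
removed by the link matrix such cases are rare. Classification is validated
against direct numerical integration (perturb the steady state by 0.1%,
integrate, test return) on toy ensembles; agreement is required on at least
95% of 200 models.

For stable models, unscaled concentration control is
\(C_S = -L (N_R E L)^{-1} N_R\) and flux control \(C_J = I + E\,C_S\), scaled
by steady-state fluxes and concentrations. The summation theorems (scaled
\(C_J\) rows sum to 1, \(C_S\) rows to 0) are asserted for every stable model
at 1e-6, and the connectivity theorem is checked on toys. Flux control
coefficients are additionally validated against a +1% `Vmax` perturbation
oracle (re-solving the steady state by ODE relaxation) within 2% relative on
branched three-step toys. Rows belonging to zero-flux reactions cannot be
flux-scaled and are reported unscaled with a flag.

`run_ensemble()` aggregates per-(concentration set, parameter set) records:
the stable fraction per concentration set and its median across sets (the
headline stability statistic), the pooled fraction, and median plus raw
median-absolute-deviation flux control coefficients over stable models. Both
the pooled FCC median and the median-of-per-set-medians are emitted, since
the original aggregation is ambiguous. Individual model failures are counted,
never fatal. `compare_variants()` differences the medians of two ensembles
run on identical concentration sets.

At the packaged study conditions a 40 x 60 ensemble takes on the order of a
minute on one CPU; the test suite and acceptance script use sizes between
6 x 25 and 50 x 200. On the reconstruction, median stability is ~75-77% with
the regulated variant typically a point or two below the base variant, and
the median flux control exerted by the F/SBPase reactions over the cycle
fluxes shifts consistently upward (+0.001 to +0.005) when GAP activation and
NADPH inhibition are added. Both directions agree with the study system; the
absolute stability level does not (91% there), which is expected given the
stand-in ranges, Gibbs energies and fluxes. The self-control component of the
shift is noisier and its sign can vary between seeds at these reduced sizes.

## LiP-SMap statistics

The caller takes replicate-level peptide intensities in three groups
(control, low, high metabolite concentration; four technical replicates).
Peptides observed in fewer than three replicates of any group are excluded
(never imputed). Differential abundance per peptide and comparison is the
difference of group means of log2 intensities with a two-sided
equal-variance t-test, and Benjamini-Hochberg q-values within each
comparison family. This deliberately simplifies the original pipeline's
mixed-model machinery to a transparent per-peptide test behind the same
interface; per-peptide numbers will therefore differ from the deposited
results, while the calling rules are identical: a protein interacts with a
metabolite at a concentration when **at least one** peptide has `q < 0.01`
(strict inequality).

Cross-species comparison binarizes calls per ortholog (1 if any interacting
protein of that organism maps to it), restricts columns to orthologs mapped
in every organism, and drops all-zero columns. PCA is mean-centered and not
variance-scaled (the R default this mirrors). Category heatmaps use the
fraction of interacting orthologs per one-letter functional category,
Euclidean distances, and `ward.D2` agglomeration, returning leaf orders.

The synthetic generator (`gen_peptide_table()`) emulates the DIA scale:
log-normal baselines spanning ~4 orders of magnitude, ~5 peptides per
protein (Poisson), 2000 proteins by default (~10^4 peptides), 4 replicates
per group, a 0.9 per-record observation probability to exercise the
replicate filter, and planted effects on a random subset (>= 1) of an
interacting protein's peptides, with the low-concentration group receiving
half the high-concentration shift. It does **not** emulate peptide-level
correlation within proteins, intensity-dependent variance, or the sporadic
peptide detection of real DIA data, so a calibrated caller here is necessary
but not sufficient evidence for real-data calibration.

Two power facts shape the planted-recovery test. Under a complete null,
BH at `q < 0.01` is conservative: the protein-level false-positive rate is
near zero, far below the nominal level, so calibration is asserted as "not
exceeding the binomial 95% upper bound at nominal". And with four replicates
a planted shift of exactly 4 within-group SDs gives a per-peptide t of ~5.7
(df = 6), which survives BH at 0.01 only ~20-60% of the time once ~1500
peptides compete; the recovery study therefore plants 8-SD effects
(log2 shift 2 at sigma 0.25) on at least two peptides — the regime of the
strong binders the technique is designed to find — where recovery is >= 95%.

`replicate_overlap()` reports, per q-cutoff tier, the union and intersection
of significant peptides of two experiments, the mutual fraction, and the
Pearson correlation of log2 fold changes; the worked 48-of-155 = 31% case is
in the acceptance tests.

## Enzyme assays and thermal shifts

`fit_standard_curve()` is ordinary least squares of A620 on the phosphate
standards. `compute_rates()` subtracts each well's time-zero background,
converts to phosphate via the slope, removes readings below the 10 uM
sensitivity floor and readings beyond 60% substrate conversion — except that
10-min time points are always kept — and regresses the survivors on time;
fewer than two surviving points withholds the rate with a flag. Both filters
are strict in the directions stated ("lower than 10 uM", "exceeded 60%"), so
boundary readings at exactly 10 uM or exactly 60% conversion are kept.

`fit_hill()` fits \(v = V_{max} S^h / (K^h + S^h)\) by Levenberg-Marquardt
least squares from a small multistart grid (two `Vmax`, three `K`, two `h`
starting points), with standard errors from the Jacobian at the optimum;
fixing `h = 1` reproduces a Michaelis-Menten fit exactly. The synthetic
plate generator runs the forward model (Hill rate, linear phosphate
accumulation over 10/20/30 min, standard-curve conversion, Gaussian A620
noise) at the eight-point substrate design (0-300 uM), with the default
`Vmax` of 2 uM/min chosen so the design sits in the initial-rate regime the
assay assumes; noiseless plates invert to the true parameters at 1e-6, and
95% confidence intervals cover the truth in >= 90% of noisy simulations.

`effector_test()` applies the study's compound rule: significant iff a
two-sided Student t-test gives `p < 0.05` **and** the maximum relative rate
change exceeds 20%. With replicate Hill fits the t-test compares each fitted
parameter across conditions; with raw rate sets it is a paired t-test of
per-level mean rates across the shared substrate design (the whole curve,
rather than the selected extreme level, decides significance).

`melt_tm()` smooths the F350/F330 ratio with a centered 5-point moving
average (the grid is 1 degree C per minute from 20 to 95), takes the first
derivative, and calls T_m at its maximum; a transition is only accepted when
the derivative peak exceeds 5x the median absolute derivative, otherwise the
T_m is flagged undefined rather than reporting noise. Shifts are significant
only beyond 2 degrees C (strict). Scattering traces are differentiated the
same way and peaks reported for detecting secondary populations (the
two-population case appears in the tests as a mixture of sigmoids).

## Pipeline and reproducibility

`run_config()` validates stages, thresholds (defaults: q 0.01, p 0.05,
effect 20%, delta-T_m 2 degrees C) and paths before anything runs;
`run_pipeline()` executes the selected stages in dependency order, writes
TSV outputs plus a JSON manifest (package version, seed, per-stage row
counts, output digests), preserves partial outputs on failure, and is
byte-reproducible for a fixed configuration. The package's functions are the
primary interface; the pipeline exists so a full synthetic study can be
re-run with one call.

## Known limitations

* The packaged network is a structural stand-in: absolute stability levels
  and control-coefficient magnitudes are not comparable to the original
  study's values, only the qualitative structure (supply reactions dominate
  flux control; regulation shifts control toward F/SBPase; stability dips
  slightly with added regulation) is.
* The per-peptide equal-variance t-test ignores peptide-protein hierarchy
  and shared variance; the statistical interface is a single function and
  can be swapped.
* `km_activation` is implemented for irreversible laws only (its one use);
  requesting it on a reversible law is an error rather than a silent
  approximation.
* The ODE-based oracles use `deSolve::lsoda` with tight tolerances; they are
  test instruments, not exported analysis paths.
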