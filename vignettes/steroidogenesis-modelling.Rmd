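---
title: "Modelling adrenal steroidogenesis in H295R cells: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling adrenal steroidogenesis in H295R cells: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(adrenosim)
```

# The biological system and the model

NCI-H295R adrenocortical carcinoma cells express the full complement of
steroidogenic enzymes and are the standard in vitro system for screening
endocrine-disrupting compounds. Under stimulation they take up
cholesterol, store it as esters, traffic it to the inner mitochondrial
membrane (the StAR-regulated, rate-limiting step), cleave it to
pregnenolone (PREG) via CYP11A1, and elaborate PREG through the
C21-steroid biosynthesis network into mineralocorticoids (aldosterone),
glucocorticoids (cortisol and its precursors), and sex steroids.
Steroids partition passively between cells and culture medium, where
they are measured by LC-MS/MS.

`adrenosim` implements this system as a 35-state ODE model over two
compartments:

* 7 cholesterol/oxysterol pools: medium cholesterol (CHOL), stored
  esters (CHOS), intracellular free cholesterol (CHOC), mitochondrial
  free cholesterol (CHOM), a CYP11A1-remote and a CYP11A1-proximal
  mitochondrial pool (CHOR, CHON; their exchange models StAR-mediated
  localization), and an oxysterol sink (OXY) drawn from CHOC as a
  bypass that consumes cholesterol outside steroidogenesis.
* 14 steroids, each with an intracellular and a medium concentration.

Wiring of the cholesterol pools is CHOL -> CHOC (uptake),
CHOC <-> CHOS (ester storage via `k_f_acc`/`k_b_acc` plus hydrolysis via
`k_CEH`), CHOC <-> CHOM (`k_f_MTR`/`k_b_MTR`), CHOM <-> CHOR (a fast
intramitochondrial distribution pair, `k_dist_f`/`k_dist_b`), and
CHOR <-> CHON (`k_f_loc`/`k_b_loc`, the StAR step). Whether the
oxysterol bypass draws from CHOC or CHOM is not decidable from the
cell-biology literature alone; CHOC was chosen as the free cytosolic
pool from which side reactions are most plausible, and the choice is a
single constant in the reaction wiring.

## Kinetics

The 17 enzymatic reactions (9 enzymes; see `reaction_table()`) use
**competing-substrate rapid-equilibrium kinetics**: for an enzyme with
substrates $S_1 \dots S_n$ bound at a single active site,

$$ v_i = a_E \, V_{max,i} \frac{S_i/K_{m,i}}{1 + \sum_j S_j/K_{m,j}} $$

with $a_E$ a relative activity multiplier (1 = unperturbed). This form
realizes the substrate inhibition that first-order models cannot: most
steroidogenic enzymes accept several steroids, so accumulation of one
substrate suppresses turnover of the others. CYP11B2
(corticosterone -> aldosterone) is the one first-order reaction,
reflecting its far-from-saturation operating point. Transport and
localization fluxes are first-order.

Passive steroid diffusion uses a forward/backward rate pair per steroid
acting on concentrations, with the amount flux referenced to the cell
volume so that total moles are conserved exactly; at equilibrium
$k_f \cdot C_{med} = k_b \cdot C_{cell}$, which is also how
`equilibrate_initial_state()` initializes intracellular concentrations
from t = 0 medium measurements.

Cell growth follows exponential laws $N(t) = N_0 e^{g_N t}$,
$v(t) = v_0 e^{g_v t}$; intracellular concentrations are diluted at
rate $g_N + g_v$ (a switch, on by default). With dilution on, the total
molar amount over all pools and compartments is conserved analytically,
and the simulator holds the drift below $10^{-6}$ relative over 72 h
(machine-level in practice).

## The 42-parameter kinetic inventory

The kinetic inventory (`kinetic_parameter_names()`) comprises 9
transport/localization rate constants and 33 enzyme constants. Units:
concentrations nmol/L, time h, volumes mL; Vmax in nmol/L/h referred to
the intracellular compartment. Legacy listings of this inventory sometimes carry duplicated labels
at positions 16 and 25; the package uses the only readings consistent
with the reaction table, `KmA_CYP17L` and `VmaxC_HSD3B2`, and notes
the discrepancy here rather than renaming anything silently.

## The default parameter table is non-authoritative

No public, redistributable calibrated parameter table exists for this
assay, so `default_parameters()` ships a plausibility-checked
synthetic default set. It was designed to satisfy, a priori, the qualitative operating
regime the system is known to have:

* 72-h medium concentrations follow the characteristic ranking
  PREG > CORTICO > CORT >> ALDO, with the major/moderate/minor
  grouping of the steroid panel;
* intracellular steroid concentrations sit above the Km values
  (saturated, substrate-competing regime);
* the CYP11A1 supply flux is close to the combined PREG-consuming
  capacity of CYP17H and HSD3B2, so perturbing either enzyme makes
  PREG accumulate and cross-suppress the other branch — the mechanism
  behind the activity-balance phenotypes;
* all effective first-order rates stay below ~1/h so that the explicit
  RK4 scheme meets its accuracy contract across the whole admissible
  step range (see below).

Anything quantitative beyond these structural properties (absolute
concentrations, exact phenotype boundary positions) should not be read
off the defaults; calibrate to your own data with `fit_parameters()`.

# Numerical integration

The integrator is the classic fourth-order Runge-Kutta scheme with a
variable step: $dt = \mathrm{clamp}(c / \max|v|, 10^{-5}, 10^{-2})$ h,
where $\max|v|$ is the largest instantaneous flux velocity considered
in both compartments' concentration units. Only the clamp range of the
step is fixed by convention; the $c$-based rule is this package's
construction, with $c$ exposed in `integrator_config()` (default 20
nmol/L, making the per-step relative change of the major pools about
$10^{-3}$). Steps are shortened to land exactly on record times, so
recorded grid points (including the assay times 0, 8, 24, 48, 72 h)
are never interpolated.

`error_ratio()` verifies the scheme by re-running with fixed steps
drawn from the clamp range and reporting the largest relative deviation
(relative floor $10^{-12}$ nmol/L to avoid 0/0 on empty pools). On the
default model the ratio is below $10^{-8}$ across
$dt \in \{10^{-5}, 10^{-4}, 10^{-3}, 10^{-2}\}$; the acceptance suite
asserts this. Closed-form oracles (exponential decay, a two-step
first-order chain) agree to better than $10^{-7}$, and halving a fixed
step shrinks the error ~16x, confirming fourth order.

Inside optimization loops (`moa_config()`'s default integrator
settings) the step-control constant is relaxed to $c = 100$, which
parks the step at $dt_{max}$ for the default model; fold-change
objective values agree with the tight setting to ~$10^{-13}$ while each
of the thousands of evaluations costs about a third as much. The
deSolve package is used only as an independent cross-check in the test
suite, never as the simulation path.

# Calibration

`nlsd()` implements the normalized least squares distance: squared
measured-minus-simulated differences normalized per trace by the
squared maximum measured concentration, summed over compartments,
species and the five assay time points. Below-LLOQ points are excluded
— not imputed — matching how censored LC-MS data are treated.
Replicates enter as per-time-point means; their SD is carried for
reporting only, since the objective is unweighted.

`fit_parameters()` minimizes the NLSD with Levenberg-Marquardt
(`minpack.lm::nls.lm`) over any subset of the 42 parameters, in **log
space**: all parameters are positive and span decades, and the log
transform makes the search scale-free. Fitted objective values for real assays depend on raw measurements
that are not public, so the test suite exercises the estimator on
planted-parameter synthetic data: exact recovery from noiseless data,
single-parameter recovery within 1%, and three-parameter recovery
within 25% on >= 90% of 20 noisy replicates.

`fitting_sensitivity()` scores each parameter by the relative
finite-difference effect of a +10% perturbation on the NLSD — the same
structure as the dynamic sensitivity below, applied to the objective.

# Mechanism-of-action estimation

The estimator inverts a 12-steroid, 72-h medium fold-change profile
(treated/control) into relative activities of 8 enzymes (CYP19A1 fixed:
its products E1/E2 are not in the LC-MS panel). Genes are
$\log_{10}$ activities on $[-2, 2]$ (search space 1/100 to 100); the
log coding was chosen so inhibition and activation are searched
symmetrically.

Step 1 is a real-coded GA: REX crossover (children sampled around the
parent centroid with i.i.d. coefficients of mean 0 and variance
$1/(k-1)$; uniform by default, Gaussian behind a flag — the cited
crossover does not pin the distribution) and JGG generation
alternation (6 parents sampled without replacement, 25 children, best
6 children replace the parents). Defaults follow the standard screening protocol: population 100, up
to 1000 generations, termination when the fitness falls below 0.1. Step 2 polishes the GA result with bounded
Levenberg-Marquardt in the same coordinates, started from the top
three elite individuals (multi-start over the elite costs a few
hundred extra evaluations and removes the sensitivity to a single
poor basin that a lone start shows when the GA budget is reduced). The fitness is
$\sum_i ((FC^{obs}_i - FC^{sim}_i)/FC^{obs}_i)^2$ over non-censored
steroids — the NLSD structure collapsed to one compartment and time
point (each steroid normalized by its own observed ratio); a raw-SSR
switch exists. Censored steroids are dropped from the objective, and
enzymes whose downstream readouts are censored are flagged as weakly
identifiable (e.g. CYP11B2 when ALDO is below the LLOQ), mirroring how
such estimates should be read.

`duplicate = TRUE` reruns the whole two-step optimization from an
independent initial population as a numerical-stability check; both
solutions are reported.

Supporting statistics follow standard practice: per-steroid Welch
t-tests with Bonferroni correction (significant at adjusted p < 0.01),
and Ward clustering (`hclust` `"ward.D2"`) of compound profiles on the
standardized Euclidean metric, with a unit-scale floor for constant
columns.

# Dynamic sensitivity and the 2-D activity scan

`dynamic_sensitivity()` computes
$S_{x,y}(t) = (\Delta y/y)/(\Delta x/x)$ from one forward simulation
with $x$ scaled by 1.1 (one-sided +10%; central differences are
available as a diagnostic through negative `delta`). Both the
cytosolic and the medium concentration are meaningful response
variables; both are implemented, and the medium — the measured,
screening-relevant compartment — is the default report.
`auc_ranking()` integrates $|S(t)|$ by the trapezoid rule and sums over
species; the unsigned form was chosen because several sensitivities
change sign mid-course and a signed integral would cancel — the score
is an importance measure, not a direction.

`scan_activity_grid()` sweeps two enzymes' activities (default
CYP17H x HSD3B2, 0-200% in 10% steps, 441 cells) and classifies each
cell with `classify_phenotype()`: a steroid is "produced" when its
72-h medium concentration reaches $\theta$ times baseline. No
canonical production threshold exists; $\theta = 0.01$ was chosen so
the baseline cell is trivially all-producing, and it is an exposed
argument with category stability verified over
$\theta \in [0.005, 0.02]$. On the default parameter set the scan
reproduces the topology-forced results exactly (CYP17H at 0 yields a
mineralocorticoid-only cell; HSD3B2 at 0 terminates steroidogenesis
upstream) and shows the expected metabolic shifts
(inhibition of either enzyme pushes output toward mineralocorticoids,
activation toward glucocorticoids). Exact phenotype boundary
positions, however, are properties of a calibrated parameter set:
with the synthetic defaults the responses attenuate smoothly and
sub-1% extinction at partial inhibition is not reached, so category
switches occur at the grid axes rather than at intermediate
activities. The acceptance suite measures the boundary positions
honestly rather than asserting them away.

# The synthetic-data generator

`generate_timecourse()`, `generate_foldchange()` and
`make_inhibitor_panel()` emulate the assay's statistical structure: 5
time points {0, 8, 24, 48, 72} h, two compartments, 4 replicate wells,
multiplicative log-normal noise with constant CV (default 10%,
LC-MS-like; mean-one parameterization so expectations are unbiased),
and per-steroid LLOQ censoring with the highest limits on the minor
steroids (ALDO, TESTO, E2), reproducing real panels' censoring
pathology under strong inhibition. Planted perturbations use a
one-site binding law $a = 1/(1 + dose/IC_{50})$ so dose-response
monotonicity holds by construction. Everything is reproducible from
(spec, seed).

What passing tests on synthetic data do **not** show: the generator
draws from the same model family as the estimator (no model
misspecification), its noise is exactly log-normal with equal CV
across steroids, and true assay LLOQs are unknown. Recovery results
are therefore best-case; on real data, identifiability of CYP11B2 and
HSD17B3 in particular is limited whenever ALDO or TESTO is censored.

# Problem sizes and budgets

The test suite runs the full 72-h model (roughly 7,000-20,000 RK4
steps per simulation) throughout. GA-based recovery tests use reduced
budgets (population 40-100, 40-120 generations) with the LM polish
supplying the precision; the fixed-step reference runs in the
integrator check go down to $dt = 10^{-5}$ h (7.2 million steps). The
noisy calibration study uses 20 replicates, and the two-enzyme
recovery experiment 5 seeds. These sizes were chosen so the complete
check runs comfortably on a laptop core while still exercising every
code path at the model's real dimensionality.

# Known limitations

* No receptor signalling: stimulation (ACTH/forskolin/angiotensin II)
  is implicit in the calibrated parameters, so the model cannot
  distinguish receptor-level from enzyme-level drug action.
* The default parameter table is synthetic (see above); quantitative
  conclusions require calibration to measured time courses.
* The explicit RK4 contract restricts the model to the non-stiff
  regime (effective rates up to ~1/h); stiff parameterizations would
  need an implicit solver behind the same interface.
* Fold-change inversion uses a single time point (72 h); mechanisms
  that differ only in transient dynamics are not separable.
* Cytotoxic concentration ranges are out of scope; fold changes are
  assumed to reflect enzyme-level action, not cell loss.
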