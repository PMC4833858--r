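---
title: "Models and methods behind fretrelease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fretrelease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `fretrelease`, the
assumptions they rest on, the numerical choices made where the design was
genuinely open, and what the synthetic-data generator does and does not
emulate.

## 1. Compatibility descriptors

Drug–matrix miscibility is quantified by the Flory–Huggins interaction
parameter

$$\chi = \frac{V\,(\delta_\text{drug}-\delta_\text{poly})^2}{R\,T},$$

where $V$ is the drug molar volume (cm³ mol⁻¹), $\delta$ are Hildebrand
solubility parameters (MPa$^{0.5}$), $R$ = 8.314 J mol⁻¹ K⁻¹ and $T$ the
absolute temperature. Internally $V$ is converted to m³ mol⁻¹ and $\delta$
to Pa$^{0.5}$, so no 10⁶ bookkeeping leaks into user code; since
1 MPa = 1 J cm⁻³, the stored units are self-consistent. $\chi$ is
non-negative, zero exactly at matched solubility parameters, symmetric in
the two $\delta$s, linear in $V$ and quadratic in
$\Delta\delta$ — properties the test suite asserts directly.

$\delta$ and $V$ come from a group-contribution table: Fedors-style additive
cohesive-energy and molar-volume increments,
$\delta = \sqrt{\sum_i n_i E_i / \sum_i n_i V_i}$, $V = \sum_i n_i V_i$.
The table is an ordinary, pluggable data object (`group_table()`): the
method, not any particular published table, is the point, and users with a
preferred scheme (e.g. Hoftyzer–Van Krevelen) can load their own via
`read_group_table()`. Branch carbons and structural corrections carry
negative volume increments and are flagged as correction terms; a
composition whose total volume is not positive is rejected rather than
silently producing a complex $\delta$.

Temperature is a required explicit input to $\chi$ — the package does not
presume whether a screening study evaluates miscibility at 298 K or at
310 K.

Hydrophobicity (log *D* at pH 7.4) is primarily a *user input*, because
credible log *D* prediction for ionizable drugs needs a dedicated predictor.
The additive fragment estimator (`estimate_logd_additive()`) exists only so
synthetic studies are self-contained; a `supplied_logd` always wins, and
estimated values are labelled as such in outputs.

The release-zone classifier places a drug in the (χ, log *D*) plane:
`slow_release` if χ ≤ χ_lo **or** log *D* ≥ logD_hi, `fast_release` if
χ ≥ χ_hi **and** log *D* ≤ logD_lo, `intermediate` otherwise. The rule is
monotone by construction: improving miscibility or raising hydrophobicity
never moves a drug toward the fast corner. The default thresholds
(χ_lo = 1, χ_hi = 3.2, logD_lo = 3.5, logD_hi = 8) are package conventions —
the underlying guideline's axes are qualitative — chosen so the four
model-drug archetypes land in the expected zones; they are plain arguments
and should be recalibrated for any specific carrier system.

## 2. The FRET observable

The assay reports drug–particle association through Förster transfer from a
core-bound donor dye to the acceptor-tagged drug. The package deliberately
avoids Förster-distance photophysics and uses the simplest model consistent
with the empirically linear ratio–loading relation: each bound drug removes
a fraction $e$ ("quench coefficient per load", default 0.01) of donor
emission and re-emits it in the FRET channel, and a fraction $b$ (bleed-
through, default 0.05) of residual donor emission is detected in the FRET
channel:

$$I_\text{donor} \propto B\,(1-eL), \qquad
  I_\text{FRET} \propto B\,(eL + b\,(1-eL)).$$

The FRET ratio $I_\text{FRET}/I_\text{donor} = b + (1-b)\,eL/(1-eL)$ is
independent of particle concentration and strictly increasing in the mean
load $L$. It is *exactly* linear only as $eL \to 0$; the declared valid
range (default $L \le 10$, i.e. at most 10% total quench) is defined as the
regime where the deviation from a straight line stays below 1%
($r^2 > 0.999$ for the default parameters). Loads outside the range are
errors in the forward model and flagged extrapolations in the inverse
calibration. The calibration itself is an ordinary least-squares line with
at least three distinct loading levels; `invert_loading()` is its exact
algebraic inverse, so calibrate-then-invert is the identity on the fitted
line. A non-zero intercept (the bleed-through baseline of control
particles) is permitted and tested in both the zero and non-zero cases.

## 3. Two-compartment release fitting

Normalized FRET-ratio decays are fitted with

$$y(t) = \text{plateau} + f_\text{fast}\,e^{-k_\text{fast}t}
       + f_\text{slow}\,e^{-k_\text{slow}t},$$

the standard two-compartment release form: a fast interface-bound pool, a
slow core-embedded pool, and a plateau absorbing the bleed-through baseline
plus any non-releasing fraction. Amplitudes are constrained non-negative;
an option constrains $f_\text{fast}+f_\text{slow}+\text{plateau} = 1$
exactly for series normalized to their pre-mix value (default: free
plateau).

Numerical design, chosen for determinism over speed:

* **Initialization** is variable-projection style: a log-spaced grid of 25
  rates spanning 0.05/span to 2/interval, all ordered (k_fast, k_slow)
  pairs, amplitudes solved per pair by non-negative linear least squares.
  No random starts; identical inputs give bit-identical fits.
* **Polish** by bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) on
  (amplitudes, log-rates), from two deterministic seeds — the best rate
  pair and the best single rate — keeping the lower residual. The
  lower-level `nls.lm` interface is used because degenerate optima
  (exactly-equal rates) make the model Jacobian singular.
* **Degeneracies.** A constant series is returned as plateau-only with a
  `no_decay` flag (rates are meaningless there). Optima with
  k_fast/k_slow < 1.001 are collapsed to one compartment, since the
  amplitude split between equal rates is arbitrary. A slow compartment
  with $k_\text{slow}\cdot t_\text{span} < 0.5$ — less than ~40% of an
  e-fold of decay inside the observation window — is statistically
  indistinguishable from baseline and would corrupt the fitted plateau
  (and with it the half-life), so it is absorbed into the plateau and the
  fit is re-polished in single-exponential form with a `slow_unresolved`
  flag. Fits with rate separation < 2 carry a `poorly_separated` flag:
  biexponential decompositions are notoriously ill-conditioned there, and
  downstream summaries should rely on the half-life, not on the individual
  rates.

The **half-life** is defined on the fitted curve, relative to its plateau:
the unique $t^\*$ with $y(t^\*) = \text{plateau} + (y(0)-\text{plateau})/2$,
found by root bracketing. Fitting first and scanning the model makes the
summary robust to noise; if half decay lies beyond the search horizon a
flagged lower bound is returned instead of a fabricated number. Condition
summaries (temperature series, serum titrations) use the effective rate
$\ln 2 / t_{1/2}$ rather than $k_\text{fast}$, precisely because the
half-life is stable under poorly-separated splits while the individual
rates are not.

Apparent activation energies come from ordinary least squares of
$\ln k$ on $1/T$ over at least three temperatures,
$E_a = -R \cdot \text{slope}$.

Identifiability sets the sampling-design rule used throughout the tests:
recovering a rate requires observing a few e-folds of its decay, so
simulation-recovery studies sample to roughly $5/k_\text{slow}$. Within
that design, both rates of 10×-separated biexponentials are recovered with
median error well under 10% at 1–2% multiplicative noise; a window covering
only a third of an e-fold of the slow phase cannot identify that rate at
any realistic noise level, which is an experimental-design limit, not a
fitting failure.

## 4. Mass-action exchange simulator

The mechanism is encoded as the simplest scheme exhibiting every reported
qualitative behaviour: first-order dissociation from each bound pool into a
free intermediate, and mass-action capture of free drug by every pool,

$$\frac{d x_i}{dt} = -k_{\text{off},i}\,x_i + k_{\text{cap},i}[S_i]\,x_\text{free},$$

with binding sites far from saturation (all rates linear in the state).
Columns of the rate matrix sum to zero, so total drug is conserved *by
construction*; the integrator (`deSolve::lsoda`, analytic constant
Jacobian, rtol 10⁻¹², atol 10⁻¹⁴·total) preserves it to ~10⁻¹⁴ in
practice, and trajectories agree with the closed-form matrix-exponential
solution of the linear system to better than 10⁻⁶ (an independent oracle
used only in tests). The stationary distribution is computed from the
SVD null space of the rate matrix and verified against long-horizon
integration; degenerate systems (all rates zero, or several absorbing
pools making the stationary state depend on the initial condition) are
errors, not silent answers.

Donor particles carry two sub-pools. The interface (surface) pool holds
weakly associated drug stabilized mainly by hydrophobic contacts; the core
pool holds matrix-embedded drug and may never release faster than the
surface. Core escape is modelled as direct slow first-order exit rather
than a core→surface cascade: at the observable level the two are
indistinguishable at this scale, and the direct form has one fewer free
parameter.

**Initialization.** By default a system starts from the *donor-only
stationary state* (pool:free ratios $k_\text{cap}[S]/k_\text{off}$) — the
particle stock equilibrated in buffer before acceptors are introduced.
This is why a buffer-only system shows a rigorously time-invariant FRET
ratio: drug still exchanges microscopically between identical particles,
but there is no net release to observe. The alternative `"loaded"`
initialization (all drug bound, split by the core fraction, zero free)
exposes the post-formulation transient instead.

**Descriptor mapping.** Hydrophobicity sets the surface dissociation
barrier, $E_a = E_{a,0} + s_E \log D$ (defaults 62.5 kJ/mol + 1.5 kJ/mol
per log *D* unit), and dissociation rates use the absolute Arrhenius form
$k = A\,e^{-E_a/RT}$ with a single attempt frequency $A = 10^9$ s⁻¹ — so a
higher barrier means slower release at *every* temperature, not only at
the reference point. Miscibility sets the core-loaded fraction through a
falling logistic, $f_\text{core} = 1/(1+e^{s(\chi-\chi_0)})$ (defaults
$s = 3$, $\chi_0 = 1.5$): miscible drugs disperse homogeneously in the
core, immiscible ones crowd the interface. Core capture is then chosen so
the donor-only stationary split reproduces $f_\text{core}$ — the loading
split *is* the drug's equilibrium preference, which keeps the
pre-equilibrated initial state self-consistent. All of these are
calibration constants, not measured values; they were fixed once so that
the four archetypes span minutes-to-hours half-lives at 37 °C in full
serum, and they are exposed as arguments.

**Acceptor pools.** Default serum pools (albumin 600 µM of sites with the
majority of capture capacity, γ-globulin, HDL, LDL; site concentrations
scale linearly with serum fraction) are deliberately *deep traps*:
dissociation barriers of 86–90 kJ/mol put their off-rates far below the
donor's, so serum-captured drug is effectively sequestered on assay
timescales. This choice is what makes the effective release rate
$k_\text{off}\cdot P(\text{capture by serum})$ — and hence the fitted
half-life — strictly monotone in serum fraction; with fast acceptor
back-exchange the half-life to the *equilibrium* plateau is reached sooner
at low serum fraction even though less drug departs, inverting the trend.
The defaults are illustrative, not a quantitative serum model: the
end-point pool-distribution snapshot makes no numerical claim about the
albumin/HDL/LDL partition. Whether inter-particle transfer proceeds
through free solution or by collision is not resolved by the observable;
the free-intermediate formulation is a modelling commitment, not a claim.

## 5. Synthetic data and what passing tests show

The generator emulates dual-channel plate-reader kinetic experiments:
simulate the exchange system, push the donor-bound fraction through the
forward model, then apply (in order) an optional common-mode photobleach
decay, independent multiplicative Gaussian noise per channel (default CV
1%), and an additive floor. Seeds propagate deterministically (panel trace
*i* uses seed·1000+*i*), every trace carries its noise-free truth, and
panel manifests record the true rates, core fraction and half-life of each
condition, the latter from a dense scan of the noise-free bound amount
toward its stationary value.

Default study conditions mirror the dynamic-experiment design: serum
fractions {5, 10, 25, 50, 100}%, temperatures {25, 31, 37, 41} °C
(a declared stand-in set), 10 s plate-reader sampling for single traces
and coarser grids for day-long panels. Test problem sizes — e.g. 24 h
panels at 240–300 s intervals, 20-replicate recovery studies, 100 random
conservation systems — are chosen as the smallest designs that exercise
each property cleanly.

What passing tests do *not* show about real data: the noise model is
uncharacterized instrument noise stood in by Gaussians; real serum
exhibits saturable, heterogeneous binding, lipoprotein remodelling and
particle aggregation, none of which the linear scheme represents; the
archetype descriptor values are documented stand-ins ordered by chemistry,
not measurements; and the FRET forward model ignores spectral overlap
changes, inner-filter effects and distance-dependent transfer efficiency.
The package validates its own chain — descriptors → mechanism → observable
→ fit → summary — end to end, which is a statement about internal
consistency, not about any particular instrument or serum lot.

## 6. Known limitations

* No model selection: the two-compartment form is the only release model
  (no stretched exponentials or Weibull), and fits operate on normalized
  ratios, never raw intensities.
* χ from group contributions inherits every limitation of additive
  schemes (no conformational, crystallinity or specific-interaction
  effects); the shipped table is one published scheme among several.
* The additive log *P* estimator is a toy; supply measured or predicted
  log *D* for real decisions.
* The exchange model is linear: no binding-site saturation, no
  carrier-concentration effects on capture, no direct particle–protein
  collision pathway.
* Half-lives relative to a fitted plateau are only as good as the plateau:
  windows much shorter than the slow compartment's e-fold time yield
  `slow_unresolved` fits whose plateau silently contains the unresolved
  pool — by design, but worth knowing when comparing across very
  different window lengths.
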