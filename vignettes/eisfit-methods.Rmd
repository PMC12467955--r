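---
title: "Automated equivalent-circuit analysis of impedance spectra: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated equivalent-circuit analysis of impedance spectra: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eisfit)
```

## The problem

Electrochemical impedance spectroscopy (EIS) measures the complex impedance
$Z(\omega) = Z'(\omega) + jZ''(\omega)$ of an electrochemical cell over a
wide frequency band. Interpretation proceeds through an equivalent-circuit
model (ECM): a network of idealized elements whose parameters map onto
physical quantities — solution resistance, charge-transfer resistance
$R_{ct}$, double-layer capacitance, diffusion impedance, film properties.
Two tasks are traditionally manual and subjective: choosing *which* circuit
describes the data, and finding *good parameter values*, since the
least-squares objective is non-convex with many local minima. `eisfit`
automates both: a boosted-tree classifier selects the circuit from
multi-metric error features, and a hybrid differential-evolution +
Levenberg–Marquardt (DE–LM) optimizer estimates parameters under physical
constraints. Kramers–Kronig (KK) validation screens the data themselves,
and an interpretable random-forest regression maps fitted parameters to an
external quantity such as analyte concentration.

## Circuit models

Four elements are supported — resistor $Z=R$, capacitor $Z = 1/(j\omega C)$,
constant phase element (CPE) $Z = 1/(Q(j\omega)^n)$ with $n\in[0,1]$, and
the semi-infinite Warburg element $Z = \sigma(1-j)/\sqrt\omega$ — composed
through a series/parallel grammar (`"R0-p(R1-W1,CPE1)"`). All formulas use
$\omega = 2\pi f$ with $f$ in Hz as read from data files; $Z''$ is negative
for capacitive behavior. The catalog of eight candidate circuits runs from
a bare resistor through the classical Randles cell to layered
biofilm-electrode models; the most complex member has ten parameters
(interfacial charge transfer with diffusion under a CPE, plus a compact
R–C film layer and a second dispersive film layer).

Three design choices deserve note.

* **Sections and canonical ordering.** Each parallel R–C or R–CPE block
  ("section") represents one relaxation process with characteristic time
  $\tau = RC$ or $(RQ)^{1/n}$. Catalog circuits number their sections from
  fastest (interfacial) to slowest (outer film). Because permuting which
  section models which relaxation yields near-equivalent impedances, the
  DE fitness multiplies in a soft penalty on descending $\tau$ ordering.
  This is pure symmetry breaking: it removes permutation-duplicate optima
  without excluding any physically distinct model.
* **CPE exponent bounds.** Catalog circuits confine $n$ to $[0.5, 1]$. A
  "capacitive" CPE with $n < 0.5$ no longer models distributed
  capacitance ($n = 0.5$ is pure diffusion, $n \to 0$ a resistor) and, if
  allowed, serves as an escape route into degenerate minima where a CPE
  imitates a resistor. User-defined circuits keep the full $[0,1]$ range.
* **The ten-parameter circuit.** The two-layer biofilm model extends the
  single-layer variant with a second dispersive film section. Layered
  films with separated relaxations are the regime where such a model is
  identifiable at all; the generator (below) draws the layer time
  constants in separated bands for exactly this reason.

## Error metrics and the composite loss

Six statistics are computed on the stacked comparison vector
$y = [Z'; Z'']$ (length $2N$): $\chi^2$ (with $|\hat y_i|$ floored at
$10^{-12}$ in the denominator, since imaginary parts are negative), MSE,
RMSE, MAE, $R^2$ and MAPE in percent (terms with $|y_i| < 10^{-12}$
skipped). They are deliberately complementary: $\chi^2$ is sensitive to
pointwise distributional deviation in the low-frequency diffusion region,
MAE/MAPE resist outliers, $R^2$/RMSE capture global trend fidelity.

The composite loss $L = \sum_m \omega_m\,\phi(e_m)$ makes the six
commensurate through a normalization $\phi$ over a *peer set* of candidate
fits ($R^2$ enters as $1-R^2$). Two normalizations are provided:

* `minmax` — each metric mapped to $[0,1]$ across the peers; used for
  ranking candidate circuits against each other.
* `mean` — each metric divided by the peer mean. A two-member peer set
  (e.g. *before* vs *after* optimization) is degenerate under min–max
  (the worse member scores exactly 1 and the better 0 regardless of the
  actual gap), so convergence measurements use the mean normalization,
  which stays scale-free but preserves the gap.

Weights $\omega_m$ come from the classifier's per-metric feature
importances; entries below the threshold $\delta = 0.1$ are multiplied by
0.1 and the vector renormalized, concentrating the loss on the informative
error dimensions.

## The DE–LM optimizer

**Objective.** $\min_\theta \sum_i [Z'_i - f'(\omega_i;\theta)]^2 +
[Z''_i - f''(\omega_i;\theta)]^2$, i.e. unweighted complex nonlinear least
squares. Magnitude parameters ($R$, $C$, $Q$, $\sigma$) are optimized in
log space — they span decades, and multiplicative moves are the natural
geometry; CPE exponents stay linear.

**Global stage.** Bounded DE/rand/1/bin: mutation
$v_i = \theta_{r_1} + F(\theta_{r_2} - \theta_{r_3})$ with $F$ dithered
uniformly in $[0.4, 1.0]$ per generation, binomial crossover at $CR=0.9$,
reflective boundary handling, population 200 (configurable 200–500).
Convergence: the search stops when the best RSS improves by less than
$\epsilon = 0.1$ (relative) over a 20-generation window — armed only after
60 generations, because early DE exploration has a slow, uninformative
improvement rate. The initial population is data-informed: resistive
scales are bounded by the measured $|Z|$, Warburg coefficients by the
low-frequency modulus, and each section's time constant is drawn within
its own sub-band of the measured window $[1/\omega_{max}, 1/\omega_{min}]$.
The declared bounds remain the hard constraint throughout; initialization
only concentrates the population where the data live.

**Elite handoff.** The top 10% of the final population seeds the local
stage. For multi-section circuits the elite is *basin-aware*: the best
member of each distinct section-$\tau$ configuration enters first, so the
refinement seeds cover the surviving basins rather than one.

**Local stage.** Levenberg–Marquardt on $(J^TJ + \mu\,s\,I)\Delta\theta =
J^Tr$ with $s = \max \mathrm{diag}(J^TJ)$, so the damping factor $\mu$ is
the relative (Nielsen) parameter meaningfully adjustable in
$[10^{-3}, 10^2]$ for any circuit. Nielsen's update: on an accepted step
$\mu \leftarrow \mu \max(1/3, 1-(2\rho-1)^3)$, $\nu \leftarrow 2$; on
rejection $\mu \leftarrow \mu\nu$, $\nu \leftarrow 2\nu$. The Jacobian is
forward finite differences (relative step $10^{-6}$) in the internal
parameterization, evaluated as one vectorized population call; steps are
reflected into bounds.

**Restarts.** If the column-equilibrated Jacobian condition number at the
solution exceeds 10, the fitter resamples 50–100 individuals within ±5% of
the incumbent, runs a short DE and re-refines (at most 3 cycles). The
equilibrated reading matters: the raw Jacobian of a log-scaled
multi-magnitude problem is always ill-conditioned, while the equilibrated
condition number actually flags parameter-direction degeneracy.
Independently of this, circuits with ≥6 parameters get extra DE islands
(two for 6–7 parameters, three for ≥8; islands after the first run at
$CR=0.7$, where coordinate-wise mixing reassembles partially correct
section assignments), and up to four *rescue* islands fire while the fit
looks pathological — RSS far above the attainable floor (estimated
model-free from the KK measurement-model residual), a collapsed section,
or $R^2<0.99$. These are the standard safeguards for genuinely multimodal
ten-dimensional landscapes; on the catalog's noiseless spectra they bring
ground-truth recovery to similarity 1.0 across all eight circuits.

**Uncertainty.** Parameter intervals are computed in the internal (log)
scale and mapped back — hence positive and asymmetric. EIS noise is
typically proportional to $|Z|$ and the real/imaginary parts of one
frequency point share the same disturbance, so the classical
pooled-variance form $\hat\sigma^2(J^TJ)^{-1}$ is miscalibrated exactly
for the low-frequency parameters one cares about ($R_{ct}$, $\sigma$).
The default (`ci_type = "bootstrap"`) is a wild cluster bootstrap: the
two residuals of each frequency point are flipped together by a
Rademacher weight, with HC3-style leverage scaling $r_i/(1-h_i)$, and the
model is re-refined per replicate (80 by default) — this propagates the
heteroscedastic, within-point-correlated noise through the actual
nonlinear estimator, where first-order covariances demonstrably
understate the spread. A cluster-robust sandwich
(`"robust"`, used by the cheap featurization fits) and the classical
Wald form (`"wald"`) remain available.

## Circuit selection

Every candidate circuit is quick-fitted (small DE population, single-seed
short LM polish, no rescues) and its six metrics recorded: a 48-dimensional
feature vector with schema `<circuit>.<metric>`. An XGBoost classifier
(300 trees, depth 6, learning rate 0.1, L1 0.1, L2 1.0, subsample 0.8)
is trained on these features; its per-metric gain importances (summed over
the eight circuit slots, normalized) become the composite-loss weights via
the $\delta$-rule, per-circuit composite-loss features are computed under
those weights, and the model is retrained once on the augmented table —
the error-feedback cycle. At prediction time, if the top-two class margin
is below 0.1 the decision falls back to the composite-loss ranking. A
single-metric baseline (argmin quick-fit MSE) is reported alongside; on
the default synthetic benchmark it reaches roughly 40–50% accuracy against
the classifier's high-90s, which is the qualitative feedback-vs-no-feedback
contrast.

A post hoc nested F-test,
$F = \frac{(RSS_s - RSS_c)/(p_c - p_s)}{RSS_c/(2n - p_c)}$,
verifies that a more complex winner improves significantly over each
nested simpler alternative; the selector-free ranking path in `batch_fit`
prefers the simpler circuit whenever $p > 0.05$.

## Kramers–Kronig validation and time constants

KK consistency (causality/linearity) is tested with the linear measurement
model: series resistance, a series capacitive term, and Voigt R–C elements
on a fixed log-$\tau$ grid spanning $1/(2\pi f_{max})$ to
$1/(2\pi f_{min})$, fitted by unconstrained linear least squares on the
stacked channels. The per-decade density is raised (3, 5, 7) until the
residual improves by less than 5%. The reported residual is
modulus-relative, $\overline{|Z_{fit}-Z|/|Z|}\times 100$, with the maximum
alongside; the pass threshold is 0.1% on the *mean* (the max is reported
but not thresholded — an interpretation choice documented here). Every
noiseless catalog spectrum passes below 0.1%; direct numerical
Hilbert-transform integration and full Tikhonov-regularized DRT are out of
scope. The time-constant distribution uses the same basis with nonnegative
least squares and a light ridge, and reports local maxima above 5% of the
peak weight.

## The synthetic-data generator

No experimental corpus ships with the package, so training and validation
use a generator that emulates biofilm-electrode measurements: 120
log-spaced frequencies from 1 mHz to 100 kHz (the `adaptive` mode inserts
points near each sample's characteristic frequencies and resamples), a
uniform class mix over the eight circuits, and parameters drawn
log-uniformly from ranges representative of ferri/ferrocyanide redox
probes on small electrodes — solution resistance 5–30 Ω, charge-transfer
resistance 20–100 Ω, interfacial capacitance in the µF range, Warburg
coefficients 0.5–4 Ω s^-1/2^, CPE exponents 0.7–1. Multi-layer circuits
draw each layer's relaxation time inside separated physical bands
(sub-ms interfacial, 5–50 ms compact film, 0.3–0.9 s outer layer),
because distinct film layers with merged relaxations are not resolvable
by any method. With these ranges the faradaic classes stay inside an
envelope of a few hundred Ω (real) by a few tens of Ω (imaginary); the
blocking-electrode class (series R–C) necessarily exceeds it at mHz
frequencies, where a series capacitor dominates. A latent-growth
trajectory mode moves $R_{ct}$, $\sigma$ and film resistances
monotonically along a maturation variable for concentration/growth-series
experiments.

Noise is proportional complex Gaussian — independent perturbations of
$Z'$ and $Z''$ with standard deviation 1% of $|Z|$ plus a small floor —
the standard EIS measurement model. Instrument artifacts can be injected
(missing values, carried-over duplicates); the cleaning stage re-grids
onto the canonical frequency axis by log-linear interpolation, flags
anomalies (modulus > 5 MADs from a moving median across frequency), and
imputes duplicates/missing entries to the fixed value 0.01 before
assembling the wide 480-attribute table.

What passing tests on this generator do *not* show: robustness to
correlated drift (the noise model is independent across frequencies), to
inductive artifacts (none are modeled), or to chemistry outside the
calibrated impedance envelope. Results on real electrodes depend on how
well these ranges represent the cell at hand.

## Benchmark protocols

The package ships its validation experiments as `benchmark_*` functions;
`scripts/acceptance.R` runs them end to end. Problem sizes are the
package's chosen benchmark scales: 2,500 spectra (2,000 train / 500 test)
for classification; 100 spectra for the composite-error convergence and
similarity studies; 200 Monte-Carlo replicates for CI coverage; 50 runs
for warm-start stability and the optimizer ablation.

Two protocol details are easy to get wrong and are therefore fixed here.
The *convergence* study scores the DE initial guess (median-fitness member
of a fresh population) and the final fit with the mean-normalized
composite loss, for the reason given above. The *ablation* study compares
DE–LM and DE-only at an identical evaluation budget of ~3,600 model
evaluations per spectrum — a short interactive analysis. The budget is
deliberately scarce: both optimizers eventually reach the noise floor
given unlimited evaluations, and the hybrid's value is precisely what it
achieves when evaluations are rationed. The hybrid arm spends 12
generations on search and a 30-iteration LM polish on its top-10
individuals; fits are scored by $\log_{10}$ RSS and the reduction
reported relative to the DE-only score.

## Known limitations

* Semi-infinite Warburg only; no finite-length diffusion, Gerischer,
  transmission-line or inductive elements.
* The CNLS objective is unweighted, as specified; modulus-weighted CNLS
  would change the relative influence of high- and low-frequency points.
* Quick-fit features are stochastic; classification is deterministic only
  under the derived-seed scheme.
* The F-test assumes independent Gaussian residuals on the stacked
  channels; with proportional noise it is approximate and used only as a
  parsimony guard, not as the primary selector.
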