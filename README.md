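# eisfit

Automated equivalent-circuit analysis of electrochemical impedance spectra.

Electrochemical impedance spectroscopy (EIS) resolves the interfacial
kinetics of an electrochemical cell — a biosensor electrode, a corroding
surface, a growing biofilm — as a complex impedance spectrum
Z(ω) = Z′(ω) + jZ″(ω). Quantitative interpretation fits an equivalent
circuit model (ECM), but two steps are traditionally manual and fragile:
choosing the circuit, and estimating its parameters in a non-convex
least-squares landscape. `eisfit` automates the full workflow for users
who analyze many spectra (sensing series, growth experiments, batch QC):

* **Circuit library** — series/parallel grammar over R, C, constant-phase
  (CPE, Z = 1/(Q(jω)ⁿ)) and Warburg (Z = σ(1−j)/√ω) elements, with an
  eight-member catalog from the bare interface through the classical
  Randles cell (Rs + Rct‖Cdl) to layered biofilm-electrode models.
* **Hybrid DE–LM fitting** — bounded differential evolution
  (vᵢ = θr₁ + F(θr₂ − θr₃), F ∈ [0.4,1], CR = 0.9) explores the
  physically constrained space; its top-10% elite seeds
  Levenberg–Marquardt refinement, (JᵀJ + μ·s·I)Δθ = Jᵀr with Nielsen
  damping (μ ∈ [10⁻³, 10²]), condition-triggered ±5% restarts, and
  95% confidence intervals. All passive parameters stay positive and CPE
  exponents in range by construction.
* **Circuit selection** — all candidates are quick-fitted; the six error
  metrics per fit (χ², MSE, RMSE, MAE, R², MAPE) form a 48-dimensional
  feature vector scored by an XGBoost classifier whose per-metric
  importances feed back into a weighted composite loss
  L = Σ ωₘ·φ(eₘ) (importances below δ = 0.1 are downweighted), plus a
  post hoc nested F-test as a parsimony guard.
* **Data validation** — Kramers–Kronig measurement-model (Voigt chain)
  consistency checking and time-constant distribution analysis.
* **Synthetic data** — a calibrated generator of labeled biofilm-style
  spectra (120 points, 1 mHz–100 kHz, proportional complex noise,
  missing/duplicate imputation to 0.01) for training and benchmarking.
* **Interpretable regression** — random-forest mapping from fitted
  parameters to an external quantity (e.g. analyte concentration) with
  feature importances and out-of-fold R².

## Worked example

Simulate a nanoparticle-film electrode (circuit `C6`,
Rs + (Rct + W)‖CPE) with 1% proportional noise and recover its
parameters:

```r
library(eisfit)
set.seed(7)
cat8  <- circuit_catalog()
truth <- c(R0 = 18, R1 = 65, W1 = 1.8, CPE1.Q = 3e-5, CPE1.n = 0.88)
sp    <- generate_spectrum(cat8$C6, truth, gen_config(noise_sd = 0.01))
fit   <- eis_fit(sp, cat8$C6, seed = 7)
summary(fit)
#> Equivalent-circuit fit: nano-biofilm [C6]
#>
#> Parameters:
#>          estimate   ci_lower   ci_upper
#> R0     1.8025e+01 1.7932e+01 1.8118e+01
#> R1     6.5231e+01 6.4967e+01 6.5495e+01
#> W1     1.7857e+00 1.7314e+00 1.8418e+00
#> CPE1.Q 3.0589e-05 2.9155e-05 3.2094e-05
#> CPE1.n 8.7808e-01 8.7186e-01 8.8430e-01
#>
#> RSS: 115.86   Jacobian condition (equilibrated): 9.806
#> Restarts: 0   Model evaluations: 23258
#>
#> EIS error metrics (basis: reim)
#>     chi2      mse     rmse      mae       r2     mape
#> 16.26300  0.48276  0.69481  0.49910  0.99973  9.93270
```

Every estimate sits within ~2% of the generating value (mean parameter
similarity 0.9966) and the 95% intervals bracket the truth. `R0` is the
solution resistance (Ω), `R1` the charge-transfer resistance — the Nyquist
semicircle diameter that biosensing assays track — `W1` the Warburg
diffusion coefficient (Ω s^−1/2), and `CPE1.Q`/`CPE1.n` the distributed
double-layer capacitance of the rough film.

Validity screening reports how KK-consistent the sweep is; the residual
tracks the data's noise floor (here ~1%, so a 1%-noise sweep fails the
strict 0.1% threshold reserved for high-quality data):

```r
kk_check(sp)
#> Kramers-Kronig measurement-model check
#>   RC terms: 41
#>   mean relative residual: 1.049% (max 2.409%)
#>   passed (threshold 0.1%): FALSE
```

Other entry points: `plot(fit)` (Nyquist + Bode with the fitted curve),
`classify_spectrum()` / `train_selector()` for automatic circuit choice,
`batch_fit()` for multi-file parallel processing with a reproducibility
manifest, `time_constant_analysis()`, and `fit_importance_regressor()` /
`evaluate_feature_subsets()` for concentration calibration. The methods
vignette (`vignettes/eisfit-methods.Rmd`) documents the models, numerical
choices and generator calibration.

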