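#' Benchmark protocols for the fitting and selection framework
#'
#' These functions reproduce, at desk scale and on synthetic data, the
#' validation experiments the framework is assessed by: classifier holdout
#' accuracy, composite-error convergence, parameter-similarity recovery,
#' Monte-Carlo confidence-interval coverage, catalog-wide goodness of fit,
#' Kramers-Kronig validity, warm-start stability in the 10-parameter
#' circuit, and the hybrid-vs-global-only optimizer ablation. Each takes a
#' seed and returns the headline number together with its ingredients.
#'
#' @name eis-benchmarks
#' @keywords internal
NULL

#' Median-fitness member of a fresh DE initial population
#'
#' A reproducible "unoptimized" parameter vector: the median-fitness member
#' of a newly initialized differential-evolution population for the given
#' circuit and spectrum. Used as the baseline state in before/after
#' convergence comparisons.
#'
#' @inheritParams de_search
#' @param pop_size population size to initialize.
#' @return named parameter vector (natural scale).
#' @export
de_initial_guess <- function(circuit, spectrum, pop_size = 200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  b <- .internal_bounds(circuit)
  U <- .de_init(circuit, spectrum, pop_size, b)
  rss <- .rss_pop(circuit, U, 2 * pi * spectrum$freq,
                  spectrum$z_real, spectrum$z_imag, penalize = FALSE)
  pick <- order(rss)[ceiling(pop_size / 2)]
  theta <- .from_internal(circuit, U[pick, ])
  names(theta) <- circuit$theta_names
  theta
}

#' @describeIn eis-benchmarks Train/test the circuit selector on a freshly
#'   generated labeled dataset and report holdout accuracy (percent).
#' @param n_samples,holdout_frac dataset size and holdout fraction.
#' @param noise_sd proportional noise level of the generated spectra.
#' @param seed integer seed.
#' @param workers forked workers for featurization.
#' @export
benchmark_classification <- function(n_samples = 2500, holdout_frac = 0.2,
                                     noise_sd = 0.01, seed = 1,
                                     workers = 1L) {
  cfg <- gen_config(n_samples = n_samples, noise_sd = noise_sd)
  d <- generate_dataset(cfg, seed = seed)
  ft <- feature_table(d$spectra, seed = seed, workers = workers)
  sel <- train_selector(ft, d$labels, holdout_frac = holdout_frac,
                        seed = seed)
  list(accuracy_pct = 100 * sel$accuracy,
       accuracy_prefeedback_pct = 100 * sel$accuracy_prefeedback,
       baseline_pct = 100 * sel$baseline_accuracy,
       n_test = length(sel$test_idx), selector = sel)
}

#' @describeIn eis-benchmarks Mean percentage reduction of the uniform-weight
#'   composite error score from the DE initial guess to the full DE-LM fit.
#' @param n number of spectra.
#' @export
benchmark_composite_reduction <- function(n = 100, noise_sd = 0.01, seed = 1) {
  cfg <- gen_config(n_samples = n, noise_sd = noise_sd)
  d <- generate_dataset(cfg, seed = seed)
  catalog <- circuit_catalog()
  seeds <- derive_seeds(seed, n, salt = "composite")
  w <- eis_weights()
  red <- numeric(n)
  for (i in seq_len(n)) {
    sp <- d$spectra[[i]]
    cc <- catalog[[d$labels[i]]]
    th0 <- de_initial_guess(cc, sp, seed = seeds[i])
    m0 <- compute_metrics(sp, circuit_impedance(cc, th0, sp$freq))
    fit <- eis_fit(sp, cc, seed = seeds[i])
    m1 <- fit$metrics
    peers <- list(m0, m1)
    L0 <- composite_loss(m0, peers, w, norm = "mean")$L
    L1 <- composite_loss(m1, peers, w, norm = "mean")$L
    red[i] <- 100 * (L0 - L1) / L0
  }
  list(mean_reduction_pct = mean(red), per_spectrum = red)
}

#' @describeIn eis-benchmarks Mean parameter similarity between ground truth
#'   and DE-LM estimates over low-noise synthetic fits of one circuit.
#' @param circuit_id catalog id of the generating circuit.
#' @export
benchmark_similarity <- function(n = 100, circuit_id = "C5",
                                 noise_sd = 0.005, seed = 1) {
  cc <- circuit_catalog()[[circuit_id]]
  cfg <- gen_config(noise_sd = noise_sd)
  seeds <- derive_seeds(seed, n, salt = "similarity")
  sims <- numeric(n)
  set.seed(seed)
  for (i in seq_len(n)) {
    th <- sample_parameters(cc)
    sp <- generate_spectrum(cc, th, cfg)
    fit <- eis_fit(sp, cc, seed = seeds[i])
    sims[i] <- parameter_similarity(th, fit$theta_hat)
  }
  list(mean_similarity = mean(sims), per_fit = sims)
}

#' @describeIn eis-benchmarks Empirical coverage (percent) of the 95%
#'   confidence interval for the charge-transfer resistance under uniform
#'   multiplicative data perturbations of up to +/-10%.
#' @param perturbation half-width of the per-point multiplicative
#'   perturbation.
#' @export
benchmark_ci_coverage <- function(n = 200, perturbation = 0.10, seed = 1) {
  cc <- circuit_catalog()$C3
  truth <- cc$theta
  base <- circuit_impedance(cc, truth, make_frequency_grid(gen_config()))
  seeds <- derive_seeds(seed, n, salt = "coverage")
  hits <- logical(n)
  for (i in seq_len(n)) {
    set.seed(seeds[i])
    fac <- stats::runif(nrow(base), 1 - perturbation, 1 + perturbation)
    sp <- eis_spectrum(base$freq, base$z_real * fac, base$z_imag * fac)
    fit <- eis_fit(sp, cc, seed = seeds[i])
    ci <- fit$ci["R1", ]
    hits[i] <- ci["lower"] <= truth["R1"] && truth["R1"] <= ci["upper"]
  }
  list(coverage_pct = 100 * mean(hits), hits = hits)
}

#' @describeIn eis-benchmarks Goodness of fit across the whole catalog:
#'   every circuit fitted to a matched synthetic spectrum; reports the
#'   minimum R-squared.
#' @export
benchmark_catalog_r2 <- function(noise_sd = 0.01, seed = 1) {
  catalog <- circuit_catalog()
  cfg <- gen_config(noise_sd = noise_sd)
  seeds <- derive_seeds(seed, length(catalog), salt = "r2")
  r2 <- numeric(length(catalog))
  names(r2) <- names(catalog)
  set.seed(seed)
  for (i in seq_along(catalog)) {
    cc <- catalog[[i]]
    sp <- generate_spectrum(cc, sample_parameters(cc), cfg)
    fit <- eis_fit(sp, cc, seed = seeds[i])
    r2[i] <- fit$metrics$r2
  }
  list(min_r2 = min(r2), per_circuit = r2)
}

#' @describeIn eis-benchmarks Kramers-Kronig residual (percent) of a
#'   noiseless 120-point Randles spectrum at catalog default parameters.
#' @export
benchmark_kk_residual <- function(seed = 1) {
  sp <- circuit_impedance(circuit_catalog()$C3,
                          freq = make_frequency_grid(gen_config()))
  kk <- kk_check(sp, n_rc = 7)
  list(residual_pct = kk$residual_pct, passed = kk$passed, report = kk)
}

#' @describeIn eis-benchmarks Warm-start stability of the 10-parameter
#'   circuit: mean similarity (percent) between re-fits started from
#'   +/-10%-perturbed centers and the unperturbed reference fit.
#' @export
benchmark_warmstart_stability <- function(n = 50, noise_sd = 0.005, seed = 1) {
  cc <- circuit_catalog()$C8
  set.seed(seed)
  sp <- generate_spectrum(cc, cc$theta, gen_config(noise_sd = noise_sd))
  ref <- eis_fit(sp, cc, seed = seed)
  seeds <- derive_seeds(seed, n, salt = "warmstart")
  sims <- numeric(n)
  short <- de_control(pop_size = 64, max_gen = 40, min_gen = 20,
                      patience = 10)
  for (i in seq_len(n)) {
    set.seed(seeds[i])
    center <- ref$theta_hat * stats::runif(cc$n_params, 0.9, 1.1)
    pop0 <- reflect_bounds(
      sweep(matrix(stats::runif(64 * cc$n_params, 0.95, 1.05), 64), 2L,
            center, "*"), cc$lower, cc$upper)
    s <- de_search(cc, sp, short, init_pop = pop0)
    fit <- lm_refine(cc, sp, s$elite[1L, ])
    sims[i] <- parameter_similarity(ref$theta_hat, fit$theta)
  }
  list(mean_similarity_pct = 100 * mean(sims), per_run = sims, ref = ref)
}

#' @describeIn eis-benchmarks Optimizer ablation at matched evaluation
#'   budgets: mean percentage reduction of the log10-RSS score of the
#'   hybrid DE-LM fit relative to DE-only.
#' @param circuit_id generating circuit for the ablation spectra.
#' @export
benchmark_optimizer_ablation <- function(n = 50, circuit_id = "C5",
                                         noise_sd = 0.01, seed = 1) {
  cc <- circuit_catalog()[[circuit_id]]
  cfg <- gen_config(noise_sd = noise_sd)
  seeds <- derive_seeds(seed, n, salt = "ablation")
  # a scarcity budget (~3600 evaluations, a short interactive analysis):
  # the hybrid spends 12 generations on global search and polishes its top
  # 10 individuals with a 30-iteration LM; DE-only receives exactly the
  # evaluation count the hybrid consumed
  hybrid_de <- de_control(pop_size = 200, max_gen = 12, min_gen = 12,
                          elite_frac = 0.05)
  red <- numeric(n)
  set.seed(seed)
  for (i in seq_len(n)) {
    th <- sample_parameters(cc)
    sp <- generate_spectrum(cc, th, cfg)
    hybrid <- eis_fit(sp, cc, de = hybrid_de,
                      lm = lm_control(max_iter = 30), seed = seeds[i],
                      n_starts = 1, max_rescues = 0)
    de_only <- eis_fit(sp, cc,
                       de = de_control(pop_size = 200,
                                       max_evals = hybrid$n_evals,
                                       max_gen = 10000, min_gen = 10000),
                       seed = seeds[i], refine = FALSE)
    s_de <- log10(de_only$rss); s_hy <- log10(hybrid$rss)
    red[i] <- 100 * (s_de - s_hy) / abs(s_de)
  }
  list(mean_reduction_pct = mean(red), per_spectrum = red)
}
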