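#' Configuration of the synthetic EIS dataset generator
#'
#' The generator emulates a hybrid training corpus of biofilm-electrode
#' impedance spectra: each sample is one 120-point sweep over 0.001 Hz to
#' 1e5 Hz drawn from one of the eight catalog circuits, with parameters
#' drawn from physically representative ranges (charge-transfer resistance
#' tracking surface coverage, Warburg coefficient tracking film thickness
#' and porosity, film R-C evolution), corrupted by proportional complex
#' Gaussian measurement noise, and assembled into a wide table of
#' 4 attributes x 120 points = 480 columns per sample.
#'
#' @param n_samples number of spectra (full-scale default 4000; tests and
#'   benchmarks use smaller values).
#' @param n_freq frequency points per sweep.
#' @param f_range frequency range in Hz, ascending.
#' @param class_mix per-circuit sampling proportions (named by catalog id;
#'   default uniform over the 8 circuits).
#' @param noise_sd proportional noise level: each of the real and imaginary
#'   parts receives independent Gaussian noise with standard deviation
#'   `noise_sd * |Z|` plus the additive floor `noise_floor`.
#' @param noise_floor additive noise floor (Ohm).
#' @param missing_rate,duplicate_rate per-value rates of injected missing
#'   values and duplicated (carried-over) values, emulating instrument
#'   artifacts; both imputed to `impute_value` during assembly.
#' @param impute_value replacement value for duplicates/missing entries.
#' @param sampling `"exponential"` (log-spaced grid) or `"adaptive"`
#'   (log-spaced plus extra points near each circuit's characteristic
#'   frequencies, resampled back to `n_freq`).
#' @return list of class `"eis_gen_config"`.
#' @export
gen_config <- function(n_samples = 4000, n_freq = 120,
                       f_range = c(1e-3, 1e5),
                       class_mix = NULL, noise_sd = 0.01,
                       noise_floor = 1e-4, missing_rate = 0,
                       duplicate_rate = 0, impute_value = 0.01,
                       sampling = c("exponential", "adaptive")) {
  stopifnot(n_freq >= 10, f_range[1L] > 0, f_range[2L] > f_range[1L])
  if (is.null(class_mix)) {
    class_mix <- rep(1 / 8, 8)
    names(class_mix) <- paste0("C", 1:8)
  }
  stopifnot(abs(sum(class_mix) - 1) < 1e-8)
  structure(list(n_samples = n_samples, n_freq = as.integer(n_freq),
                 f_range = f_range, class_mix = class_mix,
                 noise_sd = noise_sd, noise_floor = noise_floor,
                 missing_rate = missing_rate, duplicate_rate = duplicate_rate,
                 impute_value = impute_value,
                 sampling = match.arg(sampling)),
            class = "eis_gen_config")
}

# physically representative sampling ranges per circuit parameter, narrower
# than the search bounds: calibrated so that spectra span the few-hundred-Ohm
# real / tens-of-Ohm imaginary envelope of ferri/ferrocyanide biofilm cells
.gen_ranges <- function(circuit) {
  rng <- list(
    R0 = c(5, 30), R1 = c(20, 100), R2 = c(5, 50), R3 = c(10, 50),
    C0 = c(1e-4, 1e-2), C1 = c(1e-6, 1e-4), C2 = c(1e-4, 1e-2),
    CPE1.Q = c(1e-6, 1e-4), CPE2.Q = c(1e-5, 1e-3),
    CPE1.n = c(0.7, 1), CPE2.n = c(0.7, 1),
    W1 = c(0.5, 4)
  )
  out <- do.call(rbind, rng[circuit$theta_names])
  rownames(out) <- circuit$theta_names
  out
}

# relaxation-time bands (seconds) per parallel section for multi-layer
# circuits: the interfacial process relaxes in the sub-ms range, a compact
# film in the 10-100 ms range, an outer diffuse layer near a second --
# distinct layers of a real film have separated relaxations, which is what
# makes the layered circuit resolvable in the first place
.section_tau_bands <- list(
  `2` = list(c(2e-5, 1e-3), c(1e-2, 0.3)),
  `3` = list(c(2e-5, 1e-3), c(5e-3, 5e-2), c(0.3, 0.9))
)

#' Log-spaced (optionally physics-adaptive) frequency grid
#'
#' @param cfg a [gen_config].
#' @param char_freq optional characteristic frequencies (Hz) of the sampled
#'   circuit, e.g. \eqn{1/(2\pi R C)} per RC pair; in `"adaptive"` mode the
#'   grid is densified near them and resampled back to `n_freq` points.
#' @return ascending frequency vector of length `cfg$n_freq` with the exact
#'   range endpoints.
#' @export
make_frequency_grid <- function(cfg = gen_config(), char_freq = NULL) {
  base <- 10^seq(log10(cfg$f_range[1L]), log10(cfg$f_range[2L]),
                 length.out = cfg$n_freq)
  if (cfg$sampling == "exponential" || is.null(char_freq)) return(base)
  char_freq <- char_freq[char_freq > cfg$f_range[1L] &
                           char_freq < cfg$f_range[2L]]
  if (length(char_freq) == 0L) return(base)
  extra <- unlist(lapply(char_freq, function(fc)
    fc * 10^seq(-0.5, 0.5, length.out = 9)))
  all_f <- sort(unique(c(base, extra)))
  all_f <- all_f[all_f >= cfg$f_range[1L] & all_f <= cfg$f_range[2L]]
  # resample back to n_freq, keeping endpoints
  idx <- unique(round(seq(1L, length(all_f), length.out = cfg$n_freq)))
  f <- all_f[idx]
  f[1L] <- cfg$f_range[1L]; f[length(f)] <- cfg$f_range[2L]
  sort(unique(f))
}

#' Draw ground-truth parameters for a circuit
#'
#' Magnitude parameters (R, C, Q, sigma) are drawn log-uniformly within the
#' physically representative generator ranges; CPE exponents uniformly in
#' \[0.7, 1\] (electrode-like dispersion). In `trajectory` mode a latent
#' "growth" variable in \[0, 1\] drives correlated monotone trends in the
#' film-related parameters (charge-transfer resistance and film resistance
#' increase, Warburg coefficient increases with film thickness), emulating
#' biofilm maturation series.
#'
#' @param circuit an [eis_circuit] (catalog member).
#' @param growth optional latent growth value in \[0, 1\] switching on
#'   trajectory mode.
#' @return named parameter vector within the generator ranges.
#' @export
sample_parameters <- function(circuit, growth = NULL) {
  rng <- .gen_ranges(circuit)
  kinds <- circuit$param_kinds
  theta <- numeric(nrow(rng))
  for (i in seq_len(nrow(rng))) {
    if (kinds[i] == "n") theta[i] <- stats::runif(1, rng[i, 1L], rng[i, 2L])
    else theta[i] <- exp(stats::runif(1, log(rng[i, 1L]), log(rng[i, 2L])))
  }
  names(theta) <- circuit$theta_names
  if (!is.null(growth)) {
    stopifnot(growth >= 0, growth <= 1)
    # monotone placement along the range for film-linked parameters,
    # jittered log-normally within a narrow band
    for (nm in intersect(c("R1", "W1", "R2", "R3"), names(theta))) {
      lo <- rng[nm, 1L]; hi <- rng[nm, 2L]
      center <- exp(log(lo) + growth * (log(hi) - log(lo)))
      theta[nm] <- center * exp(stats::rnorm(1, 0, 0.05))
      theta[nm] <- min(max(theta[nm], lo), hi)
    }
  }
  # multi-layer circuits: re-derive each section's capacitive parameter
  # from a relaxation time drawn in that layer's band (see
  # .section_tau_bands), so the layers keep separated, ordered relaxations
  S <- length(circuit$sections)
  if (S >= 2L) {
    bands <- .section_tau_bands[[as.character(S)]]
    for (s in seq_len(S)) {
      sec <- circuit$sections[[s]]
      tau <- exp(stats::runif(1, log(bands[[s]][1L]), log(bands[[s]][2L])))
      if (sec$type == "RC") theta[sec$c] <- tau / theta[sec$r]
      else theta[sec$q] <- tau^theta[sec$n] / theta[sec$r]
    }
  }
  theta
}

#' Add proportional complex Gaussian noise to a spectrum
#'
#' @param spectrum an [eis_spectrum].
#' @param noise_sd proportional noise level (sd as a fraction of |Z|).
#' @param noise_floor additive floor (Ohm).
#' @return noisy [eis_spectrum] (ground-truth attributes preserved).
#' @export
add_proportional_noise <- function(spectrum, noise_sd = 0.01,
                                   noise_floor = 1e-4) {
  mod <- Mod(.spectrum_z(spectrum))
  sd_i <- noise_sd * mod + noise_floor
  eis_spectrum(freq = spectrum$freq,
               z_real = spectrum$z_real + stats::rnorm(nrow(spectrum), 0, sd_i),
               z_imag = spectrum$z_imag + stats::rnorm(nrow(spectrum), 0, sd_i),
               pt = spectrum$pt, source = attr(spectrum, "source"),
               circuit_id = attr(spectrum, "circuit_id"),
               theta = attr(spectrum, "theta"))
}

#' Generate one synthetic spectrum
#'
#' Evaluates the circuit on the grid, adds proportional complex Gaussian
#' noise and optionally injects missing/duplicate values (as NA and
#' carried-over values respectively; imputed later by
#' [clean_and_assemble]).
#'
#' @param circuit an [eis_circuit].
#' @param theta parameter vector (default: drawn by [sample_parameters]).
#' @param cfg a [gen_config].
#' @param grid optional frequency grid override.
#' @return an [eis_spectrum] carrying `circuit_id` and `theta` ground truth.
#' @export
generate_spectrum <- function(circuit, theta = sample_parameters(circuit),
                              cfg = gen_config(), grid = NULL) {
  if (is.null(grid)) {
    cf <- NULL
    if (cfg$sampling == "adaptive") {
      rc <- intersect(c("R1", "R2", "R3"), names(theta))
      cc <- intersect(c("C1", "C2"), names(theta))
      if (length(rc) && length(cc))
        cf <- 1 / (2 * pi * theta[rc[seq_along(cc)]] * theta[cc])
    }
    grid <- make_frequency_grid(cfg, char_freq = cf)
  }
  sp <- circuit_impedance(circuit, theta, grid)
  if (cfg$noise_sd > 0 || cfg$noise_floor > 0)
    sp <- add_proportional_noise(sp, cfg$noise_sd, cfg$noise_floor)
  n <- nrow(sp)
  if (cfg$missing_rate > 0) {
    miss <- stats::runif(n) < cfg$missing_rate
    sp$z_real[miss] <- NA_real_
    miss2 <- stats::runif(n) < cfg$missing_rate
    sp$z_imag[miss2] <- NA_real_
  }
  if (cfg$duplicate_rate > 0 && n > 1L) {
    dup <- which(stats::runif(n - 1L) < cfg$duplicate_rate) + 1L
    sp$z_real[dup] <- sp$z_real[dup - 1L]
    sp$z_imag[dup] <- sp$z_imag[dup - 1L]
  }
  sp
}

#' Clean a set of spectra and assemble the wide labeled dataset
#'
#' Performs the dataset-construction pipeline: frequency alignment onto the
#' canonical grid by log-linear interpolation where needed, anomaly flagging
#' (modulus deviating more than 5 median absolute deviations from a moving
#' median across frequency), replacement of missing and duplicated values by
#' the fixed imputation value (default 0.01), and assembly into one wide
#' table with 4 attributes (Pt, Freq, Z_real, Z_imag) per frequency point.
#' Spectra with fewer than 50% valid points are dropped with a warning.
#'
#' @param spectra list of [eis_spectrum] objects (ground-truth attributes
#'   are carried into `labels`/`truths`).
#' @param cfg a [gen_config].
#' @return list of class `"eis_dataset"`: `table` (n x 4*n_freq numeric
#'   matrix), `labels` (circuit ids), `truths` (list of parameter vectors),
#'   `freq` (canonical grid), `anomaly_count` per sample, and `stats`
#'   (column sds and the frequency/Z correlations).
#' @export
clean_and_assemble <- function(spectra, cfg = gen_config()) {
  stopifnot(length(spectra) > 0L)
  grid <- make_frequency_grid(gen_config(n_freq = cfg$n_freq,
                                         f_range = cfg$f_range))
  nf <- length(grid)
  rows <- vector("list", length(spectra))
  labels <- character(length(spectra))
  truths <- vector("list", length(spectra))
  anomalies <- integer(length(spectra))
  keep <- logical(length(spectra))
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    valid <- is.finite(sp$z_real) & is.finite(sp$z_imag)
    if (mean(valid) < 0.5) {
      warning("spectrum ", i, " has <50% valid points; dropped")
      next
    }
    zr <- sp$z_real; zi <- sp$z_imag
    # duplicate detection: identical consecutive (z_real, z_imag) pairs
    if (nrow(sp) > 1L) {
      dup <- c(FALSE, diff(zr) == 0 & diff(zi) == 0)
      zr[dup] <- NA_real_; zi[dup] <- NA_real_
    }
    # frequency alignment by log-linear interpolation onto the common grid
    if (nrow(sp) != nf || max(abs(log(sort(sp$freq) / grid))) > 1e-9) {
      ord <- order(sp$freq)
      zr <- stats::approx(log(sp$freq[ord]), zr[ord], xout = log(grid),
                          rule = 2)$y
      zi <- stats::approx(log(sp$freq[ord]), zi[ord], xout = log(grid),
                          rule = 2)$y
    }
    # anomaly flag: modulus > 5 MADs from a moving median across frequency
    mod <- sqrt(zr^2 + zi^2)
    med <- stats::runmed(ifelse(is.finite(mod), mod, stats::median(mod, na.rm = TRUE)),
                         k = min(11L, nf - (1 - nf %% 2)))
    dev <- abs(mod - med)
    madv <- stats::mad(dev, na.rm = TRUE)
    anomalies[i] <- sum(dev > 5 * madv & madv > 0, na.rm = TRUE)
    # imputation of remaining missing/duplicate values
    zr[!is.finite(zr)] <- cfg$impute_value
    zi[!is.finite(zi)] <- cfg$impute_value
    rows[[i]] <- as.numeric(rbind(seq_len(nf), grid, zr, zi))
    labels[i] <- if (!is.null(attr(sp, "circuit_id")))
      attr(sp, "circuit_id") else NA_character_
    truths[[i]] <- attr(sp, "theta")
    keep[i] <- TRUE
  }
  tab <- do.call(rbind, rows[keep])
  colnames(tab) <- as.vector(rbind(
    paste0("Pt_", seq_len(nf)), paste0("Freq_", seq_len(nf)),
    paste0("Z_real_", seq_len(nf)), paste0("Z_imag_", seq_len(nf))))
  zr_cols <- grep("^Z_real_", colnames(tab))
  zi_cols <- grep("^Z_imag_", colnames(tab))
  f_long <- rep(grid, each = sum(keep))
  zr_long <- as.numeric(tab[, zr_cols])
  zi_long <- as.numeric(tab[, zi_cols])
  stats <- list(
    sd = c(freq = stats::sd(f_long), z_real = stats::sd(zr_long),
           z_imag = stats::sd(zi_long)),
    cor = c(freq_z_real = stats::cor(f_long, zr_long),
            freq_z_imag = stats::cor(f_long, zi_long),
            z_real_z_imag = stats::cor(zr_long, zi_long)))
  structure(list(table = tab, labels = labels[keep], truths = truths[keep],
                 freq = grid, anomaly_count = anomalies[keep], stats = stats),
            class = "eis_dataset")
}

#' @export
print.eis_dataset <- function(x, ...) {
  cat("Synthetic EIS dataset: ", nrow(x$table), " samples x ",
      ncol(x$table), " attributes (", length(x$freq),
      " frequency points)\n", sep = "")
  cat("  class counts:\n")
  print(table(x$labels))
  cat("  correlations: ", paste(names(x$stats$cor),
      signif(x$stats$cor, 4), sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Generate a labeled synthetic dataset
#'
#' Draws circuit labels from `cfg$class_mix`, parameters from the
#' physically representative ranges, simulates and corrupts each spectrum
#' and assembles the cleaned wide table. Fully reproducible from
#' `(cfg, seed)`.
#'
#' @param cfg a [gen_config].
#' @param seed integer seed.
#' @param catalog circuit catalog to sample from.
#' @return an `"eis_dataset"` (see [clean_and_assemble]) with an extra
#'   `spectra` element holding the individual [eis_spectrum] objects.
#' @export
generate_dataset <- function(cfg = gen_config(), seed = NULL,
                             catalog = circuit_catalog()) {
  if (!is.null(seed)) set.seed(seed)
  ids <- sample(names(cfg$class_mix), cfg$n_samples, replace = TRUE,
                prob = cfg$class_mix)
  spectra <- lapply(ids, function(id)
    generate_spectrum(catalog[[id]], cfg = cfg))
  out <- clean_and_assemble(spectra, cfg)
  out$spectra <- spectra
  out
}
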