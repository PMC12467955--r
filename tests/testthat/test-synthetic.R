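test_that("frequency grid has the canonical design", {
  g <- make_frequency_grid(gen_config())
  expect_length(g, 120L)
  expect_equal(g[1], 1e-3)
  expect_equal(g[120], 1e5)
  # constant ratio between consecutive log-spaced points
  expect_equal(diff(range(diff(log(g)))), 0, tolerance = 1e-12)
  # adaptive grid stays in range, sorted, right length
  cfg <- gen_config(sampling = "adaptive")
  ga <- make_frequency_grid(cfg, char_freq = c(5, 2000))
  expect_true(all(diff(ga) > 0))
  expect_true(all(ga >= 1e-3 & ga <= 1e5))
})

test_that("parameter draws respect ranges and reproduce under a seed", {
  cat8 <- circuit_catalog()
  set.seed(31)
  for (k in 1:200) {
    cc <- cat8[[sample(8, 1)]]
    th <- sample_parameters(cc)
    expect_true(all(th >= cc$lower & th <= cc$upper))
    ns <- grepl("\\.n$", names(th))
    expect_true(all(th[ns] >= 0.7 & th[ns] <= 1))
  }
  set.seed(7); a <- sample_parameters(cat8$C6)
  set.seed(7); b <- sample_parameters(cat8$C6)
  expect_identical(a, b)
})

test_that("growth trajectories drive monotone film parameters", {
  cc <- circuit_catalog()$C6
  set.seed(5)
  g <- seq(0, 1, length.out = 9)
  # average over jitter replicates: medians along the latent variable rise
  r1 <- sapply(g, function(gi) {
    median(replicate(20, sample_parameters(cc, growth = gi)["R1"]))
  })
  expect_true(all(diff(r1) > 0))
})

test_that("proportional noise has the declared magnitude", {
  cc <- circuit_catalog()$C3
  f <- test_freq(60)
  base <- circuit_impedance(cc, freq = f)
  set.seed(41)
  devs <- replicate(100, {
    noisy <- add_proportional_noise(base, noise_sd = 0.01)
    median(Mod(complex(real = noisy$z_real - base$z_real,
                       imaginary = noisy$z_imag - base$z_imag)) /
             Mod(complex(real = base$z_real, imaginary = base$z_imag)))
  })
  # median modulus deviation of a complex N(0, (1%)^2 I) is ~1.18%
  expect_gt(mean(devs), 0.008)
  expect_lt(mean(devs), 0.016)
})

test_that("zero-noise generated spectra are KK consistent", {
  set.seed(51)
  cfg <- gen_config(noise_sd = 0, noise_floor = 0)
  for (id in c("C3", "C6", "C8")) {
    sp <- generate_spectrum(circuit_catalog()[[id]], cfg = cfg)
    expect_true(kk_check(sp)$passed)
  }
})

test_that("cleaning imputes, aligns and assembles the wide table", {
  set.seed(61)
  cfg <- gen_config(n_samples = 24, n_freq = 40, missing_rate = 0.05,
                    duplicate_rate = 0.05)
  d <- generate_dataset(cfg, seed = 61)
  expect_identical(ncol(d$table), 160L)          # 4 attributes per point
  expect_false(any(!is.finite(d$table)))
  # injected NA became exactly the imputation value
  sp <- generate_spectrum(circuit_catalog()$C3, cfg = cfg)
  sp$z_real[5] <- NA
  out <- clean_and_assemble(list(sp), cfg)
  expect_equal(unname(out$table[1, "Z_real_5"]), 0.01)
  # duplicates also map to the imputation value
  sp2 <- generate_spectrum(circuit_catalog()$C3, cfg = gen_config(n_freq = 40))
  sp2$z_real[10] <- sp2$z_real[9]; sp2$z_imag[10] <- sp2$z_imag[9]
  out2 <- clean_and_assemble(list(sp2), cfg)
  expect_equal(unname(out2$table[1, "Z_real_10"]), 0.01)
  expect_equal(unname(out2$table[1, "Z_imag_10"]), 0.01)
  # mostly-invalid spectra are dropped with a warning
  sp3 <- sp2; sp3$z_real[1:30] <- NA
  expect_warning(o3 <- clean_and_assemble(list(sp2, sp3), cfg), "dropped")
  expect_identical(nrow(o3$table), 1L)
})

test_that("default generation reproduces the qualitative dataset statistics", {
  d <- generate_dataset(gen_config(n_samples = 160), seed = 71)
  # negative correlation between real and imaginary parts (capacitive sign
  # convention); the magnitude is generator-dependent, so only the sign is
  # asserted
  expect_lt(d$stats$cor["z_real_z_imag"], 0)
  # frequency only weakly correlated with either part
  expect_lt(abs(d$stats$cor["freq_z_real"]), 0.3)
  expect_lt(abs(d$stats$cor["freq_z_imag"]), 0.3)
  # class proportions within multinomial sampling error of uniform
  counts <- table(factor(d$labels, levels = paste0("C", 1:8)))
  expect_true(all(abs(counts - 20) < 4.5 * sqrt(160 * (1 / 8) * (7 / 8))))
  # reproducibility from (config, seed)
  d2 <- generate_dataset(gen_config(n_samples = 160), seed = 71)
  expect_identical(d$table, d2$table)
  expect_identical(d$labels, d2$labels)
})

test_that("faradaic spectra stay within the impedance envelope", {
  set.seed(81)
  cfg <- gen_config(noise_sd = 0.01)
  cat8 <- circuit_catalog()
  zr_max <- 0; zi_min <- 0
  for (k in 1:40) {
    id <- sample(paste0("C", 3:8), 1)      # faradaic classes
    sp <- generate_spectrum(cat8[[id]], cfg = cfg)
    zr_max <- max(zr_max, sp$z_real)
    zi_min <- min(zi_min, sp$z_imag)
  }
  # a few hundred Ohm real, tens of Ohm (negative) imaginary
  expect_lt(zr_max, 500)
  expect_gt(zi_min, -150)
  expect_lt(zi_min, -10)
})

test_that("ground-truth circuits are recovered from zero-noise samples", {
  set.seed(91)
  cfg <- gen_config(noise_sd = 0, noise_floor = 0)
  cat8 <- circuit_catalog()
  for (id in c("C2", "C5", "C7")) {
    th <- sample_parameters(cat8[[id]])
    sp <- generate_spectrum(cat8[[id]], th, cfg)
    fit <- eis_fit(sp, cat8[[id]], seed = 17)
    expect_gte(parameter_similarity(th, fit$theta_hat), 0.999)
  }
})
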