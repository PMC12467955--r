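# shared fixtures: small grids and cheap fit controls keep unit tests fast
test_freq <- function(n = 40) 10^seq(-2, 5, length.out = n)

fast_de <- function(...) de_control(pop_size = 40, max_gen = 40,
                                    min_gen = 20, patience = 10, ...)
fast_lm <- function(...) lm_control(max_iter = 60, boot_B = 30, ...)

# independent scalar oracles for the six error metrics (deliberately naive)
oracle_metrics <- function(y, yh) {
  n <- length(y)
  list(chi2 = sum((y - yh)^2 / pmax(abs(yh), 1e-12)),
       mse = sum((y - yh)^2) / n,
       rmse = sqrt(sum((y - yh)^2) / n),
       mae = sum(abs(y - yh)) / n,
       r2 = 1 - sum((y - yh)^2) / sum((y - mean(y))^2),
       mape = 100 / n * sum(abs((y - yh) / y)))
}

make_fixture_files <- function(dir, n = 4) {
  cat8 <- circuit_catalog()
  ids <- c("C1", "C3", "C5", "C3")[seq_len(n)]
  paths <- character(n)
  set.seed(301)
  for (i in seq_len(n)) {
    sp <- generate_spectrum(cat8[[ids[i]]],
                            cfg = gen_config(n_freq = 40, noise_sd = 0.01))
    paths[i] <- file.path(dir, sprintf("spec_%02d.csv", i))
    write_spectrum(sp, paths[i])
  }
  paths
}

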