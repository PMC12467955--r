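test_that("feature vectors follow the 48-slot schema and are reproducible", {
  cat8 <- circuit_catalog()
  set.seed(101)
  sp <- generate_spectrum(cat8$C3, cfg = gen_config())
  fv <- build_features(sp, cat8, seed = 5)
  expect_length(fv, 48L)
  expect_identical(names(fv)[1:6],
                   paste("C1", c("chi2", "mse", "rmse", "mae", "r2", "mape"),
                         sep = "."))
  expect_true(all(is.finite(fv)))
  fv2 <- build_features(sp, cat8, seed = 5)
  expect_identical(fv, fv2)
  # the true circuit's mse is the best among equal-or-simpler candidates
  simpler <- paste0("C", 1:3)
  expect_identical(which.min(fv[paste0(simpler, ".mse")]), c(C3.mse = 3L))
})

test_that("training on linearly separable toy features is perfect", {
  set.seed(11)
  n <- 120
  # discrete feature levels so split thresholds cannot fall between a
  # training cluster and a test point
  X <- cbind(a = rep(c(-1, 1), each = n / 2) + rep(c(-.2, 0, .2), n / 3),
             b = rnorm(n))
  colnames(X) <- c("C1.mse", "C2.mse")
  y <- rep(c("C1", "C2"), each = n / 2)
  sel <- train_selector(X, y, nrounds = 50, seed = 2)
  expect_equal(sel$accuracy, 1.0)
  expect_equal(sum(sel$importances), 1)
  # confusion-matrix bookkeeping: row sums equal per-class test counts,
  # accuracy recomputable from the diagonal
  expect_equal(unname(rowSums(sel$confusion)),
               as.vector(table(y[sel$test_idx])))
  expect_equal(sum(diag(sel$confusion)) / sum(sel$confusion), sel$accuracy)
  expect_error(train_selector(X, rep("C1", n)), "2 classes")
})

test_that("adapt_weights applies the importance threshold rule", {
  fake <- structure(list(importances = c(chi2 = 0.4, mse = 0.3, rmse = 0.2,
                                         mae = 0.05, r2 = 0.03, mape = 0.02)),
                    class = "eis_selector")
  w <- adapt_weights(fake, delta = 0.1)
  raw <- c(0.4, 0.3, 0.2, 0.005, 0.003, 0.002)
  expect_equal(unname(w$omega), raw / sum(raw))
  expect_equal(sum(w$omega), 1)
})

test_that("the trained selector classifies low-noise spectra end to end", {
  cat8 <- circuit_catalog()
  set.seed(103)
  cfg <- gen_config(n_samples = 160, noise_sd = 0.01)
  d <- generate_dataset(cfg, seed = 103)
  ft <- feature_table(d$spectra, cat8, seed = 103)
  sel <- train_selector(ft, d$labels, seed = 103)
  expect_gt(sel$accuracy, 0.6)          # small-sample sanity floor
  # classify a fresh unmistakable Randles spectrum
  sp <- generate_spectrum(cat8$C3, cfg = gen_config(noise_sd = 0.005))
  out <- classify_spectrum(sel, sp, cat8, seed = 9)
  expect_equal(sum(out$prob), 1, tolerance = 1e-6)
  expect_identical(out$circuit_id, "C3")
  # determinism of classification under a fixed seed
  out2 <- classify_spectrum(sel, sp, cat8, seed = 9)
  expect_identical(out$prob, out2$prob)
  # persistence round-trip
  path <- tempfile(fileext = ".rds")
  save_selector(sel, path)
  sel2 <- load_selector(path)
  out3 <- classify_spectrum(sel2, sp, cat8, seed = 9)
  expect_identical(out3$circuit_id, out$circuit_id)
})

test_that("nested F-test matches the closed form and is monotone", {
  mk_fit <- function(id, rss, n = 120) {
    cc <- circuit_catalog()[[id]]
    structure(list(circuit = cc, rss = rss, residuals = numeric(2 * n)),
              class = "eis_fit")
  }
  # direct substitution: ((2-1)/(5-3)) / (1/(240-5)) = 117.5
  f_simple <- mk_fit("C3", 2); f_simple$circuit$n_params <- 3L
  f_complex <- mk_fit("C5", 1); f_complex$circuit$n_params <- 5L
  got <- nested_f_test(f_simple, f_complex)
  expect_equal(got$F, 117.5)
  # oracle p-value from the F distribution at those dof
  expect_equal(got$p_value, pf(117.5, 2, 235, lower.tail = FALSE))
  expect_lt(got$p_value, 1e-10)
  # equal RSS -> F = 0, p = 1
  same <- nested_f_test(mk_fit("C3", 1), mk_fit("C5", 1))
  expect_equal(same$F, 0)
  expect_equal(same$p_value, 1)
  # p monotone decreasing in F at fixed dof
  ps <- sapply(c(1, 2, 5), function(rss_s)
    nested_f_test(mk_fit("C3", rss_s), mk_fit("C5", 1))$p_value)
  expect_true(all(diff(ps) < 0))
  # non-nested pair refuses
  expect_error(nested_f_test(mk_fit("C2", 2), mk_fit("C5", 1)), "not declared")
})

test_that("classification accuracy improves monotonically as noise vanishes", {
  # distinguishable pair (pure resistor vs Randles) featurized against a
  # two-circuit catalog at three noise levels
  cat2 <- circuit_catalog()[c("C1", "C3")]
  attr(cat2, "nested_pairs") <- attr(circuit_catalog(), "nested_pairs")
  small_b <- quick_budget(pop_size = 16, max_gen = 12, lm_iter = 6)
  acc <- sapply(c(0.5, 0.05, 0.001), function(nz) {
    set.seed(401)
    cfg <- gen_config(noise_sd = nz)
    spectra <- lapply(1:60, function(i)
      generate_spectrum(cat2[[1 + i %% 2]], cfg = cfg))
    labels <- sapply(1:60, function(i) names(cat2)[1 + i %% 2])
    ft <- feature_table(spectra, cat2, small_b, seed = 401)
    train_selector(ft, labels, nrounds = 80, seed = 401)$accuracy
  })
  expect_true(all(diff(acc) >= 0))
  expect_equal(acc[3], 1.0)
})

test_that("circuit configs round-trip through plain lists", {
  for (cc in circuit_catalog()[c("C4", "C8")]) {
    back <- circuit_from_config(circuit_config(cc))
    expect_identical(back$theta, cc$theta)
    expect_identical(back$lower, cc$lower)
    expect_identical(back$definition, cc$definition)
  }
  # JSON round-trip preserves the numbers
  cfg <- circuit_config(circuit_catalog()$C6)
  js <- jsonlite::fromJSON(jsonlite::toJSON(cfg, auto_unbox = TRUE,
                                            digits = NA))
  expect_equal(unlist(js$theta), circuit_catalog()$C6$theta)
})
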