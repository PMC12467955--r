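test_that("reflect_bounds mirrors values into the box", {
  expect_equal(reflect_bounds(c(1.2, -0.3, 0.5, 2.5), 0, 1),
               c(0.8, 0.3, 0.5, 0.5))
  # matrix form with per-column bounds
  m <- matrix(c(1.5, -1, 0.25, 3.2), 2, 2)
  got <- reflect_bounds(m, c(0, 0), c(1, 2))
  expect_true(all(got >= 0 & got <= matrix(c(1, 1, 2, 2), 2)))
  expect_equal(got[2, 1], 1)         # -1 reflects to 1
  # interior values untouched
  expect_equal(reflect_bounds(0.5, 0, 1), 0.5)
})

test_that("DE mutation and crossover follow the variational operator", {
  # deterministic check of v = r1 + F (r2 - r3) via a 4-member population
  # where all partners are identical: the mutant equals that vector
  pop <- rbind(c(1, 1), c(1, 1), c(1, 1), c(5, 9))
  set.seed(1)
  tr <- de_mutate_crossover(pop[c(1, 2, 3, 1), , drop = FALSE], F = 0.5,
                            CR = 1)
  expect_true(all(tr == 1))          # theta_r2 == theta_r3 -> v = theta_r1
  # direct substitution oracle with controlled indices: emulate one row
  v <- c(1, 1) + 0.5 * (c(3, 1) - c(1, 1))
  expect_equal(v, c(2, 1))
  # CR = 1 makes the trial equal the mutant in every coordinate: with a
  # homogeneous population any trial must stay in the population's span
  expect_error(de_mutate_crossover(pop[1:3, ], 0.5, 0.9), "at least 4")
})

test_that("DE search contract: determinism, monotone trace, elite decile", {
  cc <- circuit_catalog()$C3
  sp <- circuit_impedance(cc, freq = test_freq(40))
  a <- de_search(cc, sp, fast_de(), seed = 5)
  b <- de_search(cc, sp, fast_de(), seed = 5)
  expect_identical(a$elite, b$elite)               # bit-identical under seed
  expect_true(all(diff(a$best_trace) <= 0))        # monotone best fitness
  expect_identical(nrow(a$elite), as.integer(ceiling(0.1 * 40)))
  expect_true(all(a$elite_rss <= sort(a$fitness)[ceiling(0.1 * 40)] + 1e-12))
  # 1-parameter resistor model on noiseless data: truth recovered closely
  r1 <- circuit_catalog()$C1
  spr <- circuit_impedance(r1, theta = 42, freq = test_freq(20))
  s <- de_search(r1, spr, fast_de(), seed = 2)
  expect_lt(abs(s$elite[1, 1] - 42) / 42, 0.01)
})

test_that("LM refinement solves the linear case exactly and stays put at optima", {
  r1 <- circuit_catalog()$C1
  set.seed(3)
  sp <- add_proportional_noise(circuit_impedance(r1, theta = 42,
                                                 freq = test_freq(30)), 0.02)
  fit <- lm_refine(r1, sp, theta0 = 10)
  # closed-form least squares: mean of the real parts (imaginary target 0
  # pulls nothing because dZ/dR has zero imaginary component)
  expect_equal(unname(fit$theta), mean(sp$z_real), tolerance = 1e-8)
  expect_true(fit$converged)
  # starting at the optimum of a noiseless spectrum: immediate fixed point
  cc <- circuit_catalog()$C3
  spn <- circuit_impedance(cc, freq = test_freq(40))
  f2 <- lm_refine(cc, spn, cc$theta)
  expect_lt(f2$rss, 1e-18)
  expect_lte(f2$iterations, 2L)
})

test_that("LM recovers Randles+Warburg parameters from nearby starts", {
  cc <- circuit_catalog()$C5
  spn <- circuit_impedance(cc, freq = test_freq(60))
  set.seed(4)
  for (k in 1:3) {
    th0 <- cc$theta * runif(4, 0.8, 1.2)
    fit <- lm_refine(cc, spn, th0)
    expect_lt(max(abs(fit$theta - cc$theta) / cc$theta), 1e-3)
  }
})

test_that("finite-difference Jacobian agrees with central differences", {
  cc <- circuit_catalog()$C5
  sp <- circuit_impedance(cc, freq = test_freq(25))
  omega <- 2 * pi * sp$freq
  set.seed(8)
  for (k in 1:3) {
    th <- cc$theta * runif(4, 0.7, 1.3)
    u <- log(th)   # all four parameters are magnitude-type (log scale)
    fj <- eisfit:::.model_and_jacobian(cc, u, omega)
    # oracle: central differences at a different step size
    h <- 1e-5 * pmax(abs(u), 1)
    J_oracle <- sapply(seq_along(u), function(j) {
      up <- u; un <- u; up[j] <- up[j] + h[j]; un[j] <- un[j] - h[j]
      zp <- circuit_impedance(cc, exp(up), sp$freq, as_spectrum = FALSE)
      zn <- circuit_impedance(cc, exp(un), sp$freq, as_spectrum = FALSE)
      (c(Re(zp), Im(zp)) - c(Re(zn), Im(zn))) / (2 * h[j])
    })
    rel <- max(abs(fj$J - J_oracle)) / max(abs(J_oracle))
    expect_lt(rel, 1e-5)
  }
})

test_that("LM refinement agrees with an independent LM implementation", {
  cc <- circuit_catalog()$C3
  set.seed(14)
  sp <- add_proportional_noise(circuit_impedance(cc, freq = test_freq(50)),
                               0.01)
  th0 <- cc$theta * runif(3, 0.85, 1.15)
  ours <- lm_refine(cc, sp, th0)
  # independent route: minpack.lm on the same stacked-residual objective in
  # the same log parameterization
  resid_fn <- function(u) {
    z <- circuit_impedance(cc, exp(u), sp$freq, as_spectrum = FALSE)
    c(sp$z_real - Re(z), sp$z_imag - Im(z))
  }
  ref <- minpack.lm::nls.lm(par = log(th0), fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  expect_equal(unname(ours$theta), unname(exp(ref$par)), tolerance = 1e-4)
  expect_equal(ours$rss, sum(ref$fvec^2), tolerance = 1e-6)
})

test_that("full fit respects bounds, beats its seeds and reproduces", {
  cc <- circuit_catalog()$C3
  set.seed(9)
  sp <- add_proportional_noise(circuit_impedance(cc, freq = test_freq(50)), 0.01)
  fit <- eis_fit(sp, cc, de = fast_de(), lm = fast_lm(), seed = 11)
  expect_true(all(fit$theta_hat >= cc$lower & fit$theta_hat <= cc$upper))
  expect_equal(fit$rss, sum(fit$residuals^2), tolerance = 1e-10)
  fit2 <- eis_fit(sp, cc, de = fast_de(), lm = fast_lm(), seed = 11)
  expect_identical(fit$theta_hat, fit2$theta_hat)
  # argmin contract: the returned RSS cannot exceed any single refined seed
  s <- de_search(cc, sp, fast_de(), seed = 11)
  one <- lm_refine(cc, sp, s$elite[1, ], fast_lm())
  expect_lte(fit$rss, one$rss + 1e-9)
  # CI brackets the estimate
  expect_true(all(fit$ci[, "lower"] <= fit$theta_hat + 1e-12))
  expect_true(all(fit$ci[, "upper"] >= fit$theta_hat - 1e-12))
})

test_that("DE-only mode and model methods work", {
  cc <- circuit_catalog()$C3
  set.seed(10)
  sp <- add_proportional_noise(circuit_impedance(cc, freq = test_freq(40)), 0.01)
  fit <- eis_fit(sp, cc, de = fast_de(), seed = 3, refine = FALSE)
  expect_identical(fit$method, "de")
  full <- eis_fit(sp, cc, de = fast_de(), lm = fast_lm(), seed = 3)
  expect_lte(full$rss, fit$rss)
  expect_named(coef(full), cc$theta_names)
  expect_identical(dim(vcov(full)), c(3L, 3L))
  pr <- predict(full, newdata = c(1, 10, 100))
  expect_identical(nrow(pr), 3L)
  expect_length(residuals(full), 2 * nrow(sp))
  sims <- simulate(full, nsim = 2, seed = 1)
  expect_length(sims, 2L)
  expect_s3_class(sims[[1]], "eis_spectrum")
  out <- capture.output(print(summary(full)))
  expect_true(any(grepl("RSS", out)))
})

test_that("parameter similarity has its closed-form properties", {
  expect_equal(parameter_similarity(c(1), c(1)), 1)
  expect_equal(parameter_similarity(c(1), c(3)), 0.5)   # 1 - 2/4
  th <- c(2, 5); th2 <- c(3, 4)
  expect_equal(parameter_similarity(th, th2), parameter_similarity(th2, th))
  expect_equal(parameter_similarity(10 * th, 10 * th2),
               parameter_similarity(th, th2))
  expect_warning(s <- parameter_similarity(c(0, 1), c(0, 1)), "zero")
  expect_equal(s, 1)
})

test_that("physical constraints hold across a randomized fit fuzz", {
  cat8 <- circuit_catalog()
  set.seed(12)
  for (k in 1:20) {
    id <- sample(names(cat8), 1)
    cc <- cat8[[id]]
    sp <- generate_spectrum(cc, cfg = gen_config(noise_sd = 0.05))
    fit <- eis_fit(sp, cc, de = de_control(pop_size = 24, max_gen = 12),
                   lm = lm_control(max_iter = 10), seed = k,
                   n_starts = 1, max_rescues = 0)
    expect_true(all(fit$theta_hat > 0))
    ns <- grepl("\\.n$", names(fit$theta_hat))
    expect_true(all(fit$theta_hat[ns] >= 0 & fit$theta_hat[ns] <= 1))
    expect_true(all(fit$theta_hat >= cc$lower & fit$theta_hat <= cc$upper))
  }
})
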