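test_that("the six metrics match hand computation and the naive oracle", {
  m <- compute_metrics(c(1, 2, 3), c(2, 2, 2))
  # hand evaluation: chi2 = 1/2 + 0 + 1/2; mse = 2/3; r2 = 1 - 2/2 = 0;
  # mape = (100/3)(1 + 0 + 1/3)
  expect_equal(m$chi2, 1)
  expect_equal(m$mse, 2 / 3)
  expect_equal(m$rmse, sqrt(2 / 3))
  expect_equal(m$mae, 2 / 3)
  expect_equal(m$r2, 0)
  expect_equal(m$mape, (100 / 3) * (4 / 3))
  set.seed(42)
  for (k in 1:5) {
    y <- rnorm(50, sd = 10); yh <- y + rnorm(50)
    o <- oracle_metrics(y, yh)
    got <- compute_metrics(y, yh)
    for (nm in names(o)) expect_equal(got[[nm]], o[[nm]], tolerance = 1e-12)
    expect_equal(got$rmse^2, got$mse, tolerance = 1e-12)
  }
})

test_that("metrics behave under scaling and for the mean predictor", {
  y <- c(2, 5, 9, 4); yh <- c(1, 6, 8, 5)
  a <- compute_metrics(y, yh)
  b <- compute_metrics(3 * y, 3 * yh)
  expect_equal(b$r2, a$r2)
  expect_equal(b$mape, a$mape)
  expect_equal(b$mae, 3 * a$mae)
  expect_equal(b$mse, 9 * a$mse)
  expect_equal(compute_metrics(y, rep(mean(y), 4))$r2, 0)
  # perfect fit
  p <- compute_metrics(y, y)
  expect_equal(unlist(p[c("chi2", "mse", "rmse", "mae", "mape")]),
               c(chi2 = 0, mse = 0, rmse = 0, mae = 0, mape = 0))
  expect_equal(p$r2, 1)
})

test_that("chi-square is additive over disjoint point subsets", {
  set.seed(1)
  y <- rnorm(60, 5); yh <- y + rnorm(60, sd = 0.3)
  whole <- compute_metrics(y, yh)$chi2
  parts <- compute_metrics(y[1:25], yh[1:25])$chi2 +
    compute_metrics(y[26:60], yh[26:60])$chi2
  expect_equal(whole, parts, tolerance = 1e-12)
})

test_that("spectrum metrics use the stacked real/imaginary basis", {
  f <- test_freq(20)
  obs <- circuit_impedance(circuit_catalog()$C3, freq = f)
  mod <- obs; mod$z_real <- mod$z_real + 1
  m <- compute_metrics(obs, mod)
  expect_equal(m$mse, 0.5)   # half the stacked entries off by 1
  expect_error(compute_metrics(obs, mod[1:10, ]), "length")
  # constant observed vector flags R^2
  cst <- eis_spectrum(f, rep(5, 20), rep(5, 20))
  expect_warning(compute_metrics(cst, cst), "constant")
})

test_that("weight vectors renormalize and apply the delta threshold", {
  w <- eis_weights(c(0.4, 0.3, 0.2, 0.05, 0.03, 0.02), delta = 0.1)
  expect_equal(sum(w$omega), 1)
  # the three sub-threshold entries are shrunk by x0.1 then renormalized
  raw <- c(0.4, 0.3, 0.2, 0.005, 0.003, 0.002)
  expect_equal(unname(w$omega), raw / sum(raw))
  # all-equal importances stay uniform
  expect_equal(unname(eis_weights(rep(1, 6))$omega), rep(1 / 6, 6))
})

test_that("composite loss ranks dominated candidates correctly", {
  f <- test_freq(25)
  obs <- add_proportional_noise(circuit_impedance(circuit_catalog()$C3, freq = f),
                                0.02)
  good <- compute_metrics(obs, circuit_impedance(circuit_catalog()$C3, freq = f))
  bad_sp <- circuit_impedance(circuit_catalog()$C3,
                              theta = c(30, 150, 2e-5), freq = f)
  bad <- compute_metrics(obs, bad_sp)
  peers <- list(good, bad)
  Lg <- composite_loss(good, peers)$L
  Lb <- composite_loss(bad, peers)$L
  expect_lt(Lg, Lb)
  # ranking invariant to a common positive rescaling of all raw metrics
  scale_m <- function(m, c) {
    m$chi2 <- m$chi2 * c; m$mse <- m$mse * c; m$rmse <- m$rmse * c
    m$mae <- m$mae * c; m$mape <- m$mape * c
    m$r2 <- 1 - (1 - m$r2) * c
    m
  }
  peers2 <- lapply(peers, scale_m, c = 7)
  expect_equal(composite_loss(peers2[[1]], peers2)$L, Lg, tolerance = 1e-12)
  # single candidate with uniform weights: L is the mean of the phi terms
  single <- composite_loss(good, list(good), norm = "mean")
  expect_equal(single$L, mean(single$per_metric), tolerance = 1e-12)
  # degenerate peers warn
  w <- capture_warnings(composite_loss(good, list(good, good)))
  expect_true(any(grepl("degenerate", w)))
})
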