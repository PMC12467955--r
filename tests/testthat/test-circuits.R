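test_that("element impedances match their closed forms", {
  expect_equal(element_impedance("R", c(R = 100), c(1, 1e3, 1e6)),
               rep(100 + 0i, 3))
  # 1/(j w C) with w C = 1
  expect_equal(element_impedance("C", c(C = 1e-6), 1e6), 0 - 1i)
  # CPE with n = 1 collapses to the capacitor at every frequency
  w <- 10^seq(-2, 6, length.out = 30)
  expect_equal(element_impedance("CPE", c(Q = 3e-6, n = 1), w),
               element_impedance("C", c(C = 3e-6), w))
  # Warburg phase is -45 degrees everywhere
  zw <- element_impedance("W", c(sigma = 5), w)
  expect_equal(Arg(zw), rep(-pi / 4, length(w)))
  # domain errors
  expect_error(element_impedance("R", c(R = 1), -1), "positive")
  expect_error(element_impedance("CPE", c(Q = 1, n = 1.2), 1), "\\[0, 1\\]")
})

test_that("CPE converges to its limiting elements", {
  w <- 10^seq(-1, 4, length.out = 25)
  zc <- element_impedance("C", c(C = 2e-6), w)
  sup_err <- sapply(c(0.99, 0.999, 0.9999), function(n) {
    zq <- element_impedance("CPE", c(Q = 2e-6, n = n), w)
    max(Mod(zq - zc) / Mod(zc))
  })
  expect_true(all(diff(sup_err) < 0))   # sup-norm -> 0 as n -> 1
  expect_lt(sup_err[3], 1e-2)
  # n -> 0 approaches the resistor 1/Q
  zr <- element_impedance("CPE", c(Q = 0.01, n = 1e-6), w)
  expect_lt(max(Mod(zr - 100) / 100), 1e-4)
})

test_that("series and parallel composition follow circuit algebra", {
  # two 100-Ohm resistors in parallel -> 50 Ohm at any frequency
  pc <- eis_circuit("p(R0,R1)")
  expect_equal(circuit_impedance(pc, c(100, 100), c(0.1, 10, 1e4),
                                 as_spectrum = FALSE), rep(50 + 0i, 3))
  # parallel equals admittance-sum oracle for random R/C branches
  set.seed(7)
  w <- 2 * pi * test_freq(15)
  for (k in 1:5) {
    R <- runif(1, 1, 1e3); C <- 10^runif(1, -7, -4)
    za <- element_impedance("R", c(R = R), w)
    zb <- element_impedance("C", c(C = C), w)
    direct <- 1 / (1 / za + 1 / zb)
    got <- circuit_impedance(eis_circuit("p(R0,C0)"), c(R, C),
                             w / (2 * pi), as_spectrum = FALSE)
    expect_equal(got, direct, tolerance = 1e-12)
  }
})

test_that("Randles circuit shows the textbook kinetic limits and apex", {
  rs <- 10; rct <- 100; cdl <- 1e-5
  randles <- eis_circuit("R0-p(R1,C1)")
  hi <- circuit_impedance(randles, c(rs, rct, cdl), 1e9, as_spectrum = FALSE)
  lo <- circuit_impedance(randles, c(rs, rct, cdl), 1e-9, as_spectrum = FALSE)
  expect_equal(Re(hi), rs, tolerance = 1e-4)
  expect_equal(Re(lo), rs + rct, tolerance = 1e-4)
  # Nyquist semicircle apex at w = 1/(Rct Cdl), where -Zim = Rct / 2;
  # oracle: independently coded closed-form Randles expression
  w_apex <- 1 / (rct * cdl)
  z_oracle <- rs + rct / (1 + 1i * w_apex * rct * cdl)
  got <- circuit_impedance(randles, c(rs, rct, cdl), w_apex / (2 * pi),
                           as_spectrum = FALSE)
  expect_equal(got, z_oracle, tolerance = 1e-12)
  expect_equal(-Im(got), rct / 2, tolerance = 1e-12)
})

test_that("impedance evaluation is deterministic and grid-order invariant", {
  cc <- circuit_catalog()$C6
  f <- test_freq(30)
  a <- circuit_impedance(cc, freq = f)
  b <- circuit_impedance(cc, freq = rev(f))
  expect_equal(a$z_real, rev(b$z_real))
  expect_equal(a$z_imag, rev(b$z_imag))
  expect_identical(circuit_impedance(cc, freq = f)$z_real, a$z_real)
})

test_that("the catalog has 8 well-formed circuits with declared nesting", {
  cat8 <- circuit_catalog()
  expect_length(cat8, 8L)
  ids <- vapply(cat8, `[[`, character(1), "id")
  expect_false(anyDuplicated(ids) > 0)
  for (cc in cat8) {
    expect_false(anyDuplicated(cc$theta_names) > 0)
    expect_true(all(cc$lower < cc$upper))
    expect_true(all(cc$theta >= cc$lower & cc$theta <= cc$upper))
    # flatten/rebuild round-trip
    expect_identical(length(cc$theta), cc$n_params)
    # leading series solution resistance
    expect_identical(cc$theta_names[1L], "R0")
  }
  # most complex member spans a 10-dimensional parameter space
  expect_identical(max(vapply(cat8, `[[`, integer(1), "n_params")), 10L)
  # declared nested pairs: the simple member always has strictly fewer
  # parameters and the relation is queryable (nesting is by pinning
  # parameters at boundary values, e.g. sigma -> 0 or n -> 1, so parameter
  # kinds need not be subsets)
  np <- attr(cat8, "nested_pairs")
  for (r in seq_len(nrow(np))) {
    expect_lt(cat8[[np[r, 1L]]]$n_params, cat8[[np[r, 2L]]]$n_params)
    expect_true(circuit_is_nested(np[r, 1L], np[r, 2L], cat8))
  }
  expect_true(circuit_is_nested("C3", "C8", cat8))   # transitive
  expect_false(circuit_is_nested("C2", "C3", cat8))
})

test_that("the grammar parser rejects malformed definitions", {
  expect_error(eis_circuit("R0-p(R1)"), "two branches")
  expect_error(eis_circuit("R0-X1"), "cannot parse")
  expect_error(circuit_impedance(circuit_catalog()$C3, theta = c(1, 2), freq = 1),
               "length")
})
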