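test_that("derived seeds are valid, distinct and order-stable", {
  s <- derive_seeds(123, 50)
  expect_true(all(s > 0 & s < 2^31))
  expect_false(anyDuplicated(s) > 0)
  expect_identical(s, derive_seeds(123, 50))
  expect_false(any(derive_seeds(124, 50) == s))
  expect_false(any(derive_seeds(123, 10, salt = "C3") ==
                     derive_seeds(123, 10, salt = "C4")))
})

test_that("batch results are identical across worker counts", {
  dir <- tempfile(); dir.create(dir)
  paths <- make_fixture_files(dir)
  small_b <- quick_budget(pop_size = 16, max_gen = 10, lm_iter = 6)
  serial <- batch_fit(paths, de = fast_de(), lm = fast_lm(),
                      budget = small_b, seed = 7, workers = 1)
  parallel2 <- batch_fit(paths, de = fast_de(), lm = fast_lm(),
                         budget = small_b, seed = 7, workers = 2)
  expect_identical(serial$results, parallel2$results)
  # schema: every success row carries circuit, metrics and KK verdict
  ok <- serial$results[is.na(serial$results$error), ]
  expect_true(all(c("circuit_id", "chi2", "mse", "rmse", "mae", "r2",
                    "mape", "kk_residual_pct", "kk_passed")
                  %in% names(serial$results)))
  expect_true(all(!is.na(ok$circuit_id)))
})

test_that("a corrupted file is isolated as a recorded failure", {
  dir <- tempfile(); dir.create(dir)
  paths <- make_fixture_files(dir, 3)
  bad <- file.path(dir, "broken.csv")
  writeLines(c("x,y", "1,2"), bad)
  res <- batch_fit(c(paths, bad), de = fast_de(), lm = fast_lm(),
                   budget = quick_budget(16, 10, 6), seed = 1)
  expect_identical(sum(!is.na(res$results$error)), 1L)
  expect_identical(sum(is.na(res$results$error)), 3L)
})

test_that("batch runs write a reproducibility manifest", {
  dir <- tempfile(); dir.create(dir)
  paths <- make_fixture_files(dir, 2)
  out <- file.path(dir, "out")
  batch_fit(paths, de = fast_de(), lm = fast_lm(),
            budget = quick_budget(16, 10, 6), seed = 99, output_dir = out)
  expect_true(file.exists(file.path(out, "results.csv")))
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(man$seed, 99)
  expect_identical(length(unlist(man$per_task_seeds)), 2L)
  expect_true(!is.null(man$package_version))
})

test_that("composite-loss ranking selects a sensible circuit without a selector", {
  set.seed(302)
  cat8 <- circuit_catalog()
  sp <- generate_spectrum(cat8$C3, cfg = gen_config(noise_sd = 0.005))
  res <- batch_fit(list(sp), seed = 5,
                   de = fast_de(), lm = fast_lm(),
                   budget = quick_budget(24, 16, 8))
  pick <- res$results$circuit_id[1]
  # the parsimony-guarded pick explains the data essentially perfectly
  expect_gt(res$results$r2[1], 0.999)
  expect_true(circuit_is_nested("C3", pick) || pick == "C3")
})
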