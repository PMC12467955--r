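#' Deterministic per-task seed derivation
#'
#' Splits one global seed into reproducible per-task seeds so that batch
#' results are independent of evaluation order and parallelism degree. A
#' small multiplicative hash keeps every derived seed a valid 32-bit
#' integer.
#'
#' @param seed global integer seed.
#' @param n number of tasks.
#' @param salt optional stream label (e.g. a circuit id).
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n, salt = 0L) {
  if (is.character(salt)) salt <- sum(utf8ToInt(salt))
  base <- (as.numeric(seed) * 48271 + as.numeric(salt) * 16807) %% 2147483647
  as.integer((base + 104729 * seq_len(n)) %% 2147483647 + 1)
}

#' Batch classification and fitting of spectrum files
#'
#' Runs the full pipeline over a set of spectrum files: read, classify the
#' best circuit (with a trained selector, or by composite-loss ranking of
#' quick fits of the whole catalog when no selector is given), full DE-LM
#' fit of the selected circuit, Kramers-Kronig validity check, and the
#' six-metric error panel. Files are processed with process-level
#' parallelism; per-task seeds are derived deterministically from the
#' global seed and the file index, so results are identical for any worker
#' count (up to row order, which is normalized). Failures are isolated: an
#' unreadable or unfittable file yields a recorded failure row and the
#' batch continues.
#'
#' @param inputs character vector of file paths, or a list of
#'   [eis_spectrum] objects.
#' @param selector optional trained `"eis_selector"`.
#' @param catalog circuit catalog.
#' @param de,lm controls for the final full fit.
#' @param budget quick-fit budget for featurization/classification.
#' @param seed global seed.
#' @param workers number of forked workers.
#' @param output_dir optional directory; when given, a `results.csv` table
#'   and a `manifest.json` (config, seeds, package version) sufficient to
#'   reproduce the run are written there.
#' @return list with `results` (data frame: file, circuit_id, parameters as
#'   JSON, rss, r2, the six metrics, kk_residual_pct, kk_passed, error
#'   message if failed) and `fits` (list of [eis_fit] or NULL).
#' @export
batch_fit <- function(inputs, selector = NULL, catalog = circuit_catalog(),
                      de = de_control(), lm = lm_control(),
                      budget = quick_budget(), seed = 1, workers = 1L,
                      output_dir = NULL) {
  labels <- if (is.character(inputs)) basename(inputs)
            else sprintf("spectrum_%03d", seq_along(inputs))
  seeds <- derive_seeds(seed, length(inputs))
  one <- function(i) {
    tryCatch({
      sp <- if (is.character(inputs)) read_spectrum(inputs[i]) else inputs[[i]]
      cid <- if (!is.null(selector)) {
        classify_spectrum(selector, sp, catalog, budget, seed = seeds[i])$circuit_id
      } else {
        .rank_circuits(sp, catalog, budget, seeds[i])
      }
      fit <- eis_fit(sp, catalog[[cid]], de = de, lm = lm, seed = seeds[i])
      kk <- kk_check(sp)
      row <- data.frame(
        file = labels[i], circuit_id = cid,
        theta = as.character(jsonlite::toJSON(as.list(signif(fit$theta_hat, 8)),
                                              auto_unbox = TRUE)),
        rss = fit$rss, chi2 = fit$metrics$chi2, mse = fit$metrics$mse,
        rmse = fit$metrics$rmse, mae = fit$metrics$mae, r2 = fit$metrics$r2,
        mape = fit$metrics$mape, kk_residual_pct = kk$residual_pct,
        kk_passed = kk$passed, error = NA_character_,
        stringsAsFactors = FALSE)
      list(row = row, fit = fit)
    }, error = function(e) {
      list(row = data.frame(file = labels[i], circuit_id = NA_character_,
                            theta = NA_character_, rss = NA_real_,
                            chi2 = NA_real_, mse = NA_real_, rmse = NA_real_,
                            mae = NA_real_, r2 = NA_real_, mape = NA_real_,
                            kk_residual_pct = NA_real_, kk_passed = NA,
                            error = conditionMessage(e),
                            stringsAsFactors = FALSE),
           fit = NULL)
    })
  }
  res <- if (workers > 1L)
    parallel::mclapply(seq_along(inputs), one, mc.cores = workers)
  else lapply(seq_along(inputs), one)
  results <- do.call(rbind, lapply(res, `[[`, "row"))
  results <- results[order(results$file), , drop = FALSE]
  rownames(results) <- NULL
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(results, file.path(output_dir, "results.csv"),
                     row.names = FALSE)
    manifest <- list(
      timestamp = format(Sys.time(), tz = "UTC"),
      package_version = as.character(utils::packageVersion("eisfit")),
      seed = seed, per_task_seeds = seeds, workers = workers,
      n_inputs = length(inputs),
      de = unclass(de), lm = unclass(lm),
      selector = !is.null(selector))
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(results = results, fits = lapply(res, `[[`, "fit"))
}

# composite-loss ranking over quick fits of the whole catalog, with an
# F-test parsimony guard: a complex winner must beat every nested simpler
# candidate at p < 0.05, otherwise the simpler circuit is preferred
.rank_circuits <- function(spectrum, catalog, budget, seed) {
  set.seed(seed)
  fits <- lapply(catalog, function(cc)
    tryCatch(eis_fit(spectrum, cc, de = budget$de, lm = budget$lm),
             error = function(e) NULL))
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("all candidate fits failed")
  panels <- lapply(fits[ok], `[[`, "metrics")
  L <- vapply(panels, function(p)
    suppressWarnings(composite_loss(p, panels)$L), numeric(1))
  pick <- names(catalog)[ok][which.min(L)]
  for (simple in names(catalog)[ok]) {
    if (simple == pick || !circuit_is_nested(simple, pick, catalog)) next
    ft <- nested_f_test(fits[[simple]], fits[[pick]], catalog)
    if (ft$p_value > 0.05 &&
        catalog[[simple]]$n_params < catalog[[pick]]$n_params)
      pick <- simple
  }
  pick
}
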