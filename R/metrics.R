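#' Six-metric error panel for a fitted spectrum
#'
#' Computes the six complementary goodness-of-fit statistics used throughout
#' the framework, on the concatenated comparison vector
#' \eqn{y = [Z_{real}; Z_{imag}]} (2N values) by default:
#' \deqn{\chi^2 = \sum (y_i - \hat y_i)^2 / |\hat y_i|}
#' \deqn{MSE = \frac1n \sum (y_i - \hat y_i)^2, \quad RMSE = \sqrt{MSE}}
#' \deqn{MAE = \frac1n \sum |y_i - \hat y_i|}
#' \deqn{R^2 = 1 - \sum (y_i - \hat y_i)^2 / \sum (y_i - \bar y)^2}
#' \deqn{MAPE = \frac{100}{n} \sum |{(y_i - \hat y_i)}/{y_i}|}
#' The chi-square denominator uses \eqn{|\hat y_i|} floored at 1e-12 because
#' imaginary parts are negative for capacitive cells; MAPE skips terms with
#' \eqn{|y_i| < 10^{-12}} (the count is adjusted). The chi-square statistic
#' measures distributional deviation point by point, MAE/MAPE are robust to
#' outliers, and R-squared/RMSE capture global trend fidelity.
#'
#' @param observed,fitted [eis_spectrum] objects of equal length on matching
#'   frequency grids, or plain numeric vectors (then compared directly).
#' @param basis `"reim"` (concatenated real and imaginary parts, default) or
#'   `"modulus"`.
#' @return object of class `"eis_metrics"`: named list with `chi2`, `mse`,
#'   `rmse`, `mae`, `r2`, `mape` (percent) and the `basis` label.
#' @examples
#' compute_metrics(c(1, 2, 3), c(2, 2, 2))
#' @export
compute_metrics <- function(observed, fitted, basis = c("reim", "modulus")) {
  basis <- match.arg(basis)
  if (inherits(observed, "eis_spectrum")) {
    stopifnot(inherits(fitted, "eis_spectrum"))
    if (nrow(observed) != nrow(fitted))
      stop("observed and fitted spectra differ in length")
    if (max(abs(log(observed$freq / fitted$freq))) > 1e-6)
      stop("observed and fitted frequency grids do not match")
    if (basis == "reim") {
      y <- c(observed$z_real, observed$z_imag)
      yh <- c(fitted$z_real, fitted$z_imag)
    } else {
      y <- Mod(.spectrum_z(observed)); yh <- Mod(.spectrum_z(fitted))
    }
  } else {
    y <- as.numeric(observed); yh <- as.numeric(fitted)
    if (length(y) != length(yh)) stop("length mismatch")
  }
  n <- length(y)
  res <- y - yh
  sse <- sum(res^2)
  mse <- sse / n
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) {
    warning("observed vector is constant; R^2 undefined, returning NA")
    NA_real_
  } else 1 - sse / sst
  keep <- abs(y) >= 1e-12
  if (!all(keep) && sum(keep) == 0L) stop("all observed values are ~0; MAPE undefined")
  out <- list(
    chi2 = sum(res^2 / pmax(abs(yh), 1e-12)),
    mse = mse,
    rmse = sqrt(mse),
    mae = mean(abs(res)),
    r2 = r2,
    mape = 100 * mean(abs(res[keep] / y[keep])),
    basis = basis
  )
  class(out) <- "eis_metrics"
  out
}

#' @export
print.eis_metrics <- function(x, ...) {
  v <- unlist(x[c("chi2", "mse", "rmse", "mae", "r2", "mape")])
  cat("EIS error metrics (basis: ", x$basis, ")\n", sep = "")
  print(signif(v, 5))
  invisible(x)
}

.metric_names <- c("chi2", "mse", "rmse", "mae", "r2", "mape")

#' Metric weight vector with importance-threshold downweighting
#'
#' Holds the six metric weights \eqn{\omega_m} of the composite loss. Weights
#' whose importance falls below the threshold `delta` (default 0.1) are
#' multiplied by `downweight_factor` and the vector is renormalized to sum
#' to 1, concentrating the loss on the informative error dimensions.
#'
#' @param omega nonnegative weights, named by metric (`chi2`, `mse`, `rmse`,
#'   `mae`, `r2`, `mape`) or in that order.
#' @param delta downweight threshold in (0, 1).
#' @param downweight_factor multiplier applied to weights below `delta`.
#' @param apply_threshold apply the delta rule on construction (default TRUE).
#' @return class `"eis_weights"`: normalized weight vector plus settings.
#' @examples
#' w <- eis_weights(c(0.4, 0.3, 0.2, 0.05, 0.03, 0.02))
#' sum(w$omega)  # 1
#' @export
eis_weights <- function(omega = rep(1 / 6, 6), delta = 0.1,
                        downweight_factor = 0.1, apply_threshold = TRUE) {
  stopifnot(length(omega) == 6L, all(omega >= 0), sum(omega) > 0,
            delta > 0, delta < 1)
  if (is.null(names(omega))) names(omega) <- .metric_names
  omega <- omega[.metric_names]
  omega <- omega / sum(omega)
  if (apply_threshold) {
    low <- omega < delta
    omega[low] <- omega[low] * downweight_factor
    omega <- omega / sum(omega)
  }
  structure(list(omega = omega, delta = delta,
                 downweight_factor = downweight_factor),
            class = "eis_weights")
}

#' Weighted composite loss over a candidate peer set
#'
#' Combines the six error metrics into a single score
#' \eqn{L = \sum_m \omega_m \phi(e_m)} where \eqn{\phi} normalizes each
#' metric across the peer set of candidate fits so that heterogeneous scales
#' (a chi-square and a percentage) become commensurate. R-squared enters as
#' \eqn{1 - R^2} so that all six terms are smaller-is-better.
#'
#' Two normalizations are available: `"minmax"` maps each metric to \[0, 1\]
#' across the peers (the ranking mode used for candidate-circuit comparison)
#' and `"mean"` divides by the peer mean (scale-free but non-degenerate for
#' peer sets as small as two, used for before/after convergence scoring).
#'
#' @param metrics an `"eis_metrics"` object (the candidate being scored).
#' @param peers list of `"eis_metrics"` for the full candidate set that
#'   defines the normalization context; must contain `metrics` itself or at
#'   least share its scale. Must be nonempty.
#' @param weights an [eis_weights] object.
#' @param norm `"minmax"` or `"mean"`.
#' @return class `"eis_composite"`: list with `L` and the six normalized
#'   `per_metric` terms.
#' @export
composite_loss <- function(metrics, peers = list(metrics),
                           weights = eis_weights(),
                           norm = c("minmax", "mean")) {
  norm <- match.arg(norm)
  stopifnot(inherits(metrics, "eis_metrics"), length(peers) >= 1L)
  to_vec <- function(m) {
    v <- unlist(m[.metric_names])
    v["r2"] <- 1 - v["r2"]  # smaller-is-better
    v
  }
  x <- to_vec(metrics)
  P <- do.call(rbind, lapply(peers, to_vec))
  phi <- numeric(6L); names(phi) <- .metric_names
  for (j in seq_len(6L)) {
    col <- P[, j]
    if (norm == "minmax") {
      rng <- range(col, na.rm = TRUE)
      if (!is.finite(diff(rng)) || diff(rng) == 0) {
        if (diff(range(col, na.rm = TRUE)) == 0)
          warning("degenerate peer set for metric '", .metric_names[j],
                  "'; phi set to 0")
        phi[j] <- 0
      } else phi[j] <- (x[j] - rng[1L]) / diff(rng)
    } else {
      mu <- mean(col, na.rm = TRUE)
      phi[j] <- if (mu == 0) 0 else x[j] / mu
    }
  }
  om <- weights$omega
  L <- sum(om * phi, na.rm = TRUE)
  structure(list(L = L, per_metric = phi, weights = om, norm = norm),
            class = "eis_composite")
}

#' @export
print.eis_composite <- function(x, ...) {
  cat("Composite loss L = ", signif(x$L, 5), " (", x$norm,
      " normalization)\n", sep = "")
  print(signif(x$per_metric, 4))
  invisible(x)
}
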