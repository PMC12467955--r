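#' Kramers-Kronig consistency check (measurement model)
#'
#' Tests the physical plausibility (causality, linearity, stability) of a
#' spectrum by fitting the linear Voigt measurement model: a series
#' resistance, a series capacitive term \eqn{1/(j\omega C_0)}, and M
#' parallel-RC (Voigt) elements on a fixed logarithmic relaxation-time grid
#' spanning \eqn{1/(2\pi f_{max})} to \eqn{1/(2\pi f_{min})}. Because the
#' model is KK-transformable by construction, a small fit residual implies
#' the data are KK-consistent; an inconsistent spectrum cannot be fitted by
#' any such chain. Element weights are obtained by unconstrained linear
#' least squares on the stacked real/imaginary parts (sign-unconstrained, as
#' in the standard lin-KK test).
#'
#' The residual is modulus-relative and averaged over both channels:
#' \eqn{mean(|Z_{fit,i} - Z_i| / |Z_i|) \times 100} (percent). With
#' `n_rc = "auto"` the per-decade density is increased (3, 5, 7 per decade)
#' until the residual improves by less than 5%; a fixed integer gives that
#' many RC terms per decade directly (default heuristic ceiling 7).
#'
#' @param spectrum an [eis_spectrum] with at least 10 points spanning at
#'   least 2 decades.
#' @param n_rc `"auto"` or RC terms per decade.
#' @param threshold pass threshold on the mean relative residual, percent.
#' @return object of class `"kk_report"`: `residual_pct` (mean),
#'   `max_residual_pct`, `per_point_residuals` (real/imaginary relative
#'   residuals), `n_rc` (total RC terms used), `passed`, and the fitted
#'   model values.
#' @examples
#' sp <- circuit_impedance(circuit_catalog()$C3,
#'                         freq = 10^seq(-2, 4, length.out = 40))
#' kk_check(sp)$passed
#' @export
kk_check <- function(spectrum, n_rc = "auto", threshold = 0.1) {
  .kk_precheck(spectrum)
  densities <- if (identical(n_rc, "auto")) c(3L, 5L, 7L) else as.integer(n_rc)
  last <- NULL
  for (d in densities) {
    fit <- .voigt_fit(spectrum, d)
    if (!is.null(last) &&
        (last$residual_pct - fit$residual_pct) < 0.05 * last$residual_pct) {
      fit <- if (fit$residual_pct < last$residual_pct) fit else last
      break
    }
    last <- fit
  }
  res <- fit
  res$passed <- res$residual_pct < threshold
  res$threshold <- threshold
  class(res) <- "kk_report"
  res
}

.kk_precheck <- function(spectrum) {
  stopifnot(inherits(spectrum, "eis_spectrum"))
  if (nrow(spectrum) < 10L)
    stop("KK check needs at least 10 frequency points")
  if (log10(max(spectrum$freq) / min(spectrum$freq)) < 2)
    stop("KK check needs a frequency span of at least 2 decades")
}

.voigt_tau_grid <- function(freq, per_decade) {
  t_min <- 1 / (2 * pi * max(freq))
  t_max <- 1 / (2 * pi * min(freq))
  n <- max(2L, ceiling(log10(t_max / t_min) * per_decade) + 1L)
  10^seq(log10(t_min), log10(t_max), length.out = n)
}

# design matrix of the measurement model on the stacked [Re; Im] channels
.voigt_design <- function(omega, tau) {
  den <- 1 + (omega %o% tau)^2
  re_rc <- 1 / den
  im_rc <- -(omega %o% tau) / den
  # columns: R_series, 1/C0 (series capacitance), R_k of each Voigt element
  rbind(cbind(1, 0, re_rc),
        cbind(0, -1 / omega, im_rc))
}

.voigt_fit <- function(spectrum, per_decade) {
  omega <- 2 * pi * spectrum$freq
  tau <- .voigt_tau_grid(spectrum$freq, per_decade)
  X <- .voigt_design(omega, tau)
  y <- c(spectrum$z_real, spectrum$z_imag)
  beta <- stats::lm.fit(X, y)$coefficients
  beta[is.na(beta)] <- 0
  yh <- X %*% beta
  n <- nrow(spectrum)
  mod <- Mod(.spectrum_z(spectrum))
  dre <- (spectrum$z_real - yh[seq_len(n)]) / mod
  dim_ <- (spectrum$z_imag - yh[n + seq_len(n)]) / mod
  pt_res <- sqrt(dre^2 + dim_^2)
  list(residual_pct = mean(pt_res) * 100,
       max_residual_pct = max(pt_res) * 100,
       per_point_residuals = data.frame(freq = spectrum$freq,
                                        rel_real = dre, rel_imag = dim_),
       n_rc = length(tau), tau = tau, weights = beta)
}

#' @export
print.kk_report <- function(x, ...) {
  cat("Kramers-Kronig measurement-model check\n")
  cat("  RC terms: ", x$n_rc, "\n", sep = "")
  cat("  mean relative residual: ", signif(x$residual_pct, 4), "% (max ",
      signif(x$max_residual_pct, 4), "%)\n", sep = "")
  cat("  passed (threshold ", x$threshold, "%): ", x$passed, "\n", sep = "")
  invisible(x)
}

#' Time-constant distribution of a spectrum
#'
#' Nonnegative least-squares fit of Voigt-element weights on a log-spaced
#' relaxation-time grid with light ridge smoothing, followed by peak
#' detection (local maxima above 5% of the maximum weight). Peaks locate the
#' characteristic time constants (tau = RC) of the underlying processes.
#'
#' @inheritParams kk_check
#' @param grid_size number of tau grid points.
#' @param ridge ridge penalty weight (relative to the mean diagonal of the
#'   normal matrix).
#' @return class `"eis_tcd"`: `tau_grid`, `weights` (nonnegative), `peaks`
#'   (data frame of tau and amplitude, sorted by tau).
#' @examples
#' sp <- circuit_impedance(circuit_catalog()$C3,
#'                         freq = 10^seq(-2, 4, length.out = 40))
#' time_constant_analysis(sp)$peaks
#' @export
time_constant_analysis <- function(spectrum, grid_size = 60, ridge = 1e-4) {
  .kk_precheck(spectrum)
  omega <- 2 * pi * spectrum$freq
  t_min <- 1 / (2 * pi * max(spectrum$freq))
  t_max <- 1 / (2 * pi * min(spectrum$freq))
  tau <- 10^seq(log10(t_min), log10(t_max), length.out = grid_size)
  X <- .voigt_design(omega, tau)
  y <- c(spectrum$z_real, spectrum$z_imag)
  # scale-aware ridge on the Voigt columns only, implemented by row
  # augmentation; series R and C0 columns unpenalized
  lam <- sqrt(ridge * mean(colSums(X[, -(1:2)]^2)))
  Xa <- rbind(X, cbind(0, 0, lam * diag(grid_size)))
  ya <- c(y, rep(0, grid_size))
  # series terms unconstrained, Voigt weights nonnegative: shift the series
  # columns out by an unconstrained pre-fit, then NNLS on the remainder
  pre <- stats::lm.fit(Xa[, 1:2, drop = FALSE], ya)$coefficients
  pre[is.na(pre)] <- 0
  resid0 <- ya - Xa[, 1:2, drop = FALSE] %*% pre
  w <- pracma::lsqnonneg(Xa[, -(1:2), drop = FALSE], as.numeric(resid0))$x
  w <- pmax(w, 0)
  peaks <- which(diff(sign(diff(c(-Inf, w, -Inf)))) == -2)
  keep <- w[peaks] > 0.05 * max(w)
  peaks <- peaks[keep]
  structure(list(tau_grid = tau, weights = w,
                 peaks = data.frame(tau = tau[peaks],
                                    amplitude = w[peaks])[order(tau[peaks]), ]),
            class = "eis_tcd")
}

#' @export
print.eis_tcd <- function(x, ...) {
  cat("Time-constant distribution: ", length(x$tau_grid),
      " grid points, ", nrow(x$peaks), " peak(s)\n", sep = "")
  print(x$peaks)
  invisible(x)
}
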