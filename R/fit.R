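#' Control parameters for the differential-evolution global search
#'
#' @param pop_size population size (default 200; typical range 200-500).
#' @param F_range mutation factor range; F is drawn uniformly per generation
#'   (dither) from this interval.
#' @param CR crossover rate (high to preserve population diversity).
#' @param eps convergence threshold: the search stops when the relative
#'   improvement of the best residual sum of squares over a `patience`-
#'   generation window falls below `eps`.
#' @param patience window length (generations) for the `eps` rule.
#' @param min_gen minimum generations before the plateau rule can fire
#'   (differential evolution has a slow exploratory early phase whose
#'   improvement rate is not informative about convergence).
#' @param max_gen generation cap.
#' @param max_evals optional cap on total objective evaluations (used for
#'   budget-matched optimizer comparisons).
#' @param elite_frac fraction of the final population handed to local
#'   refinement (top individuals by fitness).
#' @return list of class `"de_control"`.
#' @export
de_control <- function(pop_size = 200, F_range = c(0.4, 1.0), CR = 0.9,
                       eps = 0.1, patience = 20, min_gen = 60,
                       max_gen = 120, max_evals = Inf, elite_frac = 0.10) {
  stopifnot(pop_size >= 4, CR > 0, CR <= 1,
            all(F_range > 0), all(F_range < 2), eps > 0)
  structure(list(pop_size = as.integer(pop_size), F_range = F_range, CR = CR,
                 eps = eps, patience = as.integer(patience),
                 min_gen = as.integer(min_gen), max_gen = as.integer(max_gen),
                 max_evals = max_evals,
                 elite_frac = elite_frac), class = "de_control")
}

#' Control parameters for Levenberg-Marquardt refinement
#'
#' @param mu_init initial damping factor.
#' @param mu_bounds damping is clipped to this range.
#' @param nielsen_nu rejection growth factor of Nielsen's damping update.
#' @param max_iter iteration cap.
#' @param cond_threshold restart trigger: if the condition number of the
#'   column-equilibrated Jacobian at the optimum exceeds this value the
#'   fitter resamples around the incumbent and retries (see [eis_fit]).
#' @param restart_pop number of perturbed individuals for a restart (50-100).
#' @param restart_frac half-width of the restart neighborhood (multiplicative,
#'   0.05 = +/-5%).
#' @param max_restarts restart cap.
#' @param ci_level confidence level for parameter intervals.
#' @param ci_type `"bootstrap"` (default for full fits) refits under a wild
#'   cluster bootstrap of the residuals — one Rademacher weight per
#'   frequency point, so the correlated real/imaginary noise of a point
#'   stays together — which captures both the heteroscedastic noise and the
#'   nonlinear propagation into the estimates; `"robust"` is the (cheaper)
#'   cluster-robust first-order sandwich; `"wald"` the classical
#'   \eqn{\hat\sigma^2 (J^T J)^{-1}} (miscalibrated when noise scales
#'   with |Z|, kept for reference).
#' @param boot_B bootstrap replicates.
#' @return list of class `"lm_control"`.
#' @export
lm_control <- function(mu_init = 1e-3, mu_bounds = c(1e-3, 1e2),
                       nielsen_nu = 2.0, max_iter = 200, cond_threshold = 10,
                       restart_pop = 64, restart_frac = 0.05,
                       max_restarts = 3, ci_level = 0.95,
                       ci_type = c("bootstrap", "robust", "wald"),
                       boot_B = 80L) {
  stopifnot(restart_pop >= 50, restart_pop <= 100, mu_init > 0)
  structure(list(mu_init = mu_init, mu_bounds = mu_bounds,
                 nielsen_nu = nielsen_nu, max_iter = as.integer(max_iter),
                 cond_threshold = cond_threshold,
                 restart_pop = as.integer(restart_pop),
                 restart_frac = restart_frac,
                 max_restarts = as.integer(max_restarts),
                 ci_level = ci_level, ci_type = match.arg(ci_type),
                 boot_B = as.integer(boot_B)),
            class = "lm_control")
}

#' Reflect parameter values into box bounds
#'
#' Out-of-range values are mirrored about the violated bound, repeatedly
#' until inside; values already inside are unchanged.
#'
#' @param theta numeric vector (or matrix, reflected column-wise against
#'   recycled bounds).
#' @param lo,hi bounds with `lo < hi`.
#' @return reflected values, same shape as `theta`.
#' @examples
#' reflect_bounds(c(1.2, -0.3, 0.5, 2.5), 0, 1)  # 0.8 0.3 0.5 0.5
#' @export
reflect_bounds <- function(theta, lo, hi) {
  w <- hi - lo
  if (any(w <= 0)) stop("bounds must satisfy lo < hi")
  if (is.matrix(theta)) {
    lo <- matrix(lo, nrow(theta), ncol(theta), byrow = TRUE)
    w <- matrix(w, nrow(theta), ncol(theta), byrow = TRUE)
  } else {
    lo <- rep_len(lo, length(theta))
    w <- rep_len(w, length(theta))
  }
  y <- (theta - lo) %% (2 * w)
  over <- y > w
  y[over] <- (2 * w)[over] - y[over]
  lo + y
}

# ---- parameter transform: decades-spanning magnitudes in log space ---------

.to_internal <- function(circuit, theta) {
  u <- theta
  if (is.matrix(theta)) u[, circuit$log_scale] <- log(theta[, circuit$log_scale])
  else u[circuit$log_scale] <- log(theta[circuit$log_scale])
  u
}

.from_internal <- function(circuit, u) {
  th <- u
  if (is.matrix(u)) th[, circuit$log_scale] <- exp(u[, circuit$log_scale])
  else th[circuit$log_scale] <- exp(u[circuit$log_scale])
  th
}

.internal_bounds <- function(circuit) {
  lo <- circuit$lower; hi <- circuit$upper
  lo[circuit$log_scale] <- log(pmax(lo[circuit$log_scale], 1e-300))
  hi[circuit$log_scale] <- log(hi[circuit$log_scale])
  list(lo = lo, hi = hi)
}

# Data-informed initialization window (internal scale), intersected with the
# declared bounds. The measured spectrum fixes the relevant scales: resistive
# parameters cannot exceed a small multiple of max |Z|, Warburg coefficients
# are bounded by the low-frequency modulus, and capacitive time constants
# must fall near the measured band for the element to be visible at all.
# The hard bounds still constrain the whole evolution; only the initial
# population is concentrated where the data live.
.init_ranges <- function(circuit, spectrum, b) {
  zmod <- sqrt(spectrum$z_real^2 + spectrum$z_imag^2)
  zmax <- max(zmod, 1e-6)
  omega <- 2 * pi * spectrum$freq
  w_min <- min(omega); w_max <- max(omega)
  lo <- b$lo; hi <- b$hi
  for (i in seq_len(circuit$n_params)) {
    k <- circuit$param_kinds[i]
    r <- switch(k,
      R = c(1e-3 * zmax, 3 * zmax),
      W = c(1e-3 * zmax * sqrt(w_min), 2 * zmax * sqrt(w_min)),
      C = c(1 / (w_max * zmax * 1e2), 1e2 / (w_min * zmax)),
      Q = c(1 / (w_max * zmax * 1e2), 1e2 / (w_min * zmax)),
      n = c(0.5, 1))
    if (k == "n") {
      lo[i] <- max(lo[i], r[1L]); hi[i] <- min(hi[i], r[2L])
    } else {
      lo[i] <- max(lo[i], log(r[1L])); hi[i] <- min(hi[i], log(r[2L]))
    }
    if (lo[i] >= hi[i]) { lo[i] <- b$lo[i]; hi[i] <- b$hi[i] }
  }
  list(lo = lo, hi = hi)
}

# Model-free estimate of the attainable residual floor: the Voigt
# measurement-model (KK) fit is linear and KK-consistent by construction,
# so its residual sum of squares approximates the part of the data no
# causal model can explain (the noise). A circuit fit stuck well above the
# floor is in a local minimum (or the circuit is wrong) and worth a
# diversified restart.
.rss_floor <- function(spectrum) {
  tryCatch({
    v <- .voigt_fit(spectrum, 7L)
    mod2 <- spectrum$z_real^2 + spectrum$z_imag^2
    sum((v$per_point_residuals$rel_real^2 +
           v$per_point_residuals$rel_imag^2) * mod2)
  }, error = function(e) 0)
}

# a fit looks pathological when its RSS sits far above the attainable
# floor, a parallel section has effectively vanished (the fitted model has
# lower order than the requested circuit), or the fit is outright poor
.looks_pathological <- function(spectrum, circuit, best, rss_floor) {
  tiny <- 1e-10 * sum(spectrum$z_real^2 + spectrum$z_imag^2)
  if (best$rss > max(3 * rss_floor, tiny)) return(TRUE)
  if (.fit_r2(spectrum, circuit, best$theta) < 0.99) return(TRUE)
  if (length(circuit$sections) >= 2L) {
    zmax <- max(sqrt(spectrum$z_real^2 + spectrum$z_imag^2))
    rsec <- vapply(circuit$sections, function(s) best$theta[s$r], numeric(1))
    if (any(rsec < 1e-3 * zmax)) return(TRUE)
  }
  FALSE
}

.fit_r2 <- function(spectrum, circuit, theta) {
  z <- circuit_impedance(circuit, theta, spectrum$freq, as_spectrum = FALSE)
  y <- c(spectrum$z_real, spectrum$z_imag)
  1 - sum((y - c(Re(z), Im(z)))^2) / sum((y - mean(y))^2)
}

# Initial DE population (internal scale): independent data-informed draws,
# with each parallel section's capacitive parameter re-derived from a
# relaxation time drawn inside that section's own sub-band of the measured
# time-constant window (sections run fastest to slowest), so the population
# starts spread across the spectral bands in the canonical order.
.de_init <- function(circuit, spectrum, m, b) {
  p <- circuit$n_params
  ir <- .init_ranges(circuit, spectrum, b)
  U <- matrix(stats::runif(m * p, rep(ir$lo, each = m), rep(ir$hi, each = m)),
              m, p)
  S <- length(circuit$sections)
  if (S >= 1L) {
    omega <- 2 * pi * spectrum$freq
    lt_min <- log(1 / max(omega)); lt_max <- log(1 / min(omega))
    w <- (lt_max - lt_min) / S
    for (s in seq_len(S)) {
      sec <- circuit$sections[[s]]
      # half-band overlap keeps adjacent sections competitive
      ltau <- stats::runif(m, lt_min + (s - 1.5) * w * 0.5 + (s - 1) * w * 0.5,
                           lt_min + s * w)
      ltau <- pmax(ltau, lt_min)
      R <- U[, sec$r]                       # already log scale
      if (sec$type == "RC") {
        U[, sec$c] <- pmin(pmax(ltau - R, b$lo[sec$c]), b$hi[sec$c])
      } else {
        nn <- U[, sec$n]
        U[, sec$q] <- pmin(pmax(nn * ltau - R, b$lo[sec$q]), b$hi[sec$q])
      }
    }
  }
  U
}

# residual sum of squares for a population of internal-space vectors; the
# DE fitness multiplies in a soft penalty on violations of the canonical
# ascending section time-constant ordering (symmetry breaking between
# permutation-equivalent assignments of the parallel sections; the LM stage
# optimizes the pure RSS)
.rss_pop <- function(circuit, U, omega, zr, zi, penalize = TRUE) {
  Th <- .from_internal(circuit, U)
  Z <- .circuit_impedance_pop(circuit, Th, omega)
  rss <- rowSums((Re(Z) - matrix(zr, nrow(U), length(zr), byrow = TRUE))^2) +
    rowSums((Im(Z) - matrix(zi, nrow(U), length(zi), byrow = TRUE))^2)
  if (penalize && length(circuit$sections) >= 2L) {
    taus <- .section_taus(circuit, Th)
    pen <- 0
    for (s in seq_len(ncol(taus) - 1L))
      pen <- pen + pmax(0, log10(taus[, s] / taus[, s + 1L]))
    rss <- rss * (1 + pen)
  }
  rss
}

#' Differential-evolution mutation and crossover
#'
#' One generation of trial-vector construction: for each population member
#' \eqn{i}, three distinct partners \eqn{r_1, r_2, r_3 \neq i} are drawn and
#' the mutant \eqn{v_i = \theta_{r_1} + F (\theta_{r_2} - \theta_{r_3})} is
#' crossed binomially with the parent at rate `CR` (one mutant coordinate is
#' always inherited), then reflected into the bounds.
#'
#' @param population numeric matrix, one row per member (at least 4 rows).
#' @param F mutation factor.
#' @param CR crossover rate in (0, 1].
#' @param lo,hi bounds for reflection (default: no reflection).
#' @return matrix of trial vectors, same shape as `population`.
#' @export
de_mutate_crossover <- function(population, F, CR, lo = -Inf, hi = Inf) {
  m <- nrow(population); p <- ncol(population)
  if (m < 4L) stop("population must have at least 4 members")
  idx <- vapply(seq_len(m), function(i) sample(seq_len(m)[-i], 3L), integer(3))
  V <- population[idx[1L, ], , drop = FALSE] +
    F * (population[idx[2L, ], , drop = FALSE] -
           population[idx[3L, ], , drop = FALSE])
  cross <- matrix(stats::runif(m * p) < CR, m, p)
  jrand <- cbind(seq_len(m), sample.int(p, m, replace = TRUE))
  cross[jrand] <- TRUE
  trial <- population
  trial[cross] <- V[cross]
  if (any(is.finite(lo)) || any(is.finite(hi)))
    trial <- reflect_bounds(trial, lo, hi)
  trial
}

#' Bounded differential-evolution search for circuit parameters
#'
#' Global exploration of the parameter space, minimizing the residual sum of
#' squares of the stacked real/imaginary impedance residuals. Magnitude
#' parameters (R, C, Q, sigma) are searched in log space; CPE exponents on
#' the linear scale. Returns the elite set (top `elite_frac` of the final
#' population by fitness) used to seed local refinement.
#'
#' @param circuit an [eis_circuit].
#' @param spectrum an [eis_spectrum].
#' @param control a [de_control] list.
#' @param seed optional integer seed (fixed seed implies bit-identical
#'   output).
#' @param init_pop optional initial population (natural scale, one row per
#'   member) overriding uniform initialization.
#' @return list with `elite` (matrix of parameter vectors, natural scale,
#'   best first), `elite_rss`, `best_trace` (best RSS per generation),
#'   `n_evals`, and the full final `population`/`fitness`.
#' @export
de_search <- function(circuit, spectrum, control = de_control(),
                      seed = NULL, init_pop = NULL) {
  if (!is.null(seed)) set.seed(seed)
  b <- .internal_bounds(circuit)
  if (any(!is.finite(b$lo)) || any(!is.finite(b$hi)))
    stop("de_search requires finite parameter bounds")
  p <- circuit$n_params
  omega <- 2 * pi * spectrum$freq
  zr <- spectrum$z_real; zi <- spectrum$z_imag
  m <- control$pop_size
  U <- if (is.null(init_pop)) {
    .de_init(circuit, spectrum, m, b)
  } else {
    m <- nrow(init_pop)
    reflect_bounds(.to_internal(circuit, init_pop), b$lo, b$hi)
  }
  fit <- .rss_pop(circuit, U, omega, zr, zi)
  if (all(!is.finite(fit))) stop("all initial fitness values are non-finite")
  fit[!is.finite(fit)] <- .Machine$double.xmax
  n_evals <- m
  best_trace <- min(fit)
  for (g in seq_len(control$max_gen)) {
    if (n_evals + m > control$max_evals) break
    F <- stats::runif(1, control$F_range[1L], control$F_range[2L])
    trial <- de_mutate_crossover(U, F, control$CR, b$lo, b$hi)
    tfit <- .rss_pop(circuit, trial, omega, zr, zi)
    tfit[!is.finite(tfit)] <- .Machine$double.xmax
    n_evals <- n_evals + m
    better <- tfit <= fit
    U[better, ] <- trial[better, ]
    fit[better] <- tfit[better]
    best_trace <- c(best_trace, min(fit))
    g0 <- g + 1L - control$patience
    if (g >= control$min_gen && g0 >= 1L) {
      prev <- best_trace[g0]
      if (prev > 0 && (prev - min(fit)) / prev < control$eps) break
    }
  }
  k <- max(1L, ceiling(control$elite_frac * m))
  ord <- order(fit)
  if (length(circuit$sections) >= 2L && k > 1L) {
    # basin-aware elite: the best member of each distinct section-time-
    # constant configuration first, then fill by plain fitness rank, so the
    # local-refinement seeds cover the surviving basins instead of one
    Th <- .from_internal(circuit, U[ord, , drop = FALSE])
    key <- apply(round(log10(.section_taus(circuit, Th))), 1L,
                 paste, collapse = "/")
    ord <- c(ord[!duplicated(key)], ord[duplicated(key)])
  }
  ord <- ord[seq_len(k)]
  list(elite = .from_internal(circuit, U[ord, , drop = FALSE]),
       elite_rss = fit[ord], best_trace = best_trace, n_evals = n_evals,
       population = .from_internal(circuit, U), fitness = fit)
}

# finite-difference Jacobian of the model vector wrt internal parameters,
# computed in one vectorized population evaluation
.model_and_jacobian <- function(circuit, u, omega, h_rel = 1e-6) {
  p <- length(u)
  h <- h_rel * pmax(abs(u), 1)
  Up <- matrix(u, p + 1L, p, byrow = TRUE)
  Up[cbind(seq_len(p) + 1L, seq_len(p))] <-
    Up[cbind(seq_len(p) + 1L, seq_len(p))] + h
  Z <- .circuit_impedance_pop(circuit, .from_internal(circuit, Up), omega)
  f0 <- c(Re(Z[1L, ]), Im(Z[1L, ]))
  J <- matrix(0, length(f0), p)
  for (j in seq_len(p))
    J[, j] <- (c(Re(Z[j + 1L, ]), Im(Z[j + 1L, ])) - f0) / h[j]
  list(f = f0, J = J, n_evals = p + 1L)
}

.equilibrated_cond <- function(J) {
  cn <- sqrt(colSums(J^2))
  cn[cn == 0] <- 1
  Jn <- sweep(J, 2L, cn, "/")
  sv <- svd(Jn, nu = 0, nv = 0)$d
  if (min(sv) == 0) Inf else max(sv) / min(sv)
}

#' Levenberg-Marquardt refinement with Nielsen damping
#'
#' Local least-squares refinement of circuit parameters from a starting
#' point, solving \eqn{(J^T J + \mu I)\Delta = J^T r} with the damping
#' factor \eqn{\mu} adapted by Nielsen's rule (on acceptance
#' \eqn{\mu \leftarrow \mu \max(1/3, 1-(2\rho-1)^3)}, \eqn{\nu \leftarrow 2};
#' on rejection \eqn{\mu \leftarrow \mu\nu}, \eqn{\nu \leftarrow 2\nu}),
#' clipped to `mu_bounds`. Steps are reflected into the parameter bounds.
#' The Jacobian is obtained by forward finite differences (relative step
#' 1e-6) in the internal (log-magnitude) parameterization.
#'
#' @inheritParams de_search
#' @param theta0 starting parameter vector (natural scale, within bounds).
#' @param control an [lm_control] list.
#' @return list with `theta` (natural scale), `rss`, `residuals`,
#'   `converged`, `iterations`, `mu_trace`, `jacobian_cond` (column-
#'   equilibrated condition number at the optimum), `se_internal`,
#'   `ci` (parameter confidence intervals, natural scale), `n_evals`.
#' @export
lm_refine <- function(circuit, spectrum, theta0, control = lm_control()) {
  b <- .internal_bounds(circuit)
  u <- reflect_bounds(.to_internal(circuit, theta0), b$lo, b$hi)
  omega <- 2 * pi * spectrum$freq
  y <- c(spectrum$z_real, spectrum$z_imag)
  p <- length(u); N2 <- length(y)
  mu <- control$mu_init; nu <- control$nielsen_nu
  mu_trace <- mu
  fj <- .model_and_jacobian(circuit, u, omega)
  n_evals <- fj$n_evals
  r <- y - fj$f
  rss <- sum(r^2)
  converged <- FALSE
  iter <- 0L
  while (iter < control$max_iter) {
    iter <- iter + 1L
    J <- fj$J
    g <- crossprod(J, r)                      # J^T r
    if (max(abs(g)) < 1e-10 * (1 + rss)) { converged <- TRUE; break }
    A <- crossprod(J)
    # mu is the relative damping (Nielsen's tau): the identity is scaled by
    # max diag(J^T J) so the [1e-3, 1e2] range is meaningful for any circuit
    dscale <- max(diag(A), .Machine$double.eps)
    step_ok <- FALSE
    for (try in 1:25) {                       # escalate mu on singularity
      delta <- tryCatch(
        solve(A + mu * dscale * diag(p), g),
        error = function(e) NULL)
      if (!is.null(delta) && all(is.finite(delta))) { step_ok <- TRUE; break }
      mu <- min(mu * nu, control$mu_bounds[2L]); nu <- 2 * nu
    }
    if (!step_ok) break
    u_new <- reflect_bounds(u + as.numeric(delta), b$lo, b$hi)
    Z <- .circuit_impedance_pop(circuit,
                                matrix(.from_internal(circuit, u_new), 1L),
                                omega)
    n_evals <- n_evals + 1L
    r_new <- y - c(Re(Z[1L, ]), Im(Z[1L, ]))
    rss_new <- sum(r_new^2)
    pred <- sum(delta * (mu * dscale * delta + g))  # predicted reduction
    rho <- if (pred > 0) (rss - rss_new) / pred else -1
    if (is.finite(rss_new) && rss_new < rss) {
      accepted_drop <- (rss - rss_new) <= 1e-12 * (rss + 1e-30)
      u <- u_new; r <- r_new; rss <- rss_new
      mu <- mu * max(1 / 3, 1 - (2 * rho - 1)^3); nu <- control$nielsen_nu
      mu <- min(max(mu, control$mu_bounds[1L]), control$mu_bounds[2L])
      fj <- .model_and_jacobian(circuit, u, omega)
      n_evals <- n_evals + fj$n_evals
      r <- y - fj$f
      if (accepted_drop) { converged <- TRUE; break }
    } else {
      mu <- mu * nu; nu <- 2 * nu
      if (mu >= control$mu_bounds[2L]) {
        mu <- control$mu_bounds[2L]
        if (nu > 2^12) break                  # persistent failure
      }
    }
    mu_trace <- c(mu_trace, mu)
  }
  if (!converged)
    converged <- max(abs(crossprod(fj$J, r))) < 1e-6 * (1 + rss)
  J <- fj$J
  kcond <- .equilibrated_cond(J)
  dof <- max(N2 - p, 1L)
  JtJ <- crossprod(J)
  cov_u <- tryCatch({
    JtJinv <- solve(JtJ)
    if (control$ci_type %in% c("robust", "bootstrap")) {
      # cluster-robust sandwich with one cluster per frequency point: the
      # real and imaginary residuals of the same point share the same
      # multiplicative noise draw, so they are correlated and must enter
      # the meat jointly
      A <- J * r
      npt <- N2 %/% 2L
      G <- A[seq_len(npt), , drop = FALSE] +
        A[npt + seq_len(npt), , drop = FALSE]
      meat <- crossprod(G)
      (N2 / dof) * JtJinv %*% meat %*% JtJinv
    } else {
      (sum(r^2) / dof) * JtJinv
    }
  }, error = function(e) matrix(NA_real_, p, p))
  se_u <- sqrt(pmax(diag(cov_u), 0))
  tq <- stats::qt(1 - (1 - control$ci_level) / 2, dof)
  ci_lo_u <- u - tq * se_u
  ci_hi_u <- u + tq * se_u
  ci <- cbind(lower = .from_internal(circuit, ci_lo_u),
              upper = .from_internal(circuit, ci_hi_u))
  rownames(ci) <- circuit$theta_names
  theta <- .from_internal(circuit, u)
  names(theta) <- circuit$theta_names
  list(theta = theta, rss = rss, residuals = r, converged = converged,
       iterations = iter, mu_trace = mu_trace, jacobian_cond = kcond,
       se_internal = se_u, cov_internal = cov_u, ci = ci, n_evals = n_evals)
}

# Wild cluster bootstrap of the fitted model: residuals are flipped by a
# Rademacher weight per frequency point (keeping the correlated real and
# imaginary components of a point together), the model is re-refined from
# the incumbent estimate, and the spread of the re-estimates in the
# internal scale yields the confidence intervals. Unlike first-order
# covariances this propagates the noise through the actual nonlinear
# estimator.
.bootstrap_ci <- function(circuit, spectrum, theta_hat, lm, B) {
  fitted <- circuit_impedance(circuit, theta_hat, spectrum$freq,
                              as_spectrum = FALSE)
  fre <- Re(fitted); fim <- Im(fitted)
  rre <- spectrum$z_real - fre
  rim <- spectrum$z_imag - fim
  # HC3-style leverage adjustment (wild bootstrap of restricted residuals
  # underestimates variance at high-leverage points; dividing by 1 - h_i
  # restores it -- the low-frequency rows that determine R_ct and sigma
  # carry the highest leverage)
  lev <- tryCatch({
    u0 <- .to_internal(circuit, theta_hat)
    J <- .model_and_jacobian(circuit, u0, 2 * pi * spectrum$freq)$J
    h <- rowSums((J %*% solve(crossprod(J))) * J)
    pmin(h, 0.9)
  }, error = function(e) rep(0, 2L * nrow(spectrum)))
  npt <- nrow(spectrum)
  rre <- rre / (1 - lev[seq_len(npt)])
  rim <- rim / (1 - lev[npt + seq_len(npt)])
  ctl <- lm
  ctl$max_iter <- 25L
  u_hat <- .to_internal(circuit, theta_hat)
  U <- matrix(NA_real_, B, circuit$n_params)
  for (b in seq_len(B)) {
    w <- sample(c(-1, 1), nrow(spectrum), replace = TRUE)
    sp_b <- eis_spectrum(spectrum$freq, fre + w * rre, fim + w * rim,
                         pt = spectrum$pt)
    rb <- tryCatch(lm_refine(circuit, sp_b, theta_hat, ctl),
                   error = function(e) NULL)
    if (!is.null(rb)) U[b, ] <- .to_internal(circuit, rb$theta)
  }
  ok <- stats::complete.cases(U)
  if (sum(ok) < max(10L, B / 2)) return(NULL)
  se_u <- apply(U[ok, , drop = FALSE], 2L, stats::sd)
  tq <- stats::qt(1 - (1 - lm$ci_level) / 2, sum(ok) - 1L)
  ci <- cbind(lower = .from_internal(circuit, u_hat - tq * se_u),
              upper = .from_internal(circuit, u_hat + tq * se_u))
  rownames(ci) <- circuit$theta_names
  list(ci = ci, se_u = se_u, cov_u = diag(se_u^2, length(se_u)))
}

#' Fit an equivalent-circuit model to an impedance spectrum
#'
#' The central fitting routine: a bounded differential-evolution global
#' search explores the physically constrained parameter space, its top-10%
#' elite individuals seed Levenberg-Marquardt refinement, and the best
#' refined solution is returned. If the column-equilibrated Jacobian
#' condition number at the solution exceeds `lm$cond_threshold`, the fitter
#' resamples 50-100 individuals within a +/-5% neighborhood of the incumbent,
#' runs a short DE, re-refines, and keeps the better solution (at most
#' `lm$max_restarts` cycles). All returned parameters respect positivity and
#' the CPE-exponent range by construction.
#'
#' @param spectrum an [eis_spectrum], or anything [eis_spectrum] accepts.
#' @param circuit an [eis_circuit], or a catalog id such as `"C3"`.
#' @param de a [de_control] list.
#' @param lm an [lm_control] list.
#' @param seed integer seed; fixed seed implies reproducible results.
#' @param refine set `FALSE` for a DE-only fit (no LM stage; used for
#'   optimizer ablation comparisons).
#' @param n_starts number of independent DE starts (islands). Default
#'   (`NULL`): one start for circuits with fewer than 6 parameters, two for
#'   6-7, three for 8 or more. Islands after the first run at a lower
#'   crossover rate (0.7): coordinate-wise mixing favors reassembly of
#'   partially correct section assignments, which diversifies the restarts.
#'   Up to `max_rescues` extra rescue islands run when the incumbent
#'   solution looks pathological (residual far above the Kramers-Kronig
#'   measurement-model floor, a collapsed parallel section, or
#'   \eqn{R^2 < 0.99}) —
#'   high-dimensional layered circuits have genuinely multimodal objectives
#'   and diversified restarts are the standard safeguard.
#' @param max_rescues cap on rescue islands (0 disables the pathology
#'   check; used by reduced-budget featurization fits).
#' @return an object of class `"eis_fit"` with components `theta_hat`,
#'   `rss`, `residuals`, `ci`, `metrics` (six-metric panel), `converged`,
#'   `jacobian_cond`, `mu_trace`, `n_restarts`, `n_evals`,
#'   `fitted_spectrum` and the inputs; supports `print`, `summary`, `coef`,
#'   `vcov`, `confint`, `fitted`, `residuals`, `predict`, `plot` and
#'   `simulate` methods.
#' @examples
#' cat8 <- circuit_catalog()
#' sp <- circuit_impedance(cat8$C3, freq = 10^seq(-1, 5, length.out = 40))
#' fit <- eis_fit(sp, cat8$C3, de = de_control(pop_size = 40, max_gen = 30),
#'                seed = 1)
#' coef(fit)
#' @export
eis_fit <- function(spectrum, circuit, de = de_control(), lm = lm_control(),
                    seed = NULL, refine = TRUE, n_starts = NULL,
                    max_rescues = 4L) {
  if (is.character(circuit)) circuit <- circuit_catalog()[[circuit]]
  stopifnot(inherits(circuit, "eis_circuit"),
            inherits(spectrum, "eis_spectrum"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_starts))
    n_starts <- if (circuit$n_params < 6L) 1L
                else if (circuit$n_params < 8L) 2L else 3L
  search <- de_search(circuit, spectrum, de)
  n_evals <- search$n_evals
  if (!refine) {
    theta <- search$elite[1L, ]
    names(theta) <- circuit$theta_names
    fitted_sp <- circuit_impedance(circuit, theta, spectrum$freq)
    res <- c(spectrum$z_real - fitted_sp$z_real,
             spectrum$z_imag - fitted_sp$z_imag)
    out <- list(circuit = circuit, spectrum = spectrum, theta_hat = theta,
                rss = search$elite_rss[1L], residuals = res, ci = NULL,
                se = NULL, converged = NA, jacobian_cond = NA_real_,
                mu_trace = numeric(), n_restarts = 0L, n_evals = n_evals,
                de_trace = search$best_trace, fitted_spectrum = fitted_sp,
                metrics = compute_metrics(spectrum, fitted_sp),
                method = "de", call = match.call())
    class(out) <- "eis_fit"
    return(out)
  }
  refine_all <- function(seeds) {
    best <- NULL
    for (i in seq_len(nrow(seeds))) {
      cand <- lm_refine(circuit, spectrum, seeds[i, ], lm)
      n_evals <<- n_evals + cand$n_evals
      if (is.null(best) || cand$rss < best$rss ||
          (cand$rss == best$rss &&
             sum(cand$theta^2) < sum(best$theta^2))) best <- cand
    }
    best
  }
  best <- refine_all(search$elite)
  de2 <- de; de2$CR <- min(de$CR, 0.7)
  island <- 1L; rescues <- 0L
  rss_floor <- if (max_rescues > 0L) .rss_floor(spectrum) else 0
  repeat {
    if (island < n_starts) {
      island <- island + 1L
    } else if (rescues < max_rescues &&
               .looks_pathological(spectrum, circuit, best, rss_floor)) {
      rescues <- rescues + 1L
    } else break
    s2 <- de_search(circuit, spectrum, de2)
    n_evals <- n_evals + s2$n_evals
    cand <- refine_all(s2$elite)
    if (cand$rss < best$rss) best <- cand
  }
  n_restarts <- 0L
  while (is.finite(best$jacobian_cond) &&
         best$jacobian_cond > lm$cond_threshold &&
         n_restarts < lm$max_restarts) {
    n_restarts <- n_restarts + 1L
    center <- best$theta
    pert <- matrix(stats::runif(lm$restart_pop * length(center),
                                1 - lm$restart_frac, 1 + lm$restart_frac),
                   lm$restart_pop)
    pop0 <- reflect_bounds(sweep(pert, 2L, center, "*"),
                           circuit$lower, circuit$upper)
    short <- de_control(pop_size = lm$restart_pop, max_gen = 15,
                        patience = 10, eps = de$eps)
    s2 <- de_search(circuit, spectrum, short, init_pop = pop0)
    n_evals <- n_evals + s2$n_evals
    cand <- refine_all(s2$elite[1L, , drop = FALSE])
    if (cand$rss <= best$rss) best <- cand
  }
  if (lm$ci_type == "bootstrap") {
    bs <- .bootstrap_ci(circuit, spectrum, best$theta, lm, lm$boot_B)
    if (!is.null(bs)) {
      best$ci <- bs$ci
      best$se_internal <- bs$se_u
      best$cov_internal <- bs$cov_u
    }
  }
  fitted_sp <- circuit_impedance(circuit, best$theta, spectrum$freq)
  out <- list(circuit = circuit, spectrum = spectrum,
              theta_hat = best$theta, rss = best$rss,
              residuals = best$residuals, ci = best$ci,
              se = best$se_internal, cov_internal = best$cov_internal,
              converged = best$converged, jacobian_cond = best$jacobian_cond,
              mu_trace = best$mu_trace, n_restarts = n_restarts,
              n_evals = n_evals, de_trace = search$best_trace,
              fitted_spectrum = fitted_sp,
              metrics = compute_metrics(spectrum, fitted_sp),
              ci_level = lm$ci_level, method = "delm", call = match.call())
  class(out) <- "eis_fit"
  out
}

#' Relative-agreement similarity between parameter vectors
#'
#' Mean over dimensions of \eqn{1 - |\hat\theta_k - \theta_k| /
#' (|\hat\theta_k| + |\theta_k|)}: 1 for identical vectors, symmetric, and
#' invariant to a common per-dimension rescaling. Dimensions with a zero
#' denominator are skipped with a warning.
#'
#' @param theta_true,theta_hat equal-length parameter vectors.
#' @return scalar in \[0, 1\].
#' @examples
#' parameter_similarity(c(1), c(3))  # 0.5
#' @export
parameter_similarity <- function(theta_true, theta_hat) {
  stopifnot(length(theta_true) == length(theta_hat))
  den <- abs(theta_true) + abs(theta_hat)
  keep <- den > 0
  if (!all(keep)) warning("skipping dimension(s) with zero denominator")
  if (!any(keep)) return(NA_real_)
  mean(1 - abs(theta_hat[keep] - theta_true[keep]) / den[keep])
}

# ---- standard model methods -------------------------------------------------

#' @export
print.eis_fit <- function(x, ...) {
  cat("Equivalent-circuit fit: ", x$circuit$name, " [", x$circuit$id, "] ",
      "(", x$method, ")\n", sep = "")
  cat("  RSS = ", signif(x$rss, 5), ", R^2 = ", signif(x$metrics$r2, 5),
      ", converged: ", x$converged, "\n", sep = "")
  print(signif(x$theta_hat, 5))
  invisible(x)
}

#' @export
summary.eis_fit <- function(object, ...) {
  tab <- data.frame(estimate = object$theta_hat)
  if (!is.null(object$ci)) {
    tab$ci_lower <- object$ci[, "lower"]
    tab$ci_upper <- object$ci[, "upper"]
  }
  out <- list(circuit = object$circuit, table = tab, rss = object$rss,
              metrics = object$metrics, converged = object$converged,
              jacobian_cond = object$jacobian_cond,
              n_restarts = object$n_restarts, n_evals = object$n_evals)
  class(out) <- "summary.eis_fit"
  out
}

#' @export
print.summary.eis_fit <- function(x, ...) {
  cat("Equivalent-circuit fit: ", x$circuit$name, " [", x$circuit$id,
      "]\n\nParameters:\n", sep = "")
  print(format(x$table, digits = 5))
  cat("\nRSS: ", signif(x$rss, 5),
      "   Jacobian condition (equilibrated): ", signif(x$jacobian_cond, 4),
      "\nRestarts: ", x$n_restarts, "   Model evaluations: ", x$n_evals,
      "\n\n", sep = "")
  print(x$metrics)
  invisible(x)
}

#' @export
coef.eis_fit <- function(object, ...) object$theta_hat

#' @export
vcov.eis_fit <- function(object, ...) {
  if (is.null(object$cov_internal)) return(NULL)
  # delta method back to the natural scale: d theta / d u = theta for
  # log-scale parameters, 1 otherwise
  sc <- ifelse(object$circuit$log_scale, object$theta_hat, 1)
  V <- object$cov_internal * tcrossprod(sc)
  dimnames(V) <- list(object$circuit$theta_names, object$circuit$theta_names)
  V
}

#' @export
confint.eis_fit <- function(object, parm, level, ...) {
  ci <- object$ci
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
fitted.eis_fit <- function(object, ...) object$fitted_spectrum

#' @export
residuals.eis_fit <- function(object, ...) object$residuals

#' @export
predict.eis_fit <- function(object, newdata = NULL, ...) {
  freq <- if (is.null(newdata)) object$spectrum$freq
          else if (is.list(newdata)) newdata$freq else newdata
  circuit_impedance(object$circuit, object$theta_hat, freq)
}

#' @export
plot.eis_fit <- function(x, which = c("both", "nyquist", "bode"), ...) {
  plot.eis_spectrum(x$spectrum, fitted = x$fitted_spectrum,
                    which = match.arg(which), ...)
}

#' @export
simulate.eis_fit <- function(object, nsim = 1, seed = NULL,
                             noise_sd = 0.01, ...) {
  if (!is.null(seed)) set.seed(seed)
  base <- object$fitted_spectrum
  lapply(seq_len(nsim), function(i)
    add_proportional_noise(base, noise_sd))
}
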