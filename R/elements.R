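#' Circuit elements and equivalent-circuit models
#'
#' An equivalent-circuit model (ECM) is a series/parallel network of idealized
#' elements whose complex impedance reproduces a measured spectrum. Four
#' element kinds are supported:
#' \describe{
#'   \item{R}{resistor, \eqn{Z = R} (Ohm).}
#'   \item{C}{capacitor, \eqn{Z = 1/(j\omega C)} (C in Farad).}
#'   \item{CPE}{constant phase element, \eqn{Z = 1/(Q (j\omega)^n)} with
#'     \eqn{Q} in S s\eqn{^n} and dimensionless exponent \eqn{n \in [0,1]};
#'     models the distributed, non-ideal capacitance of rough or
#'     heterogeneous electrode surfaces.}
#'   \item{W}{semi-infinite Warburg diffusion element,
#'     \eqn{Z = \sigma (1 - j)/\sqrt{\omega}} with coefficient \eqn{\sigma}
#'     in Ohm s\eqn{^{-1/2}}; the -45 degree low-frequency tail of
#'     diffusion-limited kinetics.}
#' }
#' All formulas use the angular frequency \eqn{\omega = 2\pi f} with \eqn{f}
#' in Hz as read from data files.
#'
#' @name circuit-elements
#' @keywords internal
NULL

# default physical bounds per parameter kind; wide enough to cover typical
# electrochemical cells (mOhm contacts to MOhm films) with margin
.element_bounds <- list(
  R   = c(1e-3, 1e6),
  C   = c(1e-12, 1e-1),
  Q   = c(1e-12, 1e-1),
  n   = c(0, 1),
  W   = c(1e-3, 1e5)
)

#' Impedance of a single circuit element
#'
#' @param kind one of `"R"`, `"C"`, `"CPE"`, `"W"`.
#' @param params named numeric vector of element parameters: `R` (Ohm) for a
#'   resistor, `C` (F) for a capacitor, `Q` and `n` for a CPE, `sigma`
#'   (Ohm s^-1/2) for a Warburg element.
#' @param omega angular frequency (rad/s), strictly positive; vectorized.
#' @return complex impedance, one value per `omega`.
#' @examples
#' element_impedance("R", c(R = 100), omega = c(1, 10))
#' element_impedance("CPE", c(Q = 1e-6, n = 1), omega = 1e6) # == ideal capacitor
#' @export
element_impedance <- function(kind, params, omega) {
  kind <- match.arg(kind, c("R", "C", "CPE", "W"))
  if (any(!is.finite(omega)) || any(omega <= 0))
    stop("omega must be finite and strictly positive")
  switch(kind,
    R = {
      R <- params[["R"]]
      if (R < 0) stop("resistance must be non-negative")
      rep(complex(real = R, imaginary = 0), length(omega))
    },
    C = {
      C <- params[["C"]]
      if (C <= 0) stop("capacitance must be strictly positive")
      1 / (1i * omega * C)
    },
    CPE = {
      Q <- params[["Q"]]; n <- params[["n"]]
      if (Q <= 0) stop("CPE coefficient Q must be strictly positive")
      if (n < 0 || n > 1) stop("CPE exponent n must lie in [0, 1]")
      1 / (Q * (1i * omega)^n)
    },
    W = {
      s <- if ("sigma" %in% names(params)) params[["sigma"]] else params[[1L]]
      if (s <= 0) stop("Warburg coefficient must be strictly positive")
      s * (1 - 1i) / sqrt(omega)
    }
  )
}

# ---- circuit-description grammar --------------------------------------------
#
#   series   := term ('-' term)*
#   term     := element | 'p(' series (',' series)+ ')'
#   element  := ('R'|'C'|'CPE'|'W') digits
#
# e.g. "R0-p(R1-W1,CPE1)" is a solution resistance in series with the
# parallel combination of (charge-transfer resistance + Warburg) and a CPE.

.split_top <- function(x, sep) {
  depth <- 0L; parts <- character(); buf <- ""
  for (ch in strsplit(x, "", fixed = TRUE)[[1L]]) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (ch == sep && depth == 0L) { parts <- c(parts, buf); buf <- "" }
    else buf <- paste0(buf, ch)
  }
  c(parts, buf)
}

.parse_series <- function(x) {
  x <- gsub("[[:space:]]", "", x)
  parts <- .split_top(x, "-")
  nodes <- lapply(parts, .parse_term)
  if (length(nodes) == 1L) nodes[[1L]]
  else list(type = "series", children = nodes)
}

.parse_term <- function(x) {
  if (grepl("^p\\(.*\\)$", x)) {
    inner <- substr(x, 3L, nchar(x) - 1L)
    branches <- .split_top(inner, ",")
    if (length(branches) < 2L)
      stop("parallel node needs at least two branches: ", x)
    list(type = "parallel", children = lapply(branches, .parse_series))
  } else {
    m <- regmatches(x, regexec("^(CPE|R|C|W)([0-9]+)$", x))[[1L]]
    if (length(m) == 0L) stop("cannot parse circuit token: '", x, "'")
    list(type = "element", kind = m[2L], label = x)
  }
}

# walk the tree assigning parameter slots; returns list(tree, names, kinds)
.index_tree <- function(node, names = character(), kinds = character()) {
  if (node$type == "element") {
    pn <- switch(node$kind,
      R   = node$label,
      C   = node$label,
      W   = node$label,
      CPE = paste0(node$label, c(".Q", ".n")))
    pk <- switch(node$kind, R = "R", C = "C", W = "W", CPE = c("Q", "n"))
    node$idx <- seq_along(pn) + length(names)
    list(node = node, names = c(names, pn), kinds = c(kinds, pk))
  } else {
    children <- vector("list", length(node$children))
    for (i in seq_along(node$children)) {
      res <- .index_tree(node$children[[i]], names, kinds)
      children[[i]] <- res$node; names <- res$names; kinds <- res$kinds
    }
    node$children <- children
    list(node = node, names = names, kinds = kinds)
  }
}

#' Construct an equivalent-circuit model from a description string
#'
#' Builds a circuit model from the series/parallel grammar: elements
#' (`R0`, `C1`, `CPE1`, `W1`, ...) joined in series by `-`, parallel
#' combinations written `p(branch, branch, ...)` where each branch may itself
#' be a series chain. A CPE contributes two parameters (`<label>.Q`,
#' `<label>.n`); every other element contributes one, named by its label.
#'
#' @param definition circuit-description string, e.g. `"R0-p(R1,CPE1)"`.
#' @param id short identifier (defaults to the definition string).
#' @param name human-readable name.
#' @param theta optional default parameter vector (recycled against the
#'   parameter names in order).
#' @param lower,upper optional per-parameter bounds; defaults are wide
#'   physical ranges per element kind (R in \[1e-3, 1e6\] Ohm, C and Q in
#'   \[1e-12, 0.1\], n in \[0, 1\], Warburg sigma in \[1e-3, 1e5\]).
#' @return an object of class `"eis_circuit"` with fields `id`, `name`,
#'   `definition`, `theta_names`, `theta`, `lower`, `upper`, `log_scale`
#'   (which parameters are searched in log space) and the parsed topology.
#' @examples
#' randles <- eis_circuit("R0-p(R1,C1)", name = "Randles")
#' randles$theta_names
#' @export
eis_circuit <- function(definition, id = definition, name = id,
                        theta = NULL, lower = NULL, upper = NULL) {
  tree <- .parse_series(definition)
  idx <- .index_tree(tree)
  kinds <- idx$kinds
  lo <- vapply(kinds, function(k) .element_bounds[[k]][1L], numeric(1))
  hi <- vapply(kinds, function(k) .element_bounds[[k]][2L], numeric(1))
  if (!is.null(lower)) lo <- rep_len(lower, length(lo))
  if (!is.null(upper)) hi <- rep_len(upper, length(hi))
  if (any(lo < 0) || any(lo >= hi)) stop("bounds must satisfy 0 <= lo < hi")
  th <- if (is.null(theta)) sqrt(pmax(lo, 1e-12) * hi) else rep_len(theta, length(lo))
  names(th) <- names(lo) <- names(hi) <- idx$names
  obj <- list(id = id, name = name, definition = definition,
              tree = idx$node, theta_names = idx$names,
              param_kinds = kinds, theta = th, lower = lo, upper = hi,
              log_scale = kinds != "n", n_params = length(idx$names),
              sections = .find_sections(idx$node))
  class(obj) <- "eis_circuit"
  validate_circuit(obj)
  obj
}

validate_circuit <- function(x) {
  stopifnot(inherits(x, "eis_circuit"))
  if (anyDuplicated(x$theta_names))
    stop("duplicate parameter names in circuit ", x$id)
  if (length(x$theta) != x$n_params)
    stop("parameter count mismatch in circuit ", x$id)
  # every catalog-style topology starts with a series solution resistance
  invisible(x)
}

#' @export
print.eis_circuit <- function(x, ...) {
  cat("Equivalent circuit model: ", x$name, " [", x$id, "]\n", sep = "")
  cat("  definition: ", x$definition, "\n", sep = "")
  cat("  parameters (", x$n_params, "):\n", sep = "")
  tab <- data.frame(default = x$theta, lower = x$lower, upper = x$upper)
  print(format(tab, digits = 4))
  invisible(x)
}

# Parallel R-C / R-CPE "sections" of a circuit (the relaxation processes).
# Sections are numbered in definition order, which by catalog convention runs
# from the fastest (interfacial) to the slowest (outer film) process; the
# optimizer uses this to impose a canonical time-constant ordering that
# removes permutation-equivalent local minima.
.find_sections <- function(root) {
  leaves <- function(node) {
    if (node$type == "element") list(node)
    else do.call(c, lapply(node$children, leaves))
  }
  tops <- if (root$type == "series") root$children else list(root)
  sections <- list()
  for (ch in tops) {
    if (ch$type != "parallel") next
    ll <- leaves(ch)
    kinds <- vapply(ll, `[[`, character(1), "kind")
    r_i <- which(kinds == "R")[1L]
    c_i <- which(kinds == "C")[1L]
    q_i <- which(kinds == "CPE")[1L]
    if (is.na(r_i) || (is.na(c_i) && is.na(q_i))) next
    sections[[length(sections) + 1L]] <-
      if (!is.na(c_i)) list(type = "RC", r = ll[[r_i]]$idx[1L],
                            c = ll[[c_i]]$idx[1L])
      else list(type = "RCPE", r = ll[[r_i]]$idx[1L],
                q = ll[[q_i]]$idx[1L], n = ll[[q_i]]$idx[2L])
  }
  sections
}

# characteristic relaxation times per section for a population matrix
.section_taus <- function(circuit, theta_mat) {
  S <- length(circuit$sections)
  out <- matrix(NA_real_, nrow(theta_mat), S)
  for (s in seq_len(S)) {
    sec <- circuit$sections[[s]]
    out[, s] <- if (sec$type == "RC")
      theta_mat[, sec$r] * theta_mat[, sec$c]
    else (theta_mat[, sec$r] * theta_mat[, sec$q])^(1 / theta_mat[, sec$n])
  }
  out
}

# vectorized impedance of a tree for a population matrix of parameter vectors:
# theta_mat is m x p, omega length nf; returns m x nf complex matrix
.tree_impedance <- function(node, theta_mat, omega) {
  nf <- length(omega)
  m <- nrow(theta_mat)
  if (node$type == "element") {
    switch(node$kind,
      R = matrix(complex(real = theta_mat[, node$idx[1L]], imaginary = 0), m, nf),
      C = 1 / (1i * (theta_mat[, node$idx[1L]] %o% omega)),
      CPE = {
        Q <- theta_mat[, node$idx[1L]]; nn <- theta_mat[, node$idx[2L]]
        # (j w)^n = exp(n log w) * exp(i n pi/2), split so rows carry n
        mag <- exp(nn %o% log(omega))
        1 / ((Q * exp(1i * (pi / 2) * nn)) * mag)
      },
      W = (theta_mat[, node$idx[1L]] %o% (1 / sqrt(omega))) * (1 - 1i)
    )
  } else if (node$type == "series") {
    Z <- .tree_impedance(node$children[[1L]], theta_mat, omega)
    for (ch in node$children[-1L])
      Z <- Z + .tree_impedance(ch, theta_mat, omega)
    Z
  } else {
    Y <- 1 / .tree_impedance(node$children[[1L]], theta_mat, omega)
    for (ch in node$children[-1L])
      Y <- Y + 1 / .tree_impedance(ch, theta_mat, omega)
    if (any(Mod(Y) == 0)) stop("singular parallel combination (zero admittance)")
    1 / Y
  }
}

#' Complex impedance of a circuit model over a frequency grid
#'
#' Series nodes sum impedances; parallel nodes sum admittances.
#'
#' @param circuit an [eis_circuit] object.
#' @param theta parameter vector (defaults to the circuit's stored values).
#' @param freq frequencies in Hz, strictly positive. Angular frequency
#'   \eqn{\omega = 2\pi f} is used in all element formulas.
#' @param as_spectrum return an [eis_spectrum] (default) or a raw complex
#'   vector.
#' @return an `eis_spectrum` with `z_real`, `z_imag` columns, or a complex
#'   vector when `as_spectrum = FALSE`.
#' @examples
#' rc <- eis_circuit("R0-p(R1,C1)")
#' z <- circuit_impedance(rc, theta = c(10, 100, 1e-5), freq = 10^seq(-2, 4))
#' @export
circuit_impedance <- function(circuit, theta = circuit$theta, freq,
                              as_spectrum = TRUE) {
  stopifnot(inherits(circuit, "eis_circuit"))
  if (length(theta) != circuit$n_params)
    stop("theta has length ", length(theta), ", expected ", circuit$n_params)
  if (any(freq <= 0)) stop("frequencies must be strictly positive")
  z <- .tree_impedance(circuit$tree, matrix(theta, nrow = 1L),
                       2 * pi * freq)[1L, ]
  if (!as_spectrum) return(z)
  eis_spectrum(freq = freq, z_real = Re(z), z_imag = Im(z),
               source = circuit$id, circuit_id = circuit$id, theta = theta)
}

# population version used by the optimizer: theta_mat m x p -> m x nf complex
.circuit_impedance_pop <- function(circuit, theta_mat, omega) {
  .tree_impedance(circuit$tree, theta_mat, omega)
}
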