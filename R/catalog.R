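#' Catalog of candidate equivalent-circuit models
#'
#' Returns the eight candidate topologies the framework fits in parallel,
#' spanning simple solution interfaces through layered biofilm-modified
#' electrodes:
#' \describe{
#'   \item{C1 resistor}{`R0` — purely ohmic cell.}
#'   \item{C2 rc-series}{`R0-C0` — blocking (ideally polarizable) electrode.}
#'   \item{C3 randles}{`R0-p(R1,C1)` — classical Randles: solution resistance
#'     with charge-transfer resistance in parallel with the double-layer
#'     capacitance. `R1` is the Nyquist semicircle diameter.}
#'   \item{C4 bare-electrode}{`R0-p(R1,CPE1)` — Randles with a CPE replacing
#'     the ideal capacitor, for the rough/heterogeneous bare electrode.}
#'   \item{C5 randles-warburg}{`R0-p(R1-W1,C1)` — Randles with semi-infinite
#'     diffusion in series with the charge-transfer branch.}
#'   \item{C6 nano-biofilm}{`R0-p(R1-W1,CPE1)` — nanoparticle-film electrode:
#'     the porous assembled film adds a tortuous diffusion path (W) and
#'     distributed capacitance (CPE).}
#'   \item{C7 biofilm}{`R0-p(R1,CPE1)-p(R2,C2)` — generalized biofilm: a
#'     distinct parallel R-C for the film's bulk ionic resistance and
#'     dielectric capacitance on top of the interfacial process.}
#'   \item{C8 biofilm-warburg}{`R0-p(R1-W1,CPE1)-p(R2,C2)-p(R3,CPE2)` —
#'     two-layer biofilm with diffusion: interfacial charge transfer plus
#'     Warburg under a CPE, a compact film R-C layer, and a second
#'     dispersive (CPE) film layer; 10 parameters.}
#' }
#'
#' Default parameter values are representative of ferri/ferrocyanide redox
#' probes on small electrodes (tens of Ohm solution resistance, 20-100 Ohm
#' charge transfer, microfarad-scale interfacial capacitance) so that every
#' default spectrum lies in the few-hundred-Ohm envelope typical of biofilm
#' sensing cells.
#'
#' Declared nested pairs (simple circuit recoverable from the complex one by
#' fixing parameters at a boundary value, used by [nested_f_test]) are stored
#' in `attr(catalog, "nested_pairs")`.
#'
#' @return named list of [eis_circuit] objects, length 8, with attribute
#'   `nested_pairs` (two-column character matrix of circuit ids).
#' @examples
#' cat8 <- circuit_catalog()
#' names(cat8)
#' attr(cat8, "nested_pairs")
#' @export
circuit_catalog <- function() {
  specs <- list(
    list(id = "C1", name = "resistor",        def = "R0",
         theta = c(R0 = 20)),
    list(id = "C2", name = "rc-series",       def = "R0-C0",
         theta = c(R0 = 20, C0 = 1e-5)),
    list(id = "C3", name = "randles",         def = "R0-p(R1,C1)",
         theta = c(R0 = 20, R1 = 100, C1 = 1e-5)),
    list(id = "C4", name = "bare-electrode",  def = "R0-p(R1,CPE1)",
         theta = c(R0 = 20, R1 = 100, CPE1.Q = 2e-5, CPE1.n = 0.85)),
    list(id = "C5", name = "randles-warburg", def = "R0-p(R1-W1,C1)",
         theta = c(R0 = 20, R1 = 80, W1 = 2, C1 = 1e-5)),
    list(id = "C6", name = "nano-biofilm",    def = "R0-p(R1-W1,CPE1)",
         theta = c(R0 = 20, R1 = 80, W1 = 2, CPE1.Q = 2e-5, CPE1.n = 0.85)),
    list(id = "C7", name = "biofilm",         def = "R0-p(R1,CPE1)-p(R2,C2)",
         theta = c(R0 = 20, R1 = 80, CPE1.Q = 2e-5, CPE1.n = 0.85,
                   R2 = 30, C2 = 1e-3)),
    list(id = "C8", name = "biofilm-warburg",
         def = "R0-p(R1-W1,CPE1)-p(R2,C2)-p(R3,CPE2)",
         theta = c(R0 = 20, R1 = 80, W1 = 2, CPE1.Q = 2e-5, CPE1.n = 0.85,
                   R2 = 30, C2 = 1e-3, R3 = 30, CPE2.Q = 5e-2, CPE2.n = 0.8))
  )
  out <- lapply(specs, function(s) {
    cc <- eis_circuit(s$def, id = s$id, name = s$name, theta = s$theta)
    # physical plausibility: a double-layer/film CPE with n < 0.5 no longer
    # models distributed capacitance (n = 0.5 is pure diffusion, n = 0 a
    # resistor), so catalog circuits confine the exponent to [0.5, 1]
    cc$lower[cc$param_kinds == "n"] <- 0.5
    cc
  })
  names(out) <- vapply(out, `[[`, character(1), "id")
  # simple -> complex: the simple model is the complex one with some
  # parameters pinned (sigma -> 0, n -> 1, R_film -> 0)
  attr(out, "nested_pairs") <- rbind(
    c("C1", "C3"), c("C3", "C4"), c("C3", "C5"), c("C4", "C6"),
    c("C5", "C6"), c("C4", "C7"), c("C6", "C8"), c("C7", "C8"))
  out
}

#' Export / rebuild a circuit as a plain configuration list
#'
#' The configuration is JSON-serializable (definition string, default
#' parameters, bounds) and `circuit_from_config` rebuilds an identical
#' [eis_circuit] from it, so user catalogs can live in config files.
#'
#' @param circuit an [eis_circuit].
#' @return `circuit_config`: a named list; `circuit_from_config`: an
#'   [eis_circuit].
#' @examples
#' cfg <- circuit_config(circuit_catalog()$C3)
#' identical(circuit_from_config(cfg)$theta, circuit_catalog()$C3$theta)
#' @export
circuit_config <- function(circuit) {
  stopifnot(inherits(circuit, "eis_circuit"))
  list(id = circuit$id, name = circuit$name,
       definition = circuit$definition,
       theta = as.list(circuit$theta),
       lower = as.list(circuit$lower),
       upper = as.list(circuit$upper))
}

#' @rdname circuit_config
#' @param config a list as produced by `circuit_config` (or parsed from
#'   JSON/YAML).
#' @export
circuit_from_config <- function(config) {
  eis_circuit(config$definition, id = config$id, name = config$name,
              theta = unlist(config$theta),
              lower = unlist(config$lower),
              upper = unlist(config$upper))
}

#' Is one catalog circuit nested in another?
#'
#' @param simple,complex circuit ids from [circuit_catalog].
#' @param catalog the catalog the declaration lives on.
#' @return logical; nesting is taken as the reflexive-transitive closure of
#'   the declared pairs.
#' @export
circuit_is_nested <- function(simple, complex, catalog = circuit_catalog()) {
  if (identical(simple, complex)) return(TRUE)
  pairs <- attr(catalog, "nested_pairs")
  seen <- simple
  repeat {
    nxt <- unique(pairs[pairs[, 1L] %in% seen, 2L])
    if (complex %in% nxt) return(TRUE)
    if (all(nxt %in% seen)) return(FALSE)
    seen <- union(seen, nxt)
  }
}
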