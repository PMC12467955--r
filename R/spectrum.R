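#' Impedance spectrum container
#'
#' An ordered set of per-frequency complex impedance records. The capacitive
#' sign convention of the stored data is preserved: `z_imag` is negative for
#' capacitive arcs and Nyquist plots show `-z_imag` on the ordinate.
#'
#' @param freq frequencies in Hz, strictly positive, strictly monotone
#'   (ascending or descending; the stored order is preserved).
#' @param z_real,z_imag real and imaginary impedance parts (Ohm).
#' @param pt integer point index (defaults to `1:n`).
#' @param source free-text provenance label.
#' @param circuit_id,theta optional ground truth for synthetic spectra.
#' @return a data frame of class `"eis_spectrum"` with columns `pt`, `freq`,
#'   `z_real`, `z_imag` and attributes `source`, `circuit_id`, `theta`.
#' @examples
#' sp <- eis_spectrum(freq = c(100, 10, 1), z_real = c(10, 50, 100),
#'                    z_imag = c(-5, -40, -10))
#' @export
eis_spectrum <- function(freq, z_real, z_imag, pt = seq_along(freq),
                         source = "unknown", circuit_id = NULL, theta = NULL) {
  n <- length(freq)
  stopifnot(length(z_real) == n, length(z_imag) == n, length(pt) == n)
  if (any(freq <= 0) || any(!is.finite(freq)))
    stop("frequencies must be finite and strictly positive")
  d <- diff(freq)
  if (n > 1L && !(all(d > 0) || all(d < 0)))
    stop("frequencies must be strictly monotone")
  if (anyDuplicated(pt)) stop("pt indices must be unique")
  out <- data.frame(pt = as.integer(pt), freq = freq,
                    z_real = z_real, z_imag = z_imag)
  attr(out, "source") <- source
  attr(out, "circuit_id") <- circuit_id
  attr(out, "theta") <- theta
  class(out) <- c("eis_spectrum", "data.frame")
  out
}

#' @export
print.eis_spectrum <- function(x, ...) {
  cat("EIS spectrum: ", nrow(x), " points, ",
      format(min(x$freq), digits = 3), " - ",
      format(max(x$freq), digits = 3), " Hz (source: ",
      attr(x, "source"), ")\n", sep = "")
  if (!is.null(attr(x, "circuit_id")))
    cat("  ground truth: ", attr(x, "circuit_id"), "\n", sep = "")
  print(utils::head(as.data.frame(x), 4L))
  if (nrow(x) > 4L) cat("  ... ", nrow(x) - 4L, " more rows\n", sep = "")
  invisible(x)
}

# complex impedance vector
.spectrum_z <- function(sp) complex(real = sp$z_real, imaginary = sp$z_imag)

# recognized column-name dialects (case-insensitive, punctuation stripped)
.spectrum_dialects <- list(
  pt     = c("pt", "index", "idx", "point"),
  freq   = c("freq", "frequency", "freqhz", "f", "hz"),
  z_real = c("zreal", "zre", "realz", "zr", "re", "real"),
  z_imag = c("zimag", "zim", "imagz", "zi", "im", "imag", "imaginary")
)

#' Read / write an impedance spectrum as long-format CSV
#'
#' The canonical file layout has one row per frequency point with a header
#' and columns `Pt`, `Freq`, `Z_real`, `Z_imag`. Common header synonyms
#' (`Zre`/`Zim`, `frequency`, ...) are mapped case-insensitively after
#' stripping punctuation; the `Pt` column is optional.
#'
#' @param path file path.
#' @return `read_spectrum` returns an [eis_spectrum]; `write_spectrum`
#'   invisibly returns `path`.
#' @export
read_spectrum <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  key <- tolower(gsub("[^[:alnum:]]", "", names(tab)))
  pick <- function(field) {
    hit <- which(key %in% .spectrum_dialects[[field]])
    if (length(hit) == 0L) NA_integer_ else hit[1L]
  }
  cols <- vapply(names(.spectrum_dialects), pick, integer(1))
  if (is.na(cols["freq"]) || is.na(cols["z_real"]) || is.na(cols["z_imag"]))
    stop("file ", path, " lacks required columns Freq/Z_real/Z_imag ",
         "(found: ", paste(names(tab), collapse = ", "), ")")
  pt <- if (is.na(cols["pt"])) seq_len(nrow(tab)) else tab[[cols["pt"]]]
  eis_spectrum(freq = tab[[cols["freq"]]], z_real = tab[[cols["z_real"]]],
               z_imag = tab[[cols["z_imag"]]], pt = pt,
               source = basename(path))
}

#' @rdname read_spectrum
#' @param spectrum an [eis_spectrum].
#' @export
write_spectrum <- function(spectrum, path) {
  out <- data.frame(Pt = spectrum$pt, Freq = spectrum$freq,
                    Z_real = spectrum$z_real, Z_imag = spectrum$z_imag)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Nyquist / Bode plot of one or two spectra
#'
#' @param x an [eis_spectrum] (observed).
#' @param fitted optional second spectrum overlaid as a line (a model fit).
#' @param which `"nyquist"`, `"bode"` or `"both"` (default: both, side by
#'   side).
#' @param ... passed to [graphics::plot].
#' @export
plot.eis_spectrum <- function(x, fitted = NULL,
                              which = c("both", "nyquist", "bode"), ...) {
  which <- match.arg(which)
  if (which == "both") {
    op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  }
  if (which %in% c("both", "nyquist")) {
    graphics::plot(x$z_real, -x$z_imag, xlab = "Z' (Ohm)",
                   ylab = "-Z'' (Ohm)", main = "Nyquist", asp = 1,
                   col = "steelblue", ...)
    if (!is.null(fitted))
      graphics::lines(fitted$z_real, -fitted$z_imag, col = "darkorange", lwd = 2)
  }
  if (which %in% c("both", "bode")) {
    mod <- Mod(.spectrum_z(x))
    graphics::plot(x$freq, mod, log = "xy", xlab = "f (Hz)",
                   ylab = "|Z| (Ohm)", main = "Bode", col = "steelblue", ...)
    if (!is.null(fitted))
      graphics::lines(fitted$freq, Mod(.spectrum_z(fitted)),
                      col = "darkorange", lwd = 2)
  }
  invisible(x)
}

#' Export Nyquist and Bode plot-ready tables for a fit
#'
#' @param fit an [eis_fit] object.
#' @return list with data frames `nyquist` (`freq`, `z_real`,
#'   `neg_z_imag`, observed/fitted series) and `bode` (`freq`, `mod_ohm`,
#'   `phase_deg`, series); phase in degrees.
#' @export
export_plot_data <- function(fit) {
  stopifnot(inherits(fit, "eis_fit"))
  obs <- fit$spectrum; mod <- fit$fitted_spectrum
  both <- rbind(
    data.frame(series = "observed", freq = obs$freq, z_real = obs$z_real,
               z_imag = obs$z_imag),
    data.frame(series = "fitted", freq = mod$freq, z_real = mod$z_real,
               z_imag = mod$z_imag))
  z <- complex(real = both$z_real, imaginary = both$z_imag)
  list(
    nyquist = data.frame(series = both$series, freq = both$freq,
                         z_real = both$z_real, neg_z_imag = -both$z_imag),
    bode = data.frame(series = both$series, freq = both$freq,
                      mod_ohm = Mod(z), phase_deg = Arg(z) * 180 / pi)
  )
}
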