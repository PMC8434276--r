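#' Write a pole table to a delimited file
#'
#' Plain tab-delimited table with a header and one pole per row, columns
#' `f_Hz`, `damping_per_s`, `residue_re`, `residue_im`.
#'
#' @param model an [mpm()] fit.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_poles <- function(model, path) {
  stopifnot(inherits(model, "mpm"))
  d <- data.frame(f_Hz = model$poles$f,
                  damping_per_s = model$poles$damping,
                  residue_re = Re(model$poles$residue),
                  residue_im = Im(model$poles$residue))
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pole table written by [write_poles()]
#'
#' @param path file path.
#' @param ts,n sampling interval (s) and sample count to attach, so the model
#'   can be reconstructed.
#' @param tol,L metadata to attach (informational).
#' @return an [mpm()] object (without stored samples; `fitted()` and
#'   `residuals()` are unavailable, [reconstruct()] works).
#' @export
read_poles <- function(path, ts, n, tol = NA_real_, L = NA_integer_) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  s <- complex(real = d$damping_per_s, imaginary = 2 * pi * d$f_Hz)
  poles <- data.frame(f = d$f_Hz, damping = d$damping_per_s)
  poles$residue <- complex(real = d$residue_re, imaginary = d$residue_im)
  poles$z <- exp(s * ts)
  poles$conj <- conj_partners(poles$z)
  structure(list(poles = poles, Ts = ts, N = as.integer(n), t0 = 0,
                 tol = tol, L = L, y = rep(NA_real_, n)),
            class = "mpm")
}

#' Read a two-column I/Q table
#'
#' @param path delimited file with two numeric columns (I, Q); a header line
#'   is auto-detected.
#' @param fs sampling rate in Hz.
#' @param carrier_ghz carrier frequency in GHz (default 24.17).
#' @return an [iq_record()].
#' @export
read_iq <- function(path, fs, carrier_ghz = 24.17) {
  first <- readLines(path, n = 1)
  header <- is.na(suppressWarnings(as.numeric(strsplit(trimws(first), "[,\t ]+")[[1]][1])))
  d <- utils::read.table(path, header = header)
  iq_record(d[[1]], d[[2]], fs = fs, wavelength = carrier_wavelength(carrier_ghz))
}

#' Write a one-column signal table with metadata comment lines
#'
#' @param y a [sampled_signal()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(y, path) {
  stopifnot(inherits(y, "sampled_signal"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# ts %.12g", y$ts), sprintf("# t0 %.12g", y$t0),
               "value"), con)
  writeLines(format(y$samples, digits = 12, trim = TRUE, scientific = TRUE), con)
  invisible(path)
}

#' Read a signal table written by [write_signal()]
#'
#' @param path file path.
#' @return a [sampled_signal()].
#' @export
read_signal <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  ts <- as.numeric(sub("^# ts ", "", grep("^# ts ", meta, value = TRUE)[1]))
  t0 <- as.numeric(sub("^# t0 ", "", grep("^# t0 ", meta, value = TRUE)[1]))
  body <- lines[!grepl("^#", lines)][-1]
  sampled_signal(as.numeric(body), ts = ts, t0 = if (is.na(t0)) 0 else t0)
}
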