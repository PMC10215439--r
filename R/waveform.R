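#' Periodic inflow waveform as a truncated Fourier series
#'
#' Container for a pulsatile inlet waveform
#' \eqn{v(t) = a_0 + \sum_k a_k \cos(2\pi k t/T) + b_k \sin(2\pi k t/T)}.
#'
#' @param period cycle period T (s), positive.
#' @param a0 mean (DC) coefficient.
#' @param a cosine coefficients, one per harmonic (may be length 0).
#' @param b sine coefficients, same length as `a`.
#' @param unit physical unit tag, e.g. `"m/s"` or `"L/min"`.
#' @return object of class `waveform`.
#' @export
waveform <- function(period, a0, a = numeric(0), b = numeric(0), unit = "m/s") {
  if (!(is.numeric(period) && length(period) == 1L && period > 0)) {
    stop("period must be a positive scalar")
  }
  if (length(a) != length(b)) stop("a and b must have equal length")
  structure(list(period = period, a0 = as.numeric(a0),
                 a = as.numeric(a), b = as.numeric(b), unit = unit),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("waveform: T = %g s, %d harmonics, mean = %g %s\n",
              x$period, length(x$a), x$a0, x$unit))
  invisible(x)
}

fourier_design <- function(t, period, K) {
  X <- matrix(1, length(t), 1L + 2L * K)
  if (K > 0) {
    for (k in seq_len(K)) {
      w <- 2 * pi * k * t / period
      X[, 2L * k] <- cos(w)
      X[, 2L * k + 1L] <- sin(w)
    }
  }
  X
}

#' Fit a Fourier-series waveform to sampled data
#'
#' Least-squares fit of a K-harmonic Fourier series on a design matrix, so
#' non-uniform sampling is supported. The fit is exact (to machine precision)
#' when the signal is itself a band-limited series of order at most K sampled
#' at more than 2K+1 distinct points.
#'
#' @param time sample times (s), strictly increasing, within one period.
#' @param value sampled values.
#' @param K number of harmonics to fit.
#' @param period cycle period T (s); default `max(time)` rounded up is NOT
#'   assumed — the period must be given explicitly.
#' @param unit physical unit tag stored with the result.
#' @return a [waveform()] with attribute `rms_error`, the root-mean-square
#'   residual of the reconstruction at the sample times.
#' @export
fit_waveform <- function(time, value, K, period, unit = "m/s") {
  time <- as.numeric(time); value <- as.numeric(value)
  if (length(time) != length(value)) stop("time and value lengths differ")
  if (any(diff(time) <= 0)) stop("sample times must be strictly increasing")
  if (any(time < 0 | time >= period)) stop("sample times must lie in [0, period)")
  K <- as.integer(K)
  if (K < 0) stop("K must be >= 0")
  if (length(time) < 2L * K + 1L) {
    stop("need at least 2K+1 = ", 2L * K + 1L, " samples for K = ", K, " harmonics")
  }
  X <- fourier_design(time, period, K)
  coef <- qr.coef(qr(X), value)
  coef[is.na(coef)] <- 0
  w <- waveform(period, coef[1L],
                a = if (K > 0) coef[2L * seq_len(K)] else numeric(0),
                b = if (K > 0) coef[2L * seq_len(K) + 1L] else numeric(0),
                unit = unit)
  attr(w, "rms_error") <- sqrt(mean((X %*% coef - value)^2))
  w
}

#' Evaluate a waveform
#'
#' Exactly T-periodic: `t` is used through `cos`/`sin` of `2*pi*k*t/T`, so any
#' real `t` is admissible.
#'
#' @param w a [waveform()].
#' @param t time(s) in seconds.
#' @return waveform value(s) at `t`.
#' @export
evaluate_waveform <- function(w, t) {
  stopifnot(inherits(w, "waveform"))
  t <- as.numeric(t)
  out <- rep(w$a0, length(t))
  for (k in seq_along(w$a)) {
    ph <- 2 * pi * k * t / w$period
    out <- out + w$a[k] * cos(ph) + w$b[k] * sin(ph)
  }
  out
}

#' Read / write waveform sample CSV
#'
#' Two-column CSV `time_s,value`; the period is stored in a `# period_s=`
#' comment on the first line, as is the unit (`# unit=`).
#'
#' @param w a [waveform()]; written as samples at `n` uniform times.
#' @param path file path.
#' @param n number of uniform samples per period to write.
#' @return `read_waveform_csv` returns a list with `time`, `value`,
#'   `period`, `unit`; `write_waveform_csv` returns `path` invisibly.
#' @export
write_waveform_csv <- function(w, path, n = 128L) {
  t <- seq(0, w$period, length.out = n + 1L)[seq_len(n)]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# period_s=%.17g unit=%s", w$period, w$unit), con)
  writeLines("time_s,value", con)
  writeLines(sprintf("%.17g,%.17g", t, evaluate_waveform(w, t)), con)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path) {
  header <- readLines(path, n = 1L)
  period <- NA_real_; unit <- "m/s"
  if (grepl("^#", header)) {
    m <- regmatches(header, regexec("period_s=([0-9.eE+-]+)", header))[[1L]]
    if (length(m) == 2L) period <- as.numeric(m[2L])
    m <- regmatches(header, regexec("unit=(\\S+)", header))[[1L]]
    if (length(m) == 2L) unit <- m[2L]
  }
  df <- utils::read.csv(path, comment.char = "#")
  list(time = df$time_s, value = df$value, period = period, unit = unit)
}

#' Serialize waveform coefficients to JSON
#'
#' @param w a [waveform()].
#' @param path file path; for `waveform_from_json`, a path to a file written
#'   by `waveform_to_json`.
#' @return `waveform_from_json` returns the reconstructed [waveform()].
#' @export
waveform_to_json <- function(w, path) {
  jsonlite::write_json(list(period = w$period, a0 = w$a0, a = w$a, b = w$b,
                            unit = w$unit),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname waveform_to_json
#' @export
waveform_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  waveform(x$period, x$a0, x$a, x$b, x$unit)
}
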