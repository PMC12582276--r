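#' @keywords internal
"_PACKAGE"

## Classed conditions -------------------------------------------------------

ca_stop <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "chromaccess_error")))
}

param_error <- function(msg, ...) ca_stop(msg, "chromaccess_param_error", ...)

format_error <- function(msg, line = NA_integer_, path = NULL) {
  where <- if (!is.na(line)) sprintf(" (line %d)", line) else ""
  pre <- if (!is.null(path)) sprintf("%s: ", path) else ""
  ca_stop(paste0(pre, msg, where), "chromaccess_format_error",
          line = line, path = path)
}

insufficient_data_error <- function(msg, n) {
  ca_stop(msg, "chromaccess_insufficient_data", n = n)
}

check_number <- function(x, name, min = -Inf, max = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    param_error(sprintf("`%s` must be a single finite number", name))
  if (integer && x != round(x))
    param_error(sprintf("`%s` must be an integer", name))
  if (x < min || x > max)
    param_error(sprintf("`%s` must be in [%s, %s]", name,
                        format(min), format(max)))
  invisible(x)
}

## Mass-preserving Gaussian smoothing ---------------------------------------

# Smooths `y` on a uniform grid (spacing `bin`) with a Gaussian kernel of
# bandwidth `bw` (sd, same units as the grid). Near the boundaries the
# kernel is renormalized over its in-domain support (so a flat input stays
# exactly flat), and the result is rescaled so sum(output) == sum(input)
# to machine precision.
smooth_mass <- function(y, bw, bin = 1) {
  n <- length(y)
  if (bw <= 0 || n < 2L) return(y)
  r <- ceiling(4 * bw / bin)
  k <- stats::dnorm((-r:r) * bin, 0, bw)
  k <- k / sum(k)
  conv_same <- function(x) {
    full <- stats::convolve(x, rev(k), type = "open")
    full[(r + 1L):(r + n)]
  }
  cover <- conv_same(rep(1, n))   # in-domain kernel mass per output bin
  out <- conv_same(y) / cover
  s <- sum(out)
  if (s > 0) out <- out * (sum(y) / s)
  out
}
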