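#' Parameters for the nucleosome-ladder fragment-length generator
#'
#' Describes one stratum's fragment-length mixture: a ladder of Gaussian
#' peaks at the mono/di/tri-nucleosomal lengths plus a sub-nucleosomal
#' exponential background. Ladder peak k (k = 1..`n_orders`) is centred at
#' `core_bp + (k - 1) * period_bp`, so a regression of peak centre on order
#' recovers `period_bp` exactly; peak weights decay geometrically by
#' `order_decay`.
#'
#' @param period_bp Dyad-to-dyad spacing in bp (the true NRL). Must be
#'   at least `core_bp`.
#' @param core_bp Protected nucleosome-core length in bp; default 147, the
#'   canonical length of DNA wrapped around the histone octamer.
#' @param n_orders Number of ladder peaks (1 = mono-nucleosomal only).
#' @param peak_sd_bp Gaussian spread of each ladder peak in bp.
#' @param order_decay Geometric weight ratio between successive orders,
#'   in (0, 1].
#' @param periodic_fraction Fraction of fragments drawn from the ladder
#'   (the rest come from the sub-nucleosomal background), in \[0, 1\].
#' @param background_scale_bp Scale of the exponential short-fragment
#'   background, truncated below at 1 bp.
#' @param n_fragments Number of fragment lengths to draw.
#' @param seed Integer seed; generation is fully reproducible given it.
#' @return An object of class `fragment_sim_params`.
#' @seealso [simulate_fragment_lengths()]
#' @export
fragment_sim_params <- function(period_bp = 190, core_bp = 147, n_orders = 3,
                                peak_sd_bp = 15, order_decay = 0.5,
                                periodic_fraction = 0.6,
                                background_scale_bp = 60,
                                n_fragments = 100000L, seed = 1L) {
  check_number(core_bp, "core_bp", min = 1)
  check_number(period_bp, "period_bp", min = core_bp)
  check_number(n_orders, "n_orders", min = 1, integer = TRUE)
  check_number(peak_sd_bp, "peak_sd_bp", min = 0)
  check_number(order_decay, "order_decay", min = 1e-12, max = 1)
  check_number(periodic_fraction, "periodic_fraction", min = 0, max = 1)
  check_number(background_scale_bp, "background_scale_bp", min = 1e-12)
  check_number(n_fragments, "n_fragments", min = 1, integer = TRUE)
  check_number(seed, "seed", integer = TRUE)
  structure(list(period_bp = period_bp, core_bp = core_bp,
                 n_orders = as.integer(n_orders), peak_sd_bp = peak_sd_bp,
                 order_decay = order_decay,
                 periodic_fraction = periodic_fraction,
                 background_scale_bp = background_scale_bp,
                 n_fragments = as.integer(n_fragments),
                 seed = as.integer(seed)),
            class = "fragment_sim_params")
}

# Draws n lengths using the current RNG state (no seeding); lets composite
# simulators share one seeded stream.
sample_lengths <- function(params, n) {
  if (n == 0L) return(numeric(0))
  ladder <- stats::runif(n) < params$periodic_fraction
  n_lad <- sum(ladder)
  len <- numeric(n)
  if (n_lad > 0L) {
    w <- params$order_decay^(seq_len(params$n_orders) - 1)
    k <- sample.int(params$n_orders, n_lad, replace = TRUE, prob = w)
    centre <- params$core_bp + (k - 1) * params$period_bp
    len[ladder] <- stats::rnorm(n_lad, centre, params$peak_sd_bp)
  }
  if (n_lad < n) {
    # exponential truncated below at 1 bp (memoryless: 1 + Exp(scale))
    len[!ladder] <- 1 + stats::rexp(n - n_lad, rate = 1 / params$background_scale_bp)
  }
  pmax(len, 1)
}

#' Simulate ATAC-style fragment lengths with nucleosome-ladder structure
#'
#' Draws `params$n_fragments` fragment lengths from the mixture described by
#' [fragment_sim_params()]: with probability `periodic_fraction` from a
#' Gaussian ladder peak (order chosen with geometrically decaying weights),
#' otherwise from an exponential sub-nucleosomal background truncated below
#' at 1 bp. All returned lengths are >= 1.
#'
#' @param params A [fragment_sim_params()] object.
#' @return Numeric vector of fragment lengths in bp.
#' @examples
#' p <- fragment_sim_params(period_bp = 190, n_fragments = 1000, seed = 7)
#' len <- simulate_fragment_lengths(p)
#' range(len)
#' @export
simulate_fragment_lengths <- function(params) {
  if (!inherits(params, "fragment_sim_params"))
    param_error("`params` must be created by fragment_sim_params()")
  withr::with_seed(params$seed, sample_lengths(params, params$n_fragments))
}
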