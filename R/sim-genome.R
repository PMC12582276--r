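#' Specification of one simulated chromatin state
#'
#' Bundles the fragment-length parameters for both conditions with the
#' state's target sequence GC and its share of the simulated genome.
#'
#' @param state_label State name (e.g. `"E1"`).
#' @param wt_params,tx_params [fragment_sim_params()] for the untreated (WT)
#'   and treated conditions.
#' @param gc_fraction Target GC fraction of this state's sequence, in \[0, 1\].
#' @param genome_share Fraction of the simulated genome assigned to this
#'   state; shares across states must sum to 1.
#' @return An object of class `state_sim_spec`.
#' @export
state_sim_spec <- function(state_label, wt_params, tx_params,
                           gc_fraction = 0.45, genome_share = 1) {
  if (!is.character(state_label) || length(state_label) != 1L || !nzchar(state_label))
    param_error("`state_label` must be a nonempty string")
  for (p in list(wt_params, tx_params))
    if (!inherits(p, "fragment_sim_params"))
      param_error("`wt_params`/`tx_params` must be fragment_sim_params objects")
  check_number(gc_fraction, "gc_fraction", min = 0, max = 1)
  check_number(genome_share, "genome_share", min = 1e-12, max = 1)
  structure(list(state_label = state_label, wt_params = wt_params,
                 tx_params = tx_params, gc_fraction = gc_fraction,
                 genome_share = genome_share),
            class = "state_sim_spec")
}

# Deterministic-GC random sequence: exactly round(gc * n) G/C bases,
# positions and purine/pyrimidine identity randomized.
random_sequence <- function(n, gc) {
  n_gc <- round(gc * n)
  bases <- c(sample(c("G", "C"), n_gc, replace = TRUE),
             sample(c("A", "T"), n - n_gc, replace = TRUE))
  paste(sample(bases), collapse = "")
}

#' Reweight per-state read fractions by an exponential GC bias
#'
#' Models condition-specific under-representation of low-GC chromatin:
#' the new fraction is proportional to
#' `old * exp(slope * (gc - mean(gc)))`, renormalized to sum 1. A positive
#' slope over-samples high-GC states; `slope = 0` is the identity; negating
#' the slope inverts the ordering.
#'
#' @param state_fractions Named numeric vector of per-state fractions
#'   summing to 1.
#' @param gc_by_state Named numeric vector of per-state GC fractions
#'   (same names).
#' @param slope Dimensionless bias slope.
#' @return Named numeric vector of reweighted fractions summing to 1.
#' @examples
#' apply_gc_bias(c(a = 0.5, b = 0.5), c(a = 0.4, b = 0.6), slope = 2)
#' @export
apply_gc_bias <- function(state_fractions, gc_by_state, slope) {
  if (length(state_fractions) == 0L)
    param_error("`state_fractions` must be nonempty")
  if (abs(sum(state_fractions) - 1) > 1e-6)
    param_error("`state_fractions` must sum to 1")
  if (any(gc_by_state < 0 | gc_by_state > 1))
    param_error("`gc_by_state` values must be in [0, 1]")
  if (is.null(names(state_fractions)) || is.null(names(gc_by_state)))
    param_error("fractions and GC values must be named by state")
  gc <- gc_by_state[names(state_fractions)]
  if (anyNA(gc)) param_error("`gc_by_state` is missing some states")
  check_number(slope, "slope")
  w <- state_fractions * exp(slope * (gc - mean(gc)))
  w / sum(w)
}

#' Simulate a full stratified dataset: genome, state map, and fragments
#'
#' Tiles a single chromosome with contiguous non-overlapping state blocks in
#' proportion to each state's `genome_share`, draws each block's sequence at
#' its target GC (exact to rounding), and places fragments uniformly within
#' their state's block with lengths from the state's condition-specific
#' ladder mixture. Per-state fragment counts are multinomial with
#' probabilities proportional to `genome_share`, optionally reweighted by
#' [apply_gc_bias()] per condition.
#'
#' @param specs List of [state_sim_spec()] objects; `genome_share`s must sum
#'   to 1 and every block must be at least 1 kb.
#' @param chrom_length Chromosome length in bp.
#' @param n_fragments Fragments per condition.
#' @param seed Integer seed.
#' @param chrom Chromosome name.
#' @param conditions Length-2 character vector naming the WT and treated
#'   conditions, in that order.
#' @param bias_slope Named numeric vector giving the GC-bias slope applied
#'   to each condition's state sampling weights (default 0 for both).
#' @return A list with components `genome` (named character vector,
#'   chrom -> sequence), `states` (BED4-style data frame: chrom, start, end,
#'   state), and `fragments` (named list per condition of data frames with
#'   chrom, start, end, state; the state column is generator ground truth).
#' @export
simulate_state_dataset <- function(specs, chrom_length, n_fragments = 100000L,
                                   seed = 1L, chrom = "chrS",
                                   conditions = c("WT", "iH1.0"),
                                   bias_slope = c(0, 0)) {
  if (length(specs) == 0L) param_error("`specs` must be nonempty")
  if (inherits(specs, "state_sim_spec")) specs <- list(specs)
  shares <- vapply(specs, function(s) s$genome_share, numeric(1))
  labels <- vapply(specs, function(s) s$state_label, character(1))
  if (abs(sum(shares) - 1) > 1e-9)
    param_error("state genome_share values must sum to 1")
  if (anyDuplicated(labels)) param_error("duplicate state labels")
  check_number(chrom_length, "chrom_length", min = 1000 * length(specs),
               integer = TRUE)
  if (length(conditions) != 2L) param_error("`conditions` must have length 2")
  if (is.null(names(bias_slope))) names(bias_slope) <- conditions
  bias_slope <- bias_slope[conditions]
  bias_slope[is.na(bias_slope)] <- 0

  widths <- floor(shares * chrom_length)
  widths[length(widths)] <- chrom_length - sum(widths[-length(widths)])
  if (any(widths < 1000))
    param_error("every state block must be at least 1 kb; increase chrom_length")
  starts <- cumsum(c(0, widths[-length(widths)]))
  ends <- starts + widths
  states <- data.frame(chrom = chrom, start = starts, end = ends,
                       state = labels, stringsAsFactors = FALSE)

  withr::with_seed(seed, {
    genome_seq <- paste(mapply(random_sequence, widths,
                               vapply(specs, function(s) s$gc_fraction,
                                      numeric(1))),
                        collapse = "")
    gc_by_state <- stats::setNames(
      vapply(specs, function(s) s$gc_fraction, numeric(1)), labels)
    base_frac <- stats::setNames(shares / sum(shares), labels)

    fragments <- lapply(seq_along(conditions), function(ci) {
      cond <- conditions[ci]
      frac <- apply_gc_bias(base_frac, gc_by_state, bias_slope[[cond]])
      n_per_state <- as.vector(stats::rmultinom(1, n_fragments, frac))
      out <- vector("list", length(specs))
      for (si in seq_along(specs)) {
        n_s <- n_per_state[si]
        if (n_s == 0L) next
        p <- if (ci == 1L) specs[[si]]$wt_params else specs[[si]]$tx_params
        len <- pmax(1L, as.integer(round(sample_lengths(p, n_s))))
        len <- pmin(len, widths[si])
        start <- starts[si] +
          floor(stats::runif(n_s) * (widths[si] - len + 1))
        out[[si]] <- data.frame(chrom = chrom, start = start,
                                end = start + len, state = labels[si],
                                stringsAsFactors = FALSE)
      }
      do.call(rbind, out)
    })
    names(fragments) <- conditions
    list(genome = stats::setNames(genome_seq, chrom), states = states,
         fragments = fragments)
  })
}
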