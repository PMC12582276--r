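# Shared fixture builders; everything is generated in code.

# A periodicity_profile with prescribed strength/NRL, for typing tests.
make_profile <- function(state, condition, strength, nrl = NA_real_,
                         n = 50000L) {
  structure(list(state = state, condition = condition, n_fragments = n,
                 nrl_bp = nrl, nrl_stderr_bp = NA_real_,
                 strength = strength, peak_centers = numeric(0),
                 peak_orders = integer(0), config = nrl_config()),
            class = "periodicity_profile")
}

# Run the full fragment-length pipeline and return the NRL estimate.
pipeline_nrl <- function(lengths, config = nrl_config()) {
  d <- length_density(lengths, bin_bp = config$bin_bp,
                      smooth_bw_bp = config$smooth_bw_bp,
                      range = config$range,
                      min_fragments = config$min_fragments)
  o <- detrend_density(d, config$trend_bw_bp)
  estimate_nrl(detect_ladder_peaks(o, min_len_bp = config$min_len_bp,
                                   max_orders = config$max_orders))$nrl_bp
}

# Run the full pipeline and return the repeat-strength score.
pipeline_strength <- function(lengths) {
  repeat_strength(detrend_density(length_density(lengths)))
}

# A small two-transcript gene model in read_bed12() shape.
toy_gene_model <- function() {
  data.frame(
    chrom = c("chr1", "chr1"),
    start = c(10000L, 50000L),
    end = c(16000L, 56000L),
    name = c("plusGene", "minusGene"),
    strand = c("+", "-"),
    thick_start = c(12800L, 50500L),
    thick_end = c(15200L, 53200L),
    block_sizes = I(list(c(1000L, 1000L, 1000L), c(1000L, 1000L, 1000L))),
    block_starts = I(list(c(0L, 2500L, 5000L), c(0L, 2500L, 5000L))),
    stringsAsFactors = FALSE)
}
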