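## Per-state GC content and the regression of between-condition read
## representation on GC (bedtools-nuc-style GC over a state's intervals,
## fragment midpoint assignment, log2 representation ratios).

#' Pooled GC content of a set of genomic intervals
#'
#' Computes (G+C) / (A+C+G+T) pooled over all intervals. Ambiguity codes
#' (N etc.) are excluded from both numerator and denominator; soft-masked
#' lowercase bases count like uppercase.
#'
#' @param genome Named character vector (chrom -> sequence) as returned by
#'   [read_fasta()], or a `Biostrings::DNAStringSet`.
#' @param intervals Data frame of intervals (`chrom`, `start`, `end`,
#'   0-based half-open).
#' @return GC fraction in \[0, 1\].
#' @export
gc_content <- function(genome, intervals) {
  if (!methods::is(genome, "DNAStringSet")) {
    if (is.null(names(genome))) param_error("`genome` must be named")
    genome <- Biostrings::DNAStringSet(unlist(genome))
  }
  if (nrow(intervals) == 0L) param_error("`intervals` must be nonempty")
  missing_chrom <- setdiff(unique(intervals$chrom), names(genome))
  if (length(missing_chrom))
    ca_stop(sprintf("chromosome '%s' not in genome", missing_chrom[1]),
            "chromaccess_bounds_error")
  tot <- c(A = 0, C = 0, G = 0, T = 0)
  for (ch in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    seq_len_ch <- Biostrings::width(genome[ch])
    if (any(iv$end > seq_len_ch) || any(iv$start < 0))
      ca_stop(sprintf("interval beyond sequence bounds on '%s'", ch),
              "chromaccess_bounds_error")
    sub <- Biostrings::extractAt(
      genome[[ch]], IRanges::IRanges(start = iv$start + 1L, end = iv$end))
    tot <- tot + colSums(Biostrings::letterFrequency(sub, c("A", "C", "G", "T")))
  }
  denom <- sum(tot)
  if (denom == 0)
    ca_stop("no unambiguous bases in intervals (all N?)",
            "chromaccess_undefined_content")
  unname((tot[["G"]] + tot[["C"]]) / denom)
}

# Midpoint-based fragment -> state assignment. States must not overlap.
# Returns the state label per fragment, NA where the midpoint lies in no
# state.
assign_states <- function(fragments, states) {
  label_col <- intersect(c("state", "label", "name"), names(states))
  if (length(label_col) == 0L)
    param_error("`states` needs a state/label column")
  st <- GenomicRanges::GRanges(
    states$chrom,
    IRanges::IRanges(start = states$start + 1L, end = states$end))
  hits_self <- GenomicRanges::findOverlaps(st, st)
  if (length(hits_self) > length(st))
    ca_stop("chromatin-state intervals overlap",
            "chromaccess_annotation_conflict")
  mid <- fragments$start + (fragments$end - fragments$start) %/% 2L
  fr <- GenomicRanges::GRanges(fragments$chrom,
                               IRanges::IRanges(start = mid + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(fr, st, select = "first")
  states[[label_col[1]]][hits]
}

#' Per-state read percentages for each condition
#'
#' Assigns every fragment to the chromatin state containing its midpoint;
#' fragments whose midpoint falls in no state go to an `"unannotated"`
#' bucket that is excluded from the normalization, so the reported
#' percentages sum to 100 within each condition.
#'
#' @param fragments_by_condition Named list (condition -> fragment data
#'   frame with `chrom`, `start`, `end`).
#' @param states State map data frame (`chrom`, `start`, `end`,
#'   `state`/`label`); intervals must not overlap.
#' @return Data frame with `state`, `condition`, `n_fragments`, `pct`, plus
#'   an attribute `unannotated` giving excluded fragment counts per
#'   condition.
#' @export
state_read_fractions <- function(fragments_by_condition, states) {
  if (is.null(names(fragments_by_condition)))
    param_error("`fragments_by_condition` must be a named list")
  label_col <- intersect(c("state", "label", "name"), names(states))[1]
  state_levels <- unique(states[[label_col]])
  out <- list(); unann <- c()
  for (cond in names(fragments_by_condition)) {
    lab <- assign_states(fragments_by_condition[[cond]], states)
    unann[cond] <- sum(is.na(lab))
    counts <- table(factor(lab, levels = state_levels))
    n_in <- sum(counts)
    out[[cond]] <- data.frame(state = state_levels, condition = cond,
                              n_fragments = as.integer(counts),
                              pct = if (n_in > 0) 100 * as.numeric(counts) / n_in
                                    else NA_real_,
                              stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "unannotated") <- unann
  res
}

#' Build the per-state representation table (GC vs. read share)
#'
#' Joins per-state GC content with the two conditions' read percentages and
#' the log2 representation ratio (treated over WT). States with zero reads
#' in either condition get a non-finite ratio and are dropped (with a
#' warning) by [representation_regression()].
#'
#' @param fragments_by_condition Named list of fragment data frames; the
#'   first element is taken as WT unless `wt_condition` says otherwise.
#' @param states State map data frame.
#' @param genome Genome sequences (see [gc_content()]).
#' @param wt_condition Label of the untreated condition.
#' @return Data frame with `state`, `gc_fraction`, `wt_read_pct`,
#'   `tx_read_pct`, `log2_ratio`.
#' @export
state_representation <- function(fragments_by_condition, states, genome,
                                 wt_condition = "WT") {
  fr <- state_read_fractions(fragments_by_condition, states)
  conds <- unique(fr$condition)
  if (length(conds) != 2L || !(wt_condition %in% conds))
    param_error("need exactly two conditions including the WT label")
  tx_condition <- setdiff(conds, wt_condition)
  label_col <- intersect(c("state", "label", "name"), names(states))[1]
  st_levels <- unique(states[[label_col]])
  gc <- vapply(st_levels, function(s)
    gc_content(genome, states[states[[label_col]] == s, , drop = FALSE]),
    numeric(1))
  wt <- fr[fr$condition == wt_condition, ]
  tx <- fr[fr$condition == tx_condition, ]
  wt <- wt[match(st_levels, wt$state), ]
  tx <- tx[match(st_levels, tx$state), ]
  data.frame(state = st_levels, gc_fraction = unname(gc),
             wt_read_pct = wt$pct, tx_read_pct = tx$pct,
             log2_ratio = log2(tx$pct / wt$pct),
             stringsAsFactors = FALSE)
}

#' Regression of representation log-ratio on state GC content
#'
#' Ordinary least squares of `log2_ratio` on `gc_fraction` across chromatin
#' states. A positive slope means low-GC states are under-represented in
#' the treated condition relative to WT.
#'
#' @param reps Data frame from [state_representation()] (needs
#'   `gc_fraction` and `log2_ratio`).
#' @return List with `slope`, `intercept`, `r_squared`, `p_value`
#'   (two-sided, slope = 0) and `n_points`.
#' @export
representation_regression <- function(reps) {
  ok <- is.finite(reps$log2_ratio) & is.finite(reps$gc_fraction)
  if (any(!ok))
    warning(sprintf("dropping %d state(s) with non-finite log2 ratio",
                    sum(!ok)))
  reps <- reps[ok, , drop = FALSE]
  if (nrow(reps) < 3L)
    insufficient_data_error(
      sprintf("need >= 3 states with finite log2 ratio, have %d", nrow(reps)),
      n = nrow(reps))
  fit <- stats::lm(log2_ratio ~ gc_fraction, data = reps)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[["gc_fraction"]]),
       intercept = unname(stats::coef(fit)[["(Intercept)"]]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients["gc_fraction", "Pr(>|t|)"],
       n_points = nrow(reps))
}
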