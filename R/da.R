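## Differential accessibility between two conditions on a peak count table:
## median-of-ratios normalization, per-peak testing on log2 normalized
## counts (empirical-Bayes moderated t by default, plain Welch t as an
## alternative), the two-tier raw-P/fold-change cutoffs, significance/effect
## ranking, and genomic feature annotation.

#' Median-of-ratios count normalization
#'
#' Size factors are the per-sample median of count ratios to the per-peak
#' geometric-mean reference, computed over peaks with all-positive counts.
#' When no such peak exists, falls back to total-count scaling (factors
#' proportional to column sums, geometric mean 1) with a warning.
#'
#' @param table A [peak_count_table()].
#' @return List with `normalized` (matrix, raw counts divided by size
#'   factor) and `size_factors` (named vector).
#' @export
normalize_counts <- function(table) {
  stopifnot(inherits(table, "peak_count_table"))
  counts <- table$counts
  if (any(colSums(counts) == 0))
    param_error("every sample must have total count > 0")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    warning("no peak with all-positive counts; falling back to total-count scaling")
    sf <- colSums(counts)
    sf <- sf / exp(mean(log(sf)))
  } else {
    logc <- log(counts[pos, , drop = FALSE])
    ref <- rowMeans(logc)                 # log geometric mean per peak
    sf <- apply(exp(logc - ref), 2, stats::median)
  }
  list(normalized = sweep(counts, 2, sf, "/"),
       size_factors = stats::setNames(sf, colnames(counts)))
}

welch_log_test <- function(logm, is_wt, is_tx) {
  n1 <- sum(is_wt); n2 <- sum(is_tx)
  m1 <- rowMeans(logm[, is_wt, drop = FALSE])
  m2 <- rowMeans(logm[, is_tx, drop = FALSE])
  v1 <- apply(logm[, is_wt, drop = FALSE], 1, stats::var)
  v2 <- apply(logm[, is_tx, drop = FALSE], 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  # degenerate zero-variance rows: identical values -> p = 1, else p -> 0
  zero <- se2 == 0
  p[zero] <- ifelse(m2[zero] == m1[zero], 1, 0)
  p
}

#' Per-peak Welch t test on log-scale normalized counts
#'
#' The plain two-sample test used by `method = "welch"` of [da_test()]:
#' two-sided Welch t on `log2(normalized + pseudo)` across replicates,
#' with the fold change taken as the ratio of pseudo-counted condition
#' means. A peak with all-zero counts in both conditions returns
#' `(log2_fc = 0, p_value = 1)`.
#'
#' @param normalized Numeric vector of normalized counts for one peak,
#'   named by sample.
#' @param condition_of Named character vector mapping sample -> condition.
#' @param wt_condition Baseline condition label.
#' @param pseudo Pseudo-count added before log and ratio (default 0.5).
#' @return List with `log2_fc` (treated over WT) and `p_value`.
#' @export
test_peak <- function(normalized, condition_of, wt_condition = "WT",
                      pseudo = 0.5) {
  if (is.null(names(normalized)))
    normalized <- stats::setNames(normalized, names(condition_of))
  condition_of <- condition_of[names(normalized)]
  is_wt <- condition_of == wt_condition
  is_tx <- !is_wt
  if (sum(is_wt) < 2L || sum(is_tx) < 2L)
    param_error("need >= 2 replicates per condition")
  lfc <- log2((mean(normalized[is_tx]) + pseudo) /
                (mean(normalized[is_wt]) + pseudo))
  if (all(normalized == 0)) return(list(log2_fc = 0, p_value = 1))
  logm <- matrix(log2(normalized + pseudo), nrow = 1)
  list(log2_fc = lfc,
       p_value = welch_log_test(logm, is_wt, is_tx)[1])
}

#' Differential accessibility test across all peaks
#'
#' Normalizes the count table by median-of-ratios, then tests each peak's
#' `log2(normalized + pseudo)` values between conditions. The default
#' `"moderated"` method fits a per-peak linear model and applies
#' empirical-Bayes variance moderation with a mean-variance trend
#' (limma), which keeps small-replicate p-values calibrated while
#' borrowing variance information across peaks; `"welch"` is the plain
#' per-peak Welch t test. The reported `log2_fc` is always
#' `log2((mean_tx + pseudo) / (mean_wt + pseudo))` on normalized counts,
#' so the tier fold-change filters are identical across methods.
#'
#' @param table A [peak_count_table()].
#' @param wt_condition Baseline condition label.
#' @param method `"moderated"` (default) or `"welch"`.
#' @param pseudo Pseudo-count (default 0.5).
#' @return A `da_result` data frame: peak coordinates and name,
#'   `base_mean`, `log2_fc`, `p_value`, `p_adj` (Benjamini-Hochberg).
#' @export
da_test <- function(table, wt_condition = "WT",
                    method = c("moderated", "welch"), pseudo = 0.5) {
  stopifnot(inherits(table, "peak_count_table"))
  method <- match.arg(method)
  conds <- unique(table$condition_of)
  if (length(conds) != 2L || !(wt_condition %in% conds))
    param_error("need exactly two conditions including the WT label")
  if (any(table(table$condition_of) < 2L))
    param_error("need >= 2 replicates per condition")
  norm <- normalize_counts(table)$normalized
  is_wt <- table$condition_of == wt_condition
  is_tx <- !is_wt
  logm <- log2(norm + pseudo)
  lfc <- log2((rowMeans(norm[, is_tx, drop = FALSE]) + pseudo) /
                (rowMeans(norm[, is_wt, drop = FALSE]) + pseudo))
  if (method == "welch") {
    p <- welch_log_test(logm, is_wt, is_tx)
  } else {
    design <- cbind(intercept = 1, tx = as.numeric(is_tx))
    fit <- limma::eBayes(limma::lmFit(logm, design), trend = TRUE)
    p <- fit$p.value[, "tx"]
  }
  allzero <- rowSums(table$counts) == 0
  p[allzero] <- 1
  lfc[allzero] <- 0
  out <- data.frame(chrom = table$peaks$chrom, start = table$peaks$start,
                    end = table$peaks$end, name = table$peaks$name,
                    base_mean = rowMeans(norm), log2_fc = unname(lfc),
                    p_value = unname(p),
                    p_adj = stats::p.adjust(unname(p), method = "BH"),
                    stringsAsFactors = FALSE)
  class(out) <- c("da_result", class(out))
  out
}

#' Apply the two-tier significance/fold-change cutoffs
#'
#' Relaxed tier: `p < 0.01` and linear fold change > 2 (`|log2_fc| > 1`).
#' Stringent tier: `p < 0.001` and fold change > 4 (`|log2_fc| > 2`).
#' Every stringent peak also satisfies the relaxed cutoffs. Direction is
#' `"closed"` for negative and `"open"` for positive treated-vs-WT
#' log-fold changes. Raw p-values are used, matching the tier definitions.
#'
#' @param results A `da_result` data frame from [da_test()].
#' @param relaxed_p,relaxed_fc,stringent_p,stringent_fc Tier cutoffs
#'   (p-value and linear fold change).
#' @return `results` with `tier` (`"none"`, `"relaxed"`, `"stringent"`)
#'   and `direction` (`"open"`, `"closed"`, `"none"`) columns.
#' @export
apply_tiers <- function(results, relaxed_p = 0.01, relaxed_fc = 2,
                        stringent_p = 0.001, stringent_fc = 4) {
  afc <- abs(results$log2_fc)
  stringent <- results$p_value < stringent_p & afc > log2(stringent_fc)
  relaxed <- results$p_value < relaxed_p & afc > log2(relaxed_fc)
  results$tier <- ifelse(stringent, "stringent",
                         ifelse(relaxed, "relaxed", "none"))
  results$direction <- ifelse(results$log2_fc > 0, "open",
                              ifelse(results$log2_fc < 0, "closed", "none"))
  results
}

#' Rank results by statistical significance and effect size
#'
#' Primary key ascending p-value, secondary key descending absolute
#' log2 fold change, ties broken by genomic order; rank 1 is the strongest
#' call.
#'
#' @param results A `da_result` data frame (tiers applied or not).
#' @return `results` sorted with a `rank` column added.
#' @export
rank_results <- function(results) {
  ord <- order(results$p_value, -abs(results$log2_fc),
               results$chrom, results$start)
  results <- results[ord, , drop = FALSE]
  results$rank <- seq_len(nrow(results))
  rownames(results) <- NULL
  results
}

#' Tier summary table (counts by tier and direction)
#'
#' Stringent-tier peaks are included in the relaxed counts as well, since
#' the stringent cutoffs are a subset of the relaxed ones.
#'
#' @param results A tiered `da_result` data frame.
#' @return Data frame with `tier`, `direction`, `n`.
#' @export
tier_summary <- function(results) {
  rows <- expand.grid(tier = c("relaxed", "stringent"),
                      direction = c("open", "closed"),
                      stringsAsFactors = FALSE)
  rows$n <- mapply(function(tier, dir) {
    in_tier <- if (tier == "relaxed") results$tier %in% c("relaxed", "stringent")
               else results$tier == "stringent"
    sum(in_tier & results$direction == dir)
  }, rows$tier, rows$direction)
  rows
}

feature_levels <- c("promoter", "5'UTR", "3'UTR", "exon", "intron", "distal")

point_feature <- function(mid, gene, promoter_bp) {
  tss <- if (gene$strand == "+") gene$start else gene$end - 1L
  hits <- character(0)
  if (abs(mid - tss) <= promoter_bp) hits <- c(hits, "promoter")
  if (mid >= gene$start && mid < gene$end) {
    ex_start <- gene$start + gene$block_starts[[1]]
    ex_end <- ex_start + gene$block_sizes[[1]]
    in_exon <- any(mid >= ex_start & mid < ex_end)
    if (!in_exon) {
      hits <- c(hits, "intron")
    } else if (gene$thick_start >= gene$thick_end) {
      hits <- c(hits, "exon")            # non-coding transcript
    } else if (mid < gene$thick_start) {
      hits <- c(hits, if (gene$strand == "+") "5'UTR" else "3'UTR")
    } else if (mid >= gene$thick_end) {
      hits <- c(hits, if (gene$strand == "+") "3'UTR" else "5'UTR")
    } else hits <- c(hits, "exon")
  }
  hits
}

#' Annotate peaks with their genomic feature category
#'
#' Assigns each peak midpoint a category with precedence
#' promoter > 5'UTR > 3'UTR > exon > intron > distal across all
#' transcripts. The promoter is the strand-aware window TSS +/-
#' `promoter_bp`.
#'
#' @param peaks Data frame of peak intervals (`chrom`, `start`, `end`).
#' @param genes Gene model from [read_bed12()] (or a data frame of the
#'   same shape).
#' @param promoter_bp Promoter half-window in bp (default 2000).
#' @return Factor of feature categories, one per peak.
#' @export
annotate_feature <- function(peaks, genes, promoter_bp = 2000) {
  need <- c("chrom", "start", "end", "strand", "thick_start", "thick_end",
            "block_sizes", "block_starts")
  if (!all(need %in% names(genes)))
    format_error(sprintf("gene model is missing columns: %s",
                         paste(setdiff(need, names(genes)), collapse = ", ")))
  mids <- peaks$start + (peaks$end - peaks$start) %/% 2L
  out <- vapply(seq_len(nrow(peaks)), function(i) {
    g <- genes[genes$chrom == peaks$chrom[i], , drop = FALSE]
    hits <- "distal"
    for (j in seq_len(nrow(g)))
      hits <- c(hits, point_feature(mids[i], g[j, , drop = FALSE],
                                    promoter_bp))
    feature_levels[min(match(hits, feature_levels))]
  }, character(1))
  factor(out, levels = feature_levels)
}

#' Relative accessibility against a reference region
#'
#' Divides a region's accessibility signal by that of a reference region
#' (e.g. a housekeeping promoter), making the result invariant to common
#' scaling of both signals.
#'
#' @param region_signal Accessibility signal of the region of interest.
#' @param reference_signal Accessibility signal of the reference region;
#'   must be > 0.
#' @return `region_signal / reference_signal`.
#' @export
normalize_to_reference <- function(region_signal, reference_signal) {
  if (any(reference_signal <= 0))
    ca_stop("reference signal must be > 0", "chromaccess_undefined_value")
  region_signal / reference_signal
}

#' Full differential-accessibility pipeline
#'
#' Runs [da_test()], [apply_tiers()], [rank_results()] and (optionally)
#' [annotate_feature()] in sequence.
#'
#' @param table A [peak_count_table()].
#' @param genes Optional gene model from [read_bed12()].
#' @param wt_condition Baseline condition label.
#' @param method Test method, see [da_test()].
#' @param promoter_bp Promoter half-window for annotation.
#' @return Ranked, tiered `da_result` data frame (with `feature` when a
#'   gene model is supplied).
#' @export
da_analyze <- function(table, genes = NULL, wt_condition = "WT",
                       method = c("moderated", "welch"),
                       promoter_bp = 2000) {
  res <- da_test(table, wt_condition = wt_condition, method = method)
  res <- apply_tiers(res)
  if (!is.null(genes)) res$feature <- annotate_feature(res, genes, promoter_bp)
  rank_results(res)
}
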