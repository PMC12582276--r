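## Linker-histone stoichiometry and lineage-output metrics. All operations
## act on given (already response-normalized) protein abundances; no
## peptide-level inference is attempted.

#' Construct and validate a protein abundance table
#'
#' @param abundance Non-negative numeric matrix, proteins x samples (a
#'   named vector is treated as a single sample).
#' @param h1_subtypes Character vector of row names designated as H1
#'   isoforms.
#' @param core_histones Character vector of the four core-histone row
#'   names, default `c("H2A", "H2B", "H3", "H4")`. Must be disjoint from
#'   `h1_subtypes`.
#' @return An object of class `protein_abundance_table`.
#' @export
protein_abundance_table <- function(abundance, h1_subtypes,
                                    core_histones = c("H2A", "H2B", "H3", "H4")) {
  if (is.null(dim(abundance)))
    abundance <- matrix(abundance, ncol = 1,
                        dimnames = list(names(abundance), "sample_1"))
  if (is.null(rownames(abundance)))
    param_error("`abundance` must have protein row names")
  if (anyNA(abundance) || any(abundance < 0))
    param_error("abundances must be non-negative and non-missing")
  if (length(intersect(h1_subtypes, core_histones)))
    param_error("`h1_subtypes` and `core_histones` must be disjoint")
  missing <- setdiff(h1_subtypes, rownames(abundance))
  if (length(missing))
    param_error(sprintf("H1 subtypes missing from table: %s",
                        paste(missing, collapse = ", ")))
  structure(list(abundance = abundance, h1_subtypes = h1_subtypes,
                 core_histones = core_histones),
            class = "protein_abundance_table")
}

#' H1 subtype abundance as percent of total H1
#'
#' `100 * subtype / sum(all H1 subtypes)`; the percentages over all
#' subtypes sum to exactly 100.
#'
#' @param table A [protein_abundance_table()].
#' @param subtype H1 subtype id.
#' @param sample Sample column (index or name), default the first.
#' @return Percent of total H1.
#' @export
percent_of_total_h1 <- function(table, subtype, sample = 1L) {
  stopifnot(inherits(table, "protein_abundance_table"))
  if (!(subtype %in% table$h1_subtypes))
    param_error(sprintf("'%s' is not a designated H1 subtype", subtype))
  ab <- table$abundance[, sample]
  total <- sum(ab[table$h1_subtypes])
  if (total <= 0)
    ca_stop("total H1 abundance is zero", "chromaccess_undefined_value")
  100 * ab[[subtype]] / total
}

#' H1 molecules per nucleosome
#'
#' The nucleosome count is anchored to the mean of the four core-histone
#' abundances divided by two (two copies of each core histone per
#' octamer); the ratio is the H1 abundance (one subtype, or all subtypes
#' for `"total"`) over that count. Scale-invariant: multiplying every
#' abundance by a constant leaves the ratio unchanged. Core-histone
#' divergence above 20% of their mean triggers a warning.
#'
#' @param table A [protein_abundance_table()].
#' @param subtype H1 subtype id, or `"total"` for all subtypes combined.
#' @param sample Sample column (index or name), default the first.
#' @return H1 per nucleosome.
#' @export
h1_per_nucleosome <- function(table, subtype = "total", sample = 1L) {
  stopifnot(inherits(table, "protein_abundance_table"))
  ab <- table$abundance[, sample]
  missing <- setdiff(table$core_histones, names(ab))
  if (length(missing) || any(ab[table$core_histones] <= 0))
    ca_stop("all four core histones must be present with abundance > 0",
            "chromaccess_incomplete_data")
  cores <- ab[table$core_histones]
  if ((max(cores) - min(cores)) / mean(cores) > 0.2)
    warning("core-histone abundances diverge by more than 20% of their mean")
  nucleosomes <- mean(cores) / 2
  h1 <- if (identical(subtype, "total")) sum(ab[table$h1_subtypes])
        else {
          if (!(subtype %in% table$h1_subtypes))
            param_error(sprintf("'%s' is not a designated H1 subtype", subtype))
          ab[[subtype]]
        }
  unname(h1 / nucleosomes)
}

#' Lymphoid/myeloid lineage-output ratio
#'
#' `(pct_b + pct_t) / pct_myeloid` on percentages of donor-derived cells
#' (B220+, CD3+ and CD11b+ gates).
#'
#' @param pct_b Percent B cells (B220+).
#' @param pct_t Percent T cells (CD3+).
#' @param pct_myeloid Percent myeloid cells (CD11b+); must be > 0.
#' @return The ratio.
#' @export
lymphoid_myeloid_ratio <- function(pct_b, pct_t, pct_myeloid) {
  for (v in list(pct_b, pct_t, pct_myeloid))
    if (any(v < 0 | v > 100)) param_error("percentages must be in [0, 100]")
  if (any(pct_myeloid == 0))
    ca_stop("myeloid percentage is zero", "chromaccess_undefined_value")
  (pct_b + pct_t) / pct_myeloid
}

#' Simple fold change
#'
#' @param a Numerator count or mean.
#' @param b Denominator count or mean; must be > 0.
#' @return `a / b`.
#' @export
fold_change <- function(a, b) {
  if (any(b == 0))
    ca_stop("fold change undefined for zero denominator",
            "chromaccess_undefined_value")
  a / b
}

#' Per-sample stoichiometry summary
#'
#' Percent of total H1 for every subtype plus the total-H1 and per-subtype
#' nucleosome ratios, for each sample column.
#'
#' @param table A [protein_abundance_table()].
#' @return Data frame with `sample`, `subtype`, `pct_of_total_h1`,
#'   `per_nucleosome`, and the sample-level `total_h1_per_nucleosome`.
#' @export
stoichiometry_summary <- function(table) {
  stopifnot(inherits(table, "protein_abundance_table"))
  samples <- colnames(table$abundance)
  do.call(rbind, lapply(samples, function(s) {
    data.frame(sample = s, subtype = table$h1_subtypes,
               pct_of_total_h1 = vapply(table$h1_subtypes, function(h)
                 percent_of_total_h1(table, h, s), numeric(1)),
               per_nucleosome = vapply(table$h1_subtypes, function(h)
                 h1_per_nucleosome(table, h, s), numeric(1)),
               total_h1_per_nucleosome = h1_per_nucleosome(table, "total", s),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}
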