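#' Parameters for the peak count-table simulator
#'
#' @param n_peaks Number of peaks.
#' @param n_reps_per_condition Replicates per condition.
#' @param mean_depth Expected count per peak in the baseline condition.
#' @param dispersion Negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`); 0 gives Poisson counts.
#' @param planted Optional data frame with columns `peak` (index), `fold`
#'   (true linear fold change > 0) and `direction` (`"open"` multiplies the
#'   treated mean, `"closed"` divides it). Default: no planted effects.
#' @param seed Integer seed.
#' @return An object of class `count_sim_params`.
#' @export
count_sim_params <- function(n_peaks = 32000L, n_reps_per_condition = 3L,
                             mean_depth = 100, dispersion = 0.05,
                             planted = NULL, seed = 1L) {
  check_number(n_peaks, "n_peaks", min = 1, integer = TRUE)
  check_number(n_reps_per_condition, "n_reps_per_condition", min = 1,
               integer = TRUE)
  check_number(mean_depth, "mean_depth", min = 1e-9)
  check_number(dispersion, "dispersion", min = 0)
  check_number(seed, "seed", integer = TRUE)
  if (is.null(planted)) {
    planted <- data.frame(peak = integer(0), fold = numeric(0),
                          direction = character(0))
  }
  if (!all(c("peak", "fold", "direction") %in% names(planted)))
    param_error("`planted` needs columns peak, fold, direction")
  if (nrow(planted) > n_peaks)
    param_error("more planted effects than peaks")
  if (any(planted$peak < 1 | planted$peak > n_peaks))
    param_error("planted peak indices out of range")
  if (anyDuplicated(planted$peak))
    param_error("duplicate planted peak indices")
  if (any(planted$fold <= 0)) param_error("planted folds must be > 0")
  if (!all(planted$direction %in% c("open", "closed")))
    param_error("planted direction must be 'open' or 'closed'")
  structure(list(n_peaks = as.integer(n_peaks),
                 n_reps_per_condition = as.integer(n_reps_per_condition),
                 mean_depth = mean_depth, dispersion = dispersion,
                 planted = planted, seed = as.integer(seed)),
            class = "count_sim_params")
}

#' Simulate a peak-by-sample count table with planted accessibility changes
#'
#' Counts are negative-binomial with the stated mean and dispersion
#' (Poisson when `dispersion = 0`). For planted peaks, the treated-condition
#' mean is multiplied (`direction = "open"`) or divided
#' (`direction = "closed"`) by the true fold change. The planted truth is
#' carried in the returned table's `truth` component.
#'
#' @param params A [count_sim_params()] object.
#' @param conditions Length-2 character vector: baseline then treated.
#' @return A [peak_count_table()] with an extra `truth` data frame
#'   (`peak`, `fold`, `direction`).
#' @export
simulate_peak_counts <- function(params, conditions = c("WT", "iH1.0")) {
  if (!inherits(params, "count_sim_params"))
    param_error("`params` must be created by count_sim_params()")
  if (length(conditions) != 2L) param_error("`conditions` must have length 2")
  n <- params$n_peaks
  reps <- params$n_reps_per_condition
  mu_wt <- rep(params$mean_depth, n)
  mu_tx <- mu_wt
  pl <- params$planted
  if (nrow(pl) > 0) {
    mult <- ifelse(pl$direction == "open", pl$fold, 1 / pl$fold)
    mu_tx[pl$peak] <- mu_tx[pl$peak] * mult
  }
  samples <- c(paste0(conditions[1], "_", seq_len(reps)),
               paste0(conditions[2], "_", seq_len(reps)))
  condition_of <- stats::setNames(rep(conditions, each = reps), samples)
  mu <- cbind(matrix(rep(mu_wt, reps), ncol = reps),
              matrix(rep(mu_tx, reps), ncol = reps))
  counts <- withr::with_seed(params$seed, {
    if (params$dispersion == 0) {
      matrix(stats::rpois(length(mu), mu), nrow = n)
    } else {
      matrix(stats::rnbinom(length(mu), mu = mu,
                            size = 1 / params$dispersion), nrow = n)
    }
  })
  colnames(counts) <- samples
  peaks <- data.frame(chrom = "chrS",
                      start = (seq_len(n) - 1L) * 1000L,
                      end = (seq_len(n) - 1L) * 1000L + 500L,
                      name = paste0("peak_", seq_len(n)),
                      stringsAsFactors = FALSE)
  tab <- peak_count_table(peaks, counts, condition_of)
  tab$truth <- pl
  tab
}

#' Simulate a histone protein-abundance table
#'
#' Core histones H2A, H2B, H3 and H4 are set to 2 units per nucleosome
#' (two copies of each per octamer); total H1 is `h1_per_nucleosome` units
#' split across subtypes by `subtype_fractions`. Multiplicative lognormal
#' noise with coefficient of variation `noise_cv` is applied to every
#' abundance (mean-preserving parameterization).
#'
#' @param subtype_fractions Named numeric vector (H1 subtype -> fraction of
#'   total H1), summing to 1.
#' @param h1_per_nucleosome Total H1 per nucleosome (>= 0).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (0 = noiseless).
#' @param seed Integer seed.
#' @param n_samples Number of replicate sample columns.
#' @return A [protein_abundance_table()].
#' @export
simulate_abundance_table <- function(subtype_fractions, h1_per_nucleosome,
                                     noise_cv = 0, seed = 1L, n_samples = 1L) {
  if (length(subtype_fractions) == 0L || is.null(names(subtype_fractions)))
    param_error("`subtype_fractions` must be a named vector")
  if (abs(sum(subtype_fractions) - 1) > 1e-9)
    param_error("`subtype_fractions` must sum to 1")
  check_number(h1_per_nucleosome, "h1_per_nucleosome", min = 0)
  check_number(noise_cv, "noise_cv", min = 0)
  check_number(n_samples, "n_samples", min = 1, integer = TRUE)
  cores <- c(H2A = 2, H2B = 2, H3 = 2, H4 = 2)
  h1 <- subtype_fractions * h1_per_nucleosome
  truth <- c(cores, h1)
  ab <- matrix(rep(truth, n_samples), ncol = n_samples,
               dimnames = list(names(truth),
                               paste0("sample_", seq_len(n_samples))))
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    ab <- withr::with_seed(seed, {
      noise <- matrix(stats::rlnorm(length(ab), meanlog = -sdlog^2 / 2,
                                    sdlog = sdlog), nrow = nrow(ab))
      ab * noise
    })
  }
  protein_abundance_table(ab, h1_subtypes = names(subtype_fractions),
                          core_histones = names(cores))
}
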