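# chromaccess

Chromatin-state-stratified analysis of ATAC-style fragment data for
studies of linker-histone (H1) dosage. When H1 rises in a cell
population, nucleosome arrays become more regular, low-GC chromatin loses
relative read representation, and a subset of accessibility peaks closes.
`chromaccess` quantifies all three signatures, plus the H1 stoichiometry
and hematopoietic lineage-output metrics such studies report. It is aimed
at epigenomics analysts who have fragment intervals (BED), a
chromatin-state segmentation (BED4), a genome (FASTA) and a peak count
table (TSV), and who want the whole analysis reproducible against
simulations with known ground truth.

## What it computes

**Nucleosome repeat length (NRL).** Tn5 cuts linker DNA, so ATAC fragment
lengths pile up at mono/di/tri-nucleosomal sizes. Per stratum (chromatin
state × condition) the pipeline builds a smoothed fragment-length density,
subtracts a heavy-bandwidth trend, detects ladder peaks at centres
$c + (k-1)\,\mathrm{NRL}$, and estimates the NRL as the least-squares
slope of peak centre on order $k$, with a bounded spectral score
(band power over total power, in [0, 1]) for the strength of the repeat
signal.

**Type A/B/C response classification.** Each state's paired (WT, treated)
strengths are classified: A = no repeat signal in either condition; B =
weak signal that persists, with the treated−WT NRL shift reported; C = no
signal in WT but strong repeats after treatment.

**GC representation regression.** Per-state GC content, pooled
bedtools-nuc style over the state's intervals, is regressed against the
log2 ratio of treated to WT read percentages (fragments assigned to states
by midpoint). A positive slope means low-GC states are under-represented
after treatment.

**Tiered differential accessibility.** Median-of-ratios normalization,
per-peak testing on `log2(normalized + 0.5)` with empirical-Bayes variance
moderation (plain Welch t available), two cutoff tiers on raw p-values —
relaxed (P < 0.01, |FC| > 2) and stringent (P < 0.001, |FC| > 4) —
ranking by significance then effect size, and midpoint feature annotation
(promoter > 5'UTR > 3'UTR > exon > intron > distal).

**Stoichiometry and lineage metrics.** Percent of total H1 per subtype;
H1 per nucleosome with the nucleosome count anchored to the core-histone
octamer (mean of H2A/H2B/H3/H4 divided by 2); lymphoid/myeloid ratio
`(%B220+ + %CD3+) / %CD11b+`; guarded fold changes.

**Synthetic data with ground truth.** A generator produces genomes with
exact per-state GC, state maps, ladder-structured fragment sets, optional
exponential GC sampling bias, negative-binomial peak counts with planted
fold changes, and noisy protein-abundance tables — so every estimator is
testable by parameter recovery.

## Worked example

```r
library(chromaccess)

mk <- function(lbl, pf_wt, pf_tx, gc, share, per_wt = 190, per_tx = 190)
  state_sim_spec(lbl,
    fragment_sim_params(period_bp = per_wt, periodic_fraction = pf_wt),
    fragment_sim_params(period_bp = per_tx, periodic_fraction = pf_tx),
    gc_fraction = gc, genome_share = share)

specs <- list(mk("open",      0,   0,   0.55, 0.3),
              mk("weak",      0.3, 0.3, 0.45, 0.3, per_wt = 186),
              mk("quiescent", 0,   0.7, 0.35, 0.4))
ds <- simulate_state_dataset(specs, chrom_length = 3e6,
                             n_fragments = 150000, seed = 42)

profiles <- list()
for (st in c("open", "weak", "quiescent"))
  for (cond in c("WT", "iH1.0"))
    profiles[[paste(st, cond)]] <-
      profile_stratum(ds$fragments[[cond]], st, cond)

profiles[["quiescent iH1.0"]]
#> periodicity_profile [quiescent / iH1.0]: n=59853, NRL=190.5 bp (se 0.29), strength=0.363, 3 peak(s)

classify_all(profiles)$calls[, c("state", "call", "wt_strength",
                                 "tx_strength", "delta_nrl_bp")]
#>       state call wt_strength tx_strength delta_nrl_bp
#> 1      open    A  0.02240342  0.02266231          -38
#> 2      weak    B  0.14466927  0.14696586            4
#> 3 quiescent    C  0.02370737  0.36266559           53
```

The quiescent state was simulated with no ladder in WT and a strong
190 bp ladder after H1.0 induction: the pipeline recovers the planted
NRL within 0.5 bp and calls it Type C; the weak state's planted 4 bp
NRL increase (186 → 190 bp) is recovered exactly. (The `delta_nrl_bp` of
a Type A state compares two noise fits and carries no signal.)

Differential accessibility on a count table with 50 planted 8-fold
closing peaks:

```r
planted <- data.frame(peak = 1:50, fold = 8, direction = "closed")
tab <- simulate_peak_counts(count_sim_params(
  n_peaks = 5000, mean_depth = 100, dispersion = 0.05,
  planted = planted, seed = 1))
res <- da_analyze(tab)
tier_summary(res)
#>        tier direction  n
#> 1   relaxed      open  4
#> 2 stringent      open  0
#> 3   relaxed    closed 50
#> 4 stringent    closed 50
```

All 50 planted closings are recovered at the stringent tier; the 4
relaxed-tier "open" calls are the expected handful of raw-P false
positives among 4,950 null peaks.

```r
ab <- simulate_abundance_table(c(H1.0 = 0.18, H1.2 = 0.41, H1.4 = 0.41),
                               h1_per_nucleosome = 0.7)
percent_of_total_h1(ab, "H1.0")   #> 18
h1_per_nucleosome(ab, "H1.0")     #> 0.126
```

## Layout

- `R/` — simulation, I/O, NRL, typing, GC regression, DA, stoichiometry
- `tests/testthat/` — unit, property and end-to-end recovery tests
- `vignettes/chromatin-accessibility-methods.Rmd` — model assumptions,
  parameter choices, calibration rationale, limitations
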