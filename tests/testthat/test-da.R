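make_table <- function(counts, reps = 2) {
  cond <- stats::setNames(rep(c("WT", "iH1.0"), each = ncol(counts) / 2),
                          colnames(counts))
  n <- nrow(counts)
  peaks <- data.frame(chrom = "chr1", start = (seq_len(n) - 1L) * 1000L,
                      end = (seq_len(n) - 1L) * 1000L + 500L,
                      stringsAsFactors = FALSE)
  peak_count_table(peaks, counts, cond)
}

test_that("median-of-ratios size factors match their definition", {
  counts <- matrix(c(10L, 20L, 30L, 10L, 20L, 30L), ncol = 2,
                   dimnames = list(NULL, c("WT_1", "WT_2")))
  cond <- c(WT_1 = "WT", WT_2 = "iH1.0")
  tab <- peak_count_table(data.frame(chrom = "c", start = 0:2 * 10L,
                                     end = 0:2 * 10L + 5L), counts, cond)
  expect_equal(unname(normalize_counts(tab)$size_factors), c(1, 1))

  tab2 <- peak_count_table(tab$peaks, counts * c(1L, 1L, 1L, 2L, 2L, 2L),
                           cond)
  sf2 <- normalize_counts(tab2)$size_factors
  expect_equal(unname(sf2[2] / sf2[1]), 2)

  set.seed(12)
  counts3 <- matrix(rpois(400, 50), ncol = 4,
                    dimnames = list(NULL, paste0("s", 1:4)))
  tab3 <- peak_count_table(
    data.frame(chrom = "c", start = 0:99 * 10L, end = 0:99 * 10L + 5L),
    counts3, stats::setNames(rep(c("WT", "iH1.0"), 2), paste0("s", 1:4)))
  sf3 <- normalize_counts(tab3)$size_factors
  # brute-force definition
  pos <- rowSums(counts3 > 0) == 4
  ref <- apply(counts3[pos, ], 1, function(r) exp(mean(log(r))))
  oracle <- apply(counts3[pos, ] / ref, 2, median)
  expect_equal(unname(sf3), unname(oracle), tolerance = 1e-9)
})

test_that("the per-peak Welch test matches the textbook computation", {
  cond <- stats::setNames(rep(c("WT", "iH1.0"), each = 3),
                          c(paste0("WT_", 1:3), paste0("TX_", 1:3)))
  x <- c(100, 120, 90, 30, 40, 25)
  names(x) <- names(cond)
  res <- test_peak(x, cond)
  oracle <- stats::t.test(log2(x[4:6] + 0.5), log2(x[1:3] + 0.5))
  expect_equal(res$p_value, oracle$p.value, tolerance = 1e-9)
  expect_equal(res$log2_fc,
               log2((mean(x[4:6]) + 0.5) / (mean(x[1:3]) + 0.5)))

  # swapping condition labels negates the fold change, p unchanged
  flipped <- stats::setNames(rev(cond), names(cond))
  res2 <- test_peak(x, flipped)
  expect_equal(res2$log2_fc, -res$log2_fc)
  expect_equal(res2$p_value, res$p_value, tolerance = 1e-12)

  same <- stats::setNames(c(10, 20, 30, 10, 20, 30), names(cond))
  res3 <- test_peak(same, cond)
  expect_equal(res3$log2_fc, 0)
  expect_equal(res3$p_value, 1)

  zero <- stats::setNames(rep(0, 6), names(cond))
  expect_equal(test_peak(zero, cond), list(log2_fc = 0, p_value = 1))
})

test_that("the matrix Welch route agrees with the per-peak test", {
  set.seed(3)
  counts <- matrix(rpois(600, 80), ncol = 6,
                   dimnames = list(NULL,
                                   c(paste0("WT_", 1:3), paste0("TX_", 1:3))))
  tab <- make_table(counts)
  res <- da_test(tab, method = "welch")
  norm <- normalize_counts(tab)$normalized
  for (i in c(1, 17, 50)) {
    single <- test_peak(norm[i, ], tab$condition_of)
    expect_equal(res$p_value[i], single$p_value, tolerance = 1e-12)
    expect_equal(res$log2_fc[i], single$log2_fc, tolerance = 1e-12)
  }
})

test_that("tier cutoffs and directions follow the two-tier definition", {
  res <- data.frame(chrom = "c", start = c(0, 10, 20, 30),
                    end = c(5, 15, 25, 35), name = paste0("p", 1:4),
                    base_mean = 10,
                    log2_fc = c(log2(3), -log2(5), log2(10), 0),
                    p_value = c(0.005, 5e-4, 0.05, 0.5))
  out <- apply_tiers(res)
  expect_equal(out$tier, c("relaxed", "stringent", "none", "none"))
  expect_equal(out$direction, c("open", "closed", "open", "none"))
})

test_that("every stringent peak also satisfies the relaxed cutoffs", {
  planted <- data.frame(peak = 1:200, fold = 6,
                        direction = rep(c("open", "closed"), 100))
  cp <- count_sim_params(n_peaks = 4000, mean_depth = 80, dispersion = 0.08,
                         planted = planted, seed = 14)
  res <- apply_tiers(da_test(simulate_peak_counts(cp)))
  stringent <- res$tier == "stringent"
  expect_true(all(res$p_value[stringent] < 0.01 &
                    abs(res$log2_fc[stringent]) > 1))
  summ <- tier_summary(res)
  expect_true(all(summ$n[summ$tier == "relaxed"] >=
                    summ$n[summ$tier == "stringent"]))
})

test_that("ranking orders by significance then effect then genomic position", {
  res <- data.frame(chrom = "c", start = c(30, 0, 10, 20),
                    end = c(35, 5, 15, 25), name = paste0("p", 1:4),
                    base_mean = 10,
                    log2_fc = c(3, 1.5, 3, 3),
                    p_value = c(1e-3, 1e-5, 1e-3, 1e-5))
  ranked <- rank_results(res)
  # oracle: brute-force sort of the same keys
  oracle <- res[order(res$p_value, -abs(res$log2_fc), res$chrom, res$start), ]
  expect_equal(ranked$name, oracle$name)
  expect_equal(ranked$rank, 1:4)
  expect_equal(ranked$name[1], "p4")  # tied p, larger |fc| first
})

test_that("peak midpoints annotate with promoter > UTR > exon > intron > distal", {
  genes <- toy_gene_model()
  peak <- function(mid) data.frame(chrom = "chr1", start = mid - 50L,
                                   end = mid + 50L)
  ann <- function(mid) as.character(annotate_feature(peak(mid), genes))
  expect_equal(ann(9500), "promoter")     # 500 bp upstream of + TSS
  expect_equal(ann(10200), "promoter")    # inside gene but promoter wins
  expect_equal(ann(12600), "5'UTR")       # exonic, before the CDS start
  expect_equal(ann(13800), "intron")      # between exons 2 and 3
  expect_equal(ann(13000), "exon")        # exon 2 within the CDS
  expect_equal(ann(15700), "3'UTR")       # exon 3 past the CDS end
  expect_equal(ann(300000), "distal")     # 100s of kb from any gene
  # minus-strand gene: TSS at the right end, UTR polarity flips
  expect_equal(ann(56500), "promoter")    # 500 bp right of - TSS
  expect_equal(ann(53300), "5'UTR")       # exonic past thick_end on -
  expect_equal(ann(50200), "3'UTR")       # exonic before thick_start on -
  expect_equal(ann(53800), "intron")
  expect_error(annotate_feature(peak(1), genes[, 1:3]),
               class = "chromaccess_format_error")
})

test_that("reference normalization is a scale-invariant ratio", {
  expect_equal(normalize_to_reference(10, 10), 1)
  expect_equal(normalize_to_reference(5, 10), 0.5)
  expect_equal(normalize_to_reference(5 * 7, 10 * 7),
               normalize_to_reference(5, 10))
  expect_error(normalize_to_reference(5, 0),
               class = "chromaccess_undefined_value")
})

test_that("the full DA pipeline returns ranked, tiered, annotated results", {
  planted <- data.frame(peak = 1L, fold = 10, direction = "closed")
  cp <- count_sim_params(n_peaks = 50, mean_depth = 200, dispersion = 0.02,
                         planted = planted, seed = 6)
  tab <- simulate_peak_counts(cp)
  tab$peaks$chrom <- "chr1"
  res <- da_analyze(tab, genes = toy_gene_model())
  expect_equal(res$rank, seq_len(nrow(res)))
  expect_equal(res$name[1], "peak_1")
  expect_equal(res$tier[1], "stringent")
  expect_equal(res$direction[1], "closed")
  expect_true(all(levels(res$feature) ==
                    c("promoter", "5'UTR", "3'UTR", "exon", "intron", "distal")))
})
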