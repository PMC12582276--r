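test_that("length density concentrates, flattens, and conserves mass as expected", {
  d <- length_density(rep(300, 20000), smooth_bw_bp = 0)
  expect_equal(d$density[d$bin_centers == 300], 1)
  expect_equal(sum(d$density), 1, tolerance = 1e-9)

  u <- length_density(rep(1:800, each = 25))
  inner <- u$density[u$bin_centers > 30 & u$bin_centers < 770]
  expect_lt(max(abs(inner - 1 / 800)) / (1 / 800), 0.02)
  expect_equal(sum(u$density), 1, tolerance = 1e-9)

  err <- expect_error(length_density(rep(300, 50)),
                      class = "chromaccess_insufficient_data")
  expect_equal(err$n, 50)
})

test_that("detrending removes the smooth background and conserves mass", {
  flat <- length_density(rep(1:800, each = 25))
  o <- detrend_density(flat)
  expect_lt(max(abs(o$oscillation[o$bin_centers > 310 &
                                    o$bin_centers < 490])), 1e-6)
  expect_lt(abs(mean(o$oscillation)), 1e-9)  # exact mass conservation

  # a cosine riding on a flat background comes through attenuated by the
  # Gaussian kernel's transfer factor 1 - exp(-2 pi^2 bw^2 / T^2)
  period <- 190; bw_trend <- 75
  x <- 1:800
  dens <- (1 + 0.3 * cos(2 * pi * x / period)) / 800
  d <- structure(list(bin_centers = x, density = dens / sum(dens),
                      n_fragments = 1e6L, bin_bp = 1L, smooth_bw_bp = 0,
                      stratum = NULL), class = "length_density")
  o <- detrend_density(d, bw_trend)
  expected_amp <- 0.3 / 800 * (1 - exp(-2 * pi^2 * bw_trend^2 / period^2))
  inner <- o$bin_centers > 150 & o$bin_centers < 650
  obs_amp <- (max(o$oscillation[inner]) - min(o$oscillation[inner])) / 2
  expect_equal(obs_amp, expected_amp, tolerance = 0.02)
})

test_that("ladder peaks are detected with order assignment and exclusions", {
  x <- 1:800
  z <- numeric(800)
  z[c(147, 337, 527)] <- 1
  d <- structure(list(bin_centers = x, density = z / sum(z),
                      n_fragments = 60000L, bin_bp = 1L, smooth_bw_bp = 0,
                      stratum = NULL), class = "length_density")
  pk <- detect_ladder_peaks(detrend_density(d, 75))
  expect_equal(pk$center, c(147, 337, 527))
  expect_equal(pk$order, 1:3)

  flat <- detrend_density(length_density(rep(1:800, each = 25)))
  expect_equal(nrow(detect_ladder_peaks(flat)), 0)

  # two maxima 5 bp apart within one separation window: keep the higher
  z2 <- numeric(800)
  z2[200] <- 1; z2[205] <- 0.8; z2[400] <- 0.9
  d2 <- structure(list(bin_centers = x, density = z2 / sum(z2),
                       n_fragments = 60000L, bin_bp = 1L, smooth_bw_bp = 0,
                       stratum = NULL), class = "length_density")
  pk2 <- detect_ladder_peaks(detrend_density(d2, 75),
                             min_separation_bp = 100)
  expect_equal(pk2$center, c(200, 400))

  # sub-nucleosomal maxima below the floor are excluded
  z3 <- numeric(800)
  z3[50] <- 5; z3[210] <- 1; z3[420] <- 0.8
  d3 <- structure(list(bin_centers = x, density = z3 / sum(z3),
                       n_fragments = 60000L, bin_bp = 1L, smooth_bw_bp = 0,
                       stratum = NULL), class = "length_density")
  pk3 <- detect_ladder_peaks(detrend_density(d3, 75), min_len_bp = 100)
  expect_equal(pk3$center, c(210, 420))
})

test_that("NRL regression matches least squares and is offset-invariant", {
  pk <- function(centers) data.frame(center = centers,
                                     order = seq_along(centers))
  expect_equal(estimate_nrl(pk(c(190, 380, 570)))$nrl_bp, 190)
  expect_equal(estimate_nrl(pk(c(150, 340, 530)))$nrl_bp, 190)

  # independent oracle: R's own linear-model fit
  set.seed(7)
  for (i in 1:100) {
    k <- sample(3:6, 1)
    centers <- sort(147 + (0:(k - 1)) * 190 + rnorm(k, 0, 8))
    est <- estimate_nrl(pk(centers))
    fit <- stats::lm(centers ~ seq_along(centers))
    expect_equal(est$nrl_bp, unname(coef(fit)[2]), tolerance = 1e-9)
    expect_equal(est$stderr_bp,
                 unname(summary(fit)$coefficients[2, 2]), tolerance = 1e-9)
    offset <- estimate_nrl(pk(centers + 37.5))
    expect_equal(offset$nrl_bp, est$nrl_bp, tolerance = 1e-9)
  }

  two <- estimate_nrl(pk(c(147, 338)))
  expect_equal(two$nrl_bp, 191)
  expect_true(is.na(two$stderr_bp))
  expect_error(estimate_nrl(pk(147)),
               class = "chromaccess_insufficient_peaks")
})

test_that("repeat strength is zero for flat input and monotone in ladder fraction", {
  flat <- detrend_density(length_density(rep(1:800, each = 25)))
  expect_equal(repeat_strength(flat), 0, tolerance = 1e-3)
  for (seed in 1:3) {
    s <- vapply(c(0, 0.3, 0.7), function(pf) {
      p <- fragment_sim_params(period_bp = 190, periodic_fraction = pf,
                               n_fragments = 50000, seed = seed)
      pipeline_strength(simulate_fragment_lengths(p))
    }, numeric(1))
    expect_true(all(diff(s) > 0))
  }
})

test_that("the NRL estimator is scale-equivariant and tightens with depth", {
  p <- fragment_sim_params(period_bp = 190, periodic_fraction = 0.6,
                           n_fragments = 100000, seed = 13)
  len <- simulate_fragment_lengths(p)
  base <- pipeline_nrl(len)
  scaled <- pipeline_nrl(len * 1.1)
  expect_equal(scaled, 1.1 * base, tolerance = 2 / 209)

  prof_se <- function(n, seed) {
    p <- fragment_sim_params(period_bp = 190, periodic_fraction = 0.6,
                             n_fragments = n, seed = seed)
    d <- detrend_density(length_density(simulate_fragment_lengths(p)))
    estimate_nrl(detect_ladder_peaks(d))
  }
  small <- prof_se(20000, 31)
  big <- prof_se(200000, 31)
  expect_lt(abs(big$nrl_bp - 190), 2)
  expect_lte(big$stderr_bp, small$stderr_bp)
})

test_that("stratum profiles subset fragments and flag empty strata", {
  specs <- list(
    state_sim_spec("quiet",
                   fragment_sim_params(periodic_fraction = 0, seed = 1),
                   fragment_sim_params(periodic_fraction = 0, seed = 2),
                   gc_fraction = 0.4, genome_share = 0.5),
    state_sim_spec("laddered",
                   fragment_sim_params(periodic_fraction = 0, seed = 3),
                   fragment_sim_params(period_bp = 190,
                                       periodic_fraction = 0.7, seed = 4),
                   gc_fraction = 0.5, genome_share = 0.5))
  ds <- simulate_state_dataset(specs, 4e5, n_fragments = 120000, seed = 6)
  prof <- profile_stratum(ds$fragments$iH1.0, "laddered", "iH1.0",
                          states = ds$states)
  expect_equal(prof$state, "laddered")
  expect_lt(abs(prof$nrl_bp - 190), 2)
  quiet <- profile_stratum(ds$fragments$iH1.0, "quiet", "iH1.0",
                           states = ds$states)
  expect_lt(quiet$strength, prof$strength)
  expect_error(profile_stratum(ds$fragments$WT, "absent", "WT",
                               states = ds$states),
               class = "chromaccess_insufficient_data")
})
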