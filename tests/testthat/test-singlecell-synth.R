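test_that("synthetic populations honour their configuration", {
  # degenerate config: no variability anywhere
  cfg <- assay_config(dose_grid = c(0.1, 1), n_cells = 50, amplitude = 0,
                      cv = 0, af1_sd = 0, af2_sd = 0, ch2_cv = 0, bleed21 = 0)
  tab <- generate_population(cfg)
  expect_equal(unique(tab$ch1_raw), cfg$basal + cfg$af1_mean)
  # dose at EC50 gives basal + amplitude/2 after correction
  cfg2 <- assay_config(dose_grid = c(2), n_cells = 2e4, ec50 = 2, seed = 8)
  tab2 <- generate_population(cfg2)
  tab2 <- correct_fluorescence(tab2, cfg2$af1_mean, cfg2$af2_mean, cfg2$bleed21)
  expect_equal(mean(tab2$ch1_corrected), cfg2$basal + cfg2$amplitude / 2,
               tolerance = 0.01)
  # reproducibility
  expect_identical(generate_population(cfg), generate_population(cfg))
})

test_that("per-dose CV of the generated signal matches the configuration", {
  cfg <- assay_config(dose_grid = 30, n_cells = 1e4, cv = 0.3, basal = 0,
                      amplitude = 2000, ec50 = 0.5, af1_sd = 1, bleed21 = 0,
                      seed = 2)
  tab <- generate_population(cfg)
  tab <- correct_fluorescence(tab, cfg$af1_mean, cfg$af2_mean, 0)
  expect_equal(noise_cv(tab$ch1_corrected), 0.3, tolerance = 0.05 * 0.3 / 0.3)
})

test_that("percentile trimming removes tails per group and channel", {
  # both channels rank identically: 3 cells per tail, counted once
  n <- 100
  tab <- data.frame(dose_nM = 1, field_of_view = 1, time_point = 1,
                    cell_id = 1:n, ch1_raw = 1:n, ch2_raw = 1:n,
                    ch1_corrected = NA_real_)
  out <- trim_percentiles(tab)
  expect_equal(nrow(out), 94)
  expect_equal(range(out$ch1_raw), c(4, 97))
  # ties at the cut survive: identical values lose nothing
  tab2 <- tab; tab2$ch1_raw <- 5; tab2$ch2_raw <- 7
  expect_equal(nrow(trim_percentiles(tab2)), n)
  # an extreme outlier in channel 2 alone is removed
  tab3 <- tab
  tab3$ch2_raw <- 50 + seq(0, 0.99, length.out = n)  # nearly tied
  tab3$ch2_raw[50] <- 1e5                            # ch1 is central (50)
  out3 <- trim_percentiles(tab3)
  expect_false(50 %in% out3$cell_id)
  # never removes more than the two-channel, two-tail maximum
  set.seed(5)
  tab4 <- tab
  tab4$ch1_raw <- rnorm(n); tab4$ch2_raw <- rnorm(n)
  expect_gte(nrow(trim_percentiles(tab4)), ceiling(0.88 * n))
  # small groups are dropped with a warning
  expect_warning(out5 <- trim_percentiles(tab[1:10, ]), "min_group")
  expect_equal(nrow(out5), 0)
})

test_that("control strains calibrate the fluorescence correction", {
  # reporter strain with known autofluorescence and bleed-through
  cfg <- assay_config(n_cells = 2000, af1_mean = 25, af2_mean = 12,
                      bleed21 = 0.08, seed = 31)
  # GFP-only control: no marker channel signal
  gfp_cfg <- cfg; gfp_cfg$ch2_mean <- 0; gfp_cfg$dose_grid <- 10
  gfp_only <- generate_population(gfp_cfg)
  # mCherry-only control: no reporter expression
  mch_cfg <- cfg; mch_cfg$basal <- 0; mch_cfg$amplitude <- 0
  mch_cfg$dose_grid <- 10
  mcherry_only <- generate_population(mch_cfg)
  est <- estimate_correction(gfp_only, mcherry_only)
  expect_equal(est$af2_mean, 12, tolerance = 0.02)
  expect_equal(est$bleed21, 0.08, tolerance = 0.05)
  expect_equal(est$af1_mean, 25, tolerance = 0.05)
  # control strain reads ~0 after correction
  corr <- correct_fluorescence(mcherry_only, est$af1_mean, est$af2_mean,
                               est$bleed21)
  expect_lt(abs(mean(corr$ch1_corrected)), 1)
  # round trip: corrected dose response recovers the generating sigmoid
  tab <- generate_population(cfg)
  tab <- correct_fluorescence(tab, est$af1_mean, est$af2_mean, est$bleed21)
  s <- summarize_doses(as_dose_response_sc(tab))
  truth <- cfg$basal + cfg$amplitude * s$dose_nM / (s$dose_nM + cfg$ec50)
  expect_lt(max(abs(s$mean - truth) / max(truth)), 0.03)
  expect_error(correct_fluorescence(tab, 0, 0, -0.1), ">= 0")
})

test_that("identity correction leaves raw values untouched", {
  cfg <- assay_config(n_cells = 20, dose_grid = c(1), bleed21 = 0)
  tab <- generate_population(cfg)
  out <- correct_fluorescence(tab, 0, 0, 0)
  expect_equal(out$ch1_corrected, tab$ch1_raw)
})

test_that("sigmoid fits recover EC50 and flag unidentifiable data", {
  doses <- 10^seq(-2, 3, length.out = 10)
  y <- 5 + 80 * doses / (doses + 4)
  fit <- fit_sigmoid_ec50(doses, y)
  expect_equal(fit$ec50, 4, tolerance = 1e-4)
  expect_equal(fit$hill, 1, tolerance = 1e-3)
  expect_true(fit$identifiable)
  flat <- fit_sigmoid_ec50(doses, rep(10, 10) + c(1e-6, rep(0, 9)))
  expect_false(flat$identifiable)
})

test_that("EC50 is recovered within 15% under multiplicative noise", {
  doses <- 10^seq(-2, 3, length.out = 8)
  truth <- 5 + 80 * doses / (doses + 4)
  set.seed(17)
  errs <- replicate(100, {
    y <- truth * (1 + rnorm(8, 0, 0.05))
    c(fixed = abs(fit_sigmoid_ec50(doses, y, fix_hill = TRUE)$ec50 - 4) / 4,
      free = abs(fit_sigmoid_ec50(doses, y)$ec50 - 4) / 4)
  })
  # 5% multiplicative noise on 8 points puts the EC50 standard error near
  # 7% (known slope), so individual replicates can stray; the bulk must
  # stay within 15% and the free-slope fit must remain unbiased
  expect_lt(unname(quantile(errs["fixed", ], 0.9)), 0.15)
  expect_lt(mean(errs["fixed", ]), 0.07)
  expect_lt(mean(errs["free", ]), 0.12)
})

test_that("twofold induction classification follows the stated thresholds", {
  expect_equal(classify_induction(c(20, 10, 4), c(10, 10, 10)),
               c("induced", "unchanged", "repressed"))
  expect_equal(classify_induction(20, 10), "induced")    # boundary inclusive
  expect_equal(classify_induction(5, 10), "repressed")   # boundary inclusive
  expect_equal(classify_induction(12, 10), "unchanged")
  expect_error(classify_induction(1, 0), "> 0")
})

test_that("the full synthetic pipeline recovers the generating Fisher profile", {
  # generate -> correct -> Fisher is unbiased against the closed-form
  # channel moments; the percentile filter then rescales the noise by the
  # truncation factor, so the filtered pipeline is compared against the
  # exact (large-sample) moments of the filtered channel
  cfg <- assay_config(dose_grid = 10^seq(-2, 2, length.out = 9),
                      n_cells = 3000, cv = 0.2, seed = 23)
  mu_true <- cfg$basal + cfg$amplitude * cfg$dose_grid / (cfg$dose_grid + cfg$ec50)
  # observed sd combines signal CV, autofluorescence and bleed-through noise
  sd_true <- sqrt((cfg$cv * mu_true)^2 + cfg$af1_sd^2 +
                    (cfg$bleed21 * cfg$ch2_cv * cfg$ch2_mean)^2)
  truth <- fisher_profile(data.frame(dose_nM = cfg$dose_grid, n = cfg$n_cells,
                                     mean = mu_true, sd = sd_true))
  tab <- generate_population(cfg)
  corr_only <- correct_fluorescence(tab, cfg$af1_mean, cfg$af2_mean, cfg$bleed21)
  prof0 <- fisher_profile(summarize_doses(as_dose_response_sc(corr_only)))
  expect_equal(attr(prof0, "aggregated"), attr(truth, "aggregated"),
               tolerance = 0.1)

  # filtered pipeline vs exact filtered-channel moments (brute-force oracle)
  pipeline <- function(config) {
    t2 <- trim_percentiles(generate_population(config))
    t2 <- correct_fluorescence(t2, config$af1_mean, config$af2_mean,
                               config$bleed21)
    summarize_doses(as_dose_response_sc(t2))
  }
  big <- cfg; big$n_cells <- 30000; big$seed <- 91
  truth_filt <- fisher_profile(pipeline(big))
  prof <- fisher_profile(pipeline(cfg))
  expect_equal(attr(prof, "aggregated"), attr(truth_filt, "aggregated"),
               tolerance = 0.1)
})
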