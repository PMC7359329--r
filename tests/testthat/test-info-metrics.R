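test_that("coefficient of variation matches hand arithmetic and closed forms", {
  expect_equal(noise_cv(c(5, 5, 5, 5)), 0)
  expect_equal(noise_cv(c(1, 3)), sqrt(2) / 2)
  # log-normal: CV -> sqrt(exp(s^2) - 1)
  set.seed(1)
  s <- 0.4
  x <- rlnorm(1e5, sdlog = s)
  expect_equal(noise_cv(x), sqrt(exp(s^2) - 1), tolerance = 0.02)
  expect_warning(noise_cv(-2, 1), "non-positive")
})

test_that("spline smoothing reproduces lines and Hill curves with derivatives", {
  doses <- 10^seq(-3, 2, length.out = 6)
  u <- log10(doses)
  s <- data.frame(dose_nM = doses, n = 100, mean = 2 + 3 * u, sd = 1 + 0 * u)
  sm <- smooth_dose_response(s)
  expect_equal(sm$dmu(u), rep(3, 6), tolerance = 1e-6)
  expect_equal(sm$dsigma(u), rep(0, 6), tolerance = 1e-6)

  doses <- 1e-4 * 3^(0:14)
  hill <- 10 + 100 * doses / (doses + 0.5)
  s2 <- data.frame(dose_nM = doses, n = 100, mean = hill, sd = 0.1 * hill)
  sm2 <- smooth_dose_response(s2)
  ugrid <- seq(min(log10(doses)), max(log10(doses)), length.out = 200)
  truth <- 10 + 100 * 10^ugrid / (10^ugrid + 0.5)
  expect_lt(max(abs(sm2$mu(ugrid) - truth)), 0.01 * diff(range(hill)))
})

test_that("quadrature Fisher information equals the Gaussian closed form", {
  # frozen example values
  expect_equal(fisher_information(0, 0, 1, 0), 0, tolerance = 1e-10)
  expect_equal(fisher_information(0, 2, 1, 0), 4, tolerance = 1e-6)
  expect_equal(fisher_information(5, 1, 0.5, 0.1), 4.08, tolerance = 1e-6)
  # randomized sweep against the closed form
  set.seed(99)
  n <- 120
  mu <- runif(n, -10, 10); dmu <- runif(n, -5, 5)
  sig <- runif(n, 0.2, 4); dsig <- runif(n, -1, 1)
  fq <- fisher_information(mu, dmu, sig, dsig, method = "quadrature")
  fc <- fisher_information(mu, dmu, sig, dsig, method = "closed_form")
  expect_equal(fq, fc, tolerance = 1e-6)
  expect_true(all(fq >= 0))
})

test_that("Fisher information obeys the reparameterization rule", {
  # F in theta equals F in u = log10(theta) times (du/dtheta)^2
  theta <- c(0.1, 1, 10)
  mu <- c(2, 5, 9); sig <- c(0.5, 0.6, 0.7)
  dmu_du <- c(3, 4, 2); dsig_du <- c(0.1, 0, -0.1)
  dudtheta <- 1 / (theta * log(10))
  f_u <- fisher_information(mu, dmu_du, sig, dsig_du)
  f_theta <- fisher_information(mu, dmu_du * dudtheta, sig, dsig_du * dudtheta)
  expect_equal(f_theta, f_u * dudtheta^2, tolerance = 1e-6)
})

test_that("maximum-likelihood input estimation saturates the Cramer-Rao bound", {
  # linear-Gaussian channel: x ~ N(a + b u, sigma); the ML estimate of u is
  # (xbar - a) / b with variance sigma^2 / (n b^2) = 1 / (n F)
  a <- 1; b <- 2; sigma <- 0.8; u0 <- 0.3
  f <- fisher_information(a + b * u0, b, sigma, 0)
  set.seed(7)
  for (n in c(100, 1000)) {
    est <- replicate(400, (mean(rnorm(n, a + b * u0, sigma)) - a) / b)
    ratio <- var(est) * n * f
    expect_gt(ratio, 0.8)   # not below the bound (within MC error)
    expect_lt(ratio, 1.25)  # efficient estimator: attains it
  }
})

test_that("local mutual information hits its zero and log2(3) limits", {
  doses <- c(1, 3, 9)
  set.seed(3)
  # identical distributions: MI ~ 0 up to small-sample binning bias
  same <- dose_response_table(rep(doses, each = 3000), output = rnorm(9000, 10, 1))
  mi0 <- local_mutual_information(same)
  expect_lt(mi0$mi_bits, 0.01)
  # disjoint distributions: exactly log2(3) at the binning level
  apart <- dose_response_table(rep(doses, each = 500),
                               output = c(runif(500, 0, 1), runif(500, 10, 11),
                                          runif(500, 20, 21)))
  expect_equal(local_mutual_information(apart)$mi_bits, log2(3))
})

test_that("binned local MI agrees with a fine-grid quadrature oracle", {
  # three Gaussians with known parameters; oracle integrates the mixture
  mus <- c(0, 1.5, 3); sig <- 1
  h_cond <- 0.5 * log2(2 * pi * exp(1) * sig^2)
  xs <- seq(-8, 12, length.out = 20001)
  dens <- sapply(mus, function(m) dnorm(xs, m, sig))
  mix <- rowMeans(dens)
  h_mix <- -sum(ifelse(mix > 0, mix * log2(mix), 0)) * diff(xs[1:2])
  oracle <- h_mix - h_cond
  set.seed(11)
  tab <- dose_response_table(rep(c(1, 3, 9), each = 1e4),
                             output = rnorm(3e4, rep(mus, each = 1e4), sig))
  est <- local_mutual_information(tab)$mi_bits
  expect_lt(abs(est - oracle) / oracle, 0.05)
})

test_that("MI estimator is non-negative and bounded by log2(window)", {
  set.seed(21)
  doses <- 1e-2 * 4^(0:5)
  for (rep in 1:5) {
    tab <- dose_response_table(rep(doses, each = 60),
                               output = rlnorm(360, rep(log(1:6), each = 60), 0.3))
    mi <- local_mutual_information(tab)
    expect_true(all(mi$mi_bits >= 0))
    expect_true(all(mi$mi_bits <= log2(3) + 1e-12))
  }
})

test_that("aggregation integrates, averages and partitions per-input values", {
  u <- seq(0, 3, by = 0.5)
  f <- rep(2, length(u))
  expect_equal(aggregate_information(f, u, "aggregated"), 2 * 3)
  expect_equal(aggregate_information(5, 1, "total"), 5)
  # quadrature consistency under grid refinement of a smooth profile
  u1 <- seq(-4, 2, length.out = 16)
  u2 <- seq(-4, 2, length.out = 31)
  fshape <- function(u) exp(-(u + 1)^2)
  a1 <- aggregate_information(fshape(u1), u1, "aggregated")
  a2 <- aggregate_information(fshape(u2), u2, "aggregated")
  expect_lt(abs(a1 - a2) / a2, 0.01)
  # output-level partition sums to the aggregated value
  out <- seq_along(u1)
  a3 <- aggregate_information(fshape(u1), u1, "aggregated", output = out,
                              n_output_bins = 4)
  expect_equal(sum(attr(a3, "partition")), as.numeric(a3))
})

test_that("noise projection is the identity on itself and scales as 1/sigma^2", {
  doses <- 1e-3 * 4^(0:9)
  u <- log10(doses)
  mu <- 100 / (1 + (0.5 / doses))
  sd0 <- 2 + 0.15 * mu
  s <- data.frame(dose_nM = doses, n = 500, mean = mu, sd = sd0)
  f_self <- fisher_profile(s)
  proj <- project_noise(s, s)
  f_proj <- fisher_profile(proj)
  expect_equal(f_proj$fisher, f_self$fisher, tolerance = 1e-3)
  # halving sigma everywhere quadruples F where sigma' contributes little
  s_half <- s; s_half$sd <- s$sd / 2
  f_half <- fisher_profile(s_half)
  mid <- which.max(f_self$fisher)
  expect_equal(f_half$fisher[mid] / f_self$fisher[mid], 4, tolerance = 0.05)
  # non-overlapping output scales are refused
  s_far <- s; s_far$mean <- s$mean + 1e4
  expect_error(project_noise(s_far, s), "overlap")
})

test_that("hybrid noise-projected channels fall between the pure strains", {
  cfg <- ensemble_config(n_cells = 100, seed = 11)
  wt <- run_ensemble(cfg)
  md <- run_ensemble(ensemble_config(n_cells = 100, seed = 11,
                                     genotype = "msg5d"))
  f_wt <- attr(fisher_profile(as_dose_response(wt)), "aggregated")
  f_md <- attr(fisher_profile(as_dose_response(md)), "aggregated")
  hybrid <- project_noise(as_dose_response(md), as_dose_response(wt))
  f_hy <- attr(fisher_profile(hybrid), "aggregated")
  expect_gt(f_wt, f_md)
  expect_gt(f_hy, f_md * 0.99)   # mutant range with wild-type noise helps
  expect_lt(f_hy, f_wt)          # but cannot restore the full range
})

test_that("dose-response tables round-trip through delimited text", {
  tab <- dose_response_table(rep(c(0.1, 1, 10), each = 4),
                             output = rlnorm(12, 3, 0.2))
  f <- tempfile(fileext = ".tsv")
  write_dose_response(tab, f)
  back <- read_dose_response(f)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12)
  expect_s3_class(back, "dose_response_table")
})
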