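#' Smooth the dose dependence of response and noise
#'
#' Fits cubic smoothing splines (generalized cross-validated smoothing
#' parameter) to the per-dose mean and standard deviation as functions of
#' u = log10(dose), and returns evaluators for the curves and their
#' analytic first derivatives.  The sigma curve is floor-clamped at a small
#' positive value so downstream Fisher computations stay finite.
#'
#' @param x A `dose_response_table` or a per-dose summary data frame with
#'   columns `dose_nM`, `mean`, `sd`.
#' @param spar Optional fixed smoothing parameter (default: GCV).
#' @param sigma_floor Lower clamp for the smoothed sd, as a fraction of the
#'   largest per-dose sd.
#' @return A `smooth_dose_response` list with functions `mu(u)`, `sigma(u)`,
#'   `dmu(u)`, `dsigma(u)` and the fitted grid `$u`.
#' @export
smooth_dose_response <- function(x, spar = NULL, sigma_floor = 1e-4) {
  s <- if (inherits(x, "dose_response_table")) summarize_doses(x) else x
  stopifnot(all(c("dose_nM", "mean", "sd") %in% names(s)))
  s <- s[s$dose_nM > 0, ]
  if (any(diff(s$dose_nM) <= 0)) stop("dose grid must be strictly increasing")
  if (nrow(s) < 4) stop("need at least 4 positive doses for cubic smoothing")
  u <- log10(s$dose_nM)
  fit1 <- if (is.null(spar)) stats::smooth.spline(u, s$mean, cv = FALSE)
          else stats::smooth.spline(u, s$mean, spar = spar)
  fit2 <- if (is.null(spar)) stats::smooth.spline(u, s$sd, cv = FALSE)
          else stats::smooth.spline(u, s$sd, spar = spar)
  floor_val <- sigma_floor * max(s$sd)
  structure(list(
    u = u,
    mu = function(uu) stats::predict(fit1, uu)$y,
    dmu = function(uu) stats::predict(fit1, uu, deriv = 1)$y,
    sigma = function(uu) pmax(stats::predict(fit2, uu)$y, floor_val),
    dsigma = function(uu) stats::predict(fit2, uu, deriv = 1)$y,
    floor = floor_val),
    class = "smooth_dose_response")
}

#' Fisher information of a Gaussian dose-response channel
#'
#' For an output assumed normal with input-dependent mean and standard
#' deviation, computes F(u) = E[(d/du log N(x; mu(u), sigma(u)))^2] at each
#' input.  `method = "quadrature"` evaluates the expectation by numerical
#' integration over the output distribution (the reference route);
#' `"closed_form"` uses the Gaussian identity (mu'^2 + 2 sigma'^2) / sigma^2.
#' The two agree to high precision and are cross-checked in the test suite.
#'
#' @param mu,dmu,sigma,dsigma Mean, mean derivative, sd and sd derivative at
#'   each input (vectors of equal length).  Derivatives are with respect to
#'   whatever input coordinate the caller smoothed in (log10 dose by
#'   default elsewhere in the package).
#' @param method `"quadrature"` or `"closed_form"`.
#' @return Vector of Fisher information values (nats per input-unit^2).
#' @export
fisher_information <- function(mu, dmu, sigma, dsigma,
                               method = c("quadrature", "closed_form")) {
  method <- match.arg(method)
  n <- length(mu)
  stopifnot(length(dmu) == n, length(sigma) == n, length(dsigma) == n)
  if (any(sigma < 0)) stop("sigma must be positive")
  if (any(sigma == 0)) {
    if (any(sigma == 0 & dmu != 0))
      warning("sigma = 0 with nonzero mean derivative: infinite information")
    return(ifelse(sigma == 0, ifelse(dmu == 0 & dsigma == 0, 0, Inf),
                  fisher_information(mu[sigma > 0], dmu[sigma > 0],
                                     sigma[sigma > 0], dsigma[sigma > 0],
                                     method = method)))
  }
  if (method == "closed_form") return((dmu^2 + 2 * dsigma^2) / sigma^2)
  vapply(seq_len(n), function(i) {
    m <- mu[i]; s <- sigma[i]; dm <- dmu[i]; ds <- dsigma[i]
    f <- function(x) {
      z <- (x - m) / s
      score <- dm * z / s + ds * (z^2 - 1) / s
      score^2 * stats::dnorm(x, m, s)
    }
    stats::integrate(f, m - 10 * s, m + 10 * s, rel.tol = 1e-10,
                     abs.tol = 0)$value
  }, numeric(1))
}

#' Fisher-information profile of a dose-response channel
#'
#' Pipeline used for both simulated and synthetic-experimental data:
#' per-dose mean and sd, spline smoothing in u = log10(dose), Gaussian
#' Fisher information at every input of the grid, and aggregated/total
#' summaries.
#'
#' @param x A `dose_response_table` or per-dose summary (`dose_nM`, `mean`,
#'   `sd`).
#' @param method Passed to [fisher_information()].
#' @param spar Optional fixed smoothing parameter for the splines.
#' @return An `info_profile` data frame (`dose_nM`, `u`, `mu`, `sigma`,
#'   `fisher`) with attributes `aggregated` (trapezoidal integral over u)
#'   and `total` (mean over inputs).
#' @export
fisher_profile <- function(x, method = "closed_form", spar = NULL) {
  s <- if (inherits(x, "dose_response_table")) summarize_doses(x) else x
  s <- s[s$dose_nM > 0, ]
  sm <- smooth_dose_response(s, spar = spar)
  u <- sm$u
  f <- fisher_information(sm$mu(u), sm$dmu(u), sm$sigma(u), sm$dsigma(u),
                          method = method)
  prof <- data.frame(dose_nM = s$dose_nM, u = u, mu = sm$mu(u),
                     sigma = sm$sigma(u), fisher = f)
  class(prof) <- c("info_profile", "data.frame")
  attr(prof, "aggregated") <- trapz(u, f)
  attr(prof, "total") <- mean(f)
  prof
}

#' Aggregate a per-input information profile
#'
#' `"aggregated"` integrates the per-input values over log10 dose by the
#' trapezoid rule (the summed-over-the-output-range quantity used for bar
#' plots); `"total"` is the unweighted mean over inputs.  With `output`
#' given, the aggregated value is additionally partitioned into output-level
#' bins through the input-to-output mapping.
#'
#' @param values Per-input information values.
#' @param u Input coordinate (log10 dose) of each value.
#' @param mode `"aggregated"` or `"total"`.
#' @param output Optional output level (e.g. mean response) per input.
#' @param n_output_bins Number of equal-width output-level bins.
#' @return Scalar, with a `"partition"` attribute when `output` is given.
#' @export
aggregate_information <- function(values, u, mode = c("aggregated", "total"),
                                  output = NULL, n_output_bins = 4) {
  mode <- match.arg(mode)
  if (mode == "total") return(mean(values))
  n <- length(u)
  stopifnot(length(values) == n, n >= 2)
  du <- diff(u)
  w <- c(du[1] / 2, (du[-1] + du[-(n - 1)]) / 2, du[n - 1] / 2)
  total <- sum(w * values)
  if (!is.null(output)) {
    br <- seq(min(output), max(output), length.out = n_output_bins + 1)
    bin <- cut(output, br, include.lowest = TRUE)
    attr(total, "partition") <- tapply(w * values, bin, sum, default = 0)
  }
  total
}

# Shannon entropy (bits) of a count vector, with the 0 log 0 = 0 convention
.entropy_bits <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Local mutual information over a sliding input window
#'
#' Mutual information between input and output restricted to windows of
#' `window` consecutive inputs with a uniform prior.  Outputs pooled over
#' the window define common equal-width bin edges; I = H(pooled) - mean of
#' the per-input entropies, in bits, bounded by log2(window).
#'
#' @param table A `dose_response_table`.
#' @param window Number of consecutive inputs per window (default 3).
#' @param n_bins Number of equal-width output bins (default 20).
#' @return Data frame with one row per window centre: `dose_nM` (centre
#'   dose), `mu` (centre mean output), `mi_bits`.
#' @export
local_mutual_information <- function(table, window = 3, n_bins = 20) {
  doses <- sort(unique(table$dose_nM))
  if (length(doses) < window) stop("need at least ", window, " doses")
  out <- lapply(seq_len(length(doses) - window + 1), function(i0) {
    dset <- doses[i0:(i0 + window - 1)]
    groups <- lapply(dset, function(d) table$output[table$dose_nM == d])
    pooled <- unlist(groups)
    rng <- range(pooled)
    if (diff(rng) == 0) {
      mi <- 0
    } else {
      br <- seq(rng[1], rng[2], length.out = n_bins + 1)
      cnt <- lapply(groups, function(g)
        tabulate(findInterval(g, br, rightmost.closed = TRUE,
                              all.inside = TRUE), nbins = n_bins))
      # uniform prior over the window's inputs: weight each input equally
      pooled_p <- Reduce(`+`, lapply(cnt, function(ci) ci / sum(ci))) / window
      h_pool <- -sum(pooled_p[pooled_p > 0] * log2(pooled_p[pooled_p > 0]))
      h_cond <- mean(vapply(cnt, .entropy_bits, numeric(1)))
      mi <- max(h_pool - h_cond, 0)
    }
    centre <- dset[(window + 1) %/% 2]
    data.frame(dose_nM = centre,
               mu = mean(table$output[table$dose_nM == centre]),
               mi_bits = mi)
  })
  do.call(rbind, out)
}

#' Project one strain's noise onto another's dose response
#'
#' Builds a hybrid channel whose mean dose response comes from
#' `response_from` while the standard deviation is taken from `noise_from`
#' at the matched output level (sd interpolated as a function of the mean).
#' Used to decompose Fisher-information differences into output-range and
#' noise contributions.
#'
#' @param response_from,noise_from `dose_response_table`s (or per-dose
#'   summaries) on comparable output scales.
#' @return A per-dose summary data frame (`dose_nM`, `mean`, `sd`) suitable
#'   for [fisher_profile()].
#' @export
project_noise <- function(response_from, noise_from) {
  sr <- if (inherits(response_from, "dose_response_table"))
    summarize_doses(response_from) else response_from
  sn <- if (inherits(noise_from, "dose_response_table"))
    summarize_doses(noise_from) else noise_from
  if (max(sr$mean) < min(sn$mean) || min(sr$mean) > max(sn$mean))
    stop("output ranges of the two tables do not overlap; refusing to extrapolate")
  o <- order(sn$mean)
  sd_of_mu <- stats::approxfun(sn$mean[o], sn$sd[o], rule = 2, ties = mean)
  data.frame(dose_nM = sr$dose_nM, n = sr$n, mean = sr$mean,
             sd = sd_of_mu(sr$mean))
}
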