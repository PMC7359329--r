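#' Configuration of the synthetic single-cell assay
#'
#' Emulates the statistical structure of microscopy reporter measurements:
#' a sigmoidal mean dose response, log-normal (median-1) cell-to-cell
#' variability of the true signal, additive Gaussian autofluorescence per
#' channel, and linear bleed-through from the constitutive second channel
#' into the reporter channel.
#'
#' @param dose_grid Doses (nM).
#' @param n_cells Cells per dose (per field of view/time point).
#' @param basal,amplitude,ec50,hill Sigmoid mean response
#'   `basal + amplitude * dose^hill / (dose^hill + ec50^hill)` (a.u.).
#' @param cv Log-normal cell-to-cell CV of the true signal.
#' @param af1_mean,af1_sd Autofluorescence mean/sd in the reporter channel.
#' @param af2_mean,af2_sd Autofluorescence mean/sd in the marker channel.
#' @param ch2_mean,ch2_cv Constitutive marker signal mean and log-normal CV.
#' @param bleed21 Bleed-through coefficient of channel-2 signal into
#'   channel 1, in [0, 1).
#' @param cells_per_fov Cells per field of view (grouping used by
#'   percentile trimming).
#' @param seed RNG seed.
#' @return An `assay_config` list.
#' @export
assay_config <- function(dose_grid = 1e-4 * 3^(0:14), n_cells = 300,
                         basal = 20, amplitude = 200, ec50 = 1, hill = 1,
                         cv = 0.25,
                         af1_mean = 15, af1_sd = 3,
                         af2_mean = 10, af2_sd = 2,
                         ch2_mean = 150, ch2_cv = 0.2,
                         bleed21 = 0.05, cells_per_fov = 100, seed = 1) {
  stopifnot(ec50 > 0, cv >= 0, ch2_cv >= 0, bleed21 >= 0, bleed21 < 1,
            n_cells >= 1)
  structure(as.list(environment()), class = "assay_config")
}

# sigmoid (Hill) mean dose response
.sigmoid <- function(dose, basal, amplitude, ec50, hill) {
  basal + amplitude * dose^hill / (dose^hill + ec50^hill)
}

#' Generate a synthetic single-cell table
#'
#' Per cell: true reporter signal = sigmoid(dose) x log-normal factor;
#' observed channel 1 = signal + autofluorescence + bleed-through of the
#' cell's channel-2 signal; observed channel 2 = marker signal +
#' autofluorescence.  Fully reproducible from the config seed.
#'
#' @param config An [assay_config()].
#' @return A `single_cell_table` data frame with columns `dose_nM`,
#'   `field_of_view`, `time_point`, `cell_id`, `ch1_raw`, `ch2_raw`,
#'   `ch1_corrected` (NA until [correct_fluorescence()] is applied).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "assay_config"))
  cfg <- config
  rows <- lapply(seq_along(cfg$dose_grid), function(i) {
    d <- cfg$dose_grid[i]
    with_substream(cfg$seed, i, 1L, {
      n <- cfg$n_cells
      sig <- .sigmoid(d, cfg$basal, cfg$amplitude, cfg$ec50, cfg$hill) *
        .lognormal_factor(n, cfg$cv, center = "mean")
      ch2_sig <- cfg$ch2_mean * .lognormal_factor(n, cfg$ch2_cv, center = "mean")
      af1 <- stats::rnorm(n, cfg$af1_mean, cfg$af1_sd)
      af2 <- stats::rnorm(n, cfg$af2_mean, cfg$af2_sd)
      ch1 <- pmax(sig + af1 + cfg$bleed21 * ch2_sig, 0)
      ch2 <- pmax(ch2_sig + af2, 0)
      data.frame(dose_nM = d,
                 field_of_view = (seq_len(n) - 1) %/% cfg$cells_per_fov + 1,
                 time_point = 1L,
                 cell_id = seq_len(n),
                 ch1_raw = ch1, ch2_raw = ch2,
                 ch1_corrected = NA_real_)
    })
  })
  out <- do.call(rbind, rows)
  class(out) <- c("single_cell_table", "data.frame")
  out
}

#' Remove upper and lower percentiles per field of view and time point
#'
#' Cells outside the [lower, 100 - upper] percentile band in either
#' fluorescence channel are removed, independently within each
#' field-of-view x time-point (x dose) group.  Percentiles use linear
#' interpolation; cells exactly at the cut survive, so all-identical
#' groups lose nothing.
#'
#' @param table A `single_cell_table`.
#' @param lower,upper Percentiles to trim from each tail (default 3).
#' @param min_group Minimum group size; smaller groups are dropped with a
#'   warning (default 34, the smallest size at which a 3-percentile tail
#'   contains at least one cell).
#' @return The trimmed table.
#' @export
trim_percentiles <- function(table, lower = 3, upper = 3, min_group = 34) {
  key <- interaction(table$dose_nM, table$field_of_view, table$time_point,
                     drop = TRUE)
  keep <- unlist(lapply(split(seq_len(nrow(table)), key), function(idx) {
    if (length(idx) < min_group) {
      warning("group of ", length(idx), " cells below min_group; dropped")
      return(integer(0))
    }
    ok <- rep(TRUE, length(idx))
    for (ch in c("ch1_raw", "ch2_raw")) {
      v <- table[[ch]][idx]
      q <- stats::quantile(v, c(lower, 100 - upper) / 100, type = 7,
                           names = FALSE)
      ok <- ok & v >= q[1] & v <= q[2]
    }
    idx[ok]
  }), use.names = FALSE)
  out <- table[sort(keep), ]
  rownames(out) <- NULL
  out
}

#' Estimate correction constants from control strains
#'
#' Mirrors the use of GFP-only and mCherry-only strains: the GFP-only
#' population (no marker) provides the channel-2 autofluorescence mean; a
#' regression of channel 1 on channel 2 in the mCherry-only population (no
#' reporter) provides the bleed-through coefficient and, combined with the
#' channel-2 autofluorescence, the channel-1 autofluorescence mean.
#'
#' @param gfp_only,mcherry_only `single_cell_table`s of the control strains.
#' @return List with `af1_mean`, `af2_mean`, `bleed21`.
#' @export
estimate_correction <- function(gfp_only, mcherry_only) {
  af2 <- mean(gfp_only$ch2_raw)
  fit <- stats::lm(ch1_raw ~ ch2_raw, data = mcherry_only)
  bleed <- unname(stats::coef(fit)[2])
  af1 <- unname(stats::coef(fit)[1]) + bleed * af2
  list(af1_mean = af1, af2_mean = af2, bleed21 = bleed)
}

#' Correct fluorescence for autofluorescence and bleed-through
#'
#' `ch1_corrected = ch1_raw - af1_mean - bleed21 * (ch2_raw - af2_mean)`.
#'
#' @param table A `single_cell_table`.
#' @param af1_mean,af2_mean Autofluorescence means per channel.
#' @param bleed21 Bleed-through coefficient (must be >= 0).
#' @return The table with `ch1_corrected` filled in.
#' @export
correct_fluorescence <- function(table, af1_mean, af2_mean, bleed21) {
  if (bleed21 < 0) stop("bleed-through coefficient must be >= 0")
  table$ch1_corrected <- table$ch1_raw - af1_mean -
    bleed21 * (table$ch2_raw - af2_mean)
  table
}

#' Convert a corrected single-cell table to a dose-response table
#'
#' @param table A `single_cell_table` with `ch1_corrected` filled in.
#' @return A [dose_response_table()] using the corrected reporter channel.
#' @export
as_dose_response_sc <- function(table) {
  if (all(is.na(table$ch1_corrected)))
    stop("apply correct_fluorescence() first")
  dose_response_table(table$dose_nM, table$cell_id, table$ch1_corrected)
}

#' Fit a sigmoidal dose-response curve
#'
#' Least-squares fit of `y = basal + amplitude * dose^h / (dose^h + EC50^h)`
#' with EC50 parameterized on the log10 scale and optional
#' multiplicative-error weighting (weights 1/y^2), via
#' Levenberg-Marquardt.
#'
#' @param dose,response Paired dose (nM) and mean response values
#'   (>= 4 points spanning the transition).
#' @param weighting `"multiplicative"` (default) or `"none"`.
#' @param fix_hill Fix the Hill slope at 1 instead of estimating it; the
#'   free slope roughly doubles the EC50 sampling error on sparse designs.
#' @return List with `basal`, `amplitude`, `ec50`, `hill`, the `fit`
#'   object, residual standard error, and a logical `identifiable` flag
#'   (FALSE when the fitted amplitude is indistinguishable from flat data).
#' @export
fit_sigmoid_ec50 <- function(dose, response, weighting = "multiplicative",
                             fix_hill = FALSE) {
  stopifnot(length(dose) == length(response), length(dose) >= 4)
  d <- data.frame(dose = dose, y = response)
  rng <- range(response)
  start <- list(basal = rng[1], amplitude = diff(rng),
                lec50 = stats::median(log10(dose[dose > 0])))
  if (!fix_hill) start$h <- 1
  w <- if (identical(weighting, "multiplicative")) 1 / pmax(response, 1e-12)^2
       else rep(1, length(response))
  form <- if (fix_hill) y ~ basal + amplitude * dose / (dose + 10^lec50)
          else y ~ basal + amplitude * dose^h / (dose^h + (10^lec50)^h)
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = d, start = start, weights = w,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error"))
    stop("sigmoid fit did not converge: ", conditionMessage(fit))
  cf <- stats::coef(fit)
  amp <- unname(cf["amplitude"])
  identifiable <- is.finite(amp) && abs(amp) > 0.02 * max(abs(response))
  list(basal = unname(cf["basal"]), amplitude = amp,
       ec50 = unname(10^cf["lec50"]),
       hill = if (fix_hill) 1 else unname(cf["h"]),
       fit = fit, sigma = stats::sigma(fit), identifiable = identifiable)
}

#' Classify induction of a gene at saturating stimulus
#'
#' Twofold-change rule on expression at the maximal dose relative to the
#' untreated sample: ratio >= 2 is induced, <= 0.5 repressed, otherwise
#' unchanged.
#'
#' @param treated,untreated Expression levels (> 0).
#' @return `"induced"`, `"repressed"` or `"unchanged"` (vectorized).
#' @export
classify_induction <- function(treated, untreated) {
  if (any(untreated <= 0) || any(treated <= 0))
    stop("expression values must be > 0")
  ratio <- treated / untreated
  ifelse(ratio >= 2, "induced", ifelse(ratio <= 0.5, "repressed", "unchanged"))
}
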