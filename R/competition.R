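#' Configuration of a co-culture growth-competition experiment
#'
#' Two labelled strains grow exponentially between serial dilutions (1:50
#' twice a day by default); the competitor carries a fractional growth
#' deficit `s` that acts only in the stimulated culture.  Daily
#' flow-cytometry measurements draw a fixed number of cells per sample
#' (multinomial counting noise).
#'
#' @param r Reference growth rate (1/day).
#' @param s Selection coefficient (fitness defect) of the competitor,
#'   in [0, 1).
#' @param dilution_factor Fold dilution at each transfer (> 1).
#' @param dilutions_per_day Number of transfers per day.
#' @param days Duration (days); measurements once a day including day 0.
#' @param n0 Initial cells per strain.
#' @param n_counted Cells acquired per flow sample (0 = noise-free).
#' @param seed RNG seed.
#' @return A `coculture_config` list.
#' @export
coculture_config <- function(r = 10, s = 0.005, dilution_factor = 50,
                             dilutions_per_day = 2, days = 7,
                             n0 = 1e6, n_counted = 1e4, seed = 1) {
  stopifnot(r > 0, s >= 0, s < 1, dilution_factor > 1, days >= 1, n0 > 0)
  structure(as.list(environment()), class = "coculture_config")
}

#' Simulate a paired co-culture competition
#'
#' Deterministic exponential growth at rates `r` (reference) and
#' `r * (1 - s)` (competitor) between dilution events; the paired
#' unstimulated culture grows with `s = 0`.  Strain ratios are measured
#' once per day with multinomial counting noise, and the stimulated ratio
#' is normalized to the unstimulated one.
#'
#' @param config A [coculture_config()].
#' @return A `coculture_trajectory` data frame with columns `day`,
#'   `ratio_plus` (competitor/reference with stimulus), `ratio_minus`
#'   (without), `norm_ratio` (plus/minus, 1 at day 0 by construction of
#'   equal inocula).
#' @export
simulate_coculture <- function(config) {
  stopifnot(inherits(config, "coculture_config"))
  cfg <- config
  # between measurements the dilutions cancel out of the ratio; track
  # log abundances to avoid overflow over many generations
  days <- 0:cfg$days
  log_ref <- log(cfg$n0) + cfg$r * days
  log_cmp_plus <- log(cfg$n0) + cfg$r * (1 - cfg$s) * days
  log_cmp_minus <- log(cfg$n0) + cfg$r * days
  measure <- function(log_a, log_b, day, salt) {
    pa <- 1 / (1 + exp(log_b - log_a))
    if (pa <= 0 || pa >= 1) stop("strain extinct at day ", day)
    if (cfg$n_counted <= 0) return(pa / (1 - pa))
    counts <- with_substream(cfg$seed, day, salt,
                             stats::rbinom(1, cfg$n_counted, pa))
    if (counts == 0 || counts == cfg$n_counted)
      stop("strain extinct in sample at day ", day)
    counts / (cfg$n_counted - counts)
  }
  ratio_plus <- vapply(seq_along(days), function(i)
    measure(log_cmp_plus[i], log_ref[i], days[i], 2L), numeric(1))
  ratio_minus <- vapply(seq_along(days), function(i)
    measure(log_cmp_minus[i], log_ref[i], days[i], 3L), numeric(1))
  out <- data.frame(day = days, ratio_plus = ratio_plus,
                    ratio_minus = ratio_minus,
                    norm_ratio = ratio_plus / ratio_minus)
  class(out) <- c("coculture_trajectory", "data.frame")
  attr(out, "config") <- cfg
  out
}

#' Rate of divergence of the strain ratio
#'
#' Ordinary least-squares slope of log(normalized ratio) against time.
#' For exponential competition the expectation is `-r * s` per day for the
#' competitor/reference ratio (sign tells which strain wins).
#'
#' @param trajectory A `coculture_trajectory`, or a data frame with
#'   columns `day` and `norm_ratio`.
#' @return List with `slope` (1/day), `se`, and 95% confidence interval.
#' @export
divergence_rate <- function(trajectory) {
  if (nrow(trajectory) < 3) stop("need at least 3 time points")
  if (any(trajectory$norm_ratio <= 0)) stop("non-positive ratios")
  fit <- stats::lm(log(norm_ratio) ~ day, data = trajectory)
  cf <- summary(fit)$coefficients
  ci <- stats::confint(fit)["day", ]
  list(slope = unname(cf["day", "Estimate"]), se = unname(cf["day", "Std. Error"]),
       ci = unname(ci))
}

#' Convert a divergence slope to a percent fitness defect
#'
#' Under exponential competition the log-ratio diverges at `r * s` per
#' day, so the fitness defect is `100 * |slope| / r` percent.
#'
#' @param slope Divergence rate (1/day).
#' @param growth_rate Reference growth rate (1/day), > 0.
#' @return Percent fitness defect.
#' @export
fitness_defect <- function(slope, growth_rate) {
  if (growth_rate <= 0) stop("growth_rate must be > 0")
  100 * abs(slope) / growth_rate
}

#' Growth rate from doubling time
#'
#' @param doubling_time_min Doubling time in minutes (> 0).
#' @return Growth rate in 1/day (`ln 2 / doubling time`).
#' @export
growth_rate_from_doubling <- function(doubling_time_min) {
  if (any(doubling_time_min <= 0)) stop("doubling time must be > 0")
  log(2) / doubling_time_min * 60 * 24
}

#' Energetic fitness cost as a fraction of the cell's energy budget
#'
#' Relates a signalling ATP-consumption rate (e.g. the Fus3 futile-cycle
#' flux from [energy_rate_at_endpoint()], converted to molecules per cell
#' per second by the caller) to the total cellular energy turnover, under
#' the assumption that fitness cost is proportional to the energy share.
#'
#' @param atp_rate_per_cell Signalling ATP rate (molecules/s/cell), > 0
#'   allowed to be 0.
#' @param total_energy_budget Total cellular energy turnover
#'   (molecules/s/cell), > 0.
#' @return Percent of the energy budget.
#' @export
predicted_fitness_cost <- function(atp_rate_per_cell, total_energy_budget) {
  if (total_energy_budget <= 0) stop("total energy budget must be > 0")
  if (atp_rate_per_cell < 0) stop("ATP rate must be >= 0")
  100 * atp_rate_per_cell / total_energy_budget
}
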