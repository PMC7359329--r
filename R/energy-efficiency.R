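#' Per-dose energy-consumption profile of an ensemble
#'
#' Population-mean total hydrolysis rate (GTP + ATP) and its components at
#' every dose, plus the (relative Fus3-PP, energy) curve with Fus3-PP
#' normalized to its per-profile maximum for cross-genotype comparison.
#'
#' @param res An `ensemble_result` from [run_ensemble()].
#' @return An `energy_profile` data frame (`dose_nM`, `E` = mean total
#'   rate, `E_gtp`, `E_atp`, `fpp_rel`).
#' @export
energy_profile <- function(res) {
  s <- res$summary
  out <- data.frame(dose_nM = s$dose_nM,
                    E = s$mean_jtotal, E_gtp = s$mean_jgtp,
                    E_atp = s$mean_jatp,
                    fpp_rel = s$mean_Fpp / max(s$mean_Fpp))
  class(out) <- c("energy_profile", "data.frame")
  out
}

#' Information-per-energy efficiency
#'
#' Prior-weighted integral of Fisher information per unit energy rate over
#' the input range: Efficiency = integral of F(theta)/E(theta) P(theta)
#' d(theta) between `theta1` and `theta2`, evaluated by trapezoidal
#' quadrature on the supplied grid (in log10-dose coordinate, matching the
#' geometric grids used throughout).  The default prior is uniform over
#' log10 dose on the restricted range.
#'
#' @param fisher Per-input Fisher information values.
#' @param energy Per-input energy rates (must be > 0 on the range).
#' @param dose Input grid (nM), strictly increasing.
#' @param prior Optional prior density over log10 dose at the grid points;
#'   normalized internally.  Default uniform.
#' @param theta1,theta2 Integration limits (nM); default full grid.
#' @return Scalar efficiency (information per unit energy rate).
#' @export
efficiency <- function(fisher, energy, dose, prior = NULL,
                       theta1 = min(dose), theta2 = max(dose)) {
  stopifnot(length(fisher) == length(dose), length(energy) == length(dose))
  keep <- dose >= theta1 & dose <= theta2
  if (sum(keep) < 2) stop("fewer than two grid points inside [theta1, theta2]")
  f <- fisher[keep]; e <- energy[keep]; u <- log10(dose[keep])
  if (any(e <= 0))
    stop("energy rate must be positive on the integration range; ",
         "zero/negative at dose ", paste(dose[keep][e <= 0], collapse = ", "))
  p <- if (is.null(prior)) rep(1, length(u)) else prior[keep]
  p <- p / trapz(u, p)
  trapz(u, f / e * p)
}

#' Sweep the feedback-promoter affinities
#'
#' For every (KD_SST2, KD_MSG5) pair on the grid, runs a population
#' ensemble, computes the total Fisher information of the Fus3-PP output
#' (mean of the per-input profile), the prior-weighted mean energy rate,
#' and the information-per-energy efficiency.  Each grid cell uses the same
#' ensemble seed, so results are reproducible and differences between cells
#' reflect the affinities alone.
#'
#' @param base Baseline `cascade_params` (default: shipped calibration).
#' @param kd_sst2,kd_msg5 Affinity grids (nM), positive; log spacing
#'   recommended.
#' @param config An [ensemble_config()]; `n_cells` may be reduced for
#'   desk-scale runs.
#' @param output Endpoint used as the information-carrying output
#'   (default `"Fpp_end"`, active Fus3).
#' @return A `kd_sweep` list: `$grid` long-format data frame (`kd_sst2`,
#'   `kd_msg5`, `total_fisher`, `mean_energy`, `efficiency`), plus the
#'   configuration for provenance.
#' @export
kd_sweep <- function(base = NULL, kd_sst2, kd_msg5, config,
                     output = "Fpp_end") {
  if (is.null(base)) base <- default_parameters()
  stopifnot(all(kd_sst2 > 0), all(kd_msg5 > 0))
  rows <- list()
  for (ks in kd_sst2) for (km in kd_msg5) {
    p <- base
    p$genes["SST2", "KD"] <- ks
    p$genes["MSG5", "KD"] <- km
    p$init <- basal_steady_state(p)
    row <- tryCatch({
      res <- run_ensemble(config, base = p)
      cell_metrics(res, output = output)
    }, error = function(e) {
      warning("sweep cell (KD_SST2=", ks, ", KD_MSG5=", km, ") failed: ",
              conditionMessage(e))
      c(total_fisher = NA_real_, mean_energy = NA_real_,
        efficiency = NA_real_)
    })
    rows[[length(rows) + 1]] <- data.frame(kd_sst2 = ks, kd_msg5 = km,
                                           total_fisher = row[["total_fisher"]],
                                           mean_energy = row[["mean_energy"]],
                                           efficiency = row[["efficiency"]])
  }
  structure(list(grid = do.call(rbind, rows), config = config),
            class = "kd_sweep")
}

#' Information, energy and efficiency of one ensemble
#'
#' @param res An `ensemble_result`.
#' @param output Endpoint column used as the channel output.
#' @return Named vector `total_fisher` (mean per-input Fisher information),
#'   `mean_energy` (log-dose-uniform mean of the per-dose energy rate) and
#'   `efficiency` (Eq.-style information per energy).
#' @export
cell_metrics <- function(res, output = "Fpp_end") {
  tb <- as_dose_response(res, output = output)
  prof <- fisher_profile(tb)
  ep <- energy_profile(res)
  ep <- ep[ep$dose_nM %in% prof$dose_nM, ]
  u <- log10(ep$dose_nM)
  c(total_fisher = attr(prof, "total"),
    mean_energy = trapz(u, ep$E) / (max(u) - min(u)),
    efficiency = efficiency(prof$fisher, ep$E, ep$dose_nM))
}
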