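# Per-cell RNG substreams.  Each (seed, cell_id, salt) triple is hashed to
# its own base-R seed so parameter draws do not depend on the order in which
# cells are simulated.  The hash chains exact Lehmer (MINSTD) steps — all
# intermediate products stay below 2^53, so the modular arithmetic is exact
# in doubles and nearby inputs map to well-separated states.  The global RNG
# state is saved and restored around the draw.
.substream_seed <- function(seed, cell_id, salt = 0L) {
  m <- 2147483647
  step <- function(x) (48271 * x) %% m
  x <- (as.double(seed) %% (m - 1)) + 1
  x <- step(x)
  x <- step((x + as.double(cell_id)) %% (m - 1) + 1)
  x <- step((x + as.double(salt)) %% (m - 1) + 1)
  as.integer(step(x))
}

with_substream <- function(seed, cell_id, salt, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(.substream_seed(seed, cell_id, salt))
  expr
}

# log-normal factor with coefficient of variation cv, centred at median 1
# (parameter ensembles) or mean 1 (assay signals, so configured sigmoids
# are recovered exactly in expectation)
.lognormal_factor <- function(n, cv, center = c("median", "mean")) {
  center <- match.arg(center)
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- if (center == "mean") -sdlog^2 / 2 else 0
  stats::rlnorm(n, meanlog = meanlog, sdlog = sdlog)
}

#' Ensemble configuration
#'
#' Defaults follow the simulated study conditions: 500 cells for 1000 s over
#' a 15-point geometric dose grid of serial 3-fold increases starting at
#' 1e-4 nM (so the top dose is 1e-4 * 3^14, about 478 nM, a 3^14 ~ 4.8e6-fold
#' range).
#'
#' @param n_cells Number of cells per dose.
#' @param dose_grid Strictly increasing pheromone doses (nM), all > 0
#'   (an optional leading 0 is allowed as a basal point).
#' @param t_end Simulated duration per cell (s).
#' @param cv_extrinsic Coefficient of variation of the log-normal (median-1)
#'   factors applied to synthesis rates and initial concentrations.
#' @param seed Integer RNG seed.
#' @param genotype Genotype label understood by [apply_genotype()].
#' @param shared_factor If `TRUE`, one log-normal factor per cell multiplies
#'   all randomized quantities (a fully correlated extrinsic mode); default
#'   is independent factors per quantity.
#' @return An `ensemble_config` list.
#' @export
ensemble_config <- function(n_cells = 500,
                            dose_grid = 1e-4 * 3^(0:14),
                            t_end = 1000,
                            cv_extrinsic = 0.25,
                            seed = 1,
                            genotype = "wt",
                            shared_factor = FALSE) {
  stopifnot(n_cells >= 2, t_end > 0, cv_extrinsic >= 0)
  pos <- dose_grid[dose_grid > 0]
  if (any(dose_grid < 0) || sum(dose_grid == 0) > 1)
    stop("doses must be > 0, with at most one basal theta = 0 point")
  if (any(diff(dose_grid) <= 0)) stop("dose grid must be strictly increasing")
  structure(list(n_cells = as.integer(n_cells), dose_grid = dose_grid,
                 t_end = t_end, cv_extrinsic = cv_extrinsic,
                 seed = as.integer(seed), genotype = genotype,
                 shared_factor = shared_factor),
            class = "ensemble_config")
}

#' Randomize parameters for one cell
#'
#' Multiplies every synthesis rate (`beta0`, `beta` of each induced gene)
#' and every nonzero initial concentration by an independent log-normal
#' factor with median 1 and coefficient of variation `cv_extrinsic`.
#' Deterministic in `(seed, cell_id)` and independent of call order.
#'
#' @param base A `cascade_params` object.
#' @param cv_extrinsic Extrinsic-noise CV (>= 0).
#' @param seed Ensemble seed.
#' @param cell_id Integer cell index.
#' @param shared_factor Use a single per-cell factor for all quantities.
#' @return A `cascade_params` object for this cell.
#' @export
sample_cell_parameters <- function(base, cv_extrinsic, seed, cell_id,
                                   shared_factor = FALSE) {
  if (cv_extrinsic < 0) stop("cv_extrinsic must be >= 0")
  if (cv_extrinsic == 0) return(base)
  p <- base
  with_substream(seed, cell_id, 0L, {
    ng <- nrow(p$genes)
    if (shared_factor) {
      f <- .lognormal_factor(1, cv_extrinsic)
      fb0 <- rep(f, ng); fb1 <- rep(f, ng); fi <- rep(f, 6)
    } else {
      fb0 <- .lognormal_factor(ng, cv_extrinsic)
      fb1 <- .lognormal_factor(ng, cv_extrinsic)
      fi <- .lognormal_factor(6, cv_extrinsic)
    }
    p$genes$beta0 <- p$genes$beta0 * fb0
    p$genes$beta <- p$genes$beta * fb1
    init <- p$init
    perturbable <- c("Rtot", "Ftot", "Ttot", "Sst2", "Msg5", "Rep")
    init[perturbable] <- init[perturbable] * fi
    p$init <- init
  })
  p$Ttot <- unname(p$init["Ttot"])
  p
}

#' Simulate a heterogeneous cell population over a dose grid
#'
#' Every cell draws its own randomized parameters once (via
#' [sample_cell_parameters()]) and is integrated at every dose of the grid.
#' Endpoint outputs and terminal-window energy rates are tabulated per
#' (dose, cell), with per-dose population summaries.
#'
#' @param config An [ensemble_config()].
#' @param base Baseline `cascade_params`; defaults to the shipped
#'   calibration with `config$genotype` applied.
#' @param energy_window Terminal window (s) for energy-rate averaging.
#' @return An `ensemble_result` list: `$cells` (data frame with columns
#'   `dose_nM`, `cell_id`, `Fpp_end`, `Rep_end`, `jgtp`, `jatp`, `jtotal`),
#'   `$summary` (per-dose mean/sd/cv of both outputs and mean energy rates),
#'   and the configuration.
#' @export
run_ensemble <- function(config, base = NULL, energy_window = 200) {
  stopifnot(inherits(config, "ensemble_config"))
  if (is.null(base)) base <- default_parameters()
  base <- apply_genotype(base, config$genotype)
  doses <- config$dose_grid
  n <- config$n_cells
  rows <- vector("list", n)
  first_error <- NULL
  for (cell in seq_len(n)) {
    pc <- sample_cell_parameters(base, config$cv_extrinsic, config$seed, cell,
                                 config$shared_factor)
    out <- lapply(doses, function(th) {
      pc$theta <- th
      tryCatch({
        traj <- simulate_cell(pc, t_end = config$t_end)
        ep <- endpoint_state(traj)
        er <- energy_rate_at_endpoint(traj, window = energy_window)
        c(dose_nM = th, cell_id = cell, Fpp_end = unname(ep["Fpp"]),
          Rep_end = unname(ep["Rep"]), jgtp = er$jgtp,
          jatp = er$jatp1 + er$jatp2, jtotal = er$jtotal)
      }, error = function(e) {
        if (is.null(first_error)) first_error <<- conditionMessage(e)
        c(dose_nM = th, cell_id = cell, Fpp_end = NA_real_, Rep_end = NA_real_,
          jgtp = NA_real_, jatp = NA_real_, jtotal = NA_real_)
      })
    })
    rows[[cell]] <- do.call(rbind, out)
  }
  cells <- as.data.frame(do.call(rbind, rows))
  nfail <- sum(is.na(cells$Fpp_end))
  if (nfail > 0.01 * nrow(cells))
    stop(nfail, " of ", nrow(cells), " cell/dose integrations failed",
         if (!is.null(first_error)) paste0(" (first error: ", first_error, ")"))
  if (nfail > 0) warning(nfail, " cell/dose integrations failed; dropped")
  cells <- cells[!is.na(cells$Fpp_end), ]
  summ <- do.call(rbind, lapply(split(cells, cells$dose_nM), function(d) {
    data.frame(dose_nM = d$dose_nM[1], n = nrow(d),
               mean_Fpp = mean(d$Fpp_end), sd_Fpp = stats::sd(d$Fpp_end),
               mean_Rep = mean(d$Rep_end), sd_Rep = stats::sd(d$Rep_end),
               mean_jgtp = mean(d$jgtp), mean_jatp = mean(d$jatp),
               mean_jtotal = mean(d$jtotal))
  }))
  summ <- summ[order(summ$dose_nM), ]
  summ$cv_Fpp <- ifelse(summ$mean_Fpp > 0, summ$sd_Fpp / summ$mean_Fpp, NA)
  summ$cv_Rep <- ifelse(summ$mean_Rep > 0, summ$sd_Rep / summ$mean_Rep, NA)
  rownames(summ) <- NULL
  structure(list(cells = cells, summary = summ, config = config),
            class = "ensemble_result")
}

#' Write an ensemble result as delimited text plus JSON metadata
#'
#' @param res An `ensemble_result`.
#' @param dir Output directory (created if needed); writes `cells.tsv`,
#'   `summary.tsv` and `metadata.json`.
#' @return `dir`, invisibly.
#' @export
write_ensemble <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(res$cells, file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res$summary, file.path(dir, "summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(unclass(res$config),
                         file.path(dir, "metadata.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
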