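#' @useDynLib mapkinfo
NULL

# state vector layout shared by the R and C right-hand sides
.state_names <- c("A", "Rtot", "Ftot", "Fpp", "Ttot", "Tp",
                  "Sst2", "Msg5", "Rep", "Egtp", "Eatp")
.gene_names <- c("STE2", "FUS3", "SST2", "MSG5", "FUS1")
.scalar_par_names <- c("theta", "KR", "kact", "kact0", "kgap0", "kgap", "kf",
                       "kd0", "kd", "kt", "ktb", "Ttot", "natp_fus3",
                       "natp_ste12")

#' Default calibration of the pheromone cascade model
#'
#' Reads the versioned calibration shipped with the package
#' (`extdata/default_params.yaml`) and returns a validated parameter set.
#'
#' @param file Optional path to an alternative YAML calibration file.
#' @return An object of class `cascade_params`: a list of rate constants,
#'   a `genes` data frame (one row per Ste12-P-inducible gene with columns
#'   `beta0`, `beta`, `KD`, `n`, `gamma`), and the pre-stimulus initial
#'   state in `$init`.
#' @seealso [cascade_params()], [simulate_cell()]
#' @export
default_parameters <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "default_params.yaml",
                        package = "mapkinfo", mustWork = TRUE)
  }
  read_parameters(file)
}

#' Construct a cascade parameter set
#'
#' @param theta Pheromone dose (nM).
#' @param KR Receptor half-activation dose (nM).
#' @param kact,kgap0,kgap Upstream activation and (Sst2-dependent)
#'   deactivation rate constants; every deactivation event hydrolyses one GTP.
#' @param kact0 Receptor-independent basal activation rate (1/s); gives the
#'   pathway its pheromone-free basal activity, which the negative
#'   feedbacks suppress.
#' @param kf,kd0,kd Fus3 phosphorylation and (Msg5-dependent)
#'   dephosphorylation rate constants.
#' @param kt,ktb Ste12 phosphorylation/dephosphorylation rate constants.
#' @param Ttot Total Ste12 (nM); Ste12 is not transcriptionally induced.
#' @param natp_fus3,natp_ste12 ATP hydrolysed per activation event at each
#'   cascade stage (2 for the doubly phosphorylated Fus3, 1 for Ste12).
#' @param genes Data frame with rownames `STE2, FUS3, SST2, MSG5, FUS1` and
#'   columns `beta0` (basal synthesis, nM/s), `beta` (induced synthesis),
#'   `KD` (promoter affinity, nM of Ste12-P), `n` (Hill coefficient), and
#'   `gamma` (degradation/dilution, 1/s).
#' @param init Optional named initial-state vector; defaults to the
#'   pre-stimulus steady state at `theta = 0`.
#' @return A `cascade_params` object.
#' @export
cascade_params <- function(theta = 0, KR = 20, kact = 0.02, kact0 = 5e-7,
                           kgap0 = 0.001, kgap = 1e-4,
                           kf = 0.08, kd0 = 0.01, kd = 2e-3,
                           kt = 5e-5, ktb = 5e-3, Ttot = 200,
                           natp_fus3 = 2, natp_ste12 = 1,
                           genes, init = NULL) {
  p <- list(theta = theta, KR = KR, kact = kact, kact0 = kact0,
            kgap0 = kgap0, kgap = kgap,
            kf = kf, kd0 = kd0, kd = kd, kt = kt, ktb = ktb, Ttot = Ttot,
            natp_fus3 = natp_fus3, natp_ste12 = natp_ste12,
            genes = genes)
  class(p) <- "cascade_params"
  validate_parameters(p)
  p$init <- if (is.null(init)) basal_steady_state(p) else init
  p
}

#' Validate a cascade parameter set
#'
#' Checks positivity of rate constants and promoter affinities, the gene
#' table layout, and non-negative synthesis rates.  Called by all
#' constructors; exported so externally assembled lists can be checked.
#'
#' @param p A `cascade_params` object (or plain list with the same fields).
#' @return `p`, invisibly, if valid; otherwise an error.
#' @export
validate_parameters <- function(p) {
  rates <- c("KR", "kact", "kgap0", "kgap", "kf", "kd0", "kd", "kt", "ktb")
  for (nm in rates) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] <= 0)
      stop("parameter '", nm, "' must be a single positive number")
  }
  if (p$theta < 0) stop("pheromone dose theta must be >= 0")
  if (p$kact0 < 0) stop("kact0 must be >= 0")
  if (p$Ttot <= 0) stop("Ttot must be > 0")
  if (p$natp_fus3 < 0 || p$natp_ste12 < 0) stop("ATP stoichiometries must be >= 0")
  g <- p$genes
  if (!is.data.frame(g) || !setequal(rownames(g), .gene_names))
    stop("genes must be a data frame with rows ", paste(.gene_names, collapse = ", "))
  need <- c("beta0", "beta", "KD", "n", "gamma")
  if (!all(need %in% names(g)))
    stop("gene table must have columns ", paste(need, collapse = ", "))
  if (any(g$beta0 < 0) || any(g$beta < 0)) stop("synthesis rates must be >= 0")
  if (any(g$KD <= 0) || any(g$n <= 0) || any(g$gamma <= 0))
    stop("KD, n and gamma must be > 0")
  invisible(p)
}

#' Read / write cascade parameters as YAML
#'
#' The on-disk schema mirrors [cascade_params()]: scalar rate constants plus
#' a `genes` block keyed by gene name.  Unknown keys are rejected so that
#' typos in configuration files fail loudly.
#'
#' @param file Path to a YAML file.
#' @return `read_parameters()` returns a `cascade_params` object;
#'   `write_parameters()` returns `file` invisibly.
#' @export
read_parameters <- function(file) {
  raw <- yaml::read_yaml(file)
  known <- c(.scalar_par_names, "genes")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0)
    stop("unknown parameter keys in ", file, ": ", paste(extra, collapse = ", "))
  if (is.null(raw$genes)) stop("parameter file must contain a 'genes' block")
  # YAML 1.1 reads a bare 'n' key as boolean FALSE; map it back
  raw$genes <- lapply(raw$genes, function(gl) {
    names(gl)[names(gl) %in% c("FALSE", "n")] <- "n"
    gl
  })
  g <- do.call(rbind, lapply(raw$genes, as.data.frame))
  rownames(g) <- names(raw$genes)
  args <- raw[setdiff(names(raw), "genes")]
  do.call(cascade_params, c(args, list(genes = g)))
}

#' @rdname read_parameters
#' @param p A `cascade_params` object.
#' @export
write_parameters <- function(p, file) {
  out <- p[.scalar_par_names]
  out$genes <- lapply(rownames(p$genes), function(g) as.list(p$genes[g, ]))
  names(out$genes) <- rownames(p$genes)
  yaml::write_yaml(out, file)
  invisible(file)
}

#' Pre-stimulus steady state
#'
#' Relaxes the cascade at `theta = 0` from the zero-activity state (induced
#' genes at their basal level `beta0 / gamma`) until it settles.  With basal
#' activation (`kact0 > 0`) the resting pathway carries a small pheromone-free
#' activity that the negative feedbacks suppress, so the steady state has no
#' closed form and is computed numerically.  Energy counters are reset to 0.
#'
#' @param p A `cascade_params` object (the `init` field is not used).
#' @param t_relax Relaxation horizon (s); generous relative to the slowest
#'   (gene-expression) timescale.
#' @return Named state vector (concentrations in nM, energy counters at 0).
#' @export
basal_steady_state <- function(p, t_relax = 5e4) {
  g <- p$genes
  basal <- g$beta0 / g$gamma
  names(basal) <- rownames(g)
  y0 <- c(A = 0,
          Rtot = unname(basal["STE2"]),
          Ftot = unname(basal["FUS3"]),
          Fpp = 0,
          Ttot = p$Ttot,
          Tp = 0,
          Sst2 = unname(basal["SST2"]),
          Msg5 = unname(basal["MSG5"]),
          Rep = unname(basal["FUS1"]),
          Egtp = 0, Eatp = 0)[.state_names]
  if (p$kact0 == 0) return(y0)
  p0 <- p
  p0$theta <- 0
  out <- deSolve::ode(y = y0, times = c(0, t_relax / 2, t_relax),
                      func = "cascade_derivs", parms = .parms_vector(p0),
                      dllname = "mapkinfo", initfunc = "cascade_initmod",
                      method = "lsoda", atol = 1e-10, rtol = 1e-10)
  st <- out[nrow(out), .state_names]
  st[st < 0 & st > -1e-6] <- 0   # solver round-off
  st[c("Egtp", "Eatp")] <- 0
  st
}

# Hill occupancy of a Ste12-P-driven promoter; 0 for non-positive Tp.
.hill <- function(Tp, KD, n) {
  if (Tp <= 0) return(0)
  Tp^n / (Tp^n + KD^n)
}

#' Time derivatives of the cascade state
#'
#' Mass-action/Hill kinetics of the two-step phosphorylation cascade:
#' receptor/G-protein activation by pheromone with Sst2(GAP)-dependent
#' deactivation (one GTP per deactivation event), a Fus3
#' phosphorylation/dephosphorylation cycle with Msg5-dependent phosphatase
#' activity, a Ste12 activation cycle, Ste12-P-driven transcription of
#' STE2, FUS3, SST2, MSG5 and the FUS1 reporter, and cumulative GTP/ATP
#' hydrolysis counters.
#'
#' @param t Time (unused; the system is autonomous).
#' @param state Named state vector (see [basal_steady_state()] for layout).
#' @param p A `cascade_params` object.
#' @return A list whose first element is the derivative vector, as expected
#'   by [deSolve::ode()].
#' @export
cascade_rhs <- function(t, state, p) {
  if (any(state[c("A", "Rtot", "Ftot", "Fpp", "Ttot", "Tp",
                  "Sst2", "Msg5", "Rep")] < -1e-9))
    stop("negative concentration in state")
  if (p$theta < 0) stop("pheromone dose theta must be >= 0")
  with(as.list(state), {
    occR <- p$theta / (p$theta + p$KR)
    deact <- (p$kgap0 + p$kgap * Sst2)
    dA <- (p$kact0 + p$kact * occR) * (Rtot - A) - deact * A
    phos_f <- p$kf * A * (Ftot - Fpp)
    dephos_f <- (p$kd0 + p$kd * Msg5) * Fpp
    dFpp <- phos_f - dephos_f
    phos_t <- p$kt * Fpp * (Ttot - Tp)
    dTp <- phos_t - p$ktb * Tp
    g <- p$genes
    occ <- vapply(rownames(g), function(nm) .hill(Tp, g[nm, "KD"], g[nm, "n"]),
                  numeric(1))
    synth <- g$beta0 + g$beta * occ
    names(synth) <- rownames(g)
    dRtot <- synth[["STE2"]] - g["STE2", "gamma"] * Rtot
    dFtot <- synth[["FUS3"]] - g["FUS3", "gamma"] * Ftot
    dSst2 <- synth[["SST2"]] - g["SST2", "gamma"] * Sst2
    dMsg5 <- synth[["MSG5"]] - g["MSG5", "gamma"] * Msg5
    dRep  <- synth[["FUS1"]] - g["FUS1", "gamma"] * Rep
    dEgtp <- deact * A
    dEatp <- p$natp_fus3 * phos_f + p$natp_ste12 * phos_t
    list(c(dA, dRtot, dFtot, dFpp, 0, dTp, dSst2, dMsg5, dRep, dEgtp, dEatp))
  })
}

# flatten parameters into the fixed-order numeric vector used by the C rhs
.parms_vector <- function(p) {
  g <- p$genes[.gene_names, ]
  c(p$theta, p$KR, p$kact, p$kact0, p$kgap0, p$kgap, p$kf, p$kd0, p$kd,
    p$kt, p$ktb, p$natp_fus3, p$natp_ste12,
    as.vector(t(as.matrix(g[, c("beta0", "beta", "KD", "n", "gamma")]))))
}

#' Simulate a single cell
#'
#' Integrates the cascade from its (possibly cell-specific) pre-stimulus
#' state after a pheromone step at `t = 0`, using a stiff-capable solver
#' (`lsoda`) on a fixed output grid.  The compiled right-hand side is used
#' by default; `engine = "R"` uses [cascade_rhs()] (identical dynamics,
#' exercised against each other in the test suite).
#'
#' @param p A `cascade_params` object with `theta` set to the dose.
#' @param t_end Duration of the simulation (s); default 1000.
#' @param dt_out Output grid spacing (s).
#' @param engine `"compiled"` or `"R"`.
#' @param atol,rtol Solver tolerances, scaled for nM-level species.
#' @return A `cascade_trajectory`: the deSolve output matrix (time plus the
#'   state columns) with the parameters attached as an attribute.
#' @export
simulate_cell <- function(p, t_end = 1000, dt_out = 10, engine = "compiled",
                          atol = 1e-8, rtol = 1e-8) {
  if (t_end <= 0) stop("t_end must be > 0")
  validate_parameters(p)
  times <- seq(0, t_end, by = dt_out)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  y0 <- p$init[.state_names]
  y0[y0 < 0 & y0 > -1e-9] <- 0   # tolerate solver round-off from relaxation
  if (any(y0[1:9] < 0)) stop("negative concentration in initial state")
  out <- if (identical(engine, "compiled")) {
    deSolve::ode(y = y0, times = times, func = "cascade_derivs",
                 parms = .parms_vector(p), dllname = "mapkinfo",
                 initfunc = "cascade_initmod", method = "lsoda",
                 atol = atol, rtol = rtol)
  } else {
    deSolve::ode(y = y0, times = times, func = cascade_rhs, parms = p,
                 method = "lsoda", atol = atol, rtol = rtol)
  }
  if (attr(out, "istate")[1] < 0)
    stop("integration failed at theta = ", p$theta)
  structure(out, class = c("cascade_trajectory", class(out)), params = p)
}

#' Endpoint of a trajectory
#'
#' @param traj A `cascade_trajectory`.
#' @return Named state vector at the final time point.
#' @export
endpoint_state <- function(traj) {
  last <- traj[nrow(traj), ]
  last[.state_names]
}

#' Time-averaged energy fluxes over the terminal window
#'
#' Instantaneous hydrolysis rates are reconstructed from the stored state
#' (GTP: G-protein deactivation; ATP: Fus3 and Ste12 phosphorylation
#' influx weighted by their stoichiometries) and averaged over the last
#' `window` seconds by trapezoidal quadrature.
#'
#' @param traj A `cascade_trajectory`.
#' @param window Length of the terminal averaging window (s).
#' @return List with components `jgtp`, `jatp1` (Fus3 cycle), `jatp2`
#'   (Ste12 cycle) and `jtotal`, in nM-equivalents per second.
#' @export
energy_rate_at_endpoint <- function(traj, window = 200) {
  if (window <= 0) stop("window must be > 0")
  p <- attr(traj, "params")
  t <- traj[, "time"]
  t_end <- t[length(t)]
  if (window > t_end) stop("window longer than simulated duration")
  keep <- t >= t_end - window
  if (sum(keep) < 2) stop("terminal window contains fewer than two points")
  tt <- t[keep]
  jgtp <- (p$kgap0 + p$kgap * traj[keep, "Sst2"]) * traj[keep, "A"]
  jatp1 <- p$natp_fus3 * p$kf * traj[keep, "A"] *
    (traj[keep, "Ftot"] - traj[keep, "Fpp"])
  jatp2 <- p$natp_ste12 * p$kt * traj[keep, "Fpp"] *
    (traj[keep, "Ttot"] - traj[keep, "Tp"])
  avg <- function(v) trapz(tt, v) / (tt[length(tt)] - tt[1])
  jg <- avg(jgtp); j1 <- avg(jatp1); j2 <- avg(jatp2)
  list(jgtp = jg, jatp1 = j1, jatp2 = j2, jtotal = jg + j1 + j2)
}

#' Apply a genotype to a parameter set
#'
#' `"wt"` leaves the calibration untouched; `"msg5d"` and `"sst2d"` delete
#' the respective feedback gene (synthesis and initial protein set to zero);
#' `"msg5_sensitized"` lowers the MSG5 promoter KD to the sensitive SST2
#' value (8 nM), emulating replacement of the native MSG5 promoter by an
#' early-induced pheromone-responsive promoter.
#'
#' @param p A `cascade_params` object.
#' @param genotype One of `"wt"`, `"msg5d"`, `"sst2d"`, `"msg5_sensitized"`.
#' @return Modified `cascade_params` object with `init` recomputed.
#' @export
apply_genotype <- function(p, genotype = c("wt", "msg5d", "sst2d",
                                           "msg5_sensitized")) {
  genotype <- match.arg(genotype)
  if (genotype == "msg5d") {
    p$genes["MSG5", c("beta0", "beta")] <- 0
  } else if (genotype == "sst2d") {
    p$genes["SST2", c("beta0", "beta")] <- 0
  } else if (genotype == "msg5_sensitized") {
    p$genes["MSG5", "KD"] <- 8
  }
  p$init <- basal_steady_state(p)
  p
}

# trapezoidal quadrature on an (x, y) grid
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

#' Write a trajectory as tidy delimited text with a JSON parameter sidecar
#'
#' @param traj A `cascade_trajectory`.
#' @param file Output path for the tab-separated trajectory table; the
#'   parameter sidecar is written next to it as `<file>.json`.
#' @return `file`, invisibly.
#' @export
write_trajectory <- function(traj, file) {
  utils::write.table(as.data.frame(unclass(traj)), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  p <- attr(traj, "params")
  sidecar <- paste0(file, ".json")
  meta <- p[.scalar_par_names]
  meta$genes <- as.data.frame(p$genes)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  }
  invisible(file)
}
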