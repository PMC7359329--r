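# Small parameter sets and tables shared across tests.

# frozen-feedback parameters: induced synthesis off and basal synthesis
# balancing degradation, so all protein totals stay constant and the cascade
# reduces to independent push-pull cycles with closed-form steady states
frozen_params <- function(theta = 1, Rtot = 150, Ftot = 300,
                          Sst2 = 25, Msg5 = 30) {
  p <- default_parameters()
  totals <- c(STE2 = Rtot, FUS3 = Ftot, SST2 = Sst2, MSG5 = Msg5, FUS1 = 10)
  p$genes$beta <- 0
  p$genes$beta0 <- p$genes$gamma * totals[rownames(p$genes)]
  p$kact0 <- 0
  p$theta <- theta
  init <- basal_steady_state(p)   # closed form: kact0 = 0
  p$init <- init
  p
}

# closed-form fixed points of the frozen cascade
frozen_steady <- function(p) {
  occR <- p$theta / (p$theta + p$KR)
  act <- p$kact0 + p$kact * occR
  deact <- p$kgap0 + p$kgap * p$init[["Sst2"]]
  A <- act * p$init[["Rtot"]] / (act + deact)
  kdtot <- p$kd0 + p$kd * p$init[["Msg5"]]
  Fpp <- p$init[["Ftot"]] * p$kf * A / (p$kf * A + kdtot)
  Tp <- p$init[["Ttot"]] * p$kt * Fpp / (p$kt * Fpp + p$ktb)
  list(A = A, Fpp = Fpp, Tp = Tp, kdtot = kdtot, deact = deact)
}

# Gaussian dose-response table on a geometric grid
gaussian_table <- function(doses, mu, sigma, n = 200, seed = 42) {
  set.seed(seed)
  do.call(rbind, lapply(seq_along(doses), function(i) {
    data.frame(dose_nM = doses[i], cell_id = seq_len(n),
               output = stats::rnorm(n, mu[i], sigma[i]))
  })) |> (\(d) dose_response_table(d$dose_nM, d$cell_id, d$output))()
}
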