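# Default calibration of the pheromone-pathway cascade model.
#
# Units: concentrations in nM, time in seconds.  Rate constants are first
# order (1/s) or second order (1/(nM s)).  Synthesis rates beta0/beta in
# nM/s.  The calibration is chosen so that the wild type (KD of the MSG5
# promoter = 700 nM) produces a graded, monotone dose response over the
# default 10^-4 .. ~480 nM pheromone grid, and so that Ste12
# phosphorylation and promoter binding saturate at lower pathway activity
# than Fus3 phosphorylation does.
theta: 0.0          # pheromone dose (nM); set per simulation
KR: 20.0            # receptor half-activation dose (nM)
kact: 0.02          # upstream activation rate constant (1/s)
kact0: 5.0e-7       # receptor-independent basal activation (1/s); sets basal pathway activity
kgap0: 0.001        # basal G-protein deactivation (1/s)
kgap: 1.0e-4        # Sst2-dependent deactivation (1/(nM s)); each event burns one GTP
kf: 0.08            # Fus3 phosphorylation by active upstream signal (1/(nM s))
kd0: 0.01           # basal Fus3 dephosphorylation (1/s)
kd: 2.0e-3          # Msg5-dependent Fus3 dephosphorylation (1/(nM s))
kt: 5.0e-5          # Ste12 phosphorylation by Fus3-PP (1/(nM s))
ktb: 5.0e-3         # Ste12 dephosphorylation (1/s)
Ttot: 200.0         # total Ste12 (nM), not transcriptionally induced
natp_fus3: 2        # ATP per Fus3 activation event (double phosphorylation)
natp_ste12: 1       # ATP per Ste12 activation event
genes:              # Ste12-P-driven promoters: X' = beta0 + beta*occ(Tp) - gamma*X
  STE2:  {beta0: 0.50, beta: 1.00, KD: 50.0,  n: 1, gamma: 0.005}
  FUS3:  {beta0: 1.00, beta: 1.00, KD: 50.0,  n: 1, gamma: 0.005}
  SST2:  {beta0: 0.10, beta: 1.50, KD: 8.0,   n: 1, gamma: 0.005}
  MSG5:  {beta0: 0.10, beta: 1.50, KD: 700.0, n: 1, gamma: 0.005}
  FUS1:  {beta0: 0.02, beta: 1.00, KD: 100.0, n: 1, gamma: 0.005}
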