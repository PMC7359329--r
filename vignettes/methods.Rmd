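---
title: "Modelling information transmission and its energetic cost in the yeast pheromone pathway"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling information transmission and its energetic cost in the yeast pheromone pathway}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapkinfo)
```

# The model

`mapkinfo` simulates the *Saccharomyces cerevisiae* pheromone (mating)
response as a two-step phosphorylation cascade in a single cell:

* **Upstream signal `A`** (active receptor/G-protein, lumped): activated at
  rate $(k_{act,0} + k_{act}\,\theta/(\theta+K_R))\,(R_{tot}-A)$ and
  deactivated at rate $(k_{gap,0} + k_{gap}\,[\mathrm{Sst2}])\,A$.  Every
  deactivation event hydrolyses one GTP, which the model counts.  The small
  receptor-independent term $k_{act,0}$ gives the resting pathway a basal
  activity; this is deliberate, because the suppression of basal activity by
  the negative feedbacks is one of the phenomena the package studies, and a
  model with identically zero basal output cannot express it.
* **MAP kinase Fus3**: a push–pull cycle
  $dF_{pp}/dt = k_f A (F_{tot}-F_{pp}) - (k_{d,0} + k_d\,[\mathrm{Msg5}])\,F_{pp}$.
  Double phosphorylation is lumped into one activation step that costs
  `natp_fus3 = 2` ATP, preserving the two-phosphate stoichiometry of the
  active Fus3-PP species.
* **Transcription factor Ste12**: an analogous cycle driven by Fus3-PP,
  costing one ATP per activation.  Its parameters are chosen so that Ste12
  phosphorylation and promoter occupancy saturate at lower pathway activity
  than Fus3 phosphorylation does — the downstream bottleneck that makes the
  transcriptional reporter lose information at high stimulation.
* **Gene expression**: active Ste12-P drives the promoters of *STE2*,
  *FUS3* (positive feedbacks), *SST2*, *MSG5* (negative feedbacks) and the
  *FUS1* reporter through first-order Hill terms
  $\beta_{g,0} + \beta_g\,T_p^{n}/(T_p^{n}+K_{D,g}^{n})$ with degradation
  $\gamma_g X$.  The two promoter affinities $K_D^{SST2}$ and $K_D^{MSG5}$
  are the sweepable design parameters of the study; the wild-type
  calibration uses 8 nM for *SST2* (early, sensitive induction) and 700 nM
  for *MSG5* (late, insensitive induction).

All eleven state variables (including the cumulative GTP and ATP counters)
are integrated with a stiff-capable solver (`deSolve::lsoda`) on a fixed
output grid; the right-hand side is compiled C for the population runs and
has a reference R implementation tested against it.  Cells start from the
pre-stimulus steady state at $\theta = 0$, computed by relaxation, and
receive a pheromone step at $t = 0$.

## Units and default calibration

Concentrations are in nM, time in seconds, doses in nM of pheromone, energy
in nM-equivalents of hydrolysed nucleotide per second per cell.  The
supplementary parameter values of the original model are not available to
this package, so the shipped calibration
(`inst/extdata/default_params.yaml`, a versioned configuration file rather
than constants in code) was chosen to satisfy the qualitative constraints
the study states: a graded, monotone response of both Fus3-PP and the
reporter across the default dose grid ($10^{-4}$ nM with fourteen serial
3-fold increases, ≈ 480 nM top, a $3^{14} \approx 5\times10^6$-fold range);
early Ste12 saturation; suppressed basal activity and lower noise in the
wild type relative to feedback deletions; and the information/efficiency
structure of the promoter-affinity sweeps discussed below.  Timescales are
compressed relative to physiology (protein turnover $\gamma = 0.005$
s$^{-1}$) so that transcriptional feedback acts within the 1000-s
simulations, matching the short-horizon design of the study.

# The population ensemble

Cell-to-cell variability is extrinsic: every synthesis rate
($\beta_{g,0}, \beta_g$) and every initial protein concentration is
multiplied by an independent log-normal factor with median 1 and
coefficient of variation `cv_extrinsic` (default 0.25, a typical
extrinsic-noise magnitude; the source text does not print the spread).
Draws are keyed by `(seed, cell_id)` through a counter-based substream, so
results are independent of execution order and bit-reproducible.  A
`shared_factor` mode (one factor per cell) is available for fully
correlated extrinsic noise.  Intrinsic molecular-number stochasticity is
out of scope: the ensemble is deterministic ODEs with randomized
parameters.

What this emulates — and what it does not: the generator reproduces the
statistical structure used by the study (log-normal population spread,
graded mean responses, saturation), but not mechanistic features such as
receptor trafficking, the Kss1 branch, cell-cycle arrest, or slow
fluctuation dynamics within a cell's lifetime.  Tests passing on these
ensembles therefore validate the estimators and the comparative design
claims, not any particular quantitative prediction about real cells.

# Information metrics

Per-dose output samples (simulated reporter or Fus3-PP endpoints, or
synthetic microscopy intensities) are reduced to mean $\mu$ and standard
deviation $\sigma$ per dose, smoothed as functions of $u = \log_{10}\theta$
with cubic smoothing splines (smoothing chosen by generalized
cross-validation; the smoothed $\sigma$ is floor-clamped at $10^{-4}$ of
its maximum so Fisher information stays finite).  Fisher information of the
assumed-Gaussian channel is computed by numerical quadrature of
$E[(\partial_u \log N(x;\mu(u),\sigma(u)))^2]$ and must agree with the
closed form $(\mu'^2 + 2\sigma'^2)/\sigma^2$ to $10^{-6}$ relative — the
test suite sweeps randomized parameters over both routes.  Information is
reported per $(\log_{10}\text{dose})^2$; the log-dose coordinate matches
the geometric dose grids, and the reparameterization to linear dose is the
exact chain rule (also tested).

Local mutual information follows the sliding-window construction: three
consecutive doses with uniform prior, outputs pooled to define 20
equal-width bins, $I = H(\text{pooled}) - \overline{H(\text{per dose})}$
in bits, bounded by $\log_2 3$.  Empty bins contribute $0\log 0 = 0$; no
bias correction is applied by default (none is stated by the source), and
the zero/saturation limits are pinned by construction-based tests.

Aggregated information is the trapezoidal integral of the per-input values
over $u$ (optionally partitioned into output-level bins through the
$\mu_i$ mapping); total information is the unweighted mean over inputs.

`project_noise()` builds hybrid channels — one strain's mean response with
another strain's noise interpolated at matched output level — to decompose
information differences into output-range and noise contributions.
Interpolation is linear in $\mu$ with constant extrapolation at the
boundary; non-overlapping output ranges are refused.

# Energy and efficiency

Energy rates are reconstructed from the states (GTP: deactivation flux;
ATP: the two phosphorylation influxes weighted by their stoichiometries)
and averaged over the terminal 200 s of each simulation; a quadrature test
checks the counters against the integrated rates.  The efficiency
functional is the prior-weighted integral of $F(\theta)/E(\theta)$ over the
dose range, evaluated by the trapezoid rule in $u$ with a uniform-in-$u$
prior by default (the input prior is a modelling choice; any prior can be
supplied).  The integration range defaults to the full simulated grid.

Two structural facts drive the sweep results and are worth stating
explicitly, because they are properties of the model class rather than of a
particular calibration.  First, with static extrinsic noise a
transcriptional negative feedback suppresses the slope of the mean response
and the transmitted noise by the same loop gain, so feedback earns Fisher
information mainly where it prevents saturation (of Fus3 phosphorylation,
of Ste12, of the receptor), not by linear noise filtering.  Second, at a
fixed output level a stronger downstream phosphatase raises the futile-cycle
flux at *both* cascade stages (the compensating input must rise), whereas a
stronger upstream GAP raises only the cheap GTP flux; this asymmetry is
what breaks the symmetry of the efficiency landscape toward insensitive
*MSG5* induction, and it survives any calibration in which the ATP cycle
dominates the energy budget.

# Synthetic single-cell assay

`generate_population()` emulates microscopy tables: a Hill-sigmoid mean
response, log-normal cell-to-cell factors (centred at mean 1 so the
configured sigmoid is the exact expectation), Gaussian autofluorescence in
both channels, and linear bleed-through of the constitutive marker channel
into the reporter channel.  Correction constants are estimated the way the
experimental design does it: the marker-free control gives the channel-2
autofluorescence; regressing channel 1 on channel 2 in the reporter-free
control gives the bleed-through slope and, combined, the channel-1
autofluorescence.  Percentile trimming removes the upper and lower three
linear-interpolation percentiles per field of view and time point in either
channel; ties at the cut survive, so degenerate groups lose nothing, and a
group can lose at most ~12%.

Trimming is a truncation filter: it shrinks the per-dose standard deviation
by the truncation factor (~15% for near-Gaussian outputs) and therefore
*raises* Fisher information of the filtered channel relative to the
unfiltered one.  The round-trip validation accounts for this by comparing
the desk-scale pipeline against the exact (large-sample) moments of the
*filtered* channel; the unfiltered pipeline is separately checked against
the closed-form channel moments.

EC50 fitting uses Levenberg–Marquardt least squares on the Hill function
with the EC50 parameterized on the log scale and multiplicative-error
weighting ($1/y^2$), the GLS-optimal choice for proportional noise.  The
Hill slope is free by default; `fix_hill = TRUE` halves the EC50 sampling
error on sparse designs and is used where the slope is known.  Flat data
are flagged unidentifiable rather than returned as a spurious EC50.

# Competition assays

Co-cultures grow exponentially between twice-daily 1:50 dilutions (the
regime that keeps cells in exponential phase, so lag and stationary phases
are not modelled); the competitor's growth rate is $r(1-s)$ under stimulus
and $r$ without, and the measured quantity is the daily strain ratio from a
fixed number (default $10^4$) of counted cells, normalized to the paired
unstimulated culture.  The divergence rate is the OLS slope of the
log-ratio in time — exactly $-rs$ per day in the noise-free limit — and
$100\,|{\rm slope}|/r$ converts it to a percent fitness defect (a 100-min
doubling time gives $r \approx 10\,\mathrm{day}^{-1}$).  Counting noise
sets a hard floor on per-replicate precision: two binomial samples of
$10^4$ cells per day over eight days give the slope a standard error near
9% of a 0.05/day signal, so recovery guarantees are stated for the bulk of
replicates (95%) and for the mean, which is unbiased.

# Problem sizes and reproducibility

The analysis scripts and the validation suite run at desk scale by choice:
100 cells per dose on the 15-dose grid for population contrasts, corner
pairs instead of dense grids for the affinity sweeps (a `--full` flag
switches the scripts to 500 cells and denser grids), 3000 cells per dose
for the microscopy round trip, and 200 replicate co-cultures.  Every
random quantity is derived from an explicit seed: ensembles use per-cell
substreams, the analysis scripts fix seed 11, and `scripts/acceptance.R`
threads its `--seed` argument through every component.

# Known limitations

* The ODE parameterization is a reconstruction calibrated to stated
  phenomena, not fitted to data; absolute magnitudes (concentrations,
  energy rates) are meaningful only relatively.
* Gaussian-channel Fisher information understates the information of
  strongly skewed output distributions; the log-normal population factors
  keep per-dose outputs close enough to Gaussian for the comparisons made
  here, but heavy-tailed real data would need a different channel model.
* The binned MI estimator carries the usual small-sample positive bias
  (visible in the identical-distributions limit); an optional
  Miller–Madow-style correction is deliberately not applied by default so
  estimates are comparable to the uncorrected convention.
* Feedback deletions are modelled as zero synthesis of the regulator, not
  as removal of the protein's other roles; compensatory phosphatases are
  outside the model.
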