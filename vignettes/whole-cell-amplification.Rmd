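---
title: "Whole-cell balanced amplification: models, estimators and simulation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-cell balanced amplification: models, estimators and simulation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampscale)
```

# The scientific question

Whole-cell balanced amplification is the hypothesis that a neuron can scale
its entire synaptic input at once: a CaMKII-dependent phosphorylation
doubles the single-channel conductance of every AMPA and every GABA~A~
receptor in the cell, so that all excitatory and all inhibitory synaptic
responses double together.  Because the operation is multiplicative and
balanced, it should (i) double the net synaptic current under voltage
clamp without moving its reversal point, (ii) multiply both the mean and
the standard deviation of the free-running net current by a common factor
smaller than two (driving-force compression), and (iii) act as a
near-linear gain control on the spiking response, effective the instant
the synaptic input changes.

`ampscale` implements three layers of that programme:

1. **Miniature-event statistics** — estimators for the signatures that
   whole-cell scaling leaves in miniature postsynaptic current (mEPSC /
   mIPSC) recordings: per-cell blocker-effect ratios, two-cluster
   segregation, affected-fraction estimation, computational reversal of a
   blocker effect under competing generative models, and permutation
   Cramér–von Mises / Kolmogorov–Smirnov distribution tests.
2. **Peak-scaled non-stationary fluctuation analysis (NSFA)** — recovery
   of the single-channel current $i$ and channel count $N$ from the
   parabolic relation between ensemble variance and mean current during
   event decay, $\sigma^2(t) = i\,I(t) - I(t)^2/N + \sigma_b^2$.
3. **A conductance-based single-neuron model** — a three-cylinder
   pyramidal cell under Poisson synaptic bombardment, with the ×2
   whole-cell conductance operator, voltage-clamp and bump protocols, and
   the closed-form theory (shot-noise variance; Gaussian threshold-linear
   firing rate) that predicts the amplification factor.

A synthetic-data generator with known ground truth drives all recovery
tests: the raw recordings behind the miniature-event analyses are not
publicly available, so every statistical claim in this package is tested
as *structural recovery on generated data*, never as a reproduction of
experimental cell counts.

# Miniature-event model and estimators

## Amplitude model

`amplitude_model()` describes a per-cell mini amplitude distribution as a
Gaussian body truncated to `[detection_floor, tail_start]` plus an
exponential tail above `tail_start`:

| parameter | default | meaning |
|---|---|---|
| `body_mean`, `body_sd` | 8, 2.5 pA | Gaussian body of the weak-synapse section |
| `tail_weight` | 0.15 | probability mass of the strong-synapse tail |
| `tail_start` | 13 pA | conventional strong/weak boundary |
| `tail_scale` | 3 pA | mean excess of tail events over the boundary |
| `detection_floor` | 5 pA | smallest detectable event |

The family is a pragmatic choice: empirical mini histograms show a
Gaussian-like body with a heavy right tail, and the mixture makes the
tail mass (the "strong" events) an explicit, testable parameter.  The
analytic mean is available via `mean()`, and sampling is inverse-CDF so
that a fixed seed plus an amplification factor yields exactly the scaled
sample (`sample_cell_events(..., amplification = 2)` returns twice the
base draws).

## Blocker effect, affected fraction, and the two generative conventions

If a blocker divides the amplitude of a fraction $x$ of events by a
factor $a$, the ratio of mean amplitudes before/after the drug is
$y = (1-x) + x\,a$, inverted by `affected_fraction()` as
$x = (y-1)/(a-1)$.  Two generative conventions are implemented for
pre/post pairs (`make_blocker_pair()`, `simulate_blocker_experiment()`):

* **mixture-on-pre** (default): the post sample is the base distribution
  and the pre sample is a mixture with a fraction $x$ of events
  $a$-fold amplified.  Under this convention the formula above and the
  multiplicative reversal procedure are both *exact*, which is why it is
  the default for recovery tests.
* **fully-doubled-pre**: the pre sample is entirely amplified and the
  blocker divides a random fraction $x$ of the post events — the
  biologically literal story of a partially effective drug.  Under this
  convention $y = a/(a - x(a-1))$, so the formula-based $\hat x$ is a
  biased approximation (e.g. true $x = 0.65$, $a = 2$ gives
  $\hat x \approx 0.48$).  The two conventions coincide only at
  $x \in \{0, 1\}$; the package keeps both so the tension is explicit
  rather than hidden.

## Clustering and distribution tests

`cluster_effects()` uses 2-means on the z-scored `(y_mean, y_sd)` plane
with 50 restarts under a fixed seed, labelling the cluster with the
larger centroid mean ratio "affected", and reports the mean silhouette
width (Euclidean distance).  k-means with two centres is the simplest
method consistent with reporting a silhouette, and at the sample sizes
involved (tens of cells) nothing more elaborate is identifiable.

`cvm_two_sample()` computes the two-sample Cramér–von Mises criterion
$T = \frac{nm}{(n+m)^2}\sum_k (F_1(z_k) - F_2(z_k))^2$ over the pooled
observations, with a label-permutation p-value (default 9,999
permutations; tests use fewer).  Ties are handled by evaluating both
empirical CDFs after each tie block.  Whether the reference analyses used
permutation or asymptotic p-values is not stated anywhere we could
check; permutation is exact for exchangeable data and needs no
large-sample assumption, so it is the package's choice.  Alongside `p`,
the complement `difference_likelihood = 1 - p` is reported because the
distribution-overlap claims of this literature are usually quoted in
that direction.  Affected-event counts are rounded half-to-even.

## Reversal procedures

`reverse_blocker()` reconstructs the pre-blocker distribution from the
post events under three models: multiplicative (a random
$\mathrm{round}(\hat x n)$ of events ×$a$), additive (every event plus
an independent uniform draw from $[0, 2(\bar{\text{pre}} -
\bar{\text{post}})]$ — restores the mean, not the shape), and triple
(the multiplicative procedure with the factor forced to 3).  On
mixture-convention data the multiplicative reversal is statistically
indistinguishable from the true pre sample while both negative controls
are rejected — the model-comparison logic the estimators are built for.

# Peak-scaled NSFA

`preprocess_events()` discards events whose measured 10–90% rise time is
≥ 1.5 ms (electrotonically remote events violate the point-source
assumption), baseline-subtracts, aligns events on their 3-point-smoothed
peak, scales each trace to the ensemble mean peak and estimates the
background variance from a 5 ms pre-event window (the window length is a
package choice; only "background variance subtracted" is conventionally
specified).  `decay_variance_profile()` divides the decay — peak down to
10% of peak, another package choice — into 30 equal-time bins and
computes per-bin mean current and ensemble variance about the scaled
mean.  `fit_nsfa()` fits $\sigma^2 - \sigma_b^2 = iI - I^2/N$ by
unweighted linear least squares in $(I, I^2)$, reporting $R$ as the
Pearson correlation between observed and fitted variances and rejecting
fits with $R \le 0.85$ or non-physical parameters.  Unweighted least
squares and Pearson-$R$ acceptance mirror the conventions of the
standard NSFA software chain.

The generator (`synth_nsfa_waveforms()`) sums $N$ independent binary
channels whose open probability follows a unit-peak dual-exponential, so
all channels are open at the peak and the binomial variance law holds
exactly during the decay; Gaussian baseline noise is added.  This is the
minimal generative model for which peak scaling is consistent — it omits
multi-conductance states, gating correlations and quantal variability,
so passing recovery tests demonstrate estimator correctness, not
robustness to every biological nuisance.

# The conductance-based cell

## Structure and parameters

The cell is an unbranched chain of cylindrical compartments (≤ 10 µm):
basal dendrite 80 × 3 µm, soma 12 × 20 µm, apical dendrite 200 × 2.5 µm;
axial resistivity 50 Ω cm, C~m~ 2 µF/cm², leak 2·10⁻⁴ S/cm² at −80 mV
(swept −100…−70 mV in the excitability protocols).  Spike currents
(transient Na 0.2, delayed-rectifier K 0.14, A-type K 0.1 S/cm²) sit in
the soma; adaptation currents (M-type K 0.01, high-threshold Ca 0.003,
Ca-dependent AHP K 0.002 S/cm²) in the proximal 30 µm of the apical
dendrite, with a single calcium pool
$[\mathrm{Ca}]' = -\varphi I_{Ca} - ([\mathrm{Ca}]-[\mathrm{Ca}]_0)/\tau$,
$\tau = 10$ ms, $\varphi = 1/(2F\cdot d)$ with $d$ the cell diameter
(units chosen so the pool lives in µM and the AHP conductance activates
during spiking).

Channel kinetics are standard Traub–Miles/Hodgkin–Huxley forms for the
spike currents and Mainen-style forms for the modulatory currents.  The
kinetics themselves are not uniquely determined by any printed parameter
set, so they were calibrated *once* against the model's published
emergent behaviour and then frozen:

* the spike-threshold parameter (`VT = −50 mV`) was set so that the cell
  is a regular spiker with moderate adaptation under step currents *and*
  sits in the sparse, fluctuation-driven regime under background
  bombardment (with the textbook `VT = −58` the cell fires tens of Hz at
  the background operating point and brief input bumps saturate);
* AMPA kinetics default to rise 0.5 / decay 1.5 ms and GABA~A~ to rise
  1 / decay 5 ms.  With slower decays (AMPA 3, GABA 8 ms) the
  time-integrated conductances are too large relative to the leak: the
  subthreshold voltage SD, the balanced rate ratio, and the unitary EPSP
  all drift away from their published values simultaneously.  The faster
  constants restore all of them at once (voltage SD ≈ 3.9→4.0 mV,
  reversal ≈ −37→−39 mV, paired-run scaling ≈ 1.46/1.59).

Numerics: semi-implicit backward Euler on the voltage chain (tridiagonal
solve, dt = 0.025 ms default), exponential Euler for gating and calcium,
and analytic per-step decay of the aggregated dual-exponential synaptic
states, so cost per step is independent of the synapse count.  Halving
dt changes 500 ms spike counts by ≤ 1 and subthreshold voltage by
< 0.2 mV RMS; halving the spatial step moves the resting potential by
< 0.1 mV.  Spikes are upward crossings of −10 mV with a 2 ms
deduplication interval.

## Synaptic population and calibration

350 excitatory and 350 inhibitory dual-exponential synapses are placed
uniformly (by length) along both dendrites.  Peak conductances are
calibrated the way synaptic strength is actually measured: a passive
soma-clamp simulation of a unit-conductance event gives, per
compartment, the somatic current per nS, and each synapse's conductance
is its target amplitude divided by that transfer amplitude.  Excitatory
amplitudes follow the mini amplitude model scaled to a mean of 70 pA
(recorded at −80 mV against a 0 mV reversal); inhibitory amplitudes are
uniform with mean 100 pA (recorded at −60 mV against the ~0 mV chloride
reversal of a CsCl electrode), while the running model uses an
inhibitory reversal of −75 mV.  The resulting inhibitory conductances
span ≈ 0.9–2.7 nS — exactly the published per-synapse spread, which is
what identifies those printed ranges as per-synapse, not per-set,
quantities.  Synapses whose base mini draw is ≥ 13 pA are flagged
`strong`.

Background Poisson rates are *constructed*, not free: given the
time-averaged conductance per Hz of each class (analytic for
dual-exponential synapses), `background_rates()` solves for the
inhibitory rate that places the conductance-weighted reversal of the net
synaptic current at −37 mV, the value measured in vivo during UP states
and expected at balance.  With the calibrated amplitudes this puts the
inhibitory rate at roughly 0.2–0.5× the excitatory rate; it is treated
as the dependent variable throughout (its value can fall below the 2 Hz
lower edge quoted for the excitatory sweep — the reversal target takes
precedence, because the model's construction is explicitly "rates such
that the reversal is −37 mV").

## Whole-cell amplification and its measurement

`apply_whole_cell_amplification()` multiplies every synaptic peak
conductance by the factor (default 2), touching nothing else.  Under an
ideal space clamp every synaptic current is linear in its conductance,
so the net current doubles *exactly*, sample by sample, its polarity and
reversal potential are preserved, and its SD doubles exactly — these are
machine-precision invariants in the test suite, not approximations.

Free-running measurements use paired runs with identical event times
(the schedule is fixed; only conductances change), so every ratio is a
within-realisation comparison.  Analog statistics (net-current mean/SD,
voltage mean/SD and Gaussian-fit r²) are taken from sodium-off companion
runs: with spikes in the trace the scaling ratios are contaminated by
action currents and blanking, and clean Gaussian voltage fits require
spike-free traces.  Spike counts come from the sodium-on runs of the
same schedules.

# Protocols

* `protocol_balance_sweep()` sweeps the inhibitory/excitatory rate balance
  (11→3 Hz against 2→10 Hz in 0.5 Hz steps) under space clamp, measuring
  the 200 ms-averaged net current before/after ×2 scaling and the
  reversal potential of each (invariant within 1 mV).
* `protocol_gain()` samples the gain-protocol space by Latin hypercube —
  excitatory strength scale ×1–3 on a log axis (stretching the
  per-synapse AMPA spread over ≈ 0.6–10 nS) and excitatory rate 2–5 Hz,
  inhibitory rate from the balance construction — and, per set, runs
  paired 500 ms simulations at strong-synapse activation fractions
  15/30/45/60% (rate reallocation that conserves the expected total
  excitatory event count).  Sets whose sodium-off mean potential is
  ≥ −55 mV are excluded and not simulated further.  Outputs per-set
  current-scaling ratios and input–output slopes
  (spikes vs pre-amplification mean current, with an `r > 0.95`
  linearity gate).
* `protocol_bumps()` / `protocol_bump_probability()` modulate the excitatory rate by
  $1 + 5\,\alpha(t/\tau)$, with the classical alpha function
  $\alpha(u) = u e^{-u}$ (peak $1/e$), at 30 random non-overlapping
  onsets per trace (τ = 24 ms and 12 ms respectively), across a
  leak-reversal (−100…−70 mV) × synaptic-strength (×0.6–2, independent
  for E and I) × rate-co-modulation (×1–3) space.  The unit-peak alpha
  convention was rejected because it drives the cell into saturated
  burst firing inside every bump, which contradicts the published
  description of bumps as moderate transients.  The base excitatory
  rate of this protocol (0.6 Hz before co-modulation) was anchored to
  two published quantities: the within-bump firing-rate increase after
  amplification (≈ 10 Hz) and the depolarised edge (−62 mV) of the
  baseline-potential span.  Spike-attribution windows are
  $[t_{on}, t_{on}+4\tau]$.
* `run_mini_pipeline()` chains the miniature-event estimators:
  per-cell effects → clustering → affected fraction from the affected
  cluster's mean effect → per-cell reversals under the three models →
  doubled-control reconstruction → cumulative-curve reconstruction from
  per-cell means.

Problem sizes in the shipped tests and acceptance script (40 parameter
sets for the gain protocol, 35 sets × 30 bumps for the bump protocol,
2.5 s background runs, 100-seed calibration loops, ~10² permutations in
loops and ~10⁴ available for single calls) are the package's default
working sizes; all counts are arguments, so larger studies just pass
larger numbers.

# Closed-form theory

`shot_noise_variance()` evaluates the within-window variance of a
current made of $N$ exponentially decaying events (decay τ, mean
amplitude $\bar\omega$, amplitude CV) with onsets uniform in a window
$T$:
$$\sigma^2 = \bar\omega^2 N \frac{\tau}{T}
  \left(\frac{1+CV^2}{2} - \frac{\tau}{T}\right), \qquad \tau \ll T .$$
This is Campbell's theorem with the finite-window mean correction; the
test suite verifies it against a brute-force event-superposition
simulation to 3 Monte-Carlo standard errors and checks that the
approximation error grows with τ/T.  (An alternative arrangement of the
CV term that places it at order $(\tau/T)^2$ fails the brute-force
oracle for CV > 0 by ~25% and was therefore not used.)  The quadratic
dependence on $\bar\omega$ — versus linear dependence on $N$ — is the
analytic reason amplitude-side scaling moves current fluctuations so
much more than rate-side changes.

`rate_threshold_linear()` is the Gaussian positive-part expectation
$F = \beta\,[\sigma\varphi(z) + (\bar I - \theta)\Phi(z)]$,
$z = (\bar I - \theta)/\sigma$ — the firing rate of a threshold-linear
neuron driven by Gaussian net current — with the exact degenerate limit
at $\sigma = 0$.  `amplification_factor()` forms the ratio after scaling
$(\bar I, \sigma)$ jointly by $k$ ($\beta$ cancels; the ratio is exactly
$k$ at $\theta = 0$ and converges to $k$ far above threshold).
`amplification_sweep()` tabulates the ratio over the
$(\theta/\sigma,\ \bar I/\sigma)$ plane, and `bump_probability_sweep()`
converts rates to per-bump spike probabilities via
$P = 1 - e^{-F w}$ (Poisson spiking in a window $w$, default 30 ms — the
half-time of the short bumps), with $\beta$ set so the rate at
$\theta + 3\sigma$ equals a 100 or 150 Hz ceiling.  Under that mapping,
near-threshold bumps ($P \approx 0.5$) rise to $P \approx 0.75$ on
average after ×1.7 scaling while negligible bumps stay negligible; the
">90%" reliability quoted for simulated bumps is not reached by the
analytic mapping on the stated grid, because the β-ceiling rule places
all near-0.5 rows at low $\theta/\sigma$ where the closed-form rate
ratio is only ≈ 2.

# What the calibrated model does and does not reproduce

Computed at the package's default sizes (see `scripts/acceptance.R`):

* the four blocker-affected fractions follow exactly from the printed
  mean effects (65/47/73/48%);
* mean and SD scaling of the net synaptic current: ≈ 1.46 and ≈ 1.59
  (published 1.47 ± 0.06 and 1.70 ± 0.07).  The SD factor sits a few
  percent low because the doubled synaptic conductance is comparable to
  the leak in this cell and shunts the membrane; for the same reason the
  voltage-SD ratio (~1.1–1.3) stays well below the published 1.65;
* background calibration: subthreshold voltage SD ≈ 3.8 mV (3.9 ± 0.23)
  and net-current reversal ≈ −36 mV (−37);
* bump amplification: with the bump drive anchored to the published
  ~10 Hz within-bump rate increase, the mean spike gain per bump is
  ≈ 0.9 and near-Poisson, so the *strict-increase* share is ≈ 40–50%
  versus the published 74/23/<5 split.  Reproducing 74% requires an
  under-dispersed (almost always exactly +1 spike) response and a much
  narrower excitability spread across parameter sets than the published
  leak-reversal sweep produces here; the published membrane time
  constant and input resistance are themselves inconsistent with the
  published morphology table (τ_m 12 ms / R_in 114 MΩ vs the table's
  10 ms / 160 MΩ — the table is taken as authoritative), and that same
  tension is the likely root.  The anchored calibration was kept rather
  than tuning the statistic.

# Known limitations

* The morphology/passive inconsistency above means no parameterisation
  can match every published emergent number at once; the package
  documents which anchors each calibration used.
* The generator omits recording artefacts (series resistance,
  detection-threshold bias), inter-animal hierarchy, NMDA receptors and
  multi-state channel kinetics.
* The ideal space clamp used for clamp measurements makes the ×2
  linearity exact by construction; a real somatic electrode (the
  `clamp = "soma"` mode, used for synapse calibration) leaves dendritic
  driving forces free and breaks exactness at the few-percent level.
* Permutation tests assume exchangeability across events; hierarchical
  (cell-level) dependence is handled by analysing cells separately, not
  by a mixed model.
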