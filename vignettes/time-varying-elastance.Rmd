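---
title: "Time-varying respiratory elastance for spontaneously breathing patients"
author: "edrs package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-varying respiratory elastance for spontaneously breathing patients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(edrs)
```

## The problem

Respiratory mechanics estimated from ventilator waveforms can guide
mechanical ventilation, but conventional single-compartment estimation
assumes a passive patient. A spontaneously breathing patient generates
negative pleural pressure with every inspiration, and that effort corrupts
passive parameter estimates unless it is measured invasively (oesophageal
manometry) or modelled. This package implements the opposite approach:
instead of removing effort, it folds effort into a *time-varying* lumped
elastance and tracks that quantity breath by breath.

## Model

The single-compartment equation of motion during partial support is

$$P_{aw}(t) = R_{rs}\,Q(t) + E_{lung} V(t) + E_{chest} V(t) + E_{demand}(t) V(t) + \mathrm{PEEP},$$

where $P_{aw}$ is airway pressure (cmH$_2$O), $Q$ flow (L/s, inspiration
positive), $V$ inspired volume (L), $R_{rs}$ airway resistance
(cmH$_2$O·s/L). The three elastance components — lung tissue, chest wall,
and a *demand* term expressing the apparent elastance reduction produced by
the patient's inspiratory muscles — are not separately identifiable from
airway data, so they are lumped into one time-varying respiratory system
elastance $E_{drs}(t)$ and estimated per sample as

$$E_{drs}(t) = \frac{P_{aw}(t) - \mathrm{PEEP} - R_{rs} Q(t)}{V(t)}.$$

During active effort the muscular pressure $P_{mus}(t) \le 0$ makes
$E_{demand}(t) = P_{mus}(t)/V(t) \le 0$, so early in a patient-triggered
breath — large effort, small volume — $E_{drs}$ is *negative*. That sign is
the model's signature of spontaneous effort; a passive, machine-ventilated
breath has constant positive $E_{drs} = E_{lung} + E_{chest}$. Negative
elastance is a construct, not a physical tissue property: it encodes energy
injected by the patient.

Two conventions make $E_{drs}$ comparable across breaths, modes and
patients:

* **Fixed resistance.** $R_{rs}$ is held at 5 cmH$_2$O·s/L, a realistic
  value for intubated adults. Per-sample resistance is not identifiable
  from these waveforms, and a common constant preserves *trend*
  comparisons. The sensitivity is monotone: a larger assumed $R_{rs}$
  shifts the whole trajectory down wherever flow is positive (the package
  asserts this for $R_{rs} \in \{1, 5, 10\}$).
* **Normalised inspiratory time.** Each breath's inspiration is mapped
  onto $\tau \in [0, 1]$ (0–100% of inspiration) so trajectories with
  different inspiratory times overlay.

## Estimation pipeline

`edrs_fit()` chains four steps, each available separately:

1. **Segmentation** (`detect_breaths`). Inspiration is triggered where
   flow rises through `q_on` (default 0.05 L/s) and stays non-negative for
   `t_min` (default 0.2 s). The onset is then back-tracked to the start of
   the surrounding positive-flow run: volume integration must begin where
   flow departs from zero, because starting at the threshold crossing
   omits the first few millilitres and that bias — divided by the small
   near-onset volume — would corrupt exactly the early negative portion of
   the trajectory that carries the effort signal. Inspiration ends at the
   first negative-flow sample; expiration is kept only to delimit breaths.
2. **Volume** (`compute_volume`). Cumulative trapezoidal integration of
   flow, reset to zero at every onset so integrator drift cannot
   accumulate across breaths.
3. **Baseline pressure** (`estimate_peep`). The model is defined on
   pressure above baseline; the per-breath offset is the median airway
   pressure over the 0.05 s before onset (median, so a single spike
   artefact cannot move it). The first breath of a session that begins
   mid-support has no pre-onset window and falls back to the pressure at
   onset.
4. **Elastance and normalisation** (`compute_edrs_trace`,
   `normalize_trajectory`). The ratio above is evaluated wherever volume
   exceeds `v_min_frac` (default 2%) of the breath's tidal volume; earlier
   samples are masked invalid rather than clipped, preserving genuinely
   negative values at small-but-meaningful volumes while discarding the
   singular ones. The valid part is linearly interpolated onto a uniform
   grid of `n_grid = 101` points (one node per percent, so the common
   window endpoints 0.3 and 1.0 are grid nodes).

```{r fit}
sim <- simulate_session(sim_config(n_breaths = 30, seed = 7))
fit <- edrs_fit(sim$record)
fit
```

## Trajectory summaries and the AUC metric

Percentile trajectories (5th, 25th, 50th, 75th, 95th) are computed
*pointwise across breaths* at every grid node — the only construction that
yields one smooth curve per level over the whole inspiration — using the
standard linear-interpolation empirical quantile. The 5th–95th band width
summarises breath-to-breath variability.

The severity metric integrates each percentile trajectory over
$\tau \in [0.3, 1.0]$, skipping the effort-dominated first 30% of
inspiration. The normalised axis is treated as nominally one second, so a
constant elastance $E$ gives $0.7E$ and units stay cmH$_2$O·s/L. An AUC at
or above 25 (inclusive) flags ARDS-like stiffness, matching the elastance
level reported for sedated ARDS patients. The window is a *fraction* of
normalised inspiration: expressing it in seconds would make the metric
depend on each breath's true inspiratory time and defeat the
normalisation.

```{r summary}
summary(fit)
```

```{r plot, fig.alt = "Percentile trajectories of Edrs"}
plot(fit)
```

## Comparing ventilation modes

Pressure Support (PS) and Neurally Adjusted Ventilatory Assist (NAVA)
sessions of the same patient are compared with the patient as their own
control. Each breath is reduced to the median of its valid elastance over
the AUC window — pooling raw samples would pseudo-replicate the strong
within-breath correlation — and the per-breath values of the two modes are
tested with a two-sample Kolmogorov–Smirnov test and a two-sample Wilcoxon
rank-sum test at $p < 0.05$. Breaths are not paired across modes, which is
why the unpaired rank-sum form is used; the KS test gates the
`significant` flag because it is sensitive to any distributional change,
not only a location shift, and both p-values are reported. No
multiple-testing correction is applied across patients: results are
reported per patient. Note the two-sample KS test is slightly conservative
at these sample sizes (empirical size ≈ 0.035 at a nominal 0.05 with 100
breaths per mode).

```{r compare}
nava <- simulate_session(sim_config(n_breaths = 30, mode = "NAVA", seed = 8))
compare_modes(fit, edrs_fit(nava$record))
```

## The simulator

`simulate_session()` is a first-class component: it supplies waveforms
*and* the analytic elastance truth
$E_{drs}^{true}(t) = E_{lung} + E_{chest} + P_{mus}(t)/V(t)$, which is what
the test suite and the acceptance script validate the pipeline against.

**Mechanics and effort.** One linear compartment ($E_{lung} + E_{chest}$,
$R_{rs}$, PEEP). Effort is injected as a half-sine muscular pressure
$P_{mus}(t) = -a\,\sin(\pi t / t_{neural})$ over a neural inspiration of
$t_{neural}$ (default 1 s); the demand elastance is derived from it, never
generated directly, so there is no division-by-zero generative form. The
half-sine is a convention — the shape of real $P_{mus}$ is not prescribed
by the model.

**Controllers.** Both modes trigger where effort drives flow through
0.05 L/s. PS then applies a constant support (default 10 cmH$_2$O) with an
exponential pressurisation rise ($t_{rise}$, default 0.1 s, clinical range
0.05–0.2 s); NAVA applies `nava_gain` times the emitted Eadi with the same
rise, the gain defaulting to the value that delivers the same mean support
as PS. Support ends with the neural time; expiration is passive. The rise
matters numerically as well as clinically: an instantaneous pressure step
puts a discontinuity in flow, and no fixed-rate quadrature of a
discontinuous integrand can track volume accurately near the onset
(`t_rise = 0` is supported for textbook step-response checks).

**Integration.** Within each controller phase the forcing is a sum of
complex-exponential terms, so the volume ODE is solved in closed form and
the emitted waveforms are the exact continuous-time solution sampled on
the grid. The estimator's trapezoidal quadrature therefore shows its
honest $O(\Delta t^2)$ error against the truth: at 100 Hz the maximum
elastance recovery error over valid samples is below 0.5 cmH$_2$O/L, and
shrinks by roughly two orders of magnitude at 1 kHz.

**Variability.** Effort amplitude is lognormal across breaths
(`pmus_amplitude_cv`, default 0.25) in both modes. The emitted Eadi
carries an additional lognormal neuroventilatory-coupling factor
(`coupling_cv`, default 0.4): diaphragm electrical activity is an
imperfect surrogate of muscular pressure. This term is what differentiates
the modes' output variability. Under exactly proportional assist the
delivered pressure would scale with each breath's effort, volume would
scale with it too, and $P_{mus}/V$ — hence the whole $E_{drs}$ trajectory —
would be *invariant* to the amplitude, making NAVA look artificially
uniform. With imperfect coupling the NAVA controller inherits Eadi
variability that does not cancel, while PS clamps its pressure and damps
it. The default CVs reproduce the published tidal-volume variability
contrast between the modes (roughly 8–10% CV in PS versus 25–30% in
NAVA), and give the expected direction — a wider 5th–95th elastance band
under NAVA — in essentially all simulated patients.

**Noise.** Gaussian measurement noise is added to the emitted pressure and
flow only (defaults 0.1 cmH$_2$O, 0.005 L/s); the truth stays noise-free.

**What the simulator does not emulate.** Elastance is constant within a
breath (no volume-dependent stiffening or recruitment), effort timing is
metronomic (no respiratory-rate variability, apnoeas or asynchronies),
there is no leak, no expiratory muscle activity, and Eadi is a scaled
mirror of $P_{mus}$ rather than a measured electromyogram. Passing the
validation suite therefore demonstrates that the estimator recovers the
model's elastance exactly under the model's own assumptions and that the
statistical machinery is calibrated — not that real patients satisfy those
assumptions.

## Numerical and design choices

* Trapezoidal quadrature throughout (volume, AUC); AUC integrates the
  piecewise-linear interpolant exactly, with interpolated window
  endpoints.
* The early-volume mask threshold is relative (2% of tidal volume), so it
  adapts to breath depth; the invalid region is always a prefix.
* Grid points with fewer than two valid breaths are invalid in percentile
  output; AUC refuses windows containing invalid points rather than
  bridging them.
* The severity threshold is inclusive (`auc >= 25`).
* Ties in interpolation cannot arise (sample times are strictly
  increasing); the empirical quantile is the linear-interpolation type.
* Degenerate breaths (no inspired volume, fewer than two valid samples)
  are dropped with a warning by `edrs_fit` and counted.

## Validation problem sizes

The shipped test-suite and acceptance script validate: oracle recovery on
10-breath noise-free sessions at 100 Hz and 1 kHz (both modes); the
passive limit at $E = 30$; onset negativity over 100 effortful breaths;
resistance monotonicity at $R_{rs} \in \{1, 5, 10\}$; AUC closed forms;
null calibration of the mode comparison over 1,000 Monte-Carlo replicates
of 100 breaths per mode, with power checked against a 20 cmH$_2$O/L
stiffness shift; and the PS/NAVA band-width direction over 20 synthetic
patients with 100 breaths per mode. These sizes give stable Monte-Carlo
estimates (binomial SE ≈ 0.006 on the type-I rate) at desk-scale runtimes.

## Limitations

The estimate inherits every limitation of the lumped model: a wrong
assumed resistance biases the level (though not within-patient trends);
PEEP subtraction assumes the pre-onset airway pressure reflects the
elastic baseline (intrinsic PEEP violates this); and the negative
elastance reading is a surrogate for effort, not a measurement of
muscular pressure — separating $E_{lung}$, $E_{chest}$ and $E_{demand}$
requires oesophageal pressure, which this package deliberately does not
use.
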