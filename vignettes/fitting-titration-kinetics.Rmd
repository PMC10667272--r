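---
title: "Fitting label-free titration kinetics with sensorkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting label-free titration kinetics with sensorkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sensorkin)
```

## The measurement and the model

A label-free biosensor (SPR, SPRi or BLI) records a *sensorgram*: the binding
response over time while an analyte at concentration $C_i$ flows over (or a
sensor dips into) a surface carrying an immobilized ligand. A titration
series repeats this over a dilution series of the analyte, cycle by cycle.
`sensorkin` fits such series globally to the 1:1 Langmuir interaction model.

During association ($t_0 \le t \le t_{asso}$):

$$R(t) = R_{shift,i} + R_{max,i}\,\frac{k_a C_i}{k_a C_i + k_d}
  \left(1 - e^{-(k_a C_i + k_d)(t - t_{0,i})}\right)$$

and during dissociation ($t > t_{asso}$):

$$R(t) = (R_{max,i} + R_{drift,i})\,\frac{k_a C_i}{k_a C_i + k_d}
  \left(1 - e^{-(k_a C_i + k_d)(t_{asso} - t_{0,i})}\right)
  e^{-k_d (t - t_{asso})}$$

with association rate constant $k_a$ (M$^{-1}$s$^{-1}$), dissociation rate
constant $k_d$ (s$^{-1}$) and derived affinity $K_D = k_d/k_a$. The
dissociation form above carries the optional drift amplitude
*multiplicatively*; the additive-drift variant (a constant $R_{drift,i}$
floor) is provided as `eval_dissociation_legacy()` for comparison only. The
two coincide exactly when $R_{drift,i} = 0$; when drift is floated the
multiplicative form decays to zero instead of a fitted floor, which avoids a
flat direction between the drift floor and slow dissociation and is therefore
the form used in fitting.

Model variants (`model_variant()`):

* **regenerative** cycles start from zero bound analyte and $t_{0,i}$ is the
  scheduled association start (fixed). In **non-regenerative** (single-cycle)
  titrations the response accumulates; $t_{0,i}$ is floated per cycle as the
  extrapolated time at which the response would have been zero, which makes
  the association equation absorb the carried-over response with no explicit
  carry term.
* **global vs local $R_{max}$**: one shared maximal response, or one per
  cycle (e.g. when surface capacity drifts between cycles).
* **bulk shift** ($R_{shift,i}$, association only) and **drift**
  ($R_{drift,i}$, dissociation onset) are mutually exclusive nuisance terms;
  fitting both per cycle would over-parameterize the amplitude structure, so
  the drift term is dropped whenever the shift term is requested.

Assumptions: 1:1 stoichiometry, no mass-transport limitation, reference
subtraction (and any smoothing) already done upstream, concentrations known
exactly, and i.i.d. residual noise across pooled association and
dissociation points (all points have weight 1).

## Preprocessing pipeline

`run_batch()` applies, per sample-sheet entry:

1. **Baseline alignment** (`align_baseline()`, optional per entry): each
   regenerative cycle is shifted so the mean of its baseline window
   ($[t_0 - \mathrm{baseline\_len}, t_0)$) is zero. Non-regenerative cycles
   are stitched: cycle 1 is zeroed, then each cycle's baseline mean is
   matched to the mean of the final 5 s of the previous cycle's dissociation.
   The 5 s terminal anchor is a robustness choice: long enough to average
   noise, short enough that dissociation decay within the window is
   negligible at typical $k_d$. Alignment uses means (not single points) so
   that pointwise noise does not propagate into cycle offsets. For data that
   are already aligned — notably simulator output, which is continuous by
   construction — alignment can and should be disabled (`align = FALSE` in
   the sheet): matching a 120 s baseline mean to a 5 s anchor on a decaying
   continuous trace would inject small per-cycle offsets of order
   $k_d \cdot \mathrm{baseline\_len} \cdot R$.
2. **Blank subtraction** (`subtract_blank()`): when a zero-concentration
   cycle is declared it is subtracted pointwise on each cycle's own clock
   relative to $t_0$, with linear interpolation between blank timestamps.
3. **Thinning** (`thin_to_rate()`, default 1 Hz): keeps the first point of
   each $1/\mathrm{rate}$ bin. First-point selection (not averaging) keeps
   thinning a pure subsample: it never fabricates values, never moves the
   first timestamp and never reorders points.
4. **Concentration down-selection** (`select_concentrations()`): at most 5
   concentrations are fitted. In automatic mode, with cycles sorted by
   ascending concentration, the window of 5 consecutive concentrations with
   the largest accumulated increase of end-of-association response (last
   minus first of the window; equal to the sum of successive increments) is
   chosen, ties going to the lowest-concentration window. This targets the
   steep, most informative part of the dose response. The end-of-association
   response is the last observed point of the association window, not a
   fitted plateau.
5. **Window extraction** (`extract_fit_windows()`): association points in
   $[t_0 + \mathrm{skip}_a, t_{asso}]$ and dissociation points in
   $[t_{asso} + \mathrm{skip}_d, t_{asso} + \mathrm{dissoc\_fit\_len}]$.

## Estimation

The packed parameter vector carries $\log_{10} k_a$ and $\log_{10} k_d$
(positivity by construction, comparable scale across the decades spanned by
real affinities) plus the linear-scale amplitudes and, for non-regenerative
fits, the per-cycle $t_{0,i}$ bounded to
$[t_0 - 10(t_{asso} - t_0),\, t_0]$ — an extrapolated zero-response time
cannot postdate the association start, and the loose lower bound keeps the
search stable. The pooled sum of squared residuals over all selected cycles
is minimized with bounded Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`; relative step/gradient tolerances $10^{-10}$, at most
2000 function evaluations). Non-convergence is reported on the result
(`converged = FALSE`), never raised, so batch panels run to completion.

Initialization is fully deterministic, which makes fits byte-reproducible:

* $k_{d,0}$: slope of a log-linear regression on the last half of the
  highest-concentration dissociation window, floored at $10^{-6}$ s$^{-1}$;
* $k_{a,0}$: a coarse grid over $\log_{10} k_a \in \{2,\dots,7\}$ scored by
  sum of squares with the amplitude(s) solved linearly at each grid point
  (variable projection);
* $R_{max,0} = 1.5 \times$ the largest observed response; shift/drift start
  at 0;
* $t_{0,i}$: the scheduled $t_0$ for regenerative fits. For non-regenerative
  fits, starting every $t_{0,i}$ at the scheduled $t_0$ proved unreliable —
  the optimizer can satisfy its relative-decrease tolerance on a shallow
  plateau with the $t_{0,i}$ unmoved — so each $t_{0,i}$ is instead
  extrapolated from the response carried into the cycle (its first
  association response), by inverting the association equation at the
  initial rates and clamping to the bounds. This is still deterministic and
  purely data-derived.

Standard errors use the classical nonlinear least-squares covariance
$(rss/\mathrm{dof})\,(J^\top J)^{-1}$ with a central-difference Jacobian at
the optimum and $\mathrm{dof} = n_{points} - n_{parameters}$. Log-scale rate
SEs are delta-transformed to the linear scale
($\mathrm{SE} = \ln(10)\,\hat\theta\,\mathrm{SE}_{\log_{10}}$). A
rank-deficient $J^\top J$ (over-parameterization) yields `NA` SEs plus a
diagnostics flag. The affinity error is propagated as

$$\Delta K_D = K_D \sqrt{(\Delta k_a/k_a)^2 + (\Delta k_d/k_d)^2}.$$

Replicate summaries report, per parameter: the arithmetic mean, the percent
coefficient of variation ($100\,\mathrm{sd}/\mathrm{mean}$, sample sd), the
fold range (max/min) and each replicate's relative SE. These are computed on
the linear-scale estimates, not on logs.

## The simulator

`simulate_series()` generates titrations directly from the two model
equations, so a noise-free simulate-then-fit round trip is an exact test of
the estimation machinery. Defaults mirror a typical high-throughput SPRi
titration: $k_a = 10^5$ M$^{-1}$s$^{-1}$, $k_d = 10^{-4}$ s$^{-1}$,
$R_{max} = 100$ RU, 8 two-fold dilutions topping at 1 µM, 120 s baseline /
300 s association / 750 s dissociation, sampled at 0.5 Hz. In
non-regenerative mode each cycle's baseline continues the previous
dissociation decay and the association start is solved for the $t_{0,i}$
that reproduces the carried response, so the stitched trace is continuous at
every junction and exactly representable by the fitted model. Noise is
i.i.d. Gaussian per point under a caller-supplied seed (the global RNG state
is saved and restored).

What the simulator does **not** emulate — and what passing round-trip tests
therefore do not demonstrate about instrument data: mass-transport-limited
binding, autocorrelated or heteroscedastic noise, spikes and air-bubble
artifacts, imperfect reference subtraction, concentration errors in the
dilution series, and surface heterogeneity. Recovery within 0.1 % on
noise-free simulated data validates the estimator, not the 1:1 model's
adequacy for any particular interaction.

```{r roundtrip}
ser <- simulate_series(sim_spec())          # noise-free defaults
entry <- sample_entry(location = "sim",
                      concentrations = vapply(ser$cycles, `[[`, 0, "conc"),
                      conc_unit = "M", global_rmax = TRUE)
fit <- fit_series(ser, entry)
fit
```

## Numerical and design choices

* Time is stored in absolute exported seconds; all window arithmetic is
  relative to each cycle's $t_0$, which accommodates both stitched
  (Carterra-style) and per-cycle (Biacore-style) clocks. Cycle indexing is
  1-based, matching instrument exports.
* Concentrations are stored in molar; sheet readers convert from
  mM/µM/nM/pM. Response units (RU or nm) are an opaque label — the model is
  unit-agnostic.
* The estimates CSV writes numbers at 13 significant digits so a write/read
  round trip is faithful to at least 12; displayed report values are
  3-significant-digit renderings of the same numbers.
* Degenerate inputs fail loudly and specifically: empty fit windows, blank
  traces that do not cover a cycle, all-zero responses ("no signal"), fewer
  points than parameters.
* Tie-breaks: equal down-selection scores go to the lowest-concentration
  window; `which.max` semantics make this deterministic.
* Test problem sizes: the suite exercises full-size default titrations
  (about 2 600 fitted points per series) for round trips, 100 seeded noisy
  replicates for the ±3 SE coverage property, 1000 randomized vectors for
  the down-selection oracle, and dozens of randomized truths for recovery —
  sizes chosen to probe each property well while keeping the suite fast.

## Known limitations

* Only the 1:1 Langmuir model: no bivalent-analyte, heterogeneous-ligand,
  two-state or mass-transport models, and no steady-state ($R_{eq}$)
  analysis.
* The SE convention of other software packages may differ (dof divisor,
  covariance estimator); cross-software SE comparisons should be read with
  that in mind. The $\Delta K_D$ propagation above ignores the $k_a$–$k_d$
  covariance by construction.
* Platform adapters target the documented export *shapes* (one file/many
  spots; one file per channel or sensor; a time column plus response
  columns), not byte-level vendor formats, and assume reference-subtracted
  input.
* The automatic 5-window selection is a heuristic proxy for the
  dose-response linear range, not a linear-range detector.
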