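---
title: "Quantifying gastric myogenic contractions and their pharmacology"
author: "gastromot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gastric myogenic contractions and their pharmacology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gastromot)
```

## The measurement problem

Strips of gastric smooth muscle mounted on isometric force transducers in an
organ bath contract spontaneously: pacemaker (ICC-driven) depolarisations
produce rhythmic phasic contractions at roughly 2–3 per minute, riding on a
sustained baseline tension ("tone") of about 20 mN after stretching. Proximal
(fundus/corpus) strips produce small, slow, symmetric contractions; distal
(antral) strips produce contractions around five times larger that rise fast
and decay slowly. Drugs added to the bath change the tone, the amplitude and
the frequency of this rhythm, and the standard quantitative readouts are:

* per-contraction **motility parameters**: amplitude *C* (mN), total
  contraction time *D* (s), time to peak *E* and decay time *F* (s)
  (*D = E + F*), areas under the contraction above local baseline during
  development (*G*) and decay (*H*) (mN·s), total AUC = *G + H*, and the
  rates of development *C/E* and decay *C/F* (mN/s);
* **windowed summaries**: the tone change *A* between a window and a pre-drug
  reference window, and the contraction frequency in contractions per minute
  (c.p.m.), usually over 5-min windows;
* **concentration–response** parameters per endpoint: threshold decade,
  pEC50 and Emax from a Hill (sigmoid Emax) fit
  $E(c) = E_{\max}\, c^{n} / (c^{n} + EC_{50}^{n})$;
* **antagonist potency**: dose ratios $CR$ of fitted EC50s, Schild regression
  of $\log_{10}(CR-1)$ on $\log_{10}[B]$ giving pKB (slope constrained to 1
  when compatible) and the single-concentration Gaddum–Schild estimate
  $pA_2 = \log_{10}(CR-1) - \log_{10}[B]$;
* **combination effects**: per-subject excess of the combined response over
  the sum of the individual responses (super-additivity/synergy), and
  Bland–Altman limits of agreement for paired rating tables.

No raw tissue recordings are distributed with analyses of this kind, so the
package pairs the analysis pipeline with a synthetic-trace generator whose
defaults encode the published regional study conditions. Every pipeline claim
is then testable as parameter recovery: simulate with known ground truth,
analyse, and read the generating values back out.

## The synthetic force-trace model

A trace is built as

```
force(t) = baseline_tone + tone_envelope(t) + drift·t + kernel_train(t) + ε(t)
```

with `ε ~ N(0, additive_sd²)` white Gaussian noise on each sample.

**Contraction waveform.** Each contraction is an asymmetric raised cosine:
a half-cosine rise from 0 to *C* over *E* seconds followed by a half-cosine
decay over *F* seconds. This family is smooth, peaks at exactly *C*, has
closed-form phase areas *C·E/2* and *C·F/2* (handy as an area oracle for the
feature extractor), and realises the distinct development/decay phases of the
measured waveform. Onsets repeat every `inter_onset_interval` seconds; only
contractions that complete inside the trace are generated, and the ground
truth lists their onsets.

**Regional presets.** `proximal-default` uses C = 1.1 mN, E = F = 11.75 s,
interval 23.5 s (back-to-back events, 60/23.5 ≈ 2.55 → 2.6 c.p.m. printed),
baseline 20 mN, noise SD 0.05 mN. `distal-default` uses C = 5.0 mN,
E = 4.3 s, F = 17.2 s, interval 22.2 s, noise SD 0.10 mN. The published
distal duration (22.8 s) and frequency (2.7 c.p.m.) are mutually inconsistent
for a back-to-back rhythm (60/22.8 = 2.63); the preset resolves this in
favour of the frequency, using a 21.5 s contraction in a 22.2 s cycle so that
the detected frequency rounds to 2.7 c.p.m. The contraction shape itself
(rise roughly 4× faster than decay distally, symmetric proximally) preserves
the qualitative regional contrast.

**Pharmacodynamics.** An agonist acts through three Hill models — tone
change (mN), fractional amplitude change and fractional frequency change.
After each scheduled addition the corresponding envelopes relax toward their
Hill targets with a first-order time constant interpolated log-linearly from
200 s near threshold concentrations to 30 s at saturating ones (responses
plateau over roughly 2–10 min, faster at high concentrations). Above a
transience threshold the target itself fades with a configurable half-life,
reproducing the shorter-lived responses seen at high agonist concentrations.
Competitive antagonists shift the generating EC50 by the Schild factor
`1 + [B]/KB`; biphasic (adrenaline-like) agents are the sum of an excitatory
and a negative-Emax inhibitory Hill term. EFS recordings place one
monophasic evoked contraction in each 10 s/min stimulation train, scaled by
a time-dependent drug multiplier.

**What the generator does not emulate.** Slow-wave electrophysiology,
spatial propagation, inter-subject variability of waveform shape, correlated
(1/f) noise, motion/bubble artefacts, and rhythm jitter: onsets are strictly
periodic given the frequency envelope. Passing recovery tests therefore
demonstrates correctness of the measurement pipeline under the stated noise
model, not robustness to every artefact of real organ-bath data.

## Detection and feature-extraction choices

The acquisition software behind the published measurements is cited but its
algorithms are not described, so all detection choices here are this
package's own, made for robustness and testability:

* **Smoothing**: a 1 s centred moving average before peak search
  (at 10 Hz this attenuates white noise ~3× while flattening a 20 s-period
  contraction peak by well under 1%).
* **Baseline tone**: a rolling 8th-percentile lower envelope over 60 s,
  smoothed over 10 s. The percentile sits slightly below the 10th so that
  after smoothing the estimate remains a true lower envelope (below at least
  90% of samples) on noisy data. Tone changes *A* are differences of window
  means, so the small constant offset of any percentile envelope cancels.
* **Peaks**: local maxima with prominence ≥ `max(0.2 mN, 5 × noise SD)`,
  the noise SD estimated from the median absolute deviation of first
  differences (the slow contraction waveform contributes little
  sample-to-sample change); minimum peak separation 5 s, the more prominent
  peak winning conflicts.
* **Event boundaries**: the troughs flanking each peak — the minimum of the
  smoothed trace between adjacent peaks, refined on the raw trace within one
  smoothing window (ties resolved toward the peak). A fractional-prominence
  onset criterion (e.g. 10% of peak height) was considered and rejected: on
  a raised-cosine waveform it truncates the event to ~59% of its true width,
  biasing *D*, *G* and *H* heavily; trough segmentation recovers the full
  *E + F* duration exactly on noise-free traces. The 10% fraction is kept as
  a validity check — a trough must descend below
  `baseline + fraction × prominence` to delimit an event.
* **Local baseline per event**: the mean smoothed force at the two flanking
  troughs; amplitude is peak minus this local baseline, areas are trapezoids
  above it. On continuous back-to-back rhythms shared troughs make
  consecutive durations telescope, so mean *D* equals the mean inter-onset
  interval — which is what a rhythm's "total contraction time" means when
  contractions abut.
* **Frequency**: complete-event count per window divided by window minutes
  (not an inverse-interval estimate), with an event assigned to a window by
  its peak. Feature means use only events lying wholly inside the window.

Known limitation: on sparse rhythms with long flat gaps and realistic noise
the trough of a gap is located only to within the gap (the argmin of noise),
so single-event durations carry up to a gap's width of jitter; means remain
unbiased.

## Fitting choices

`fit_hill` fits `Emax·cⁿ/(cⁿ+EC50ⁿ)` (basal fixed at 0) by bounded
Levenberg–Marquardt on (log10 EC50, Emax, n), with the Hill slope bounded to
[0.3, 5] (no slopes are reported in the source setting, so the slope is
free but regularised by bounds). Starts are taken from a fixed 13-point
log-grid of EC50 spanning the tested concentrations; the lowest
sum-of-squares wins, ties going to the lowest EC50, so fits are
deterministic for given data. Constant responses return a non-converged fit
rather than parameters. Biphasic curves can be fitted on their ascending
limb only; the limb is delimited at the signed maximum in the direction of
the initial response, not at the maximum magnitude (otherwise a strong
late inhibitory limb would capture the window).

Threshold concentrations are reported as the decade interval
`(last sub-criterion concentration, first supra-criterion concentration]`,
with `below range`/`above range` sentinels and an ambiguity flag when the
response re-crosses the criterion. The criterion is configurable; the
analysis scripts use `max(2 × SD of the lowest-concentration responses,
0.2 mN)`.

`schild_regression` tests slope unity by a t-based 95% CI; when the CI
contains 1 the slope is fixed at 1 and the constrained intercept
`mean(log10(CR−1) − log10 B)` is reported as pKB, otherwise the free-slope
x-intercept is reported as pA2 with a warning. Replicate fitted curves are
averaged on the log-EC50 scale before dose ratios are formed. The synergy
test declares super-additivity only when the mean per-subject excess is
positive *and* the two-sided paired t-test is significant at α = 0.05; under
the additive null this direction-aware rule has type-I error near α/2
(verified ≤ 0.06 over 1000 simulated cohorts). Dunnett comparisons use the
single-step multivariate-t adjustment.

## Problem sizes and determinism

The recovery studies use ten 20-min, 10 Hz traces per regional preset
(~510–540 detected contractions per region), five 5-replicate
concentration–response datasets at eight log-spaced concentrations for
potency recovery, and 1000 five-subject cohorts for the synergy null — sizes
chosen so every study in the package re-runs from scratch in a couple of
minutes while keeping Monte-Carlo error well inside the reported precision.
All randomness flows through explicit integer seeds (one per simulated
tissue); identical seeds give bitwise-identical traces, and
`scripts/acceptance.R` derives all of its sub-seeds from a single `--seed`
argument.

## Worked example

```{r example}
sim <- simulate_trace("distal-default", duration = 1200, fs = 10, seed = 1)
events <- extract_features(sim$trace, detect_contractions(sim$trace))
nrow(events)                       # 54 contractions in 20 min = 2.7 c.p.m.
round(colMeans(events[, c("C_mN", "D_s", "E_s", "F_s")]), 2)

crc <- simulate_crc_dataset(preset("AVP-tone-proximal"),
                            10^seq(-12, -5, 1), n_reps = 5,
                            noise_cv = 0.05, seed = 1)
fit_hill(crc)
```

The numbered scripts under `analysis/` run the full set of studies —
simulation, regional characterisation, concentration–response, antagonism,
synergy and agreement — writing their tables under `results/`.
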