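---
title: "Methods: en face VNO calcium imaging analysis in vnoca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: en face VNO calcium imaging analysis in vnoca}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vnoca)
```

## The measurement and its model

En face calcium imaging of the vomeronasal epithelium records one
fluorescence time series per dendritic knob — the apical ending of a
vomeronasal sensory neuron (VSN) and the imaging unit of the preparation.
Frames are acquired every 1.5 s; a two-stimulus panel (e.g. urine from
healthy vs. inflamed donors) is applied for 30 s at least twice per
stimulus with at least 4 min between onsets. The analysis asks, per knob:
did it respond to stimulus A, to B, to both, or to neither — and then
summarizes the four-way partition as responder densities normalized to the
knob population of the recorded field.

Each trace is normalized to its resting level, $F_x/F_0$, with $F_0$ the
mean raw fluorescence over the first 50 frames. A response to one stimulus
application must satisfy three criteria:

1. the normalized trace exceeds $\bar b + 2\,s_b$, where $\bar b$ and
   $s_b$ are the mean and sample SD of the baseline window of the
   normalized trace (the baseline fluorescence noise);
2. the crossing begins within 60 s of application onset;
3. *repeatability*: the knob must respond during **every** application of
   that stimulus to count as a responder.

Two readings in criterion 1–2 are genuinely open and are fixed here as
package policy:

* the noise SD is computed on the **normalized** trace (the object the
  rest of the analysis manipulates), not the raw trace, and it is the
  sample SD of the window — a standard error would make the threshold
  depend on the window length;
* "within 1 min" is anchored at application **onset**, the only
  unambiguous time point (the 30-s application lies inside the window).

### Sustained crossings, not single frames

For iid Gaussian baseline noise the probability that *some* frame in a
41-frame latency window exceeds $\bar b + 2 s_b$ is $\approx 1 - (1 -
0.023)^{41} \approx 0.6$ per application, *independent of the noise
level* — a single-frame reading of criterion 1 would label roughly 40% of
silent knobs "repeatable responders" and no fraction-of-knobs summary
could survive. A true Ca²⁺ transient is nothing like a single-frame
excursion: with rise τ ≈ 3 s and decay τ ≈ 15 s, a transient peaking at
5 noise SDs stays above a 2-SD threshold for ~10 consecutive frames.
`detect_responses()` therefore requires the crossing to be sustained for
`min_run_frames` consecutive frames, default **3 frames (4.5 s)**, which
drops the per-application false-positive probability to ~$7\times10^{-4}$
while leaving transient detection essentially perfect at amplitudes ≥ 5
SD. Setting `min_run_frames = 1` restores the literal first-crossing rule
(the package's null-calibration tests exercise both settings against a
brute-force oracle). Latency is reported to the first frame of the first
qualifying run.

A numerical guard: the threshold offset above $\bar b$ is floored at
$10^{-6}$ normalized units (`threshold_floor`), so that an exactly
noiseless baseline ($s_b = 0$) does not turn infinitesimal tails — e.g.
the $10^{-8}$ residue of a transient four minutes after its onset — into
responses.

## Density normalization and summaries

Responder counts only become comparable across recording sites when
divided by the knob population of the field. Knob density is estimated by
counting knob-like structures in 40 × 40 µm sampling squares
(`estimate_density()`, reported per 100 µm²); the working constant is the
simple mean of the per-genotype mean densities rounded half away from
zero to two decimals (`pooled_density()`) — 8.42 and 8.21 knobs/100 µm²
pool to **8.32**, and `estimate_total_knobs()` converts a recorded area to
its knob number (40,000 µm² → 3,328 knobs). A simple mean of genotype
means is used because site-level counts are balanced by design; a per-site
or per-genotype density can be selected instead (`density_convention`).

Group summaries report the class densities as mean ± SEM across sites and
the Venn shares of each class among all responsive knobs under **both**
conventions in circulation — shares of pooled counts and shares of mean
site densities — explicitly labelled, because the two disagree whenever
sites differ in size or rate and published figures mix them. Headline
shares and folds round half away from zero at the printed precision
(`round_half_away()`), since R's own `round()` rounds half to even.

`detect_knobs()` replaces manual counting with multiscale
Laplacian-of-Gaussian blob detection (local maxima of the scale-normalized
band-pass response above a relative threshold, non-maximum suppressed at
2 µm — the physical knob spacing floor). Its only pipeline role is density
estimation, so it is validated by recall/precision ≥ 0.95 against the
generator's truth tables rather than by any published number.

## The synthetic generator

`synth_config()` fixes the study conditions as defaults:

| parameter | default | unit | rationale |
|---|---|---|---|
| `knob_density` | 8.32 | knobs/100 µm² | pooled measured density |
| `class_fractions` | both 1.6%, A-only 0.5%, B-only 0.1% | of all knobs | the urine-panel responder fractions |
| `noise_sd` | 0.02 | fraction of F0 | typical baseline noise of such recordings |
| `amp_range` | 5–8 | × noise SD | clearly supra-threshold transients; must exceed 2 |
| `rise_tau_s`, `decay_tau_s` | 3, 15 | s | somatic Rhod-2-like kinetics |
| `latency_range_s` | 1.5–6 | s | onset lag of perfusion-driven responses |
| `respond_prob` | 1 | — | planted responders satisfy repeatability by construction; lower it to stress criterion 3 |
| `bleach_slope` | 0 | fraction/frame | no bleaching correction is applied by default |

Knobs are placed on a jittered hexagonal lattice (not a Poisson process):
real knobs cannot overlap, and the jitter bound keeps all pairs ≥ 2 µm
apart while preserving the target density. Traces are
$F_0(1 - \beta t) + \mathcal N(0, \sigma F_0)$ per frame plus
peak-normalized double-exponential transients; the generator is exactly
linear in $F_0$, which the tests exploit (scaling `f0_range` must scale
raw traces and leave normalized traces untouched). All randomness flows
from the single `seed`; identical configs reproduce bit-identical data.

The behavior generator plants a log2 investigation-time ratio: per side,
bout counts are Poisson(10) and durations Gamma(shape 2, mean 3 s), side-A
durations scaled by $2^{\mu}$. These rates give per-side investigation
times near 30 s/10 min and a per-animal score SD ≈ 0.86, matching the
scale implied by a published group SEM of 0.27 at n = 11. Direct
simulation (20,000 cohorts) puts the one-sample-test power at planted
µ = 0.8, n = 11 at **0.78**; the cohort Monte-Carlo test asserts the
rejection rate in the band [0.72, 0.84] derived from that simulation
before the pipeline was wired up. The count generator is
Poisson-total/Binomial-positive per region, with positive fractions
defaulting to the published pS6 values (2.19% vs 0.98%).

What the generator does **not** emulate: motion/registration artifacts,
correlated (pink) noise, indicator saturation, focus drift, overlapping
ROIs, and scorer disagreement in bout logs. Passing tests therefore
demonstrate the correctness of the analysis rules and their calibration
under the stated noise model — not robustness to every pathology of real
recordings.

## Statistics policy

`compare_two_groups()` gates on Shapiro-Wilk normality (α = 0.05, both
groups must pass; a constant sample fails the gate by definition) and
runs a pooled-variance Student's t-test or a two-sided Mann-Whitney
accordingly. Multi-group comparisons are Kruskal-Wallis with pairwise
Mann-Whitney post hocs under step-down Šídák (Holm-Šídák) adjustment,
implemented directly (adjusted $p_{(i)} = 1-(1-p_{(i)})^{m-i+1}$,
cumulative-max monotonized, floored at the raw p to absorb floating-point
undershoot at the last step). The behavioral group statistic is the mean
of per-animal scores — deliberately not the score of the mean times, which
differs by Jensen's inequality — with a two-sided one-sample t-test
against zero. Zero investigation times are an error by default; an
epsilon policy (+0.5 s to both sides, flagged) exists for simulation
loops where Poisson bout counts can reach zero.

## Degenerate inputs and conventions

* Frames are 0-based in protocols and on-disk tables; windows are
  half-open `[start, end)`; times are frame × 1.5 s.
* A density of 0 yields an empty field; an empty image yields no
  detections; one sampling square reports an undefined (NA) SEM.
* `fold_change(x, 0)` is infinite and flagged; `fold_change(0, 0)` is
  undefined and flagged.
* Protocols with inter-onset gaps under 4 min warn but do not fail
  (compact protocols are useful for large null simulations where only the
  latency windows matter).

## Problem sizes

The shipped tests and drivers use: null calibration at 10⁵ pure-noise
knobs against a 10⁵-replicate brute-force oracle; class-fraction recovery
at ~20,000 knobs (the scale of a full imaging dataset); 11 + 8 synthetic
recording sites of ~1,870 knobs each in the genotype comparison; 1,000
cohorts of 11 mice in the power Monte-Carlo; and 10,000 sample pairs in
the type-I-error calibration of the gated two-group test. These sizes make
binomial/Monte-Carlo error small against every asserted tolerance while
keeping a full run in about a minute.

## Known limitations

* The detector assumes registered, planar stills; there is no 3-D
  segmentation or cross-frame tracking.
* The sustained-run length is a discrete knob; 2 frames admits ~50× more
  null false positives than 3 at these window lengths, and 4 begins to
  cost sensitivity for fast-decaying transients.
* Transient kinetics and SNR defaults are plausible for Rhod-2-type
  indicators, not fitted to any dataset.
* The Venn-share ambiguity is structural: without per-site counts of a
  published panel, pooled-count shares cannot be recomputed exactly from
  printed per-class means, which is why both conventions are always
  emitted side by side.
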