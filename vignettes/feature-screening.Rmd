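---
title: "Screening multimodal stress biosignals: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening multimodal stress biosignals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(physioscreen)
```

## The problem

When people perform demanding cognitive tasks, their autonomic state shifts:
heart rate rises and its variability redistributes between spectral bands,
the skin conducts more and produces more phasic conductance responses, and
peripheral skin temperature drifts as vessels constrict. `physioscreen`
implements the full analysis path for studies that ask *which* features of
photoplethysmography (PPG), electrodermal activity (EDA) and skin
temperature discriminate self-assessed stress / mental-workload classes:

1. a seeded simulator producing multimodal cohorts with known
   class-dependent effects (so every downstream stage is testable without
   human data);
2. the acquisition-side filter chain and phase/window segmentation;
3. a fixed catalogue of 43 per-phase features;
4. per-subject max–min normalization into labeled feature tables;
5. a two-tier nonparametric screen: Kruskal–Wallis across the five class
   populations, then pairwise Mann–Whitney U with Benjamini–Hochberg
   correction, in *binary* (class 0 vs each altered class) and *overall*
   (all pairs) modes, summarized as significance-count tables and a
   cross-test "bullet" matrix of consistently discriminative features.

The emulated design is 28 participants, four test datasets (Stroop and
visual/auditory/dual N-Back), and four phases per test: one initial rest
phase, always labeled class 0, plus three task sub-phases whose classes 1–4
come from a post-task self-assessment. This yields the row identity

$$ n_\mathrm{data} = n_\mathrm{participants} \times n_\mathrm{phases}
   \times n_\mathrm{features} = 28 \times 4 \times 43 = 4816 $$

per test dataset, which `assemble_dataset()` enforces on every assembly
(missing measurements stay as flagged `NA` rows so the identity is a
structural invariant, not an accident of complete data).

## The cohort simulator

The simulator is first-class, tested code, not a fixture. Its defaults are
the study conditions; where the design leaves a quantity unstated we chose
a value once and document it here.

**Inter-beat intervals.** `simulate_ibi_series()` draws
$$ \mathrm{IBI}(t) = \mu + a_\mathrm{LF}\sin(2\pi\,0.1\,t)
   + a_\mathrm{HF}\sin(2\pi\,0.25\,t) + \varepsilon $$
with white jitter $\varepsilon$. The two sinusoids sit at the centres of
the low-frequency (0.04–0.15 Hz) and high-frequency (0.15–0.4 Hz) bands of
heart-rate variability, so the simulator plants *known* spectral power that
the feature extractor must recover. Parameters that could drive an
interval to or below the 0.3 s beat-detector refractory floor are rejected
(`a_LF + a_HF + 4\sigma < \mu - 0.3`).

**PPG.** `synthesize_ppg()` places one template pulse per beat at the
cumulative-IBI onsets: a half-cosine rise over the (class-modulated) rise
time followed by an exponential decay, renormalized to end at zero. Any
smooth unimodal template would do — downstream only amplitude, duration
and rise time are consumed — and the half-cosine/exponential pair makes
foot, peak and rise time exactly computable for tests.

**EDA.** `synthesize_eda()` builds tonic level + slope, plus
Poisson-timed skin-conductance responses: driver impulses convolved with
the Bateman kernel $k(t) = e^{-t/\tau_2} - e^{-t/\tau_1}$. Ground truth
(event times, amplitudes, exact tonic curve) is returned alongside the
signal.

**Temperature.** Linear drift with class-dependent slope plus AR(1) noise
whose marginal SD and correlation time are configurable. Noise is
autocorrelated on purpose — skin temperature sensors drift slowly — and
the validation tests use the autocorrelation-adjusted standard error
($n_\mathrm{eff} = n(1-\phi)/(1+\phi)$) when checking unbiasedness.

**Defaults that are our choices, not published values.** Phase duration
defaults to 300 s (long enough that a 60 s spectral frame resolves the
0.04 Hz band edge several times per phase). The class-label distribution
over classes 1–4 defaults to the skewed vector (0.15, 0.35, 0.35, 0.15);
the reference allocation is only reported graphically, so this is a
configurable stand-in, not a claim. The acquisition rate is documented at
1200 Hz, but because all simulated content lies below 10 Hz the simulation
tests run at 50–200 Hz; that changes only computation, not the model. No
published effect sizes link classes to physiological quantities, so the
`effect_spec()` defaults (heart rate up, HF variability down, LF up, SCL
and SCR rate up, faster skin cooling with class) are validation settings
chosen to be physiologically plausible in direction and moderate in size.

## Preprocessing

`apply_filters()` reproduces the acquisition chain — 50 Hz notch (biquad,
Q = 30), 30 Hz low-pass, and for PPG a 0.1 Hz high-pass — as zero-phase
(forward–backward) 4th-order Butterworth stages, so feature timings are
never shifted. Two numerical points matter:

* Forward–backward filtering with zero initial state rings badly at record
  edges, especially at slow corners. All filtering therefore runs through
  an odd-reflection padding wrapper (pad of about 1.5 /
  $f_\mathrm{corner}$ seconds, capped at the record length); reflection
  continues constants and ramps exactly, so the transient decays inside
  the pad.
* For *smoothing* filters (unit DC gain) applied to trend-like signals —
  temperature before differentiation, EDA before decimation — the best-fit
  line is removed before filtering and restored after, which makes
  constants and linear ramps pass through exactly. This is what lets the
  temperature-derivative contract ("exact on linear inputs") hold to
  machine precision.

A 50 Hz notch is meaningless below a 100 Hz sampling rate; `apply_filters()`
rejects any stage at or above Nyquist, and `filter_spec(notch_hz = NULL)`
skips the stage for simulated data, which carry no mains interference.

Windows for pulse-shape statistics are 10 s, non-overlapping, with the
trailing partial window discarded (never padded), so every window
statistic sees a full window.

## The 43-feature catalogue

`feature_catalogue()` fixes names and order:

* **PPG shape (9):** mean/SD/median of per-beat amplitude, duration and
  rise time, computed per 10 s window and averaged across windows. Sample
  (n−1) standard deviations are used throughout. Duration is foot-to-foot,
  i.e. the inter-beat interval of the closing beat.
* **Heart rate (3):** mean/SD/median of the BPM trend — instantaneous
  60/IBI assigned at beat times, linearly interpolated onto a 4 Hz grid
  spanning exactly the first-to-last beat (no extrapolation).
* **Heart-rate variability (9):** pNN50 and RMSSD computed from the IBIs
  in milliseconds (pNN50 with the standard 50 ms threshold on absolute
  successive differences — the interval-domain definition, which is the
  defined one even where descriptions attach it to the BPM trend); mean
  and SD over time of the PLF and PHF band powers of a short-time
  periodogram of the mean-removed trend (Hann window, 60 s, 50% overlap);
  and mean/SD/median of the per-frame PLF/PHF ratio.
* **EDA (8):** SCL mean/SD/least-squares slope on the tonic component;
  SCR amplitude mean/SD, rise-time mean/SD and count per phase, measured
  on the phasic component (peaks above a 0.01 µS amplitude floor).
  "Averaged number per phase" is implemented as the count per phase;
  phases have equal duration by default, so count and rate differ only by
  a constant.
* **Temperature (14):** initial value, final value, delta, mean, SD,
  variation over time, and the regression slope — for the raw signal and
  for its first derivative (0.1 Hz smoothing, central differences).

The published core table enumerates 41 names while the catalogue is
normative at 43; the two additional entries here are RMSSD and the median
PLF/PHF ratio — interval-domain and ratio-domain analogues of statistics
already in the set — chosen so the $28 \times 4 \times 43$ identity holds
and documented as this package's completion of the catalogue.

Band-edge convention: 0.15 Hz belongs to PHF (bands are [0.04, 0.15) and
[0.15, 0.4]), so PLF + PHF equals the total 0.04–0.4 Hz power with no
double counting; the choice is arbitrary but fixed and tested.

Temperature endpoint convention: initial/final values are means over the
first/last second (single samples are noise-dominated), and the
variation-over-time denominator is the time between the centres of those
windows. That makes `delta = final − initial` exact by construction *and*
`variation = slope` exact on noiseless ramps — with the raw phase duration
as denominator those two contracts cannot hold simultaneously.

## EDA decomposition

`decompose_eda()` solves the convex program

$$ \min_{q \ge 0,\,c}\; \tfrac12\|y - Kq - Bc\|^2 + \alpha\|q\|_1
   + \tfrac{\gamma}{2}\|D^2 B c\|^2 $$

with $K$ the Bateman-kernel convolution, $q$ the sparse non-negative
sudomotor driver, $B$ a cubic B-spline tonic basis (knots every 10 s) and
$D^2$ a curvature operator. The engine is coordinate descent
(`glmnet`) with box constraints on the driver, unpenalized spline columns,
and the curvature penalty expressed as augmented least-squares rows; the
program itself — kernel, basis, penalties — is defined here. Defaults
$\tau_1 = 0.7$ s, $\tau_2 = 3$ s (conventional Bateman values),
$\alpha = 0.02$ µS, $\gamma = 10$, chosen on simulated records so that
noiseless planted events are recovered exactly and a noise floor of
0.01 µS suppresses dust; the amplitude floor reappears as the SCR peak
acceptance threshold. The input is low-pass filtered and decimated to 8 Hz
before solving — EDA bandwidth is far below that, and the kernel matrix
grows quadratically with the rate. The decomposition returns the exact
identity `tonic + phasic + residual = input` on the solver grid, asserts
driver non-negativity, and reports the objective against the zero-driver
feasible point. We do not claim numerical equality with any particular
published solver's output; the contract is the stated program, validated
against simulator ground truth (planted events recovered within ±0.5 s,
counts exact at zero noise, monotone in the planted rate).

## Normalization and assembly

Max–min normalization maps each (subject, test, feature) triple's phase
values onto [0, 1] using that subject's own range *within the test
dataset* — test datasets are analyzed separately throughout, so pooling
ranges across tests would couple analyses that are otherwise independent;
the within-test scope is our resolution of an ambiguity and is configurable
in effect by normalizing a differently assembled table. Constant triples
map to 0 and carry a `degenerate` flag. The transform is invariant to
positive affine rescalings of a subject's raw feature, which is the
property that makes cross-subject pooling of rank tests meaningful.

## The screening procedure

Per feature and test dataset:

1. **Kruskal–Wallis** across the populated class distributions
   (tie-corrected mid-rank H; p from the $\chi^2_{k-1}$ approximation).
   Group sizes here are ~28 per class, where the approximation is
   standard. For very small groups the approximation is materially wrong,
   so `kruskal_wallis(method = "permutation")` provides a Monte-Carlo
   permutation p-value; the test suite validates it against an independent
   enumeration oracle.
2. **Mann–Whitney U** on each class pair — 4 pairs in binary analysis
   (class 0 vs 1, 2, 3, 4), all 10 pairs in overall analysis. Exact
   enumeration when both groups have ≤ 8 tie-free observations, otherwise
   the normal approximation with mid-rank tie correction and continuity
   correction (normalized feature tables are tie-heavy by construction —
   every subject contributes an exact 0 and 1 — so the tie-corrected path
   is the operative one at cohort scale). Both U statistics are reported
   and sum to $n_1 n_2$.
3. **Benjamini–Hochberg** at FDR 0.05 over the family of pairwise p-values
   *within one feature* (4 or 10 p-values). The alternative — one family
   pooled across all features and pairs — is supported via
   `screening_config(bh_scope = "pooled")`; per-feature is the default
   because each feature's multiple-comparison family is what the
   correction is described as protecting. Significance everywhere
   downstream (counts, bullets) means the BH-adjusted decision, not raw
   p < 0.05.

`significance_counts()` reports the number of features with Kruskal–Wallis
p < 0.05 (`test_significance`) and, for each n, the number of features
significant in more than n pairwise comparisons. `bullet_matrix()` marks
features significant in *all four* class-0 comparisons per test and
intersects across tests into the common-feature list.

## What validation shows — and what it cannot

The test suite validates, at the sizes given, using seeds fixed in the
tests:

* exact recovery of planted structure at zero noise (beats, SCR count and
  times, temperature slopes), and quantitative recovery under the default
  noise levels (≥ 99% of beats within 50 ms at 5% PPG noise; median IBI
  error below 10 ms);
* spectral planting: band-pure IBI modulation drives > 90% of 0.04–0.4 Hz
  BPM-trend power into the planted band (checked against R's own
  periodogram, not the package's spectrogram), and the PLF/PHF ratio
  features respond by orders of magnitude;
* statistical calibration: on 50 null feature-level cohorts of the full
  design, the fraction of per-feature binary-analysis families with any
  BH discovery stays at or below 0.10 (all discoveries being false under
  the null); with a planted monotone shift of 2 pooled SDs per class step
  on five designated features, the cross-test common list recovers the
  planted set in 20 of 20 replicates;
* the rank tests against independent oracles: complete enumeration for
  Mann–Whitney (equality to machine precision), Monte-Carlo permutation
  for Kruskal–Wallis (agreement within Monte-Carlo error), and the
  closed-form anchors H = 32/7 and p = 0.1 on the worked examples.

The statistical-calibration studies run on the *feature-level* generator
(`simulate_feature_table()`), which draws per-phase feature values
directly (Gaussian within class, optional per-class shifts) and reuses the
design's labeling and normalization; hundreds of full signal-synthesis
cohorts would measure the same screening properties at far higher cost.
The signal-level generator is exercised by the recovery tests above.

None of this validates the pipeline against real physiology: the simulator
plants effects as clean monotone shifts with Gaussian/Poisson noise,
whereas real cohorts have motion artifacts, non-monotone and
subject-heterogeneous responses, label noise in self-assessments, and
class imbalance far from any configured vector. Passing tests show the
*procedure* is implemented correctly and calibrated under its stated
model, not that the published counts for any human cohort would be
reproduced — those depend on unreleased recordings and are out of scope by
design.

## Known limitations

* The beat detector is built for the simulator's morphology (and validated
  there); dicrotic notches, arrhythmia and motion artifacts would need a
  more elaborate detector behind the same `beat_series` interface.
* The EDA solver's $\alpha$ trades event sensitivity against noise
  rejection globally; records whose SCR amplitudes vary by orders of
  magnitude would benefit from an adaptive weight.
* Spectral HRV features need ≥ 60 s of trend; shorter phases return
  flagged `NA`s and propagate as missing (still-counted) table rows.
* `kruskal_wallis()`'s default chi-square p-value is an approximation;
  at per-class sizes below ~8 use the permutation method.
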