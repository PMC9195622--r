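---
title: "Methods: longitudinal ALFF classification with RFE-SVM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal ALFF classification with RFE-SVM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The analysis problem

In a longitudinal expertise design, the same subjects are scanned at rest
before and after a training period. The scientific claim to be tested is
that training changes the *baseline* level of spontaneous activity, and the
index of that level is the amplitude of low-frequency fluctuations (ALFF):
the mean amplitude of a voxel's BOLD spectrum over 0.01–0.08 Hz. Because
pre- and post-training scans of the same subject are strongly correlated,
the design is paired throughout: the paired t test drives screening, the
cross-validation unit is a subject (both scans leave the training set
together), and the default permutation scheme flips the two scans of a
subject coherently.

`alffsvm` implements the full path — motion quality control, voxel- and
region-wise ALFF, two-stage feature selection, leave-one-out SVM evaluation,
permutation inference, and brain–behavior correlation — plus a synthetic
cohort generator with planted ground truth, because subject-level data of
this kind are typically not shareable.

# ALFF: definition and numerical conventions

For a detrended in-mask voxel series $x_t$, $t = 0,\dots,N-1$, sampled at
interval $TR$:

$$\mathrm{ALFF} = \frac{1}{|K|}\sum_{k \in K} \frac{2|X_k|}{N},
\qquad K = \{k : f_\mathrm{lo} \le k/(N \cdot TR) \le f_\mathrm{hi}\},$$

with $X_k$ the unpadded, untapered DFT. Conventions, each chosen for
determinism and testability:

* **Spectrum scaling.** Amplitude $2|X_k|/N$, so a unit-amplitude sinusoid
  at a DFT frequency has amplitude exactly 1. Legacy ALFF tools inherit
  other fixed scalings; any such constant cancels under whole-brain
  standardization, so the choice only affects readability of closed-form
  tests (a 0.05 Hz amplitude-2 sinusoid with $N = 200$, $TR = 2$ s gives
  ALFF $= 2/29$ exactly).
* **Band edges.** The closed interval is used; with $N = 175$, $TR = 2$ s
  the in-band bins are $k = 4, \dots, 28$.
* **Detrending.** The ALFF operation assumes detrended input (its contract);
  `compute_voxel_alff(detrend = TRUE)` (the default) applies the
  least-squares line removal itself, which is idempotent on already
  detrended data.
* **Band-pass prefiltering.** Filtering to 0.01–0.08 Hz and then averaging
  the amplitude over the same band is redundant for a rectangular filter;
  the default skips the time-domain filter, and `prefilter = TRUE` applies
  it explicitly (the test suite verifies the equivalence to 1e-10).
* **Standardization.** Division by the whole-brain in-mask mean; the
  standardized in-mask mean is 1 to 1e-9 by construction, and the operation
  is idempotent.
* **Missing regions.** Atlas regions without in-mask voxels yield NA region
  values and are dropped from the feature matrix with a warning.

# Motion quality control

Power framewise displacement from the 6 rigid-body parameters,
$FD_i = \sum |\Delta \mathrm{trans}| + r \sum |\Delta \mathrm{rot}|$ with
$FD_1 = 0$ and head radius $r = 50$ mm (the standard sphere; configurable).
The per-scan summary is the **mean** FD by default — the emulated study
reports only a "0.2 mm" threshold without naming the statistic, so the
summary is explicit and configurable (`"mean"` or `"max"`). A subject is
excluded entirely when either scan exceeds the threshold.

# Two-stage feature selection

**Stage 1 (screening).** For each leave-one-out iteration the paired t test
is run per region on the remaining subjects' post − pre differences; the
returned set is the **union** over iterations of regions with $p < \alpha$
(default 0.05). Union (rather than intersection) follows the reading of
"features that survived from each iteration" as pooling across iterations;
with $n$ around 30 the leave-one-out t statistics are highly correlated, so
the union inflates the survivor set only mildly. Zero-variance differences
are a contract edge: all-zero differences give $t = 0, p = 1$; constant
nonzero differences give NaN with a warning (the statistic is undefined).

**Confound removal.** Surviving features are residualized per column against
the CFMT score (each scan against its own session's score), with intercept;
residuals are exactly mean-zero and uncorrelated with the confound. This
removes face-expertise variance that could masquerade as training-related
change.

**Rescaling.** The source description conflates "between 0 and 1" with
"normalization of mean variance"; both are implemented, min–max to [0, 1]
is the default, z-scoring is available (`rescale_method = "zscore"`), and
neither is asserted as the original intent. Constant columns map to 0.5
(min–max) with a warning. Inside cross-validation, scaling parameters can be
learned on training rows only (`scale_in_fold`); the global variant matches
the emulated study's procedure.

**Stage 2 (accuracy-driven RFE).** Per round, with current feature set $F$:

1. `accuracy_0` = LOOCV-SVM accuracy on $F$;
2. for each $i \in F$, `accuracy_i` = LOOCV-SVM accuracy on
   $F \setminus \{i\}$;
3. every $i$ with `accuracy_i >= accuracy_0` is removable; the batch is
   deleted simultaneously;
4. repeat until no removal keeps the accuracy, or one feature remains.

Two guards make the batch rule coherent with the invariant that the
accuracy trace never decreases (which simultaneous deletion alone cannot
guarantee, since jointly necessary features can each look individually
removable):

* a batch whose joint removal would *reduce* the LOOCV accuracy is rejected
  and the single feature with the highest removal-accuracy is removed
  instead (ties: highest region label removed) — this is precisely "stop
  when further elimination reduces the accuracy", applied to the batch;
* a batch that would empty the set retains the single feature with the
  highest removal-accuracy (ties: lowest label retained).

A strict one-at-a-time mode (`batch = FALSE`) is available for comparison.
On problems with ≤ 8 features and ≤ 12 samples the implementation is tested
against an independent brute-force simulator of the same greedy rule.

# Classifier and evaluation

The linear soft-margin SVM
$\min_{w,b} \tfrac12\|w\|^2 + C\sum_i \max(0, 1 - y_i(w^\top x_i + b))$
is solved in compiled code by SMO on the dual with maximal-violating-pair
selection (KKT tolerance 1e-8; training objective within 1e-6 relative of
the optimum, certified in the tests by the duality gap and, during
development, against LIBSVM). $C = 1$ by default — the emulated study never
states its cost — and every report logs it.

LOOCV holds out one **subject** (both scans) by default; scan-level
hold-out ("each sample designated as the test sample") is available as the
study-faithful option but leaks the held-out subject's other scan into
training. Predictions are pooled into the confusion matrix; accuracy,
sensitivity and specificity follow the standard ratios with post-training
coded positive; AUC uses the Mann–Whitney form (ties count one half),
identical to the trapezoidal area under the pooled-decision ROC. Pooling
decision values across folds (each from a different model) is the standard,
imperfect convention for cross-validated ROC curves.

Degenerate folds — a single-class training set, possible under per-scan
label permutation — are classified by the constant majority-class rule
rather than aborting.

# Permutation inference

`permutation_test` retrains on randomly reassigned labels and scores the
held-out scans against their *true* labels; `p_raw = \#\{null \ge obs\}/B`
(reported as "< 1/B" when 0) and the add-one corrected
`(\#\{null \ge obs\}+1)/(B+1)` are both returned.

Two axes are deliberately exposed:

* **Pairing.** Default: coherent per-subject flips, preserving the paired
  structure; the exchangeable unit is the subject. The study-faithful
  alternative assigns every scan an independent random label. With few
  subjects the flip space ($2^n$) bounds the attainable p from below, and
  under very strong signal the subject-flip null is heavy-tailed (a
  near-identity flip reproduces the observed accuracy); both behaviors are
  real properties of the schemes, not artifacts.
* **Scope.** Default `"selected"` permutes labels on the already selected
  features — the emulated study's procedure, which inherits selection
  optimism. `"honest"` re-runs the *entire* selection path (screening,
  residualization, rescaling, RFE) inside every permutation, pricing that
  optimism into the null. The null-calibration acceptance test shows the
  honest p values are approximately uniform under a null generator; the
  selected-scope p values on null data are anti-conservative, which is
  exactly the leakage worth measuring.

`selection_mode = "nested"` analogously re-runs both selection stages inside
each outer LOOCV fold for leakage-free point estimates of the metrics; in
nested mode the permutation test is always honest.

# Brain–behavior correlation

Per-subject post − pre deltas of region ALFF (selected regions by default,
all regions via `corr_scope = "all"`) are correlated with deltas of CFMT,
RET accuracy, and RET response time; Benjamini–Hochberg is applied across
the entire region × measure family as one family — the most conservative
reading of "after multiple comparison correction". The full table is always
emitted. Group-level behavioral comparisons reproduce the unpaired
Mann–Whitney convention of the emulated study, with a paired Wilcoxon
signed-rank alternative behind `paired = TRUE`.

# The synthetic cohort: the stated world

Each in-mask voxel series is

$$x_t = 100 + \underbrace{\beta\,(2t/N - 1)}_{\text{drift}}
 + \underbrace{\varepsilon_t}_{\mathrm{AR}(1)}
 + \underbrace{a_{s,r,c}\sum_{k \in K}\cos(2\pi k t/N + \phi_{v,k})}_{\text{band-limited oscillation}}$$

with random phases per voxel and one cosine at every in-band DFT frequency,
so the oscillation contributes exactly $a_{s,r,c}$ to the region's ALFF.
The amplitude factorizes as

$$a_{s,r,c} = a_0 \; g_{s,r} \; (1 + \eta_{s,r,c}) \; (1 + \delta_r
\,[c = \mathrm{post}, r \text{ planted}]),$$

* $a_0 = 0.5$ — baseline per-bin amplitude (arbitrary BOLD units; the
  oscillation then carries roughly twice the noise variance at rest,
  a realistic low-frequency share),
* $g_{s,r} = 1 + \mathcal N(0, 0.35^2)$ — the subject's region profile,
  drawn once and shared across conditions. This is what makes the design
  paired; 35% regional between-subject variability is in the range seen for
  standardized ALFF, and it keeps single-scan discriminability moderate, so
  classification accuracy lives in the realistic (non-saturated) regime,
* $\eta \sim \mathcal N(0, 0.1^2)$ — session-to-session amplitude jitter,
* noise: AR(1) with lag-1 correlation 0.4 and marginal SD 1,
* drift slope $\beta \sim \mathcal N(0, 0.5)$, removed by detrending,
* TR 2 s, 175 volumes, 246 Voronoi regions in an ellipsoidal mask; the
  default grid is 18×18×12 voxels so whole-cohort runs take seconds while
  the 246-region selection problem keeps its dimensionality.

**Effect calibration.** `effect_size` is the standardized *paired* effect
(Cohen's d of post − pre region ALFF). The generator solves for $\delta_r$
per planted region from the analytic variance of the paired difference —
session jitter, subject-profile interaction, and the noise-floor amplitude
variance $\mathrm{Var}(2|X_k|/N) \approx 2S(f_k)/N$ summed over in-band bins
and averaged over the region's voxels (signal-dominated regime, AR(1)
spectrum $S$). Neglected higher-order terms (noise–signal interplay, the
global-standardization compensation) leave the realized d a few percent
below nominal; Monte-Carlo over 200 subjects lands near 1.85 for a nominal
2.0, within the generator's contract of ±0.3. Because only ~4% of regions
are planted, standardization also induces a small *negative* compensatory
shift in unplanted regions — as it does on real data.

**Behavior.** CFMT is drawn once per subject (mean 56.9, SD 4.29, integer
0–72) and held constant up to small jitter; RET accuracy moves from
0.61 ± 0.05 to 0.84 ± 0.04 and RET response time from 3.08 ± 0.30 s to
2.53 ± 0.34 s. A configurable CFMT–ALFF coupling exists to exercise the
confound regression; it is off by default. Motion traces are random walks
tuned to a mean FD near 0.1 mm; injected high-motion subjects are scaled to
~0.33 mm so they exceed the 0.2 mm threshold deterministically.

**What the generator does not emulate** — scanner artifacts, slice timing,
spatial smoothness and autocorrelation, physiological noise spectra,
anatomy, registration error. A green test therefore establishes that the
*pipeline machinery* behaves as specified under a controlled world; it says
nothing about preprocessing quality on real scans.

**Determinism.** Every random draw flows from per-subject and per-scan
streams derived arithmetically from the configuration seed; identical
configurations regenerate cohorts bit for bit, and the pipeline report is
byte-identical across reruns.

# Known limitations

* **Recovery under redundancy.** With ten regions planted at the *same*
  effect size, the planted features are mutually redundant: removing one
  rarely costs LOOCV accuracy, so accuracy-driven RFE retains only a
  minimal sufficient subset. Across 20 strong-signal replicates, screening
  recovers 10/10 planted regions every time, while the final RFE set
  retains 5/10 on average. This is a property of accuracy-driven
  elimination itself (margin- or weight-based RFE would behave
  differently, and is out of scope); the corresponding acceptance
  criterion is left failing by design and documented in the repository's
  decision notes.
* **Selection leakage in the faithful mode.** The default
  (`paper_faithful` + `selected`-scope permutation) reproduces the emulated
  procedure, optimism included; `nested` and `honest` quantify it. The two
  modes answer different questions and neither is hidden behind the other.
* The printed accuracy/sensitivity/specificity triple of the emulated study
  is mutually inconsistent on 60 balanced samples; the package asserts the
  defining ratios of its own confusion matrices, not that triple.
* Voxel geometry is metadata only: no registration, resampling, smoothing,
  or anatomical realism.
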