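---
title: "Microstate analysis of ERPs: models, choices, and what the tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate analysis of ERPs: models, choices, and what the tests show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpmicrostates)
```

## The model

EEG microstate analysis treats the multichannel scalp potential as a
sequence of brief periods (tens of milliseconds) during which the spatial
*configuration* of the potential — the topography — stays quasi-stable
while its overall amplitude waxes and wanes, and during which the
topography may invert its polarity. The analysis therefore works with the
map vector $v_t \in \mathbb{R}^C$ ($C$ channels, average-referenced so
$\sum_c v_{tc} = 0$) and treats $v_t$ and $-v_t$ as the same brain state.

Three quantities organize everything:

* **GFP** (global field power): $\mathrm{GFP}_t = \sqrt{\frac{1}{C}\sum_c
  v_{tc}^2}$, a reference-free amplitude.
* **Spatial correlation**: for zero-mean maps the Pearson correlation over
  channels equals the cosine similarity
  $r(u,v) = \frac{u^\top v}{\|u\|\,\|v\|}$; polarity-invariant analyses use
  $|r|$.
* **GEV** (global explained variance) of an assignment of frames to
  templates $T_{L(t)}$:
  $\mathrm{GEV} = \frac{\sum_t \mathrm{GFP}_t^2\, r(v_t,
  T_{L(t)})^2}{\sum_t \mathrm{GFP}_t^2}$.

## Polarity-invariant modified k-means

`modified_kmeans()` alternates two steps on the unit-normalized maps
$\hat v_t$:

1. **Assignment**: each frame goes to the template with the largest
   $r^2$ (equivalently the largest $|r|$) — the polarity-ignored best fit.
2. **Update**: each template becomes the dominant eigenvector of the
   scatter $\sum_{t \in \text{cluster}} \mathrm{GFP}_t^2\, \hat v_t \hat
   v_t^\top$ of its members, which is the same as the first principal
   direction of the *raw* zero-mean member maps. The eigenvector is the
   polarity-invariant mean: it is blind to the sign of each member.

With this update both steps are coordinate ascent on GEV, so GEV increases
monotonically, convergence is declared when the relative GEV improvement
falls below `tol` (default 1e-7), and the best of `n_restarts` (default
64) random initializations is kept. This exactness matters: on instances
small enough to enumerate every partition, the best-of-200-restarts GEV
matches the global optimum to 1e-9 (the test suite checks this), which
would not hold if the update ignored the GFP weighting — an update built
from unweighted normalized maps optimizes a slightly different objective
than the GEV used to score solutions. Using the raw-map scatter keeps the
algorithm identical to the classical modified k-means of the microstate
literature while making the reported GEV the true objective.

Practical details: zero-GFP frames are excluded (labelled `NA`) rather
than aborting; an empty cluster is re-seeded from the worst-fitting map; a
per-map polarity sign ($+1$ on ties) aligns each map to its template. All
time frames of the analysis window are clustered, not only GFP peaks.

## Choosing the number of microstates: Krzanowski–Lai

For $k = 1 \dots 12$ the within-cluster dispersion
$W(k) = \sum_{\text{clusters}} \sum_{\text{members}} \| s_m \hat v_m -
T \|^2$ is computed on the best-of-restarts solution, and the
Krzanowski–Lai index is built from dimension-scaled successive
differences ($p$ = number of channels):

$$\mathrm{DIFF}(k) = (k-1)^{2/p}\,W(k-1) - k^{2/p}\,W(k), \qquad
\mathrm{KL}(k) = \left|\frac{\mathrm{DIFF}(k)}{\mathrm{DIFF}(k+1)}\right|.$$

Candidate cluster numbers are the local maxima of $\mathrm{KL}(k)$. The
phrase "second KL maximum value" admits two readings — the second-largest
maximum, or the second maximum in ascending $k$. We implement the literal
value reading as the `second_max` rule (local maxima ranked by KL value,
second-ranked chosen, falling back with a warning when only one exists)
and expose `global_max` and `first_max` alongside; the rule is a logged
configuration choice, and the package's own validation studies use
`global_max`, which empirically tracks the planted state count best.

Two stabilizations proved necessary in practice. First, each $k$ is
warm-started from the best $k-1$ templates plus the worst-fitted map (as
one extra restart): without it, occasional under-converged $W(k)$ values
make $\mathrm{DIFF}(k+1)$ cross zero by chance and the KL ratio explodes
at arbitrary $k$. Second, degenerate curves are special-cased: a $k$ whose
$W$ is numerically zero (noiseless planting) is chosen outright as the
smallest perfect fit, and a flat $W$ curve is flagged
`no_clear_structure`. Fewer than four evaluable $k$ values cannot support
the criterion and trigger an explicit error (or, inside
`select_k_for_erp()`, a documented fallback to the smallest $k$ attaining
maximal GEV, which handles noiseless epochs containing fewer distinct maps
than `max(k_range)`).

## Two-level template extraction and backfitting

Level one runs k-means with KL selection per subject × condition ERP over
the 400 ms post-onset window. Level two pools every subject-level template
(one map, one vote; each unit-normalized) and clusters the pool again over
$k = 1 \dots 12$ with the same rule, yielding the global templates. Their
order after clustering is arbitrary, so they are canonically re-ordered by
total cohort coverage after backfitting (descending), making labels stable
across runs with a fixed seed.

Backfitting assigns every frame of each ERP to the global template with
the highest $|r|$, ties toward the lower index, zero-GFP frames
unassigned. No temporal smoothing or minimum-duration rejection is applied
by default (`min_duration_ms = 0`); the hook exists because some
laboratories do reject very short runs, but switching it on changes the
metric definitions subtly and is off everywhere in the validation suite.

From the label sequence the three metrics per class are

* **duration** — mean contiguous-run length, in ms (undefined, reported
  `NA`, when the class never occurs; *not* zero);
* **occurrence** — number of runs divided by the window length in
  seconds;
* **coverage** — percentage of assigned frames carrying the class.

When no frame is unassigned these satisfy exactly
$\mathrm{coverage}/100 = \mathrm{occurrence} \times
\mathrm{duration}/1000$, which the suite asserts on every synthetic
sequence. Runs truncated by the window edges count as full runs with their
observed lengths — the simplest literal reading, which biases edge runs
short; the bias is visible below in the gap between planted (125 ms) and
realized (~105 ms) long-state durations.

## The condition-level statistics

The metrics table (subject × condition × class) feeds classical
univariate within-subject ANOVAs (`rm_anova()`, fitted through
`stats::aov` with an `Error(subject/...)` stratum; uncorrected degrees of
freedom, no sphericity correction by default, $\alpha = 0.05$), Duncan's
multiple range test for post-hocs (`duncan_posthoc()`, studentized-range
critical values at protection level $1-(1-\alpha)^{r-1}$ with the usual
step-down blocking), and Pearson correlations between per-subject mean
metrics and handedness scores in $[-100, 100]$. `run_battery()` replays
the full battery declaratively: omnibus one-way ANOVAs over the four
classes per metric; per class a 2×2 Emotion × Side ANOVA on the
unilateral conditions and a one-way ANOVA over the bilateral ones; and
per class two five-level one-way ANOVAs, one per valence family (each
family replayed independently even though the mixed bilateral conditions
appear in both, mirroring how such designs are conventionally reported).

`rm_anova()` requires a complete balanced design and errors naming the
offending subject/cell otherwise. Because *duration* is undefined for a
class absent from an epoch, duration ANOVAs are only defined on complete
tables; `run_battery()` skips (and reports) analyses whose cells are
incomplete rather than aborting. Occurrence and coverage are zero for
absent classes and always yield complete designs.

## The synthetic cohort generator

`synthetic_spec()` + `make_cohort()` emulate the divided-visual-field
study design: 16 subjects × 8 conditions (AN/HA × LVF/RVF unilateral;
AN-AN, HA-HA, AN-HA, HA-AN bilateral), 128 channels on a hemispherical
montage, 250 Hz (the sampling rate is a free input; 250 Hz is our
default), a 400 ms post-onset window, and 4 planted template
topographies.

* **Templates**: spatially smooth random maps (Gaussian kernel, length
  scale 0.7 on the unit sphere — global, dipolar-looking patterns),
  orthogonalized and then blended back toward their smooth versions as far
  as the pairwise bound $|r| \le 0.5$ allows.
* **State sequences**: semi-Markov — class drawn from condition-specific
  occupancy weights with no immediate self-transition, run length from a
  truncated normal (mean ~100 ms, matching the 80–120 ms quasi-stability
  range reported for microstates; SD 20 ms; at least 2 frames).
* **Amplitude**: an ERP-like envelope of two raised-cosine components
  peaking near 100 and 200 ms over a 0.4 floor, times a random per-run
  polarity.
* **Noise**: Gaussian, spatially smoothed at length scale 0.1 — the
  nearest-neighbor electrode spacing of a 128-channel net — and scaled so
  that $10\log_{10}(\overline{\mathrm{GFP}^2_{\text{signal}}} /
  \overline{\mathrm{GFP}^2_{\text{noise}}})$ matches `snr_db` (default
  5 dB) over the epoch. The noise length scale is deliberately far below
  the template length scale: noise that is smoothed at the *template*
  scale is not noise but confusable topography (its correlation with an
  arbitrary smooth template reaches ~0.5), and model selection degrades
  long before backfitting does. We state this as a limitation: on real
  data, where residual activity *is* brain-shaped, KL-based selection
  should be expected to be noisier than in these simulations.
* **Subject effects**: per-subject duration-mean jitter (SD 5 ms) and a
  5% template perturbation; synthetic handedness scores (mean 79, SD 9,
  clamped to $[-100,100]$) optionally coupled to the class-1 duration
  offset via `beta_hand` for correlation-recovery tests.

The default condition effects plant the qualitative pattern the analysis
is meant to detect: class-4 states run longer for LVF than RVF unilateral
presentations (125 vs 95 ms vs 100 ms baseline) *and* occupy a larger
share of draws (0.26 vs 0.18), while class 2 is favored in unilateral
(0.30) over bilateral (0.18) presentations. The occupancy component of the
class-4 effect is planted directly because the duration route alone is
heavily dampened by 400 ms window truncation: a ~30 ms planted duration
difference survives as barely one percentage point of coverage, too small
for a 16-subject cohort to detect, whereas lateralized occupancy plants
the coverage difference at full strength. `null_effects = TRUE` switches
every condition to flat durations and equal occupancies for calibration
studies.

A consequence of ~100 ms runs in a 400 ms window is that an epoch holds
only ~4 runs, so roughly two thirds of epochs do not contain all four
classes — their planted structure genuinely is 2 or 3 states. Planted-k
recovery studies therefore either condition on presence
(`require_all_classes = TRUE`) or score recovery of each epoch's own
planted state count; both are reported. Relatedly, per-epoch duration can
be undefined for a class, which is why the recovery checks of the planted
condition effects use coverage and occurrence for their significance
tests and check duration at the level of condition-mean ordering.

## Problem sizes and numerical choices

The validation studies run at the full study scale where the property
lives at that scale — one 16 × 8 cohort (128 epochs, 12 candidate k, 64
restarts each) for template recovery and condition-effect recovery; 50
single-ERP draws for planted-k selection; 1000 simulated metric tables
for the type-I calibration of the ANOVA (5% ± 2% target) and 200 for the
power of a planted 5 ms effect ($\sigma_\text{within} = 3$ ms, n = 16) —
and at enumerable scale for the oracle checks (≤ 12 maps, ≤ 6 channels,
k ≤ 3 against exhaustive partition search). Determinism is end-to-end:
every stochastic operation takes an explicit seed, cohort generation is
byte-identical under a fixed seed, and rerunning a pipeline config
reproduces every artifact.

Known limitations: no GFP-peak-only clustering, no topographic consistency
testing (TANOVA), no source localization, no temporal smoothing in
backfitting, white-in-time noise (real ERP residuals are temporally
correlated), and a montage that is a geometric idealization. Passing the
synthetic recovery suite shows the pipeline implements its own model
correctly and recovers planted structure at the stated SNR; it does not
show that 400 ms ERP windows of real recordings contain four states, nor
that KL selection is reliable under brain-shaped residual noise.
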