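---
title: "Decoding covert attention and quantifying value coding: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding covert attention and quantifying value coding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its methods: what is modelled,
which parameters matter and why their defaults were chosen, what the
synthetic generator does and does not emulate, and where genuinely open
design choices were settled.

## 1. The task model

The generator emulates a covert-attention detection task with reward-salient
stimuli. Timing constants (seconds from trial start): fixation at 0, saccade
target at 0.5, frame cue at 1.0, stimulus pair at 1.2, cue offset at 1.4
(0.2 s after stimulus onset). The frame appears **opposite** the cued
location, so the cue side (`att_cue_loc`, coded −1/+1) and the attended side
are mirror images — the geometry that makes below-chance cross-temporal
decoding interpretable.

Two paradigms: `"D"` (valid/invalid cueing, `p_valid = 0.90`) and `"G"`
(target 80% / distractor-only 10% / distractor+target 10%). Luminance-change
latencies are `offset + X`, `X ~ Exp(tau)` truncated at `cutoff`
(D target: tau 2.5 s, cutoff 1.4 s; G target: 2.5/1.9; G distractor:
1.25/1.9; offset 0.4 s everywhere), which flattens temporal expectation while
bounding trial length. Reward levels {0, 1, 2, 4, 8} standard drops (the
"small drop" stimulus codes as 0 in all regressions) are drawn uniformly and
independently for the two sides; the delivered reward is a random pick
between the two, so neither the cue nor salience predicts payout.
Single-stimulus trials (7.1% in D, 10.1% in G) are always validly cued, with
the stimulus at the cued location.

Derived trial regressors are pure functions of the design: cued/un-cued
value CV/UCV (by the frame side), salient/non-salient value
SV = max(LV, RV), NSV = min(LV, RV), total value, the three differences, and
V_sin for single-stimulus trials. When LV = RV the pair is equally salient;
such a change is scored "at the salient stimulus".

**Behavioural outcomes** are Bernoulli per condition cell
(trial type × change-at-salient), with reaction times from a normal
truncated to the legal 0.1–0.4 s response window. Default cell
probabilities and RT means are set to values typical of well-trained
subjects on this task (valid ≈ 94%, invalid ≈ 90%, target ≈ 91–94%,
distractor correct rejection ≈ 81%; RTs 220–300 ms). The RT standard
deviation (0.04 s) is a generator choice: only means are constrained by
published performance, and 40 ms keeps nearly all mass inside the window
while producing realistic fast/slow halves for the median-split analysis.
In distractor+target trials the distractor is resolved first; a false alarm
terminates the trial before the target change is displayed (its latency
becomes `NA`), which keeps the simulator and the scorer (`score_trials`)
exactly consistent. A response falling in both the distractor's and the
target's window is credited to the target — the task software would reward
it — an edge the task description leaves open.

## 2. The spiking model

Each neuron is an inhomogeneous Poisson process on a rectified linear rate:

\[
\lambda(t) = \max\Big(0,\; b + \sum_c \beta_c\, k_c(t)\, x_c(\text{trial})\Big)
\]

with baseline \(b\) (Hz), coefficients \(\beta_c\) in Hz per regressor unit,
saturating-rise/exponential-decay kernels \(k_c(t)\), and covariates
\(x_c\): the signed cue side for the `cue_pre`/`cue_post` components, z-scored
value regressors for `sv`/`nsv`/`cv`/`ucv`, and a side-independent `frame`
transient at cue onset. The pre/post pair shares a flip time
(`flip_latency_s`, default 0.15 s after stimulus onset); choosing
`cue_post = -cue_pre` reproduces the attention-shift geometry in which the
early frame-captured representation reverses once attention settles on the
opposite side. Kernels are a deliberate invention — no response dynamics are
prescribed by the task — and their time constants (rise 30 ms, decay 50 ms)
simply give physiologically plausible transients.

The encoding noise is Poisson count noise rather than the additive Gaussian
assumed by the analysis regressions. This is intentional: the generator must
emit spike trains, and at the 5–15 Hz baselines used the rate-level Gaussian
approximation is adequate. Where a test needs exactly Gaussian responses
(e.g. selectivity-screen calibration), it bypasses spiking and feeds rate
tables directly into the analysis functions.

Area profiles set the coefficient mixtures: `ofc_like` draws ~55% value-tuned
neurons (log-normal |SV| coefficients, ~58/42 positive/negative), no
sustained cue coding, and a brief frame transient; `dlpfc_like` gives every
neuron a cue coefficient (log-normal magnitude, random sign, post = −pre)
and moderate mixed-sign SV coefficients. The tuned fractions and sign split
follow the rough proportions reported for these areas; the coefficient
magnitudes are free parameters chosen so that single sessions of 25–150
neurons produce clearly resolvable effects. *What passing tests show*:
the pipeline recovers the structure it is pointed at, with calibrated nulls.
*What they do not show*: anything about real data — the generator has no
correlated variability between neurons (trials are resampled independently,
exactly as the pseudo-population construction assumes), no slow drifts,
bursting, or history dependence, and no behaviour–spiking coupling beyond
the optional RT-gain knob (`cue_rt_scaling`).

## 3. Decoding pipeline

Numerical conventions: all windows are half-open, bin labels are centers,
times are relative to trial start. Raw binning is 5 ms so the 25-ms decode
window and 10-ms step are exact integer multiples (no partial-bin
averaging); z-scoring is per neuron across all trials and all time points of
both alignment windows jointly (−400–600 ms around stimulus onset and
−400–400 ms around the change), zero-variance neurons are excluded with a
warning; smoothing uses a Gaussian kernel (sigma 50 ms) truncated to a
100-ms window and renormalized at edges so constants are preserved.

Pseudo-ensembles sample `n_per_class = 100` trials per cue side per neuron
without replacement (inclusion requires at least 100 trials per side);
pseudo-trial m pairs the m-th sample of every neuron. PCA retains the
smallest component count reaching 70% cumulative variance — per bin for the
same-time decoder, or once on the `MT×N` unfolding for cross-temporal
decoding so all bins share one subspace. The LDA uses pooled covariance,
equal priors (0.5), and a trace-scaled 1e−6 ridge only if the covariance is
near-singular (PCA normally prevents this).

**Cross-validation and leakage.** "Repeated leave-one-out" is read as
independent ensemble resamplings (`n_cv`), each with a full leave-one-out
pass. The supervised step is strictly honest: the held-out trial never
touches the LDA fit, implemented as an exact rank-one-downdate
(Sherman–Morrison) leave-one-out that the tests verify against naive
refitting to 1e−10. The label-blind preprocessing (z-score, smoothing, PCA)
is fitted once per ensemble rather than per fold: it sees no labels, so it
cannot leak class information, and refitting an SVD inside every fold of
every bin of every resample would multiply cost by the ensemble size for no
statistical gain. A `strict_folds` switch refits PCA per fold for small
instances; the tests confirm the two paths agree.

**Significance.** True-label posteriors are compared against runs with
labels shuffled *within* the assembled ensemble (the natural null for the
fixed ensemble geometry), by per-bin two-tailed paired t-tests under
Benjamini–Hochberg FDR (the procedure behind every "FDR corrections"
statement here). Above- and below-null bins are reported as separate masks
because below-chance performance carries meaning (a sign-reversed
representation), and folding it into two-sidedness would discard the
direction. The RT median split assigns the median trial to the slow half; a
session with tied RTs is flagged degenerate rather than split arbitrarily.

## 4. Encoding analyses

Selectivity: one simple regression per variable (LV, RV, LV−RV, CV, UCV,
CV−UCV, SV, NSV, SV−NSV, TV, cue location; V_sin on single-stimulus trials)
per epoch (cue-stimulus 0–0.2 s, early 0.2–0.6 s post-onset, late −0.4–0 s
pre-change — a trial enters the late epoch only if its latency is ≥ 0.4 s),
two-sided slope test at p < 0.005. Value-selective neurons split into
positively and negatively tuned; any pair of significant slopes with
opposite signs (across variables or epochs) marks the neuron contradictory
and excludes it from tuned groups.

CPD: the full model (intercept + cue + two value regressors, all predictors
z-scored **on the analyzed trial subset**) and each leave-one-regressor-out
model are fitted by OLS; `CPD_i = (SSE_−i − SSE_all)/SSE_−i`, which model
nesting bounds to [0, 1) and which equals the squared partial correlation —
an identity the tests assert to 1e−10 on random designs. Time courses use
consecutive 25-ms bins on both alignments; the baseline is the CPD from the
mean rate in the 200-ms pre-cue window, averaged across the three regressors
(a window mean, not a single 25-ms bin — the less noisy of the two readings
of that definition, with the alternative one line away). Because no
stimulus information exists pre-cue, the baseline is a same-n null for the
stimulus-period CPDs. Epoch-level CPDs use the variable-length per-trial
stimulus period (onset to change), or the post-cue period (cue offset to
change) for the top-down attention contrast ΔCPD = CPD(cue) − CPD(SV);
per-neuron coefficient significance is reported uncorrected (p < 0.05) as in
the corresponding figure conventions, while population time courses carry
FDR correction. Only correct trials enter all neural analyses, and neurons
need ≥ 100 eligible trials and ≥ 1 Hz mean rate.

A useful emergent symmetry: under salience-only coding, cue side is
independent of which side is salient, so CV and UCV carry identical signal
in expectation and their CPDs coincide — the package's tests use this as an
oracle, and it is why a CV≈UCV result is diagnostic of attention-free value
coding rather than an artifact.

The grouped-response path averages each neuron over the trials of a group
(same-reward pairs by value; by SV, CV, or UCV; the salient-8 attention
contrast), then across neurons; the additive two-way ANOVA (grouping ×
value, no interaction, type-II sums of squares via `drop1`) tests whether
SV-grouped responses differ from the same-reward-pair reference.

## 5. Problem sizes and determinism

Every stochastic entry point takes an integer seed and restores the caller's
RNG state; identical seeds give byte-identical sessions, ensembles, and
decoders. The shipped analyses and tests run single-threaded in minutes:
sessions of 400–600 trials with 25–150 neurons, `n_cv` of 5–20 resamples,
and 500-design oracle sweeps — sizes chosen so the full validation suite
documents the method's behaviour (signal recovery, null calibration,
monotonicity in signal strength and population size) at comfortably
interactive cost. Scaling any of them up is a parameter change, not a code
change.

## 6. Known limitations

* Pseudo-populations assume exchangeable trials within condition; real
  simultaneous recordings would add noise correlations the decoder here
  never sees, typically inflating its accuracy relative to real ensembles.
* The Poisson generator cannot produce sub- or supra-Poisson variability
  (Fano ≠ 1), so dispersion-sensitive behaviour is untested.
* The behavioural simulator draws outcomes independently per trial; there
  are no learning, fatigue, or sequential effects.
* The signed-rank exact branch handles ties by midrank enumeration, but
  heavily tied data with n > 15 falls back to the normal approximation,
  whose tie correction is asymptotic.
* `fit_cpd` flags near-collinear designs and still reports CPDs; with
  strongly correlated value regressors (e.g. SV and TV in the same model)
  partial contributions become ill-conditioned — the shipped model specs
  avoid this by construction.
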