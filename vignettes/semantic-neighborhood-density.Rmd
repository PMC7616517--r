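---
title: "Semantic neighborhood density and auditory lexical decision: models and methods"
author: "semdense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic neighborhood density and auditory lexical decision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
# Chunks are displayed, not executed: the heavier ones are simulation
# harnesses that the test suite runs at full size.
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Distributional semantic models represent word meanings as high-dimensional
vectors estimated from co-occurrence statistics of large corpora; the cosine
of the angle between two vectors is the standard proxy for semantic
relatedness. A word's **semantic neighborhood density** (SNeigh) is the mean
cosine similarity between the word and its $k$ closest neighbors ($k = 5$
here) within a reference vocabulary of the 20,000 most frequent words of a
subtitle-frequency norm, excluding the word itself. Words in dense
neighborhoods are recognized faster in lexical decision.

This package implements the full analysis chain for asking whether **early
blind (EB)** listeners are more sensitive to this purely linguistic,
distributional statistic than **sighted controls (SC)** in an auditory
lexical decision task: if visual experience is missing, distributional
linguistic experience may carry more weight in the organization of semantic
knowledge, which should surface as a steeper (more negative) RT-by-density
slope in the blind group.

## The statistic

For a stimulus $w$ with vector $\mathbf{w}$ and reference vocabulary $R$,

$$\mathrm{SNeigh}(w) = \frac{1}{k}\sum_{v \in N_k(w)} \cos(\mathbf{w}, \mathbf{v}),
\qquad \cos(\mathbf{u}, \mathbf{v}) = \frac{\mathbf{u}\cdot\mathbf{v}}{\lVert\mathbf{u}\rVert\,\lVert\mathbf{v}\rVert},$$

where $N_k(w)$ are the $k$ reference words with the largest cosine to
$\mathbf{w}$, excluding $w$ itself *by exact string identity* (a different
word with an identical vector is a legitimate neighbor). Ties at the $k$-th
position break by cosine descending, then word lexicographically ascending,
so outputs are bit-reproducible. Stimulus vectors and reference vectors are
obtained as two independent sets: a stimulus need not be inside the top-N
reference, and stimuli that happen to be inside the reference may serve as
neighbors of other stimuli (the reference is purely frequency-defined;
`compute_density_table()` would make a stimulus-excluding variant a
one-line change, but the default deliberately does not exclude them).

Reference-vocabulary construction reads the top `n_top` words of the
frequency list and keeps those with vectors; words lacking vectors are
**skipped, not back-filled** from lower ranks, keeping "the N most frequent
words" literal. Word matching is exact after Unicode NFC normalization — no
case folding, no diacritic stripping, because orthography is meaningful.
Out-of-vocabulary stimuli are an error: a plain-text vector file cannot
synthesize subword vectors, so silently imputing them would change the
statistic.

## Trial cleaning

The cascade mirrors standard chronometric practice, in a fixed order:

1. **Participants**: within each group, a participant is excluded when
   their error rate over all trials exceeds the mean + 2.5 SD of the error
   rates of the *other* participants of that group. The leave-one-out form
   follows the wording "higher than the other participants"; a whole-group
   variant would only differ by including the candidate in its own
   reference distribution.
2. **Items**: a word is excluded when its accuracy falls 2.5 SD below the
   item mean *in both groups separately* (AND rule — reading "lower than
   the average rate in both groups" literally; an OR rule would exclude
   more items).
3. **Trials** (words only, since only words enter the RT model):
   incorrect trials, then responses faster than 300 ms, then per-participant
   trimming of RTs more than 3 SD from that participant's mean, computed on
   the raw millisecond scale over the trials surviving the earlier steps.
   Each step's percentage uses the count remaining before that step as its
   denominator (the tiny fast-response percentage only reproduces under
   this convention); percentages over all pre-cleaning trials are reported
   alongside, since the denominator convention is not always stated in
   published tables.
4. **Transforms**: natural logs of RT and duration (milliseconds). The base
   only rescales coefficients, never F statistics.

Degenerate cases are defined, not patched: zero within-participant SD keeps
all trials (strict inequality), participants left with fewer than two
trials are skipped by the SD filter with a warning.

## The mixed model

```{r model}
fit <- fit_sneigh_lmm(clean$trials, density = density)
anova_type3(fit)       # Type III F table, Satterthwaite denominator df
simple_slopes(fit)     # per-group SNeigh slope, SE, z and t
posthoc_type(fit)      # pairwise word-type contrasts on marginal means
r2_nakagawa(fit)       # marginal / conditional R2
model_criticism(fit)   # 2.5 SD standardized-residual trim + refit
```

The model, in `lme4` syntax:

```
log(RT) ~ group * (sneigh + type) + log(duration) +
          (sneigh | participant) + (1 | stimulus)
```

REML estimation (ML behind `reml = FALSE` for model comparison), crossed
random effects: correlated by-participant intercepts and density slopes,
and by-stimulus intercepts. SNeigh enters raw — uncentered and unscaled —
so slopes are on the cosine scale that published tables use; `center_sneigh
= TRUE` changes the intercept only. Factors are coded sum-to-zero
internally, which makes each term's Type-III hypothesis its coefficient
block; group-specific slopes and pairwise type contrasts are linear
combinations of the fixed effects, so the coding never surfaces.

**Denominator degrees of freedom.** The Satterthwaite approximation is
implemented in the package itself on top of `lme4`'s deviance machinery:
the variance parameters $\hat\eta = (\hat\theta, \hat\sigma)$ are treated
as asymptotically normal with covariance $A = 2H^{-1}$, $H$ the numerical
Hessian of the REML criterion in $\eta$; a contrast $L$ with variance
$f(\eta) = L^\top C(\eta) L$ gets
$\mathrm{df} = 2 f(\hat\eta)^2 / (\nabla f^\top A\, \nabla f)$, and
multi-df terms diagonalize $L C L^\top$ and pool the per-component dfs by
matching the mean of the F distribution. The implementation is validated
against closed-form dfs in balanced designs (a between-cluster covariate
has exactly $J - 2$ df) and against the standard published result for the
`sleepstudy` example (t(17) = 6.77). Kenward–Roger is not offered: no
installed package provides it and the published table is Satterthwaite-
style (between-participant terms carry participant-level df). Because
published slope and post-hoc tables report $z$ statistics, those functions
report both the normal-approximation $p$ and the Satterthwaite-$t$ $p$.

**Model criticism** refits after dropping observations whose conditional
residuals, standardized by the residual SD, exceed 2.5 in absolute value.
Singular or non-converged fits are *reported* in the fit object's
diagnostics, never silently simplified: changing the random-effects
structure on the fly would break comparability across fits.

**R².** Marginal R² is the variance of the fixed-effect predictor over the
total of fixed, random and residual variance; conditional R² adds the
random-effect variance, where the random-slope term contributes the mean
quadratic form of its design rows with the estimated covariance matrix (the
standard extension of the variance-partitioning R² to random-slope models).

## The synthetic world

The generator exists so every stage is testable without any download, and
its defaults *are* the published conditions, not free dials:

| parameter | default | source |
|---|---|---|
| slopes (EB, SC) | −0.37, −0.25 | published group-specific slopes |
| duration slope | 0.25 | published coefficient |
| participant intercept SD | 0.13 | published variance table |
| stimulus intercept SD | 0.06 | published variance table |
| participant slope SD | 0.11 | published variance table |
| intercept–slope correlation | −0.50 | published variance table |
| trial error probability | 0.0175 | published inaccurate-trial rate |
| design | 2 × 20 participants, 3 × 39 words, 2 presentations | study geometry after exclusions |
| residual SD | calibrated | see below |

The residual variance is not published; it is **calibrated** so the implied
conditional R² equals the published 0.50 given the other components and the
realized design: $\sigma^2_e = (v_f + v_r)(1 - R^2_c)/R^2_c$, computed and
logged by `calibrate_residual_sd()`. Quantities the study does not print
are fixed once as plausible values and not revisited: intercept 5.5 log-ms
(putting mean RTs near 1.1 s), a group main effect of 0.065 (the magnitude
implied by the published group F at these variance components; its sign is
arbitrary), type effects (+0.0172, −0.0088, −0.0084) reproducing the
published pairwise type differences, and log-normal durations around 700 ms
(sdlog 0.15), a typical spoken-adjective length.

The synthetic embedding space draws words from Gaussian clusters with
spreads ranging from 0.3 to 1.2 around unit-scale centers in 50 dimensions,
which places 5-nearest-neighbor cosines in roughly the 0.5–0.95 band real
pretrained spaces produce and makes density vary systematically with
cluster tightness. What the generator does **not** emulate: the lexical
statistics of any real language, subword structure, anisotropy of trained
embedding spaces, participant-level error-rate heterogeneity, or
speed–accuracy trade-offs. A green simulation test therefore establishes
that the *pipeline* is correct and the *estimator* well calibrated under
the stated model — not that the empirical effect replicates; that requires
the deposited data and the ~4 GB pretrained vectors, which this package
deliberately does not download.

`recovery_experiment()` keeps the embedding space and density table fixed
across replicates — the same stimuli, as in a repeated experiment — and
redraws design noise, random effects and residuals with a deterministic
per-replicate seed stream. Two harnesses matter:

* **Null calibration**: equal slopes in both groups at a reduced geometry
  (10 participants/group, 30 words); the group-by-density interaction
  should reject at the nominal rate. This is where the Satterthwaite df
  earn their keep — at ~20 participants a normal-approximation test is
  anticonservative.
* **Recovery at study geometry**: 40 participants / 117 words; mean slope
  estimates should sit within Monte-Carlo error of −0.37 / −0.25 with
  nominal CI coverage.

## Numerical choices and edge cases

* Cosines are computed in double precision and clamped to $[-1, 1]$;
  zero-norm vectors raise an error rather than returning NaN.
* All randomness flows through explicit seeds; per-replicate seeds are
  derived as `(seed + 7919 r) mod (2^31 − 1)` to stay inside R's integer
  range.
* The Hessian and Jacobian for the Satterthwaite machinery use central
  finite differences (`numDeriv`); a computationally singular Hessian
  falls back to a pseudo-inverse with a warning rather than failing.
* Log-duration defaults to milliseconds; seconds would shift only the
  intercept and the duration slope's scale, not any F test.
* Pipeline stages communicate via files (TSV/JSON) in the run directory so
  each stage is independently inspectable and resumable, and each run
  appends a manifest entry (input hashes, config snapshot, row counts,
  seed, version).

## Known limitations

* No binary word2vec or fastText `.bin` subword inference; vectors are
  read from text, never trained, so out-of-vocabulary stimuli error out
  where the original pipeline could synthesize subword vectors.
* No approximate nearest-neighbor index: at $N \approx 20{,}000$ the
  exhaustive search is a few matrix products.
* Exact reproduction of the published F table needs the deposited trial
  data and the pretrained Italian vectors; this package verifies the
  machinery by construction (oracles, closed forms, simulation) instead.
* The error model is a constant Bernoulli rate; accuracy itself is not
  modeled (no generalized mixed model), matching the scope of the RT
  analysis.
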