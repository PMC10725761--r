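---
title: "Methods: cognitive and sensory models of harmonic expectancy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cognitive and sensory models of harmonic expectancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models implemented in `chordexpect`, the
assumptions behind them, the numerical and design choices that were
genuinely open, and what the synthetic-data generator does and does not
emulate. The README shows a worked end-to-end example; here the focus is
on *why* each piece is built the way it is.

## Chord representation

Chords are reduced to a token `root:quality` with the root as a pitch
class (0–11, C = 0) and one of nine quality classes (`maj`, `min`,
`dom7`, `maj7`, `min7`, `dim`, `aug`, `sus`, `other`). Harte-style labels
are parsed by stripping inversions and added-note lists and mapping the
remaining quality shorthand through a documented table
(`quality_templates()` lists the interval templates). This bounds the
symbolic alphabet at 108 tokens so that n-gram counts stay dense at desk
scale. No-chord (`N`) events are dropped before modelling: the models
predict chords, and a silence token would distort both the n-gram
statistics and the spectral chain. Sequences are transposed to a common
tonic (C) before modelling, matching stimuli presented in a single key.

Symbolic chords are rendered to pitches with a deterministic
root-position closed voicing anchored at MIDI octave 4 (`C:maj` becomes
60-64-67). Any fixed rule suffices for the spectral models — what matters
is that the same chord always yields the same spectrum — and root
position is the conventional neutral choice.

## Cognitive expectancy: variable-order Markov prediction

The long-term model (LTM) accumulates n-gram counts of all context
lengths 0..10 over a training corpus; the short-term model (STM) starts
empty at each song and ingests each chord *after* predicting it, with
unbounded context length (the context is the entire song prefix, read
literally). Prediction blends orders by interpolated
prediction-by-partial-matching: starting from the longest observed suffix
of the context, each order contributes its maximum-likelihood estimate
and passes the escape mass down, terminating in a uniform distribution
over the full training vocabulary. This order-(-1) floor guarantees
strictly positive probabilities, hence finite information content.

Choices worth recording:

- **Escape method.** The PPM family leaves the escape estimator open.
  The reference configuration here is method C (escape mass proportional
  to the number of distinct continuations), with methods A and D also
  implemented and exposed; C is the classical default and the one our
  brute-force oracle tests pin down to 1e-12.
- **LTM/STM combination.** Geometric mean of the two distributions,
  renormalized. Renormalization is required for IC and entropy to be
  well-defined; the combination is idempotent and exact closed forms are
  tested.
- **Components.** `chord_expectancy(..., components = "ltm")` disables
  the STM. This matters for validation: on corpora drawn from a known
  first-order Markov chain, the mean cross-validated IC of the LTM
  converges to the chain's conditional entropy (tested within 5% at
  roughly 10^4 events), whereas the STM's contribution does not vanish
  with corpus size — it is an online learner of each individual song.
- **Cross-validation.** Songs are shuffled by a recorded seed and split
  into 10 folds; each song's predictions come from an LTM trained on the
  other folds plus its own STM, so no song is predicted by a model that
  saw it. The fold assignment and seed are stored as attributes of the
  returned frame.
- **Bigram control.** `bigram = TRUE` caps the context at a single chord
  in both components, giving a control model whose context length is
  comparable to the sensory models' integration window.

## Sensory expectancy

**Spectral distance.** Each chord tone contributes 12 overtones with
weight `i^-0.75`; overtones land on a circular log-frequency axis with
1200 bins per octave (cents) folded to pitch class, and the vector is
smoothed with a unit-mass circular Gaussian of width 6.83 bins. The
weighting exponent and smoothing width follow the published optimization
of this model family; the smoothing parameter is printed without units in
the source literature, and this implementation fixes its unit as cents
(1200 bins/octave), exposed in the configuration. Harmonics are rounded
to the nearest bin for platform-stable reproducibility. Spectral distance
between adjacent chords is the cosine distance, clipped to [0, 1]; zero
vectors are a contract error.

**Periodicity pitch.** The original auditory model transduces audio
through a cochlear/inner-hair-cell front end and a windowed
autocorrelation. This package deliberately replaces that front end with
an idealized periodicity image computed by subharmonic summation over the
chord's unfolded harmonic spectrum (candidates MIDI 24–96, 12 multiples,
1/m weighting). **This is a substantive approximation**: it preserves the
model's memory and contextuality mechanism — which is what the
behavioural claims rest on — while discarding level, timbre and phase
effects. Results should be read as the memory model operating on
idealized spectral input, not as a reimplementation of the audio
pipeline.

The memory stage is exact: global and local images are leaky integrators
`out = e^(-dt/tau) prev + (1 - e^(-dt/tau)) incoming` applied once per
chord with dt equal to the 2.4 s chord duration; default time constants
are 4 s (global) and 0.5 s (local), the pair selected in the source
analysis from the 6-point grid {1.5, 2.5, 4} x {0.1, 0.5} s, with the
whole grid runnable. Tonal dissimilarity is minus the Fisher z-transform
of the Pearson correlation between the global image carried from the
*previous* chord's end and the current local image; the first chord of
each song is missing by construction. The correlation is clamped at
|r| = 1 - 1e-6 before `atanh` so identical images give a finite minimum.
A flag (`global_includes_current = TRUE`) switches to the variant where
the global image is updated before the comparison; the strict variant is
the default because the quantity is meant to compare the incoming chord
against its preceding context.

## Behavioural preprocessing

Slider traces (integers 0–1023 at 20 Hz) are cleaned with a five-sample
symmetric median filter; edge samples use shrunken symmetric windows
(window widths 1, 3, 5, ...), avoiding padding artefacts on short traces.
Per chord, the modal filtered value is read from the window
`[onset + 1 s, next onset)`; the 1 s delay absorbs the manual reaction
time, and ties are broken by the smallest value (the rule is arbitrary
but must be deterministic, and this one is stable under monotone
relabelling — the whole pipeline commutes with strictly monotone
transformations of the slider scale, which is tested). First-chord
ratings are discarded (trials begin with a slider reset), remaining
ratings are averaged across subjects within groups, and all variables are
standardized; the means and standard deviations are retained for the
inverse transform.

Stationarity of each per-song series is assessed with an augmented
Dickey-Fuller regression with drift; the augmentation lag is chosen by
AIC up to 10 (the test's source names no lag policy) and the 5% critical
value uses the MacKinnon (2010) finite-sample response surface for the
constant-only case. Differencing is not applied by the pipeline — the
check is computed and reported, and on the synthetic data (as in the
emulated study) the series reject unit roots.

## Regression, sampling and model comparison

The response is modelled with a Gaussian multilevel linear model. Every
term of a preset enters twice: as a population-level coefficient (the
reported effect) and as a song-level varying effect (hierarchical
centering). Residuals follow an AR(1) process along chord order within
each series; when ratings are split by listener group, the two
group-averaged series of a song are separate AR(1) chains sharing one
correlation parameter. The first observation of each series uses the
stationary marginal (variance `sigma^2 / (1 - rho^2)`), which is also the
convention of the pointwise log-likelihood used for cross-validation (the
innovation decomposition: each observation conditioned on its
predecessor). Group-wise effects (e.g. the musician and non-musician
slopes) are computed draw-wise from the population coefficient and its
interaction with the group code (+0.5 / -0.5) before summarizing.

**Sampler.** The posterior is drawn by a blocked Gibbs sampler: conjugate
multivariate-normal updates for population coefficients and song effects
after quasi-differencing at the current AR(1) coefficient; the innovation
variance via the exact inverse-gamma mixture representation of the
Half-Cauchy(0,1) prior; the song-effect covariance via the Huang–Wand
(2013) hierarchical inverse-Wishart with nu = 2 and A = 1, whose margins
are Half-t(2,1) scales and uniform correlations — the closest fully
conjugate member of the weakly-informative family usually written as
half-Cauchy scales with an LKJ(2) correlation; and the AR(1) coefficient
by griddy Gibbs on a 199-point grid over (-0.99, 0.99) under a uniform
prior (its full conditional is cheap in closed form given three residual
sufficient statistics). Coefficient priors are Normal(0,1) on the
standardized scale. The default budget is 4 chains x 2500 warmup + 2500
kept draws; split R-hat and an initial-positive-sequence effective sample
size are computed per parameter, and any split R-hat above 1.01 raises a
convergence warning carrying the offending parameters.

Two caveats are worth stating plainly. First, varying slopes on
predictors that are constant within a song (valence, arousal) are only
weakly identified against the varying intercept; their variance
components mix slowly and routinely trigger the R-hat warning while all
reported population-level effects converge. This is a property of the
model, not the sampler. Second, with Normal(0,1) priors on every
coefficient of standardized predictors, the prior predictive standard
deviation of the response grows like the square root of the number of
terms (each term contributes about one unit of prior variance, and the
AR(1) stationary inflation adds more); the "order 1" scale check in the
test suite is therefore applied to the intercept-only scale kernel.

**PSIS-LOO.** Pointwise out-of-sample predictive densities are estimated
by Pareto-smoothed importance sampling: per observation, raw importance
ratios (inverse likelihood), a generalized-Pareto fit to the largest 20%
of ratios by the Zhang–Stephens posterior-mean estimator (shape
regularized towards 0.5 with prior weight 10), replacement of that tail
by expected order statistics, truncation at the largest raw weight, and
the weighted log predictive density. Observations with Pareto shape above
0.7 are flagged. The implementation is validated against exact
leave-one-out refits of a conjugate Gaussian mean model (n = 20, within
0.5 of the exact total). Model comparison reports ELPD differences
against the best model with the standard error of the pointwise
differences; stacking maximizes the log score of the weighted predictive
mixture over the simplex (softmax parameterization from the uniform
start, so exchangeable models keep equal weights; the objective is
concave in the weights and a constructed known-optimum instance is
recovered within 0.05).

## The synthetic-data generator

The generator defines the study conditions under which everything is
tested:

- **Corpora and stimuli.** Songs are drawn from a seeded first-order
  Markov chain over the chord vocabulary with Dirichlet-distributed
  sparse transition rows (concentration 0.1 per cell by default).
  Sparsity produces the left-skewed information-content profile
  characteristic of pop harmony (mostly predictable transitions, a few
  very surprising ones); raising the concentration provably flattens
  usage towards uniform. Stimulus sets default to 30 progressions of
  30–38 chords (2.4 s per chord), optionally constrained to an exact
  total chord count (1039 across 30 songs reproduces the emulated
  stimulus set, with 1009 rated chords per listener group after
  first-chord discard).
- **Raters.** Ratings are the generative mirror of the regression model:
  group-specific population slopes, song-level random effects shared
  across subjects, and an AR(1) residual chain per song x subject.
  Default effect sizes are information content 0.53 / 0.32 and tonal
  dissimilarity 0.19 / 0.17 (musicians / non-musicians), a -0.28
  musician intercept shift, arousal 0.18 and valence 0.03, AR(1)
  correlation 0.3 — the posterior means this analysis family reports,
  used as simulation inputs so that recovery tests run at realistic
  signal-to-noise. They are inputs, not reproduction claims.
- **Slider kinematics.** Latent ratings are rendered as 20 Hz step
  traces: start at 0 (slider reset), hold, jump to each chord's target
  after a 1 s reaction delay, affine map to 0–1023 with clipping,
  optional integer jitter. A physical movement model is unnecessary
  because the preprocessing uses only order statistics within windows;
  with zero jitter the pipeline round-trips the discretized latents
  exactly, which is tested.

What the generator does **not** emulate: higher-order or hierarchical
harmonic structure (the chain is first-order, so the PPM order blending
is exercised but long contexts carry no extra signal); audio, timbre and
loudness; listener idiosyncrasies beyond group membership (no per-subject
random effects, matching the group-averaged analysis); non-stationary
drifts in slider use. Passing tests therefore demonstrate correctness of
the machinery under the model's own assumptions, not behavioural validity
on real recordings.

## Problem sizes

The test suite and acceptance script run deliberately scaled instances:
PPM oracle equivalence on a 5-symbol, 30-event corpus; entropy-rate
convergence on ~10^4 events; recovery fits on ~2000-row datasets with 2
chains x 300–500 kept draws per replicate (8–12 replicates); model
comparison on ~650-row datasets. The full default budget (4 x 2500 +
2500) is used in the README example. These sizes are the package's chosen
trade-off between statistical resolution and a test suite that runs in
minutes.

## Known limitations

- The PP front end is idealized (see above); absolute tonal-dissimilarity
  values are not comparable to implementations operating on audio, only
  the within-pipeline contrasts are meaningful.
- The exact historical configuration of the PPM escape mechanism in the
  emulated analyses is not recoverable; method C is a documented,
  oracle-tested choice, and A/D are available for sensitivity analysis.
- ELPD magnitudes depend on the synthetic study conditions; orderings
  (additive over single-predictor models) are the robust, tested claim.
- The Gibbs sampler is exact but can mix slowly for weakly identified
  variance components; the diagnostics contract surfaces this rather than
  hiding it.
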