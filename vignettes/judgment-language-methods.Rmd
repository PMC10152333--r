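---
title: "Methods: detecting judgment language and estimating documentation disparities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting judgment language and estimating documentation disparities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`judgmentlang` implements a complete judgment-language analysis of
home-health visit notes: a synthetic corpus generator with ground truth, an
embedding-based lexicon-expansion workflow, a rule-based matcher with
attribution and negation exclusions, and the disparity statistics. This
vignette explains the models and the design choices; the README shows the
workflow itself. The package is organized as an analysis (numbered drivers
under `analysis/` over the functions in `R/`) because the deliverable is a
sequence of analyses over data rather than a standalone shell tool; the
driver scripts and `run_pipeline()` are the orchestration surface.

## The synthetic corpus as study conditions

Real home-health notes are not shareable, so every downstream stage is
developed and validated against a generator whose defaults *are* the study
conditions being emulated, not tuning knobs:

* **Cohort.** Race/ethnicity is drawn from
  (White, Black, Hispanic, Asian) = (0.44, 0.24, 0.23, 0.09); an "other"
  category is excluded as too small to analyze. Gender defaults to
  F/M = 0.6/0.4, the usual skew of home-health censuses.
* **Notes.** Counts per patient are 1-shifted Poisson with mean 6 (every
  admitted patient has at least one visit note; the exact distribution is
  unspecified in the emulated setting, and the shifted Poisson is the
  simplest count law with the right support). Texts are assembled from a
  bank of neutral telegraphic home-care sentences to a mean of ~298
  characters. The bank contains no judgment-lexicon surface form, so every
  judgment occurrence is planted with a known character span.
* **Positivity.** A note is positive with probability
  `plogis(qlogis(rate[race]) + u_clinician)`, with
  rates (0.095, 0.107, 0.108, 0.078) and `u ~ N(0, 0.5²)` over 200
  clinicians (assigned per note uniformly at random). Planting on the logit
  scale makes the clinician effect compose exactly with the race-specific
  rates, mirroring the mixed-logit analysis model. With `clinician_re_sd =
  0` the empirical rates converge to the planted ones; with heterogeneity
  the *marginal* rates sit slightly higher (Jensen effect), which is
  visible in the README example.
* **Judgment words.** Positive notes embed a 1-shifted Poisson number of
  judgment phrases (mean 1.14) in patient-subject framing ("pt claims …");
  misspellings ("claimes", "clai med") are used at rate 0.05. Negative
  notes carry a provider-attributed confounder ("cardiologist stated …") at
  rate 0.05.
* **Visit minutes** are `70 − 21 × words + N(0, 10²)`, floored at 5
  minutes. The mean of 1.14 words per positive note reconciles three
  quantities: a 70-minute baseline, a 21-minute per-word decrement, and a
  ~46-minute mean positive visit (70 − 21×1.14 ≈ 46), hence a ~24-minute
  mean gap. The 10-minute noise SD keeps the 5-minute floor active on
  fewer than 0.1% of notes, so the OLS slope is effectively unbiased.

What the generator does **not** emulate: real lexical diversity (the
sentence bank is small, so embedding vocabularies are far smaller than a
real corpus'), topic/severity confounding between race and visit length,
within-patient correlation beyond the shared race, documentation-time vs
encounter-time distinctions, and longitudinal episode structure. Passing
tests therefore demonstrate that the *pipeline machinery* is correct and
well-calibrated under the stated conditions — not that the matcher would
achieve the same sensitivity on real EHR text.

## Lexicon expansion

The seed vocabulary is `adamant, apparently, claims, insists, states`.
"states" is kept despite its routineness (it is part of the emulated
protocol and its limitation is discussed there); `expand_lexicon()` takes
an arbitrary seed vector, so sensitivity analyses can simply drop it.

Embeddings are trained by window co-occurrence (window 5) → positive PMI →
truncated SVD (dimension 100, `min_count` 5), the count-based member of the
word2vec family. We chose this factorization over stochastic-gradient
skip-gram because it is exactly deterministic — identical corpora give
identical vectors (singular-vector signs are pinned to the
largest-magnitude loading), which strengthens the package's reproducibility
contracts — and because at the vocabulary sizes of template-generated
corpora it is both faster and more stable than SGNS with few epochs. The
hyperparameters `epochs` and `seed` are accepted and recorded for
interface compatibility. Cosine similarities are rounded to 10 decimals
before ranking so that ties (and float noise under rescaling) break
lexicographically.

Candidate review is file-driven rather than interactive: a decisions table
(`candidate, canonical, decision`) is applied by `expand_lexicon()`;
`merge_decisions()` unions two reviewers' tables and *flags* contradictions
for adjudication instead of resolving them silently. A candidate accepted
under two canonicals is an error, keeping surface-form sets pairwise
disjoint. Split-token misspellings ("clai med") are stored as bigram
surface forms and matched at the token-sequence level. No similarity
cutoff or fixed k is baked in; they are arguments to `query_neighbors()`.

## Matching and exclusion rules

Tokenization lowercases, strips punctuation, and keeps dotted clinical
abbreviations ("d.m.") as single tokens; sentence boundaries are inferred
from inter-token punctuation, so an abbreviation's own periods never split
a sentence.

Candidate matches are token-level (word boundaries for free), then two
exclusion rules apply, both restricted to the match's sentence and to a
window of `W = 5` tokens before the match:

* **Provider attribution**: excluded when a provider cue (vn, rn, md, pcp,
  cardiologist, "primary care", …) is the nearest preceding subject cue and
  no patient/family cue (pt, patient, husband, he, she, …) is nearer —
  nearest-cue-wins. The emulated protocol states the exclusion goal but not
  its mechanism; the windowed nearest-cue heuristic was chosen for
  transparency and testability, and `W` and both cue lists are
  configurable because the original inventories are unpublished.
* **Negation**: excluded when a negation cue (no, not, never, without)
  precedes within the window — a cue-and-scope rule in the NegEx style.
  The rule targets negation of the judgment *term itself* ("was not
  adamant"), not patient denial of clinical content: "pt vehemently denies
  this" keeps "vehemently". "denies" is deliberately not a default
  negation cue for the same reason.

A note is positive iff it has at least one retained match;
`n_judgment_words` counts retained *occurrences* (not distinct terms),
because the visit-time regression is per judgment word. Excluded-only notes
are negative. Degenerate inputs are defined: empty text is a negative
result; an empty lexicon fails at compile time; duplicate surface forms
across canonicals fail at lexicon construction.

## Disparity statistics

* **Contingency** (`build_contingency()`): per-group note counts,
  percentage positive, and relative change
  `100·(p_g − p_ref)/p_ref` against the White reference. Report rounding
  matches the conventional presentation (percentages 1 dp, relative change
  0 dp, odds ratios 2 dp).
* **Chi-square**: Pearson test without continuity correction on the
  groups × {positive, negative} table; zero expected counts error with
  advice to collapse.
* **Fixed logistic** (`fit_logistic()`): `glm` IRLS with tightened
  tolerance (`epsilon 1e-10`); Wald 95% CIs on odds ratios (profile
  likelihood is unnecessary at these cell sizes). Separation and aliasing
  are explicit errors, not silent results.
* **Mixed logistic** (`fit_mixed_logistic()`): a clinician random intercept
  integrated out by *adaptive* Gauss–Hermite quadrature — nodes are
  centered at each cluster's conditional mode and scaled by the curvature
  there — and maximized over `(β, log σ)` with L-BFGS-B. The implementation
  is in-package because the analysis contract pins the quadrature order (up
  to 41, above what common mixed-model fitters expose); it is cross-checked
  against `lme4::glmer` in the test suite, where both agree to ~1e-4 in
  log-likelihood and ~1e-3 in parameters. Data are first aggregated to
  binomial counts per unique (clinician, design row), which makes each
  likelihood evaluation cheap even at 10⁵ notes. `log σ` is bounded in
  `[−8, 3]`; an estimate at the lower bound is reported as an SD pinned at
  the zero boundary rather than an error. The default order 15 is odd (so a
  node sits at the mode) and well past the point where the likelihood is
  stable to 1e-4 in this model family.
* **Model comparison** (`compare_models()`): LRT with the boundary-corrected
  null `0.5·χ²₀ + 0.5·χ²₁` for a single variance component, and the
  relative log-likelihood change `100·(ll_mixed − ll_fixed)/|ll_mixed|`,
  reported as the size of the drop incurred by removing the random effect.
  A mixed likelihood below the fixed one (beyond 1e-6) is treated as an
  optimizer failure.
* **Visit time**: OLS of visit minutes on judgment-word count adjusted for
  race and gender; the headline quantity is the *decrement* (minus the
  word-count coefficient). `group_mean_difference()` reports the raw
  negative-minus-positive mean gap.

The unit of analysis is the note; within-patient correlation is not
modeled beyond the clinician random effect. This mirrors the emulated
analysis and is a known simplification — patient-level clustering would
narrow nothing here because the generator draws notes independently within
patient, but on real data the fixed-model CIs would be anticonservative.

## Problem sizes and determinism

The test suite exercises the generator at up to 30,000 patients (~180,000
notes) for rate recovery with `clinician_re_sd = 0` and 10,000 patients
(~60,000 notes) for visit-time and mixed-model recovery; these sizes give
Monte-Carlo standard errors comfortably inside the asserted tolerances
(±0.5 pp on rates, ±1 min on the 21-minute decrement, ±1.5 min on the
24-minute gap, ±20% on the clinician SD). Every stochastic path is seeded:
corpora are byte-identical given a `corpus_config`, the embedding is
deterministic outright, the fits have no hidden randomness, and
`run_pipeline()` fans a single global seed into per-stage child seeds via a
counter scheme (`stage_seed()`) so stages can be re-run independently. The
pipeline manifest records the config hash, seed, and package version needed
to reproduce a run.

## Known limitations

* Frequency-based matching cannot read context; "states" especially often
  introduces a neutral symptom report, so real-data positive rates are
  upper bounds on intent. Contextual (transformer) detection is out of
  scope by design.
* Quotation-mark "judgment" (the patient had a "reaction") is not
  implemented; the emulated protocol dropped the category because quotes
  are rare in home-health notes.
* The attribution and negation cue inventories are configurable defaults,
  not a validated clinical resource.
* The generator's marginal-vs-conditional rate gap under clinician
  heterogeneity is a modeling fact, not a bug; analyses comparing to the
  planted rates must either set `clinician_re_sd = 0` or compare on the
  conditional scale.
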