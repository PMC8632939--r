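---
title: "Methods: paired emotion change and language shift in two-wave cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired emotion change and language shift in two-wave cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emoshift)
```

emoshift analyses repeated-measures emotion surveys: the same participants
rate nine emotions (1–9 Likert) and write free text at two collection
waves, and the questions of interest are (a) how the emotion ratings
changed, (b) whether the change is homogeneous or falls into subgroups,
and (c) how the accompanying language shifted. This vignette documents the
statistical models, the tunable parameters, the synthetic data the tests
rely on, and the numerical and design choices.

## Cohort cleaning and pairing

Each wave is screened by four sequential rules — non-English text,
punctuation share above 20%, invalid participant id, duplicated id — and
each excluded record is tagged with the *first* rule it violates, so the
rule counts always partition the exclusions
(`initial = retained + sum(counts)`). Choices the data format leaves open:

* **Punctuation share** is punctuation characters (the fixed 32-character
  ASCII set) over *non-whitespace* characters. A whitespace denominator
  would make the filter sensitive to formatting rather than content.
* **English detection** has no canonical rule, so it is a pluggable
  predicate. The default is deterministic and dependency-free: a text of
  at least 20 tokens is English when at least 5% of its tokens appear in
  the packaged 175-entry English stopword snapshot. Function words are the
  most reliable language signal in informal writing; shorter texts carry
  too little evidence and pass. Fixtures can override per record via an
  `english_override` column.
* **Valid id** defaults to the 24-hexadecimal-character format of the
  common crowdsourcing platform and is a configurable pattern.
* **Duplicates** keep the first occurrence in file order; which copy a
  study keeps is rarely stated, and first-in-file is reproducible.

Pairing keeps exactly the participants with complete emotion scores in
both waves (records with missing scores are dropped with a warning, never
silently) and computes per-emotion change scores Δ = score₂ − score₁
∈ [−8, 8]. The sign convention is change *towards* wave 2: positive means
the emotion rose. Demographics are taken from the wave-2 record.
Implausible ages (above a configurable bound, default 110) stay in the
cohort but are excluded from age statistics only.

## The paired change battery

For each emotion with paired differences `x`:

* Cohen's d (paired form) is |mean(x)| / sd(x), reported as a magnitude;
  the signed mean difference is carried separately. The confidence
  interval (default level 0.99) uses the large-sample normal
  approximation SE(d) = √(1/n + d²/(2n)). With n in the hundreds or
  thousands this is indistinguishable from noncentral-t constructions;
  second-decimal differences from other software are expected and
  documented.
* The t test is the ordinary one-sample t on the differences, two-sided.
* The phase-1/phase-2 Pearson r gets a Fisher-z interval.
* The JZS Bayes factor places a Cauchy(0, √2/2) prior on the
  standardized effect — the conventional "medium" default, symmetric
  about zero to match the two-sided alternative — and integrates the
  t likelihood over it.

### Bayes factor numerics

BF₁₀ is evaluated through the one-dimensional g-representation of the
Cauchy prior (normal slab with inverse-gamma(1/2, r²/2) mixing variance):

```
m1 = ∫ (1 + N g)^(-1/2) (1 + t²/((1+N g)ν))^(-(ν+1)/2) π(g) dg,
BF10 = m1 / (1 + t²/ν)^(-(ν+1)/2)
```

with N the effective sample size (n for the paired design,
n₁n₂/(n₁+n₂) with ν = n₁+n₂−2 for two groups). The integrand is evaluated
in log space; its mode is located on a wide log-spaced grid (10⁻¹² to
10¹²), the integrand is rescaled by the mode, and adaptive quadrature
(`stats::integrate`, rel.tol 1e-10) finishes. Everything downstream uses
`log10_bf10`, which remains finite and accurate where BF₁₀ itself
overflows (a paired t near 35 at n ≈ 1700 gives BF₁₀ ≈ 10²⁰⁰). The test
suite pins both designs against an independent oracle — a fine midpoint
rule over the noncentral-t marginal on the Cauchy quantile scale — to a
relative error of 1e-6.

## Subgroup discovery on change vectors

Change vectors are clustered **raw**: all nine coordinates live on the
same Likert-difference scale, so standardisation would only distort the
geometry. k-means uses Lloyd iterations with k-means++ seeding, the best
of 25 restarts (cap 300 iterations), an empty-cluster rescue that
re-seeds a dying center from the point farthest from its assigned center,
and full determinism under a seed.

The selection sweep fits k = 1…20. The operative selector is the largest
mean silhouette over k ≥ 2 (ties towards smaller k); the elbow — the k
with maximum second difference of the WCSS curve — is reported alongside
as corroboration. Each k ≥ 2 additionally warm-starts from the best
(k−1)-model plus its farthest point, which guarantees the WCSS curve
never increases with k. Silhouette cannot score k = 1, so a
`low_structure` flag (best silhouette < 0.2) guards the no-cluster case:
an isotropic Gaussian in nine dimensions stays well under that bound
while genuinely clustered change data sit above it.

Cluster profiles report per-emotion mean change with a deviation-from-zero
t test at α = 0.01, cluster prevalences, mean age on the plausible-age
subset, and % female among gender-reporting members (the denominator a
published table might use is ambiguous; gender-reporters is the
documented choice here). Two-cluster demographic comparisons use the
pooled-SD d for age and a continuity-corrected 2×2 χ² for gender — the
conventional default of the surrounding ecosystem, with a switch to
disable the correction.

## Text analyses

**Tokens** are maximal lower-cased alphanumeric runs with internal
apostrophes kept (`don't`); **sentences** are maximal segments terminated
by `.`, `!` or `?`, a trailing unterminated segment counting as one.
External tokenisers differ in detail, so corpus descriptives (token and
sentence counts, type-token ratio) are exact on fixtures and approximate
against other toolchains.

**Dictionary scoring** consumes any category dictionary in the de-facto
`.dic` layout (`%`-delimited header of category ids, then one pattern per
line with tab-separated ids) or an equivalent JSON object. Patterns are
literal tokens or prefix wildcards (`fear*`, matching the exact form
too). A category's score in a document is the percentage of tokens
matching it — the output convention of the established dictionary
scorers. The widely used 2015 psycholinguistic dictionary is proprietary
and is **not** shipped; the package includes an open 8-category,
~120-pattern demonstration dictionary for tests and examples, and
published category tables are not reproduction targets. Category shifts
are ranked by the Bayes factor of the paired score differences, without
multiplicity correction — the scan is explicitly exploratory.

**n-gram differentiation.** The joint corpus of both waves is lower-cased,
tokenized, stopword-filtered (packaged Snowball-style list, swappable) and
stemmed. The stemmer is the classic Porter suffix-stripping algorithm
with the English-stemmer refinements relevant to this corpus: `-us`/`-ss`
endings are left alone (`serious`, `virus`), a bare `-s` drops only when
a vowel precedes its preceding letter, and y→i applies only after a
consonant that is not the word's first letter (`stay` survives, `worry` →
`worri`), plus the standard small invariant list (`news`, `sky`, …).
n-grams of orders 1–3 are formed over the *surviving* token sequence —
post-removal adjacency, so "we are staying at home" yields `stay_home` —
without sentence-boundary blocking, and only n-grams with document
frequency ≥ 5% of the joint corpus are retained (one joint threshold
across orders). Frequencies are raw per-document counts; documents of
similar length make per-token normalisation immaterial, and a
relative-frequency mode is a config switch away.

Count data of this kind make the Wilcoxon signed-rank test tie-heavy, so
ties are broken at random: per iteration, zero differences are dropped
(the classical handling — and the only one consistent with r = ±1 for a
term absent in one wave), tied |Δ| blocks receive a random permutation of
the ranks the block occupies, and the matched-pairs rank-biserial
correlation r = (W⁺ − W⁻)/(W⁺ + W⁻) ∈ [−1, 1] is computed, with r > 0
meaning higher counts in wave 2. The reported statistic is the mean over
500 seeded iterations and its across-iteration SD (labelled "SE" in
shift tables, following the convention of reporting the spread of the
randomised statistic rather than a standard error of that mean — spreads
of 0.02–0.04 at 500 iterations are only compatible with the SD reading).
The rank-biserial form is used, rather than Z/√n, because the latter is
bounded near 0.87 and cannot express the near-±1 values that
wave-exclusive terms produce; the Z/√n variant remains available. The
expected rank of each member of a tied block equals its midrank, so the
randomisation is unbiased; the suite verifies this, the [−1, 1] bounds,
exact antisymmetry under wave swap, agreement with a brute-force
rank-biserial oracle in the tie-free case, and a centred null under
exchangeable pairings.

**Term-mention split.** Participants are split by whether any token of
their wave-2 text stems to the target prefix (default `vaccin`, so
`vaccine`, `vaccinated`, `vaccination` count but `vacation` — stem
`vacat` — does not; stemmed matching is the default, surface-prefix
matching a switch). Per emotion, the change scores of the two groups are
compared with the pooled-SD d and the two-sample JZS Bayes factor.

## The synthetic cohort generator

The generator exists so every stage is testable end to end. Its defaults
are the study conditions of the motivating design:

* Two latent change-clusters — a *well-coping* pattern (negative emotions
  down, positive emotions up) at proportion 0.4358 and a *resignation*
  pattern (anger, disgust, sadness, desire up; fear, worry, happiness,
  relaxation down) at 0.5642, with per-emotion change SDs around 2.1.
  Their mean-change vectors sit ≈ 7.3 apart in the nine-dimensional
  change space.
* Phase-1 score means 2.9–6.6 with SDs 1.8–2.3 per emotion.
* Long texts of 125 ± 32 tokens (short: 25 ± 15), sentences of mean
  length 22, drawn bag-of-tokens from a phase-specific vocabulary:
  function words (≈ 45% of mass, so the texts read as English to the
  stopword heuristic), neutral fillers, emotion words aligned with the
  demonstration dictionary, terms whose rates fall in wave 2 (worry,
  staying, home, news, …) and terms that rise, including a `vaccin`-stem
  family with rate exactly 0 in wave 1 and a wave-2 rate chosen so that
  about 60% of wave-2 long texts mention it — the mention/no-mention
  split the term-split analysis expects.

Scores are generated additively: phase-1 scores are round-then-clip
normals; the change is drawn from the participant's cluster; phase 2 is
`clip(round(phase1 + change), 1, 9)`. Consequences worth knowing:

* The wave-1/wave-2 correlation is *emergent*, approximately
  SD₁/√(SD₁² + SD_Δ²) (plus 1/12 rounding variance in each term), not a
  targeted parameter. With the default phase-1 SDs this lands near
  0.55–0.70 — higher than the 0.34–0.50 real cohorts show, because the
  additive model cannot match the published phase SDs, change SDs and
  correlations simultaneously. Tests predict r from the formula rather
  than from published correlations.
* Round-then-clip discretisation is simple and mean-preserving away from
  the scale boundary; recovery tests therefore use interior
  configurations (phase-1 means near the scale centre, moderate change
  SDs) where clipping is negligible. Clipping also costs cluster
  separation: label recovery at the default separations averages ARI
  ≈ 0.85 on the continuous change vectors and ≈ 0.05 less after
  discretisation.
* One master seed is split (via a seeded `sample.int`) into per-stage
  substreams — cluster assignment, phase-1 scores, changes, demographics,
  texts — so regenerating texts never disturbs scores, and identical
  config + seed reproduces the cohort byte for byte.
* The token model is bag-of-tokens with sequential emission: no grammar,
  topics or realistic content, but exactly the document-frequency and
  adjacency structure the downstream statistics consume (a term with
  per-token rate p appears in a length-L document with probability
  1 − (1−p)^L; bigrams arise from sequential draws). Passing tests
  therefore demonstrate correctness of the statistics, not performance
  on real prose.

## Problem sizes and runtime choices

The suite runs parameter recovery at n = 2000–20000 where a mean is being
checked against a planted value, label recovery over 20 seeds at
n = 1000, the k sweep at n = 1000 with 25 restarts, exchangeable-null
Wilcoxon checks over 200 replicates of n = 200 with 50–100 iterations,
and null calibration of the α = 0.01 test over 1000 replicates — sizes at
which the Monte-Carlo bands (3 SE) are tight enough to be informative
while the whole suite stays around a minute. The acceptance script uses
the full default conditions: n = 1000, k = 1…20, 25 restarts.

## Known limitations

* The exclusion rules' English predicate is a heuristic; it is meant for
  fixtures and clearly English/non-English corpora, not borderline
  multilingual text.
* The d confidence intervals are normal approximations; at n below ~50
  a noncentral-t construction would be preferable.
* The stemmer implements the classic Porter algorithm with the English
  refinements noted above; it is not a full implementation of the later
  two-stage English stemmer (no special-form lists beyond the invariant
  words).
* Topic modelling and supervised prediction of cluster membership are out
  of scope; the package covers the paired battery, clustering, dictionary
  and n-gram analyses.
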