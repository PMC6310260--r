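---
title: "Distributional bootstrapping of lexical categories: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distributional bootstrapping of lexical categories: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Children group words into lexical categories (nouns, verbs, ...) long before
anyone teaches them grammar. The *distributional bootstrapping* hypothesis
holds that the local co-occurrence patterns of words — what tends to appear
immediately before and after them — carry enough signal to support this
grouping. `distboot` implements a complete item-level test of that
hypothesis: it builds longitudinal word–context co-occurrence models from
tagged child-directed-speech corpora, categorizes every word by its nearest
distributional neighbour without ever using the tags for learning, and then
asks *which distributional properties of a word* (frequency, contextual
diversity, predictability, context usefulness) make it easier or harder to
categorize.

## Pipeline and model

**Input.** One or more PoS-tagged corpora of adult utterances, each in
chronological order. Fine annotation tags are mapped to five coarse
categories used for evaluation only: `N` (nouns, including pronouns), `V`
(verbs, including auxiliaries and non-finite forms), `ADJ`, `ADV`, and
`FUNCT`, a residual bucket that collapses everything else. The shipped
default table covers the common MOR-style tags and sends unknown tags to
`FUNCT`; this residual-bucket choice is configurable (`strict_tags`) because
no published inventory pins down every minor category. Homographs —
wordforms carrying more than one fine tag — are kept distinct throughout
(`lead-1`, `lead-2`, ...), both as targets and inside context strings, since
transcription conventions, not the child's input, decide which homophones
are spelled alike. No lemmatization is performed and wordforms are
lower-cased.

**Contexts.** For each token, up to five lexically specific contexts are
recorded: the preceding and following bigram (`w-1_X`, `X_w+1`), the two
trigrams (`w-2_w-1_X`, `X_w+1_w+2`), and the surrounding frame
(`w-1_X_w+1`). Utterance boundaries are real distributional events: exactly
one `#start` and one `#end` symbol flank each utterance and fill the slot
immediately outside it. A template that needs a slot *beyond* a boundary
symbol is simply skipped rather than padded with a second dummy — a
single-token utterance therefore contributes three contexts, not five. This
skip rule is our documented edge convention; padding further dummies would
manufacture contexts no listener hears.

**Longitudinal design.** Word–context counts are accumulated over cumulative
prefixes covering 40%, 50%, ..., 100% of each corpus's utterances — seven
time points, indexed 0–6. Prefix sizes are `max(1, floor(fraction * N))`;
the floor-with-clamp rule is deterministic and safe for tiny corpora, and
the last slice always covers the whole corpus. Starting at 40% ensures the
first categorization already rests on a substantial sample.

**Categorization.** At every time point, every word seen so far is reduced
to its co-occurrence vector and categorized by its single nearest neighbour
(leave-one-out, so a word can never retrieve itself). Two distances are
implemented:

* *cosine*: `1 − A·B / (‖A‖‖B‖)` — scale-invariant, driven by the
  co-occurrence *pattern*;
* *numeric overlap*: `Σ_i |A_i − B_i| / (max(i) − min(i))` — each
  element-wise difference scaled by the value range of its column over all
  word rows of the current matrix, so it is sensitive to absolute frequency
  differences. A column whose range is zero contributes 0 by definition.
  Ranges are recomputed per slice, because the scaling is defined over the
  rows of the *current* matrix.

Ties are resolved by a fixed cascade: all rows within a relative tolerance
of the minimum distance count as tied (`|d1 − d2| ≤ tol · max(d1, d2, ε)`,
default `tol = 1e-9`; exact floating-point equality would make the tie set
ill-defined); among ties the most frequent word wins, frequency being the
token count in the current prefix — the only frequency a learner could know
at that point; remaining ties are broken uniformly at random from a single
seeded RNG consumed in row order, which makes whole runs bit-reproducible.
A *hit* is recorded when the neighbour's coarse tag matches the target's;
the tags play no role in choosing the neighbour (permuting them changes hit
flags but never neighbours, and the test suite asserts exactly that).

**Predictors.** Per word, corpus, and time point:

* log frequency and log contextual diversity (number of distinct
  co-occurring contexts). Natural logs; the base only rescales regression
  coefficients.
* average conditional probability of the word given its contexts: mean over
  the word's contexts of `count(word, context) / frequency(context)` — the
  operationalization of predictability, in `(0, 1]`.
* median information gain (IG) of the word's contexts. IG of a context is
  the reduction in entropy of the coarse-tag distribution from conditioning
  on co-occurrence with that context,
  `IG(c) = H(Y) − P(c)H(Y|c) − P(¬c)H(Y|¬c)`, with natural-log entropies.
  Each co-occurrence event counts as one observation (token weighting);
  type weighting — each word–context pairing counted once — is available as
  a config switch (`ig_weighting = "type"`), since either convention is
  defensible for count data and the choice is not empirically settled. The
  median over a word's contexts (midpoint convention for even counts) is
  used because context IG distributions are strongly skewed.

**Statistics.** Item-level accuracy (hit/miss) is modelled with logistic
mixed-effects regressions (`lme4::glmer`):
`hit ~ time + predictors + (1 | corpus) + (1 + time | word)`. The by-word
random slope over time absorbs the autocorrelation between outcomes for the
same word at successive time points; the random structure is fixed rather
than re-searched. Time enters as a numeric 0–6 term and predictors enter
unstandardized on their stated scales. The analysis table is restricted to
words occurring in *all* sub-corpora and already present in each corpus's
50% prefix, and frequency-1 observations are dropped (a single occurrence
fully determines diversity, creating a perfect predictor correlation).
Model building follows AIC: each predictor is first evaluated alone over
the time-only baseline, then a full model is grown forward, adding the
best-improving predictor until none reduces the AIC or a fit stops
converging. Convergence problems are carried in the result object, never
silently ignored; a constant response (complete separation) is reported as
a non-converged result rather than an error. Variance explained is reported
as marginal and conditional r² on the logit scale (distribution-specific
variance π²/3), with the random-effect variance averaged over observations
via `diag(ZΛΛ'Z')` so that random slopes are handled correctly. The error
analysis cross-tabulates correct against predicted tags and flags cells by
standardized Pearson residuals at |r| > 1.96, the conventional mosaic-plot
shading, without multiplicity correction.

## The synthetic generator

Real child-directed corpora cannot be redistributed with the package, so
`generate_study()` provides a synthetic stand-in that preserves the input
properties the pipeline is sensitive to:

* multiple chronologically ordered sub-corpora (default 13, ~3,000 short
  utterances each) sharing a core vocabulary plus per-corpus idiosyncratic
  words, so the occurs-in-all-corpora filter has real work to do;
* short utterances built from function-word *carriers* followed by open
  slots (geometric number of carrier–filler pairs, mean length ≈ 5), giving
  the informative utterance boundaries and local frames the context scheme
  presupposes;
* Zipfian word frequencies within each class (`zipf_exponent`, default 1);
* category-selective contexts: each carrier prefers one tag and its slot is
  filled from that tag with probability `selectivity` (default 0.75),
  otherwise from a uniformly chosen other class. Selectivity is the
  category-signal dial: at 1.0 every carrier is perfectly diagnostic, and
  hit rates rise monotonically with it;
* homographs: a fraction of wordforms (default 5%) carries both a noun and
  a verb fine tag;
* collocational structure: each content word has a quasi-random (against
  frequency rank) probability, up to `formulaicity` (default 0.6), of being
  emitted inside a fixed two-word collocation with a same-class companion.
  Formulaic occurrences concentrate a word's mass in word-specific
  contexts: its conditional probability given those contexts rises toward
  1 and its per-token contextual diversity falls. This is the
  predictability dial, and it emulates a real property of child-directed
  speech — stock phrases and collocations — without which all predictors
  would collapse onto a single frequency dimension and the predictability
  effect would have no variance to show up in.

What the generator deliberately does **not** model: English syntax or
morphology, discourse coherence, semantic structure, or the vocabulary
statistics of any particular corpus. Passing tests on synthetic data
therefore show that the *pipeline* measures what it claims to measure (and
that the signs of the diversity and predictability effects are recoverable
when the generating process contains them); they do not certify effect
magnitudes on real corpora, whose coefficients depend on properties this
generator does not reproduce.

## Numerical and design choices

* Prefix sizes, row/column orderings, homograph sense indices, and RNG
  consumption order are all deterministic, so a run is a pure function of
  (input corpora, seed).
* Distance ties use a relative tolerance (`1e-9`) rather than exact
  equality; the cosine kernel clips tiny negative rounding residues to 0.
* The numeric-overlap range convention: per-column max and min are taken
  over *all* word rows of the current matrix, zeros included (a column is
  only range-0 when every row agrees on it). With counts being
  non-negative, the pairwise scaled-L1 kernel uses
  `|a − b| = a + b − 2·min(a, b)` over the sparse columns, which makes the
  cost proportional to the squared nonzeros per column instead of
  `rows² × columns`.
* Mixed models default to the Laplace approximation (`nAGQ = 1`); the
  repeated-seed robustness checks and the analysis drivers use `nAGQ = 0`,
  which is substantially faster and adequate for sign-level conclusions.
* Problem sizes in the shipped tests: the reference study (13 × 3,000
  utterances) for the predictor-invariant and sign-recovery checks (ten
  seeds for the latter), 20 random matrices up to 50 × 200 for the
  brute-force oracle equivalence, 10,000 seeded replicates for the
  tie-break sampling law, and a planted-coefficient simulation of ~6,700
  rows for mixed-model recovery.

## Known limitations

* The fine-to-coarse tag table ships with a pragmatic residual rule
  (everything unlisted is `FUNCT`); corpora with exotic tag inventories
  should supply overrides via `tag_mapping`.
* Numeric overlap degrades as corpora grow — absolute count differences
  swamp the pattern — and the analysis drivers show it failing to benefit
  from time. That behaviour is a finding about the metric, not a bug; the
  cosine configuration is the reference one.
* Interactions and non-linear predictor effects are out of scope, as is
  any collinearity correction beyond comparing single-predictor and full
  models: frequency and diversity are nearly collinear by construction,
  and the full-model coefficients of that pair should be read with that
  in mind.
* The generator's formulaicity mechanism induces predictability variation
  by collocation only; real speech has other sources (routines, discourse
  repetition) with possibly different signatures.

## Reproducing the numbers

`scripts/acceptance.R --seed 1 --out results/acceptance.json` recomputes
the desk-scale reference quantities (the cosine worked example and the two
range-scaling illustrations) from the installed package. The numbered
drivers under `analysis/` regenerate the full synthetic study and all
tables under `results/`; `tests/testthat/` contains the complete oracle,
invariant, and sign-recovery suite.
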