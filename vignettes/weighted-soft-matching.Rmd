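---
title: "Weighted soft matching: scoring fragmented span extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted soft matching: scoring fragmented span extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spanscore)
library(dplyr)
```

## The problem

Clinical concept recognition increasingly targets not just short disease
names but long, clause-like expressions ("progressive dyspnea on exertion
over three weeks despite diuretics"). Exact-match span evaluation treats a
prediction that captures 95% of such an expression as a total failure;
plain character-level F1 goes to the other extreme and cannot tell one
clean extraction from five scattered shreds covering the same characters.
And token-level metrics are not comparable across systems at all, because
every model brings its own tokenizer.

`spanscore` evaluates span extraction on *character offsets* (Unicode code
points, 0-based, half-open), which makes it tokenizer-agnostic, and scores
partial matches with an explicit, tunable *fragmentation penalty*.

## The score

For one gold entity of length $l$ characters, extracted as $m$ fragments
of lengths $a_1,\dots,a_m$ (the non-empty intersections of the predicted
spans with the entity), the entity score is the $\ell^p$-norm of the
coverage ratios:

$$ s_p \;=\; \left( \sum_{i=1}^{m} \left(\frac{a_i}{l}\right)^{p} \right)^{1/p},
\qquad p \ge 1 . $$

Properties that make this the right shape for the task:

* $p = 1$: $s_1 = \sum a_i / l$, plain character coverage — fragmentation
  is free.
* $p \to \infty$: $s_\infty = \max_i a_i / l$, the longest-fragment ratio —
  only the best single piece counts.
* $m = 1$: $s_p = a_1/l$ for every $p$; the penalty only ever acts on
  *splits*.
* $s_p$ is non-increasing in $p$, and splitting any fragment strictly
  lowers $s_p$ for $p > 1$.

```{r entity}
entity_soft_score(10, c(5, 5), p = c(1, 1.5, 2, 100, Inf))
```

### Corpus aggregation

Two aggregation rules turn entity scores into precision/recall/F1. Both
count no true negatives — characters outside every gold and predicted span
play no role, so a generative system that mangles unannotated text is
neither rewarded nor punished for it there (text fidelity is audited
separately, below).

**Weighted soft matching** (the headline metric) weights each entity by its
length: soft TP mass $= \sum_e l_e\, s_e(p)$, FN mass $= \sum_e l_e -$ TP,
and FP mass $=$ the number of predicted characters outside every gold
entity. Recall $=$ TP/(TP+FN), precision $=$ TP/(TP+FP). Long, hard targets
therefore dominate — extracting a 20-character expression matters ten times
as much as a 2-character abbreviation.

**Marker matching** counts every entity as 1 regardless of length
(TP $= \sum_e s_e(p)$, one FP per predicted span fully disjoint from the
gold). Frequent short terms can make this average look much better than
the weighted one; reporting both exposes exactly that contrast.

At $p = 1$ the weighted rule is *identical* to per-character binary
classification — the package asserts this as an exact mass identity, not an
approximation (see "Numerical choices").

### Which precision?

Recall-side masses follow directly from the definition; the precision side
of a *penalized* score is genuinely underdetermined: should a predicted
character outside the gold count 1 regardless of $p$, or should predicted
spans be penalized for being split across gold entities? We default to the
first (`precision_rule = "mass"`): FP mass is the raw out-of-gold character
count, closest to a plain TP/FP/FN accounting and independent of $p$. The
role-swapped alternative (`"symmetric"`) scores each predicted span by its
gold-covered fragments with the same Hölder formula, length-weighted by
predicted length. Both coincide at $p = 1$, which the tests verify.

### Fragment identity

`m` counts *markers* — distinct extractions. Two predicted spans that touch
without overlapping therefore stay separate fragments (default
`semantics = "marker"`). For token-classification output only the character
mask is meaningful, so `semantics = "mask"` merges contiguous fragments
instead. Overlapping predicted spans are always merged first; adjacency is
preserved.

## Labeling scheme and generated text

The same annotations have three interchangeable representations, used by
different model families:

* character-offset spans (the canonical form, JSONL);
* binary character labels (`"0110..."`) for sequence labeling;
* inline `@@`…`##` marker text for instruction-tuned generation.

`spans_to_marked_text()` / `parse_marked_text()` convert losslessly; marker
literals occurring in the text itself are backslash-escaped. Gold files are
always parsed strictly (unbalanced or nested markers are errors); model
output is parsed leniently by default — unmatched or empty markers are
dropped and logged, never fatal.

Generative models occasionally fail to reproduce the input verbatim. For
the minority of non-exact reproductions, `align_generated_to_source()`
computes a global unit-cost Levenshtein alignment (via `utils::adist` edit
traces) and `project_spans_to_source()` maps each marked character through
it, taking the covering interval of the images. Where several minimal
alignments exist the DP's deterministic choice is used; for the
few-character drifts this path exists to handle, the projected interval is
insensitive to that choice. Documents that cannot be aligned at all score
zero credit rather than being dropped — dropping would silently inflate
precision.

`fidelity_audit()` quantifies reproduction quality directly: exact-match
rate over documents, and — over mismatches only — mean Ratcliff–Obershelp
similarity, mean Levenshtein distance, and mean signed length difference
(generated − source, so shorter outputs give a negative mean). The raw
Ratcliff–Obershelp recursion can depend on argument order when longest
blocks tie; we symmetrize by averaging the matched-character count over
both orders, trading faithfulness to any one library for determinism.

## Length stratification and folds

`stratified_scores()` re-scores within entity-length bins (defaults 1–2,
3–6, 7–10, 11–20, ≥21 characters), since short- and long-entity behavior
of a system routinely diverge. Recall masses restrict naturally to each
bin; precision has no canonical stratification, so each predicted span is
assigned to the bin of the gold entity with which it shares the most
characters, and spans touching no gold entity form a separate `"spurious"`
stratum — a documented reconstruction, chosen so that per-bin masses sum
exactly to the unstratified ones (tested as a conservation law). Empty
bins report `NA`, never a misleading 0.

`aggregate_folds()` implements the cross-validation reporting convention
`mean(SD)` with the sample (n−1) standard deviation, e.g. `0.758(0.002)`.

## The synthetic generator

Real clinical corpora cannot ship with an evaluation package, so every
component is exercised on synthetic data whose *offset statistics* mimic
the real task. `generate_corpus()` builds documents as alternating
unannotated gaps and gold entities, so validity holds by construction:

* entity lengths: drawn per bin with proportions 0.09 / 0.35 / 0.25 /
  0.21 / 0.10 over the five bins — 1–2-character entities are a ~9%
  minority, as in clinical concept annotation, with the remainder spread
  over the longer bins (the within-bin split is our choice; ≥21 draws
  uniformly from 21–35);
* entities per document: $1 + \mathrm{Poisson}(\lambda - 1)$ with
  $\lambda = 3$ by default;
* gaps: uniform 1–8 characters, so gold spans are always separated;
* alphabet: mixed hiragana/katakana/CJK/ASCII code points, exercising
  multi-byte text without clinical content.

`perturb_predictions()` corrupts gold into predictions through the error
modes an extraction system exhibits — misses, boundary jitter,
fragmentation (split into $k$ fragments, one dropped character per split,
so coverage shrinks by $k-1$ characters and the $p=1$ score stays
interpretable), and spurious spans — and `corrupt_generation()` adds
character noise to marker text payloads (markers untouched). One run seed
yields fixed sub-stream seeds for corpus/perturb/corrupt, so changing one
stage's configuration never disturbs another's draws.

What the generator does *not* emulate: linguistic structure, realistic
entity surface forms, annotator disagreement, or correlated errors (a
model that always fragments the same construction). Passing tests
demonstrate that the *metrics* behave as specified on data with the right
offset statistics — they say nothing about any particular model's clinical
performance.

```{r sim}
sim <- run_simulation(
  corpus_spec(n_docs = 50),
  perturbation_config(frag_prob = 0.5, seed = 7)
)
sim$report |> filter(mode == "weighted") |> select(p, precision, recall, f1)
```

## Numerical choices

* **Large penalties.** $s_p$ is computed with max-factoring,
  $s = x_{\max}\,(\sum (x_i/x_{\max})^p)^{1/p}$: a coverage ratio of 0.01
  raised to $p = 100$ underflows double precision without it. $p = \infty$
  is computed exactly as $\max_i a_i / l$, never as a large-$p$
  approximation.
* **Exact $p=1$ identity.** At $p = 1$ the weighted TP mass is computed as
  the integer covered-character count $\sum_e \sum_i a_i$ — algebraically
  equal to $\sum_e l_e s_e(1)$ but free of float division — so equality
  with the character-level masses is exact, not within tolerance.
* **Degenerate inputs.** Both sides empty ⇒ P = R = F1 = 1; exactly one
  side empty ⇒ the affected metric is 0 and the report row is flagged
  (`note` column). Deterministic by fiat; real evaluations never hit it.
* **Straddling spans.** A predicted span crossing several gold entities
  contributes a fragment to each; only its characters outside every gold
  entity are FP mass — consistent with character accounting at $p = 1$.
* **Marker-mode FPs** count only predicted spans fully disjoint from the
  gold; a partially overlapping span already pays through its fragment
  scores.

## Problem sizes

The test suite checks the scoring path against a brute-force per-character
enumeration on a 1,000-document corpus, penalty monotonicity on 10,000
random fragment decompositions, the $p=1$ character-level identity on 200
perturbed corpora, and the fragmentation sensitivity sweep on a corpus of
about 2,100 entities over the grid frag ∈ {0, 0.25, 0.5, 1} — sizes chosen
to give stable Monte-Carlo behavior while keeping a full run in the order
of a couple of minutes.

## Limitations

* The score is computed against reference boundaries; clinically
  acceptable boundary variants are still penalized. Its agreement with
  clinician judgment is an open validation question, outside this
  package's scope.
* Gold entities must be disjoint and contiguous: no nested, overlapping or
  discontinuous targets, and no entity classes (the task is binary
  important-concept extraction).
* Offsets are code points, not grapheme clusters; for Japanese clinical
  text these coincide for practical purposes, and cluster segmentation
  would change every denominator.
* No Unicode normalization is applied: Japanese text mixes full- and
  half-width forms whose conflation would silently shift offsets.
* The token-level mode labels a token 1 if *any* of its characters is
  labeled (the `"all"` rule is available); published token-level numbers
  rarely state their rule, which is one more reason to prefer the
  character-based scores.
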