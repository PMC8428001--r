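---
title: "Checking the internal consistency of reported significance tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Checking the internal consistency of reported significance tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metacheckr)
```

## The problem and the model

An APA-style significance report — `t(28) = 0.32, p = .751` — is
internally redundant: the statistic and its degrees of freedom determine
the p-value. `metacheckr` exploits that redundancy to audit articles
without access to their data. The pipeline is convert → extract →
recompute → compare:

1. **Convert.** PDF, HTML, DOCX or plain text becomes normalized raw
   text. Normalization maps Unicode minus/dash/space variants to ASCII,
   expands ligatures, flattens superscripts and subscript markup (`χ²`
   → `χ2`, `Q_b_` → `Qb`) and collapses runs of spaces; it is total and
   idempotent, so offsets into normalized text are stable.
2. **Extract.** A family-specific grammar matches the eight supported
   test families (t, F, χ², Z, r, and the meta-analytic Q, Q-between,
   Q-within heterogeneity tests), case-insensitively and tolerant of
   optional spacing. All three elements are required — a statistic
   without a p-value claim (or the `ns` sentinel) is never extracted,
   which is also what de facto excludes statistics inside tables and
   non-APA shapes like `Q=35.72, 17 d.f., p<.0001` (free-floating
   degrees of freedom).
3. **Recompute.** Two-tailed for t, Z, and r (via its t transform with
   df = n − 2); upper-tail for F, χ² and the Q family, the latter
   referred to a χ² distribution with the printed df, the standard
   distribution of Cochran's Q under homogeneity. No continuity
   corrections.
4. **Compare.** A printed statistic of 2.35 stands for any value in
   [2.345, 2.355). Each family's tail function is monotone in the
   statistic's magnitude, so evaluating the endpoints (plus the zero
   crossing, where the interval spans zero) bounds the attainable
   p-values. The reported claim is accepted if any p in that interval
   satisfies it; a failed claim is *inconsistent*, and *grossly
   inconsistent* when the significance conclusion also flips at α.

## Decision rules and their rationale

Several comparisons admit more than one defensible convention; the
package fixes them as follows.

* **`p = v` claims** are satisfied when the recomputed interval
  overlaps `[v − 5·10^−(d+1), v + 5·10^−(d+1))`, the round-half-up
  preimage of the printed value at its d printed decimals — the
  symmetric counterpart of the statistic's rounding rule.
* **Bound claims** use strict inequalities: `p < .05` fails when every
  attainable p is ≥ .05. A reported bound exactly at α counts as a
  significance claim (`p < .05` claims significance at α = .05); a
  printed `p = v` with v exactly equal to α counts nonsignificant.
  These strict conventions reproduce the published worked examples in
  which recomputed p-values of .050 and .051 against `p < .05` are
  graded gross.
* **`ns` claims** are judged against the point-recomputed p (consistent
  iff p > α). An `ns` carries no printed digits, so there is no rounding
  interval to propagate; using the statistic's interval here would
  excuse reports like `Z = 1.96, ns` at α = .05 (the interval reaches
  .0506), contradicting how such reports are graded in practice. This
  also makes `ns` consistency monotone in α.
* **`p = .000`** is an APA violation (the correct form is `p < .001`)
  and is always flagged; it is graded gross only when the significance
  conclusion additionally flips. The check can be disabled via
  `check_config(zero_p_always_inconsistent = FALSE)`.
* **One-tailed rescue.** If the document mentions "one-tailed",
  "one-sided" or "directional" anywhere (whole words, case-insensitive),
  a failed claim on a t, Z or r result is retested against the halved
  interval and, if it then succeeds, graded consistent. The rescue never
  applies to F, χ² or Q tests: upper-tail statistics have no two-sided
  convention to halve. We apply the rescue to exact and bound claims
  alike; limiting it to exact claims would be the only other defensible
  reading, and the difference is visible only for bound claims within a
  factor of two of the recomputed p.
* **Indeterminate reported significance** (e.g. `p < .10` at α = .05,
  where the true reported side of α is unknowable) is never graded
  gross, and such results are excluded from the denominators of the
  bias-by-reported-significance split.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | level for the gross/non-gross severity decision |
| `one_tailed_detection` | `TRUE` | enable the one-tailed rescue |
| `zero_p_always_inconsistent` | `TRUE` | flag `p = .000` as a violation |

α = .05 is the conventional default of consistency-checking tools;
articles that state a different level (e.g. α = .01) should be re-run
with it — two of the published worked examples are `ns` reports that
are gross at .05 but correctly reported at the article's stated .01.

## Numerical choices

Recomputed p-values are *displayed* floor-truncated to three decimals
without a leading zero (`.089`); all comparisons use full precision,
and truncation (with a 10⁻⁸ guard against binary representation noise)
is presentation-only. This convention reproduces all published
recomputed values exactly, including `.083` and `.049` where
round-half-up would print `.084` and `.050`. Intervals are half-open on
the upper side, matching the round-half-up reading of printed numbers.
A correlation of |r| = 1 is degenerate (p = 0, with a warning); interval
endpoints for r are clamped to [−1, 1]. Document-level aggregation
computes the median number of results per document over documents with
at least one result, and the averaged-within-article inconsistency rate
over the same set.

## The synthetic corpus generator

`generate_corpus(plant_spec(...), dir)` writes seeded TXT/HTML/DOCX
documents of filler prose with planted APA-style results and returns a
manifest of ground-truth verdict labels. It emulates the statistical
reporting landscape of published meta-analyses: the default family mix
follows the proportions observed across such corpora (about a third
Z-tests, then F, χ², and the Q family, with Q-within rare), and the
default error mix approximates observed result-level prevalence (85%
clean, 7% rounding slips, 4% digit typos, 2% significance flips, 2%
`p = .000`). Error transformations are constructed so their labels are
stable: statistics are drawn so the recomputed p avoids a ±0.002 band
around α; rounding slips perturb the last printed digit by one in a
direction that keeps the mismatch on the reported side of α; flips
rewrite p across α with a margin. Labels are computed inside the
generator with its own interval arithmetic, account for the one-tailed
rescue in documents flagged as one-tailed, and documents receive non-APA
decoy statements (CI-only reports, free-floating df) that must not be
extracted. Fixed seeds yield byte-identical corpora; the DOCX container
is written with fixed timestamps for that reason.

What the generator does *not* emulate: PDF layout artifacts (hyphenation
across line breaks, multi-column reflow, glyph loss such as a χ printed
as a bare `2`), tables, reference lists, or any real journal's prose.
Passing the planted-corpus checks therefore demonstrates correctness of
the grammar, the recomputation and the classifier on well-formed input —
not robustness to arbitrary conversion noise. Real-world recall of
APA-style results from converted PDFs is known to be materially below
100% for any tool of this kind.

## Validation and problem sizes

The test suite validates the classifier against a brute-force oracle
that scans a dense grid (20,001 points) of statistic values across the
rounding interval and tests the reported claim pointwise — a code path
independent of the interval-endpoint logic. The acceptance script runs
this comparison on 3,000 randomized results (the suite uses 10,000), a
planted corpus of 150 documents with ≥1,000 results, and
distribution-identity grids (χ²(1) vs squared normal, F(1, ν) vs t(ν)²,
r vs its t transform) at 10⁻¹⁰ tolerance. These sizes give the
binomial checks enough resolution while keeping a full run in the
low minutes on a single core.

## Known limitations

* Scanned PDFs (no text layer) yield empty text; the built-in PDF reader
  handles plain and Flate-compressed content streams in natural drawing
  order but does not decode CID/Type0 font programs.
* The checker cannot tell *which* element (statistic, df, or p) is
  wrong — only that the triple is incoherent.
* Reference lists and supplements are scanned along with everything
  else; at the precision of the full APA grammar this adds few if any
  false positives.
* `Q` without parenthesized degrees of freedom is not extractable even
  when the df appears elsewhere in the sentence; that is non-APA
  reporting and out of the grammar by design.
* Confidence intervals, effect sizes, I², and τ² are not verified.
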