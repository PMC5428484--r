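---
title: "Scoring protein functional similarity from GO annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring protein functional similarity from GO annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gofunsim)
```

## The model

Two proteins are functionally similar when the Gene Ontology (GO) terms
annotating them are semantically close in the ontology graph. `gofunsim`
scores this in three layers.

**Information content.** For a namespace (BP, MF or CC) and an
annotation corpus, every term gets a probability
$P(t) = N(t)/N(\mathrm{root})$, where $N(t)$ counts the *distinct*
proteins annotated to $t$ or to any of its descendants, and an
information content $I(t) = -\log P(t)$. The root always has $I = 0$;
rare, specific terms have high $I$. Natural logarithms are the default
(`base` argument of `build_ic()`); the base only rescales the Resnik
measure, every normalized measure is invariant to it. Counting distinct
proteins (rather than annotation rows) is the classic Resnik convention:
annotating one protein to several descendants of $t$ must not inflate
$N(t)$.

**Term-level semantic similarity.** With $S(s,t)$ the common ancestors
of terms $s,t$ (ancestor sets are reflexive, so $s \in S(s,s)$) and
$c^*$ the most informative common ancestor (MICA), the six supported
measures are Resnik $I(c^*)$; Lin $2I(c^*)/(I(s){+}I(t))$; the Schlicker
relevance measure, which multiplies Lin's ratio by $1-P(c)$ and
maximizes the product over *all* common ancestors (the
`simrel_all_ancestors` flag switches to a MICA-only variant); the
information coefficient, Lin weighted by $1 - 1/(1{+}I(c^*))$; the
Jiang–Conrath transform $1/(1 + I(s) + I(t) - 2I(c^*))$; and the
pairwise graph-information-content measure, the ratio of summed $I$
over the intersection versus the union of the two ancestor sets. All
but Resnik live in $[0,1]$.

**Mixing and combining.** A protein pair yields the $m\times n$ matrix
of term similarities over their *direct* annotation sets; the ancestor
closure enters only through the information content (and simGIC's
sums). Five mixing strategies reduce the matrix: the mean (`fsAvg`),
the maximum (`fsMax`), and three best-match variants built from row and
column maxima — `fsBMM` (max of the two best-match means), `fsBMA`
(their average) and `fsABM` (the pooled mean over $m+n$ maxima). They
always satisfy fsAvg ≤ fsABM, fsBMA ≤ fsBMM ≤ fsMax. Scores from
several namespaces combine by root mean square,
$F = \sqrt{\tfrac1k\sum_o F_o^2}$; a pair lacking annotation in a
requested namespace is *unscorable* (a classed error), which is
deliberately distinct from a present zero — a genuine 0 in one
namespace enters the RMS and drags the combination down.

## Background z-scores

Raw scores are not comparable across proteins: annotation bias (a
disease gene with dozens of terms, or a protein carrying only shallow,
near-root terms) shifts whole score distributions. For each protein we
therefore estimate the background of its score against `k` partners
sampled without replacement from the other organism's annotated pool
(default `k = 1000`, clamped to the pool) and normalize a pair score as

$$ z(P,R) = \frac{2F(P,R) - (\mu_P + \mu_R)}{\sqrt{\sigma_P^2 + \sigma_R^2}} , $$

the central-limit form for the sum of the two per-protein scores.
Sample standard deviations ($n-1$) are used. Backgrounds of combined
scores are estimated on the combined score itself (sample, combine,
then average), not combined from per-namespace backgrounds. The
median-based "modified" z-score variant is intentionally not
implemented.

## The orthology benchmark

Orthologous proteins should score higher than random pairs. Cases are
one-to-one orthologue pairs (pairs at ≥ 80% sequence identity are
excluded as trivial; identity is read from the input, never computed);
controls replace the second-organism protein by a derangement — a
permutation with no fixed point, each control gene used exactly once —
sampled by rejection. Classification uses the rule score ≥ h, with
candidate thresholds at midpoints of adjacent distinct observed scores
plus infinite sentinels (exact for the step-constant empirical error
curve; ties resolved toward the smallest h). The reported quantity is
the mean over `R = 225` control resamples of the minimized error rate
$(FP{+}FN)/\text{total}$, with a normal-theory 99% confidence interval
of the mean, for raw scores and z-scores side by side. Corpus variants
(with/without IEA evidence, all-organisms versus
annotations-of-the-organisms-only) are compared by a one-sided paired
Wilcoxon signed-rank test on per-repeat error rates, Bonferroni-scaled
for 30 measure combinations at family level α = 0.01; an all-zero
difference vector is reported as degenerate and non-significant.

Because the threshold is optimized on the same scores it is evaluated
on, the mean minimized error sits slightly *below* the true separation
error of the score distributions (an optimization-bias effect of order
$n^{-2/3}$); calibration checks against analytic overlap values should
therefore use the sampling error of an error-rate estimate at the
benchmark's size, not the standard error of the repeat mean, as their
yardstick.

Case pairs unscorable under the active measure are excluded *before*
control construction, which keeps case and control sets equally sized
and—since controls are drawn from the case columns—makes unscorable
control pairs impossible for both single and combined namespaces.

## The synthetic world generator

`fixture_spec()` / `make_world()` emit a complete, parseable world:
random single-rooted DAGs per namespace (default 40/20/12 terms,
≤ 3 parents, 15% `part_of` edges), two organisms of 60 proteins, and
GAF 2.2 / OBO / TSV files byte-reproducible under a fixed seed. The
defaults encode the study conditions the scoring stack targets:

* annotation counts are a mixture — most proteins draw ~1–4 terms
  (shifted Poisson, mean 2.5), a 10% tail draws 15+ — emulating
  heavily annotated disease genes;
* tail proteins sample terms with weight $1/(1+\text{depth})$, i.e.
  preferentially shallow terms, so they are "sticky" under raw scores —
  exactly the bias z-scores exist to correct;
* 25% of proteins are IEA-only, so evidence filtering removes whole
  proteins, not just rows;
* orthologue partners share 60% of their counterpart's terms (planted
  signal), and 10% of pairs carry ≥ 80% identity to exercise the
  exclusion rule.

These sizes keep every end-to-end test in seconds while leaving enough
DAG structure for nontrivial MICAs. What the generator does *not*
emulate: real GO topology statistics (term fan-out, depth profile),
realistic evidence-code mixtures, or inter-namespace correlation of
annotations — so passing tests demonstrate correctness of the
machinery and directional behaviour of z-scores, not absolute error
rates on real corpora. Published error rates for human/mouse/fly
orthologues depend on a specific ontology release and orthologue build
and are not reproducible from synthetic worlds; the test suite instead
pins the measure formulas to independent oracles, the worked
best-match-average example to all printed digits, and the benchmark
engine to an analytic Gaussian-overlap calibration.

## Numerical and design choices

* **Unscorable terms.** Terms with $N=0$ have undefined $I$; any
  similarity whose inputs are only unscorable terms returns 0 with a
  warning, keeping all measures total without inventing information.
* **Degenerate ratios.** $I(s)+I(t)=0$ (both terms of probability 1)
  returns 0 for the ratio measures. The Jiang–Conrath denominator is
  evaluated as $1 + (I(s)-I(c^*)) + (I(t)-I(c^*))$ so self-similarity
  is exactly 1 in floating point.
* **The information-coefficient sign.** The weight is implemented as
  $1 - 1/(1+I(c^*))$, the only sign that keeps the measure in $[0,1]$;
  a `simic_variant = "as_printed"` option evaluates the
  minus-sign form, which leaves the unit interval and is provided for
  comparison only.
* **Tie-breaks.** Equal-information MICA candidates resolve to the
  lexicographically smallest term id; equal-error thresholds resolve to
  the smallest h. Both make runs reproducible.
* **Relations.** Ancestry uses `is_a` + `part_of` by default
  (configurable); edges crossing namespaces are dropped so each
  ontology is scored independently.
* **Derangements by rejection** rather than exact uniform sampling over
  derangements: the expected number of shuffles is $e \approx 2.72$,
  and the benchmark only needs fixed-point-free bijections, not exact
  uniformity.
* **Problem sizes in tests.** Oracle comparisons run on 20–40-term
  DAGs with 30–60 proteins per organism; the calibration benchmark uses
  200 Gaussian case/control pairs over 225 repeats. These sizes were
  chosen so brute-force oracles (transitive closures, exhaustive
  descendant counts, all-pairs means) stay exact and fast.

## Limitations

Identifier mapping between annotation sources (e.g. UniProt versus
model-organism database ids) is out of scope: protein ids are taken
verbatim from GAF column 2 and must match across inputs. GPAD and OWL
inputs are unsupported. The group-wise form of simGIC over whole
annotation sets is intentionally absent — the pairwise form flows
through mixing strategies like every other measure. Background
estimates assume the partner pool is large enough for sampling without
replacement to be meaningful; with tiny pools, `k` clamps to the pool
and the background becomes exhaustive.

## A worked session

```{r example, eval = FALSE}
spec <- fixture_spec(seed = 7)
world <- make_world(spec)
ctx <- load_context(world$paths$obo, world$paths$gaf)

fun_sim("A0001", "B0001", ctx$corpus, ctx$dags, ctx$ics,
        measure = "simGIC", mix = "fsBMA", namespaces = "BP")

orth <- read_orthologs(world$paths$orthologs)
scorer <- fs_scorer(ctx$corpus, ctx$dags, ctx$ics, "simGIC", "fsBMA", "BP")
bench <- repeat_benchmark(orth, scorer, R = 225, seed = 1)
summary(bench)
```
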