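---
title: "Similarity models, benchmark protocol and synthetic data in binrf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Similarity models, benchmark protocol and synthetic data in binrf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binrf)
```

## The problem

Ligand-based virtual screening ranks a compound library by similarity to a
known active molecule (the *reference structure*), in the hope that
molecules with similar fingerprints share its bioactivity. `binrf`
implements three ranking models over folded count fingerprints
(ECFC-style, default width 1024) and the simulated-screening protocol used
to compare them: recall of an activity class within the top 1% and 5% of
the ranked database, averaged over ten randomly chosen reference
structures per class.

## The three models

**Continuous Tanimoto (TAN).** For count vectors $w_k$ and $w_l$,

$$S_{k,l} = \frac{\sum_j w_{jk} w_{jl}}
  {\sum_j w_{jk}^2 + \sum_j w_{jl}^2 - \sum_j w_{jk} w_{jl}},$$

the standard continuous generalization of the Tanimoto coefficient. It is
1 exactly for identical fingerprints and reduces to the binary Tanimoto
when all counts are 1 (`tanimoto_continuous()`).

**Bayesian inference network (BIN).** Compounds are root nodes, fragments
intermediate nodes, the reference structure the leaf. The belief a
compound $c_j$ contributes through fragment $f_i$ is the Okapi (BM25-style)
function

$$bel_i(c_j) = \alpha + (1-\alpha)\,
  \frac{ff_{ij}}{ff_{ij} + 0.5 + 1.5\,|c_j|/|C_{avg}|}\,
  \frac{\log\left[(m+0.5)/cf_i\right]}{\log(m+1)},$$

where $ff_{ij}$ is the fragment's count in the compound, $|c_j|$ the
compound size, $|C_{avg}|$ the mean compound size, $cf_i$ the number of
compounds containing the fragment and $m$ the collection size. The
compound's score is the arithmetic mean (SUM operator) of the beliefs of
the query's unique fragments; a compound sharing no fragment with the
query scores exactly $\alpha$. The baseline $\alpha$ defaults to 0.4, the
value reported to perform best for this belief function; it is
configurable in `[0, 1)`. The idf term is a ratio of logarithms and
therefore independent of the base.

**BIN with reweighted fragments (BINRF).** Given a set of active
references, each fragment of their union receives a reweighting factor
$rwf_i = F_{fi} / \max F$, where $F_{fi}$ is the fragment's frequency
across the reference set. The query's fragments then get new weights
$nw_i = w_i + rwf_i$ ($w_i$ = the fragment's count in the query; fragments
outside the reference set keep $w_i$). Fragments shared by many active
references — the ones most plausibly tied to the activity — are promoted;
idiosyncratic ones are relatively penalized.

The combination of the reweighted fragments at the reference node is not
fully determined by the method's description, which stops at "a new
weight". We combine beliefs by the normalized weighted sum
$\sum_i nw_i\,bel_i / \sum_i nw_i$ (`belief_wsum()`), the weighted
counterpart of the SUM operator from the same retrieval framework. The
choice is guarded by an exact reduction: with uniform new weights (a
count-uniform query that is its own reference set) BINRF scores are
identical to BIN.

Two further readings are configurable because the source description is
ambiguous:

* `size_mode` — whether $|c_j|$ counts total fragment occurrences
  (default; the analogue of document length in token-based retrieval) or
  distinct fragments;
* `frequency_mode` — whether $F_{fi}$ sums occurrence counts over the
  references (default; "frequency" elsewhere in the model means occurrence
  counts) or counts the references containing the fragment.

## The benchmark protocol

For each activity class, `run_activity_class()` draws `n_references`
members (default 10) reproducibly from a seed derived from the master seed
and the class id. Each reference in turn is the single query for TAN and
BIN; for BINRF the same query is reweighted against the full selected
reference set. Rankings are deterministic: descending score with ties
broken by ascending molecule id. Recall is evaluated at the top 1% and 5%
(cutoff = fraction times database size, rounded half up with a floor of
one position; floor/ceiling variants are provided since the convention is
not standardized). References stay in the database and count as actives by
default; an `exclude_references` switch removes the non-query references
from both the ranking and the actives.

Per cutoff, results form a class-by-model matrix summarized three ways:

* the **mean row** (`table_mean()` per column);
* **best cells**: per class, the model with the highest recall (ties: all
  maxima). The per-model count of best cells is the "share cells"
  statistic; a near-best display mark (within 5% relative, configurable)
  is also rendered but never counted, because the published counts sum to
  the number of classes;
* **Kendall's coefficient of concordance** (`kendall_w()`), treating
  classes as judges ranking the models, with average ranks for ties, the
  tie-corrected denominator, and significance from the chi-square
  approximation $\chi^2 = m(n-1)W$ on $n-1$ degrees of freedom (adequate
  for the 10–11 judges used here; an exact permutation test is out of
  scope). Model ordering is by mean rank, best first.

The published per-class recall tables for the three MDDR benchmark subsets
ship with the package (`mddr_recall()`), so all three summary statistics
can be recomputed exactly from the printed cells — this is what
`scripts/acceptance.R` and the `tables` CLI command do. Two published
summary values are internally inconsistent with their own cells (one
top-5% mean and the top-1% best-cell counts of the homogeneous subset) and
one reported concordance analysis lacks a stated tie/rank convention;
these are reported as recomputed, not asserted.

## The synthetic data generator

The real MDDR database is proprietary, so `generate_benchmark()` emulates
its structure at desk scale: a background of unrelated molecules plus
activity classes with the published class counts, relative sizes (divided
by 10, floor 11 so ten references remain selectable) and mean pairwise
similarities. Defaults, chosen once:

* width 1024, background 5,000 molecules;
* distinct fragments per molecule: Poisson(60) truncated at 10, indices
  uniform over the width;
* per-fragment counts: 1 + Geometric(0.8), i.e. mostly 1–2 with mean 1.25,
  the regime of folded circular count fingerprints of drug-like molecules.
  Count skew matters: because the reweighted query weight is
  $nw_i = w_i + rwf_i$, heavy-tailed counts let $w_i$ — which carries no
  information about which fragments are class-discriminative — drown the
  reweighting signal and turn BINRF into BIN with random weights;
* activity classes are perturbed copies of a prototype molecule: member
  $k$ keeps prototype fragment $i$ with probability $(1-q)^{e_i}$ and
  replaces each deletion with a fresh uniform fragment (size preserved in
  expectation). The exponents $e_i$ are mean-1 Gamma(0.5) quantiles,
  stratified (the same spectrum every class, permuted across fragments):
  small exponents give conserved *core* fragments — the scaffold or
  pharmacophore that real activity classes share — and large exponents
  give peripheral decoration. This core/periphery split is the structural
  feature that multi-reference reweighting exploits; a generator with
  uniform retention offers it nothing to find. Stratification keeps the
  achieved class diversity stable across prototypes, which the calibration
  tolerance below relies on.

`calibrate_perturbation()` maps a target class diversity (mean pairwise
binary Tanimoto) to $q$ by bisection against three probe classes of 50
members, generated with common random numbers so the estimate is exactly
monotone in $q$ and the search deterministic. Achieved diversity is within
±0.02 of targets across the published range 0.10–0.40. Near the bottom of
that range the achieved value sits on a plateau (about 0.109) created by
the near-immortal core fragments as $q \to 1$; this is within tolerance,
and at exactly $q = 1$ members are unrelated (background similarity,
about 0.03).

What the generator does **not** emulate: real chemistry, fragment
co-occurrence structure, non-uniform fragment popularity, or the absolute
recall levels of the real database (synthetic classes are considerably
easier to retrieve). Passing the directional checks therefore shows the
models behave as expected *given* conserved-core class structure, not that
absolute published recall values are reproduced — those require the
proprietary database and are explicitly out of scope.

## Numerical and design choices

* Folding is modulo-width with count summation; indices are 0-based.
* Binary Tanimoto of two empty fingerprints is 1 (identical objects);
  continuous Tanimoto of two empty fingerprints is an error (undefined
  0/0 with no identity argument).
* Query fragments absent from the whole collection are dropped before
  belief computation ($cf_i = 0$ would make the idf undefined); they
  cannot occur when the query comes from the database itself.
* All randomness flows from a single master seed through labelled derived
  streams (`derive_seed()`), so adding a model or class never shifts
  another's draws, and every report is byte-identical under rerun.
* Desk-scale problem sizes: the default synthetic benchmark is roughly
  5,900 molecules; the full three-subset suite and the ten-replicate
  directional experiment each run in about a minute on one CPU.

## Limitations

* The BINRF combination operator is a documented interpretation (see
  above), not a published formula.
* The chi-square significance of Kendall's W is approximate, and the
  reported concordance convention of the original analysis is unknown, so
  W values are comparable only within this package's convention.
* Synthetic recall levels are optimistic relative to real screening data;
  only orderings and directional effects should be read from them.
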