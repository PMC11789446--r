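---
title: "Methods: the variant prioritization cascade and network stage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the variant prioritization cascade and network stage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varcascade)
```

## Overview and assumptions

`varcascade` prioritizes germline variants from annotated exomes of
familial cancer index cases. Its central assumption is the standard one of
rare-variant candidate studies: a variant contributing to a dominant-like
familial cancer predisposition should be **rare** in reference populations,
**predicted deleterious** by orthogonal in-silico evidence, and its gene
should connect to the disease's known biology. The pipeline composes those
assumptions as an ordered sequence of gates, each a pure function of the
variant's annotation and one configuration object, so that a run is fully
described by (cohort, `threshold_config`) and every decision is auditable
in the gate trace.

The pipeline consumes *annotated* variants — the external predictors (VEP,
CADD, the nine missense tools, conservation scores, MutPred2, SpliceAI,
MMSplice, gnomAD constraint) are upstream inputs, never recomputed here.
Coordinates are 1-based VCF positions and are never used arithmetically;
indels are taken as left-normalized by the caller. Canonical-transcript
selection trusts the annotation's canonical flag. Multi-allelic records
are split one alternate allele per row, matching annotation blocks by
their declared allele when present.

## Gates, cutoffs and their semantics

All cutoffs live in `threshold_config()`; strictness follows the wording
each rule is conventionally stated with, and the boundary cases are pinned
by unit tests.

| Parameter | Default | Comparison | Meaning |
|---|---|---|---|
| `maf_max` | 0.001 | strict `<` | gnomAD exomes AF/NFE/popmax rarity bound |
| `cadd_min` | 20 | strict `>` | scaled CADD PHRED (top 1% proxy) |
| `vote_fraction` | 0.5 | strict `>` | nine-tool consensus vote fraction |
| `gerp_min` | 2.0 | strict `>` | GERP conservation vote |
| `phastcons_min` | 0.3 | strict `>` | PhastCons vote (score in [0,1]) |
| `phylop_min` | 3.0 | inclusive `>=` | PhyloP vote |
| `conservation_min_votes` | 2 | `>=` | votes required of the three |
| `mutpred2_min` | 0.50 | inclusive `>=` | likely-pathogenic tier (5% FPR point) |
| `spliceai_confident` / `spliceai_high` | 0.5 / 0.8 | inclusive | tiers on the max of the four deltas |
| `mmsplice_medium` / `mmsplice_high` | 1.5 / 2.0 | strict `>` on &#124;score&#124; | splice effect confidence |
| `loeuf_max` | 0.6 | strict `<` | gene LoF-constraint flag |
| `string_min_score` | 0.400 | inclusive | minimum combined interaction score |
| `string_prior` | 0.041 | — | random-interaction prior |
| `fdr_alpha` | 0.05 | — | BH significance level |

Missing-data policy is asymmetric by design and stated in the gate
documentation: an absent allele frequency *passes* the frequency gate
(absence from gnomAD is rarity evidence), whereas an absent CADD score
*fails* its gate (the filter is an inclusion criterion and missing
evidence cannot demonstrate deleteriousness). Absent predictor calls and
conservation scores contribute nothing to their votes but do not shrink
the denominators: the vote denominator is fixed at 9 tools and the
conservation rule at 2-of-3. This is deliberately conservative — a variant
cannot pass on two confident calls out of two available.

Where the design was genuinely open we chose as follows. (1) The frequency
rule requires **all** present gnomAD fields below the bound (the most
stringent reading of a jointly stated three-field filter); an "any-field"
mode is available. (2) The per-variant report prints fractional consensus
scores such as 5.5 and 6.75 out of 9; we model these as intermediate calls
(PolyPhen-2 "possibly damaging", MutationAssessor "medium") worth 0.5, with
the call-to-weight table shipped as data
(`extdata/call_weights.yaml`) and numeric calls in [0, 1] accepted
verbatim, so finer alphabets (e.g. quarter steps, which 6.75 requires) need
no code change. (3) The MutPred2 threshold is inclusive at 0.50 because a
variant scoring exactly 0.50 is conventionally treated as meeting the
recommended cutoff. (4) The last-exon exclusion applies to stop-gain and
frameshift variants only; canonical splice variants are intronic, carry no
exon rank, and are not excluded even in the last intron — the cascade
records a note instead of guessing. (5) Other-class variants (synonymous,
UTR, deep intronic) are dropped with a count rather than carried.

## The network stage

Survivor genes are pooled with a seed list of known predisposition genes
(the packaged default carries the 11 seed genes printed in the reference
cluster report and is user-replaceable). Edge confidences follow the
STRING convention: each active channel score `s` is stripped of the shared
random-interaction prior `p` (`s' = max(0, (s - p)/(1 - p))`), the
stripped channels combine as independent probabilities, and the prior is
re-added. The combination is symmetric, floors at the prior, equals the
single active channel when only one is nonzero, and is monotone in every
channel — all tested as exact identities. Edges need combined score
`>= 0.400` (a *minimum required* score, hence inclusive).

Clustering is the Markov Cluster algorithm on the weighted adjacency with
self-loops. Numerical choices: self-loop weight equals the node's maximum
incident edge weight (1 for isolated nodes), expansion 2, inflation 3.0
(the default granularity of the STRING web tool), entries below 1e-12
pruned each iteration, convergence when the flow matrix changes by less
than `1e-6` (cap 100 iterations, with a warning and the current partition
on non-convergence). Cluster reading is deterministic: attractor rows are
scanned in node order and an overlap is assigned to the lowest-index
attractor; cluster ids are relabelled by size, then first member. Cluster
ids of any particular external tool run are *not* reproduced — only
composition properties are meaningful — and every cluster provably lies
within one connected component.

Enrichment uses the hypergeometric upper tail `P(X >= k)` computed by
direct log-space summation of the exact mass (no normal approximation; no
underflow at small p), and Benjamini–Hochberg adjustment via the textbook
step-up rule. Both are implemented in the package and cross-checked in the
test suite against independent oracles (`stats::phyper`, enumeration of
all draws on small urns, `stats::p.adjust`, and a literal step-up
transcription). BH is applied within each collection (GO BP, KEGG,
Reactome) separately, matching per-category FDR reporting; the background
universe defaults to the collection's annotation space because the
reference web tool's internal background is not reproducible. Published
FDR values therefore depend on that tool's database version and are never
asserted exactly here.

The whole-network PPI enrichment p-value offers two nulls, both labelled
approximations: a permutation null (random node sets of equal size from
the background interactome's node universe; add-one estimator
`p = (1 + #{perm >= obs})/(n_perm + 1)`, which cannot return 0 and keeps
the p-value valid) and a Poisson null with degree-configuration mean
`lambda = sum over query pairs of min(1, d_i d_j / (2m))`. The permutation
seed is a mandatory argument. Super-uniformity of the permutation p under
null resampling is checked by simulation in the test suite.

## The synthetic generator: what it does and does not show

`generate_cohort()` stands in for controlled-access patient exomes. It
emulates exactly the statistical structure the cascade consumes: a class
mix over missense/truncating/splice/other variants, and per-gate marginal
pass probabilities realized by *inverse construction* — the gate outcome
is drawn first (Bernoulli with the configured probability) and the scores
are then drawn from the matching side of the threshold. Consequently each
gate's marginal pass rate equals its configured value by construction, the
gates are independent, and `expected_survivors()` gives the exact
closed-form survivor distribution (Binomial per class) used as the test
oracle. Predictor concordance is modelled as a latent pathogenicity state
with per-tool binomial noise (`concordance` controls how tightly the
deleterious-call count concentrates near 9 or 0).

Defaults describe a nine-family study at desk scale: 9 families, 1000
variants per family, class mix 55% missense / 3% stop-gain / 4% frameshift
/ 2% canonical splice / 36% other, pass rates 0.15 (rarity), 0.10 (CADD),
0.30 (vote), 0.5 (conservation), 10% last-exon truncations, and 30% of
rare variants novel (no gnomAD record). These are one-time choices of
plausible post-annotation magnitudes, not fits to any dataset.

What the generator does **not** emulate — and therefore what passing tests
do not show about real data: correlations between annotations (real CADD,
conservation and predictor calls are strongly dependent; here gates are
independent by construction), realistic mutation spectra and gene-length
effects, haplotypes and segregation, multi-transcript annotation
ambiguity, and batch/annotation-version artifacts. Tests on synthetic
cohorts validate the *mechanics* of the cascade (routing, counting,
thresholds, determinism), not the biological yield of any particular
threshold setting.

`generate_network_and_sets()` plants a partition (default four 10-node
modules, within-edge probability 0.9, between 0.03, within-module channel
scores in [0.7, 0.95] vs [0.42, 0.55] between) with one annotation term
per module plus size-matched decoys, giving ground truth for cluster
recovery (adjusted Rand agreement > 0.9 in the default regime) and for
enrichment ranking (the planted term should attain the minimal q).

## Degenerate inputs and determinism

Empty cohorts, header-only tables, graphs with no edges, single-node
graphs and clusters disjoint from every term all return typed empty
results rather than errors; these paths are unit-tested. Parsers never
coerce an absent value to a numeric default. All reports are written with
a deterministic column order, so identical inputs and configuration give
byte-identical files; the pipeline manifest records input checksums, the
effective configuration and the package version.

Problem sizes used by the test and acceptance suites — a 10,000-variant
synthetic cohort for cascade recovery, 20 seeded replicates of 40-node
planted-partition graphs for clustering, 2,000-permutation nulls over
60–80-node backgrounds for the enrichment p-value, and exhaustive
enumeration of all 3^9 = 19,683 call vectors for the vote — are the
package's chosen desk-scale study conditions: large enough for the
binomial tolerances stated in the tests, small enough to run anywhere.

## Known limitations

* The cascade inherits every bias of its upstream annotators; it cannot
  rescue a variant the annotation mislabels, and per-tool numeric scores
  are not re-thresholded (inputs are categorical calls).
* The last-exon rule is a coarse NMD-escape proxy; no transcript-structure
  modelling beyond exon ranks is attempted.
* Gene symbols are the identifier namespace (upper-cased, no mapping
  service); edge lists and cohorts must agree on symbols.
* The PPI enrichment nulls approximate, but are not identical to, the
  reference web tool's calibrated background; cluster ids and database-
  version-dependent FDRs are not reproducible by design.
* Family-level burden counts depend on the gene-to-category map, which is
  packaged data (`extdata/category_map.tsv`) and should be replaced when
  the candidate space changes.
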