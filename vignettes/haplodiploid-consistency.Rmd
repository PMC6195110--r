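---
title: "Auditing WGA RADseq haplotypes with a haplodiploid pedigree"
author: "radmendel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing WGA RADseq haplotypes with a haplodiploid pedigree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radmendel)
```

## The design being modelled

Whole-genome amplification (WGA) is unavoidable when building RADseq
libraries from single micro-insects: a specimen yields about 10 ng of DNA
or less, and often under 1 ng survives re-concentration, while library
construction wants two orders of magnitude more. Multiple displacement
amplification is accurate, but at sub-nanogram input it can drop one
allele of a heterozygote (allele dropout) or introduce spurious variants
(polymerase or enrichment-PCR error).

Haplodiploid insects offer a built-in control. Males arise from
unfertilized eggs and are haploid; females are diploid. Cross one haploid
F0 male with one diploid F0 female, isolate virgin F1 daughters, and pool
*all* their haploid F2 sons before extraction: the pool is a biological,
amplification-free amplification of the parental genomes, large enough to
sequence without WGA. Genotype the WGA'd F0 pair and one WGA'd F1 female
alongside the pool and every RAD locus becomes a tiny pedigree test.

Two comparisons are supported:

* **pair mode** — genotyped F1 female versus pool. Categories:
  identical homozygous, identical heterozygous, *explained by the
  experimental setup* (the pool carries extra alleles contributed by the
  unsampled sister F1 females), and *unexplained*.
* **quartet mode** — all four samples, with culprit attribution for
  inconsistent loci.

## The consistency predicate

With `m`, `f0`, `f1`, `P` the allele sets of male, F0 female, genotyped F1
female and pool (haplotypes compared as atomic strings), consistency is
the conjunction of:

* **C1** `|m| = 1` and **C2** `|f0| ≤ 2`, `|f1| ≤ 2` — ploidy;
* **C3** `f1` is one paternal plus one maternal allele; a homozygous
  `f1 = {h}` needs `h = m` and `h ∈ f0`;
* **C4** `P ⊆ {m} ∪ f0` — pool alleles descend from the founders;
* **C5** `f1 ⊆ P` — the genotyped female's alleles reach the pool through
  her own sons;
* **C6** `{m} ∪ f0 ⊆ P` — every founder allele is corroborated by the
  pool.

C6 deserves comment because it is the one genuinely open modelling
decision. The published analysis treats the haplotype observed in the
pool of F2 males as *the reference* for judging the WGA'd samples; an F0
allele that no son carries is then evidence of a spurious call in the
amplified library, not of bad luck in segregation. That reading is what
reproduces every worked example in the published five-way categorization
— including the case of an F0 female `C/T` with all other samples `C`
(blamed on the female's `T`), and the case where an allele shared by the
F0 and F1 females is absent from the pool (blamed on the pool) — so C6 is
on by default. It is an asymptotic rule: it assumes families large
enough that every founder allele segregates into at least one pooled son.
The probability that a maternal allele reaches no F1 daughter is
`2^-n_f1_females` per heterozygous locus, so with the benchmark's family
sizes (hundreds to ~1,400 pooled sons from ten or more daughters) false
flags are vanishingly rare, but with one or two F1 females the rule would
mislabel segregation chance as error. `quartet_consistent(...,
pool_complete = FALSE)` disables C6 for such designs.

## Culprit attribution

For an inconsistent quartet the attribution searches, for each sample,
every alternative call whose alleles are drawn from the union of observed
alleles (singletons for the male, singletons and pairs for the females,
any non-empty subset for the pool), keeps the replacements that restore
consistency, and scores them by symmetric set difference: adding or
removing one allele costs 1, substitution costs 2. The verdict is the
minimum-cost single-sample fix, with two tie-break rules:

1. across samples, a fix that only *removes* alleles beats one that adds
   (blaming an observed spurious allele is preferred to positing an
   unobserved dropout elsewhere);
2. a tie that survives rule 1, or the absence of any single-sample fix,
   yields `COMBINATION`.

A winning fix that adds exactly one allele to the F0 or F1 female flags
that female as a dropout candidate — the "one allele was missing to fit"
situation. The tie-break hierarchy is this package's resolution of an
attribution rule the published analysis leaves implicit; it reproduces
all fourteen worked examples and is deliberately isolated in one routine
so it can be replaced. Restricting candidate alleles to those observed in
the quartet is safe: a fix using a never-observed allele can never beat
the minimal observed-allele fix, a claim the test suite asserts against a
brute-force oracle that *does* search an enlarged alphabet (exhaustively,
over all quartets on a three-allele alphabet plus one unobserved allele).

Degenerate inputs follow the same machinery: a diploid call with three or
more alleles violates C2, and since no other sample's edit can repair
that, the search automatically blames the over-called sample. Missing
calls are a precondition violation — loci must pass `filter_loci()`
first.

## The simulator

`simulate_cross()` generates, per locus: an ancestral haplotype (default
2 concatenated variable positions); the F0 female heterozygous with
probability `maternal_het_rate` (her second allele one mutation away);
the F0 male novel with probability `novel_paternal_rate`, otherwise equal
to a maternal allele; each F1 daughter takes the paternal allele plus one
maternal allele uniformly; each F2 son draws his mother uniformly and one
of her alleles uniformly (realized as multinomial mother counts plus
binomial allele splits, which is distributionally identical and fast);
the pool call is every allele carried by at least `pool_detection_min`
sons. WGA noise applies **only** to the F0 male, F0 female and genotyped
F1 female: dropout (per *heterozygous* call — a haploid or homozygous
call has nothing to drop), spurious single-base substitution of one
allele, and missingness, in that order, with every injected event written
to the truth labels. Depths are negative binomial, independent of pool
size (library input was mass-normalized in the benchmark protocol, so
pool depth does not scale with the number of pooled males). One RNG
stream seeded from `seed` drives all draws in a fixed documented order,
so datasets are byte-reproducible.

Default parameters are the package's one-time calibration to the
benchmark cross design and are not meant to be tuned per analysis:

| parameter | default | rationale |
|---|---|---|
| `locus_length_bp` | 109 | tag length of the benchmark libraries |
| `n_f2_males` | 933 | pool size of the most deeply sampled cross |
| `n_f1_females` | 20 | mid-range of the 0–38 daughters observed |
| `maternal_het_rate` | 0.012 | reproduces ~1.3% heterozygous-identical loci |
| `novel_paternal_rate` | 0.007 | reproduces ~0.6% setup-explained loci |
| `p_dropout` | 0.1 per het call | with the low het rate, lands dropout cases near the observed ~0.3% of loci |
| `p_spurious` | 0.003 | three WGA'd samples land total problematic loci near the observed ~1% |
| `p_missing` | 0.02 | typical share of incomplete calls |
| `depth_mean`, `depth_dispersion` | 40, 8 | a few percent of loci fall under the depth-10 filter |
| `input_dna_ng` | 1.5 / 0.39 / 0.35 | benchmark input masses (male, F0 female, F1 female) |

An optional dose model (`dropout_dose = c(rate_at_1ng,
slope_per_log2_ng)`) lets the dropout rate fall with input DNA mass, to
emulate the suspected dose dependence of WGA bias; the default is the
flat rate, since the benchmark itself drew no definite conclusion.

**What the simulator does not emulate** — and hence what passing tests do
*not* establish about real data: read-level sequencing error and the
stack-assembly pipeline that precedes the haplotype matrix (loci arrive
already called), restriction-site polymorphism, paralogous loci collapsing
into one stack, recombination (haplotypes are atomic), mortality or
sex-ratio distortion, and any correlation of noise across loci within a
library. The simulator validates the classifiers and summaries, not the
upstream variant caller.

## Filtering, IO and numerical conventions

* The retention rule is per-sample: a locus is kept only if every sample
  has a call and every call has stack depth ≥ `min_depth` (default 10).
  Whether the original analysis filtered on per-sample or mean depth is
  not stated; the per-sample reading is the stricter and is what "all
  samples had a sequence" suggests.
* The matrix dialect interleaves `<sample>` and `<sample>.depth` columns
  so one file carries everything the filter needs; `-` is missing,
  `consensus` is a reserved allele shared by all samples at monomorphic
  loci (it compares like any allele, so such loci count as identical
  homozygous), lowercase input is uppercased.
* Printed percentages use half-up rounding at each table's precision
  (1 decimal for locus percentages, 2 for occurrence shares, 1
  significant figure for nucleotide shares); base R's banker's rounding
  would drift on exact halves. Across-cross averages are means of the
  *rounded per-cross percentages* — each cross weighs equally — which is
  the only reading that reproduces the published 98.3% from (99.0, 97.4,
  98.5), since pooling loci would let the largest cross dominate.
* Cut-site coordinates are 0-based motif starts; ambiguous bases never
  match; each site contributes exactly two tags with no chromosome-end
  correction (2 × 59,433 = 118,866 in the benchmark genome's arithmetic).

## Problem sizes used in the checks

The shipped verification uses 5,000-locus noise-free simulations across
F1 family counts of 10–38 for the zero-noise guarantee, 50 replicates of
2,000 loci for dropout recovery, exhaustive attribution-oracle comparison
over all quartets on a three-allele alphabet, and 10–200 kb synthetic
sequences for the digestion oracle — sizes at which every stochastic
assertion has comfortable statistical margin while the whole suite runs
in about a minute.

The dropout-recovery experiment runs at fully informative markers
(`maternal_het_rate = 1`, `novel_paternal_rate = 1`). This is a
deliberate choice: when the paternal allele coincides with a maternal
allele, a dropout that leaves the paternal allele produces a call
indistinguishable from a true homozygote, so at realistic marker
informativeness the attributable fraction is bounded below the injected
fraction by an information limit, not by the machinery. Fully informative
markers remove that bound and make recovery exact.

## Known limitations

* C6 misreads segregation chance as error for very small F1 families
  (see above); disable `pool_complete` there.
* Dropout detection is bounded by marker informativeness; reported
  dropout shares are floors, not unbiased rates.
* Haplotypes are compared as whole strings; a per-SNP-column mode is out
  of scope, consistent with the worked examples which mix one- and
  two-base haplotypes at haplotype level.
* Pool calls carry no allele frequencies, only presence; an allele seen
  in a single son counts as present (`pool_detection_min = 1`), so the
  classifiers cannot distinguish a rare true allele from a pool-side
  artifact except through the consistency rules themselves.
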