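---
title: "Querying splice-junction compilations with sjquery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Querying splice-junction compilations with sjquery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The data model

A *compilation* is a frozen snapshot of exon-exon splice junctions called
across a cohort of RNA-seq samples. Each junction is the excised intron,
identified by chromosome, first and last intronic base (1-based, fully
closed) and strand; the annotated intron derived from a gene model is
therefore `exon1.end + 1 .. exon2.start - 1`. Per-sample read support is
stored sparsely: a sample appears in a junction's coverage list only when at
least one spliced read supports the junction, so every stored coverage value
is at least 1 and absence encodes zero. Each junction also carries
precomputed summaries over its covered samples — `samples_count`,
`coverage_sum`, `coverage_avg`, `coverage_median` — and an annotation status
(the sources that contain the exact intron, plus per-splice-site source sets
for the left and right boundaries, named in genomic coordinate order so
strand `?` is unambiguous).

On disk a compilation is two tab-separated files: a 17-column junction table
whose coverage lists are packed as `,id:count,id:count,...` with strictly
increasing sample ids, and a sample-metadata table keyed by integer
`sample_id` with free-text fields (a tissue field is required for tissue
specificity queries). Averages and medians serialize with exactly two
decimals; the *strict* loader (the default) verifies counts and sums
exactly and the floating summaries to half a unit of that serialization
(0.005), so corrupt compilations cannot pass silently, while the lax loader
recomputes summaries without complaint. Because summaries and medians are
over covered samples only, `coverage_avg`/`coverage_median` here mean
"among samples with evidence"; the alternative convention (over all
samples, zeros included) is not used anywhere in the package.

## Indices and the query planner

Three index families serve the three constraint kinds:

* **R (region)** — a per-chromosome interval structure over the intron
  intervals (closed-interval overlap: `[a,b]` meets `[c,d]` iff
  `a <= d && c <= b`), with five query modes: `overlap`, `within`, `exact`,
  `start_equals`, `end_equals`. The point-equality modes exist because
  cassette-exon screens anchor queries on single splice sites. Strand is a
  filter column, not part of the interval key: region queries are
  strand-agnostic by default.
* **F (filters)** — ordered numeric indices over the summary columns plus
  `length`, and the categorical columns `strand` and `annotated` (the 0/1
  "any source" flag).
* **M (metadata)** — a term-document inverted index over the metadata.
  Text is normalized by case folding and splitting on runs of
  non-alphanumeric characters; matching is exact on normalized terms (no
  stemming, no substring search), which keeps results deterministic and
  testable. An empty metadata query is an error rather than "all samples".

The planner picks a driver index — the interval index when a region is
present, otherwise the usable filter with the smallest estimated bucket
mass, otherwise the metadata constraint — and applies everything else as
refinements. A full-scan fallback keeps the engine total even with no
index. Every plan records its steps (`--explain` on the command line).

**The most consequential semantic choice** is what F filters apply to. When
a metadata (or explicit sample) restriction is present, the admitted sample
set is computed first, every candidate junction's coverages are restricted
to it, summaries are *recomputed over the restriction*, junctions left with
no admitted sample are dropped, and only then are F filters evaluated — on
the post-restriction summaries. Without a restriction, filters apply to the
stored summaries. A junction covered only in liver therefore fails
`samples_count>=1` under `metadata=tissue:brain`. One planner subtlety
follows: restriction can only shrink `samples_count` and `coverage_sum`, so
a `>=` filter on those columns (or any filter on the restriction-invariant
`length`/`strand`/`annotated`) can safely drive the plan from stored
values; `<=`/`=` bounds, and any bound on `coverage_avg`/`coverage_median`
(which can move either way under restriction), are applied only as
post-restriction refinements.

Query groups combine member queries by union or intersection, keyed
positionally by `(chrom, start, end, strand)`. When several members return
the same junction, its summaries come from the member with the widest
admitted sample set (an unrestricted member wins). Results are always
ordered by `(chrom, start, end, strand, junction_id)` so output is
reproducible byte for byte.

## The four high-level statistics

**Shared Sample Count (SSC).** For groups `g = 1..k`, `S_g` is the set of
samples with coverage in at least one junction returned by `g`;
`SSC = |S_1 ∩ ... ∩ S_k|`. It measures the prevalence of a compound
splicing pattern; for a cassette exon the two groups are the flank queries
`end_equals exonStart-1` and `start_equals exonEnd+1`. Adding a group can
never increase SSC.

**Junction Inclusion Ratio (JIR).** For sample `s` with coverage sums `a`
(group A) and `b` (group B),

$$\mathrm{JIR}(s) = \frac{b - a}{a + b + 1}.$$

The `+1` regularizer is this package's normative definition: it keeps the
score finite and in `[-1, 1)` and shrinks low-coverage samples toward 0.
Samples with `a + b = 0` are omitted; ties in the descending ranking break
by ascending `sample_id`; swapping the groups negates every score. Raw
coverages are summed — no per-sample normalization is applied, since the
ratio form already cancels overall depth to first order.

**Percent Spliced In (PSI).** The cassette special case: with flank
coverages `c_L`, `c_R` and exclusion coverage `e`, inclusion evidence is
the *mean* of the two flanks, `i = (c_L + c_R)/2` (symmetric treatment of
the flanks, and an exon supported by both flanks is not double-counted),
and `PSI = i / (i + e)` in `[0, 1]`. Samples with `i + e = 0` or with total
evidence `c_L + c_R + e` below `min_total` (default 20 reads, a
conventional depth floor for interpretable PSI) are omitted.

**Tissue Specificity (TS).** Every sample with a nonempty tissue label gets
a value — by default 1/0 presence of any coverage in the group's junctions
(robust to depth differences between samples), optionally the raw coverage
sum for sensitivity analyses — and the per-tissue value vectors are
compared with a tie-corrected Kruskal-Wallis rank test:

$$H = \frac{12}{N(N+1)} \sum_i n_i\left(\bar r_i - \frac{N+1}{2}\right)^2,
\qquad H' = \frac{H}{1 - \sum_t (t^3 - t)/(N^3 - N)},$$

with midranks over the pooled values and tie-group sizes `t`. When every
value is tied the corrected statistic is defined as 0 with `p = 1`. Fewer
than two nonempty tissue groups is an error, since the test is undefined.

The p-value defaults to the upper chi-square tail with `k - 1` degrees of
freedom, the standard choice at compilation scale. At small `N` (roughly
`N <= 8`) the chi-square approximation is materially inaccurate — its error
against the exact permutation distribution is on the order of 0.05–0.2,
orders of magnitude larger than Monte-Carlo noise at typical draw counts —
so a label-permutation p-value
(`(1 + #{H* >= H}) / (B + 1)`) is available behind
`p_method = "permutation"` and is the recommended choice there.

## The synthetic-data generator

Real junction compilations cannot ship with a package, so validation runs
on seeded synthetic compilations with planted structure; generation is
byte-deterministic for a fixed seed and every planted event is recorded in
a human-readable truth table that binds it to a checkable expectation
(`expected_truth_queries()`).

Defaults describe a mid-sized multi-tissue cohort: 200 samples over four
equally weighted tissues and 1000 background junctions. Per-junction sample
prevalence is uniform on `[0.1, 0.8]` (compilations only contain evidenced
junctions, so very rare junctions are underrepresented relative to a full
archive, but the range covers rare through near-constitutive events), and
coverage conditional on presence is `1 + NB(mu = 7, size = 2)` — negative
binomial rather than Poisson, matching the overdispersion of RNA-seq counts,
with the `+1` shift enforcing the sparse "at least one read" model. Planted
events:

* **Cassette exons** emit the two inclusion flanks and the exclusion
  junction; each expressing sample (probability `prevalence`) splits a
  negative-binomial read depth binomially between inclusion and exclusion
  at the (optionally per-tissue) inclusion rate. At inclusion rate 1 no
  exclusion reads exist anywhere, and a junction no sample covers is not
  emitted at all.
* **Tissue-specific junctions** are covered only in samples of the active
  tissue, at the stated prevalence (default 0.6).
* **JIR outlier patterns** plant a pair of junctions covered in every
  sample at `1 + NB(19, 4)` (a well-expressed constitutive pair). Outlier
  samples model a dramatic isoform switch: their group A (excised)
  junction loses all coverage and their group B coverage is multiplied by
  the effect size (default 10). The full switch — not mere inflation of B —
  is what makes the planted samples separable from 200 overdispersed
  nulls: under negative-binomial noise the null JIR spread is roughly
  `cv/sqrt(2)` ≈ 0.3, so only near-total switching reliably occupies the
  top ranks, which is exactly the situation the statistic is designed to
  find.

What the generator does *not* emulate, and hence what passing tests do not
show about real data: per-sample library-size variation (junction coverages
are drawn independently, so cross-junction correlation within a sample is
absent), splice-motif sequence content (motif columns are fixed GT/AG
placeholders), realistic annotation structure (status columns are stamped
directly rather than derived from a genome-wide gene model), batch effects,
and metadata vocabulary drift. Conclusions about statistical calibration
(e.g. the TS null rejection rate) transfer to real data only to the extent
that real per-sample evidence is exchangeable within tissue under the null.

## Validation problem sizes and numerical choices

The test suite validates the planner against an independently written
linear-scan oracle on 10 000 randomized query specifications over a
1000-junction / 200-sample compilation (exact set equality in all cases),
checks TS calibration on 1000 null compilations and TS power on 200
planted replicates (4 tissues x ~50 samples, prevalence 0.6, p < 0.01
required in >= 95%), JIR rank recovery on 200 replicates, and an SSC
prevalence screen over 50 planted cassette exons (25 at prevalence 0.6
vs 25 at 0.15, one-sided Wilcoxon). These sizes keep the whole suite in a
few minutes on one core while leaving the binomial error of every rate
estimate well inside its acceptance band. `scripts/acceptance.R` recomputes
the same quantities from scratch at slightly smaller query counts.

Numerical conventions, fixed once and used everywhere: averages and medians
serialize with 2 decimals (hence the 0.005 strict-load tolerance); scores
and p-values print with 6 significant digits; `coverage_avg` is computed as
sum-then-divide; the even-count median is the mean of the two central
values; ranking ties break by ascending `sample_id`; result order is
genomic with `junction_id` as the final tiebreak; group identity is
positional; junctions whose admitted-sample count drops to zero under a
restriction are dropped from results (the alternative — returning them with
zeroed summaries — was rejected so that `samples_count>=1` means what it
says under restriction).

## Known limitations

* The metadata tokenizer is a design choice; any external service with a
  different normalization will match differently on punctuated terms.
* The chi-square TS p-value is approximate; at small per-tissue counts use
  the permutation option.
* One compilation per index set; cross-compilation joins and an HTTP
  service layer are out of scope.
* Numeric equality filters on `coverage_avg` compare IEEE doubles exactly;
  they are intended for values taken from the table itself.
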