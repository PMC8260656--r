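---
title: "Methods: summit-based co-occupancy analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: summit-based co-occupancy analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coocseq)
```

## The model

Two ChIP-seq factors are said to co-occupy a genomic site when their
called peaks place their summits within a window $w$ of each other
(default $w = 1000$ bp, inclusive: distance $\le w$). The summit — the
base of maximal estimated enrichment, narrowPeak column 10 — is the best
single-point estimate of the binding position, so all distance and
annotation logic in this package operates on summits, not on interval
overlap. Peak intervals are carried along for provenance but only the
summit decides.

### One-to-one matching

`colocalize()` forms all same-chromosome candidate pairs with summit
distance $\le w$ (found by a sorted sweep, i.e. binary search of each
cofactor summit into the sorted anchor summits — never an all-pairs
scan), sorts them by (distance, summit$_A$, summit$_B$) and accepts
greedily while both peaks are unmatched. The choice of a *one-to-one*
matching is deliberate: it produces a single co-occupied-site count $m$
that can be meaningfully divided by either input size
($m/n_A$, $m/n_B$), the way co-occupancy studies report one site count
against both denominators. The full tie-break chain makes the matching a
deterministic function of its inputs, and the sweep is checked
site-for-site against an $O(n^2)$ brute-force greedy oracle in the test
suite (200 random instances, sizes up to 500).

`partition_proximal()` is the deliberately different second primitive: an
*existence* test (is any anchor summit within $w$?) that partitions the
cofactor set into proximal and distal subsets. Proximal/distal counts in
the literature sum to the whole cofactor set, which identifies them as a
partition, not a matching; conflating the two rules is a common source of
irreproducible counts.

### Distance statistics and reporting

`distance_fractions()` is the empirical CDF of matched-summit distances
at user thresholds (20, 200, $w$ by default) — monotone, equal to 1 at
$w$, and reported as `NA` (flagged), never 0, when there are no sites.
Reported percentages are rounded half away from zero to one decimal
(`round_half_up()`), with raw fractions retained; the active-gene
fraction is displayed to the whole percent. Base R's round-half-to-even
would silently disagree with conventionally reported values at the
boundary.

## Annotation

Each summit is classified into exactly one of promoter, enhancer, exon,
intron, intergenic. The promoter window covers signed TSS distances in
$[-\mathrm{up}, \mathrm{down})$ in gene orientation (defaults
$-2000/+500$; the downstream edge is exclusive, so a summit exactly
`down` bp past the TSS is genic, not promoter). Candidates from all
overlapping features are resolved by a configurable priority
(promoter > enhancer > exon > intron > intergenic: the most specific
regulatory class wins), then by smallest $|$TSS distance$|$, then by
lexicographic gene id — a fully specified tie-break chain, again for
determinism. Signed TSS distance is $s - \mathrm{tss}$ on the + strand
and $\mathrm{tss} - s$ on the −, so upstream is always negative.

Enhancers are supplied intervals (their derivation from chromatin data is
upstream of this package); an enhancer summit links to the nearest TSS
within `enhancer_link_radius` (default 50 kb) and may remain unlinked.
The promoter window, priority order and radius are all config-exposed
because no single convention is universal; reanalyses can match whatever
the original choice was. Overlap queries run on IRanges interval trees
per chromosome and are verified against a naive linear-scan oracle.

Target genes are the distinct genes with at least one non-intergenic
assignment. Activity classification is `value >= threshold` on a supplied
expression table (default threshold 1.0 in the table's declared unit —
expression pipelines differ, so the cutoff is surfaced, not hidden);
genes missing from the table are conservatively counted inactive and
logged. A gene bears a histone mark iff a mark-peak summit falls in its
promoter window, consistent with the annotator's summit semantics.

## Differential-expression procedures

DE tables are *inputs* (produced by standard limma/DESeq-style fitting
upstream); the package implements only the procedures layered on them:

- `de_filter()`: strict inequalities, $|\log_2 FC| > 0.37$ and adjusted
  $p < 0.05$ by default. Strictness matters at the boundary and is
  pinned by tests.
- `overlap_test()`: upper-tail hypergeometric probability of at least
  the observed intersection — the standard choice for gene-set overlap,
  and exhaustively enumerable for universes $\le 15$, which is exactly
  how it is tested.
- `attenuation_slope()`: OLS of one contrast's log2 fold changes on
  another's over the shared genes (`lm`), optionally restricted to genes
  modulated in either contrast. A slope below 1 means a globally
  attenuated response.
- `extract_signature()`: filter at $p <$ cutoff (default 0.1, on
  adjusted p by default with a `p_kind = "raw"` escape hatch, since
  published pipelines are often ambiguous on this point), intersect with
  the target set, rank by p ascending with ties broken by
  $|\log_2 FC|$ descending then gene id, take the top $k$ (default 50).
  "Top ranking" without a stated metric is not reproducible; the explicit
  chain here is a documented design choice, not a claim about what any
  particular study did.

## The synthetic-data generator

The generator exists so that every estimator above can be validated
against planted truth without external downloads. Its defaults *are* the
reference study conditions used throughout the tests: one 100-Mb
chromosome, 2000 genes, 5000 anchor and 2000 cofactor peaks,
$\rho = 0.25$, offset scale 100 bp, window 1 kb, 66% active genes, 0.9
mark concordance, attenuation 0.44 with residual s.d. 0.3.

- **Annotation**: gene spans (2–20 kb) are placed uniformly without
  overlap by the stick-breaking construction (lengths drawn first, gaps
  distributed as sorted uniforms over the slack), each with 2–6 exons
  tiling the span from TSS to end; enhancers (200–1000 bp) are
  rejection-sampled into intergenic space away from default promoter
  windows, with a bounded retry budget that fails loudly as a capacity
  error.
- **Peaks**: anchor summits are uniform; a fraction $\rho$ of cofactor
  summits is planted at a distinct anchor summit plus a
  Laplace(0, scale) offset truncated at $\pm w$ by inverse-CDF sampling
  (`rlaplace_trunc`), so planted pairs are recoverable at $w$ by
  construction. The Laplace law concentrates offsets near zero — the
  shape real co-binding shows — while staying one-parameter;
  `plaplace_trunc` provides the closed-form CDF the tests compare
  against.
- **Expression/marks**: each gene is independently active with
  probability `active_fraction` (so the recovered fraction has exact
  binomial sampling error); active genes draw a log-normal value above
  the threshold, inactive ones a value below it, and marks are planted in
  promoters at the concordance probability.
- **DE tables**: wild-type fold changes are Normal(0, 1.2) with a spiked
  modulated subset ($|\log_2 FC| \ge 1$); mutant fold changes are
  `attenuation` · WT + Normal(0, `noise_sd`). Adjusted p values are rank
  maps of $|\log_2 FC|$, decreasing within the modulated group (into
  $(0, 0.05)$) and within the null group (into $[0.05, 1)$) separately.
  A single global monotone map cannot coexist with exact recoverability
  of the planted set — null genes drawn from an unbounded normal exceed
  any fold-change threshold with positive probability — so the map is
  monotone within groups, which mirrors how p values reflect evidence
  rather than fold change alone, and makes `de_filter` recover the
  planted set exactly in the noiseless limit.

Each generator draws from a private RNG stream seeded as
`seed + fixed offset` and restores the ambient RNG state, giving
stage-level, byte-identical reproducibility (asserted in the tests, and
end-to-end on the pipeline's JSON report).

**What the generator does not emulate**: read-level noise, GC and
mappability bias, peak-caller artifacts, correlated peak widths and
scores, clustered (non-uniform) binding site placement, and realistic
expression distributions. Passing recovery tests therefore shows the
estimators are correct under the planted model, not that any particular
biological dataset will behave this way.

### The chance co-localization term

With $n_A$ anchor summits uniform on a genome of length $G$, a uniform
cofactor summit has at least one anchor within $w$ with probability
$1 - e^{-n_A \cdot 2w/G}$ (Poisson approximation). The expected matched
fraction of the cofactor set is therefore

$$E[\hat f_B] \approx \rho + (1-\rho)\left(1 - e^{-n_A 2w/G}\right),$$

implemented as `expected_matched_fraction()`: only the non-planted
fraction is exposed to chance matching, which is why the chance term is
scaled by $(1-\rho)$ rather than added wholesale. Two further
approximations are worth naming. First, the Poisson rate is an
*existence* probability, while the matcher is one-to-one: when two
cofactor peaks compete for the same lone anchor, one goes unmatched. At
the reference densities this depletion is small (about 0.003 at
$\rho = 0$, against a per-replicate binomial s.e. of 0.0066) and the
tests use the binomial replicate envelope, which absorbs it. Second,
planted peaks whose anchor is stolen by a closer competitor almost always
re-match nearby, so the $\rho$ term is treated as exact.

## Numerical choices and degenerate inputs

- Coordinates are 0-based half-open everywhere inside the package; GTF's
  1-based inclusive convention is converted at the reader boundary, the
  only place $\pm 1$ arithmetic appears.
- narrowPeak summit offset $-1$ falls back to the floored interval
  midpoint.
- Duplicate peak names are auto-suffixed with a warning rather than
  rejected; readers report accepted/rejected counts and fail on
  malformed rows with the line number.
- Empty peak sets are valid inputs yielding empty results; empty
  distance CDFs and empty class distributions are flagged `NA`, never 0.
- Windows and thresholds are validated strictly positive; the
  co-localization window is inclusive at its boundary.

## Validation problem sizes

The shipped test suite validates: matching against the brute-force
oracle on 200 instances of up to 500 peaks; planted-$\rho$ recovery on
50 replicates of the 5000-vs-2000 reference simulation; the offset CDF
on 1500 planted pairs; annotation against the linear-scan oracle on 20
simulated genomes × 100 peaks; activity recovery at 2000 genes;
hypergeometric enumeration up to universe 15; slope recovery at 5000
genes; and byte-identical pipeline reports under a fixed seed. These
sizes make the whole suite run in a few minutes while keeping every
binomial envelope at 3 standard errors or tighter.

## Known limitations

- One-to-one greedy matching is maximal, not maximum-cardinality; in
  adversarial tie structures it can differ from an optimal assignment
  (the brute-force oracle shares the same greedy rule, so this is a
  definition, not a bug).
- Enhancer–gene linkage is nearest-TSS-within-radius; no contact-map or
  loop-based linking.
- The annotator is single-label by design; peaks genuinely spanning
  feature boundaries are represented by their summit class only.
- The activity cutoff and promoter window are conventions, not
  estimates; conclusions sensitive to them should be checked across a
  range of values, which the configs make cheap.
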