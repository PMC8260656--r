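# coocseq

Summit-based co-occupancy analysis of two ChIP-seq peak sets.

## The problem

When a transcription factor and a chromatin cofactor (say, an ETS factor
and a histone methyltransferase) are suspected of binding DNA together,
the genomic evidence is two independently called peak sets. This package
answers the downstream questions a regulatory-genomics analyst asks of
such a pair:

- **Where do the two factors co-occupy the genome?** Two peaks are scored
  as one co-occupied site when their summits lie within a window *w*
  (default 1 kb). Candidate same-chromosome pairs with
  |s<sub>A</sub> − s<sub>B</sub>| ≤ *w* are sorted by (distance,
  s<sub>A</sub>, s<sub>B</sub>) and accepted greedily into a one-to-one
  matching, so a single site count *m* can be expressed against both
  inputs: 100·*m*/n<sub>A</sub> and 100·*m*/n<sub>B</sub>.
- **How tight is the co-binding?** The empirical CDF of matched-summit
  distances, evaluated at thresholds such as 20, 200 and 1000 bp.
- **Which cofactor peaks are "proximal"?** A many-to-one existence
  partition (≥1 anchor summit within *w*) that splits the cofactor set
  into proximal/distal subsets ready for motif analysis.
- **What do the sites hit?** Each peak summit is assigned to exactly one
  of promoter / enhancer / exon / intron / intergenic with a signed TSS
  distance, and target genes are collected from the non-intergenic
  assignments.
- **Are the targets transcriptionally active?** Histone-mark peaks in
  promoter windows plus an expression cutoff classify each target gene as
  active or inactive.
- **What happens to the transcriptional program?** Modulated-gene
  filtering (|log2FC| > 0.37, adjusted p < 0.05, strict), hypergeometric
  overlap between gene sets, the OLS *attenuation slope* of one
  contrast's log2 fold changes on another's, and top-*k* signature
  extraction (p < 0.1 against a target set, rank by p, k = 50).

Every stage can also run on synthetic data with planted ground truth: a
generator plants a co-localization fraction ρ with truncated-Laplace
summit offsets, an active-gene fraction, mark/expression concordance and
an attenuation slope, so each estimator is validated against what was
planted.

## Worked example

The headline arithmetic on published peak counts — 3567 co-occupied sites
out of 48,274 transcription-factor and 14,780 cofactor peaks:

```r
library(coocseq)
unlist(summarize_fractions(3567, 48274, 14780))
#>   percent_a   percent_b      frac_a      frac_b
#>  7.40000000 24.10000000  0.07389071  0.24133965
```

7.4% of the factor's binding events and 24.1% of the cofactor's are
co-occupied (display values are rounded half-up to one decimal; raw
fractions are kept alongside).

A full simulated run — 5000 vs 2000 peaks on 100 Mb with ρ = 0.25,
2000 genes at 66% active, attenuation 0.44:

```r
rep <- run_pipeline(run_config(sim = sim_config(seed = 7), seed = 7))
rep
#> co-occupancy pipeline report (schema 1.0, seed 7)
#>   peaks: 5000 (A) / 2000 (B); co-occupied sites: 618 (12.4% / 30.9%)
#>   target genes: 154
#>   active targets: 105/154 (68%)
#>   attenuation slope: 0.437 over 2000 genes; signature: 24 gene(s)
```

The matched fraction of set B (0.309) sits where the planted model puts
it: ρ plus chance co-localization of the remaining peaks,
ρ + (1 − ρ)(1 − e^(−n_A·2w/G)) ≈ 0.321. Re-running with the same seed
reproduces the report byte for byte (`write_report()`).

A thin CLI over the same functions lives at `inst/cli/coocseq.R`
(subcommands `simulate`, `colocalize`, `partition`, `annotate`,
`classify`, `designature`, `run`, `report`).

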