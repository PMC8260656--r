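test_that("summit classification follows the worked promoter/exon/intron fixture", {
  ann <- toy_annotation()
  cfg <- annotation_config()
  # g1: + strand, tss 10000, exons [10000,10200) and [10800,11200),
  # promoter window [8000, 10500)
  cases <- list(
    list(summit = 9000L, feature = "promoter", tssd = -1000L),
    list(summit = 10900L, feature = "exon", tssd = 900L),
    list(summit = 10500L, feature = "intron", tssd = 500L),
    list(summit = 150000L, feature = "intergenic", tssd = NA_integer_))
  for (cs in cases) {
    got <- annotate_peak(toy_peak(cs$summit), ann, cfg)
    expect_equal(got$feature, cs$feature, info = cs$summit)
    expect_equal(got$tss_distance, cs$tssd, info = cs$summit)
  }
  # summit exactly at the TSS
  at_tss <- annotate_peak(toy_peak(10000L), ann, cfg)
  expect_equal(at_tss$feature, "promoter")
  expect_equal(at_tss$tss_distance, 0L)
})

test_that("minus-strand TSS distances are mirrored", {
  ann <- toy_annotation()
  # g2: - strand, span [60000,64000), tss 63999
  up <- annotate_peak(toy_peak(64500L), ann, annotation_config())
  expect_equal(up$feature, "promoter")
  expect_equal(up$gene_id, "g2")
  expect_equal(up$tss_distance, -501L)
  inside <- annotate_peak(toy_peak(63000L), ann, annotation_config())
  expect_equal(inside$feature, "exon")
  expect_equal(inside$tss_distance, 999L)
})

test_that("feature priority resolves summits claimed by several classes", {
  # promoter of gB overlaps an exon of gA: promoter must win
  ann <- genome_annotation(
    genes = data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                       start = c(1000, 6000), end = c(5800, 9000),
                       strand = "+"),
    exons = data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                       start = c(5000, 6000), end = c(5800, 9000)),
    chrom_sizes = c(chr1 = 20000))
  got <- annotate_peak(toy_peak(5500L), ann, annotation_config())
  expect_equal(got$feature, "promoter")
  expect_equal(got$gene_id, "gB")
  # with a priority that ranks exon first, the same summit is exonic
  cfg2 <- annotation_config(feature_priority = c("exon", "promoter",
                                                 "enhancer", "intron",
                                                 "intergenic"))
  got2 <- annotate_peak(toy_peak(5500L), ann, cfg2)
  expect_equal(got2$feature, "exon")
  expect_equal(got2$gene_id, "gA")
})

test_that("enhancer peaks link to the nearest TSS within the radius", {
  ann <- toy_annotation()  # enhancer [40000,41000); g1 tss 10000, g2 tss 63999
  got <- annotate_peak(toy_peak(40500L), ann, annotation_config())
  expect_equal(got$feature, "enhancer")
  expect_equal(got$gene_id, "g2")   # 23.5 kb beats g1's 30.5 kb
  expect_equal(got$tss_distance, 23499L)
  # radius too small for either TSS: enhancer stays unlinked
  got2 <- annotate_peak(toy_peak(40500L), ann,
                        annotation_config(enhancer_link_radius = 10000))
  expect_equal(got2$feature, "enhancer")
  expect_true(is.na(got2$gene_id))
  # a radius window excluding g2 but reaching g1 links g1 instead
  got3 <- annotate_peak(toy_peak(12000L), ann, annotation_config())
  expect_equal(got3$feature, "intergenic")  # not in any enhancer
  # target genes include the enhancer-linked gene
  expect_true("g2" %in% assign_target_genes(
    annotate_set(toy_peak(40500L), ann, annotation_config())))
})

test_that("annotate_set yields one class per peak with fractions summing to 1", {
  ann <- toy_annotation()
  peaks <- peak_set(data.frame(
    chrom = "chr1", summit = c(9000L, 10900L, 10500L, 150000L),
    start = c(8990L, 10890L, 10490L, 149990L),
    end = c(9010L, 10910L, 10510L, 150010L),
    name = paste0("p", 1:4)), "mix")
  res <- annotate_set(peaks, ann, annotation_config())
  expect_equal(unname(res$fractions[c("promoter", "exon", "intron",
                                      "intergenic")]),
               rep(0.25, 4))
  expect_equal(sum(res$fractions), 1)
  expect_setequal(names(res$counts),
                  c("promoter", "enhancer", "exon", "intron", "intergenic"))
  expect_equal(nrow(res$assignments), nrow(peaks))
})

test_that("peaks on chromosomes absent from the annotation are intergenic", {
  ann <- toy_annotation()
  got <- suppressMessages(annotate_peak(toy_peak(500L, chrom = "chrUn"),
                                        ann, annotation_config()))
  expect_equal(got$feature, "intergenic")
})

test_that("an empty peak set is flagged and yields an empty distribution", {
  expect_warning(res <- annotate_set(peak_set(data.frame(), "e"),
                                     toy_annotation()), "empty")
  expect_equal(sum(res$counts), 0L)
  expect_true(all(is.na(res$fractions)))
})

test_that("TSS-distance sign convention holds for random genes and summits", {
  set.seed(5)
  for (rep in 1:20) {
    strand <- sample(c("+", "-"), 1)
    start <- sample(20000:40000, 1)
    len <- sample(3000:8000, 1)
    ann <- genome_annotation(
      genes = data.frame(gene_id = "g", chrom = "chr1", start = start,
                         end = start + len, strand = strand),
      exons = data.frame(gene_id = "g", chrom = "chr1", start = start,
                         end = start + len),
      chrom_sizes = c(chr1 = 100000))
    tss <- if (strand == "+") start else start + len - 1L
    # a summit genuinely upstream of the TSS in gene orientation
    upstream <- if (strand == "+") tss - sample(1:1999, 1) else
      tss + sample(1:1999, 1)
    got <- annotate_peak(toy_peak(as.integer(upstream)), ann,
                         annotation_config())
    expect_true(got$tss_distance < 0)
    # and one downstream inside the gene
    downstream <- if (strand == "+") tss + sample(600:(len - 1), 1) else
      tss - sample(600:(len - 1), 1)
    got2 <- annotate_peak(toy_peak(as.integer(downstream)), ann,
                          annotation_config())
    expect_true(got2$tss_distance > 0)
  }
})

test_that("interval-tree annotation equals the linear-scan oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    cfg <- sim_config(genome_length = 2e6, n_genes = 40, n_enhancers = 15,
                      seed = seed)
    ann <- gen_annotation(cfg)
    peaks <- random_peak_set(60, genome = 2e6, chroms = "chr1",
                             label = "q")
    res <- annotate_set(peaks, ann, annotation_config())$assignments
    for (i in seq_len(nrow(res))) {
      want <- naive_annotate_one(peaks$summit[i], peaks$chrom[i], ann,
                                 annotation_config())
      expect_equal(res$feature[i], want$feature,
                   info = sprintf("seed %d peak %d", seed, i))
      expect_equal(res$gene_id[i], want$gene_id,
                   info = sprintf("seed %d peak %d", seed, i))
      expect_equal(res$tss_distance[i],
                   as.integer(want$tss_distance),
                   info = sprintf("seed %d peak %d", seed, i))
    }
  }
})

test_that("assign_target_genes deduplicates genes across assignments", {
  ann <- toy_annotation()
  peaks <- peak_set(data.frame(chrom = "chr1",
                               summit = c(9000L, 10500L),
                               start = c(8990L, 10490L),
                               end = c(9010L, 10510L),
                               name = c("p1", "p2")), "two")
  tg <- assign_target_genes(annotate_set(peaks, ann))
  expect_equal(tg, "g1")
  expect_length(assign_target_genes(
    suppressWarnings(annotate_set(peak_set(data.frame(), "e"),
                                  ann))), 0)
})
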