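test_that("every generator is byte-deterministic under a fixed seed", {
  cfg <- sim_config(genome_length = 5e6, n_genes = 80, n_enhancers = 20,
                    n_peaks_a = 300, n_peaks_b = 150, seed = 17)
  a1 <- gen_annotation(cfg); a2 <- gen_annotation(cfg)
  expect_identical(a1, a2)
  p1 <- gen_cooccupancy_peaks(cfg, a1); p2 <- gen_cooccupancy_peaks(cfg, a2)
  expect_identical(p1, p2)
  e1 <- gen_expression(cfg, a1); e2 <- gen_expression(cfg, a1)
  expect_identical(e1, e2)
  d1 <- gen_de_tables(cfg, a1); d2 <- gen_de_tables(cfg, a1)
  expect_identical(d1, d2)
  # generators draw from private streams: ambient RNG state is untouched
  set.seed(1); before <- .Random.seed
  invisible(gen_annotation(cfg))
  expect_identical(.Random.seed, before)
})

test_that("generated gene spans never overlap (brute-force check)", {
  cfg <- sim_config(genome_length = 1e7, n_genes = 100, n_enhancers = 0,
                    seed = 3)
  ann <- gen_annotation(cfg)
  expect_equal(nrow(ann$genes), 100)
  g <- ann$genes
  for (ch in unique(g$chrom)) {
    gg <- g[g$chrom == ch, ]
    n <- nrow(gg)
    if (n < 2) next
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        expect_true(gg$end[i] <= gg$start[j] || gg$end[j] <= gg$start[i],
                    label = sprintf("genes %d/%d on %s", i, j, ch))
      }
    }
  }
  # exon structure: 2-6 exons per gene, sorted, inside the span
  counts <- table(ann$exons$gene_id)
  expect_true(all(counts >= 2 & counts <= 6))
})

test_that("annotation generation respects feature count edge cases", {
  cfg0 <- sim_config(n_genes = 0, n_enhancers = 25, genome_length = 1e6,
                     seed = 4)
  ann0 <- gen_annotation(cfg0)
  expect_equal(nrow(ann0$genes), 0)
  expect_equal(nrow(ann0$enhancers), 25)
  expect_error(gen_annotation(sim_config(genome_length = 5e4, n_genes = 50,
                                         seed = 1)),
               "capacity")
})

test_that("enhancers never overlap gene spans or default promoter windows", {
  cfg <- sim_config(genome_length = 5e6, n_genes = 60, n_enhancers = 40,
                    seed = 9)
  ann <- gen_annotation(cfg)
  proms <- coocseq:::promoter_windows(ann$genes, annotation_config())
  for (i in seq_len(nrow(ann$enhancers))) {
    e <- ann$enhancers[i, ]
    g <- ann$genes[ann$genes$chrom == e$chrom, ]
    expect_false(any(e$start < g$end & g$start < e$end),
                 label = sprintf("enhancer %d vs gene spans", i))
    pr <- proms[proms$chrom == e$chrom, ]
    expect_false(any(e$start <= pr$pend & pr$pstart < e$end),
                 label = sprintf("enhancer %d vs promoters", i))
  }
})

test_that("rho = 1 with a vanishing offset scale collapses B onto A summits", {
  cfg <- sim_config(genome_length = 1e7, n_genes = 0, n_enhancers = 0,
                    n_peaks_a = 200, n_peaks_b = 100, rho = 1,
                    offset_scale = 1e-9, seed = 6)
  pk <- gen_cooccupancy_peaks(cfg, gen_annotation(cfg))
  a_summits <- paste(pk$set_a$chrom, pk$set_a$summit)
  expect_true(all(paste(pk$set_b$chrom, pk$set_b$summit) %in% a_summits))
  expect_equal(nrow(pk$planted_pairs), 100)
  expect_true(all(pk$planted_pairs$offset == 0))
})

test_that("planted pairs are always recoverable by colocalize at the window", {
  cfg <- sim_config(genome_length = 2e7, n_genes = 0, n_enhancers = 0,
                    n_peaks_a = 800, n_peaks_b = 400, rho = 0.4, seed = 12)
  pk <- gen_cooccupancy_peaks(cfg, gen_annotation(cfg))
  expect_true(all(abs(pk$planted_pairs$offset) <= cfg$window))
  # every planted B peak has an anchor within the window (truncation
  # guarantee), so the planted structure is recoverable at that window
  pp <- partition_proximal(pk$set_b, pk$set_a, cfg$window)
  expect_true(all(pk$planted_pairs$name_b %in% pp$proximal$name))
  # and the one-to-one matcher finds at least the planted mass
  r <- colocalize(pk$set_a, pk$set_b, cfg$window)
  expect_gte(nrow(r$sites), nrow(pk$planted_pairs))
})

test_that("expression generator honors degenerate activity fractions", {
  cfg <- sim_config(genome_length = 1e7, n_genes = 150, n_enhancers = 0,
                    active_fraction = 1, seed = 5)
  ann <- gen_annotation(cfg)
  ex <- gen_expression(cfg, ann)
  rep <- classify_activity(ann$genes$gene_id, ex$expression,
                           cfg$expr_threshold)
  expect_equal(rep$fraction_active, 1)
  cfg0 <- sim_config(genome_length = 1e7, n_genes = 150, n_enhancers = 0,
                     active_fraction = 0, seed = 5)
  ex0 <- gen_expression(cfg0, ann)
  rep0 <- classify_activity(ann$genes$gene_id, ex0$expression,
                            cfg0$expr_threshold)
  expect_equal(rep0$fraction_active, 0)
})

test_that("noiseless DE tables are identical at attenuation 1 and exactly recoverable", {
  cfg <- sim_config(genome_length = 2e7, n_genes = 400, n_enhancers = 0,
                    attenuation = 1, noise_sd = 0, seed = 8)
  ann <- gen_annotation(cfg)
  de <- gen_de_tables(cfg, ann)
  expect_equal(de$wt$log2fc, de$mut$log2fc)
  f <- de_filter(de$wt, 0.37, 0.05)
  expect_setequal(c(f$up, f$down), de$modulated)
  expect_equal(length(f$up) + length(f$down), length(de$modulated))
})

test_that("sim_config validates its parameter ranges", {
  expect_error(sim_config(rho = 1.2), "rho")
  expect_error(sim_config(offset_scale = 0), "offset_scale")
  expect_error(sim_config(active_fraction = -0.1), "active_fraction")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
})

test_that("truncated-Laplace sampler matches its CDF", {
  set.seed(13)
  x <- rlaplace_trunc(20000, scale = 100, trunc = 1000)
  expect_true(all(abs(x) <= 1000))
  for (q in c(-500, -100, 0, 50, 200, 800)) {
    emp <- mean(x <= q)
    expect_lt(abs(emp - plaplace_trunc(q, 100, 1000)),
              3 * sqrt(0.25 / 20000) + 0.005)
  }
})

test_that("simulate_dataset writes files the readers load back faithfully", {
  cfg <- sim_config(genome_length = 5e6, n_genes = 60, n_enhancers = 10,
                    n_peaks_a = 120, n_peaks_b = 60, seed = 14)
  dir <- withr::local_tempdir()
  dat <- simulate_dataset(cfg, out_dir = dir)
  back_a <- suppressMessages(read_narrowpeak(dat$files$peaks_a, label = "A"))
  expect_equal(back_a$summit, dat$peaks$set_a$summit)
  expect_equal(back_a$score, dat$peaks$set_a$score)
  back_ann <- suppressMessages(
    read_gene_annotation(dat$files$genes, "tsv",
                         chrom_sizes = dat$annotation$chrom_sizes))
  expect_equal(back_ann$genes, dat$annotation$genes)
  expect_equal(read_expression(dat$files$expression),
               dat$expression$expression)
  expect_equal(read_de_table(dat$files$de_wt)$log2fc, dat$de$wt$log2fc)
})
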