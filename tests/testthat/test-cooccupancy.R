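make_summit_set <- function(summits, label, chrom = "chr1") {
  peak_set(data.frame(chrom = chrom, start = summits - 50L,
                      end = summits + 50L, summit = summits,
                      name = sprintf("%s%d", label, seq_along(summits))),
           label = label)
}

test_that("colocalize matches the worked five-vs-four summit fixture", {
  a <- make_summit_set(c(100L, 5000L, 10000L, 20000L, 30000L), "A")
  b <- make_summit_set(c(900L, 5100L, 19000L, 32000L), "B")
  r <- colocalize(a, b, window = 1000)
  expect_s3_class(r, "cooccupancy")
  expect_equal(nrow(r$sites), 3)
  expect_setequal(r$sites$distance, c(800, 100, 1000))
  # 30000 vs 32000 is 2000 bp apart: both unmatched
  expect_false("A5" %in% r$sites$name_a)
  expect_false("B4" %in% r$sites$name_b)
  expect_equal(r$frac_a, 3 / 5)
  expect_equal(r$frac_b, 3 / 4)
})

test_that("a set matched against itself self-matches at distance zero", {
  set.seed(3)
  a <- random_peak_set(40, genome = 20000)
  r <- colocalize(a, a, window = 1000)
  expect_equal(nrow(r$sites), nrow(a))
  expect_true(all(r$sites$distance == 0))
  expect_equal(r$sites$name_a, r$sites$name_b)
})

test_that("the matching window is inclusive at exactly its boundary", {
  a <- make_summit_set(5000L, "A")
  b <- make_summit_set(6000L, "B")
  expect_equal(nrow(colocalize(a, b, 1000)$sites), 1)
  b2 <- make_summit_set(6001L, "B")
  expect_equal(nrow(colocalize(a, b2, 1000)$sites), 0)
})

test_that("sweep matching equals the brute-force greedy oracle on random instances", {
  for (seed in 0:4) {
    set.seed(seed)
    for (rep in 1:3) {
      a <- random_peak_set(sample(5:120, 1), genome = 20000, label = "a")
      b <- random_peak_set(sample(5:120, 1), genome = 20000, label = "b")
      w <- sample(c(100, 500, 1000), 1)
      got <- colocalize(a, b, w)$sites
      want <- brute_colocalize(a, b, w)
      expect_equal(got, want, info = sprintf("seed %d rep %d", seed, rep))
    }
  }
})

test_that("empty and chromosome-disjoint inputs give valid empty results", {
  a <- make_summit_set(100L, "A")
  empty <- peak_set(data.frame(), "E")
  r <- colocalize(a, empty, 1000)
  expect_equal(nrow(r$sites), 0)
  expect_equal(r$n_b, 0)
  b <- make_summit_set(100L, "B", chrom = "chr9")
  expect_equal(nrow(suppressMessages(colocalize(a, b, 1000))$sites), 0)
})

test_that("distance_fractions is a CDF evaluated at the thresholds", {
  a <- make_summit_set(c(100L, 5000L, 10000L, 20000L, 30000L), "A")
  b <- make_summit_set(c(900L, 5100L, 19000L, 32000L), "B")
  r <- colocalize(a, b, 1000)
  cdf <- distance_fractions(r, c(200, 1000))
  expect_equal(unname(cdf), c(1 / 3, 1))
  # monotone and capped at 1 on random instances
  set.seed(11)
  x <- random_peak_set(150, genome = 30000, label = "x")
  y <- random_peak_set(150, genome = 30000, label = "y")
  rr <- colocalize(x, y, 1000)
  cc <- distance_fractions(rr, c(10, 50, 200, 500, 1000))
  expect_true(all(diff(cc) >= 0))
  expect_equal(unname(cc[length(cc)]), 1)
  # degenerate all-zero distances
  z <- colocalize(x, x, 1000)
  expect_true(all(distance_fractions(z, c(20, 200)) == 1))
})

test_that("distance_fractions flags an empty result as undefined, not zero", {
  a <- make_summit_set(100L, "A")
  b <- make_summit_set(90000L, "B")
  r <- colocalize(a, b, 1000)
  expect_warning(cdf <- distance_fractions(r, c(200, 1000)), "undefined")
  expect_true(all(is.na(cdf)))
})

test_that("summarize_fractions rounds half-up to one decimal for reporting", {
  expect_equal(summarize_fractions(3, 5, 4)[c("percent_a", "percent_b")],
               list(percent_a = 60.0, percent_b = 75.0))
  expect_equal(summarize_fractions(7, 7, 7)$percent_a, 100.0)
  # half-up at the rounding boundary (0.05 -> 0.1)
  expect_equal(summarize_fractions(1, 2000, 2000)$percent_a, 0.1)
  expect_error(summarize_fractions(1, 0, 5), "positive")
  expect_error(summarize_fractions(6, 5, 5), "n_matched")
})

test_that("partition_proximal is a many-to-one existence partition", {
  anchor <- make_summit_set(c(100L, 5000L, 10000L, 20000L, 30000L), "A")
  cof <- make_summit_set(c(900L, 5100L, 19000L, 32000L), "B")
  p <- partition_proximal(cof, anchor, 1000)
  expect_setequal(p$proximal$summit, c(900, 5100, 19000))
  expect_equal(p$distal$summit, 32000)
  # empty anchor: everything distal
  p0 <- partition_proximal(cof, peak_set(data.frame(), "E"), 1000)
  expect_equal(nrow(p0$proximal), 0)
  expect_equal(nrow(p0$distal), nrow(cof))
  # partition property on random input, and many-to-one vs one-to-one
  set.seed(21)
  co <- random_peak_set(200, genome = 40000, label = "c")
  an <- random_peak_set(30, genome = 40000, label = "n")
  pp <- partition_proximal(co, an, 1000)
  expect_equal(nrow(pp$proximal) + nrow(pp$distal), nrow(co))
  expect_length(intersect(pp$proximal$name, pp$distal$name), 0)
  expect_gte(nrow(pp$proximal), nrow(colocalize(an, co, 1000)$sites))
})

test_that("peak_gene_overlap reports Venn-style counts and coverage fractions", {
  ov <- peak_gene_overlap(list(X = c("a", "b", "c", "d", "e"),
                               Y = c("c", "d", "e", "f")))
  expect_equal(ov$pairs$intersection, 3)
  expect_equal(ov$pairs$frac1, 0.6)
  expect_equal(ov$pairs$frac2, 0.75)
  same <- peak_gene_overlap(list(A = letters[1:4], B = letters[1:4]))
  expect_equal(same$pairs$frac1, 1)
  disj <- peak_gene_overlap(list(A = c("a"), B = c("b")))
  expect_equal(disj$pairs$intersection, 0)
  three <- peak_gene_overlap(list(A = c("a", "b", "c"), B = c("b", "c", "d"),
                                  C = c("c", "d", "e")))
  expect_equal(three$triple, 1)
  expect_equal(nrow(three$pairs), 3)
})
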