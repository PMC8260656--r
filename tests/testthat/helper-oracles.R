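# Independent oracles and fixture builders used across the suite.

# O(n^2) brute-force greedy matcher: enumerate ALL same-chromosome pairs
# with |summit_a - summit_b| <= window, order by (distance, summit_a,
# summit_b), accept greedily while both peaks are free.  Returns the
# accepted pair table, ordered like colocalize()'s sites.
brute_colocalize <- function(set_a, set_b, window) {
  a <- as.data.frame(set_a)
  b <- as.data.frame(set_b)
  rows <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          abs(a$summit[i] - b$summit[j]) <= window) {
        rows[[length(rows) + 1]] <- data.frame(
          ia = i, ib = j, summit_a = a$summit[i], summit_b = b$summit[j],
          distance = abs(a$summit[i] - b$summit[j]))
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(chrom = character(), name_a = character(),
                      name_b = character(), summit_a = integer(),
                      summit_b = integer(), distance = integer(),
                      stringsAsFactors = FALSE))
  }
  cand <- do.call(rbind, rows)
  cand <- cand[order(cand$distance, cand$summit_a, cand$summit_b), ,
               drop = FALSE]
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!used_a[cand$ia[k]] && !used_b[cand$ib[k]]) {
      used_a[cand$ia[k]] <- TRUE; used_b[cand$ib[k]] <- TRUE
      keep[k] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  out <- data.frame(chrom = a$chrom[cand$ia], name_a = a$name[cand$ia],
                    name_b = b$name[cand$ib], summit_a = cand$summit_a,
                    summit_b = cand$summit_b, distance = cand$distance,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$summit_a, out$summit_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Naive linear-scan annotator: classify one summit by scanning every
# feature, applying the documented rules directly (no index structures).
naive_annotate_one <- function(summit, chrom, ann, cfg) {
  cand <- list()
  g <- ann$genes
  for (i in seq_len(nrow(g))) {
    if (g$chrom[i] != chrom) next
    d <- if (g$strand[i] == "+") summit - g$tss[i] else g$tss[i] - summit
    if (d >= -cfg$promoter_up && d < cfg$promoter_down) {
      cand[[length(cand) + 1]] <- list(feature = "promoter",
                                       gene_id = g$gene_id[i],
                                       tss_distance = d)
    }
    if (summit >= g$start[i] && summit < g$end[i]) {
      ex <- ann$exons[ann$exons$gene_id == g$gene_id[i], , drop = FALSE]
      inex <- any(summit >= ex$start & summit < ex$end)
      cand[[length(cand) + 1]] <- list(
        feature = if (inex) "exon" else "intron",
        gene_id = g$gene_id[i], tss_distance = d)
    }
  }
  enh <- ann$enhancers
  in_enh <- any(enh$chrom == chrom & summit >= enh$start & summit < enh$end)
  if (in_enh) {
    best <- NA_character_; bestd <- Inf; bestsigned <- NA_integer_
    for (i in seq_len(nrow(g))) {
      if (g$chrom[i] != chrom) next
      ad <- abs(summit - g$tss[i])
      if (ad < bestd || (ad == bestd && !is.na(best) && g$gene_id[i] < best)) {
        bestd <- ad; best <- g$gene_id[i]
        bestsigned <- if (g$strand[i] == "+") summit - g$tss[i] else
          g$tss[i] - summit
      }
    }
    if (is.infinite(bestd) || bestd > cfg$enhancer_link_radius) {
      best <- NA_character_; bestsigned <- NA_integer_
    }
    cand[[length(cand) + 1]] <- list(feature = "enhancer", gene_id = best,
                                     tss_distance = bestsigned)
  }
  if (length(cand) == 0) {
    return(list(feature = "intergenic", gene_id = NA_character_,
                tss_distance = NA_integer_))
  }
  prio <- match(vapply(cand, `[[`, "", "feature"), cfg$feature_priority)
  absd <- vapply(cand, function(x) abs(as.numeric(x$tss_distance %||% NA)),
                 numeric(1))
  gid <- vapply(cand, function(x) as.character(x$gene_id %||% NA), "")
  ord <- order(prio, absd, gid, na.last = TRUE)
  cand[[ord[1]]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive hypergeometric upper tail: probability that a uniformly drawn
# size-|set2| subset of 1..universe intersects a fixed size-|set1| subset
# in at least k elements.  Enumerates all C(universe, n2) draws.
enum_overlap_p <- function(n1, n2, k, universe) {
  draws <- utils::combn(universe, n2)
  hits <- colSums(draws <= n1)   # fixed set = 1..n1
  mean(hits >= k)
}

# Random peak set on a small genome (forces collisions and ties).
random_peak_set <- function(n, genome = 50000, chroms = c("chr1", "chr2"),
                            label = "rnd") {
  ch <- sample(chroms, n, replace = TRUE)
  s <- sample.int(genome, n, replace = TRUE) - 1L
  peak_set(data.frame(chrom = ch, start = pmax(0L, s - 50L),
                      end = s + 50L, summit = s,
                      name = sprintf("%s_%d", label, seq_len(n)),
                      score = round(runif(n, 0, 10), 2)),
           label = label)
}

# Hand-constructed annotation: one + strand gene with the worked-example
# geometry, one - strand gene, and one enhancer 30 kb from gene g1.
toy_annotation <- function() {
  genome_annotation(
    genes = data.frame(gene_id = c("g1", "g2"),
                       chrom = c("chr1", "chr1"),
                       start = c(10000, 60000), end = c(11200, 64000),
                       strand = c("+", "-")),
    exons = data.frame(gene_id = c("g1", "g1", "g2", "g2"),
                       chrom = "chr1",
                       start = c(10000, 10800, 60000, 63000),
                       end = c(10200, 11200, 60500, 64000)),
    enhancers = data.frame(chrom = "chr1", start = 40000, end = 41000),
    chrom_sizes = c(chr1 = 200000, chr2 = 100000))
}

toy_peak <- function(summit, chrom = "chr1", name = "p1") {
  peak_set(data.frame(chrom = chrom, start = summit - 10L,
                      end = summit + 10L, summit = summit, name = name),
           label = "toy")
}
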