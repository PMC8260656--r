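#' Annotate a peak set against a genome annotation
#'
#' Re-implementation of a summit-based peak annotator: each peak is
#' classified by its summit position into exactly one of five feature
#' classes (promoter, enhancer, exon, intron, intergenic).  Candidate
#' classes are collected from all features overlapping the summit, then
#' resolved by the configured priority order; ties within a class go to the
#' gene with the smallest absolute TSS distance, then lexicographic
#' `gene_id`.  The signed TSS distance is reported in gene orientation
#' (negative = upstream of the TSS).  Overlap lookups run on IRanges
#' interval trees per chromosome.
#'
#' @param peaks a [peak_set()].
#' @param ann a [genome_annotation()].
#' @param cfg an [annotation_config()].
#' @return an object of class `peak_annotation`: list with `assignments`
#'   (data.frame `peak_name`, `feature`, `gene_id`, `tss_distance`),
#'   `counts` and `fractions` (named over the five classes, fractions sum
#'   to 1 for non-empty input).
#' @export
annotate_set <- function(peaks, ann, cfg = annotation_config()) {
  stopifnot(inherits(ann, "genome_annotation"),
            inherits(cfg, "annotation_config"))
  df <- as.data.frame(peaks)
  classes <- c("promoter", "enhancer", "exon", "intron", "intergenic")
  if (nrow(df) == 0) {
    warning("empty peak set: empty annotation distribution")
    assignments <- data.frame(peak_name = character(), feature = character(),
                              gene_id = character(),
                              tss_distance = integer(),
                              stringsAsFactors = FALSE)
    counts <- stats::setNames(rep(0L, 5), classes)
    return(structure(list(assignments = assignments, counts = counts,
                          fractions = stats::setNames(rep(NA_real_, 5),
                                                      classes)),
                     class = "peak_annotation"))
  }
  unknown <- setdiff(unique(df$chrom), names(ann$chrom_sizes))
  if (length(unknown) > 0) {
    coc_log("annotate_set: ", length(unknown),
            " chromosome(s) absent from annotation; peaks there are intergenic")
  }
  cand <- candidate_features(df, ann, cfg)
  prio <- match(cand$feature, cfg$feature_priority)
  ord <- order(cand$peak_idx, prio, abs(cand$tss_distance), cand$gene_id,
               na.last = TRUE)
  cand <- cand[ord, , drop = FALSE]
  first <- cand[!duplicated(cand$peak_idx), , drop = FALSE]
  feature <- rep("intergenic", nrow(df))
  gene_id <- rep(NA_character_, nrow(df))
  tssd <- rep(NA_integer_, nrow(df))
  feature[first$peak_idx] <- first$feature
  gene_id[first$peak_idx] <- first$gene_id
  tssd[first$peak_idx] <- first$tss_distance
  assignments <- data.frame(peak_name = df$name, feature = feature,
                            gene_id = gene_id, tss_distance = tssd,
                            stringsAsFactors = FALSE)
  counts <- stats::setNames(
    vapply(classes, function(cl) sum(feature == cl), integer(1)), classes)
  structure(list(assignments = assignments, counts = counts,
                 fractions = counts / nrow(df)),
            class = "peak_annotation")
}

# Internal: all (peak, feature-class, gene) candidates whose feature
# overlaps the peak summit.  Uses IRanges overlap per chromosome.
candidate_features <- function(df, ann, cfg) {
  genes <- ann$genes
  proms <- promoter_windows(genes, cfg)
  res <- list()
  add <- function(peak_idx, feature, gene_id, tssd) {
    if (length(peak_idx) > 0) {
      res[[length(res) + 1]] <<- data.frame(
        peak_idx = peak_idx, feature = feature, gene_id = gene_id,
        tss_distance = as.integer(tssd), stringsAsFactors = FALSE)
    }
  }
  for (ch in unique(df$chrom)) {
    ip <- which(df$chrom == ch)
    pts <- IRanges::IRanges(start = df$summit[ip], width = 1L)
    # promoters
    ig <- which(proms$chrom == ch)
    if (length(ig) > 0) {
      h <- IRanges::findOverlaps(pts, IRanges::IRanges(proms$pstart[ig],
                                                       proms$pend[ig]))
      q <- ip[S4Vectors::queryHits(h)]
      g <- ig[S4Vectors::subjectHits(h)]
      add(q, "promoter", genes$gene_id[g],
          signed_tss_distance(df$summit[q], genes$tss[g], genes$strand[g]))
    }
    # exons (end exclusive -> closed end is end-1)
    ie <- which(ann$exons$chrom == ch)
    if (length(ie) > 0) {
      h <- IRanges::findOverlaps(pts,
                                 IRanges::IRanges(ann$exons$start[ie],
                                                  ann$exons$end[ie] - 1L))
      q <- ip[S4Vectors::queryHits(h)]
      g <- match(ann$exons$gene_id[ie[S4Vectors::subjectHits(h)]],
                 genes$gene_id)
      add(q, "exon", genes$gene_id[g],
          signed_tss_distance(df$summit[q], genes$tss[g], genes$strand[g]))
    }
    # gene bodies -> intron candidates (summit in span; priority resolution
    # drops them whenever an exon candidate exists for the same gene, since
    # exon outranks intron in any sane priority)
    ig <- which(genes$chrom == ch)
    if (length(ig) > 0) {
      h <- IRanges::findOverlaps(pts, IRanges::IRanges(genes$start[ig],
                                                       genes$end[ig] - 1L))
      q <- ip[S4Vectors::queryHits(h)]
      g <- ig[S4Vectors::subjectHits(h)]
      # exclude (peak, gene) pairs where the summit is exonic for that gene
      exo <- paste(df$name[q], genes$gene_id[g]) %in% {
        ie <- which(ann$exons$chrom == ch)
        if (length(ie) > 0) {
          hh <- IRanges::findOverlaps(pts,
                                      IRanges::IRanges(ann$exons$start[ie],
                                                       ann$exons$end[ie] - 1L))
          paste(df$name[ip[S4Vectors::queryHits(hh)]],
                ann$exons$gene_id[ie[S4Vectors::subjectHits(hh)]])
        } else character()
      }
      q <- q[!exo]; g <- g[!exo]
      add(q, "intron", genes$gene_id[g],
          signed_tss_distance(df$summit[q], genes$tss[g], genes$strand[g]))
    }
    # enhancers: linked to the nearest TSS within the link radius
    ien <- which(ann$enhancers$chrom == ch)
    if (length(ien) > 0) {
      h <- IRanges::findOverlaps(pts,
                                 IRanges::IRanges(ann$enhancers$start[ien],
                                                  ann$enhancers$end[ien] - 1L))
      q <- unique(ip[S4Vectors::queryHits(h)])
      if (length(q) > 0) {
        link <- nearest_tss(df$summit[q], ch, genes, cfg$enhancer_link_radius)
        add(q, "enhancer", link$gene_id, link$tss_distance)
      }
    }
  }
  if (length(res) == 0) {
    return(data.frame(peak_idx = integer(), feature = character(),
                      gene_id = character(), tss_distance = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, res)
}

# Internal: nearest gene TSS (by absolute distance) within radius, on one
# chromosome.  Returns gene_id (NA when none in radius) and the signed TSS
# distance in gene orientation.
nearest_tss <- function(summits, chrom, genes, radius) {
  ig <- which(genes$chrom == chrom)
  n <- length(summits)
  out <- list(gene_id = rep(NA_character_, n),
              tss_distance = rep(NA_integer_, n))
  if (length(ig) == 0) return(out)
  ordg <- ig[order(genes$tss[ig], genes$gene_id[ig])]
  tss <- genes$tss[ordg]
  for (k in seq_len(n)) {
    s <- summits[k]
    j <- findInterval(s, tss)
    best <- NA_integer_; bestd <- Inf
    for (jj in c(j, j + 1L)) {
      if (jj >= 1 && jj <= length(tss)) {
        d <- abs(s - tss[jj])
        if (d < bestd || (d == bestd && !is.na(best) &&
                          genes$gene_id[ordg[jj]] < genes$gene_id[best])) {
          best <- ordg[jj]; bestd <- d
        }
      }
    }
    if (!is.na(best) && bestd <= radius) {
      out$gene_id[k] <- genes$gene_id[best]
      out$tss_distance[k] <- signed_tss_distance(s, genes$tss[best],
                                                 genes$strand[best])
    }
  }
  out
}

#' Annotate a single peak
#'
#' Convenience wrapper over [annotate_set()] for one peak.
#'
#' @param peak a one-row [peak_set()] (or a peak set; the first peak is
#'   used).
#' @inheritParams annotate_set
#' @return one-row data.frame `peak_name`, `feature`, `gene_id`,
#'   `tss_distance`.
#' @export
annotate_peak <- function(peak, ann, cfg = annotation_config()) {
  df <- as.data.frame(peak)
  res <- annotate_set(peak_set(df[1, , drop = FALSE],
                               label = set_label(peak)), ann, cfg)
  res$assignments
}

#' @export
print.peak_annotation <- function(x, ...) {
  cat("peak_annotation:", nrow(x$assignments), "peak(s)\n")
  if (nrow(x$assignments) > 0) {
    for (cl in names(x$counts)) {
      cat(sprintf("  %-10s %6d  (%.1f%%)\n", cl, x$counts[[cl]],
                  100 * x$fractions[[cl]]))
    }
  }
  invisible(x)
}

#' @export
plot.peak_annotation <- function(x, ...) {
  graphics::barplot(x$fractions, ylab = "fraction of peaks",
                    main = "Feature class distribution", col = "grey70", ...)
  invisible(x)
}

#' Target genes of an annotated peak set
#'
#' Distinct genes with at least one non-intergenic peak assignment
#' (promoter, exon, intron, or a gene-linked enhancer).
#'
#' @param annotation a [annotate_set()] result, or its `assignments`
#'   data.frame.
#' @return sorted character vector of gene ids.
#' @export
assign_target_genes <- function(annotation) {
  a <- if (inherits(annotation, "peak_annotation")) annotation$assignments
  else annotation
  need_cols(a, c("feature", "gene_id"), "assignments")
  sort(unique(a$gene_id[a$feature != "intergenic" & !is.na(a$gene_id)]))
}
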