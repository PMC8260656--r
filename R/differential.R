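#' Filter a differential-expression table into modulated gene sets
#'
#' Applies the conventional fold-change + significance filter with strict
#' inequalities: up = `log2fc > lfc_min` and `adj_p < p_max`; down =
#' `log2fc < -lfc_min` and `adj_p < p_max`.  Boundary values are excluded
#' on both axes.
#'
#' @param table data.frame with columns `gene_id`, `log2fc`, `adj_p`.
#' @param lfc_min minimum absolute log2 fold change (default 0.37).
#' @param p_max maximum adjusted p (default 0.05).
#' @return list with character vectors `up` and `down` (disjoint).
#' @examples
#' tab <- data.frame(gene_id = c("g1", "g2"), log2fc = c(0.5, 0.37),
#'                   adj_p = c(0.01, 0.01))
#' de_filter(tab)  # g2 excluded: the 0.37 boundary is strict
#' @export
de_filter <- function(table, lfc_min = 0.37, p_max = 0.05) {
  if (lfc_min <= 0 || p_max <= 0) stop("thresholds must be positive")
  if (nrow(table) == 0) return(list(up = character(), down = character()))
  need_cols(table, c("gene_id", "log2fc", "adj_p"), "DE table")
  sig <- table$adj_p < p_max
  list(up = as.character(table$gene_id[sig & table$log2fc > lfc_min]),
       down = as.character(table$gene_id[sig & table$log2fc < -lfc_min]))
}

#' Hypergeometric gene-set overlap test
#'
#' Upper-tail hypergeometric probability of observing at least the given
#' intersection between two gene sets drawn from a finite universe — the
#' standard significance test for Venn-style overlaps.
#'
#' @param set1,set2 character vectors of gene ids (deduplicated).
#' @param universe size of the gene universe (must be at least
#'   `|set1 U set2|`).
#' @return list with `intersection` (count) and `p` (upper-tail
#'   probability, includes the observed count).
#' @export
overlap_test <- function(set1, set2, universe) {
  set1 <- unique(as.character(set1))
  set2 <- unique(as.character(set2))
  if (universe < length(union(set1, set2))) {
    stop("universe smaller than the union of the two sets")
  }
  k <- length(intersect(set1, set2))
  p <- stats::phyper(k - 1, length(set1), universe - length(set1),
                     length(set2), lower.tail = FALSE)
  list(intersection = k, p = p)
}

#' Attenuation slope between two differential-expression contrasts
#'
#' Ordinary-least-squares regression of one contrast's log2 fold changes on
#' another's, over the genes present in both tables.  A slope below 1
#' indicates a globally attenuated transcriptional response (e.g. a
#' methylation-defective mutant versus the wild-type factor).
#'
#' @param wt,mut data.frames with columns `gene_id`, `log2fc` (and
#'   `adj_p` when `modulated_only = TRUE`).
#' @param modulated_only restrict to genes modulated in either table at
#'   (`lfc_min`, `p_max`) before fitting (default FALSE).
#' @param lfc_min,p_max thresholds for `modulated_only`.
#' @return list with `slope`, `intercept`, `n` (genes used) and the
#'   underlying `lm` fit.
#' @export
attenuation_slope <- function(wt, mut, modulated_only = FALSE,
                              lfc_min = 0.37, p_max = 0.05) {
  need_cols(wt, c("gene_id", "log2fc"), "WT DE table")
  need_cols(mut, c("gene_id", "log2fc"), "mutant DE table")
  shared <- intersect(wt$gene_id, mut$gene_id)
  if (modulated_only) {
    mod <- union(unlist(de_filter(wt, lfc_min, p_max)),
                 unlist(de_filter(mut, lfc_min, p_max)))
    shared <- intersect(shared, mod)
  }
  if (length(shared) < 3) stop("fewer than 3 shared genes between tables")
  x <- wt$log2fc[match(shared, wt$gene_id)]
  y <- mut$log2fc[match(shared, mut$gene_id)]
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = length(shared), fit = fit)
}

#' Extract a top-k co-regulated gene signature
#'
#' Filters a cohort differential-expression table at a p cutoff, intersects
#' it with a target gene set (e.g. co-occupied genes), ranks by p ascending
#' (ties by `|log2fc|` descending, then `gene_id`) and keeps the top `k`.
#' When fewer than `k` genes survive, all survivors are returned with a
#' warning.
#'
#' @param cohort_de data.frame with columns `gene_id`, `log2fc`, `adj_p`
#'   (and `p` when `p_kind = "raw"`).
#' @param target_set character vector of gene ids.
#' @param p_cutoff p threshold, strict (default 0.1).
#' @param k signature size (default 50).
#' @param p_kind which p column to filter and rank on: `"adjusted"`
#'   (default) or `"raw"`.
#' @return an object of class `de_signature`: list with `genes`
#'   (data.frame `gene_id`, `log2fc`, `p`, `direction`), `k` and
#'   `provenance` (thresholds and source-set sizes).
#' @export
extract_signature <- function(cohort_de, target_set, p_cutoff = 0.1, k = 50,
                              p_kind = c("adjusted", "raw")) {
  p_kind <- match.arg(p_kind)
  if (p_cutoff <= 0 || p_cutoff > 1) stop("p_cutoff must be in (0, 1]")
  if (k <= 0) stop("k must be positive")
  need_cols(cohort_de, c("gene_id", "log2fc"), "cohort DE table")
  pcol <- if (p_kind == "adjusted") "adj_p" else "p"
  if (!pcol %in% names(cohort_de)) {
    stop("cohort DE table lacks the '", pcol, "' column required for p_kind='",
         p_kind, "'")
  }
  target_set <- unique(as.character(target_set))
  keep <- cohort_de[[pcol]] < p_cutoff & cohort_de$gene_id %in% target_set
  surv <- cohort_de[keep, , drop = FALSE]
  ord <- order(surv[[pcol]], -abs(surv$log2fc), surv$gene_id)
  surv <- surv[ord, , drop = FALSE]
  if (nrow(surv) < k) {
    warning("only ", nrow(surv), " gene(s) survive the cutoff; signature ",
            "shorter than k = ", k)
  }
  top <- utils::head(surv, k)
  genes <- data.frame(gene_id = as.character(top$gene_id),
                      log2fc = top$log2fc,
                      p = top[[pcol]],
                      direction = ifelse(top$log2fc > 0, "up",
                                         ifelse(top$log2fc < 0, "down",
                                                "zero")),
                      stringsAsFactors = FALSE)
  rownames(genes) <- NULL
  structure(list(genes = genes, k = k,
                 provenance = list(p_cutoff = p_cutoff, p_kind = p_kind,
                                   n_cohort = nrow(cohort_de),
                                   n_targets = length(target_set),
                                   n_survivors = nrow(surv))),
            class = "de_signature")
}

#' @export
print.de_signature <- function(x, ...) {
  cat(sprintf(
    "de_signature: %d gene(s) (k = %d requested; %d survivor(s) at p < %g on %s p)\n",
    nrow(x$genes), x$k, x$provenance$n_survivors, x$provenance$p_cutoff,
    x$provenance$p_kind))
  if (nrow(x$genes) > 0) {
    print.data.frame(utils::head(x$genes, 10))
    if (nrow(x$genes) > 10) cat("... (", nrow(x$genes) - 10, " more)\n", sep = "")
  }
  invisible(x)
}

#' Direction split of a gene list's fold changes
#'
#' Fractions of genes with positive versus negative log2 fold change in a
#' cohort contrast; zero-fold-change genes are counted separately and do
#' not enter the up/down denominators.
#'
#' @param log2fc numeric vector of finite log2 fold changes (non-empty).
#' @return list with `frac_up`, `frac_down`, `n_up`, `n_down`, `n_zero`.
#' @examples
#' direction_split(c(rep(1, 11), rep(-1, 14)))  # 44% up, 56% down
#' @export
direction_split <- function(log2fc) {
  if (length(log2fc) == 0) stop("empty input")
  if (any(!is.finite(log2fc))) stop("log2fc must be finite")
  n_up <- sum(log2fc > 0)
  n_down <- sum(log2fc < 0)
  n_zero <- sum(log2fc == 0)
  nn <- n_up + n_down
  list(frac_up = if (nn > 0) n_up / nn else NA_real_,
       frac_down = if (nn > 0) n_down / nn else NA_real_,
       n_up = n_up, n_down = n_down, n_zero = n_zero)
}
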