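#' Histone-mark profile over target genes
#'
#' For each histone-mark peak set, the fraction of target genes bearing
#' that mark, where a gene bears a mark iff at least one mark-peak summit
#' falls inside the gene's promoter window (same summit semantics as the
#' annotator).  Target genes absent from the annotation are excluded with a
#' logged warning.
#'
#' @param targets character vector of gene ids.
#' @param marks named list of [peak_set()]s, one per mark label (e.g.
#'   `H3K4me3`, `H3K27me3`).
#' @param ann a [genome_annotation()].
#' @param cfg an [annotation_config()] (promoter window definition).
#' @return named numeric vector, mark label -> fraction of targets with
#'   the mark.
#' @export
mark_profile <- function(targets, marks, ann, cfg = annotation_config()) {
  stopifnot(inherits(ann, "genome_annotation"), is.list(marks))
  if (is.null(names(marks)) || any(!nzchar(names(marks)))) {
    stop("marks must be a named list of peak sets")
  }
  targets <- unique(as.character(targets))
  known <- targets %in% ann$genes$gene_id
  if (any(!known)) {
    coc_log("mark_profile: ", sum(!known),
            " target gene(s) absent from annotation; excluded")
    warning(sum(!known), " target gene(s) absent from annotation")
    targets <- targets[known]
  }
  if (length(targets) == 0) {
    return(stats::setNames(rep(NA_real_, length(marks)), names(marks)))
  }
  gi <- match(targets, ann$genes$gene_id)
  proms <- promoter_windows(ann$genes[gi, , drop = FALSE], cfg)
  vapply(marks, function(ps) {
    df <- as.data.frame(ps)
    has <- logical(nrow(proms))
    for (ch in unique(proms$chrom)) {
      ipr <- which(proms$chrom == ch)
      s <- sort(df$summit[df$chrom == ch])
      if (length(s) == 0) next
      cnt <- findInterval(proms$pend[ipr] + 0.5, s) -
        findInterval(proms$pstart[ipr] - 0.5, s)
      has[ipr] <- cnt > 0
    }
    mean(has)
  }, numeric(1))
}

#' Classify target genes as transcriptionally active or inactive
#'
#' A gene is active iff its expression value is at or above `threshold`.
#' Genes missing from the expression table are counted inactive (and
#' logged): the conservative, auditable default.  The active fraction is
#' reported both raw and as a whole percent (half-up).
#'
#' @param targets character vector of gene ids (deduplicated; must be
#'   non-empty).
#' @param expr data.frame with columns `gene_id`, `value` (see
#'   [read_expression()]).
#' @param threshold expression cutoff in the table's declared unit
#'   (default 1.0).
#' @return an object of class `activity_report`: list with `n_genes`,
#'   `n_active`, `fraction_active`, `percent_active` (whole percent),
#'   `n_missing`, `threshold`.
#' @export
classify_activity <- function(targets, expr, threshold = 1.0) {
  if (threshold < 0) stop("threshold must be >= 0")
  targets <- unique(as.character(targets))
  if (length(targets) == 0) stop("no target genes to classify")
  need_cols(expr, c("gene_id", "value"), "expression table")
  idx <- match(targets, expr$gene_id)
  missing <- sum(is.na(idx))
  if (missing > 0) {
    coc_log("classify_activity: ", missing,
            " target gene(s) missing from expression table; counted inactive")
  }
  val <- expr$value[idx]
  active <- !is.na(val) & val >= threshold
  structure(list(n_genes = length(targets),
                 n_active = sum(active),
                 fraction_active = mean(active),
                 percent_active = round_half_up(100 * mean(active), 0),
                 n_missing = missing,
                 threshold = threshold),
            class = "activity_report")
}

#' @export
print.activity_report <- function(x, ...) {
  cat(sprintf(
    "activity_report: %d/%d target gene(s) active (%.0f%%) at threshold %g\n",
    x$n_active, x$n_genes, x$percent_active, x$threshold))
  if (x$n_missing > 0) {
    cat("  (", x$n_missing, " gene(s) missing from expression table, counted inactive)\n",
        sep = "")
  }
  invisible(x)
}
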