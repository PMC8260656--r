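#' Construct a peak set
#'
#' A peak set is the package's container for called ChIP-seq peaks: a
#' data.frame with one row per peak, holding the enclosing interval
#' (0-based half-open), the absolute summit coordinate, a score and a unique
#' name.  Peaks are kept sorted by (chrom, summit); duplicate names are
#' auto-suffixed with an ordinal and a warning is logged rather than
#' failing, so tolerant ingestion remains auditable.
#'
#' @param peaks data.frame with columns `chrom`, `start`, `end`, `summit`,
#'   and optionally `name`, `score`, `strand`.  Coordinates are 0-based
#'   half-open; `summit` is an absolute coordinate with
#'   `start <= summit < end`.
#' @param label character label for the set (e.g. `"ERG"`).
#' @return an object of class `peak_set` (a sorted data.frame with columns
#'   `chrom`, `start`, `end`, `summit`, `name`, `score`, `strand` and a
#'   `label` attribute).
#' @examples
#' ps <- peak_set(data.frame(chrom = "chr1", start = 100, end = 500,
#'                           summit = 150), label = "toy")
#' ps
#' @export
peak_set <- function(peaks, label = "peaks") {
  stopifnot(is.data.frame(peaks))
  if (nrow(peaks) == 0) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      summit = integer(), name = character(),
                      score = numeric(), strand = character(),
                      stringsAsFactors = FALSE)
    attr(out, "label") <- label
    class(out) <- c("peak_set", "data.frame")
    return(out)
  }
  need_cols(peaks, c("chrom", "start", "end", "summit"), "peak table")
  out <- data.frame(
    chrom  = as.character(peaks$chrom),
    start  = as.integer(peaks$start),
    end    = as.integer(peaks$end),
    summit = as.integer(peaks$summit),
    name   = if ("name" %in% names(peaks)) as.character(peaks$name) else
      sprintf("%s_%d", label, seq_len(nrow(peaks))),
    score  = if ("score" %in% names(peaks)) as.numeric(peaks$score) else 0,
    strand = if ("strand" %in% names(peaks)) as.character(peaks$strand) else ".",
    stringsAsFactors = FALSE
  )
  if (any(is.na(out$start) | is.na(out$end) | is.na(out$summit)) ||
      any(out$chrom == "") || anyNA(out$chrom)) {
    stop("peak table contains missing coordinates or empty chromosome names")
  }
  if (any(out$start < 0) || any(out$start >= out$end)) {
    stop("invalid peak interval: need 0 <= start < end")
  }
  if (any(out$summit < out$start | out$summit >= out$end)) {
    stop("peak summit outside its interval")
  }
  if (any(out$score < 0)) stop("peak scores must be non-negative")
  dup <- duplicated(out$name)
  if (any(dup)) {
    warning(sum(dup), " duplicate peak name(s) auto-suffixed in set '",
            label, "'")
    out$name <- make.unique(out$name, sep = "_")
  }
  out <- out[order(out$chrom, out$summit, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "label") <- label
  class(out) <- c("peak_set", "data.frame")
  out
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set '%s': %d peaks on %d chromosome(s)\n",
              attr(x, "label") %||% "peaks", nrow(x),
              length(unique(x$chrom))))
  if (nrow(x) > 0) {
    print.data.frame(utils::head(as.data.frame(x), 6))
    if (nrow(x) > 6) cat("... (", nrow(x) - 6, " more)\n", sep = "")
  }
  invisible(x)
}

# Internal accessor used throughout
set_label <- function(x) attr(x, "label") %||% "peaks"
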