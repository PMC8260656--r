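#' Construct a genome annotation
#'
#' Bundles gene models (span, strand, TSS, exon structure), optional
#' enhancer intervals and chromosome sizes into one validated object.  All
#' coordinates are 0-based half-open; the TSS is the first transcribed base
#' (`start` on the + strand, `end - 1` on the - strand).
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (`+` or `-`).  The TSS is derived from the strand.
#' @param exons data.frame with columns `gene_id`, `chrom`, `start`, `end`;
#'   exons must lie within their gene's span and not overlap one another.
#' @param enhancers optional data.frame with columns `chrom`, `start`,
#'   `end`.
#' @param chrom_sizes named numeric vector, chromosome -> length in bp.
#' @return an object of class `genome_annotation`: a list with elements
#'   `genes` (with derived `tss` column), `exons`, `enhancers`,
#'   `chrom_sizes`.
#' @examples
#' ann <- genome_annotation(
#'   genes = data.frame(gene_id = "g1", chrom = "chr1", start = 1000,
#'                      end = 5000, strand = "+"),
#'   exons = data.frame(gene_id = "g1", chrom = "chr1",
#'                      start = c(1000, 4000), end = c(1500, 5000)),
#'   chrom_sizes = c(chr1 = 10000))
#' ann
#' @export
genome_annotation <- function(genes, exons = NULL, enhancers = NULL,
                              chrom_sizes) {
  stopifnot(is.data.frame(genes))
  if (is.null(names(chrom_sizes)) || anyNA(names(chrom_sizes))) {
    stop("chrom_sizes must be a named vector")
  }
  if (nrow(genes) > 0) {
    need_cols(genes, c("gene_id", "chrom", "start", "end", "strand"), "gene table")
    genes <- data.frame(gene_id = as.character(genes$gene_id),
                        chrom = as.character(genes$chrom),
                        start = as.integer(genes$start),
                        end = as.integer(genes$end),
                        strand = as.character(genes$strand),
                        stringsAsFactors = FALSE)
    if (!all(genes$strand %in% c("+", "-"))) {
      stop("gene strand must be '+' or '-'")
    }
    if (any(genes$start < 0 | genes$start >= genes$end)) {
      stop("invalid gene span: need 0 <= start < end")
    }
    if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id in annotation")
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
    bad <- !(genes$chrom %in% names(chrom_sizes)) |
      genes$end > chrom_sizes[genes$chrom]
    if (any(bad)) {
      stop("gene(s) outside chrom_sizes bounds: ",
           paste(utils::head(genes$gene_id[bad], 5), collapse = ", "))
    }
  } else {
    genes <- data.frame(gene_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        strand = character(), tss = integer(),
                        stringsAsFactors = FALSE)
  }
  if (is.null(exons) || nrow(exons) == 0) {
    exons <- data.frame(gene_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        stringsAsFactors = FALSE)
  } else {
    need_cols(exons, c("gene_id", "chrom", "start", "end"), "exon table")
    exons <- data.frame(gene_id = as.character(exons$gene_id),
                        chrom = as.character(exons$chrom),
                        start = as.integer(exons$start),
                        end = as.integer(exons$end),
                        stringsAsFactors = FALSE)
    gi <- match(exons$gene_id, genes$gene_id)
    if (anyNA(gi)) stop("exon refers to unknown gene_id")
    if (any(exons$start < genes$start[gi] | exons$end > genes$end[gi])) {
      stop("exon outside its gene span")
    }
    exons <- exons[order(gi, exons$start), , drop = FALSE]
    rownames(exons) <- NULL
    # per-gene non-overlap check (exons sorted within gene)
    gi <- match(exons$gene_id, genes$gene_id)
    same <- which(diff(gi) == 0)
    if (length(same) > 0 && any(exons$start[same + 1] < exons$end[same])) {
      stop("overlapping exons within a gene")
    }
  }
  if (is.null(enhancers) || nrow(enhancers) == 0) {
    enhancers <- data.frame(chrom = character(), start = integer(),
                            end = integer(), stringsAsFactors = FALSE)
  } else {
    need_cols(enhancers, c("chrom", "start", "end"), "enhancer table")
    enhancers <- data.frame(chrom = as.character(enhancers$chrom),
                            start = as.integer(enhancers$start),
                            end = as.integer(enhancers$end),
                            stringsAsFactors = FALSE)
    if (any(enhancers$start < 0 | enhancers$start >= enhancers$end)) {
      stop("invalid enhancer interval")
    }
    bad <- !(enhancers$chrom %in% names(chrom_sizes)) |
      enhancers$end > chrom_sizes[enhancers$chrom]
    if (any(bad)) stop("enhancer(s) outside chrom_sizes bounds")
    enhancers <- enhancers[order(enhancers$chrom, enhancers$start), ,
                           drop = FALSE]
    rownames(enhancers) <- NULL
  }
  structure(list(genes = genes, exons = exons, enhancers = enhancers,
                 chrom_sizes = chrom_sizes),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf(
    "genome_annotation: %d gene(s), %d exon(s), %d enhancer(s), %d chromosome(s)\n",
    nrow(x$genes), nrow(x$exons), nrow(x$enhancers), length(x$chrom_sizes)))
  invisible(x)
}

#' Annotation configuration
#'
#' Tunable parameters of the peak annotator.  The promoter window covers
#' signed TSS distances in `[-promoter_up, promoter_down)` in gene
#' orientation (half-open at its downstream edge, so with the defaults a
#' summit exactly 500 bp downstream of the TSS is genic, not promoter);
#' a peak summit inside several feature classes is
#' resolved by `feature_priority`; enhancer peaks are linked to the nearest
#' TSS within `enhancer_link_radius` bp.
#'
#' @param promoter_up bp upstream of the TSS (default 2000).
#' @param promoter_down bp downstream of the TSS (default 500).
#' @param feature_priority character vector, a permutation of
#'   `c("promoter", "enhancer", "exon", "intron", "intergenic")`; earlier
#'   classes win.
#' @param enhancer_link_radius bp for nearest-gene linkage of enhancer
#'   peaks (default 50000).
#' @return a list of class `annotation_config`.
#' @export
annotation_config <- function(promoter_up = 2000, promoter_down = 500,
                              feature_priority = c("promoter", "enhancer",
                                                   "exon", "intron",
                                                   "intergenic"),
                              enhancer_link_radius = 50000) {
  classes <- c("promoter", "enhancer", "exon", "intron", "intergenic")
  if (promoter_up < 0 || promoter_down < 0) {
    stop("promoter window extents must be non-negative")
  }
  if (!setequal(feature_priority, classes) ||
      length(feature_priority) != 5) {
    stop("feature_priority must be a permutation of the five feature classes")
  }
  if (enhancer_link_radius < 0) stop("enhancer_link_radius must be >= 0")
  structure(list(promoter_up = as.integer(promoter_up),
                 promoter_down = as.integer(promoter_down),
                 feature_priority = feature_priority,
                 enhancer_link_radius = as.integer(enhancer_link_radius)),
            class = "annotation_config")
}

# Internal: promoter window [pstart, pend] (closed, in summit coordinates)
# for each gene under cfg, strand-aware.  Membership means a signed TSS
# distance in [-promoter_up, promoter_down), i.e. the window is half-open
# at its downstream edge in gene orientation.
promoter_windows <- function(genes, cfg) {
  up <- cfg$promoter_up
  down <- cfg$promoter_down
  pstart <- ifelse(genes$strand == "+", genes$tss - up, genes$tss - down + 1L)
  pend <- ifelse(genes$strand == "+", genes$tss + down - 1L, genes$tss + up)
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             pstart = as.integer(pstart), pend = as.integer(pend),
             stringsAsFactors = FALSE)
}

# Internal: signed TSS distance of summit(s) for gene rows (vectorised).
# Negative = upstream of the TSS in gene orientation.
signed_tss_distance <- function(summit, tss, strand) {
  ifelse(strand == "+", summit - tss, tss - summit)
}
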