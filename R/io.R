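#' Read an ENCODE narrowPeak file
#'
#' narrowPeak is the 10-column BED6+4 format emitted by MACS-style peak
#' callers.  Column 10 is the summit offset from `start`; an offset of -1
#' means "no summit called" and falls back to the interval midpoint
#' (floored).  Coordinates are 0-based half-open and kept that way.
#' Malformed rows abort with the offending line number; accepted/rejected
#' counts are logged.
#'
#' @param path path to a narrowPeak file.
#' @param label label for the returned set (default: file base name).
#' @return a [peak_set()].
#' @export
read_narrowpeak <- function(path, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  label <- label %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    coc_log("read_narrowpeak: 0 peaks from ", path)
    return(peak_set(data.frame(), label = label))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 10)) {
    stop("narrowPeak format error: expected 10 tab-separated columns at line ",
         which(nf != 10)[1])
  }
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  score <- suppressWarnings(as.numeric(m[, 7]))
  offset <- suppressWarnings(as.integer(m[, 10]))
  bad <- which(is.na(start) | is.na(end) | is.na(offset) | start < 0 |
                 start >= end)
  if (length(bad) > 0) {
    stop("narrowPeak format error: malformed coordinates at line ", bad[1])
  }
  badoff <- which(offset < -1L | offset >= (end - start))
  if (length(badoff) > 0) {
    stop("narrowPeak format error: summit offset outside [-1, end-start) at line ",
         badoff[1])
  }
  summit <- ifelse(offset == -1L, (start + end) %/% 2L, start + offset)
  ps <- peak_set(data.frame(chrom = m[, 1], start = start, end = end,
                            summit = summit, name = m[, 4],
                            score = score, strand = m[, 6],
                            stringsAsFactors = FALSE),
                 label = label)
  coc_log("read_narrowpeak: accepted ", nrow(ps), " peak(s) from ", path)
  ps
}

#' Write a peak set as narrowPeak
#'
#' Inverse of [read_narrowpeak()]: emits 10 columns with the summit encoded
#' as an offset from `start`, so a write/read roundtrip preserves
#' coordinates, summits and scores.
#'
#' @param peaks a [peak_set()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  df <- as.data.frame(peaks)
  lines <- if (nrow(df) == 0) character() else
    sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%s\t-1\t-1\t%d",
            df$chrom, df$start, df$end, df$name,
            pmin(1000L, as.integer(round(df$score))), df$strand,
            format(df$score, trim = TRUE, scientific = FALSE),
            df$summit - df$start)
  writeLines(lines, path)
  invisible(path)
}

#' Write intervals as BED6
#'
#' Emits 0-based half-open BED6.  For peak sets the summit is carried in
#' the name field as `name|summit` so it survives tools that only keep
#' BED6.  An empty set produces an empty file.
#'
#' @param items a [peak_set()] or a data.frame with `chrom`, `start`, `end`
#'   (and optionally `name`, `score`, `strand`).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_bed <- function(items, path) {
  df <- as.data.frame(items)
  if (nrow(df) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  name <- if ("name" %in% names(df)) df$name else
    sprintf("item_%d", seq_len(nrow(df)))
  if (inherits(items, "peak_set")) name <- sprintf("%s|%d", name, df$summit)
  score <- if ("score" %in% names(df)) df$score else 0
  strand <- if ("strand" %in% names(df)) df$strand else "."
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s", df$chrom, df$start, df$end,
                     name, format(score, trim = TRUE, scientific = FALSE),
                     strand),
             path)
  invisible(path)
}

#' Read a gene annotation
#'
#' Two dialects are supported.  `gtf`: feature lines of type `gene` and
#' `exon` with a `gene_id` attribute; GTF's 1-based inclusive coordinates
#' are converted to the package's 0-based half-open convention at this
#' boundary (the only place +/-1 arithmetic appears).  `tsv`: a header line
#' and columns `gene_id`, `chrom`, `start`, `end`, `strand`,
#' `exon_starts`, `exon_ends` (comma-separated, already 0-based
#' half-open).
#'
#' @param path input file.
#' @param dialect `"gtf"` or `"tsv"`.
#' @param enhancers optional BED file of enhancer intervals.
#' @param chrom_sizes optional named vector; inferred from feature extents
#'   when absent.
#' @return a [genome_annotation()].
#' @export
read_gene_annotation <- function(path, dialect = c("gtf", "tsv"),
                                 enhancers = NULL, chrom_sizes = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "gtf") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (length(lines) > 0 && any(nf < 9)) {
      stop("GTF format error: fewer than 9 columns at line ", which(nf < 9)[1])
    }
    m <- if (length(lines) > 0) do.call(rbind, fields) else
      matrix(character(), ncol = 9)
    keep <- m[, 3] %in% c("gene", "exon")
    m <- m[keep, , drop = FALSE]
    gid <- sub('.*gene_id[ =]+"?([^";]+)"?.*', "\\1", m[, 9])
    if (any(gid == m[, 9])) {
      stop("GTF format error: missing gene_id attribute")
    }
    strand <- m[, 7]
    if (length(strand) > 0 && !all(strand %in% c("+", "-"))) {
      stop("GTF format error: unknown strand '",
           strand[!(strand %in% c("+", "-"))][1], "'")
    }
    start0 <- as.integer(m[, 4]) - 1L   # 1-based inclusive -> 0-based
    end0 <- as.integer(m[, 5])          # inclusive end -> exclusive end
    isg <- m[, 3] == "gene"
    genes <- data.frame(gene_id = gid[isg], chrom = m[isg, 1],
                        start = start0[isg], end = end0[isg],
                        strand = strand[isg], stringsAsFactors = FALSE)
    exons <- data.frame(gene_id = gid[!isg], chrom = m[!isg, 1],
                        start = start0[!isg], end = end0[!isg],
                        stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, quote = "")
    need_cols(tab, c("gene_id", "chrom", "start", "end", "strand",
                     "exon_starts", "exon_ends"), "gene-model TSV")
    genes <- tab[, c("gene_id", "chrom", "start", "end", "strand")]
    split_int <- function(s) lapply(strsplit(as.character(s), ","),
                                    function(v) as.integer(v[nzchar(v)]))
    es <- split_int(tab$exon_starts)
    ee <- split_int(tab$exon_ends)
    if (any(lengths(es) != lengths(ee))) {
      stop("gene-model TSV: exon_starts/exon_ends length mismatch")
    }
    exons <- data.frame(
      gene_id = rep(tab$gene_id, lengths(es)),
      chrom = rep(tab$chrom, lengths(es)),
      start = unlist(es, use.names = FALSE) %||% integer(),
      end = unlist(ee, use.names = FALSE) %||% integer(),
      stringsAsFactors = FALSE)
  }
  enh <- NULL
  if (!is.null(enhancers)) {
    if (!file.exists(enhancers)) stop("file not found: ", enhancers)
    bed <- utils::read.table(enhancers, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE, quote = "")
    enh <- data.frame(chrom = bed[[1]], start = bed[[2]], end = bed[[3]],
                      stringsAsFactors = FALSE)
  }
  if (is.null(chrom_sizes)) {
    ext <- c(genes$end, if (!is.null(enh)) enh$end else integer())
    chr <- c(genes$chrom, if (!is.null(enh)) enh$chrom else character())
    if (length(chr) == 0) stop("cannot infer chrom_sizes from an empty annotation")
    chrom_sizes <- tapply(ext, chr, max)
    chrom_sizes <- stats::setNames(as.numeric(chrom_sizes), names(chrom_sizes))
  }
  ann <- genome_annotation(genes, exons, enh, chrom_sizes)
  coc_log("read_gene_annotation: ", nrow(ann$genes), " gene(s), ",
          nrow(ann$exons), " exon(s) from ", path)
  ann
}

#' Write a gene annotation in the TSV dialect
#'
#' Emits the tabular gene-model dialect read by
#' `read_gene_annotation(dialect = "tsv")` (0-based half-open, exon lists
#' comma-separated).
#'
#' @param ann a [genome_annotation()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gene_annotation <- function(ann, path) {
  g <- ann$genes
  estr <- function(gid, col) {
    v <- ann$exons[[col]][ann$exons$gene_id == gid]
    paste(v, collapse = ",")
  }
  lines <- c("gene_id\tchrom\tstart\tend\tstrand\texon_starts\texon_ends",
             if (nrow(g) > 0)
               vapply(seq_len(nrow(g)), function(i) {
                 sprintf("%s\t%s\t%d\t%d\t%s\t%s\t%s", g$gene_id[i],
                         g$chrom[i], g$start[i], g$end[i], g$strand[i],
                         estr(g$gene_id[i], "start"), estr(g$gene_id[i], "end"))
               }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression table
#'
#' TSV with header columns `gene_id` and `value` (expression level in the
#' unit declared by the producing pipeline, e.g. TPM-like).
#'
#' @param path input file.
#' @return data.frame with columns `gene_id`, `value`.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  need_cols(tab, c("gene_id", "value"), "expression table")
  if (any(tab$value < 0)) stop("expression values must be non-negative")
  if (anyDuplicated(tab$gene_id)) stop("duplicate gene_id in expression table")
  tab[, c("gene_id", "value")]
}

#' Read a differential-expression table
#'
#' TSV with header columns `gene_id`, `log2fc`, `adj_p` (and optionally
#' `p`).  These tables are produced upstream by standard DE fitting
#' (limma/DESeq-style); this package only filters and compares them.
#'
#' @param path input file.
#' @return data.frame with columns `gene_id`, `log2fc`, `adj_p` (and `p`
#'   when present).
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  need_cols(tab, c("gene_id", "log2fc", "adj_p"), "DE table")
  if (any(tab$adj_p < 0 | tab$adj_p > 1)) stop("adj_p outside [0, 1]")
  if (any(!is.finite(tab$log2fc))) stop("non-finite log2fc")
  tab
}

#' Write a table as TSV with header
#'
#' @param df data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
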