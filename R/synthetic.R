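#' Simulation configuration
#'
#' Parameters of the synthetic-data generator.  The defaults describe the
#' reference simulation used throughout the package's validation: a 100-Mb
#' single-chromosome genome, 2000 genes, 5000 anchor (set A) and 2000
#' cofactor (set B) peaks with a planted co-localization fraction of 0.25
#' under a truncated-Laplace summit-offset law (scale 100 bp, truncated at
#' the 1-kb matching window), two thirds of genes transcriptionally active
#' with 0.9 mark/expression concordance, and mutant fold changes attenuated
#' to 0.44 of wild type with residual s.d. 0.3.
#'
#' @param genome_length bp per chromosome.
#' @param n_chroms number of chromosomes.
#' @param n_genes,n_enhancers feature counts.
#' @param n_peaks_a,n_peaks_b peak counts for sets A (anchor) and B
#'   (cofactor).
#' @param rho planted co-localization fraction of set B, in `[0, 1]`.
#' @param offset_scale Laplace scale of planted summit offsets (bp).
#' @param window co-localization window (bp); planted offsets are
#'   truncated at +/- this value so planted pairs are always recoverable.
#' @param active_fraction per-gene probability of being expressed.
#' @param mark_prob probability that an active (inactive) gene receives an
#'   activating (repressive) mark peak in its promoter.
#' @param expr_threshold expression value separating active from inactive.
#' @param attenuation planted slope relating mutant to wild-type log2 fold
#'   changes.
#' @param noise_sd residual s.d. of mutant log2 fold changes.
#' @param mod_fraction fraction of genes spiked as truly modulated.
#' @param seed integer seed; each generator draws from its own stream
#'   derived from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 1e8, n_chroms = 1, n_genes = 2000,
                       n_enhancers = 500, n_peaks_a = 5000,
                       n_peaks_b = 2000, rho = 0.25, offset_scale = 100,
                       window = 1000, active_fraction = 0.66,
                       mark_prob = 0.9, expr_threshold = 1.0,
                       attenuation = 0.44, noise_sd = 0.3,
                       mod_fraction = 0.1, seed = 1) {
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]")
  if (offset_scale <= 0) stop("offset_scale must be positive")
  if (window <= 0) stop("window must be positive")
  if (any(c(genome_length, n_chroms) < 1)) stop("genome dimensions must be positive")
  if (any(c(n_genes, n_enhancers, n_peaks_a, n_peaks_b) < 0)) {
    stop("feature counts must be non-negative")
  }
  if (active_fraction < 0 || active_fraction > 1) {
    stop("active_fraction must lie in [0, 1]")
  }
  if (mark_prob < 0 || mark_prob > 1) stop("mark_prob must lie in [0, 1]")
  if (!is.finite(attenuation)) stop("attenuation must be finite")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (mod_fraction < 0 || mod_fraction > 1) stop("mod_fraction must lie in [0, 1]")
  structure(list(genome_length = genome_length, n_chroms = as.integer(n_chroms),
                 n_genes = as.integer(n_genes),
                 n_enhancers = as.integer(n_enhancers),
                 n_peaks_a = as.integer(n_peaks_a),
                 n_peaks_b = as.integer(n_peaks_b),
                 rho = rho, offset_scale = offset_scale, window = window,
                 active_fraction = active_fraction, mark_prob = mark_prob,
                 expr_threshold = expr_threshold, attenuation = attenuation,
                 noise_sd = noise_sd, mod_fraction = mod_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Internal: run `expr` under a private RNG stream seeded from the config
# seed plus a fixed per-generator offset, restoring the caller's RNG state.
with_sim_seed <- function(cfg, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((cfg$seed + offset) %% .Machine$integer.max)
  expr
}

#' Truncated-Laplace distribution of planted summit offsets
#'
#' Density mass of a Laplace(0, `scale`) variable conditioned on
#' `|x| <= trunc`; `plaplace_trunc` gives the CDF, `rlaplace_trunc` draws
#' by inverse-CDF sampling.
#'
#' @param q quantile(s).
#' @param n number of draws.
#' @param scale Laplace scale (bp).
#' @param trunc truncation bound (bp).
#' @return CDF values, or `n` draws in `[-trunc, trunc]`.
#' @export
plaplace_trunc <- function(q, scale, trunc) {
  lap <- function(x) ifelse(x < 0, 0.5 * exp(x / scale),
                            1 - 0.5 * exp(-x / scale))
  q <- pmin(pmax(q, -trunc), trunc)
  (lap(q) - lap(-trunc)) / (lap(trunc) - lap(-trunc))
}

#' @rdname plaplace_trunc
#' @export
rlaplace_trunc <- function(n, scale, trunc) {
  u <- stats::runif(n)
  lo <- 0.5 * exp(-trunc / scale)
  hi <- 1 - lo
  p <- lo + u * (hi - lo)
  ifelse(p < 0.5, scale * log(2 * p), -scale * log(2 * (1 - p)))
}

#' Generate a synthetic genome annotation
#'
#' Places `n_genes` non-overlapping gene spans uniformly on each
#' chromosome (lengths 2-20 kb, random strand, 2-6 exons tiling each span
#' from TSS to end), then `n_enhancers` intergenic enhancers (200-1000 bp)
#' that never overlap a gene span or a default promoter window.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return a [genome_annotation()].
#' @export
gen_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_sim_seed(cfg, 1L, {
    L <- cfg$genome_length
    chroms <- paste0("chr", seq_len(cfg$n_chroms))
    sizes <- stats::setNames(rep(L, cfg$n_chroms), chroms)
    gene_chrom <- if (cfg$n_genes > 0) sample(chroms, cfg$n_genes,
                                              replace = TRUE) else character()
    genes_l <- list(); exons_l <- list()
    gnum <- 0L
    for (ch in chroms) {
      n_c <- sum(gene_chrom == ch)
      if (n_c == 0) next
      len <- sample(2000:20000, n_c, replace = TRUE)
      free <- L - sum(len)
      if (free < n_c) {
        stop("capacity error: genome too small to place ", n_c,
             " gene span(s) on ", ch)
      }
      gaps <- sort(stats::runif(n_c, 0, free))
      starts <- as.integer(floor(gaps)) + c(0L, cumsum(len[-n_c]))
      strand <- sample(c("+", "-"), n_c, replace = TRUE)
      ids <- sprintf("gene%05d", gnum + seq_len(n_c))
      gnum <- gnum + n_c
      genes_l[[ch]] <- data.frame(gene_id = ids, chrom = ch, start = starts,
                                  end = starts + len, strand = strand,
                                  stringsAsFactors = FALSE)
      exons_l[[ch]] <- do.call(rbind, lapply(seq_len(n_c), function(i) {
        k <- sample(2:6, 1)
        cuts <- sort(sample(seq_len(len[i] - 1L), 2L * k - 2L))
        bounds <- c(0L, cuts, len[i])
        seg_start <- bounds[seq(1, 2 * k - 1, by = 2)]
        seg_end <- bounds[seq(2, 2 * k, by = 2)]
        data.frame(gene_id = ids[i], chrom = ch,
                   start = starts[i] + seg_start,
                   end = starts[i] + seg_end, stringsAsFactors = FALSE)
      }))
    }
    genes <- if (length(genes_l) > 0) do.call(rbind, genes_l) else NULL
    exons <- if (length(exons_l) > 0) do.call(rbind, exons_l) else NULL
    # enhancers: rejection-sample against gene spans and default promoter
    # windows (the generator commits to the annotator's default window)
    enh <- NULL
    if (cfg$n_enhancers > 0) {
      cfg_ann <- annotation_config()
      blocked <- if (!is.null(genes)) {
        tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
        data.frame(chrom = c(genes$chrom, genes$chrom),
                   start = c(genes$start,
                             ifelse(genes$strand == "+",
                                    tss - cfg_ann$promoter_up,
                                    tss - cfg_ann$promoter_down)),
                   end = c(genes$end,
                           ifelse(genes$strand == "+",
                                  tss + cfg_ann$promoter_down + 1L,
                                  tss + cfg_ann$promoter_up + 1L)))
      } else data.frame(chrom = character(), start = integer(),
                        end = integer())
      placed <- 0L
      tries <- 0L
      max_tries <- 200L * cfg$n_enhancers
      rows <- vector("list", cfg$n_enhancers)
      while (placed < cfg$n_enhancers) {
        tries <- tries + 1L
        if (tries > max_tries) {
          stop("capacity error: could not place ", cfg$n_enhancers,
               " enhancer(s) in intergenic space")
        }
        ch <- sample(chroms, 1)
        w <- sample(200:1000, 1)
        s <- as.integer(floor(stats::runif(1, 0, L - w)))
        blk <- blocked[blocked$chrom == ch, , drop = FALSE]
        if (nrow(blk) == 0 || all(s + w <= blk$start | s >= blk$end)) {
          placed <- placed + 1L
          rows[[placed]] <- data.frame(chrom = ch, start = s, end = s + w,
                                       stringsAsFactors = FALSE)
        }
      }
      enh <- do.call(rbind, rows)
    }
    genome_annotation(genes %||% data.frame(), exons, enh, sizes)
  })
}

#' Generate two peak sets with a planted co-localization structure
#'
#' Set A summits fall uniformly on the genome.  A fraction `rho` of set B
#' summits is planted at a matched A summit plus a truncated-Laplace
#' offset (scale `offset_scale`, truncated at `window`, so every planted
#' pair is recoverable at that window); the remainder is uniform.  Peak
#' intervals extend 75-250 bp (uniform) on each side of the summit.
#'
#' @param cfg a [sim_config()].
#' @param ann a [genome_annotation()] (supplies chromosome names/sizes).
#' @return list with `set_a`, `set_b` ([peak_set()]s) and `planted_pairs`
#'   (data.frame `name_a`, `name_b`, `offset`).
#' @export
gen_cooccupancy_peaks <- function(cfg, ann) {
  stopifnot(inherits(cfg, "sim_config"), inherits(ann, "genome_annotation"))
  with_sim_seed(cfg, 2L, {
    chroms <- names(ann$chrom_sizes)
    sizes <- ann$chrom_sizes
    rand_peaks <- function(n, prefix) {
      ch <- sample(chroms, n, replace = TRUE)
      s <- as.integer(floor(stats::runif(n) * sizes[ch]))
      data.frame(chrom = ch, summit = s,
                 name = sprintf("%s_%05d", prefix, seq_len(n)),
                 stringsAsFactors = FALSE)
    }
    a <- rand_peaks(cfg$n_peaks_a, "a")
    n_pl <- round(cfg$rho * cfg$n_peaks_b)
    if (n_pl > cfg$n_peaks_a) {
      stop("cannot plant ", n_pl, " pairs with only ", cfg$n_peaks_a,
           " anchor peaks")
    }
    b_ch <- character(cfg$n_peaks_b)
    b_s <- integer(cfg$n_peaks_b)
    planted <- NULL
    if (n_pl > 0) {
      ai <- sample.int(cfg$n_peaks_a, n_pl)
      off <- as.integer(round(rlaplace_trunc(n_pl, cfg$offset_scale,
                                             cfg$window)))
      b_ch[seq_len(n_pl)] <- a$chrom[ai]
      raw <- a$summit[ai] + off
      b_s[seq_len(n_pl)] <- pmin(pmax(raw, 0L),
                                 as.integer(sizes[a$chrom[ai]]) - 1L)
      planted <- data.frame(name_a = a$name[ai],
                            name_b = sprintf("b_%05d", seq_len(n_pl)),
                            offset = b_s[seq_len(n_pl)] - a$summit[ai],
                            stringsAsFactors = FALSE)
    }
    if (cfg$n_peaks_b > n_pl) {
      rest <- rand_peaks(cfg$n_peaks_b - n_pl, "x")
      b_ch[(n_pl + 1):cfg$n_peaks_b] <- rest$chrom
      b_s[(n_pl + 1):cfg$n_peaks_b] <- rest$summit
    }
    b <- data.frame(chrom = b_ch, summit = b_s,
                    name = sprintf("b_%05d", seq_len(cfg$n_peaks_b)),
                    stringsAsFactors = FALSE)
    widen <- function(df) {
      n <- nrow(df)
      left <- sample(75:250, n, replace = TRUE)
      right <- sample(75:250, n, replace = TRUE)
      df$start <- pmax(0L, df$summit - left)
      df$end <- pmin(as.integer(sizes[df$chrom]), df$summit + right)
      df$score <- round(stats::runif(n, 1, 100), 2)
      df
    }
    list(set_a = peak_set(widen(a), label = "A"),
         set_b = peak_set(widen(b), label = "B"),
         planted_pairs = planted %||%
           data.frame(name_a = character(), name_b = character(),
                      offset = integer(), stringsAsFactors = FALSE))
  })
}

#' Generate expression values and histone-mark peaks
#'
#' Each gene is independently expressed with probability
#' `active_fraction`; expressed genes draw a log-normal value above
#' `expr_threshold`, silent genes a value below it.  Active genes receive
#' an activating-mark (`H3K4me3`) peak in their promoter window with
#' probability `mark_prob`; inactive genes a repressive-mark (`H3K27me3`)
#' peak likewise.
#'
#' @param cfg a [sim_config()].
#' @param ann a [genome_annotation()].
#' @return list with `expression` (data.frame `gene_id`, `value`),
#'   `marks` (named list of [peak_set()]s) and `active` (named logical,
#'   the planted states).
#' @export
gen_expression <- function(cfg, ann) {
  stopifnot(inherits(cfg, "sim_config"), inherits(ann, "genome_annotation"))
  with_sim_seed(cfg, 3L, {
    genes <- ann$genes
    n <- nrow(genes)
    if (n == 0) stop("annotation has no genes")
    active <- stats::runif(n) < cfg$active_fraction
    thr <- cfg$expr_threshold
    value <- numeric(n)
    value[active] <- thr * exp(abs(stats::rnorm(sum(active), 0, 1)) + 0.05)
    value[!active] <- thr * stats::runif(sum(!active), 0, 0.95)
    expr <- data.frame(gene_id = genes$gene_id, value = value,
                       stringsAsFactors = FALSE)
    proms <- promoter_windows(genes, annotation_config())
    mk_peaks <- function(idx, prefix) {
      if (length(idx) == 0) return(peak_set(data.frame(), label = prefix))
      lo <- pmax(0L, proms$pstart[idx])
      hi <- pmin(as.integer(ann$chrom_sizes[proms$chrom[idx]]) - 1L,
                 proms$pend[idx])
      s <- as.integer(floor(stats::runif(length(idx), lo, hi + 1)))
      peak_set(data.frame(chrom = proms$chrom[idx],
                          start = pmax(0L, s - 150L),
                          end = pmin(as.integer(ann$chrom_sizes[proms$chrom[idx]]),
                                     s + 150L),
                          summit = s,
                          name = sprintf("%s_%05d", prefix, seq_along(idx)),
                          score = round(stats::runif(length(idx), 1, 50), 2),
                          stringsAsFactors = FALSE),
               label = prefix)
    }
    act_idx <- which(active & stats::runif(n) < cfg$mark_prob)
    rep_idx <- which(!active & stats::runif(n) < cfg$mark_prob)
    list(expression = expr,
         marks = list(H3K4me3 = mk_peaks(act_idx, "H3K4me3"),
                      H3K27me3 = mk_peaks(rep_idx, "H3K27me3")),
         active = stats::setNames(active, genes$gene_id))
  })
}

#' Generate wild-type and mutant differential-expression tables
#'
#' Wild-type log2 fold changes are Normal(0, 1.2) with a spiked truly
#' modulated subset (`mod_fraction` of genes, |log2FC| >= 1); mutant fold
#' changes are `attenuation * WT + Normal(0, noise_sd)`.  Adjusted p values
#' are rank maps of |log2FC|, decreasing within the modulated group (into
#' (0, 0.05)) and within the null group (into [0.05, 1)), so the planted
#' modulated set is exactly what survives the standard filter when
#' `noise_sd = 0`.
#'
#' @param cfg a [sim_config()].
#' @param ann a [genome_annotation()].
#' @return list with `wt`, `mut` (data.frames `gene_id`, `log2fc`,
#'   `adj_p`) and `modulated` (character vector of planted gene ids).
#' @export
gen_de_tables <- function(cfg, ann) {
  stopifnot(inherits(cfg, "sim_config"), inherits(ann, "genome_annotation"))
  with_sim_seed(cfg, 4L, {
    genes <- ann$genes$gene_id
    n <- length(genes)
    if (n == 0) stop("annotation has no genes")
    wt <- stats::rnorm(n, 0, 1.2)
    n_mod <- round(cfg$mod_fraction * n)
    mod_idx <- sort(sample.int(n, n_mod))
    sgn <- sample(c(-1, 1), n_mod, replace = TRUE)
    wt[mod_idx] <- sgn * (1 + stats::rexp(n_mod, rate = 1))
    mut <- cfg$attenuation * wt + stats::rnorm(n, 0, cfg$noise_sd)
    planted <- logical(n)
    planted[mod_idx] <- TRUE
    adj_p_map <- function(lfc) {
      p <- numeric(n)
      if (n_mod > 0) {
        r <- rank(-abs(lfc[planted]), ties.method = "first")
        p[planted] <- 0.05 * r / (n_mod + 1)
      }
      n0 <- n - n_mod
      if (n0 > 0) {
        r0 <- rank(-abs(lfc[!planted]), ties.method = "first")
        p[!planted] <- 0.05 + 0.95 * (r0 - 1) / n0
      }
      p
    }
    list(wt = data.frame(gene_id = genes, log2fc = wt,
                         adj_p = adj_p_map(wt), stringsAsFactors = FALSE),
         mut = data.frame(gene_id = genes, log2fc = mut,
                          adj_p = adj_p_map(mut), stringsAsFactors = FALSE),
         modulated = genes[mod_idx])
  })
}

#' Generate a full synthetic dataset, optionally writing it to disk
#'
#' Runs all four generators under one configuration and (when `out_dir` is
#' given) writes the standard-format files the pipeline reads back:
#' narrowPeak peak sets and marks, the TSV gene-model dialect, an enhancer
#' BED, the expression table and both DE tables.
#'
#' @param cfg a [sim_config()].
#' @param out_dir optional output directory (created if needed).
#' @return list with `annotation`, `peaks` (from
#'   [gen_cooccupancy_peaks()]), `expression` (from [gen_expression()]),
#'   `de` (from [gen_de_tables()]) and `files` (named paths when written).
#' @export
simulate_dataset <- function(cfg, out_dir = NULL) {
  ann <- gen_annotation(cfg)
  pk <- gen_cooccupancy_peaks(cfg, ann)
  ex <- if (nrow(ann$genes) > 0) gen_expression(cfg, ann) else NULL
  de <- if (nrow(ann$genes) > 0) gen_de_tables(cfg, ann) else NULL
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(out_dir, f)
    write_narrowpeak(pk$set_a, p("peaks_a.narrowPeak"))
    write_narrowpeak(pk$set_b, p("peaks_b.narrowPeak"))
    write_gene_annotation(ann, p("genes.tsv"))
    write_bed(ann$enhancers, p("enhancers.bed"))
    files <- list(peaks_a = p("peaks_a.narrowPeak"),
                  peaks_b = p("peaks_b.narrowPeak"),
                  genes = p("genes.tsv"), enhancers = p("enhancers.bed"))
    if (!is.null(ex)) {
      write_tsv(ex$expression, p("expression.tsv"))
      write_narrowpeak(ex$marks$H3K4me3, p("mark_H3K4me3.narrowPeak"))
      write_narrowpeak(ex$marks$H3K27me3, p("mark_H3K27me3.narrowPeak"))
      files$expression <- p("expression.tsv")
    }
    if (!is.null(de)) {
      write_tsv(de$wt, p("de_wt.tsv"))
      write_tsv(de$mut, p("de_mut.tsv"))
      files$de_wt <- p("de_wt.tsv")
      files$de_mut <- p("de_mut.tsv")
    }
  }
  list(annotation = ann, peaks = pk, expression = ex, de = de, files = files)
}
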