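#' Pipeline run configuration
#'
#' Bundles per-stage parameters for [run_pipeline()].  When `inputs` is
#' NULL the pipeline simulates its data from `sim`; otherwise `inputs` is a
#' named list of file paths (`peaks_a`, `peaks_b`, `genes`, and optionally
#' `enhancers`, `expression`, `marks` (named label=path vector), `de_wt`,
#' `de_mut`).
#'
#' @param sim a [sim_config()] used when simulating.
#' @param inputs optional named list of input files (see above).
#' @param genes_dialect `"tsv"` or `"gtf"` for the `genes` input file.
#' @param window co-localization window (bp).
#' @param annotation an [annotation_config()].
#' @param expr_threshold activity cutoff for [classify_activity()].
#' @param lfc_min,p_max modulated-gene filter thresholds.
#' @param sig_p_cutoff,sig_k signature extraction parameters.
#' @param seed integer seed recorded in the report and forwarded to the
#'   simulator.
#' @return a list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), inputs = NULL,
                       genes_dialect = "tsv", window = 1000,
                       annotation = annotation_config(),
                       expr_threshold = 1.0, lfc_min = 0.37, p_max = 0.05,
                       sig_p_cutoff = 0.1, sig_k = 50, seed = 1) {
  if (!is.null(inputs)) {
    required <- c("peaks_a", "peaks_b", "genes")
    miss <- required[!required %in% names(inputs)]
    if (length(miss) > 0) {
      stop("inputs must provide '", paste(miss, collapse = "', '"), "'")
    }
    for (f in required) {
      if (!file.exists(inputs[[f]])) stop("input file not found: ", inputs[[f]])
    }
  }
  sim$seed <- as.integer(seed)
  structure(list(sim = sim, inputs = inputs, genes_dialect = genes_dialect,
                 window = window, annotation = annotation,
                 expr_threshold = expr_threshold, lfc_min = lfc_min,
                 p_max = p_max, sig_p_cutoff = sig_p_cutoff, sig_k = sig_k,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full co-occupancy pipeline
#'
#' Orchestrates simulate (or load) -> colocalize -> annotate -> classify ->
#' differential/signature into one machine-readable report.  Every random
#' stage is seeded from the configuration, so two runs with the same
#' configuration produce byte-identical reports (see [write_report()]).
#' Numeric headline fields carry both raw and display (rounded) values.
#'
#' @param cfg a [run_config()].
#' @return a nested list of class `coc_report`.
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$inputs)) {
    dat <- simulate_dataset(cfg$sim)
    ann <- dat$annotation
    set_a <- dat$peaks$set_a
    set_b <- dat$peaks$set_b
    expr <- dat$expression$expression
    marks <- dat$expression$marks
    de_wt <- dat$de$wt
    de_mut <- dat$de$mut
  } else {
    inp <- cfg$inputs
    ann <- read_gene_annotation(inp$genes, dialect = cfg$genes_dialect,
                                enhancers = inp$enhancers)
    set_a <- read_narrowpeak(inp$peaks_a, label = "A")
    set_b <- read_narrowpeak(inp$peaks_b, label = "B")
    expr <- if (!is.null(inp$expression)) read_expression(inp$expression)
    marks <- if (!is.null(inp$marks)) {
      stats::setNames(lapply(seq_along(inp$marks), function(i) {
        read_narrowpeak(inp$marks[[i]], label = names(inp$marks)[i])
      }), names(inp$marks))
    }
    de_wt <- if (!is.null(inp$de_wt)) read_de_table(inp$de_wt)
    de_mut <- if (!is.null(inp$de_mut)) read_de_table(inp$de_mut)
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  coc <- stage("colocalize", colocalize(set_a, set_b, cfg$window))
  pct <- summarize_fractions(nrow(coc$sites), max(coc$n_a, 1),
                             max(coc$n_b, 1))
  cdf_thresholds <- sort(unique(c(20, 200, cfg$window)))
  cdf <- if (nrow(coc$sites) > 0) {
    distance_fractions(coc, cdf_thresholds)
  } else stats::setNames(rep(NA_real_, length(cdf_thresholds)),
                         cdf_thresholds)

  # annotate the co-occupied sites through their anchor (set A) peaks
  site_peaks <- stage("annotate", {
    a_df <- as.data.frame(set_a)
    peak_set(a_df[a_df$name %in% coc$sites$name_a, , drop = FALSE],
             label = "cooccupied")
  })
  annres <- stage("annotate", annotate_set(site_peaks, ann, cfg$annotation))
  targets <- assign_target_genes(annres)

  activity <- NULL
  mark_fracs <- NULL
  if (!is.null(expr) && length(targets) > 0) {
    activity <- stage("classify", classify_activity(targets, expr,
                                                    cfg$expr_threshold))
    if (!is.null(marks)) {
      mark_fracs <- stage("classify",
                          suppressWarnings(mark_profile(targets, marks, ann,
                                                        cfg$annotation)))
    }
  }

  de_part <- NULL
  if (!is.null(de_wt) && !is.null(de_mut)) {
    de_part <- stage("differential", {
      f_wt <- de_filter(de_wt, cfg$lfc_min, cfg$p_max)
      f_mut <- de_filter(de_mut, cfg$lfc_min, cfg$p_max)
      ov <- overlap_test(unlist(f_wt, use.names = FALSE),
                         unlist(f_mut, use.names = FALSE),
                         universe = nrow(de_wt))
      slope <- attenuation_slope(de_wt, de_mut)
      sig <- suppressWarnings(
        extract_signature(de_wt, targets, cfg$sig_p_cutoff, cfg$sig_k))
      dirs <- if (nrow(sig$genes) > 0) direction_split(sig$genes$log2fc)
      list(n_modulated_wt = length(f_wt$up) + length(f_wt$down),
           n_modulated_mut = length(f_mut$up) + length(f_mut$down),
           overlap = ov$intersection, overlap_p = ov$p,
           attenuation_slope = slope$slope,
           attenuation_intercept = slope$intercept,
           n_regression = slope$n,
           signature = sig$genes$gene_id,
           signature_size = nrow(sig$genes),
           signature_frac_up = if (!is.null(dirs)) dirs$frac_up else NA_real_,
           signature_frac_down = if (!is.null(dirs)) dirs$frac_down else NA_real_)
    })
  }

  report <- list(
    schema_version = "1.0",
    seed = cfg$seed,
    window = cfg$window,
    inputs = list(n_peaks_a = coc$n_a, n_peaks_b = coc$n_b,
                  n_genes = nrow(ann$genes),
                  n_enhancers = nrow(ann$enhancers)),
    cooccupancy = list(
      n_sites = nrow(coc$sites),
      frac_a = list(raw = coc$frac_a, display = pct$percent_a),
      frac_b = list(raw = coc$frac_b, display = pct$percent_b),
      distance_cdf = as.list(cdf)),
    annotation = list(counts = as.list(annres$counts),
                      fractions = as.list(annres$fractions),
                      n_target_genes = length(targets)),
    activity = if (!is.null(activity)) list(
      n_genes = activity$n_genes, n_active = activity$n_active,
      fraction_active = list(raw = activity$fraction_active,
                             display = activity$percent_active),
      mark_fractions = if (!is.null(mark_fracs)) as.list(mark_fracs)),
    differential = de_part
  )
  class(report) <- c("coc_report", "list")
  report
}

#' Write a pipeline report as canonical JSON
#'
#' Serializes a [run_pipeline()] report deterministically (no timestamps,
#' full numeric precision), so identical runs produce byte-identical
#' files.
#'
#' @param report a `coc_report`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @export
print.coc_report <- function(x, ...) {
  cat("co-occupancy pipeline report (schema ", x$schema_version, ", seed ",
      x$seed, ")\n", sep = "")
  cat(sprintf("  peaks: %d (A) / %d (B); co-occupied sites: %d (%.1f%% / %.1f%%)\n",
              x$inputs$n_peaks_a, x$inputs$n_peaks_b,
              x$cooccupancy$n_sites, x$cooccupancy$frac_a$display,
              x$cooccupancy$frac_b$display))
  cat("  target genes:", x$annotation$n_target_genes, "\n")
  if (!is.null(x$activity)) {
    cat(sprintf("  active targets: %d/%d (%.0f%%)\n", x$activity$n_active,
                x$activity$n_genes, x$activity$fraction_active$display))
  }
  if (!is.null(x$differential)) {
    cat(sprintf("  attenuation slope: %.3f over %d genes; signature: %d gene(s)\n",
                x$differential$attenuation_slope, x$differential$n_regression,
                x$differential$signature_size))
  }
  invisible(x)
}
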