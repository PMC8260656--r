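#' Match two peak sets by summit proximity
#'
#' Scores co-occupancy of two ChIP-seq factors as one-to-one matched summit
#' pairs: every same-chromosome pair of peaks whose summits lie within
#' `window` bp of each other (inclusive) is a candidate; candidates are
#' sorted by (distance, summit_a, summit_b) and accepted greedily while
#' both peaks are unmatched.  The result is deterministic and each peak
#' appears in at most one site, so a single site count can be expressed as
#' a fraction of either input set.  Candidate generation runs as a sorted
#' sweep over summits, not an all-pairs scan.
#'
#' @param set_a,set_b [peak_set()] objects (sorted by construction).
#' @param window maximum summit distance in bp (default 1000, i.e. the
#'   conventional "within 1 kb" rule).
#' @return an object of class `cooccupancy`: list with `sites` (data.frame
#'   `chrom`, `name_a`, `name_b`, `summit_a`, `summit_b`, `distance`),
#'   `window`, `n_a`, `n_b`, `frac_a`, `frac_b`, `label_a`, `label_b`.
#' @examples
#' a <- peak_set(data.frame(chrom = "chr1", start = c(0, 4900),
#'                          end = c(200, 5200), summit = c(100, 5000)), "A")
#' b <- peak_set(data.frame(chrom = "chr1", start = c(800, 9000),
#'                          end = c(1000, 9500), summit = c(900, 9100)), "B")
#' colocalize(a, b, window = 1000)
#' @export
colocalize <- function(set_a, set_b, window = 1000) {
  if (window <= 0) stop("window must be positive")
  a <- as.data.frame(set_a)
  b <- as.data.frame(set_b)
  sites <- data.frame(chrom = character(), name_a = character(),
                      name_b = character(), summit_a = integer(),
                      summit_b = integer(), distance = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(a) > 0 && nrow(b) > 0) {
    shared <- intersect(unique(a$chrom), unique(b$chrom))
    only <- setdiff(union(unique(a$chrom), unique(b$chrom)), shared)
    if (length(only) > 0) {
      coc_log("colocalize: ", length(only),
              " chromosome(s) present in only one set; no matches there")
    }
    cand <- candidate_pairs(a, b, shared, window)
    if (nrow(cand) > 0) {
      ord <- order(cand$distance, cand$summit_a, cand$summit_b)
      cand <- cand[ord, , drop = FALSE]
      used_a <- logical(nrow(a))
      used_b <- logical(nrow(b))
      keep <- logical(nrow(cand))
      for (k in seq_len(nrow(cand))) {
        i <- cand$ia[k]; j <- cand$ib[k]
        if (!used_a[i] && !used_b[j]) {
          used_a[i] <- TRUE
          used_b[j] <- TRUE
          keep[k] <- TRUE
        }
      }
      cand <- cand[keep, , drop = FALSE]
      sites <- data.frame(chrom = a$chrom[cand$ia],
                          name_a = a$name[cand$ia],
                          name_b = b$name[cand$ib],
                          summit_a = cand$summit_a,
                          summit_b = cand$summit_b,
                          distance = cand$distance,
                          stringsAsFactors = FALSE)
      sites <- sites[order(sites$chrom, sites$summit_a, sites$summit_b), ,
                     drop = FALSE]
      rownames(sites) <- NULL
    }
  }
  structure(list(sites = sites, window = window,
                 n_a = nrow(a), n_b = nrow(b),
                 frac_a = if (nrow(a) > 0) nrow(sites) / nrow(a) else NA_real_,
                 frac_b = if (nrow(b) > 0) nrow(sites) / nrow(b) else NA_real_,
                 label_a = set_label(set_a), label_b = set_label(set_b)),
            class = "cooccupancy")
}

# Internal sweep: same-chromosome summit pairs with |d| <= window, found by
# binary search (findInterval) into the sorted A summits for each B summit.
candidate_pairs <- function(a, b, chroms, window) {
  out <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    ia <- which(a$chrom == ch)
    ib <- which(b$chrom == ch)
    sa <- a$summit[ia]            # sorted: peak_set orders by (chrom, summit)
    sb <- b$summit[ib]
    lo <- findInterval(sb - window - 0.5, sa) + 1L
    hi <- findInterval(sb + window + 0.5, sa)
    n <- pmax(0L, hi - lo + 1L)
    if (sum(n) == 0) next
    jb <- rep.int(seq_along(sb), n)
    ja <- sequence(n, from = lo)
    out[[ci]] <- data.frame(ia = ia[ja], ib = ib[jb],
                            summit_a = sa[ja], summit_b = sb[jb],
                            distance = abs(sa[ja] - sb[jb]))
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(data.frame(ia = integer(), ib = integer(), summit_a = integer(),
                      summit_b = integer(), distance = integer()))
  }
  do.call(rbind, out)
}

#' @export
print.cooccupancy <- function(x, ...) {
  cat(sprintf("cooccupancy: %d site(s) between '%s' (n=%d) and '%s' (n=%d), window %d bp\n",
              nrow(x$sites), x$label_a, x$n_a, x$label_b, x$n_b, x$window))
  if (!is.na(x$frac_a)) {
    pct <- summarize_fractions(nrow(x$sites), max(x$n_a, 1), max(x$n_b, 1))
    cat(sprintf("  matched: %.1f%% of %s, %.1f%% of %s\n",
                pct$percent_a, x$label_a, pct$percent_b, x$label_b))
  }
  invisible(x)
}

#' @export
summary.cooccupancy <- function(object, thresholds = c(20, 200, object$window),
                                ...) {
  thresholds <- sort(unique(thresholds))
  cdf <- distance_fractions(object, thresholds)
  out <- list(n_sites = nrow(object$sites), window = object$window,
              n_a = object$n_a, n_b = object$n_b,
              frac_a = object$frac_a, frac_b = object$frac_b,
              percent_a = if (object$n_a > 0)
                round_half_up(100 * object$frac_a, 1) else NA_real_,
              percent_b = if (object$n_b > 0)
                round_half_up(100 * object$frac_b, 1) else NA_real_,
              distance_cdf = cdf)
  class(out) <- "summary.cooccupancy"
  out
}

#' @export
print.summary.cooccupancy <- function(x, ...) {
  cat(sprintf("co-occupied sites: %d (%.1f%% of set A, %.1f%% of set B), window %d bp\n",
              x$n_sites, x$percent_a, x$percent_b, x$window))
  if (!all(is.na(x$distance_cdf))) {
    for (i in seq_along(x$distance_cdf)) {
      cat(sprintf("  summit distance <= %s bp: %.1f%%\n",
                  names(x$distance_cdf)[i], 100 * x$distance_cdf[i]))
    }
  }
  invisible(x)
}

#' @export
plot.cooccupancy <- function(x, breaks = 30, ...) {
  if (nrow(x$sites) == 0) {
    stop("no co-occupied sites to plot")
  }
  graphics::hist(x$sites$distance, breaks = breaks,
                 main = sprintf("Summit distances (%s vs %s)",
                                x$label_a, x$label_b),
                 xlab = "summit distance (bp)", col = "grey80", ...)
  invisible(x)
}

#' @export
as.data.frame.cooccupancy <- function(x, ...) x$sites

#' Cumulative summit-distance fractions
#'
#' Fraction of co-occupied sites whose summit distance is at or below each
#' threshold: the empirical CDF of the matched-summit offsets, evaluated at
#' the given thresholds.  For an empty result the fractions are undefined
#' and returned as `NA` with a warning (not 0).
#'
#' @param result a [colocalize()] result.
#' @param thresholds positive distances in bp, sorted ascending.
#' @return named numeric vector, threshold -> fraction.
#' @export
distance_fractions <- function(result, thresholds = c(20, 200, 1000)) {
  stopifnot(inherits(result, "cooccupancy"))
  if (any(thresholds <= 0)) stop("thresholds must be positive")
  if (is.unsorted(thresholds)) stop("thresholds must be sorted ascending")
  if (nrow(result$sites) == 0) {
    warning("distance fractions undefined for an empty co-occupancy result")
    return(stats::setNames(rep(NA_real_, length(thresholds)), thresholds))
  }
  d <- result$sites$distance
  stats::setNames(vapply(thresholds, function(t) mean(d <= t), numeric(1)),
                  thresholds)
}

#' Matched-site fractions of the two input sets
#'
#' Expresses one matched-site count against both input-set sizes, as
#' percentages rounded half-up to one decimal for reporting (raw fractions
#' are retained unrounded).
#'
#' @param n_matched number of matched sites.
#' @param n_a,n_b input set sizes (must be positive).
#' @return list with `percent_a`, `percent_b` (one-decimal display values)
#'   and `frac_a`, `frac_b` (raw).
#' @examples
#' summarize_fractions(3567, 48274, 14780)  # 7.4% and 24.1%
#' @export
summarize_fractions <- function(n_matched, n_a, n_b) {
  if (n_a <= 0 || n_b <= 0) stop("set sizes must be positive")
  if (n_matched < 0 || n_matched > min(n_a, n_b)) {
    stop("n_matched must lie in [0, min(n_a, n_b)]")
  }
  list(percent_a = round_half_up(100 * n_matched / n_a, 1),
       percent_b = round_half_up(100 * n_matched / n_b, 1),
       frac_a = n_matched / n_a,
       frac_b = n_matched / n_b)
}

#' Partition a cofactor peak set into proximal and distal subsets
#'
#' A cofactor peak is proximal iff at least one anchor summit lies within
#' `window` bp of its summit.  Unlike [colocalize()] this is an existence
#' test (many cofactor peaks may be proximal to one anchor), so the two
#' outputs always partition the cofactor set; the proximal subset is what
#' motif discovery is typically run on.
#'
#' @param cofactor,anchor [peak_set()] objects.
#' @param window distance in bp (default 1000).
#' @return list with `proximal` and `distal` [peak_set()]s.
#' @export
partition_proximal <- function(cofactor, anchor, window = 1000) {
  if (window <= 0) stop("window must be positive")
  co <- as.data.frame(cofactor)
  an <- as.data.frame(anchor)
  prox <- logical(nrow(co))
  if (nrow(co) > 0 && nrow(an) > 0) {
    for (ch in intersect(unique(co$chrom), unique(an$chrom))) {
      ic <- which(co$chrom == ch)
      sa <- sort(an$summit[an$chrom == ch])
      sb <- co$summit[ic]
      cnt <- findInterval(sb + window + 0.5, sa) -
        findInterval(sb - window - 0.5, sa)
      prox[ic] <- cnt > 0
    }
  }
  lab <- set_label(cofactor)
  list(proximal = peak_set(co[prox, , drop = FALSE],
                           label = paste0(lab, "_proximal")),
       distal = peak_set(co[!prox, , drop = FALSE],
                         label = paste0(lab, "_distal")))
}

#' Pairwise overlap of gene sets
#'
#' Venn-style intersection counts for two or three gene sets: for each
#' pair, the intersection size and the fraction of each set covered; for
#' three sets also the triple intersection.
#'
#' @param sets named list of 2-3 character vectors (duplicates removed).
#' @return list with `sizes` (named set sizes), `pairs` (data.frame
#'   `set1`, `set2`, `intersection`, `frac1`, `frac2`) and, for three
#'   sets, `triple` (size of the common intersection).
#' @export
peak_gene_overlap <- function(sets) {
  if (!is.list(sets) || length(sets) < 2 || length(sets) > 3) {
    stop("sets must be a list of 2 or 3 gene-id vectors")
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  cmb <- utils::combn(length(sets), 2)
  pairs <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(k) {
    i <- cmb[1, k]; j <- cmb[2, k]
    n <- length(intersect(sets[[i]], sets[[j]]))
    data.frame(set1 = names(sets)[i], set2 = names(sets)[j],
               intersection = n,
               frac1 = if (length(sets[[i]]) > 0) n / length(sets[[i]]) else NA_real_,
               frac2 = if (length(sets[[j]]) > 0) n / length(sets[[j]]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out <- list(sizes = stats::setNames(lengths(sets), names(sets)),
              pairs = pairs)
  if (length(sets) == 3) {
    out$triple <- length(Reduce(intersect, sets))
  }
  out
}

#' Expected matched fraction of the cofactor set under the planted model
#'
#' Closed-form prediction for the fraction of cofactor (set B) peaks that
#' acquire a match within `window` bp when a fraction `rho` is planted next
#' to anchor summits and the remainder falls uniformly on a genome of
#' `genome` bp carrying `n_a` anchor summits: planted peaks always match,
#' and a uniform peak finds at least one anchor within the window with the
#' Poisson-approximation probability `1 - exp(-n_a * 2 * window / genome)`.
#'
#' @param rho planted co-localization fraction in `[0, 1]`.
#' @param n_a number of anchor peaks.
#' @param window matching window in bp.
#' @param genome total genome length in bp.
#' @return expected matched fraction of set B.
#' @export
expected_matched_fraction <- function(rho, n_a, window, genome) {
  chance <- 1 - exp(-n_a * 2 * window / genome)
  rho + (1 - rho) * chance
}
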