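#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; reported percentages here follow
#' the conventional half-up rule (e.g. 7.35 -> 7.4 at one decimal).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(c(7.35, 24.1339), 1)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Internal: quiet-able progress/audit messages.  All tolerant-ingestion
# decisions (rejected rows, renamed peaks, missing genes) go through here so
# callers can count them.
coc_log <- function(...) {
  message("[coocseq] ", ...)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Internal: check a data.frame has the named columns.
need_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop(what, " is missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}
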