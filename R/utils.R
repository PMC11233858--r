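# Tail selection used throughout the scan: "top x%" means the k = ceiling(n*x)
# largest values, with every value tied at the cutoff included. This matches
# bedtools/VCFtools-style outlier picking (1 window out of 100 at 1%), not the
# textbook nearest-rank percentile (which would pick 2 of 100 at the 99th).

#' Cutoff value for an upper tail of given fraction
#'
#' @param x numeric vector (NAs dropped).
#' @param fraction tail fraction in (0, 1].
#' @returns The k-th largest value, k = `ceiling(n * fraction)`; selecting
#'   `x >= cutoff` yields the top tail with ties included.
#' @keywords internal
top_tail_cutoff <- function(x, fraction) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) return(NA_real_)
  k <- max(1L, min(n, as.integer(ceiling(n * fraction))))
  sort(x, decreasing = TRUE)[k]
}

#' @rdname top_tail_cutoff
#' @keywords internal
bottom_tail_cutoff <- function(x, fraction) {
  -top_tail_cutoff(-x, fraction)
}

# z-score across a window set; all-NA or zero-variance input gives NA scores
# (degenerate threshold: nothing can exceed it).
zscore <- function(x) {
  mu <- mean(x, na.rm = TRUE)
  s <- sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(rep(NA_real_, length(x)))
  (x - mu) / s
}

`%k%` <- function(x, nm) if (nm %in% names(x)) x[[nm]] else NULL

check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < lo) || any(x > hi)) {
    abort(sprintf("`%s` must be numeric in [%g, %g]", name, lo, hi))
  }
  invisible(x)
}
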