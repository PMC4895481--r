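#' Nx assembly/transcriptome length statistic
#'
#' Sorts lengths in decreasing order and returns the length at which the
#' cumulative sum first reaches `fraction` of the total: N50 is
#' `fraction = 0.5`, N90 is `fraction = 0.9`. The "first cumulative sum
#' >= threshold" convention is used, with ties inclusive.
#'
#' @param lengths Positive lengths in nucleotides (non-empty).
#' @param fraction Fraction of the total in (0, 1).
#' @return The Nx length.
#' @export
nx_metric <- function(lengths, fraction) {
  if (length(lengths) == 0L) stop("empty length set")
  if (any(lengths <= 0)) stop("lengths must be positive")
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1) {
    stop("fraction must lie in (0, 1)")
  }
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= fraction * sum(s))[1L]]
}

#' Length-composition summary of a sequence set
#'
#' Counts sequences per length bin together with overall summary
#' statistics. Bins are half-open `[e_i, e_{i+1})` with a final open-ended
#' bin `[e_last, Inf)`; lengths below the first edge fall into an explicit
#' underflow bin rather than being silently dropped.
#'
#' @param lengths Positive lengths (may be empty).
#' @param bin_edges Strictly ascending integer bin edges.
#' @return List with `bins` (data.frame `lower`, `upper`, `count`,
#'   `percent`; the first row is the underflow bin when non-empty
#'   `lengths` fall below the first edge), and `n`, `total`, `mean`,
#'   `min`, `max`.
#' @export
length_summary <- function(lengths, bin_edges) {
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop("bin edges must be strictly ascending")
  }
  lower <- c(-Inf, bin_edges)
  upper <- c(bin_edges, Inf)
  count <- vapply(seq_along(lower), function(i) {
    sum(lengths >= lower[i] & lengths < upper[i])
  }, 0L)
  if (count[1L] == 0L) {  # drop unused underflow bin
    lower <- lower[-1L]; upper <- upper[-1L]; count <- count[-1L]
  }
  n <- length(lengths)
  bins <- data.frame(lower = lower, upper = upper, count = count,
                     percent = if (n > 0L) 100 * count / n else rep(0, length(count)))
  list(bins = bins, n = n,
       total = if (n > 0L) sum(lengths) else 0,
       mean = if (n > 0L) mean(lengths) else NA_real_,
       min = if (n > 0L) min(lengths) else NA_real_,
       max = if (n > 0L) max(lengths) else NA_real_)
}
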