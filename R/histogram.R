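#' Filter and log-transform raw classifier values
#'
#' Keeps values `v` with `vmin <= v <= vmax` (the outlier filter applied to
#' the raw measurements, default 0.1--100 ng/mL for serum PSA) and returns
#' their natural logarithms in the original order. The number of excluded
#' records is attached as attribute `"n_excluded"`.
#'
#' @param values Numeric vector of raw positive measurements.
#' @param vmin,vmax Inclusion bounds on the original scale; `vmin` must be
#'   strictly positive (the log transform is undefined otherwise).
#' @return Numeric vector of log-values with attribute `n_excluded`.
#' @examples
#' x <- preprocess_values(c(0.05, 1, 150), vmin = 0.1, vmax = 100)
#' attr(x, "n_excluded")  # 2
#' @export
preprocess_values <- function(values, vmin = 0.1, vmax = 100) {
  stopifnot(is.numeric(values), is.numeric(vmin), is.numeric(vmax))
  if (vmin <= 0) stop("'vmin' must be strictly positive (log undefined)")
  if (vmax <= vmin) stop("'vmax' must exceed 'vmin'")
  keep <- is.finite(values) & values >= vmin & values <= vmax
  if (!any(keep)) stop("no data in range [", vmin, ", ", vmax, "]")
  out <- log(values[keep])
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Freedman-Diaconis bin width
#'
#' Bin width \eqn{h = 2\,\mathrm{IQR}(x) / n^{1/3}} for the histogram of the
#' log-values. The interquartile range uses linear interpolation between
#' order statistics (`stats::quantile` type 7), fixed so the rule is
#' reproducible.
#'
#' @param logvals Numeric vector of log-scale values, length at least 4.
#' @return Positive bin width in log-units.
#' @examples
#' fd_bin_width(1:8)  # IQR 3.5, n^(1/3) = 2  ->  3.5
#' @export
fd_bin_width <- function(logvals) {
  logvals <- as.numeric(logvals)
  stopifnot(all(is.finite(logvals)))
  n <- length(logvals)
  if (n < 4) stop("need at least 4 values for the Freedman-Diaconis rule")
  iqr <- unname(diff(stats::quantile(logvals, c(0.25, 0.75), type = 7)))
  if (iqr <= 0) stop("degenerate data: interquartile range is zero")
  2 * iqr / n^(1 / 3)
}

#' Relative-frequency histogram of log-values
#'
#' Builds the equal-width relative-frequency histogram the mixture is
#' fitted to. The bin width is the Freedman-Diaconis width
#' ([fd_bin_width()]), the number of bins is
#' \eqn{n_{bin} = \lceil (\max x - \min x)/h \rceil}, and bins are anchored
#' at `min(x)` with no rounding of edges. Bins are half-open
#' `[left, right)`; when the maximum falls exactly on the top edge one
#' further bin is appended so no sample is ever lost. Relative frequencies
#' are counts divided by `n` and sum to 1 exactly. The construction is
#' fully deterministic.
#'
#' @param logvals Numeric vector of finite log-scale values (length >= 4).
#' @param h Optional bin width override (log-units); default is the
#'   Freedman-Diaconis width.
#' @return An object of class `"relfreq_hist"`: a list with `edges`
#'   (length `n_bin + 1`), `centers`, `counts`, `rel_freq`, `h`, `n`,
#'   `n_bin`.
#' @examples
#' h <- rel_freq_hist(log(rlnorm(500)))
#' sum(h$rel_freq)  # 1
#' @export
rel_freq_hist <- function(logvals, h = NULL) {
  logvals <- as.numeric(logvals)
  stopifnot(all(is.finite(logvals)))
  n <- length(logvals)
  if (n < 4) stop("need at least 4 values to build a histogram")
  if (is.null(h)) h <- fd_bin_width(logvals)
  stopifnot(is.numeric(h), length(h) == 1L, h > 0)
  lo <- min(logvals)
  span <- max(logvals) - lo
  idx <- as.integer(floor((logvals - lo) / h)) + 1L
  n_bin <- max(1L, as.integer(ceiling(span / h)), max(idx))
  counts <- tabulate(idx, nbins = n_bin)
  edges <- lo + h * (0:n_bin)
  structure(list(edges = edges,
                 centers = lo + h * (seq_len(n_bin) - 0.5),
                 counts = counts,
                 rel_freq = counts / n,
                 h = h, n = n, n_bin = n_bin),
            class = "relfreq_hist")
}

#' @export
print.relfreq_hist <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Relative-frequency histogram: n = %d, %d bins of width %s over [%s, %s]\n",
    x$n, x$n_bin, format(x$h, digits = digits),
    format(x$edges[1], digits = digits),
    format(x$edges[length(x$edges)], digits = digits)))
  invisible(x)
}

#' @export
plot.relfreq_hist <- function(x, xlab = "log(value)", ylab = "relative frequency",
                              col = "grey85", border = "grey40", ...) {
  graphics::plot(NA, xlim = range(x$edges), ylim = c(0, max(x$rel_freq) * 1.05),
                 xlab = xlab, ylab = ylab, ...)
  graphics::rect(x$edges[-length(x$edges)], 0, x$edges[-1], x$rel_freq,
                 col = col, border = border)
  invisible(x)
}
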