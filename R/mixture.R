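#' Class-conditional Gaussian component
#'
#' A single Gaussian component on the natural-log scale of the classifier
#' variable, representing either the negative (non-diseased) or the positive
#' (diseased) class.
#'
#' @param mu Mean of the log-transformed variable (log-units).
#' @param sigma Standard deviation of the log-transformed variable
#'   (log-units); must be strictly positive.
#'
#' @return An object of class `"normal_component"`: a list with elements
#'   `mu` and `sigma`.
#'
#' @examples
#' neg <- normal_component(-0.124, 0.643)
#' pos <- normal_component(1.033, 0.766)
#' @export
normal_component <- function(mu, sigma) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(sigma), length(sigma) == 1L, is.finite(sigma))
  if (sigma <= 0) stop("'sigma' must be strictly positive")
  structure(list(mu = mu, sigma = sigma), class = "normal_component")
}

#' @export
print.normal_component <- function(x, digits = 4, ...) {
  cat(sprintf("Gaussian component (log scale): mu = %s, sigma = %s\n",
              format(x$mu, digits = digits), format(x$sigma, digits = digits)))
  invisible(x)
}

#' Binormal mixture of two class-conditional components
#'
#' The superposition of two Gaussian densities on the log scale,
#' \deqn{y(x) = \frac{a(1-pr)}{\sigma_1}\varphi\!\left(\frac{x-\mu_1}{\sigma_1}\right)
#'            + \frac{a\,pr}{\sigma_2}\varphi\!\left(\frac{x-\mu_2}{\sigma_2}\right),}
#' where the first term is the negative (non-diseased) class, the second the
#' positive (diseased) class, `pr` the prior probability (prevalence) of the
#' positive class, and `a` a free scale factor mapping a probability density
#' onto relative-frequency bin heights (for a relative-frequency histogram
#' with bin width `h`, the fitted `a` is approximately `h`).
#'
#' Each point of the curve is the sum of the two weighted component
#' densities; the model deliberately differs from the three-parameter
#' "two half-Gaussian" binormal variant. Only the two-component case is
#' supported: it encodes the working hypothesis of one homogeneous
#' negative cell population and one heterogeneous positive population.
#'
#' @param neg,pos [normal_component()] objects (or objects coercible via
#'   `normal_component(mu, sigma)` given as length-2 numeric vectors) for the
#'   negative and positive class. Components are stored as given; fitting
#'   code relabels so that `neg$mu <= pos$mu`.
#' @param pr Prior probability (prevalence) of the positive class, in
#'   \eqn{[0, 1]}.
#' @param a Non-negative scale factor; defaults to 1, in which case the
#'   mixture is a probability density.
#'
#' @return An object of class `"binorm_mixture"`.
#'
#' @examples
#' mix <- binorm_mixture(normal_component(-0.124, 0.643),
#'                       normal_component(1.033, 0.766),
#'                       pr = 0.198)
#' dbinorm(0, mix)
#' @export
binorm_mixture <- function(neg, pos, pr, a = 1) {
  if (is.numeric(neg) && length(neg) == 2L) neg <- normal_component(neg[1L], neg[2L])
  if (is.numeric(pos) && length(pos) == 2L) pos <- normal_component(pos[1L], pos[2L])
  stopifnot(inherits(neg, "normal_component"), inherits(pos, "normal_component"),
            is.numeric(pr), length(pr) == 1L, is.finite(pr),
            is.numeric(a), length(a) == 1L, is.finite(a))
  if (pr < 0 || pr > 1) stop("'pr' must lie in [0, 1]")
  if (a < 0) stop("'a' must be non-negative")
  structure(list(neg = neg, pos = pos, pr = pr, a = a),
            class = "binorm_mixture")
}

#' @export
print.binorm_mixture <- function(x, digits = 4, ...) {
  cat("Binormal mixture (log scale)\n")
  cat(sprintf("  negative class: mu1 = %s, sigma1 = %s\n",
              format(x$neg$mu, digits = digits), format(x$neg$sigma, digits = digits)))
  cat(sprintf("  positive class: mu2 = %s, sigma2 = %s\n",
              format(x$pos$mu, digits = digits), format(x$pos$sigma, digits = digits)))
  cat(sprintf("  prevalence pr = %s, scale a = %s\n",
              format(x$pr, digits = digits), format(x$a, digits = digits)))
  invisible(x)
}

#' @export
coef.binorm_mixture <- function(object, ...) {
  c(a = object$a, pr = object$pr,
    mu1 = object$neg$mu, sigma1 = object$neg$sigma,
    mu2 = object$pos$mu, sigma2 = object$pos$sigma)
}

## coerce fits / mixtures to a binorm_mixture; used by all index functions
as_binorm_mixture <- function(object) {
  if (inherits(object, "binorm_mixture")) return(object)
  if (inherits(object, "binorm_fit")) return(object$mixture)
  stop("cannot interpret 'object' as a binormal mixture")
}

## extract a class component from mixture / fit / bare component
component_of <- function(object, which = c("pos", "neg")) {
  which <- match.arg(which)
  if (inherits(object, "normal_component")) return(object)
  as_binorm_mixture(object)[[which]]
}

#' Component density and cumulative distribution
#'
#' Density and CDF of a single class-conditional Gaussian component on the
#' log scale: `normal_pdf` returns
#' \eqn{(1/\sigma)\,\varphi((x-\mu)/\sigma)} (per log-unit) and
#' `normal_cdf` returns \eqn{\Phi((x-\mu)/\sigma)}. The standard-normal CDF
#' \eqn{\Phi} is evaluated through the error function (base R's `pnorm`),
#' never a lookup table.
#'
#' @param x Numeric vector of log-scale values; must be finite.
#' @param comp A [normal_component()].
#' @return Numeric vector of densities (strictly positive) or probabilities.
#' @examples
#' normal_pdf(0, normal_component(0, 1))   # 1/sqrt(2*pi)
#' normal_cdf(1.96, normal_component(0, 1))
#' @export
normal_pdf <- function(x, comp) {
  stopifnot(inherits(comp, "normal_component"), is.numeric(x))
  if (any(!is.finite(x))) stop("'x' must be finite")
  stats::dnorm(x, mean = comp$mu, sd = comp$sigma)
}

#' @rdname normal_pdf
#' @export
normal_cdf <- function(x, comp) {
  stopifnot(inherits(comp, "normal_component"), is.numeric(x))
  if (any(!is.finite(x))) stop("'x' must be finite")
  stats::pnorm(x, mean = comp$mu, sd = comp$sigma)
}

#' Binormal mixture density
#'
#' Evaluates the binormal superposition
#' \eqn{a[(1-pr) f_1(x) + pr\, f_2(x)]} at log-scale values `x`. The
#' integral over the real line equals `a`; with `a = 1` this is the
#' population probability density of the log-transformed classifier.
#'
#' @param x Numeric vector of log-scale values.
#' @param mix A [binorm_mixture()].
#' @return Numeric vector of (relative-frequency-scale) densities.
#' @seealso [normal_pdf()]
#' @export
dbinorm <- function(x, mix) {
  mix <- as_binorm_mixture(mix)
  mix$a * ((1 - mix$pr) * normal_pdf(x, mix$neg) +
             mix$pr * normal_pdf(x, mix$pos))
}
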