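#' Control parameters for the mixture fit
#'
#' @param maxiter Maximum Levenberg-Marquardt iterations per start.
#' @param ftol,ptol Relative tolerances on the residual sum of squares and
#'   on the parameter vector passed to the LM solver.
#' @param sigma_floor Lower bound used for both standard deviations: the
#'   non-negativity constraint on the sigmas is enforced as
#'   `sigma >= sigma_floor` so the model stays numerically defined.
#' @param restarts Number of deterministic jittered restarts taken when the
#'   first run fails to converge or terminates on a bound.
#' @param seed Seed of the (local, state-restoring) RNG that generates the
#'   restart jitters; fixing it makes the multi-start fully deterministic.
#' @return A list of class `"binorm_control"`.
#' @export
binorm_control <- function(maxiter = 200, ftol = 1e-12, ptol = 1e-12,
                           sigma_floor = 1e-6, restarts = 5, seed = 1234L) {
  stopifnot(maxiter >= 1, ftol > 0, ptol > 0, sigma_floor > 0, restarts >= 0)
  structure(list(maxiter = as.integer(maxiter), ftol = ftol, ptol = ptol,
                 sigma_floor = sigma_floor, restarts = as.integer(restarts),
                 seed = as.integer(seed)),
            class = "binorm_control")
}

## run code under a fixed seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

## quantile of bin centers weighted by relative frequency
weighted_quantile <- function(centers, w, p) {
  cw <- cumsum(w) / sum(w)
  stats::approx(cw, centers, xout = p, rule = 2, ties = "ordered")$y
}

#' Feasible starting point for the mixture fit
#'
#' Heuristic starting values read off the histogram: the negative-class mean
#' starts at the 25th weighted percentile of the bin centers, the
#' positive-class mean at the 90th, both standard deviations at the weighted
#' SD of the centers, the prevalence at 0.3, and the scale factor at the bin
#' width `h` (the value it takes when the mixture integrates to the total
#' relative frequency). All values respect the fit constraints.
#'
#' @param hist A [rel_freq_hist()].
#' @param control A [binorm_control()] (supplies the sigma floor).
#' @return A [binorm_mixture()] usable as a starting point.
#' @export
initial_guess <- function(hist, control = binorm_control()) {
  stopifnot(inherits(hist, "relfreq_hist"))
  w <- hist$rel_freq
  mu1 <- weighted_quantile(hist$centers, w, 0.25)
  mu2 <- weighted_quantile(hist$centers, w, 0.90)
  if (mu2 <= mu1) mu2 <- mu1 + hist$h
  m <- sum(w * hist$centers) / sum(w)
  s <- sqrt(sum(w * (hist$centers - m)^2) / sum(w))
  s <- max(s, control$sigma_floor)
  binorm_mixture(normal_component(mu1, s), normal_component(mu2, s),
                 pr = 0.3, a = hist$h)
}

#' Coefficient of determination of a fitted curve
#'
#' \eqn{r^2 = 1 - SS_{res}/SS_{tot}} with the total sum of squares taken
#' about the mean of the observed bin heights -- the convention of R's
#' nonlinear least-squares ecosystem for reporting goodness of fit of a
#' fitted curve.
#'
#' @param observed,fitted Numeric vectors of equal length (at least 2).
#' @return A scalar; 1 for a perfect fit, 0 for a fit no better than the
#'   mean.
#' @export
r_squared <- function(observed, fitted) {
  stopifnot(is.numeric(observed), is.numeric(fitted),
            length(observed) == length(fitted), length(observed) >= 2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("observed values are constant; r-squared undefined")
  1 - sum((observed - fitted)^2) / ss_tot
}

## one bounded LM run; returns the nls.lm object or NULL on hard failure
lm_run <- function(par0, hist, fixed_pos, control) {
  obs <- hist$rel_freq
  cen <- hist$centers
  fn <- if (is.null(fixed_pos)) {
    function(p) obs - p[1] * ((1 - p[2]) * stats::dnorm(cen, p[3], p[4]) +
                                p[2] * stats::dnorm(cen, p[5], p[6]))
  } else {
    function(p) obs - p[1] * ((1 - p[2]) * stats::dnorm(cen, p[3], p[4]) +
                                p[2] * stats::dnorm(cen, fixed_pos$mu, fixed_pos$sigma))
  }
  k <- length(par0)
  lower <- c(0, 0, -Inf, control$sigma_floor, -Inf, control$sigma_floor)[seq_len(k)]
  upper <- c(Inf, 1, Inf, Inf, Inf, Inf)[seq_len(k)]
  tryCatch(
    minpack.lm::nls.lm(par = par0, lower = lower, upper = upper, fn = fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = control$maxiter, ftol = control$ftol,
                         ptol = control$ptol)),
    error = function(e) NULL)
}

at_bound <- function(par, control) {
  k <- length(par)
  pr <- par[2]
  sig <- if (k == 6L) par[c(4, 6)] else par[4]
  pr <= 1e-9 || pr >= 1 - 1e-9 || any(sig <= control$sigma_floor * (1 + 1e-6)) ||
    par[1] <= 1e-12
}

#' Decompose a relative-frequency histogram into two Gaussian components
#'
#' Bounded Levenberg-Marquardt least squares of the binormal model against
#' the bin heights: minimizes \eqn{\sum_b [p_b - y(c_b)]^2} over
#' \eqn{(a, pr, \mu_1, \sigma_1, \mu_2, \sigma_2)} subject to \eqn{a \ge 0},
#' \eqn{\sigma_1, \sigma_2 \ge} the sigma floor and \eqn{pr \in [0, 1]}.
#' When `fixed_pos` is supplied, the positive component is frozen to it and
#' only the remaining four parameters are estimated (the second pass of the
#' two-pass strategy). If the first run fails to converge or terminates on a
#' bound, up to `control$restarts` deterministic jittered restarts from the
#' initial guess are attempted; the run with the smallest residual sum of
#' squares wins, ties broken by smaller fitted prevalence. After fitting,
#' components are relabeled so the negative mean does not exceed the
#' positive mean (the model is invariant under component swap combined with
#' `pr -> 1 - pr`; the positive class is by definition the upper one).
#'
#' @param hist A [rel_freq_hist()] with at least 8 bins.
#' @param fixed_pos Optional [normal_component()]: freeze the positive
#'   component to these values.
#' @param control A [binorm_control()].
#' @return An object of class `"binorm_fit"`; see [binorm_fit()] for the
#'   elements and available methods.
#' @export
fit_binorm_hist <- function(hist, fixed_pos = NULL, control = binorm_control()) {
  stopifnot(inherits(hist, "relfreq_hist"))
  if (!is.null(fixed_pos)) stopifnot(inherits(fixed_pos, "normal_component"))
  if (hist$n_bin < 8) stop("insufficient resolution: need at least 8 bins, have ",
                           hist$n_bin)
  guess <- initial_guess(hist, control)
  p0 <- c(guess$a, guess$pr, guess$neg$mu, guess$neg$sigma,
          guess$pos$mu, guess$pos$sigma)
  if (!is.null(fixed_pos)) p0 <- p0[1:4]

  runs <- list(lm_run(p0, hist, fixed_pos, control))
  need_restart <- is.null(runs[[1]]) || !(runs[[1]]$info %in% 1:4) ||
    at_bound(runs[[1]]$par, control)
  if (need_restart && control$restarts > 0) {
    jitters <- with_local_seed(control$seed, {
      lapply(seq_len(control$restarts), function(i) {
        j <- p0
        j[1] <- p0[1] * exp(stats::rnorm(1, sd = 0.2))
        j[2] <- stats::runif(1, 0.05, 0.95)
        j[3] <- p0[3] + stats::rnorm(1, sd = 0.5 * p0[4])
        j[4] <- max(p0[4] * exp(stats::rnorm(1, sd = 0.3)), control$sigma_floor)
        if (length(j) == 6L) {
          j[5] <- p0[5] + stats::rnorm(1, sd = 0.5 * p0[6])
          j[6] <- max(p0[6] * exp(stats::rnorm(1, sd = 0.3)), control$sigma_floor)
        }
        j
      })
    })
    for (j in jitters) runs <- c(runs, list(lm_run(j, hist, fixed_pos, control)))
  }

  ok <- !vapply(runs, is.null, logical(1))
  runs <- runs[ok]
  conv <- vapply(runs, function(r) r$info %in% 1:4, logical(1))
  if (!any(conv))
    stop("mixture fit did not converge after multi-start (",
         length(runs), " runs); last solver message: ",
         if (length(runs)) runs[[length(runs)]]$message else "none")
  runs <- runs[conv]
  dev <- vapply(runs, stats::deviance, numeric(1))
  prs <- vapply(runs, function(r) r$par[2], numeric(1))
  best <- order(dev, prs)[1L]
  res <- runs[[best]]

  p <- res$par
  if (is.null(fixed_pos)) {
    mu1 <- p[3]; s1 <- p[4]; mu2 <- p[5]; s2 <- p[6]; pr <- p[2]
    if (mu1 > mu2) {  # component identity: positive class sits higher
      tmp <- c(mu1, s1); mu1 <- mu2; s1 <- s2; mu2 <- tmp[1]; s2 <- tmp[2]
      pr <- 1 - pr
    }
    mix <- binorm_mixture(normal_component(mu1, s1), normal_component(mu2, s2),
                          pr = pr, a = p[1])
    n_params <- 6L
  } else {
    mix <- binorm_mixture(normal_component(p[3], p[4]), fixed_pos,
                          pr = p[2], a = p[1])
    n_params <- 4L
  }

  fit_vals <- dbinorm(hist$centers, mix)
  resid <- hist$rel_freq - fit_vals
  structure(list(mixture = mix,
                 r.squared = r_squared(hist$rel_freq, fit_vals),
                 fixed_pos = !is.null(fixed_pos),
                 n_params = n_params,
                 converged = TRUE,
                 info = res$info,
                 message = res$message,
                 niter = res$niter,
                 deviance = sum(resid^2),
                 sstrace = res$rsstrace,
                 fitted.values = fit_vals,
                 residuals = resid,
                 histogram = hist,
                 stratum = NULL,
                 call = match.call()),
            class = "binorm_fit")
}

#' Two-pass stratified decomposition
#'
#' First pass: the anchor stratum (by default the oldest, highest-prevalence
#' one, where both components carry comparable weight and the positive
#' component is therefore well identified) is fitted with all six
#' parameters free. Second pass: every other stratum is fitted with the
#' positive component frozen to the anchor's estimate -- the working
#' hypothesis being that the positive-class distribution does not depend on
#' age -- leaving four free parameters (`a`, `pr`, `mu1`, `sigma1`). The
#' per-stratum prevalence is the fitted `pr`.
#'
#' @param hists Named list of [rel_freq_hist()] objects, one per stratum.
#' @param anchor Name of the anchor stratum in `hists`.
#' @param control A [binorm_control()].
#' @return Named list of `"binorm_fit"` objects (same names as `hists`).
#'   A stratum whose second-pass fit fails is returned as an object of class
#'   `"binorm_fit_error"` carrying the error message; a failure of the
#'   anchor fit aborts everything.
#' @export
two_pass_fit <- function(hists, anchor, control = binorm_control()) {
  stopifnot(is.list(hists), !is.null(names(hists)), anchor %in% names(hists))
  anchor_fit <- fit_binorm_hist(hists[[anchor]], control = control)
  out <- vector("list", length(hists))
  names(out) <- names(hists)
  for (nm in names(hists)) {
    if (nm == anchor) {
      out[[nm]] <- anchor_fit
    } else {
      out[[nm]] <- tryCatch(
        fit_binorm_hist(hists[[nm]], fixed_pos = anchor_fit$mixture$pos,
                        control = control),
        error = function(e) structure(list(stratum = nm, error = conditionMessage(e)),
                                      class = "binorm_fit_error"))
    }
    if (inherits(out[[nm]], "binorm_fit")) out[[nm]]$stratum <- nm
  }
  out
}
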