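#' Fit the binormal mixture to a cohort of classifier values
#'
#' The main modelling function. Raw measurements are filtered to
#' `[vmin, vmax]`, log-transformed, binned into a Freedman-Diaconis
#' relative-frequency histogram, and decomposed into the two
#' class-conditional Gaussian components by bounded Levenberg-Marquardt
#' least squares ([fit_binorm_hist()]). With an age variable on the
#' right-hand side of the formula the cohort is split into age bands and
#' fitted by the two-pass strategy ([two_pass_fit()]): the pooled stratum
#' of ages `>= anchor_min_age` is fitted with all six parameters free, and
#' each age band inherits its positive component from that anchor.
#'
#' Everything a diagnostic-test evaluation needs is then available from the
#' returned object: `summary()` derives the full index report
#' ([index_report()]), `plot()` shows the decomposed histogram or the ROC
#' curve, `simulate()` draws labeled cohorts from the fitted mixture, and
#' `coef()`, `fitted()`, `residuals()`, `predict()` behave as usual.
#'
#' @param formula A formula `value ~ 1` (single pooled fit) or
#'   `value ~ age` (age-stratified two-pass fit), with variables looked up
#'   in `data`.
#' @param data A data frame containing the variables of `formula`.
#' @param vmin,vmax Inclusion bounds on the original measurement scale
#'   (defaults 0.1 and 100, the serum-PSA outlier filter).
#' @param age_breaks Left endpoints of the age bands (the last band is
#'   open-ended); records younger than the first break are excluded.
#' @param anchor_min_age Minimum age of the pooled anchor stratum.
#' @param min_n Minimum number of records for a stratum to be fitted;
#'   smaller strata are reported as skipped.
#' @param log_transform If `TRUE` (default) values are analysed on the
#'   natural-log scale; set to `FALSE` only for variables already on an
#'   additive scale (then `vmin`/`vmax` still filter on the raw values).
#' @param control A [binorm_control()].
#'
#' @return For `value ~ 1`, an object of class `"binorm_fit"` with elements
#'   `mixture` (the fitted [binorm_mixture()]), `r.squared`, `fixed_pos`,
#'   `n_params`, `converged`, `residuals`, `fitted.values`, `histogram`,
#'   `n_excluded`. For `value ~ age`, an object of class `"binorm_strata"`
#'   holding the anchor fit, the per-band fits, and the skipped strata.
#'
#' @examples
#' spec <- cohort_spec(n = 5000)
#' cohort <- generate_cohort(spec, seed = 1)
#' fit <- binorm_fit(value ~ age, data = cohort)
#' summary(fit)
#' @export
binorm_fit <- function(formula, data,
                       vmin = 0.1, vmax = 100,
                       age_breaks = c(20, 40, 50, 60, 70, 80),
                       anchor_min_age = 65, min_n = 200,
                       log_transform = TRUE,
                       control = binorm_control()) {
  stopifnot(inherits(formula, "formula"), length(formula) == 3L)
  value_name <- deparse(formula[[2L]])
  rhs <- formula[[3L]]
  values <- eval(formula[[2L]], data, environment(formula))
  if (!is.numeric(values)) stop("the response variable must be numeric")

  stratified <- !identical(rhs, 1) && !identical(deparse(rhs), "1")
  if (!stratified) {
    lv <- if (log_transform) preprocess_values(values, vmin, vmax) else {
      keep <- is.finite(values) & values >= vmin & values <= vmax
      structure(values[keep], n_excluded = sum(!keep))
    }
    fit <- fit_binorm_hist(rel_freq_hist(as.numeric(lv)), control = control)
    fit$n_excluded <- attr(lv, "n_excluded")
    fit$stratum <- "all"
    fit$call <- match.call()
    return(fit)
  }

  age_name <- deparse(rhs)
  age <- eval(rhs, data, environment(formula))
  if (!is.numeric(age)) stop("the age variable must be numeric")
  if (length(age) != length(values)) stop("value and age lengths differ")
  keep <- is.finite(values) & values >= vmin & values <= vmax &
    is.finite(age) & age >= age_breaks[1L]
  if (!any(keep)) stop("no data in range")
  lv <- if (log_transform) log(values[keep]) else values[keep]
  age <- age[keep]

  labels <- c(paste(age_breaks[-length(age_breaks)],
                    age_breaks[-1L] - 1, sep = "-"),
              paste0(age_breaks[length(age_breaks)], "+"))
  band <- cut(age, c(age_breaks, Inf), right = FALSE, labels = labels)

  anchor_lab <- paste0(">=", anchor_min_age)
  anchor_lv <- lv[age >= anchor_min_age]
  if (length(anchor_lv) < min_n)
    stop("anchor stratum (age >= ", anchor_min_age, ") has fewer than ",
         min_n, " records")

  hists <- list()
  skipped <- integer(0)
  hists[[anchor_lab]] <- rel_freq_hist(anchor_lv)
  for (lab in labels) {
    x <- lv[band == lab]
    if (length(x) < min_n) skipped[lab] <- length(x)
    else hists[[lab]] <- rel_freq_hist(x)
  }

  fits <- two_pass_fit(hists, anchor = anchor_lab, control = control)
  structure(list(anchor = fits[[anchor_lab]],
                 strata = fits[names(fits) != anchor_lab],
                 skipped = skipped,
                 age_breaks = age_breaks,
                 anchor_min_age = anchor_min_age,
                 n_excluded = sum(!keep),
                 value_name = value_name,
                 age_name = age_name,
                 call = match.call()),
            class = "binorm_strata")
}

#' @export
print.binorm_fit <- function(x, digits = 4, ...) {
  cat("Binormal mixture decomposition",
      if (!is.null(x$stratum)) paste0(" [stratum: ", x$stratum, "]"), "\n",
      sep = "")
  cat(sprintf("  n = %d in %d bins (h = %s); %d free parameters%s\n",
              x$histogram$n, x$histogram$n_bin,
              format(x$histogram$h, digits = digits), x$n_params,
              if (x$fixed_pos) " (positive component fixed)" else ""))
  print(x$mixture, digits = digits)
  cat(sprintf("  r-squared = %s\n", format(x$r.squared, digits = digits)))
  invisible(x)
}

#' @export
coef.binorm_fit <- function(object, ...) coef(object$mixture)

#' @export
fitted.binorm_fit <- function(object, ...) object$fitted.values

#' @export
residuals.binorm_fit <- function(object, ...) object$residuals

#' @rdname binorm_fit
#' @param object,x A fitted `"binorm_fit"` object.
#' @param cost_ratio Relative cost of a false negative to a false positive,
#'   passed to [index_report()] by `summary()`.
#' @param ... Further arguments passed on.
#' @export
summary.binorm_fit <- function(object, cost_ratio = 4, ...) {
  rep <- index_report(object$mixture, cost_ratio = cost_ratio, ...)
  structure(list(fit = object, report = rep), class = "summary.binorm_fit")
}

#' @export
print.summary.binorm_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\n")
  print(x$report, digits = digits)
  invisible(x)
}

#' Predict from a fitted binormal decomposition
#'
#' @param object A `"binorm_fit"`.
#' @param newdata Numeric vector of values at which to predict; raw scale
#'   by default. Defaults to the fitted bin centers (log scale).
#' @param type `"density"` for the fitted relative-frequency curve,
#'   `"posterior"` for the posterior probability of the positive class
#'   given the value, `"lr"` for the point likelihood ratio.
#' @param log_scale Set to `TRUE` if `newdata` is already on the log scale.
#' @param ... Unused.
#' @export
predict.binorm_fit <- function(object, newdata = NULL,
                               type = c("density", "posterior", "lr"),
                               log_scale = is.null(newdata), ...) {
  type <- match.arg(type)
  x <- if (is.null(newdata)) object$histogram$centers else as.numeric(newdata)
  if (!log_scale) {
    if (any(x <= 0)) stop("raw-scale 'newdata' must be positive")
    x <- log(x)
  }
  mix <- object$mixture
  switch(type,
         density = dbinorm(x, mix),
         posterior = {
           f1 <- (1 - mix$pr) * normal_pdf(x, mix$neg)
           f2 <- mix$pr * normal_pdf(x, mix$pos)
           f2 / (f1 + f2)
         },
         lr = point_lr(x, mix))
}

#' @rdname predict.binorm_fit
#' @param what `"fit"` for the decomposed histogram, `"roc"` for the ROC
#'   curve, `"lr"` for the point likelihood ratio against the raw value
#'   (both axes logarithmic).
#' @export
plot.binorm_fit <- function(x, what = c("fit", "roc", "lr"), ...) {
  what <- match.arg(what)
  mix <- x$mixture
  if (what == "fit") {
    h <- x$histogram
    plot(h, main = if (!is.null(x$stratum)) x$stratum else "", ...)
    grid_x <- seq(h$edges[1], h$edges[length(h$edges)], length.out = 400)
    graphics::lines(grid_x, dbinorm(grid_x, mix), col = "darkorange", lwd = 2)
    graphics::lines(grid_x, mix$a * (1 - mix$pr) * normal_pdf(grid_x, mix$neg),
                    col = "steelblue", lty = 2)
    graphics::lines(grid_x, mix$a * mix$pr * normal_pdf(grid_x, mix$pos),
                    col = "magenta3", lty = 2)
    rr <- reference_range(mix$neg)
    graphics::abline(v = log(c(rr$low, rr$high)), col = "forestgreen")
  } else if (what == "roc") {
    roc <- roc_curve(mix)
    graphics::plot(roc$fpr, roc$tpr, type = "l", xlab = "1 - Specificity",
                   ylab = "Sensitivity", ...)
    graphics::abline(0, 1, lty = 3, col = "grey")
    t_opt <- optimal_cutoff(mix)
    graphics::points(1 - specificity(t_opt, mix), sensitivity(t_opt, mix),
                     pch = 19, col = "darkorange")
  } else {
    grid_x <- seq(mix$neg$mu - 3 * mix$neg$sigma,
                  mix$pos$mu + 3 * mix$pos$sigma, length.out = 400)
    graphics::plot(exp(grid_x), point_lr(grid_x, mix), type = "l", log = "xy",
                   xlab = "value", ylab = "likelihood ratio", ...)
    graphics::abline(h = 1, lty = 3, col = "grey")
  }
  invisible(x)
}

#' Simulate labeled cohorts from a fitted mixture
#'
#' Draws labeled observations from the fitted binormal mixture: each record
#' is positive with probability the fitted prevalence, its log-value drawn
#' from the corresponding component, and the raw value is the exponential.
#'
#' @param object A `"binorm_fit"`.
#' @param nsim Number of cohorts to simulate.
#' @param seed Optional seed, handled as in [stats::simulate()] (the
#'   caller's RNG state is restored).
#' @param n Records per cohort; defaults to the fitted sample size.
#' @param ... Unused.
#' @return A list of `nsim` data frames with columns `value` and `label`
#'   (`"neg"`/`"pos"`); a single data frame when `nsim = 1`.
#' @export
simulate.binorm_fit <- function(object, nsim = 1, seed = NULL, n = NULL, ...) {
  if (is.null(n)) n <- object$histogram$n
  mix <- object$mixture
  draw <- function() {
    lab <- stats::rbinom(n, 1L, mix$pr)
    comp_mu <- ifelse(lab == 1L, mix$pos$mu, mix$neg$mu)
    comp_sd <- ifelse(lab == 1L, mix$pos$sigma, mix$neg$sigma)
    data.frame(value = exp(stats::rnorm(n, comp_mu, comp_sd)),
               label = ifelse(lab == 1L, "pos", "neg"))
  }
  run <- function() {
    sims <- replicate(nsim, draw(), simplify = FALSE)
    if (nsim == 1L) sims[[1L]] else sims
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}

#' @export
print.binorm_strata <- function(x, digits = 4, ...) {
  cat("Age-stratified binormal decomposition (two-pass)\n")
  cat(sprintf("  anchor: age >= %s, n = %d, r-squared = %s\n",
              x$anchor_min_age, x$anchor$histogram$n,
              format(x$anchor$r.squared, digits = digits)))
  cat(sprintf("  shared positive component: mu2 = %s, sigma2 = %s\n",
              format(x$anchor$mixture$pos$mu, digits = digits),
              format(x$anchor$mixture$pos$sigma, digits = digits)))
  tab <- coef(x)
  print(round(tab, digits))
  if (length(x$skipped))
    cat("  skipped (insufficient data):",
        paste(sprintf("%s (n=%d)", names(x$skipped), x$skipped), collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
coef.binorm_strata <- function(object, ...) {
  fits <- c(list(object$anchor), object$strata)
  names(fits) <- c(paste0(">=", object$anchor_min_age), names(object$strata))
  ok <- vapply(fits, inherits, logical(1), what = "binorm_fit")
  t(vapply(fits[ok], function(f) c(coef(f), n = f$histogram$n,
                                   r.squared = f$r.squared),
           numeric(8)))
}

#' @rdname binorm_fit
#' @export
summary.binorm_strata <- function(object, cost_ratio = 4, ...) {
  fits <- object$strata
  reports <- lapply(fits, function(f) {
    if (!inherits(f, "binorm_fit")) return(f)
    index_report(f$mixture, cost_ratio = cost_ratio, ...)
  })
  structure(list(object = object, reports = reports,
                 cost_ratio = cost_ratio),
            class = "summary.binorm_strata")
}

#' @export
print.summary.binorm_strata <- function(x, digits = 4, ...) {
  print(x$object, digits = digits)
  for (nm in names(x$reports)) {
    cat("\n--- stratum", nm, "---\n")
    r <- x$reports[[nm]]
    if (inherits(r, "binorm_fit_error")) cat("  fit failed:", r$error, "\n")
    else print(r, digits = digits)
  }
  invisible(x)
}
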