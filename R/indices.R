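#' Sensitivity and specificity at a cut-off
#'
#' For a log-scale cut-off `t`, the sensitivity is the positive-class mass
#' above the cut-off, \eqn{Se(t) = 1 - \Phi((t-\mu_2)/\sigma_2)}, and the
#' specificity the negative-class mass below it,
#' \eqn{Sp(t) = \Phi((t-\mu_1)/\sigma_1)}. Both are analytic in the fitted
#' components: no gold-standard labels are involved.
#'
#' @param t Numeric vector of log-scale cut-offs.
#' @param object A [binorm_mixture()], `"binorm_fit"`, or a bare
#'   [normal_component()] (taken as the positive class for `sensitivity`,
#'   the negative class for `specificity`).
#' @return Numeric vector of proportions in \eqn{[0, 1]}; `sensitivity` is
#'   decreasing in `t`, `specificity` increasing.
#' @examples
#' mix <- binorm_mixture(c(-0.124, 0.643), c(1.033, 0.766), pr = 0.198)
#' sensitivity(log(1.61), mix)  # 0.766
#' specificity(log(1.61), mix)  # 0.825
#' @export
sensitivity <- function(t, object) {
  comp <- component_of(object, "pos")
  1 - normal_cdf(t, comp)
}

#' @rdname sensitivity
#' @export
specificity <- function(t, object) {
  comp <- component_of(object, "neg")
  normal_cdf(t, comp)
}

#' Binormal ROC curve
#'
#' Sweeps a grid of log-scale cut-offs from \eqn{\mu_1 - 6\sigma_1} to
#' \eqn{\mu_2 + 6\sigma_2} and records the (1 - Sp, Se) pairs; the exact
#' endpoints (0, 0) and (1, 1) are appended so trapezoid integration of the
#' curve is well defined.
#'
#' @param object A [binorm_mixture()] or `"binorm_fit"`.
#' @param grid_size Number of cut-offs in the sweep (at least 3).
#' @return A data frame of class `"roc_curve"` with columns `threshold`
#'   (log-units; `-Inf`/`Inf` for the appended endpoints), `fpr`, `tpr`,
#'   ordered by increasing threshold so `fpr` and `tpr` are non-increasing.
#' @export
roc_curve <- function(object, grid_size = 512) {
  mix <- as_binorm_mixture(object)
  stopifnot(grid_size >= 3)
  t <- seq(mix$neg$mu - 6 * mix$neg$sigma, mix$pos$mu + 6 * mix$pos$sigma,
           length.out = grid_size)
  out <- data.frame(threshold = c(-Inf, t, Inf),
                    fpr = c(1, 1 - specificity(t, mix), 0),
                    tpr = c(1, sensitivity(t, mix), 0))
  class(out) <- c("roc_curve", "data.frame")
  out
}

#' Area under the binormal ROC curve
#'
#' The closed form is \eqn{\Phi\!\big((\mu_2-\mu_1)/\sqrt{\sigma_1^2 +
#' \sigma_2^2}\big)}, the probability that a random positive-class value
#' exceeds a random negative-class one. The `"trapezoid"` method integrates
#' the discrete [roc_curve()] instead; the two agree to about 1e-3 at the
#' default grid.
#'
#' @inheritParams roc_curve
#' @param method `"closed_form"` (default) or `"trapezoid"`.
#' @return The area, a number in \eqn{[0, 1]}.
#' @examples
#' mix <- binorm_mixture(c(-0.124, 0.643), c(1.033, 0.766), pr = 0.198)
#' auc(mix)               # 0.876
#' auc(mix, "trapezoid")
#' @export
auc <- function(object, method = c("closed_form", "trapezoid"),
                grid_size = 512) {
  mix <- as_binorm_mixture(object)
  method <- match.arg(method)
  if (method == "closed_form") {
    stats::pnorm((mix$pos$mu - mix$neg$mu) /
                   sqrt(mix$neg$sigma^2 + mix$pos$sigma^2))
  } else {
    roc <- roc_curve(mix, grid_size = grid_size)
    ## fpr runs 1 -> 0; integrate tpr d(fpr) with the sign flipped
    x <- rev(roc$fpr); y <- rev(roc$tpr)
    sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  }
}

## log point-likelihood-ratio and its analytic pieces
log_point_lr <- function(t, mix) {
  log(mix$neg$sigma / mix$pos$sigma) -
    (t - mix$pos$mu)^2 / (2 * mix$pos$sigma^2) +
    (t - mix$neg$mu)^2 / (2 * mix$neg$sigma^2)
}

#' Optimal cut-off of the fitted classifier
#'
#' `mode = "youden"` returns the cut-off maximizing Youden's index
#' \eqn{Se(t) + Sp(t) - 1}, which is the crossing point of the two
#' class-conditional densities between the component means. `mode = "cost"`
#' weighs a false negative at `cost_ratio` times a false positive and
#' returns the first-order optimum of the expected misclassification cost
#' \eqn{C\,pr\,(1-Se) + (1-pr)(1-Sp)}: the cut-off where the point
#' likelihood ratio equals \eqn{(1-pr)/(C\,pr)}. Both reduce to the same
#' equation \eqn{LR(t) = k}, solved analytically as the admissible root of
#' the quadratic obtained by equating log-densities (with a root-finding
#' fallback on the increasing branch of the likelihood ratio when neither
#' quadratic root falls between the means).
#'
#' @inheritParams roc_curve
#' @param mode `"youden"` (default) or `"cost"`.
#' @param cost_ratio Relative cost of a false negative to a false positive
#'   (`C > 0`); only used for `mode = "cost"`.
#' @return The optimal cut-off on the log scale; exponentiate for the
#'   original units.
#' @examples
#' mix <- binorm_mixture(c(-0.124, 0.643), c(1.033, 0.766), pr = 0.198)
#' exp(optimal_cutoff(mix))  # 1.61
#' @export
optimal_cutoff <- function(object, mode = c("youden", "cost"), cost_ratio = 4) {
  mix <- as_binorm_mixture(object)
  mode <- match.arg(mode)
  mu1 <- mix$neg$mu; s1 <- mix$neg$sigma
  mu2 <- mix$pos$mu; s2 <- mix$pos$sigma
  if (mode == "cost") {
    if (cost_ratio <= 0) stop("'cost_ratio' must be positive")
    if (mix$pr <= 0 || mix$pr >= 1)
      stop("cost mode needs a prevalence strictly inside (0, 1)")
    k <- (1 - mix$pr) / (cost_ratio * mix$pr)
  } else {
    k <- 1
  }
  ## log LR(t) = log k  <=>  A t^2 + B t + C0 = 0
  A <- 1 / (2 * s1^2) - 1 / (2 * s2^2)
  B <- mu2 / s2^2 - mu1 / s1^2
  C0 <- mu1^2 / (2 * s1^2) - mu2^2 / (2 * s2^2) + log(s1 / s2) - log(k)
  roots <- if (abs(A) < 1e-14) {
    if (abs(B) < 1e-14) numeric(0) else -C0 / B
  } else {
    disc <- B^2 - 4 * A * C0
    if (disc < 0) numeric(0)
    else (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  }
  lo <- min(mu1, mu2); hi <- max(mu1, mu2)
  inside <- roots[roots >= lo & roots <= hi]
  if (length(inside)) return(inside[which.min(abs(inside - (lo + hi) / 2))])
  ## fallback: bisection on the increasing branch of log LR
  g <- function(t) log_point_lr(t, mix) - log(k)
  t_lo <- if (abs(A) < 1e-14) mu1 - 12 * s1 else max(-B / (2 * A), mu1 - 12 * s1)
  t_hi <- mu2 + 12 * s2
  if (!is.finite(g(t_lo)) || !is.finite(g(t_hi)) || g(t_lo) * g(t_hi) > 0)
    stop("no admissible cut-off: likelihood ratio never crosses ",
         format(k), " between the component means (extreme overlap?)")
  stats::uniroot(g, c(t_lo, t_hi), tol = 1e-12)$root
}

#' Reference interval of the negative class
#'
#' The central 95% interval of the variable in the (apparently healthy)
#' negative class, \eqn{\exp(\mu_1 \pm 1.96\,\sigma_1)}, together with the
#' 95th percentile \eqn{\exp(\mu_1 + 1.645\,\sigma_1)}, all reported on the
#' original measurement scale.
#'
#' @param object A [normal_component()] (the negative class), a
#'   [binorm_mixture()] or a `"binorm_fit"`.
#' @return A list with `low`, `high` and `p95` (original units).
#' @examples
#' reference_range(normal_component(-0.124, 0.643))
#' @export
reference_range <- function(object) {
  comp <- component_of(object, "neg")
  list(low = exp(comp$mu - 1.96 * comp$sigma),
       high = exp(comp$mu + 1.96 * comp$sigma),
       p95 = exp(comp$mu + stats::qnorm(0.95) * comp$sigma))
}

#' Predictive values from sensitivity, specificity and prevalence
#'
#' \deqn{PPV = \frac{pr\,Se}{pr\,Se + (1-pr)(1-Sp)}, \qquad
#'       NPV = \frac{(1-pr)\,Sp}{(1-pr)\,Sp + pr\,(1-Se)}.}
#'
#' @param se,sp,pr Proportions in \eqn{[0, 1]}.
#' @return Named numeric vector `c(ppv, npv)`.
#' @examples
#' predictive_values(0.766, 0.825, 0.198)  # PPV 51.9%, NPV 93.5%
#' @export
predictive_values <- function(se, sp, pr) {
  stopifnot(se >= 0, se <= 1, sp >= 0, sp <= 1, pr >= 0, pr <= 1)
  d_ppv <- pr * se + (1 - pr) * (1 - sp)
  d_npv <- (1 - pr) * sp + pr * (1 - se)
  if (d_ppv == 0) stop("PPV undefined: no positive test results under these inputs")
  if (d_npv == 0) stop("NPV undefined: no negative test results under these inputs")
  c(ppv = pr * se / d_ppv, npv = (1 - pr) * sp / d_npv)
}

#' Likelihood ratios of a positive and a negative result
#'
#' \eqn{LR^+ = Se/(1-Sp)} and \eqn{LR^- = (1-Se)/Sp}.
#'
#' @param se,sp Proportions in \eqn{[0, 1]}.
#' @return Named numeric vector `c(lr_pos, lr_neg)`.
#' @examples
#' likelihood_ratios(0.766, 0.825)  # 4.38, 0.28
#' @export
likelihood_ratios <- function(se, sp) {
  stopifnot(se >= 0, se <= 1, sp >= 0, sp <= 1)
  if (sp >= 1) stop("LR+ undefined at specificity 1")
  if (sp <= 0) stop("LR- undefined at specificity 0")
  c(lr_pos = se / (1 - sp), lr_neg = (1 - se) / sp)
}

#' Likelihood ratio of a value interval
#'
#' For an observation known only to lie in \eqn{[t_1, t_2)}:
#' \deqn{LR(t_1 \le x < t_2) = -\frac{Se(t_1) - Se(t_2)}{Sp(t_1) - Sp(t_2)},}
#' the ratio of the positive- to negative-class probability mass in the
#' interval.
#'
#' @param t1,t2 Log-scale interval bounds, `t1 < t2`.
#' @param object A [binorm_mixture()] or `"binorm_fit"`.
#' @return The interval likelihood ratio (dimensionless).
#' @examples
#' mix <- binorm_mixture(c(-0.124, 0.643), c(1.033, 0.766), pr = 0.198)
#' interval_lr(log(4), log(6), mix)  # about 20
#' @export
interval_lr <- function(t1, t2, object) {
  mix <- as_binorm_mixture(object)
  stopifnot(is.numeric(t1), is.numeric(t2), t1 < t2)
  dse <- sensitivity(t1, mix) - sensitivity(t2, mix)
  dsp <- specificity(t1, mix) - specificity(t2, mix)
  if (dsp == 0) stop("degenerate interval: no negative-class mass between t1 and t2")
  -dse / dsp
}

#' Point likelihood ratio
#'
#' The likelihood ratio of one exact value,
#' \deqn{LR(x) = \frac{\sigma_1\,\varphi((x-\mu_2)/\sigma_2)}
#'                    {\sigma_2\,\varphi((x-\mu_1)/\sigma_1)}
#'             = \frac{f_2(x)}{f_1(x)},}
#' which is also the slope of the ROC curve at the operating point of `x` --
#' a quantity that is awkward to read off a discrete empirical ROC but
#' immediate from the fitted components.
#'
#' @param x Numeric vector of log-scale values.
#' @param object A [binorm_mixture()] or `"binorm_fit"`.
#' @return Numeric vector of likelihood ratios (strictly positive).
#' @examples
#' mix <- binorm_mixture(c(-0.124, 0.643), c(1.033, 0.766), pr = 0.198)
#' point_lr(log(6), mix)  # about 43
#' point_lr(0, mix)       # about 0.34
#' @export
point_lr <- function(x, object) {
  mix <- as_binorm_mixture(object)
  normal_pdf(x, mix$pos) / normal_pdf(x, mix$neg)
}

#' Bayes posterior probability
#'
#' \deqn{P(D^+\mid E) = \frac{P(E \mid D^+)}{P(E)}\,P(D^+)} for an evidence
#' event `E` (for instance "the value is at most some threshold").
#'
#' @param p_evidence_given_disease \eqn{P(E \mid D^+)}, in \eqn{(0, 1]}.
#' @param p_evidence \eqn{P(E)}, in \eqn{(0, 1]}.
#' @param prior \eqn{P(D^+)}, in \eqn{[0, 1]}.
#' @return The posterior probability, in \eqn{[0, 1]}; inputs whose implied
#'   posterior exceeds 1 are rejected as incoherent.
#' @examples
#' posterior_probability(0.678, 0.820, 0.494)  # 0.408
#' @export
posterior_probability <- function(p_evidence_given_disease, p_evidence, prior) {
  stopifnot(p_evidence_given_disease > 0, p_evidence_given_disease <= 1,
            p_evidence > 0, p_evidence <= 1, prior >= 0, prior <= 1)
  post <- p_evidence_given_disease / p_evidence * prior
  if (post > 1 + 1e-12)
    stop("incoherent inputs: implied posterior exceeds 1")
  min(post, 1)
}

#' Full performance-index report for one fitted mixture
#'
#' Derives every standard diagnostic-test index from the fitted components
#' at one cut-off: by default the optimal cut-off of
#' [optimal_cutoff()] in the requested mode.
#'
#' @inheritParams roc_curve
#' @param cost_ratio Relative cost of a false negative to a false positive.
#' @param cutoff Optional log-scale cut-off; overrides the automatic one.
#' @param mode Cut-off criterion passed to [optimal_cutoff()].
#' @return A list of class `"index_report"`: `cutoff_log`, `cutoff_raw`,
#'   `se`, `sp`, `youden`, `ppv`, `npv`, `lr_pos`, `lr_neg`, `auc` (closed
#'   form), `prevalence`, `ref_low`, `ref_high`, `p95`, `cost_ratio`.
#' @examples
#' mix <- binorm_mixture(c(-0.124, 0.643), c(1.033, 0.766), pr = 0.198)
#' index_report(mix)
#' @export
index_report <- function(object, cost_ratio = 4, cutoff = NULL,
                         mode = c("youden", "cost")) {
  mix <- as_binorm_mixture(object)
  mode <- match.arg(mode)
  t <- if (is.null(cutoff)) optimal_cutoff(mix, mode = mode,
                                           cost_ratio = cost_ratio)
       else cutoff
  se <- sensitivity(t, mix)
  sp <- specificity(t, mix)
  pv <- predictive_values(se, sp, mix$pr)
  lr <- likelihood_ratios(se, sp)
  rr <- reference_range(mix$neg)
  structure(list(cutoff_log = t, cutoff_raw = exp(t),
                 se = se, sp = sp, youden = se + sp - 1,
                 ppv = unname(pv["ppv"]), npv = unname(pv["npv"]),
                 lr_pos = unname(lr["lr_pos"]), lr_neg = unname(lr["lr_neg"]),
                 auc = auc(mix),
                 prevalence = mix$pr,
                 ref_low = rr$low, ref_high = rr$high, p95 = rr$p95,
                 cost_ratio = cost_ratio),
            class = "index_report")
}

#' @export
print.index_report <- function(x, digits = 4, ...) {
  pct <- function(v) sprintf("%.1f%%", 100 * v)
  cat(sprintf("Cut-off: %s (log scale %s)\n",
              format(x$cutoff_raw, digits = digits),
              format(x$cutoff_log, digits = digits)))
  cat(sprintf("  Se = %s   Sp = %s   Youden = %s\n",
              pct(x$se), pct(x$sp), format(x$youden, digits = digits)))
  cat(sprintf("  PPV = %s  NPV = %s  (prevalence %s)\n",
              pct(x$ppv), pct(x$npv), pct(x$prevalence)))
  cat(sprintf("  LR+ = %s  LR- = %s  AUC = %s\n",
              format(x$lr_pos, digits = digits),
              format(x$lr_neg, digits = digits),
              format(x$auc, digits = digits)))
  cat(sprintf("  Reference range: %s - %s (95th percentile %s)\n",
              format(x$ref_low, digits = digits),
              format(x$ref_high, digits = digits),
              format(x$p95, digits = digits)))
  invisible(x)
}
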