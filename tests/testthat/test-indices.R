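mix <- mix5459()

test_that("sensitivity and specificity follow the component tail masses", {
  expect_equal(round(sensitivity(log(1.61), mix), 3), 0.766)
  expect_equal(round(specificity(log(1.61), mix), 3), 0.825)
  expect_equal(round(sensitivity(log(4), mix), 3), 0.322)
  expect_equal(round(specificity(log(4), mix), 3), 0.991)
  expect_equal(round(sensitivity(log(6), mix), 3), 0.161)
  expect_equal(round(specificity(log(6), mix), 3), 0.999)
  expect_equal(sensitivity(1.033, mix), 0.5)
  expect_equal(specificity(-0.124, mix), 0.5)
  t <- seq(-3, 4, length.out = 200)
  expect_true(all(diff(sensitivity(t, mix)) < 0))
  expect_true(all(diff(specificity(t, mix)) > 0))
})

test_that("ROC curve is monotone with exact endpoints", {
  roc <- roc_curve(mix)
  expect_true(all(diff(roc$fpr) <= 0))
  expect_true(all(diff(roc$tpr) <= 0))
  expect_equal(roc$fpr[c(1, nrow(roc))], c(1, 0))
  expect_equal(roc$tpr[c(1, nrow(roc))], c(1, 0))
  # an uninformative classifier lies on the diagonal
  flat <- binorm_mixture(mix$neg, mix$neg, pr = 0.3)
  rf <- roc_curve(flat)
  expect_lt(max(abs(rf$tpr - rf$fpr)), 1e-12)
  # the reported operating point lies on the curve
  d <- sqrt((roc$fpr - (1 - 0.825))^2 + (roc$tpr - 0.766)^2)
  expect_lt(min(d), 0.01)
})

test_that("AUC closed form, trapezoid and Monte-Carlo agree", {
  a_cf <- auc(mix)
  expect_equal(a_cf, pnorm((1.033 + 0.124) / sqrt(0.643^2 + 0.766^2)))
  expect_lt(abs(auc(mix, "trapezoid") - a_cf), 1e-3)
  expect_equal(auc(binorm_mixture(mix$neg, mix$neg, 0.5)), 0.5)
  far <- binorm_mixture(normal_component(0, 0.5), normal_component(100, 0.5), 0.5)
  expect_gt(auc(far), 1 - 1e-12)
  # P(X2 > X1) by paired Monte-Carlo draws
  set.seed(17)
  n <- 1e6
  x1 <- rnorm(n, -0.124, 0.643)
  x2 <- rnorm(n, 1.033, 0.766)
  p_hat <- mean(x2 > x1)
  expect_lt(abs(a_cf - p_hat), 3 * sqrt(p_hat * (1 - p_hat) / n))
})

test_that("optimal cut-off maximizes Youden's index at the density crossing", {
  t_star <- optimal_cutoff(mix)
  expect_equal(exp(t_star), 1.61, tolerance = 0.005)
  # density-crossing property: point LR equals 1 at the Youden optimum
  expect_equal(point_lr(t_star, mix), 1, tolerance = 1e-8)
  # it is a maximum of Se + Sp - 1 on a dense grid
  grid <- seq(-1, 1.5, length.out = 2001)
  youden <- sensitivity(grid, mix) + specificity(grid, mix) - 1
  expect_gte(sensitivity(t_star, mix) + specificity(t_star, mix) - 1,
             max(youden) - 1e-6)
  # equal sigmas give the midpoint exactly
  eqmix <- binorm_mixture(normal_component(0, 0.5), normal_component(2, 0.5), 0.3)
  expect_equal(optimal_cutoff(eqmix), 1, tolerance = 1e-10)
  # cost mode with C = (1-pr)/pr is the Youden root (LR = 1)
  expect_equal(optimal_cutoff(mix, "cost", cost_ratio = (1 - 0.198) / 0.198),
               t_star, tolerance = 1e-9)
  # C = 4 at pr = 0.198 gives a constant near 1, so it sits within a hair
  # of the Youden root
  expect_equal(exp(optimal_cutoff(mix, "cost", cost_ratio = 4)), 1.61,
               tolerance = 0.01)
})

test_that("reference range transforms the negative-class quantiles", {
  rr <- reference_range(mix)
  expect_equal(rr$low, 0.250, tolerance = 1e-2)
  expect_equal(rr$high, 3.11, tolerance = 1e-2)
  expect_equal(rr$p95, 2.54, tolerance = 1e-2)
  expect_true(rr$low < rr$p95 && rr$p95 < rr$high)
  # 95% of negative-class draws fall inside the interval
  set.seed(23)
  v <- exp(rnorm(1e5, -0.124, 0.643))
  inside <- mean(v >= rr$low & v <= rr$high)
  expect_lt(abs(inside - 0.95), 3 * sqrt(0.95 * 0.05 / 1e5))
})

test_that("predictive values follow Bayes' rule for the test result", {
  pv <- predictive_values(0.766, 0.825, 0.198)
  expect_equal(unname(pv["ppv"]), 0.519, tolerance = 1e-3)
  expect_equal(unname(pv["npv"]), 0.935, tolerance = 1e-3)
  expect_equal(unname(predictive_values(0.7, 0.8, 1)["ppv"]), 1)
  # an uninformative test returns the prior
  pv0 <- predictive_values(0.5, 0.5, 0.3)
  expect_equal(unname(pv0["ppv"]), 0.3)
  expect_equal(unname(pv0["npv"]), 0.7)
  expect_error(predictive_values(0, 1, 0.5), "undefined")
  # PPV increases with prevalence at fixed se, sp
  ppvs <- vapply(seq(0.05, 0.95, 0.05),
                 function(p) predictive_values(0.766, 0.825, p)[["ppv"]],
                 numeric(1))
  expect_true(all(diff(ppvs) > 0))
})

test_that("likelihood ratios of a positive and negative result", {
  lr <- likelihood_ratios(0.766, 0.825)
  expect_equal(round(unname(lr["lr_pos"]), 2), 4.38)
  expect_equal(round(unname(lr["lr_neg"]), 2), 0.28)
  expect_equal(unname(likelihood_ratios(0.3, 0.7)["lr_pos"]), 1)  # chance level
  lr9 <- likelihood_ratios(0.999, 0.999)
  expect_equal(unname(lr9["lr_pos"]), 999, tolerance = 1e-8)
  expect_error(likelihood_ratios(0.5, 1), "LR\\+")
  expect_error(likelihood_ratios(0.5, 0), "LR-")
})

test_that("interval likelihood ratio is the class mass ratio", {
  expect_equal(interval_lr(log(4), log(6), mix), 20, tolerance = 0.05 * 20)
  # identity: ratio of component probability masses over the interval
  t1 <- 0.2; t2 <- 0.9
  mass2 <- pnorm(t2, 1.033, 0.766) - pnorm(t1, 1.033, 0.766)
  mass1 <- pnorm(t2, -0.124, 0.643) - pnorm(t1, -0.124, 0.643)
  expect_equal(interval_lr(t1, t2, mix), mass2 / mass1, tolerance = 1e-12)
  # identical components give 1 on any interval
  flat <- binorm_mixture(mix$neg, mix$neg, 0.5)
  expect_equal(interval_lr(-1, 2, flat), 1, tolerance = 1e-12)
  # (-inf, t) limit equals the (1-Se)/Sp mass ratio
  expect_equal(interval_lr(-30, 0.5, mix),
               (1 - sensitivity(0.5, mix)) / specificity(0.5, mix),
               tolerance = 1e-9)
  expect_error(interval_lr(1, 0.5, mix))
})

test_that("point likelihood ratio matches the density ratio and the interval limit", {
  expect_equal(round(point_lr(1.79, mix)), 43)
  expect_equal(round(point_lr(0, mix), 2), 0.34)
  flat <- binorm_mixture(mix$neg, mix$neg, 0.5)
  expect_equal(point_lr(seq(-2, 2, 0.5), flat), rep(1, 9))
  # shrinking intervals converge to the point value (Richardson-style)
  x0 <- 0.8
  errs <- vapply(c(1e-3, 1e-4, 1e-5, 1e-6), function(w) {
    abs(interval_lr(x0, x0 + w, mix) - point_lr(x0 + w / 2, mix))
  }, numeric(1))
  expect_lt(errs[4], errs[1])
  expect_lt(errs[4], 1e-6)
})

test_that("posterior probability applies Bayes' theorem coherently", {
  expect_equal(round(posterior_probability(0.678, 0.820, 0.494), 3), 0.408)
  expect_equal(posterior_probability(0.4, 0.4, 0.37), 0.37)  # independent evidence
  expect_equal(posterior_probability(0.5, 0.6, 0), 0)
  expect_error(posterior_probability(0.9, 0.1, 0.5), "incoherent")
})

test_that("predictive values and the Bayes posterior are the same computation", {
  se <- sensitivity(0.4, mix); sp <- specificity(0.4, mix)
  p_pos <- 0.198 * se + 0.802 * (1 - sp)  # P(test positive)
  expect_equal(unname(predictive_values(se, sp, 0.198)["ppv"]),
               posterior_probability(se, p_pos, 0.198), tolerance = 1e-12)
})

test_that("index report assembles all indices consistently", {
  rep <- index_report(mix, cost_ratio = 4)
  expect_s3_class(rep, "index_report")
  expect_equal(rep$cutoff_raw, exp(rep$cutoff_log))
  expect_equal(rep$youden, rep$se + rep$sp - 1)
  expect_equal(rep$lr_pos, rep$se / (1 - rep$sp))
  expect_equal(rep$lr_neg, (1 - rep$se) / rep$sp)
  expect_equal(rep$prevalence, 0.198)
  expect_true(rep$ref_low < rep$ref_high)
  expect_output(print(rep), "Cut-off")
})
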