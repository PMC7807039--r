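# end-to-end orchestration and the modelling interface

make_input <- function(n = 15000, seed = 101, blind = TRUE, path = tempfile(fileext = ".csv")) {
  coh <- generate_cohort(cohort_spec(n = n), seed = seed)
  names(coh)[names(coh) == "value"] <- "PSA"
  if (blind) coh$label <- NULL
  write.csv(coh, path, row.names = FALSE, quote = FALSE)
  path
}

test_that("formula interface dispatches between pooled and stratified fits", {
  coh <- generate_cohort(cohort_spec(n = 8000), seed = 55)
  pooled <- binorm_fit(value ~ 1, coh)
  expect_s3_class(pooled, "binorm_fit")
  expect_identical(pooled$n_params, 6L)
  expect_false(pooled$fixed_pos)
  strat <- binorm_fit(value ~ age, coh, min_n = 200)
  expect_s3_class(strat, "binorm_strata")
  expect_false(strat$anchor$fixed_pos)
  for (f in strat$strata) {
    if (inherits(f, "binorm_fit")) {
      expect_true(f$fixed_pos)
      expect_equal(f$mixture$pos$mu, strat$anchor$mixture$pos$mu)
    }
  }
  # methods behave
  expect_named(coef(pooled), c("a", "pr", "mu1", "sigma1", "mu2", "sigma2"))
  expect_length(fitted(pooled), pooled$histogram$n_bin)
  expect_equal(residuals(pooled), pooled$histogram$rel_freq - fitted(pooled))
  expect_output(print(strat), "two-pass")
  s <- summary(pooled)
  expect_s3_class(s$report, "index_report")
  sim <- simulate(pooled, seed = 1, n = 500)
  expect_identical(nrow(sim), 500L)
  expect_true(all(sim$label %in% c("neg", "pos")))
  post <- predict(pooled, newdata = c(1, 4, 10), type = "posterior")
  expect_true(all(post >= 0 & post <= 1) && !is.unsorted(post))
})

test_that("run harvest writes complete, re-runnable reports", {
  input <- make_input()
  out1 <- file.path(tempdir(), "harvest_out1")
  res <- run_harvest(input, value_col = "PSA", age_col = "age", out_dir = out1)
  expect_true(file.exists(file.path(out1, "fit_summary.json")))
  expect_true(file.exists(file.path(out1, "run_log.txt")))
  summ <- jsonlite::read_json(file.path(out1, "fit_summary.json"))
  expect_true(length(summ) >= 2)
  prs <- vapply(summ, function(s) s$prevalence, numeric(1))
  expect_true(all(prs >= 0 & prs <= 1))
  # prevalence should rise across the mid-age bands as generated
  nm <- vapply(summ, function(s) s$stratum, character(1))
  expect_gt(prs[nm == "60-69"], prs[nm == "40-49"])
  roc_files <- list.files(out1, pattern = "^roc_.*\\.tsv$", full.names = TRUE)
  expect_gt(length(roc_files), 0)
  roc <- read.delim(roc_files[1])
  expect_true(all(diff(roc$tpr) <= 0))
  # bit-identical re-run
  out2 <- file.path(tempdir(), "harvest_out2")
  run_harvest(input, value_col = "PSA", age_col = "age", out_dir = out2)
  for (f in list.files(out1)) {
    if (f == "run_log.txt") next  # log contains the input path only
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)
  }
  unlink(c(out1, out2), recursive = TRUE)
})

test_that("malformed rows are skipped and counted, run proceeds", {
  input <- make_input(n = 6000)
  lines <- readLines(input)
  lines <- append(lines, c("not_a_number,55", "3.2,not_an_age"), after = 3)
  writeLines(lines, input)
  out <- file.path(tempdir(), "harvest_bad")
  expect_silent(res <- run_harvest(input, value_col = "PSA", age_col = "age",
                                   out_dir = out))
  log <- readLines(file.path(out, "run_log.txt"))
  expect_true(any(grepl("malformed rows skipped: 2", log)))
  unlink(out, recursive = TRUE)
})

test_that("input without an age column yields a single six-parameter fit", {
  input <- make_input(n = 8000)
  out <- file.path(tempdir(), "harvest_noage")
  res <- run_harvest(input, value_col = "PSA", age_col = NULL, out_dir = out)
  expect_s3_class(res$fit, "binorm_fit")
  summ <- jsonlite::read_json(file.path(out, "fit_summary.json"))
  expect_length(summ, 1)
  expect_identical(summ[[1]]$n_params, 6L)
  unlink(out, recursive = TRUE)
})

test_that("label-free prevalence tracks the generating prevalence end to end", {
  # blind cohort in, prevalence out: the core promise of the method
  coh <- generate_cohort(recovery_spec(), seed = 77)
  coh$label <- NULL
  fit <- binorm_fit(value ~ age, coh, age_breaks = c(54, 65),
                    anchor_min_age = 65)
  pr_hat <- fit$strata[["54-64"]]$mixture$pr
  expect_lt(abs(pr_hat - 0.198), 0.1)
  expect_gte(fit$strata[["54-64"]]$r.squared, 0.95)
})
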