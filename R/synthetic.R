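#' Specification of a synthetic labeled cohort
#'
#' Describes an age-structured population with the statistical structure the
#' decomposition method assumes: within each age band, log-values of the
#' negative class follow a Gaussian whose mean rises with age (one
#' homogeneous population of normal cells producing more marker with age),
#' while the positive class follows a single age-invariant Gaussian (a
#' heterogeneous malignant population). Raw values are truncated to
#' `[vmin, vmax]` by resampling.
#'
#' Defaults emulate a serum-PSA screening population: six age bands
#' 20-39, 40-49, 50-59, 60-69, 70-79, 80+, prevalences 0.02, 0.08, 0.18,
#' 0.41, 0.545, 0.50 (rising steeply through midlife, flattening after 75),
#' negative-class log-means -0.45, -0.30, -0.124, 0, 0.10, 0.20 with
#' common sigma 0.643, and positive component (1.033, 0.766).
#'
#' @param n Total number of records.
#' @param age_breaks Left endpoints of the age bands (last band open,
#'   capped at `age_max` when drawing integer ages).
#' @param pr Per-band prevalence of the positive class (recycled if scalar).
#' @param neg_mu Per-band negative-class log-mean (recycled if scalar);
#'   should be non-decreasing with age.
#' @param neg_sigma Negative-class log-SD (scalar).
#' @param pos A [normal_component()], the age-invariant positive class.
#' @param age_weights Sampling weights of the age bands.
#' @param vmin,vmax Truncation bounds on the original scale.
#' @param age_max Upper cap for ages drawn in the last band.
#' @return A list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n = 20000,
                        age_breaks = c(20, 40, 50, 60, 70, 80),
                        pr = c(0.02, 0.08, 0.18, 0.41, 0.545, 0.50),
                        neg_mu = c(-0.45, -0.30, -0.124, 0, 0.10, 0.20),
                        neg_sigma = 0.643,
                        pos = normal_component(1.033, 0.766),
                        age_weights = rep(1, length(age_breaks)),
                        vmin = 0.1, vmax = 100, age_max = 95) {
  nb <- length(age_breaks)
  pr <- rep_len(pr, nb)
  neg_mu <- rep_len(neg_mu, nb)
  age_weights <- rep_len(age_weights, nb)
  stopifnot(n >= 1, all(diff(age_breaks) > 0),
            all(pr >= 0), all(pr <= 1), neg_sigma > 0,
            inherits(pos, "normal_component"),
            all(age_weights >= 0), sum(age_weights) > 0,
            vmin > 0, vmax > vmin, age_max > age_breaks[nb],
            all(diff(neg_mu) >= 0))
  structure(list(n = as.integer(n), age_breaks = age_breaks, pr = pr,
                 neg_mu = neg_mu, neg_sigma = neg_sigma, pos = pos,
                 age_weights = age_weights / sum(age_weights),
                 vmin = vmin, vmax = vmax, age_max = age_max),
            class = "cohort_spec")
}

#' Generate a labeled synthetic cohort
#'
#' Draws `spec$n` records: an age band from the band weights, an integer
#' age uniform within the band, a hidden class label positive with the
#' band's prevalence, a log-value from the label's component, and the raw
#' value as its exponential. Values outside `[vmin, vmax]` are resampled
#' (within the same band and label) so the record count is exact; the
#' resampling slightly reshapes the extreme tails relative to the
#' untruncated components.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional integer seed; the caller's RNG state is restored,
#'   and a fixed seed makes the cohort fully reproducible.
#' @return A data frame with columns `age` (integer), `value` (original
#'   scale) and `label` (`"neg"`/`"pos"`).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 1000), seed = 7)
#' table(cohort$label)
#' @export
generate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  run <- function() {
    nb <- length(spec$age_breaks)
    upper <- c(spec$age_breaks[-1] - 1, spec$age_max)
    band <- sample.int(nb, spec$n, replace = TRUE, prob = spec$age_weights)
    age <- spec$age_breaks[band] +
      floor(stats::runif(spec$n) * (upper[band] - spec$age_breaks[band] + 1))
    label <- stats::rbinom(spec$n, 1L, spec$pr[band])
    mu <- ifelse(label == 1L, spec$pos$mu, spec$neg_mu[band])
    sd <- ifelse(label == 1L, spec$pos$sigma, spec$neg_sigma)
    value <- exp(stats::rnorm(spec$n, mu, sd))
    bad <- which(value < spec$vmin | value > spec$vmax)
    if (length(bad) > 0.99 * spec$n)
      stop("spec inconsistent with bounds: truncation acceptance rate < 1%")
    tries <- 0L
    while (length(bad) && tries < 1000L) {
      value[bad] <- exp(stats::rnorm(length(bad), mu[bad], sd[bad]))
      bad <- bad[value[bad] < spec$vmin | value[bad] > spec$vmax]
      tries <- tries + 1L
    }
    if (length(bad))
      stop("spec inconsistent with bounds: resampling did not terminate")
    data.frame(age = as.integer(age), value = value,
               label = ifelse(label == 1L, "pos", "neg"))
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}

#' Label-based performance indices (gold-standard oracle)
#'
#' Classifies each record by whether its log-value exceeds the cut-off and
#' compares against the hidden labels, giving the contingency-table
#' estimates \eqn{Se = TP/(TP+FN)}, \eqn{Sp = TN/(TN+FP)},
#' \eqn{PPV = TP/(TP+FP)}, \eqn{NPV = TN/(TN+FN)}. This is the
#' gold-standard route the label-free analytic indices are validated
#' against.
#'
#' @param cohort A data frame with columns `value` and `label`
#'   (`"neg"`/`"pos"`), as from [generate_cohort()].
#' @param t Log-scale cut-off.
#' @return Named numeric vector `c(se, sp, ppv, npv)`.
#' @export
empirical_indices <- function(cohort, t) {
  stopifnot(is.data.frame(cohort), all(c("value", "label") %in% names(cohort)),
            is.numeric(t), length(t) == 1L)
  pos <- cohort$label == "pos"
  if (!any(pos) || all(pos)) stop("both classes must be present in the cohort")
  test_pos <- log(cohort$value) > t
  tp <- sum(pos & test_pos); fn <- sum(pos & !test_pos)
  tn <- sum(!pos & !test_pos); fp <- sum(!pos & test_pos)
  c(se = tp / (tp + fn), sp = tn / (tn + fp),
    ppv = tp / (tp + fp), npv = tn / (tn + fn))
}

#' Write a cohort to CSV
#'
#' @param cohort A data frame from [generate_cohort()].
#' @param path Output file path.
#' @param blind Drop the `label` column, producing input indistinguishable
#'   from a real unlabeled cohort.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, blind = FALSE) {
  out <- if (blind) cohort[setdiff(names(cohort), "label")] else cohort
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
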