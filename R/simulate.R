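# Synthetic cohorts with covariate-dependent concept drift, plus raw
# Bernoulli error streams for detector tests.

#' Configure the cohort simulator
#'
#' The simulator emulates a two-class (sex) metabolomic cohort: a panel of
#' shared metabolites with per-feature class separation, a young-skewed age
#' distribution over a configurable range, and a change in the
#' feature-to-label relationship for samples whose age exceeds a true
#' threshold. Missing values and occasional outliers are injected on top.
#'
#' @param n_samples Number of samples.
#' @param n_features Number of metabolite features (default 22, the size of
#'   a typical cross-study intersection panel).
#' @param sex_effect Class separation per feature, in units of the
#'   within-class standard deviation (recycled to `n_features`). The
#'   default `c(1.5, 0.8)` alternates strongly and weakly dimorphic
#'   metabolites: real panels mix a few sex-marked compounds (creatinine
#'   and friends) with many weak ones.
#' @param drift_covariate Name of the drifting covariate (default `"age"`).
#' @param covariate_range Range of the covariate, in years (default
#'   `c(18, 75)`, a healthy adult cohort).
#' @param age_shape Beta shape parameters of the covariate distribution on
#'   its range; the default `c(1, 9)` gives a young-skewed cohort (median
#'   ~22 y) typical of volunteer/student recruitment.
#' @param true_threshold Covariate value above which the concept changes
#'   (default 26 years).
#' @param drift_mode `"flip"` (class effect scaled by
#'   `1 - 2 * drift_magnitude`: unchanged at 0, erased at 0.5, fully
#'   sign-reversed at 1), `"attenuate"` (effect times `1 - drift_magnitude`)
#'   or `"shift"` (class-independent mean offset of `drift_magnitude`
#'   within-class sds).
#' @param drift_magnitude Strength of the concept change in `[0, 1]` for
#'   flip/attenuate, or in sd units for shift (default 1).
#' @param drift_fraction Fraction of features carrying the drift (default
#'   0.5). The drifted subset is the most strongly dimorphic features:
#'   confounding tracks the very metabolites that carry the predictive
#'   signal, which is what makes it damaging.
#' @param noise_cv Within-class coefficient of variation of each feature
#'   (sd as a fraction of the baseline abundance, default 0.15).
#' @param missing_rate,outlier_rate Per-cell injection rates in `[0, 1)`.
#' @param outlier_sd_multiplier Outliers are placed at the baseline mean
#'   plus/minus this many within-class sds (default 4).
#' @param seed Integer seed; the whole cohort is reproducible.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_samples = 500, n_features = 22,
                       sex_effect = c(1.5, 0.8),
                       drift_covariate = "age", covariate_range = c(18, 75),
                       age_shape = c(1, 9), true_threshold = 26,
                       drift_mode = c("flip", "attenuate", "shift"),
                       drift_magnitude = 1, drift_fraction = 0.5,
                       noise_cv = 0.15, missing_rate = 0.02,
                       outlier_rate = 0.005, outlier_sd_multiplier = 4,
                       seed = 1) {
  drift_mode <- match.arg(drift_mode)
  stopifnot(n_features >= 1, length(covariate_range) == 2)
  if (!(missing_rate >= 0 && missing_rate < 1) ||
      !(outlier_rate >= 0 && outlier_rate < 1)) {
    abort("`missing_rate` and `outlier_rate` must lie in [0, 1).")
  }
  if (true_threshold < covariate_range[1] || true_threshold > covariate_range[2]) {
    abort("`true_threshold` must lie inside `covariate_range`.")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic cohort with covariate-dependent concept drift
#'
#' Draws class labels, covariates and feature values according to a
#' [sim_config()], then injects missing values and outliers. Features are
#' Gaussian within class; for samples whose drift covariate exceeds the true
#' threshold the class effect is flipped, attenuated or shifted on the
#' drifted feature subset.
#'
#' @param config A [sim_config()].
#' @return A list with elements `cohort` (a [cohort()], split unassigned)
#'   and `truth` (ground truth: labels, covariates, drifted features,
#'   threshold, injected missing/outlier coordinates).
#' @examples
#' gen <- generate_cohort(sim_config(n_samples = 40, seed = 7))
#' gen$cohort
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  withr::with_seed(as.integer(cfg$seed), {
    n <- cfg$n_samples
    p <- cfg$n_features
    ids <- sprintf("S%04d", seq_len(n))
    feats <- sprintf("C9%04d", seq_len(p))
    sex <- ifelse(rbinom(n, 1, 0.5) == 1, "female", "male")
    lo <- cfg$covariate_range[1]; hi <- cfg$covariate_range[2]
    age <- lo + (hi - lo) * rbeta(n, cfg$age_shape[1], cfg$age_shape[2])
    bmi <- rnorm(n, 24, 3)  # non-confounding covariate for scanning
    mu <- runif(p, 100, 1000)
    sigma <- cfg$noise_cv * mu
    dir <- sample(c(-1, 1), p, replace = TRUE)
    eff_size <- rep_len(cfg$sex_effect, p)
    effect <- eff_size * sigma * dir
    n_drift <- max(1L, round(cfg$drift_fraction * p))
    # drift hits the most dimorphic metabolites (random ties)
    drifted <- sort(feats[order(-abs(eff_size), sample(p))][seq_len(n_drift)])
    is_drifted <- feats %in% drifted
    yy <- as.numeric(sex == "female") - 0.5           # -/+ 0.5
    post <- age > cfg$true_threshold
    m <- matrix(0, n, p, dimnames = list(ids, feats))
    for (j in seq_len(p)) {
      eff <- rep(effect[j], n)
      base <- rep(mu[j], n)
      if (is_drifted[j]) {
        if (cfg$drift_mode == "flip") {
          # interpolates from unchanged (0) through null (0.5) to fully
          # sign-reversed (1)
          eff[post] <- (1 - 2 * cfg$drift_magnitude) * eff[post]
        } else if (cfg$drift_mode == "attenuate") {
          eff[post] <- (1 - cfg$drift_magnitude) * eff[post]
        } else {
          base[post] <- base[post] + cfg$drift_magnitude * sigma[j]
        }
      }
      m[, j] <- rnorm(n, base + yy * eff, sigma[j])
    }
    # outliers first (on observed values), then missingness on top
    out_mask <- matrix(rbinom(n * p, 1, cfg$outlier_rate) == 1, n, p)
    if (any(out_mask)) {
      idx <- which(out_mask, arr.ind = TRUE)
      sign <- sample(c(-1, 1), nrow(idx), replace = TRUE)
      m[idx] <- mu[idx[, 2]] + sign * cfg$outlier_sd_multiplier * sigma[idx[, 2]]
    }
    miss_mask <- matrix(FALSE, n, p)
    if (cfg$missing_rate > 0) {
      for (try in 1:10) {
        miss_mask <- matrix(rbinom(n * p, 1, cfg$missing_rate) == 1, n, p)
        if (all(colSums(!miss_mask) > 0)) break
        if (try == 10) abort("missing_rate leaves an all-missing column; lower it.")
        inform("generate_cohort: resampling missing mask (all-missing column).")
      }
      m[miss_mask] <- NA_real_
    }
    abundance <- matrix_to_abundance(m, ids)
    clinical <- tibble(sample_id = ids, sex = sex, age = age, bmi = bmi)
    truth <- list(
      labels = setNames(sex, ids),
      covariates = clinical[c("sample_id", "age", "bmi")],
      drifted_features = drifted,
      true_threshold = cfg$true_threshold,
      missing_cells = as_tibble(which(miss_mask, arr.ind = TRUE),
                                .name_repair = ~c("row", "col")),
      outlier_cells = as_tibble(which(out_mask, arr.ind = TRUE),
                                .name_repair = ~c("row", "col")),
      config = cfg
    )
    list(cohort = cohort(abundance, clinical, target = "sex"), truth = truth)
  })
}

#' Generate a piecewise-Bernoulli misclassification stream
#'
#' A raw 0/1 error sequence for exercising the drift detectors: the error
#' probability is piecewise constant, changing at the given 0-based indices.
#'
#' @param length Stream length.
#' @param change_points Data frame (or list coercible to one) with columns
#'   `index` (0-based start of the segment, first must be 0, strictly
#'   ascending) and `rate` (Bernoulli error probability in `[0, 1]`).
#' @param seed Integer seed.
#' @return An `"error_stream"` tibble with columns `position`, `sample_id`,
#'   `error`.
#' @examples
#' generate_error_stream(10, data.frame(index = 0, rate = 0), seed = 1)
#' @export
generate_error_stream <- function(length, change_points, seed = 1) {
  cp <- as.data.frame(change_points)
  stopifnot(all(c("index", "rate") %in% names(cp)))
  if (is.unsorted(cp$index, strictly = TRUE)) {
    abort("`change_points` indices must be strictly ascending.")
  }
  if (cp$index[1] != 0) abort("first change point must start at index 0.")
  if (any(cp$rate < 0 | cp$rate > 1)) abort("rates must lie in [0, 1].")
  if (any(cp$index >= length)) abort("change point beyond stream length.")
  starts <- cp$index + 1L
  ends <- c(cp$index[-1], length)
  err <- integer(length)
  withr::with_seed(as.integer(seed), {
    for (k in seq_len(nrow(cp))) {
      span <- starts[k]:ends[k]
      err[span] <- rbinom(length(span), 1, cp$rate[k])
    }
  })
  new_error_stream(err, sprintf("t%04d", seq_len(length)), "dataset_order")
}

new_error_stream <- function(errors, sample_ids, ordering_key,
                             covariate_values = NULL) {
  out <- tibble(position = seq_along(errors),
                sample_id = sample_ids,
                error = as.integer(errors))
  if (!is.null(covariate_values)) out$ordering_value <- covariate_values
  structure(out, ordering_key = ordering_key,
            class = c("error_stream", class(out)))
}
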