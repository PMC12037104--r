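# Correction of a confounded classifier: cohort segmentation at the
# nominated threshold, or scaling parameters fitted within confounder strata.

#' Binarize a covariate at a threshold
#'
#' Stratum 0 collects samples with covariate value at or below the
#' threshold, stratum 1 the rest (boundary samples go to the lower stratum).
#'
#' @param clinical Clinical tibble.
#' @param covariate Covariate column name (must be complete).
#' @param threshold Finite threshold in covariate units (e.g. 26 years).
#' @return A tibble with columns `sample_id` and `stratum` (integer 0/1).
#' @export
binarize_covariate <- function(clinical, covariate, threshold) {
  if (!covariate %in% names(clinical)) {
    abort(sprintf("covariate `%s` not found.", covariate))
  }
  if (!is.finite(threshold)) abort("`threshold` must be finite.")
  v <- clinical[[covariate]]
  if (anyNA(v)) {
    abort(sprintf("missing `%s` values for sample(s): %s.", covariate,
                  toString(clinical$sample_id[is.na(v)])))
  }
  stratum <- as.integer(v > threshold)
  if (length(unique(stratum)) == 1) {
    warn(sprintf("binarize_covariate: threshold %.3g leaves a single stratum.",
                 threshold))
  }
  tibble(sample_id = clinical$sample_id, stratum = stratum)
}

#' Segment a cohort at a confounder threshold
#'
#' Partitions the cohort into the below- and above-threshold strata, each
#' keeping its own train/test assignment, so downstream models can be
#' trained per stratum.
#'
#' @param dataset A [cohort()].
#' @param covariate Confounding covariate name.
#' @param threshold Segmentation threshold.
#' @return A named list of two cohorts, `low` (covariate <= threshold) and
#'   `high`.
#' @export
segment_by_threshold <- function(dataset, covariate, threshold) {
  stopifnot(inherits(dataset, "cohort"))
  strata <- binarize_covariate(dataset$clinical, covariate, threshold)
  if (length(unique(strata$stratum)) < 2) {
    abort("segmentation produced an empty stratum; adjust the threshold.")
  }
  y <- as.character(target_factor(dataset))
  for (s in c(low = 0L, high = 1L)) {
    counts <- table(factor(y[strata$stratum == s], levels = unique(y)))
    if (any(counts < 2)) {
      abort(sprintf(
        "stratum `%s` has < 2 samples in class(es) %s; segmentation needs a substantial amount of data per stratum - consider stratified scaling instead.",
        names(which(c(low = 0L, high = 1L) == s)),
        toString(names(counts)[counts < 2])))
    }
  }
  purrr::map(c(low = 0L, high = 1L), function(s) {
    keep_samples(dataset, strata$sample_id[strata$stratum == s])
  })
}

#' Scale features within confounder strata
#'
#' Fits scaling parameters separately within each binary stratum (on the
#' designated fitting samples of that stratum) and applies them to the
#' stratum's members in all splits. No samples are lost and the sample
#' order is unchanged - the stated advantage of this correction over
#' segmentation. With a threshold outside the covariate range (a single
#' stratum) this reduces exactly to ordinary scaling.
#'
#' @param abundance Complete abundance tibble.
#' @param strata Tibble from [binarize_covariate()] (or any data frame with
#'   `sample_id`, `stratum`) covering all samples.
#' @param spec A [scaling_spec()].
#' @param fit_samples Optional character vector of sample ids to estimate
#'   the parameters on (e.g. the training split); defaults to all samples.
#' @return The scaled abundance tibble, same shape and order as the input.
#' @export
stratified_scale <- function(abundance, strata, spec = scaling_spec(),
                             fit_samples = NULL) {
  check_abundance(abundance, complete = TRUE)
  strata <- as_tibble(strata)
  stopifnot(all(c("sample_id", "stratum") %in% names(strata)))
  if (!all(abundance$sample_id %in% strata$sample_id)) {
    abort("`strata` must cover every sample in `abundance`.")
  }
  s <- strata$stratum[match(abundance$sample_id, strata$sample_id)]
  out <- abundance
  for (lv in unique(s)) {
    rows <- which(s == lv)
    part <- abundance[rows, ]
    fit_part <- if (is.null(fit_samples)) part else {
      sel <- part$sample_id %in% fit_samples
      if (!any(sel)) {
        warn(sprintf("stratum %s has no fitting samples; fitting on all its members.", lv))
        part
      } else part[sel, ]
    }
    params <- fit_scaler(fit_part, spec)
    out[rows, feature_names(abundance)] <-
      apply_scaler(part, params, spec)[feature_names(abundance)]
  }
  out
}

#' Pair before/after pipeline evaluations
#'
#' Joins the per-(classifier x scaling) metrics of an uncorrected and a
#' corrected run into a single comparison report with accuracy and event
#' count deltas. Both runs must share splits, seeds and model grid.
#'
#' @param before,after `"pipeline_eval"` objects (see [run_pipeline()]).
#' @return A `"comparison_report"` tibble with columns `scaling`, `family`,
#'   `accuracy_before`, `accuracy_after`, `accuracy_delta`,
#'   `warning_count_before/after` and `drift_count_before/after`; replicates
#'   where no drift remains after correction are flagged in
#'   `drift_free_after`.
#' @export
compare_before_after <- function(before, after) {
  stopifnot(inherits(before, "pipeline_eval"), inherits(after, "pipeline_eval"))
  if (!identical(before$split_ids, after$split_ids) ||
      !identical(before$seed, after$seed)) {
    abort("before/after runs differ in split or seed; refusing to pair them.")
  }
  b <- before$metrics; a <- after$metrics
  if (!identical(b[c("scaling", "family")], a[c("scaling", "family")])) {
    abort("before/after runs cover different (scaling, family) grids.")
  }
  out <- tibble(
    scaling = b$scaling, family = b$family,
    accuracy_before = b$accuracy, accuracy_after = a$accuracy,
    accuracy_delta = a$accuracy - b$accuracy,
    warning_count_before = b$warning_count, warning_count_after = a$warning_count,
    drift_count_before = b$drift_count, drift_count_after = a$drift_count,
    drift_free_after = a$drift_count == 0
  )
  structure(out, correction = after$correction,
            class = c("comparison_report", class(out)))
}
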