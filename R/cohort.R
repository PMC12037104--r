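#' Bundle an abundance table with clinical annotations
#'
#' A cohort ties together a sample-by-metabolite abundance tibble, a clinical
#' table carrying the prediction target and candidate confounding covariates,
#' and an optional train/test split assignment. All downstream stages
#' (scaling, classification, drift detection, correction) operate on cohorts.
#'
#' @param abundance Tibble with a `sample_id` column followed by numeric
#'   metabolite columns (KEGG compound ids or free-text names). `NA` marks a
#'   missing measurement.
#' @param clinical Tibble with `sample_id`, the target column and any
#'   covariate columns (e.g. `age` in years, `bmi` in kg/m^2). Must cover
#'   exactly the samples present in `abundance`.
#' @param target Name of the clinical column holding the two-class label.
#' @param split Optional tibble with columns `sample_id` and `split`
#'   (`"train"`, `"test"`, `"validation"` or `"unassigned"`). Defaults to
#'   all samples unassigned; see [split_dataset()].
#'
#' @return An object of class `"cohort"`: a list with elements `abundance`,
#'   `clinical`, `target` and `split`, each a tibble (or string).
#' @examples
#' ab <- tibble::tibble(sample_id = c("s1", "s2"), C00300 = c(1, 2))
#' cl <- tibble::tibble(sample_id = c("s1", "s2"), sex = c("male", "female"))
#' cohort(ab, cl)
#' @export
cohort <- function(abundance, clinical, target = "sex", split = NULL) {
  abundance <- as_tibble(abundance)
  clinical <- as_tibble(clinical)
  check_abundance(abundance)
  check_clinical(clinical, target = target)
  if (!setequal(abundance$sample_id, clinical$sample_id)) {
    abort("`abundance` and `clinical` must cover the same sample ids.")
  }
  # align clinical to abundance row order
  clinical <- clinical[match(abundance$sample_id, clinical$sample_id), ]
  if (is.null(split)) {
    split <- tibble(sample_id = abundance$sample_id, split = "unassigned")
  }
  split <- as_tibble(split)
  stopifnot(all(c("sample_id", "split") %in% names(split)))
  if (!setequal(split$sample_id, abundance$sample_id)) {
    abort("`split` must cover the same sample ids as `abundance`.")
  }
  ok <- split$split %in% c("train", "test", "validation", "unassigned")
  if (!all(ok)) abort("`split` values must be train/test/validation/unassigned.")
  split <- split[match(abundance$sample_id, split$sample_id), ]
  structure(
    list(abundance = abundance, clinical = clinical,
         target = target, split = split),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  nfeat <- length(feature_names(x$abundance))
  cat(sprintf("<cohort> %d samples x %d features; target `%s`\n",
              nrow(x$abundance), nfeat, x$target))
  tab <- table(x$split$split)
  cat("  split:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  covariates:",
      toString(setdiff(names(x$clinical), c("sample_id", x$target))), "\n")
  invisible(x)
}

#' Extract one split of a cohort
#'
#' @param x A [cohort()].
#' @param which Split tag to keep (`"train"`, `"test"`, ...).
#' @return A cohort containing only the selected samples (split tags kept).
#' @export
cohort_subset <- function(x, which) {
  stopifnot(inherits(x, "cohort"))
  keep <- x$split$sample_id[x$split$split %in% which]
  if (!length(keep)) abort(sprintf("no samples in split `%s`.", toString(which)))
  keep_samples(x, keep)
}

# subset a cohort to an explicit set of sample ids (order of `x` preserved)
keep_samples <- function(x, ids) {
  sel <- x$abundance$sample_id %in% ids
  cohort(x$abundance[sel, ], x$clinical[sel, ], target = x$target,
         split = x$split[sel, ])
}

# target labels as a factor with stable (sorted) level order
target_factor <- function(x) {
  y <- x$clinical[[x$target]]
  factor(as.character(y), levels = sort(unique(as.character(y))))
}
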