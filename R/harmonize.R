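# Dataset harmonization: identifier unification, feature intersection,
# half-minimum imputation, 2-SD outlier screening, stratified splitting.

#' Read an abundance, clinical or mapping table from CSV/TSV
#'
#' The delimiter is sniffed from the file extension: `.tsv`/`.txt`/`.tab`
#' are read as tab-separated, anything else as comma-separated. Files are
#' expected UTF-8 with `.` as decimal point.
#'
#' @param path Path to the file. For abundance tables the first column is the
#'   sample id and the header names the metabolite features; for clinical
#'   tables columns are `sample_id`, the target and covariates; for mapping
#'   tables columns are `name` and `kegg_id`.
#' @return A tibble. Abundance tables have their first column renamed to
#'   `sample_id`.
#' @export
read_abundance <- function(path) {
  x <- read_delim_sniff(path)
  names(x)[1] <- "sample_id"
  x$sample_id <- as.character(x$sample_id)
  check_abundance(x)
  x
}

#' @rdname read_abundance
#' @export
read_clinical <- function(path) {
  x <- read_delim_sniff(path)
  names(x)[1] <- "sample_id"
  x$sample_id <- as.character(x$sample_id)
  check_clinical(x)
  x
}

#' @rdname read_abundance
#' @export
read_mapping <- function(path) {
  x <- read_delim_sniff(path)
  if (!all(c("name", "kegg_id") %in% names(x))) {
    abort("mapping file must have columns `name` and `kegg_id`.")
  }
  x
}

read_delim_sniff <- function(path) {
  delim <- if (grepl("\\.(tsv|txt|tab)$", path, ignore.case = TRUE)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

#' Write a harmonized abundance table as TSV
#'
#' @param abundance Abundance tibble.
#' @param path Output path.
#' @return The input, invisibly.
#' @export
write_abundance <- function(abundance, path) {
  readr::write_tsv(abundance, path)
  invisible(abundance)
}

#' Rename metabolite features to KEGG compound identifiers
#'
#' Applies a name-to-KEGG mapping table to the feature columns of an
#' abundance table. Features without a mapping entry are dropped (and
#' reported via a message and the `"dropped"` attribute). Two input features
#' mapping to the same KEGG id is an ambiguity the caller must resolve:
#' merging columns would silently average distinct assays, so this errors.
#'
#' @param abundance Abundance tibble (`sample_id` + feature columns).
#' @param mapping Data frame with columns `name` (feature name as it appears
#'   in `abundance`) and `kegg_id` (well-formed `C#####` identifier).
#' @return The abundance tibble with features renamed to KEGG ids; dropped
#'   feature names are attached as attribute `"dropped"`.
#' @examples
#' ab <- tibble::tibble(sample_id = "s1", Creatinine = 2.5)
#' map <- data.frame(name = "Creatinine", kegg_id = "C00791")
#' map_identifiers(ab, map)
#' @export
map_identifiers <- function(abundance, mapping) {
  check_abundance(abundance)
  if (!all(c("name", "kegg_id") %in% names(mapping))) {
    abort("`mapping` must have columns `name` and `kegg_id`.")
  }
  bad <- mapping$kegg_id[!is_kegg_id(mapping$kegg_id)]
  if (length(bad)) {
    abort(sprintf("malformed KEGG compound ids in mapping: %s.",
                  toString(unique(bad))))
  }
  feats <- feature_names(abundance)
  hit <- mapping[mapping$name %in% feats, , drop = FALSE]
  dup <- hit$kegg_id[duplicated(hit$kegg_id)]
  if (length(dup)) {
    colliders <- hit[hit$kegg_id %in% dup, , drop = FALSE]
    abort(sprintf(
      "ambiguous mapping: features map to the same KEGG id: %s.",
      paste(sprintf("%s -> %s", colliders$name, colliders$kegg_id),
            collapse = ", ")))
  }
  dropped <- setdiff(feats, hit$name)
  if (length(dropped)) {
    inform(sprintf("map_identifiers: dropped %d unmapped feature(s): %s",
                   length(dropped), toString(dropped)))
  }
  keep <- abundance[c("sample_id", hit$name)]
  names(keep) <- c("sample_id", hit$kegg_id[match(names(keep)[-1], hit$name)])
  structure(keep, dropped = dropped)
}

#' Reduce abundance tables to their common metabolites
#'
#' Takes two or more abundance tables keyed by KEGG ids and restricts each to
#' the intersection of their feature sets, in a single canonical
#' (lexicographic) column order so downstream outputs are bit-stable.
#' Sample rows are untouched.
#'
#' @param matrices A list of abundance tibbles (each `sample_id` + features).
#' @return A list of abundance tibbles, all with identical feature columns.
#' @export
intersect_features <- function(matrices) {
  if (!is.list(matrices) || length(matrices) < 2) {
    abort("`matrices` must be a list of at least 2 abundance tables.")
  }
  purrr::walk(matrices, check_abundance)
  sets <- purrr::map(matrices, feature_names)
  common <- Reduce(intersect, sets)
  if (!length(common)) {
    abort(sprintf("empty feature intersection (per-table feature counts: %s).",
                  toString(lengths(sets))))
  }
  common <- sort(common)
  purrr::map(matrices, ~ .x[c("sample_id", common)])
}

#' Half-minimum imputation of missing abundances
#'
#' Replaces every missing entry of a metabolite column by half the minimum
#' observed value of that column (the standard left-censoring surrogate for
#' abundances below the detection limit). Observed entries are untouched, so
#' the operation is idempotent.
#'
#' @param abundance Abundance tibble; each feature must have at least one
#'   observed value.
#' @return The abundance tibble with no missing values.
#' @examples
#' ab <- tibble::tibble(sample_id = paste0("s", 1:4),
#'                      C00300 = c(2, 4, NA, 8))
#' impute_half_min(ab)  # NA -> 1
#' @export
impute_half_min <- function(abundance) {
  check_abundance(abundance)
  feats <- feature_names(abundance)
  all_na <- feats[vapply(abundance[feats], function(x) all(is.na(x)), logical(1))]
  if (length(all_na)) {
    abort(sprintf("cannot impute all-missing feature(s): %s.", toString(all_na)))
  }
  out <- abundance
  for (f in feats) {
    x <- out[[f]]
    if (anyNA(x)) x[is.na(x)] <- 0.5 * min(x, na.rm = TRUE)
    out[[f]] <- x
  }
  out
}

#' Flag measurements outside two standard deviations of their group mean
#'
#' An entry is flagged when it falls strictly outside mean +/- 2 sd, with
#' mean and sd (n-1 denominator) computed per condition group and per
#' metabolite. Constant columns (sd 0) flag nothing. The function only
#' returns the mask; the removal policy (replace-and-re-impute vs report
#' only) is applied by [screen_outliers()].
#'
#' @param abundance Complete abundance tibble (impute first).
#' @param groups Character/factor vector of condition labels, one per sample
#'   (typically the target class).
#' @return A logical matrix (samples x features, dimnames set) with `TRUE`
#'   where the measurement is an outlier for its group.
#' @export
flag_outliers <- function(abundance, groups) {
  check_abundance(abundance, complete = TRUE)
  m <- feature_matrix(abundance)
  groups <- as.character(groups)
  if (length(groups) != nrow(m)) {
    abort("`groups` must have one label per sample.")
  }
  small <- names(which(table(groups) < 2))
  if (length(small)) {
    abort(sprintf("condition group(s) with a single sample (sd undefined): %s.",
                  toString(small)))
  }
  mask <- matrix(FALSE, nrow(m), ncol(m), dimnames = dimnames(m))
  for (g in unique(groups)) {
    rows <- which(groups == g)
    mu <- colMeans(m[rows, , drop = FALSE])
    sg <- apply(m[rows, , drop = FALSE], 2, sd)
    dev <- abs(sweep(m[rows, , drop = FALSE], 2, mu))
    mask[rows, ] <- sweep(dev, 2, 2 * sg) > 0
  }
  mask
}

#' Screen outliers and apply the configured policy
#'
#' Runs [flag_outliers()] and either replaces the flagged entries with
#' missing values followed by one round of [impute_half_min()] (default) or
#' leaves the values in place and only reports them.
#'
#' @inheritParams flag_outliers
#' @param policy `"replace"` (set flagged entries missing and re-impute once)
#'   or `"report"` (leave values untouched).
#' @return A list with `abundance` (the treated table) and `report`, a tibble
#'   with columns `sample_id`, `feature_id`, `value`, `group`, `group_mean`,
#'   `group_sd` describing every flagged cell.
#' @export
screen_outliers <- function(abundance, groups, policy = c("replace", "report")) {
  policy <- match.arg(policy)
  mask <- flag_outliers(abundance, groups)
  idx <- which(mask, arr.ind = TRUE)
  m <- feature_matrix(abundance)
  groups <- as.character(groups)
  report <- tibble(
    sample_id = rownames(mask)[idx[, 1]],
    feature_id = colnames(mask)[idx[, 2]],
    value = m[idx],
    group = groups[idx[, 1]]
  )
  # group statistics that triggered each flag
  if (nrow(report)) {
    stats <- purrr::map_dfr(seq_len(nrow(report)), function(i) {
      rows <- groups == report$group[i]
      x <- m[rows, report$feature_id[i]]
      tibble(group_mean = mean(x), group_sd = sd(x))
    })
    report <- bind_cols(report, stats)
  } else {
    report$group_mean <- numeric(0)
    report$group_sd <- numeric(0)
  }
  out <- abundance
  if (policy == "replace" && nrow(report)) {
    m[idx] <- NA_real_
    out <- bind_cols(out["sample_id"], as_tibble(m))
    out <- impute_half_min(out)
  }
  list(abundance = out, report = report)
}

#' Stratified train/test split of a cohort
#'
#' Assigns each sample to the training or test split, stratified by the
#' target class so both splits keep the cohort's class balance. The
#' assignment is reproducible for a fixed seed.
#'
#' @param dataset A [cohort()].
#' @param test_fraction Fraction of samples assigned to the test split
#'   (default 0.2, i.e. an 80/20 split).
#' @param seed Integer seed controlling the assignment (default 42).
#' @return The cohort with its `split` table filled with `"train"`/`"test"`.
#' @export
split_dataset <- function(dataset, test_fraction = 0.2, seed = 42) {
  stopifnot(inherits(dataset, "cohort"))
  if (!(test_fraction > 0 && test_fraction < 1)) {
    abort("`test_fraction` must be in (0, 1).")
  }
  y <- as.character(target_factor(dataset))
  ids <- dataset$abundance$sample_id
  counts <- table(y)
  if (any(counts < 2)) {
    abort(sprintf("class(es) with fewer than 2 samples: %s.",
                  toString(names(counts)[counts < 2])))
  }
  assign <- rep("train", length(ids))
  withr::with_seed(as.integer(seed), {
    for (cl in sort(unique(y))) {
      rows <- which(y == cl)
      n_test <- round(length(rows) * test_fraction)
      n_test <- min(max(n_test, 0L), length(rows) - 1L)
      if (n_test > 0) {
        # sample over sorted ids so the draw is invariant to row order
        rows <- rows[order(ids[rows])]
        assign[sample(rows, n_test)] <- "test"
      }
    }
  })
  dataset$split <- tibble(sample_id = ids, split = assign)
  dataset
}
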