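# Internal helpers shared across modules.

# Column layout convention: an abundance table is a tibble whose first column
# is `sample_id` (character, unique) and whose remaining columns are numeric
# metabolite abundances, one column per feature. NA marks a missing value.

feature_names <- function(abundance) {
  setdiff(names(abundance), "sample_id")
}

feature_matrix <- function(abundance) {
  m <- as.matrix(abundance[feature_names(abundance)])
  rownames(m) <- abundance$sample_id
  storage.mode(m) <- "double"
  m
}

matrix_to_abundance <- function(m, sample_ids = rownames(m)) {
  out <- as_tibble(m)
  tibble(sample_id = sample_ids) |> bind_cols(out)
}

check_abundance <- function(abundance, complete = FALSE,
                            arg = deparse(substitute(abundance))) {
  if (!is.data.frame(abundance)) {
    abort(sprintf("`%s` must be a data frame.", arg))
  }
  if (!"sample_id" %in% names(abundance)) {
    abort(sprintf("`%s` must have a `sample_id` column.", arg))
  }
  ids <- abundance$sample_id
  if (anyDuplicated(ids)) {
    abort(sprintf("`%s` has duplicated sample ids: %s.", arg,
                  toString(unique(ids[duplicated(ids)]))))
  }
  feats <- feature_names(abundance)
  if (anyDuplicated(feats)) {
    abort(sprintf("`%s` has duplicated feature columns.", arg))
  }
  bad <- feats[!vapply(abundance[feats], is.numeric, logical(1))]
  if (length(bad)) {
    abort(sprintf("`%s`: non-numeric feature columns: %s.", arg, toString(bad)))
  }
  if (complete && anyNA(abundance[feats])) {
    abort(sprintf("`%s` contains missing values; impute first.", arg))
  }
  invisible(abundance)
}

check_clinical <- function(clinical, target = NULL,
                           arg = deparse(substitute(clinical))) {
  if (!is.data.frame(clinical) || !"sample_id" %in% names(clinical)) {
    abort(sprintf("`%s` must be a data frame with a `sample_id` column.", arg))
  }
  if (anyDuplicated(clinical$sample_id)) {
    abort(sprintf("`%s` has duplicated sample ids.", arg))
  }
  if (!is.null(target)) {
    if (!target %in% names(clinical)) {
      abort(sprintf("target column `%s` not found in `%s`.", target, arg))
    }
    y <- clinical[[target]][!is.na(clinical[[target]])]
    if (length(unique(y)) < 2) {
      abort(sprintf("target `%s` must have at least 2 classes.", target))
    }
  }
  invisible(clinical)
}

# KEGG compound identifiers: "C" followed by exactly five digits.
is_kegg_id <- function(x) grepl("^C[0-9]{5}$", x)

# deterministic child seeds: small integers derived from a user seed, kept
# well inside 32-bit range
child_seed <- function(seed, offset) {
  (as.integer(seed) %% 100000L) * 211L + as.integer(offset) %% 211L
}
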