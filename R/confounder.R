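# Associating drift/warning positions with covariates the classifier never
# saw, and deriving a candidate confounding threshold from them.

#' Associate drift events with a clinical covariate
#'
#' For every warning/drift event, records the value of `covariate` for the
#' ordered sample at the event position. The covariate may be any clinical
#' column, including a metabolite re-used as covariate (join it onto the
#' clinical table first); it does not need to be the stream's ordering key.
#' Warnings are additionally flagged as *confirmed* when they open the
#' warning period in which a drift of the same detector fires (the last
#' warning entry of a drift episode). Earlier warning entries of the episode
#' were cancelled when the statistic fell back below the warning threshold,
#' and warning-only episodes more often reflect transient data drift than a
#' concept change.
#'
#' @param events A `"drift_events"` tibble from [detect_drift()] /
#'   [ddm_detect()] / [eddm_detect()].
#' @param stream The `"error_stream"` the events were detected on.
#' @param clinical Clinical tibble covering the streamed samples.
#' @param covariate Name of the covariate column.
#' @return A `"covariate_association"`: list with the per-event `values`
#'   tibble (including `confirmed` flags and each drift episode's sustained
#'   error `elevation` over the 30 instances after its trigger),
#'   `values_at_warnings`, `values_at_drifts`, a per-level `summary`
#'   (n, mean, min, max) and `candidate_threshold` (elevation-weighted mean
#'   of confirmed warnings; `NA` and flagged when there are no warnings).
#' @export
associate_covariate <- function(events, stream, clinical, covariate) {
  stopifnot(inherits(events, "drift_events"), inherits(stream, "error_stream"))
  if (!covariate %in% names(clinical)) {
    abort(sprintf("covariate `%s` not found in the clinical table.", covariate))
  }
  ev <- as_tibble(unclass(events))
  if (nrow(ev) && any(ev$position < 1 | ev$position > nrow(stream))) {
    abort("event positions fall outside the stream.")
  }
  cov <- clinical[[covariate]][match(stream$sample_id, clinical$sample_id)]
  if (anyNA(cov)) {
    abort(sprintf("missing `%s` values among streamed samples.", covariate))
  }
  ev$value <- cov[ev$position]
  # A drift's onset is the warning period still active when it fires: the
  # last warning entry of its episode. Earlier warning entries of the same
  # episode were cancelled (the statistic fell back below the warning
  # threshold), i.e. false alarms, and warning-only episodes never
  # confirmed at all.
  ev$confirmed <- ev$level == "drift"
  # elevation: how far the error rate actually settles above the episode's
  # reference level after the drift fires. A false alarm reverts to its
  # baseline (elevation near 0); a genuine transition sustains it. Warnings
  # of strong transitions therefore carry more weight when averaging.
  ev$elevation <- NA_real_
  drifts <- which(ev$level == "drift")
  for (r in drifts) {
    post <- stream$error[seq(ev$position[r] + 1L,
                             min(ev$position[r] + 30L, nrow(stream)))]
    rate <- if (length(post) >= 5) mean(post) else ev$stat[r]
    ev$elevation[r] <- max(rate - ev$ref[r], 0)
    w <- which(ev$level == "warning" &
                 ev$detector == ev$detector[r] &
                 ev$episode == ev$episode[r] &
                 ev$position <= ev$position[r])
    if (length(w)) {
      ev$confirmed[max(w)] <- TRUE
      ev$elevation[max(w)] <- ev$elevation[r]
    }
  }
  summary <- ev |>
    group_by(.data$level) |>
    summarise(n = n(), mean = mean(.data$value), min = min(.data$value),
              max = max(.data$value), .groups = "drop")
  assoc <- structure(
    list(covariate = covariate, values = ev,
         values_at_warnings = ev$value[ev$level == "warning"],
         values_at_drifts = ev$value[ev$level == "drift"],
         summary = summary, candidate_threshold = NA_real_,
         threshold_rule = "mean_of_warnings"),
    class = "covariate_association")
  if (length(assoc$values_at_warnings)) {
    assoc$candidate_threshold <- derive_threshold(assoc)
  } else {
    assoc$no_events <- nrow(ev) == 0
  }
  assoc
}

#' @export
print.covariate_association <- function(x, ...) {
  cat(sprintf("<covariate_association> %s: %d warning(s), %d drift(s)\n",
              x$covariate, length(x$values_at_warnings),
              length(x$values_at_drifts)))
  cat(sprintf("  candidate threshold (%s): %s\n", x$threshold_rule,
              format(x$candidate_threshold, digits = 4)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.covariate_association <- function(x, ...) x$values

#' @exportS3Method generics::glance
glance.covariate_association <- function(x, ...) {
  tibble(covariate = x$covariate,
         n_warnings = length(x$values_at_warnings),
         n_drifts = length(x$values_at_drifts),
         candidate_threshold = x$candidate_threshold)
}

#' Derive a candidate confounding threshold
#'
#' @param assoc A `"covariate_association"`.
#' @param rule `"mean_of_warnings"` (default: the arithmetic mean of the
#'   covariate values at warning events), `"mean_of_drifts"`, or
#'   `"midpoint"` (`(min + max) / 2` over both event levels).
#' @param use For warning-based rules: `"confirmed"` restricts to warnings
#'   whose episode ended in a drift (falling back to all warnings when no
#'   episode was confirmed), `"all"` uses every warning.
#' @return The threshold (a single number, in covariate units).
#' @export
derive_threshold <- function(assoc, rule = c("mean_of_warnings",
                                             "mean_of_drifts", "midpoint"),
                             use = c("confirmed", "all")) {
  stopifnot(inherits(assoc, "covariate_association"))
  rule <- match.arg(rule)
  use <- match.arg(use)
  ev <- assoc$values
  pick <- function(values, what) {
    if (!length(values)) {
      abort(sprintf("no %s events to derive a threshold from; try rule = %s.",
                    what,
                    toString(setdiff(c("mean_of_warnings", "mean_of_drifts",
                                       "midpoint"), rule))))
    }
    values
  }
  level_mean <- function(lev) {
    w <- ev[ev$level == lev, ]
    if (use == "confirmed" && any(w$confirmed)) {
      w <- w[w$confirmed, ]
      pick(w$value, lev)
      # keep the dominant transitions (episodes sustaining at least half
      # the strongest elevation) and weight by elevation; minor episodes
      # are detector noise around the main change
      keep <- w$elevation >= 0.5 * max(w$elevation)
      w <- w[keep | !any(keep), ]
      stats::weighted.mean(w$value, w$elevation + 1e-9)
    } else {
      mean(pick(w$value, lev))
    }
  }
  switch(rule,
    mean_of_warnings = level_mean("warning"),
    mean_of_drifts = level_mean("drift"),
    midpoint = {
      v <- pick(ev$value, "warning or drift")
      (min(v) + max(v)) / 2
    }
  )
}

#' Scan candidate covariates and rank them
#'
#' Associates the same event list with each candidate covariate and ranks
#' the candidates by how tightly the warning events cluster in covariate
#' space (the range of covariate values at warnings, scaled by the
#' covariate's own range over the stream; smaller is a stronger candidate).
#'
#' @inheritParams associate_covariate
#' @param covariates Character vector of clinical column names to scan.
#' @return A tibble with one row per covariate (`covariate`, `n_warnings`,
#'   `n_drifts`, `warning_range`, `scaled_range`, `candidate_threshold`),
#'   ordered strongest candidate first.
#' @export
scan_covariates <- function(events, stream, clinical, covariates) {
  rows <- purrr::map(covariates, function(cv) {
    assoc <- associate_covariate(events, stream, clinical, cv)
    w <- assoc$values[assoc$values$level == "warning", ]
    if (any(w$confirmed)) w <- w[w$confirmed, ]
    cov_all <- clinical[[cv]][match(stream$sample_id, clinical$sample_id)]
    rng <- if (nrow(w)) diff(range(w$value)) else NA_real_
    tibble(covariate = cv,
           n_warnings = length(assoc$values_at_warnings),
           n_drifts = length(assoc$values_at_drifts),
           warning_range = rng,
           scaled_range = rng / max(diff(range(cov_all)), .Machine$double.eps),
           candidate_threshold = assoc$candidate_threshold)
  })
  out <- bind_rows(rows)
  out[order(is.na(out$scaled_range), out$scaled_range), ]
}
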