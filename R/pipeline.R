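# End-to-end orchestration: conventional classifiers (Section A), drift
# detection and confounder nomination (Section B), correction and
# re-evaluation (Section C).

#' Configure a pipeline run
#'
#' Exactly one of `simulate` or `input` must be given. All block defaults
#' reproduce the package's standard workflow; any element can be overridden
#' by supplying a partial list.
#'
#' @param simulate A [sim_config()] (or a list of its arguments) to generate
#'   the cohort in place of input files.
#' @param input List with `abundance` (path, or character vector of paths -
#'   multiple tables are reduced to their common KEGG features and the first
#'   is modelled), `clinical` (path) and optional `mapping` (path to a
#'   name-to-KEGG table).
#' @param harmonize List: `outlier_policy` (`"replace"`/`"report"`),
#'   `test_fraction` (0.2), `condition` (outlier grouping column; default
#'   the target class).
#' @param scaling List: `methods` (default all nine), `fit_on`, `epsilon`,
#'   `power_exponent`, `log_offset`.
#' @param classify List: `families` (default all five), `cv_folds` (10),
#'   `hyperparameters` (named per family).
#' @param drift List: `detectors` (default both), `config`
#'   (a [detector_config()]), `stream_scope` (`"test"`, the default: the
#'   reported warning/drift counts are detected on the fixed model's
#'   held-out test stream; or `"all"`).
#' @param confounder List: `covariates` (default `c("age", "bmi")`),
#'   `rule` (threshold rule), `use` (`"confirmed"`/`"all"` warnings),
#'   `scan_scope` (`"all"`, the default: the nomination scan runs on the
#'   fixed model's predictions over the whole cohort, which samples the
#'   covariate axis densely enough to localise the change point; or
#'   `"test"`).
#' @param nominate List: `detector` (`"ddm"`), `family` (`"ridge"`),
#'   `scaling` (`"autoscaling"`) - the primary combination whose stream
#'   drives confounder nomination, with automatic fallback to the
#'   tightest-clustering drift-positive combination.
#' @param correct List: `strategy` (`"auto"`, `"segmentation"` or
#'   `"stratified_scaling"`; auto picks segmentation when every stratum can
#'   support per-stratum training, the data-hungrier option), `threshold`
#'   (override; default the derived one), `auto_accept` (skip the
#'   interactive confirmation of the nominated confounder).
#' @param seed Global integer seed propagated to every seeded stage.
#' @param out_dir Optional directory for artifacts (TSV/JSON).
#' @return A validated `"run_config"` list.
#' @export
run_config <- function(simulate = NULL, input = NULL, harmonize = list(),
                       scaling = list(), classify = list(), drift = list(),
                       confounder = list(), nominate = list(),
                       correct = list(), seed = 1, out_dir = NULL) {
  if (is.null(simulate) == is.null(input)) {
    abort("exactly one of `simulate` or `input` must be supplied.")
  }
  if (!is.null(simulate) && !inherits(simulate, "sim_config")) {
    simulate <- do.call(sim_config, simulate)
  }
  cfg <- list(
    simulate = simulate, input = input,
    harmonize = modifyList(list(outlier_policy = "replace",
                                test_fraction = 0.2, condition = NULL),
                           harmonize),
    scaling = modifyList(list(methods = SCALING_METHODS, fit_on = "train",
                              epsilon = 1e-9, power_exponent = 0.5,
                              log_offset = FALSE), scaling),
    classify = modifyList(list(families = MODEL_FAMILIES, cv_folds = 10,
                               hyperparameters = list()), classify),
    drift = modifyList(list(detectors = c("ddm", "eddm"),
                            config = detector_config(),
                            stream_scope = "test"), drift),
    confounder = modifyList(list(covariates = c("age", "bmi"),
                                 rule = "mean_of_warnings",
                                 use = "confirmed",
                                 scan_scope = "all"), confounder),
    nominate = modifyList(list(detector = "ddm", family = "ridge",
                               scaling = "autoscaling"), nominate),
    correct = modifyList(list(strategy = "auto", threshold = NULL,
                              auto_accept = FALSE), correct),
    seed = as.integer(seed), out_dir = out_dir
  )
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path Path to a YAML file whose top-level keys mirror the
#'   arguments of [run_config()].
#' @return A `"run_config"`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

# evaluate the (scaling x family) grid on one cohort; returns pipeline_eval
evaluate_grid <- function(x, cfg, ordering, correction = NULL,
                          trainer = NULL) {
  scalings <- cfg$scaling$methods
  families <- cfg$classify$families
  rows <- list(); events <- list(); stream_results <- list()
  for (sc in scalings) {
    spec <- scaling_spec(sc, epsilon = cfg$scaling$epsilon,
                         power_exponent = cfg$scaling$power_exponent,
                         log_offset = cfg$scaling$log_offset)
    scaled <- tryCatch(prepare_scaled(x, spec, cfg, correction),
                       error = function(e) e)
    for (fam in families) {
      key <- paste(sc, fam, sep = "|")
      if (inherits(scaled, "error")) {
        inform(sprintf("scaling `%s` skipped: %s", sc,
                       conditionMessage(scaled)))
        rows[[key]] <- tibble(scaling = sc, family = fam,
                              accuracy = NA_real_, warning_count = NA_integer_,
                              drift_count = NA_integer_)
        next
      }
      mseed <- child_seed(cfg$seed, match(sc, scalings) * 10 + match(fam, families))
      fit_fun <- trainer %||% default_trainer
      res <- fit_fun(scaled, fam, mseed, cfg)
      # reported counts come from the stream_scope stream (held-out test by
      # default); the confounder scan uses the scan_scope stream
      metric_res <- if (cfg$drift$stream_scope == "all") res$all_result
                    else res$test_result
      stream <- build_error_stream(metric_res, x$clinical, ordering)
      ev <- detect_drift(stream, cfg$drift$config, cfg$drift$detectors)
      rows[[key]] <- tibble(scaling = sc, family = fam,
                            accuracy = res$test_result$accuracy,
                            warning_count = sum(ev$level == "warning"),
                            drift_count = sum(ev$level == "drift"))
      events[[key]] <- ev
      stream_results[[key]] <- if (cfg$confounder$scan_scope == "all")
        res$all_result else res$test_result
    }
  }
  structure(list(metrics = bind_rows(rows), events = events,
                 stream_results = stream_results,
                 seed = cfg$seed, ordering = ordering,
                 split_ids = sort(x$split$sample_id[x$split$split == "test"]),
                 correction = correction),
            class = "pipeline_eval")
}

prepare_scaled <- function(x, spec, cfg, correction) {
  if (!is.null(correction) && correction$strategy == "stratified_scaling") {
    strata <- binarize_covariate(x$clinical, correction$covariate,
                                 correction$threshold)
    train_ids <- x$split$sample_id[x$split$split == "train"]
    x$abundance <- stratified_scale(x$abundance, strata, spec,
                                    fit_samples = train_ids)
    x
  } else {
    scale_cohort(x, spec, fit_on = cfg$scaling$fit_on)
  }
}

# plain (uncorrected or stratified-scaled) training: one model on the
# training split, evaluated on the test split and on the stream scope
default_trainer <- function(scaled, fam, mseed, cfg) {
  spec <- model_spec(fam, cfg$classify$hyperparameters[[fam]] %||% list(),
                     seed = mseed, cv_folds = cfg$classify$cv_folds)
  model <- train_model(cohort_subset(scaled, "train"), spec)
  all_res <- evaluate(model, scaled, "all")
  test_ids <- scaled$split$sample_id[scaled$split$split == "test"]
  list(test_result = subset_result(all_res, test_ids, "test"),
       all_result = all_res)
}

# restrict a prediction_result to a set of samples
subset_result <- function(res, ids, split) {
  tab <- res$predictions[res$predictions$sample_id %in% ids, ]
  structure(list(predictions = tab, accuracy = mean(tab$correct),
                 family = res$family, split = split),
            class = "prediction_result")
}

# segmentation training: one model per stratum, predictions pooled
segmented_trainer <- function(correction) {
  function(scaled, fam, mseed, cfg) {
    cut <- correction$cut %||% correction$threshold
    strata <- binarize_covariate(scaled$clinical, correction$covariate, cut)
    pooled <- list()
    for (s in sort(unique(strata$stratum))) {
      part <- keep_samples(scaled, strata$sample_id[strata$stratum == s])
      spec <- model_spec(fam, cfg$classify$hyperparameters[[fam]] %||% list(),
                         seed = mseed, cv_folds = cfg$classify$cv_folds)
      train_part <- cohort_subset(part, "train")
      # exclude the uncertain transition band from training (evaluation
      # still covers every sample of the stratum)
      lim <- if (s == 0L) correction$lower_train_max else correction$upper_train_min
      if (!is.null(lim)) {
        cov <- train_part$clinical[[correction$covariate]]
        keep_ids <- train_part$abundance$sample_id[
          if (s == 0L) cov <= lim else cov >= lim]
        trimmed <- train_part$clinical[[train_part$target]][
          train_part$abundance$sample_id %in% keep_ids]
        if (length(keep_ids) && all(table(trimmed) >= 2)) {
          train_part <- keep_samples(train_part, keep_ids)
        }
      }
      model <- train_model(train_part, spec)
      pooled[[as.character(s)]] <- evaluate(model, part, "all")
    }
    tab <- bind_rows(purrr::map(pooled, "predictions"))
    all_res <- structure(list(predictions = tab, accuracy = mean(tab$correct),
                              family = fam, split = "all"),
                         class = "prediction_result")
    test_ids <- scaled$split$sample_id[scaled$split$split == "test"]
    list(test_result = subset_result(all_res, test_ids, "test"),
         all_result = all_res)
  }
}

# Section B: pick the nomination combination, scan covariates (each ordered
# by itself), rank, and derive the threshold.
nominate_confounder <- function(before, x, cfg) {
  preferred <- paste(cfg$nominate$scaling, cfg$nominate$family, sep = "|")
  keys <- unique(c(intersect(preferred, names(before$stream_results)),
                   names(before$stream_results)))
  scans <- list()
  for (key in keys) {
    scans[[key]] <- scan_one(before$stream_results[[key]], x$clinical, cfg)
  }
  # a combination is eligible when its scan stream shows a confirmed drift
  # with a derivable threshold; the preferred combination wins, otherwise
  # the one whose warnings cluster tightest in covariate space
  eligible <- keys[vapply(keys, function(key) {
    any(!is.na(scans[[key]]$candidate_threshold))
  }, logical(1))]
  if (!length(eligible)) {
    return(list(status = "no_drift", scans = scans,
                message = "no confirmed drift in any combination; nothing to correct."))
  }
  combo <- if (preferred %in% eligible) preferred else {
    rng <- vapply(eligible, function(key) scans[[key]]$scaled_range[1],
                  numeric(1))
    eligible[which.min(rng)]
  }
  # pool over all drift-positive combinations: the same underlying concept
  # change should surface across normalizations, so the covariate is chosen
  # by majority vote and the threshold is the median of the per-combination
  # estimates - one normalization's detection noise then cannot dominate
  tops <- bind_rows(purrr::map(eligible, function(key) {
    scans[[key]][!is.na(scans[[key]]$candidate_threshold), ][1, ]
  }))
  votes <- sort(table(tops$covariate), decreasing = TRUE)
  covariate <- names(votes)[1]
  sel <- tops$covariate == covariate
  list(status = "nominated", combo = combo, scan = scans[[combo]],
       n_combos = sum(sel), covariate = covariate,
       threshold = stats::median(tops$candidate_threshold[sel]),
       drift_boundary = stats::median(tops$drift_boundary[sel]))
}

# scan candidate covariates for one combination: each candidate gets its own
# stream ordering, detection, association and threshold
scan_one <- function(stream_res, clinical, cfg) {
  det <- cfg$nominate$detector
  rows <- purrr::map(cfg$confounder$covariates, function(cv) {
    stream <- build_error_stream(stream_res, clinical, cv)
    ev <- detect_drift(stream, cfg$drift$config, det)
    assoc <- associate_covariate(ev, stream, clinical, cv)
    w <- assoc$values[assoc$values$level == "warning", ]
    if (any(w$confirmed)) w <- w[w$confirmed, ]
    n_drift <- length(assoc$values_at_drifts)
    rng <- if (nrow(w)) diff(range(w$value)) else NA_real_
    thr <- if (n_drift > 0 && nrow(w)) {
      derive_threshold(assoc, cfg$confounder$rule, cfg$confounder$use)
    } else NA_real_
    # where the drift was confirmed: the upper end of the transition band
    bnd <- if (n_drift > 0) {
      derive_threshold(assoc, "mean_of_drifts", cfg$confounder$use)
    } else NA_real_
    drifts <- assoc$values[assoc$values$level == "drift", ]
    tibble(covariate = cv, n_warnings = nrow(w), n_drifts = n_drift,
           warning_range = rng,
           scaled_range = rng / max(diff(range(clinical[[cv]])),
                                    .Machine$double.eps),
           max_elevation = if (n_drift > 0) max(drifts$elevation) else NA_real_,
           candidate_threshold = thr, drift_boundary = bnd)
  })
  out <- bind_rows(rows)
  # strongest candidate first: the ordering covariate under which the drift
  # sustains the largest error elevation; warning-cluster tightness breaks
  # ties (a lone coincident warning has range 0, so range alone is unusable)
  out[order(is.na(out$candidate_threshold), -out$max_elevation,
            out$scaled_range), ]
}

#' Run the full semi-automated pipeline
#'
#' Executes the three sections end to end: harmonization and conventional
#' classifier evaluation over the (scaling x family) grid; drift detection
#' on covariate-ordered error streams with confounder nomination; and
#' correction (segmentation or stratified scaling at the nominated
#' threshold) followed by retraining and a paired before/after comparison.
#' The expert confirmation of the nominated confounder is interactive
#' unless `correct$auto_accept` is set or the session is non-interactive.
#'
#' @param config A [run_config()].
#' @return A `"metadrift_run"` list: `cohort` (harmonized), `before` and
#'   `after` evaluations, `nomination` (combo, covariate scan, threshold),
#'   `report` (a `"comparison_report"`, `NULL` when no drift was found) and
#'   `config`. Artifacts are written to `config$out_dir` when set.
#' @examples
#' \donttest{
#' cfg <- run_config(simulate = sim_config(n_samples = 150, seed = 3),
#'                   scaling = list(methods = "autoscaling"),
#'                   classify = list(families = "ridge", cv_folds = 3),
#'                   correct = list(auto_accept = TRUE))
#' run <- run_pipeline(cfg)
#' run$report
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  x <- acquire_cohort(cfg)
  # harmonization: impute, screen outliers, split; the imputed-but-unscreened
  # table is kept so Section C can re-screen with confounder-aware groups
  x$abundance <- impute_half_min(x$abundance)
  imputed <- x$abundance
  groups <- if (!is.null(cfg$harmonize$condition)) {
    x$clinical[[cfg$harmonize$condition]]
  } else as.character(target_factor(x))
  screened <- screen_outliers(x$abundance, groups,
                              policy = cfg$harmonize$outlier_policy)
  x$abundance <- screened$abundance
  x <- split_dataset(x, cfg$harmonize$test_fraction, seed = cfg$seed)

  ordering <- cfg$confounder$covariates[1]
  before <- evaluate_grid(x, cfg, ordering)
  nomination <- nominate_confounder(before, x, cfg)
  run <- list(cohort = x, before = before, nomination = nomination,
              outlier_report = screened$report, after = NULL, report = NULL,
              config = cfg)
  class(run) <- "metadrift_run"
  if (nomination$status != "nominated") {
    inform(nomination$message)
    return(write_artifacts(run))
  }
  threshold <- cfg$correct$threshold %||% nomination$threshold
  if (!isTRUE(cfg$correct$auto_accept) && interactive()) {
    ans <- readline(sprintf(
      "Nominated confounder `%s` at threshold %.3g - accept? [y/N] ",
      nomination$covariate, threshold))
    if (!tolower(ans) %in% c("y", "yes")) {
      inform("nomination declined; stopping after Section B.")
      return(write_artifacts(run))
    }
  } else {
    inform(sprintf("accepting nominated confounder `%s` at threshold %.4g.",
                   nomination$covariate, threshold))
  }
  # The nominated threshold (mean of confirmed warnings) marks the onset of
  # suspicion; the drift boundary marks where the change was confirmed. The
  # concept inside that band is uncertain, so segmentation trains each
  # stratum outside the band and assigns band samples at its midpoint.
  boundary <- max(threshold, nomination$drift_boundary %||% threshold)
  band <- cfg$correct$band %||% "none"
  correction <- list(
    covariate = nomination$covariate, threshold = threshold,
    cut = if (band == "midpoint") (threshold + boundary) / 2 else threshold,
    lower_train_max = if (band == "midpoint") threshold,
    upper_train_min = if (band == "midpoint") boundary,
    strategy = resolve_strategy(cfg, x, nomination$covariate, threshold))
  run$nomination$threshold <- threshold
  # once the confounder is known it becomes part of the outlier screen's
  # "condition": re-screen within class x stratum so genuine stratum-level
  # signal is no longer mistaken for outlying measurements
  x_after <- x
  strata <- binarize_covariate(x$clinical, correction$covariate,
                               correction$cut)
  groups2 <- paste(groups, strata$stratum, sep = "/")
  if (min(table(groups2)) >= 2) {
    x_after$abundance <- screen_outliers(
      imputed, groups2, policy = cfg$harmonize$outlier_policy)$abundance
  }
  trainer <- if (correction$strategy == "segmentation") {
    segmented_trainer(correction)
  } else NULL
  run$after <- evaluate_grid(x_after, cfg, ordering, correction = correction,
                             trainer = trainer)
  run$report <- compare_before_after(before, run$after)
  write_artifacts(run)
}

acquire_cohort <- function(cfg) {
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    sim$seed <- child_seed(cfg$seed, 1) + sim$seed  # global seed propagates
    gen <- generate_cohort(sim)
    return(gen$cohort)
  }
  paths <- cfg$input$abundance
  tabs <- purrr::map(paths, read_abundance)
  if (!is.null(cfg$input$mapping)) {
    mapping <- read_mapping(cfg$input$mapping)
    tabs <- purrr::map(tabs, map_identifiers, mapping = mapping)
  }
  if (length(tabs) > 1) {
    tabs <- intersect_features(tabs)
    inform("multiple abundance tables: modelling the first after reducing all to their common features.")
  }
  clinical <- read_clinical(cfg$input$clinical)
  target <- cfg$input$target %||% "sex"
  cohort(tabs[[1]],
         clinical[clinical$sample_id %in% tabs[[1]]$sample_id, ],
         target = target)
}

resolve_strategy <- function(cfg, x, covariate, threshold) {
  strategy <- cfg$correct$strategy
  if (strategy != "auto") return(strategy)
  feasible <- tryCatch({
    parts <- segment_by_threshold(x, covariate, threshold)
    all(vapply(parts, function(p) {
      tr <- cohort_subset(p, "train")
      all(table(target_factor(tr)) >= 2) &&
        any(p$split$split == "test")
    }, logical(1)))
  }, error = function(e) FALSE)
  if (feasible) "segmentation" else "stratified_scaling"
}

write_artifacts <- function(run) {
  dir <- run$config$out_dir
  if (is.null(dir)) return(run)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(mutate(run$before$metrics, seed = run$config$seed),
                   file.path(dir, "metrics_before.tsv"))
  readr::write_tsv(run$outlier_report, file.path(dir, "outlier_report.tsv"))
  all_events <- bind_rows(purrr::imap(run$before$events, function(ev, key) {
    mutate(as_tibble(unclass(ev)), combo = key,
           ordering_key = attr(ev, "ordering_key") %||% NA_character_)
  }))
  readr::write_tsv(all_events, file.path(dir, "drift_events_before.tsv"))
  if (!is.null(run$report)) {
    readr::write_tsv(run$report, file.path(dir, "comparison_report.tsv"))
    jsonlite::write_json(
      list(nomination = run$nomination[c("combo", "covariate", "threshold")],
           report = run$report),
      file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  run
}

#' @export
print.metadrift_run <- function(x, ...) {
  cat("<metadrift_run>\n")
  cat(sprintf("  grid: %d scaling method(s) x %d classifier family(ies)\n",
              length(unique(x$before$metrics$scaling)),
              length(unique(x$before$metrics$family))))
  if (x$nomination$status == "nominated") {
    cat(sprintf("  nominated confounder: %s @ %.4g (combo %s)\n",
                x$nomination$covariate, x$nomination$threshold,
                x$nomination$combo))
  } else {
    cat("  no confounder nominated\n")
  }
  if (!is.null(x$report)) {
    cat(sprintf("  mean accuracy before %.3f -> after %.3f; drifts %d -> %d\n",
                mean(x$report$accuracy_before, na.rm = TRUE),
                mean(x$report$accuracy_after, na.rm = TRUE),
                sum(x$report$drift_count_before, na.rm = TRUE),
                sum(x$report$drift_count_after, na.rm = TRUE)))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.metadrift_run <- function(x, ...) {
  if (!is.null(x$report)) as_tibble(x$report) else x$before$metrics
}

#' @exportS3Method generics::glance
glance.metadrift_run <- function(x, ...) {
  tibble(
    n_samples = nrow(x$cohort$abundance),
    n_features = length(feature_names(x$cohort$abundance)),
    nominated = x$nomination$status == "nominated",
    covariate = if (x$nomination$status == "nominated")
      x$nomination$covariate else NA_character_,
    threshold = if (x$nomination$status == "nominated")
      x$nomination$threshold else NA_real_,
    corrected = !is.null(x$report)
  )
}
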