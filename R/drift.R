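# Prequential concept drift detection: DDM monitors the running error rate
# and its binomial standard deviation; EDDM monitors the distribution of
# distances (in instances) between consecutive errors.

#' Configure the drift detectors
#'
#' Defaults follow the original published update rules: DDM warns at two and
#' drifts at three binomial standard deviations above the historical minimum
#' error level after 30 instances; EDDM warns when its normalised
#' error-distance statistic falls below 0.95 (drift below 0.90) of its
#' historical maximum, after 30 observed errors.
#'
#' @param ddm_min_instances Instances before DDM may signal (default 30).
#' @param ddm_warning_sigma,ddm_drift_sigma Warning/drift multipliers of
#'   `s_min` (defaults 2 and 3; warning must be looser than drift).
#' @param eddm_min_errors Errors before EDDM may signal (default 30).
#' @param eddm_alpha,eddm_beta Warning/drift ratio thresholds (defaults
#'   0.95 and 0.90; `alpha > beta`).
#' @return An object of class `"detector_config"`.
#' @export
detector_config <- function(ddm_min_instances = 30, ddm_warning_sigma = 2,
                            ddm_drift_sigma = 3, eddm_min_errors = 30,
                            eddm_alpha = 0.95, eddm_beta = 0.90) {
  if (ddm_warning_sigma >= ddm_drift_sigma) {
    abort("DDM warning sigma must be smaller than the drift sigma.")
  }
  if (eddm_alpha <= eddm_beta) abort("EDDM alpha (warning) must exceed beta (drift).")
  if (ddm_min_instances < 1 || eddm_min_errors < 1) {
    abort("minimum instance/error counts must be >= 1.")
  }
  structure(as.list(environment()), class = "detector_config")
}

#' Build an ordered misclassification stream
#'
#' Turns per-sample predictions into the 0/1 error sequence a drift
#' detector consumes. Samples are ordered ascending by the chosen clinical
#' covariate (ties broken by sample id, so the stream is reproducible) or
#' left in dataset order.
#'
#' @param result A `"prediction_result"` from [evaluate()].
#' @param clinical Clinical tibble covering the predicted samples.
#' @param ordering_key Name of a covariate column, or `"dataset_order"`.
#' @return An `"error_stream"` tibble (`position`, `sample_id`, `error`,
#'   and `ordering_value` when ordered by a covariate), with the ordering
#'   key attached as an attribute.
#' @export
build_error_stream <- function(result, clinical, ordering_key = "dataset_order") {
  stopifnot(inherits(result, "prediction_result"))
  tab <- result$predictions
  if (identical(ordering_key, "dataset_order")) {
    return(new_error_stream(as.integer(!tab$correct), tab$sample_id,
                            "dataset_order"))
  }
  if (!ordering_key %in% names(clinical)) {
    abort(sprintf("unknown ordering key `%s`.", ordering_key))
  }
  cov <- clinical[[ordering_key]][match(tab$sample_id, clinical$sample_id)]
  if (anyNA(cov)) {
    abort(sprintf("missing `%s` values for sample(s): %s.", ordering_key,
                  toString(tab$sample_id[is.na(cov)])))
  }
  ord <- order(cov, tab$sample_id)
  new_error_stream(as.integer(!tab$correct[ord]), tab$sample_id[ord],
                   ordering_key, covariate_values = cov[ord])
}

empty_events <- function(stream) {
  structure(
    tibble(detector = character(0), level = character(0),
           index = integer(0), position = integer(0), episode = integer(0),
           sample_id = character(0), ordering_value = numeric(0),
           stat = numeric(0), stat_sd = numeric(0),
           ref = numeric(0), ref_sd = numeric(0)),
    ordering_key = attr(stream, "ordering_key"),
    stream_length = nrow(stream),
    class = c("drift_events", "tbl_df", "tbl", "data.frame"))
}

event_row <- function(stream, detector, level, t, episode, stat, stat_sd,
                      ref, ref_sd) {
  tibble(detector = detector, level = level,
         index = t - 1L, position = t, episode = episode,
         sample_id = stream$sample_id[t],
         ordering_value = if ("ordering_value" %in% names(stream))
           stream$ordering_value[t] else NA_real_,
         stat = stat, stat_sd = stat_sd, ref = ref, ref_sd = ref_sd)
}

finish_events <- function(rows, stream) {
  out <- empty_events(stream)
  if (length(rows)) {
    body <- bind_rows(rows)
    out <- structure(bind_rows(out, body),
                     ordering_key = attr(stream, "ordering_key"),
                     stream_length = nrow(stream),
                     class = class(out))
  }
  out
}

#' Drift Detection Method (DDM)
#'
#' Processes the stream one instance at a time, maintaining the error rate
#' `p_i` since the last reset and its binomial standard deviation
#' `s_i = sqrt(p_i (1 - p_i) / i)`, and tracking the minimum of `p_i + s_i`
#' (components stored as `p_min`, `s_min`). After `ddm_min_instances`
#' instances it signals a warning when `p_i + s_i > p_min + 2 s_min` and a
#' drift when `p_i + s_i > p_min + 3 s_min` (defaults), resetting all state
#' after a drift. A drift with no preceding warning in its episode emits a
#' coincident warning first, so every episode's warning index is at most
#' its drift index.
#'
#' @param stream An `"error_stream"`.
#' @param config A [detector_config()].
#' @return A `"drift_events"` tibble: one row per event with `detector`,
#'   `level` (`"warning"`/`"drift"`), 0-based `index`, `position`,
#'   `episode`, `sample_id`, `ordering_value`, and the trigger statistics
#'   (`stat` = p_i, `stat_sd` = s_i, `ref` = p_min, `ref_sd` = s_min).
#' @export
ddm_detect <- function(stream, config = detector_config()) {
  stopifnot(inherits(stream, "error_stream"))
  if (!nrow(stream)) abort("empty error stream.")
  e <- stream$error
  rows <- list(); nr <- 0L
  i <- 0L; ne <- 0L
  p_min <- Inf; s_min <- Inf; ps_min <- Inf
  warn_active <- FALSE; episode_warned <- FALSE; episode <- 1L
  for (t in seq_along(e)) {
    i <- i + 1L; ne <- ne + e[t]
    p <- ne / i
    s <- sqrt(p * (1 - p) / i)
    if (i >= config$ddm_min_instances) {
      if (p + s < ps_min) { p_min <- p; s_min <- s; ps_min <- p + s }
      if (p + s > p_min + config$ddm_drift_sigma * s_min) {
        if (!episode_warned) {
          nr <- nr + 1L
          rows[[nr]] <- event_row(stream, "ddm", "warning", t, episode,
                                  p, s, p_min, s_min)
        }
        nr <- nr + 1L
        rows[[nr]] <- event_row(stream, "ddm", "drift", t, episode,
                                p, s, p_min, s_min)
        i <- 0L; ne <- 0L
        p_min <- Inf; s_min <- Inf; ps_min <- Inf
        warn_active <- FALSE; episode_warned <- FALSE
        episode <- episode + 1L
      } else if (p + s > p_min + config$ddm_warning_sigma * s_min) {
        if (!warn_active) {
          nr <- nr + 1L
          rows[[nr]] <- event_row(stream, "ddm", "warning", t, episode,
                                  p, s, p_min, s_min)
          warn_active <- TRUE; episode_warned <- TRUE
        }
      } else {
        warn_active <- FALSE
      }
    }
  }
  finish_events(rows, stream)
}

#' Early Drift Detection Method (EDDM)
#'
#' Monitors the distances, in instances, between consecutive errors.
#' At each error it updates the running mean `p'_i` and standard deviation
#' `s'_i` of the distances observed since the last reset and tracks the
#' maximum of `p'_i + 2 s'_i` (components `p'_max`, `s'_max`). Once at
#' least `eddm_min_errors` errors have been seen, it signals a warning when
#' `(p'_i + 2 s'_i) / (p'_max + 2 s'_max) < 0.95` and a drift below 0.90
#' (defaults), resetting all state after a drift.
#'
#' @inheritParams ddm_detect
#' @return A `"drift_events"` tibble (see [ddm_detect()]); `stat` = p'_i,
#'   `stat_sd` = s'_i, `ref` = p'_max, `ref_sd` = s'_max.
#' @export
eddm_detect <- function(stream, config = detector_config()) {
  stopifnot(inherits(stream, "error_stream"))
  if (!nrow(stream)) abort("empty error stream.")
  e <- stream$error
  rows <- list(); nr <- 0L
  last_err <- NA_integer_; ne <- 0L
  k <- 0L; s1 <- 0; s2 <- 0
  m2s_max <- -Inf; p_max <- NA_real_; sd_max <- NA_real_
  warn_active <- FALSE; episode_warned <- FALSE; episode <- 1L
  for (t in seq_along(e)) {
    if (e[t] != 1L) next
    ne <- ne + 1L
    reset <- FALSE
    if (!is.na(last_err)) {
      d <- t - last_err
      k <- k + 1L; s1 <- s1 + d; s2 <- s2 + d^2
      mu <- s1 / k
      vr <- if (k > 1) max((s2 - s1^2 / k) / (k - 1), 0) else 0
      sdd <- sqrt(vr)
      m2s <- mu + 2 * sdd
      if (m2s > m2s_max) { m2s_max <- m2s; p_max <- mu; sd_max <- sdd }
      if (ne >= config$eddm_min_errors && m2s_max > 0) {
        ratio <- m2s / m2s_max
        if (ratio < config$eddm_beta) {
          if (!episode_warned) {
            nr <- nr + 1L
            rows[[nr]] <- event_row(stream, "eddm", "warning", t, episode,
                                    mu, sdd, p_max, sd_max)
          }
          nr <- nr + 1L
          rows[[nr]] <- event_row(stream, "eddm", "drift", t, episode,
                                  mu, sdd, p_max, sd_max)
          last_err <- NA_integer_; ne <- 0L; k <- 0L; s1 <- 0; s2 <- 0
          m2s_max <- -Inf; p_max <- NA_real_; sd_max <- NA_real_
          warn_active <- FALSE; episode_warned <- FALSE
          episode <- episode + 1L
          reset <- TRUE
        } else if (ratio < config$eddm_alpha) {
          if (!warn_active) {
            nr <- nr + 1L
            rows[[nr]] <- event_row(stream, "eddm", "warning", t, episode,
                                    mu, sdd, p_max, sd_max)
            warn_active <- TRUE; episode_warned <- TRUE
          }
        } else {
          warn_active <- FALSE
        }
      }
    }
    if (!reset) last_err <- t
  }
  finish_events(rows, stream)
}

#' Run one or both drift detectors on a stream
#'
#' @inheritParams ddm_detect
#' @param detectors Character vector among `"ddm"`, `"eddm"`.
#' @return A `"drift_events"` tibble combining the requested detectors.
#' @export
detect_drift <- function(stream, config = detector_config(),
                         detectors = c("ddm", "eddm")) {
  detectors <- match.arg(detectors, c("ddm", "eddm"), several.ok = TRUE)
  parts <- list()
  if ("ddm" %in% detectors) parts <- c(parts, list(ddm_detect(stream, config)))
  if ("eddm" %in% detectors) parts <- c(parts, list(eddm_detect(stream, config)))
  out <- bind_rows(parts)
  structure(out, ordering_key = attr(stream, "ordering_key"),
            stream_length = nrow(stream),
            class = c("drift_events", "tbl_df", "tbl", "data.frame"))
}

#' @exportS3Method generics::tidy
tidy.drift_events <- function(x, ...) as_tibble(unclass(x))

#' @exportS3Method generics::glance
glance.drift_events <- function(x, ...) {
  tab <- as_tibble(unclass(x))
  tab |>
    group_by(.data$detector) |>
    summarise(warnings = sum(.data$level == "warning"),
              drifts = sum(.data$level == "drift"), .groups = "drop")
}
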