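# The family of metabolomics normalizations: centering, autoscaling, pareto,
# range, vast, level, log10 and power, with parameters fitted on a designated
# (training) matrix and applied unchanged to held-out data.

SCALING_METHODS <- c("none", "centering", "autoscaling", "pareto", "range",
                     "vast", "level", "log10", "power")

#' Describe a scaling transform
#'
#' @param method One of `"none"`, `"centering"`, `"autoscaling"`, `"pareto"`,
#'   `"range"`, `"vast"`, `"level"`, `"log10"`, `"power"`. The canonical
#'   per-feature definitions are: centering `x - mean`; autoscaling
#'   `(x - mean)/sd`; pareto `(x - mean)/sqrt(sd)`; range
#'   `(x - mean)/(max - min)`; vast `((x - mean)/sd) * (mean/sd)`; level
#'   `(x - mean)/mean`; log10 `log10(x)`; power `x^power_exponent`
#'   (square root by default). Means/sds use the n-1 sample convention.
#' @param epsilon Small positive offset added inside `log10` when
#'   `log_offset = TRUE`; also guards denominators in inverse transforms.
#' @param power_exponent Exponent of the power transform (default 0.5).
#' @param log_offset If `TRUE`, `log10(x + epsilon)` is used and nonpositive
#'   values are tolerated; otherwise nonpositive values are a domain error.
#' @return An object of class `"scaling_spec"`.
#' @export
scaling_spec <- function(method = "autoscaling", epsilon = 1e-9,
                         power_exponent = 0.5, log_offset = FALSE) {
  method <- match.arg(method, SCALING_METHODS)
  if (!(is.numeric(epsilon) && epsilon > 0)) abort("`epsilon` must be > 0.")
  structure(list(method = method, epsilon = epsilon,
                 power_exponent = power_exponent, log_offset = log_offset),
            class = "scaling_spec")
}

#' @export
print.scaling_spec <- function(x, ...) {
  cat(sprintf("<scaling_spec> %s\n", x$method))
  invisible(x)
}

#' Estimate per-feature scaling parameters
#'
#' Computes, for every feature of a complete abundance table, the sample
#' mean, standard deviation (n-1), minimum and maximum. Fitting on the
#' training split and applying to held-out data keeps evaluation leakage
#' free; see [scale_cohort()].
#'
#' @param abundance Complete abundance tibble (no missing values).
#' @param spec A [scaling_spec()]; domain constraints of the method are
#'   checked here (log10 requires strictly positive values unless
#'   `log_offset`; fractional powers require non-negative values).
#' @return A tibble of class `"scaling_params"` with columns `feature`,
#'   `mean`, `sd`, `min`, `max`.
#' @examples
#' ab <- tibble::tibble(sample_id = paste0("s", 1:3), C00001 = c(1, 2, 3))
#' fit_scaler(ab, scaling_spec("autoscaling"))
#' @export
fit_scaler <- function(abundance, spec = scaling_spec()) {
  check_abundance(abundance, complete = TRUE)
  stopifnot(inherits(spec, "scaling_spec"))
  m <- feature_matrix(abundance)
  check_domain(m, spec)
  sds <- apply(m, 2, sd)
  sds[is.na(sds)] <- 0  # single-sample fit: sd undefined, treated as degenerate
  params <- tibble(
    feature = colnames(m),
    mean = colMeans(m),
    sd = sds,
    min = apply(m, 2, min),
    max = apply(m, 2, max)
  )
  class(params) <- c("scaling_params", class(params))
  params
}

check_domain <- function(m, spec) {
  if (spec$method == "log10" && !spec$log_offset && any(m <= 0)) {
    abort(paste0("log10 scaling requires strictly positive values ",
                 "(enable `log_offset` to add epsilon)."))
  }
  if (spec$method == "power" && spec$power_exponent %% 1 != 0 && any(m < 0)) {
    abort("power scaling with a fractional exponent requires non-negative values.")
  }
  invisible(m)
}

#' Apply a fitted scaling transform
#'
#' Transforms every entry of an abundance table using parameters estimated
#' by [fit_scaler()]. Features whose denominator is degenerate on the
#' fitting data (sd 0 for autoscaling/pareto/vast, zero range, or zero mean
#' for level/vast) are passed through as centered values with a warning.
#'
#' @param abundance Complete abundance tibble whose features match `params`.
#' @param params A `"scaling_params"` tibble from [fit_scaler()].
#' @param spec The [scaling_spec()] used at fit time.
#' @return The scaled abundance tibble (same shape, same sample order).
#' @export
apply_scaler <- function(abundance, params, spec = scaling_spec()) {
  check_abundance(abundance, complete = TRUE)
  stopifnot(inherits(spec, "scaling_spec"))
  feats <- feature_names(abundance)
  if (!identical(sort(feats), sort(params$feature))) {
    abort("feature mismatch between `abundance` and `params`.")
  }
  m <- feature_matrix(abundance)[, params$feature, drop = FALSE]
  check_domain(m, spec)
  out <- m
  degenerate <- character(0)
  for (j in seq_len(ncol(m))) {
    p <- params[j, ]
    x <- m[, j]
    z <- switch(spec$method,
      none = x,
      centering = x - p$mean,
      autoscaling = if (p$sd > 0) (x - p$mean) / p$sd else NULL,
      pareto = if (p$sd > 0) (x - p$mean) / sqrt(p$sd) else NULL,
      range = if (p$max > p$min) (x - p$mean) / (p$max - p$min) else NULL,
      vast = if (p$sd > 0 && p$mean != 0)
        ((x - p$mean) / p$sd) * (p$mean / p$sd) else NULL,
      level = if (p$mean != 0) (x - p$mean) / p$mean else NULL,
      log10 = if (spec$log_offset) log10(x + spec$epsilon) else log10(x),
      power = x^spec$power_exponent
    )
    if (is.null(z)) {  # degenerate denominator: fall back to centering
      degenerate <- c(degenerate, p$feature)
      z <- x - p$mean
    }
    out[, j] <- z
  }
  if (length(degenerate)) {
    warn(sprintf("apply_scaler: degenerate denominator, centered instead: %s.",
                 toString(degenerate)))
  }
  matrix_to_abundance(out, abundance$sample_id)
}

#' Invert an affine scaling transform
#'
#' Recovers the original abundances from scaled values for the affine
#' methods (`none`, `centering`, `autoscaling`, `pareto`, `range`, `vast`,
#' `level`). `log10` and `power` are inverted analytically when
#' representable.
#'
#' @inheritParams apply_scaler
#' @return The abundance tibble on the original scale.
#' @export
invert_scaler <- function(abundance, params, spec = scaling_spec()) {
  check_abundance(abundance, complete = TRUE)
  m <- feature_matrix(abundance)[, params$feature, drop = FALSE]
  out <- m
  for (j in seq_len(ncol(m))) {
    p <- params[j, ]
    z <- m[, j]
    out[, j] <- switch(spec$method,
      none = z,
      centering = z + p$mean,
      autoscaling = if (p$sd > 0) z * p$sd + p$mean else z + p$mean,
      pareto = if (p$sd > 0) z * sqrt(p$sd) + p$mean else z + p$mean,
      range = if (p$max > p$min) z * (p$max - p$min) + p$mean else z + p$mean,
      vast = if (p$sd > 0 && p$mean != 0)
        z * p$sd^2 / p$mean + p$mean else z + p$mean,
      level = if (p$mean != 0) z * p$mean + p$mean else z + p$mean,
      log10 = if (spec$log_offset) 10^z - spec$epsilon else 10^z,
      power = z^(1 / spec$power_exponent)
    )
  }
  matrix_to_abundance(out, abundance$sample_id)
}

#' Scale a cohort with train-fitted parameters
#'
#' Fits scaling parameters on the training split (or the whole cohort when
#' `fit_on = "all"`, for exploratory use) and applies them to every sample.
#'
#' @param x A [cohort()] with a complete abundance table.
#' @param spec A [scaling_spec()].
#' @param fit_on `"train"` (default; leakage-free) or `"all"`.
#' @return The cohort with scaled abundances; the fitted parameters are
#'   attached as attribute `"scaling_params"`.
#' @export
scale_cohort <- function(x, spec = scaling_spec(), fit_on = c("train", "all")) {
  stopifnot(inherits(x, "cohort"))
  fit_on <- match.arg(fit_on)
  fit_tab <- if (fit_on == "train") {
    ids <- x$split$sample_id[x$split$split == "train"]
    if (!length(ids)) abort("no training samples; run split_dataset() first.")
    x$abundance[x$abundance$sample_id %in% ids, ]
  } else {
    x$abundance
  }
  params <- fit_scaler(fit_tab, spec)
  x$abundance <- apply_scaler(x$abundance, params, spec)
  attr(x, "scaling_params") <- params
  x
}
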