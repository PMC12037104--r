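# small fixtures built in code

abundance_tbl <- function(values, sample_ids = NULL) {
  m <- as.matrix(values)
  if (is.null(sample_ids)) sample_ids <- sprintf("s%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("C%05d", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(sample_id = sample_ids),
                   tibble::as_tibble(m))
}

# a small, linearly separable two-class cohort: class means +/- delta on
# every feature, within-class sd `sd`
toy_cohort <- function(n = 40, p = 2, delta = 3, sd = 0.1, seed = 1,
                       with_age = FALSE) {
  withr::with_seed(seed, {
    sex <- rep(c("male", "female"), length.out = n)
    mu <- ifelse(sex == "female", delta, -delta)
    m <- sapply(seq_len(p), function(j) rnorm(n, mu, sd))
    colnames(m) <- sprintf("C%05d", seq_len(p))
    ab <- abundance_tbl(m)
    cl <- tibble::tibble(sample_id = ab$sample_id, sex = sex)
    if (with_age) cl$age <- runif(n, 18, 75)
    cohort(ab, cl)
  })
}

stream_from <- function(errors) {
  metadrift:::new_error_stream(as.integer(errors),
                               sprintf("t%04d", seq_along(errors)),
                               "dataset_order")
}

# hand-derived scaling vectors shared by the unit and acceptance suites
hand_cases <- list(
  list(method = "centering",   x = c(1, 2, 3),    expected = c(-1, 0, 1)),
  list(method = "autoscaling", x = c(1, 2, 3),    expected = c(-1, 0, 1)),
  list(method = "vast",        x = c(1, 2, 3),    expected = c(-2, 0, 2)),
  list(method = "pareto",      x = c(1, 2, 3),    expected = c(-1, 0, 1)),
  list(method = "range",       x = c(1, 2, 3),    expected = c(-0.5, 0, 0.5)),
  list(method = "level",       x = c(1, 2, 3),    expected = c(-0.5, 0, 0.5)),
  list(method = "log10",       x = c(1, 10, 100), expected = c(0, 1, 2)),
  list(method = "power",       x = c(1, 4, 9),    expected = c(1, 2, 3))
)
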