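# drift-position / covariate association and threshold derivation

events_at <- function(positions, levels, stream,
                      episodes = seq_along(positions), detector = "ddm") {
  dplyr::bind_rows(lapply(seq_along(positions), function(i) {
    metadrift:::event_row(stream, detector, levels[i], positions[i],
                          episodes[i], 0.1, 0.01, 0.05, 0.01)
  })) -> body
  metadrift:::finish_events(list(body), stream)
}

test_that("association records the covariate of the ordered sample at each event", {
  st <- stream_from(c(0, 1, 0))
  clin <- tibble::tibble(sample_id = st$sample_id, age = c(20, 24, 28))
  ev <- events_at(c(1, 3), c("warning", "warning"), st)
  assoc <- associate_covariate(ev, st, clin, "age")
  expect_equal(assoc$values_at_warnings, c(20, 28))
  expect_equal(length(assoc$values_at_drifts), 0)

  # single drift at the sample aged 20
  ev2 <- events_at(1, "drift", st)
  assoc2 <- associate_covariate(ev2, st, clin, "age")
  expect_equal(assoc2$values_at_drifts, 20)
})

test_that("an empty event list yields an empty association, not an error", {
  st <- stream_from(c(0, 0, 1))
  clin <- tibble::tibble(sample_id = st$sample_id, age = c(20, 24, 28))
  ev <- metadrift:::empty_events(st)
  assoc <- suppressWarnings(associate_covariate(ev, st, clin, "age"))
  expect_length(assoc$values_at_warnings, 0)
  expect_true(is.na(assoc$candidate_threshold))
  expect_error(derive_threshold(assoc), "no warning")
})

test_that("threshold rules reproduce their analytic values", {
  st <- stream_from(rep(0, 12))
  clin <- tibble::tibble(sample_id = st$sample_id,
                         age = c(24, 26, 28, 18, 29, 20, 22, 23, 25, 27, 19, 21))
  ev <- events_at(1:3, rep("warning", 3), st, episodes = c(1, 1, 1))
  assoc <- associate_covariate(ev, st, clin, "age")
  # warnings at ages 24, 26, 28 -> mean 26 (no drift: plain mean)
  expect_equal(derive_threshold(assoc, "mean_of_warnings"), 26)
  # midpoint over both levels
  ev2 <- events_at(c(4, 5), c("warning", "drift"), st, episodes = c(1, 1))
  assoc2 <- associate_covariate(ev2, st, clin, "age")
  expect_equal(derive_threshold(assoc2, "midpoint"), (18 + 29) / 2)
  expect_equal(derive_threshold(assoc2, "mean_of_drifts"), 29)
})

test_that("only the final warning of a drift episode counts as confirmed", {
  # two warning entries in one episode: the first was cancelled before the
  # drift fired, so only the second opens the confirmed warning period
  e <- c(rep(0, 3), 1, rep(0, 6))
  st <- stream_from(e)
  clin <- tibble::tibble(sample_id = st$sample_id, age = seq(20, 38, by = 2))
  ev <- events_at(c(2, 6, 8), c("warning", "warning", "drift"), st,
                  episodes = c(1, 1, 1))
  assoc <- associate_covariate(ev, st, clin, "age")
  v <- assoc$values
  expect_identical(v$confirmed[v$level == "warning"], c(FALSE, TRUE))
  # the confirmed-warning mean uses only the final warning (age 30)
  expect_equal(derive_threshold(assoc, "mean_of_warnings", use = "confirmed"), 30)
  expect_equal(derive_threshold(assoc, "mean_of_warnings", use = "all"),
               mean(c(22, 30)))
})

test_that("association works with a covariate other than the ordering key", {
  st <- stream_from(c(0, 0, 1, 0))
  clin <- tibble::tibble(sample_id = st$sample_id,
                         age = c(20, 30, 40, 50),
                         creatinine = c(80, 95, 120, 60))
  ev <- events_at(3, "drift", st)
  assoc <- associate_covariate(ev, st, clin, "creatinine")
  expect_equal(assoc$values_at_drifts, 120)
})

test_that("association is invariant to permuting un-streamed clinical rows", {
  st <- stream_from(c(0, 1, 0, 1))
  clin <- tibble::tibble(sample_id = st$sample_id, age = c(20, 25, 30, 35))
  ev <- events_at(c(2, 4), c("warning", "drift"), st, episodes = c(1, 1))
  a1 <- associate_covariate(ev, st, clin, "age")
  a2 <- associate_covariate(ev, st, clin[sample(4), ], "age")
  expect_equal(a1$values, a2$values)
})

test_that("simulated cohorts recover the true threshold within two years", {
  # single-cohort spot check of the end-to-end property exercised in full by
  # the acceptance suite
  cfg <- run_config(simulate = sim_config(n_samples = 500),
                    scaling = list(methods = "autoscaling"),
                    classify = list(families = "ridge"),
                    correct = list(auto_accept = TRUE), seed = 42)
  run <- suppressMessages(suppressWarnings(run_pipeline(cfg)))
  expect_identical(run$nomination$status, "nominated")
  expect_identical(run$nomination$covariate, "age")
  expect_lt(abs(run$nomination$threshold - 26), 2.5)
})

test_that("scan_covariates ranks the drifting covariate first", {
  cfg <- run_config(simulate = sim_config(n_samples = 400),
                    scaling = list(methods = "autoscaling"),
                    classify = list(families = "ridge"),
                    correct = list(auto_accept = TRUE), seed = 11)
  run <- suppressMessages(suppressWarnings(run_pipeline(cfg)))
  expect_identical(run$nomination$scan$covariate[1], "age")
})
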