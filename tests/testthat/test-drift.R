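# DDM / EDDM behaviour: analytic traces, stationarity, oracle agreement,
# warning/drift ordering, stream construction

test_that("DDM stays silent on an all-correct stream", {
  expect_equal(nrow(ddm_detect(stream_from(rep(0, 100)))), 0)
})

test_that("DDM drifts at 0-based index 30 after 30 clean instances and one error", {
  ev <- ddm_detect(stream_from(c(rep(0, 30), 1)))
  expect_identical(ev$level, c("warning", "drift"))
  expect_identical(ev$index, c(30L, 30L))
  expect_identical(ev$episode, c(1L, 1L))
})

test_that("DDM detects an abrupt error-rate step well after the change point", {
  hits <- vapply(1:50, function(s) {
    st <- generate_error_stream(1000, data.frame(index = c(0, 500),
                                                 rate = c(0.05, 0.5)), seed = s)
    ev <- ddm_detect(st)
    any(ev$level == "drift" & ev$index >= 500)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("EDDM needs at least two errors and ignores constant spacing", {
  expect_equal(nrow(eddm_detect(stream_from(c(rep(0, 50), 1)))), 0)
  # all-ones: every distance is 1, the ratio is constantly 1 -> no events
  expect_equal(nrow(eddm_detect(stream_from(rep(1, 100)))), 0)
})

test_that("EDDM flags a drop in error spacing, at the oracle's exact index", {
  # errors every 20 instances for 40 errors, then every 2 instances
  e <- rep(c(rep(0, 19), 1), 40)
  e <- c(e, rep(c(0, 1), 120))
  ev <- eddm_detect(stream_from(e))
  expect_true(any(ev$level == "drift"))
  expect_gt(min(ev$index[ev$level == "drift"]), 800)  # after the change
  expect_identical(events_key(ev), events_key(oracle_eddm(e)))
})

test_that("streaming DDM equals the from-scratch oracle on random streams", {
  withr::with_seed(123, {
    for (rep in 1:60) {
      n <- sample(50:800, 1)
      rate <- runif(1, 0.01, 0.5)
      cps <- if (rep %% 2 == 0) {
        data.frame(index = c(0, sample(20:(n - 10), 1)),
                   rate = c(rate, runif(1, 0.01, 0.5)))
      } else data.frame(index = 0, rate = rate)
      st <- generate_error_stream(n, cps, seed = rep)
      expect_identical(events_key(ddm_detect(st)),
                       events_key(oracle_ddm(st$error)),
                       label = sprintf("ddm stream %d", rep))
    }
  })
})

test_that("streaming EDDM equals the from-scratch oracle on random streams", {
  withr::with_seed(321, {
    for (rep in 1:40) {
      n <- sample(100:800, 1)
      cps <- data.frame(index = c(0, sample(30:(n - 20), 1)),
                        rate = runif(2, 0.05, 0.5))
      st <- generate_error_stream(n, cps, seed = 1000 + rep)
      expect_identical(events_key(eddm_detect(st)),
                       events_key(oracle_eddm(st$error)),
                       label = sprintf("eddm stream %d", rep))
    }
  })
})

test_that("every drift is preceded or accompanied by a warning in its episode", {
  withr::with_seed(77, {
    for (rep in 1:25) {
      st <- generate_error_stream(
        600, data.frame(index = c(0, 300), rate = runif(2, 0.02, 0.5)),
        seed = 2000 + rep)
      for (ev in list(ddm_detect(st), eddm_detect(st))) {
        for (epi in unique(ev$episode[ev$level == "drift"])) {
          d_idx <- ev$index[ev$level == "drift" & ev$episode == epi]
          w_idx <- ev$index[ev$level == "warning" & ev$episode == epi]
          expect_true(length(w_idx) > 0 && min(w_idx) <= d_idx)
        }
      }
    }
  })
})

test_that("detector configuration is validated", {
  expect_error(detector_config(ddm_warning_sigma = 3, ddm_drift_sigma = 2),
               "warning sigma")
  expect_error(detector_config(eddm_alpha = 0.8, eddm_beta = 0.9), "alpha")
  expect_error(detector_config(ddm_min_instances = 0), ">= 1")
})

test_that("build_error_stream orders by covariate with stable id tie-breaks", {
  res <- structure(list(predictions = tibble::tibble(
    sample_id = c("a", "b", "c"),
    truth = c("male", "male", "male"),
    predicted = c("male", "female", "male"),
    correct = c(TRUE, FALSE, TRUE)),
    accuracy = 2 / 3, family = "knn", split = "test"),
    class = "prediction_result")
  clin <- tibble::tibble(sample_id = c("a", "b", "c"), age = c(30, 20, 25))

  # dataset order keeps prediction order
  st0 <- build_error_stream(res, clin, "dataset_order")
  expect_identical(st0$error, c(0L, 1L, 0L))

  # age order sorts ascending
  st1 <- build_error_stream(res, clin, "age")
  expect_identical(st1$sample_id, c("b", "c", "a"))
  expect_identical(st1$error, c(1L, 0L, 0L))

  # ties broken by sample id, reproducibly
  clin2 <- tibble::tibble(sample_id = c("a", "b", "c"), age = c(25, 25, 20))
  st2 <- build_error_stream(res, clin2, "age")
  expect_identical(st2$sample_id, c("c", "a", "b"))
  expect_identical(st2, build_error_stream(res, clin2, "age"))

  # unknown key / missing values are errors
  expect_error(build_error_stream(res, clin, "bmi"), "unknown ordering key")
  clin$age[2] <- NA
  expect_error(build_error_stream(res, clin, "age"), "missing")
})
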