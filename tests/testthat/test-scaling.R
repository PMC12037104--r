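# the eight normalizations: hand-derived vectors, train-fit/test-apply,
# identities, inverses, monotonicity

test_that("all eight transforms reproduce the hand-computed vectors to 1e-10", {
  for (case in hand_cases) {
    ab <- abundance_tbl(matrix(case$x, 3))
    spec <- scaling_spec(case$method)
    out <- apply_scaler(ab, fit_scaler(ab, spec), spec)
    expect_equal(out[[2]], case$expected, tolerance = 1e-10,
                 label = case$method)
  }
})

test_that("fit_scaler estimates per-feature mean/sd/min/max independently", {
  ab <- abundance_tbl(cbind(c(1, 2, 3), c(5, 5, 5)))
  p <- fit_scaler(ab, scaling_spec("centering"))
  expect_equal(unname(p$mean), c(2, 5))
  expect_equal(unname(p$sd), c(1, 0))
  expect_equal(unname(p$min), c(1, 5))
  expect_equal(unname(p$max), c(3, 5))
})

test_that("scaled training columns satisfy the analytic identities", {
  withr::with_seed(3, {
    m <- matrix(rexp(200, 0.1) + 1, 20, 10)
    ab <- abundance_tbl(m)
    auto <- apply_scaler(ab, fit_scaler(ab, scaling_spec("autoscaling")),
                         scaling_spec("autoscaling"))
    am <- as.matrix(auto[-1])
    expect_true(all(abs(colMeans(am)) < 1e-10))
    expect_true(all(abs(apply(am, 2, sd) - 1) < 1e-10))
    rng <- apply_scaler(ab, fit_scaler(ab, scaling_spec("range")),
                        scaling_spec("range"))
    expect_true(all(as.matrix(rng[-1]) >= -1 & as.matrix(rng[-1]) <= 1))
    cen <- apply_scaler(ab, fit_scaler(ab, scaling_spec("centering")),
                        scaling_spec("centering"))
    expect_true(all(abs(colMeans(as.matrix(cen[-1]))) < 1e-10))
  })
})

test_that("every transform matches brute-force recomputation on random matrices", {
  withr::with_seed(9, {
    for (rep in 1:3) {
      m <- matrix(runif(60, 1, 100), 12, 5)
      ab <- abundance_tbl(m)
      for (method in c("none", "centering", "autoscaling", "pareto", "range",
                       "vast", "level", "log10", "power")) {
        spec <- scaling_spec(method)
        out <- apply_scaler(ab, fit_scaler(ab, spec), spec)
        expect_equal(unname(as.matrix(out[-1])), unname(oracle_scale(m, method)),
                     tolerance = 1e-12, label = method)
      }
    }
  })
})

test_that("affine transforms invert back to the input to 1e-10", {
  withr::with_seed(4, {
    m <- matrix(runif(40, 1, 50), 8, 5)
    ab <- abundance_tbl(m)
    for (method in c("centering", "autoscaling", "pareto", "range", "vast",
                     "level", "log10", "power")) {
      spec <- scaling_spec(method)
      params <- fit_scaler(ab, spec)
      back <- invert_scaler(apply_scaler(ab, params, spec), params, spec)
      expect_equal(as.matrix(back[-1]), as.matrix(ab[-1]), tolerance = 1e-10,
                   label = method)
    }
  })
})

test_that("transforms preserve within-feature rank order", {
  withr::with_seed(6, {
    m <- matrix(runif(30, 1, 9), 10, 3)
    ab <- abundance_tbl(m)
    for (method in c("centering", "autoscaling", "pareto", "range", "vast",
                     "level", "log10", "power")) {
      spec <- scaling_spec(method)
      out <- as.matrix(apply_scaler(ab, fit_scaler(ab, spec), spec)[-1])
      for (j in 1:3) expect_identical(order(out[, j]), order(m[, j]),
                                      label = method)
    }
  })
})

test_that("train-fitted parameters are applied unchanged to held-out data", {
  train <- abundance_tbl(matrix(c(1, 2, 3), 3))
  test <- abundance_tbl(matrix(c(4, 10), 2), sample_ids = c("t1", "t2"))
  spec <- scaling_spec("autoscaling")
  params <- fit_scaler(train, spec)
  out <- apply_scaler(test, params, spec)
  expect_equal(out[[2]], c((4 - 2) / 1, (10 - 2) / 1))
})

test_that("degenerate denominators fall back to centering with a warning", {
  ab <- abundance_tbl(cbind(c(5, 5, 5), c(1, 2, 3)))
  spec <- scaling_spec("autoscaling")
  params <- fit_scaler(ab, spec)
  expect_warning(out <- apply_scaler(ab, params, spec), "degenerate")
  expect_equal(out[[2]], c(0, 0, 0))       # centered constant column
  expect_equal(out[[3]], c(-1, 0, 1))      # healthy column autoscaled
})

test_that("domain violations are hard errors unless the epsilon mode is enabled", {
  ab <- abundance_tbl(matrix(c(-1, 2, 3), 3))
  expect_error(fit_scaler(ab, scaling_spec("log10")), "positive")
  expect_error(fit_scaler(ab, scaling_spec("power")), "non-negative")
  eps_ok <- scaling_spec("log10", log_offset = TRUE, epsilon = 2)
  expect_silent(fit_scaler(ab, eps_ok))
})

test_that("scale_cohort fits on the training split only", {
  x <- toy_cohort(n = 20)
  x <- split_dataset(x, 0.25, seed = 2)
  out <- scale_cohort(x, scaling_spec("autoscaling"))
  params <- attr(out, "scaling_params")
  train_ids <- x$split$sample_id[x$split$split == "train"]
  manual <- fit_scaler(x$abundance[x$abundance$sample_id %in% train_ids, ],
                       scaling_spec("autoscaling"))
  expect_equal(params, manual)
})
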