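# identifier mapping, feature intersection, half-minimum imputation,
# 2-SD outlier screening, stratified splitting

test_that("map_identifiers renames, drops unmapped features and detects collisions", {
  ab <- abundance_tbl(matrix(1:2, 1), sample_ids = "s1")
  names(ab)[2:3] <- c("Creatinine", "Mystery")
  map <- data.frame(name = "Creatinine", kegg_id = "C00791")

  out <- suppressMessages(map_identifiers(ab, map))
  expect_identical(names(out), c("sample_id", "C00791"))
  expect_identical(attr(out, "dropped"), "Mystery")

  # empty mapping: everything dropped, reported
  empty <- data.frame(name = character(0), kegg_id = character(0))
  out2 <- suppressMessages(map_identifiers(ab, empty))
  expect_identical(names(out2), "sample_id")
  expect_setequal(attr(out2, "dropped"), c("Creatinine", "Mystery"))

  # two features colliding on one KEGG id must raise, not merge
  ab3 <- ab
  names(ab3)[2:3] <- c("Serine", "L-Serine")
  map3 <- data.frame(name = c("Serine", "L-Serine"),
                     kegg_id = c("C00065", "C00065"))
  expect_error(map_identifiers(ab3, map3), "Serine.*C00065")

  # malformed KEGG ids rejected
  expect_error(map_identifiers(ab, data.frame(name = "Creatinine",
                                              kegg_id = "X123")),
               "malformed")
})

test_that("intersect_features reduces all tables to the sorted common set", {
  a <- abundance_tbl(matrix(1:3, 1)); names(a)[2:4] <- c("C00001", "C00002", "C00003")
  b <- abundance_tbl(matrix(1:3, 1)); names(b)[2:4] <- c("C00004", "C00003", "C00002")
  out <- intersect_features(list(a, b))
  expect_identical(names(out[[1]]), c("sample_id", "C00002", "C00003"))
  expect_identical(names(out[[2]]), names(out[[1]]))

  # identical sets of 22 stay complete, order canonicalised
  big <- abundance_tbl(matrix(rnorm(22), 1))
  shuffled <- big[c("sample_id", sample(names(big)[-1]))]
  out22 <- intersect_features(list(big, shuffled))
  expect_length(names(out22[[1]]), 23)
  expect_identical(names(out22[[1]])[-1], sort(names(big)[-1]))

  # disjoint sets error with per-table counts
  d1 <- abundance_tbl(matrix(1, 1)); names(d1)[2] <- "C00001"
  d2 <- abundance_tbl(matrix(1, 1)); names(d2)[2] <- "C00002"
  expect_error(intersect_features(list(d1, d2)), "empty feature intersection")
})

test_that("intersect_features matches brute-force set intersection on random tables", {
  withr::with_seed(11, {
    for (rep in 1:10) {
      pool <- sprintf("C%05d", 1:40)
      tabs <- lapply(1:3, function(i) {
        feats <- sample(pool, sample(10:30, 1))
        ab <- abundance_tbl(matrix(rnorm(2 * length(feats)), 2))
        names(ab)[-1] <- feats
        ab
      })
      expected <- sort(Reduce(intersect, lapply(tabs, function(t) names(t)[-1])))
      if (!length(expected)) next
      out <- intersect_features(tabs)
      for (o in out) expect_identical(names(o)[-1], expected)
    }
  })
})

test_that("impute_half_min fills with half the column minimum and is idempotent", {
  ab <- abundance_tbl(cbind(c(2, 4, NA, 8), c(0.4, NA, 1, 1)))
  out <- impute_half_min(ab)
  expect_equal(out[[2]], c(2, 4, 1, 8))
  expect_equal(out[[3]], c(0.4, 0.2, 1, 1))
  # observed entries bit-identical, idempotent
  expect_identical(impute_half_min(out), out)
  expect_identical(out[[2]][c(1, 2, 4)], ab[[2]][c(1, 2, 4)])
  # all-missing column is an error naming the feature
  bad <- abundance_tbl(cbind(c(NA, NA), c(1, 2)))
  expect_error(impute_half_min(bad), names(bad)[2])
})

test_that("flag_outliers matches the hand-computed single-spike case", {
  x <- c(rep(0, 9), 9)
  ab <- abundance_tbl(matrix(x, 10))
  mask <- flag_outliers(ab, rep("a", 10))
  # mean 0.9, sd sqrt(72.9/9) = 2.846, threshold 0.9 + 2*2.846 = 6.59
  expect_identical(unname(mask[, 1]), c(rep(FALSE, 9), TRUE))
  # constant column in one group: sd 0, strict inequality flags nothing
  const <- abundance_tbl(matrix(5, 4))
  expect_false(any(flag_outliers(const, rep("a", 4))))
  # two groups with identical data flag identically
  two <- abundance_tbl(matrix(rep(x, 2), 20))
  mask2 <- flag_outliers(two, rep(c("a", "b"), each = 10))
  expect_identical(unname(mask2[1:10, 1]), unname(mask2[11:20, 1]))
  # singleton group: sd undefined
  expect_error(flag_outliers(ab, c(rep("a", 9), "b")), "single sample")
})

test_that("flag_outliers equals brute-force recomputation on random matrices", {
  withr::with_seed(7, {
    for (rep in 1:5) {
      m <- matrix(rnorm(50 * 10), 50, 10,
                  dimnames = list(sprintf("s%02d", 1:50),
                                  sprintf("C%05d", 1:10)))
      groups <- sample(c("ctl", "trt"), 50, replace = TRUE)
      if (min(table(groups)) < 2) next
      ab <- abundance_tbl(m, sample_ids = rownames(m))
      expect_identical(flag_outliers(ab, groups), oracle_outlier_mask(m, groups))
    }
  })
})

test_that("screen_outliers replace policy re-imputes and reports flagged cells", {
  x <- c(rep(1, 9), 9)
  ab <- abundance_tbl(matrix(x, 10))
  out <- screen_outliers(ab, rep("a", 10), policy = "replace")
  expect_equal(nrow(out$report), 1)
  expect_equal(out$report$value, 9)
  expect_equal(out$report$group_mean, mean(x))
  # flagged entry replaced by half of the remaining minimum
  expect_equal(out$abundance[[2]][10], 0.5)
  # report policy leaves values untouched
  rep_only <- screen_outliers(ab, rep("a", 10), policy = "report")
  expect_identical(rep_only$abundance, ab)
  expect_equal(nrow(rep_only$report), 1)
})

test_that("split_dataset stratifies by class and is seed-reproducible", {
  x <- toy_cohort(n = 10)
  s1 <- split_dataset(x, test_fraction = 0.2, seed = 1)
  tab <- table(s1$split$split, metadrift:::target_factor(s1))
  expect_equal(sum(s1$split$split == "test"), 2)
  expect_equal(unname(tab["test", ]), c(1, 1))  # one test sample per class
  # determinism
  s2 <- split_dataset(x, test_fraction = 0.2, seed = 1)
  expect_identical(s1$split, s2$split)
  expect_false(identical(s1$split,
                         split_dataset(x, test_fraction = 0.2, seed = 2)$split))
  # 80/20 at n = 100
  s3 <- split_dataset(toy_cohort(n = 100), 0.2, seed = 3)
  expect_equal(sum(s3$split$split == "test"), 20)
  expect_equal(sum(s3$split$split == "train"), 80)
})

test_that("split_dataset per-class test fractions deviate by < 1/class-size", {
  withr::with_seed(5, {
    for (n in c(30, 57, 101)) {
      x <- toy_cohort(n = n)
      s <- split_dataset(x, 0.25, seed = n)
      y <- metadrift:::target_factor(s)
      for (cl in levels(y)) {
        sel <- y == cl
        frac <- mean(s$split$split[sel] == "test")
        expect_lt(abs(frac - 0.25), 1 / sum(sel))
      }
    }
  })
})

test_that("abundance round-trips through TSV and delimiter sniffing works", {
  ab <- abundance_tbl(matrix(c(1.5, 2.5, 3.5, 4.5), 2))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_abundance(ab, tsv)
  expect_equal(as.data.frame(read_abundance(tsv)), as.data.frame(ab))
  csv <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(ab, csv)
  expect_equal(as.data.frame(read_abundance(csv)), as.data.frame(ab))
})
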