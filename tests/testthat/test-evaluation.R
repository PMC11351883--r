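test_that("scheme I folds realise the record-level 3-1-1 protocol", {
  ids <- sprintf("r%02d", 1:15)
  plan <- make_folds_scheme1(ids, k = 5, seed = 2)
  expect_equal(nrow(plan), 5)
  for (i in 1:5) {
    expect_length(plan$test[[i]], 3)
    expect_length(plan$train[[i]], 9)
    expect_length(plan$validation[[i]], 3)
    expect_length(intersect(plan$train[[i]], plan$test[[i]]), 0)
    expect_length(intersect(plan$validation[[i]], plan$test[[i]]), 0)
    expect_length(intersect(plan$train[[i]], plan$validation[[i]]), 0)
  }
  expect_setequal(unlist(plan$test), ids) # every record tested exactly once
  expect_identical(make_folds_scheme1(ids, k = 5, seed = 2), plan)
  expect_error(make_folds_scheme1(ids[1:4], k = 5), "at least 5")
})

test_that("scheme I handles non-divisible record counts", {
  ids <- sprintf("r%02d", 1:14)
  plan <- make_folds_scheme1(ids, k = 5, seed = 7)
  sizes <- sort(lengths(plan$test), decreasing = TRUE)
  expect_equal(sizes, c(3, 3, 3, 3, 2))
  expect_setequal(unlist(plan$test), ids)
  expect_equal(sum(lengths(plan$test)), 14)
})

test_that("scheme II holds the target subject out and swaps the halves", {
  idx <- tibble::tibble(
    subject_id = rep(c("A", "B", "C"), c(15, 14, 11)),
    record_id = sprintf("%s%02d", rep(c("A", "B", "C"), c(15, 14, 11)),
                        c(1:15, 1:14, 1:11)))
  plan <- make_split_scheme2(idx, "B", seed = 3)
  expect_equal(nrow(plan), 2)
  for (i in 1:2) {
    expect_length(plan$train[[i]], 26)
    expect_false(any(grepl("^B", plan$train[[i]])))
  }
  expect_equal(sort(lengths(plan$validation)), c(7, 7))
  # swap completeness: the two test sets partition the target's records
  expect_setequal(c(plan$test[[1]], plan$test[[2]]),
                  idx$record_id[idx$subject_id == "B"])
  expect_length(intersect(plan$test[[1]], plan$test[[2]]), 0)
  expect_error(make_split_scheme2(idx[idx$subject_id == "B", ], "B"),
               "at least one other")
})

test_that("calibration moves validation records into training only", {
  idx <- tibble::tibble(subject_id = rep(c("A", "B"), c(10, 14)),
                        record_id = sprintf("%s%02d", rep(c("A", "B"), c(10, 14)),
                                            c(1:10, 1:14)))
  base <- make_split_scheme2(idx, "B", seed = 5)
  cal <- make_split_calibration(idx, "B", n_cal = 1, seed = 5)
  for (i in 1:2) {
    expect_length(cal$train[[i]], length(base$train[[i]]) + 1)
    expect_length(cal$validation[[i]], length(base$validation[[i]]) - 1)
    expect_identical(cal$test[[i]], base$test[[i]])
    moved <- setdiff(cal$train[[i]], base$train[[i]])
    expect_true(moved %in% base$validation[[i]])
  }
  zero <- make_split_calibration(idx, "B", n_cal = 0, seed = 5)
  expect_identical(zero$train, base$train)
  expect_error(make_split_calibration(idx, "B", n_cal = 7, seed = 5),
               "at least one validation")
})

test_that("metrics handle identity, offset and degenerate cases", {
  y <- c(1, 2, 3, 4, 5)
  m0 <- compute_metrics(y, y)
  expect_equal(m0$me, 0); expect_equal(m0$mae, 0); expect_equal(m0$sd, 0)
  expect_equal(m0$cc, 1)
  m1 <- compute_metrics(y + 1, y)
  expect_equal(m1$me, 1); expect_equal(m1$mae, 1); expect_equal(m1$sd, 0)
  expect_equal(m1$cc, 1)
  # constant series: CC flagged undefined, other metrics still present
  mc <- compute_metrics(rep(2, 5), y)
  expect_false(mc$cc_defined)
  expect_true(is.na(mc$cc))
  expect_equal(mc$mae, mean(abs(2 - y)))
})

test_that("metrics match a hand computation on the four-point case", {
  est <- c(1, 2, 3, 4); meas <- c(1.5, 1.5, 3.5, 3.5)
  m <- compute_metrics(est, meas)
  e <- est - meas
  expect_equal(m$me, mean(e))
  expect_equal(m$mae, mean(abs(e)))
  expect_equal(m$sd, sd(e))
  expect_equal(m$cc, cor(est, meas))
  expect_equal(m$n, 4L)
})

test_that("metrics agree with a brute-force oracle on random pairs", {
  set.seed(10)
  worst <- 0
  for (i in 1:100) {
    n <- sample(5:60, 1)
    yhat <- rnorm(n, sd = runif(1, 0.5, 50))
    y <- yhat + rnorm(n, sd = runif(1, 0.1, 20))
    m <- compute_metrics(yhat, y)
    o <- oracle_metrics(yhat, y)
    worst <- max(worst, abs(m$me - o$me), abs(m$mae - o$mae),
                 abs(m$sd - o$sd), abs(m$cc - o$cc))
    # invariants
    expect_gte(m$mae, abs(m$me))
    expect_true(m$cc >= -1 && m$cc <= 1)
    expect_true(m$ci_low <= m$cc && m$cc <= m$ci_high)
  }
  expect_lt(worst, 1e-10)
})

test_that("SD is invariant under constant error shifts", {
  set.seed(11)
  y <- rnorm(50); yhat <- y + rnorm(50)
  m1 <- compute_metrics(yhat, y)
  m2 <- compute_metrics(yhat + 7, y)
  expect_equal(m1$sd, m2$sd)
  expect_equal(m2$me, m1$me + 7)
})

test_that("confidence intervals and p-values behave sensibly", {
  set.seed(12)
  y <- rnorm(200)
  yhat <- y + rnorm(200, sd = 0.2)
  m <- compute_metrics(yhat, y)
  expect_lt(m$p_value, 1e-10)
  expect_true(m$ci_low > 0.9 && m$ci_high < 1)
  # uncorrelated data: p typically large, CI wide
  m2 <- compute_metrics(rnorm(20), rnorm(20))
  expect_true(m2$ci_high - m2$ci_low > 0.5)
})

test_that("run_scheme refuses plans that reference missing records", {
  dat <- tibble::tibble(record_id = "r1", cycle_index = 1,
                        window = list(matrix(0, 1000, 2)),
                        sbp = 100, dbp = 0, mrr = 2000, mrd = -2000)
  plan <- make_folds_scheme1(c("r1", "r2", "r3", "r4", "r5"), seed = 1)
  expect_error(run_scheme(dat, plan), "absent records")
})
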