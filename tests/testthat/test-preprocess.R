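# Preprocessing pipeline: resampling, one-hot, outliers, tiered imputation.

toy_events <- function() {
  data.frame(
    subject_id = 1L, hadm_id = 1L,
    time_h = c(2.1, 2.8, 5.0, 71.5, 10.2),
    item = c("glucose", "glucose", "sbp", "sbp", "antihypertensive"),
    value = c(100, 140, 150, 160, 1))
}

test_that("hourly resampling keeps the last observation per half-open bin", {
  m <- resample_hourly(toy_events(), duration = 72)[["1"]]
  expect_equal(nrow(m), 72L)
  expect_equal(unname(m[3, "glucose"]), 140)       # later value in [2, 3) wins
  expect_equal(unname(m[6, "sbp"]), 150)
  expect_equal(unname(m[72, "sbp"]), 160)          # event at 71.5 lands in the final bin
  expect_equal(unname(m[11, "antihypertensive"]), 1)
  expect_equal(unname(m[10, "antihypertensive"]), 0)  # med absence is 0, not missing
  expect_true(all(is.na(m[, "inr"])))
  mr <- attr(resample_hourly(toy_events(), 72), "missing_rate")
  expect_equal(unname(mr["inr"]), 1)
  expect_equal(unname(mr["glucose"]), 71 / 72)
  expect_error(resample_hourly(toy_events(), 72, subjects = c(1L, 2L)),
               "no events")
})

test_that("one-hot encoding produces exactly-one indicators and handles gaps", {
  d <- data.frame(admission_type = c("EMERGENCY", "URGENT", "ELECTIVE",
                                     "EMERGENCY", NA),
                  gender = c("M", "F", "M", NA, "F"))
  oh <- one_hot_encode(d, c("admission_type", "gender"))
  expect_equal(ncol(oh$matrix), 5L)
  sums <- rowSums(oh$matrix[, 1:3])
  expect_equal(sums[1:4], rep(1, 4), ignore_attr = TRUE)
  expect_true(all(is.na(oh$matrix[5, 1:3])))   # missing source: NA indicators
  expect_true(all(is.na(oh$matrix[4, 4:5])))
  oh1 <- one_hot_encode(d, "gender", drop_first = TRUE)
  expect_equal(colnames(oh1$matrix), "gender_M")

  # frozen levels: unseen category errors or routes to "other"
  lv <- list(admission_type = c("ELECTIVE", "EMERGENCY"))
  d2 <- data.frame(admission_type = "URGENT")
  expect_error(one_hot_encode(d2, "admission_type", levels = lv), "unseen")
  oh2 <- one_hot_encode(d2, "admission_type", levels = lv, unseen = "other")
  expect_equal(unname(oh2$matrix[1, "admission_type__other_"]), 1)
})

test_that("outlier handling removes impossible values and winsorizes extremes", {
  x <- c(0:100, 10000)
  st <- list(sbp = list(mean = mean(x), sd = sd(x),
                        q025 = quantile(x, 0.025, names = FALSE),
                        q975 = quantile(x, 0.975, names = FALSE)))
  ranges <- data.frame(name = "sbp", lower = 40, upper = 300)

  m1 <- matrix(c(120, 305, 150), 3, 1, dimnames = list(NULL, "sbp"))
  out1 <- clean_outliers(m1, ranges, st)
  expect_true(is.na(out1$matrix[2, 1]))    # systolic BP 305 removed
  expect_equal(out1$n_removed[["sbp"]], 1L)

  xm <- matrix(c(60, 70, 290), 3, 1, dimnames = list(NULL, "sbp"))
  st2 <- list(sbp = list(mean = 65, sd = 10, q025 = 50, q975 = 80))
  out2 <- clean_outliers(xm, ranges, st2)
  expect_equal(unname(out2$matrix[3, 1]), 80)      # beyond 3 SD -> upper percentile
  expect_equal(out2$n_winsorized[["sbp"]], 1L)
  # within 3 SD: unchanged
  calm <- matrix(c(60, 65, 70), 3, 1, dimnames = list(NULL, "sbp"))
  out3 <- clean_outliers(calm, ranges, st2)
  expect_equal(out3$matrix, calm)
  expect_equal(out3$n_winsorized[["sbp"]], 0L)
})

test_that("winsorization pulls a toy extreme to the training 97.5th percentile", {
  base <- c(0:100, 10000)
  st <- list(f = list(mean = mean(base), sd = sd(base),
                      q025 = quantile(base, 0.025, names = FALSE),
                      q975 = quantile(base, 0.975, names = FALSE)))
  m <- matrix(base, ncol = 1, dimnames = list(NULL, "f"))
  out <- clean_outliers(m, data.frame(name = "f", lower = -Inf, upper = Inf), st)
  expect_equal(unname(out$matrix[102, 1]), quantile(base, 0.975, names = FALSE))
  expect_true(all(out$matrix[1:101, 1] == base[1:101]))
})

test_that("median imputation fills sparse gaps with the training median", {
  fake <- structure(list(
    kept = "f", tiers = list(f = "median"),
    medians = list(f = median(c(1, 2, 4, 100))), modes = list(),
    knn = list()), class = "mskt_pipeline")
  m <- matrix(c(1, 2, NA, 4, 100), ncol = 1, dimnames = list(NULL, "f"))
  out <- tiered_impute(m, fake)
  expect_equal(unname(out[3, 1]), 3)               # median of 1, 2, 4, 100
  expect_false(anyNA(out))
})

test_that("the fitted pipeline drops, imputes and audits by missing-rate tier", {
  coh <- small_cohort()
  sp <- split_cohort(coh, seed = 4)
  pl <- fit_pipeline(coh, sp$train)
  expect_s3_class(pl, "mskt_pipeline")
  # > 20% missing features are dropped unless whitelisted
  expect_true(all(c("aptt", "fibrinogen") %in%
                    pl$audit$feature[pl$audit$action == "dropped"]))
  expect_equal(pl$tiers[["inr"]], "knn")
  expect_equal(pl$tiers[["sbp"]], "median")
  expect_true(all(pl$audit$missing_rate[pl$audit$tier == "median"] < 0.05))
  expect_true(all(pl$audit$missing_rate[pl$audit$tier == "drop"] > 0.20))

  pl_white <- fit_pipeline(coh, sp$train, whitelist = "fibrinogen")
  expect_equal(pl_white$tiers[["fibrinogen"]], "whitelist_median")
  expect_true("fibrinogen" %in% pl_white$kept)

  mats <- apply_pipeline(pl, coh, sp$test)
  expect_false(any(vapply(mats, anyNA, logical(1))))
  expect_equal(colnames(mats[[1]]), pl$kept)
})

test_that("KNN-imputed values lie within the donor neighbours' range", {
  coh <- small_cohort()
  sp <- split_cohort(coh, seed = 4)
  pl <- fit_pipeline(coh, sp$train)
  sid <- sp$test[1]
  raw <- msktgp:::assemble_raw(coh, sid, levels = pl$levels)$matrices[[1]]
  feat <- "inr"
  if (!any(is.na(raw[, feat]))) raw[1:3, feat] <- NA
  filled <- pipeline_transform(pl, raw, subject_id = sid)
  donors <- pl$knn$donor_values[[feat]]
  expect_true(all(filled[, feat] >= min(donors, na.rm = TRUE) - 1e-9))
  expect_true(all(filled[, feat] <= max(donors, na.rm = TRUE) + 1e-9))
})

test_that("reference statistics are frozen: no leakage from application data", {
  coh <- small_cohort()
  sp <- split_cohort(coh, seed = 4)
  pl <- fit_pipeline(coh, sp$train)
  solo <- apply_pipeline(pl, coh, sp$test[1])[[1]]
  joint <- apply_pipeline(pl, coh, sp$test)[[1]]
  expect_identical(solo, joint)   # other subjects cannot influence a transform
})

test_that("the fitted transform is idempotent and complete", {
  coh <- small_cohort()
  sp <- split_cohort(coh, seed = 4)
  pl <- fit_pipeline(coh, sp$train)
  ids <- c(sp$train[1], sp$test[1])
  for (sid in ids) {
    raw <- msktgp:::assemble_raw(coh, sid, levels = pl$levels)$matrices[[1]]
    once <- pipeline_transform(pl, raw, subject_id = sid)
    twice <- pipeline_transform(pl, once, subject_id = sid)
    expect_equal(twice, once, tolerance = 1e-12)
    expect_false(anyNA(once))
  }
})

test_that("pipeline serializes to JSON and model data is standardized", {
  coh <- small_cohort()
  sp <- split_cohort(coh, seed = 4)
  pl <- fit_pipeline(coh, sp$train)
  path <- tempfile(fileext = ".json")
  write_pipeline_json(pl, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$kept, pl$kept)
  expect_equal(back$medians$sbp, pl$medians$sbp, tolerance = 1e-12)

  dat <- as_mskt_data(coh, pl, sp$train)
  expect_s3_class(dat, "mskt_data")
  expect_true("baseline_volume" %in% colnames(dat$features[[1]]))
  allx <- do.call(rbind, dat$features)
  zcols <- intersect(pl$std$columns, colnames(allx))
  expect_lt(max(abs(colMeans(allx[, zcols]))), 1e-8)
  expect_lt(max(abs(apply(allx[, zcols], 2, sd) - 1)), 1e-6)
  expect_equal(length(dat$v0), length(sp$train))
})
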