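# Evaluation metrics: coverage, width, RNH, confusion metrics, AUC, errors.

test_that("interval coverage counts hits of the fixed-z 95% band", {
  expect_equal(interval_coverage(rep(5, 10), runif(10, 0.1, 3), rep(5, 10)), 1)
  m <- rnorm(20); s <- rexp(20) + 0.1
  expect_equal(interval_coverage(m, s, m + 10 * s), 0)
  # boundary uses z = 1.96 exactly
  expect_equal(interval_coverage(0, 1, 1.96), 1)
  expect_equal(interval_coverage(0, 1, 1.9600001), 0)
  expect_error(interval_coverage(numeric(0), numeric(0), numeric(0)), "non-empty")
  expect_error(interval_coverage(0, 0, 0), "positive")
})

test_that("well-specified simulated intervals cover at the nominal rate", {
  set.seed(2024)
  n <- 100000
  mu <- rnorm(n, 20, 10)
  s <- exp(runif(n, log(0.1), log(10)))
  y <- rnorm(n, mu, s)
  cov <- interval_coverage(mu, s, y)
  nominal <- 2 * pnorm(1.96) - 1            # 0.9500042...
  se <- sqrt(nominal * (1 - nominal) / n)
  expect_lt(abs(cov - nominal), 3 * se)
})

test_that("interval width is 2 * 1.96 * sigma on average", {
  expect_equal(interval_width(rep(1, 5)), 3.92)
  expect_equal(interval_width(rep(0.5, 3)), 1.96)
  expect_equal(interval_width(c(1, 3)), 7.84)
  s <- rexp(50) + 0.1
  expect_equal(interval_width(3 * s), 3 * interval_width(s), tolerance = 1e-12)
  expect_error(interval_width(c(1, 0)), "positive")
})

test_that("RNH measures relative error change and handles degeneracy", {
  y <- c(10, 20)
  clean <- c(11, 22)
  expect_equal(as.numeric(rnh(clean, clean, y)), 0)
  doubled <- y + 2 * (clean - y)
  expect_equal(as.numeric(rnh(clean, doubled, y)), 1)
  expect_equal(as.numeric(rnh(c(11, 22), c(11.5, 22.5), y)), 0.375)
  # near-zero baseline errors are excluded and counted
  r <- rnh(c(10, 22), c(10.3, 22.5), y)
  expect_equal(as.numeric(r), 0.25)
  expect_equal(attr(r, "n_excluded"), 1L)
  expect_error(rnh(y, y + 1, y), "undefined")
  expect_error(rnh(1:3, 1:2, 1:3), "aligned")
})

test_that("confusion metrics reproduce the test-set confusion matrix arithmetic", {
  cm <- confusion_matrix(tn = 79, fp = 17, fn = 4, tp = 42)
  m <- confusion_metrics(cm)
  expect_equal(m$recall, 42 / 46)
  expect_equal(m$specificity, 79 / 96)
  expect_equal(m$precision, 42 / 59)
  expect_equal(m$accuracy, 121 / 142)
  # printed rounding: 91.3%, 82.3%, 71.2%
  expect_equal(round(100 * m$recall, 1), 91.3)
  expect_equal(round(100 * m$specificity, 1), 82.3)
  expect_equal(round(100 * m$precision, 1), 71.2)

  perfect <- confusion_metrics(confusion_matrix(tn = 10, fp = 0, fn = 0, tp = 5))
  expect_equal(unlist(perfect), c(recall = 1, specificity = 1, precision = 1,
                                  accuracy = 1))
  sym <- confusion_metrics(confusion_matrix(tn = 6, fp = 6, fn = 9, tp = 9))
  expect_equal(sym$recall, 0.5)
  expect_equal(sym$specificity, 0.5)

  und <- confusion_metrics(confusion_matrix(tn = 5, fp = 0, fn = 0, tp = 0))
  expect_true(is.na(und$recall))
  expect_true(is.na(und$precision))
  expect_equal(und$accuracy, 1)
  expect_error(confusion_matrix(tn = 0, fp = 0, fn = 0, tp = 0), "positive total")
  expect_error(confusion_matrix(tn = -1, fp = 1, fn = 1, tp = 1))
})

test_that("confusion counts from predictions equal explicit enumeration", {
  set.seed(31)
  pred <- rbinom(200, 1, 0.4)
  act <- rbinom(200, 1, 0.3)
  cm <- confusion_matrix(predicted = pred, actual = act)
  expect_equal(cm$tp, sum(pred & act))
  expect_equal(cm$tn, sum(!pred & !act))
  expect_equal(cm$fp + cm$fn + cm$tp + cm$tn, 200)
  met <- confusion_metrics(cm)
  expect_equal(met$accuracy, mean(pred == act))
})

test_that("rank-based AUC equals brute-force pair counting", {
  pair_auc <- function(s, l) {
    pos <- s[l == 1]; neg <- s[l == 0]
    tot <- 0
    for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)),
               pair_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)))
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  set.seed(17)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    s <- sample(seq(0, 1, 0.05), n, replace = TRUE)   # ties on purpose
    l <- rbinom(n, 1, 0.5)
    if (length(unique(l)) < 2) next
    expect_equal(roc_auc(s, l), pair_auc(s, l))
  }
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUC under label permutation is near 1/2, and pROC agrees", {
  set.seed(99)
  n <- 10000
  s <- rnorm(n)
  l <- rbinom(n, 1, 0.4)          # independent of scores
  auc <- roc_auc(s, l)
  n1 <- sum(l); n0 <- n - n1
  se <- sqrt((n + 1) / (12 * n1 * n0))  # Mann-Whitney null SE
  expect_lt(abs(auc - 0.5), 3 * se)

  skip_if_not_installed("pROC")
  s2 <- rnorm(300) + l[1:300]
  expect_equal(roc_auc(s2, l[1:300]),
               as.numeric(pROC::auc(pROC::roc(l[1:300], s2, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("regression errors follow their definitions", {
  expect_equal(regression_errors(1:5, 1:5), list(mse = 0, mae = 0))
  expect_equal(regression_errors(rep(3, 4), rep(1, 4)), list(mse = 4, mae = 2))
  expect_equal(regression_errors(c(1, -3) + c(5, 5), c(5, 5)),
               list(mse = 5, mae = 2))
  expect_error(regression_errors(numeric(0), numeric(0)), "non-empty")
})

test_that("evaluation report aggregates the suite and serializes to JSON", {
  set.seed(5)
  n <- 400
  truth <- rnorm(n, 30, 8)
  mu <- truth + rnorm(n, sd = 2)
  s <- rep(2, n)
  scores <- plogis((mu - 30) / 4)
  labels <- as.integer(truth > 30)
  rep <- evaluation_report(mu, s, truth, scores = scores, labels = labels,
                           noisy_mean = mu + rnorm(n, sd = 0.5))
  expect_s3_class(rep, "evaluation_report")
  expect_true(rep$coverage > 0.8 && rep$coverage <= 1)
  expect_equal(rep$mean_width, 2 * 1.96 * 2)
  expect_gt(rep$auc, 0.8)
  expect_gte(rep$rnh, 0)
  path <- tempfile(fileext = ".json")
  write_evaluation_report(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$mse, rep$mse, tolerance = 1e-12)
  expect_equal(back$coverage, rep$coverage, tolerance = 1e-12)
  # zero-noise run: identical predictions give RNH exactly 0
  rep0 <- evaluation_report(mu, s, truth, noisy_mean = mu)
  expect_equal(rep0$rnh, 0)
})
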