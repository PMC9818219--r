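test_that("ROC endpoints, perfect separation, and the symmetric 0.5 case", {
  perfect <- make_scored(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))
  rc <- roc_curve(perfect)
  expect_equal(rc$fpr[1], 0); expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[length(rc$fpr)], 1)
  expect_equal(rc$tpr[length(rc$tpr)], 1)
  expect_true(any(rc$fpr == 0 & rc$tpr == 1))
  expect_equal(auc(rc), 1.0)
  expect_true(all(diff(rc$thresholds) < 0))
  expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
  # interleaved scores: 2 concordant of 4 pairs
  mixed <- make_scored(c(0.9, 0.2, 0.8, 0.3), c(1, 1, 0, 0))
  expect_equal(auc_scored(mixed), 0.5)
  expect_error(roc_curve(make_scored(c(0.4, 0.6), c(1, 1))), "both labels")
})

test_that("trapezoidal AUC equals Mann-Whitney pair counting on 1000 cases", {
  set.seed(19)
  for (i in 1:1000) {
    n <- sample(4:100, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.5))      # both classes present
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # force ties sometimes
    sc <- make_scored(scores, labels)
    expect_lt(abs(auc_scored(sc) - auc_rank_oracle(scores, labels)), 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(23)
  scores <- runif(40); labels <- rbinom(40, 1, 0.5); labels[1:2] <- c(0, 1)
  a0 <- auc_scored(make_scored(scores, labels))
  expect_equal(auc_scored(make_scored(scores^3, labels)), a0)
  expect_equal(auc_scored(make_scored(plogis(5 * scores - 2), labels)), a0)
})

test_that("log-loss matches hand-computed values and clips degenerate scores", {
  sc <- make_scored(c(0.8, 0.2), c(1, 0))
  expect_equal(log_loss(sc), -mean(log(c(0.8, 0.8))), tolerance = 1e-12)
  expect_equal(round(log_loss(sc), 5), 0.22314)
  near_perfect <- make_scored(c(0.999999, 1e-6), c(1, 0))
  expect_lt(log_loss(near_perfect), 1e-4)
  clipped <- log_loss(make_scored(c(0, 1), c(1, 0)))   # worst case, clipped
  expect_true(is.finite(clipped))
})

test_that("threshold metrics count the confusion matrix with >= calls", {
  sc <- make_scored(c(0.9, 0.6, 0.2, 0.7), c(1, 1, 0, 0))
  m <- threshold_metrics(sc, 0.5)   # TP=2 FN=0 TN=1 FP=1
  expect_equal(m$sensitivity, 1.0)
  expect_equal(m$specificity, 0.5)
  expect_equal(m$accuracy, 0.75)
  all_right <- make_scored(c(0.9, 0.1), c(1, 0))
  m2 <- threshold_metrics(all_right, 0.5)
  expect_equal(unlist(m2), c(accuracy = 1, sensitivity = 1, specificity = 1))
  m3 <- threshold_metrics(sc, 0.95)   # above max score
  expect_equal(m3$sensitivity, 0)
  expect_equal(m3$specificity, 1)
  expect_error(threshold_metrics(make_scored(0.4, 0), 0.5), "no positive")
})

test_that("bootstrap intervals are seeded and collapse on constant metrics", {
  sc <- make_scored(rep(0.5, 10), c(rep(1, 5), rep(0, 5)))
  ci <- bootstrap_ci(sc, log_loss, n_iter = 200, seed = 4)
  expect_equal(ci[1], ci[2])
  expect_equal(ci[1], log_loss(sc))
  set.seed(99)  # global RNG state must not leak in
  sc2 <- make_scored(runif(30), rbinom(30, 1, 0.5))
  sc2$true_label[1:2] <- c("neoplastic", "negative")
  ci1 <- bootstrap_ci(sc2, auc_scored, n_iter = 300, seed = 7)
  ci2 <- bootstrap_ci(sc2, auc_scored, n_iter = 300, seed = 7)
  expect_identical(ci1, ci2)
  expect_lt(ci1[1], ci1[2])
})

test_that("test-split builders honour designs, quotas and shortfall errors", {
  set.seed(31)
  pool <- data.frame(
    slide_id = sprintf("p%04d", 1:400),
    cytology_class = sample(rep(cytology_classes(), c(150, 120, 60, 40, 30))))
  eq <- build_test_split(pool, split_spec("equal_balance", 50), seed = 2)
  expect_equal(sum(eq$binary_label == "negative"), 50)
  expect_equal(sum(eq$binary_label == "neoplastic"), 50)
  expect_false(any(duplicated(eq$slide_id)))
  cl <- build_test_split(pool, split_spec("clinical_balance", 20, 10), seed = 2)
  expect_equal(sum(cl$binary_label == "negative"), 200)
  expect_equal(sum(cl$binary_label == "neoplastic"), 20)
  # per-class quotas honoured exactly
  q <- c(I = 30, II = 20, III = 25, IV = 15, V = 10)
  eqq <- build_test_split(pool, split_spec("equal_balance", 50, class_quotas = q), 3)
  expect_equal(as.vector(table(eqq$cytology_class)[names(q)]), unname(q))
  # shortfall names the deficient class
  small_pool <- pool[pool$cytology_class %in% c("I", "III"), ][1:10, ]
  expect_error(build_test_split(small_pool, split_spec("equal_balance", 10), 1),
               "shortfall")
  expect_error(
    build_test_split(pool, split_spec("equal_balance", 50,
                                      class_quotas = c(I = 50, III = 40, IV = 35)), 1),
    "class V|sum")
  # label ratio is exact across random feasible pools
  for (i in 1:20) {
    n_neo <- sample(3:15, 1); ratio <- sample(2:6, 1)
    pool_i <- data.frame(
      slide_id = sprintf("q%04d", 1:500),
      cytology_class = sample(cytology_classes(), 500, replace = TRUE))
    spl <- build_test_split(pool_i, split_spec("clinical_balance", n_neo, ratio), i)
    expect_equal(sum(spl$binary_label == "negative"),
                 ratio * sum(spl$binary_label == "neoplastic"))
  }
})

test_that("evaluate_predictions builds a coherent report and is reproducible", {
  set.seed(41)
  n <- 40
  manifest <- data.frame(
    slide_id = sprintf("t%03d", 1:n), path = NA,
    cytology_class = rep(c("I", "II", "III", "IV", "V"), 8),
    split = "test")
  manifest$binary_label <- vapply(manifest$cytology_class, binary_label, "")
  y <- manifest$binary_label == "neoplastic"
  preds <- data.frame(slide_id = manifest$slide_id,
                      score = ifelse(y, rbeta(n, 8, 2), rbeta(n, 2, 8)))
  rep1 <- evaluate_predictions(preds, manifest, n_bootstrap = 200, seed = 5)
  rep2 <- evaluate_predictions(preds, manifest, n_bootstrap = 200, seed = 5)
  for (nm in names(rep1$metrics)) {
    m <- rep1$metrics[[nm]]
    expect_lte(m$lo, m$point + 1e-12)
    expect_lte(m$point, m$hi + 1e-12)
    expect_identical(m, rep2$metrics[[nm]])
  }
  # perfectly separable predictions: AUC CI upper bound 1.0
  perfect <- data.frame(slide_id = manifest$slide_id,
                        score = ifelse(y, 0.95, 0.05))
  repp <- evaluate_predictions(perfect, manifest, n_bootstrap = 100, seed = 1)
  expect_equal(repp$metrics$roc_auc$hi, 1.0)
  # a missing prediction is named
  expect_error(evaluate_predictions(preds[-3, ], manifest), "t003")
  # report writing round-trips through JSON
  p <- withr::local_tempfile(fileext = ".json")
  write_report(rep1, p)
  back <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(back$metrics$roc_auc$point, rep1$metrics$roc_auc$point)
  expect_equal(back$n_bootstrap, 200)
})
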