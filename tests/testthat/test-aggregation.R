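test_that("prediction bags validate their invariants", {
  expect_error(prediction_bag("s", character(0)), "empty")
  expect_error(prediction_bag("s", c("SCC", "XX")), "SCC or AC")
  expect_error(prediction_bag("s", c("SCC", "AC"), c(0.9, 0.9)),
               "inconsistent")
  b <- prediction_bag("s", c("SCC", "AC"), c(0.2, 0.8))
  expect_s3_class(b, "prediction_bag")
})

test_that("majority vote counts tokens with ties to AC", {
  expect_equal(majority_vote(prediction_bag("s", c("SCC", "SCC", "SCC", "AC"))),
               "SCC")
  expect_equal(majority_vote(prediction_bag("s", c("AC", "AC", "SCC"))), "AC")
  expect_equal(majority_vote(prediction_bag("s", c("SCC", "AC"))), "AC")
})

test_that("majority vote agrees with exhaustive counting on all length-12 bags", {
  for (code in 0:(2^12 - 1)) {
    bits <- as.integer(intToBits(code)[1:12])
    tokens <- ifelse(bits == 1, "AC", "SCC")
    expected <- if (sum(bits) >= 6) "AC" else "SCC"
    got <- majority_vote(prediction_bag("s", tokens))
    if (got != expected) fail(sprintf("bag %d: got %s", code, got))
  }
  succeed()
})

test_that("histogram features bin probabilities into a simplex vector", {
  b1 <- prediction_bag("s", rep("AC", 5), rep(1, 5))
  expect_equal(as.numeric(histogram_features(b1, 10)),
               c(rep(0, 9), 1))
  b2 <- prediction_bag("s", c("SCC", "AC"), c(0.05, 0.95))
  expect_equal(as.numeric(histogram_features(b2, 10)),
               c(0.5, rep(0, 8), 0.5))
  set.seed(1)
  pr <- runif(37)
  b3 <- prediction_bag("s", ifelse(pr >= 0.5, "AC", "SCC"), pr)
  expect_equal(sum(histogram_features(b3, 10)), 1)
  expect_true(all(histogram_features(b3, 10) >= 0))
})

test_that("tf-idf follows the smoothed formula on the two-document example", {
  b1 <- prediction_bag("d1", c("SCC", "SCC"))
  b2 <- prediction_bag("d2", "AC")
  res <- tfidf_features(list(b1, b2), ngram_range = c(1, 1), dim = 10)
  # raw tf-idf(doc1, SCC) = 2 * (ln(3/2) + 1); doc1 contains only SCC,
  # so after L2 normalization that component is exactly 1
  expect_equal(unname(res$features[1, "SCC"]), 1)
  expect_equal(unname(res$features[1, "AC"]), 0)
  expect_equal(unname(res$features[2, "AC"]), 1)
  expect_equal(unname(res$model$idf["SCC"]), log(3 / 2) + 1)
})

test_that("tf-idf matches a brute-force oracle on random small corpora", {
  set.seed(42)
  for (rep in 1:100) {
    n_docs <- sample(2:5, 1)
    token_lists <- lapply(seq_len(n_docs), function(i) {
      sample(c("SCC", "AC"), sample(1:6, 1), replace = TRUE)
    })
    bags <- lapply(seq_len(n_docs), function(i) {
      prediction_bag(paste0("d", i), token_lists[[i]])
    })
    got <- tfidf_features(bags, ngram_range = c(1, 3), dim = 10)$features
    want <- brute_tfidf(token_lists, c(1L, 3L), 10L)
    expect_lt(max(abs(got[, colnames(want)] - want)), 1e-12)
  }
})

test_that("identical documents map to identical unit-norm rows", {
  b <- prediction_bag("a", c("AC", "SCC", "AC", "AC"))
  b2 <- prediction_bag("b", c("AC", "SCC", "AC", "AC"))
  res <- tfidf_features(list(b, b2, prediction_bag("c", rep("SCC", 3))))
  expect_equal(res$features[1, ], res$features[2, ])
  norms <- sqrt(rowSums(res$features^2))
  expect_equal(unname(norms), rep(1, 3), tolerance = 1e-12)
})

test_that("features ignore the slide id and sub-threshold probability jitter", {
  pr <- c(0.12, 0.81, 0.67, 0.33)
  tok <- ifelse(pr >= 0.5, "AC", "SCC")
  b1 <- prediction_bag("id1", tok, pr)
  b2 <- prediction_bag("other", tok, pr + c(0.01, -0.01, 0.02, 0.01))
  expect_equal(as.numeric(histogram_features(b1)),
               as.numeric(histogram_features(b2)))
  vec <- tfidf_fit(list(b1, prediction_bag("x", rep("SCC", 4))))
  expect_equal(tfidf_transform(vec, list(b1)), tfidf_transform(vec, list(b2)))
})

test_that("class weights are inverse frequencies normalized to the sample size", {
  labels <- rep(c("SCC", "AC"), c(245, 36))
  w <- compute_class_weights(labels)
  expect_equal(w$w_ac / w$w_scc, 245 / 36)
  expect_equal(w$w_scc * 245 + w$w_ac * 36, 281)
  wb <- compute_class_weights(rep(c("SCC", "AC"), 10))
  expect_equal(wb$w_scc, 1)
  expect_equal(wb$w_ac, 1)
  expect_error(compute_class_weights(rep("SCC", 5)), "both classes")
})

test_that("slide classifiers separate a linearly separable toy and stay null on noise", {
  set.seed(7)
  x <- cbind(a = rnorm(60, rep(c(0, 4), each = 30)), b = rnorm(60))
  lab <- rep(c("SCC", "AC"), each = 30)
  m <- fit_slide_classifier(x, lab, "lr", seed = 0)
  expect_equal(max(m$cv_table$mean_auroc, na.rm = TRUE), 1)
  # label permutation: null behavior
  set.seed(8)
  m0 <- fit_slide_classifier(x, sample(lab), "lr", seed = 0)
  expect_gt(max(m0$cv_table$mean_auroc, na.rm = TRUE), 0.3)
  expect_lt(max(m0$cv_table$mean_auroc, na.rm = TRUE), 0.7)
})

test_that("all five algorithms fit, carry the scheme, and emit probabilities", {
  bags <- make_prediction_bags(60, 0.5, 0.9, seed = 5)
  tf <- tfidf_features(bags$bags)
  for (algo in c("lr", "rf", "svm", "adaboost", "xgb")) {
    m <- fit_slide_classifier(tf$features, bags$truth$label, algo,
                              case_ids = bags$truth$case_id, seed = 0)
    pr <- predict_slide(m, tf$features)
    expect_true(all(pr$p_ac >= 0 & pr$p_ac <= 1), info = algo)
    expect_gt(max(m$cv_table$mean_auroc, na.rm = TRUE), 0.9)
  }
})

test_that("scaling all class weights leaves the logistic decision boundary unchanged", {
  set.seed(9)
  x <- cbind(a = rnorm(80, rep(c(0, 2), each = 40)), b = rnorm(80))
  lab <- rep(c("SCC", "AC"), each = 40)
  w1 <- compute_class_weights(lab)
  w2 <- list(w_scc = 2 * w1$w_scc, w_ac = 2 * w1$w_ac)
  m1 <- fit_slide_classifier(x, lab, "lr", weights = w1, seed = 0)
  m2 <- fit_slide_classifier(x, lab, "lr", weights = w2, seed = 0)
  expect_equal(predict_slide(m1, x)$p_ac, predict_slide(m2, x)$p_ac,
               tolerance = 1e-6)
})

test_that("prediction rejects mismatched feature schemes and dimensions", {
  bags <- make_prediction_bags(30, 0.5, 0.9, seed = 6)
  tf <- tfidf_features(bags$bags)
  m <- fit_slide_classifier(tf$features, bags$truth$label, "lr", seed = 0)
  hist_f <- structure(t(vapply(bags$bags, histogram_features, numeric(10))),
                      scheme = "histogram")
  expect_error(predict_slide(m, hist_f), "scheme")
  expect_error(predict_slide(m, tf$features[, 1:3]), "dimension")
})

test_that("too few slides per class for stratified CV is a clear error", {
  x <- matrix(rnorm(20), 10, 2)
  lab <- rep(c("SCC", "AC"), c(8, 2))
  expect_error(fit_slide_classifier(x, lab, "lr"), "AC")
})

test_that("bags survive a CSV round trip", {
  bags <- make_prediction_bags(5, 0.5, 0.8, bag_size = c(3, 9), seed = 2)$bags
  path <- tempfile(fileext = ".csv")
  write_bags(bags, path)
  back <- read_bags(path)
  expect_equal(length(back), 5)
  for (i in 1:5) {
    expect_equal(back[[i]]$tokens, bags[[i]]$tokens)
    expect_equal(back[[i]]$probs, bags[[i]]$probs, tolerance = 1e-12)
  }
})
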