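#' A slide's bag of patch predictions
#'
#' Each whole-slide image is treated as a document whose tokens are the
#' patch-level class predictions, in row-major scan order, with the
#' parallel AC probabilities.
#'
#' @param slide_id Slide identifier.
#' @param tokens Character vector of `"SCC"`/`"AC"`.
#' @param probs Parallel numeric vector of `p_ac` in `[0, 1]`.
#' @param threshold Consistency threshold between tokens and probs
#'   (default 0.5; `p_ac >= threshold` must mean AC).
#' @return Object of class `prediction_bag`.
#' @export
prediction_bag <- function(slide_id, tokens, probs = NULL,
                           threshold = 0.5) {
  tokens <- as.character(tokens)
  if (!length(tokens)) stop("prediction bag for '", slide_id, "' is empty")
  if (!all(tokens %in% c("SCC", "AC"))) stop("tokens must be SCC or AC")
  if (is.null(probs)) probs <- ifelse(tokens == "AC", 0.75, 0.25)
  stopifnot(length(probs) == length(tokens),
            all(probs >= 0 & probs <= 1))
  if (any((probs >= threshold) != (tokens == "AC"))) {
    stop("tokens inconsistent with probabilities at threshold ", threshold)
  }
  structure(list(slide_id = slide_id, tokens = tokens, probs = probs),
            class = "prediction_bag")
}

#' @export
print.prediction_bag <- function(x, ...) {
  cat(sprintf("<prediction_bag %s: %d tokens, %d AC / %d SCC>\n",
              x$slide_id, length(x$tokens), sum(x$tokens == "AC"),
              sum(x$tokens == "SCC")))
  invisible(x)
}

#' Majority-vote slide label
#'
#' The slide is assigned the most frequent patch prediction; an exact tie
#' goes to AC, the minority class (mirroring the class-weighting intent
#' of the slide-level classifiers).
#'
#' @param bag A [prediction_bag()].
#' @return `"SCC"` or `"AC"`.
#' @export
majority_vote <- function(bag) {
  stopifnot(inherits(bag, "prediction_bag"))
  n_ac <- sum(bag$tokens == "AC")
  if (n_ac >= length(bag$tokens) - n_ac) "AC" else "SCC"
}

#' Histogram features of a prediction bag
#'
#' Counts the patch AC-probabilities into `n_bins` equal-width bins on
#' `[0, 1]` (last bin right-closed) and normalizes by bag size, yielding a
#' probability vector.
#'
#' @param bag A [prediction_bag()].
#' @param n_bins Number of bins (default 10).
#' @return Numeric vector of length `n_bins` summing to 1, with attribute
#'   `scheme = "histogram"`.
#' @export
histogram_features <- function(bag, n_bins = 10L) {
  stopifnot(inherits(bag, "prediction_bag"), n_bins >= 2)
  idx <- pmin(floor(bag$probs * n_bins) + 1L, n_bins)
  v <- tabulate(idx, nbins = n_bins) / length(idx)
  structure(v, scheme = "histogram")
}

# n-grams of a token sequence as underscore-joined strings
.ngrams <- function(tokens, orders) {
  out <- character(0)
  n <- length(tokens)
  for (k in orders) {
    if (n < k) next
    if (k == 1) out <- c(out, tokens)
    else {
      m <- vapply(seq_len(n - k + 1),
                  function(i) paste(tokens[i:(i + k - 1)], collapse = "_"),
                  character(1))
      out <- c(out, m)
    }
  }
  out
}

#' Fit a TF-IDF vectorizer on a corpus of prediction bags
#'
#' Treats each slide as a document of SCC/AC tokens and builds n-gram
#' (orders 1-3 by default) term counts. Because the raw vocabulary of a
#' binary token alphabet is small, the feature space is the `dim` n-grams
#' of highest document frequency (ties broken lexicographically for
#' determinism). IDF is smoothed: `idf(t) = ln((1 + n) / (1 + df(t))) + 1`;
#' term frequency is the raw count; rows are L2-normalized.
#'
#' @param bags List of [prediction_bag()] (>= 2 for a meaningful IDF).
#' @param ngram_range Integer range of n-gram orders (default `c(1, 3)`).
#' @param dim Feature dimension (default 10).
#' @return Object of class `tfidf_model` with `vocab`, `idf`,
#'   `ngram_range`.
#' @export
tfidf_fit <- function(bags, ngram_range = c(1L, 3L), dim = 10L) {
  if (!length(bags)) stop("empty corpus")
  orders <- ngram_range[1]:ngram_range[2]
  grams <- lapply(bags, function(b) .ngrams(b$tokens, orders))
  df <- table(unlist(lapply(grams, unique)))
  df <- df[order(-as.vector(df), names(df))]
  vocab <- names(df)[seq_len(min(dim, length(df)))]
  n_docs <- length(bags)
  idf <- log((1 + n_docs) / (1 + as.vector(df[vocab]))) + 1
  names(idf) <- vocab
  structure(list(vocab = vocab, idf = idf, ngram_range = ngram_range,
                 dim = length(vocab)),
            class = "tfidf_model")
}

#' Transform prediction bags into TF-IDF feature vectors
#'
#' @param model A [tfidf_fit()] vectorizer.
#' @param bags List of [prediction_bag()].
#' @return Matrix (bags x features) with unit-L2 rows (all-zero rows,
#'   possible only when no vocabulary n-gram occurs, trigger a warning),
#'   attribute `scheme = "tfidf"`.
#' @export
tfidf_transform <- function(model, bags) {
  orders <- model$ngram_range[1]:model$ngram_range[2]
  m <- matrix(0, length(bags), length(model$vocab),
              dimnames = list(NULL, model$vocab))
  for (i in seq_along(bags)) {
    g <- .ngrams(bags[[i]]$tokens, orders)
    if (!length(g)) {
      warning("bag '", bags[[i]]$slide_id,
              "' is shorter than the minimum n-gram order; zero vector")
      next
    }
    tf <- table(g)
    common <- intersect(names(tf), model$vocab)
    m[i, common] <- as.vector(tf[common]) * model$idf[common]
    nrm <- sqrt(sum(m[i, ]^2))
    if (nrm > 0) m[i, ] <- m[i, ] / nrm
  }
  structure(m, scheme = "tfidf")
}

#' TF-IDF features in one step
#'
#' Convenience wrapper: fits the vectorizer on the corpus and returns the
#' transformed matrix together with the fitted model.
#'
#' @inheritParams tfidf_fit
#' @return List with `features` (matrix) and `model` (`tfidf_model`).
#' @export
tfidf_features <- function(bags, ngram_range = c(1L, 3L), dim = 10L) {
  model <- tfidf_fit(bags, ngram_range, dim)
  list(features = tfidf_transform(model, bags), model = model)
}

#' Inverse-frequency class weights
#'
#' `w_c = N / (2 * n_c)`, so the minority class (AC) receives the larger
#' weight and `sum_c w_c * n_c = N`.
#'
#' @param labels Character vector of `"SCC"`/`"AC"`.
#' @return List with `w_scc`, `w_ac`.
#' @export
compute_class_weights <- function(labels) {
  labels <- as.character(labels)
  n_scc <- sum(labels == "SCC"); n_ac <- sum(labels == "AC")
  if (n_scc == 0 || n_ac == 0) {
    stop("both classes must be present to compute class weights")
  }
  n <- n_scc + n_ac
  list(w_scc = n / (2 * n_scc), w_ac = n / (2 * n_ac))
}

# ---- slide-level classifiers -------------------------------------------

.default_grids <- list(
  lr = expand.grid(C = c(0.01, 0.1, 1, 10)),
  svm = expand.grid(C = c(0.1, 1, 10), gamma = c(NA, 0.01, 0.1)),
  rf = expand.grid(ntree = c(100, 300), maxdepth = c(NA, 5)),
  adaboost = expand.grid(n_estimators = c(50, 200)),
  xgb = expand.grid(max_depth = c(2, 4), nrounds = c(100, 300),
                    eta = c(0.05, 0.1))
)

# fit one algorithm at one grid point; returns object with a prob method
.fit_algo <- function(x, y01, algo, pars, obs_w) {
  switch(algo,
    lr = {
      fit <- glmnet::glmnet(x, factor(y01), family = "binomial",
                            alpha = 0, lambda = 1 / (pars$C * nrow(x)),
                            weights = obs_w, standardize = FALSE)
      list(kind = "lr", fit = fit)
    },
    svm = {
      g <- if (is.na(pars$gamma)) {
        v <- mean(apply(x, 2, stats::var)); 1 / (ncol(x) * max(v, 1e-8))
      } else pars$gamma
      cw <- c("0" = obs_w[y01 == 0][1], "1" = obs_w[y01 == 1][1])
      fit <- e1071::svm(x, factor(y01), kernel = "radial", cost = pars$C,
                        gamma = g, probability = TRUE, class.weights = cw,
                        scale = FALSE)
      list(kind = "svm", fit = fit)
    },
    rf = {
      cw <- c("0" = obs_w[y01 == 0][1], "1" = obs_w[y01 == 1][1])
      fit <- randomForest::randomForest(
        x, factor(y01), ntree = pars$ntree, classwt = cw,
        maxnodes = if (is.na(pars$maxdepth)) NULL else 2^pars$maxdepth)
      list(kind = "rf", fit = fit)
    },
    adaboost = {
      fit <- .adaboost_fit(x, y01, n_estimators = pars$n_estimators,
                           obs_w = obs_w)
      list(kind = "adaboost", fit = fit)
    },
    xgb = {
      dtr <- xgboost::xgb.DMatrix(x, label = y01, weight = obs_w)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = pars$max_depth, eta = pars$eta,
                      nthread = 1),
        data = dtr, nrounds = pars$nrounds, verbose = 0)
      list(kind = "xgb", fit = fit)
    },
    stop("unknown algorithm '", algo, "'"))
}

.predict_algo <- function(model, x) {
  # ensure the learner's S3 predict methods are registered even when the
  # model was deserialized in a fresh session
  pkg <- c(lr = "glmnet", svm = "e1071", rf = "randomForest",
           adaboost = "rpart", xgb = "xgboost")[[model$kind]]
  requireNamespace(pkg, quietly = TRUE)
  switch(model$kind,
    lr = as.vector(stats::predict(model$fit, x, type = "response")),
    svm = {
      pr <- stats::predict(model$fit, x, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    rf = stats::predict(model$fit, x, type = "prob")[, "1"],
    adaboost = .adaboost_prob(model$fit, x),
    xgb = stats::predict(model$fit, xgboost::xgb.DMatrix(x)))
}

# SAMME AdaBoost over depth-1 rpart stumps, with observation weights
.adaboost_fit <- function(x, y01, n_estimators, obs_w) {
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(x)))
  yy <- factor(y01)
  w <- obs_w / sum(obs_w)
  stumps <- list(); alphas <- numeric(0)
  for (m in seq_len(n_estimators)) {
    fit <- rpart::rpart(y ~ ., data = cbind(df, y = yy), weights = w * nrow(df),
                        method = "class",
                        control = rpart::rpart.control(maxdepth = 1,
                                                       cp = -1, minsplit = 2,
                                                       xval = 0))
    pred <- stats::predict(fit, df, type = "class")
    err <- sum(w * (pred != yy))
    err <- min(max(err, 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    if (err >= 0.5 && m > 1) break
    stumps[[m]] <- fit; alphas[m] <- alpha
    w <- w * exp(alpha * ifelse(pred != yy, 1, -1))
    w <- w / sum(w)
  }
  list(stumps = stumps, alphas = alphas, cols = names(df))
}

.adaboost_prob <- function(fit, x) {
  df <- as.data.frame(x)
  names(df) <- fit$cols
  f <- rep(0, nrow(df))
  for (m in seq_along(fit$stumps)) {
    pred <- stats::predict(fit$stumps[[m]], df, type = "class")
    f <- f + fit$alphas[m] * ifelse(pred == "1", 1, -1)
  }
  1 / (1 + exp(-2 * f))
}

# stratified, case-grouped fold assignment
.make_folds <- function(labels, case_ids, k, seed) {
  old <- .subtyper_seed_state(seed)
  on.exit(.subtyper_restore_seed(old), add = TRUE)
  fold_of_case <- integer(0)
  for (lab in unique(labels)) {
    cases <- unique(case_ids[labels == lab])
    cases <- sample(cases)
    f <- rep_len(seq_len(k), length(cases))
    fold_of_case[cases] <- f
  }
  fold_of_case[case_ids]
}

#' Fit a class-weighted slide-level classifier
#'
#' Trains one of five algorithms (logistic regression, random forest,
#' RBF-kernel SVM, AdaBoost over decision stumps, gradient boosting) on
#' slide feature vectors, with inverse-class-frequency weights and
#' stratified, case-grouped 5-fold cross-validation over a hyperparameter
#' grid scored by AUROC; the best configuration is refit on all slides.
#'
#' @param features Matrix (slides x features), e.g. from
#'   [tfidf_transform()] or stacked [histogram_features()].
#' @param labels Character vector of slide labels (`"SCC"`/`"AC"`).
#' @param algo One of `"lr"`, `"rf"`, `"svm"`, `"adaboost"`, `"xgb"`.
#' @param case_ids Case identifiers for fold grouping (default: one case
#'   per slide).
#' @param weights A [compute_class_weights()] list; computed from
#'   `labels` when NULL.
#' @param cv_grid Hyperparameter data.frame (one row per configuration);
#'   defaults to the package grid for `algo`.
#' @param n_folds CV folds (default 5).
#' @param seed Seed for fold assignment and stochastic learners
#'   (default 0).
#' @return Object of class `slide_model` with the refit `model`, the
#'   selected `pars`, the `cv_table` of mean out-of-fold AUROCs, and the
#'   feature `scheme`.
#' @export
fit_slide_classifier <- function(features, labels,
                                 algo = c("lr", "rf", "svm", "adaboost", "xgb"),
                                 case_ids = NULL, weights = NULL,
                                 cv_grid = NULL, n_folds = 5L, seed = 0L) {
  algo <- match.arg(algo)
  labels <- as.character(labels)
  x <- as.matrix(features)
  y01 <- as.numeric(labels == "AC")
  n_ac <- sum(y01 == 1); n_scc <- sum(y01 == 0)
  if (min(n_ac, n_scc) < n_folds) {
    stop("class '", if (n_ac < n_scc) "AC" else "SCC", "' has fewer than ",
         n_folds, " slides; cannot stratify ", n_folds, "-fold CV")
  }
  if (is.null(case_ids)) case_ids <- sprintf("case_%d", seq_along(labels))
  if (is.null(weights)) weights <- compute_class_weights(labels)
  obs_w <- ifelse(y01 == 1, weights$w_ac, weights$w_scc)
  grid <- if (is.null(cv_grid)) .default_grids[[algo]] else cv_grid
  folds <- .make_folds(labels, case_ids, n_folds, seed)
  cv_auc <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    fold_auc <- rep(NA_real_, n_folds)
    for (f in seq_len(n_folds)) {
      tr <- folds != f; te <- !tr
      if (length(unique(y01[tr])) < 2 || length(unique(y01[te])) < 2) next
      old <- .subtyper_seed_state(seed + 1000L * gi + f)
      m <- .fit_algo(x[tr, , drop = FALSE], y01[tr], algo, grid[gi, , drop = FALSE],
                     obs_w[tr])
      .subtyper_restore_seed(old)
      fold_auc[f] <- auroc(.predict_algo(m, x[te, , drop = FALSE]), labels[te])
    }
    cv_auc[gi] <- mean(fold_auc, na.rm = TRUE)
  }
  best <- which.max(cv_auc)
  old <- .subtyper_seed_state(seed)
  model <- .fit_algo(x, y01, algo, grid[best, , drop = FALSE], obs_w)
  .subtyper_restore_seed(old)
  structure(list(algo = algo, model = model,
                 pars = grid[best, , drop = FALSE],
                 cv_table = cbind(grid, mean_auroc = cv_auc),
                 scheme = attr(features, "scheme") %||% "custom",
                 n_features = ncol(x), weights = weights),
            class = "slide_model")
}

#' @export
print.slide_model <- function(x, ...) {
  cat(sprintf("<slide_model %s on %s features (%d-dim); CV AUROC %.3f>\n",
              x$algo, x$scheme, x$n_features,
              max(x$cv_table$mean_auroc, na.rm = TRUE)))
  invisible(x)
}

#' Predict a slide-level subtype call
#'
#' @param model A [fit_slide_classifier()] object.
#' @param features Feature matrix (slides x features) built with the same
#'   scheme the model was fitted on.
#' @param threshold Probability cut for the AC label (default 0.5).
#' @return data.frame with `p_ac` and `label`.
#' @export
predict_slide <- function(model, features, threshold = 0.5) {
  stopifnot(inherits(model, "slide_model"))
  scheme <- attr(features, "scheme")
  if (!is.null(scheme) && !identical(scheme, model$scheme)) {
    stop("feature scheme '", scheme, "' does not match the fitted scheme '",
         model$scheme, "'")
  }
  x <- as.matrix(features)
  if (ncol(x) != model$n_features) {
    stop("feature dimension ", ncol(x), " does not match the fitted ",
         model$n_features)
  }
  p <- .predict_algo(model$model, x)
  data.frame(p_ac = p, label = ifelse(p >= threshold, "AC", "SCC"))
}

#' @export
predict.slide_model <- function(object, newdata, ...) {
  predict_slide(object, newdata, ...)
}
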