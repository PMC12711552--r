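# shared fixtures, built lazily and cached for the session

.fixture_env <- new.env(parent = emptyenv())

# a small trained tinycnn on clearly separable synthetic patches
fixture_patch_model <- function() {
  if (is.null(.fixture_env$model)) {
    d <- make_patch_dataset(100, delta = 1, size = 64, seed = 101)
    cfg <- training_config(epochs = 5, batch_size = 8, lr0 = 0.003,
                           seed = 0)
    .fixture_env$model <- train_patch_model(d$patches, d$labels, cfg)
    .fixture_env$train_data <- d
  }
  .fixture_env$model
}

fixture_train_data <- function() {
  fixture_patch_model()
  .fixture_env$train_data
}

# uniform RGB patch
flat_patch <- function(r, g, b, size = 32L) {
  array(rep(c(r, g, b), each = size * size), c(size, size, 3L))
}

# rectangle polygon (x0, y0) - (x1, y1)
rect_poly <- function(x0, y0, x1, y1) {
  rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))
}

# independent trapezoidal ROC integration (oracle for auroc)
trapezoid_auc <- function(scores, labels, positive = "AC") {
  pos <- labels == positive
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(th, function(t) mean(scores[pos] >= t), numeric(1)))
  fpr <- c(0, vapply(th, function(t) mean(scores[!pos] >= t), numeric(1)))
  tpr <- c(tpr, 1); fpr <- c(fpr, 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# brute-force smoothed tf-idf (oracle for tfidf_features)
brute_tfidf <- function(token_lists, ngram_range = c(1L, 3L), dim = 10L) {
  grams_of <- function(tokens) {
    out <- character(0)
    for (k in ngram_range[1]:ngram_range[2]) {
      if (length(tokens) < k) next
      for (i in 1:(length(tokens) - k + 1)) {
        out <- c(out, paste(tokens[i:(i + k - 1)], collapse = "_"))
      }
    }
    out
  }
  docs <- lapply(token_lists, grams_of)
  all_terms <- sort(unique(unlist(docs)))
  df <- vapply(all_terms, function(t)
    sum(vapply(docs, function(d) t %in% d, logical(1))), numeric(1))
  ord <- order(-df, all_terms)
  vocab <- all_terms[ord][seq_len(min(dim, length(all_terms)))]
  n <- length(docs)
  idf <- log((1 + n) / (1 + df[vocab])) + 1
  m <- matrix(0, n, length(vocab), dimnames = list(NULL, vocab))
  for (i in seq_len(n)) {
    for (j in seq_along(vocab)) {
      m[i, j] <- sum(docs[[i]] == vocab[j]) * idf[j]
    }
    nrm <- sqrt(sum(m[i, ]^2))
    if (nrm > 0) m[i, ] <- m[i, ] / nrm
  }
  m
}
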