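#' Patch-classifier training configuration
#'
#' Mirrors the optimization recipe used for the patch-level subtype
#' classifier: Adam, batch size 64, weight decay 0.001, initial learning
#' rate 1e-4 with per-epoch exponential decay, 50 epochs. The bundled
#' backbone is `tinycnn`, a three-block convolutional network (~30k
#' parameters, 64 x 64 inputs) that trains on a CPU in minutes; the named
#' large backbones (AlexNet, VGG19, ResNet-50, Inception-v3) are accepted
#' by the interface but require an external deep-learning runtime and are
#' not bundled.
#'
#' @param backbone One of `"tinycnn"`, `"alexnet"`, `"vgg19"`,
#'   `"resnet50"`, `"inception_v3"`.
#' @param batch_size Mini-batch size (default 64).
#' @param weight_decay L2 regularization strength lambda (default 0.001).
#' @param lr0 Initial learning rate (default 1e-4).
#' @param lr_gamma Per-epoch exponential decay factor (default 0.95).
#' @param epochs Training epochs (default 50).
#' @param seed Integer seed (default 0).
#' @param class_weighting Weight the loss by inverse class frequency
#'   (default FALSE).
#' @param input_size Square input edge fed to the network (default 64;
#'   larger patches are downscaled).
#' @return Object of class `training_config`.
#' @export
training_config <- function(backbone = "tinycnn", batch_size = 64L,
                            weight_decay = 0.001, lr0 = 1e-4,
                            lr_gamma = 0.95, epochs = 50L, seed = 0L,
                            class_weighting = FALSE, input_size = 64L) {
  backbone <- match.arg(backbone, c("tinycnn", "alexnet", "vgg19",
                                    "resnet50", "inception_v3"))
  stopifnot(batch_size >= 1, lr0 > 0, lr_gamma > 0, lr_gamma <= 1,
            epochs >= 1)
  structure(list(backbone = backbone, batch_size = as.integer(batch_size),
                 weight_decay = weight_decay, lr0 = lr0,
                 lr_gamma = lr_gamma, epochs = as.integer(epochs),
                 seed = as.integer(seed),
                 class_weighting = class_weighting,
                 input_size = as.integer(input_size)),
            class = "training_config")
}

# ---- tensor plumbing (batch layout: H, W, C, N) -------------------------

#' Stack patches into a network input tensor
#'
#' Downscales patches bilinearly to `size` x `size` and stacks them into
#' an H x W x 3 x N array, standardized to roughly zero mean and unit
#' scale (`(I/255 - 0.5) / 0.25`), which keeps the small convolutional
#' network trainable in few epochs.
#'
#' @param patches List of RGB arrays (0..255).
#' @param size Target edge length.
#' @return Numeric array `size` x `size` x 3 x N.
#' @export
patches_to_tensor <- function(patches, size = 64L) {
  n <- length(patches)
  x <- array(0, c(size, size, 3L, n))
  for (i in seq_len(n)) {
    p <- patches[[i]]
    if (dim(p)[1] != size || dim(p)[2] != size) p <- resize_image(p, size, size)
    x[, , , i] <- (p / 255 - 0.5) / 0.25
  }
  x
}

# im2col for 3x3 same-padding convolution; rows ordered (h, w, n)
.im2col3 <- function(x) {
  d <- dim(x); h <- d[1]; w <- d[2]; cc <- d[3]; n <- d[4]
  xp <- array(0, c(h + 2L, w + 2L, cc, n))
  xp[2:(h + 1), 2:(w + 1), , ] <- x
  cols <- matrix(0, h * w * n, 9L * cc)
  k <- 1L
  for (ch in seq_len(cc)) for (dx in 0:2) for (dy in 0:2) {
    cols[, k] <- as.vector(aperm(xp[(1 + dy):(h + dy), (1 + dx):(w + dx),
                                    ch, , drop = FALSE], c(1, 2, 4, 3)))
    k <- k + 1L
  }
  cols
}

# scatter-add inverse of .im2col3 for the input gradient
.col2im3 <- function(cols, dims) {
  h <- dims[1]; w <- dims[2]; cc <- dims[3]; n <- dims[4]
  xp <- array(0, c(h + 2L, w + 2L, cc, n))
  k <- 1L
  for (ch in seq_len(cc)) for (dx in 0:2) for (dy in 0:2) {
    xp[(1 + dy):(h + dy), (1 + dx):(w + dx), ch, ] <-
      xp[(1 + dy):(h + dy), (1 + dx):(w + dx), ch, ] +
      array(cols[, k], c(h, w, n))
    k <- k + 1L
  }
  xp[2:(h + 1), 2:(w + 1), , , drop = FALSE]
}

.conv_fwd <- function(x, w, b) {
  d <- dim(x); n <- d[4]; f <- ncol(w)
  cols <- .im2col3(x)
  y <- sweep(cols %*% w, 2, b, "+")
  list(out = aperm(array(y, c(d[1], d[2], n, f)), c(1, 2, 4, 3)),
       cols = cols, in_dim = d)
}

.conv_bwd <- function(dy, cache, w) {
  d <- cache$in_dim; n <- d[4]
  dymat <- matrix(aperm(dy, c(1, 2, 4, 3)), ncol = dim(dy)[3])
  dw <- crossprod(cache$cols, dymat)
  db <- colSums(dymat)
  dx <- .col2im3(dymat %*% t(w), d)
  list(dx = dx, dw = dw, db = db)
}

.pool2_fwd <- function(x) {
  d <- dim(x)
  io <- seq(1, d[1], 2); ie <- io + 1
  jo <- seq(1, d[2], 2); je <- jo + 1
  parts <- list(x[io, jo, , , drop = FALSE], x[io, je, , , drop = FALSE],
                x[ie, jo, , , drop = FALSE], x[ie, je, , , drop = FALSE])
  out <- pmax(parts[[1]], parts[[2]], parts[[3]], parts[[4]])
  masks <- vector("list", 4L)
  taken <- out * 0
  for (k in 1:4) {
    m <- (parts[[k]] == out) & (taken == 0)
    taken <- taken + m
    masks[[k]] <- m
  }
  list(out = out, masks = masks, in_dim = d)
}

.pool2_bwd <- function(dy, cache) {
  d <- cache$in_dim
  dx <- array(0, d)
  io <- seq(1, d[1], 2); ie <- io + 1
  jo <- seq(1, d[2], 2); je <- jo + 1
  idx <- list(list(io, jo), list(io, je), list(ie, jo), list(ie, je))
  for (k in 1:4) {
    dx[idx[[k]][[1]], idx[[k]][[2]], , ] <- dy * cache$masks[[k]]
  }
  dx
}

.lrelu <- function(x, slope = 0.1) pmax(x, 0) + slope * pmin(x, 0)
.lrelu_grad <- function(x, slope = 0.1) ifelse(x > 0, 1, slope)

.tinycnn_init <- function(seed, in_ch = 3L) {
  old <- .subtyper_seed_state(seed)
  on.exit(.subtyper_restore_seed(old), add = TRUE)
  he <- function(fan_in, nr, nc) {
    matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
  }
  list(w1 = he(9 * in_ch, 9 * in_ch, 8L), b1 = rep(0, 8L),
       w2 = he(9 * 8, 72L, 16L), b2 = rep(0, 16L),
       w3 = he(9 * 16, 144L, 32L), b3 = rep(0, 32L),
       wd = matrix(stats::rnorm(32L, 0, sqrt(1 / 32)), 32L, 1L), bd = 0)
}

# forward pass; with cache = TRUE keeps intermediates for backprop
.tinycnn_fwd <- function(params, x, cache = FALSE) {
  c1 <- .conv_fwd(x, params$w1, params$b1)
  a1 <- .lrelu(c1$out)
  p1 <- .pool2_fwd(a1)
  c2 <- .conv_fwd(p1$out, params$w2, params$b2)
  a2 <- .lrelu(c2$out)
  p2 <- .pool2_fwd(a2)
  c3 <- .conv_fwd(p2$out, params$w3, params$b3)
  a3 <- .lrelu(c3$out)
  p3 <- .pool2_fwd(a3)
  d <- dim(p3$out)
  gap <- matrix(colMeans(matrix(p3$out, d[1] * d[2], d[3] * d[4])),
                d[3], d[4])                           # C x N
  logit <- as.vector(crossprod(gap, params$wd)) + params$bd
  p <- 1 / (1 + exp(-logit))
  if (!cache) return(list(p = p, logit = logit))
  list(p = p, logit = logit, x = x, c1 = c1, a1 = a1, p1 = p1,
       c2 = c2, a2 = a2, p2 = p2, c3 = c3, a3 = a3, p3 = p3, gap = gap)
}

.tinycnn_bwd <- function(params, fwd, y, sample_w) {
  n <- length(y)
  dlogit <- (fwd$p - y) * sample_w / sum(sample_w)   # dL/dlogit, 1 x N
  dwd <- fwd$gap %*% matrix(dlogit, n, 1)
  dbd <- sum(dlogit)
  dgap <- params$wd %*% matrix(dlogit, 1, n)          # C x N
  d3 <- dim(fwd$p3$out)
  dpool3 <- array(rep(dgap, each = d3[1] * d3[2]) / (d3[1] * d3[2]), d3)
  da3 <- .pool2_bwd(dpool3, fwd$p3)
  dc3 <- da3 * .lrelu_grad(fwd$c3$out)
  g3 <- .conv_bwd(dc3, fwd$c3, params$w3)
  da2 <- .pool2_bwd(g3$dx, fwd$p2)
  dc2 <- da2 * .lrelu_grad(fwd$c2$out)
  g2 <- .conv_bwd(dc2, fwd$c2, params$w2)
  da1 <- .pool2_bwd(g2$dx, fwd$p1)
  dc1 <- da1 * .lrelu_grad(fwd$c1$out)
  cols <- fwd$c1$cols
  dymat <- matrix(aperm(dc1, c(1, 2, 4, 3)), ncol = dim(dc1)[3])
  list(w1 = crossprod(cols, dymat), b1 = colSums(dymat),
       w2 = g2$dw, b2 = g2$db, w3 = g3$dw, b3 = g3$db,
       wd = dwd, bd = dbd)
}

#' Train the patch-level SCC/AC classifier
#'
#' Trains the configured backbone with Adam (bias-corrected moments),
#' L2 weight decay and an exponentially decaying learning rate, on
#' binary cross-entropy with AC as the positive class. Deterministic for
#' a fixed seed under single-threaded numerics.
#'
#' @param patches List of RGB arrays (0..255) or a pre-built tensor from
#'   [patches_to_tensor()].
#' @param labels Character vector of `"SCC"`/`"AC"`, one per patch.
#' @param cfg A [training_config()].
#' @return Object of class `patch_model` with elements `params`, `cfg`,
#'   `loss_history`, `n_params`.
#' @export
train_patch_model <- function(patches, labels, cfg = training_config()) {
  if (cfg$backbone != "tinycnn") {
    stop("backbone '", cfg$backbone, "' requires an external deep-learning ",
         "runtime; 'tinycnn' is the bundled backbone")
  }
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) {
    stop("training data contains a single class; both SCC and AC required")
  }
  x <- if (is.array(patches)) patches else
    patches_to_tensor(patches, cfg$input_size)
  n <- dim(x)[4]
  stopifnot(length(labels) == n)
  y <- as.numeric(labels == "AC")
  sw <- rep(1, n)
  if (cfg$class_weighting) {
    cw <- compute_class_weights(labels)
    sw <- ifelse(labels == "AC", cw$w_ac, cw$w_scc)
  }
  params <- .tinycnn_init(cfg$seed, dim(x)[3])
  mom <- lapply(params, function(p) p * 0)
  vel <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t_step <- 0L
  loss_hist <- numeric(cfg$epochs)
  old <- .subtyper_seed_state(cfg$seed + 1L)
  on.exit(.subtyper_restore_seed(old), add = TRUE)
  for (ep in seq_len(cfg$epochs)) {
    lr <- cfg$lr0 * cfg$lr_gamma^(ep - 1)
    ord <- sample.int(n)
    ep_loss <- 0; n_batch <- 0L
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      xb <- x[, , , idx, drop = FALSE]
      fwd <- .tinycnn_fwd(params, xb, cache = TRUE)
      pb <- pmin(pmax(fwd$p, 1e-12), 1 - 1e-12)
      wb <- sw[idx]
      ep_loss <- ep_loss - sum(wb * (y[idx] * log(pb) +
                                       (1 - y[idx]) * log(1 - pb))) / sum(wb)
      n_batch <- n_batch + 1L
      grads <- .tinycnn_bwd(params, fwd, y[idx], wb)
      t_step <- t_step + 1L
      for (nm in names(params)) {
        g <- grads[[nm]] + cfg$weight_decay * params[[nm]]
        mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * g
        vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * g^2
        mhat <- mom[[nm]] / (1 - beta1^t_step)
        vhat <- vel[[nm]] / (1 - beta2^t_step)
        params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    loss_hist[ep] <- ep_loss / n_batch
  }
  structure(list(backbone = cfg$backbone, params = params, cfg = cfg,
                 loss_history = loss_hist,
                 n_params = sum(vapply(params, length, numeric(1)))),
            class = "patch_model")
}

#' @export
print.patch_model <- function(x, ...) {
  cat(sprintf("<patch_model %s: %d parameters, %d epochs, final loss %.4f>\n",
              x$backbone, x$n_params, x$cfg$epochs,
              utils::tail(x$loss_history, 1)))
  invisible(x)
}

#' Predict patch-level subtype probabilities
#'
#' @param model A fitted [train_patch_model()] object.
#' @param patches List of RGB arrays or a tensor from
#'   [patches_to_tensor()].
#' @param threshold Probability cut for the AC label; ties go to AC, the
#'   minority class (default 0.5).
#' @return data.frame with `p_ac` and `label`, in input order.
#' @export
predict_patches <- function(model, patches, threshold = 0.5) {
  x <- if (is.array(patches)) patches else
    patches_to_tensor(patches, model$cfg$input_size)
  if (dim(x)[1] != model$cfg$input_size) {
    stop("patch shape ", dim(x)[1], " does not match the model input size ",
         model$cfg$input_size)
  }
  n <- dim(x)[4]
  p <- numeric(n)
  for (start in seq(1, n, by = 256L)) {
    idx <- start:min(start + 255L, n)
    p[idx] <- .tinycnn_fwd(model$params, x[, , , idx, drop = FALSE])$p
  }
  data.frame(p_ac = p, label = ifelse(p >= threshold, "AC", "SCC"))
}

#' @export
predict.patch_model <- function(object, newdata, ...) {
  predict_patches(object, newdata, ...)
}

#' Select the best backbone by validation AUROC
#'
#' @param models List of fitted `patch_model` objects.
#' @param scores Parallel numeric vector of validation AUROCs.
#' @return The winning model; ties are broken toward fewer parameters.
#' @export
select_backbone <- function(models, scores) {
  if (!length(models)) stop("no candidate models supplied")
  stopifnot(length(models) == length(scores))
  best <- which(scores == max(scores))
  if (length(best) > 1) {
    np <- vapply(models[best], function(m) m$n_params, numeric(1))
    best <- best[which.min(np)]
  }
  models[[best[1]]]
}

#' Save / load a fitted patch model
#'
#' The serialized artifact records the full configuration (including the
#' seed), so save/load/predict round-trips bitwise-identically.
#'
#' @param model A `patch_model`.
#' @param path File path.
#' @return `load_model` returns the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)

#' Grad-CAM heatmap for a patch
#'
#' Computes the gradient of the target-class score with respect to the
#' final convolutional block's activations, weights each activation map
#' by its spatially averaged gradient, rectifies the weighted sum, and
#' upsamples it to the patch size with min-max normalization to `[0, 1]`.
#' A constant activation field (zero gradient signal) yields an all-zero
#' heatmap.
#'
#' @param model A fitted `patch_model` (must expose a convolutional
#'   block, as `tinycnn` does).
#' @param patch One RGB array (0..255).
#' @param target_class `"AC"` or `"SCC"` (gradient of +logit or -logit).
#' @return Numeric matrix of the patch's spatial size, values in `[0, 1]`.
#' @export
gradcam <- function(model, patch, target_class = "AC") {
  if (is.null(model$params$w3)) stop("model has no convolutional block")
  sign_ <- if (match.arg(target_class, c("AC", "SCC")) == "AC") 1 else -1
  x <- patches_to_tensor(list(patch), model$cfg$input_size)
  fwd <- .tinycnn_fwd(model$params, x, cache = TRUE)
  # d logit / d pooled-activations, routed back through the max-pool
  d3 <- dim(fwd$p3$out)
  dpool3 <- array(rep(sign_ * model$params$wd, each = d3[1] * d3[2]) /
                    (d3[1] * d3[2]), d3)
  da3 <- .pool2_bwd(dpool3, fwd$p3)          # H x W x C x 1
  alpha <- apply(da3[, , , 1, drop = FALSE], 3, mean)
  maps <- fwd$a3[, , , 1]
  cam <- matrix(0, dim(maps)[1], dim(maps)[2])
  for (k in seq_along(alpha)) cam <- cam + alpha[k] * maps[, , k]
  cam <- pmax(cam, 0)
  cam <- .resize_bilinear(cam, dim(patch)[1], dim(patch)[2])
  rng <- range(cam)
  if (diff(rng) < 1e-12) return(cam * 0)
  (cam - rng[1]) / diff(rng)
}
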