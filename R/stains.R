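#' Standard H&E-DAB stain basis
#'
#' The classical optical-density vectors for hematoxylin, eosin and DAB
#' (Ruifrok & Johnston color deconvolution), as unit-norm columns of a
#' 3 x 3 matrix (rows = R, G, B optical density; columns = H, E, D).
#'
#' @return 3 x 3 numeric matrix with unit-norm columns.
#' @export
ruifrok_basis <- function() {
  m <- cbind(h = c(0.65, 0.70, 0.29),
             e = c(0.07, 0.99, 0.11),
             d = c(0.27, 0.57, 0.78))
  sweep(m, 2, sqrt(colSums(m^2)), "/")
}

#' Convert 8-bit RGB intensities to optical density
#'
#' `OD = -log10((I + 1) / 256)`, so a pure-white pixel has OD close to 0 and
#' darker pixels have larger OD.
#'
#' @param img RGB array (height x width x 3) or matrix (n x 3), values 0..255.
#' @return Same shape, optical densities.
#' @export
rgb_to_od <- function(img) -log10((img + 1) / 256)

#' Convert optical density back to 8-bit RGB
#' @param od Optical densities (array or matrix).
#' @return Intensities clipped to 0..255 (not rounded).
#' @export
od_to_rgb <- function(od) pmin(pmax(256 * 10^(-od) - 1, 0), 255)

# flatten an H x W x 3 array into an (H*W) x 3 matrix (column = channel)
.pix_mat <- function(img) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  matrix(img, ncol = 3L)
}

#' Per-pixel stain concentrations
#'
#' Solves `OD = basis %*% c` per pixel. With `method = "pinv"` the
#' least-squares solution through the pseudo-inverse is clipped at zero
#' (exact and fast when pixels lie in the stain subspace); with
#' `method = "lasso"` a non-negative, L1-penalized coordinate-descent
#' solution is returned, as used inside the Vahadane fit.
#'
#' @param img RGB array 0..255, or an (n x 3) OD matrix with `is_od = TRUE`.
#' @param basis 3 x k stain matrix (unit-norm columns).
#' @param method `"pinv"` or `"lasso"`.
#' @param lambda L1 penalty for `"lasso"` (default 0.01).
#' @param is_od Set `TRUE` if `img` is already an OD matrix.
#' @return n x k concentration matrix (n = pixels, row-major per channel
#'   flattening as in [rgb_to_od()]).
#' @export
stain_concentrations <- function(img, basis = ruifrok_basis(),
                                 method = c("pinv", "lasso"),
                                 lambda = 0.01, is_od = FALSE) {
  method <- match.arg(method)
  v <- if (is_od) img else rgb_to_od(.pix_mat(img))
  if (method == "pinv") {
    pinv <- MASS::ginv(basis)          # k x 3
    pmax(v %*% t(pinv), 0)
  } else {
    .nnlasso_conc(v, basis, lambda)
  }
}

# non-negative lasso via cyclic coordinate descent, vectorized over pixels
.nnlasso_conc <- function(v, m, lambda, n_iter = 30L) {
  k <- ncol(m)
  cc <- pmax(v %*% m %*% solve(crossprod(m) + diag(1e-8, k)), 0)
  gram <- crossprod(m)                  # k x k
  mv <- v %*% m                         # n x k
  for (it in seq_len(n_iter)) {
    for (j in seq_len(k)) {
      rj <- mv[, j] - cc %*% gram[, j] + cc[, j] * gram[j, j]
      cc[, j] <- pmax((rj - lambda) / gram[j, j], 0)
    }
  }
  cc
}

#' Deconvolve a patch into the HED color space
#'
#' Converts an RGB patch to optical density and separates it into
#' hematoxylin, eosin and (residual) DAB concentration planes through a
#' stain basis matrix. Concentrations are clipped at zero unless
#' `clip = FALSE`.
#'
#' @param patch RGB array (height x width x 3), 0..255.
#' @param basis 3 x k stain matrix, k in 2..3; must have full column rank.
#' @param clip Clip negative concentrations at 0 (default TRUE).
#' @return List with matrices `h`, `e` and (if k = 3) `d`, each
#'   height x width.
#' @export
hed_deconvolve <- function(patch, basis = ruifrok_basis(), clip = TRUE) {
  if (length(dim(patch)) != 3L || dim(patch)[3] != 3L) {
    stop("hed_deconvolve: patch must be a 3-channel RGB array")
  }
  if (qr(basis)$rank < ncol(basis)) stop("stain basis is singular")
  v <- rgb_to_od(.pix_mat(patch))
  cc <- v %*% t(MASS::ginv(basis))
  if (clip) cc <- pmax(cc, 0)
  h <- dim(patch)[1]; w <- dim(patch)[2]
  out <- list(h = matrix(cc[, 1], h, w), e = matrix(cc[, 2], h, w))
  if (ncol(basis) >= 3) out$d <- matrix(cc[, 3], h, w)
  out
}

#' Re-render stain concentration planes as an RGB patch
#'
#' Inverse of [hed_deconvolve()]: multiplies the concentration planes by the
#' stain basis and converts optical density back to RGB.
#'
#' @param planes List of concentration matrices (as from [hed_deconvolve()])
#'   or an n x k concentration matrix.
#' @param basis 3 x k stain matrix.
#' @param dim_hw `c(height, width)` when `planes` is a matrix.
#' @return RGB array 0..255.
#' @export
hed_reconstruct <- function(planes, basis = ruifrok_basis(), dim_hw = NULL) {
  if (is.list(planes)) {
    dim_hw <- dim(planes[[1]])
    cc <- do.call(cbind, lapply(planes, as.vector))
  } else cc <- planes
  od <- cc %*% t(basis[, seq_len(ncol(cc)), drop = FALSE])
  array(od_to_rgb(od), c(dim_hw, 3L))
}

#' Fit a stain basis by sparse non-negative factorization (Vahadane)
#'
#' Estimates the slide-specific hematoxylin/eosin basis by factorizing the
#' optical-density matrix of tissue pixels into a non-negative, unit-column
#' basis and sparse non-negative concentrations, alternating a non-negative
#' lasso concentration update with a projected least-squares basis update.
#' Initialization follows the extreme-angle heuristic in the OD plane, so
#' the fit is deterministic given the seed (used only to subsample pixels).
#'
#' @param patch Reference RGB patch (0..255) containing tissue.
#' @param n_stains Number of stains (default 2: H and E).
#' @param lambda Sparsity penalty on concentrations (default 0.01).
#' @param od_threshold Pixels with OD norm below this are treated as
#'   background and excluded from the fit (default 0.15).
#' @param max_pixels Subsample cap for speed (default 5000).
#' @param n_iter Alternating iterations (default 30).
#' @param seed Seed for pixel subsampling (default 0).
#' @return 3 x `n_stains` stain matrix, unit-norm columns, hematoxylin
#'   first (columns ordered by decreasing red-channel optical density).
#' @export
vahadane_fit <- function(patch, n_stains = 2L, lambda = 0.01,
                         od_threshold = 0.15, max_pixels = 5000L,
                         n_iter = 30L, seed = 0L) {
  v <- rgb_to_od(.pix_mat(patch))
  keep <- sqrt(rowSums(v^2)) > od_threshold
  if (sum(keep) < 50L) {
    stop("reference patch is nearly blank (", sum(keep),
         " tissue pixels); choose a reference with visible tissue")
  }
  v <- v[keep, , drop = FALSE]
  if (nrow(v) > max_pixels) {
    old <- .subtyper_seed_state(seed)
    on.exit(.subtyper_restore_seed(old), add = TRUE)
    v <- v[sample.int(nrow(v), max_pixels), , drop = FALSE]
  }
  w <- .stain_init(v, n_stains)
  for (it in seq_len(n_iter)) {
    cc <- .nnlasso_conc(v, w, lambda, n_iter = 10L)
    gram <- crossprod(cc)
    if (any(diag(gram) < 1e-10)) {
      # dead stain: re-seed it from the worst-reconstructed pixel
      resid <- v - cc %*% t(w)
      j <- which(diag(gram) < 1e-10)
      worst <- which.max(rowSums(resid^2))
      w[, j] <- v[worst, ] / sqrt(sum(v[worst, ]^2))
      next
    }
    w <- t(solve(gram + diag(1e-10, n_stains), crossprod(cc, v)))
    w <- pmax(w, 0)
    nrm <- sqrt(colSums(w^2)); nrm[nrm == 0] <- 1
    w <- sweep(w, 2, nrm, "/")
  }
  w[, order(w[1, ], decreasing = TRUE), drop = FALSE]
}

# extreme-angle initialization in the dominant OD plane
.stain_init <- function(v, k) {
  sv <- svd(v, nu = 0, nv = min(3, ncol(v)))
  basis2 <- sv$v[, 1:2, drop = FALSE]
  proj <- v %*% basis2
  # orient so most projections are positive on the first axis
  if (mean(proj[, 1]) < 0) { basis2[, 1] <- -basis2[, 1]; proj[, 1] <- -proj[, 1] }
  phi <- atan2(proj[, 2], proj[, 1])
  qs <- stats::quantile(phi, c(0.01, 0.99), names = FALSE)
  dirs <- rbind(cos(qs), sin(qs))
  w <- basis2 %*% dirs
  if (k > 2) w <- cbind(w, ruifrok_basis()[, 3])
  w <- pmax(w, 1e-6)
  sweep(w, 2, sqrt(colSums(w^2)), "/")
}

#' Stain concentration reference scale
#'
#' Per-stain robust maximum (99th percentile) of the concentrations of a
#' patch under a basis; used to match concentration ranges during
#' normalization.
#'
#' @param patch RGB patch 0..255.
#' @param basis 3 x k stain matrix.
#' @param probs Quantile used (default 0.99).
#' @return Numeric vector of length k.
#' @export
stain_concentration_scale <- function(patch, basis, probs = 0.99) {
  cc <- stain_concentrations(patch, basis, method = "pinv")
  apply(cc, 2, stats::quantile, probs = probs, names = FALSE)
}

#' Vahadane stain normalization
#'
#' Re-renders a patch through a target stain basis: the patch's stain
#' concentrations under its source basis are rescaled so that their
#' 99th-percentile per-stain values match the target's concentration scale,
#' then recombined with the target basis. White pixels (zero optical
#' density) are invariant.
#'
#' @param patch RGB patch 0..255.
#' @param source_basis 3 x k basis fitted to the patch's slide
#'   (e.g. [vahadane_fit()]).
#' @param target_basis 3 x k reference basis.
#' @param target_scale Per-stain 99th-percentile concentrations of the
#'   reference (e.g. [stain_concentration_scale()]); `NULL` skips
#'   concentration matching.
#' @return Normalized RGB patch, clipped to 0..255.
#' @export
vahadane_normalize <- function(patch, source_basis, target_basis,
                               target_scale = NULL) {
  stopifnot(ncol(source_basis) == ncol(target_basis))
  cc <- stain_concentrations(patch, source_basis, method = "pinv")
  if (!is.null(target_scale)) {
    src_scale <- apply(cc, 2, stats::quantile, probs = 0.99, names = FALSE)
    ratio <- ifelse(src_scale > 1e-8, target_scale / src_scale, 1)
    cc <- sweep(cc, 2, ratio, "*")
  }
  od <- cc %*% t(target_basis)
  array(od_to_rgb(od), dim(patch))
}

# save/restore RNG state around seeded internals
.subtyper_seed_state <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

.subtyper_restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
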