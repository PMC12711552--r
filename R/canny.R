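# shift a matrix by (dy, dx), replicating the border
.shift_mat <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h) + dy, 1), h)
  ci <- pmin(pmax(seq_len(w) + dx, 1), w)
  m[ri, ci, drop = FALSE]
}

# separable Gaussian blur with replicate padding
.gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2)); k <- k / sum(k)
  acc <- m * 0
  for (i in seq_along(k)) acc <- acc + k[i] * .shift_mat(m, (-r:r)[i], 0)
  out <- acc * 0
  for (i in seq_along(k)) out <- out + k[i] * .shift_mat(acc, 0, (-r:r)[i])
  out
}

#' Canny edge detection
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along the
#' quantized gradient direction, then hysteresis thresholding: pixels with
#' gradient magnitude at or above `high` seed edges, which grow through
#' 8-connected pixels at or above `low`. Thresholds are on the Sobel
#' magnitude of the 0..255 grayscale image (the conventional 100/200
#' operating point for 8-bit input).
#'
#' @param gray Numeric matrix, grayscale intensities 0..255.
#' @param low,high Hysteresis thresholds (defaults 100, 200).
#' @param sigma Gaussian smoothing sigma in pixels (default 1).
#' @return 0/255 integer matrix of edges, same shape as `gray`.
#' @export
canny_edges <- function(gray, low = 100, high = 200, sigma = 1) {
  g <- .gauss_blur(gray, sigma)
  gx <- (.shift_mat(g, 0, 1) - .shift_mat(g, 0, -1)) * 2 +
    (.shift_mat(g, -1, 1) - .shift_mat(g, -1, -1)) +
    (.shift_mat(g, 1, 1) - .shift_mat(g, 1, -1))
  gy <- (.shift_mat(g, 1, 0) - .shift_mat(g, -1, 0)) * 2 +
    (.shift_mat(g, 1, -1) - .shift_mat(g, -1, -1)) +
    (.shift_mat(g, 1, 1) - .shift_mat(g, -1, 1))
  mag <- sqrt(gx^2 + gy^2)
  # non-maximum suppression in 4 quantized directions
  ang <- atan2(gy, gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  sector <- as.integer(floor((ang + pi / 8) / (pi / 4))) %% 4L
  n1 <- mag * 0; n2 <- mag * 0
  offs <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  for (s in 0:3) {
    o <- offs[[s + 1]]
    sel <- sector == s
    a <- .shift_mat(mag, o[1], o[2]); b <- .shift_mat(mag, -o[1], -o[2])
    n1[sel] <- a[sel]; n2[sel] <- b[sel]
  }
  keep <- mag >= n1 & mag >= n2
  keep[1, ] <- FALSE; keep[nrow(keep), ] <- FALSE
  keep[, 1] <- FALSE; keep[, ncol(keep)] <- FALSE
  strong <- keep & mag >= high
  weak <- keep & mag >= low
  # hysteresis: grow strong edges through weak pixels (8-connected)
  edges <- strong
  repeat {
    grown <- edges
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      grown <- grown | .shift_mat(edges, dy, dx)
    }
    grown <- grown & weak
    if (identical(grown, edges)) break
    edges <- grown
  }
  matrix(ifelse(edges, 255L, 0L), nrow(gray), ncol(gray))
}

#' Population variance of an edge map
#'
#' For a 0/255 edge map with edge fraction `p` this equals
#' `255^2 * p * (1 - p)`, the scale on which the edge-variance QC cutoff
#' is defined.
#'
#' @param edge_map Numeric matrix (0/255).
#' @return Non-negative number.
#' @export
edge_map_variance <- function(edge_map) {
  mean((edge_map - mean(edge_map))^2)
}
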