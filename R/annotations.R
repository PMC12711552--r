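#' Construct a set of annotated tumor regions
#'
#' @param polygons List of n x 2 numeric matrices (x, y vertex columns,
#'   level-0 pixel coordinates, implicitly closed).
#' @param slide_id Slide the regions belong to.
#' @return Object of class `region_set`.
#' @export
region_set <- function(polygons, slide_id = NA_character_) {
  for (p in polygons) {
    if (!is.matrix(p) || ncol(p) != 2 || nrow(p) < 3) {
      stop("each polygon must be a matrix with >= 3 vertices and 2 columns")
    }
  }
  structure(list(polygons = polygons, slide_id = slide_id),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set %s: %d polygon(s), %d vertices total>\n",
              x$slide_id, length(x$polygons),
              sum(vapply(x$polygons, nrow, integer(1)))))
  invisible(x)
}

# O(n^2) proper-crossing test used only to flag suspicious annotations
.self_intersects <- function(p) {
  n <- nrow(p)
  seg <- cbind(p, p[c(2:n, 1), ])
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next
      a <- seg[i, ]; b <- seg[j, ]
      d1 <- cross(a[1], a[2], a[3], a[4], b[1], b[2])
      d2 <- cross(a[1], a[2], a[3], a[4], b[3], b[4])
      d3 <- cross(b[1], b[2], b[3], b[4], a[1], a[2])
      d4 <- cross(b[1], b[2], b[3], b[4], a[3], a[4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Read tumor annotations from a GeoJSON file
#'
#' Accepts a FeatureCollection of Polygon / MultiPolygon features in level-0
#' pixel coordinates, as exported by slide-annotation tools (e.g. QuPath).
#' Multi-polygons are flattened; only outer rings are used (holes in tumor
#' annotations are rare and ignored here). Self-intersecting rings are
#' accepted with a warning.
#'
#' @param path GeoJSON file.
#' @param slide_id Optional slide id to attach.
#' @return A [region_set()].
#' @export
read_annotation <- function(path, slide_id = NA_character_) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features
           else list(gj)
  polys <- list()
  for (i in seq_along(feats)) {
    geom <- feats[[i]]$geometry
    if (is.null(geom)) geom <- feats[[i]]
    rings <- switch(
      geom$type %||% "",
      Polygon = list(geom$coordinates[[1]]),
      MultiPolygon = lapply(geom$coordinates, function(pg) pg[[1]]),
      stop("annotation feature ", i, " has unsupported geometry type '",
           geom$type %||% "NULL", "'")
    )
    for (r in rings) {
      m <- tryCatch(
        do.call(rbind, lapply(r, function(pt) c(pt[[1]], pt[[2]]))),
        error = function(e) stop("annotation feature ", i,
                                 " has malformed coordinates"))
      if (!is.numeric(m) || nrow(m) < 3) {
        stop("annotation feature ", i, " has malformed geometry (",
             nrow(m), " vertices)")
      }
      # drop the GeoJSON closing vertex if present
      if (nrow(m) > 3 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
      if (.self_intersects(m)) {
        warning("annotation feature ", i, " is self-intersecting; accepted as drawn")
      }
      polys[[length(polys) + 1L]] <- m
    }
  }
  if (!length(polys)) warning("annotation file '", path,
                              "' contains no polygons")
  region_set(polys, slide_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shoelace area of a polygon matrix (absolute value)
.poly_area <- function(p) {
  n <- nrow(p)
  if (n < 3) return(0)
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

# Sutherland-Hodgman: clip polygon p against axis-aligned rectangle
.clip_poly_rect <- function(p, xmin, ymin, xmax, ymax) {
  inside_fns <- list(
    function(v) v[1] >= xmin, function(v) v[1] <= xmax,
    function(v) v[2] >= ymin, function(v) v[2] <= ymax)
  isect_fns <- list(
    function(a, b) { t <- (xmin - a[1]) / (b[1] - a[1]); c(xmin, a[2] + t * (b[2] - a[2])) },
    function(a, b) { t <- (xmax - a[1]) / (b[1] - a[1]); c(xmax, a[2] + t * (b[2] - a[2])) },
    function(a, b) { t <- (ymin - a[2]) / (b[2] - a[2]); c(a[1] + t * (b[1] - a[1]), ymin) },
    function(a, b) { t <- (ymax - a[2]) / (b[2] - a[2]); c(a[1] + t * (b[1] - a[1]), ymax) })
  out <- p
  for (k in 1:4) {
    if (nrow(out) == 0) return(out)
    inside <- inside_fns[[k]]; isect <- isect_fns[[k]]
    res <- list()
    n <- nrow(out)
    for (i in seq_len(n)) {
      cur <- out[i, ]; prev <- out[if (i == 1) n else i - 1, ]
      ci <- inside(cur); pi_ <- inside(prev)
      if (ci) {
        if (!pi_) res[[length(res) + 1L]] <- isect(prev, cur)
        res[[length(res) + 1L]] <- cur
      } else if (pi_) {
        res[[length(res) + 1L]] <- isect(prev, cur)
      }
    }
    out <- if (length(res)) do.call(rbind, res) else matrix(0, 0, 2)
  }
  out
}

#' Restrict a patch grid to annotated tumor regions
#'
#' Keeps a patch iff the fraction of its pixel window covered by the union
#' of annotation polygons is at least `min_overlap_fraction` (the boundary
#' is inclusive). Polygon/window intersection areas are computed exactly by
#' polygon clipping; annotation polygons are assumed non-overlapping (their
#' clipped areas are summed and capped at the window area).
#'
#' @param grid A `patch_grid` (or data.frame with `x_px`, `y_px`, `size_px`).
#' @param regions A [region_set()]; coordinates must be in the same plane as
#'   the grid (level-0 pixels for a scale-1 grid).
#' @param min_overlap_fraction Minimum covered fraction in `[0, 1]`
#'   (default 0.5).
#' @return The subset of `grid` rows that pass, same class and attributes.
#' @export
patches_in_regions <- function(grid, regions, min_overlap_fraction = 0.5) {
  stopifnot(inherits(regions, "region_set"),
            min_overlap_fraction >= 0, min_overlap_fraction <= 1)
  if (!length(regions$polygons)) {
    warning("region set for slide '", regions$slide_id,
            "' is empty; no patches retained (unannotated slide?)")
    return(grid[integer(0), , drop = FALSE])
  }
  keep <- vapply(seq_len(nrow(grid)), function(i) {
    x <- grid$x_px[i]; y <- grid$y_px[i]; s <- grid$size_px[i]
    a <- 0
    for (p in regions$polygons) {
      # cheap bounding-box reject
      if (max(p[, 1]) <= x || min(p[, 1]) >= x + s ||
          max(p[, 2]) <= y || min(p[, 2]) >= y + s) next
      a <- a + .poly_area(.clip_poly_rect(p, x, y, x + s, y + s))
    }
    min(a, s * s) / (s * s) >= min_overlap_fraction
  }, logical(1))
  grid[keep, , drop = FALSE]
}

#' Dice overlap coefficient between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; two empty masks give 1 by convention. Used to
#' flag annotation disagreement between pathologists (slides below 0.9 go to
#' consensus review).
#'
#' @param a,b Binary (0/1 or logical) arrays of identical shape.
#' @return Number in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b)) || length(a) != length(b)) {
    stop("dice: mask shapes differ")
  }
  a <- as.logical(a); b <- as.logical(b)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Rasterize a region set to a binary mask
#'
#' Pixel centers (x + 0.5, y + 0.5) are tested against the polygon union by
#' the even-odd rule; a utility for Dice comparisons of annotations.
#'
#' @param regions A [region_set()].
#' @param width,height Mask dimensions in pixels.
#' @return `height` x `width` 0/1 matrix.
#' @export
region_mask <- function(regions, width, height) {
  m <- matrix(0L, height, width)
  xs <- rep(seq_len(width) - 0.5, each = height)
  ys <- rep(seq_len(height) - 0.5, times = width)
  inside <- rep(FALSE, length(xs))
  for (p in regions$polygons) {
    inside <- xor(inside, .points_in_poly(xs, ys, p))
  }
  m[inside] <- 1L
  m
}

# even-odd rule point-in-polygon, vectorized over points
.points_in_poly <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
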