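#' Describe a slide
#'
#' A `slide_record` is the package's lightweight handle on one whole-slide
#' image. Gigapixel pyramidal formats need a dedicated reading backend; this
#' package works with plain RGB images (PNG/TIFF) treated as single-level
#' slides with a declared objective magnification, which is sufficient for
#' synthetic benchmarks and for pre-extracted slide planes.
#'
#' @param slide_id Character scalar, unique slide identifier.
#' @param case_id Character scalar, the patient/case the slide belongs to.
#' @param width,height Level-0 pixel dimensions.
#' @param objective_magnification Scanner objective power (e.g. 20 or 40).
#' @param label Optional subtype label, `"SCC"` or `"AC"`; may be `NA` for
#'   pure-inference slides.
#' @param path Optional path to the image file backing the slide.
#' @param level_dimensions Optional list of `c(width, height)` per pyramid
#'   level; defaults to the single level 0.
#' @return An object of class `slide_record`.
#' @export
slide_record <- function(slide_id, case_id, width, height,
                         objective_magnification,
                         label = NA_character_, path = NA_character_,
                         level_dimensions = NULL) {
  stopifnot(is.character(slide_id), length(slide_id) == 1L,
            width >= 1, height >= 1)
  if (!is.na(label)) label <- match.arg(label, c("SCC", "AC"))
  if (is.null(objective_magnification) || is.na(objective_magnification) ||
      objective_magnification <= 0) {
    stop("slide '", slide_id, "': objective magnification metadata is missing")
  }
  if (is.null(level_dimensions)) {
    level_dimensions <- list(c(width, height))
  }
  dims <- vapply(level_dimensions, function(d) d[1] * d[2], numeric(1))
  if (any(diff(dims) >= 0)) {
    if (length(dims) > 1) stop("level dimensions must strictly decrease")
  }
  structure(list(slide_id = slide_id, case_id = case_id,
                 label = label, path = path,
                 level_dimensions = level_dimensions,
                 objective_magnification = objective_magnification),
            class = "slide_record")
}

#' @export
print.slide_record <- function(x, ...) {
  d <- x$level_dimensions[[1]]
  cat(sprintf("<slide_record %s  case %s  %dx%d px @ %gx  label %s>\n",
              x$slide_id, x$case_id, d[1], d[2],
              x$objective_magnification,
              ifelse(is.na(x$label), "-", x$label)))
  invisible(x)
}

#' Tile a slide into a non-overlapping patch grid
#'
#' Produces the deterministic row-major grid of non-overlapping square
#' patches at the requested magnification. Partial tiles at the right and
#' bottom edges are dropped so every patch is exactly `size_px` square.
#' Coordinates are 0-based with half-open pixel windows
#' `[x, x + size) x [y, y + size)` in the tiling plane.
#'
#' When `target_magnification` is below the slide's objective power the grid
#' is laid out on the resampled plane of dimensions
#' `floor(dim * target / objective)`; [extract_patches()] performs the
#' matching resampling.
#'
#' @param slide A [slide_record()].
#' @param size_px Patch edge length in pixels (default 512).
#' @param target_magnification Magnification at which to tile (default 20).
#' @return A data.frame of class `patch_grid` with columns
#'   `row`, `col`, `x_px`, `y_px`, `size_px` (0-based indices, row-major
#'   order) and attributes `slide_id`, `scale` (target/objective) and
#'   `plane_dim`.
#' @export
tile_slide <- function(slide, size_px = 512L, target_magnification = 20) {
  stopifnot(inherits(slide, "slide_record"), size_px >= 32)
  obj <- slide$objective_magnification
  if (target_magnification > obj) {
    stop("slide '", slide$slide_id, "': requested magnification ",
         target_magnification, "x exceeds objective ", obj, "x")
  }
  scale <- target_magnification / obj
  d0 <- slide$level_dimensions[[1]]
  w <- floor(d0[1] * scale)
  h <- floor(d0[2] * scale)
  n_col <- w %/% size_px
  n_row <- h %/% size_px
  if (n_col == 0L || n_row == 0L) {
    g <- data.frame(row = integer(0), col = integer(0),
                    x_px = integer(0), y_px = integer(0),
                    size_px = integer(0))
  } else {
    row <- rep(seq_len(n_row) - 1L, each = n_col)
    col <- rep(seq_len(n_col) - 1L, times = n_row)
    g <- data.frame(row = row, col = col,
                    x_px = col * as.integer(size_px),
                    y_px = row * as.integer(size_px),
                    size_px = as.integer(size_px))
  }
  attr(g, "slide_id") <- slide$slide_id
  attr(g, "scale") <- scale
  attr(g, "plane_dim") <- c(width = w, height = h)
  class(g) <- c("patch_grid", "data.frame")
  g
}

#' Read a plain image file as a 0-255 RGB array
#'
#' @param path PNG (or, with the tiff package installed, TIFF) file.
#' @return Numeric array height x width x 3 with values in 0..255.
#' @export
read_slide_image <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
  } else {
    stop("unsupported image format: ", path, " (PNG expected)")
  }
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  round(img * 255)
}

#' Write a 0-255 RGB array as PNG
#' @param img Numeric array height x width x 3, values 0..255.
#' @param path Output path.
#' @export
write_slide_image <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 255) / 255, path)
}

# bilinear resize of one channel matrix to out_h x out_w
.resize_bilinear <- function(m, out_h, out_w) {
  in_h <- nrow(m); in_w <- ncol(m)
  if (in_h == out_h && in_w == out_w) return(m)
  ys <- (seq_len(out_h) - 0.5) * in_h / out_h - 0.5
  xs <- (seq_len(out_w) - 0.5) * in_w / out_w - 0.5
  y0 <- pmin(pmax(floor(ys), 0), in_h - 1); y1 <- pmin(y0 + 1, in_h - 1)
  x0 <- pmin(pmax(floor(xs), 0), in_w - 1); x1 <- pmin(x0 + 1, in_w - 1)
  wy <- ys - y0; wy[wy < 0] <- 0
  wx <- xs - x0; wx[wx < 0] <- 0
  a <- m[y0 + 1, x0 + 1, drop = FALSE]; b <- m[y0 + 1, x1 + 1, drop = FALSE]
  c_ <- m[y1 + 1, x0 + 1, drop = FALSE]; d <- m[y1 + 1, x1 + 1, drop = FALSE]
  top <- a * outer(rep(1, out_h), 1 - wx) + b * outer(rep(1, out_h), wx)
  bot <- c_ * outer(rep(1, out_h), 1 - wx) + d * outer(rep(1, out_h), wx)
  top * outer(1 - wy, rep(1, out_w)) + bot * outer(wy, rep(1, out_w))
}

#' Resize an RGB image array bilinearly
#' @param img height x width x 3 array.
#' @param out_h,out_w Output dimensions.
#' @return Resized array.
#' @export
resize_image <- function(img, out_h, out_w) {
  out <- array(0, c(out_h, out_w, dim(img)[3]))
  for (ch in seq_len(dim(img)[3])) {
    out[, , ch] <- .resize_bilinear(img[, , ch], out_h, out_w)
  }
  out
}

#' Extract patch pixel windows from a slide image
#'
#' @param img Level-0 RGB array (0..255) of the slide.
#' @param grid A `patch_grid` from [tile_slide()].
#' @return List of `size_px` x `size_px` x 3 arrays, in grid order. If the
#'   grid was tiled at a lower magnification than the image, the image is
#'   first downsampled bilinearly to the tiling plane.
#' @export
extract_patches <- function(img, grid) {
  scale <- attr(grid, "scale")
  if (!is.null(scale) && scale != 1) {
    pd <- attr(grid, "plane_dim")
    img <- resize_image(img, pd["height"], pd["width"])
  }
  lapply(seq_len(nrow(grid)), function(i) {
    x <- grid$x_px[i]; y <- grid$y_px[i]; s <- grid$size_px[i]
    img[(y + 1):(y + s), (x + 1):(x + s), , drop = FALSE]
  })
}

#' Read a slide manifest CSV
#'
#' Expected columns: `slide_id`, `case_id`, `label`, `path`,
#' `annotation_path` (the last two may be empty).
#'
#' @param path CSV file.
#' @return data.frame with character columns.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("slide_id", "case_id", "label")
  missing <- setdiff(needed, names(m))
  if (length(missing)) stop("manifest lacks columns: ",
                            paste(missing, collapse = ", "))
  m
}
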