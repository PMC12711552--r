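#' Synthetic-data generator configuration
#'
#' Controls the H&E-like synthetic benchmark: two tissue classes whose
#' separability is tunable, five artifact kinds matched one-to-one to the
#' QC cascade steps, slide mosaics with tumor annotations, and
#' token-level prediction bags for the aggregation stage.
#'
#' @param seed Integer seed; identical configs generate identical data.
#' @param delta Class separability >= 0; at 0 the two tissue classes are
#'   drawn from the identical distribution.
#' @param patch_size Patch edge in pixels (64 for classifier-scale work,
#'   512 for native-resolution QC).
#' @param artifact_mix Named fractions for `white`, `black`, `glare`,
#'   `pen`, `blank` artifact patches on a slide (sum <= 1).
#' @param n_slides Number of slides for slide-level benchmarks.
#' @param patches_per_slide Perfect square; slide grid is its square root.
#' @param tumor_fraction Fraction of the slide grid covered by the
#'   annotated tumor block.
#' @param q Token fidelity for prediction bags: probability a patch token
#'   equals its slide's label (in `[0.5, 1]`).
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(seed = 0L, delta = 1, patch_size = 64L,
                             artifact_mix = c(white = 0.04, black = 0.02,
                                              glare = 0.02, pen = 0.02,
                                              blank = 0.02),
                             n_slides = 40L, patches_per_slide = 16L,
                             tumor_fraction = 0.5, q = 0.9) {
  stopifnot(delta >= 0, sum(artifact_mix) <= 1, q >= 0.5, q <= 1,
            abs(sqrt(patches_per_slide) %% 1) < 1e-9)
  structure(list(seed = as.integer(seed), delta = delta,
                 patch_size = as.integer(patch_size),
                 artifact_mix = artifact_mix, n_slides = as.integer(n_slides),
                 patches_per_slide = as.integer(patches_per_slide),
                 tumor_fraction = tumor_fraction, q = q),
            class = "generator_config")
}

# paint filled ellipses into a field matrix (value added in place)
.paint_blobs <- function(field, cx, cy, rx, ry, theta, value) {
  s <- nrow(field)
  for (i in seq_along(cx)) {
    r <- ceiling(max(rx[i], ry[i]))
    xs <- max(1, floor(cx[i] - r)):min(s, ceiling(cx[i] + r))
    ys <- max(1, floor(cy[i] - r)):min(s, ceiling(cy[i] + r))
    dx <- outer(ys - cy[i], rep(1, length(xs))) * 0 +
      matrix(xs - cx[i], length(ys), length(xs), byrow = TRUE)
    dy <- matrix(ys - cy[i], length(ys), length(xs))
    u <- (dx * cos(theta[i]) + dy * sin(theta[i])) / rx[i]
    v <- (-dx * sin(theta[i]) + dy * cos(theta[i])) / ry[i]
    sel <- u^2 + v^2 <= 1
    sub <- field[ys, xs, drop = FALSE]
    sub[sel] <- sub[sel] + value[i]
    field[ys, xs] <- sub
  }
  field
}

# paint annuli (rings); interior gets a separate additive value
.paint_rings <- function(field, cx, cy, r0, thick, ring_val,
                         interior = NULL, interior_val = 0) {
  s <- nrow(field)
  for (i in seq_along(cx)) {
    r <- ceiling(r0[i] + thick[i])
    xs <- max(1, floor(cx[i] - r)):min(s, ceiling(cx[i] + r))
    ys <- max(1, floor(cy[i] - r)):min(s, ceiling(cy[i] + r))
    dx <- matrix(xs - cx[i], length(ys), length(xs), byrow = TRUE)
    dy <- matrix(ys - cy[i], length(ys), length(xs))
    d <- sqrt(dx^2 + dy^2)
    on_ring <- abs(d - r0[i]) <= thick[i]
    sub <- field[ys, xs, drop = FALSE]
    sub[on_ring] <- sub[on_ring] + ring_val[i]
    field[ys, xs] <- sub
    if (!is.null(interior)) {
      inside <- d < r0[i] - thick[i]
      sub2 <- interior[ys, xs, drop = FALSE]
      sub2[inside] <- sub2[inside] + interior_val[i]
      interior[ys, xs] <- sub2
    }
  }
  if (is.null(interior)) field else list(field = field, interior = interior)
}

#' Generate a synthetic H&E-like tissue patch
#'
#' Patches are rendered through the two-stain optical-density model:
#' hematoxylin and eosin concentration fields are composed and converted
#' to RGB with the standard H&E basis, giving pink-based textures with
#' dark nuclear speckles. Class structure scales with `delta`: SCC patches
#' gain dense small dark elliptical blobs (hyperchromatic nuclei), AC
#' patches gain ring/annulus structures with lightened lumina (gland-like
#' contours). At `delta = 0` both classes reduce to the identical
#' class-free texture.
#'
#' @param class `"SCC"` or `"AC"`.
#' @param delta Separability >= 0.
#' @param size Patch edge in pixels (default 512).
#' @param seed Integer seed.
#' @return RGB array `size` x `size` x 3, values 0..255.
#' @export
make_tissue_patch <- function(class = c("SCC", "AC"), delta = 1,
                              size = 512L, seed = 0L) {
  class <- match.arg(class)
  old <- .subtyper_seed_state(seed)
  on.exit(.subtyper_restore_seed(old), add = TRUE)
  s <- as.integer(size)
  # base concentration fields (class-free)
  c_e <- matrix(0.35 + stats::rnorm(s * s, 0, 0.05), s, s)
  c_h <- matrix(0.22 + stats::rnorm(s * s, 0, 0.06), s, s)
  # neutral nuclear speckles: identical distribution in both classes,
  # they carry the fine texture the edge-variance filter expects
  n_spk <- round(0.04 * s * s)
  c_h <- .paint_blobs(c_h,
                      cx = stats::runif(n_spk, 1, s),
                      cy = stats::runif(n_spk, 1, s),
                      rx = stats::runif(n_spk, 1.0, 2.2),
                      ry = stats::runif(n_spk, 1.0, 2.2),
                      theta = stats::runif(n_spk, 0, pi),
                      value = stats::runif(n_spk, 0.5, 0.9))
  if (delta > 0) {
    if (class == "SCC") {
      n_b <- max(1L, round(s * s / 900))
      c_h <- .paint_blobs(c_h,
                          cx = stats::runif(n_b, 1, s),
                          cy = stats::runif(n_b, 1, s),
                          rx = stats::runif(n_b, 3, 6),
                          ry = stats::runif(n_b, 2, 5),
                          theta = stats::runif(n_b, 0, pi),
                          value = rep(delta * 0.6, n_b))
    } else {
      n_r <- max(1L, round(s * s / 1800))
      res <- .paint_rings(c_h,
                          cx = stats::runif(n_r, 1, s),
                          cy = stats::runif(n_r, 1, s),
                          r0 = stats::runif(n_r, 7, 12),
                          thick = rep(1.5, n_r),
                          ring_val = rep(delta * 0.6, n_r),
                          interior = c_e,
                          interior_val = rep(-delta * 0.2, n_r))
      c_h <- res$field
      c_e <- res$interior
    }
  }
  # clamp concentrations so rendered intensities stay inside the 8-bit
  # gamut: patches then lie exactly in the two-stain OD subspace
  cc <- cbind(pmin(pmax(as.vector(c_h), 0), 2.3),
              pmin(pmax(as.vector(c_e), 0), 0.6))
  hed_reconstruct(cc, ruifrok_basis()[, 1:2], dim_hw = c(s, s))
}

#' Generate a synthetic artifact patch
#'
#' Each artifact kind is constructed to trip exactly one QC step and no
#' earlier step: `white`/`black` fail the RGB background filter, `glare`
#' the HSV filter, `pen` (eosin-like ink) the HED pen-mark filter and
#' `blank` (texture-free glass) the Canny edge-variance filter.
#'
#' @param kind One of `"white"`, `"black"`, `"glare"`, `"pen"`, `"blank"`.
#' @param size Patch edge in pixels (default 512).
#' @param seed Integer seed.
#' @return RGB array `size` x `size` x 3, values 0..255.
#' @export
make_artifact_patch <- function(kind, size = 512L, seed = 0L) {
  old <- .subtyper_seed_state(seed)
  on.exit(.subtyper_restore_seed(old), add = TRUE)
  s <- as.integer(size)
  n <- s * s
  mk <- function(r, g, b) array(c(r, g, b), c(s, s, 3L))
  switch(kind,
    white = mk(stats::runif(n, 248, 255), stats::runif(n, 248, 255),
               stats::runif(n, 248, 255)),
    black = mk(stats::runif(n, 3, 15), stats::runif(n, 3, 15),
               stats::runif(n, 3, 15)),
    glare = mk(rep(231, n), rep(210, n), rep(209, n)),
    pen = {
      # high-eosin ink, rendered through the stain model
      ce <- 1.2 + stats::rnorm(n, 0, 0.01)
      ch <- rep(0.02, n)
      hed_reconstruct(cbind(ch, pmax(ce, 0)), ruifrok_basis()[, 1:2],
                      dim_hw = c(s, s))
    },
    blank = {
      ch <- 0.05 + stats::rnorm(n, 0, 0.002)
      ce <- 0.12 + stats::rnorm(n, 0, 0.002)
      hed_reconstruct(cbind(pmax(ch, 0), pmax(ce, 0)),
                      ruifrok_basis()[, 1:2], dim_hw = c(s, s))
    },
    stop("unknown artifact kind '", kind, "'")
  )
}

#' Assemble a synthetic slide with annotation
#'
#' Mosaics a square grid of patches: tissue of the slide's class inside a
#' rectangular tumor block (emitted as the annotation polygon), class-free
#' stroma texture elsewhere, with the configured artifact fractions
#' replacing non-tumor cells.
#'
#' @param label `"SCC"` or `"AC"`.
#' @param cfg A [generator_config()].
#' @param slide_id Identifier for the slide.
#' @param case_id Case identifier (defaults to the slide id).
#' @return List with `image` (RGB array), `regions` ([region_set()]),
#'   `record` ([slide_record()]), and `plant` (data.frame `row`, `col`,
#'   `kind` in `{tumor, stroma, white, black, glare, pen, blank}`),
#'   0-based grid indices.
#' @export
make_slide <- function(label, cfg = generator_config(), slide_id = "slide_1",
                       case_id = slide_id) {
  label <- match.arg(label, c("SCC", "AC"))
  old <- .subtyper_seed_state(cfg$seed)
  on.exit(.subtyper_restore_seed(old), add = TRUE)
  g <- as.integer(round(sqrt(cfg$patches_per_slide)))
  ps <- cfg$patch_size
  n_cells <- g * g
  # centered square-ish tumor block covering ~tumor_fraction of the grid
  t_side <- max(1L, round(sqrt(cfg$tumor_fraction) * g))
  off <- (g - t_side) %/% 2L
  tumor_cells <- as.vector(outer((off:(off + t_side - 1)) * g,
                                 off:(off + t_side - 1), "+")) + 1L
  kind <- rep("stroma", n_cells)
  kind[tumor_cells] <- "tumor"
  non_tumor <- setdiff(seq_len(n_cells), tumor_cells)
  n_art <- pmin(round(cfg$artifact_mix * n_cells),
                length(non_tumor))
  pool <- sample(non_tumor)
  taken <- 0L
  for (k in names(n_art)) {
    if (n_art[[k]] <= 0 || taken >= length(pool)) next
    idx <- pool[(taken + 1):min(taken + n_art[[k]], length(pool))]
    kind[idx] <- k
    taken <- taken + length(idx)
  }
  img <- array(0, c(g * ps, g * ps, 3L))
  cell_seeds <- sample.int(.Machine$integer.max %/% 2L, n_cells)
  for (i in seq_len(n_cells)) {
    row <- (i - 1L) %/% g
    col <- (i - 1L) %% g
    p <- switch(kind[i],
      tumor = make_tissue_patch(label, cfg$delta, ps, cell_seeds[i]),
      stroma = make_tissue_patch("SCC", 0, ps, cell_seeds[i]),
      make_artifact_patch(kind[i], ps, cell_seeds[i]))
    img[(row * ps + 1):(row * ps + ps),
        (col * ps + 1):(col * ps + ps), ] <- p
  }
  x0 <- off * ps; y0 <- off * ps
  x1 <- (off + t_side) * ps; y1 <- (off + t_side) * ps
  poly <- rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))
  regions <- region_set(list(poly), slide_id)
  rec <- slide_record(slide_id, case_id, g * ps, g * ps,
                      objective_magnification = 20, label = label)
  plant <- data.frame(row = (seq_len(n_cells) - 1L) %/% g,
                      col = (seq_len(n_cells) - 1L) %% g,
                      kind = kind)
  list(image = img, regions = regions, record = rec, plant = plant)
}

#' Generate labeled patch datasets for classifier benchmarks
#'
#' @param n_per_class Patches per class.
#' @param delta Separability.
#' @param size Patch edge (default 64).
#' @param seed Integer seed.
#' @return List with `patches` (list of RGB arrays), `labels`
#'   (character vector of `"SCC"`/`"AC"`) and `case_id` (one synthetic
#'   case per patch pair, for case-level splits).
#' @export
make_patch_dataset <- function(n_per_class, delta = 1, size = 64L,
                               seed = 0L) {
  old <- .subtyper_seed_state(seed)
  on.exit(.subtyper_restore_seed(old), add = TRUE)
  seeds <- sample.int(.Machine$integer.max %/% 2L, 2L * n_per_class)
  labels <- rep(c("SCC", "AC"), each = n_per_class)
  patches <- lapply(seq_along(labels), function(i) {
    make_tissue_patch(labels[i], delta, size, seeds[i])
  })
  list(patches = patches, labels = labels,
       case_id = sprintf("case_%03d", seq_along(labels)))
}

#' Generate synthetic per-slide prediction bags
#'
#' Emulates the output of a patch classifier: each slide's label is drawn
#' with probability `prevalence` of AC; each patch token equals the slide
#' label with probability `q` and is flipped otherwise; `p_ac` is drawn
#' uniformly on the side of 0.5 consistent with the token.
#'
#' @param n_slides Number of slides.
#' @param prevalence Probability a slide is AC (default 0.5).
#' @param q Token fidelity in `[0.5, 1]`.
#' @param bag_size Integer range `c(min, max)`; sizes drawn uniformly
#'   (default `c(50, 150)`).
#' @param seed Integer seed.
#' @return List with `bags` (list of [prediction_bag()]) and `truth`
#'   (data.frame `slide_id`, `case_id`, `label`).
#' @export
make_prediction_bags <- function(n_slides, prevalence = 0.5, q = 0.9,
                                 bag_size = c(50L, 150L), seed = 0L) {
  stopifnot(q >= 0.5, q <= 1)
  old <- .subtyper_seed_state(seed)
  on.exit(.subtyper_restore_seed(old), add = TRUE)
  labels <- ifelse(stats::runif(n_slides) < prevalence, "AC", "SCC")
  sizes <- sample(bag_size[1]:bag_size[2], n_slides, replace = TRUE)
  bags <- vector("list", n_slides)
  for (i in seq_len(n_slides)) {
    match_lab <- stats::runif(sizes[i]) < q
    tokens <- ifelse(match_lab, labels[i],
                     ifelse(labels[i] == "AC", "SCC", "AC"))
    probs <- ifelse(tokens == "AC", stats::runif(sizes[i], 0.5, 1),
                    stats::runif(sizes[i], 0, 0.5))
    bags[[i]] <- prediction_bag(sprintf("slide_%03d", i), tokens, probs)
  }
  list(bags = bags,
       truth = data.frame(slide_id = sprintf("slide_%03d", seq_len(n_slides)),
                          case_id = sprintf("case_%03d", seq_len(n_slides)),
                          label = labels))
}
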