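#' Quality-control configuration
#'
#' Bundles the thresholds of the five-step patch preprocessing cascade:
#' RGB background rejection, HSV glare rejection, HED pen-mark rejection,
#' Canny edge-variance rejection, and Vahadane stain normalization of the
#' survivors.
#'
#' @param rgb_high A pixel whose mean channel intensity exceeds this is
#'   white background (default 220).
#' @param rgb_low A pixel whose mean channel intensity is below this is a
#'   black region (default 40).
#' @param rgb_fraction Reject a patch when its background-pixel fraction
#'   exceeds this (default 0.80, the "more than 80 percent background" rule).
#' @param hsv_sat_low Saturation below this (0..255 scale) marks a
#'   glare-like pixel (default 25).
#' @param hsv_val_high Value/intensity above this (0..255 scale) marks a
#'   glare-like pixel (default 230).
#' @param hsv_fraction Reject when the glare-like fraction exceeds this
#'   (default 0.70).
#' @param eosin_quantile Reject when the patch's eosin statistic exceeds
#'   this fraction of the reference eosin range (default 0.90).
#' @param eosin_ref Global eosin concentration ceiling the eosin plane is
#'   rescaled by (default 1.0 OD units).
#' @param eosin_mode `"mean"` (default): statistic is the mean rescaled
#'   eosin concentration; `"fraction"`: statistic is the fraction of pixels
#'   whose rescaled eosin exceeds `eosin_quantile`, rejecting when that
#'   fraction exceeds 0.5.
#' @param canny_variance_min Reject when the population variance of the
#'   0/255 Canny edge map falls below this (default 7000).
#' @param canny_low,canny_high,canny_sigma Canny operating point
#'   (defaults 100, 200, 1).
#' @param steps Which filters run, in cascade order; subset of
#'   `c("rgb", "hsv", "hed", "canny")`.
#' @param normalize Stain-normalize surviving patches (default TRUE).
#' @param hed_basis Stain basis used by the pen-mark filter (default
#'   [ruifrok_basis()]).
#' @return Object of class `qc_config`.
#' @export
qc_config <- function(rgb_high = 220, rgb_low = 40, rgb_fraction = 0.80,
                      hsv_sat_low = 25, hsv_val_high = 230,
                      hsv_fraction = 0.70,
                      eosin_quantile = 0.90, eosin_ref = 1.0,
                      eosin_mode = c("mean", "fraction"),
                      canny_variance_min = 7000,
                      canny_low = 100, canny_high = 200, canny_sigma = 1,
                      steps = c("rgb", "hsv", "hed", "canny"),
                      normalize = TRUE, hed_basis = ruifrok_basis()) {
  stopifnot(rgb_low >= 0, rgb_low < rgb_high, rgb_high <= 255,
            rgb_fraction > 0, rgb_fraction <= 1,
            hsv_fraction > 0, hsv_fraction <= 1,
            canny_variance_min >= 0)
  steps <- intersect(c("rgb", "hsv", "hed", "canny"), steps)
  structure(list(rgb_high = rgb_high, rgb_low = rgb_low,
                 rgb_fraction = rgb_fraction,
                 hsv_sat_low = hsv_sat_low, hsv_val_high = hsv_val_high,
                 hsv_fraction = hsv_fraction,
                 eosin_quantile = eosin_quantile, eosin_ref = eosin_ref,
                 eosin_mode = match.arg(eosin_mode),
                 canny_variance_min = canny_variance_min,
                 canny_low = canny_low, canny_high = canny_high,
                 canny_sigma = canny_sigma,
                 steps = steps, normalize = normalize,
                 hed_basis = hed_basis),
            class = "qc_config")
}

.check_rgb_patch <- function(patch) {
  if (length(dim(patch)) != 3L || dim(patch)[3] != 3L) {
    stop("patch must be a 3-channel RGB array")
  }
}

#' RGB background filter (QC step 1)
#'
#' A pixel is background when its mean channel intensity exceeds
#' `rgb_high` (white) or falls below `rgb_low` (black); the patch is
#' rejected when the background fraction exceeds `rgb_fraction`.
#'
#' @param patch RGB array 0..255.
#' @param cfg A [qc_config()].
#' @return List with `reject` (logical) and `stat` (background fraction).
#' @export
rgb_background_filter <- function(patch, cfg = qc_config()) {
  .check_rgb_patch(patch)
  pm <- (patch[, , 1] + patch[, , 2] + patch[, , 3]) / 3
  frac <- mean(pm > cfg$rgb_high | pm < cfg$rgb_low)
  list(reject = frac > cfg$rgb_fraction, stat = frac)
}

#' HSV glare filter (QC step 2)
#'
#' Flags glass reflections and similar scanning artifacts: a pixel is
#' glare-like when its saturation is low (`S < hsv_sat_low`) and its value
#' is high (`V > hsv_val_high`); the patch is rejected when the glare-like
#' fraction exceeds `hsv_fraction`.
#'
#' @inheritParams rgb_background_filter
#' @return List with `reject` and `stat` (glare-like fraction).
#' @export
hsv_artifact_filter <- function(patch, cfg = qc_config()) {
  .check_rgb_patch(patch)
  hsv <- grDevices::rgb2hsv(t(.pix_mat(patch)), maxColorValue = 255)
  glare <- hsv["s", ] < cfg$hsv_sat_low / 255 &
    hsv["v", ] > cfg$hsv_val_high / 255
  frac <- mean(glare)
  list(reject = frac > cfg$hsv_fraction, stat = frac)
}

#' HED pen-mark filter (QC step 3)
#'
#' Deconvolves the patch into stain concentrations and rejects patches
#' whose eosin channel is implausibly strong (ink rather than tissue): the
#' eosin plane is rescaled by the global reference ceiling `eosin_ref` and
#' the patch is rejected when the mean rescaled eosin exceeds
#' `eosin_quantile` (default 0.90).
#'
#' @inheritParams rgb_background_filter
#' @return List with `reject` and `stat` (the eosin statistic).
#' @export
hed_penmark_filter <- function(patch, cfg = qc_config()) {
  planes <- hed_deconvolve(patch, cfg$hed_basis)
  e <- planes$e / cfg$eosin_ref
  if (cfg$eosin_mode == "mean") {
    stat <- mean(e)
    list(reject = stat > cfg$eosin_quantile, stat = stat)
  } else {
    stat <- mean(e > cfg$eosin_quantile)
    list(reject = stat > 0.5, stat = stat)
  }
}

#' Canny edge-variance filter (QC step 4)
#'
#' Rejects texture-free patches (out-of-focus tissue, empty glass): the
#' patch is converted to grayscale, Canny edges are extracted, and the
#' patch is rejected when the population variance of the 0/255 edge map
#' falls below `canny_variance_min` (default 7000).
#'
#' @inheritParams rgb_background_filter
#' @return List with `reject` and `stat` (the edge-map variance).
#' @export
canny_variance_filter <- function(patch, cfg = qc_config()) {
  .check_rgb_patch(patch)
  gray <- (patch[, , 1] + patch[, , 2] + patch[, , 3]) / 3
  em <- canny_edges(gray, cfg$canny_low, cfg$canny_high, cfg$canny_sigma)
  v <- edge_map_variance(em)
  list(reject = v < cfg$canny_variance_min, stat = v)
}

# default stain-normalization reference: a packaged synthetic tissue patch
.subtyper_env <- new.env(parent = emptyenv())

#' Default stain-normalization reference
#'
#' A synthetic reference: basis fitted by [vahadane_fit()] to a generated
#' tissue patch, with its 99th-percentile concentration scale. Memoized.
#' Users normalizing real slides should supply their own reference patch.
#'
#' @return List with `basis` (3 x 2) and `scale` (length 2).
#' @export
default_stain_reference <- function() {
  if (is.null(.subtyper_env$stain_ref)) {
    ref <- make_tissue_patch("SCC", delta = 1, size = 256L, seed = 7L)
    basis <- vahadane_fit(ref, seed = 0L)
    .subtyper_env$stain_ref <- list(basis = basis,
                                    scale = stain_concentration_scale(ref, basis))
  }
  .subtyper_env$stain_ref
}

#' Run the five-step QC cascade over patches
#'
#' Applies the filters strictly in order (rgb, hsv, hed, canny); a patch
#' stops at its first rejecting step, and every executed step's statistic
#' is recorded. Survivors are stain-normalized when `cfg$normalize` is
#' TRUE: a source basis is fitted once (from `source_basis` or the first
#' surviving patch) and all survivors are re-rendered through the target
#' basis.
#'
#' @param patches List of RGB arrays 0..255.
#' @param cfg A [qc_config()].
#' @param source_basis Optional pre-fitted 3 x 2 source stain basis.
#' @param target Optional list with `basis` and `scale` (default
#'   [default_stain_reference()]).
#' @return List with `kept` (list of surviving, possibly normalized
#'   patches), `kept_idx` (their indices in `patches`), `verdicts`
#'   (data.frame: `patch`, `kept`, `rejected_at`, per-step stats), and
#'   `counts` (named rejection count per step plus `kept`).
#' @export
run_qc <- function(patches, cfg = qc_config(), source_basis = NULL,
                   target = NULL) {
  steps <- cfg$steps
  filters <- list(rgb = rgb_background_filter, hsv = hsv_artifact_filter,
                  hed = hed_penmark_filter, canny = canny_variance_filter)
  stat_names <- c(rgb = "rgb_fraction", hsv = "hsv_fraction",
                  hed = "eosin_stat", canny = "canny_variance")
  n <- length(patches)
  verdicts <- data.frame(patch = seq_len(n), kept = rep(TRUE, n),
                         rejected_at = rep("none", n),
                         rgb_fraction = rep(NA_real_, n),
                         hsv_fraction = rep(NA_real_, n),
                         eosin_stat = rep(NA_real_, n),
                         canny_variance = rep(NA_real_, n))
  for (i in seq_len(n)) {
    for (s in steps) {
      res <- filters[[s]](patches[[i]], cfg)
      verdicts[i, stat_names[[s]]] <- res$stat
      if (res$reject) {
        verdicts$kept[i] <- FALSE
        verdicts$rejected_at[i] <- s
        break
      }
    }
  }
  kept_idx <- which(verdicts$kept)
  kept <- patches[kept_idx]
  if (cfg$normalize && length(kept)) {
    if (is.null(target)) target <- default_stain_reference()
    if (is.null(source_basis)) source_basis <- vahadane_fit(kept[[1]])
    kept <- lapply(kept, vahadane_normalize, source_basis = source_basis,
                   target_basis = target$basis, target_scale = target$scale)
  }
  counts <- c(vapply(steps, function(s) sum(verdicts$rejected_at == s),
                     numeric(1)), kept = length(kept_idx))
  list(kept = kept, kept_idx = kept_idx, verdicts = verdicts,
       counts = counts)
}
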