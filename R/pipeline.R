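#' Classify one slide end to end
#'
#' Runs the inference pipeline on a single slide: tile the image into
#' non-overlapping patches at the target magnification, restrict the grid
#' to the annotated tumor regions, apply the QC cascade, predict each
#' surviving patch with the patch model, and aggregate to a slide call.
#'
#' @param image RGB array (0..255) of the slide plane.
#' @param record A [slide_record()] describing it.
#' @param regions A [region_set()] of tumor annotations; `NULL` uses the
#'   whole slide.
#' @param model A fitted [train_patch_model()] object.
#' @param qc A [qc_config()].
#' @param size_px Patch size in pixels (default 512).
#' @param target_magnification Tiling magnification (default 20).
#' @param min_overlap_fraction Region-restriction threshold (default 0.5).
#' @param aggregator Either `"majority"` or a list with a fitted
#'   [fit_slide_classifier()] `slide_model` plus, for the TF-IDF scheme,
#'   the fitted `tfidf_model` (names `model`, `tfidf`), or for histograms
#'   `n_bins`.
#' @return List with `bag` (the slide's [prediction_bag()]), `label`, and
#'   `p_ac` (`NA` for the majority-vote path, which ignores classifier
#'   probabilities), and the QC `counts`.
#' @export
classify_slide <- function(image, record, regions, model,
                           qc = qc_config(), size_px = 512L,
                           target_magnification = 20,
                           min_overlap_fraction = 0.5,
                           aggregator = "majority") {
  grid <- tile_slide(record, size_px, target_magnification)
  if (!is.null(regions)) {
    grid <- patches_in_regions(grid, regions, min_overlap_fraction)
  }
  if (!nrow(grid)) stop("slide '", record$slide_id,
                        "' has no patches inside its annotated regions")
  patches <- extract_patches(image, grid)
  res <- run_qc(patches, qc)
  if (!length(res$kept)) stop("slide '", record$slide_id,
                              "': no patch survived QC")
  pr <- predict_patches(model, res$kept)
  bag <- prediction_bag(record$slide_id, pr$label, pr$p_ac)
  if (identical(aggregator, "majority")) {
    return(list(bag = bag, label = majority_vote(bag), p_ac = NA_real_,
                counts = res$counts))
  }
  feats <- if (!is.null(aggregator$tfidf)) {
    tfidf_transform(aggregator$tfidf, list(bag))
  } else {
    structure(matrix(histogram_features(bag, aggregator$n_bins %||% 10L),
                     nrow = 1), scheme = "histogram")
  }
  call <- predict_slide(aggregator$model, feats)
  list(bag = bag, label = call$label, p_ac = call$p_ac, counts = res$counts)
}

#' Write / read prediction bags as CSV
#'
#' Long format: one row per patch, columns `slide_id`, `idx`, `p_ac`,
#' `token`.
#'
#' @param bags List of [prediction_bag()].
#' @param path CSV path.
#' @return `read_bags` returns the list of bags.
#' @export
write_bags <- function(bags, path) {
  df <- do.call(rbind, lapply(bags, function(b) {
    data.frame(slide_id = b$slide_id, idx = seq_along(b$tokens),
               p_ac = b$probs, token = b$tokens)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bags
#' @export
read_bags <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, factor(df$slide_id, levels = unique(df$slide_id))),
         function(d) {
           d <- d[order(d$idx), ]
           prediction_bag(d$slide_id[1], d$token, d$p_ac)
         })
}
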