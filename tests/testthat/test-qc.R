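cfg <- qc_config(normalize = FALSE)

test_that("RGB background filter applies the 220/40 thresholds and 80% rule", {
  expect_true(rgb_background_filter(flat_patch(255, 255, 255), cfg)$reject)
  expect_equal(rgb_background_filter(flat_patch(255, 255, 255), cfg)$stat, 1)
  expect_false(rgb_background_filter(flat_patch(128, 128, 128), cfg)$reject)
  expect_true(rgb_background_filter(flat_patch(10, 10, 10), cfg)$reject)

  # exactly 81% white pixels -> rejected; exactly 80% -> kept (strict >)
  p80 <- flat_patch(128, 128, 128, size = 10)
  for (ch in 1:3) p80[, , ch][1:80] <- 255
  expect_equal(rgb_background_filter(p80, cfg)$stat, 0.80)
  expect_false(rgb_background_filter(p80, cfg)$reject)
  p81 <- flat_patch(128, 128, 128, size = 10)
  for (ch in 1:3) p81[, , ch][1:81] <- 255
  expect_equal(rgb_background_filter(p81, cfg)$stat, 0.81)
  expect_true(rgb_background_filter(p81, cfg)$reject)

  expect_error(rgb_background_filter(matrix(0, 4, 4), cfg), "3-channel")
})

test_that("HSV glare filter flags low-saturation high-value pixels", {
  # near-white: S ~ 0, V = 255
  expect_true(hsv_artifact_filter(flat_patch(255, 254, 254), cfg)$reject)
  # saturated magenta: S = 255
  expect_false(hsv_artifact_filter(flat_patch(255, 0, 255), cfg)$reject)
  # 71% glare-like pixels under defaults -> rejected; verified against an
  # independent RGB->HSV conversion of the two pixel colors used
  glare_px <- c(231, 210, 209)   # S ~ 24.3 < 25, V = 231 > 230
  tissue_px <- c(220, 160, 190)  # S ~ 69
  hsv_g <- grDevices::rgb2hsv(glare_px[1], glare_px[2], glare_px[3],
                              maxColorValue = 255)
  expect_lt(hsv_g["s", 1] * 255, 25)
  expect_gt(hsv_g["v", 1] * 255, 230)
  p <- flat_patch(tissue_px[1], tissue_px[2], tissue_px[3], size = 10)
  sel <- 1:71
  for (ch in 1:3) p[, , ch][sel] <- glare_px[ch]
  res <- hsv_artifact_filter(p, cfg)
  expect_equal(res$stat, 0.71)
  expect_true(res$reject)
  p2 <- flat_patch(tissue_px[1], tissue_px[2], tissue_px[3], size = 10)
  for (ch in 1:3) p2[, , ch][1:70] <- glare_px[ch]
  expect_false(hsv_artifact_filter(p2, cfg)$reject)
})

test_that("pen-mark filter rejects eosin-saturated ink and passes hematoxylin", {
  # eosin concentration at the top of the reference range everywhere
  s <- 16
  pen <- hed_reconstruct(cbind(rep(0.02, s * s), rep(1.2, s * s)),
                         ruifrok_basis()[, 1:2], dim_hw = c(s, s))
  expect_true(hed_penmark_filter(pen, cfg)$reject)

  # pure-hematoxylin synthetic patch: eosin ~ 0 -> kept
  hem <- hed_reconstruct(cbind(rep(0.8, s * s), rep(0, s * s)),
                         ruifrok_basis()[, 1:2], dim_hw = c(s, s))
  res <- hed_penmark_filter(hem, cfg)
  expect_false(res$reject)
  expect_lt(res$stat, 0.05)

  # blank white patch is kept by THIS step (rgb catches it earlier)
  expect_false(hed_penmark_filter(flat_patch(255, 255, 255), cfg)$reject)
})

test_that("edge-map variance matches the closed form 255^2 p (1-p)", {
  n <- 100 * 100
  mk <- function(p) matrix(c(rep(255, round(p * n)),
                             rep(0, n - round(p * n))), 100, 100)
  expect_equal(edge_map_variance(mk(0.2)), 255^2 * 0.2 * 0.8)
  expect_gte(edge_map_variance(mk(0.2)), 7000)
  expect_equal(edge_map_variance(mk(0.012)), 255^2 * 0.012 * 0.988)
  expect_lt(edge_map_variance(mk(0.012)), 7000)
  expect_equal(edge_map_variance(mk(0)), 0)
})

test_that("Canny filter rejects uniform patches and keeps textured tissue", {
  res <- canny_variance_filter(flat_patch(128, 128, 128, 64), cfg)
  expect_true(res$reject)
  expect_equal(res$stat, 0)
  tissue <- make_tissue_patch("SCC", 1, 512, 3)
  expect_false(canny_variance_filter(tissue, cfg)$reject)
})

test_that("Canny edges localize a step boundary", {
  g <- matrix(0, 64, 64); g[, 33:64] <- 255
  em <- canny_edges(g)
  hit_cols <- which(colSums(em) > 0)
  expect_true(length(hit_cols) > 0)
  expect_true(all(hit_cols >= 30 & hit_cols <= 36))
})

test_that("the cascade stops at the first failing step, in fixed order", {
  patches <- list(make_artifact_patch("white", 64, 1),
                  make_artifact_patch("glare", 64, 2),
                  make_artifact_patch("pen", 64, 3),
                  make_artifact_patch("blank", 64, 4),
                  make_tissue_patch("AC", 1, 64, 5))
  res <- run_qc(patches, cfg)
  expect_equal(res$verdicts$rejected_at,
               c("rgb", "hsv", "hed", "canny", "none"))
  expect_equal(res$verdicts$kept, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # stats recorded for every executed step, none after the rejecting one
  expect_false(is.na(res$verdicts$rgb_fraction[1]))
  expect_true(is.na(res$verdicts$hsv_fraction[1]))
  expect_false(is.na(res$verdicts$hsv_fraction[2]))
  expect_true(is.na(res$verdicts$eosin_stat[2]))
  # total rejected equals the sum of per-step counts
  expect_equal(sum(res$counts[c("rgb", "hsv", "hed", "canny")]), 4)
  expect_equal(unname(res$counts["kept"]), 1)
})

test_that("disabling all filters keeps every patch; empty input is empty", {
  off <- qc_config(steps = character(0), normalize = FALSE)
  patches <- list(make_artifact_patch("white", 32, 1),
                  make_artifact_patch("blank", 32, 2))
  res <- run_qc(patches, off)
  expect_equal(res$kept_idx, 1:2)
  res0 <- run_qc(list(), cfg)
  expect_length(res0$kept, 0)
  expect_equal(nrow(res0$verdicts), 0)
})

test_that("hue rotation does not change the RGB verdict on achromatic pixels", {
  # background rule depends only on the channel mean: permuting channels
  # (a 120-degree hue rotation) leaves the verdict unchanged
  p <- flat_patch(240, 230, 225, 16)
  rot <- p[, , c(2, 3, 1)]
  expect_equal(rgb_background_filter(p, cfg)$stat,
               rgb_background_filter(rot, cfg)$stat)
})

test_that("normalization runs after filtering and preserves the verdict set", {
  patches <- list(make_tissue_patch("SCC", 1, 64, 7),
                  make_artifact_patch("white", 64, 8))
  cfg_n <- qc_config(normalize = TRUE)
  res <- run_qc(patches, cfg_n)
  expect_equal(res$kept_idx, 1L)
  # same verdicts as without normalization
  res0 <- run_qc(patches, cfg)
  expect_equal(res$verdicts$rejected_at, res0$verdicts$rejected_at)
  # output is still a valid 8-bit patch
  expect_true(all(res$kept[[1]] >= 0 & res$kept[[1]] <= 255))
})
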