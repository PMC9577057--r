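test_that("TSR formula and its degenerate cases", {
  expect_equal(tsr_from_counts(50, 50), 0.5)
  expect_equal(tsr_from_counts(0, 10), 0)
  expect_equal(tsr_from_counts(10, 0), 1)
  expect_error(tsr_from_counts(0, 0), class = "wsis_undefined_metric_error")
  expect_error(tsr_from_counts(-1, 5), class = "wsis_parameter_error")
})

test_that("RandomSpot layout is a randomized triangular lattice", {
  set.seed(1)
  pts <- randomspot_layout(c(10000, 10000), 6122, 120)
  expect_equal(nrow(pts), 120L)
  half <- 6122 / 2
  expect_true(all(abs(pts[, 1] - 10000) <= half &
                    abs(pts[, 2] - 10000) <= half))
  pitch <- attr(pts, "pitch_px")
  expect_gte(pitch, 224)
  # nearest-neighbour distance equals the pitch for interior points
  d <- as.matrix(dist(pts)); diag(d) <- Inf
  nn <- apply(d, 1, min)
  interior <- abs(pts[, 1] - 10000) < half - pitch &
    abs(pts[, 2] - 10000) < half - pitch
  expect_true(all(abs(nn[interior] - pitch) < 1))

  set.seed(2)
  pts2 <- randomspot_layout(c(10000, 10000), 6122, 120)
  expect_equal(attr(pts2, "pitch_px"), pitch)    # same pitch
  expect_false(isTRUE(all.equal(pts[1, ], pts2[1, ])))  # different offset

  expect_error(randomspot_layout(c(500, 500), 600, 120),
               class = "wsis_parameter_error")
})

test_that("max-density centre equals exhaustive candidate search", {
  dims <- c(20000, 20000)
  blob1 <- cbind(runif(10, 2000, 3000), runif(10, 2000, 3000))
  blob2 <- cbind(runif(30, 15000, 16000), runif(30, 15000, 16000))
  set.seed(8)
  ctr <- max_density_centre(rbind(blob1, blob2), 6122, dims)
  expect_true(abs(ctr[1] - 15500) < 6122 / 2 + 1531)
  expect_equal(attr(ctr, "count"), 30L)

  # oracle: evaluate every candidate centre directly
  set.seed(10)
  for (rep in 1:10) {
    pts <- cbind(runif(40, 0, 20000), runif(40, 0, 20000))
    got <- max_density_centre(pts, 6122, dims)
    half <- 3061; stride <- 6122 / 4
    cand <- unique(c(seq(half, 20000 - half, by = stride), 20000 - half))
    best <- -1; best_ctr <- NULL
    for (cy in cand) for (cx in cand) {
      n <- sum(abs(pts[, 1] - cx) <= half & abs(pts[, 2] - cy) <= half)
      if (n > best) { best <- n; best_ctr <- c(cx, cy) }
    }
    expect_equal(attr(got, "count"), best)
  }

  one <- max_density_centre(cbind(500, 700), 6122, dims)
  expect_equal(attr(one, "count"), 1L)
  expect_error(max_density_centre(matrix(numeric(0), ncol = 2), 6122, dims),
               class = "wsis_undefined_metric_error")
})

test_that("uniform-ROI TSR recovers the area ground truth with a perfect classifier", {
  s <- generate_slide(12000, 12000, 0.2,
                      composition = c(tumour = 0.5, stroma_fibrosis = 0.5),
                      seed = 4)
  set.seed(5)
  r <- tsr_uniform_roi(s, s$gt_roi, perfect_classifier(), n = 100)
  expect_equal(nrow(r$locations), 100L)
  gt <- gt_area_tsr(s)
  sigma <- sqrt(gt * (1 - gt) / (r$T + r$S))
  expect_lt(abs(r$value - gt), 3 * sigma + 0.03)
  expect_error(tsr_uniform_roi(s, list(), perfect_classifier()),
               class = "wsis_undefined_metric_error")
})

test_that("max-density-box TSR matches the window-local cell fraction", {
  s <- generate_slide(12000, 12000, 0.2,
                      composition = c(tumour = 0.5, stroma_fibrosis = 0.5),
                      seed = 4)
  tum_cells <- which(s$label_raster == tissue_class_codes()[["tumour"]])
  nr <- nrow(s$label_raster); D <- s$raster_step
  pts <- cbind(((tum_cells - 1) %/% nr + 0.5) * D,
               ((tum_cells - 1) %% nr + 0.5) * D)
  set.seed(6)
  r <- tsr_box_max_density(s, pts, perfect_classifier())
  expect_equal(nrow(r$locations), 120L)
  ctr <- max_density_centre(pts, 6122, s)
  inw <- abs(pts[, 1] - ctr[1]) <= 3061 & abs(pts[, 2] - ctr[2]) <= 3061
  # window-local tumour/(tumour+stroma) fraction from the raster
  cc <- wsisampler:::cell_centres(s)
  in_box <- abs(cc$x - ctr[1]) <= 3061 & abs(cc$y - ctr[2]) <= 3061
  lab <- as.vector(s$label_raster)
  t_n <- sum(in_box & lab == tissue_class_codes()[["tumour"]])
  s_n <- sum(in_box & lab == tissue_class_codes()[["stroma_fibrosis"]])
  local <- t_n / (t_n + s_n)
  sigma <- sqrt(local * (1 - local) / (r$T + r$S))
  expect_lt(abs(r$value - local), 3 * sigma + 0.03)
  expect_error(tsr_box_max_density(s, matrix(numeric(0), ncol = 2),
                                   perfect_classifier()),
               class = "wsis_undefined_metric_error")
})

test_that("sliding-mean TSR reduces to the single window's value", {
  s <- uniform_slide("tumour", n_cells = 150L)   # 4800 px < one window
  p <- wsisampler:::patch_table(20L)
  p$x <- as.integer(seq(100, 4000, length.out = 20)); p$y <- 2000L
  p$pred_class <- rep(c("tumour", "stroma_fibrosis"), 10)
  hull <- cbind(c(0, 4800, 4800, 0), c(0, 0, 4800, 4800))
  r <- tsr_sliding_mean(p, hull, c(4800, 4800))
  expect_equal(nrow(r$locations), 1L)
  expect_equal(r$value, 0.5)
  expect_equal(c(r$T, r$S), c(10L, 10L))
  expect_error(tsr_sliding_mean(p, hull, c(4800, 4800), min_counts = 50),
               class = "wsis_undefined_metric_error")
})

test_that("ground-truth-location TSR is exact under a perfect classifier", {
  s <- generate_slide(12000, 12000, 0.2,
                      composition = c(tumour = 0.6, stroma_fibrosis = 0.4),
                      seed = 9)
  gtp <- gt_sample_points(s)
  r <- tsr_gt_locations(s, gtp, perfect_classifier())
  t_n <- sum(gtp$tissue_class == "tumour")
  s_n <- sum(gtp$tissue_class == "stroma_fibrosis")
  expect_equal(r$value, t_n / (t_n + s_n))
  expect_gte(r$value, 0); expect_lte(r$value, 1)
  expect_error(tsr_gt_locations(s, NULL, perfect_classifier()),
               class = "wsis_parameter_error")
})

test_that("error report computes RMSE and signed mean error", {
  r <- error_report(data.frame(gt = 0.5, est = 0.6))
  expect_equal(r$rmse, 0.1)
  expect_equal(r$me, -0.1)
  r2 <- error_report(data.frame(gt = c(0.3, 0.7), est = c(0.3, 0.7)))
  expect_equal(c(r2$rmse, r2$me), c(0, 0))
  r3 <- error_report(data.frame(gt = c(0, 1), est = c(1, 0)))
  expect_equal(r3$rmse, 1)
  expect_equal(r3$me, 0)
  expect_error(error_report(data.frame()),
               class = "wsis_undefined_metric_error")
  expect_error(error_report(data.frame(gt = 1.5, est = 0)),
               class = "wsis_parameter_error")
})
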