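test_that("generated slides recover the requested composition inside the ROI", {
  s <- generate_slide(20000, 20000, 0.15,
                      composition = c(tumour = 0.5, stroma_fibrosis = 0.4,
                                      lumen = 0.1),
                      seed = 7)
  inside <- s$label_raster[s$roi_mask]
  classes <- tissue_classes()[inside + 1L]
  frac <- table(classes) / length(classes)
  expect_true(frac[["tumour"]] >= 0.47 && frac[["tumour"]] <= 0.53)
  expect_lt(abs(frac[["stroma_fibrosis"]] - 0.4), 0.03)
  expect_lt(abs(frac[["lumen"]] - 0.1), 0.03)
  # only composition classes appear inside the ROI
  expect_setequal(unique(classes), c("tumour", "stroma_fibrosis", "lumen"))
  # realized ROI area within 10% relative of the request
  tissue_cells <- sum(s$label_raster != tissue_class_codes()[["background"]])
  expect_lt(abs(sum(s$roi_mask) / tissue_cells - 0.15) / 0.15, 0.10)
})

test_that("slide generation is deterministic in (parameters, seed)", {
  a <- small_slide(seed = 7)
  b <- small_slide(seed = 7)
  expect_identical(a$label_raster, b$label_raster)
  expect_identical(a$gt_roi, b$gt_roi)
  expect_false(identical(small_slide(seed = 8)$label_raster,
                         a$label_raster))
})

test_that("normal epithelium lies strictly outside the ROI; ROI containment matches an independent oracle", {
  s <- small_slide(seed = 3)
  cc <- wsisampler:::cell_centres(s)
  oracle_mask <- matrix(ray_cast_inside(cbind(cc$x, cc$y), s$gt_roi),
                        nrow = nrow(s$label_raster))
  # the two containment implementations may only disagree on centres
  # grazing the polygon boundary
  expect_lt(sum(oracle_mask != s$roi_mask), 0.001 * sum(oracle_mask))
  ne <- s$label_raster == tissue_class_codes()[["normal_epithelium"]]
  expect_false(any(ne & oracle_mask))
  expect_false(any(ne & s$roi_mask))
})

test_that("gt_area_tsr equals brute-force per-cell counting", {
  s <- generate_slide(20000, 20000, 0.15,
                      composition = c(tumour = 0.5, stroma_fibrosis = 0.4,
                                      lumen = 0.1),
                      seed = 7)
  expect_lt(abs(gt_area_tsr(s) - 0.5 / 0.9), 0.05)
  cc <- wsisampler:::cell_centres(s)
  inside <- ray_cast_inside(cbind(cc$x, cc$y), s$gt_roi)
  lab <- as.vector(s$label_raster)
  t_n <- sum(inside & lab == tissue_class_codes()[["tumour"]])
  s_n <- sum(inside & lab == tissue_class_codes()[["stroma_fibrosis"]])
  expect_lt(abs(gt_area_tsr(s) - t_n / (t_n + s_n)), 0.005)

  half <- generate_slide(6400, 6400, 0.15,
                         composition = c(tumour = 0.5,
                                         stroma_fibrosis = 0.5),
                         seed = 1)
  expect_lt(abs(gt_area_tsr(half) - 0.5), 0.05)
  no_ts <- uniform_slide("lumen", gt_roi = cbind(c(100, 600, 600, 100),
                                                 c(100, 100, 600, 600)))
  expect_error(gt_area_tsr(no_ts), class = "wsis_degenerate_error")
})

test_that("label_at is a pure half-open raster lookup", {
  s <- small_slide(seed = 2)
  expect_identical(label_at(s, 0, 0), "background")
  # centre of a known cell reproduces the raster entry
  code <- s$label_raster[10, 20]
  D <- s$raster_step
  expect_identical(label_at(s, (20 - 0.5) * D, (10 - 0.5) * D),
                   tissue_classes()[code + 1L])
  expect_error(label_at(s, s$width_px, 0), class = "wsis_bounds_error")
  expect_error(label_at(s, -1, 0), class = "wsis_bounds_error")
})

test_that("generator rejects invalid parameters", {
  expect_error(generate_slide(6400, 6400, 0.9, seed = 1),
               class = "wsis_parameter_error")
  expect_error(generate_slide(6400, 6400, 0.15,
                              composition = c(tumour = 0.7,
                                              stroma_fibrosis = 0.7),
                              seed = 1),
               class = "wsis_parameter_error")
  expect_error(generate_slide(6400, 6400, 0.15,
                              composition = c(weird = 1), seed = 1),
               class = "wsis_parameter_error")
  expect_error(generate_slide(800, 800, 0.15, seed = 1),
               class = "wsis_dimension_error")
})

test_that("slide container round-trips exactly and rejects malformed files", {
  s <- small_slide(seed = 5)
  base <- file.path(withr::local_tempdir(), "slide")
  write_slide(s, base)
  r <- read_slide(base)
  expect_equal(r, s)

  # missing sidecar
  file.remove(paste0(base, ".json"))
  expect_error(read_slide(base), class = "wsis_format_error")

  # unknown class code in the raster
  base2 <- file.path(withr::local_tempdir(), "bad")
  write_slide(s, base2)
  png::writePNG(matrix(250 / 255, 10, 10), paste0(base2, ".png"))
  expect_error(read_slide(base2), class = "wsis_format_error")
})
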