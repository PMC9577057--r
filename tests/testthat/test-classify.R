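test_that("confusion rows are probability distributions with the requested diagonal", {
  cs <- make_confusion(0.79, 0.3)
  expect_equal(unname(rowSums(cs$matrix)), rep(1, 11), tolerance = 1e-12)
  expect_true(all(cs$matrix >= 0))
  for (cls in classifier_classes())
    expect_equal(unname(cs$matrix[cls, cls]), 0.79)
  # extra mass on the tumour/stroma confusion pair
  expect_gt(cs$matrix["tumour", "stroma_fibrosis"],
            cs$matrix["tumour", "lumen"])
  expect_equal(unname(cs$matrix["background", "non_informative"]), 1)
  expect_equal(unname(cs$matrix["normal_epithelium", "tumour"]), 0.3)

  id <- make_confusion(1, 0)
  expect_equal(unname(diag(id$matrix[classifier_classes(),
                                     classifier_classes()])), rep(1, 9))
  expect_equal(unname(id$matrix["normal_epithelium", "tumour"]), 0)
  expect_error(make_confusion(0.79, 1.2), class = "wsis_parameter_error")
  expect_error(make_confusion(-0.1, 0), class = "wsis_parameter_error")
})

test_that("simulated classification follows the confusion rows", {
  tum <- uniform_slide("tumour", n_cells = 200L)
  g <- build_grid(tum, 640)
  # 10,000 tumour-centred patches: binomial check on the diagonal
  p <- wsisampler:::patch_table(10000L)
  p$x <- 100L; p$y <- 100L; p$box_col <- 0L; p$box_row <- 0L
  set.seed(11)
  p <- simulate_classify(p, tum, make_confusion(0.79, 0.3))
  expect_true(all(p$gt_class == "tumour"))
  expect_true(all(p$pred_class %in% classifier_classes()))
  frac <- mean(p$pred_class == "tumour")
  expect_lt(abs(frac - 0.79), 3 * sqrt(0.79 * 0.21 / 10000))

  # identity confusion is deterministic
  p2 <- simulate_classify(wsisampler:::patch_table(5L) |>
                            transform(x = 100L, y = 100L),
                          tum, make_confusion(1, 0))
  expect_true(all(p2$pred_class == "tumour"))

  # background row always maps to non_informative
  bg <- uniform_slide("background", n_cells = 200L)
  p3 <- wsisampler:::patch_table(50L)
  p3$x <- 100L; p3$y <- 100L
  p3 <- simulate_classify(p3, bg, make_confusion(0.5, 0.3))
  expect_true(all(p3$pred_class == "non_informative"))
})

test_that("FP correction removes normal-epithelium false positives", {
  ne <- uniform_slide("normal_epithelium", n_cells = 200L)
  p <- wsisampler:::patch_table(1000L)
  p$x <- 100L; p$y <- 100L
  p$gt_class <- "normal_epithelium"; p$pred_class <- "tumour"
  p$pred_raw <- "tumour"

  perfect <- fp_correct(p, fp_stage(1, 1))
  expect_true(all(perfect$pred_class == "normal_epithelium"))
  expect_true(all(perfect$fp_corrected))

  off <- fp_correct(p, fp_stage(1, 0))
  expect_identical(off$pred_class, p$pred_class)

  set.seed(5)
  real <- fp_correct(p, fp_stage(specificity = 0.927))
  kept <- sum(real$pred_class == "tumour")
  expect_lt(abs(kept - 1000 * 0.073), 3 * sqrt(1000 * 0.073 * 0.927))

  # true tumour is kept by a perfect stage
  pt <- p; pt$gt_class <- "tumour"
  expect_true(all(fp_correct(pt, fp_stage(1, 1))$pred_class == "tumour"))
})

test_that("FP correction never touches non-tumour predictions and never adds tumour", {
  set.seed(21)
  for (rep in 1:20) {
    n <- 200L
    p <- wsisampler:::patch_table(n)
    p$x <- 100L; p$y <- 100L
    p$gt_class <- sample(tissue_classes(), n, replace = TRUE)
    p$pred_class <- sample(classifier_classes(), n, replace = TRUE)
    p$pred_raw <- p$pred_class
    out <- fp_correct(p, fp_stage(0.8, 0.8))
    non_tum <- p$pred_class != "tumour"
    expect_identical(out$pred_class[non_tum], p$pred_class[non_tum])
    expect_lte(sum(out$pred_class == "tumour"),
               sum(p$pred_class == "tumour"))
    changed <- out$pred_class != p$pred_class
    expect_true(all(out$fp_corrected[changed]))
    expect_true(all(out$pred_class[changed] == "normal_epithelium"))
  }
})

test_that("tumour-inside-ROI fraction counts tumour-predicted centres", {
  roi <- cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000))
  p <- wsisampler:::patch_table(5L)
  p$x <- as.integer(c(100, 200, 300, 2000, 100))
  p$y <- as.integer(c(100, 200, 300, 2000, 100))
  p$pred_class <- c("tumour", "tumour", "tumour", "tumour",
                    "stroma_fibrosis")
  expect_equal(tumour_inside_fraction(p, roi), 75)
  p$pred_class[4] <- "lumen"
  expect_equal(tumour_inside_fraction(p, roi), 100)
  p$pred_class <- "lumen"
  expect_error(tumour_inside_fraction(p, roi),
               class = "wsis_undefined_metric_error")
})
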