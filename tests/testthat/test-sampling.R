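test_that("grid covers the slide with ceiling arithmetic", {
  g <- build_grid(c(6400, 3200), 640)
  expect_equal(c(g$n_cols, g$n_rows), c(10L, 5L))
  g2 <- build_grid(c(6401, 3200), 640)
  expect_equal(c(g2$n_cols, g2$n_rows), c(11L, 5L))
  expect_error(build_grid(c(6400, 3200), 100),
               class = "wsis_parameter_error")
})

test_that("overlap uses half-open 224 px squares", {
  expect_false(overlaps(0, 0, 224, 0))   # edge-touching
  expect_true(overlaps(0, 0, 223, 0))
  expect_true(overlaps(0, 0, 0, 0))      # identity
  expect_false(overlaps(0, 0, 0, 224))
})

test_that("initial allocation places at most one tissue patch per box", {
  tissue <- uniform_slide("tumour", n_cells = 200L)   # 6400 px square
  g <- build_grid(tissue, 640)
  set.seed(42)
  p <- allocate_initial(g, tissue)
  expect_equal(nrow(p), 100L)                         # one per box
  expect_equal(anyDuplicated(p[c("box_col", "box_row")]), 0L)
  expect_true(all(p$iteration == 0L))
  # patches fully inside the slide; top-left inside the parent box
  expect_true(all(p$x >= p$box_col * 640 & p$x < (p$box_col + 1) * 640))
  expect_true(all(p$x + 224 <= 6400 & p$y + 224 <= 6400))

  bg <- uniform_slide("background", n_cells = 200L)
  expect_equal(nrow(allocate_initial(g, bg)), 0L)

  set.seed(7); a <- allocate_initial(g, tissue)
  set.seed(7); b <- allocate_initial(g, tissue)
  expect_identical(a, b)
})

test_that("densification honours the per-box cap and non-overlap", {
  tissue <- uniform_slide("tumour", n_cells = 200L)
  g <- build_grid(tissue, 640)

  one <- wsisampler:::patch_table(1L)
  one$x <- 100L; one$y <- 100L; one$box_col <- 0L; one$box_row <- 0L
  one$pred_class <- "tumour"
  set.seed(1)
  new <- allocate_resample(one, g, tissue)
  expect_equal(nrow(new), 4L)                         # 4 per tumour patch
  allp <- rbind(one, new)
  for (i in 1:4) for (j in (i + 1):5) if (j <= 5)
    expect_false(overlaps(allp$x[i], allp$y[i], allp$x[j], allp$y[j]))
  expect_true(all(new$iteration == 1L))

  # box already at the cap gains nothing
  five <- wsisampler:::patch_table(5L)
  five$x <- as.integer(c(0, 230, 460, 0, 230)); five$y <- as.integer(c(0, 0, 0, 230, 230))
  five$box_col <- 0L; five$box_row <- 0L
  five$pred_class <- c("tumour", rep("stroma_fibrosis", 4))
  expect_equal(nrow(allocate_resample(five, g, tissue)), 0L)

  # cap binds before per-tumour multiplicity: 2 tumour + 1 other -> 2 new
  three <- wsisampler:::patch_table(3L)
  three$x <- as.integer(c(0, 300, 0)); three$y <- as.integer(c(0, 0, 300))
  three$box_col <- 0L; three$box_row <- 0L
  three$pred_class <- c("tumour", "tumour", "lumen")
  set.seed(2)
  expect_equal(nrow(allocate_resample(three, g, tissue)), 2L)
})

test_that("ROI fill tops up only boxes whose centre is inside a hull", {
  tissue <- uniform_slide("tumour", n_cells = 200L)
  g <- build_grid(tissue, 640)
  hull <- cbind(c(0, 1280, 1280, 0), c(0, 0, 1280, 1280))  # boxes (0:1, 0:1)
  one <- wsisampler:::patch_table(1L)
  one$x <- 100L; one$y <- 100L; one$box_col <- 0L; one$box_row <- 0L
  set.seed(3)
  fill <- suppressWarnings(allocate_roi_fill(one, g, tissue, list(hull)))
  counts <- table(paste(fill$box_col, fill$box_row))
  expect_equal(sort(names(counts)), sort(c("0 0", "1 0", "0 1", "1 1")))
  expect_equal(unname(counts[["0 0"]]), 4L)           # 5 - 1 existing
  # every inside-hull box is topped to the cap except slots skipped as
  # geometrically blocked (counted in the retry_exhausted attribute)
  expect_equal(sum(counts), 4L * 5L - 1L - attr(fill, "retry_exhausted"))
  expect_true(all(counts <= 5L))
  expect_true(all(!c("2 2", "3 0") %in% names(counts)))  # outside unchanged

  # box already at the cap is unchanged
  five <- wsisampler:::patch_table(5L)
  five$x <- as.integer(c(0, 230, 460, 0, 230)); five$y <- as.integer(c(0, 0, 0, 230, 230))
  five$box_col <- 0L; five$box_row <- 0L
  small_hull <- cbind(c(0, 640, 640, 0), c(0, 0, 640, 640))
  expect_equal(nrow(allocate_roi_fill(five, g, tissue, list(small_hull))), 0L)
})

test_that("five non-overlapping patches fit a 640 px box", {
  # existence: a 3 x 2 lattice packing of 224 px patches with top-left
  # inside the box never overlaps
  lat <- expand.grid(x = c(0, 224, 448), y = c(0, 224))
  cc <- utils::combn(6L, 2L)
  expect_false(any(overlaps(lat$x[cc[1, ]], lat$y[cc[1, ]],
                            lat$x[cc[2, ]], lat$y[cc[2, ]])))

  # sequential random placement reaches the cap except for rare
  # geometric deadlocks (four patches can block every position for a
  # fifth); placed patches are always pairwise non-overlapping
  tissue <- uniform_slide("tumour", n_cells = 200L)
  g <- build_grid(tissue, 640)
  one <- wsisampler:::patch_table(1L)
  one$box_col <- 1L; one$box_row <- 1L
  short <- 0L
  for (seed in 1:100) {
    set.seed(seed)
    tl <- wsisampler:::draw_topleft(1L, 1L, g)
    one$x <- as.integer(tl[1]); one$y <- as.integer(tl[2])
    one$pred_class <- "tumour"
    new <- suppressWarnings(allocate_resample(one, g, tissue))
    expect_lte(nrow(new), 4L)
    if (nrow(new) < 4L) short <- short + 1L
    allp <- rbind(one, new)
    pr <- utils::combn(nrow(allp), 2L)
    expect_false(any(overlaps(allp$x[pr[1, ]], allp$y[pr[1, ]],
                              allp$x[pr[2, ]], allp$y[pr[2, ]])))
  }
  expect_lte(short, 5L)
})

test_that("patch tables round-trip through CSV", {
  tissue <- uniform_slide("tumour", n_cells = 200L)
  g <- build_grid(tissue, 640)
  set.seed(9)
  p <- allocate_initial(g, tissue)
  p <- fp_correct(simulate_classify(p, tissue, make_confusion(0.9, 0.3)),
                  fp_stage())
  path <- withr::local_tempfile(fileext = ".csv")
  write_patches(p, path)
  back <- read_patches(path)
  rownames(p) <- NULL
  expect_identical(back, p)
})
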