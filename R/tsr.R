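# Tumour-stroma ratio estimation.
#
# TSR_est = T / (T + S), where T and S are the counts of sampled
# patches classified tumour and stroma_fibrosis. Four sampling
# strategies are implemented:
#   uniform_roi     - 100 fresh patches uniform over the predicted ROI;
#   box_max_density - 120 patches on a RandomSpot-style triangular
#                     lattice inside the 3 mm (6122 px) window of
#                     maximum tumour-point density, emulating the
#                     pathologist protocol;
#   sliding_mean    - unweighted mean of per-window TSRs of the already
#                     sampled patches, over 3 mm windows sliding across
#                     the predicted ROI;
#   gt_locations    - classification at the ground-truth annotation
#                     points (the theoretical accuracy ceiling).
# Estimates across a slide set are summarised by RMSE and signed mean
# error (ground truth minus estimate).

#' TSR from tumour and stroma counts
#'
#' @param T tumour patch count.
#' @param S stroma_fibrosis patch count.
#' @return T / (T + S).
#' @export
tsr_from_counts <- function(T, S) {
  if (T < 0 || S < 0) stop_parameter("counts must be non-negative")
  if (T + S == 0) stop_undefined("TSR undefined: T + S = 0")
  T / (T + S)
}

new_tsr_result <- function(method_id, locations, value = NULL) {
  T <- sum(locations$pred_class == "tumour", na.rm = TRUE)
  S <- sum(locations$pred_class == "stroma_fibrosis", na.rm = TRUE)
  structure(list(method_id = method_id, T = T, S = S,
                 value = value %||% tsr_from_counts(T, S),
                 locations = locations),
            class = "tsr_result")
}

#' @export
print.tsr_result <- function(x, ...) {
  cat(sprintf("<tsr_result> %s: TSR = %.3f (T = %d, S = %d, %d locations)\n",
              x$method_id, x$value, x$T, x$S, nrow(x$locations)))
  invisible(x)
}

#' RandomSpot-style hexagonal sampling layout
#'
#' Systematic random sampling: points on a triangular (hexagonal
#' packing) lattice with a uniformly random offset and fixed
#' orientation. The pitch is the largest value for which at least
#' `n_points` lattice points fall inside the box for every offset; the
#' first `n_points` in row-major order are returned. The minimum pitch
#' is 224 px so adjacent spots cannot yield near-duplicate patches.
#'
#' @param box_centre `c(x, y)` centre of the square sampling window.
#' @param box_side_px window side (default 6122 px = 3 mm at 0.49
#'   micron/px).
#' @param n_points number of points (>= 1).
#' @return `n_points` x 2 matrix of point coordinates, all inside the
#'   box; attribute `pitch_px` records the lattice pitch.
#' @export
randomspot_layout <- function(box_centre, box_side_px = 6122,
                              n_points = 120L) {
  if (n_points < 1) stop_parameter("n_points must be >= 1")
  side <- box_side_px
  guaranteed <- function(p) {
    floor(side / (p * sqrt(3) / 2)) * floor(side / p)
  }
  if (guaranteed(224) < n_points)
    stop_parameter(sprintf("box of %g px cannot hold %d points at minimum pitch 224 px",
                           side, n_points))
  lo <- 224; hi <- floor(side)
  while (lo < hi) {           # largest integer pitch with guaranteed() >= n
    mid <- (lo + hi + 1) %/% 2
    if (guaranteed(mid) >= n_points) lo <- mid else hi <- mid - 1
  }
  pitch <- lo
  rs <- pitch * sqrt(3) / 2
  ox <- stats::runif(1, 0, pitch); oy <- stats::runif(1, 0, rs)
  xs <- ys <- numeric(0)
  i <- 0L
  repeat {
    y <- oy + i * rs
    if (y >= side) break
    x0 <- (ox + (i %% 2L) * pitch / 2) %% pitch
    xrow <- seq(x0, side - 1e-9, by = pitch)
    xs <- c(xs, xrow); ys <- c(ys, rep(y, length(xrow)))
    i <- i + 1L
  }
  stopifnot(length(xs) >= n_points)
  out <- cbind(x = xs[seq_len(n_points)] + box_centre[1] - side / 2,
               y = ys[seq_len(n_points)] + box_centre[2] - side / 2)
  attr(out, "pitch_px") <- pitch
  out
}

#' Centre of the window of maximum tumour-point density
#'
#' Evaluates axis-aligned square windows on a discrete lattice of
#' candidate centres and returns the centre whose window contains the
#' most tumour points; ties break to the smallest (y, x).
#'
#' @param tumour_points 2-column matrix of (FP-corrected) tumour point
#'   coordinates.
#' @param window_px window side (default 6122).
#' @param slide_dims `c(width_px, height_px)` or a `virtual_slide`.
#' @param stride_px candidate lattice stride (default window / 4).
#' @return `c(x, y)` of the winning centre; attribute `count` holds the
#'   number of tumour points in its window.
#' @export
max_density_centre <- function(tumour_points, window_px = 6122,
                               slide_dims, stride_px = window_px / 4) {
  if (inherits(slide_dims, "virtual_slide"))
    slide_dims <- c(slide_dims$width_px, slide_dims$height_px)
  pts <- matrix(as.numeric(as.matrix(tumour_points)), ncol = 2)
  if (!nrow(pts)) stop_undefined("no tumour points: density centre undefined")
  half <- window_px / 2
  cand_axis <- function(dim) {
    if (dim <= window_px) return(dim / 2)
    unique(c(seq(half, dim - half, by = stride_px), dim - half))
  }
  cxs <- cand_axis(slide_dims[1]); cys <- cand_axis(slide_dims[2])
  best <- NULL; best_n <- -1L
  for (cy in cys) for (cx in cxs) {
    n <- sum(abs(pts[, 1] - cx) <= half & abs(pts[, 2] - cy) <= half)
    if (n > best_n) { best_n <- n; best <- c(cx, cy) }
  }
  structure(best, count = best_n)
}

# Classify 224 px patches centred at `centres` with the full simulated
# two-stage classifier. Centres closer than half a patch to the slide
# edge are dropped (a partial patch has no defined centre-class
# semantics).
classify_at_points <- function(slide, centres, bundle) {
  centres <- matrix(as.numeric(as.matrix(centres)), ncol = 2)
  half <- PATCH_PX / 2
  ok <- centres[, 1] >= half & centres[, 1] <= slide$width_px - half &
        centres[, 2] >= half & centres[, 2] <= slide$height_px - half
  if (!all(ok))
    message(sprintf("classify_at_points: %d point(s) within %d px of the slide edge dropped",
                    sum(!ok), half))
  centres <- centres[ok, , drop = FALSE]
  p <- patch_table(nrow(centres))
  # floor keeps the integer patch centre in the same raster cell as the
  # requested point, preserving the centre-pixel ground-truth identity
  p$x <- as.integer(floor(centres[, 1])) - half
  p$y <- as.integer(floor(centres[, 2])) - half
  p <- simulate_classify(p, slide, bundle$confusion)
  fp_correct(p, bundle$fp)
}

#' TSR from uniform sampling over the predicted ROI
#'
#' Draws `n` fresh patch centres by rejection sampling uniformly over
#' the union of the predicted-ROI hulls (centres at least 112 px from
#' the slide edge), classifies them with the two-stage classifier, and
#' computes TSR from the resulting counts.
#'
#' @param slide a `virtual_slide`.
#' @param hulls list of predicted-ROI polygons.
#' @param bundle a `classifier_bundle`.
#' @param n number of patches (default 100).
#' @return a `tsr_result` with `method_id = "uniform_roi"`.
#' @export
tsr_uniform_roi <- function(slide, hulls, bundle, n = 100L) {
  if (is.matrix(hulls)) hulls <- list(hulls)
  if (!length(hulls)) stop_undefined("empty predicted ROI: TSR undefined")
  bb <- apply(do.call(rbind, lapply(hulls, function(h) apply(h, 2, range))),
              2, range)
  half <- PATCH_PX / 2
  lo <- pmax(bb[1, ], half)
  hi <- pmin(bb[2, ], c(slide$width_px, slide$height_px) - half)
  if (any(lo >= hi)) stop_undefined("predicted ROI has no sampleable area")
  acc <- matrix(numeric(0), ncol = 2)
  tries <- 0L
  while (nrow(acc) < n) {
    m <- max(4L * n, 64L)
    cand <- cbind(stats::runif(m, lo[1], hi[1]), stats::runif(m, lo[2], hi[2]))
    keep <- points_in_polys(cand, hulls)
    acc <- rbind(acc, cand[keep, , drop = FALSE])
    tries <- tries + 1L
    if (tries > 200L)
      stop_undefined("rejection sampling over the predicted ROI failed")
  }
  new_tsr_result("uniform_roi",
                 classify_at_points(slide, acc[seq_len(n), , drop = FALSE],
                                    bundle))
}

#' TSR from the 3 mm maximum-tumour-density window
#'
#' Emulates the pathologist sampling protocol: a RandomSpot-style
#' triangular lattice of `n` points inside the window of maximum
#' tumour-point density, classified with the two-stage classifier.
#'
#' @param slide a `virtual_slide`.
#' @param tumour_points FP-corrected tumour point coordinates.
#' @param bundle a `classifier_bundle`.
#' @param n number of points (default 120).
#' @param window_px window side (default 6122 px = 3 mm).
#' @return a `tsr_result` with `method_id = "box_max_density"`.
#' @export
tsr_box_max_density <- function(slide, tumour_points, bundle, n = 120L,
                                window_px = 6122) {
  ctr <- max_density_centre(tumour_points, window_px,
                            c(slide$width_px, slide$height_px))
  xy <- randomspot_layout(ctr, window_px, n)
  new_tsr_result("box_max_density", classify_at_points(slide, xy, bundle))
}

#' TSR as the mean over sliding 3 mm windows
#'
#' Windows slide across the slide on a stride lattice; a window
#' participates iff its centre lies inside the predicted-ROI hull
#' union and it holds at least `min_counts` tumour + stroma patches.
#' The estimate is the unweighted mean of per-window TSRs of the
#' already-classified pipeline patches.
#'
#' @param patches classified (FP-corrected) patch table.
#' @param hulls list of predicted-ROI polygons.
#' @param slide_dims `c(width_px, height_px)` or a `virtual_slide`.
#' @param window_px window side (default 6122).
#' @param stride_px stride of the window lattice (default window / 2).
#' @param min_counts minimum T + S for a window to participate.
#' @return a `tsr_result` with `method_id = "sliding_mean"`; `T` and
#'   `S` total over participating windows and `locations` holds the
#'   participating window centres with per-window counts and TSR.
#' @export
tsr_sliding_mean <- function(patches, hulls, slide_dims, window_px = 6122,
                             stride_px = window_px / 2, min_counts = 10L) {
  if (inherits(slide_dims, "virtual_slide"))
    slide_dims <- c(slide_dims$width_px, slide_dims$height_px)
  if (is.matrix(hulls)) hulls <- list(hulls)
  if (!nrow(patches)) stop_undefined("no classified patches")
  if (!length(hulls)) stop_undefined("empty predicted ROI: TSR undefined")
  half <- window_px / 2
  cand_axis <- function(dim) {
    if (dim <= window_px) return(dim / 2)
    unique(c(seq(half, dim - half, by = stride_px), dim - half))
  }
  ctr <- expand.grid(x = cand_axis(slide_dims[1]),
                     y = cand_axis(slide_dims[2]))
  in_roi <- points_in_polys(as.matrix(ctr), hulls)
  cc <- patch_centres(patches)
  is_t <- !is.na(patches$pred_class) & patches$pred_class == "tumour"
  is_s <- !is.na(patches$pred_class) & patches$pred_class == "stroma_fibrosis"
  rows <- list()
  for (i in which(in_roi)) {
    inw <- abs(cc[, 1] - ctr$x[i]) <= half & abs(cc[, 2] - ctr$y[i]) <= half
    t_n <- sum(is_t & inw); s_n <- sum(is_s & inw)
    if (t_n + s_n >= min_counts)
      rows[[length(rows) + 1L]] <- data.frame(x = ctr$x[i], y = ctr$y[i],
                                              t = t_n, s = s_n,
                                              tsr = t_n / (t_n + s_n))
  }
  if (!length(rows))
    stop_undefined("no sliding window met the minimum tumour+stroma count")
  win <- do.call(rbind, rows)
  structure(list(method_id = "sliding_mean",
                 T = sum(win$t), S = sum(win$s),
                 value = mean(win$tsr), locations = win),
            class = "tsr_result")
}

#' TSR at the ground-truth annotation points
#'
#' Classifies patches at exactly the ground-truth sampling locations
#' (the theoretical accuracy ceiling of any location-prediction
#' scheme).
#'
#' @param slide a `virtual_slide`.
#' @param gt_points data.frame with columns `x`, `y` (e.g. from
#'   [gt_sample_points()] or an annotation set).
#' @param bundle a `classifier_bundle`.
#' @return a `tsr_result` with `method_id = "gt_locations"`.
#' @export
tsr_gt_locations <- function(slide, gt_points, bundle) {
  if (is.null(gt_points) || !nrow(gt_points))
    stop_parameter("gt_points must be non-empty")
  new_tsr_result("gt_locations",
                 classify_at_points(slide,
                                    cbind(gt_points$x, gt_points$y), bundle))
}

#' RMSE and mean error of TSR estimates across a slide set
#'
#' @param pairs data.frame (or 2-col matrix) with ground-truth TSR in
#'   the first column and estimates in the second.
#' @return a `tsr_error_report`: `n_slides`, `rmse`,
#'   `me` (signed, ground truth minus estimate), and the per-slide
#'   pairs.
#' @export
error_report <- function(pairs) {
  pairs <- as.data.frame(pairs)
  if (!nrow(pairs)) stop_undefined("error report needs at least one pair")
  names(pairs)[1:2] <- c("tsr_gt", "tsr_est")
  if (any(pairs$tsr_gt < 0 | pairs$tsr_gt > 1 |
          pairs$tsr_est < 0 | pairs$tsr_est > 1, na.rm = TRUE))
    stop_parameter("TSR values must lie in [0, 1]")
  d <- pairs$tsr_gt - pairs$tsr_est
  structure(list(n_slides = nrow(pairs),
                 rmse = sqrt(mean(d^2)),
                 me = mean(d),
                 pairs = pairs),
            class = "tsr_error_report")
}

#' @export
print.tsr_error_report <- function(x, ...) {
  cat(sprintf("<tsr_error_report> N = %d: RMSE = %.3f (%.1f%%), ME = %+.3f\n",
              x$n_slides, x$rmse, 100 * x$rmse, x$me))
  invisible(x)
}
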