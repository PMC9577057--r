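# Pipeline orchestration.
#
# Attention mode: initial sparse allocation -> classify -> FP-correct
# -> [densify -> classify -> FP-correct] x iterations -> DBSCAN ->
# convex hulls -> uniform ROI fill -> classify fill -> final ROI
# re-estimate from all FP-corrected tumour points -> TSR methods ->
# metrics. Tile mode replaces the sampling stages with a dense
# non-overlapping 224 px tiling in a single pass and shares everything
# downstream.

#' Pipeline configuration
#'
#' @param box_px grid box side: 640, 768 or 1024 (224 selects tile
#'   mode).
#' @param resample_iterations densification rounds before the final
#'   fill: 1 or 2.
#' @param per_box_cap per-box patch cap (default 5).
#' @param per_tumour new patches per tumour patch during densification
#'   (default 4).
#' @param eps_px DBSCAN neighbourhood radius (default 2000 px).
#' @param min_samples DBSCAN core threshold (default 3).
#' @param patch_px patch side (224).
#' @param microns_per_px physical resolution (default 0.49).
#' @param accuracy simulated classifier diagonal accuracy (default
#'   0.79).
#' @param normal_epi_to_tumour_rate normal-epithelium to tumour
#'   confusion rate (default 0.3).
#' @param fp_sensitivity,fp_specificity FP-correction stage parameters
#'   (default 0.927 each).
#' @param tsr_methods TSR strategies to run.
#' @param n_uniform,n_randomspot sample sizes for the uniform-ROI (100)
#'   and max-density-box (120) TSR methods.
#' @param tsr_window_px TSR window side (default 6122 px = 3 mm).
#' @param sliding_stride_px stride of the sliding-mean window lattice
#'   (default `tsr_window_px / 2`).
#' @param min_counts minimum T + S per sliding window (default 10).
#' @param max_retries placement retries per sampling slot (default
#'   100).
#' @param seed pipeline seed; `NULL` uses the current RNG state.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(box_px = 640L, resample_iterations = 1L,
                            per_box_cap = 5L, per_tumour = 4L,
                            eps_px = 2000, min_samples = 3L,
                            patch_px = 224L, microns_per_px = 0.49,
                            accuracy = 0.79,
                            normal_epi_to_tumour_rate = 0.3,
                            fp_sensitivity = 0.927,
                            fp_specificity = 0.927,
                            tsr_methods = c("uniform_roi",
                                            "box_max_density",
                                            "sliding_mean",
                                            "gt_locations"),
                            n_uniform = 100L, n_randomspot = 120L,
                            tsr_window_px = 6122,
                            sliding_stride_px = NULL,
                            min_counts = 10L, max_retries = 100L,
                            seed = NULL) {
  if (!box_px %in% c(224L, 640L, 768L, 1024L))
    stop_parameter("box_px must be one of 640, 768, 1024 (224 for tile mode)")
  if (!resample_iterations %in% c(1L, 2L))
    stop_parameter("resample_iterations must be 1 or 2")
  if (patch_px != 224L) stop_parameter("patch_px is fixed at 224")
  tsr_methods <- match.arg(tsr_methods, several.ok = TRUE)
  cfg <- list(box_px = as.integer(box_px),
              resample_iterations = as.integer(resample_iterations),
              per_box_cap = as.integer(per_box_cap),
              per_tumour = as.integer(per_tumour),
              eps_px = as.numeric(eps_px),
              min_samples = as.integer(min_samples),
              patch_px = 224L,
              microns_per_px = as.numeric(microns_per_px),
              accuracy = as.numeric(accuracy),
              normal_epi_to_tumour_rate = as.numeric(normal_epi_to_tumour_rate),
              fp_sensitivity = as.numeric(fp_sensitivity),
              fp_specificity = as.numeric(fp_specificity),
              tsr_methods = tsr_methods,
              n_uniform = as.integer(n_uniform),
              n_randomspot = as.integer(n_randomspot),
              tsr_window_px = as.numeric(tsr_window_px),
              sliding_stride_px = as.numeric(sliding_stride_px %||%
                                               (tsr_window_px / 2)),
              min_counts = as.integer(min_counts),
              max_retries = as.integer(max_retries),
              seed = if (is.null(seed)) NULL else as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

config_bundle <- function(config) {
  classifier_bundle(
    make_confusion(config$accuracy, config$normal_epi_to_tumour_rate),
    fp_stage(config$fp_sensitivity, config$fp_specificity))
}

#' Write / read a pipeline configuration as YAML
#'
#' Round-trips verbatim (all fields restored with their types).
#'
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

tumour_points_of <- function(patches) {
  tum <- !is.na(patches$pred_class) & patches$pred_class == "tumour"
  patch_centres(patches[tum, , drop = FALSE])
}

predict_roi <- function(patches, config) {
  pts <- tumour_points_of(patches)
  clusters <- dbscan_cluster(pts, config$eps_px, config$min_samples)
  # each tumour point stands for a full patch footprint
  list(clusters = clusters,
       hulls = build_hulls(clusters, expand_px = config$patch_px / 2))
}

run_tsr_methods <- function(slide, patches, hulls, bundle, gt_points,
                            config) {
  dims <- c(slide$width_px, slide$height_px)
  safely <- function(expr) tryCatch(expr, wsis_error = function(e) {
    structure(list(error = conditionMessage(e)), class = "tsr_undefined")
  })
  out <- list()
  for (m in config$tsr_methods) {
    out[[m]] <- switch(m,
      uniform_roi = safely(tsr_uniform_roi(slide, hulls, bundle,
                                           config$n_uniform)),
      box_max_density = safely(tsr_box_max_density(
        slide, tumour_points_of(patches), bundle, config$n_randomspot,
        config$tsr_window_px)),
      sliding_mean = safely(tsr_sliding_mean(
        patches, hulls, dims, config$tsr_window_px,
        config$sliding_stride_px, config$min_counts)),
      gt_locations = safely(tsr_gt_locations(slide, gt_points, bundle)))
  }
  out
}

finish_report <- function(slide, patches, roi, stage_counts, config,
                          bundle, gt_points, mode) {
  gt_roi <- slide$gt_roi
  dims <- c(slide$width_px, slide$height_px)
  dice <- if (is.null(gt_roi)) NA_real_ else
    dice_roi(roi$hulls, gt_roi, dims, slide$raster_step)
  tif <- function(col) {
    if (is.null(gt_roi)) return(NA_real_)
    tryCatch(tumour_inside_fraction(patches, gt_roi, col),
             wsis_undefined_metric_error = function(e) NA_real_)
  }
  tsr_gt_point <- if (is.null(gt_points)) NA_real_ else {
    t_n <- sum(gt_points$tissue_class == "tumour")
    s_n <- sum(gt_points$tissue_class == "stroma_fibrosis")
    if (t_n + s_n > 0) t_n / (t_n + s_n) else NA_real_
  }
  structure(list(
    mode = mode,
    patches = patches,
    clusters = roi$clusters,
    hulls = roi$hulls,
    dice = dice,
    tumour_inside_pre = tif("pred_raw"),
    tumour_inside_post = tif("pred_class"),
    tsr = run_tsr_methods(slide, patches, roi$hulls, bundle, gt_points,
                          config),
    tsr_gt_point = tsr_gt_point,
    tsr_gt_area = tryCatch(gt_area_tsr(slide),
                           wsis_error = function(e) NA_real_),
    gt_points = gt_points,
    stage_counts = stage_counts,
    total_patches = nrow(patches),
    slide_info = list(width_px = slide$width_px,
                      height_px = slide$height_px,
                      raster_step = slide$raster_step,
                      seed = slide$seed),
    config = config
  ), class = "wsi_run")
}

#' Run the attention-guided sampling pipeline on one slide
#'
#' Executes the full adaptive pipeline: sparse initial allocation,
#' classification and FP correction, one or two densification rounds
#' around tumour-classified patches, DBSCAN clustering and convex-hull
#' ROI prediction, uniform fill of the predicted ROI, a final ROI
#' re-estimate from all FP-corrected tumour points, the configured TSR
#' methods, and ground-truth metrics (Dice, tumour-inside-ROI fraction)
#' when ground truth is available. Deterministic given
#' (`slide`, `config$seed`).
#'
#' @param slide a `virtual_slide`.
#' @param config a `pipeline_config`.
#' @param annotations optional `annotation_set` supplying ground-truth
#'   sample points (defaults to the slide's own designated layout when
#'   it has tumour cells).
#' @return a `wsi_run` report.
#' @export
run_attention_pipeline <- function(slide, config = pipeline_config(),
                                   annotations = NULL) {
  if (config$box_px == 224L)
    stop_parameter("box_px 224 is tile mode; use run_tiled_reference()")
  if (!is.null(config$seed)) set.seed(config$seed)
  bundle <- config_bundle(config)
  grid <- build_grid(slide, config$box_px)
  stage_counts <- integer(0)

  patches <- allocate_initial(grid, slide)
  patches <- fp_correct(simulate_classify(patches, slide,
                                          bundle$confusion), bundle$fp)
  stage_counts["initial"] <- nrow(patches)

  for (it in seq_len(config$resample_iterations)) {
    new <- allocate_resample(patches, grid, slide, config$per_tumour,
                             config$per_box_cap, config$max_retries)
    new <- fp_correct(simulate_classify(new, slide, bundle$confusion),
                      bundle$fp)
    stage_counts[paste0("resample_", it)] <- nrow(new)
    patches <- rbind(patches, new)
  }

  roi_pre <- predict_roi(patches, config)
  fill <- allocate_roi_fill(patches, grid, slide, roi_pre$hulls,
                            config$per_box_cap, config$max_retries)
  fill <- fp_correct(simulate_classify(fill, slide, bundle$confusion),
                     bundle$fp)
  stage_counts["roi_fill"] <- nrow(fill)
  patches <- rbind(patches, fill)

  # final ROI estimate from all accumulated FP-corrected tumour points
  roi_final <- predict_roi(patches, config)

  gt_points <- annotations$sample_points %||%
    tryCatch(gt_sample_points(slide), wsis_error = function(e) NULL)
  finish_report(slide, patches, roi_final, stage_counts, config, bundle,
                gt_points, mode = "attention")
}

#' Run the dense tile-by-tile reference pipeline
#'
#' Contiguous, non-overlapping 224 px tiles cover the slide in a single
#' pass (incomplete edge tiles are dropped; background-centred tiles
#' excluded); all tiles are classified and FP-corrected, then the same
#' ROI-prediction, TSR and metric stages run as in attention mode.
#'
#' @inheritParams run_attention_pipeline
#' @return a `wsi_run` report with `mode = "tiled"`.
#' @export
run_tiled_reference <- function(slide, config = pipeline_config(box_px = 224L),
                                annotations = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  config$box_px <- 224L
  bundle <- config_bundle(config)
  n_cols <- slide$width_px %/% PATCH_PX
  n_rows <- slide$height_px %/% PATCH_PX
  bc <- rep(0:(n_cols - 1L), each = n_rows)
  br <- rep(0:(n_rows - 1L), times = n_cols)
  patches <- patch_table(length(bc))
  patches$x <- bc * PATCH_PX; patches$y <- br * PATCH_PX
  patches$box_col <- bc; patches$box_row <- br
  cc <- patch_centres(patches)
  keep <- label_at(slide, cc[, 1], cc[, 2]) != "background"
  patches <- patches[keep, , drop = FALSE]
  rownames(patches) <- NULL
  patches <- fp_correct(simulate_classify(patches, slide,
                                          bundle$confusion), bundle$fp)
  stage_counts <- c(tiles = nrow(patches))
  roi <- predict_roi(patches, config)
  gt_points <- annotations$sample_points %||%
    tryCatch(gt_sample_points(slide), wsis_error = function(e) NULL)
  finish_report(slide, patches, roi, stage_counts, config, bundle,
                gt_points, mode = "tiled")
}

#' Compare an attention run with a tiled reference run
#'
#' Speed is represented hardware-independently by the patch-count
#' ratio.
#'
#' @param attention_report,tiled_report `wsi_run` reports on the same
#'   slide.
#' @return list with `patch_count_ratio` (tiled / attention),
#'   `dice_delta` (attention minus tiled) and, per shared TSR method,
#'   the absolute-error delta against the point ground truth
#'   (attention minus tiled; negative favours attention).
#' @export
compare_runs <- function(attention_report, tiled_report) {
  a <- attention_report; t <- tiled_report
  if (!identical(a$slide_info, t$slide_info))
    stop_input("reports come from different slides")
  tsr_err <- function(r, m) {
    est <- r$tsr[[m]]
    if (is.null(est) || inherits(est, "tsr_undefined") ||
        is.na(r$tsr_gt_point)) return(NA_real_)
    abs(r$tsr_gt_point - est$value)
  }
  shared <- intersect(names(a$tsr), names(t$tsr))
  deltas <- vapply(shared, function(m) tsr_err(a, m) - tsr_err(t, m),
                   numeric(1))
  list(patch_count_ratio = t$total_patches / a$total_patches,
       dice_delta = a$dice - t$dice,
       tsr_abs_err_delta = deltas,
       attention_patches = a$total_patches,
       tiled_patches = t$total_patches)
}

#' Run the pipeline over a set of slides and aggregate
#'
#' @param slides list of `virtual_slide`s (or a single slide).
#' @param config a `pipeline_config`; per-slide seeds are derived as
#'   `config$seed + index` when a seed is set.
#' @param annotations optional list of `annotation_set`s parallel to
#'   `slides`.
#' @return a `wsi_eval`: per-slide `wsi_run`s, mean Dice, and a
#'   `tsr_error_report` per TSR method (estimates paired with the
#'   point-sampled ground-truth TSR).
#' @export
run_evaluation_set <- function(slides, config = pipeline_config(),
                               annotations = NULL) {
  if (inherits(slides, "virtual_slide")) slides <- list(slides)
  if (!length(slides)) stop_input("slide set is empty")
  runs <- vector("list", length(slides))
  for (i in seq_along(slides)) {
    cfg_i <- config
    if (!is.null(config$seed)) cfg_i$seed <- config$seed + i
    ann_i <- if (is.null(annotations)) NULL else annotations[[i]]
    runs[[i]] <- run_attention_pipeline(slides[[i]], cfg_i, ann_i)
  }
  mean_dice <- mean(vapply(runs, function(r) r$dice, numeric(1)),
                    na.rm = TRUE)
  reports <- list()
  for (m in config$tsr_methods) {
    gt <- vapply(runs, function(r) r$tsr_gt_point, numeric(1))
    est <- vapply(runs, function(r) {
      v <- r$tsr[[m]]
      if (is.null(v) || inherits(v, "tsr_undefined")) NA_real_ else v$value
    }, numeric(1))
    ok <- !is.na(gt) & !is.na(est)
    reports[[m]] <- if (any(ok))
      error_report(data.frame(tsr_gt = gt[ok], tsr_est = est[ok]))
    else NULL
  }
  structure(list(runs = runs, mean_dice = mean_dice,
                 tsr_error_reports = reports, config = config),
            class = "wsi_eval")
}

#' @export
print.wsi_run <- function(x, ...) {
  cat(sprintf("<wsi_run> %s mode, %d patches (%s)\n", x$mode,
              x$total_patches,
              paste(names(x$stage_counts), x$stage_counts, sep = "=",
                    collapse = ", ")))
  cat(sprintf("  predicted ROI: %d hull(s); Dice vs ground truth: %s\n",
              length(x$hulls),
              ifelse(is.na(x$dice), "n/a", sprintf("%.3f", x$dice))))
  cat(sprintf("  tumour inside ROI: %.1f%% pre-FPC, %.1f%% post-FPC\n",
              x$tumour_inside_pre, x$tumour_inside_post))
  for (m in names(x$tsr)) {
    v <- x$tsr[[m]]
    if (inherits(v, "tsr_undefined"))
      cat(sprintf("  TSR [%s]: undefined (%s)\n", m, v$error))
    else
      cat(sprintf("  TSR [%s]: %.3f (T=%d, S=%d)\n", m, v$value, v$T, v$S))
  }
  cat(sprintf("  ground truth: point TSR %.3f, area TSR %.3f\n",
              x$tsr_gt_point, x$tsr_gt_area))
  invisible(x)
}

#' @export
summary.wsi_run <- function(object, ...) {
  print(object)
  cat("  patches per iteration:\n")
  print(table(object$patches$iteration))
  invisible(object)
}

#' @export
plot.wsi_run <- function(x, slide = NULL, ...) {
  p <- x$patches
  cc <- patch_centres(p)
  tum <- !is.na(p$pred_class) & p$pred_class == "tumour"
  graphics::plot(cc[, 1], -cc[, 2], pch = ".", col = "grey60", asp = 1,
                 xlab = "x (px)", ylab = "-y (px)",
                 main = sprintf("%s run: patches and predicted ROI", x$mode),
                 ...)
  graphics::points(cc[tum, 1], -cc[tum, 2], pch = 20, cex = 0.4,
                   col = "firebrick")
  for (h in x$hulls)
    graphics::polygon(h[, 1], -h[, 2], border = "blue", lwd = 2)
  if (!is.null(slide) && !is.null(slide$gt_roi))
    graphics::polygon(slide$gt_roi[, 1], -slide$gt_roi[, 2],
                      border = "darkgreen", lty = 2)
  invisible(x)
}

#' @export
print.wsi_eval <- function(x, ...) {
  cat(sprintf("<wsi_eval> %d slide(s); mean ROI Dice = %.3f\n",
              length(x$runs), x$mean_dice))
  for (m in names(x$tsr_error_reports)) {
    r <- x$tsr_error_reports[[m]]
    if (is.null(r)) next
    cat(sprintf("  %-16s RMSE = %5.1f%%  ME = %+.3f  (N = %d)\n",
                m, 100 * r$rmse, r$me, r$n_slides))
  }
  invisible(x)
}

#' Export predicted-ROI hulls as GeoJSON
#'
#' Polygon features with `role = "predicted_roi"` and a `cluster_id`
#' property, in level-0 pixel coordinates.
#'
#' @param hulls list of hull polygons (from a `wsi_run` or
#'   [build_hulls()]).
#' @param path output path.
#' @export
write_hulls <- function(hulls, path) {
  features <- lapply(hulls, function(h) {
    geojson_polygon_feature(h, list(role = "predicted_roi",
                                    cluster_id = attr(h, "cluster_id") %||% NA))
  })
  fc <- list(type = "FeatureCollection", crs = "pixel:level0",
             features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Serialize a run report to JSON
#'
#' Writes the scalar metrics, stage counts and TSR results (values and
#' counts) of a `wsi_run`; the patch table and hulls are written
#' separately as CSV / GeoJSON.
#'
#' @param report a `wsi_run`.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  tsr <- lapply(report$tsr, function(v) {
    if (inherits(v, "tsr_undefined")) list(undefined = v$error)
    else list(value = v$value, T = v$T, S = v$S)
  })
  out <- list(mode = report$mode,
              total_patches = report$total_patches,
              stage_counts = as.list(report$stage_counts),
              n_hulls = length(report$hulls),
              dice = report$dice,
              tumour_inside_pre = report$tumour_inside_pre,
              tumour_inside_post = report$tumour_inside_post,
              tsr = tsr,
              tsr_gt_point = report$tsr_gt_point,
              tsr_gt_area = report$tsr_gt_area,
              slide_info = report$slide_info,
              config = unclass(report$config))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
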