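# Patch sampling.
#
# The slide is covered by a coarse square grid (640/768/1024 px boxes;
# 224 px selects tile mode). Sampling proceeds in generations:
#   iteration 0: one 224 px patch placed uniformly at random per box
#     (dropped when its centre falls on background);
#   iterations 1..k: densification — boxes holding tumour-classified
#     patches are topped up, four patches per tumour patch, capped at 5
#     per box, re-drawing placements that overlap existing patches of
#     the same box or land centre-on-background;
#   final iteration: every box whose centre lies inside the predicted
#     ROI hull is topped up to the cap.
#
# A patch's top-left corner is drawn uniformly over its box and then
# clamped so the whole 224 px square stays inside the slide; the patch
# may extend past its box's right/bottom edge (constraining it to the
# box would make 5 non-overlapping patches geometrically impossible in
# a 640 px box, contradicting the per-box cap of 5).

PATCH_PX <- 224L

#' Build the coarse sampling grid
#'
#' @param slide_dims a `virtual_slide` or `c(width_px, height_px)`.
#' @param box_px grid box side in level-0 px (>= 224).
#' @return a `wsi_grid`: box size and column/row counts covering the
#'   slide (half-open boxes; the last row/column may overhang the slide
#'   edge).
#' @export
build_grid <- function(slide_dims, box_px) {
  if (inherits(slide_dims, "virtual_slide"))
    slide_dims <- c(slide_dims$width_px, slide_dims$height_px)
  if (box_px < PATCH_PX)
    stop_parameter("box_px must be >= 224 (the patch size)")
  if (any(slide_dims <= 0)) stop_parameter("slide dimensions must be positive")
  structure(list(box_px = as.integer(box_px),
                 n_cols = as.integer(ceiling(slide_dims[1] / box_px)),
                 n_rows = as.integer(ceiling(slide_dims[2] / box_px)),
                 width_px = as.integer(slide_dims[1]),
                 height_px = as.integer(slide_dims[2])),
            class = "wsi_grid")
}

#' @export
print.wsi_grid <- function(x, ...) {
  cat(sprintf("<wsi_grid> %d px boxes, %d cols x %d rows over %d x %d px\n",
              x$box_px, x$n_cols, x$n_rows, x$width_px, x$height_px))
  invisible(x)
}

# Empty patch table. Box indices are 0-based, matching the half-open
# box [col*box_px, (col+1)*box_px) x [row*box_px, (row+1)*box_px).
patch_table <- function(n = 0L) {
  data.frame(x = integer(n), y = integer(n), size_px = rep(PATCH_PX, n),
             box_col = integer(n), box_row = integer(n),
             iteration = integer(n),
             gt_class = rep(NA_character_, n),
             pred_class = rep(NA_character_, n),
             pred_raw = rep(NA_character_, n),
             fp_corrected = logical(n),
             stringsAsFactors = FALSE)
}

patch_centres <- function(patches) {
  cbind(patches$x + patches$size_px / 2, patches$y + patches$size_px / 2)
}

#' Do two patches overlap?
#'
#' Half-open 224 px squares: `TRUE` iff they intersect in positive
#' area, so edge-touching patches do not overlap. Vectorized.
#'
#' @param ax,ay,bx,by top-left corners of the two patches.
#' @param size_px patch side.
#' @return logical.
#' @export
overlaps <- function(ax, ay, bx, by, size_px = PATCH_PX) {
  abs(ax - bx) < size_px & abs(ay - by) < size_px
}

# Draw one top-left uniformly over box (bc, br), clamped into the slide.
draw_topleft <- function(bc, br, grid) {
  x <- bc * grid$box_px + floor(stats::runif(1) * grid$box_px)
  y <- br * grid$box_px + floor(stats::runif(1) * grid$box_px)
  c(min(x, grid$width_px - PATCH_PX), min(y, grid$height_px - PATCH_PX))
}

#' Initial quasi-random allocation: one patch per grid box
#'
#' Places one 224 px patch uniformly at random in every grid box and
#' keeps it only when the ground truth under its centre is tissue
#' (background-centred placements are dropped, not re-drawn, so empty
#' slide regions stay unsampled). Iteration index 0.
#'
#' @param grid a `wsi_grid`.
#' @param slide a `virtual_slide`.
#' @return patch table (data.frame), one row per retained patch.
#' @export
allocate_initial <- function(grid, slide) {
  n <- grid$n_cols * grid$n_rows
  bc <- rep(0:(grid$n_cols - 1L), each = grid$n_rows)
  br <- rep(0:(grid$n_rows - 1L), times = grid$n_cols)
  x <- pmin(bc * grid$box_px + floor(stats::runif(n) * grid$box_px),
            grid$width_px - PATCH_PX)
  y <- pmin(br * grid$box_px + floor(stats::runif(n) * grid$box_px),
            grid$height_px - PATCH_PX)
  keep <- label_at(slide, x + PATCH_PX / 2, y + PATCH_PX / 2) != "background"
  out <- patch_table(sum(keep))
  out$x <- as.integer(x[keep]); out$y <- as.integer(y[keep])
  out$box_col <- bc[keep]; out$box_row <- br[keep]
  out
}

# All admissible top-left positions for a new patch in box (bc, br):
# inside the clamped box, non-background centre, overlapping no
# existing patch of the box. Used as an exact fallback when rejection
# sampling fails; enumerates the integer placement lattice.
free_positions <- function(bc, br, exist_x, exist_y, grid, slide) {
  x0 <- bc * grid$box_px; y0 <- br * grid$box_px
  xs <- x0:min(x0 + grid$box_px - 1L, grid$width_px - PATCH_PX)
  ys <- y0:min(y0 + grid$box_px - 1L, grid$height_px - PATCH_PX)
  xs <- unique(pmin(xs, grid$width_px - PATCH_PX))
  ys <- unique(pmin(ys, grid$height_px - PATCH_PX))
  cand_x <- rep(xs, times = length(ys))
  cand_y <- rep(ys, each = length(xs))
  ok <- label_at(slide, cand_x + PATCH_PX / 2, cand_y + PATCH_PX / 2) !=
    "background"
  for (i in seq_along(exist_x)) {
    ok <- ok & !overlaps(cand_x, cand_y, exist_x[i], exist_y[i])
    if (!any(ok)) break
  }
  cbind(cand_x[ok], cand_y[ok])
}

# Top up one box by `n_new` patches, honouring non-overlap (within the
# box only) and background re-draw rules: each slot re-draws uniform
# placements until a clear space is found, falling back after
# max_retries to exact uniform sampling over the remaining admissible
# positions; a slot is skipped only when no admissible position exists.
# Returns list(x, y, skipped).
fill_box_slots <- function(bc, br, n_new, exist_x, exist_y, grid, slide,
                           max_retries) {
  xs <- ys <- integer(0); skipped <- 0L
  for (s in seq_len(n_new)) {
    placed <- FALSE
    for (r in seq_len(max_retries)) {
      tl <- draw_topleft(bc, br, grid)
      if (label_at(slide, tl[1] + PATCH_PX / 2, tl[2] + PATCH_PX / 2) ==
          "background") next
      if (length(exist_x) &&
          any(overlaps(tl[1], tl[2], exist_x, exist_y))) next
      xs <- c(xs, tl[1]); ys <- c(ys, tl[2])
      exist_x <- c(exist_x, tl[1]); exist_y <- c(exist_y, tl[2])
      placed <- TRUE
      break
    }
    if (!placed) {
      free <- free_positions(bc, br, exist_x, exist_y, grid, slide)
      if (nrow(free)) {
        i <- free[sample.int(nrow(free), 1L), ]
        xs <- c(xs, i[1]); ys <- c(ys, i[2])
        exist_x <- c(exist_x, i[1]); exist_y <- c(exist_y, i[2])
      } else {
        skipped <- skipped + 1L
      }
    }
  }
  list(x = xs, y = ys, skipped = skipped)
}

#' Densification around tumour-classified patches
#'
#' For every grid box holding at least one patch currently predicted
#' `tumour`, adds `per_tumour` new patches per tumour patch, never
#' letting the box exceed `cap` patches in total. New placements are
#' re-drawn (up to `max_retries`) until they overlap no existing patch
#' of the same box and are not background-centred; exhausted slots are
#' skipped with a warning. New patches carry the next iteration index.
#'
#' @param patches accumulated patch table (classified; FP-corrected).
#' @param grid a `wsi_grid`.
#' @param slide a `virtual_slide`.
#' @param per_tumour new patches per tumour patch (default 4).
#' @param cap per-box total cap (default 5).
#' @param max_retries placement retries per slot before skipping.
#' @return patch table of the new patches only (attribute
#'   `retry_exhausted` counts skipped slots).
#' @export
allocate_resample <- function(patches, grid, slide, per_tumour = 4L,
                              cap = 5L, max_retries = 100L) {
  it <- if (nrow(patches)) max(patches$iteration) + 1L else 1L
  key <- paste(patches$box_col, patches$box_row)
  tum <- !is.na(patches$pred_class) & patches$pred_class == "tumour"
  boxes <- unique(key[tum])
  new_list <- list(); skipped <- 0L
  for (b in boxes) {
    in_box <- key == b
    n_exist <- sum(in_box)
    n_tum <- sum(in_box & tum)
    n_new <- min(per_tumour * n_tum, cap - n_exist)
    if (n_new <= 0) next
    bc <- patches$box_col[in_box][1]; br <- patches$box_row[in_box][1]
    res <- fill_box_slots(bc, br, n_new, patches$x[in_box],
                          patches$y[in_box], grid, slide, max_retries)
    skipped <- skipped + res$skipped
    if (length(res$x)) {
      np <- patch_table(length(res$x))
      np$x <- as.integer(res$x); np$y <- as.integer(res$y)
      np$box_col <- bc; np$box_row <- br; np$iteration <- it
      new_list[[length(new_list) + 1L]] <- np
    }
  }
  if (skipped > 0)
    warning(sprintf("allocate_resample: %d slot(s) had no admissible position and were skipped",
                    skipped), call. = FALSE)
  out <- if (length(new_list)) do.call(rbind, new_list) else patch_table(0L)
  attr(out, "retry_exhausted") <- skipped
  out
}

#' Uniform fill of the predicted ROI
#'
#' Tops up every grid box whose centre lies inside any predicted-ROI
#' hull polygon to `cap` patches, using the same placement, overlap and
#' background rules as densification. Boxes outside the hulls keep
#' their existing (sparse) density.
#'
#' @param patches accumulated patch table.
#' @param grid a `wsi_grid`.
#' @param slide a `virtual_slide`.
#' @param hulls list of convex polygons (from [build_hulls()]).
#' @param cap per-box total cap (default 5).
#' @param max_retries placement retries per slot.
#' @return patch table of the new patches only (attribute
#'   `retry_exhausted` counts skipped slots).
#' @export
allocate_roi_fill <- function(patches, grid, slide, hulls, cap = 5L,
                              max_retries = 100L) {
  it <- if (nrow(patches)) max(patches$iteration) + 1L else 1L
  if (!length(hulls)) {
    out <- patch_table(0L); attr(out, "retry_exhausted") <- 0L
    return(out)
  }
  bc <- rep(0:(grid$n_cols - 1L), each = grid$n_rows)
  br <- rep(0:(grid$n_rows - 1L), times = grid$n_cols)
  ctr <- cbind((bc + 0.5) * grid$box_px, (br + 0.5) * grid$box_px)
  in_hull <- points_in_polys(ctr, hulls)
  key <- paste(patches$box_col, patches$box_row)
  new_list <- list(); skipped <- 0L
  for (i in which(in_hull)) {
    b <- paste(bc[i], br[i])
    in_box <- key == b
    n_new <- cap - sum(in_box)
    if (n_new <= 0) next
    res <- fill_box_slots(bc[i], br[i], n_new, patches$x[in_box],
                          patches$y[in_box], grid, slide, max_retries)
    skipped <- skipped + res$skipped
    if (length(res$x)) {
      np <- patch_table(length(res$x))
      np$x <- as.integer(res$x); np$y <- as.integer(res$y)
      np$box_col <- bc[i]; np$box_row <- br[i]; np$iteration <- it
      new_list[[length(new_list) + 1L]] <- np
    }
  }
  if (skipped > 0)
    warning(sprintf("allocate_roi_fill: %d slot(s) had no admissible position and were skipped",
                    skipped), call. = FALSE)
  out <- if (length(new_list)) do.call(rbind, new_list) else patch_table(0L)
  attr(out, "retry_exhausted") <- skipped
  out
}

#' Write / read a patch table as CSV
#'
#' Columns: x, y, size_px, box_col, box_row, iteration, gt_class,
#' pred_class, pred_raw (pre-FP-correction label), fp_corrected.
#'
#' @param patches patch table.
#' @param path CSV path.
#' @export
write_patches <- function(patches, path) {
  utils::write.csv(patches, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_patches
#' @export
read_patches <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(x = "integer", y = "integer",
                                       size_px = "integer",
                                       box_col = "integer",
                                       box_row = "integer",
                                       iteration = "integer",
                                       gt_class = "character",
                                       pred_class = "character",
                                       pred_raw = "character",
                                       fp_corrected = "logical"))
  df
}
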