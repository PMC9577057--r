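# Virtual slides.
#
# A virtual slide stands in for a gigapixel WSI: instead of pixels it
# holds a downsampled raster of tissue-class labels (one label per
# raster_step x raster_step block of level-0 pixels), a ground-truth
# tumour ROI polygon, and the composition parameters it was generated
# from. A patch's ground-truth class is the raster label under its
# centre pixel, mirroring the central-pixel convention used when
# pathologist point annotations are turned into patch labels. Patch
# "content" is never rendered: the model exercises the sampling and
# estimation machinery, not a CNN.
#
# Coordinates are 0-based level-0 pixels, x rightward, y downward,
# half-open intervals everywhere.

# Run expr with a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

new_virtual_slide <- function(width_px, height_px, microns_per_px, raster_step,
                              label_raster, gt_roi, composition,
                              outside_composition = NULL,
                              roi_area_fraction = NA_real_,
                              normal_epi_band_px = NA_real_,
                              seed = NA_integer_) {
  slide <- list(
    width_px = as.integer(width_px),
    height_px = as.integer(height_px),
    microns_per_px = as.numeric(microns_per_px),
    raster_step = as.integer(raster_step),
    label_raster = label_raster,
    gt_roi = gt_roi,
    composition = composition,
    outside_composition = outside_composition,
    roi_area_fraction = as.numeric(roi_area_fraction),
    normal_epi_band_px = as.numeric(normal_epi_band_px),
    seed = as.integer(seed)
  )
  slide$roi_mask <- compute_roi_mask(slide)
  class(slide) <- "virtual_slide"
  slide
}

# Level-0 coordinates of every raster cell centre, as two vectors in
# column-major (matrix) order.
cell_centres <- function(slide) {
  D <- slide$raster_step
  nr <- nrow(slide$label_raster); nc <- ncol(slide$label_raster)
  list(
    x = rep((seq_len(nc) - 0.5) * D, each = nr),
    y = rep((seq_len(nr) - 0.5) * D, times = nc)
  )
}

compute_roi_mask <- function(slide) {
  if (is.null(slide$gt_roi)) return(NULL)
  cc <- cell_centres(slide)
  dim_out <- dim(slide$label_raster)
  poly <- slide$gt_roi
  # restrict the containment test to the polygon's bounding box
  bb <- apply(poly, 2, range)
  cand <- cc$x >= bb[1, 1] & cc$x <= bb[2, 1] &
          cc$y >= bb[1, 2] & cc$y <= bb[2, 2]
  mask <- logical(length(cc$x))
  if (any(cand)) {
    mask[cand] <- points_in_polys(cbind(cc$x[cand], cc$y[cand]), poly)
  }
  matrix(mask, nrow = dim_out[1], ncol = dim_out[2])
}

# Sum-of-random-cosines spatial noise field over cell centres: smooth,
# isotropic in expectation, wavelengths between lambda_min and lambda_max
# level-0 px. Fully deterministic given the RNG state.
noise_field <- function(x, y, n_waves = 40L,
                        lambda_min = 1500, lambda_max = 6000) {
  f <- numeric(length(x))
  for (k in seq_len(n_waves)) {
    th <- stats::runif(1, 0, 2 * pi)
    lambda <- stats::runif(1, lambda_min, lambda_max)
    phi <- stats::runif(1, 0, 2 * pi)
    f <- f + cos((x * cos(th) + y * sin(th)) * (2 * pi / lambda) + phi)
  }
  f
}

# Partition the index set `idx` into classes with fractions `fractions`
# (named, summing to 1) by quantile-slicing the smooth field `f[idx]`:
# realized counts are exact to +-1 cell and spatially clumped.
partition_by_field <- function(idx, f, fractions) {
  n <- length(idx)
  out <- character(n)
  ord <- order(f[idx])
  cum <- round(cumsum(fractions) * n)
  cum[length(cum)] <- n
  sizes <- diff(c(0L, cum))
  at <- 1L
  for (j in seq_along(fractions)) {
    if (sizes[j] > 0) {
      out[ord[at:(at + sizes[j] - 1L)]] <- names(fractions)[j]
      at <- at + sizes[j]
    }
  }
  out
}

check_composition <- function(composition, allowed, what) {
  if (is.null(names(composition)) || any(!nzchar(names(composition))))
    stop_parameter(paste(what, "must be a named numeric vector"))
  if (!all(names(composition) %in% allowed))
    stop_parameter(paste0(what, " contains unknown classes: ",
      paste(setdiff(names(composition), allowed), collapse = ", ")))
  if (any(composition < 0) || abs(sum(composition) - 1) > 1e-9)
    stop_parameter(paste(what, "fractions must be >= 0 and sum to 1"))
  invisible(composition)
}

#' Generate a synthetic virtual slide with known ground truth
#'
#' Emulates an H&E whole-slide image at the label level: a background
#' margin surrounds an elliptical tissue section; a contiguous,
#' star-convex tumour ROI of known mixed composition sits inside the
#' tissue; the surrounding normal tissue contains stroma, muscle,
#' inflammation and lumen plus a contiguous band of normal epithelium
#' at the luminal rim (the false-positive source for tumour
#' classifiers). Class fractions inside (and outside) the ROI are
#' realized by quantile-slicing smooth random fields, so they match the
#' requested composition to within one raster cell while remaining
#' spatially clumped like real tissue.
#'
#' @param width_px,height_px slide dimensions in level-0 pixels.
#' @param roi_area_fraction target ROI area as a fraction of tissue
#'   area; must lie in (0.01, 0.6).
#' @param composition named fractions over classifier classes for cells
#'   inside the ROI; must sum to 1.
#' @param seed generation seed; regeneration with identical parameters
#'   and seed is bit-identical.
#' @param raster_step downsample factor of the label raster (level-0 px
#'   per raster cell).
#' @param microns_per_px physical resolution.
#' @param outside_composition named fractions for non-ROI tissue outside
#'   the normal-epithelium band.
#' @param normal_epi_band_px thickness (level-0 px, measured along the
#'   tissue minor axis) of the normal-epithelium band at the tissue rim.
#' @return a `virtual_slide` object.
#' @examples
#' s <- generate_slide(8000, 8000, seed = 1)
#' s
#' gt_area_tsr(s)
#' @export
generate_slide <- function(width_px = 20000, height_px = 20000,
                           roi_area_fraction = 0.15,
                           composition = c(tumour = 0.45,
                                           stroma_fibrosis = 0.35,
                                           necrosis = 0.05, lumen = 0.05,
                                           inflammation = 0.05,
                                           mucin = 0.05),
                           seed = 1L,
                           raster_step = 32L, microns_per_px = 0.49,
                           outside_composition = c(stroma_fibrosis = 0.55,
                                                   muscle = 0.20,
                                                   inflammation = 0.10,
                                                   lumen = 0.10,
                                                   non_informative = 0.05),
                           normal_epi_band_px = 768) {
  if (roi_area_fraction <= 0.01 || roi_area_fraction >= 0.6)
    stop_parameter("roi_area_fraction must lie in (0.01, 0.6)")
  check_composition(composition, classifier_classes(), "composition")
  check_composition(outside_composition, classifier_classes(),
                    "outside_composition")
  if (width_px < 50 * raster_step || height_px < 50 * raster_step)
    stop_dimension(width_px, height_px, raster_step)

  with_seed(seed, {
    D <- raster_step
    nr <- ceiling(height_px / D); nc <- ceiling(width_px / D)
    cx <- rep((seq_len(nc) - 0.5) * D, each = nr)
    cy <- rep((seq_len(nr) - 0.5) * D, times = nc)

    # tissue section: jittered ellipse with a background margin
    ex <- width_px / 2 + stats::runif(1, -0.02, 0.02) * width_px
    ey <- height_px / 2 + stats::runif(1, -0.02, 0.02) * height_px
    a <- 0.44 * width_px * stats::runif(1, 0.95, 1)
    b <- 0.44 * height_px * stats::runif(1, 0.95, 1)
    rho <- sqrt(((cx - ex) / a)^2 + ((cy - ey) / b)^2)
    tissue <- rho <= 1
    tissue_area <- sum(tissue) * D^2
    rho_band <- 1 - normal_epi_band_px / min(a, b)

    # star-convex ROI blob: radial-harmonic perturbed circle whose
    # polygon area hits roi_area_fraction * tissue_area
    off <- stats::runif(2, -0.03, 0.03) * min(a, b)
    bx <- ex + off[1]; by <- ey + off[2]
    allowed_rmax <- 0.95 * (rho_band * min(a, b) - sqrt(sum(off^2)))
    target_area <- roi_area_fraction * tissue_area
    r0 <- sqrt(target_area / pi)
    if (allowed_rmax <= r0)
      stop_parameter("roi_area_fraction too large for the slide geometry")
    n_harm <- sample(8:16, 1)
    amp_raw <- stats::runif(n_harm) / seq_len(n_harm)
    phi <- stats::runif(n_harm, 0, 2 * pi)
    amp_total <- min(0.2, allowed_rmax / r0 - 1)
    amp <- amp_raw / sum(amp_raw) * amp_total
    th <- seq(0, 2 * pi, length.out = 257)[-257]
    for (i in 1:5) {
      runit <- 1 + colSums(amp * cos(outer(seq_len(n_harm), th) +
                                       phi))
      area_unit <- abs(polygon_signed_area(cbind(runit * cos(th),
                                                 runit * sin(th))))
      r0 <- sqrt(target_area / area_unit)
      if (r0 * (1 + sum(amp)) <= allowed_rmax) break
      amp <- amp * max(0, (allowed_rmax / r0 - 1)) / max(sum(amp), 1e-12)
    }
    gt_roi <- cbind(x = bx + r0 * runit * cos(th),
                    y = by + r0 * runit * sin(th))

    labels <- rep(class_to_code("background"), length(cx))

    # inside-ROI cells (centre-in-polygon) take the requested composition
    bb <- apply(gt_roi, 2, range)
    cand <- which(tissue & cx >= bb[1, 1] & cx <= bb[2, 1] &
                    cy >= bb[1, 2] & cy <= bb[2, 2])
    in_roi_idx <- cand[points_in_polys(cbind(cx[cand], cy[cand]), gt_roi)]
    roi_flag <- logical(length(cx)); roi_flag[in_roi_idx] <- TRUE
    # intra-tumoral gland/stroma texture is sub-millimetre: a finer
    # wavelength band than the surrounding normal-tissue mosaic
    f_in <- noise_field(cx, cy, lambda_min = 400, lambda_max = 1600)
    labels[in_roi_idx] <-
      class_to_code(partition_by_field(in_roi_idx, f_in, composition))

    # non-ROI tissue: normal-epithelium band at the rim, mixed normal
    # tissue elsewhere
    band_idx <- which(tissue & !roi_flag & rho >= rho_band)
    labels[band_idx] <- class_to_code("normal_epithelium")
    rest_idx <- which(tissue & !roi_flag & rho < rho_band)
    f_out <- noise_field(cx, cy)
    labels[rest_idx] <-
      class_to_code(partition_by_field(rest_idx, f_out, outside_composition))

    raster <- matrix(as.integer(labels), nrow = nr, ncol = nc)
    new_virtual_slide(width_px, height_px, microns_per_px, D, raster,
                      gt_roi, composition, outside_composition,
                      roi_area_fraction, normal_epi_band_px, seed)
  })
}

stop_dimension <- function(w, h, D) {
  abort_wsis(
    sprintf("slide %dx%d too small for raster_step %d (need >= %d px)",
            w, h, D, 50 * D),
    "wsis_dimension_error")
}

#' Wrap an existing label raster as a virtual slide
#'
#' Low-level constructor for tests and for plugging in externally
#' derived label maps (e.g. from a region reader plus a real
#' classifier). `label_raster` may hold class labels (character) or
#' integer class codes; see [tissue_class_codes()].
#'
#' @param label_raster matrix of labels or codes, one cell per
#'   `raster_step` x `raster_step` block of level-0 pixels.
#' @param raster_step level-0 px per raster cell.
#' @param gt_roi optional ground-truth ROI polygon (2-col matrix, level-0
#'   px).
#' @param width_px,height_px slide dimensions; default the raster extent.
#' @param microns_per_px physical resolution.
#' @return a `virtual_slide`.
#' @export
as_virtual_slide <- function(label_raster, raster_step = 32L, gt_roi = NULL,
                             width_px = ncol(label_raster) * raster_step,
                             height_px = nrow(label_raster) * raster_step,
                             microns_per_px = 0.49) {
  if (is.character(label_raster)) {
    label_raster <- matrix(class_to_code(label_raster),
                           nrow = nrow(label_raster))
  } else {
    code_to_class(as.integer(label_raster))  # validates
    label_raster <- matrix(as.integer(label_raster),
                           nrow = nrow(label_raster))
  }
  new_virtual_slide(width_px, height_px, microns_per_px, raster_step,
                    label_raster, gt_roi, composition = NULL)
}

#' Ground-truth tissue class at a level-0 pixel
#'
#' Pure raster lookup at `floor(y / raster_step), floor(x / raster_step)`;
#' no interpolation. Vectorized over `x`, `y`.
#'
#' @param slide a `virtual_slide`.
#' @param x,y level-0 pixel coordinates, `0 <= x < width_px`,
#'   `0 <= y < height_px` (half-open bounds).
#' @return character vector of tissue class labels.
#' @export
label_at <- function(slide, x, y) {
  if (any(x < 0 | x >= slide$width_px | y < 0 | y >= slide$height_px))
    stop_bounds("coordinate outside slide bounds")
  D <- slide$raster_step
  row <- floor(y / D) + 1L
  col <- floor(x / D) + 1L
  code_to_class(slide$label_raster[cbind(row, col)])
}

#' Ground-truth area-level tumour-stroma ratio
#'
#' The TSR implied by exhaustive counting of raster cells inside the
#' ground-truth ROI: tumour / (tumour + stroma_fibrosis).
#'
#' @param slide a `virtual_slide` with a ground-truth ROI.
#' @return ratio in \[0, 1\].
#' @export
gt_area_tsr <- function(slide) {
  mask <- slide$roi_mask
  if (is.null(mask)) stop_degenerate("slide has no ground-truth ROI")
  inside <- slide$label_raster[mask]
  t_n <- sum(inside == class_to_code("tumour"))
  s_n <- sum(inside == class_to_code("stroma_fibrosis"))
  if (t_n + s_n == 0)
    stop_degenerate("no tumour or stroma_fibrosis cells inside the ROI")
  t_n / (t_n + s_n)
}

#' Ground-truth sampling points for a slide
#'
#' The slide's designated ground-truth point layout, emulating a
#' pathologist's workflow: a systematic hexagonal-lattice point set
#' (RandomSpot-style) inside the 3 mm window of maximum ground-truth
#' tumour density. Deterministic per slide (seeded from the slide's own
#' seed).
#'
#' @param slide a `virtual_slide`.
#' @param n number of points (default 50, the per-slide annotation count
#'   the layout emulates).
#' @param window_px side of the square window (default 6122 px = 3 mm at
#'   0.49 micron/px).
#' @param seed RNG seed for the lattice offset.
#' @return data.frame with columns `x`, `y`, `tissue_class`.
#' @export
gt_sample_points <- function(slide, n = 50L, window_px = 6122,
                             seed = slide$seed + 1L) {
  codes <- slide$label_raster
  tum <- which(codes == class_to_code("tumour"))
  if (!length(tum)) stop_degenerate("slide has no tumour cells")
  D <- slide$raster_step
  nr <- nrow(codes)
  pts <- cbind(((tum - 1L) %/% nr + 0.5) * D, ((tum - 1L) %% nr + 0.5) * D)
  ctr <- max_density_centre(pts, window_px,
                            c(slide$width_px, slide$height_px))
  with_seed(seed, {
    xy <- randomspot_layout(ctr, window_px, n)
    data.frame(x = xy[, 1], y = xy[, 2],
               tissue_class = label_at(slide, xy[, 1], xy[, 2]),
               stringsAsFactors = FALSE)
  })
}

#' @export
print.virtual_slide <- function(x, ...) {
  cat(sprintf("<virtual_slide> %d x %d px @ %.2f um/px (raster step %d)\n",
              x$width_px, x$height_px, x$microns_per_px, x$raster_step))
  if (!is.null(x$gt_roi)) {
    cat(sprintf("  ground-truth ROI: %d-vertex polygon, %.1f%% of tissue area\n",
                nrow(x$gt_roi),
                100 * if (is.na(x$roi_area_fraction)) NA else x$roi_area_fraction))
  }
  if (!is.null(x$composition)) {
    cat("  inside-ROI composition:",
        paste(sprintf("%s=%.2f", names(x$composition), x$composition),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.virtual_slide <- function(object, ...) {
  tab <- table(factor(code_to_class(as.integer(object$label_raster)),
                      levels = tissue_classes()))
  out <- list(slide = object, cell_counts = tab,
              gt_area_tsr = tryCatch(gt_area_tsr(object),
                                     error = function(e) NA_real_))
  class(out) <- "summary.virtual_slide"
  out
}

#' @export
print.summary.virtual_slide <- function(x, ...) {
  print(x$slide)
  cat("  raster cell counts:\n")
  print(x$cell_counts)
  cat(sprintf("  ground-truth area TSR: %.3f\n", x$gt_area_tsr))
  invisible(x)
}

#' @export
plot.virtual_slide <- function(x, ...) {
  codes <- x$label_raster
  pal <- c(background = "white", non_informative = "grey80",
           tumour = "firebrick", stroma_fibrosis = "khaki",
           necrosis = "grey30", vessels = "red3",
           inflammation = "purple", lumen = "lightblue",
           mucin = "cyan3", muscle = "tan4",
           normal_epithelium = "orange")
  graphics::image(t(codes)[, nrow(codes):1], col = pal[tissue_classes()],
                  breaks = seq(-0.5, 10.5, 1), axes = FALSE, asp = nrow(codes) / ncol(codes),
                  main = "virtual slide label raster", ...)
  invisible(x)
}
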