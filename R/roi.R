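# ROI prediction from tumour points.
#
# DBSCAN over the FP-corrected tumour patch centres rejects sporadic
# noise points without multiple neighbours within eps (default 2000
# level-0 px); each remaining cluster is outlined by its convex hull,
# and the hull union is the predicted ROI, scored against ground truth
# with the Dice / F1 coefficient on a rasterized lattice.
#
# DBSCAN is implemented here directly (grid-binned neighbour search +
# breadth-first expansion over core points) with deterministic
# tie-breaking: clusters are the connected components of core points,
# numbered by their smallest point index; a border point joins the
# lowest-numbered cluster among its core neighbours. This makes the
# labelling order-independent and exactly reproducible by a brute-force
# neighbour-counting oracle.

# Neighbour lists within eps (Euclidean, inclusive), via binning into
# eps-sized cells: candidates are the 3x3 block of cells around each
# point.
neighbour_lists <- function(pts, eps) {
  n <- nrow(pts)
  cellx <- floor(pts[, 1] / eps); celly <- floor(pts[, 2] / eps)
  key <- paste(cellx, celly)
  bins <- split(seq_len(n), key)
  eps2 <- eps^2
  lapply(seq_len(n), function(i) {
    cand <- unlist(bins[paste(rep(cellx[i] + (-1:1), each = 3),
                              rep(celly[i] + (-1:1), times = 3))],
                   use.names = FALSE)
    d2 <- (pts[cand, 1] - pts[i, 1])^2 + (pts[cand, 2] - pts[i, 2])^2
    cand[d2 <= eps2]
  })
}

#' DBSCAN clustering of tumour points
#'
#' Standard DBSCAN semantics: a core point has at least `min_samples`
#' points (itself included) within `eps_px`; clusters are connected
#' components of core points plus their border points; everything else
#' is noise. Cluster ids are assigned by the smallest point index in
#' each component and border points join the lowest-id cluster among
#' their core neighbours, so the labelling is deterministic.
#'
#' @param points 2-column matrix / data.frame of point coordinates
#'   (level-0 px).
#' @param eps_px neighbourhood radius (default 2000 px).
#' @param min_samples core threshold, counting the point itself
#'   (default 3: a point plus at least two neighbours).
#' @return a `roi_clusters`: `points`, integer `labels` (0 = noise),
#'   logical `is_core`, plus the parameters.
#' @export
dbscan_cluster <- function(points, eps_px = 2000, min_samples = 3L) {
  pts <- matrix(as.numeric(as.matrix(points)), ncol = 2)
  if (eps_px <= 0) stop_parameter("eps_px must be positive")
  if (min_samples < 2) stop_parameter("min_samples must be >= 2")
  n <- nrow(pts)
  labels <- integer(n)
  if (n > 0) {
    nb <- neighbour_lists(pts, eps_px)
    is_core <- lengths(nb) >= min_samples
    cl <- 0L
    for (i in seq_len(n)) {
      if (!is_core[i] || labels[i] != 0L) next
      cl <- cl + 1L
      queue <- i; labels[i] <- cl
      while (length(queue)) {
        j <- queue[[1]]; queue <- queue[-1]
        for (k in nb[[j]]) {
          if (is_core[k] && labels[k] == 0L) {
            labels[k] <- cl
            queue <- c(queue, k)
          }
        }
      }
    }
    # border points: lowest cluster id among core neighbours
    for (i in which(!is_core)) {
      core_nb <- nb[[i]][is_core[nb[[i]]]]
      if (length(core_nb)) labels[i] <- min(labels[core_nb])
    }
  } else is_core <- logical(0)
  structure(list(points = pts, labels = labels, is_core = is_core,
                 eps_px = eps_px, min_samples = as.integer(min_samples)),
            class = "roi_clusters")
}

#' @export
print.roi_clusters <- function(x, ...) {
  k <- max(x$labels, 0L)
  cat(sprintf("<roi_clusters> %d points: %d cluster(s), %d noise (eps=%g px, min_samples=%d)\n",
              nrow(x$points), k, sum(x$labels == 0L), x$eps_px,
              x$min_samples))
  invisible(x)
}

#' Convex hulls of point clusters
#'
#' One convex polygon per cluster with at least 3 non-collinear points;
#' degenerate clusters (fewer than 3 points, or all collinear) are
#' dropped with a message. Vertices are returned in counter-clockwise
#' (positive shoelace) order.
#'
#' When the clustered points are the centres of classified patches,
#' each point evidences a square patch footprint rather than a
#' dimensionless location; `expand_px` builds the hull over the corners
#' of the `2 * expand_px` squares around the points, so the outline
#' encloses the detected regions instead of under-covering them by half
#' a patch. The pipeline uses `expand_px = patch_px / 2`; the default 0
#' gives the plain point hull.
#'
#' @param clusters a `roi_clusters`.
#' @param expand_px half-side of the square footprint each point
#'   represents (default 0).
#' @return list of 2-column vertex matrices, each with a `cluster_id`
#'   attribute.
#' @export
build_hulls <- function(clusters, expand_px = 0) {
  stopifnot(inherits(clusters, "roi_clusters"))
  out <- list()
  ids <- setdiff(sort(unique(clusters$labels)), 0L)
  for (id in ids) {
    pts <- clusters$points[clusters$labels == id, , drop = FALSE]
    if (expand_px > 0) {
      e <- expand_px
      pts <- rbind(cbind(pts[, 1] - e, pts[, 2] - e),
                   cbind(pts[, 1] + e, pts[, 2] - e),
                   cbind(pts[, 1] + e, pts[, 2] + e),
                   cbind(pts[, 1] - e, pts[, 2] + e))
    }
    h <- grDevices::chull(pts[, 1], pts[, 2])
    if (nrow(pts) < 3L || length(h) < 3L) {
      message(sprintf("build_hulls: cluster %d dropped (degenerate: %d hull vertices)",
                      id, length(h)))
      next
    }
    poly <- pts[h, , drop = FALSE]
    if (polygon_signed_area(poly) < 0) poly <- poly[nrow(poly):1, , drop = FALSE]
    colnames(poly) <- c("x", "y")
    attr(poly, "cluster_id") <- id
    out[[length(out) + 1L]] <- poly
  }
  out
}

#' Dice / F1 overlap between predicted and ground-truth ROI areas
#'
#' Both regions are rasterized on the lattice of raster-cell centres
#' (step `raster_step`) and Dice = 2|P&G| / (|P| + |G|) is computed on
#' cell counts. Both regions empty is perfect vacuous agreement (1);
#' exactly one empty is 0.
#'
#' @param pred_polygons list of predicted polygons (or a single
#'   matrix).
#' @param gt_polygon ground-truth polygon (or list).
#' @param slide_dims `c(width_px, height_px)` or a `virtual_slide`.
#' @param raster_step lattice step in level-0 px.
#' @return Dice score in \[0, 1\].
#' @export
dice_roi <- function(pred_polygons, gt_polygon, slide_dims,
                     raster_step = 32L) {
  if (inherits(slide_dims, "virtual_slide"))
    slide_dims <- c(slide_dims$width_px, slide_dims$height_px)
  if (is.matrix(pred_polygons)) pred_polygons <- list(pred_polygons)
  if (is.matrix(gt_polygon)) gt_polygon <- list(gt_polygon)
  pred_polygons <- Filter(Negate(is.null), pred_polygons)
  gt_polygon <- Filter(Negate(is.null), gt_polygon)
  if (!length(pred_polygons) && !length(gt_polygon)) return(1)
  if (!length(pred_polygons) || !length(gt_polygon)) return(0)
  nc <- ceiling(slide_dims[1] / raster_step)
  nr <- ceiling(slide_dims[2] / raster_step)
  cx <- rep((seq_len(nc) - 0.5) * raster_step, each = nr)
  cy <- rep((seq_len(nr) - 0.5) * raster_step, times = nc)
  pts <- cbind(cx, cy)
  p <- points_in_polys(pts, pred_polygons)
  g <- points_in_polys(pts, gt_polygon)
  if (!sum(p) && !sum(g)) return(1)
  2 * sum(p & g) / (sum(p) + sum(g))
}
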