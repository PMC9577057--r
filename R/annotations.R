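# Annotations: ROI polygons plus ground-truth classification points, in
# level-0 pixel coordinates. Native format is GeoJSON (RFC 7946
# structure with pixel coordinates; crs tagged "pixel:level0"): a
# Polygon feature per ROI with property role = "roi", a Point feature
# per sample with role = "sample" and its tissue_class.

#' Create an annotation set
#'
#' @param roi_polygons list of 2-column matrices (x, y level-0 px), one
#'   per ROI outline.
#' @param sample_points data.frame with columns `x`, `y`,
#'   `tissue_class` (ground-truth point classifications).
#' @return an `annotation_set`.
#' @export
annotation_set <- function(roi_polygons = list(), sample_points = NULL) {
  if (is.matrix(roi_polygons)) roi_polygons <- list(roi_polygons)
  roi_polygons <- lapply(roi_polygons, function(p) {
    p <- unname(as.matrix(p))
    if (ncol(p) != 2 || nrow(p) < 3)
      stop_format("ROI polygon must be a 2-column matrix with >= 3 vertices")
    colnames(p) <- c("x", "y"); p
  })
  if (!is.null(sample_points)) {
    if (!all(c("x", "y", "tissue_class") %in% names(sample_points)))
      stop_format("sample_points needs columns x, y, tissue_class")
    if (!all(sample_points$tissue_class %in% tissue_classes()))
      stop_format("sample_points contains unknown tissue classes")
    sample_points <- data.frame(x = as.numeric(sample_points$x),
                                y = as.numeric(sample_points$y),
                                tissue_class = as.character(sample_points$tissue_class),
                                stringsAsFactors = FALSE)
  }
  structure(list(roi_polygons = roi_polygons,
                 sample_points = sample_points,
                 coordinate_space = "level0_pixels"),
            class = "annotation_set")
}

geojson_polygon_feature <- function(poly, props) {
  ring <- lapply(seq_len(nrow(poly)), function(i) c(poly[i, 1], poly[i, 2]))
  # GeoJSON rings are closed: repeat the first vertex
  ring <- c(ring, ring[1])
  list(type = "Feature", properties = props,
       geometry = list(type = "Polygon", coordinates = list(ring)))
}

#' Write / read annotations as GeoJSON
#'
#' Coordinates are level-0 pixels (x = column, y = row); the
#' FeatureCollection carries `crs = "pixel:level0"`. ROI polygons are
#' Polygon features with `role = "roi"`; sample points are Point
#' features with `role = "sample"` and a `tissue_class` property.
#' Round-trips exactly.
#'
#' @param ann an `annotation_set`.
#' @param path file path (.geojson / .json).
#' @return `read_annotations()` an `annotation_set`;
#'   `write_annotations()` the path, invisibly.
#' @export
write_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  features <- lapply(ann$roi_polygons, geojson_polygon_feature,
                     props = list(role = "roi"))
  if (!is.null(ann$sample_points)) {
    pts <- ann$sample_points
    features <- c(features, lapply(seq_len(nrow(pts)), function(i) {
      list(type = "Feature",
           properties = list(role = "sample",
                             tissue_class = pts$tissue_class[i]),
           geometry = list(type = "Point",
                           coordinates = c(pts$x[i], pts$y[i])))
    }))
  }
  fc <- list(type = "FeatureCollection", crs = "pixel:level0",
             features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(fc$type, "FeatureCollection"))
    stop_format("annotation file is not a GeoJSON FeatureCollection")
  polys <- list(); xs <- ys <- numeric(0); cls <- character(0)
  for (ft in fc$features) {
    role <- ft$properties$role %||% ""
    geom <- ft$geometry
    if (identical(role, "roi")) {
      if (!identical(geom$type, "Polygon"))
        stop_format(paste0("ROI feature must be a Polygon, got ",
                           geom$type))
      ring <- geom$coordinates[[1]]
      m <- do.call(rbind, lapply(ring, function(v) as.numeric(unlist(v))))
      # drop the closing vertex
      if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
      colnames(m) <- c("x", "y")
      polys[[length(polys) + 1L]] <- m
    } else if (identical(role, "sample")) {
      if (!identical(geom$type, "Point"))
        stop_format("sample feature must be a Point")
      tc <- ft$properties$tissue_class
      if (is.null(tc) || !tc %in% tissue_classes())
        stop_format(paste0("unknown tissue_class in sample feature: ",
                           tc %||% "<missing>"))
      co <- as.numeric(unlist(geom$coordinates))
      xs <- c(xs, co[1]); ys <- c(ys, co[2]); cls <- c(cls, tc)
    }
  }
  pts <- if (length(xs)) data.frame(x = xs, y = ys, tissue_class = cls,
                                    stringsAsFactors = FALSE) else NULL
  annotation_set(polys, pts)
}
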