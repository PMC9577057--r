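# Slide container: <name>.png (8-bit single-channel label raster, one
# integer code per class) + <name>.json sidecar carrying dimensions,
# resolution, the ground-truth ROI polygon, composition and the code
# table. Round-trips exactly.

slide_base_path <- function(path) sub("\\.(png|json)$", "", path)

#' Write / read a virtual slide
#'
#' `write_slide()` stores the label raster as an 8-bit grayscale PNG and
#' all metadata (dimensions, resolution, raster step, ground-truth ROI,
#' composition, seed, class-code table) in a JSON sidecar next to it.
#' `read_slide()` reverses this; `read_slide(write_slide(s))` reproduces
#' `s` field by field.
#'
#' @param slide a `virtual_slide`.
#' @param path base path, or the path of either component; `.png` and
#'   `.json` extensions are added.
#' @return `write_slide()` the base path, invisibly; `read_slide()` a
#'   `virtual_slide`.
#' @export
write_slide <- function(slide, path) {
  base <- slide_base_path(path)
  png::writePNG(slide$label_raster / 255, paste0(base, ".png"))
  meta <- list(
    format = "wsisampler_virtual_slide",
    width_px = slide$width_px,
    height_px = slide$height_px,
    microns_per_px = slide$microns_per_px,
    raster_step = slide$raster_step,
    gt_roi = if (is.null(slide$gt_roi)) NULL else unname(slide$gt_roi),
    composition = as.list(slide$composition),
    outside_composition = as.list(slide$outside_composition),
    roi_area_fraction = slide$roi_area_fraction,
    normal_epi_band_px = slide$normal_epi_band_px,
    seed = slide$seed,
    class_codes = as.list(tissue_class_codes())
  )
  jsonlite::write_json(meta, paste0(base, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(base)
}

#' @rdname write_slide
#' @export
read_slide <- function(path) {
  base <- slide_base_path(path)
  png_path <- paste0(base, ".png"); json_path <- paste0(base, ".json")
  if (!file.exists(json_path))
    stop_format(paste("missing slide sidecar:", json_path))
  if (!file.exists(png_path))
    stop_format(paste("missing slide raster:", png_path))
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  if (!identical(meta$format, "wsisampler_virtual_slide"))
    stop_format("not a virtual-slide sidecar")
  codes <- unlist(meta$class_codes)
  pkg_codes <- tissue_class_codes()
  if (!all(tissue_classes() %in% names(codes)) ||
      any(codes[tissue_classes()] != pkg_codes[tissue_classes()]))
    stop_format("sidecar class-code table does not match this package")
  raster <- round(png::readPNG(png_path) * 255)
  if (length(dim(raster)) != 2L)
    stop_format("slide raster must be single-channel")
  known <- as.vector(tissue_class_codes())
  if (!all(raster %in% known))
    stop_format(paste0("unknown tissue class code in raster: ",
                       paste(setdiff(unique(as.vector(raster)), known),
                             collapse = ", ")))
  gt_roi <- if (is.null(meta$gt_roi)) NULL else {
    m <- matrix(as.numeric(meta$gt_roi), ncol = 2)
    colnames(m) <- c("x", "y"); m
  }
  comp <- if (length(meta$composition)) unlist(meta$composition) else NULL
  outc <- if (length(meta$outside_composition)) unlist(meta$outside_composition) else NULL
  new_virtual_slide(meta$width_px, meta$height_px, meta$microns_per_px,
                    meta$raster_step,
                    matrix(as.integer(raster), nrow = nrow(raster)),
                    gt_roi, comp, outc,
                    meta$roi_area_fraction %||% NA_real_,
                    meta$normal_epi_band_px %||% NA_real_,
                    meta$seed %||% NA_integer_)
}
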