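# Slides built in code for tests.

# Uniform single-class slide, n_cells x n_cells raster cells.
uniform_slide <- function(class = "stroma_fibrosis", n_cells = 200L,
                          raster_step = 32L, gt_roi = NULL) {
  as_virtual_slide(matrix(class, n_cells, n_cells),
                   raster_step = raster_step, gt_roi = gt_roi)
}

# A small generated slide for fast tests.
small_slide <- function(seed = 1L, ...) {
  generate_slide(6400, 6400, seed = seed, ...)
}

perfect_config <- function(...) {
  pipeline_config(accuracy = 1, normal_epi_to_tumour_rate = 0,
                  fp_sensitivity = 1, fp_specificity = 1, ...)
}
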