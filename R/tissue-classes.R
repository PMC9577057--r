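# Tissue class vocabulary.
#
# Eleven ground-truth labels: the nine classes a patch classifier emits
# (the annotation vocabulary of colorectal H&E pathology) plus two
# ground-truth-only labels: `background` (no tissue under the patch
# centre) and `normal_epithelium` (epithelium outside the tumour ROI,
# the documented source of false-positive tumour calls). A 9-class
# classifier never emits the latter two.

.classifier_classes <- c(
  "non_informative", "tumour", "stroma_fibrosis", "necrosis", "vessels",
  "inflammation", "lumen", "mucin", "muscle"
)

.tissue_classes <- c("background", .classifier_classes, "normal_epithelium")

# Integer codes used in the label raster and the PNG container.
.class_codes <- stats::setNames(seq_along(.tissue_classes) - 1L, .tissue_classes)

#' Tissue class vocabulary
#'
#' `tissue_classes()` returns the 11 ground-truth labels known to the
#' virtual-slide model; `classifier_classes()` the 9 labels a patch
#' classifier can emit (`background` and `normal_epithelium` are
#' ground-truth-only).
#'
#' @return character vector of class labels.
#' @export
tissue_classes <- function() .tissue_classes

#' @rdname tissue_classes
#' @export
classifier_classes <- function() .classifier_classes

#' Integer codes for tissue classes
#'
#' The code table used by the label raster and the PNG slide container
#' (8-bit, one code per class).
#'
#' @return named integer vector mapping class label to code.
#' @export
tissue_class_codes <- function() .class_codes

class_to_code <- function(cls) {
  code <- .class_codes[cls]
  if (anyNA(code)) stop_format(paste0("unknown tissue class: ",
    paste(unique(cls[is.na(code)]), collapse = ", ")))
  unname(code)
}

code_to_class <- function(code) {
  bad <- !(code %in% .class_codes)
  if (any(bad)) stop_format(paste0("unknown tissue class code: ",
    paste(unique(code[bad]), collapse = ", ")))
  .tissue_classes[code + 1L]
}
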