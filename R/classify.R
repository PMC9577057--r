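# Simulated patch classification.
#
# A real 9-class CNN is replaced by a row-stochastic confusion matrix:
# each ground-truth class (the 9 classifier classes plus the two
# ground-truth-only labels) defines a probability distribution over the
# 9 output classes. The documented failure mode — normal epithelium
# outside the tumour ROI being called tumour — gets its own row, and a
# second, binary stage (the false-positive corrector) undoes those
# calls with configurable sensitivity/specificity. Real models can be
# substituted through the same contract: any function mapping patch
# coordinates + slide to one of the 9 labels.

#' Build a simulated 9-class confusion specification
#'
#' Each of the 9 true classifier classes gets `overall_accuracy` on the
#' diagonal; the remaining mass is spread over the other classes, with
#' extra weight on the tumour/stroma_fibrosis pair (the dominant
#' confusion in colorectal H&E patch classification). The
#' `normal_epithelium` row emits `tumour` with probability
#' `normal_epi_to_tumour_rate` and otherwise splits between
#' `non_informative` and `stroma_fibrosis`; the `background` row maps
#' to `non_informative` with probability 1.
#'
#' @param overall_accuracy diagonal probability for the 9 true classes
#'   (default 0.79, a typical patch-classifier operating point).
#' @param normal_epi_to_tumour_rate probability that a
#'   normal-epithelium patch is called tumour (default 0.3).
#' @return a `confusion_spec`: list with `classes` (the 11 input rows)
#'   and `matrix` (11 x 9, rows summing to 1).
#' @export
make_confusion <- function(overall_accuracy = 0.79,
                           normal_epi_to_tumour_rate = 0.3) {
  if (overall_accuracy < 0 || overall_accuracy > 1)
    stop_parameter("overall_accuracy must lie in [0, 1]")
  if (normal_epi_to_tumour_rate < 0 || normal_epi_to_tumour_rate > 1)
    stop_parameter("normal_epi_to_tumour_rate must lie in [0, 1]")
  out_cls <- classifier_classes()
  m <- matrix(0, nrow = 11, ncol = 9,
              dimnames = list(tissue_classes(), out_cls))
  off <- 1 - overall_accuracy
  for (cls in out_cls) {
    others <- setdiff(out_cls, cls)
    m[cls, cls] <- overall_accuracy
    partner <- switch(cls, tumour = "stroma_fibrosis",
                      stroma_fibrosis = "tumour", NULL)
    if (!is.null(partner)) {
      m[cls, partner] <- off * 0.5
      rest <- setdiff(others, partner)
      m[cls, rest] <- off * 0.5 / length(rest)
    } else {
      m[cls, others] <- off / length(others)
    }
  }
  m["background", "non_informative"] <- 1
  m["normal_epithelium", "tumour"] <- normal_epi_to_tumour_rate
  m["normal_epithelium", c("non_informative", "stroma_fibrosis")] <-
    (1 - normal_epi_to_tumour_rate) / 2
  structure(list(classes = tissue_classes(), matrix = m),
            class = "confusion_spec")
}

#' False-positive correction stage specification
#'
#' @param sensitivity probability a true tumour-epithelium patch is
#'   retained as tumour.
#' @param specificity probability a normal-epithelium patch is
#'   relabelled away from tumour.
#' @return an `fp_stage_spec`. Defaults 0.927 for both, the single
#'   printed accuracy of the binary corrector this stage simulates.
#' @export
fp_stage <- function(sensitivity = 0.927, specificity = 0.927) {
  if (sensitivity < 0 || sensitivity > 1 || specificity < 0 || specificity > 1)
    stop_parameter("sensitivity and specificity must lie in [0, 1]")
  structure(list(sensitivity = sensitivity, specificity = specificity),
            class = "fp_stage_spec")
}

#' Bundle a confusion spec and an FP stage
#'
#' @param confusion a `confusion_spec`.
#' @param fp an `fp_stage_spec`.
#' @return a `classifier_bundle`.
#' @export
classifier_bundle <- function(confusion = make_confusion(),
                              fp = fp_stage()) {
  stopifnot(inherits(confusion, "confusion_spec"),
            inherits(fp, "fp_stage_spec"))
  structure(list(confusion = confusion, fp = fp),
            class = "classifier_bundle")
}

#' A perfect classifier bundle (identity confusion, perfect FP stage)
#' @return a `classifier_bundle`.
#' @export
perfect_classifier <- function() {
  classifier_bundle(make_confusion(1, 0), fp_stage(1, 1))
}

#' Simulate 9-class classification of patches
#'
#' Sets each patch's `gt_class` to the raster label under its centre
#' pixel and samples `pred_class` (and `pred_raw`, the
#' pre-FP-correction copy) from the confusion row of that ground
#' truth. Only the 9 classifier classes are ever emitted.
#'
#' @param patches patch table.
#' @param slide a `virtual_slide`.
#' @param confusion a `confusion_spec`.
#' @return the patch table with `gt_class`, `pred_class`, `pred_raw`
#'   filled in.
#' @export
simulate_classify <- function(patches, slide, confusion) {
  if (!nrow(patches)) return(patches)
  cc <- patch_centres(patches)
  gt <- label_at(slide, cc[, 1], cc[, 2])
  miss <- setdiff(unique(gt), rownames(confusion$matrix))
  if (length(miss))
    abort_wsis(paste0("ground-truth class missing from confusion spec: ",
                      paste(miss, collapse = ", ")),
               "wsis_configuration_error")
  pred <- character(nrow(patches))
  out_cls <- colnames(confusion$matrix)
  for (cls in unique(gt)) {
    idx <- which(gt == cls)
    pred[idx] <- sample(out_cls, length(idx), replace = TRUE,
                        prob = confusion$matrix[cls, ])
  }
  patches$gt_class <- gt
  patches$pred_class <- pred
  patches$pred_raw <- pred
  patches$fp_corrected <- FALSE
  patches
}

#' Two-stage false-positive correction
#'
#' Operates only on patches currently predicted `tumour`: a patch whose
#' ground truth is `normal_epithelium` is relabelled
#' `normal_epithelium` with probability `specificity`; a patch whose
#' ground truth is `tumour` keeps the label with probability
#' `sensitivity` and is otherwise relabelled `normal_epithelium`.
#' Tumour-predicted patches with any other ground truth, and all
#' non-tumour predictions, are untouched. Relabelled patches get the
#' `fp_corrected` flag; removed false positives stay in the table (as
#' `normal_epithelium`) so the correction can be audited downstream.
#'
#' @param patches classified patch table.
#' @param fp an `fp_stage_spec`.
#' @return the patch table with corrected `pred_class`.
#' @export
fp_correct <- function(patches, fp) {
  if (!nrow(patches)) return(patches)
  tum <- which(!is.na(patches$pred_class) & patches$pred_class == "tumour")
  for (i in tum) {
    gt <- patches$gt_class[i]
    if (identical(gt, "normal_epithelium")) {
      if (stats::runif(1) < fp$specificity) {
        patches$pred_class[i] <- "normal_epithelium"
        patches$fp_corrected[i] <- TRUE
      }
    } else if (identical(gt, "tumour")) {
      if (stats::runif(1) >= fp$sensitivity) {
        patches$pred_class[i] <- "normal_epithelium"
        patches$fp_corrected[i] <- TRUE
      }
    }
  }
  patches
}

#' Percentage of predicted tumour inside the ground-truth ROI
#'
#' @param patches classified patch table.
#' @param gt_roi ground-truth ROI polygon (2-col matrix).
#' @param which_pred column to evaluate: `"pred_class"`
#'   (post-FP-correction) or `"pred_raw"` (pre-correction).
#' @return percentage in \[0, 100\].
#' @export
tumour_inside_fraction <- function(patches, gt_roi,
                                   which_pred = c("pred_class", "pred_raw")) {
  which_pred <- match.arg(which_pred)
  pred <- patches[[which_pred]]
  tum <- which(!is.na(pred) & pred == "tumour")
  if (!length(tum))
    stop_undefined("no tumour-predicted patches: fraction undefined")
  cc <- patch_centres(patches[tum, , drop = FALSE])
  100 * mean(points_in_polys(cc, gt_roi))
}
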