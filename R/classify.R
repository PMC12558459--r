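#' Published threshold diagnostic rules
#'
#' Two single-feature decision criteria distilled from the classification-
#' tree analysis of the method's validation cohort: `LSB14` diagnoses
#' neglect when the count of missed left circles on bilateral trials is at
#' least 14; `KA017` diagnoses neglect when the overall asymmetry coefficient
#' is at least 0.17.
#'
#' @param sheet a `keen_scoresheet` (or list carrying `LSB` / `KA_all`)
#' @param rule "LSB14" or "KA017"
#' @return "neglect" or "no_neglect"
#' @examples
#' classify_rule(list(LSB = 14), "LSB14")   # "neglect"
#' classify_rule(list(KA_all = 0.1699), "KA017")  # "no_neglect"
#' @export
classify_rule <- function(sheet, rule = c("LSB14", "KA017")) {
  rule <- match.arg(rule)
  if (rule == "LSB14") {
    lsb <- sheet$LSB
    if (is.null(lsb) || is.na(lsb)) stop("LSB is missing; cannot classify")
    if (lsb >= 14) "neglect" else "no_neglect"
  } else {
    ka <- sheet$KA_all
    if (is.null(ka) || is.na(ka))
      stop("KA_all is undefined; cannot classify with the KA017 rule")
    if (ka >= 0.17) "neglect" else "no_neglect"
  }
}

#' Build a confusion matrix (positive class = neglect)
#' @param truth,predicted vectors of "neglect"/"no_neglect"
#' @return a `keen_confusion`: list with `TP`, `FP`, `FN`, `TN`
#' @export
confusion_matrix <- function(truth, predicted) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  stopifnot(length(truth) == length(predicted),
            all(truth %in% CLASS_LEVELS), all(predicted %in% CLASS_LEVELS))
  structure(list(
    TP = sum(truth == "neglect" & predicted == "neglect"),
    FP = sum(truth == "no_neglect" & predicted == "neglect"),
    FN = sum(truth == "neglect" & predicted == "no_neglect"),
    TN = sum(truth == "no_neglect" & predicted == "no_neglect")),
    class = "keen_confusion")
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Classification metrics from a confusion matrix
#'
#' Standard definitions with neglect as the positive class: accuracy,
#' precision = TP/(TP+FP), recall = sensitivity = TP/(TP+FN),
#' F1 = harmonic mean of precision and recall, specificity = TN/(TN+FP).
#' Ratios with a zero denominator are reported as `NA` rather than raised.
#'
#' @param cm a `keen_confusion` (or list with TP/FP/FN/TN)
#' @return named list of the six metrics
#' @export
confusion_metrics <- function(cm) {
  tot <- cm$TP + cm$FP + cm$FN + cm$TN
  if (tot == 0) stop("empty confusion matrix")
  precision <- safe_ratio(cm$TP, cm$TP + cm$FP)
  recall <- safe_ratio(cm$TP, cm$TP + cm$FN)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  list(accuracy = (cm$TP + cm$TN) / tot,
       precision = precision,
       recall = recall,
       F1 = f1,
       sensitivity = recall,
       specificity = safe_ratio(cm$TN, cm$TN + cm$FP))
}

#' Extract a feature table from a list of score sheets
#'
#' `set = "raw"` yields the six error counts used by the count-based
#' classification models (RSU, LSU, RSB, LSB, RH, LH); `set = "coef"` yields
#' the seven coefficients.
#'
#' @param sheets list of `keen_scoresheet`
#' @param set "raw" or "coef"
#' @return data.frame, one row per sheet
#' @export
cohort_features <- function(sheets, set = c("raw", "coef")) {
  set <- match.arg(set)
  cols <- if (set == "raw") c("RSU", "LSU", "RSB", "LSB", "RH", "LH")
          else c("KA_bilateral", "KPrR_bilateral", "KPrL_bilateral",
                 "KA_all", "KEf_all", "KPrR_all", "KPrL_all")
  out <- as.data.frame(lapply(cols, function(nm)
    vapply(sheets, function(s) as.numeric(s[[nm]]), numeric(1))))
  names(out) <- cols
  out
}
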