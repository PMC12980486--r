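#' Rejection sentinel label
#'
#' Label assigned to samples the classifier declines to call because the
#' confidence margin falls below the active threshold.
#' @export
REJECTED <- "REJECTED"

#' Confidence margin of a probability vector
#'
#' The difference between the top two predicted class probabilities; 0 for
#' a tie between the two best classes, 1 for a fully confident prediction.
#'
#' @param probs numeric probability vector over >= 2 classes.
#' @return The margin, in `[0, 1]`.
#' @examples
#' confidence_margin(c(0.7, 0.2, 0.1))  # 0.5
#' @export
confidence_margin <- function(probs) {
  if (length(probs) < 2) {
    abort_lcms("margin needs at least 2 classes", "lcmsnet_parameter_error")
  }
  s <- sort(probs, decreasing = TRUE)
  s[1] - s[2]
}

#' Classify with a reject option
#'
#' Predicts the argmax class unless the confidence margin is below
#' `threshold`, in which case the sample is rejected. A threshold of 0
#' never rejects. Ties in the argmax are broken toward the lowest class
#' index.
#'
#' @param probs probability vector, or `N x n_classes` matrix of
#'   probability vectors (columns named by class).
#' @param threshold margin threshold in `[0, 1]`.
#' @param class_order class labels for the columns of `probs`; defaults to
#'   `colnames(probs)`.
#' @param sample_id optional identifiers.
#' @return A data.frame of class `prediction_result` with columns
#'   `sample_id`, `predicted` ([REJECTED] where below threshold), `margin`,
#'   and one probability column per class.
#' @export
classify_with_reject <- function(probs, threshold = 0, class_order = NULL,
                                 sample_id = NULL) {
  check_number(threshold, "threshold", lower = 0, upper = 1)
  if (!is.matrix(probs)) probs <- matrix(probs, nrow = 1)
  if (is.null(class_order)) class_order <- colnames(probs)
  if (is.null(class_order)) class_order <- sprintf("class%d", seq_len(ncol(probs)))
  if (is.null(sample_id)) {
    sample_id <- if (!is.null(rownames(probs))) rownames(probs)
    else sprintf("sample%d", seq_len(nrow(probs)))
  }
  margin <- apply(probs, 1, confidence_margin)
  top <- apply(probs, 1, which.max)      # ties -> lowest index
  predicted <- ifelse(margin < threshold, REJECTED, class_order[top])
  out <- data.frame(sample_id = sample_id, predicted = predicted,
                    margin = margin, stringsAsFactors = FALSE)
  pm <- as.data.frame(probs)
  names(pm) <- paste0("p_", class_order)
  out <- cbind(out, pm)
  rownames(out) <- NULL
  class(out) <- c("prediction_result", "data.frame")
  out
}

#' Select a reject threshold by maximizing specificity
#'
#' Evaluates every candidate threshold on a validation set: samples whose
#' margin falls below the candidate are rejected and excluded from the
#' metric; the candidate maximizing macro one-vs-rest specificity over the
#' accepted samples wins. Candidates that reject the entire validation set
#' are disqualified; ties break toward the smallest threshold (fewest
#' rejections).
#'
#' @param probs `N x n_classes` probability matrix for the validation set.
#' @param labels true labels of the validation samples.
#' @param candidates candidate thresholds in `[0, 1]`
#'   (default `seq(0, 0.95, by = 0.05)`).
#' @param class_order class labels for the columns of `probs`.
#' @return The selected threshold, with attribute `"specificity"` (the
#'   macro specificity it achieved) and `"table"` (per-candidate results).
#' @export
select_threshold <- function(probs, labels, candidates = seq(0, 0.95, by = 0.05),
                             class_order = NULL) {
  if (any(candidates < 0 | candidates > 1)) {
    abort_lcms("candidate thresholds must lie in [0, 1]", "lcmsnet_parameter_error")
  }
  if (!is.matrix(probs)) probs <- matrix(probs, nrow = 1)
  if (!nrow(probs)) abort_lcms("validation set is empty", "lcmsnet_parameter_error")
  if (is.null(class_order)) class_order <- colnames(probs)
  classes <- sort(unique(c(labels, class_order)))
  res <- classify_with_reject(probs, threshold = 0, class_order = class_order)
  tab <- data.frame(threshold = sort(candidates), specificity = NA_real_,
                    n_rejected = NA_integer_)
  for (i in seq_len(nrow(tab))) {
    t <- tab$threshold[i]
    acc <- res$margin >= t
    tab$n_rejected[i] <- sum(!acc)
    if (!any(acc)) next                  # disqualified: rejects everything
    mm <- suppressWarnings(
      macro_metrics(labels[acc], res$predicted[acc], classes = classes)
    )
    tab$specificity[i] <- mm$macro$specificity
  }
  ok <- !is.na(tab$specificity)
  if (!any(ok)) {
    abort_lcms("all candidate thresholds reject the entire validation set",
               "lcmsnet_threshold_error")
  }
  best <- which(ok)[which.max(tab$specificity[ok])]  # ties -> smallest threshold
  out <- tab$threshold[best]
  attr(out, "specificity") <- tab$specificity[best]
  attr(out, "table") <- tab
  out
}
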