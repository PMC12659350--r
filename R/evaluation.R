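#' Precision, recall and F1 from a binary tally
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `F1 = 2 * recall * precision / (recall + precision)`. Empty denominators
#' follow the 0/0 -> 0 convention so degenerate classes remain scorable.
#'
#' @param tp,fp,fn,tn non-negative counts (`tn` is carried for completeness).
#' @return named numeric vector `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(tp, fp = 0, fn = 0, tn = 0) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * recall * precision / (recall + precision)
  } else 0
  c(precision = precision, recall = recall, f1 = f1)
}

#' Confusion matrix and micro-averaged accuracy
#'
#' `matrix[i, j]` counts items with true label i predicted as j, over the
#' ontology's label order; micro-averaged accuracy pools all classes:
#' trace divided by total.
#'
#' @param predicted,truth equal-length aligned label vectors.
#' @param ontology a [family_ontology], or a character vector of labels
#'   fixing the matrix order.
#' @return list with `matrix` (K x K) and `micro_accuracy`.
#' @export
confusion_and_micro_accuracy <- function(predicted, truth, ontology) {
  labels <- if (inherits(ontology, "family_ontology")) ontology$labels else
    as.character(ontology)
  if (length(predicted) != length(truth)) stop("label vectors differ in length")
  outside <- setdiff(unique(c(predicted, truth)), labels)
  if (length(outside)) {
    stop("label(s) outside the ontology: ", paste(outside, collapse = ", "))
  }
  m <- table(factor(truth, levels = labels), factor(predicted, levels = labels))
  m <- unclass(m)
  names(dimnames(m)) <- c("truth", "predicted")
  list(matrix = m,
    micro_accuracy = if (length(truth)) sum(diag(m)) / length(truth) else NaN)
}

#' ROC and precision-recall curves from scores
#'
#' Builds both curves by sweeping every distinct score value as a
#' threshold (ties grouped: one curve point per distinct value), plus the
#' trivial endpoints. Works with either polarity: forest-style scores
#' where larger means more positive (`polarity = "high"`), or e-values
#' where smaller does (`polarity = "low"`). Truth ids missing from
#' `scores` — e.g. queries a third-party tool returned no hit for — are
#' imputed the worst possible score so curves cover the full truth set.
#' AUROC and AUPR are trapezoidal.
#'
#' @param scores named numeric vector (names = ids).
#' @param truth named logical vector over the evaluation universe; needs
#'   at least one positive and one negative.
#' @param polarity `"high"` (default) or `"low"`.
#' @return list with `roc` and `pr` (data.frames `threshold`, `x`, `y`),
#'   `auroc`, `aupr`.
#' @export
roc_pr_curves <- function(scores, truth, polarity = c("high", "low")) {
  polarity <- match.arg(polarity)
  if (is.null(names(truth))) stop("truth must be a named logical vector")
  ids <- names(truth)
  tr <- as.logical(truth)
  if (anyNA(tr)) stop("truth contains NA")
  if (!any(tr) || all(tr)) {
    stop("truth needs at least one positive and one negative")
  }
  s <- rep(NA_real_, length(tr))
  names(s) <- ids
  known <- intersect(names(scores), ids)
  s[known] <- scores[known]
  imputed <- sum(is.na(s))
  s[is.na(s)] <- if (polarity == "high") -Inf else Inf
  sc <- if (polarity == "high") s else -s

  ord <- order(sc, decreasing = TRUE)
  sc_ord <- sc[ord]
  tr_ord <- tr[ord]
  # one point per distinct score: take the last index of each tie group
  grp_end <- which(c(sc_ord[-1] != sc_ord[-length(sc_ord)], TRUE))
  tp <- unname(cumsum(tr_ord)[grp_end])
  fp <- unname(cumsum(!tr_ord)[grp_end])
  thr <- unname(sc_ord[grp_end])
  if (polarity == "low") thr <- -thr
  P <- sum(tr)
  N <- sum(!tr)

  roc <- data.frame(threshold = c(Inf * if (polarity == "high") 1 else -1, thr),
    x = c(0, fp / N), y = c(0, tp / P))
  pr <- data.frame(threshold = roc$threshold,
    x = c(0, tp / P), y = c(1, tp / (tp + fp)))
  trapezoid <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  list(roc = roc, pr = pr,
    auroc = trapezoid(roc$x, roc$y), aupr = trapezoid(pr$x, pr$y),
    n_imputed = imputed)
}
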