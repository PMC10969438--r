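# Evaluation metrics and the SGD step-size stability diagnostic.

#' Confusion-matrix classification metrics
#'
#' Binary metrics from predictions and (optionally) scores: accuracy
#' `O/N`, sensitivity `T/(T+f)`, specificity `C/(C+P)`, the precision-type
#' rate `T/(T+P)` (reported as `rate_R`), F1 as the harmonic mean of
#' precision and recall, and AUC by trapezoidal integration of the ROC
#' curve over all score thresholds.  Undefined ratios (zero denominators,
#' single-class truth for AUC) are reported as `NA`, never silently
#' propagated as `NaN`.
#'
#' @param y_true,y_pred Vectors of labels (logical, 0/1, or characters);
#'   `positive` names the positive class.
#' @param scores Optional positive-class scores in `[0, 1]` for AUC.
#' @param positive Positive-class label (default: "malignant" when
#'   present, otherwise the maximum label).
#' @return List of class `metrics_report`.
#' @export
compute_metrics <- function(y_true, y_pred, scores = NULL, positive = NULL) {
  stopifnot(length(y_true) == length(y_pred))
  if (is.null(positive)) {
    positive <- if ("malignant" %in% y_true) "malignant" else max(y_true)
  }
  yt <- y_true == positive
  yp <- y_pred == positive
  TP <- sum(yt & yp); FN <- sum(yt & !yp)
  TN <- sum(!yt & !yp); FP <- sum(!yt & yp)
  N <- length(yt); O <- TP + TN
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  precision <- safe_div(TP, TP + FP)
  recall <- safe_div(TP, TP + FN)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) NA_real_
        else 2 * precision * recall / (precision + recall)
  auc <- if (!is.null(scores)) auc_roc(scores, yt) else NA_real_
  structure(list(accuracy = O / N,
                 sensitivity = recall,
                 specificity = safe_div(TN, TN + FP),
                 rate_R = precision,
                 f1 = f1,
                 auc_roc = auc,
                 counts = c(T = TP, f = FN, C = TN, P = FP, O = O, N = N)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  for (nm in setdiff(names(x), "counts")) {
    cat(sprintf("%-12s %s\n", nm, format(round(x[[nm]], 4))))
  }
  cat("counts:", paste(names(x$counts), x$counts, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Area under the ROC curve
#'
#' Trapezoidal integration of the ROC curve swept over every distinct
#' score threshold.  Invariant under strictly monotone transforms of the
#' scores; equal scores everywhere give the chance value 0.5.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Logical or 0/1 truth.
#' @return AUC in `[0, 1]`, or `NA` if only one class is present.
#' @export
auc_roc <- function(scores, labels) {
  labels <- as.logical(labels > 0 | labels == TRUE)
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # group ties so threshold sweeps move along trapezoid diagonals
  grp <- cumsum(c(TRUE, diff(s) != 0))
  tp_g <- tapply(l, grp, sum); fp_g <- tapply(!l, grp, sum)
  tpr <- c(0, cumsum(tp_g) / np)
  fpr <- c(0, cumsum(fp_g) / nn)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Step-size stability diagnostic for SGD on a quadratic model
#'
#' For the linearized update `theta_new = (I - mu R0) theta_old + const`,
#' convergence requires the spectral radius of `I - mu R0` to stay below
#' 1; for symmetric positive-definite `R0` that holds exactly for
#' `0 < mu < 2 / lambda_max(R0)`.
#'
#' @param R0 Symmetric (curvature/Hessian) matrix; non-symmetric inputs
#'   are symmetrized with a warning.
#' @param mu Optional step size at which to report the spectral radius.
#' @return List of class `stability_report` with `eigenvalues`,
#'   `max_stable_step` and (given `mu`) `spectral_radius`.
#' @export
max_stable_step <- function(R0, mu = NULL) {
  R0 <- as.matrix(R0)
  if (max(abs(R0 - t(R0))) > 1e-8 * max(1, max(abs(R0)))) {
    warning("R0 is not symmetric; symmetrizing")
    R0 <- (R0 + t(R0)) / 2
  }
  ev <- eigen(R0, symmetric = TRUE, only.values = TRUE)$values
  lam_max <- max(ev)
  report <- list(eigenvalues = ev,
                 max_stable_step = if (lam_max > 0) 2 / lam_max else Inf,
                 spectral_radius = if (is.null(mu)) NA_real_
                                   else max(abs(1 - mu * ev)),
                 mu = mu)
  structure(report, class = "stability_report")
}
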