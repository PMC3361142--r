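# Evaluation statistics for comparing similarity measures: ROC/AUC against a
# labelled positive/negative pair set, confusion-matrix precision/accuracy at
# a threshold, and Pearson correlation between score vectors. NA scores are
# sentinels for undefined similarities and are excluded before any statistic.

as_labeled <- function(data) {
  data <- as.data.frame(data)
  stopifnot(all(c("score", "label") %in% names(data)))
  if (is.logical(data$label))
    data$label <- ifelse(data$label, "positive", "negative")
  stopifnot(all(data$label %in% c("positive", "negative")))
  drop <- is.na(data$score)
  if (any(drop)) data <- data[!drop, , drop = FALSE]
  data
}

#' ROC curve of a labelled score set
#'
#' Sweeps thresholds over the distinct scores in descending order (ties
#' grouped), classifying `score >= threshold` as positive, and reports the
#' false/true positive rate at each threshold, beginning at (0, 0) and ending
#' at (1, 1).
#'
#' @param data data.frame with numeric `score` and `label` in
#'   `{"positive", "negative"}` (or logical); `NA` scores are dropped.
#' @return data.frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(data) {
  data <- as_labeled(data)
  pos <- data$label == "positive"
  if (!any(pos) || all(pos))
    stop("ROC needs both positive and negative labels")
  th <- sort(unique(data$score), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(data$score[pos] >= t), 0)
  fpr <- vapply(th, function(t) mean(data$score[!pos] >= t), 0)
  data.frame(threshold = c(Inf, th), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Area under the ROC curve
#'
#' `"trapezoid"` integrates [roc_curve()]; `"rank"` computes the equivalent
#' tie-corrected Mann-Whitney statistic. The two agree to machine precision
#' and serve as mutual cross-checks.
#'
#' @inheritParams roc_curve
#' @param method `"trapezoid"` or `"rank"`.
#' @return the AUC in \[0, 1\].
#' @export
auc <- function(data, method = c("trapezoid", "rank")) {
  method <- match.arg(method)
  data <- as_labeled(data)
  pos <- data$label == "positive"
  if (!any(pos) || all(pos))
    stop("AUC needs both positive and negative labels")
  if (method == "trapezoid") {
    rc <- roc_curve(data)
    sum(diff(rc$fpr) * (utils::head(rc$tpr, -1) + utils::tail(rc$tpr, -1)) / 2)
  } else {
    r <- rank(data$score)                 # average ranks handle ties
    n1 <- sum(pos)
    n0 <- sum(!pos)
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
}

#' Precision and accuracy at a classification threshold
#'
#' Scores at or above the threshold are predicted positive. When no pair is
#' predicted positive, precision is `NA`. The default threshold maximises
#' Youden's J (tpr - fpr) on the ROC curve — a generic operating point, not a
#' published one.
#'
#' @inheritParams roc_curve
#' @param threshold classification threshold in \[0, 1\]; `NULL` picks the
#'   Youden-J optimum.
#' @return named numeric vector `c(precision, accuracy, threshold)`.
#' @export
precision_accuracy <- function(data, threshold = NULL) {
  data <- as_labeled(data)
  if (is.null(threshold)) {
    rc <- roc_curve(data)
    rc <- rc[is.finite(rc$threshold), , drop = FALSE]
    threshold <- rc$threshold[which.max(rc$tpr - rc$fpr)]
  }
  pred <- data$score >= threshold
  pos <- data$label == "positive"
  tp <- sum(pred & pos)
  fp <- sum(pred & !pos)
  tn <- sum(!pred & !pos)
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  c(precision = precision, accuracy = (tp + tn) / nrow(data),
    threshold = threshold)
}

#' Pearson correlation between two score vectors
#'
#' Pairs where either vector is `NA` (undefined-score sentinels) are removed
#' first; at least 3 complete pairs and nonzero variance on both sides are
#' required.
#'
#' @param x,y numeric vectors of equal length.
#' @return the sample Pearson correlation coefficient.
#' @export
pearson_similarity <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(x, y)
}

#' Random negative protein-pair set
#'
#' Draws unordered protein pairs uniformly at random from the annotated
#' proteins, excluding a given positive set and self-pairs — the standard
#' recipe for building a negative control matched in size to a positive
#' interaction set.
#'
#' @param proteins character vector of (annotated) protein identifiers.
#' @param n_pairs number of negative pairs to draw.
#' @param exclude optional data.frame of pairs to avoid (first two columns).
#' @param seed integer seed.
#' @return data.frame `protein_a`, `protein_b`.
#' @export
negative_pairs <- function(proteins, n_pairs, exclude = NULL, seed = 1) {
  stopifnot(length(proteins) >= 2)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  banned <- character()
  if (!is.null(exclude)) {
    ex <- as.data.frame(exclude)
    banned <- c(paste(ex[[1]], ex[[2]], sep = "\r"),
                paste(ex[[2]], ex[[1]], sep = "\r"))
  }
  out <- matrix(character(), ncol = 2)
  guard <- 0L
  while (nrow(out) < n_pairs) {
    a <- sample(proteins, n_pairs, replace = TRUE)
    b <- sample(proteins, n_pairs, replace = TRUE)
    ok <- a != b & !(paste(a, b, sep = "\r") %in% banned)
    out <- unique(rbind(out, cbind(a[ok], b[ok])))
    guard <- guard + 1L
    if (guard > 1000L) stop("cannot draw enough distinct negative pairs")
  }
  out <- out[seq_len(n_pairs), , drop = FALSE]
  data.frame(protein_a = out[, 1], protein_b = out[, 2])
}
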