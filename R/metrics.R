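#' Evaluate a probability table
#'
#' Computes the reporting surface used throughout: overall accuracy,
#' macro-averaged one-vs-rest sensitivity TP/(TP+FN) and specificity
#' TN/(TN+FP) (all in percent), per-class one-vs-rest ROC AUC (rank-based,
#' equivalent to the trapezoidal ROC area with midpoint tie handling), and
#' the confusion matrix with truth as rows and prediction as columns.
#' Predictions are the row-wise argmax, lowest index on ties. Truth
#' classes with zero samples are excluded from the macro averages with a
#' warning.
#'
#' @param probs a [ProbabilityTable-class].
#' @return A [MetricsReport-class].
#' @export
evaluateMetrics <- function(probs) {
  P <- probs@probs
  truth <- probs@truth
  K <- ncol(P)
  labs <- colnames(P)
  pred <- max.col(P, ties.method = "first") - 1L
  conf <- matrix(0L, K, K, dimnames = list(truth = labs, pred = labs))
  for (i in seq_along(truth))
    conf[truth[i] + 1L, pred[i] + 1L] <- conf[truth[i] + 1L, pred[i] + 1L] + 1L
  acc <- 100 * sum(diag(conf)) / length(truth)
  sens <- spec <- auc <- rep(NA_real_, K)
  names(auc) <- labs
  for (k in seq_len(K)) {
    pos <- truth == k - 1L
    tp <- sum(pred[pos] == k - 1L)
    fn <- sum(pos) - tp
    fp <- sum(pred[!pos] == k - 1L)
    tn <- sum(!pos) - fp
    if (sum(pos) > 0L) sens[k] <- 100 * tp / (tp + fn)
    if (sum(!pos) > 0L) spec[k] <- 100 * tn / (tn + fp)
    auc[k] <- .rankAUC(P[, k], pos)
  }
  empty <- which(tabulate(truth + 1L, K) == 0L)
  if (length(empty))
    warning(sprintf("class(es) with zero truth samples excluded from macro averages: %s",
                    paste(labs[empty], collapse = ", ")))
  new("MetricsReport", accuracy = acc,
      sensitivity = mean(sens, na.rm = TRUE),
      specificity = mean(spec, na.rm = TRUE),
      perClassAUC = auc, confusion = conf)
}

# one-vs-rest AUC of score for the positive set; Mann-Whitney rank form,
# identical to the trapezoidal ROC area with midpoint interpolation at ties
.rankAUC <- function(score, pos) {
  nP <- sum(pos); nN <- sum(!pos)
  if (nP == 0L || nN == 0L) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[pos]) - nP * (nP + 1) / 2) / (nP * nN)
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions (1 = identical up to
#' relabelling, ~0 = random). Used to score recovered clusters against
#' planted ground truth.
#'
#' @param a,b integer label vectors of equal length.
#' @return Numeric ARI.
#' @export
ariScore <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sumij <- sum(choose(tab, 2))
  sumA <- sum(choose(rowSums(tab), 2))
  sumB <- sum(choose(colSums(tab), 2))
  expected <- sumA * sumB / choose(n, 2)
  maxIdx <- (sumA + sumB) / 2
  if (maxIdx == expected) return(ifelse(sumij == expected, 1, 0))
  (sumij - expected) / (maxIdx - expected)
}

#' Metrics report as a plain list (for JSON export)
#'
#' @param report a [MetricsReport-class].
#' @return A named list with accuracy, sensitivity, specificity,
#'   per-class AUC and the confusion matrix.
#' @export
metricsAsList <- function(report) {
  list(accuracy = report@accuracy, sensitivity = report@sensitivity,
       specificity = report@specificity,
       perClassAUC = as.list(report@perClassAUC),
       confusion = unname(apply(report@confusion, 1L, as.integer,
                                simplify = FALSE)),
       classes = colnames(report@confusion))
}
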