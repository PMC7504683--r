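#' ROC curve and AUC
#'
#' Tie-corrected AUC via mid-ranks (equal to the Mann-Whitney probability
#' that a random case outscores a random control, ties counted 1/2), and
#' the ROC curve over the sorted unique score thresholds.
#'
#' @param scores Numeric score vector (higher = more case-like).
#' @param labels 0/1 labels.
#' @return Object of class `roc_result`: `auc`, `thresholds`, `fpr`,
#'   `tpr` (both non-decreasing from 0 to 1).
#' @export
roc_auc <- function(scores, labels) {
  labels <- check_labels(labels, length(scores))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  r <- rank(scores)  # mid-ranks
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  last <- !duplicated(s, fromLast = TRUE)  # one point per distinct threshold
  tpr <- c(0, cumsum(y == 1L)[last] / n1)
  fpr <- c(0, cumsum(y == 0L)[last] / n0)
  structure(list(auc = auc, thresholds = c(Inf, s[last]),
                 fpr = fpr, tpr = tpr),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.4f (%d thresholds)\n",
              x$auc, length(x$thresholds)))
  invisible(x)
}

#' Repeated stratified holdout evaluation
#'
#' The evaluation protocol for case/control classifiers: in each
#' iteration a fixed number of samples per class is drawn for training,
#' the model is fit on them and scored on the held-out remainder. Reports
#' per-iteration test AUCs and a pooled ROC; because score scales differ
#' across refits, scores are rank-standardized within each iteration
#' before pooling.
#'
#' @param dm A [dosage_matrix()].
#' @param labels 0/1 labels.
#' @param train_sizes `c(n0_train, n1_train)` samples drawn per class.
#' @param iterations Number of random splits.
#' @param seed Integer seed.
#' @param hyper Named list of arguments passed to [labs_fit()] (e.g.
#'   `D`, `T1`, `T2`, `T3`).
#' @param reference_scores Optional fixed per-sample score vector (e.g.
#'   the generative model's exact log-likelihood ratio); its AUC on each
#'   iteration's test set is reported alongside.
#' @return List: `auc` (per-iteration), `mean_auc`, `reference_auc`
#'   (per-iteration, if requested), `pooled_roc`.
#' @export
repeated_holdout <- function(dm, labels, train_sizes, iterations = 10,
                             seed = 1, hyper = list(),
                             reference_scores = NULL) {
  labels <- check_labels(labels, nrow(dm$values))
  i0 <- which(labels == 0L); i1 <- which(labels == 1L)
  if (train_sizes[1L] >= length(i0) || train_sizes[2L] >= length(i1))
    stop("train sizes must be smaller than class sizes")
  set.seed(seed)
  aucs <- numeric(iterations)
  ref_aucs <- if (is.null(reference_scores)) NULL else numeric(iterations)
  pooled <- vector("list", iterations)
  for (it in seq_len(iterations)) {
    tr <- c(sample(i0, train_sizes[1L]), sample(i1, train_sizes[2L]))
    te <- setdiff(seq_along(labels), tr)
    model <- do.call(labs_fit,
                     c(list(dm = subset_dm(dm, tr), labels = labels[tr]),
                       hyper))
    sc <- labs_predict(model, subset_dm(dm, te))$R
    aucs[it] <- roc_auc(sc, labels[te])$auc
    if (!is.null(reference_scores))
      ref_aucs[it] <- roc_auc(reference_scores[te], labels[te])$auc
    pooled[[it]] <- data.frame(s = rank(sc) / (length(sc) + 1),
                               y = labels[te])
  }
  ps <- do.call(rbind, pooled)
  list(auc = aucs, mean_auc = mean(aucs), reference_auc = ref_aucs,
       pooled_roc = roc_auc(ps$s, ps$y))
}
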