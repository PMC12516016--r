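# Evaluation: splits, confusion-matrix metrics, curves, fold aggregation ----

#' Stratified hold-out split specification
#'
#' The 72/8/20 convention: per class of size `n`, the training set takes
#' `floor(0.72 n)`, the test set `round(0.20 n)` (half away from zero) and
#' validation the remainder -- the unique simple rounding convention that
#' reproduces the reference class-count table for counts (2765, 3464).
#'
#' @param fractions Named or positional `c(train, validation, test)`
#'   fractions summing to 1.
#' @param seed Seed for the within-class shuffle.
#' @return List of class `split_spec`.
#' @export
split_spec <- function(fractions = c(train = 0.72, validation = 0.08,
                                     test = 0.20), seed = 0L) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  structure(list(fractions = fractions, seed = as.integer(seed)),
            class = "split_spec")
}

round_half_up <- function(x) floor(x + 0.5)

#' Stratified train/validation/test split
#'
#' @param labels Binary label vector.
#' @param spec A [split_spec()].
#' @return List of index vectors `train`, `validation`, `test`; disjoint
#'   and jointly exhaustive, stratified by class.
#' @examples
#' # class counts per partition for the reference totals:
#' s <- stratified_split(rep(c(1, 0), c(2765, 3464)))
#' lengths(s)  # 4484, 499, 1246
#' @export
stratified_split <- function(labels, spec = split_spec()) {
  classes <- sort(unique(labels))
  if (length(classes) != 2L) stop("exactly two classes are required")
  f <- spec$fractions
  all_positive <- all(f > 0)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(spec$seed)
  out <- list(train = integer(0), validation = integer(0), test = integer(0))
  for (cl in classes) {
    idx <- which(labels == cl)
    n <- length(idx)
    if (all_positive && n < 3L) {
      stop("class '", cl, "' has only ", n,
           " samples; cannot populate all three partitions")
    }
    n_train <- floor(f[[1]] * n)
    n_test <- round_half_up(f[[3]] * n)
    n_val <- n - n_train - n_test
    idx <- idx[sample.int(n)]
    out$train <- c(out$train, idx[seq_len(n_train)])
    out$validation <- c(out$validation,
                        idx[seq_len(n_val) + n_train])
    out$test <- c(out$test, idx[seq_len(n_test) + n_train + n_val])
  }
  out
}

#' Stratified k-fold indices
#'
#' @param labels Binary label vector.
#' @param k Number of folds (>= 2).
#' @param seed Shuffle seed.
#' @return List of `k` disjoint, exhaustive index vectors; per-class fold
#'   sizes differ by at most one.
#' @export
kfold_indices <- function(labels, k = 5L, seed = 0L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  counts <- table(labels)
  if (any(counts < k)) stop("every class must have at least k samples")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  folds <- rep(list(integer(0)), k)
  sizes <- integer(k)
  for (cl in names(counts)) {
    idx <- which(as.character(labels) == cl)
    idx <- idx[sample.int(length(idx))]
    base <- length(idx) %/% k
    extra <- length(idx) %% k
    per_fold <- rep(base, k)
    # hand the remainder to the currently smallest folds so overall fold
    # sizes also differ by at most one
    per_fold[order(sizes)[seq_len(extra)]] <- base + 1L
    stops <- cumsum(per_fold)
    starts <- c(1L, utils::head(stops, -1L) + 1L)
    for (j in seq_len(k)) {
      if (per_fold[j] > 0L) {
        folds[[j]] <- c(folds[[j]], idx[starts[j]:stops[j]])
      }
    }
    sizes <- sizes + per_fold
  }
  folds
}

#' Confusion-matrix metrics for binary classification
#'
#' Positive class = fracture (label 1).  Accuracy, precision, recall, F1
#' and Cohen's kappa are computed from the thresholded confusion matrix;
#' AUROC (trapezoidal) and AUPRC (step interpolation) from the scores.
#' Ratios with zero denominators are reported as 0 with a warning flag.
#'
#' @param y_true Binary labels.
#' @param y_prob Scores/probabilities in `[0, 1]`.
#' @param threshold Decision threshold (ties predicted positive).
#' @param curves Also compute AUROC/AUPRC (requires both classes present).
#' @return List of class `classification_metrics`: `confusion`
#'   (TP, FP, FN, TN), `accuracy`, `precision`, `recall`, `f1`, `kappa`,
#'   `auroc`, `auprc`, `degenerate` flag.
#' @export
compute_metrics <- function(y_true, y_prob, threshold = 0.5, curves = TRUE) {
  if (length(y_true) != length(y_prob)) stop("length mismatch")
  if (!all(y_true %in% c(0, 1))) stop("y_true must be binary (0/1)")
  pred <- as.integer(y_prob >= threshold)
  TP <- sum(pred == 1 & y_true == 1)
  FP <- sum(pred == 1 & y_true == 0)
  FN <- sum(pred == 0 & y_true == 1)
  TN <- sum(pred == 0 & y_true == 0)
  n <- TP + FP + FN + TN
  degenerate <- FALSE
  safe_div <- function(num, den) {
    if (den == 0) {
      degenerate <<- TRUE
      0
    } else num / den
  }
  precision <- safe_div(TP, TP + FP)
  recall <- safe_div(TP, TP + FN)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  accuracy <- (TP + TN) / n
  p_o <- accuracy
  p_e <- ((TP + FP) * (TP + FN) + (FN + TN) * (FP + TN)) / n^2
  kappa <- safe_div(p_o - p_e, 1 - p_e)
  if (degenerate) {
    warning("degenerate confusion matrix: zero-denominator metrics set to 0")
  }
  auroc <- auprc <- NA_real_
  if (curves && length(unique(y_true)) == 2L) {
    cv <- roc_pr_curves(y_true, y_prob)
    auroc <- cv$auroc
    auprc <- cv$auprc
  }
  structure(list(confusion = c(TP = TP, FP = FP, FN = FN, TN = TN),
                 accuracy = accuracy, precision = precision, recall = recall,
                 f1 = f1, kappa = kappa, auroc = auroc, auprc = auprc,
                 threshold = threshold, degenerate = degenerate),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf(paste0("accuracy %.2f%%  precision %.2f%%  recall %.2f%%  ",
                     "F1 %.2f%%  kappa %.4f\n"),
              100 * x$accuracy, 100 * x$precision, 100 * x$recall,
              100 * x$f1, x$kappa))
  if (!is.na(x$auroc)) {
    cat(sprintf("AUROC %.4f  AUPRC %.4f\n", x$auroc, x$auprc))
  }
  invisible(x)
}

#' ROC and precision-recall curves
#'
#' AUROC by the trapezoidal rule over all score thresholds (equivalently
#' the Mann-Whitney correct-ranking probability with ties counted half);
#' AUPRC by step interpolation (average precision).
#'
#' @param y_true Binary labels (both classes must be present).
#' @param y_prob Scores.
#' @return List with `roc` (data frame fpr/tpr/threshold), `pr` (recall/
#'   precision/threshold), `auroc`, `auprc`.
#' @export
roc_pr_curves <- function(y_true, y_prob) {
  if (length(unique(y_true)) != 2L) {
    stop("both classes must be present to compute curves")
  }
  ord <- order(y_prob, decreasing = TRUE)
  y <- y_true[ord]
  p <- y_prob[ord]
  P <- sum(y == 1); N <- sum(y == 0)
  tps <- cumsum(y == 1)
  fps <- cumsum(y == 0)
  # collapse tied scores: keep the last index of each distinct score
  last <- which(diff(p) != 0)
  keep <- c(last, length(p))
  tpr <- c(0, tps[keep] / P)
  fpr <- c(0, fps[keep] / N)
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  prec <- tps[keep] / (tps[keep] + fps[keep])
  rec <- tps[keep] / P
  auprc <- sum(diff(c(0, rec)) * prec)
  list(roc = data.frame(fpr = fpr, tpr = tpr,
                        threshold = c(Inf, p[keep])),
       pr = data.frame(recall = rec, precision = prec, threshold = p[keep]),
       auroc = auroc, auprc = auprc)
}

#' Aggregate per-fold metrics
#'
#' Mean and population standard deviation (divisor k) per metric, the form
#' under which reference fold tables report mu +/- sigma.
#'
#' @param folds List (length >= 2) of `classification_metrics`.
#' @return List of class `fold_summary` with `per_fold` (data frame) and
#'   `mu`, `sigma` named vectors.
#' @export
aggregate_folds <- function(folds) {
  if (length(folds) < 2L) stop("at least two folds are required")
  fields <- c("accuracy", "precision", "recall", "f1", "kappa",
              "auroc", "auprc")
  per_fold <- as.data.frame(lapply(fields, function(f)
    vapply(folds, function(m) as.numeric(m[[f]]), numeric(1))))
  names(per_fold) <- fields
  mu <- vapply(per_fold, mean, numeric(1))
  sigma <- vapply(per_fold, function(v)
    sqrt(mean((v - mean(v))^2)), numeric(1))
  structure(list(per_fold = per_fold, mu = mu, sigma = sigma),
            class = "fold_summary")
}

#' @export
print.fold_summary <- function(x, ...) {
  cat("fold summary (mu +/- sigma, population sd):\n")
  for (f in names(x$mu)) {
    cat(sprintf("  %-9s %.4f +/- %.4f\n", f, x$mu[f], x$sigma[f]))
  }
  invisible(x)
}
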