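# Evaluation battery: hard-mask overlap metrics, pixel confusion matrix
# with one-vs-rest class statistics, rank-based ROC-AUC, and percentile
# bootstrap confidence intervals.

#' Overlap metrics between two binary masks
#'
#' Hard-mask Dice \code{2|A&B| / (|A|+|B|)}, IoU \code{|A&B| / |A|B|},
#' pixel accuracy, and foreground F1 (identical to hard Dice). When both
#' masks are empty, Dice and IoU are defined as 1.
#'
#' @param pred,gt binary masks (0/1), same shape.
#' @return list with \code{dice}, \code{iou}, \code{accuracy}, \code{f1}.
#' @export
overlap_metrics <- function(pred, gt) {
  if (length(pred) != length(gt))
    stop_shape("overlap_metrics: shape mismatch")
  p <- as.numeric(pred) > 0.5; g <- as.numeric(gt) > 0.5
  inter <- sum(p & g)
  ps <- sum(p); gs <- sum(g)
  dice <- if (ps + gs == 0) 1 else 2 * inter / (ps + gs)
  uni <- ps + gs - inter
  iou <- if (uni == 0) 1 else inter / uni
  acc <- mean(p == g)
  list(dice = dice, iou = iou, accuracy = acc, f1 = dice)
}

#' Pixel confusion matrix and one-vs-rest class statistics
#'
#' Counts the 2x2 pixel confusion matrix (foreground positive) and computes
#' precision, recall and F1 twice -- once with foreground and once with
#' background as the positive class -- plus macro (unweighted mean) and
#' weighted (by class pixel support) averages, mirroring a per-class
#' segmentation report.
#'
#' @param pred,gt binary masks (0/1), same shape.
#' @return list with \code{counts} (tp, fp, fn, tn), \code{classes}
#'   (data.frame: class, support, precision, recall, f1), \code{macro} and
#'   \code{weighted} rows, and overall \code{accuracy}.
#' @export
confusion_and_classwise <- function(pred, gt) {
  if (length(pred) != length(gt))
    stop_shape("confusion_and_classwise: shape mismatch")
  p <- as.numeric(pred) > 0.5; g <- as.numeric(gt) > 0.5
  tp <- sum(p & g); fp <- sum(p & !g); fn <- sum(!p & g); tn <- sum(!p & !g)
  prf <- function(tp, fp, fn) {
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    c(precision = prec, recall = rec, f1 = f1)
  }
  fg <- prf(tp, fp, fn)
  bg <- prf(tn, fn, fp)   # background as positive class
  support <- c(background = tn + fp, foreground = tp + fn)
  classes <- data.frame(
    class = c("background", "foreground"),
    support = as.numeric(support),
    precision = c(bg["precision"], fg["precision"]),
    recall = c(bg["recall"], fg["recall"]),
    f1 = c(bg["f1"], fg["f1"]),
    row.names = NULL)
  w <- support / sum(support)
  list(counts = list(tp = tp, fp = fp, fn = fn, tn = tn),
       classes = classes,
       macro = colMeans(classes[, c("precision", "recall", "f1")]),
       weighted = colSums(classes[, c("precision", "recall", "f1")] * w),
       accuracy = (tp + tn) / length(p))
}

#' Rank-based ROC-AUC
#'
#' The probability that a randomly chosen positive pixel outscores a
#' randomly chosen negative one, with ties counted 1/2 (Mann-Whitney rank
#' formulation). For large pixel sets a seeded subsample keeps the
#' computation tractable; \code{max_pixels = Inf} gives the exact value.
#'
#' @param scores predicted probabilities/scores.
#' @param labels binary labels; both classes must be present.
#' @param max_pixels subsample size cap (default 1e5).
#' @param seed seed for the subsample draw.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels, max_pixels = 1e5, seed = 0L) {
  s <- as.numeric(scores); y <- as.numeric(labels) > 0.5
  if (length(s) != length(y)) stop_shape("roc_auc: length mismatch")
  if (all(y) || !any(y))
    stop("roc_auc: undefined, labels contain a single class")
  if (is.finite(max_pixels) && length(s) > max_pixels) {
    keep <- with_seed(seed, sample.int(length(s), max_pixels))
    s <- s[keep]; y <- y[keep]
    if (all(y) || !any(y))
      stop("roc_auc: subsample lost one class; raise max_pixels")
  }
  r <- rank(s)            # average ranks handle ties as 1/2
  n1 <- sum(y); n0 <- length(y) - n1
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Percentile bootstrap confidence interval for a mean score
#'
#' Resamples the per-image scores with replacement \code{resamples} times,
#' takes the mean of each resample, and reports the percentile interval of
#' the resampled means around the observed mean. Deterministic given
#' \code{seed}.
#'
#' @param scores per-image metric values (at least one).
#' @param resamples number of bootstrap resamples (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed.
#' @return list with \code{lower}, \code{point} (the sample mean),
#'   \code{upper}.
#' @export
bootstrap_ci <- function(scores, resamples = 1000L, level = 0.95, seed = 0L) {
  scores <- as.numeric(scores)
  if (length(scores) < 1L) stop("bootstrap_ci: empty score vector")
  if (resamples < 1L) stop("bootstrap_ci: resamples must be >= 1")
  n <- length(scores)
  means <- with_seed(seed, {
    idx <- sample.int(n, n * resamples, replace = TRUE)
    colMeans(matrix(scores[idx], n, resamples))
  })
  a <- (1 - level) / 2
  q <- stats::quantile(means, c(a, 1 - a), names = FALSE, type = 7)
  list(lower = q[1], point = mean(scores), upper = q[2])
}

#' Per-image metric report with bootstrap confidence intervals
#'
#' Given per-image hard masks (or probability maps plus a threshold),
#' computes Dice/IoU/accuracy/F1 per image, averages them, and attaches
#' 95 percent percentile-bootstrap confidence intervals, pooled confusion
#' statistics over all pixels, and the pooled ROC-AUC of the probability
#' scores.
#'
#' @param probs list of probability maps (one per image).
#' @param gts list of binary ground-truth masks.
#' @param threshold binarization threshold (default 0.5).
#' @param resamples bootstrap resamples (default 1000).
#' @param seed seed for bootstrap and AUC subsampling.
#' @param auc_max_pixels pixel cap for the pooled AUC.
#' @return object of class \code{metric_report}: list with
#'   \code{per_image} (data.frame), \code{summary} (metric, point, lower,
#'   upper), \code{confusion}, \code{auc}, \code{n_images}.
#' @export
metric_report <- function(probs, gts, threshold = 0.5, resamples = 1000L,
                          seed = 0L, auc_max_pixels = 1e5) {
  stopifnot(length(probs) == length(gts), length(probs) > 0)
  per <- lapply(seq_along(probs), function(i) {
    m <- overlap_metrics(binarize(probs[[i]], threshold), gts[[i]])
    data.frame(image = i, dice = m$dice, iou = m$iou,
               accuracy = m$accuracy, f1 = m$f1)
  })
  per <- do.call(rbind, per)
  summ <- do.call(rbind, lapply(c("dice", "iou", "accuracy", "f1"),
    function(mname) {
      ci <- bootstrap_ci(per[[mname]], resamples = resamples, seed = seed)
      data.frame(metric = mname, point = ci$point,
                 lower = ci$lower, upper = ci$upper)
    }))
  all_p <- unlist(lapply(probs, as.numeric))
  all_g <- unlist(lapply(gts, as.numeric))
  conf <- confusion_and_classwise(as.numeric(all_p >= threshold), all_g)
  auc <- if (any(all_g > 0.5) && !all(all_g > 0.5)) {
    roc_auc(all_p, all_g, max_pixels = auc_max_pixels, seed = seed)
  } else NA_real_
  structure(list(per_image = per, summary = summ, confusion = conf,
                 auc = auc, n_images = length(probs),
                 threshold = threshold),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Segmentation metric report over", x$n_images, "images (threshold",
      x$threshold, ")\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-9s %.4f (%.4f-%.4f)\n", s$metric[i], s$point[i],
                s$lower[i], s$upper[i]))
  }
  if (!is.na(x$auc)) cat(sprintf("  pooled AUC %.4f\n", x$auc))
  invisible(x)
}

#' Write a metric report to CSV tables
#'
#' Emits two CSVs: \code{<stem>_metrics.csv} (metric, point, lower, upper)
#' and \code{<stem>_classes.csv} (per-class precision/recall/F1 with macro
#' and weighted rows).
#'
#' @param report a \code{metric_report}.
#' @param stem output path stem.
#' @return invisibly, the two file paths.
#' @export
write_metric_report <- function(report, stem) {
  f1 <- paste0(stem, "_metrics.csv")
  s <- report$summary
  s$auc <- report$auc
  utils::write.csv(s, f1, row.names = FALSE)
  cl <- report$confusion$classes
  extra <- data.frame(class = c("macro", "weighted"),
                      support = sum(cl$support),
                      precision = c(report$confusion$macro["precision"],
                                    report$confusion$weighted["precision"]),
                      recall = c(report$confusion$macro["recall"],
                                 report$confusion$weighted["recall"]),
                      f1 = c(report$confusion$macro["f1"],
                             report$confusion$weighted["f1"]))
  f2 <- paste0(stem, "_classes.csv")
  utils::write.csv(rbind(cl, extra), f2, row.names = FALSE)
  invisible(c(f1, f2))
}
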