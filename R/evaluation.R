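# ---------------------------------------------------------------------------
# Detection metrics: greedy TP/FP matching at IoU 0.5, precision / recall /
# F1 at the operating threshold, average precision over the full
# precision-recall sweep, and the average angle difference in degrees.
# ---------------------------------------------------------------------------

#' Match detections to ground truth
#'
#' Greedy matching per image in descending score order: a detection is a
#' true positive when its IoU with a not-yet-matched ground-truth box
#' reaches `iou_thresh`; each ground truth is matched at most once; all
#' remaining detections are false positives and unmatched ground truths are
#' false negatives.
#'
#' @param dets list (one element per image) of detection data frames (see
#'   [postprocess()]).
#' @param gts list (same length) of ground-truth data frames with corner
#'   boxes and optionally `theta`.
#' @param iou_thresh matching threshold.
#' @return data frame with one row per detection: `image`, `score`, `tp`
#'   (logical), `theta_pred`, `theta_true` (NA unless a matched ground truth
#'   carries an angle); attribute `n_gt` holds the total ground-truth count.
#' @export
match_detections <- function(dets, gts, iou_thresh = 0.5) {
  stopifnot(length(dets) == length(gts))
  rows <- vector("list", length(dets))
  n_gt <- 0L
  for (i in seq_along(dets)) {
    d <- dets[[i]]; g <- gts[[i]]
    n_gt <- n_gt + NROW(g)
    if (NROW(d) == 0L) next
    ord <- order(d$score, decreasing = TRUE)
    tp <- logical(nrow(d))
    theta_true <- rep(NA_real_, nrow(d))
    taken <- rep(FALSE, NROW(g))
    if (NROW(g)) {
      ious <- iou_matrix(d[, c("xmin", "ymin", "xmax", "ymax")],
                         g[, c("xmin", "ymin", "xmax", "ymax")])
      for (j in ord) {
        cand <- which(!taken & ious[j, ] >= iou_thresh)
        if (length(cand)) {
          best <- cand[which.max(ious[j, cand])]
          taken[best] <- TRUE
          tp[j] <- TRUE
          if (!is.null(g$theta)) theta_true[j] <- g$theta[best]
        }
      }
    }
    rows[[i]] <- data.frame(image = i, score = d$score, tp = tp,
                            theta_pred = if (!is.null(d$theta)) d$theta
                                         else NA_real_,
                            theta_true = theta_true)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(image = integer(0), score = numeric(0),
                      tp = logical(0), theta_pred = numeric(0),
                      theta_true = numeric(0))
  }
  attr(out, "n_gt") <- n_gt
  out
}

#' Precision, recall, F1 and average precision from matched detections
#'
#' Precision/recall/F1 are computed at the operating point (all supplied
#' detections count). AP is the area under the precision-recall curve swept
#' over score thresholds, integrated with the all-points method: recall
#' steps at each detection, precision taken as the envelope (running
#' maximum from the right).
#'
#' @param tp logical vector of per-detection true-positive flags.
#' @param scores matching score vector.
#' @param n_gt total number of ground-truth objects (positive).
#' @return list with `precision`, `recall`, `f1`, `ap`, `tp`, `fp`, `fn`
#'   counts, and the sweep `curve` (data frame recall/precision).
#' @export
pr_ap <- function(tp, scores, n_gt) {
  stopifnot(length(tp) == length(scores), n_gt >= 1)
  n_tp <- sum(tp); n_fp <- sum(!tp); n_fn <- n_gt - n_tp
  precision <- if (n_tp + n_fp > 0) n_tp / (n_tp + n_fp) else 0
  recall <- n_tp / n_gt
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  if (length(tp)) {
    ord <- order(scores, decreasing = TRUE)
    ctp <- cumsum(tp[ord])
    rec <- ctp / n_gt
    prec <- ctp / seq_along(ctp)
    env <- rev(cummax(rev(prec)))
    ap <- sum(diff(c(0, rec)) * env)
    curve <- data.frame(recall = rec, precision = prec)
  } else {
    ap <- 0
    curve <- data.frame(recall = numeric(0), precision = numeric(0))
  }
  list(precision = precision, recall = recall, f1 = f1, ap = ap,
       tp = n_tp, fp = n_fp, fn = n_fn, curve = curve)
}

#' Average angle difference in degrees
#'
#' Mean wraparound distance ([angle_distance()]) between true and predicted
#' angles, scaled to degrees. Computed over matched (true-positive)
#' detections, the only ones that have a ground-truth angle.
#'
#' @param theta_true,theta_pred canonical angle vectors of matched pairs.
#' @return mean difference in degrees, in `[0, 180]`.
#' @export
aad <- function(theta_true, theta_pred) {
  stopifnot(length(theta_true) == length(theta_pred))
  if (!length(theta_true)) stop("average angle difference needs >= 1 pair")
  mean(angle_distance(theta_true, theta_pred)) * 180
}

#' Evaluate detections against ground truth
#'
#' Runs [match_detections()], [pr_ap()] and [aad()] and assembles the full
#' metric report.
#'
#' @param dets,gts per-image lists, see [match_detections()].
#' @param iou_thresh matching threshold (0.5 is the conventional operating
#'   point).
#' @return list of class `eval_result`: precision, recall, f1, ap, aad
#'   (degrees; NA when no matched pair carries an angle), TP/FP/FN counts
#'   and the PR curve.
#' @export
evaluate_detections <- function(dets, gts, iou_thresh = 0.5) {
  m <- match_detections(dets, gts, iou_thresh)
  n_gt <- attr(m, "n_gt")
  if (n_gt < 1) stop("evaluation needs at least one ground-truth object")
  pr <- pr_ap(m$tp, m$score, n_gt)
  pair <- m$tp & !is.na(m$theta_true) & !is.na(m$theta_pred)
  angle_err <- if (any(pair)) {
    aad(m$theta_true[pair], m$theta_pred[pair])
  } else NA_real_
  structure(list(precision = pr$precision, recall = pr$recall, f1 = pr$f1,
                 ap = pr$ap, aad = angle_err, tp = pr$tp, fp = pr$fp,
                 fn = pr$fn, n_gt = n_gt, curve = pr$curve),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    paste0("detection evaluation (IoU 0.5): P %.2f%%  R %.2f%%  F1 %.2f%%",
           "  AP %.2f%%  AAD %s\n"),
    100 * x$precision, 100 * x$recall, 100 * x$f1, 100 * x$ap,
    if (is.na(x$aad)) "n/a" else sprintf("%.2f deg", x$aad)))
  cat(sprintf("  TP %d  FP %d  FN %d  (of %d objects)\n",
              x$tp, x$fp, x$fn, x$n_gt))
  invisible(x)
}
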