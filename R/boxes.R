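# ---------------------------------------------------------------------------
# Axis-aligned boxes, multi-level anchors, encode/decode, IoU, matching,
# mini-batch sampling.
#
# Boxes are data frames (or matrices coercible to them) with columns
# xmin, ymin, xmax, ymax in pixel units, half-open ([xmin, xmax)), so
# width = xmax - xmin. Center form uses columns x, y, w, h.
# ---------------------------------------------------------------------------

#' Corner-form boxes
#'
#' @param xmin,ymin,xmax,ymax numeric vectors; must satisfy `xmax > xmin`,
#'   `ymax > ymin`.
#' @return data frame with class-checked corner coordinates.
#' @export
box <- function(xmin, ymin, xmax, ymax) {
  d <- data.frame(xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax)
  if (nrow(d) && (any(d$xmax <= d$xmin) || any(d$ymax <= d$ymin))) {
    stop("degenerate box: xmax must exceed xmin and ymax must exceed ymin")
  }
  d
}

#' Convert corner boxes to center form and back
#'
#' @param b data frame of corner boxes (for `box_to_center`) or center boxes
#'   with columns x, y, w, h (for `center_to_box`).
#' @return data frame in the other parameterization; the round trip is
#'   lossless.
#' @export
box_to_center <- function(b) {
  data.frame(
    x = (b$xmin + b$xmax) / 2, y = (b$ymin + b$ymax) / 2,
    w = b$xmax - b$xmin, h = b$ymax - b$ymin
  )
}

#' @rdname box_to_center
#' @export
center_to_box <- function(b) {
  data.frame(
    xmin = b$x - b$w / 2, ymin = b$y - b$h / 2,
    xmax = b$x + b$w / 2, ymax = b$y + b$h / 2
  )
}

#' Intersection over union of two box sets
#'
#' @param a,b corner-form box data frames with `na` and `nb` rows.
#' @return `na x nb` matrix of IoU values in `[0, 1]`.
#' @export
iou_matrix <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  ix <- pmax(0, outer(a$xmax, b$xmax, pmin) - outer(a$xmin, b$xmin, pmax))
  iy <- pmax(0, outer(a$ymax, b$ymax, pmin) - outer(a$ymin, b$ymin, pmax))
  inter <- ix * iy
  area_a <- (a$xmax - a$xmin) * (a$ymax - a$ymin)
  area_b <- (b$xmax - b$xmin) * (b$ymax - b$ymin)
  inter / (outer(area_a, area_b, `+`) - inter)
}

#' IoU of two single boxes
#' @param a,b single-row corner boxes.
#' @return scalar IoU.
#' @export
iou <- function(a, b) iou_matrix(a, b)[1, 1]

#' Generate the multi-level anchor grid
#'
#' Anchors are prior boxes tied to cells of four pyramid levels. Each level
#' has stride `strides[l]` and grid `ceil(W/stride) x ceil(H/stride)`; every
#' cell carries `length(scale_ratios) * length(aspect_ratios)` template boxes
#' centered on the cell center. A template for scale `s` and aspect `a` has
#' width `base * s * sqrt(a)` and height `base * s / sqrt(a)` (constant area
#' across aspects). The flat order is level-major, then cells row-major
#' (all of row 1 left to right, then row 2, ...), then template; head outputs
#' use the same order so anchor index i always refers to the same prior.
#'
#' With the defaults at a 400 x 400 input the grids are 50, 25, 13 and 7
#' cells a side and the set holds 6 x (2500 + 625 + 169 + 49) = 20,058
#' anchors.
#'
#' @param image_w,image_h input image size in pixels.
#' @param strides per-level downsampling factors.
#' @param base_sizes per-level base anchor sizes in pixels (shallow levels
#'   get smaller anchors).
#' @param scale_ratios,aspect_ratios template multipliers shared by all
#'   levels.
#' @return object of class `anchor_set`: list with `levels` (per-level grid
#'   spec), `centers` (data frame x, y, w, h over all anchors in flat order),
#'   `n` (total count) and `k` (anchors per cell).
#' @export
generate_anchors <- function(image_w, image_h,
                             strides = c(8, 16, 32, 64),
                             base_sizes = c(32, 64, 128, 256),
                             scale_ratios = c(1, 2),
                             aspect_ratios = c(1.0, 2.0, 0.5)) {
  stopifnot(image_w > 0, image_h > 0, length(strides) == length(base_sizes))
  k <- length(scale_ratios) * length(aspect_ratios)
  # template order: scale-major, aspect within scale
  tw <- as.vector(t(outer(scale_ratios, sqrt(aspect_ratios))))
  th <- as.vector(t(outer(scale_ratios, 1 / sqrt(aspect_ratios))))
  levels <- vector("list", length(strides))
  parts <- vector("list", length(strides))
  for (l in seq_along(strides)) {
    s <- strides[l]
    gw <- ceiling(image_w / s); gh <- ceiling(image_h / s)
    cx <- (seq_len(gw) - 0.5) * s
    cy <- (seq_len(gh) - 0.5) * s
    # flat order: template fastest, then x (within row), then y (rows)
    parts[[l]] <- data.frame(
      x = rep(rep(cx, each = k), times = gh),
      y = rep(cy, each = k * gw),
      w = rep(tw * base_sizes[l], times = gw * gh),
      h = rep(th * base_sizes[l], times = gw * gh)
    )
    levels[[l]] <- list(stride = s, grid_w = gw, grid_h = gh,
                        base_size = base_sizes[l], k = k)
  }
  centers <- do.call(rbind, parts)
  structure(
    list(levels = levels, centers = centers, n = nrow(centers), k = k,
         image_w = image_w, image_h = image_h),
    class = "anchor_set"
  )
}

#' @export
print.anchor_set <- function(x, ...) {
  cat("anchor_set:", x$n, "anchors over", length(x$levels), "levels",
      sprintf("(%d per cell)\n", x$k))
  for (l in x$levels) {
    cat(sprintf("  stride %3d: %d x %d cells, base size %d\n",
                l$stride, l$grid_w, l$grid_h, l$base_size))
  }
  invisible(x)
}

#' Encode boxes as regression targets relative to anchors / decode back
#'
#' The box head regresses dimensionless offsets from each anchor:
#' `tx = 10 (x - xa) / wa`, `ty = 10 (y - ya) / ha`,
#' `tw = 5 log(w / wa)`, `th = 5 log(h / ha)` (natural log), and decoding
#' inverts this: `x = tx wa / 10 + xa`, `w = wa exp(tw / 5)`, etc.
#'
#' @param gt,anchor center-form data frames (columns x, y, w, h), row-aligned.
#' @param t data frame or matrix of encodings with columns tx, ty, tw, th.
#' @return `encode_box`: data frame of encodings; `decode_box`: center-form
#'   data frame. The two are mutually inverse.
#' @export
encode_box <- function(gt, anchor) {
  data.frame(
    tx = 10 * (gt$x - anchor$x) / anchor$w,
    ty = 10 * (gt$y - anchor$y) / anchor$h,
    tw = 5 * log(gt$w / anchor$w),
    th = 5 * log(gt$h / anchor$h)
  )
}

#' @rdname encode_box
#' @export
decode_box <- function(t, anchor) {
  t <- as.data.frame(t)
  data.frame(
    x = t$tx / 10 * anchor$w + anchor$x,
    y = t$ty / 10 * anchor$h + anchor$y,
    w = anchor$w * exp(t$tw / 5),
    h = anchor$h * exp(t$th / 5)
  )
}

#' Match anchors to ground-truth boxes
#'
#' An anchor is positive when its best IoU against the ground truth reaches
#' `pos_thresh`, or when it is the highest-IoU anchor for some ground-truth
#' box (so every object with any overlap owns at least one anchor); negative
#' when its best IoU is below `neg_thresh`; otherwise ignored. Ties take the
#' lowest anchor index. Each positive anchor is assigned the ground-truth box
#' it overlaps most.
#'
#' @param anchors an `anchor_set` or a center-form data frame of anchor boxes.
#' @param gts corner-form data frame of ground-truth boxes (0 rows allowed).
#' @param pos_thresh,neg_thresh IoU thresholds, `0 <= neg <= pos <= 1`.
#' @return list with `label` (integer per anchor: 1 positive, 0 negative,
#'   -1 ignored) and `gt_index` (matched ground-truth row for positives,
#'   NA otherwise).
#' @export
match_anchors <- function(anchors, gts, pos_thresh = 0.5, neg_thresh = 0.5) {
  centers <- if (inherits(anchors, "anchor_set")) anchors$centers else anchors
  if (nrow(centers) == 0L) stop("empty anchor set")
  stopifnot(neg_thresh >= 0, pos_thresh >= neg_thresh, pos_thresh <= 1)
  n <- nrow(centers)
  if (is.null(gts) || nrow(gts) == 0L) {
    return(list(label = integer(n), gt_index = rep(NA_integer_, n)))
  }
  ious <- iou_matrix(center_to_box(centers), gts)
  best <- apply(ious, 1L, max)
  best_gt <- apply(ious, 1L, which.max)  # lowest gt index on ties
  label <- rep(-1L, n)
  label[best < neg_thresh] <- 0L
  label[best >= pos_thresh] <- 1L
  # every ground truth with any overlapping anchor owns its argmax anchor
  for (g in seq_len(ncol(ious))) {
    if (max(ious[, g]) > 0) {
      a <- which.max(ious[, g])  # lowest anchor index on ties
      label[a] <- 1L
      best_gt[a] <- g
    }
  }
  gt_index <- ifelse(label == 1L, best_gt, NA_integer_)
  list(label = label, gt_index = gt_index)
}

#' Sample a training mini-batch of anchors
#'
#' Balances the heavy negative majority: up to `round(size * pos_fraction)`
#' positives are drawn (all positives if fewer exist), and the remainder of
#' the budget is filled with negatives. Sampling is uniform without
#' replacement and driven by the R random stream, so it is reproducible under
#' `set.seed`.
#'
#' @param match result of [match_anchors()].
#' @param size total sample budget (`Nobj` of the objectness loss).
#' @param pos_fraction target fraction of positives.
#' @return list with integer index vectors `pos` and `neg` (into the anchor
#'   set); `length(pos)` is `Nloc`.
#' @export
sample_minibatch <- function(match, size = 256L, pos_fraction = 0.25) {
  stopifnot(size > 0, pos_fraction > 0, pos_fraction <= 1)
  pos_all <- which(match$label == 1L)
  neg_all <- which(match$label == 0L)
  n_pos <- min(length(pos_all), round(size * pos_fraction))
  pos <- if (length(pos_all) > n_pos) sort(sample(pos_all, n_pos)) else pos_all
  n_neg <- min(length(neg_all), size - length(pos))
  neg <- if (length(neg_all) > n_neg) sort(sample(neg_all, n_neg)) else neg_all
  list(pos = pos, neg = neg)
}
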