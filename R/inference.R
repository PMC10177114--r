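# ---------------------------------------------------------------------------
# Post-processing of head outputs into detections, and face normalization
# (rotate about the box center, crop, scale).
# ---------------------------------------------------------------------------

#' Greedy non-maximum suppression
#'
#' Keeps boxes in descending score order, suppressing any box whose IoU with
#' an already-kept box reaches `iou_thresh`. Ties in score keep the lower
#' index first (stable order).
#'
#' @param boxes corner-form box data frame.
#' @param scores numeric vector, one per box.
#' @param iou_thresh suppression threshold.
#' @return integer indices of the kept boxes, in descending score order.
#' @export
nms <- function(boxes, scores, iou_thresh = 0.5) {
  n <- nrow(boxes)
  if (n == 0L) return(integer(0))
  ord <- order(scores, decreasing = TRUE)  # stable: ties by index
  keep <- integer(0)
  while (length(ord)) {
    i <- ord[1L]
    keep <- c(keep, i)
    ord <- ord[-1L]
    if (length(ord)) {
      ious <- as.vector(iou_matrix(boxes[i, , drop = FALSE],
                                   boxes[ord, , drop = FALSE]))
      ord <- ord[ious < iou_thresh]
    }
  }
  keep
}

#' Decode head outputs into detections
#'
#' Thresholds the objectness probability, decodes the kept anchors' boxes,
#' assembles the signed angle from the direction probability and the
#' absolute value (counterclockwise when `p_ccw > 0.5`), applies greedy NMS
#' and caps the detection count. Boxes are clipped to the image frame.
#'
#' @param decoded result of [decode_head()].
#' @param anchors the matching `anchor_set`.
#' @param score_thresh minimum objectness probability.
#' @param nms_iou NMS suppression threshold.
#' @param max_dets maximum detections returned.
#' @return data frame with columns `xmin, ymin, xmax, ymax, score, theta`
#'   (sorted by descending score) — the detection list.
#' @export
postprocess <- function(decoded, anchors, score_thresh = 0.5, nms_iou = 0.5,
                        max_dets = 100L) {
  stopifnot(score_thresh >= 0, score_thresh <= 1, nms_iou >= 0, nms_iou <= 1)
  keep <- which(decoded$p_obj >= score_thresh)
  empty <- data.frame(xmin = numeric(0), ymin = numeric(0),
                      xmax = numeric(0), ymax = numeric(0),
                      score = numeric(0), theta = numeric(0))
  if (!length(keep)) return(empty)
  enc <- decoded$enc[keep, , drop = FALSE]
  colnames(enc) <- c("tx", "ty", "tw", "th")
  ctr <- decode_box(enc, anchors$centers[keep, , drop = FALSE])
  bx <- center_to_box(ctr)
  bx$xmin <- pmax(bx$xmin, 0); bx$ymin <- pmax(bx$ymin, 0)
  bx$xmax <- pmin(bx$xmax, anchors$image_w)
  bx$ymax <- pmin(bx$ymax, anchors$image_h)
  ok <- bx$xmax > bx$xmin & bx$ymax > bx$ymin
  keep <- keep[ok]; bx <- bx[ok, , drop = FALSE]
  if (!nrow(bx)) return(empty)
  theta <- combine_angle(decoded$value[keep], decoded$p_ccw[keep] > 0.5)
  score <- decoded$p_obj[keep]
  sel <- nms(bx, score, nms_iou)
  sel <- utils::head(sel, max_dets)
  out <- cbind(bx[sel, , drop = FALSE],
               data.frame(score = score[sel], theta = theta[sel]))
  rownames(out) <- NULL
  out
}

#' Detect faces in a single image
#'
#' Convenience wrapper: letterboxes the image to the network input size,
#' runs a forward pass in inference mode, decodes, and post-processes.
#' Detections are reported in the letterboxed frame.
#'
#' @param net a trained `rotface_net`.
#' @param image `[H, W, C]` array, or an [annotated_image()].
#' @param anchors optional precomputed `anchor_set` (rebuilt otherwise).
#' @param ... passed to [postprocess()].
#' @return detection data frame, see [postprocess()].
#' @export
detect <- function(net, image, anchors = NULL, ...) {
  if (inherits(image, "annotated_image")) image <- image$image
  if (length(dim(image)) == 2L) dim(image) <- c(dim(image), 1L)
  cfg <- net$cfg
  im <- annotated_image(image, data.frame(xmin = numeric(0),
                                          ymin = numeric(0),
                                          xmax = numeric(0),
                                          ymax = numeric(0)),
                        dataset = "ds2")
  im <- letterbox(im, cfg$input_size)
  if (is.null(anchors)) {
    anchors <- generate_anchors(cfg$input_size, cfg$input_size, cfg$strides,
                                cfg$base_sizes, cfg$scale_ratios,
                                cfg$aspect_ratios)
  }
  fwd <- network_forward(net, im$image, train = FALSE, keep_cache = FALSE)
  postprocess(decode_head(fwd$head), anchors, ...)
}

#' Normalize a detected face to an upright chip
#'
#' Rotates the image by minus the detected angle about the box center (so
#' the face's keypoint axis becomes horizontal with the left keypoint on the
#' left), crops the detection box in the rotated frame, and scales the crop
#' to a square chip. Regions falling outside the source are zero-padded;
#' resampling is bilinear. Running the result through detection +
#' normalization again would be a no-op up to resampling error, because the
#' normalized face has angle zero.
#'
#' @param image `[H, W, C]` array (the frame the detection lives in).
#' @param det one detection: a list or one-row data frame with `xmin, ymin,
#'   xmax, ymax, theta`.
#' @param out_size chip side in pixels.
#' @return list of class `normalized_face` with `chip` (`[out_size,
#'   out_size, C]` array) and `detection`.
#' @export
normalize_face <- function(image, det, out_size = 224L) {
  if (length(dim(image)) == 2L) dim(image) <- c(dim(image), 1L)
  det <- as.list(det)
  w <- det$xmax - det$xmin; h <- det$ymax - det$ymin
  if (!is.finite(w) || !is.finite(h) || w <= 0 || h <= 0) {
    stop("degenerate detection box")
  }
  cx <- (det$xmin + det$xmax) / 2; cy <- (det$ymin + det$ymax) / 2
  # output pixel (u, v) -> crop-frame point -> rotate by +theta about the
  # center (the inverse of rotating the image by -theta)
  R <- rot_screen(det$theta * pi)
  S <- diag(c(w, h) / out_size)
  A <- R %*% S
  t0 <- R %*% (c(det$xmin, det$ymin) - c(cx, cy)) + c(cx, cy)
  m <- cbind(A, t0)
  chip <- .cpp_affine_sample(image, m, as.integer(out_size),
                             as.integer(out_size))
  structure(list(chip = chip, detection = det), class = "normalized_face")
}
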