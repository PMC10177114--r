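# ---------------------------------------------------------------------------
# The four-term training loss: Huber localization, focal objectness,
# dual-dataset-masked absolute-angle value, and gated angle direction.
# Standalone scalar forms are exported for analysis; detection_loss_grad()
# additionally returns the analytic gradient with respect to the raw head
# values and is what the training loop uses.
# ---------------------------------------------------------------------------

PROB_FLOOR <- 1e-7  # inside log() only; keeps the focal loss finite

#' Loss weights and loss hyperparameters
#'
#' @param lambda_loc,lambda_obj,lambda_av,lambda_ad trade-off weights of the
#'   localization, objectness, angle-value and angle-direction terms.
#' @param lambda_ds1,lambda_ds2 inner weights of the angle-value loss for
#'   positives from the angle-labeled dataset (ds1) and the box-only dataset
#'   (ds2). The ds2 term pulls predicted absolute angles toward zero and is
#'   off by default, which masks box-only images out of the angle loss.
#' @param delta Huber transition point.
#' @param gamma focal-loss focusing exponent.
#' @param epsilon direction-loss gate: only positives whose true absolute
#'   angle exceeds `epsilon` contribute (near-zero angles have an ill-defined
#'   direction).
#' @return list of class `loss_weights`.
#' @export
loss_weights <- function(lambda_loc = 1.0, lambda_obj = 5.0,
                         lambda_av = 1.0, lambda_ad = 10.0,
                         lambda_ds1 = 10.0, lambda_ds2 = 0.0,
                         delta = 1.0, gamma = 2.0, epsilon = 0.025) {
  w <- list(lambda_loc = lambda_loc, lambda_obj = lambda_obj,
            lambda_av = lambda_av, lambda_ad = lambda_ad,
            lambda_ds1 = lambda_ds1, lambda_ds2 = lambda_ds2,
            delta = delta, gamma = gamma, epsilon = epsilon)
  if (any(unlist(w) < 0)) stop("loss weights must be non-negative")
  structure(w, class = "loss_weights")
}

#' Huber (smooth-L1) penalty
#'
#' `0.5 a^2` for `|a| <= delta`, linear `delta |a| - 0.5 delta^2` beyond.
#'
#' @param a numeric vector of residuals.
#' @param delta transition point, positive.
#' @return elementwise penalty.
#' @export
huber <- function(a, delta = 1.0) {
  stopifnot(delta > 0)
  aa <- abs(a)
  ifelse(aa <= delta, 0.5 * a^2, delta * aa - 0.5 * delta^2)
}

#' Focal loss
#'
#' `-(1 - pt)^gamma log(pt)`; at `gamma = 0` this is plain cross-entropy.
#' `pt` is clamped below by a small floor so the log stays finite.
#'
#' @param pt probability assigned to the true outcome, in (0, 1].
#' @param gamma focusing exponent.
#' @return elementwise loss.
#' @export
focal <- function(pt, gamma = 2.0) {
  pt <- pmin(pmax(pt, PROB_FLOOR), 1)
  -(1 - pt)^gamma * log(pt)
}

#' Localization loss over sampled positive anchors
#'
#' Mean over positives of the Huber penalty summed across the four box
#' encoding coordinates. Returns 0 when there are no positives.
#'
#' @param pred,target matrices (or data frames) `Nloc x 4` of box encodings.
#' @param delta Huber transition point.
#' @return scalar loss.
#' @export
localization_loss <- function(pred, target, delta = 1.0) {
  pred <- as.matrix(pred); target <- as.matrix(target)
  if (!identical(dim(pred), dim(target))) stop("encoding shape mismatch")
  if (nrow(pred) == 0L) return(0)
  mean(rowSums(huber(target - pred, delta)))
}

#' Objectness loss over the sampled mini-batch
#'
#' Focal loss with `pt = 1 - |p - p_star|`: an anchor predicted exactly right
#' contributes 0, a confidently wrong one contributes most.
#'
#' @param p predicted object probabilities of the sampled anchors.
#' @param p_star 0/1 labels (1 = anchor matched to an object).
#' @param gamma focal exponent.
#' @return scalar loss (mean over the sample).
#' @export
objectness_loss <- function(p, p_star, gamma = 2.0) {
  if (length(p) == 0L) return(0)
  mean(focal(1 - abs(p - p_star), gamma))
}

#' Absolute-angle value loss with dual-dataset masking
#'
#' Positives from the angle-labeled dataset (tag `"ds1"`) pay a weighted
#' squared error against the true absolute angle; positives from the box-only
#' dataset (tag `"ds2"`) pay a weighted squared pull toward zero. With the
#' default `lambda_ds2 = 0` the box-only images are fully masked out of this
#' term. Normalization is by the total positive count.
#'
#' @param pred_v predicted absolute angle values of the positives.
#' @param true_v ground-truth absolute values (ignored, may be NA, for ds2).
#' @param ds_tag character vector of `"ds1"` / `"ds2"` per positive.
#' @param weights a [loss_weights()].
#' @return scalar loss.
#' @export
angle_value_loss <- function(pred_v, true_v, ds_tag, weights = loss_weights()) {
  n <- length(pred_v)
  if (n == 0L) return(0)
  if (!all(ds_tag %in% c("ds1", "ds2"))) stop("unknown dataset tag")
  i1 <- ds_tag == "ds1"
  s1 <- if (any(i1)) {
    sum(weights$lambda_ds1 * 0.5 * (true_v[i1] - pred_v[i1])^2)
  } else 0
  s2 <- if (any(!i1)) sum(weights$lambda_ds2 * 0.5 * pred_v[!i1]^2) else 0
  (s1 + s2) / n
}

#' Angle-direction loss over the gated positive set
#'
#' Focal loss on the counterclockwise probability, averaged over positives
#' whose ground-truth absolute angle exceeds `epsilon` (and that carry an
#' angle label at all, i.e. ds1 positives). Returns 0 when the gate is empty.
#'
#' @param p_ccw predicted counterclockwise probabilities of the positives.
#' @param ccw_star 0/1 ground-truth direction labels.
#' @param true_v ground-truth absolute angles (NA for ds2 positives, which
#'   are excluded).
#' @param epsilon gate threshold.
#' @param gamma focal exponent.
#' @return scalar loss.
#' @export
angle_direction_loss <- function(p_ccw, ccw_star, true_v,
                                 epsilon = 0.025, gamma = 2.0) {
  gate <- !is.na(true_v) & true_v > epsilon
  if (!any(gate)) return(0)
  mean(focal(1 - abs(p_ccw[gate] - ccw_star[gate]), gamma))
}

#' Weighted total loss
#'
#' @param loc,obj,av,ad the four component losses.
#' @param weights a [loss_weights()].
#' @return list of class `loss_breakdown` with the components and their
#'   weighted `total`.
#' @export
total_loss <- function(loc, obj, av, ad, weights = loss_weights()) {
  parts <- c(loc = loc, obj = obj, av = av, ad = ad)
  if (any(!is.finite(parts))) stop("non-finite loss component")
  structure(list(loc = loc, obj = obj, av = av, ad = ad,
                 total = weights$lambda_loc * loc + weights$lambda_obj * obj +
                   weights$lambda_av * av + weights$lambda_ad * ad),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("loss: total %.4f (loc %.4f, obj %.4f, av %.4f, ad %.4f)\n",
              x$total, x$loc, x$obj, x$av, x$ad))
  invisible(x)
}

# d focal / d pt, with the same clamping as focal()
focal_dpt <- function(pt, gamma) {
  pt <- pmin(pmax(pt, PROB_FLOOR), 1)
  if (gamma == 0) return(-1 / pt)
  gamma * (1 - pt)^(gamma - 1) * log(pt) - (1 - pt)^gamma / pt
}

# Loss and analytic gradient with respect to the raw head matrix for one
# image. `targets` comes from build_targets(); `sample` from
# sample_minibatch(). Gradient columns follow the head layout
# [obj_bg, obj_fg, tx, ty, tw, th, dir_cw, dir_ccw, angle_value].
detection_loss_grad <- function(head, targets, smp, weights = loss_weights()) {
  dec <- decode_head(head)
  dhead <- matrix(0, nrow(head), 9L)
  pos <- smp$pos
  sampled <- c(smp$pos, smp$neg)
  n_loc <- length(pos)
  n_obj <- length(sampled)

  # objectness (focal on softmax probability)
  obj <- 0
  if (n_obj > 0) {
    p <- dec$p_obj[sampled]
    p_star <- as.numeric(targets$label[sampled] == 1L)
    pt <- 1 - abs(p - p_star)
    obj <- mean(focal(pt, weights$gamma))
    dpt <- focal_dpt(pt, weights$gamma) / n_obj
    dp <- dpt * ifelse(p_star == 1, 1, -1)     # dpt/dp
    dz <- dp * p * (1 - p)                      # through the 2-way softmax
    dhead[sampled, 2] <- dhead[sampled, 2] + weights$lambda_obj * dz
    dhead[sampled, 1] <- dhead[sampled, 1] - weights$lambda_obj * dz
  }

  loc <- 0; av <- 0; ad <- 0
  if (n_loc > 0) {
    # localization
    tgt <- targets$enc[pos, , drop = FALSE]
    prd <- dec$enc[pos, , drop = FALSE]
    res <- tgt - prd
    loc <- mean(rowSums(huber(res, weights$delta)))
    dres <- ifelse(abs(res) <= weights$delta, res,
                   weights$delta * sign(res))
    dhead[pos, 3:6] <- dhead[pos, 3:6] - weights$lambda_loc * dres / n_loc

    # angle value (sigmoid output, dual-dataset masking)
    v <- dec$value[pos]
    tv <- targets$theta_v[pos]
    is1 <- targets$ds_tag[pos] == "ds1"
    av <- (sum(weights$lambda_ds1 * 0.5 * (tv[is1] - v[is1])^2) +
             sum(weights$lambda_ds2 * 0.5 * v[!is1]^2)) / n_loc
    dv <- numeric(n_loc)
    dv[is1] <- weights$lambda_ds1 * (v[is1] - tv[is1]) / n_loc
    dv[!is1] <- weights$lambda_ds2 * v[!is1] / n_loc
    dhead[pos, 9] <- dhead[pos, 9] + weights$lambda_av * dv * v * (1 - v)

    # angle direction (gated focal on softmax probability)
    gate <- is1 & tv > weights$epsilon
    if (any(gate)) {
      gi <- pos[gate]
      pth <- dec$p_ccw[gi]
      pth_star <- as.numeric(targets$ccw[gi])
      pt <- 1 - abs(pth - pth_star)
      ad <- mean(focal(pt, weights$gamma))
      dpt <- focal_dpt(pt, weights$gamma) / sum(gate)
      dp <- dpt * ifelse(pth_star == 1, 1, -1)
      dz <- dp * pth * (1 - pth)
      dhead[gi, 8] <- dhead[gi, 8] + weights$lambda_ad * dz
      dhead[gi, 7] <- dhead[gi, 7] - weights$lambda_ad * dz
    }
  }

  list(loss = total_loss(loc, obj, av, ad, weights), dhead = dhead)
}
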