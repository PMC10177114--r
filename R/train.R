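# ---------------------------------------------------------------------------
# Training: anchor target construction, momentum SGD with cosine learning
# rate, and the step loop binding data pipeline, network, matching and loss.
# ---------------------------------------------------------------------------

#' Build per-anchor training targets for one image
#'
#' Matches the anchor set against the image's ground-truth boxes and, for
#' each positive anchor, records the box-encoding regression target, the
#' absolute angle, the direction label and the dataset tag (which controls
#' the angle-loss masking).
#'
#' @param anchors an `anchor_set`.
#' @param img an [annotated_image()] (letterboxed to the anchor frame).
#' @param pos_thresh,neg_thresh matching thresholds, see [match_anchors()].
#' @return list with `label`, `gt_index`, `enc` (n x 4 matrix, rows defined
#'   for positives), `theta_v`, `ccw`, `ds_tag`.
#' @export
build_targets <- function(anchors, img, pos_thresh = 0.5, neg_thresh = 0.5) {
  r <- img$records
  gtb <- r[, c("xmin", "ymin", "xmax", "ymax"), drop = FALSE]
  m <- match_anchors(anchors, gtb, pos_thresh, neg_thresh)
  n <- anchors$n
  enc <- matrix(NA_real_, n, 4L)
  theta_v <- rep(NA_real_, n)
  ccw <- rep(NA, n)
  pos <- which(m$label == 1L)
  if (length(pos)) {
    gi <- m$gt_index[pos]
    enc[pos, ] <- as.matrix(encode_box(box_to_center(gtb[gi, , drop = FALSE]),
                                       anchors$centers[pos, , drop = FALSE]))
    th <- r$theta[gi]
    sp <- split_angle(ifelse(is.na(th), 0, th))
    theta_v[pos] <- ifelse(is.na(th), NA_real_, sp$value)
    ccw[pos] <- ifelse(is.na(th), NA, sp$ccw)
  }
  list(label = m$label, gt_index = m$gt_index, enc = enc,
       theta_v = theta_v, ccw = ccw,
       ds_tag = rep(img$dataset, n))
}

#' Training configuration
#'
#' @param net a [net_config()].
#' @param aug an [aug_config()] (batch sizes and augmentation
#'   probabilities).
#' @param weights a [loss_weights()].
#' @param total_steps optimizer steps.
#' @param lr peak learning rate of the cosine schedule.
#' @param momentum SGD momentum coefficient.
#' @param warmup_steps linear warm-up length.
#' @param clip_norm global gradient-norm ceiling (0 disables); rescales the
#'   whole gradient when its L2 norm exceeds this, the usual guard against
#'   occasional hard batches destabilizing SGD.
#' @param pos_thresh,neg_thresh anchor matching thresholds.
#' @param sample_size,pos_fraction mini-batch sampler settings, see
#'   [sample_minibatch()].
#' @param checkpoint_every save a checkpoint every this many steps (0 = only
#'   at the end; only used when a checkpoint path is given).
#' @param seed master seed for weight init, batching and sampling.
#' @return list of class `train_config`.
#' @export
train_config <- function(net = net_config(), aug = aug_config(),
                         weights = loss_weights(), total_steps = 50000L,
                         lr = 0.02, momentum = 0.9, warmup_steps = 100L,
                         clip_norm = 10,
                         pos_thresh = 0.5, neg_thresh = 0.5,
                         sample_size = 256L, pos_fraction = 0.25,
                         checkpoint_every = 0L, seed = 1L) {
  stopifnot(total_steps > 0, lr > 0, momentum >= 0, momentum < 1)
  structure(list(net = net, aug = aug, weights = weights,
                 total_steps = as.integer(total_steps), lr = lr,
                 momentum = momentum, warmup_steps = as.integer(warmup_steps),
                 clip_norm = clip_norm,
                 pos_thresh = pos_thresh, neg_thresh = neg_thresh,
                 sample_size = as.integer(sample_size),
                 pos_fraction = pos_fraction,
                 checkpoint_every = as.integer(checkpoint_every),
                 seed = as.integer(seed)),
            class = "train_config")
}

lr_at_step <- function(cfg, step) {
  if (step <= cfg$warmup_steps && cfg$warmup_steps > 0) {
    return(cfg$lr * step / cfg$warmup_steps)
  }
  frac <- (step - cfg$warmup_steps) /
    max(1, cfg$total_steps - cfg$warmup_steps)
  cfg$lr * 0.5 * (1 + cos(pi * min(frac, 1)))
}

# elementwise recursion over nested parameter lists
tree_zero <- function(p) {
  if (is.list(p)) lapply(p, tree_zero) else p * 0
}

tree_add <- function(a, b) {
  if (is.list(a)) {
    for (nm in names(a)) a[[nm]] <- tree_add(a[[nm]], b[[nm]])
    a
  } else a + b
}

tree_scale <- function(a, s) {
  if (is.list(a)) lapply(a, tree_scale, s = s) else a * s
}

tree_sumsq <- function(a) {
  if (is.list(a)) sum(vapply(a, tree_sumsq, numeric(1))) else sum(a * a)
}

sgd_update <- function(params, grads, vel, lr, momentum) {
  if (is.list(params)) {
    for (nm in names(params)) {
      r <- sgd_update(params[[nm]], grads[[nm]], vel[[nm]], lr, momentum)
      params[[nm]] <- r$p
      vel[[nm]] <- r$v
    }
    return(list(p = params, v = vel))
  }
  v <- momentum * vel - lr * grads
  list(p = params + v, v = v)
}

#' Train the detector
#'
#' Runs the full loop: draw a dual-dataset batch, letterbox, forward pass,
#' anchor matching and mini-batch sampling, four-term loss, backward pass,
#' momentum-SGD step under a cosine learning-rate schedule. Gradients are
#' averaged over the images of the batch; each image contributes its own
#' per-image-normalized loss. The run is deterministic given the
#' configuration seed.
#'
#' @param cfg a [train_config()].
#' @param ds1 list of angle-labeled [annotated_image()]s.
#' @param ds2 list of box-only images; defaults to `ds1` (every record's
#'   angle is simply masked by the ds2 tag), mirroring the common case where
#'   one labeled pool feeds both roles.
#' @param net optional pre-built or resumed `rotface_net`; built fresh from
#'   `cfg$net` when NULL.
#' @param checkpoint_path optional path for checkpoints.
#' @param log_every record the loss breakdown every this many steps (always
#'   includes the first and last step).
#' @param verbose print progress lines.
#' @return list with `net` (trained network), `log` (data frame of step,
#'   loc, obj, av, ad, total, lr) and `cfg`.
#' @export
train <- function(cfg, ds1, ds2 = NULL, net = NULL, checkpoint_path = NULL,
                  log_every = 10L, verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"))
  if (!length(ds1)) stop("ds1 must contain at least one image")
  set.seed(cfg$seed)
  if (is.null(net)) net <- build_network(cfg$net)
  ncfg <- net$cfg
  anchors <- generate_anchors(ncfg$input_size, ncfg$input_size,
                              ncfg$strides, ncfg$base_sizes,
                              ncfg$scale_ratios, ncfg$aspect_ratios)
  s1 <- new_image_stream(ds1)
  s2 <- new_image_stream(if (is.null(ds2)) ds1 else ds2)
  vel <- tree_zero(net$params)
  log_rows <- list()
  for (step in seq_len(cfg$total_steps)) {
    batch <- make_dual_batch(s1, s2, cfg$aug)
    gacc <- NULL
    parts <- c(loc = 0, obj = 0, av = 0, ad = 0, total = 0)
    for (im in batch) {
      im <- letterbox(im, ncfg$input_size)
      fwd <- network_forward(net, im$image, train = TRUE, keep_cache = TRUE)
      net$state <- fwd$state
      tgt <- build_targets(anchors, im, cfg$pos_thresh, cfg$neg_thresh)
      smp <- sample_minibatch(list(label = tgt$label), cfg$sample_size,
                              cfg$pos_fraction)
      lg <- tryCatch(
        detection_loss_grad(fwd$head, tgt, smp, cfg$weights),
        error = function(e) {
          stop(sprintf(
            "non-finite loss at step %d (%s image, %d positives): %s",
            step, im$dataset, length(smp$pos), conditionMessage(e)),
            call. = FALSE)
        })
      if (!is.finite(lg$loss$total)) {
        stop(sprintf(
          "non-finite loss at step %d (loc %g obj %g av %g ad %g); %s image, %d positives",
          step, lg$loss$loc, lg$loss$obj, lg$loss$av, lg$loss$ad,
          im$dataset, length(smp$pos)))
      }
      g <- network_backward(net, fwd, lg$dhead)
      gacc <- if (is.null(gacc)) g else tree_add(gacc, g)
      parts <- parts + c(lg$loss$loc, lg$loss$obj, lg$loss$av, lg$loss$ad,
                         lg$loss$total)
    }
    nb <- length(batch)
    gacc <- tree_scale(gacc, 1 / nb)
    parts <- parts / nb
    if (cfg$clip_norm > 0) {
      gn <- sqrt(tree_sumsq(gacc))
      if (gn > cfg$clip_norm) gacc <- tree_scale(gacc, cfg$clip_norm / gn)
    }
    lr <- lr_at_step(cfg, step)
    upd <- sgd_update(net$params, gacc, vel, lr, cfg$momentum)
    net$params <- upd$p
    vel <- upd$v
    if (step == 1L || step == cfg$total_steps || step %% log_every == 0L) {
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(step = step, loc = parts["loc"], obj = parts["obj"],
                   av = parts["av"], ad = parts["ad"],
                   total = parts["total"], lr = lr, row.names = NULL)
      if (verbose) {
        message(sprintf(
          "step %5d  lr %.4g  total %.4f (loc %.3f obj %.3f av %.3f ad %.3f)",
          step, lr, parts["total"], parts["loc"], parts["obj"],
          parts["av"], parts["ad"]))
      }
    }
    if (!is.null(checkpoint_path) && cfg$checkpoint_every > 0L &&
        step %% cfg$checkpoint_every == 0L) {
      save_checkpoint(net, checkpoint_path, extra = list(step = step))
    }
  }
  if (!is.null(checkpoint_path)) {
    save_checkpoint(net, checkpoint_path,
                    extra = list(step = cfg$total_steps))
  }
  list(net = net, log = do.call(rbind, log_rows), cfg = cfg)
}

#' Evaluate a trained network on annotated scenes
#'
#' Runs [detect()] on every image and scores the detections against the
#' (letterboxed) ground truth.
#'
#' @param net a trained `rotface_net`.
#' @param scenes list of [annotated_image()]s.
#' @param score_thresh,nms_iou post-processing settings.
#' @param iou_thresh evaluation matching threshold.
#' @return an `eval_result`, see [evaluate_detections()].
#' @export
evaluate_network <- function(net, scenes, score_thresh = 0.5, nms_iou = 0.5,
                             iou_thresh = 0.5) {
  anchors <- generate_anchors(net$cfg$input_size, net$cfg$input_size,
                              net$cfg$strides, net$cfg$base_sizes,
                              net$cfg$scale_ratios, net$cfg$aspect_ratios)
  dets <- vector("list", length(scenes))
  gts <- vector("list", length(scenes))
  for (i in seq_along(scenes)) {
    im <- letterbox(scenes[[i]], net$cfg$input_size)
    fwd <- network_forward(net, im$image, train = FALSE, keep_cache = FALSE)
    dets[[i]] <- postprocess(decode_head(fwd$head), anchors,
                             score_thresh, nms_iou)
    gts[[i]] <- im$records
  }
  evaluate_detections(dets, gts, iou_thresh)
}
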