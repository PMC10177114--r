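# ---------------------------------------------------------------------------
# The detector network: a 14-unit CBA backbone in five blocks, a top-down
# feature-pyramid neck producing four uniform-width maps, and one shared
# convolutional head emitting 9 values per anchor.
# ---------------------------------------------------------------------------

#' Network configuration
#'
#' @param input_channels 1 (grayscale / infrared) or 3 (RGB).
#' @param input_size square input side in pixels.
#' @param base_width channel count of the first backbone block; later blocks
#'   double it per block, and the third CBA of each block is 4x as wide as
#'   the first two.
#' @param neck_width common channel width of the four pyramid maps (the
#'   shared head requires uniformity).
#' @param head_kernel spatial size of the shared head convolution.
#' @param k anchors per cell; the head emits `k * 9` channels per map.
#' @param strides,base_sizes,scale_ratios,aspect_ratios anchor grid
#'   parameters, see [generate_anchors()].
#' @param seed integer seed used when initializing weights.
#' @return list of class `net_config`.
#' @export
net_config <- function(input_channels = 3L, input_size = 400L,
                       base_width = 16L, neck_width = 64L, head_kernel = 3L,
                       k = 6L, strides = c(8, 16, 32, 64),
                       base_sizes = c(32, 64, 128, 256),
                       scale_ratios = c(1, 2), aspect_ratios = c(1, 2, 0.5),
                       seed = 42L) {
  if (!input_channels %in% c(1L, 3L)) {
    stop("input_channels must be 1 or 3")
  }
  stopifnot(input_size > 0, base_width >= 1, neck_width >= 1, k >= 1)
  structure(list(
    input_channels = as.integer(input_channels),
    input_size = as.integer(input_size),
    base_width = as.integer(base_width),
    neck_width = as.integer(neck_width),
    head_kernel = as.integer(head_kernel),
    k = as.integer(k), strides = strides, base_sizes = base_sizes,
    scale_ratios = scale_ratios, aspect_ratios = aspect_ratios,
    seed = as.integer(seed)
  ), class = "net_config")
}

# Backbone layout: block 1 has two CBA (the first with a 7x7 kernel and
# stride 2); blocks 2-5 have three CBA each, the first at stride 2 and the
# third 4x as wide as the first two. 2 + 3 * 4 = 14 CBA in total. The
# outputs of blocks 3, 4 and 5 (strides 8, 16, 32) feed the neck.
backbone_layout <- function(cfg) {
  w <- cfg$base_width
  layers <- list(
    list(name = "b1c1", k = 7L, stride = 2L, out = w),
    list(name = "b1c2", k = 3L, stride = 1L, out = w)
  )
  for (b in 2:5) {
    wb <- as.integer(cfg$base_width * 2^(b - 1))
    layers <- c(layers, list(
      list(name = sprintf("b%dc1", b), k = 3L, stride = 2L, out = wb),
      list(name = sprintf("b%dc2", b), k = 3L, stride = 1L, out = wb),
      list(name = sprintf("b%dc3", b), k = 3L, stride = 1L, out = 4L * wb)
    ))
  }
  layers
}

#' Build the detector network
#'
#' Initializes all parameters (He-normal convolution weights, unit-gain batch
#' norms) under the configuration seed. The head's objectness-foreground bias
#' starts at -2 so that the initial object probability is low (about 0.12)
#' and the focal objectness loss is not swamped by the negative majority at
#' step 0.
#'
#' @param cfg a [net_config()].
#' @return object of class `rotface_net` holding `params`, `state` (batch
#'   norm running statistics) and the configuration.
#' @export
build_network <- function(cfg = net_config()) {
  stopifnot(inherits(cfg, "net_config"))
  set.seed(cfg$seed)
  params <- list()
  state <- list()
  cin <- cfg$input_channels
  for (l in backbone_layout(cfg)) {
    params[[l$name]] <- list(conv = init_conv(l$k, l$k, cin, l$out),
                             bn = init_bn(l$out))
    state[[l$name]] <- init_bn_state(l$out)
    cin <- l$out
  }
  widths <- vapply(backbone_layout(cfg), `[[`, integer(1), "out")
  c3 <- widths[8]; c4 <- widths[11]; c5 <- widths[14]
  nw <- cfg$neck_width
  params$lat3 <- init_conv(1L, 1L, c3, nw)
  params$lat4 <- init_conv(1L, 1L, c4, nw)
  params$lat5 <- init_conv(1L, 1L, c5, nw)
  params$p6 <- init_conv(3L, 3L, nw, nw)
  hb <- rep(0, cfg$k * 9L)
  hb[(seq_len(cfg$k) - 1L) * 9L + 2L] <- -2  # objectness-foreground bias
  # small-sd head init keeps initial logits near their biases, so training
  # starts from a calm low-objectness prior instead of saturated focal terms
  params$head <- init_conv(cfg$head_kernel, cfg$head_kernel, nw, cfg$k * 9L,
                           sd = 0.01)
  params$head$b <- hb
  structure(list(cfg = cfg, params = params, state = state),
            class = "rotface_net")
}

#' @export
print.rotface_net <- function(x, ...) {
  cat(sprintf(
    "rotface_net: %d input channels, %d px input, %s parameters\n",
    x$cfg$input_channels, x$cfg$input_size,
    format(n_params(x), big.mark = ",")))
  invisible(x)
}

#' Total trainable parameter count
#' @param net a `rotface_net`.
#' @return integer number of scalar parameters.
#' @export
n_params <- function(net) {
  sum(vapply(unlist(net$params, recursive = TRUE, use.names = FALSE),
             length, integer(1)))
}

# Reshape a per-level head tensor [gh, gw, k*9] into a per-anchor matrix
# whose rows follow the anchor flat order (template fastest, then column,
# then row) and whose 9 columns are
# [obj_bg, obj_fg, tx, ty, tw, th, dir_cw, dir_ccw, angle_value].
head_level_to_matrix <- function(h, k) {
  d <- dim(h)
  dim(h) <- c(d[1], d[2], 9L, k)
  m <- aperm(h, c(4L, 2L, 1L, 3L))
  dim(m) <- c(k * d[1] * d[2], 9L)
  m
}

head_matrix_to_level <- function(m, gh, gw, k) {
  dim(m) <- c(k, gw, gh, 9L)
  h <- aperm(m, c(3L, 2L, 4L, 1L))
  dim(h) <- c(gh, gw, 9L * k)
  h
}

#' Run the network forward
#'
#' @param net a `rotface_net`.
#' @param x input image array `[H, W, C]` with `C` matching the
#'   configuration; values are expected in `[0, 1]`.
#' @param train logical; `TRUE` uses per-image batch-norm statistics (and
#'   updates the running averages), `FALSE` uses the running averages.
#' @param keep_cache logical; keep intermediate activations for a backward
#'   pass.
#' @return list with `head` (matrix `n_anchors x 9` of raw head values in
#'   anchor flat order), `levels` (per-level grid sizes), `state` (updated
#'   running statistics) and, if requested, `cache`.
#' @export
network_forward <- function(net, x, train = TRUE, keep_cache = train) {
  cfg <- net$cfg
  if (length(dim(x)) != 3 || dim(x)[3] != cfg$input_channels) {
    stop("input must be an [H, W, C] array with C = ", cfg$input_channels)
  }
  p <- net$params; st <- net$state
  cache <- list()
  feats <- list()
  h <- x
  for (l in backbone_layout(cfg)) {
    r <- cba_fw(p[[l$name]], st[[l$name]], h, l$stride, train, keep_cache)
    h <- r$y
    st[[l$name]] <- r$state
    if (keep_cache) cache[[l$name]] <- r$cache
    if (l$name %in% c("b3c3", "b4c3", "b5c3")) feats[[l$name]] <- h
  }
  # neck: lateral 1x1 projections, top-down nearest upsampling with adds,
  # and an extra stride-2 map from the deepest merged level
  l3 <- conv_fw(p$lat3, feats$b3c3, 1L, keep_cache)
  l4 <- conv_fw(p$lat4, feats$b4c3, 1L, keep_cache)
  l5 <- conv_fw(p$lat5, feats$b5c3, 1L, keep_cache)
  p5 <- l5$y
  u5 <- upsample2_fw(p5, dim(l4$y)[1], dim(l4$y)[2])
  p4 <- l4$y + u5$y
  u4 <- upsample2_fw(p4, dim(l3$y)[1], dim(l3$y)[2])
  p3 <- l3$y + u4$y
  p6c <- conv_fw(p$p6, p5, 2L, keep_cache)
  maps <- list(p3 = p3, p4 = p4, p5 = p5, p6 = p6c$y)
  if (keep_cache) {
    cache$neck <- list(l3 = l3$cache, l4 = l4$cache, l5 = l5$cache,
                       u5 = u5$cache, u4 = u4$cache, p6 = p6c$cache)
  }
  heads <- vector("list", 4L)
  hcaches <- vector("list", 4L)
  levels <- vector("list", 4L)
  for (i in seq_len(4L)) {
    hc <- conv_fw(p$head, maps[[i]], 1L, keep_cache)
    heads[[i]] <- head_level_to_matrix(hc$y, cfg$k)
    hcaches[[i]] <- hc$cache
    levels[[i]] <- c(gh = dim(maps[[i]])[1], gw = dim(maps[[i]])[2])
  }
  if (keep_cache) cache$head <- hcaches
  list(head = do.call(rbind, heads), levels = levels, state = st,
       cache = if (keep_cache) cache else NULL)
}

#' Backpropagate a head gradient through the network
#'
#' @param net a `rotface_net`.
#' @param fwd result of [network_forward()] with `keep_cache = TRUE`.
#' @param dhead gradient of the loss with respect to the head matrix.
#' @return named list of parameter gradients with the same shapes as
#'   `net$params`.
#' @export
network_backward <- function(net, fwd, dhead) {
  cfg <- net$cfg
  p <- net$params
  cache <- fwd$cache
  if (is.null(cache)) stop("forward pass was run without keep_cache")
  grads <- list()
  # split dhead by level and push through the shared head conv
  sizes <- vapply(fwd$levels, function(l) cfg$k * l["gh"] * l["gw"],
                  numeric(1))
  offs <- cumsum(c(0, sizes))
  dmaps <- vector("list", 4L)
  gh_acc <- NULL
  for (i in seq_len(4L)) {
    gh <- fwd$levels[[i]]["gh"]; gw <- fwd$levels[[i]]["gw"]
    dm <- dhead[(offs[i] + 1):offs[i + 1], , drop = FALSE]
    dlev <- head_matrix_to_level(dm, gh, gw, cfg$k)
    g <- conv_bw(p$head, cache$head[[i]], dlev)
    dmaps[[i]] <- g$dx
    if (is.null(gh_acc)) {
      gh_acc <- list(W = g$dW, b = g$db)
    } else {
      gh_acc$W <- gh_acc$W + g$dW
      gh_acc$b <- gh_acc$b + g$db
    }
  }
  grads$head <- gh_acc
  # neck backward
  nc <- cache$neck
  g6 <- conv_bw(p$p6, nc$p6, dmaps[[4]])
  grads$p6 <- list(W = g6$dW, b = g6$db)
  dp3 <- dmaps[[1]]
  dp4 <- dmaps[[2]] + upsample2_bw(nc$u4, dp3)
  dp5 <- dmaps[[3]] + g6$dx + upsample2_bw(nc$u5, dp4)
  gl3 <- conv_bw(p$lat3, nc$l3, dp3)
  gl4 <- conv_bw(p$lat4, nc$l4, dp4)
  gl5 <- conv_bw(p$lat5, nc$l5, dp5)
  grads$lat3 <- list(W = gl3$dW, b = gl3$db)
  grads$lat4 <- list(W = gl4$dW, b = gl4$db)
  grads$lat5 <- list(W = gl5$dW, b = gl5$db)
  # backbone backward, injecting the lateral gradients at block outputs
  inject <- list(b3c3 = gl3$dx, b4c3 = gl4$dx, b5c3 = gl5$dx)
  layout <- backbone_layout(cfg)
  dh <- array(0, dim(inject$b5c3))
  for (i in rev(seq_along(layout))) {
    l <- layout[[i]]
    if (!is.null(inject[[l$name]])) dh <- dh + inject[[l$name]]
    g <- cba_bw(p[[l$name]], cache[[l$name]], dh, need_dx = (i > 1L))
    grads[[l$name]] <- g$grads
    dh <- g$dx
  }
  grads
}

#' Decode raw head values into probabilities and encodings
#'
#' Applies the two-way softmax to the objectness and direction logit pairs
#' and the logistic sigmoid to the angle-value logit; box encodings pass
#' through unchanged.
#'
#' @param head matrix `n x 9` of raw head values (see [network_forward()]).
#' @return list with `p_obj` (object probability), `p_ccw` (counterclockwise
#'   probability), `value` (absolute angle in (0, 1)) and `enc` (matrix of
#'   box encodings tx, ty, tw, th).
#' @export
decode_head <- function(head) {
  stopifnot(ncol(head) == 9)
  list(
    p_obj = stats::plogis(head[, 2] - head[, 1]),
    p_ccw = stats::plogis(head[, 8] - head[, 7]),
    value = stats::plogis(head[, 9]),
    enc = head[, 3:6, drop = FALSE]
  )
}

#' Save / load a network checkpoint
#'
#' Single-file checkpoint with a versioned schema holding the configuration,
#' parameters, batch-norm running statistics and optional training state.
#'
#' @param net a `rotface_net`.
#' @param path file path.
#' @param extra optional list (e.g. optimizer momentum, step counter).
#' @return `load_checkpoint` returns a list with `net` and `extra`.
#' @export
save_checkpoint <- function(net, path, extra = NULL) {
  obj <- list(format = "rotface-checkpoint", version = 1L,
              cfg = net$cfg, params = net$params, state = net$state,
              extra = extra)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "rotface-checkpoint")) {
    stop("not a rotface checkpoint: ", path)
  }
  net <- structure(list(cfg = obj$cfg, params = obj$params,
                        state = obj$state), class = "rotface_net")
  list(net = net, extra = obj$extra)
}
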