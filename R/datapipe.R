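# ---------------------------------------------------------------------------
# Data pipeline: angle-aware augmentations (90-degree rotation, flips,
# 2x2 / 3x3 tiling), JSONL annotation I/O, letterboxing and the
# dual-dataset batcher.
# ---------------------------------------------------------------------------

#' Augment an annotated image
#'
#' Applies one of the three pixel-exact affine augmentations and transforms
#' every box, keypoint pair and angle consistently:
#' \itemize{
#'   \item `rot90ccw` rotates the whole image 90 degrees counterclockwise
#'     (output size swaps W and H); points map as (x, y) -> (y, W - x).
#'   \item `hflip` mirrors left-right: (x, y) -> (W - x, y).
#'   \item `vflip` mirrors top-bottom: (x, y) -> (x, H - y).
#' }
#' Mirroring swaps the left/right roles of the keypoints (the keypoint that
#' lands leftmost in the upright face is the mirrored right keypoint), which
#' is what makes the closed-form angle maps of [transform_angle()] agree
#' with recomputing the angle from the transformed keypoints.
#'
#' @param img an [annotated_image()].
#' @param op one of `"rot90ccw"`, `"hflip"`, `"vflip"`.
#' @return the augmented [annotated_image()].
#' @export
augment <- function(img, op = c("rot90ccw", "hflip", "vflip")) {
  op <- match.arg(op)
  W <- img$width; H <- img$height
  r <- img$records
  x <- img$image
  has_kp <- !is.na(r$xl)
  if (op == "rot90ccw") {
    if (!is.null(x)) {
      x <- aperm(x, c(2, 1, 3))
      x <- x[rev(seq_len(dim(x)[1])), , , drop = FALSE]
    }
    r2 <- r
    r2$xmin <- r$ymin; r2$xmax <- r$ymax
    r2$ymin <- W - r$xmax; r2$ymax <- W - r$xmin
    r2$xl <- r$yl; r2$yl <- W - r$xl
    r2$xr <- r$yr; r2$yr <- W - r$xr
    nw <- H; nh <- W
  } else if (op == "hflip") {
    if (!is.null(x)) x <- x[, rev(seq_len(W)), , drop = FALSE]
    r2 <- r
    r2$xmin <- W - r$xmax; r2$xmax <- W - r$xmin
    # mirrored keypoints swap left/right roles
    r2$xl <- W - r$xr; r2$yl <- r$yr
    r2$xr <- W - r$xl; r2$yr <- r$yl
    nw <- W; nh <- H
  } else {
    if (!is.null(x)) x <- x[rev(seq_len(H)), , , drop = FALSE]
    r2 <- r
    r2$ymin <- H - r$ymax; r2$ymax <- H - r$ymin
    r2$xl <- r$xr; r2$yl <- H - r$yr
    r2$xr <- r$xl; r2$yr <- H - r$yl
    nw <- W; nh <- H
  }
  r2$theta <- ifelse(is.na(r$theta), NA_real_, transform_angle(r$theta, op))
  if (any(!has_kp)) r2[!has_kp, c("xl", "yl", "xr", "yr")] <- NA_real_
  annotated_image(x, r2, dataset = img$dataset, width = nw, height = nh)
}

# bilinear resize of an [H, W, C] array
resize_image <- function(x, out_h, out_w) {
  m <- matrix(c(dim(x)[2] / out_w, 0, 0, dim(x)[1] / out_h, 0, 0), 2, 3)
  .cpp_affine_sample(x, m, as.integer(out_h), as.integer(out_w))
}

#' Tile several annotated images into one
#'
#' Combines 4 (layout `"2x2"`) or 9 (layout `"3x3"`) equally-sized images
#' into a single image of the same size: each source is resized (bilinear)
#' to one grid cell and placed row-major. Boxes and keypoints are scaled and
#' offset; angles are unchanged because the per-cell scaling is isotropic
#' for square canvases. The output carries the union of all records.
#'
#' @param imgs list of 4 or 9 [annotated_image()]s with equal sizes and
#'   channel counts.
#' @param layout `"2x2"` or `"3x3"`.
#' @return the tiled [annotated_image()]; its dataset tag is taken from the
#'   first input.
#' @export
tile <- function(imgs, layout = c("2x2", "3x3")) {
  layout <- match.arg(layout)
  f <- if (layout == "2x2") 2L else 3L
  if (length(imgs) != f * f) {
    stop("layout ", layout, " needs ", f * f, " images")
  }
  W <- imgs[[1]]$width; H <- imgs[[1]]$height
  C <- dim(imgs[[1]]$image)[3]
  same <- vapply(imgs, function(i) {
    i$width == W && i$height == H && dim(i$image)[3] == C
  }, logical(1))
  if (!all(same)) stop("tiled images must share size and channel count")
  ch <- H %/% f; cw <- W %/% f
  sy <- ch / H; sx <- cw / W
  out <- array(0, dim = c(H, W, C))
  recs <- vector("list", f * f)
  for (i in seq_len(f * f)) {
    row <- (i - 1L) %/% f
    col <- (i - 1L) %% f
    small <- resize_image(imgs[[i]]$image, ch, cw)
    out[row * ch + seq_len(ch), col * cw + seq_len(cw), ] <- small
    r <- imgs[[i]]$records
    ox <- col * cw; oy <- row * ch
    r$xmin <- r$xmin * sx + ox; r$xmax <- r$xmax * sx + ox
    r$ymin <- r$ymin * sy + oy; r$ymax <- r$ymax * sy + oy
    r$xl <- r$xl * sx + ox; r$xr <- r$xr * sx + ox
    r$yl <- r$yl * sy + oy; r$yr <- r$yr * sy + oy
    recs[[i]] <- r
  }
  annotated_image(out, do.call(rbind, recs), dataset = imgs[[1]]$dataset)
}

#' Letterbox an annotated image to a square network input
#'
#' Scales isotropically to fit, centers, and zero-pads the borders; boxes
#' and keypoints follow, angles are unchanged.
#'
#' @param img an [annotated_image()] with pixels attached.
#' @param size target square side.
#' @return the letterboxed [annotated_image()].
#' @export
letterbox <- function(img, size) {
  W <- img$width; H <- img$height
  if (W == size && H == size) return(img)
  s <- min(size / W, size / H)
  nw <- max(1L, round(W * s)); nh <- max(1L, round(H * s))
  small <- resize_image(img$image, nh, nw)
  C <- dim(small)[3]
  out <- array(0, dim = c(size, size, C))
  ox <- (size - nw) %/% 2; oy <- (size - nh) %/% 2
  out[oy + seq_len(nh), ox + seq_len(nw), ] <- small
  r <- img$records
  sxx <- nw / W; syy <- nh / H
  r$xmin <- r$xmin * sxx + ox; r$xmax <- r$xmax * sxx + ox
  r$ymin <- r$ymin * syy + oy; r$ymax <- r$ymax * syy + oy
  r$xl <- r$xl * sxx + ox; r$xr <- r$xr * sxx + ox
  r$yl <- r$yl * syy + oy; r$yr <- r$yr * syy + oy
  annotated_image(out, r, dataset = img$dataset)
}

#' Write / read annotations as JSON lines
#'
#' One JSON object per line per image: `width`, `height`, `dataset`,
#' optional `image` (a path, written as PNG when `image_dir` is given and
#' the `png` package is installed) and `records` (boxes plus optional
#' `theta` and keypoints). Keypoint-only records get their angle derived on
#' read. The record round trip is lossless to double precision.
#'
#' @param imgs list of [annotated_image()]s.
#' @param path JSONL file path.
#' @param image_dir optional directory for PNG pixel data.
#' @return `read_annotations` returns a list of [annotated_image()]s (with
#'   pixels when their PNGs are readable).
#' @export
write_annotations <- function(imgs, path, image_dir = NULL) {
  write_png <- !is.null(image_dir) && requireNamespace("png", quietly = TRUE)
  if (write_png) dir.create(image_dir, showWarnings = FALSE, recursive = TRUE)
  lines <- vapply(seq_along(imgs), function(i) {
    im <- imgs[[i]]
    ipath <- NULL
    if (write_png && !is.null(im$image)) {
      ipath <- file.path(image_dir, sprintf("img%05d.png", i))
      png::writePNG(im$image[, , , drop = TRUE], ipath)
    }
    rec <- im$records
    keep <- c("xmin", "ymin", "xmax", "ymax", "theta", "xl", "yl", "xr", "yr")
    obj <- list(width = im$width, height = im$height, dataset = im$dataset,
                records = rec[, keep, drop = FALSE])
    if (!is.null(ipath)) obj$image <- ipath
    jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE, digits = NA,
                     na = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no such annotation file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) {
                      stop("malformed annotation record at line ", i, ": ",
                           conditionMessage(e))
                    })
    img <- NULL
    if (!is.null(obj$image) && file.exists(obj$image) &&
        requireNamespace("png", quietly = TRUE)) {
      img <- png::readPNG(obj$image)
      if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
    }
    rec <- as.data.frame(obj$records)
    tryCatch(
      annotated_image(img, rec, dataset = obj$dataset,
                      width = obj$width, height = obj$height),
      error = function(e) {
        stop("invalid annotation record at line ", i, ": ",
             conditionMessage(e))
      })
  })
}

#' Augmentation and batching configuration
#'
#' Per-operation trigger probabilities, separately for the angle-labeled
#' (ds1) and box-only (ds2) datasets, plus the two batch sizes. The affine
#' operations are applied independently of each other; tiling (when
#' triggered) merges freshly drawn images after their affine augmentation.
#' The defaults — quarter-turn rotation only for the angle-labeled stream,
#' flips for both, heavy 2x2 tiling — suit training on small photographic
#' datasets.
#'
#' @param p_rot90,p_hflip,p_vflip,p_tile2,p_tile3 length-2 numeric vectors
#'   of probabilities, `c(ds1, ds2)`.
#' @param t1,t2 images drawn per batch from ds1 and ds2.
#' @return list of class `aug_config`.
#' @export
aug_config <- function(p_rot90 = c(0.5, 0), p_hflip = c(0.5, 0.5),
                       p_vflip = c(0.5, 0.5), p_tile2 = c(0.8, 0.8),
                       p_tile3 = c(0, 0), t1 = 7L, t2 = 5L) {
  p <- list(p_rot90 = p_rot90, p_hflip = p_hflip, p_vflip = p_vflip,
            p_tile2 = p_tile2, p_tile3 = p_tile3)
  for (nm in names(p)) {
    if (length(p[[nm]]) != 2 || any(p[[nm]] < 0) || any(p[[nm]] > 1)) {
      stop(nm, " must be two probabilities (ds1, ds2)")
    }
  }
  stopifnot(t1 >= 0, t2 >= 0, t1 + t2 > 0)
  structure(c(p, list(t1 = as.integer(t1), t2 = as.integer(t2))),
            class = "aug_config")
}

# A reshuffling stream over a fixed image list: draw(n) returns n images,
# reshuffling (via the current R random stream) at each epoch boundary.
new_image_stream <- function(imgs) {
  if (length(imgs) == 0L) stop("empty image stream")
  env <- new.env(parent = emptyenv())
  env$imgs <- imgs
  env$order <- sample.int(length(imgs))
  env$pos <- 0L
  env$draw <- function(n) {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      if (env$pos >= length(env$imgs)) {
        env$order <- sample.int(length(env$imgs))
        env$pos <- 0L
      }
      env$pos <- env$pos + 1L
      out[[i]] <- env$imgs[[env$order[env$pos]]]
    }
    out
  }
  env
}

# draw one training image from a stream: affine ops first (independent
# coin flips), then optional tiling with partners drawn from the same
# stream and augmented the same way
draw_training_image <- function(stream, cfg, ds_col) {
  one <- function() {
    im <- stream$draw(1L)[[1L]]
    if (stats::runif(1) < cfg$p_rot90[ds_col]) im <- augment(im, "rot90ccw")
    if (stats::runif(1) < cfg$p_hflip[ds_col]) im <- augment(im, "hflip")
    if (stats::runif(1) < cfg$p_vflip[ds_col]) im <- augment(im, "vflip")
    im
  }
  im <- one()
  if (stats::runif(1) < cfg$p_tile3[ds_col]) {
    im <- tile(c(list(im), replicate(8L, one(), simplify = FALSE)), "3x3")
  } else if (stats::runif(1) < cfg$p_tile2[ds_col]) {
    im <- tile(c(list(im), replicate(3L, one(), simplify = FALSE)), "2x2")
  }
  im
}

#' Draw one dual-dataset training batch
#'
#' Draws `t1` images from the angle-labeled stream and `t2` from the
#' box-only stream, applies the configured augmentations, and returns them
#' tagged with their dataset of origin (the tag controls the angle-loss
#' masking). Streams reshuffle and repeat at epoch boundaries, and the whole
#' procedure is deterministic given the R random seed.
#'
#' @param ds1_stream,ds2_stream streams from `new_image_stream()` (the
#'   exported [train()] builds them from image lists; `ds2_stream` may wrap
#'   the same images as `ds1_stream`).
#' @param cfg an [aug_config()].
#' @return list of [annotated_image()]s, `t1` tagged ds1 then `t2` tagged
#'   ds2.
#' @export
make_dual_batch <- function(ds1_stream, ds2_stream, cfg = aug_config()) {
  b1 <- lapply(seq_len(cfg$t1), function(i) {
    im <- draw_training_image(ds1_stream, cfg, 1L)
    im$dataset <- "ds1"
    im
  })
  b2 <- lapply(seq_len(cfg$t2), function(i) {
    im <- draw_training_image(ds2_stream, cfg, 2L)
    im$dataset <- "ds2"
    im
  })
  c(b1, b2)
}
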