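# ---------------------------------------------------------------------------
# Synthetic oriented-face scenes: a filled ellipse "face" with two darker
# "eye" dots placed symmetrically about the face axis, rotated by a known
# angle. Every glyph's axis-aligned hull box, angle and eye keypoints are
# recorded exactly, so the generator doubles as a geometric oracle for the
# angle codec, the augmentations and the normalizer.
# ---------------------------------------------------------------------------

#' Annotated image container
#'
#' @param image `[H, W, C]` numeric array with values in `[0, 1]`, or NULL
#'   when only annotations are carried.
#' @param records data frame with columns `xmin, ymin, xmax, ymax` and
#'   optionally `theta` (half-turns) and keypoints `xl, yl, xr, yr`. For the
#'   angle-labeled dataset every record must carry an angle directly or via
#'   keypoints (from which it is derived on construction).
#' @param dataset `"ds1"` (angle-labeled) or `"ds2"` (box-only).
#' @param width,height image size in pixels (inferred from `image` when
#'   present).
#' @return list of class `annotated_image`.
#' @export
annotated_image <- function(image, records, dataset = c("ds1", "ds2"),
                            width = NULL, height = NULL) {
  dataset <- match.arg(dataset)
  if (!is.null(image)) {
    if (length(dim(image)) == 2L) dim(image) <- c(dim(image), 1L)
    height <- dim(image)[1]; width <- dim(image)[2]
  }
  if (is.null(width) || is.null(height)) {
    stop("width and height are required when no image is attached")
  }
  records <- as.data.frame(records)
  need <- c("xmin", "ymin", "xmax", "ymax")
  if (!all(need %in% names(records))) {
    stop("records need columns ", paste(need, collapse = ", "))
  }
  for (col in c("theta", "xl", "yl", "xr", "yr")) {
    if (is.null(records[[col]])) records[[col]] <- NA_real_
  }
  has_kp <- !is.na(records$xl)
  fill <- is.na(records$theta) & has_kp
  if (any(fill)) {
    records$theta[fill] <- angle_from_keypoints(
      records$xl[fill], records$yl[fill],
      records$xr[fill], records$yr[fill])
  }
  if (dataset == "ds1" && any(is.na(records$theta))) {
    stop("every record of an angle-labeled (ds1) image needs an angle ",
         "or a keypoint pair")
  }
  if (nrow(records) && (any(records$xmin < 0) || any(records$ymin < 0) ||
                        any(records$xmax > width) ||
                        any(records$ymax > height))) {
    stop("box outside image bounds")
  }
  structure(list(image = image, records = records, dataset = dataset,
                 width = width, height = height),
            class = "annotated_image")
}

#' @export
print.annotated_image <- function(x, ...) {
  cat(sprintf("annotated_image [%s]: %d x %d, %d record(s)\n",
              x$dataset, x$width, x$height, nrow(x$records)))
  invisible(x)
}

#' Synthetic scene specification
#'
#' @param canvas square canvas side in pixels.
#' @param n_faces glyphs per image.
#' @param size_range range of the ellipse semi-minor axis (half face width)
#'   in pixels; the semi-major axis (face length) is 1.35x that, so default
#'   face hull boxes span roughly 34-94 px on a 128 px canvas.
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @param channels 1 or 3.
#' @return list of class `scene_spec`. Angles are drawn uniformly on
#'   (-1, 1].
#' @export
scene_spec <- function(canvas = 128L, n_faces = 1L, size_range = c(12, 28),
                       noise_sd = 0.02, channels = 1L) {
  stopifnot(canvas > 0, n_faces >= 1, length(size_range) == 2,
            size_range[1] > 2, size_range[2] >= size_range[1],
            channels %in% c(1L, 3L))
  structure(list(canvas = as.integer(canvas), n_faces = as.integer(n_faces),
                 size_range = size_range, noise_sd = noise_sd,
                 channels = as.integer(channels)),
            class = "scene_spec")
}

# screen-coordinate rotation by phi half-turns * pi, counterclockwise as
# seen on screen (y grows downward)
rot_screen <- function(phi) {
  matrix(c(cos(phi), -sin(phi), sin(phi), cos(phi)), 2, 2)
}

#' Render one synthetic oriented-face scene
#'
#' Draws `n_faces` ellipse glyphs at uniformly random angles; each glyph's
#' recorded ground truth is exact: the box is the analytic axis-aligned hull
#' of the rotated ellipse, and the keypoints are the rotated eye centers, so
#' `angle_from_keypoints` on the recorded keypoints reproduces the sampled
#' angle to machine precision. The glyph carries two direction cues: the eye
#' pair sits toward the "forehead" end and the face is shaded brighter
#' toward it. Uses the current R random stream.
#'
#' @param spec a [scene_spec()].
#' @param dataset dataset tag for the returned image; `"ds2"` images keep
#'   their angles in the records (the loss masks them, not the generator).
#' @return an [annotated_image()].
#' @export
generate_synthetic_scene <- function(spec = scene_spec(), dataset = "ds1") {
  cv <- spec$canvas
  img <- array(0.10, dim = c(cv, cv, spec$channels))
  # pixel-center coordinate grids
  px <- matrix(rep(seq_len(cv) - 0.5, each = cv), cv, cv)   # x by column
  py <- matrix(rep(seq_len(cv) - 0.5, times = cv), cv, cv)  # y by row
  recs <- vector("list", spec$n_faces)
  placed <- NULL
  for (f in seq_len(spec$n_faces)) {
    for (attempt in seq_len(25L)) {
      a <- stats::runif(1, spec$size_range[1], spec$size_range[2])
      b <- 1.35 * a
      theta <- wrap_angle(stats::runif(1, -1, 1))
      phi <- theta * pi
      hx <- sqrt((a * cos(phi))^2 + (b * sin(phi))^2)
      hy <- sqrt((a * sin(phi))^2 + (b * cos(phi))^2)
      if (2 * hx > cv - 4 || 2 * hy > cv - 4) next
      cx <- stats::runif(1, hx + 2, cv - hx - 2)
      cy <- stats::runif(1, hy + 2, cv - hy - 2)
      bx <- data.frame(xmin = cx - hx, ymin = cy - hy,
                       xmax = cx + hx, ymax = cy + hy)
      if (!is.null(placed) && nrow(placed) &&
          max(iou_matrix(bx, placed)) > 0.15) next
      break
    }
    R <- rot_screen(phi)
    # inverse-rotate pixel offsets into the face frame
    ox <- px - cx; oy <- py - cy
    fx <- R[1, 1] * ox + R[2, 1] * oy
    fy <- R[1, 2] * ox + R[2, 2] * oy
    inside <- (fx / a)^2 + (fy / b)^2 <= 1
    # brighter toward the forehead (negative fy), the second direction cue
    shade <- 0.72 - 0.18 * (fy / b)
    eye_off_x <- 0.45 * a; eye_off_y <- -0.35 * b
    r_eye <- 0.15 * a
    eye <- ((fx - eye_off_x)^2 + (fy - eye_off_y)^2 <= r_eye^2) |
      ((fx + eye_off_x)^2 + (fy - eye_off_y)^2 <= r_eye^2)
    for (ch in seq_len(spec$channels)) {
      gain <- if (spec$channels == 3L) c(1.05, 1.0, 0.92)[ch] else 1
      plane <- img[, , ch]
      plane[inside] <- pmin(shade[inside] * gain, 1)
      plane[eye] <- 0.18
      img[, , ch] <- plane
    }
    kp_l <- c(cx, cy) + R %*% c(-eye_off_x, eye_off_y)
    kp_r <- c(cx, cy) + R %*% c(+eye_off_x, eye_off_y)
    recs[[f]] <- data.frame(
      xmin = cx - hx, ymin = cy - hy, xmax = cx + hx, ymax = cy + hy,
      theta = theta, xl = kp_l[1], yl = kp_l[2], xr = kp_r[1], yr = kp_r[2])
    placed <- rbind(placed, recs[[f]][, 1:4])
  }
  if (spec$noise_sd > 0) {
    img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd), dim(img))
    img[img < 0] <- 0; img[img > 1] <- 1
  }
  annotated_image(img, do.call(rbind, recs), dataset = dataset)
}

#' Generate a reproducible synthetic dataset
#'
#' @param n number of scenes.
#' @param spec a [scene_spec()].
#' @param seed optional seed; when given, `set.seed(seed)` is called first.
#' @param dataset dataset tag applied to all scenes.
#' @return list of [annotated_image()]s.
#' @export
generate_synthetic_dataset <- function(n, spec = scene_spec(), seed = NULL,
                                       dataset = "ds1") {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n), function(i) generate_synthetic_scene(spec, dataset))
}
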