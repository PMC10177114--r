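#' @useDynLib rotface, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Rotation-angle codec
#
# Angles live in half-turns: theta in (-1, 1], with theta * 180 the rotation
# in degrees, positive counterclockwise on screen (origin top-left, x right,
# y down). The angle of a face is the angle of the line from its left
# keypoint (left eye in the upright face) to its right keypoint.
# ---------------------------------------------------------------------------

#' Canonicalize angles into the half-open interval (-1, 1]
#'
#' Wraps by multiples of 2 (full turns) so that every angle has a unique
#' representative; exactly -1 maps to +1 (the interval is open at -1).
#'
#' @param theta numeric vector of angles in half-turns.
#' @return numeric vector with every element in (-1, 1].
#' @examples
#' wrap_angle(c(1.5, -1.25, 2, 1, -1))
#' @export
wrap_angle <- function(theta) {
  stopifnot(is.numeric(theta))
  t <- theta %% 2            # [0, 2)
  t[t > 1] <- t[t > 1] - 2   # (-1, 1]
  # guard against floating error making t land on -1 exactly
  t[t == -1] <- 1
  t
}

#' Rotation angle from a keypoint pair
#'
#' Computes the in-plane rotation angle of a face from its two eye keypoints.
#' Coordinates are distances from the left (x) and top (y) image frame, in
#' pixels. The angle is the direction of the vector from the left keypoint to
#' the right keypoint measured counterclockwise from horizontal; a face whose
#' eye line is horizontal with the left eye on the left has angle 0.
#'
#' The six case branches (slope sign, vertical eye line up/down, left/right
#' reversal) are realized by `atan2(yl - yr, xr - xl) / pi`, which keeps the
#' vertical cases exact (+0.5 / -0.5) and never forms an infinite slope.
#'
#' @param xl,yl,xr,yr coordinates of the left and right keypoints (vectors
#'   recycle as usual).
#' @return numeric vector of angles in half-turns, canonical in (-1, 1].
#' @examples
#' angle_from_keypoints(0, 1, 1, 0)  # 0.25, i.e. 45 degrees counterclockwise
#' angle_from_keypoints(5, 9, 5, 2)  # 0.5, eye line vertical
#' @export
angle_from_keypoints <- function(xl, yl, xr, yr) {
  dx <- xr - xl
  dy_up <- yl - yr  # y is measured downward, so this is the upward component
  if (any(dx == 0 & dy_up == 0)) {
    stop("coincident keypoints: rotation angle is undefined")
  }
  wrap_angle(atan2(dy_up, dx) / pi)
}

#' Split a signed angle into absolute value and direction
#'
#' The detector regresses the absolute angle and classifies the rotation
#' direction separately, which removes the discontinuity between angles just
#' below +1 and just above -1 (both are near-180-degree rotations). Zero maps
#' to direction `ccw = FALSE` by convention; [combine_angle()] is unaffected.
#'
#' @param theta numeric vector of canonical angles.
#' @return list with `value` (absolute angle in `[0, 1]`) and `ccw` (logical,
#'   `TRUE` for counterclockwise, i.e. positive theta).
#' @export
split_angle <- function(theta) {
  list(value = abs(theta), ccw = theta > 0)
}

#' Reassemble a signed angle from absolute value and direction
#'
#' Inverse of [split_angle()]: `+value` when `ccw`, else `-value`, then
#' canonicalized (so value 1 with `ccw = FALSE` maps to +1).
#'
#' @param value absolute angle in `[0, 1]` (half-turns).
#' @param ccw logical direction flag.
#' @return numeric vector of canonical signed angles.
#' @export
combine_angle <- function(value, ccw) {
  stopifnot(all(value >= 0), all(value <= 1))
  wrap_angle(ifelse(ccw, value, -value))
}

#' Transform a ground-truth angle under an image-level augmentation
#'
#' When an annotated image is rotated 90 degrees counterclockwise, flipped
#' horizontally, or flipped vertically, the face angle changes in closed
#' form:
#' \itemize{
#'   \item `rot90ccw`: theta + 0.5 (wrapped), i.e. add 90 degrees;
#'   \item `hflip`: -theta (mirroring reverses the rotation direction; the
#'     left/right keypoints swap roles in the mirrored face);
#'   \item `vflip`: 1 - theta (wrapped), the composition of `hflip` and a
#'     180-degree rotation.
#' }
#' All outputs are canonical in (-1, 1]. These maps are validated against a
#' geometric oracle: transforming the keypoints and recomputing the angle
#' gives the same result.
#'
#' @param theta numeric vector of canonical angles.
#' @param op one of `"rot90ccw"`, `"hflip"`, `"vflip"`.
#' @return transformed canonical angles.
#' @export
transform_angle <- function(theta, op = c("rot90ccw", "hflip", "vflip")) {
  op <- match.arg(op)
  switch(op,
    rot90ccw = wrap_angle(theta + 0.5),
    hflip = wrap_angle(-theta),
    vflip = wrap_angle(1 - theta)
  )
}

#' Wraparound distance between two angles
#'
#' Distance on the circle of half-turns: `|d|` when `|d| < 1`, else `2 - |d|`
#' where `d = theta_true - theta_pred`. Always in `[0, 1]`; multiply by 180
#' for degrees. This is the distance underlying the average angle difference
#' metric, and it treats 0.99 and -0.99 as close (distance 0.02), which the
#' raw difference does not.
#'
#' @param theta_true,theta_pred numeric vectors of canonical angles.
#' @return numeric vector of distances in `[0, 1]` half-turns.
#' @examples
#' angle_distance(0.99, -0.99)  # 0.02 (3.6 degrees)
#' @export
angle_distance <- function(theta_true, theta_pred) {
  d <- abs(theta_true - theta_pred)
  ifelse(d < 1, d, 2 - d)
}
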