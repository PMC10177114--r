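# Shared fixture builders. Everything is generated in code under fixed seeds.

tiny_net <- function(seed = 7L) {
  build_network(net_config(input_channels = 1L, input_size = 64L,
                           base_width = 4L, neck_width = 16L, seed = seed))
}

tiny_scene <- function(seed = 1L, canvas = 128L, n_faces = 1L,
                       channels = 1L) {
  set.seed(seed)
  generate_synthetic_scene(scene_spec(canvas = canvas, n_faces = n_faces,
                                      channels = channels))
}

# random corner boxes inside a frame
random_boxes <- function(n, frame = 100) {
  x1 <- runif(n, 0, frame - 2); y1 <- runif(n, 0, frame - 2)
  w <- runif(n, 1, frame / 2); h <- runif(n, 1, frame / 2)
  box(x1, y1, pmin(x1 + w, frame), pmin(y1 + h, frame))
}

# rotate a keypoint pair rigidly by phi half-turns counterclockwise (screen
# convention: y down) about a center -- the geometric oracle for the codec
rotate_keypoints <- function(kp, phi_half_turns, center = c(0, 0)) {
  phi <- phi_half_turns * pi
  R <- matrix(c(cos(phi), -sin(phi), sin(phi), cos(phi)), 2, 2)
  l <- center + R %*% (c(kp[1], kp[2]) - center)
  r <- center + R %*% (c(kp[3], kp[4]) - center)
  c(l[1], l[2], r[1], r[2])
}
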