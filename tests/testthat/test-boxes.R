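test_that("default anchor grid at 400 px has the published layout", {
  a <- generate_anchors(400, 400)
  expect_equal(a$n, 20058L)
  expect_equal(vapply(a$levels, function(l) l$grid_w, numeric(1)),
               c(50, 25, 13, 7))
  expect_equal(a$k, 6L)
  expect_equal(nrow(a$centers), a$n)
  # anchor centers coincide with cell centers of their stride
  l1 <- a$centers[seq_len(a$k), ]
  expect_equal(unique(l1$x), 4)
  expect_equal(unique(l1$y), 4)
})

test_that("anchor count follows the closed form for arbitrary sizes", {
  set.seed(11)
  for (i in 1:10) {
    w <- sample(60:500, 1); h <- sample(60:500, 1)
    strides <- c(8, 16, 32, 64)
    a <- generate_anchors(w, h, strides = strides)
    expect_equal(a$n, 6 * sum(ceiling(w / strides) * ceiling(h / strides)))
  }
  a <- generate_anchors(64, 64, strides = 32, base_sizes = 32,
                        scale_ratios = 1, aspect_ratios = 1)
  expect_equal(a$n, 4L)
  expect_equal(a$centers$x, c(16, 48, 16, 48))
  expect_equal(a$centers$y, c(16, 16, 48, 48))
})

test_that("box encode/decode are mutually inverse", {
  anchor <- data.frame(x = 100, y = 100, w = 50, h = 50)
  expect_equal(unlist(encode_box(anchor, anchor)),
               c(tx = 0, ty = 0, tw = 0, th = 0))
  gt <- data.frame(x = 105, y = 100, w = 50, h = 50)
  expect_equal(encode_box(gt, anchor)$tx, 1)
  expect_equal(encode_box(data.frame(x = 0, y = 0, w = 10 * exp(1), h = 10),
                          data.frame(x = 0, y = 0, w = 10, h = 10))$tw, 5)
  expect_equal(decode_box(data.frame(tx = 1, ty = 0, tw = 0, th = 0),
                          anchor)$x, 105)
  set.seed(12)
  n <- 1000
  anchors <- data.frame(x = runif(n, 0, 400), y = runif(n, 0, 400),
                        w = runif(n, 5, 200), h = runif(n, 5, 200))
  gts <- data.frame(x = runif(n, 0, 400), y = runif(n, 0, 400),
                    w = runif(n, 5, 200), h = runif(n, 5, 200))
  rt <- decode_box(encode_box(gts, anchors), anchors)
  expect_equal(rt, gts, tolerance = 1e-6)
})

test_that("IoU matches hand geometry and its invariances", {
  b <- box(0, 0, 2, 2)
  expect_equal(iou(b, b), 1)
  expect_equal(iou(b, box(5, 5, 6, 6)), 0)
  expect_equal(iou(b, box(1, 0, 3, 2)), 1 / 3)
  set.seed(13)
  a1 <- random_boxes(50); a2 <- random_boxes(50)
  m <- iou_matrix(a1, a2)
  expect_equal(m, t(iou_matrix(a2, a1)))
  expect_true(all(m >= 0 & m <= 1))
  scale_box <- function(b, s) box(b$xmin * s, b$ymin * s, b$xmax * s,
                                  b$ymax * s)
  expect_equal(iou_matrix(scale_box(a1, 3.7), scale_box(a2, 3.7)), m,
               tolerance = 1e-12)
})

test_that("anchor matching agrees with a brute-force oracle", {
  brute <- function(centers, gts, pos_t, neg_t) {
    ious <- iou_matrix(center_to_box(centers), gts)
    lab <- rep(-1L, nrow(centers))
    gi <- rep(NA_integer_, nrow(centers))
    for (i in seq_len(nrow(centers))) {
      best <- max(ious[i, ])
      if (best < neg_t) lab[i] <- 0L
      if (best >= pos_t) { lab[i] <- 1L; gi[i] <- which.max(ious[i, ]) }
    }
    for (g in seq_len(nrow(gts))) {
      if (max(ious[, g]) > 0) {
        a <- which.max(ious[, g]); lab[a] <- 1L; gi[a] <- g
      }
    }
    gi[lab != 1L] <- NA_integer_
    list(label = lab, gt_index = gi)
  }
  set.seed(14)
  for (rep in 1:20) {
    centers <- box_to_center(random_boxes(sample(5:50, 1)))
    gts <- random_boxes(sample(1:4, 1))
    got <- match_anchors(centers, gts, 0.5, 0.4)
    want <- brute(centers, gts, 0.5, 0.4)
    expect_identical(got$label, want$label)
    expect_identical(got$gt_index, want$gt_index)
  }
  # anchor equal to a gt box is positive; no gts means all negative
  a <- generate_anchors(64, 64, strides = 32, base_sizes = 32,
                        scale_ratios = 1, aspect_ratios = 1)
  m <- match_anchors(a, center_to_box(a$centers[2, , drop = FALSE]))
  expect_equal(m$label[2], 1L)
  m0 <- match_anchors(a, box(numeric(0), numeric(0), numeric(0), numeric(0)))
  expect_true(all(m0$label == 0L))
})

test_that("mini-batch sampling balances positives and is reproducible", {
  match <- list(label = c(rep(1L, 2), rep(0L, 100)))
  set.seed(15)
  s <- sample_minibatch(match, size = 8, pos_fraction = 0.25)
  expect_equal(length(s$pos), 2)
  expect_equal(length(s$neg), 6)
  expect_true(all(match$label[s$pos] == 1L))
  expect_true(all(match$label[s$neg] == 0L))
  # no positives: all-negative sample of the requested size
  s0 <- sample_minibatch(list(label = rep(0L, 500)), size = 64)
  expect_equal(length(s0$pos), 0)
  expect_equal(length(s0$neg), 64)
  # determinism under the seed
  big <- list(label = sample(c(0L, 1L), 1000, TRUE, prob = c(0.9, 0.1)))
  set.seed(99); s1 <- sample_minibatch(big, 256, 0.25)
  set.seed(99); s2 <- sample_minibatch(big, 256, 0.25)
  expect_identical(s1, s2)
  # positives capped at the fraction when abundant
  set.seed(16)
  s3 <- sample_minibatch(list(label = rep(1L, 500)), 256, 0.25)
  expect_equal(length(s3$pos), 64)
})
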