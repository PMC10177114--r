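test_that("augmentations keep keypoint geometry and angle maps in lockstep", {
  # the central consistency oracle: for random scenes and every operation,
  # the angle recomputed from the transformed keypoints must equal the
  # closed-form angle map
  set.seed(51)
  for (i in 1:40) {
    sc <- generate_synthetic_scene(scene_spec(noise_sd = 0))
    for (op in c("rot90ccw", "hflip", "vflip")) {
      au <- augment(sc, op)
      r <- au$records
      expect_equal(angle_from_keypoints(r$xl, r$yl, r$xr, r$yr),
                   transform_angle(sc$records$theta, op),
                   tolerance = 1e-9)
      expect_equal(r$theta, transform_angle(sc$records$theta, op),
                   tolerance = 1e-12)
      # boxes stay valid and inside the transformed canvas
      expect_true(all(r$xmax > r$xmin & r$ymax > r$ymin))
      expect_true(all(r$xmin >= 0 & r$xmax <= au$width &
                        r$ymin >= 0 & r$ymax <= au$height))
    }
  }
})

test_that("pixel transforms are exact and compose to the identity", {
  set.seed(52)
  sc <- generate_synthetic_scene(scene_spec(canvas = 64L))
  # two quarter-turns then both flips is the identity, pixel-exact
  back <- augment(augment(augment(augment(sc, "rot90ccw"), "rot90ccw"),
                          "vflip"), "hflip")
  expect_equal(back$image, sc$image)
  expect_equal(back$records$xmin, sc$records$xmin, tolerance = 1e-12)
  expect_equal(back$records$theta, sc$records$theta, tolerance = 1e-12)
  # flips are involutions on pixels
  expect_equal(augment(augment(sc, "hflip"), "hflip")$image, sc$image)
  expect_equal(augment(augment(sc, "vflip"), "vflip")$image, sc$image)
})

test_that("hflip maps boxes by x -> W - x", {
  img <- annotated_image(array(0, c(100, 100, 1)),
                         data.frame(xmin = 10, ymin = 20, xmax = 30,
                                    ymax = 40),
                         dataset = "ds2")
  fl <- augment(img, "hflip")
  expect_equal(unlist(fl$records[, c("xmin", "ymin", "xmax", "ymax")]),
               c(xmin = 70, ymin = 20, xmax = 90, ymax = 40))
  rt <- augment(img, "rot90ccw")
  expect_equal(unlist(rt$records[, c("xmin", "ymin", "xmax", "ymax")]),
               c(xmin = 20, ymin = 70, xmax = 40, ymax = 90))
})

test_that("tiling scales records into their cells and keeps angles", {
  set.seed(53)
  sc <- generate_synthetic_scene(scene_spec(canvas = 64L, noise_sd = 0))
  t4 <- tile(rep(list(sc), 4), "2x2")
  expect_equal(nrow(t4$records), 4L)
  expect_equal(t4$width, sc$width)
  expect_equal(t4$records$theta, rep(sc$records$theta, 4))
  # each copy sits at quarter scale with the right offset
  w0 <- sc$records$xmax - sc$records$xmin
  expect_equal(t4$records$xmax - t4$records$xmin, rep(w0 / 2, 4),
               tolerance = 1e-9)
  expect_equal(t4$records$xmin[2] - t4$records$xmin[1], 32)
  expect_equal(t4$records$ymin[3] - t4$records$ymin[1], 32)
  # a record centered in tile 1 lands at the quarter point
  ctr <- annotated_image(array(0, c(64, 64, 1)),
                         data.frame(xmin = 28, ymin = 28, xmax = 36,
                                    ymax = 36),
                         dataset = "ds2")
  t1 <- tile(rep(list(ctr), 4), "2x2")
  expect_equal((t1$records$xmin[1] + t1$records$xmax[1]) / 2, 16)
  t9 <- tile(rep(list(sc), 9), "3x3")
  expect_equal(nrow(t9$records), 9L)
  expect_error(tile(rep(list(sc), 5), "2x2"), "needs 4")
})

test_that("annotations round-trip through JSON lines", {
  set.seed(54)
  imgs <- c(generate_synthetic_dataset(6, scene_spec(canvas = 48L)),
            generate_synthetic_dataset(4, scene_spec(canvas = 48L),
                                       dataset = "ds2"))
  path <- tempfile(fileext = ".jsonl")
  write_annotations(imgs, path)
  back <- read_annotations(path)
  expect_length(back, 10L)
  for (i in seq_along(imgs)) {
    expect_equal(back[[i]]$dataset, imgs[[i]]$dataset)
    expect_equal(back[[i]]$width, imgs[[i]]$width)
    expect_equal(back[[i]]$records, imgs[[i]]$records, tolerance = 1e-12)
  }
  # malformed line reports its position
  writeLines(c(readLines(path)[1], "{not json"), path)
  expect_error(read_annotations(path), "line 2")
  file.remove(path)
})

test_that("the dual batcher draws T1+T2 tagged images deterministically", {
  set.seed(55)
  ds1 <- generate_synthetic_dataset(8, scene_spec(canvas = 48L), seed = 1)
  ds2 <- generate_synthetic_dataset(5, scene_spec(canvas = 48L), seed = 2,
                                    dataset = "ds2")
  cfg <- aug_config(t1 = 7L, t2 = 5L)
  set.seed(9)
  b <- make_dual_batch(rotface:::new_image_stream(ds1),
                       rotface:::new_image_stream(ds2), cfg)
  expect_length(b, 12L)
  expect_equal(vapply(b, `[[`, character(1), "dataset"),
               rep(c("ds1", "ds2"), c(7, 5)))
  set.seed(9)
  b2 <- make_dual_batch(rotface:::new_image_stream(ds1),
                        rotface:::new_image_stream(ds2), cfg)
  expect_equal(b, b2)
  # all probabilities zero: images pass through untouched
  quiet <- aug_config(p_rot90 = c(0, 0), p_hflip = c(0, 0),
                      p_vflip = c(0, 0), p_tile2 = c(0, 0), t1 = 3L, t2 = 0L)
  set.seed(10)
  s <- rotface:::new_image_stream(ds1)
  b3 <- make_dual_batch(s, rotface:::new_image_stream(ds2), quiet)
  imgs_drawn <- lapply(b3, `[[`, "image")
  expect_true(all(vapply(seq_along(b3), function(i) {
    any(vapply(ds1, function(d) identical(d$image, imgs_drawn[[i]]),
               logical(1)))
  }, logical(1))))
})

test_that("the stream covers every image within one epoch", {
  ds <- generate_synthetic_dataset(6, scene_spec(canvas = 48L), seed = 3)
  set.seed(11)
  s <- rotface:::new_image_stream(ds)
  drawn <- s$draw(6L)
  # one epoch = a permutation of the dataset
  match_idx <- vapply(drawn, function(d) {
    which(vapply(ds, function(o) identical(o$image, d$image), logical(1)))[1]
  }, integer(1))
  expect_setequal(match_idx, 1:6)
})

test_that("letterboxing centers, scales and preserves record geometry", {
  set.seed(56)
  sc <- generate_synthetic_scene(scene_spec(canvas = 100L, noise_sd = 0))
  lb <- letterbox(sc, 128L)
  expect_equal(dim(lb$image), c(128, 128, 1))
  s <- 128 / 100
  expect_equal(lb$records$xmin, sc$records$xmin * s, tolerance = 1e-9)
  # non-square input gets zero borders and an isotropic scale
  wide <- annotated_image(array(0.5, c(50, 100, 1)),
                          data.frame(xmin = 10, ymin = 10, xmax = 90,
                                     ymax = 40, theta = 0.3),
                          dataset = "ds1")
  lb2 <- letterbox(wide, 64L)
  expect_equal(dim(lb2$image), c(64, 64, 1))
  expect_equal(lb2$records$theta, 0.3)  # isotropic: angle untouched
  expect_equal(lb2$records$xmax - lb2$records$xmin,
               (90 - 10) * 64 / 100, tolerance = 1e-9)
  expect_equal(sum(lb2$image[1:10, , 1]), 0)  # top border is padding
})
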