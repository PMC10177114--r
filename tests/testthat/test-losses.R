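test_that("Huber penalty is quadratic inside delta and linear outside", {
  expect_equal(huber(0), 0)
  expect_equal(huber(0.5, 1), 0.125)
  expect_equal(huber(2, 1), 1.5)
  expect_equal(huber(-2, 1), 1.5)
  set.seed(21)
  a <- runif(100, -5, 5)
  expect_equal(huber(a, delta = 100), 0.5 * a^2)
})

test_that("focal loss reduces to cross-entropy at gamma zero", {
  expect_equal(focal(1, 2), 0)
  expect_equal(focal(0.5, 2), 0.25 * log(2))
  pt <- seq(0.01, 1, by = 0.01)
  expect_equal(focal(pt, gamma = 0), -log(pt), tolerance = 1e-9)
  # down-weighting: higher gamma shrinks the well-classified loss more
  expect_lt(focal(0.9, 2) / focal(0.9, 0), focal(0.4, 2) / focal(0.4, 0))
})

test_that("localization loss averages summed Huber over positives", {
  p <- matrix(0, 1, 4); t <- matrix(c(0.5, 0, 0, 0), 1, 4)
  expect_equal(localization_loss(p, t), 0.125)
  expect_equal(localization_loss(t, t), 0)
  p2 <- matrix(0, 2, 4)
  t2 <- rbind(c(0.5, 0, 0, 0), c(0.5, 0.5, 0.5, 0))
  expect_equal(localization_loss(p2, t2), mean(c(0.125, 0.375)))
  expect_equal(localization_loss(matrix(0, 0, 4), matrix(0, 0, 4)), 0)
})

test_that("objectness focal loss scores the sampled mini-batch", {
  expect_equal(objectness_loss(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(objectness_loss(0.5, 1, gamma = 2), 0.25 * log(2))
  # mean invariance under duplication
  p <- c(0.2, 0.9); s <- c(0, 1)
  expect_equal(objectness_loss(rep(p, 2), rep(s, 2)),
               objectness_loss(p, s))
})

test_that("angle-value loss masks the box-only dataset by default", {
  w <- loss_weights()
  expect_equal(w$lambda_ds1, 10)
  expect_equal(w$lambda_ds2, 0)
  # all box-only positives with the default weights contribute nothing
  expect_equal(angle_value_loss(c(0.4, 0.9), c(NA, NA), c("ds2", "ds2"), w), 0)
  # one angle-labeled positive: 10 * 0.5 * (0.5 - 0.3)^2
  expect_equal(angle_value_loss(0.3, 0.5, "ds1", w), 0.2)
  expect_equal(angle_value_loss(c(0.5, 0.2), c(0.5, NA), c("ds1", "ds2"), w),
               0)
  # enabling the ds2 weight pulls box-only predictions toward zero
  w2 <- loss_weights(lambda_ds2 = 2)
  expect_equal(angle_value_loss(0.4, NA, "ds2", w2), 2 * 0.5 * 0.16)
  expect_error(angle_value_loss(0.1, 0.1, "ds3"), "tag")
})

test_that("direction loss only sees gated, angle-labeled positives", {
  # everything at or below the gate: zero
  expect_equal(angle_direction_loss(c(0.9, 0.1), c(1, 0), c(0.02, 0.025)), 0)
  # perfectly predicted gated anchor: zero
  expect_equal(angle_direction_loss(1, 1, 0.5), 0)
  expect_equal(angle_direction_loss(0.5, 1, 0.5), 0.25 * log(2))
  # ds2 positives carry no angle (NA) and are excluded
  expect_equal(angle_direction_loss(c(0.5, 0.5), c(1, 1), c(NA, 0.5)),
               0.25 * log(2))
})

test_that("total loss is the weighted sum with the published defaults", {
  t0 <- total_loss(0, 0, 0, 0)
  expect_equal(t0$total, 0)
  t1 <- total_loss(1, 1, 1, 1)
  expect_equal(t1$total, 1 + 5 + 1 + 10)
  w <- loss_weights(lambda_obj = 10)
  expect_equal(total_loss(1, 1, 1, 1, w)$total, 22)
  expect_error(total_loss(NaN, 0, 0, 0), "finite")
})

test_that("head-gradient of the combined loss matches finite differences", {
  set.seed(22)
  n <- 40
  head <- matrix(rnorm(n * 9, 0, 0.5), n, 9)
  targets <- list(
    label = c(rep(1L, 6), rep(0L, n - 6)),
    enc = rbind(matrix(rnorm(24, 0, 0.5), 6, 4), matrix(NA, n - 6, 4)),
    theta_v = c(0.6, 0.01, 0.9, NA, 0.4, 0.3, rep(NA, n - 6)),
    ccw = c(TRUE, FALSE, TRUE, NA, FALSE, TRUE, rep(NA, n - 6)),
    ds_tag = c(rep("ds1", 3), "ds2", rep("ds1", 2), rep("ds2", n - 6))
  )
  smp <- list(pos = 1:6, neg = 7:30)
  w <- loss_weights(lambda_ds2 = 0.5)
  res <- rotface:::detection_loss_grad(head, targets, smp, w)
  eps <- 1e-6
  for (probe in list(c(1, 2), c(2, 9), c(3, 8), c(5, 3), c(6, 6), c(9, 1),
                     c(10, 2), c(4, 9), c(2, 7))) {
    hp <- head; hp[probe[1], probe[2]] <- hp[probe[1], probe[2]] + eps
    hm <- head; hm[probe[1], probe[2]] <- hm[probe[1], probe[2]] - eps
    fp <- rotface:::detection_loss_grad(hp, targets, smp, w)$loss$total
    fm <- rotface:::detection_loss_grad(hm, targets, smp, w)$loss$total
    expect_equal(res$dhead[probe[1], probe[2]], (fp - fm) / (2 * eps),
                 tolerance = 1e-4)
  }
  # breakdown consistency: the recorded total equals the weighted sum
  expect_equal(res$loss$total,
               w$lambda_loc * res$loss$loc + w$lambda_obj * res$loss$obj +
                 w$lambda_av * res$loss$av + w$lambda_ad * res$loss$ad)
})

test_that("swapping dataset tags changes the angle loss only through ds1", {
  set.seed(23)
  n <- 12
  pred_v <- runif(n)
  true_v <- runif(n)
  tags <- rep(c("ds1", "ds2"), each = n / 2)
  w <- loss_weights()  # lambda_ds2 = 0
  base <- angle_value_loss(pred_v, true_v, tags, w)
  # permuting within ds2 changes nothing
  perm <- c(seq_len(n / 2), sample((n / 2 + 1):n))
  expect_equal(angle_value_loss(pred_v[perm], true_v[perm], tags, w), base)
  # moving an anchor from ds1 to ds2 drops its contribution
  tags2 <- tags; tags2[1] <- "ds2"
  expect_equal(angle_value_loss(pred_v, true_v, tags2, w),
               base - 10 * 0.5 * (true_v[1] - pred_v[1])^2 / n)
})
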