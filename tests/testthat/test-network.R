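test_that("backbone layout has 14 CBA units with the published widths", {
  cfg <- net_config(base_width = 16L)
  lay <- rotface:::backbone_layout(cfg)
  expect_length(lay, 14L)
  # blocks: 2 + 3*4; first unit of each block at stride 2
  strides <- vapply(lay, `[[`, integer(1), "stride")
  expect_equal(sum(strides == 2L), 5L)
  # third CBA of blocks 2-5 is 4x as wide as the first two
  widths <- vapply(lay, `[[`, integer(1), "out")
  expect_equal(widths[5], 4L * widths[3])
  expect_equal(widths[14], 4L * widths[12])
  # first unit uses the large 7x7 kernel, the rest 3x3
  expect_equal(vapply(lay, `[[`, integer(1), "k"), c(7L, rep(3L, 13L)))
})

test_that("head emits k*9 = 54 channels and aligns with the anchor set", {
  cfg <- net_config(input_channels = 1L, input_size = 64L, base_width = 4L,
                    neck_width = 8L, seed = 3L)
  net <- build_network(cfg)
  expect_equal(dim(net$params$head$W)[4], 54L)
  x <- array(0.5, c(64, 64, 1))
  fwd <- network_forward(net, x, train = TRUE)
  a <- generate_anchors(64, 64)
  expect_equal(nrow(fwd$head), a$n)
  # grids shrink as ceil(dim / stride): 8, 4, 2, 1
  expect_equal(vapply(fwd$levels, `[[`, numeric(1), "gh"), c(8, 4, 2, 1),
               ignore_attr = TRUE)
})

test_that("head values map index-for-index onto anchor flat order", {
  # mark one template's channels in one cell and find it in the flat matrix
  k <- 6L
  for (probe in list(c(gh = 5L, gw = 7L, y = 2L, x = 3L, t = 4L),
                     c(gh = 4L, gw = 4L, y = 4L, x = 1L, t = 1L),
                     c(gh = 3L, gw = 5L, y = 1L, x = 5L, t = 6L))) {
    h <- array(0, c(probe["gh"], probe["gw"], 9L * k))
    ch <- (probe["t"] - 1L) * 9L + seq_len(9L)
    h[probe["y"], probe["x"], ch] <- 1:9
    m <- rotface:::head_level_to_matrix(h, k)
    flat <- probe["t"] + k * ((probe["x"] - 1L) + probe["gw"] *
                                (probe["y"] - 1L))
    expect_equal(m[flat, ], 1:9, ignore_attr = TRUE)
    expect_equal(sum(m != 0), 9L)
    # and the reshape inverts exactly
    expect_equal(rotface:::head_matrix_to_level(m, probe["gh"], probe["gw"],
                                                k), h)
  }
})

test_that("decoded probabilities follow softmax and sigmoid", {
  h <- matrix(0, 3, 9)
  h[2, 2] <- log(3)  # objectness logits (0, ln 3)
  h[3, 9] <- 0
  d <- decode_head(h)
  expect_equal(d$p_obj[1], 0.5)
  expect_equal(d$p_obj[2], 0.75)
  expect_equal(d$p_ccw[1], 0.5)
  expect_equal(d$value[3], 0.5)
  # softmax pair sums to one by construction; sigmoid is monotone
  hs <- matrix(rnorm(90), 10, 9)
  ds <- decode_head(hs)
  expect_true(all(ds$p_obj > 0 & ds$p_obj < 1))
  expect_true(all(diff(stats::plogis(sort(hs[, 9]))) >= 0))
})

test_that("a zero-weight head yields 0.5 objectness everywhere", {
  cfg <- net_config(input_channels = 1L, input_size = 64L, base_width = 4L,
                    neck_width = 8L, seed = 3L)
  net <- build_network(cfg)
  net$params$head$W[] <- 0
  net$params$head$b[] <- 0
  fwd <- network_forward(net, array(runif(64 * 64), c(64, 64, 1)))
  d <- decode_head(fwd$head)
  expect_equal(d$p_obj, rep(0.5, nrow(fwd$head)))
  expect_equal(d$value, rep(0.5, nrow(fwd$head)))
})

test_that("parameter count is invariant to input size and forward is fast", {
  n1 <- build_network(net_config(input_channels = 1L, input_size = 64L,
                                 base_width = 4L, neck_width = 8L))
  n2 <- build_network(net_config(input_channels = 1L, input_size = 128L,
                                 base_width = 4L, neck_width = 8L))
  expect_equal(n_params(n1), n_params(n2))
  t0 <- proc.time()
  network_forward(n1, array(0.5, c(64, 64, 1)), train = FALSE)
  expect_lt((proc.time() - t0)[["elapsed"]], 1)
})

test_that("single-channel and three-channel inputs are both accepted", {
  for (ch in c(1L, 3L)) {
    net <- build_network(net_config(input_channels = ch, input_size = 64L,
                                    base_width = 4L, neck_width = 8L))
    fwd <- network_forward(net, array(0.3, c(64, 64, ch)))
    expect_equal(ncol(fwd$head), 9L)
  }
  net1 <- build_network(net_config(input_channels = 1L, input_size = 64L,
                                   base_width = 4L, neck_width = 8L))
  expect_error(network_forward(net1, array(0, c(64, 64, 3))), "C = 1")
  expect_error(net_config(input_channels = 2L), "1 or 3")
})

test_that("backward gradients match finite differences end to end", {
  set.seed(31)
  net <- tiny_net(seed = 11L)
  x <- array(runif(64 * 64), c(64, 64, 1))
  fwd <- network_forward(net, x, train = TRUE, keep_cache = TRUE)
  w <- matrix(rnorm(length(fwd$head), 0, 0.1), nrow(fwd$head), 9)
  g <- network_backward(net, fwd, w)
  lossfn <- function(n2) sum(network_forward(n2, x, TRUE, FALSE)$head * w)
  probes <- list(c("b1c1", "conv", "W"), c("b2c3", "conv", "W"),
                 c("b4c2", "bn", "gamma"), c("b5c3", "bn", "beta"),
                 c("lat4", "W"), c("p6", "b"), c("head", "W"))
  getp <- function(l, p) if (length(p) == 1) l[[p]] else getp(l[[p[1]]], p[-1])
  setp <- function(l, p, v) {
    if (length(p) == 1) l[[p]] <- v else l[[p[1]]] <- setp(l[[p[1]]], p[-1], v)
    l
  }
  # small step: larger perturbations flip ReLU activations and bias the
  # central difference
  eps <- 1e-6
  for (path in probes) {
    idx <- sample(length(getp(net$params, path)), 1)
    v0 <- getp(net$params, path)[idx]
    n2 <- net
    n2$params <- setp(net$params, path, replace(getp(net$params, path),
                                                idx, v0 + eps))
    f1 <- lossfn(n2)
    n2$params <- setp(net$params, path, replace(getp(net$params, path),
                                                idx, v0 - eps))
    f0 <- lossfn(n2)
    expect_equal(getp(g, path)[idx], (f1 - f0) / (2 * eps),
                 tolerance = 1e-3)
  }
})

test_that("checkpoints round-trip the network exactly", {
  net <- tiny_net(seed = 5L)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(net, path, extra = list(step = 12L))
  back <- load_checkpoint(path)
  expect_equal(back$net$params, net$params)
  expect_equal(back$net$state, net$state)
  expect_equal(back$extra$step, 12L)
  x <- array(0.2, c(64, 64, 1))
  expect_equal(network_forward(back$net, x, FALSE)$head,
               network_forward(net, x, FALSE)$head)
  file.remove(path)
  expect_error(load_checkpoint({
    p <- tempfile(); saveRDS(list(a = 1), p); p
  }), "checkpoint")
})
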