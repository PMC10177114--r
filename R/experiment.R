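# ---------------------------------------------------------------------------
# A self-contained, CPU-sized detection experiment on synthetic scenes.
# ---------------------------------------------------------------------------

#' Run the scaled-down synthetic detection experiment
#'
#' Trains the small detector variant (128 px input, base width 8, neck width
#' 32, single channel) on synthetic oriented-face scenes and scores it on a
#' held-out set: the package's end-to-end exercise of dual-dataset batching,
#' augmentation, the four-term loss and the evaluation metrics, sized for a
#' single CPU. The box-only stream reuses the training scenes under the ds2
#' tag, so the angle-masking path is active in every batch.
#'
#' Defaults: 300 training scenes, 100 held-out scenes, 1,200 optimizer steps
#' with batches of two angle-labeled plus one box-only image, peak learning
#' rate 0.008 under the cosine schedule, quarter-turn/flip augmentation at
#' probability 0.5 and 2x2 tiling at 0.25.
#'
#' @param seed master seed; train/test scene draws, weight init and batching
#'   all derive from it.
#' @param steps optimizer steps.
#' @param n_train,n_test scene counts.
#' @param lr peak learning rate.
#' @param verbose print training progress.
#' @return list with `metrics` (an `eval_result`), `net`, `log`, and the
#'   elapsed training seconds.
#' @export
scaled_experiment <- function(seed = 1L, steps = 1200L, n_train = 300L,
                              n_test = 100L, lr = 0.008, verbose = FALSE) {
  spec <- scene_spec(canvas = 128L, channels = 1L)
  ds1 <- generate_synthetic_dataset(n_train, spec, seed = seed * 13L + 1L)
  held <- generate_synthetic_dataset(n_test, spec, seed = seed * 13L + 7L)
  cfg <- train_config(
    net = net_config(input_channels = 1L, input_size = 128L,
                     base_width = 8L, neck_width = 32L, seed = seed),
    aug = aug_config(p_rot90 = c(0.5, 0), p_hflip = c(0.5, 0.5),
                     p_vflip = c(0.5, 0.5), p_tile2 = c(0.25, 0.25),
                     t1 = 2L, t2 = 1L),
    total_steps = steps, lr = lr, warmup_steps = 50L, seed = seed)
  t0 <- proc.time()
  res <- train(cfg, ds1, verbose = verbose, log_every = 50L)
  elapsed <- (proc.time() - t0)[["elapsed"]]
  metrics <- evaluate_network(res$net, held)
  list(metrics = metrics, net = res$net, log = res$log,
       train_seconds = elapsed)
}
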