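test_that("network topology follows the eight-layer blueprint", {
  net <- build_net(net_spec("2D", width = 0.05))
  types <- vapply(net$layers, function(l) l$type, character(1))
  expect_equal(sum(types == "conv"), 5)
  expect_equal(sum(types == "fc"), 3)
  expect_equal(sum(types == "pool"), 3)
  expect_equal(sum(types == "lrn"), 2)
  expect_equal(sum(types == "dropout"), 2)
  final <- net$layers[[length(net$layers)]]
  expect_equal(final$out_dims, 2)

  # width multiplier scales filter counts but not layer counts
  wide <- build_net(net_spec("2D", width = 0.1))
  expect_equal(vapply(wide$layers, function(l) l$type, character(1)),
               types)
  conv1 <- which(types == "conv")[1]
  expect_equal(wide$layers[[conv1]]$out_dims[4], 10)   # round(96 * 0.1)
  expect_equal(net$layers[[conv1]]$out_dims[4], 5)     # round(96 * 0.05)

  # classic spatial dimensions survive the stack (55 -> 27 -> 13 -> 6)
  expect_equal(net$layers[[conv1]]$out_dims[1:2], c(55, 55))
  flat <- which(types == "flatten")
  expect_equal(net$layers[[flat - 1]]$out_dims[1:2], c(6, 6))
})

test_that("3-D networks clip kernel depth to the available extent", {
  net <- build_net(net_spec("3D", width = 0.05))
  types <- vapply(net$layers, function(l) l$type, character(1))
  conv_idx <- which(types == "conv")
  expect_equal(net$layers[[conv_idx[1]]]$in_dims, c(227, 227, 5, 1))
  # depth is preserved by same-padding then shrunk by 3-D pooling
  expect_equal(net$layers[[conv_idx[1]]]$out_dims[3], 5)
  expect_equal(net$layers[[conv_idx[2]]]$in_dims[3], 2)
  expect_equal(net$layers[[conv_idx[3]]]$in_dims[3], 1)
  expect_error(build_net(net_spec("3D"), input_dim = c(227, 227, 3)),
               "227x227x5")
  expect_error(build_net(net_spec("2D"), input_dim = c(100, 100, 3)),
               "227x227x3")
})

test_that("hold-out splits use per-class round-half-up counts", {
  manifest <- tibble::tibble(
    class = c(rep("calm", 822), rep("distress", 732)))
  set.seed(1)
  split <- holdout_split(manifest, 0.8)
  train_classes <- manifest$class[split$train]
  test_classes <- manifest$class[split$test]
  expect_equal(sum(train_classes == "calm"), 658)
  expect_equal(sum(train_classes == "distress"), 586)
  expect_equal(sum(test_classes == "calm"), 164)
  expect_equal(sum(test_classes == "distress"), 146)
  expect_equal(sort(c(split$train, split$test)), 1:1554)

  expect_warning(holdout_split(manifest, 1.0), "empty test")
})

test_that("iteration bookkeeping matches the protocol arithmetic", {
  expect_equal(iterations_per_epoch(658 + 586, 12), 103)
  expect_equal(40 * iterations_per_epoch(1244, 12), 4120)
  expect_equal(iterations_per_epoch(5, 12), 1)
})

test_that("confusion metrics implement the three rate formulas", {
  m <- confusion_metrics(tibble::tibble(tp = 146, tn = 0, fp = 164,
                                        fn = 0))
  expect_equal(m$se, 100)
  expect_equal(m$sp, 0)
  expect_equal(round(m$acc, 1), 47.1)

  expect_equal(unlist(confusion_metrics(tibble::tibble(
    tp = 50, tn = 50, fp = 0, fn = 0))),
    c(se = 100, sp = 100, acc = 100))

  m2 <- confusion_metrics(tibble::tibble(tp = 81, tn = 83, fp = 17,
                                         fn = 19))
  expect_equal(unlist(m2), c(se = 81, sp = 83, acc = 82))

  expect_error(confusion_metrics(tibble::tibble(tp = 0, tn = 5, fp = 0,
                                                fn = 0)), "undefined")
})

test_that("accuracy is the class-size-weighted mean of Se and Sp", {
  set.seed(11)
  for (i in 1:50) {
    tp <- sample(0:40, 1); fn <- sample(0:40, 1)
    tn <- sample(0:40, 1); fp <- sample(0:40, 1)
    if (tp + fn == 0 || tn + fp == 0) next
    m <- confusion_metrics(tibble::tibble(tp = tp, tn = tn, fp = fp,
                                          fn = fn))
    npos <- tp + fn; nneg <- tn + fp
    expect_equal(m$acc, (npos * m$se + nneg * m$sp) / (npos + nneg),
                 tolerance = 1e-12)
    expect_gte(m$acc, min(m$se, m$sp))
    expect_lte(m$acc, max(m$se, m$sp))
  }
})

test_that("evaluation tallies distress as the positive class", {
  truth <- c(rep("calm", 164), rep("distress", 146))
  oracle <- confusion_counts(truth, truth)
  expect_equal(unlist(oracle), c(tp = 146, tn = 164, fp = 0, fn = 0))
  constant <- confusion_counts(truth, rep("distress", 310))
  expect_equal(unlist(constant), c(tp = 146, tn = 0, fp = 164, fn = 0))
  net <- build_net(net_spec("2D", width = 0.02))
  expect_error(evaluate_net(net, list(), character(0)), "empty")
})

test_that("checkpoints embed and verify a spec fingerprint", {
  set.seed(2)
  net <- build_net(net_spec("2D", width = 0.02))
  path <- withr::local_tempfile(fileext = ".json")
  save_net(net, path)
  reloaded <- load_net(path, build_net(net_spec("2D", width = 0.02)))
  li <- topospectra:::net_params(net)[1]
  expect_equal(reloaded$layers[[li]]$W, net$layers[[li]]$W,
               tolerance = 1e-12)
  expect_error(load_net(path, build_net(net_spec("2D", width = 0.05))),
               "fingerprint")
})

test_that("experiments are reproducible under the master seed", {
  set.seed(3)
  # tiny separable image set: two channel patterns far apart
  vals_a <- named_values(20)
  vals_b <- vals_a
  vals_b[c("Fp1", "Fp2", "AF3", "AF4")] <-
    vals_b[c("Fp1", "Fp2", "AF3", "AF4")] + 3
  mk <- function(v, jitter) {
    jet_quantize(render_dmd(v + rnorm(32, sd = 0.05 * jitter)))
  }
  images <- c(lapply(1:8, function(i) mk(vals_a, i)),
              lapply(1:8, function(i) mk(vals_b, i)))
  manifest <- tibble::tibble(class = rep(c("calm", "distress"), each = 8))
  spec <- net_spec("2D", width = 0.02)
  cfg <- train_config(epochs = 1, batch_size = 4, validate_every = 2)
  r1 <- run_experiment(images, manifest, spec, cfg, n_cycles = 2,
                       seed = 99)
  r2 <- run_experiment(images, manifest, spec, cfg, n_cycles = 2,
                       seed = 99)
  expect_identical(tidy(r1), tidy(r2))
  expect_identical(glance(r1), glance(r2))
  expect_equal(nrow(tidy(r1)), 2)
  expect_equal(glance(r1)$acc_mean, mean(tidy(r1)$acc))
  sd_expect <- if (nrow(tidy(r1)) > 1) sd(tidy(r1)$acc) else 0
  expect_equal(glance(r1)$acc_sd, sd_expect)

  expect_warning(
    run_experiment(images, manifest, spec,
                   train_config(epochs = 1, batch_size = 4),
                   n_cycles = 1, seed = 5),
    "single cycle")
})

test_that("training configuration validates and derives iterations", {
  cfg <- train_config()
  expect_equal(cfg$epochs, 40)
  expect_equal(cfg$batch_size, 12)
  expect_equal(cfg$learning_rate, 0.001)
  expect_equal(cfg$momentum, 0.9)
  expect_equal(cfg$l2_decay, 0.001)
  expect_equal(cfg$validate_every, 50)
  expect_error(train_config(epochs = 0), "positive")
})
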