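# Training controls (scheduler, early stopping, clipping), checkpointing,
# warm-start transfer, and the training loop itself at miniature scale.

test_that("plateau schedule halves LR after 5 stagnant epochs", {
  cfg <- train_config(learning_rate = 1e-4)
  ctrl <- training_controller(cfg)
  controller_update(ctrl, 0.80)              # improvement, sets the best
  lr_seen <- vapply(1:5, function(i)
    controller_update(ctrl, 0.80)$lr, numeric(1))   # five flat epochs
  expect_equal(lr_seen, c(1e-4, 1e-4, 1e-4, 1e-4, 5e-5))
  # counter resets after the reduction; five more flat epochs halve again
  lr_seen2 <- vapply(1:5, function(i)
    controller_update(ctrl, 0.80)$lr, numeric(1))
  expect_equal(lr_seen2[5], 2.5e-5)
  # LR never increases
  expect_true(all(diff(c(1e-4, lr_seen, lr_seen2)) <= 0))
})

test_that("early stopping fires after 12 stagnant epochs", {
  ctrl <- training_controller(train_config())
  controller_update(ctrl, 0.75)
  stops <- vapply(1:12, function(i)
    controller_update(ctrl, 0.75)$stop, logical(1))
  expect_equal(stops, c(rep(FALSE, 11), TRUE))
  # an improvement resets the stop counter
  ctrl2 <- training_controller(train_config())
  controller_update(ctrl2, 0.75)
  for (i in 1:11) controller_update(ctrl2, 0.75)
  expect_false(controller_update(ctrl2, 0.90)$stop)
  expect_false(controller_update(ctrl2, 0.90)$lr_reduced)
})

test_that("tiny improvements below the tolerance do not reset patience", {
  ctrl <- training_controller(train_config())
  controller_update(ctrl, 0.80)
  for (i in 1:4) controller_update(ctrl, 0.80 + 1e-7)  # below min_improvement
  expect_true(controller_update(ctrl, 0.80)$lr_reduced)
})

test_that("gradient clipping caps the global norm at 5", {
  g <- list(a = matrix(3, 2, 2), b = rep(4, 5))
  before <- sqrt(sum(9 * 4) + sum(16 * 5))
  r <- clip_global_norm(g, 5.0)
  expect_equal(r$norm_before, before)
  after <- sqrt(sum(unlist(r$grads)^2))
  expect_lte(after, 5.0 + 1e-6)
  expect_equal(after, 5.0, tolerance = 1e-9)
  # directions preserved
  expect_equal(r$grads$a / r$grads$a[1], g$a / g$a[1])
  # small gradients pass through untouched
  g2 <- list(a = 0.1)
  expect_identical(clip_global_norm(g2, 5.0)$grads, g2)
})

test_that("checkpoints round-trip and reject corrupt files", {
  m <- tiny_model(seed = 1)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(m, f, epoch = 7, best_val_dice = 0.9)
  ck <- load_checkpoint(f)
  expect_equal(ck$epoch, 7L)
  m2 <- model_from_checkpoint(ck)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3, 1))
  expect_identical(model_forward(m, x)$prob, model_forward(m2, x)$prob)
  bad <- tempfile(fileext = ".rds")
  writeLines("not a checkpoint", bad)
  expect_error(load_checkpoint(bad), class = "lesionseg_io_error")
  expect_error(load_checkpoint(tempfile()), class = "lesionseg_io_error")
})

test_that("warm start: full restore, missing file, cross-architecture", {
  m <- tiny_model(seed = 2)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  # full restore reproduces predictions bit-exactly
  fresh <- tiny_model(seed = 99)
  ws <- warm_start(fresh, f)
  expect_false(ws$report$from_scratch)
  expect_true(all(names(fresh$params) %in% ws$report$matched))
  x <- array(runif(16 * 16 * 3), c(16, 16, 3, 1))
  expect_identical(model_forward(ws$model, x)$prob,
                   model_forward(m, x)$prob)
  # missing checkpoint: untouched model, from-scratch branch
  fresh2 <- tiny_model(seed = 99)
  ws2 <- warm_start(fresh2, tempfile())
  expect_true(ws2$report$from_scratch)
  expect_identical(ws2$model$params, fresh2$params)
  # cross-architecture: only name-and-shape matches restored
  big <- hybrid_unet(arch_config(in_channels = 3, base_channels = 8,
                                 num_stages = 2, transformer_layers = 1,
                                 attention_heads = 2, input_size = 16),
                     seed = 3)
  ws3 <- warm_start(big, f)
  expect_false(ws3$report$from_scratch)
  expect_gt(length(ws3$report$shape_mismatched), 0)
  # channel-dependent tensors (e.g. positional embedding / conv kernels)
  # mismatch and keep their fresh values
  expect_true("transformer.pos" %in% ws3$report$shape_mismatched)
  pos_before <- hybrid_unet(big$cfg, seed = 3)$params[["transformer.pos"]]
  expect_identical(ws3$model$params[["transformer.pos"]], pos_before)
  # anything matched was copied verbatim
  for (nm in ws3$report$matched) {
    expect_identical(ws3$model$params[[nm]], m$params[[nm]])
  }
})

test_that("train(): logging, best-checkpoint selection, determinism", {
  samples <- tiny_phantoms(n = 4, size = 16)
  m <- tiny_model(seed = 5)
  cfg <- train_config(learning_rate = 3e-3, max_epochs = 4, batch_size = 2,
                      seed = 9)
  res <- train(m, samples, cfg)
  expect_equal(nrow(res$log), 4)
  expect_equal(res$log$epoch, 1:4)
  # returned checkpoint is the best-val-Dice epoch
  expect_equal(res$checkpoint$best_val_dice, max(res$log$val_dice))
  expect_equal(res$checkpoint$epoch, which.max(res$log$val_dice))
  # LR non-increasing
  expect_true(all(diff(res$log$lr) <= 0))
  # same seed, same data -> identical logs
  res2 <- train(tiny_model(seed = 5), samples, cfg)
  expect_equal(res$log$train_loss, res2$log$train_loss, tolerance = 1e-12)
  expect_equal(res$log$val_dice, res2$log$val_dice, tolerance = 1e-12)
  expect_error(train(m, list(), cfg), "empty")
})

test_that("training reduces the loss on tiny phantoms", {
  samples <- tiny_phantoms(n = 4, size = 16)
  m <- tiny_model(seed = 6)
  cfg <- train_config(learning_rate = 3e-3, max_epochs = 10, batch_size = 4,
                      seed = 1)
  res <- train(m, samples, cfg)
  expect_lt(res$log$train_loss[nrow(res$log)], res$log$train_loss[1])
})

test_that("a huge injected gradient is clipped to the configured norm", {
  # construct an absurdly confident wrong prediction to spike the gradient
  m <- tiny_model(seed = 7)
  m$params[["head.W"]][] <- 50
  m$params[["head.b"]][] <- 50
  x <- array(runif(16 * 16 * 3), c(16, 16, 3, 1))
  y <- array(1L, c(16, 16, 1, 1)); y[1:8, , 1, 1] <- 0L
  fw <- model_forward(m, x, train = TRUE, keep = TRUE)
  g <- lesionseg:::model_backward(m, fw$cache,
                                  lesionseg:::combined_loss_logit_grad(fw$prob, y))
  r <- clip_global_norm(g, 5.0)
  expect_lte(sqrt(sum(vapply(r$grads, function(a) sum(a^2), numeric(1)))),
             5.0 + 1e-6)
})

test_that("sequential transfer warm-starts each phase from the previous best", {
  ds1 <- tiny_phantoms(n = 3, size = 16, seed = 21)
  ds2 <- tiny_phantoms(n = 3, size = 16, seed = 22)
  cfg <- train_config(learning_rate = 3e-3, max_epochs = 2, batch_size = 3,
                      seed = 2)
  phases <- sequential_transfer(list(ds1, ds2), tiny_arch(), cfg)
  expect_length(phases, 2)
  # phase-2 initialization equals phase-1 best checkpoint: replay it
  m2 <- hybrid_unet(tiny_arch(), seed = cfg$seed + 2)
  ws <- warm_start(m2, phases[[1]]$checkpoint)
  expect_identical(ws$model$params, phases[[1]]$checkpoint$params)
  # single dataset degenerates to plain train()
  single <- sequential_transfer(list(ds1), tiny_arch(), cfg)
  direct <- train(hybrid_unet(tiny_arch(), seed = cfg$seed + 1), ds1, cfg)
  expect_equal(single[[1]]$log$val_dice, direct$log$val_dice,
               tolerance = 1e-12)
})

test_that("evaluate_split matches a hand-rolled per-image loop", {
  samples <- tiny_phantoms(n = 5, size = 16)
  m <- tiny_model(seed = 8)
  rp <- evaluate_split(m, samples, resamples = 100, seed = 4)
  manual <- vapply(samples, function(s) {
    p <- model_forward(m, s$image)$prob
    overlap_metrics(binarize(p), s$mask)$dice
  }, numeric(1))
  expect_equal(rp$summary$point[rp$summary$metric == "dice"], mean(manual))
  expect_equal(rp$n_images, 5)
  # an oracle stub that returns the ground truth scores all 1s
  probs <- lapply(samples, function(s)
    array(s$mask, c(dim(s$mask), 1, 1)))
  gts <- lapply(samples, function(s) s$mask)
  perfect <- metric_report(probs, gts, resamples = 50, seed = 1)
  expect_true(all(perfect$summary$point == 1))
  # constant-0.5 probabilities give AUC 1/2
  flat <- lapply(samples, function(s)
    array(0.5, c(dim(s$mask), 1, 1)))
  expect_equal(metric_report(flat, gts, resamples = 50, seed = 1)$auc, 0.5)
  expect_error(evaluate_split(m, list()), "empty")
})
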