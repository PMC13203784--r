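# Training automation: Adam, global-norm gradient clipping, validation-Dice
# driven plateau LR schedule and early stopping, best-checkpoint selection,
# and warm-start sequential transfer across datasets.

#' Training configuration
#'
#' @param learning_rate initial Adam learning rate (default 1e-4).
#' @param max_epochs epoch cap (default 50).
#' @param early_stop_patience epochs without validation-Dice improvement
#'   before training halts (default 12).
#' @param plateau_factor multiplicative LR reduction (default 0.5).
#' @param plateau_patience stagnant epochs before an LR reduction
#'   (default 5); must be smaller than \code{early_stop_patience}.
#' @param clip_max_norm global gradient-norm cap (default 5).
#' @param batch_size images per optimization step (default 4).
#' @param mixed_precision accepted for config compatibility; training in
#'   this implementation always runs in full (double) precision.
#' @param seed RNG seed controlling shuffling and augmentation draws.
#' @param loss "dice_bce" (combined objective) or "bce".
#' @param augmentation an \code{\link{augment_config}} or NULL (none).
#' @param min_improvement validation Dice must rise by at least this much
#'   to reset the patience counters (default 1e-5).
#' @return object of class \code{train_config}.
#' @export
train_config <- function(learning_rate = 1e-4, max_epochs = 50L,
                         early_stop_patience = 12L, plateau_factor = 0.5,
                         plateau_patience = 5L, clip_max_norm = 5.0,
                         batch_size = 4L, mixed_precision = FALSE,
                         seed = 0L, loss = c("dice_bce", "bce"),
                         augmentation = NULL, min_improvement = 1e-5) {
  loss <- match.arg(loss)
  stopifnot(learning_rate > 0, max_epochs >= 1, early_stop_patience >= 1,
            plateau_factor > 0, plateau_patience >= 1, clip_max_norm > 0,
            batch_size >= 1)
  if (plateau_patience >= early_stop_patience)
    stop("plateau_patience must be smaller than early_stop_patience")
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 clip_max_norm = clip_max_norm,
                 batch_size = as.integer(batch_size),
                 mixed_precision = isTRUE(mixed_precision),
                 seed = as.integer(seed), loss = loss,
                 augmentation = augmentation,
                 min_improvement = min_improvement),
            class = "train_config")
}

#' Plateau / early-stopping controller
#'
#' Tracks the best validation Dice. An epoch counts as stagnant unless the
#' Dice improves by at least \code{min_improvement}. When the stagnation
#' count reaches \code{plateau_patience} the learning rate is multiplied by
#' \code{plateau_factor} and the plateau counter resets; when it reaches
#' \code{early_stop_patience} training stops. The two counters share the
#' monitored metric but are independent.
#'
#' @param cfg a \code{\link{train_config}}.
#' @return a controller object (environment) for
#'   \code{\link{controller_update}}.
#' @export
training_controller <- function(cfg) {
  e <- new.env(parent = emptyenv())
  e$lr <- cfg$learning_rate
  e$best <- -Inf
  e$bad_plateau <- 0L
  e$bad_stop <- 0L
  e$cfg <- cfg
  class(e) <- "training_controller"
  e
}

#' @rdname training_controller
#' @param ctrl a controller from \code{training_controller}.
#' @param val_dice the epoch's validation Dice.
#' @return list with \code{lr} (possibly reduced), \code{improved},
#'   \code{lr_reduced} and \code{stop}.
#' @export
controller_update <- function(ctrl, val_dice) {
  cfg <- ctrl$cfg
  improved <- val_dice > ctrl$best + cfg$min_improvement
  reduced <- FALSE
  if (improved) {
    ctrl$best <- val_dice
    ctrl$bad_plateau <- 0L
    ctrl$bad_stop <- 0L
  } else {
    ctrl$bad_plateau <- ctrl$bad_plateau + 1L
    ctrl$bad_stop <- ctrl$bad_stop + 1L
    if (ctrl$bad_plateau >= cfg$plateau_patience) {
      ctrl$lr <- ctrl$lr * cfg$plateau_factor
      ctrl$bad_plateau <- 0L
      reduced <- TRUE
    }
  }
  list(lr = ctrl$lr, improved = improved, lr_reduced = reduced,
       stop = ctrl$bad_stop >= cfg$early_stop_patience)
}

#' Clip gradients by global norm
#'
#' Scales the whole gradient set so its global L2 norm does not exceed
#' \code{max_norm} (no-op when already below).
#'
#' @param grads named list of gradient arrays.
#' @param max_norm norm cap.
#' @return list with scaled \code{grads}, \code{norm_before},
#'   \code{norm_after}.
#' @export
clip_global_norm <- function(grads, max_norm) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
  if (is.finite(gn) && gn > max_norm) {
    sc <- max_norm / gn
    grads <- lapply(grads, function(g) g * sc)
    list(grads = grads, norm_before = gn, norm_after = max_norm)
  } else {
    list(grads = grads, norm_before = gn, norm_after = gn)
  }
}

adam_state <- function(params) {
  zero_like <- function(p)
    if (is.null(dim(p))) numeric(length(p)) else array(0, dim(p))
  list(m = lapply(params, zero_like), v = lapply(params, zero_like), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(grads)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Mean per-image hard Dice of a model over a list of samples (eval mode).
mean_val_dice <- function(model, samples, threshold = 0.5) {
  d <- vapply(samples, function(s) {
    p <- model_forward(model, s$image, train = FALSE)$prob
    overlap_metrics(binarize(p, threshold), s$mask)$dice
  }, numeric(1))
  mean(d)
}

# One forward per sample gives both the monitored Dice and the loss.
val_stats <- function(model, samples, loss, threshold = 0.5, eps = 1e-6) {
  ds <- numeric(length(samples)); ls <- numeric(length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    p <- model_forward(model, s$image, train = FALSE)$prob
    ds[i] <- overlap_metrics(binarize(p, threshold), s$mask)$dice
    ls[i] <- if (loss == "bce") bce_loss(p, s$mask) else
      combined_loss(p, s$mask, eps = eps)$total
  }
  list(dice = mean(ds), loss = mean(ls))
}

#' Train a hybrid U-Net
#'
#' Adam optimization of the configured loss with per-step global-norm
#' gradient clipping, a validation-Dice plateau LR schedule, early
#' stopping, and best-checkpoint selection (the returned checkpoint is the
#' best-validation-Dice epoch, not the last). Augmentation, if configured,
#' is applied to training samples only.
#'
#' @param model a \code{\link{hybrid_unet}}.
#' @param train_samples list of samples, each \code{list(image, mask)} with
#'   image (H, W, 3) in [0, 1] and mask (H, W) 0/1.
#' @param cfg a \code{\link{train_config}}.
#' @param val_samples validation samples (defaults to the training samples
#'   when omitted, as in pure overfitting runs).
#' @param out_dir optional directory to write best/last checkpoints and the
#'   training log CSV.
#' @param max_steps optional cap on total optimization steps (for bounded
#'   sanity runs); NULL means epochs decide.
#' @param verbose print one line per epoch.
#' @return list with \code{checkpoint} (best epoch: params, buffers, arch,
#'   epoch, best_val_dice), \code{log} (one row per completed epoch),
#'   \code{model} (best-epoch weights) and \code{steps} taken.
#' @export
train <- function(model, train_samples, cfg = train_config(),
                  val_samples = NULL, out_dir = NULL, max_steps = NULL,
                  verbose = FALSE) {
  if (length(train_samples) == 0L) stop("empty training split")
  if (is.null(val_samples)) val_samples <- train_samples
  ctrl <- training_controller(cfg)
  opt <- adam_state(model$params)
  best <- list(params = model$params, buffers = model$buffers,
               epoch = 0L, val_dice = -Inf)
  logs <- list()
  steps <- 0L
  n <- length(train_samples)
  d1 <- dim(train_samples[[1]]$image)
  stopped <- FALSE
  for (epoch in seq_len(cfg$max_epochs)) {
    t0 <- proc.time()[["elapsed"]]
    ep_losses <- c()
    res <- with_seed(cfg$seed + 1000L * epoch, {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = cfg$batch_size)) {
        if (!is.null(max_steps) && steps >= max_steps) break
        ix <- ord[start:min(start + cfg$batch_size - 1L, n)]
        B <- length(ix)
        xb <- array(0, c(d1[1], d1[2], d1[3], B))
        yb <- array(0, c(d1[1], d1[2], 1L, B))
        for (j in seq_len(B)) {
          s <- train_samples[[ix[j]]]
          if (!is.null(cfg$augmentation)) {
            s <- augment(s$image, s$mask, cfg$augmentation)
          }
          xb[, , , j] <- s$image
          yb[, , 1, j] <- s$mask
        }
        fw <- model_forward(model, xb, train = TRUE, keep = TRUE)
        model$buffers <- fw$buffers
        p <- fw$prob
        lt <- if (cfg$loss == "bce") bce_loss(p, yb) else
          combined_loss(p, yb)$total
        if (!is.finite(lt))
          stop("non-finite training loss at epoch ", epoch,
               " (loss = ", lt, "); aborting")
        ep_losses <- c(ep_losses, lt)
        dlogits <- if (cfg$loss == "bce") bce_logit_grad(p, yb) else
          combined_loss_logit_grad(p, yb)
        grads <- model_backward(model, fw$cache, dlogits)
        grads <- clip_global_norm(grads, cfg$clip_max_norm)$grads
        st <- adam_step(model$params, grads, opt, ctrl$lr)
        model$params <- st$params
        opt <- st$state
        steps <- steps + 1L
      }
      list(model = model, opt = opt, steps = steps, ep_losses = ep_losses)
    })
    model <- res$model; opt <- res$opt; steps <- res$steps
    ep_losses <- res$ep_losses
    vs <- val_stats(model, val_samples, cfg$loss)
    vd <- vs$dice; vl <- vs$loss
    upd <- controller_update(ctrl, vd)
    if (upd$improved) {
      best <- list(params = model$params, buffers = model$buffers,
                   epoch = epoch, val_dice = vd)
    }
    logs[[epoch]] <- data.frame(
      epoch = epoch, train_loss = mean(ep_losses), val_loss = vl,
      val_dice = vd, lr = upd$lr,
      lr_reduced = upd$lr_reduced, early_stop = upd$stop,
      wall_time = proc.time()[["elapsed"]] - t0)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val dice %.4f  lr %.2e%s",
                      epoch, mean(ep_losses), vd, upd$lr,
                      if (upd$lr_reduced) "  [lr reduced]" else ""))
    if (upd$stop) { stopped <- TRUE; break }
    if (!is.null(max_steps) && steps >= max_steps) break
  }
  log <- do.call(rbind, logs)
  best_model <- structure(list(cfg = model$cfg, params = best$params,
                               buffers = best$buffers),
                          class = "hybrid_unet")
  checkpoint <- list(format = "lesionseg-checkpoint-1",
                     params = best$params, buffers = best$buffers,
                     arch = unclass(model$cfg), epoch = best$epoch,
                     best_val_dice = best$val_dice, optimizer = NULL)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    saveRDS(checkpoint, file.path(out_dir, "best.rds"))
    save_checkpoint(model, file.path(out_dir, "last.rds"),
                    epoch = nrow(log), best_val_dice = best$val_dice)
    utils::write.csv(log, file.path(out_dir, "trainlog.csv"),
                     row.names = FALSE)
  }
  list(checkpoint = checkpoint, log = log, model = best_model,
       final_model = model, steps = steps, stopped_early = stopped)
}

#' Warm-start a model from a checkpoint
#'
#' Implements incremental weight transfer: every parameter (and
#' normalization buffer) whose name AND shape match the checkpoint is
#' overwritten; everything else keeps its fresh initialization. A missing
#' checkpoint file is a defined branch -- the model is returned untouched
#' and flagged \code{from_scratch} ("Training from scratch"); a corrupt
#' file raises an I/O error.
#'
#' @param model a freshly initialized \code{\link{hybrid_unet}}.
#' @param checkpoint_path path to a checkpoint file, or a checkpoint list.
#' @param verbose print the warm-start/from-scratch message.
#' @return list with \code{model} and \code{report} (matched, missing,
#'   shape_mismatched names; \code{from_scratch} flag).
#' @export
warm_start <- function(model, checkpoint_path, verbose = FALSE) {
  if (is.character(checkpoint_path) && !file.exists(checkpoint_path)) {
    if (verbose) message("Training from scratch")
    return(list(model = model,
                report = list(from_scratch = TRUE, matched = character(0),
                              missing = names(model$params),
                              shape_mismatched = character(0))))
  }
  ck <- if (is.list(checkpoint_path)) checkpoint_path else
    load_checkpoint(checkpoint_path)
  matched <- character(0); mismatched <- character(0)
  take <- function(dst, src) {
    for (k in names(dst)) {
      s <- src[[k]]
      if (is.null(s)) next
      dd <- dim(dst[[k]]) %||% length(dst[[k]])
      ds <- dim(s) %||% length(s)
      if (identical(as.integer(dd), as.integer(ds))) {
        dst[[k]] <- s
        matched <<- c(matched, k)
      } else {
        mismatched <<- c(mismatched, k)
      }
    }
    dst
  }
  model$params <- take(model$params, ck$params)
  model$buffers <- take(model$buffers, ck$buffers)
  missing <- setdiff(names(model$params),
                     c(matched, mismatched))
  if (verbose) message("Warm-started from previous best weights")
  list(model = model,
       report = list(from_scratch = FALSE, matched = matched,
                     missing = missing, shape_mismatched = mismatched))
}

#' Sequential warm-start transfer across datasets
#'
#' Phase 1 trains from scratch; every later phase initializes from the
#' previous phase's best checkpoint (name-and-shape matching) and trains
#' with the identical loss and hyperparameters. No forgetting mitigation is
#' applied; \code{evaluate_previous} optionally re-evaluates earlier phases
#' after the chain completes as a forgetting diagnostic.
#'
#' @param datasets list of datasets, each a list of samples as in
#'   \code{\link{train}} (or a list with \code{train}/\code{val} elements).
#' @param arch an \code{\link{arch_config}}.
#' @param cfg a \code{\link{train_config}} shared by all phases.
#' @param out_dir optional root directory for per-phase artifacts.
#' @param evaluate_previous re-evaluate all earlier phases' validation sets
#'   with the final model (forgetting diagnostic).
#' @param verbose print per-phase messages.
#' @return list of per-phase results (as from \code{\link{train}}), with a
#'   \code{forgetting} data.frame when requested.
#' @export
sequential_transfer <- function(datasets, arch, cfg = train_config(),
                                out_dir = NULL, evaluate_previous = FALSE,
                                verbose = FALSE) {
  if (length(datasets) < 1L) stop("need at least one dataset")
  phases <- vector("list", length(datasets))
  prev_ck <- NULL
  for (k in seq_along(datasets)) {
    ds <- datasets[[k]]
    tr <- if (!is.null(ds$train)) ds$train else ds
    va <- if (!is.null(ds$val)) ds$val else NULL
    model <- hybrid_unet(arch, seed = cfg$seed + k)
    if (!is.null(prev_ck)) {
      ws <- warm_start(model, prev_ck, verbose = verbose)
      model <- ws$model
    } else if (verbose) message("Training from scratch")
    od <- if (!is.null(out_dir)) file.path(out_dir,
                                           sprintf("phase%02d", k)) else NULL
    res <- train(model, tr, cfg, val_samples = va, out_dir = od,
                 verbose = verbose)
    phases[[k]] <- res
    prev_ck <- res$checkpoint
  }
  if (evaluate_previous && length(datasets) > 1L) {
    final <- phases[[length(phases)]]$model
    rows <- lapply(seq_along(datasets), function(k) {
      ds <- datasets[[k]]
      va <- if (!is.null(ds$val)) ds$val else
        if (!is.null(ds$train)) ds$train else ds
      data.frame(phase = k,
                 dice_at_phase_end = phases[[k]]$checkpoint$best_val_dice,
                 dice_after_chain = mean_val_dice(final, va))
    })
    attr(phases, "forgetting") <- do.call(rbind, rows)
  }
  phases
}

#' Evaluate a model on a data split
#'
#' Runs the model over every image of the split (evaluation mode), then
#' assembles the per-image Dice/IoU/accuracy/F1 with 1000-resample
#' bootstrap confidence intervals, pooled confusion statistics and pooled
#' AUC via \code{\link{metric_report}}.
#'
#' @param model a \code{\link{hybrid_unet}}.
#' @param samples non-empty list of samples (image, mask).
#' @param threshold binarization threshold (default 0.5).
#' @param resamples bootstrap resamples (default 1000).
#' @param seed seed for bootstrap/AUC subsampling.
#' @return a \code{\link{metric_report}}.
#' @export
evaluate_split <- function(model, samples, threshold = 0.5,
                           resamples = 1000L, seed = 0L) {
  if (length(samples) == 0L) stop("empty evaluation split")
  probs <- lapply(samples, function(s)
    model_forward(model, s$image, train = FALSE)$prob)
  gts <- lapply(samples, function(s) s$mask)
  metric_report(probs, gts, threshold = threshold, resamples = resamples,
                seed = seed)
}

#' Load a manifest split into memory
#'
#' @param records data.frame of image records.
#' @param target_size image side length (default 256).
#' @return list of samples for \code{\link{train}} /
#'   \code{\link{evaluate_split}}.
#' @export
load_split <- function(records, target_size = 256L) {
  lapply(seq_len(nrow(records)), function(i) {
    pr <- load_pair(records[i, ], target_size = target_size)
    list(image = pr$image, mask = pr$mask,
         patient_id = records$patient_id[i])
  })
}

#' Predict a segmentation mask for one image
#'
#' @param model a \code{\link{hybrid_unet}}.
#' @param image (H, W, 3) array in [0, 1].
#' @param threshold binarization threshold.
#' @return list with \code{prob} (H, W) and \code{mask} (H, W, 0/1).
#' @export
predict_mask <- function(model, image, threshold = 0.5) {
  p <- model_forward(model, image, train = FALSE)$prob
  pm <- matrix(p, dim(p)[1], dim(p)[2])
  list(prob = pm, mask = binarize(pm, threshold))
}
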