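# Configuration-driven experiment runner: trains the variant grid
# (architecture x loss x augmentation), evaluates on validation and test
# splits, and writes per-run artifacts plus a consolidated report table.

#' Experiment variant
#'
#' A variant is the triple (architecture, loss, augmentation); its name --
#' e.g. "hybrid-dicebce-aug" or "unet-bce-noaug" -- uniquely identifies the
#' triple and labels all artifacts.
#'
#' @param architecture "hybrid" (transformer bottleneck) or "unet" (plain
#'   residual U-Net ablation).
#' @param loss "dice_bce" or "bce".
#' @param augmentation logical: train-time augmentation on/off.
#' @return object of class \code{experiment_variant}.
#' @export
experiment_variant <- function(architecture = c("hybrid", "unet"),
                               loss = c("dice_bce", "bce"),
                               augmentation = TRUE) {
  architecture <- match.arg(architecture)
  loss <- match.arg(loss)
  name <- paste0(architecture, "-",
                 if (loss == "dice_bce") "dicebce" else "bce", "-",
                 if (augmentation) "aug" else "noaug")
  structure(list(architecture = architecture, loss = loss,
                 augmentation = isTRUE(augmentation), name = name),
            class = "experiment_variant")
}

#' @rdname experiment_variant
#' @param name a variant name like "hybrid-dicebce-aug".
#' @export
parse_variant <- function(name) {
  parts <- strsplit(name, "-", fixed = TRUE)[[1]]
  if (length(parts) != 3L) stop_config("bad variant name: ", name)
  experiment_variant(
    architecture = match.arg(parts[1], c("hybrid", "unet")),
    loss = if (parts[2] == "dicebce") "dice_bce" else
      match.arg(parts[2], "bce"),
    augmentation = parts[3] == "aug")
}

#' Read / write an experiment configuration file
#'
#' One human-readable YAML file per suite; the training hyperparameter keys
#' use their conventional printed names ("Base (channels multiplier)",
#' "Learning rate", ...) for traceability against the training recipe.
#'
#' @param path YAML file path.
#' @return list with \code{arch} (\code{\link{arch_config}}) and
#'   \code{train} (\code{\link{train_config}}).
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  g <- function(k, d) y[[k]] %||% d
  arch <- arch_config(
    base_channels = g("Base (channels multiplier)", 32L),
    input_size = g("Input size", 256L),
    transformer_layers = g("Transformer layers", 4L),
    attention_heads = g("Transformer heads", 8L))
  tc <- train_config(
    learning_rate = g("Learning rate", 1e-4),
    max_epochs = g("Epochs", 50L),
    early_stop_patience = g("Early stopping patience", 12L),
    plateau_factor = g("Scheduler factor", 0.5),
    plateau_patience = g("Scheduler patience", 5L),
    clip_max_norm = g("Gradient clipping (max norm)", 5.0),
    batch_size = g("Batch size", 4L),
    mixed_precision = isTRUE(g("Mixed precision", FALSE)),
    seed = g("Seed", 0L))
  list(arch = arch, train = tc)
}

#' @rdname read_experiment_config
#' @param arch an \code{\link{arch_config}}.
#' @param train a \code{\link{train_config}}.
#' @export
write_experiment_config <- function(arch, train, path) {
  yaml::write_yaml(list(
    `Base (channels multiplier)` = arch$base_channels,
    `Input size` = arch$input_size,
    `Transformer layers` = arch$transformer_layers,
    `Transformer heads` = arch$attention_heads,
    `Batch size` = train$batch_size,
    `Learning rate` = train$learning_rate,
    `Epochs` = train$max_epochs,
    `Early stopping patience` = train$early_stop_patience,
    `Scheduler factor` = train$plateau_factor,
    `Scheduler patience` = train$plateau_patience,
    `Gradient clipping (max norm)` = train$clip_max_norm,
    `Mixed precision` = train$mixed_precision,
    `Seed` = train$seed), path)
  invisible(path)
}

report_row <- function(variant, split, report) {
  s <- report$summary
  data.frame(variant = variant, split = split, metric = s$metric,
             point = s$point, lower = s$lower, upper = s$upper,
             auc = report$auc)
}

write_run_plots <- function(out_dir, report, probs, gts) {
  ok <- tryCatch({
    grDevices::png(file.path(out_dir, "confusion.png"), 480, 480)
    cm <- report$confusion$counts
    m <- matrix(c(cm$tn, cm$fn, cm$fp, cm$tp), 2, 2)
    graphics::image(1:2, 1:2, m, col = grDevices::hcl.colors(64, "Blues 3",
                                                             rev = TRUE),
                    axes = FALSE, xlab = "Predicted", ylab = "Actual",
                    main = "Pixel confusion matrix")
    graphics::axis(1, 1:2, c("BG", "FG")); graphics::axis(2, 1:2, c("BG", "FG"))
    for (i in 1:2) for (j in 1:2)
      graphics::text(i, j, format(m[i, j], big.mark = ","))
    grDevices::dev.off()
    sc <- unlist(lapply(probs, as.numeric))
    lb <- unlist(lapply(gts, as.numeric)) > 0.5
    if (length(sc) > 2e4) {
      keep <- with_seed(1L, sample.int(length(sc), 2e4))
      sc <- sc[keep]; lb <- lb[keep]
    }
    if (any(lb) && !all(lb)) {
      th <- sort(unique(stats::quantile(sc, seq(0, 1, 0.01), names = FALSE)))
      tpr <- vapply(th, function(t) mean(sc[lb] >= t), numeric(1))
      fpr <- vapply(th, function(t) mean(sc[!lb] >= t), numeric(1))
      grDevices::png(file.path(out_dir, "roc.png"), 480, 480)
      graphics::plot(fpr, tpr, type = "l", xlab = "False positive rate",
                     ylab = "True positive rate", main = "Pixel ROC")
      graphics::abline(0, 1, lty = 2)
      grDevices::dev.off()
    }
    TRUE
  }, error = function(e) FALSE)
  invisible(ok)
}

#' Run a suite of experiment variants
#'
#' For each variant: build the model (hybrid or plain-U-Net ablation),
#' train on the patient-level 70/15/15 split of the manifest, evaluate on
#' validation and test, and write artifacts (config snapshot, training log
#' CSV, best/last checkpoints, metric tables, confusion/ROC plots) under
#' \code{out_root/<variant>}. A failing variant is recorded in the report
#' and does not abort the remaining variants. With \code{resume = TRUE} a
#' variant whose artifacts already exist is not retrained; its report rows
#' are regenerated from the stored tables.
#'
#' @param variants list of \code{\link{experiment_variant}}s or names.
#' @param manifest manifest data.frame or path to a manifest CSV.
#' @param arch shared \code{\link{arch_config}}.
#' @param cfg shared \code{\link{train_config}} (its \code{augmentation}
#'   field is overridden per variant).
#' @param out_root output directory root.
#' @param split_seed seed for the patient split.
#' @param resume skip variants with existing artifacts.
#' @param verbose per-epoch progress.
#' @return consolidated data.frame (variant x split x metric with CIs),
#'   also written to \code{out_root/suite_report.csv}; failed variants
#'   appear in the \code{errors} attribute.
#' @export
run_suite <- function(variants, manifest, arch = arch_config(),
                      cfg = train_config(), out_root, split_seed = 0L,
                      resume = FALSE, verbose = FALSE) {
  dir.create(out_root, recursive = TRUE, showWarnings = FALSE)
  if (length(variants) == 0L) {
    rep <- data.frame(variant = character(0), split = character(0),
                      metric = character(0), point = numeric(0),
                      lower = numeric(0), upper = numeric(0),
                      auc = numeric(0))
    utils::write.csv(rep, file.path(out_root, "suite_report.csv"),
                     row.names = FALSE)
    return(rep)
  }
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  variants <- lapply(variants, function(v)
    if (is.character(v)) parse_variant(v) else v)
  nms <- vapply(variants, function(v) v$name, character(1))
  if (anyDuplicated(nms)) stop_config("variant names must be unique")
  split <- split_by_patient(manifest, seed = split_seed)
  tr <- load_split(split$train, target_size = arch$input_size)
  va <- load_split(split$val, target_size = arch$input_size)
  te <- load_split(split$test, target_size = arch$input_size)
  rows <- list(); errors <- list()
  for (v in variants) {
    vd <- file.path(out_root, v$name)
    done <- file.exists(file.path(vd, "val_metrics.csv")) &&
      file.exists(file.path(vd, "test_metrics.csv"))
    res <- tryCatch({
      if (resume && done) {
        lapply(c(val = "val", test = "test"), function(s) {
          m <- utils::read.csv(file.path(vd, paste0(s, "_metrics.csv")))
          data.frame(variant = v$name, split = s, metric = m$metric,
                     point = m$point, lower = m$lower, upper = m$upper,
                     auc = m$auc)
        })
      } else {
        dir.create(vd, recursive = TRUE, showWarnings = FALSE)
        acfg <- arch
        acfg$use_transformer <- v$architecture == "hybrid"
        vcfg <- cfg
        vcfg$loss <- v$loss
        vcfg$augmentation <- if (v$augmentation) augment_config() else NULL
        write_experiment_config(acfg, vcfg, file.path(vd, "config.yaml"))
        model <- hybrid_unet(acfg, seed = cfg$seed)
        fit <- train(model, tr, vcfg, val_samples = va, out_dir = vd,
                     verbose = verbose)
        out <- list()
        for (s in c("val", "test")) {
          ss <- if (s == "val") va else te
          probs <- lapply(ss, function(x)
            model_forward(fit$model, x$image, train = FALSE)$prob)
          gts <- lapply(ss, function(x) x$mask)
          rp <- metric_report(probs, gts, seed = cfg$seed)
          write_metric_report(rp, file.path(vd, s))
          if (s == "test") write_run_plots(vd, rp, probs, gts)
          out[[s]] <- report_row(v$name, s, rp)
        }
        out
      }
    }, error = function(e) {
      errors[[v$name]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(res)) rows <- c(rows, res)
  }
  rep <- do.call(rbind, rows)
  rownames(rep) <- NULL
  utils::write.csv(rep, file.path(out_root, "suite_report.csv"),
                   row.names = FALSE)
  if (length(errors)) attr(rep, "errors") <- errors
  rep
}

#' Regenerate the consolidated suite report from stored artifacts
#'
#' Reads the per-variant metric tables written by \code{\link{run_suite}}
#' and rebuilds the consolidated table without any retraining.
#'
#' @param out_root a suite output directory.
#' @return consolidated report data.frame.
#' @export
report_from_artifacts <- function(out_root) {
  dirs <- list.dirs(out_root, recursive = FALSE)
  rows <- list()
  for (d in dirs) {
    for (s in c("val", "test")) {
      f <- file.path(d, paste0(s, "_metrics.csv"))
      if (file.exists(f)) {
        m <- utils::read.csv(f)
        rows[[paste(basename(d), s)]] <-
          data.frame(variant = basename(d), split = s, metric = m$metric,
                     point = m$point, lower = m$lower, upper = m$upper,
                     auc = m$auc)
      }
    }
  }
  rep <- do.call(rbind, rows)
  rownames(rep) <- NULL
  rep
}
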