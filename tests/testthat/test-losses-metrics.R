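# Loss terms, overlap metrics, confusion statistics, AUC and bootstrap.

test_that("bce_loss matches the literal mean negative log-likelihood", {
  expect_lt(bce_loss(c(1 - 1e-7, 1 - 1e-7), c(1, 1)), 1e-6)
  expect_equal(bce_loss(0.5, 1), log(2), tolerance = 1e-12)
  set.seed(3)
  p <- runif(20, 0.01, 0.99); y <- rbinom(20, 1, 0.5)
  direct <- -mean(y * log(p) + (1 - y) * log(1 - p))
  expect_equal(bce_loss(p, y), direct, tolerance = 1e-12)
  expect_error(bce_loss(c(0.1, 0.2), 1), class = "lesionseg_shape_error")
})

test_that("dice_coefficient follows the printed soft formula", {
  y <- c(rep(1, 5), rep(0, 5))
  expect_equal(dice_coefficient(y, y), 1, tolerance = 1e-6)
  eps <- 1e-6
  expect_equal(dice_coefficient(c(1, 0), c(0, 1), eps = eps), eps / (2 + eps))
  expect_equal(dice_coefficient(c(0.5, 0.5), c(1, 0), eps = 0), 0.5)
  # both empty: eps/eps = 1
  expect_equal(dice_coefficient(c(0, 0), c(0, 0)), 1)
  # symmetric for binary arguments
  a <- rbinom(30, 1, 0.4); b <- rbinom(30, 1, 0.4)
  expect_equal(dice_coefficient(a, b), dice_coefficient(b, a))
})

test_that("combined loss is BCE plus Dice loss with a correct gradient", {
  set.seed(4)
  p <- runif(40, 0.05, 0.95); y <- rbinom(40, 1, 0.5)
  lt <- combined_loss(p, y)
  expect_equal(lt$total, lt$bce + (1 - lt$dice), tolerance = 1e-12)
  expect_lt(combined_loss(pmin(pmax(y, 1e-7), 1 - 1e-7), y)$total, 1e-4)
  # finite-difference gradient on a 5-pixel instance
  p5 <- c(0.2, 0.7, 0.5, 0.9, 0.1); y5 <- c(0, 1, 1, 1, 0)
  g <- combined_loss(p5, y5, gradient = TRUE)$grad
  h <- 1e-6
  fd <- vapply(1:5, function(i) {
    pp <- p5; pp[i] <- pp[i] + h; f1 <- combined_loss(pp, y5)$total
    pp[i] <- pp[i] - 2 * h; f0 <- combined_loss(pp, y5)$total
    (f1 - f0) / (2 * h)
  }, numeric(1))
  expect_equal(g, fd, tolerance = 1e-4)
})

test_that("combined loss is minimized exactly at the labels (3-pixel grids)", {
  grids <- expand.grid(y1 = 0:1, y2 = 0:1, y3 = 0:1)
  for (r in seq_len(nrow(grids))) {
    y <- as.numeric(grids[r, ])
    at_truth <- combined_loss(y, y)$total
    expect_lt(at_truth, 1e-4)
    for (trial in 1:5) {
      p <- runif(3, 0.1, 0.9)
      expect_gt(combined_loss(p, y)$total, at_truth)
    }
  }
})

test_that("overlap metrics: worked counts and the IoU-Dice identity", {
  gt <- matrix(c(rep(1, 100), rep(0, 300)), 20, 20)  # 100 fg pixels
  pred <- matrix(c(rep(1, 50), rep(0, 350)), 20, 20) # covers 50, no FP
  m <- overlap_metrics(pred, gt)
  expect_equal(m$dice, 100 / 150, tolerance = 1e-12)
  expect_equal(m$iou, 0.5, tolerance = 1e-12)
  m2 <- overlap_metrics(gt, gt)
  expect_equal(unlist(m2[c("dice", "iou", "accuracy", "f1")]),
               c(dice = 1, iou = 1, accuracy = 1, f1 = 1))
  set.seed(5)
  for (i in 1:10) {
    a <- matrix(rbinom(64, 1, 0.3), 8, 8); b <- matrix(rbinom(64, 1, 0.3), 8, 8)
    mm <- overlap_metrics(a, b)
    expect_equal(mm$iou, mm$dice / (2 - mm$dice), tolerance = 1e-12)
    expect_equal(mm$f1, mm$dice, tolerance = 1e-12)
    expect_true(all(unlist(mm) >= 0 & unlist(mm) <= 1))
  }
})

test_that("confusion statistics enumerate pixels one-vs-rest", {
  gt <- c(1, 1, 0, 0); pred <- c(1, 0, 0, 0)
  cw <- confusion_and_classwise(pred, gt)
  expect_equal(cw$counts, list(tp = 1L, fp = 0L, fn = 1L, tn = 2L))
  fg <- cw$classes[cw$classes$class == "foreground", ]
  expect_equal(fg$recall, 0.5)
  expect_equal(fg$precision, 1)
  expect_equal(fg$f1, 2 / 3, tolerance = 1e-12)
  expect_equal(unname(cw$macro["f1"]), mean(cw$classes$f1), tolerance = 1e-12)
  perfect <- confusion_and_classwise(gt, gt)
  expect_equal(perfect$counts$fp + perfect$counts$fn, 0L)
  expect_equal(perfect$classes$f1, c(1, 1))
  total <- with(cw$counts, tp + fp + fn + tn)
  expect_equal(total, 4L)
})

test_that("roc_auc is the tie-aware pair probability", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  # 6-element brute-force pair oracle
  s <- c(0.1, 0.4, 0.4, 0.6, 0.7, 0.2); y <- c(0, 0, 1, 1, 1, 0)
  pairs <- expand.grid(p = which(y == 1), n = which(y == 0))
  want <- mean(ifelse(s[pairs$p] > s[pairs$n], 1,
                      ifelse(s[pairs$p] == s[pairs$n], 0.5, 0)))
  expect_equal(roc_auc(s, y), want, tolerance = 1e-12)
  # invariant under strictly monotone transforms
  set.seed(6)
  s2 <- runif(50); y2 <- rbinom(50, 1, 0.5)
  expect_equal(roc_auc(s2, y2), roc_auc(qlogis(s2 * 0.98 + 0.01), y2),
               tolerance = 1e-12)
  expect_error(roc_auc(s2, rep(1, 50)), "single class")
})

test_that("roc_auc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  s <- runif(200); y <- rbinom(200, 1, plogis(3 * (s - 0.5)))
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
  expect_equal(roc_auc(s, y), ref, tolerance = 1e-10)
})

test_that("bootstrap CI is seeded, ordered and degenerate on constants", {
  ci <- bootstrap_ci(c(0.9, 0.9, 0.9), seed = 1)
  expect_equal(unlist(ci), c(lower = 0.9, point = 0.9, upper = 0.9))
  set.seed(8)
  x <- runif(25)
  a <- bootstrap_ci(x, seed = 7); b <- bootstrap_ci(x, seed = 7)
  expect_identical(a, b)
  expect_lte(a$lower, a$point); expect_lte(a$point, a$upper)
  expect_error(bootstrap_ci(numeric(0)), "empty")
})

test_that("bootstrap CI width shrinks with sample size", {
  widths <- vapply(c(10, 100, 1000), function(n) {
    x <- with(list(), {set.seed(20); rnorm(n, 0.8, 0.1)})
    ci <- bootstrap_ci(x, seed = 3)
    ci$upper - ci$lower
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("metric_report averages per-image scores and pools confusion", {
  set.seed(9)
  probs <- lapply(1:6, function(i) matrix(runif(64), 8, 8))
  gts <- lapply(1:6, function(i) matrix(rbinom(64, 1, 0.4), 8, 8))
  rp <- metric_report(probs, gts, resamples = 200, seed = 1)
  # manual per-image mean
  manual <- mean(vapply(1:6, function(i)
    overlap_metrics(binarize(probs[[i]]), gts[[i]])$dice, numeric(1)))
  expect_equal(rp$summary$point[rp$summary$metric == "dice"], manual)
  expect_true(all(rp$summary$lower <= rp$summary$point + 1e-12))
  expect_true(all(rp$summary$point <= rp$summary$upper + 1e-12))
  stem <- tempfile()
  write_metric_report(rp, stem)
  expect_true(file.exists(paste0(stem, "_metrics.csv")))
  tab <- read.csv(paste0(stem, "_classes.csv"))
  expect_equal(tab$class, c("background", "foreground", "macro", "weighted"))
})
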