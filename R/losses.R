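# Combined BCE + Dice training objective. The Dice term keeps the small
# stabilizing constant in both numerator and denominator, so an
# empty-vs-empty comparison yields Dice 1 rather than 0/0.

#' Binary cross-entropy loss
#'
#' Mean negative Bernoulli log-likelihood over pixels,
#' \code{-mean(y*log(p) + (1-y)*log(1-p))}. Probabilities are clamped to
#' \code{[delta, 1-delta]} before the logarithms to avoid log(0).
#'
#' @param p predicted probabilities in [0, 1].
#' @param y binary labels (0/1), same length/shape as \code{p}.
#' @param delta clamping constant (default 1e-7).
#' @return non-negative scalar.
#' @examples
#' bce_loss(0.5, 1)  # log(2)
#' @export
bce_loss <- function(p, y, delta = 1e-7) {
  if (length(p) != length(y)) stop_shape("bce_loss: length mismatch (",
                                         length(p), " vs ", length(y), ")")
  pc <- pmin(pmax(as.numeric(p), delta), 1 - delta)
  y <- as.numeric(y)
  -mean(y * log(pc) + (1 - y) * log(1 - pc))
}

#' Soft Dice coefficient
#'
#' \code{(2 * sum(y*p) + eps) / (sum(p) + sum(y) + eps)}. With binary
#' \code{p} this is the hard Dice overlap; with probabilities it is the
#' differentiable (soft) form used in the Dice loss. The stabilizer
#' \code{eps} sits in numerator and denominator, so two empty masks give
#' Dice 1.
#'
#' @param p predicted probabilities (or a binary mask).
#' @param y binary ground-truth labels.
#' @param eps stabilizing constant (default 1e-6).
#' @return scalar; in [0, 1] for inputs in [0, 1].
#' @export
dice_coefficient <- function(p, y, eps = 1e-6) {
  if (length(p) != length(y))
    stop_shape("dice_coefficient: length mismatch")
  p <- as.numeric(p); y <- as.numeric(y)
  (2 * sum(y * p) + eps) / (sum(p) + sum(y) + eps)
}

#' Combined BCE + Dice loss
#'
#' The training objective: \code{total = bce + (1 - soft_dice)}. Returns
#' all terms; \code{gradient = TRUE} additionally returns the analytic
#' gradient of the total with respect to \code{p} (used by the training
#' loop after chaining through the sigmoid).
#'
#' @inheritParams dice_coefficient
#' @param delta BCE clamping constant.
#' @param gradient also return d(total)/dp.
#' @return list with \code{bce}, \code{dice}, \code{dice_loss},
#'   \code{total}, and optionally \code{grad} (same shape as \code{p}).
#' @export
combined_loss <- function(p, y, eps = 1e-6, delta = 1e-7, gradient = FALSE) {
  if (length(p) != length(y)) stop_shape("combined_loss: length mismatch")
  bce <- bce_loss(p, y, delta)
  dc <- dice_coefficient(p, y, eps)
  out <- list(bce = bce, dice = dc, dice_loss = 1 - dc,
              total = bce + (1 - dc))
  if (gradient) {
    pv <- as.numeric(p); yv <- as.numeric(y)
    n <- length(pv)
    pc <- pmin(pmax(pv, delta), 1 - delta)
    inside <- pv > delta & pv < 1 - delta
    dbce <- ifelse(inside, (-yv / pc + (1 - yv) / (1 - pc)) / n, 0)
    num <- 2 * sum(yv * pv) + eps
    den <- sum(pv) + sum(yv) + eps
    ddice_loss <- (num - 2 * yv * den) / den^2
    g <- dbce + ddice_loss
    if (!is.null(dim(p))) dim(g) <- dim(p)
    out$grad <- g
  }
  out
}

# Gradient of the combined loss with respect to the logits z (p = sigmoid(z)):
# BCE term simplifies to (p - y)/N; the Dice term chains through p(1-p).
combined_loss_logit_grad <- function(p, y, eps = 1e-6) {
  pv <- as.numeric(p); yv <- as.numeric(y)
  n <- length(pv)
  num <- 2 * sum(yv * pv) + eps
  den <- sum(pv) + sum(yv) + eps
  g <- (pv - yv) / n + ((num - 2 * yv * den) / den^2) * pv * (1 - pv)
  if (!is.null(dim(p))) dim(g) <- dim(p)
  g
}

# BCE-only logit gradient (for the bce-loss experiment variants).
bce_logit_grad <- function(p, y) {
  g <- (as.numeric(p) - as.numeric(y)) / length(p)
  if (!is.null(dim(p))) dim(g) <- dim(p)
  g
}
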