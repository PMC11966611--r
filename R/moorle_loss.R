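# MOORLE: Multi-Objective Optimization Regularized by Loss Entropy.
#
# The batch loss decomposes the usual pooled MSE by drug: per-drug MSEs are
# softmax-normalized into a distribution P, and the penalty a*(ln|D| - H(P))
# is added to the unweighted mean of the per-drug MSEs. The penalty is zero
# exactly when all per-drug losses are equal (uniform P attains the entropy
# bound ln|D|) and positive otherwise, steering training toward balanced
# performance across drugs instead of favoring the most-screened ones.

#' Loss configuration
#'
#' @param kind `"mse"` for the pooled mean squared error, `"moorle"` for the
#'   entropy-regularized multi-objective loss.
#' @param a Regularization weight, finite and non-negative. Ignored for
#'   `kind = "mse"`. At `a = 0` the MOORLE loss is the unweighted mean of
#'   per-drug MSEs.
#' @return A `loss_config` list.
#' @export
loss_config <- function(kind = c("mse", "moorle"), a = 0) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(a), length(a) == 1, is.finite(a), a >= 0)
  structure(list(kind = kind, a = a), class = "loss_config")
}

#' Mean squared error
#'
#' @param predictions,targets Equal-length nonzero numeric vectors.
#' @return `mean((predictions - targets)^2)`.
#' @export
mse_loss <- function(predictions, targets) {
  if (length(predictions) == 0 || length(targets) == 0) {
    stop("mse_loss: empty input")
  }
  stopifnot(length(predictions) == length(targets))
  mean((predictions - targets)^2)
}

#' Per-drug mean squared errors
#'
#' Decomposes a batch loss by group (drug): each drug's MSE is computed over
#' exactly its own pairs. A single substitution point, `base`, lets the
#' squared-error base loss be swapped for any other non-negative pairwise
#' loss without touching the aggregation path.
#'
#' @param predictions,targets Aligned numeric vectors.
#' @param groups Group (drug id) label per pair.
#' @param base Function `(predictions, targets) -> scalar` applied within
#'   each group; defaults to [mse_loss()].
#' @return Named numeric vector: one loss per distinct group in the batch.
#' @export
per_group_mse <- function(predictions, targets, groups, base = mse_loss) {
  if (is.null(predictions) || length(predictions) == 0) {
    stop("per_group_mse: batch has no predictions attached")
  }
  stopifnot(length(predictions) == length(targets),
            length(groups) == length(targets))
  idx <- split(seq_along(targets), as.character(groups))
  vapply(idx, function(i) base(predictions[i], targets[i]), numeric(1))
}

#' Softmax-normalize per-drug losses into a distribution
#'
#' P assigns each drug probability mass proportional to `exp(MSE_d)`. The
#' maximum loss is subtracted before exponentiation (softmax is invariant to
#' a common shift), so the computation is overflow-safe for arbitrarily
#' large losses.
#'
#' @param group_mse Named numeric vector of finite per-group losses.
#' @return Named numeric vector summing to 1.
#' @export
normalize_losses <- function(group_mse) {
  if (length(group_mse) == 0) stop("normalize_losses: empty loss map")
  stopifnot(all(is.finite(group_mse)))
  e <- exp(group_mse - max(group_mse))
  e / sum(e)
}

#' Shannon entropy of a loss distribution
#'
#' Natural-log entropy `H(P) = -sum(p * ln p)` with the convention
#' `0 * ln 0 = 0`. Maximized at `ln(length(p))` by the uniform distribution,
#' i.e. when all per-drug losses are equal.
#'
#' @param p Non-negative numeric vector summing to 1 (tolerance `tol`).
#' @param tol Allowed deviation of `sum(p)` from 1.
#' @return Entropy in nats.
#' @export
loss_entropy <- function(p, tol = 1e-9) {
  stopifnot(all(p >= 0))
  if (abs(sum(p) - 1) > tol) {
    stop("loss_entropy: values sum to ", format(sum(p)), ", not 1")
  }
  nz <- p > 0
  -sum(p[nz] * log(p[nz]))
}

#' MOORLE loss of a grouped batch
#'
#' Computes the full decomposition
#' `L = mean(MSE_d) + a * (ln|D| - H(P))`, where `D` is the set of drugs
#' present in the batch and `P` the softmax of the per-drug MSEs. With a
#' single drug in the batch the regularizer is exactly zero and `L` reduces
#' to that drug's MSE; with `a = 0` it is the unweighted mean of per-drug
#' MSEs. The entropy bound guarantees the regularizer is non-negative, so
#' `L >= mean(MSE_d)` always.
#'
#' @param predictions,targets Aligned numeric vectors (non-empty).
#' @param groups Drug label per pair.
#' @param a Non-negative regularization weight.
#' @return A `moorle_loss` object: list with `group_mse`, `distribution`,
#'   `entropy`, `n_groups`, `regularizer` and `total`.
#' @examples
#' y <- c(0, 0, 1); f <- c(0, 1, 1)
#' moorle_loss(f, y, groups = c("A", "A", "B"), a = 1)$total
#' @export
moorle_loss <- function(predictions, targets, groups, a = 0) {
  if (length(predictions) == 0) stop("moorle_loss: empty batch")
  stopifnot(is.finite(a), a >= 0)
  gm <- per_group_mse(predictions, targets, groups)
  k <- length(gm)
  p <- normalize_losses(gm)
  h <- loss_entropy(p)
  reg <- if (k == 1L) 0 else max(log(k) - h, 0)
  structure(list(
    group_mse = gm,
    distribution = p,
    entropy = h,
    n_groups = k,
    regularizer = reg,
    a = a,
    total = mean(gm) + a * reg
  ), class = "moorle_loss")
}

#' @export
print.moorle_loss <- function(x, ...) {
  cat("MOORLE loss over ", x$n_groups, " drug(s): total = ",
      format(x$total), "\n  mean per-drug MSE = ", format(mean(x$group_mse)),
      ", H(P) = ", format(x$entropy), " (max ", format(log(x$n_groups)),
      "), a = ", x$a, "\n", sep = "")
  invisible(x)
}

#' Scalar batch loss under a loss configuration
#'
#' @param predictions,targets,groups As in [moorle_loss()].
#' @param config A [loss_config()].
#' @return Scalar loss value.
#' @export
batch_loss <- function(predictions, targets, groups, config) {
  if (config$kind == "mse") {
    mse_loss(predictions, targets)
  } else {
    moorle_loss(predictions, targets, groups, a = config$a)$total
  }
}

#' Gradient of the batch loss with respect to predictions
#'
#' For the MOORLE loss the gradient flows through the softmax and entropy
#' terms (P is not treated as a constant): with per-drug MSEs `m` and
#' `p = softmax(m)`,
#' `dL/dm_k = 1/|D| + a * p_k * (ln p_k + H(P))`, and
#' `dm_k/df_i = 2 (f_i - y_i) / n_k` for pair `i` in drug `k`.
#' For plain MSE, `dL/df_i = 2 (f_i - y_i) / n`.
#'
#' @param predictions,targets,groups As in [moorle_loss()].
#' @param config A [loss_config()].
#' @return Numeric vector of the same length as `predictions`.
#' @export
batch_loss_gradient <- function(predictions, targets, groups, config) {
  n <- length(predictions)
  if (n == 0) stop("batch_loss_gradient: empty batch")
  resid2 <- 2 * (predictions - targets)
  if (config$kind == "mse") {
    return(resid2 / n)
  }
  g <- as.character(groups)
  idx <- split(seq_len(n), g)
  m <- vapply(idx, function(i) {
    mean((predictions[i] - targets[i])^2)
  }, numeric(1))
  k <- length(m)
  if (k == 1L) {
    # |D| = 1: regularizer identically zero, pure MSE gradient
    return(resid2 / n)
  }
  p <- normalize_losses(m)
  h <- -sum(p * log(p))
  # d(ln|D| - H)/dm_k via dp_j/dm_k = p_j (delta_jk - p_k)
  dL_dm <- 1 / k + config$a * p * (log(p) + h)
  grad <- numeric(n)
  for (d in names(idx)) {
    i <- idx[[d]]
    grad[i] <- dL_dm[[d]] * resid2[i] / length(i)
  }
  grad
}
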