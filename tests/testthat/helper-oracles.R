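# Independent oracles, written as plain loops directly off the defining
# formulas. They share no code with the package implementation.

# Entropy-regularized multi-objective loss composed step by step:
# per-group squared-error means -> softmax -> entropy -> penalized total.
oracle_moorle_total <- function(pred, targ, groups, a) {
  gs <- unique(as.character(groups))
  mses <- numeric(length(gs))
  for (j in seq_along(gs)) {
    i <- which(as.character(groups) == gs[j])
    s <- 0
    for (ii in i) s <- s + (pred[ii] - targ[ii])^2
    mses[j] <- s / length(i)
  }
  expo <- exp(mses)
  p <- expo / sum(expo)
  H <- 0
  for (pj in p) if (pj > 0) H <- H - pj * log(pj)
  mean(mses) + a * (log(length(gs)) - H)
}

# Central-difference numerical gradient of a scalar function of a vector.
numerical_gradient <- function(fun, x, eps = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- x[i] + eps
    xm <- x; xm[i] <- x[i] - eps
    g[i] <- (fun(xp) - fun(xm)) / (2 * eps)
  }
  g
}

# Textbook direct formulas for the evaluation metrics.
oracle_metrics_direct <- function(y, yhat) {
  n <- length(y)
  pearson_direct <- function(u, v) {
    mu <- sum(u) / n; mv <- sum(v) / n
    sum((u - mu) * (v - mv)) /
      sqrt(sum((u - mu)^2) * sum((v - mv)^2))
  }
  c(r2 = 1 - sum((y - yhat)^2) / sum((y - sum(y) / n)^2),
    mse = sum((y - yhat)^2) / n,
    mae = sum(abs(y - yhat)) / n,
    pearson = pearson_direct(y, yhat),
    spearman = pearson_direct(rank(y), rank(yhat)))
}

# Random grouped batch: n pairs over k drugs (every drug represented).
make_random_batch <- function(n, k, seed) {
  withr::with_seed(seed, {
    groups <- paste0("d", c(seq_len(k), sample.int(k, n - k, replace = TRUE)))
    list(pred = stats::rnorm(n), targ = stats::rnorm(n),
         groups = groups)
  })
}

# Small response table for split tests: given per-drug counts.
make_table <- function(counts, seed = 1) {
  withr::with_seed(seed, {
    rec <- do.call(rbind, lapply(names(counts), function(d) {
      data.frame(sample_id = paste0("s", sample.int(10000, counts[[d]])),
                 drug_id = d,
                 response = stats::runif(counts[[d]]),
                 stringsAsFactors = FALSE)
    }))
    drug_response_table(rec)
  })
}

# Hand-built drp_dataset with a noiseless linear response in [0, 1].
make_linear_dataset <- function(n = 200, p = 5, k = 4, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(stats::rnorm(n * p), nrow = n,
                dimnames = list(NULL, paste0("f", 1:p)))
    w <- stats::rnorm(p)
    y <- as.numeric(X %*% w)
    y <- (y - min(y)) / (max(y) - min(y))
    structure(list(features = X, response = y,
                   drug_id = paste0("d", rep_len(seq_len(k), n)),
                   sample_id = paste0("s", seq_len(n)),
                   n_pairs = n, n_sample_features = p, n_drug_features = 0L),
              class = "drp_dataset")
  })
}
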