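# Epoch samplers for minibatch SGD. Sequential shuffled sampling (the deep
# learning default) visits every record exactly once per epoch in seeded
# random order; under long-tailed per-drug counts this lets rare drugs
# contribute little to most gradient steps. Mixed sampling draws records
# with replacement from a lambda-blend of the uniform record distribution
# and the per-drug-balanced distribution, interpolating between the two.

#' Sampler configuration
#'
#' @param strategy `"sequential"` (shuffled, without replacement) or
#'   `"mixed"` (weighted, with replacement).
#' @param batch_size Positive integer minibatch size.
#' @param lambda Mixing weight in \[0, 1\] (mixed strategy only): 0 recovers
#'   uniform record sampling, 1 fully drug-balanced sampling.
#' @param seed Integer seed; all samplers are deterministic given the seed.
#' @return A `sampler_config` list.
#' @export
sampler_config <- function(strategy = c("sequential", "mixed"),
                           batch_size = 64, lambda = 0.5, seed = 1) {
  strategy <- match.arg(strategy)
  stopifnot(batch_size >= 1, lambda >= 0, lambda <= 1)
  structure(list(strategy = strategy, batch_size = as.integer(batch_size),
                 lambda = lambda, seed = as.integer(seed)),
            class = "sampler_config")
}

chunk_indices <- function(ix, batch_size) {
  unname(split(ix, ceiling(seq_along(ix) / batch_size)))
}

#' Sequential shuffled epoch
#'
#' A seeded permutation of all record indices, chunked into batches; every
#' index appears exactly once per epoch and the final batch may be smaller.
#'
#' @param n_records Number of records (>= 1).
#' @param batch_size Minibatch size.
#' @param seed Integer seed.
#' @return List of integer index vectors.
#' @export
sequential_shuffled <- function(n_records, batch_size, seed) {
  stopifnot(n_records >= 1)
  perm <- withr::with_seed(seed, sample.int(n_records))
  chunk_indices(perm, batch_size)
}

#' Per-record sampling weights of the mixed scheme
#'
#' Each record of drug `d` gets weight
#' `w(d) = (1 - lambda)/N + lambda/(|D| * count(d))`, so the total mass per
#' drug interpolates between its empirical share (`lambda = 0`) and `1/|D|`
#' (`lambda = 1`); weights sum to 1 over all records by construction.
#'
#' @param drug_counts Named integer vector of per-drug record counts (>= 1).
#' @param lambda Mixing weight in \[0, 1\].
#' @return Named numeric vector: the weight of one record of each drug.
#' @export
mixed_weights <- function(drug_counts, lambda) {
  stopifnot(length(drug_counts) > 0, lambda >= 0, lambda <= 1)
  if (any(drug_counts < 1)) {
    stop("mixed_weights: zero count for drug ",
         names(drug_counts)[drug_counts < 1][1])
  }
  n_total <- sum(drug_counts)
  k <- length(drug_counts)
  (1 - lambda) / n_total + lambda / (k * drug_counts)
}

#' Expand per-drug weights to aligned per-record weights
#'
#' @param groups Drug label per record.
#' @param lambda Mixing weight.
#' @return Numeric vector of per-record weights summing to 1.
#' @export
record_weights <- function(groups, lambda) {
  g <- as.character(groups)
  counts <- table(g)
  w <- mixed_weights(stats::setNames(as.integer(counts), names(counts)),
                     lambda)
  unname(w[g])
}

#' Weighted with-replacement epoch
#'
#' Draws `n_records` indices with replacement according to `weights` and
#' chunks them into batches, keeping the per-epoch gradient-step count equal
#' to the sequential sampler's.
#'
#' @param n_records Number of records; also the number of draws.
#' @param weights Per-record weights, non-negative, summing to 1.
#' @param batch_size Minibatch size.
#' @param seed Integer seed.
#' @return List of integer index vectors.
#' @export
sample_epoch <- function(n_records, weights, batch_size, seed) {
  stopifnot(n_records >= 1, length(weights) == n_records)
  if (any(weights < 0)) stop("sample_epoch: negative weight")
  if (abs(sum(weights) - 1) > 1e-8) {
    stop("sample_epoch: weights sum to ", format(sum(weights)), ", not 1")
  }
  draws <- withr::with_seed(
    seed, sample.int(n_records, n_records, replace = TRUE, prob = weights))
  chunk_indices(draws, batch_size)
}

#' One epoch of batches under a sampler configuration
#'
#' @param groups Drug label per record (length defines the epoch).
#' @param config A [sampler_config()].
#' @param epoch Epoch number (1-based); offsets the seed so successive
#'   epochs differ while the whole schedule stays reproducible.
#' @return List of integer index vectors.
#' @export
epoch_batches <- function(groups, config, epoch = 1L) {
  n <- length(groups)
  seed <- config$seed + as.integer(epoch) - 1L
  if (config$strategy == "sequential") {
    sequential_shuffled(n, config$batch_size, seed)
  } else {
    w <- record_weights(groups, config$lambda)
    sample_epoch(n, w, config$batch_size, seed)
  }
}
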