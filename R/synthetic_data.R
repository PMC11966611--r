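# Synthetic pair-input drug screens with known ground truth. The per-drug
# experiment-count profiles reproduce the two imbalance regimes seen in
# public cell-line screens: a small, mildly imbalanced panel (a few drugs
# below 90% of the maximum count) and a large, strongly imbalanced one
# (a long tail of drugs below 50% of the maximum). The response surface is
# a smooth function of sample and drug features squashed onto an AUC-like
# [0, 1] scale plus Gaussian noise, so a model that reads drug features can
# in principle generalize to held-out drugs.

#' Specification of a synthetic drug screen
#'
#' The defaults describe the strongly imbalanced regime at desk scale:
#' 60 drugs over 400 cell lines with a long-tailed count profile topping
#' out at 110 experiments per drug (about 5,100 pairs), responses on the
#' AUC scale with noise standard deviation 0.05.
#'
#' @param n_samples Number of cell lines.
#' @param n_drugs Number of drugs.
#' @param sample_feature_dim,drug_feature_dim Feature dimensions.
#' @param count_profile `"uniform"`, `"ccle_like"`, `"ctrp_like"`, or an
#'   explicit integer vector of per-drug counts (length `n_drugs`).
#' @param max_count Largest per-drug experiment count (ignored for explicit
#'   counts); must not exceed `n_samples` since each (sample, drug) pair is
#'   unique.
#' @param noise_sd Additive Gaussian noise on the squashed response.
#' @param drug_effect_scale Spread of drug features around their MOA
#'   cluster center; larger values make drugs within a mechanism class less
#'   alike.
#' @param interaction_scale Weight of the sample-by-drug bilinear
#'   interaction relative to the additive effects.
#' @param n_moa Number of mechanism-of-action clusters the drugs fall into.
#' @param seed Integer seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_samples = 400, n_drugs = 60,
                           sample_feature_dim = 20, drug_feature_dim = 10,
                           count_profile = "ctrp_like", max_count = 110,
                           noise_sd = 0.05, drug_effect_scale = 1,
                           interaction_scale = 0.5, n_moa = 6, seed = 1) {
  stopifnot(n_samples >= 1, n_drugs >= 1, noise_sd >= 0,
            n_moa >= 1, n_moa <= n_drugs)
  if (is.character(count_profile)) {
    stopifnot(max_count >= 1)
    if (max_count > n_samples) {
      stop("max_count = ", max_count, " exceeds n_samples = ", n_samples,
           "; each (sample, drug) pair must be unique")
    }
  } else {
    stopifnot(length(count_profile) == n_drugs,
              all(count_profile >= 1))
    if (any(count_profile > n_samples)) {
      stop("per-drug counts exceed n_samples")
    }
  }
  structure(list(n_samples = n_samples, n_drugs = n_drugs,
                 sample_feature_dim = sample_feature_dim,
                 drug_feature_dim = drug_feature_dim,
                 count_profile = count_profile, max_count = max_count,
                 noise_sd = noise_sd,
                 drug_effect_scale = drug_effect_scale,
                 interaction_scale = interaction_scale,
                 n_moa = n_moa, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Long-tailed per-drug experiment-count profiles
#'
#' `"uniform"` gives every drug `max_count` experiments. `"ccle_like"`
#' emulates the mildly imbalanced small-panel regime: 12.5% of drugs fall
#' below 90% of the maximum count, the rest sit at or near it.
#' `"ctrp_like"` emulates the strongly imbalanced large-screen regime:
#' 17.2% of drugs fall below 50% of the maximum and a further 19.6%
#' between 50% and 90%. In every profile at least one drug sits exactly at
#' `max_count`, and bucket memberships are exact by construction (rounded
#' bucket sizes), with within-bucket counts drawn uniformly.
#'
#' @param n_drugs Number of drugs.
#' @param max_count Count of the most-screened drug.
#' @param profile Profile name.
#' @param seed Integer seed.
#' @return Integer vector of length `n_drugs` (unsorted drug order).
#' @export
imbalance_profile <- function(n_drugs, max_count,
                              profile = c("ctrp_like", "ccle_like",
                                          "uniform"),
                              seed = 1) {
  stopifnot(n_drugs >= 1, max_count >= 1)
  profile <- match.arg(profile)
  if (profile == "uniform") {
    return(rep(as.integer(max_count), n_drugs))
  }
  withr::with_seed(seed, {
    draw <- function(n, lo, hi) {
      # uniform integer counts on [lo*max, hi*max): integer bounds are
      # taken with ceiling so no draw crosses a bucket edge
      lo_i <- max(1L, as.integer(ceiling(lo * max_count)))
      hi_i <- max(lo_i, as.integer(ceiling(hi * max_count)) - 1L)
      lo_i + as.integer(floor(stats::runif(n, 0, hi_i - lo_i + 1)))
    }
    if (profile == "ccle_like") {
      n_low <- round(0.125 * n_drugs)
      n_high <- n_drugs - n_low
      counts <- c(draw(n_low, 0.40, 0.90), draw(n_high, 0.90, 1.0 + 1e-9))
    } else {
      n_low <- round(0.172 * n_drugs)
      n_mid <- round(0.196 * n_drugs)
      n_high <- n_drugs - n_low - n_mid
      counts <- c(draw(n_low, 0.05, 0.50), draw(n_mid, 0.50, 0.90),
                  draw(n_high, 0.90, 1.0 + 1e-9))
    }
    counts[length(counts)] <- as.integer(max_count)  # anchor the maximum
    sample(counts)
  })
}

# Noiseless response surface for given sample/drug feature rows.
truth_response <- function(truth, sample_features, drug_features,
                           sample_id, drug_id) {
  xs <- sample_features[sample_id, , drop = FALSE]
  xd <- drug_features[drug_id, , drop = FALSE]
  raw <- as.numeric(xs %*% truth$w_sample) +
    as.numeric(xd %*% truth$w_drug) +
    truth$interaction_scale * rowSums((xs %*% truth$M) * xd)
  # squash calibrated so responses mimic dose-response AUC screens: most
  # pairs weakly responsive (mean ~0.7), spread ~0.14, keeping model MSE
  # in the regime where typical screen-fitted regressors operate
  stats::plogis(truth$squash_shift + truth$squash_scale * raw)
}

#' Generate a synthetic drug screen with known ground truth
#'
#' Sample features are standard normal. Drugs are grouped into `n_moa`
#' mechanism clusters; a drug's feature vector is its cluster center plus a
#' drug-specific perturbation scaled by `drug_effect_scale`. The noiseless
#' response of pair (c, d) is a calibrated logistic squash of
#' `<w_s, x_c> + <w_d, x_d> + interaction_scale * x_c' M x_d`, giving an
#' AUC-like value in (0, 1) — most pairs weakly responsive, spread around
#' 0.14 — to which `N(0, noise_sd)` noise is added.
#' Each drug is paired with a random subset of cell lines of the size
#' dictated by the count profile, so every (sample, drug) pair is unique.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `sample_features`, `drug_features`, `table`
#'   (a `drug_response_table`), `moa` (named map), `counts` (per-drug), and
#'   `truth` (latent parameters plus the noiseless response per record).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  counts <- if (is.character(spec$count_profile)) {
    imbalance_profile(spec$n_drugs, spec$max_count, spec$count_profile,
                      seed = spec$seed)
  } else {
    as.integer(spec$count_profile)
  }
  ps <- spec$sample_feature_dim
  pd <- spec$drug_feature_dim
  s_ids <- sprintf("CL%04d", seq_len(spec$n_samples))
  d_ids <- sprintf("DRUG%03d", seq_len(spec$n_drugs))

  withr::with_seed(spec$seed + 1L, {
    Xs <- matrix(stats::rnorm(spec$n_samples * ps), nrow = spec$n_samples,
                 dimnames = list(s_ids, paste0("g", seq_len(ps))))
    moa_of_drug <- sort(rep_len(seq_len(spec$n_moa), spec$n_drugs))
    centers <- matrix(stats::rnorm(spec$n_moa * pd, sd = 1.5),
                      nrow = spec$n_moa)
    Xd <- centers[moa_of_drug, , drop = FALSE] +
      spec$drug_effect_scale * matrix(stats::rnorm(spec$n_drugs * pd),
                                      nrow = spec$n_drugs)
    dimnames(Xd) <- list(d_ids, paste0("f", seq_len(pd)))

    truth <- list(
      w_sample = stats::rnorm(ps, sd = 1 / sqrt(ps)),
      w_drug = stats::rnorm(pd, sd = 1 / sqrt(pd)),
      M = matrix(stats::rnorm(ps * pd, sd = 1 / sqrt(ps * pd)), nrow = ps),
      interaction_scale = spec$interaction_scale,
      squash_shift = 1.0,
      squash_scale = 0.5,
      noise_sd = spec$noise_sd
    )

    rec_s <- character(0); rec_d <- character(0)
    for (j in seq_len(spec$n_drugs)) {
      chosen <- sample(s_ids, counts[j])
      rec_s <- c(rec_s, chosen)
      rec_d <- c(rec_d, rep(d_ids[j], counts[j]))
    }
    mu <- truth_response(truth, Xs, Xd, rec_s, rec_d)
    y <- mu + stats::rnorm(length(mu), sd = spec$noise_sd)

    truth$records <- data.frame(sample_id = rec_s, drug_id = rec_d,
                                mu = mu, stringsAsFactors = FALSE)
    truth$spec_seed <- spec$seed

    list(
      sample_features = Xs,
      drug_features = Xd,
      # noise can push AUC-like responses slightly outside [0, 1];
      # expected here, so the constructor's range warning is silenced
      table = suppressWarnings(drug_response_table(data.frame(
        sample_id = rec_s, drug_id = rec_d, response = y,
        stringsAsFactors = FALSE))),
      moa = stats::setNames(paste0("MOA", moa_of_drug), d_ids),
      counts = stats::setNames(counts, d_ids),
      truth = truth
    )
  })
}

#' Best-achievable per-drug R² under the generator's noise
#'
#' Scores the noiseless ground-truth response surface against the noisy
#' observed responses, drug by drug — the ceiling any fitted model can
#' reach on this dataset. With `noise_sd = 0` every ceiling is exactly 1;
#' as noise grows the ceilings decay like
#' `var(signal) / (var(signal) + noise_sd^2)`.
#'
#' @param table The generated `drug_response_table`.
#' @param truth The `truth` element returned by [generate_dataset()].
#' @param min_group_size Drugs with fewer records are skipped.
#' @return Data frame: drug_id, n, ceiling_r2.
#' @export
oracle_metrics <- function(table, truth, min_group_size = 2) {
  rec <- truth$records
  if (nrow(rec) != nrow(table) ||
      !all(rec$sample_id == table$sample_id & rec$drug_id == table$drug_id)) {
    stop("oracle_metrics: table does not match the ground-truth records")
  }
  idx <- split(seq_len(nrow(table)), table$drug_id)
  rows <- lapply(names(idx), function(d) {
    i <- idx[[d]]
    if (length(i) < min_group_size) return(NULL)
    r2 <- if (stats::sd(table$response[i]) == 0) NA_real_ else
      r_squared(table$response[i], rec$mu[i])
    data.frame(drug_id = d, n = length(i), ceiling_r2 = r2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a generated dataset to delimited files
#'
#' Emits the response table, both feature matrices, the MOA map, and the
#' ground-truth latents (JSON) into a directory.
#'
#' @param data List from [generate_dataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_response_table(data$table, file.path(dir, "response.tsv"))
  write_feature_matrix(data$sample_features,
                       file.path(dir, "sample_features.tsv"))
  write_feature_matrix(data$drug_features,
                       file.path(dir, "drug_features.tsv"))
  utils::write.table(
    data.frame(drug_id = names(data$moa), moa = unname(data$moa)),
    file.path(dir, "moa.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(
    list(w_sample = data$truth$w_sample, w_drug = data$truth$w_drug,
         M = data$truth$M, interaction_scale = data$truth$interaction_scale,
         noise_sd = data$truth$noise_sd),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
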