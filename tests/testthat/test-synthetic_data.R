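test_that("count profiles reproduce the two imbalance regimes", {
  expect_equal(imbalance_profile(5, 10, "uniform"), rep(10L, 5))

  # strong-imbalance regime: 17.2% of drugs below half the maximum,
  # 19.6% between 50% and 90% of it
  for (s in 1:5) {
    counts <- imbalance_profile(100, 799, "ctrp_like", seed = s)
    expect_length(counts, 100)
    expect_equal(max(counts), 799L)
    n_low <- sum(counts < 0.5 * 799)
    n_mid <- sum(counts >= 0.5 * 799 & counts < 0.9 * 799)
    expect_true(abs(n_low - 17) <= 3)
    expect_true(abs(n_mid - 20) <= 3)
  }

  # mild-imbalance regime: 12.5% of drugs below 90% of the maximum
  for (s in 1:5) {
    counts <- imbalance_profile(24, 474, "ccle_like", seed = s)
    expect_equal(max(counts), 474L)
    expect_true(abs(sum(counts < 0.9 * 474) - 3) <= 1)
  }

  expect_error(imbalance_profile(10, 50, "weird"))
})

test_that("generated datasets honor counts, uniqueness and determinism", {
  spec <- synthetic_spec(n_samples = 60, n_drugs = 8,
                         count_profile = c(30, 20, 10, 5, 5, 5, 3, 2),
                         noise_sd = 0.03, seed = 4)
  d <- generate_dataset(spec)
  expect_equal(nrow(d$table), 80)
  expect_equal(unname(d$counts), c(30L, 20L, 10L, 5L, 5L, 5L, 3L, 2L))
  obs <- table(d$table$drug_id)[names(d$counts)]
  expect_equal(as.integer(obs), unname(d$counts))  # count fidelity
  key <- paste(d$table$sample_id, d$table$drug_id)
  expect_false(any(duplicated(key)))               # pair uniqueness
  expect_length(unique(d$moa), spec$n_moa)

  d2 <- generate_dataset(spec)
  expect_identical(d2$table$response, d$table$response)
  spec3 <- spec; spec3$seed <- 5L
  expect_false(identical(generate_dataset(spec3)$table$response,
                         d$table$response))

  expect_error(synthetic_spec(n_samples = 4, n_drugs = 8,
                              count_profile = rep(5, 8)), "exceed")
  expect_error(synthetic_spec(n_samples = 50, n_drugs = 8,
                              max_count = 60), "max_count")
})

test_that("noiseless responses are exactly the stored ground truth", {
  spec <- synthetic_spec(n_samples = 40, n_drugs = 6, max_count = 20,
                         noise_sd = 0, seed = 7)
  d <- generate_dataset(spec)
  expect_equal(d$table$response, d$truth$records$mu, tolerance = 1e-15)
  expect_true(all(d$table$response > 0 & d$table$response < 1))

  cc <- oracle_metrics(d$table, d$truth)
  expect_true(all(abs(cc$ceiling_r2 - 1) < 1e-12))
})

test_that("oracle ceilings track the signal-to-noise variance ratio", {
  # one heavily screened drug so the Monte-Carlo error is small
  spec <- synthetic_spec(n_samples = 400, n_drugs = 2, n_moa = 2,
                         count_profile = c(400, 400), noise_sd = 0.1,
                         seed = 11)
  d <- generate_dataset(spec)
  cc <- oracle_metrics(d$table, d$truth)
  for (dr in cc$drug_id) {
    i <- d$table$drug_id == dr
    v_sig <- stats::var(d$truth$records$mu[i])
    expected <- v_sig / (v_sig + 0.1^2)
    expect_equal(cc$ceiling_r2[cc$drug_id == dr], expected,
                 tolerance = 0.12)
  }

  # rebuilt table with different records is rejected
  foreign <- d$table[seq(2, nrow(d$table)), ]
  foreign <- suppressWarnings(drug_response_table(as.data.frame(foreign)))
  expect_error(oracle_metrics(foreign, d$truth), "match")
})

test_that("very noisy responses drive the oracle ceiling toward zero", {
  spec <- synthetic_spec(n_samples = 300, n_drugs = 2, n_moa = 2,
                         count_profile = c(300, 300), noise_sd = 25,
                         seed = 3)
  d <- suppressWarnings(generate_dataset(spec))
  cc <- oracle_metrics(d$table, d$truth)
  expect_true(all(abs(cc$ceiling_r2) < 0.05))
})

test_that("a model trained drug-blind generalizes to a held-out MOA", {
  # responses depend on drugs only through their features, so predicting
  # an entire unseen mechanism cluster above chance must be possible
  spec <- synthetic_spec(n_samples = 200, n_drugs = 24, max_count = 100,
                         sample_feature_dim = 10, drug_feature_dim = 6,
                         noise_sd = 0.01, n_moa = 6, seed = 21)
  d <- generate_dataset(spec)
  ds <- assemble_dataset(d$table, d$sample_features, d$drug_features)
  held <- names(d$moa)[d$moa == "MOA1"]
  te <- which(ds$drug_id %in% held)
  tr <- setdiff(seq_len(ds$n_pairs), te)
  net <- build_model(model_config(input_dim = ncol(ds$features),
                                  hidden = c(32, 16), dropout = 0,
                                  seed = 1))
  net <- train_model(net, ds, tr,
                     sampler_config("sequential", 64, seed = 1),
                     loss_config("mse"),
                     train_config(epochs = 200, seed = 1))
  yhat <- predict(net, ds$features[te, , drop = FALSE])
  # ~290 held-out pairs: far beyond chance-level correlation
  expect_gt(stats::cor(ds$response[te], yhat), 0.3)
})

test_that("synthetic datasets write to loadable delimited files", {
  spec <- synthetic_spec(n_samples = 25, n_drugs = 4, n_moa = 2,
                         max_count = 10, seed = 2)
  d <- generate_dataset(spec)
  dir <- file.path(tempdir(), "synth_ds")
  write_synthetic_dataset(d, dir)
  # generated noise can push a few AUCs outside [0, 1]; reading warns
  tab <- suppressWarnings(read_response_table(file.path(dir, "response.tsv")))
  expect_equal(tab$response, d$table$response, tolerance = 1e-12)
  sf <- read_feature_matrix(file.path(dir, "sample_features.tsv"))
  expect_equal(sf, d$sample_features, tolerance = 1e-12)
  moa <- read_moa_map(file.path(dir, "moa.tsv"))
  expect_identical(moa, d$moa)
})
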