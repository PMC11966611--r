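test_that("r_squared follows the residual/total sum-of-squares definition", {
  y <- c(0.2, 0.4, 0.9)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(3, 2, 1)), -3)   # 1 - 8/2
  expect_true(is.na(r_squared(c(1, 1), c(0.5, 2))))     # zero variance

  for (s in 1:10) {
    withr::with_seed(s, {
      yy <- rnorm(15); hh <- rnorm(15)
    })
    expect_lte(r_squared(yy, hh), 1)
  }
})

test_that("bulk metrics agree with direct textbook formulas", {
  y <- c(0.1, 0.5, 0.3, 0.9)
  m <- bulk_metrics(y, y)
  expect_equal(unname(m), c(1, 0, 0, 1, 1))

  # monotone nonlinear transform: perfect ranks, imperfect linearity
  y2 <- seq(0.1, 1, length.out = 10)
  m2 <- bulk_metrics(y2, y2^3)
  expect_equal(m2[["spearman"]], 1)
  expect_lt(m2[["pearson"]], 1)

  for (s in 1:8) {
    withr::with_seed(40 + s, {
      yy <- rnorm(20); hh <- yy + rnorm(20)
    })
    expect_equal(bulk_metrics(yy, hh), oracle_metrics_direct(yy, hh),
                 tolerance = 1e-9)
  }

  # constant predictions: correlations undefined, reported as NA
  mc <- bulk_metrics(y, rep(0.5, 4))
  expect_true(is.na(mc[["pearson"]]) && is.na(mc[["spearman"]]))
  expect_false(is.na(mc[["mse"]]))
})

test_that("drug-wise metrics average with equal weight per drug", {
  y <- c(0.1, 0.2, 0.3, 0.4, 0.6, 0.8)
  g <- rep(c("A", "B"), each = 3)

  perfect <- groupwise_metrics(y, y, g)
  expect_equal(perfect$group_averaged[["r2"]], 1)

  # A perfect, B predicted at its own mean: (1 + 0) / 2
  yhat <- c(y[1:3], rep(mean(y[4:6]), 3))
  half <- groupwise_metrics(y, yhat, g)
  expect_equal(half$group_averaged[["r2"]], 0.5)

  # single-record drug excluded with reason
  y3 <- c(y, 0.5); g3 <- c(g, "C")
  ex <- groupwise_metrics(y3, y3, g3)
  expect_equal(ex$excluded$drug_id, "C")
  expect_match(ex$excluded$reason, "record")
  expect_false("C" %in% ex$per_group$drug_id)

  # zero-variance drug excluded
  y4 <- c(0.5, 0.5, 0.1, 0.9); g4 <- c("Z", "Z", "W", "W")
  ex4 <- groupwise_metrics(y4, y4 + 0.01, g4)
  expect_equal(ex4$excluded$drug_id, "Z")
  expect_match(ex4$excluded$reason, "variance")
})

test_that("drug-averaged MSE equals bulk MSE only for equal group sizes", {
  withr::with_seed(3, {
    y <- rnorm(12); yhat <- y + rnorm(12)
  })
  g_eq <- rep(c("A", "B", "C"), each = 4)
  gw <- groupwise_metrics(y, yhat, g_eq)
  expect_equal(gw$group_averaged[["mse"]], mean((y - yhat)^2),
               tolerance = 1e-12)

  g_uneq <- rep(c("A", "B"), c(10, 2))
  gw2 <- groupwise_metrics(y, yhat, g_uneq)
  bulk <- mean((y - yhat)^2)
  pa <- mean((y[1:10] - yhat[1:10])^2)
  pb <- mean((y[11:12] - yhat[11:12])^2)
  expect_equal(gw2$group_averaged[["mse"]], (pa + pb) / 2,
               tolerance = 1e-12)
  if (abs(pa - pb) > 1e-8) {
    expect_false(isTRUE(all.equal(gw2$group_averaged[["mse"]], bulk)))
  }
})

test_that("MOA aggregation averages member drugs and reports strays", {
  pg <- data.frame(drug_id = c("d1", "d2", "d3"), n = c(5, 5, 5),
                   r2 = c(0.2, 0.4, 0.9), mse = c(0.1, 0.3, 0.05),
                   mae = c(0.2, 0.4, 0.1), pearson = c(0.5, 0.6, 0.95),
                   spearman = c(0.5, 0.6, 0.9))
  moa <- c(d1 = "kinase", d2 = "kinase", d3 = "topo")
  agg <- aggregate_by_moa(pg, moa)
  kin <- agg$moa_averaged[agg$moa_averaged$moa == "kinase", ]
  expect_equal(kin$r2, 0.3)
  expect_equal(kin$n_drugs, 2)
  topo <- agg$moa_averaged[agg$moa_averaged$moa == "topo", ]
  expect_equal(topo$r2, 0.9)  # single-drug MOA equals the drug

  agg2 <- aggregate_by_moa(pg, moa[c("d1", "d3")])
  expect_equal(agg2$missing_drugs, "d2")
})

test_that("improvement deltas subtract matched reports and rank", {
  withr::with_seed(5, {
    y <- rnorm(72)
    g <- rep(paste0("d", sprintf("%02d", 1:24)), each = 3)
    ha <- y + rnorm(72, sd = 0.6)
  })
  ra <- metrics_report(y, ha, g)
  expect_true(all(improvement_deltas(ra, ra)$r2 == 0))

  # improve one drug only
  hb <- ha
  hb[g == "d05"] <- y[g == "d05"]
  rb <- metrics_report(y, hb, g)
  d <- improvement_deltas(ra, rb)
  expect_gt(d$r2[d$drug_id == "d05"], 0)
  expect_true(all(d$r2[d$drug_id != "d05"] == 0))

  top <- top_improvements(d, "r2", k = 10)
  expect_equal(nrow(top), 10)
  expect_true(all(diff(top$r2) <= 0))
  expect_equal(top$drug_id[1], "d05")

  rc <- metrics_report(y[1:69], ha[1:69], g[1:69])  # drops drug d24
  expect_error(improvement_deltas(ra, rc), "d24")
})

test_that("reports tidy into long format and aggregate across folds", {
  withr::with_seed(6, {
    y <- rnorm(30); h <- y + rnorm(30, sd = 0.3)
  })
  g <- rep(c("a", "b", "c"), each = 10)
  moa <- c(a = "m1", b = "m1", c = "m2")
  rep1 <- metrics_report(y, h, g, moa = moa)
  t1 <- tidy_metrics(rep1, fold = 1)
  expect_setequal(unique(t1$scope), c("bulk", "drug_averaged", "drug", "moa"))
  expect_equal(sum(t1$scope == "bulk"), 5)

  t2 <- tidy_metrics(metrics_report(y, h + 0.1, g, moa = moa), fold = 2)
  agg <- aggregate_folds(rbind(t1, t2))
  bulk_mse <- agg[agg$scope == "bulk" & agg$metric == "mse", ]
  expect_equal(bulk_mse$n_folds, 2)
  expect_equal(bulk_mse$median,
               median(c(t1$value[t1$scope == "bulk" & t1$metric == "mse"],
                        t2$value[t2$scope == "bulk" & t2$metric == "mse"])))
})
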