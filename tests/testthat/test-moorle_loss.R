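test_that("mse_loss matches the elementwise definition", {
  expect_equal(mse_loss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mse_loss(c(1, 1), c(1, 0)), 0.5)
  withr::with_seed(11, {
    p <- rnorm(10); y <- rnorm(10)
  })
  brute <- sum((p - y)^2) / 10
  expect_equal(mse_loss(p, y), brute, tolerance = 1e-12)
  expect_error(mse_loss(numeric(0), numeric(0)), "empty")
})

test_that("per-drug MSEs are the restriction of MSE to each drug's pairs", {
  expect_equal(per_group_mse(c(1, 2), c(1, 2), c("d", "d")),
               c(d = 0))
  # drug A: squared errors 0 and 1; drug B: squared error 4
  gm <- per_group_mse(c(0, 1, 2), c(0, 0, 0), c("A", "A", "B"))
  expect_equal(gm, c(A = 0.5, B = 4.0))

  b <- make_random_batch(40, 5, seed = 3)
  gm <- per_group_mse(b$pred, b$targ, b$groups)
  for (d in unique(b$groups)) {
    i <- b$groups == d
    expect_equal(gm[[d]], mse_loss(b$pred[i], b$targ[i]),
                 tolerance = 1e-12)
  }
  expect_error(per_group_mse(NULL, c(1), c("a")), "predictions")
})

test_that("softmax normalization is exact, symmetric and shift-safe", {
  u <- normalize_losses(c(a = 0.3, b = 0.3, c = 0.3, d = 0.3))
  expect_equal(unname(u), rep(0.25, 4))

  p <- normalize_losses(c(A = 0, B = 1))
  expect_equal(unname(p), c(0.2689414214, 0.7310585786), tolerance = 1e-9)
  expect_equal(sum(p), 1, tolerance = 1e-12)

  # softmax is invariant to a common shift; huge losses stay finite
  big <- normalize_losses(c(A = 1000, B = 1001))
  expect_true(all(is.finite(big)))
  expect_equal(unname(big), unname(p), tolerance = 1e-12)

  expect_error(normalize_losses(numeric(0)), "empty")
})

test_that("entropy follows the natural-log definition with 0 ln 0 = 0", {
  expect_equal(loss_entropy(rep(0.25, 4)), log(4), tolerance = 1e-12)
  expect_equal(loss_entropy(c(1, 0, 0)), 0)
  expect_equal(loss_entropy(c(0.2689414214, 0.7310585786)),
               0.5822031089, tolerance = 1e-9)
  expect_error(loss_entropy(c(0.5, 0.2)), "sum")
})

test_that("moorle_loss composes the decomposition and honors its identities", {
  # a = 0: total is the unweighted mean of per-drug MSEs
  b <- make_random_batch(30, 4, seed = 5)
  l0 <- moorle_loss(b$pred, b$targ, b$groups, a = 0)
  expect_equal(l0$total, mean(l0$group_mse), tolerance = 1e-12)

  # equal per-drug losses: regularizer vanishes for any weight
  leq <- moorle_loss(c(1, 0, 1, 0), c(0, 1, 0, 1),
                     c("A", "A", "B", "B"), a = 4.5)
  expect_equal(leq$regularizer, 0)
  expect_equal(leq$entropy, log(2), tolerance = 1e-12)

  # two drugs with MSEs {0, 1}, a = 1 (frozen scalar-oracle value)
  l2 <- moorle_loss(c(0, 1), c(0, 0), c("A", "B"), a = 1)
  expect_equal(l2$group_mse, c(A = 0, B = 1))
  expect_equal(l2$total, 0.6109440717, tolerance = 1e-9)

  # single-drug batch: regularizer exactly zero regardless of a
  l1 <- moorle_loss(c(0.3, 0.9), c(0.6, 0.3), rep("onlydrug", 2), a = 5)
  expect_identical(l1$regularizer, 0)
  expect_equal(l1$total, mse_loss(c(0.3, 0.9), c(0.6, 0.3)))

  expect_error(moorle_loss(numeric(0), numeric(0), character(0), 1),
               "empty")
})

test_that("loss decomposition invariants hold on random batches", {
  for (s in 1:25) {
    b <- make_random_batch(5 + (s %% 40), 1 + (s %% 6), seed = 200 + s)
    a <- (s %% 5) * 0.7
    l <- moorle_loss(b$pred, b$targ, b$groups, a = a)
    expect_equal(sum(l$distribution), 1, tolerance = 1e-9)
    expect_gte(l$entropy, 0)
    expect_lte(l$entropy, log(l$n_groups) + 1e-9)
    expect_gte(l$regularizer, 0)
    expect_gte(l$total, mean(l$group_mse) - 1e-9)
    expect_equal(l$total,
                 oracle_moorle_total(b$pred, b$targ, b$groups, a),
                 tolerance = 1e-9)
  }
})

test_that("batch_loss dispatches on the configured loss kind", {
  b <- make_random_batch(20, 3, seed = 9)
  expect_equal(batch_loss(b$pred, b$targ, b$groups, loss_config("mse")),
               mse_loss(b$pred, b$targ))
  expect_equal(
    batch_loss(b$pred, b$targ, b$groups, loss_config("moorle", a = 2)),
    moorle_loss(b$pred, b$targ, b$groups, a = 2)$total)
  expect_error(loss_config("moorle", a = -1))
})

test_that("analytic loss gradients match central differences", {
  for (s in 1:10) {
    b <- make_random_batch(6 + 2 * s, 1 + (s %% 4), seed = 300 + s)
    for (cfg in list(loss_config("mse"),
                     loss_config("moorle", a = 0),
                     loss_config("moorle", a = 3.2))) {
      ga <- batch_loss_gradient(b$pred, b$targ, b$groups, cfg)
      gn <- numerical_gradient(
        function(p) batch_loss(p, b$targ, b$groups, cfg), b$pred)
      denom <- pmax(abs(gn), 1e-3)
      expect_lt(max(abs(ga - gn) / denom), 1e-5)
    }
  }
})

test_that("single-drug gradient equals the plain MSE gradient", {
  p <- c(0.2, 0.8, 0.4); y <- c(0.1, 0.5, 0.9)
  g_moorle <- batch_loss_gradient(p, y, rep("d", 3),
                                  loss_config("moorle", a = 6))
  g_mse <- batch_loss_gradient(p, y, rep("d", 3), loss_config("mse"))
  expect_identical(g_moorle, g_mse)
})

test_that("the base loss is swappable at the aggregation point", {
  mae <- function(p, y) mean(abs(p - y))
  gm <- per_group_mse(c(0, 2, 3), c(0, 0, 0), c("A", "A", "B"),
                      base = mae)
  expect_equal(gm, c(A = 1, B = 3))
})
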