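test_that("attention scores follow the masked LeakyReLU-exp form", {
  net <- small_network(3, 4)
  HN <- net$HN
  n <- nrow(HN)
  mask <- mdlink:::neighborhood_mask(HN)
  # zero attention vector: every unmasked entry is exp(0) = 1
  A0 <- attention_scores(HN, numeric(2 * n), mask)
  expect_equal(unname(A0[mask]), rep(1, sum(mask)))
  expect_true(all(A0[!mask] == 0))
  # identical rows of H give constant attention over the mask
  Hsame <- matrix(1, n, n)
  a <- rnorm(2 * n)
  As <- attention_scores(Hsame, a, mask)
  vals <- As[mask]
  expect_lt(diff(range(vals)), 1e-12)
  expect_error(attention_scores(HN, numeric(3), mask), "length 2")
})

test_that("attention matches a hand evaluation on a 3-node path", {
  # path graph 1-2-3 as HN support, H = I3, a weights only H_i's first entry
  HN <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  mask <- mdlink:::neighborhood_mask(HN)
  H <- diag(3)
  a <- c(1, 0, 0, 0, 0, 0)
  A <- attention_scores(H, a, mask, leaky_slope = 0.2)
  # [H_i || H_j] . a = H[i, 1]; row 1 has value 1, rows 2-3 have 0
  expect_equal(A[1, 1], exp(1))
  expect_equal(A[1, 2], exp(1))
  expect_equal(A[2, 2], exp(0))
  expect_equal(A[3, 3], 1)
  expect_equal(A[1, 3], 0) # not adjacent
})

test_that("transition matrix reproduces the two-node worked example", {
  A <- matrix(1, 1, 1, dimnames = list("d1", "m1"))
  HN <- build_heterogeneous_network(matrix(1, 1, 1), matrix(1, 1, 1), A)
  mask <- mdlink:::neighborhood_mask(HN)
  Aatt <- attention_scores(HN, numeric(4), mask)
  Tm <- transition_matrix(Aatt, A)
  # degrees are 1 for both nodes; uniform attention rows are (1/2, 1/2);
  # (I + D)^(-1/2) scales by 1/sqrt(2) on each side
  expect_equal(unname(Tm), matrix(0.25, 2, 2), ignore_attr = TRUE)
  expect_equal(unname(rowSums(attr(Tm, "row_norm"))), c(1, 1))
})

test_that("row-normalized attention rows sum to one on random networks", {
  for (seed in 1:5) {
    net <- small_network(4, 7, p = 0.35, seed = seed)
    mask <- mdlink:::neighborhood_mask(net$HN)
    a <- rnorm(2 * nrow(net$HN)) * 0.5
    Aatt <- attention_scores(net$HN, a, mask)
    Tm <- transition_matrix(Aatt, net$A)
    expect_equal(unname(rowSums(attr(Tm, "row_norm"))),
                 rep(1, nrow(net$HN)), tolerance = 1e-10)
    expect_true(all(is.finite(Tm)) && all(Tm >= 0))
  }
})

test_that("forward pass, decoder and loss match their definitions", {
  net <- small_network(3, 5)
  n <- nrow(net$HN)
  cfg <- gcan_config(k1 = 4, epochs = 0, seed = 1)
  params <- list(W1 = matrix(0, n, 4), a1 = numeric(2 * n))
  fw <- gcan_forward(net$HN, net$A, params, cfg)
  expect_equal(unname(fw$Z), matrix(0, n, 4)) # W = 0 -> Z = 0
  expect_equal(dim(fw$Zd), c(3L, 4L))
  expect_equal(dim(fw$Zm), c(5L, 4L))

  # 2-node example: Z = relu(T %*% HN %*% W) with W = I
  A <- matrix(1, 1, 1, dimnames = list("d1", "m1"))
  HN <- build_heterogeneous_network(matrix(1, 1, 1), matrix(1, 1, 1), A)
  p2 <- list(W1 = diag(2), a1 = numeric(4))
  fw2 <- gcan_forward(HN, A, p2, gcan_config(k1 = 2))
  expect_equal(unname(fw2$Z), matrix(0.5, 2, 2)) # T all 0.25, HN all 1

  # decoder: sigmoid inner products, symmetric, in (0, 1)
  Z <- matrix(c(1, -1), 2, 1)
  ZZ <- gcan_decode(Z)
  expect_equal(ZZ, rbind(c(plogis(1), plogis(-1)), c(plogis(-1), plogis(1))))
  Zr <- matrix(rnorm(12), 4, 3)
  expect_equal(gcan_decode(Zr), t(gcan_decode(Zr)), tolerance = 1e-12)
  expect_true(all(gcan_decode(Zr) > 0 & gcan_decode(Zr) < 1))

  # loss: mean over rows of squared row distances
  expect_equal(gcan_loss(matrix(0.5, 1, 1), matrix(1, 1, 1)), 0.25)
  ZZ2 <- matrix(c(0.1, 0, 0.2, 0.2), 2, 2)
  HN2 <- matrix(0, 2, 2)
  expect_equal(gcan_loss(ZZ2, HN2), (0.1^2 + 0.2^2 + 0.2^2) / 2)
  expect_equal(gcan_loss(HN2, HN2), 0)
  expect_error(gcan_loss(matrix(0, 1, 1), HN2), "shape")
})

test_that("analytic gradients match finite differences", {
  net <- small_network(3, 4, p = 0.4, seed = 6)
  n <- nrow(net$HN)
  cfg <- gcan_config(k1 = 3, n_layers = 2, epochs = 0, seed = 5)
  params <- mdlink:::with_seed(5, mdlink:::gcan_init(n, cfg))
  set.seed(8)
  params$a1 <- rnorm(2 * n) * 0.3
  params$a2 <- rnorm(2 * cfg$k1) * 0.3
  lossfun <- function(p) {
    fw <- gcan_forward(net$HN, net$A, p, cfg)
    gcan_loss(gcan_decode(fw$Z), net$HN)
  }
  fw <- gcan_forward(net$HN, net$A, params, cfg, keep_cache = TRUE)
  gr <- mdlink:::gcan_backward(net$HN, fw, cfg)
  num <- numerical_gradient(lossfun, params)
  for (nm in names(params)) {
    denom <- max(1e-6, max(abs(num[[nm]])))
    expect_lt(max(abs(num[[nm]] - gr[[nm]])) / denom, 1e-4)
  }
})

test_that("training is seeded, deterministic, and reduces the loss", {
  net <- small_network(5, 8, p = 0.3, seed = 3)
  cfg <- gcan_config(k1 = 6, epochs = 30, seed = 42)
  fit1 <- train_gcan(net$HN, net$A, cfg)
  fit2 <- train_gcan(net$HN, net$A, cfg)
  expect_identical(fit1$Zd, fit2$Zd)
  expect_identical(fit1$Zm, fit2$Zm)
  expect_lt(fit1$loss_trace[31], fit1$loss_trace[1])
  expect_equal(length(fit1$loss_trace), 31L)

  # epochs = 0 returns the initialized forward pass
  fit0 <- train_gcan(net$HN, net$A, gcan_config(k1 = 6, epochs = 0,
                                                seed = 42))
  expect_equal(length(fit0$loss_trace), 1L)
  expect_equal(fit0$loss_trace[1], fit1$loss_trace[1])
})
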