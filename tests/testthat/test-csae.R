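test_that("attribute matrices concatenate blocks in the printed order", {
  A <- random_binary_A(2, 3, 0.5, seed = 1)
  D <- diag(2) * 0.5
  CS <- matrix(0.25, 2, 2)
  FS <- diag(2)
  AD <- assemble_attribute_matrix(A, D, CS, FS, "disease")
  expect_equal(dim(AD), c(2L, 3L + 3L * 2L))
  # block round-trip: the cosine block comes back exactly
  lay <- attr(AD, "block_layout")
  start <- 3L + 2L
  expect_equal(unname(AD[, (start + 1):(start + 2)]), unname(CS))
  expect_equal(unname(lay), c(3L, 2L, 2L, 2L))

  AM <- assemble_attribute_matrix(A, diag(3), matrix(0, 3, 3), diag(3),
                                  "microbe")
  expect_equal(dim(AM), c(3L, 2L + 3L * 3L))
  expect_error(assemble_attribute_matrix(A, diag(3), CS, FS, "disease"),
               "diffusion")
})

test_that("attribute matrix shape matches curated-database dimensions", {
  # 39 diseases x 292 microbes: microbe attribute matrix is 292 x 915
  A <- random_binary_A(39, 292, 0.04, seed = 2)
  n <- 292
  AM <- assemble_attribute_matrix(A, diag(n), diag(n), diag(n), "microbe")
  expect_equal(dim(AM), c(292L, 39L + 3L * 292L))
})

test_that("convolutional encoder matches hand values and an oracle", {
  # all-ones 3x3 input and kernel: center 9, corners 4, edges 6
  K1 <- array(1, c(3, 3, 1))
  out <- conv_encode(matrix(1, 3, 3), K1, 0)
  expect_equal(out[, , 1], rbind(c(4, 6, 4), c(6, 9, 6), c(4, 6, 4)))
  # zero kernels and bias: all zero
  expect_equal(conv_encode(matrix(rnorm(12), 3, 4), array(0, c(3, 3, 2)),
                           c(0, 0)),
               array(0, c(3, 4, 2)))
  # identity kernel passes a non-negative input through
  Kid <- array(0, c(3, 3, 1))
  Kid[2, 2, 1] <- 1
  X <- matrix(abs(rnorm(20)), 4, 5)
  expect_equal(conv_encode(X, Kid, 0)[, , 1], X)
  # random 5x7 inputs against the nested-loop oracle, all channels
  set.seed(4)
  for (rep in 1:5) {
    X <- matrix(rnorm(35), 5, 7)
    K <- array(rnorm(27), c(3, 3, 3))
    b <- rnorm(3)
    enc <- conv_encode(X, K, b)
    for (c in 1:3) {
      expect_equal(enc[, , c], pmax(oracle_conv2d(X, K[, , c]) + b[c], 0),
                   tolerance = 1e-12)
    }
  }
})

test_that("flatten and partition are exact inverses", {
  set.seed(2)
  fX <- array(rnorm(2 * 2 * 2), c(2, 2, 2))
  ft <- flatten_channels(fX)
  expect_equal(dim(ft), c(2L, 4L))
  # channel blocks are laid out side by side
  expect_equal(ft[, 1:2], fX[, , 1])
  expect_equal(ft[, 3:4], fX[, , 2])
  expect_identical(partition_channels(ft, 2), fX)
  fX2 <- array(rnorm(3 * 5 * 4), c(3, 5, 4))
  expect_identical(partition_channels(flatten_channels(fX2), 4), fX2)
  expect_error(partition_channels(matrix(0, 2, 5), 2), "divisible")
})

test_that("linear encode/decode are sigmoid affine maps", {
  ft <- matrix(rnorm(12), 3, 4)
  expect_equal(linear_encode(ft, matrix(0, 4, 2), c(0, 0)),
               matrix(0.5, 3, 2))
  # pre-activation 1 -> 0.73106, -1 -> 0.26894
  W <- matrix(c(1, 0, 0, 0), 4, 1)
  one_row <- matrix(c(1, 0, 0, 0), 1, 4)
  expect_equal(linear_encode(one_row, W, 0)[1, 1], 1 / (1 + exp(-1)),
               tolerance = 1e-5)
  h <- matrix(rnorm(6), 3, 2)
  expect_equal(dim(linear_decode(h, matrix(0, 2, 8), numeric(8))),
               c(3L, 8L))
  expect_equal(linear_decode(matrix(0, 1, 2), matrix(0, 2, 3), rep(-1, 3)),
               matrix(1 / (1 + exp(1)), 1, 3))
})

test_that("transposed-convolution decoder matches direct summation", {
  # single channel, 1x3 input, all-ones kernel: scatter reaches cols 1-2
  k1 <- array(1, c(3, 3, 1))
  expect_equal(conv_decode(matrix(c(1, 0, 0), 1, 3), k1, 0),
               matrix(c(1, 1, 0), 1, 3))
  # center-one kernel with one channel reproduces a non-negative input
  kid <- array(0, c(3, 3, 1))
  kid[2, 2, 1] <- 1
  y <- matrix(abs(rnorm(15)), 3, 5)
  expect_equal(conv_decode(y, kid, 0), y)
  # zero input and bias: zero output
  expect_equal(conv_decode(matrix(0, 2, 6), array(rnorm(18), c(3, 3, 2)), 0),
               matrix(0, 2, 3))
  # direct-summation oracle: scatter each input cell times the kernel
  set.seed(5)
  y2 <- matrix(rnorm(24), 4, 6)
  K <- array(rnorm(18), c(3, 3, 2))
  out <- conv_decode(y2, K, 0.1)
  scatter <- matrix(0.1, 4, 3)
  for (c in 1:2) {
    yc <- y2[, (c - 1) * 3 + 1:3]
    for (i in 1:4) {
      for (j in 1:3) {
        for (p in 1:3) {
          for (q in 1:3) {
            ii <- i + p - 2
            jj <- j + q - 2
            if (ii >= 1 && ii <= 4 && jj >= 1 && jj <= 3) {
              scatter[ii, jj] <- scatter[ii, jj] + yc[i, j] * K[p, q, c]
            }
          }
        }
      }
    }
  }
  expect_equal(out, pmax(scatter, 0), tolerance = 1e-12)
})

test_that("KL sparsity penalty matches scalar evaluations", {
  # all units at the target: zero penalty
  h <- matrix(0.05, 10, 4)
  expect_equal(sparsity_penalty(h, 0.05), 0)
  # one unit at 0.5 under target 0.05
  expect_equal(sparsity_penalty(matrix(0.5, 6, 1), 0.05),
               0.05 * log(0.05 / 0.5) + 0.95 * log(0.95 / 0.5),
               tolerance = 1e-12)
  expect_equal(sparsity_penalty(matrix(0.5, 6, 1), 0.05), 0.49462,
               tolerance = 1e-4)
  # non-negative on random activations
  set.seed(6)
  hr <- matrix(runif(40, 0.01, 0.99), 10, 4)
  expect_gte(sparsity_penalty(hr, 0.05), 0)
  # degenerate mean activations are clamped with a warning
  expect_warning(p <- sparsity_penalty(matrix(1, 5, 1), 0.05), "clamped")
  expect_true(is.finite(p))
})

test_that("sparse loss combines row-mean MSE and weighted penalty", {
  X <- matrix(c(0, 0), 1, 2)
  recon <- matrix(c(0.1, 0.2), 1, 2)
  h <- matrix(0.05, 1, 3)
  expect_equal(csae_loss(recon, X, h, beta = 0), 0.05)
  expect_equal(csae_loss(X, X, h, beta = 0.1), 0)
  h2 <- matrix(0.5, 1, 1)
  expect_equal(csae_loss(recon, X, h2, beta = 0.1, rho = 0.05),
               0.05 + 0.1 * sparsity_penalty(h2, 0.05))
  expect_error(csae_loss(matrix(0, 2, 2), X, h), "shapes differ")
})

test_that("encoder-decoder shape algebra round-trips arbitrary sizes", {
  for (cfgdims in list(c(3, 4, 2, 2), c(5, 7, 3, 4), c(1, 6, 1, 2))) {
    Nr <- cfgdims[1]
    Nc <- cfgdims[2]
    l <- cfgdims[3]
    k2 <- cfgdims[4]
    cfg <- csae_config(k2 = k2, channels = l, epochs = 0, seed = 3)
    params <- mdlink:::with_seed(3, mdlink:::csae_init(Nr, Nc, cfg))
    X <- matrix(abs(rnorm(Nr * Nc)), Nr, Nc)
    fX <- conv_encode(X, params$K_enc, params$b_enc)
    expect_equal(dim(fX), c(Nr, Nc, l))
    ft <- flatten_channels(fX)
    h <- linear_encode(ft, params$W_enc, params$B_enc)
    expect_equal(dim(h), c(Nr, k2))
    y <- linear_decode(h, params$W_dec, params$B_dec)
    expect_equal(dim(y), c(Nr, Nc * l))
    recon <- conv_decode(y, params$K_dec, params$b_dec)
    expect_equal(dim(recon), dim(X))
    # the internal fused forward agrees with the composed operations
    fw <- mdlink:::csae_forward(X, params, cfg)
    expect_equal(fw$h, h, tolerance = 1e-12)
    expect_equal(fw$recon, recon, tolerance = 1e-12)
  }
})

test_that("analytic gradients match finite differences", {
  set.seed(7)
  X <- matrix(runif(20), 4, 5)
  cfg <- csae_config(k2 = 3, channels = 2, epochs = 0, seed = 11)
  params <- mdlink:::with_seed(11, mdlink:::csae_init(4, 5, cfg))
  params$b_dec <- 0.3 # keep the output layer in its active region
  lossfun <- function(p) {
    fw <- mdlink:::csae_forward(X, p, cfg)
    csae_loss(fw$recon, X, fw$h, cfg$beta, cfg$rho, warn = FALSE)
  }
  fw <- mdlink:::csae_forward(X, params, cfg)
  gr <- mdlink:::csae_backward(X, params, fw, cfg)
  num <- numerical_gradient(lossfun, params)
  for (nm in names(params)) {
    denom <- max(1e-6, max(abs(num[[nm]])))
    expect_lt(max(abs(num[[nm]] - gr[[nm]])) / denom, 1e-4)
  }
})

test_that("training is seeded, deterministic, and shaped correctly", {
  A <- random_binary_A(6, 9, 0.3, seed = 4)
  AD <- assemble_attribute_matrix(A, diag(6), cosine_similarity(A, "disease"),
                                  diag(6), "disease")
  cfg <- csae_config(k2 = 4, channels = 2, epochs = 20, seed = 9)
  fit1 <- train_csae(AD, cfg)
  fit2 <- train_csae(AD, cfg)
  expect_identical(fit1$embedding, fit2$embedding)
  expect_equal(dim(fit1$embedding), c(6L, 4L))
  expect_true(all(fit1$embedding > 0 & fit1$embedding < 1))
  expect_lt(tail(fit1$loss_trace, 1), fit1$loss_trace[1])
  fit0 <- train_csae(AD, csae_config(k2 = 4, channels = 2, epochs = 0,
                                     seed = 9))
  expect_equal(fit0$loss_trace, fit1$loss_trace[1])
})
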