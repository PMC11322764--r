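test_that("GIP kernel matches hand-evaluated values", {
  A <- matrix(c(1, 0, 0, 1), 2, 2,
              dimnames = list(c("d1", "d2"), c("m1", "m2")))
  GM <- gip_similarity(A, "microbe")
  # gamma_m = 2 / (1 + 1) = 1; ||col1 - col2||^2 = 2
  expect_equal(GM[1, 2], exp(-2))
  expect_equal(diag(GM), c(m1 = 1, m2 = 1))

  allones <- matrix(1, 2, 2)
  expect_equal(unname(gip_similarity(allones, "microbe")),
               matrix(1, 2, 2))
  expect_error(gip_similarity(matrix(0, 2, 2), "disease"), "bandwidth")
})

test_that("Hamming similarity uses the true profile length", {
  A <- matrix(c(1, 0, 0, 1), 2, 2)
  HM <- hamming_similarity(A, "microbe")
  expect_equal(HM[1, 2], 0) # columns (1,0) vs (0,1), L = 2
  A2 <- matrix(c(1, 0, 1, 1), 2, 2)
  expect_equal(hamming_similarity(A2, "microbe")[1, 2], 0.5)
  # profile length differs per axis: 3 diseases x 5 microbes
  A3 <- random_binary_A(3, 5, 0.5, seed = 3)
  hd <- hamming_similarity(A3, "disease")
  expect_equal(hd[1, 2], 1 - sum(abs(A3[1, ] - A3[2, ])) / 5)
  hm <- hamming_similarity(A3, "microbe")
  expect_equal(hm[1, 2], 1 - sum(abs(A3[, 1] - A3[, 2])) / 3)
  expect_error(hamming_similarity(A3 * 0.5, "disease"), "binary")
})

test_that("integrated similarity is the elementwise mean", {
  A <- matrix(c(1, 0, 0, 1), 2, 2)
  GM <- gip_similarity(A, "microbe")
  HM <- hamming_similarity(A, "microbe")
  SM <- integrate_similarity(GM, HM)
  expect_equal(SM[1, 2], exp(-2) / 2)
  expect_equal(SM, (GM + HM) / 2)
  expect_error(integrate_similarity(GM, HM[1, 1, drop = FALSE]),
               "mismatched shapes")
})

test_that("cosine similarity matches hand values and conventions", {
  X <- matrix(c(1, 0, 1, 1, 0, 0), 2, 3, byrow = TRUE)
  # rows (1,0,1) wait -- use explicit rows
  A <- rbind(c(1, 1, 0), c(1, 0, 0))
  expect_equal(cosine_similarity(A, "disease")[1, 2], 1 / sqrt(2))
  B <- rbind(c(1, 0), c(0, 1))
  expect_equal(cosine_similarity(B, "disease")[1, 2], 0)
  # zero profile: 0 off-diagonal, 1 on the diagonal
  Z <- rbind(c(1, 1), c(0, 0))
  CZ <- cosine_similarity(Z, "disease")
  expect_equal(CZ[1, 2], 0)
  expect_equal(diag(CZ), c(1, 1))
})

test_that("similarity kernels satisfy their invariants on random fixtures", {
  for (seed in 1:10) {
    A <- random_binary_A(6, 8, 0.4, seed)
    if (sum(A) == 0) next
    for (role in c("disease", "microbe")) {
      for (f in list(gip_similarity, hamming_similarity, cosine_similarity)) {
        S <- f(A, role)
        expect_equal(S, t(S), tolerance = 1e-10)
        expect_true(all(S >= 0 & S <= 1))
        expect_equal(unname(diag(S)), rep(1, nrow(S)))
      }
    }
    # duplicated (non-empty) columns get similarity exactly 1 under every
    # kernel; an all-zero profile would fall under the cosine convention
    dup <- which(colSums(A) > 0)[1]
    A2 <- cbind(A, A[, dup])
    colnames(A2) <- paste0("m", seq_len(ncol(A2)))
    for (f in list(gip_similarity, hamming_similarity, cosine_similarity)) {
      S <- f(A2, "microbe")
      expect_equal(S[dup, ncol(A2)], 1)
    }
  }
})

test_that("RWR diffusion matches the closed-form solve", {
  S <- matrix(c(0, 1, 1, 0), 2, 2)
  out <- rwr_diffusion(S, phi = 0.1)
  expect_equal(out, oracle_rwr(S, 0.1), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(out[1, ], c(0.9 / 0.99, 0.09 / 0.99), tolerance = 1e-6,
               ignore_attr = TRUE)
  # phi = 0: restart only, identity
  expect_equal(unname(rwr_diffusion(S, phi = 0)), diag(2),
               ignore_attr = TRUE)
  # rows are probability vectors; zero-column handling
  set.seed(4)
  S2 <- matrix(runif(25), 5, 5)
  S2[, 3] <- 0
  out2 <- rwr_diffusion(S2, phi = 0.1)
  expect_equal(unname(rowSums(out2)), rep(1, 5), tolerance = 1e-8)
  expect_equal(out2, oracle_rwr(S2, 0.1), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("RWR warns instead of failing when the iteration cap is hit", {
  S <- matrix(runif(16, 0.5, 1), 4, 4)
  expect_warning(out <- rwr_diffusion(S, phi = 0.9, max_iter = 2L),
                 "did not converge")
  expect_false(attr(out, "converged"))
})

test_that("functional similarity fallback, reordering and symmetrization", {
  labs <- c("a", "b", "c")
  expect_equal(load_functional_similarity(NULL, labs),
               diag(3), ignore_attr = TRUE)

  m <- matrix(c(1, 0.2, 0.9, 0.4, 1, 0.1, 0.9, 0.1, 1), 3, 3,
              dimnames = list(c("b", "a", "c"), c("b", "a", "c")))
  out <- load_functional_similarity(m, labs)
  expect_equal(rownames(out), labs)
  # asymmetric entries are averaged: (0.2 + 0.4) / 2
  expect_equal(out["a", "b"], 0.3)
  expect_equal(out, t(out))

  expect_error(load_functional_similarity(m, c("a", "b", "zz")),
               "missing labels: zz")
})

test_that("heterogeneous network has the block layout and splits back", {
  A <- matrix(1, 1, 1, dimnames = list("d1", "m1"))
  HN <- build_heterogeneous_network(matrix(1, 1, 1), matrix(1, 1, 1), A)
  expect_equal(unname(HN), matrix(1, 2, 2), ignore_attr = TRUE)

  net <- small_network(4, 6)
  HN <- net$HN
  expect_equal(dim(HN), c(10, 10))
  expect_equal(HN, t(HN), tolerance = 1e-10)
  parts <- split_heterogeneous_network(HN)
  expect_equal(unname(parts$SD), unname(net$SD))
  expect_equal(unname(parts$SM), unname(net$SM))
  expect_equal(unname(parts$A), unname(net$A))
  expect_error(build_heterogeneous_network(net$SD, net$SD, net$A), "SM must")
})
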