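#' Configuration for the attention graph convolutional encoder
#'
#' Defaults are the selected model settings: a single propagation layer,
#' 128-column topological embeddings, Adam learning rate 0.01, LeakyReLU
#' attention slope 0.2, 200 training epochs.
#'
#' @param k1 embedding width (columns of the topological embedding).
#' @param n_layers number of propagation layers.
#' @param lr Adam learning rate (lr1).
#' @param epochs number of training epochs.
#' @param leaky_slope negative slope of the LeakyReLU inside the attention
#'   scores.
#' @param seed RNG seed for parameter initialization.
#' @return a list of class `gcan_config`.
#' @export
gcan_config <- function(k1 = 128L, n_layers = 1L, lr = 0.01, epochs = 200L,
                        leaky_slope = 0.2, seed = 1L) {
  stopifnot(k1 >= 1, n_layers >= 1, lr > 0, epochs >= 0, leaky_slope >= 0)
  structure(list(k1 = as.integer(k1), n_layers = as.integer(n_layers),
                 lr = lr, epochs = as.integer(epochs),
                 leaky_slope = leaky_slope, seed = as.integer(seed)),
            class = "gcan_config")
}

# Neighborhood mask: an edge wherever HN has positive weight, plus self-loops.
neighborhood_mask <- function(HN) {
  mask <- HN > 0
  diag(mask) <- TRUE
  mask
}

#' Masked attention scores between node representations
#'
#' For each ordered node pair (i, j) with j in the neighborhood of i (or
#' j = i), the unnormalized attention is
#' `exp(LeakyReLU(c(H[i, ], H[j, ]) %*% a))`; entries outside the mask are 0.
#' With the attention vector split as `a = c(a1, a2)` this is
#' `exp(LeakyReLU(H %*% a1 [i] + H %*% a2 [j]))`, which is how it is
#' evaluated.
#'
#' @param H node representation matrix (n x p).
#' @param a attention vector of length `2 * p`.
#' @param mask n x n logical neighborhood mask (self-loops included).
#' @param leaky_slope LeakyReLU negative slope.
#' @return n x n matrix, strictly positive on the mask and 0 elsewhere.
#' @export
attention_scores <- function(H, a, mask, leaky_slope = 0.2) {
  n <- nrow(H)
  p <- ncol(H)
  if (length(a) != 2 * p) {
    stop_mdlink("attention vector must have length 2 * ncol(H) = ", 2 * p,
                ", got ", length(a))
  }
  if (!identical(dim(mask), c(n, n))) {
    stop_mdlink("mask must be ", n, "x", n)
  }
  u <- as.vector(H %*% a[seq_len(p)])
  v <- as.vector(H %*% a[p + seq_len(p)])
  E <- matrix(u, n, n) + matrix(v, n, n, byrow = TRUE)
  Aatt <- exp(leaky_relu(E, leaky_slope))
  Aatt[!mask] <- 0
  Aatt
}

#' Attention-normalized transition matrix with self-loop degree correction
#'
#' Builds the propagation operator
#' `T = (I + D)^(-1/2) %*% P %*% (I + D)^(-1/2)` where `P` is the
#' row-normalized attention matrix (each row of the masked attention divided
#' by its sum, so rows of `P` sum to 1 on their support) and `D` is the
#' diagonal bipartite degree matrix: known-association row sums for disease
#' nodes and column sums for microbe nodes. The `I + D` term plays the role
#' of a renormalization self-loop, keeping isolated nodes well-defined.
#'
#' @param A_att masked attention matrix from [attention_scores()].
#' @param A the Nd x Nm binary association matrix supplying the bipartite
#'   degrees (disease nodes first, then microbe nodes).
#' @return (Nd+Nm) square transition matrix with attribute `row_norm`, the
#'   row-normalized attention matrix `P`.
#' @export
transition_matrix <- function(A_att, A) {
  n <- nrow(A_att)
  if (nrow(A) + ncol(A) != n) {
    stop_mdlink("node count mismatch: attention is ", n, "x", n,
                " but A is ", nrow(A), "x", ncol(A))
  }
  r <- rowSums(A_att)
  if (any(r <= 0)) {
    stop_mdlink("attention matrix has an empty row; the mask must include",
                " self-loops")
  }
  P <- A_att / r
  d <- c(rowSums(A), colSums(A))
  dh <- 1 / sqrt(1 + d)
  Tm <- P * outer(dh, dh)
  attr(Tm, "row_norm") <- P
  Tm
}

# initialize GCAN parameters: Xavier-uniform weights, zero attention vectors
# (training starts from uniform attention over each neighborhood)
gcan_init <- function(n, config) {
  params <- list()
  p_in <- n
  for (l in seq_len(config$n_layers)) {
    params[[paste0("W", l)]] <- xavier_matrix(p_in, config$k1)
    params[[paste0("a", l)]] <- numeric(2 * p_in)
    p_in <- config$k1
  }
  params
}

#' Forward pass of the attention graph convolutional encoder
#'
#' Applies `H <- ReLU(T(H) %*% H %*% W)` per layer, with the transition
#' matrix recomputed from the current layer input via [attention_scores()]
#' and [transition_matrix()]. The neighborhood mask is fixed from the support
#' of `HN`. The final activations form the topological embedding `Z`, split
#' into disease rows `Zd` and microbe rows `Zm`.
#'
#' @param HN heterogeneous network matrix (layer-0 input).
#' @param A binary association matrix (bipartite degrees for the transition
#'   matrix).
#' @param params parameter list with per-layer `W<l>` matrices and `a<l>`
#'   attention vectors (see [train_gcan()]).
#' @param config a [gcan_config()].
#' @param keep_cache internal: retain per-layer intermediates for
#'   backpropagation.
#' @return list with `Z`, `Zd`, `Zm` and (if requested) `cache`.
#' @export
gcan_forward <- function(HN, A, params, config = gcan_config(),
                         keep_cache = FALSE) {
  n <- nrow(HN)
  nd <- nrow(A)
  mask <- neighborhood_mask(HN)
  H <- HN
  cache <- if (keep_cache) vector("list", config$n_layers) else NULL
  for (l in seq_len(config$n_layers)) {
    W <- params[[paste0("W", l)]]
    a <- params[[paste0("a", l)]]
    p <- ncol(H)
    u <- as.vector(H %*% a[seq_len(p)])
    v <- as.vector(H %*% a[p + seq_len(p)])
    E0 <- matrix(u, n, n) + matrix(v, n, n, byrow = TRUE)
    Aatt <- exp(leaky_relu(E0, config$leaky_slope))
    Aatt[!mask] <- 0
    r <- rowSums(Aatt)
    P <- Aatt / r
    d <- c(rowSums(A), colSums(A))
    dh <- 1 / sqrt(1 + d)
    odh <- outer(dh, dh)
    Tm <- P * odh
    B <- H %*% W
    S <- Tm %*% B
    Hn <- relu(S)
    if (keep_cache) {
      cache[[l]] <- list(H = H, E0 = E0, Aatt = Aatt, r = r, P = P,
                         odh = odh, Tm = Tm, B = B, S = S, W = W, a = a)
    }
    H <- Hn
  }
  if (any(!is.finite(H))) {
    stop_mdlink("non-finite activations in the graph encoder forward pass")
  }
  list(Z = H, Zd = H[seq_len(nd), , drop = FALSE],
       Zm = H[nd + seq_len(n - nd), , drop = FALSE],
       mask = mask, cache = cache)
}

#' Inner-product decoder of the topological embedding
#'
#' `ZZ = sigmoid(Z %*% t(Z))`: a symmetric matrix in (0, 1) whose entries
#' estimate the reconstructed heterogeneous network.
#'
#' @param Z embedding matrix.
#' @return symmetric matrix in (0, 1).
#' @export
gcan_decode <- function(Z) {
  sigmoid(tcrossprod(Z))
}

#' Reconstruction loss of the topological encoder
#'
#' Mean over nodes of the squared Euclidean distance between rows of the
#' decoded network and rows of `HN`:
#' `L = sum((ZZ - HN)^2) / (Nd + Nm)`.
#'
#' @param ZZ decoded network from [gcan_decode()].
#' @param HN target heterogeneous network.
#' @return non-negative scalar, zero iff `ZZ == HN`.
#' @export
gcan_loss <- function(ZZ, HN) {
  if (!identical(dim(ZZ), dim(HN))) {
    stop_mdlink("shape mismatch between decoded network and HN")
  }
  sum((ZZ - HN)^2) / nrow(HN)
}

# Analytic gradients of gcan_loss wrt all parameters, given a cached forward
# pass. Returns a list shaped like `params`.
gcan_backward <- function(HN, fw, config) {
  n <- nrow(HN)
  Z <- fw$Z
  ZZ <- sigmoid(tcrossprod(Z))
  G <- (2 / n) * (ZZ - HN) * ZZ * (1 - ZZ)
  dH <- (G + t(G)) %*% Z
  grads <- list()
  slope <- config$leaky_slope
  for (l in rev(seq_len(config$n_layers))) {
    cc <- fw$cache[[l]]
    dS <- dH * (cc$S > 0)
    dB <- crossprod(cc$Tm, dS)
    grads[[paste0("W", l)]] <- crossprod(cc$H, dB)
    dT <- tcrossprod(dS, cc$B)
    dP <- dT * cc$odh
    s <- rowSums(dP * cc$P)
    dA <- (dP - s) / cc$r # row-wise recycling of s and r
    dE <- dA * cc$Aatt # zero off-mask since Aatt is masked
    dE0 <- dE * leaky_relu_grad(cc$E0, slope)
    du <- rowSums(dE0)
    dv <- colSums(dE0)
    grads[[paste0("a", l)]] <- c(as.vector(crossprod(cc$H, du)),
                                 as.vector(crossprod(cc$H, dv)))
    p <- ncol(cc$H)
    a1 <- cc$a[seq_len(p)]
    a2 <- cc$a[p + seq_len(p)]
    dH <- tcrossprod(dB, cc$W) # dB %*% t(W)
    dH <- dH + outer(du, a1) + outer(dv, a2)
  }
  grads
}

#' Train the topological encoder
#'
#' Minimizes the network reconstruction loss ([gcan_loss()]) over the
#' attention vectors and layer weights with Adam. Weights are initialized
#' Xavier-uniform and attention vectors at zero (uniform attention over each
#' neighborhood), both under the configured seed, so training is
#' deterministic given the seed. With `epochs = 0` the embeddings of the
#' freshly initialized model are returned.
#'
#' @param HN heterogeneous network matrix.
#' @param A binary association matrix (bipartite degrees).
#' @param config a [gcan_config()].
#' @return object of class `gcan_fit`: list with `Zd`, `Zm`, `Z`,
#'   `loss_trace` (length `epochs + 1`; entry 1 is the loss of the
#'   initialized model), `params` and `config`.
#' @export
train_gcan <- function(HN, A, config = gcan_config()) {
  n <- nrow(HN)
  params <- with_seed(config$seed, gcan_init(n, config))
  state <- adam_init(params)
  trace <- numeric(config$epochs + 1L)
  fw <- gcan_forward(HN, A, params, config, keep_cache = TRUE)
  trace[1L] <- gcan_loss(gcan_decode(fw$Z), HN)
  if (config$epochs > 0L) {
    for (ep in seq_len(config$epochs)) {
      grads <- gcan_backward(HN, fw, config)
      upd <- adam_step(params, grads, state, config$lr)
      params <- upd$params
      state <- upd$state
      fw <- gcan_forward(HN, A, params, config, keep_cache = TRUE)
      loss <- gcan_loss(gcan_decode(fw$Z), HN)
      if (!is.finite(loss)) {
        stop_mdlink("graph encoder training diverged at epoch ", ep,
                    " (loss is not finite); try a lower learning rate lr1")
      }
      trace[ep + 1L] <- loss
    }
  }
  structure(
    list(Zd = fw$Zd, Zm = fw$Zm, Z = fw$Z, loss_trace = trace,
         params = params, config = config),
    class = "gcan_fit"
  )
}

#' @export
print.gcan_fit <- function(x, ...) {
  cat("gcan_fit:", nrow(x$Zd), "disease +", nrow(x$Zm),
      "microbe embeddings of width", ncol(x$Z), "\n")
  cat("  loss:", signif(x$loss_trace[1], 5), "->",
      signif(x$loss_trace[length(x$loss_trace)], 5), "over",
      length(x$loss_trace) - 1L, "epochs\n")
  invisible(x)
}
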