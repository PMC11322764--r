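#' Configuration for the convolutional sparse autoencoder
#'
#' Defaults are the selected model settings: 32-column attribute embeddings,
#' 6 convolution channels with fixed 3x3 kernels, Adam learning rate 0.1,
#' sparsity weight beta = 0.1 with target mean activation rho = 0.05, and
#' 200 training epochs.
#'
#' @param k2 hidden (embedding) width.
#' @param channels number of convolution channels l.
#' @param kernel spatial kernel size (odd; 3 by default).
#' @param lr Adam learning rate (lr2).
#' @param beta weight of the KL sparsity penalty.
#' @param rho sparsity target: desired mean activation of each hidden unit.
#' @param epochs number of training epochs.
#' @param seed RNG seed for parameter initialization.
#' @return a list of class `csae_config`.
#' @export
csae_config <- function(k2 = 32L, channels = 6L, kernel = 3L, lr = 0.1,
                        beta = 0.1, rho = 0.05, epochs = 200L, seed = 1L) {
  stopifnot(k2 >= 1, channels >= 1, kernel >= 1, kernel %% 2 == 1,
            lr > 0, beta >= 0, rho > 0, rho < 1, epochs >= 0)
  structure(list(k2 = as.integer(k2), channels = as.integer(channels),
                 kernel = as.integer(kernel), lr = lr, beta = beta,
                 rho = rho, epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "csae_config")
}

#' Assemble a per-node attribute matrix
#'
#' Column-concatenates, in fixed block order, the adjacency profile with the
#' diffusion, cosine and functional similarity matrices of one node type:
#' `[A | SDMM | SDCOS | SDFS]` for diseases (Nd x (Nm + 3 Nd)) and
#' `[t(A) | SMDD | SMCOS | SMFS]` for microbes (Nm x (Nd + 3 Nm)).
#'
#' @param A Nd x Nm binary association matrix.
#' @param diffusion RWR diffusion matrix of the node type.
#' @param cosine cosine similarity matrix of the node type.
#' @param functional functional similarity matrix of the node type.
#' @param role `"disease"` or `"microbe"`.
#' @return attribute matrix with a `block_layout` attribute (named widths).
#' @export
assemble_attribute_matrix <- function(A, diffusion, cosine, functional,
                                      role = c("disease", "microbe")) {
  role <- match.arg(role)
  base <- if (role == "disease") A else t(A)
  n <- nrow(base)
  blocks <- list(adjacency = base, diffusion = diffusion, cosine = cosine,
                 functional = functional)
  for (nm in names(blocks)[-1]) {
    if (!identical(dim(blocks[[nm]]), c(n, n))) {
      stop_mdlink("attribute block '", nm, "' must be ", n, "x", n,
                  " for role ", role, ", got ",
                  paste(dim(blocks[[nm]]), collapse = "x"))
    }
  }
  out <- do.call(cbind, unname(blocks))
  attr(out, "block_layout") <- vapply(blocks, ncol, integer(1))
  attr(out, "role") <- role
  out
}

# --- convolution primitives ------------------------------------------------
# Same-padded 2-D cross-correlation is implemented through an im2col matrix:
# column (p + (q-1)*k) of im2col_same(X, k) holds vec of the zero-padded
# shift X[i + p - cen, j + q - cen], so conv(X, K) = im2col %*% vec(K).
# This turns every convolution and kernel gradient in the autoencoder into a
# BLAS product and lets the (constant) input's im2col be computed once per
# training run.

im2col_same <- function(X, k) {
  .im2col_channels(X, ncol(X), 1L, as.integer(k))
}

# 2-D cross-correlation with zero same-padding
conv2d_same <- function(X, K) {
  matrix(im2col_same(X, nrow(K)) %*% as.vector(K), nrow(X), ncol(X))
}

# vec(rot180(K)) == rev(vec(K)); stacked per channel for the decoder
rot180 <- function(K) K[rev(seq_len(nrow(K))), rev(seq_len(ncol(K))),
                        drop = FALSE]

# extract channel c of an Nr x Nc x l array as a matrix (dims preserved)
channel_slice <- function(arr, c) {
  matrix(arr[, , c], dim(arr)[1], dim(arr)[2])
}

#' Convolutional encoder
#'
#' Applies `channels` independent same-padded 2-D convolutions with
#' kernel-size `kernel` to the attribute matrix, adds the per-channel bias,
#' and passes the result through ReLU, yielding an Nr x Nc x l feature
#' tensor with the spatial shape of the input preserved.
#'
#' @param X attribute matrix (Nr x Nc).
#' @param kernels kernel array of dimension `c(kernel, kernel, channels)`.
#' @param bias numeric vector of per-channel offsets.
#' @return Nr x Nc x l array of non-negative activations.
#' @export
conv_encode <- function(X, kernels, bias) {
  k <- dim(kernels)[1]
  l <- dim(kernels)[3]
  if (length(bias) != l) stop_mdlink("bias length must equal channel count")
  flat <- im2col_same(X, k) %*% matrix(kernels, k * k, l)
  flat <- relu(flat + rep(bias, each = nrow(X) * ncol(X)))
  array(flat, dim = c(nrow(X), ncol(X), l))
}

#' Flatten / partition the channel tensor
#'
#' `flatten_channels` maps an Nr x Nc x l tensor to an Nr x (Nc*l) matrix by
#' concatenating the channel slices along columns in channel order (channel c
#' occupies columns `(c-1)*Nc + 1 ... c*Nc`). `partition_channels` is its
#' exact inverse.
#'
#' @param fX Nr x Nc x l array.
#' @return `flatten_channels`: Nr x (Nc*l) matrix.
#' @export
flatten_channels <- function(fX) {
  d <- dim(fX)
  matrix(fX, nrow = d[1], ncol = d[2] * d[3])
}

#' @rdname flatten_channels
#' @param ft flattened Nr x (Nc*l) matrix.
#' @param channels channel count l; `ncol(ft)` must be divisible by it.
#' @return `partition_channels`: Nr x Nc x l array.
#' @export
partition_channels <- function(ft, channels) {
  if (ncol(ft) %% channels != 0L) {
    stop_mdlink("column count ", ncol(ft), " is not divisible into ",
                channels, " equal channel blocks")
  }
  array(ft, dim = c(nrow(ft), ncol(ft) %/% channels, channels))
}

#' Linear (bottleneck) encoder and decoder
#'
#' `linear_encode` maps the flattened feature matrix to the k2-column hidden
#' layer with a sigmoid activation (so hidden activations lie in (0, 1), as
#' required by the Bernoulli KL sparsity penalty); `linear_decode` maps the
#' hidden layer back to the flattened width, also through a sigmoid.
#'
#' @param ft flattened features, Nr x (Nc*l).
#' @param W weight matrix ((Nc*l) x k2 for encode, k2 x (Nc*l) for decode).
#' @param b bias vector (length k2 for encode, Nc*l for decode).
#' @return matrix of sigmoid activations.
#' @export
linear_encode <- function(ft, W, b) {
  sigmoid(ft %*% W + rep(b, each = nrow(ft)))
}

#' @rdname linear_encode
#' @param h hidden matrix (Nr x k2).
#' @export
linear_decode <- function(h, W, b) {
  sigmoid(h %*% W + rep(b, each = nrow(h)))
}

#' Convolutional (transposed) decoder
#'
#' Partitions the linear decoder output into `channels` matrices of equal
#' width, applies a same-padded transposed convolution (deconvolution) with a
#' per-channel kernel that collapses the channels to a single matrix, adds
#' the scalar offset and applies ReLU. Output has the Nr x Nc shape of the
#' original attribute matrix.
#'
#' @param y linear decoder output, Nr x (Nc * channels).
#' @param kernels kernel array `c(kernel, kernel, channels)`.
#' @param bias scalar offset.
#' @return Nr x Nc reconstruction.
#' @export
conv_decode <- function(y, kernels, bias = 0) {
  l <- dim(kernels)[3]
  f <- partition_channels(y, l)
  out <- matrix(bias, dim(f)[1], dim(f)[2])
  for (c in seq_len(l)) {
    # transposed convolution = correlation with the 180-degree rotated kernel
    out <- out + conv2d_same(channel_slice(f, c),
                             rot180(channel_slice(kernels, c)))
  }
  relu(out)
}

#' Kullback-Leibler sparsity penalty on hidden activations
#'
#' For each hidden unit t, the observed mean activation over rows,
#' `rho_hat_t = colMeans(h)`, is compared with the target `rho` via the KL
#' divergence between Bernoulli distributions:
#' `KL = rho*log(rho/rho_hat) + (1-rho)*log((1-rho)/(1-rho_hat))`, summed
#' over hidden units. Mean activations at exactly 0 or 1 are clamped to
#' `[1e-8, 1 - 1e-8]`, with a warning unless `warn = FALSE`.
#'
#' @param h hidden activation matrix with entries in (0, 1).
#' @param rho sparsity target in (0, 1).
#' @param warn warn when clamping degenerate mean activations.
#' @return non-negative scalar; zero iff every `rho_hat_t == rho`.
#' @export
sparsity_penalty <- function(h, rho, warn = TRUE) {
  rho_hat <- colMeans(h)
  if (any(rho_hat <= 0 | rho_hat >= 1)) {
    if (warn) {
      warning("hidden mean activations at 0 or 1 clamped to [1e-8, 1 - 1e-8]")
    }
    rho_hat <- pmin(pmax(rho_hat, 1e-8), 1 - 1e-8)
  }
  sum(rho * log(rho / rho_hat) + (1 - rho) * log((1 - rho) / (1 - rho_hat)))
}

#' Sparse reconstruction loss
#'
#' Mean over rows of the squared reconstruction error plus the weighted
#' sparsity penalty:
#' `L = sum((recon - X)^2) / Nr + beta * sparsity_penalty(h, rho)`.
#'
#' @param recon reconstruction (Nr x Nc).
#' @param X input attribute matrix (Nr x Nc).
#' @param h hidden activations.
#' @param beta sparsity weight.
#' @param rho sparsity target.
#' @param warn warn when clamping degenerate mean activations.
#' @return non-negative scalar.
#' @export
csae_loss <- function(recon, X, h, beta = 0.1, rho = 0.05, warn = TRUE) {
  if (!identical(dim(recon), dim(X))) {
    stop_mdlink("reconstruction and input shapes differ")
  }
  sum((recon - X)^2) / nrow(X) + beta * sparsity_penalty(h, rho, warn)
}

csae_init <- function(Nr, Nc, config) {
  l <- config$channels
  k <- config$kernel
  k2 <- config$k2
  klim <- sqrt(6 / (2 * k * k))
  list(
    K_enc = array(stats::runif(k * k * l, -klim, klim), dim = c(k, k, l)),
    b_enc = numeric(l),
    W_enc = xavier_matrix(Nc * l, k2),
    B_enc = numeric(k2),
    W_dec = xavier_matrix(k2, Nc * l),
    B_dec = numeric(Nc * l),
    K_dec = array(stats::runif(k * k * l, -klim, klim), dim = c(k, k, l)),
    b_dec = 0
  )
}

# Full forward pass keeping the intermediates backpropagation needs.
# All channel tensors live in the Nr x (Nc*l) channel-block layout; the C++
# correlation primitives read that layout directly, so no shifted copies or
# im2col matrices are materialized.
csae_forward <- function(X, params, config) {
  l <- config$channels
  k <- config$kernel
  n <- nrow(X)
  m <- ncol(X)
  nm <- n * m
  kk <- k * k
  Cpre <- .conv_bc(X, k, matrix(params$K_enc, kk, l)) +
    rep(params$b_enc, each = nm)
  ft <- .relu_mat(Cpre)
  h <- .sigmoid_mat(ft %*% params$W_enc + rep(params$B_enc, each = n))
  y <- .sigmoid_mat(h %*% params$W_dec + rep(params$B_dec, each = n))
  # transposed conv: correlation with the rotated kernels, summed over
  # channels; vec(rot180(K)) = rev(vec(K))
  Kd_mat <- matrix(params$K_dec, kk, l)
  Fpre <- .conv_mc(y, m, l, k, Kd_mat[rev(seq_len(kk)), , drop = FALSE]) +
    params$b_dec
  recon <- .relu_mat(Fpre)
  list(Cpre = Cpre, ft = ft, h = h, y = y, Fpre = Fpre, recon = recon)
}

# analytic gradients of csae_loss wrt every parameter
csae_backward <- function(X, params, fw, config) {
  l <- config$channels
  k <- config$kernel
  n <- nrow(X)
  m <- ncol(X)
  kk <- k * k
  rev_kk <- rev(seq_len(kk))
  grads <- list()
  dFpre <- .relu_grad((2 / n) * (fw$recon - X), fw$Fpre)
  grads$b_dec <- sum(dFpre)
  # kernel gradient of the transposed conv, un-rotated back per channel
  dKrot <- .kernel_sums(fw$y, m, l, dFpre, k)
  grads$K_dec <- array(dKrot[rev_kk, , drop = FALSE], dim = c(k, k, l))
  # dy per channel: correlation of dFpre with the (unrotated) decoder kernel
  dy <- .conv_bc(dFpre, k, matrix(params$K_dec, kk, l))
  dypre <- .sig_grad(dy, fw$y)
  grads$W_dec <- crossprod(fw$h, dypre)
  grads$B_dec <- colSums(dypre)
  dh <- tcrossprod(dypre, params$W_dec) # dypre %*% t(W_dec)
  # sparsity penalty path: d/dh[i,t] = beta * KL'(rho_hat_t) / Nr
  rho <- config$rho
  rho_hat <- pmin(pmax(colMeans(fw$h), 1e-8), 1 - 1e-8)
  dkl <- (-rho / rho_hat + (1 - rho) / (1 - rho_hat)) / n
  dh <- dh + config$beta * rep(dkl, each = n)
  dhpre <- .sig_grad(dh, fw$h)
  grads$W_enc <- crossprod(fw$ft, dhpre)
  grads$B_enc <- colSums(dhpre)
  dft <- tcrossprod(dhpre, params$W_enc) # dhpre %*% t(W_enc)
  dC <- .relu_grad(dft, fw$Cpre)
  # adjoint of the encoder correlation wrt its kernels: sums against the
  # negated shifts of the input, i.e. the row-reversed kernel_sums of (dC, X)
  grads$K_enc <- array(.kernel_sums(dC, m, l, X, k)[rev_kk, , drop = FALSE],
                       dim = c(k, k, l))
  dim(dC) <- c(n * m, l)
  grads$b_enc <- colSums(dC)
  grads
}

#' Train the convolutional sparse autoencoder
#'
#' Minimizes [csae_loss()] over all encoder/decoder parameters with Adam.
#' Parameters are initialized Xavier-uniform (biases at zero) under the
#' configured seed, so training is deterministic given the seed. The
#' attribute embedding returned is the hidden layer of the trained model:
#' an Nr x k2 matrix of sigmoid activations in (0, 1).
#'
#' @param X attribute matrix from [assemble_attribute_matrix()] (or any
#'   numeric matrix).
#' @param config a [csae_config()].
#' @return object of class `csae_fit`: list with `embedding` (Nr x k2),
#'   `loss_trace` (length `epochs + 1`), `params` and `config`.
#' @export
train_csae <- function(X, config = csae_config()) {
  params <- with_seed(config$seed, csae_init(nrow(X), ncol(X), config))
  state <- adam_init(params)
  trace <- numeric(config$epochs + 1L)
  fw <- csae_forward(X, params, config)
  trace[1L] <- csae_loss(fw$recon, X, fw$h, config$beta, config$rho,
                         warn = FALSE)
  if (config$epochs > 0L) {
    for (ep in seq_len(config$epochs)) {
      grads <- csae_backward(X, params, fw, config)
      upd <- adam_step(params, grads, state, config$lr)
      params <- upd$params
      state <- upd$state
      fw <- csae_forward(X, params, config)
      loss <- csae_loss(fw$recon, X, fw$h, config$beta, config$rho,
                        warn = FALSE)
      if (!is.finite(loss)) {
        stop_mdlink("autoencoder training diverged at epoch ", ep,
                    " (loss is not finite); try a lower learning rate lr2")
      }
      trace[ep + 1L] <- loss
    }
  }
  emb <- fw$h
  rownames(emb) <- rownames(X)
  structure(
    list(embedding = emb, loss_trace = trace, params = params,
         config = config),
    class = "csae_fit"
  )
}

#' @export
print.csae_fit <- function(x, ...) {
  cat("csae_fit:", nrow(x$embedding), "x", ncol(x$embedding),
      "attribute embedding\n")
  cat("  loss:", signif(x$loss_trace[1], 5), "->",
      signif(x$loss_trace[length(x$loss_trace)], 5), "over",
      length(x$loss_trace) - 1L, "epochs\n")
  invisible(x)
}
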