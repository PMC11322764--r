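#' Gaussian interaction profile (GIP) kernel similarity
#'
#' Computes the GIP kernel between interaction profiles of the association
#' matrix: disease profiles are rows of `A`, microbe profiles are columns.
#' For profiles x_i the kernel is `exp(-gamma * ||x_i - x_j||^2)` with the
#' bandwidth set from the mean squared profile norm,
#' `gamma = n / sum_i ||x_i||^2` over the n profiles on the chosen axis.
#'
#' @param A binary association matrix (diseases x microbes).
#' @param role `"disease"` (profiles are rows) or `"microbe"` (columns).
#' @return symmetric n x n similarity matrix with unit diagonal and entries
#'   in \[0, 1\].
#' @export
gip_similarity <- function(A, role = c("disease", "microbe")) {
  role <- match.arg(role)
  X <- if (role == "disease") A else t(A)
  norms2 <- rowSums(X^2)
  total <- sum(norms2)
  if (total == 0) {
    stop_mdlink("GIP bandwidth undefined: the association matrix is all",
                " zero, so the mean profile norm in the bandwidth",
                " denominator vanishes")
  }
  gamma <- nrow(X) / total
  d2 <- outer(norms2, norms2, "+") - 2 * tcrossprod(X)
  d2[d2 < 0] <- 0
  S <- exp(-gamma * d2)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  dimnames(S) <- list(rownames(X), rownames(X))
  S
}

#' Hamming interaction profile similarity
#'
#' One minus the fraction of positions at which two binary interaction
#' profiles disagree. The normalizer is the actual profile length: Nm for
#' disease profiles (rows of `A`) and Nd for microbe profiles (columns), so
#' that the similarity lies in \[0, 1\] with unit diagonal.
#'
#' @inheritParams gip_similarity
#' @return symmetric n x n similarity matrix.
#' @export
hamming_similarity <- function(A, role = c("disease", "microbe")) {
  role <- match.arg(role)
  if (!is_binary_matrix(A)) {
    stop_mdlink("Hamming similarity requires a binary 0/1 matrix")
  }
  X <- if (role == "disease") A else t(A)
  # for binary profiles, #mismatches = |x_i| + |x_j| - 2 x_i . x_j
  ones <- rowSums(X)
  mism <- outer(ones, ones, "+") - 2 * tcrossprod(X)
  S <- 1 - mism / ncol(X)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  dimnames(S) <- list(rownames(X), rownames(X))
  S
}

#' Average two similarity kernels into an integrated similarity
#'
#' Elementwise mean of the GIP and Hamming kernels on the same axis,
#' producing the integrated disease similarity SD or microbe similarity SM
#' used to build the heterogeneous network.
#'
#' @param gip,hamming conformable square similarity matrices over the same
#'   labels.
#' @return symmetric matrix `(gip + hamming) / 2`.
#' @export
integrate_similarity <- function(gip, hamming) {
  if (!identical(dim(gip), dim(hamming))) {
    stop_mdlink("similarity matrices have mismatched shapes: ",
                paste(dim(gip), collapse = "x"), " vs ",
                paste(dim(hamming), collapse = "x"))
  }
  if (!is.null(rownames(gip)) && !is.null(rownames(hamming)) &&
      !identical(rownames(gip), rownames(hamming))) {
    stop_mdlink("similarity matrices have mismatched labels")
  }
  (gip + hamming) / 2
}

#' Cosine similarity between interaction profiles
#'
#' Standard cosine of the angle between profiles. A pair involving an
#' all-zero profile gets similarity 0 (there is no direction to compare),
#' except on the diagonal, which is fixed at 1 to match the other kernels.
#'
#' @inheritParams gip_similarity
#' @return symmetric n x n matrix with entries in \[0, 1\] for binary input.
#' @export
cosine_similarity <- function(A, role = c("disease", "microbe")) {
  role <- match.arg(role)
  X <- if (role == "disease") A else t(A)
  nrm <- sqrt(rowSums(X^2))
  S <- tcrossprod(X)
  denom <- outer(nrm, nrm)
  zero <- denom == 0
  S[!zero] <- S[!zero] / denom[!zero]
  S[zero] <- 0
  S <- (S + t(S)) / 2
  S <- pmin(pmax(S, 0), 1) # guard rounding spill just past the bounds
  diag(S) <- 1
  dimnames(S) <- list(rownames(X), rownames(X))
  S
}

#' Random walk with restart (RWR) diffusion over a similarity matrix
#'
#' Iterates `q <- phi * M %*% q + (1 - phi) * e_i` for every seed node i,
#' where `M` is the column-normalized transfer probability matrix derived
#' from `S` (all-zero columns are replaced by uniform columns). Iteration
#' starts from `q = e_i` and stops when the L1 change of every walker drops
#' below `tol`, or at `max_iter` with a warning. Row i of the result is the
#' converged proximity profile of node i; each row sums to 1.
#'
#' @param S square non-negative similarity matrix.
#' @param phi walk weight on the diffusion term, in \[0, 1\]; 0.1 by default.
#' @param tol L1 convergence tolerance per walker.
#' @param max_iter iteration cap.
#' @return n x n diffusion matrix (not symmetric in general) with attributes
#'   `iterations` and `converged`.
#' @export
rwr_diffusion <- function(S, phi = 0.1, tol = 1e-6, max_iter = 100L) {
  if (!is.matrix(S) || nrow(S) != ncol(S)) {
    stop_mdlink("`S` must be a square matrix")
  }
  if (any(S < 0)) stop_mdlink("`S` must be non-negative")
  if (phi < 0 || phi > 1) stop_mdlink("`phi` must lie in [0, 1]")
  if (tol <= 0) stop_mdlink("`tol` must be positive")
  n <- nrow(S)
  cs <- colSums(S)
  M <- S
  ok <- cs > 0
  M[, ok] <- sweep(S[, ok, drop = FALSE], 2, cs[ok], "/")
  M[, !ok] <- 1 / n
  eye <- diag(n)
  Q <- eye # columns are the walkers q_i, started at the restart vectors
  iter <- 0L
  converged <- FALSE
  restart <- (1 - phi) * eye
  while (iter < max_iter) {
    iter <- iter + 1L
    Qn <- phi * (M %*% Q) + restart
    delta <- max(colSums(abs(Qn - Q)))
    Q <- Qn
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("rwr_diffusion did not converge within ", max_iter,
            " iterations (last L1 change ", signif(delta, 3), ")")
  }
  out <- t(Q)
  dimnames(out) <- dimnames(S)
  attr(out, "iterations") <- iter
  attr(out, "converged") <- converged
  out
}

#' Load (or default) a functional similarity matrix
#'
#' Functional similarity of diseases or microbes is an optional external
#' input computed from biological databases outside this package. When
#' provided (as a labeled square matrix or a TSV path readable by
#' [read_matrix()]), it is re-ordered to the dataset's label order, clipped
#' to \[0, 1\], and symmetrized by averaging with its transpose. When absent,
#' the neutral fallback is the identity matrix, which preserves all pipeline
#' shapes without injecting external information.
#'
#' @param x `NULL`, a labeled square numeric matrix, or a file path.
#' @param labels character vector of dataset labels the output must cover,
#'   in canonical order.
#' @return symmetric matrix over `labels` with entries in \[0, 1\].
#' @export
load_functional_similarity <- function(x = NULL, labels) {
  if (is.null(x)) {
    out <- diag(length(labels))
    dimnames(out) <- list(labels, labels)
    return(out)
  }
  m <- if (is.character(x)) read_matrix(x) else x
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop_mdlink("functional similarity must be a square matrix")
  }
  missing <- setdiff(labels, rownames(m))
  if (length(missing) > 0L) {
    stop_mdlink("functional similarity is missing labels: ",
                paste(missing, collapse = ", "))
  }
  m <- m[labels, labels, drop = FALSE]
  m <- pmin(pmax(m, 0), 1)
  (m + t(m)) / 2
}

#' Assemble the heterogeneous disease-microbe network
#'
#' Stacks the integrated disease similarity, the bipartite adjacency, and
#' the integrated microbe similarity into the (Nd+Nm) x (Nd+Nm) block matrix
#' `HN = rbind(cbind(SD, A), cbind(t(A), SM))`, the input graph of the
#' topological encoder.
#'
#' @param SD Nd x Nd disease similarity.
#' @param SM Nm x Nm microbe similarity.
#' @param A Nd x Nm binary adjacency.
#' @return symmetric (Nd+Nm) square matrix with attributes `nd` and `nm`;
#'   node labels are diseases then microbes.
#' @seealso [split_heterogeneous_network()]
#' @export
build_heterogeneous_network <- function(SD, SM, A) {
  nd <- nrow(A)
  nm <- ncol(A)
  if (!identical(dim(SD), c(nd, nd))) {
    stop_mdlink("SD must be ", nd, "x", nd, ", got ",
                paste(dim(SD), collapse = "x"))
  }
  if (!identical(dim(SM), c(nm, nm))) {
    stop_mdlink("SM must be ", nm, "x", nm, ", got ",
                paste(dim(SM), collapse = "x"))
  }
  HN <- rbind(cbind(SD, A), cbind(t(A), SM))
  labs <- c(rownames(A), colnames(A))
  if (length(labs) == nd + nm) dimnames(HN) <- list(labs, labs)
  attr(HN, "nd") <- nd
  attr(HN, "nm") <- nm
  HN
}

#' @rdname build_heterogeneous_network
#' @param HN a heterogeneous network matrix.
#' @param nd number of disease nodes (leading block); defaults to the `nd`
#'   attribute stamped by `build_heterogeneous_network`.
#' @return `split_heterogeneous_network` returns `list(SD, SM, A)`.
#' @export
split_heterogeneous_network <- function(HN, nd = attr(HN, "nd")) {
  if (is.null(nd)) stop_mdlink("`nd` is required to split the network")
  n <- nrow(HN)
  di <- seq_len(nd)
  mi <- setdiff(seq_len(n), di)
  list(SD = HN[di, di, drop = FALSE],
       SM = HN[mi, mi, drop = FALSE],
       A = HN[di, mi, drop = FALSE])
}
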