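#' Assemble the disease and microbe feature (eigen)matrices
#'
#' Column-concatenates learned embeddings with similarity and adjacency
#' blocks into one feature matrix per node type. Blocks come in aligned
#' groups so that the disease and microbe matrices have identical column
#' counts (required for the row inner product used in scoring):
#'
#' * `gcan`: `Zd` / `Zm` (width k1)
#' * `csae`: `Ad` / `Am` (width k2)
#' * `fs`: `[SDFS | A]` / `[t(A) | SMFS]` (width Nd + Nm)
#' * `cos`: `[SDCOS | A]` / `[t(A) | SMCOS]` (width Nd + Nm)
#' * `rwr`: `[SDMM | A]` / `[t(A) | SMDD]` (width Nd + Nm)
#'
#' With all groups retained the width is `k1 + k2 + 3 * (Nd + Nm)`. The
#' `blocks` argument selects groups, which is how the ablation variants are
#' realized (e.g. `cosine_only` keeps only the `cos` group).
#'
#' @param Zd,Zm topological embeddings (Nd x k1, Nm x k1).
#' @param Ad,Am attribute embeddings (Nd x k2, Nm x k2).
#' @param SDFS,SMFS functional similarity matrices.
#' @param SDCOS,SMCOS cosine similarity matrices.
#' @param SDMM,SMDD RWR diffusion matrices.
#' @param A binary association matrix.
#' @param blocks character subset of `c("gcan", "csae", "fs", "cos", "rwr")`.
#' @return list with `FD`, `FM` and `block_layout` (named widths).
#' @export
assemble_eigenmatrices <- function(Zd = NULL, Zm = NULL, Ad = NULL, Am = NULL,
                                   SDFS = NULL, SMFS = NULL, SDCOS = NULL,
                                   SMCOS = NULL, SDMM = NULL, SMDD = NULL, A,
                                   blocks = c("gcan", "csae", "fs", "cos",
                                              "rwr")) {
  nd <- nrow(A)
  nm <- ncol(A)
  blocks <- match.arg(blocks, several.ok = TRUE)
  check <- function(x, nr, nm_block) {
    if (is.null(x) || nrow(x) != nr) {
      stop_mdlink("eigenmatrix block '", nm_block, "' has ",
                  if (is.null(x)) "no" else nrow(x), " rows, expected ", nr)
    }
    x
  }
  fd <- list()
  fm <- list()
  widths <- integer(0)
  if ("gcan" %in% blocks) {
    zd <- check(Zd, nd, "Zd")
    zm <- check(Zm, nm, "Zm")
    if (ncol(zd) != ncol(zm)) {
      stop_mdlink("eigenmatrix block 'gcan': Zd and Zm widths differ")
    }
    fd <- c(fd, list(zd))
    fm <- c(fm, list(zm))
    widths <- c(widths, gcan = ncol(zd))
  }
  if ("csae" %in% blocks) {
    ad <- check(Ad, nd, "Ad")
    am <- check(Am, nm, "Am")
    if (ncol(ad) != ncol(am)) {
      stop_mdlink("eigenmatrix block 'csae': Ad and Am widths differ")
    }
    fd <- c(fd, list(ad))
    fm <- c(fm, list(am))
    widths <- c(widths, csae = ncol(ad))
  }
  pair_group <- function(name, SDX, SMX) {
    fd <<- c(fd, list(check(SDX, nd, name), A))
    fm <<- c(fm, list(t(A), check(SMX, nm, name)))
    widths <<- c(widths, stats::setNames(nd + nm, name))
  }
  if ("fs" %in% blocks) pair_group("fs", SDFS, SMFS)
  if ("cos" %in% blocks) pair_group("cos", SDCOS, SMCOS)
  if ("rwr" %in% blocks) pair_group("rwr", SDMM, SMDD)
  FD <- do.call(cbind, fd)
  FM <- do.call(cbind, fm)
  rownames(FD) <- rownames(A)
  rownames(FM) <- colnames(A)
  if (ncol(FD) != ncol(FM)) {
    stop_mdlink("internal block misalignment: FD width ", ncol(FD),
                " != FM width ", ncol(FM))
  }
  list(FD = FD, FM = FM, block_layout = widths)
}

#' Score candidate disease-microbe pairs
#'
#' The prediction score of pair (i, j) is the sigmoid of the inner product of
#' disease feature row i and microbe feature row j:
#' `S[i, j] = sigmoid(FD[i, ] . FM[j, ])`. Scores are strictly inside (0, 1).
#' The pre-sigmoid inner products are kept in the `"logits"` attribute; being
#' a strictly monotone transform of the scores they give the same ranking and
#' avoid ties from sigmoid saturation in double precision.
#'
#' @param FD,FM feature matrices with equal column counts.
#' @return Nd x Nm score matrix with attribute `logits`.
#' @export
predict_scores <- function(FD, FM) {
  if (ncol(FD) != ncol(FM)) {
    stop_mdlink("feature width mismatch: FD has ", ncol(FD),
                " columns, FM has ", ncol(FM))
  }
  logits <- tcrossprod(FD, FM)
  S <- sigmoid(logits)
  dimnames(S) <- list(rownames(FD), rownames(FM))
  dimnames(logits) <- dimnames(S)
  attr(S, "logits") <- logits
  S
}

#' Rank candidate microbes for one disease
#'
#' Sorts microbes by prediction score (descending) for the requested disease,
#' excluding microbes with an already-known association unless
#' `include_known = TRUE`. Ties are broken alphabetically by microbe name so
#' rankings are deterministic.
#'
#' @param S score matrix from [predict_scores()].
#' @param disease disease name (must match a row of `S`).
#' @param known binary association matrix flagging known pairs.
#' @param top_n number of candidates to return; the full list if fewer
#'   remain.
#' @param include_known keep known associations in the ranking.
#' @return data.frame with columns `rank`, `microbe`, `score`.
#' @export
rank_candidates <- function(S, disease, known, top_n = 20L,
                            include_known = FALSE) {
  if (!disease %in% rownames(S)) {
    stop_mdlink("unknown disease: ", disease)
  }
  sc <- S[disease, ]
  microbes <- colnames(S)
  if (!include_known) {
    keep <- known[disease, ] == 0
    sc <- sc[keep]
    microbes <- microbes[keep]
  }
  ord <- order(-sc, microbes, method = "radix")
  n <- min(top_n, length(ord))
  ord <- ord[seq_len(n)]
  data.frame(rank = seq_len(n), microbe = microbes[ord],
             score = unname(sc[ord]), stringsAsFactors = FALSE)
}
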