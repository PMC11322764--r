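#' Cross-validation configuration
#'
#' The evaluation protocol partitions known associations into k folds and, in
#' parallel, partitions the unknown (zero) cells into k folds; each fold's
#' test set is its known pairs (as positives) plus its unknown pairs (as
#' negatives), i.e. a 1/k fraction of each, and the training adjacency is the
#' association matrix with that fold's positives zeroed. The whole protocol
#' is repeated `repeats` times with fresh seed-derived partitions.
#'
#' @param k number of folds (2 and 5 are the standard settings).
#' @param repeats number of independent repetitions.
#' @param seed integer RNG seed.
#' @return a list of class `cv_config`.
#' @export
cv_config <- function(k = 5L, repeats = 10L, seed = 1L) {
  stopifnot(k >= 2, repeats >= 1)
  structure(list(k = as.integer(k), repeats = as.integer(repeats),
                 seed = as.integer(seed)),
            class = "cv_config")
}

#' Build k-fold cross-validation splits of an association matrix
#'
#' Known pairs are partitioned into k disjoint folds of (near-)equal size;
#' unknown pairs are partitioned the same way. For each fold the training
#' adjacency is `A` with the fold's known pairs zeroed, so no test positive
#' can contribute to any similarity matrix or training loss derived from it.
#'
#' @param A binary association matrix.
#' @param k number of folds.
#' @param seed integer RNG seed; the same seed reproduces the same splits.
#' @return list of k folds, each a list with `train` (adjacency matrix),
#'   `test_pos` and `test_neg` (two-column index matrices), and the linear
#'   indices `pos_idx`, `neg_idx`.
#' @export
make_cv_splits <- function(A, k = 5L, seed = 1L) {
  if (!is_binary_matrix(A)) {
    stop_mdlink("`A` must be a binary 0/1 matrix")
  }
  pos <- which(A == 1)
  neg <- which(A == 0)
  if (length(pos) < k || length(neg) < k) {
    stop_mdlink("need at least k known and k unknown pairs for ", k,
                "-fold cross-validation")
  }
  folds <- with_seed(seed, list(
    pos = sample(rep_len(seq_len(k), length(pos))),
    neg = sample(rep_len(seq_len(k), length(neg)))
  ))
  lapply(seq_len(k), function(f) {
    pos_idx <- pos[folds$pos == f]
    neg_idx <- neg[folds$neg == f]
    train <- A
    train[pos_idx] <- 0
    list(train = train,
         test_pos = arrayInd(pos_idx, dim(A)),
         test_neg = arrayInd(neg_idx, dim(A)),
         pos_idx = pos_idx,
         neg_idx = neg_idx)
  })
}

#' Area under the ROC curve for scored pairs
#'
#' Mann-Whitney formulation: the probability that a randomly chosen positive
#' pair outscores a randomly chosen negative pair, counting ties as 1/2.
#'
#' @param scores numeric matrix of prediction scores.
#' @param positives,negatives disjoint non-empty pair sets, as two-column
#'   (row, column) index matrices or vectors of linear indices into `scores`.
#' @return scalar AUC in \[0, 1\].
#' @export
compute_auc <- function(scores, positives, negatives) {
  sp <- scores[positives]
  sn <- scores[negatives]
  if (length(sp) == 0L || length(sn) == 0L) {
    stop_mdlink("both positive and negative test sets must be non-empty")
  }
  r <- rank(c(sp, sn))
  np <- length(sp)
  nn <- length(sn)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Run the k-fold cross-validation protocol
#'
#' For every repeat and fold, all similarity matrices, the heterogeneous
#' network and the attribute matrices are rebuilt from the fold's training
#' adjacency only; the encoders are trained per the ablation mode; scores are
#' computed for the fold's test pairs; and the AUC is recorded. Rankings use
#' the pre-sigmoid inner products (a strictly monotone transform of the
#' scores) to avoid saturation ties.
#'
#' Ablation modes select eigenmatrix block groups (see
#' [assemble_eigenmatrices()]): `"full"` keeps everything, `"gcan_only"`
#' drops the attribute (autoencoder) embeddings, `"csae_only"` drops the
#' topological embeddings, and `"cosine_only"` keeps only the cosine
#' similarity and adjacency blocks. Components that no retained block needs
#' are not trained.
#'
#' @param A binary association matrix.
#' @param cv a [cv_config()].
#' @param ablation one of `"full"`, `"gcan_only"`, `"csae_only"`,
#'   `"cosine_only"`.
#' @param gcan a [gcan_config()]; its seed is re-derived per repeat/fold.
#' @param csae a [csae_config()]; likewise.
#' @param rwr_phi,rwr_tol,rwr_max_iter random-walk-with-restart settings.
#' @param functional_disease,functional_microbe optional functional
#'   similarity matrices (or paths); identity fallback when `NULL`.
#' @param verbose print per-fold progress.
#' @return object of class `cv_result`: list with `auc_per_run` (one AUC per
#'   repeat x fold), `mean_auc`, `sd_auc`, `details` (data.frame of repeat,
#'   fold, AUC, test-set sizes) and the configuration echo.
#' @export
run_cross_validation <- function(A, cv = cv_config(), ablation = c(
                                   "full", "gcan_only", "csae_only",
                                   "cosine_only"),
                                 gcan = gcan_config(), csae = csae_config(),
                                 rwr_phi = 0.1, rwr_tol = 1e-6,
                                 rwr_max_iter = 100L,
                                 functional_disease = NULL,
                                 functional_microbe = NULL,
                                 verbose = FALSE) {
  ablation <- match.arg(ablation)
  aucs <- numeric(0)
  det <- list()
  run <- 0L
  for (rep_i in seq_len(cv$repeats)) {
    rep_seed <- (cv$seed + 9973L * (rep_i - 1L)) %% .Machine$integer.max
    splits <- make_cv_splits(A, cv$k, rep_seed)
    for (fold_i in seq_len(cv$k)) {
      run <- run + 1L
      sp <- splits[[fold_i]]
      fit <- fit_pipeline(
        sp$train, ablation = ablation,
        gcan = modify_seed(gcan, rep_seed + fold_i),
        csae = modify_seed(csae, rep_seed + fold_i),
        rwr_phi = rwr_phi, rwr_tol = rwr_tol, rwr_max_iter = rwr_max_iter,
        functional_disease = functional_disease,
        functional_microbe = functional_microbe
      )
      auc <- compute_auc(attr(fit$scores, "logits"), sp$test_pos, sp$test_neg)
      aucs[run] <- auc
      det[[run]] <- data.frame(repeat_ = rep_i, fold = fold_i, auc = auc,
                               n_test_pos = nrow(sp$test_pos),
                               n_test_neg = nrow(sp$test_neg))
      if (verbose) {
        message(sprintf("repeat %d fold %d: AUC %.4f", rep_i, fold_i, auc))
      }
    }
  }
  structure(
    list(auc_per_run = aucs,
         mean_auc = mean(aucs),
         sd_auc = if (length(aucs) > 1L) stats::sd(aucs) else 0,
         details = do.call(rbind, det),
         k = cv$k, repeats = cv$repeats, seed = cv$seed,
         ablation = ablation),
    class = "cv_result"
  )
}

# replace the seed of a gcan_config/csae_config, keeping it a valid integer
modify_seed <- function(config, seed) {
  config$seed <- as.integer(seed %% .Machine$integer.max)
  config
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d-fold CV x %d repeat(s), ablation '%s'\n",
              x$k, x$repeats, x$ablation))
  cat(sprintf("  mean AUC %.4f +/- %.4f over %d runs\n",
              x$mean_auc, x$sd_auc, length(x$auc_per_run)))
  invisible(x)
}

#' Export a cross-validation result as JSON
#'
#' @param x a `cv_result`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cv_result <- function(x, path) {
  out <- list(
    mean_auc = x$mean_auc,
    sd_auc = x$sd_auc,
    auc_per_run = x$auc_per_run,
    k = x$k,
    repeats = x$repeats,
    seed = x$seed,
    ablation = x$ablation,
    details = x$details
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
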