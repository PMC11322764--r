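#' mdlink: microbe-disease association prediction
#'
#' Fits the full link-prediction model to a binary disease x microbe
#' association matrix and returns a classed fit object. The pipeline is:
#'
#' 1. Gaussian interaction profile and Hamming profile kernels on both axes,
#'    averaged into integrated similarities SD and SM
#'    ([gip_similarity()], [hamming_similarity()], [integrate_similarity()]);
#' 2. the heterogeneous network `HN = [SD A; t(A) SM]`
#'    ([build_heterogeneous_network()]);
#' 3. topological embeddings Zd, Zm from the attention graph convolutional
#'    encoder trained to reconstruct HN ([train_gcan()]);
#' 4. random-walk-with-restart diffusion, cosine similarity and (optional)
#'    functional similarity assembled into per-node attribute matrices
#'    ([rwr_diffusion()], [cosine_similarity()],
#'    [assemble_attribute_matrix()]), encoded by the convolutional sparse
#'    autoencoder into attribute embeddings ([train_csae()]);
#' 5. concatenated feature matrices FD, FM and sigmoid inner-product scores
#'    ([assemble_eigenmatrices()], [predict_scores()]).
#'
#' @param A binary association matrix (diseases in rows, microbes in
#'   columns), or an [association_data] object.
#' @param functional_disease,functional_microbe optional functional
#'   similarity matrices (or TSV paths); when `NULL` the neutral identity
#'   fallback is used.
#' @param ablation model variant: `"full"` (default), `"gcan_only"`,
#'   `"csae_only"` or `"cosine_only"` (see [run_cross_validation()]).
#' @param gcan a [gcan_config()].
#' @param csae a [csae_config()].
#' @param rwr_phi,rwr_tol,rwr_max_iter random-walk-with-restart settings;
#'   `rwr_phi` is the walk weight (0.1 by default).
#' @param seed global seed; when supplied it overrides the seeds inside
#'   `gcan` and `csae` (disease and microbe autoencoders get distinct
#'   derived seeds).
#' @return An object of class `mdlink`; a list with `scores` (the Nd x Nm
#'   score matrix with a `"logits"` attribute), `FD`, `FM`, `embeddings`
#'   (Zd, Zm, Ad, Am), `similarities` (SD, SM, SDCOS, SMCOS, SDMM, SMDD,
#'   SDFS, SMFS, HN), `loss` (training traces), `ablation`, `config`, `A`
#'   and `call`.
#' @examples
#' syn <- generate_synthetic_associations(12, 20, rank = 2, density = 0.1,
#'                                        seed = 7)
#' fit <- mdlink(syn$adjacency, gcan = gcan_config(k1 = 8, epochs = 5),
#'               csae = csae_config(k2 = 4, channels = 2, epochs = 5))
#' fit
#' head(predict(fit, disease = "d1", top_n = 3))
#' @export
mdlink <- function(A, functional_disease = NULL, functional_microbe = NULL,
                   ablation = c("full", "gcan_only", "csae_only",
                                "cosine_only"),
                   gcan = gcan_config(), csae = csae_config(),
                   rwr_phi = 0.1, rwr_tol = 1e-6, rwr_max_iter = 100L,
                   seed = NULL) {
  cl <- match.call()
  ablation <- match.arg(ablation)
  if (inherits(A, "association_data")) A <- build_adjacency(A)
  if (inherits(A, "synthetic_associations")) A <- A$adjacency
  if (!is_binary_matrix(A)) {
    stop_mdlink("`A` must be a binary 0/1 matrix (or association_data)")
  }
  if (!is.null(seed)) {
    gcan <- modify_seed(gcan, seed)
    csae <- modify_seed(csae, seed)
  }
  fit <- fit_pipeline(A, ablation = ablation, gcan = gcan, csae = csae,
                      rwr_phi = rwr_phi, rwr_tol = rwr_tol,
                      rwr_max_iter = rwr_max_iter,
                      functional_disease = functional_disease,
                      functional_microbe = functional_microbe,
                      keep_all = TRUE)
  structure(
    list(scores = fit$scores, FD = fit$FD, FM = fit$FM,
         block_layout = fit$block_layout,
         embeddings = fit$embeddings, similarities = fit$similarities,
         loss = fit$loss, ablation = ablation,
         config = list(gcan = gcan, csae = csae, rwr_phi = rwr_phi,
                       rwr_tol = rwr_tol, rwr_max_iter = rwr_max_iter),
         A = A, call = cl),
    class = "mdlink"
  )
}

# Shared pipeline core: everything is computed from `A` alone (plus the
# optional functional matrices), so cross-validation can call it on a
# training adjacency with held-out positives zeroed.
fit_pipeline <- function(A, ablation, gcan, csae, rwr_phi, rwr_tol,
                         rwr_max_iter, functional_disease = NULL,
                         functional_microbe = NULL, keep_all = FALSE) {
  blocks <- switch(ablation,
    full = c("gcan", "csae", "fs", "cos", "rwr"),
    gcan_only = c("gcan", "fs", "cos", "rwr"),
    csae_only = c("csae", "fs", "cos", "rwr"),
    cosine_only = "cos"
  )
  need_gcan <- "gcan" %in% blocks
  need_csae <- "csae" %in% blocks
  need_rwr <- need_csae || "rwr" %in% blocks
  need_fs <- need_csae || "fs" %in% blocks

  SDCOS <- cosine_similarity(A, "disease")
  SMCOS <- cosine_similarity(A, "microbe")

  SD <- SM <- HN <- NULL
  if (need_gcan || need_rwr) {
    SD <- integrate_similarity(gip_similarity(A, "disease"),
                               hamming_similarity(A, "disease"))
    SM <- integrate_similarity(gip_similarity(A, "microbe"),
                               hamming_similarity(A, "microbe"))
  }
  SDMM <- SMDD <- NULL
  if (need_rwr) {
    SDMM <- rwr_diffusion(SD, phi = rwr_phi, tol = rwr_tol,
                          max_iter = rwr_max_iter)
    SMDD <- rwr_diffusion(SM, phi = rwr_phi, tol = rwr_tol,
                          max_iter = rwr_max_iter)
  }
  SDFS <- SMFS <- NULL
  if (need_fs) {
    SDFS <- load_functional_similarity(functional_disease, rownames(A))
    SMFS <- load_functional_similarity(functional_microbe, colnames(A))
  }

  gcan_fit <- NULL
  if (need_gcan) {
    HN <- build_heterogeneous_network(SD, SM, A)
    gcan_fit <- train_gcan(HN, A, gcan)
  }

  csae_d <- csae_m <- NULL
  if (need_csae) {
    AD <- assemble_attribute_matrix(A, SDMM, SDCOS, SDFS, "disease")
    AM <- assemble_attribute_matrix(A, SMDD, SMCOS, SMFS, "microbe")
    csae_d <- train_csae(AD, csae)
    csae_m <- train_csae(AM, modify_seed(csae, csae$seed + 1L))
  }

  eig <- assemble_eigenmatrices(
    Zd = if (need_gcan) gcan_fit$Zd, Zm = if (need_gcan) gcan_fit$Zm,
    Ad = if (need_csae) csae_d$embedding,
    Am = if (need_csae) csae_m$embedding,
    SDFS = SDFS, SMFS = SMFS, SDCOS = SDCOS, SMCOS = SMCOS,
    SDMM = SDMM, SMDD = SMDD, A = A, blocks = blocks
  )
  scores <- predict_scores(eig$FD, eig$FM)

  out <- list(scores = scores, FD = eig$FD, FM = eig$FM,
              block_layout = eig$block_layout)
  if (keep_all) {
    out$embeddings <- list(
      Zd = if (need_gcan) gcan_fit$Zd, Zm = if (need_gcan) gcan_fit$Zm,
      Ad = if (need_csae) csae_d$embedding,
      Am = if (need_csae) csae_m$embedding
    )
    out$similarities <- list(SD = SD, SM = SM, SDCOS = SDCOS, SMCOS = SMCOS,
                             SDMM = SDMM, SMDD = SMDD, SDFS = SDFS,
                             SMFS = SMFS, HN = HN)
    out$loss <- list(
      gcan = if (need_gcan) gcan_fit$loss_trace,
      csae_disease = if (need_csae) csae_d$loss_trace,
      csae_microbe = if (need_csae) csae_m$loss_trace
    )
  }
  out
}

#' @export
print.mdlink <- function(x, ...) {
  cat("mdlink fit (", x$ablation, " model)\n", sep = "")
  cat("  ", nrow(x$A), " diseases x ", ncol(x$A), " microbes, ",
      sum(x$A), " known associations\n", sep = "")
  cat("  feature width: ", ncol(x$FD), " (",
      paste(names(x$block_layout), x$block_layout, sep = "=",
            collapse = ", "), ")\n", sep = "")
  if (!is.null(x$loss$gcan)) {
    cat("  topological encoder loss: ", signif(x$loss$gcan[1], 5), " -> ",
        signif(x$loss$gcan[length(x$loss$gcan)], 5), "\n", sep = "")
  }
  if (!is.null(x$loss$csae_disease)) {
    cat("  attribute encoder loss (disease): ",
        signif(x$loss$csae_disease[1], 5), " -> ",
        signif(x$loss$csae_disease[length(x$loss$csae_disease)], 5),
        "\n", sep = "")
    cat("  attribute encoder loss (microbe): ",
        signif(x$loss$csae_microbe[1], 5), " -> ",
        signif(x$loss$csae_microbe[length(x$loss$csae_microbe)], 5),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.mdlink <- function(object, ...) {
  sc <- object$scores
  known <- object$A == 1
  structure(
    list(nd = nrow(object$A), nm = ncol(object$A),
         n_known = sum(object$A),
         density = mean(object$A),
         ablation = object$ablation,
         feature_width = ncol(object$FD),
         score_quantiles = stats::quantile(sc, c(0, .25, .5, .75, 1)),
         mean_score_known = mean(sc[known]),
         mean_score_unknown = mean(sc[!known]),
         loss = object$loss),
    class = "summary.mdlink"
  )
}

#' @export
print.summary.mdlink <- function(x, ...) {
  cat("mdlink fit summary (", x$ablation, " model)\n", sep = "")
  cat(sprintf("  %d diseases x %d microbes, %d known pairs (density %.3f)\n",
              x$nd, x$nm, x$n_known, x$density))
  cat("  feature width:", x$feature_width, "\n")
  cat(sprintf("  mean score: known pairs %.4f, unknown pairs %.4f\n",
              x$mean_score_known, x$mean_score_unknown))
  cat("  score quantiles:\n")
  print(signif(x$score_quantiles, 4))
  invisible(x)
}

#' Predictions from a fitted mdlink model
#'
#' With `disease` given, returns the ranked candidate microbes for that
#' disease ([rank_candidates()]); otherwise returns the full score matrix.
#'
#' @param object an `mdlink` fit.
#' @param disease optional disease name.
#' @param top_n number of ranked candidates (when `disease` is given).
#' @param include_known keep known associations in the ranking.
#' @param ... unused.
#' @return score matrix, or a ranking data.frame.
#' @export
predict.mdlink <- function(object, disease = NULL, top_n = 20L,
                           include_known = FALSE, ...) {
  if (is.null(disease)) {
    return(object$scores)
  }
  rank_candidates(object$scores, disease, object$A, top_n = top_n,
                  include_known = include_known)
}

#' Plot training loss traces of a fitted mdlink model
#'
#' @param x an `mdlink` fit.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.mdlink <- function(x, ...) {
  traces <- Filter(Negate(is.null), x$loss)
  if (length(traces) == 0L) {
    stop_mdlink("this ablation trains no encoder; nothing to plot")
  }
  op <- graphics::par(mfrow = c(1, length(traces)))
  on.exit(graphics::par(op))
  for (nm in names(traces)) {
    graphics::plot(seq_along(traces[[nm]]) - 1L, traces[[nm]], type = "l",
                   xlab = "epoch", ylab = "loss", main = nm, ...)
  }
  invisible(x)
}
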