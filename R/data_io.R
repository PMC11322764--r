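#' Build an association edge set from disease/microbe name vectors
#'
#' Takes parallel character vectors naming the two endpoints of every reported
#' association and produces a de-duplicated, indexed edge set. Name matching is
#' case-insensitive after trimming surrounding whitespace; the first-seen
#' spelling of each name is kept as its display form.
#'
#' @param diseases character vector of disease names, one per reported
#'   association.
#' @param microbes character vector of microbe names, parallel to `diseases`.
#' @return An object of class `association_data`: a list with
#'   `disease_names`, `microbe_names` (unique, first-occurrence order),
#'   `pairs` (two-column integer matrix of disease/microbe indices, one row
#'   per unique association), `n_rows_read` and `n_pairs_kept`.
#' @seealso [read_association_table()], [build_adjacency()]
#' @export
association_data <- function(diseases, microbes) {
  if (length(diseases) != length(microbes)) {
    stop_mdlink("`diseases` and `microbes` must have equal length")
  }
  if (length(diseases) == 0L) {
    stop_mdlink("empty input: no associations provided")
  }
  diseases <- as.character(diseases)
  microbes <- as.character(microbes)
  bad <- which(is.na(diseases) | is.na(microbes) |
                 trimws(diseases) == "" | trimws(microbes) == "")
  if (length(bad) > 0L) {
    stop_mdlink("format error: empty disease or microbe field at row ",
                bad[1L])
  }
  dkey <- tolower(trimws(diseases))
  mkey <- tolower(trimws(microbes))
  dlev <- unique(dkey)
  mlev <- unique(mkey)
  # display names: first occurrence of each normalized key
  dnames <- trimws(diseases)[match(dlev, dkey)]
  mnames <- trimws(microbes)[match(mlev, mkey)]
  di <- match(dkey, dlev)
  mi <- match(mkey, mlev)
  keep <- !duplicated(cbind(di, mi))
  pairs <- cbind(disease = di[keep], microbe = mi[keep])
  structure(
    list(
      disease_names = dnames,
      microbe_names = mnames,
      pairs = pairs,
      n_rows_read = length(diseases),
      n_pairs_kept = nrow(pairs)
    ),
    class = "association_data"
  )
}

#' @export
print.association_data <- function(x, ...) {
  cat("association_data:", length(x$disease_names), "diseases x",
      length(x$microbe_names), "microbes,", x$n_pairs_kept,
      "unique associations")
  if (x$n_rows_read != x$n_pairs_kept) {
    cat(" (", x$n_rows_read - x$n_pairs_kept, " duplicate rows collapsed)",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Read a disease-microbe association table
#'
#' Reads a delimited edge list with one reported association per row.
#' Duplicate rows (after whitespace trimming and case folding of the names)
#' are collapsed, mirroring how curated association databases are
#' de-duplicated before analysis.
#'
#' @param path path to a tab- or comma-separated text file.
#' @param sep field separator; `NULL` (default) auto-detects tab vs. comma
#'   from the first line.
#' @param header logical, does the file have a header row?
#' @param disease_col,microbe_col column name (when `header = TRUE`) or
#'   1-based column index identifying the two endpoint columns. Extra columns
#'   are ignored.
#' @return An [association_data] object.
#' @export
read_association_table <- function(path, sep = NULL, header = TRUE,
                                   disease_col = 1L, microbe_col = 2L) {
  if (!file.exists(path)) {
    stop_mdlink("association file not found: ", path)
  }
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) {
    stop_mdlink("empty input: ", path, " has no rows")
  }
  if (is.null(sep)) sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = header,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "", fill = FALSE,
                           blank.lines.skip = TRUE, strip.white = FALSE)
  if (nrow(tab) == 0L) {
    stop_mdlink("empty input: ", path, " has a header but no data rows")
  }
  pick <- function(col, what) {
    if (is.character(col)) {
      if (!col %in% names(tab)) {
        stop_mdlink("format error: missing ", what, " column '", col,
                    "' in ", path)
      }
      tab[[col]]
    } else {
      if (col > ncol(tab)) {
        stop_mdlink("format error: ", what, " column index ", col,
                    " exceeds ", ncol(tab), " columns in ", path)
      }
      tab[[col]]
    }
  }
  d <- pick(disease_col, "disease")
  m <- pick(microbe_col, "microbe")
  bad <- which(is.na(d) | is.na(m) | trimws(d) == "" | trimws(m) == "")
  if (length(bad) > 0L) {
    stop_mdlink("format error in ", path, ": empty disease or microbe field",
                " at data line ", bad[1L])
  }
  association_data(d, m)
}

#' Build the binary association adjacency matrix
#'
#' Converts an [association_data] edge set into the Nd x Nm binary adjacency
#' matrix A with `A[i, j] == 1` exactly when disease i has a reported
#' association with microbe j. This matrix is the single source from which
#' all similarity matrices are derived.
#'
#' @param data an [association_data] object.
#' @return numeric Nd x Nm matrix of 0/1 with disease row names and microbe
#'   column names.
#' @export
build_adjacency <- function(data) {
  if (!inherits(data, "association_data")) {
    stop_mdlink("`data` must be an association_data object")
  }
  nd <- length(data$disease_names)
  nm <- length(data$microbe_names)
  A <- matrix(0, nd, nm,
              dimnames = list(data$disease_names, data$microbe_names))
  A[data$pairs] <- 1
  A
}

#' Generate a synthetic association matrix with planted low-rank structure
#'
#' Draws non-negative latent factors `U` (nd x rank) and `V` (nm x rank) with
#' entries `|N(0, 1)|`, scores every pair by `S = U V'`, and sets the top
#' `ceiling(density * nd * nm)` scoring cells to 1. The planted low-rank
#' block structure means profile-similarity propagation can recover held-out
#' edges, which is what the cross-validation protocol measures. Ties at the
#' density threshold are broken by (row, column) order so the output is a
#' deterministic function of the seed.
#'
#' @param nd,nm numbers of diseases (rows) and microbes (columns).
#' @param rank number of latent factors; must not exceed `min(nd, nm)`.
#' @param density fraction of cells set to 1, in (0, 1).
#' @param seed integer RNG seed.
#' @return A list of class `synthetic_associations` with `adjacency`
#'   (binary nd x nm matrix, labels `d1..dnd` / `m1..mnm`), the latent
#'   factors `U` and `V`, the pre-threshold `scores` matrix, and the call
#'   parameters in `spec`.
#' @export
generate_synthetic_associations <- function(nd, nm, rank = 3,
                                            density = 0.05, seed = 1) {
  if (rank < 1 || rank > min(nd, nm)) {
    stop_mdlink("configuration error: rank must lie in [1, min(nd, nm)]")
  }
  if (density <= 0 || density >= 1) {
    stop_mdlink("configuration error: density must lie in (0, 1)")
  }
  n_ones <- as.integer(ceiling(density * nd * nm))
  if (n_ones >= nd * nm) {
    stop_mdlink("configuration error: density leaves no unknown pairs for",
                " cross-validation")
  }
  fac <- with_seed(seed, list(
    U = matrix(abs(stats::rnorm(nd * rank)), nd, rank),
    V = matrix(abs(stats::rnorm(nm * rank)), nm, rank)
  ))
  S <- tcrossprod(fac$U, fac$V)
  ord <- order(S, row(S), col(S), method = "radix",
               decreasing = c(TRUE, FALSE, FALSE))
  A <- matrix(0, nd, nm,
              dimnames = list(paste0("d", seq_len(nd)),
                              paste0("m", seq_len(nm))))
  A[ord[seq_len(n_ones)]] <- 1
  structure(
    list(adjacency = A, U = fac$U, V = fac$V, scores = S,
         spec = list(nd = nd, nm = nm, rank = rank, density = density,
                     seed = seed)),
    class = "synthetic_associations"
  )
}

#' @export
print.synthetic_associations <- function(x, ...) {
  cat("synthetic_associations:", x$spec$nd, "x", x$spec$nm,
      "planted rank", x$spec$rank, "matrix with", sum(x$adjacency),
      "ones (seed", paste0(x$spec$seed, ")"), "\n")
  invisible(x)
}

#' Write / read a labeled numeric matrix as TSV
#'
#' Plain-text round trip for dense matrices: a header row of column labels
#' and a first column of row labels (empty top-left corner cell). Values with
#' NA/NaN/Inf entries are refused on write.
#'
#' @param m numeric matrix with complete row and column names.
#' @param path file path.
#' @return `write_matrix` returns `path` invisibly; `read_matrix` returns the
#'   labeled numeric matrix.
#' @export
write_matrix <- function(m, path) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop_mdlink("`m` must be a numeric matrix")
  }
  if (any(!is.finite(m))) {
    stop_mdlink("refusing to write matrix with non-finite entries (NA/NaN/Inf)")
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop_mdlink("matrix must have row and column labels")
  }
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     file = path, sep = "\t", quote = FALSE,
                     col.names = NA, row.names = TRUE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop_mdlink("matrix file not found: ", path)
  tab <- tryCatch(
    utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                      check.names = FALSE, quote = "", comment.char = ""),
    error = function(e) stop_mdlink("format error reading ", path, ": ",
                                    conditionMessage(e))
  )
  m <- as.matrix(tab)
  if (!is.numeric(m)) {
    stop_mdlink("format error: non-numeric entries in ", path)
  }
  m
}
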