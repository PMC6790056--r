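#' Log-transform feature counts
#'
#' `log2(eps + u_gi)` restricted to the feature genes — the transformed
#' table the raw cell-cell similarity is computed on.
#'
#' @param m a [umi_matrix].
#' @param features a `feature_set` or character vector of gene ids;
#'   `NULL` uses all genes.
#' @param eps regularizer inside the log (default 1, so zero counts map
#'   to 0).
#' @return a dense features x cells numeric matrix.
#' @export
umi_log_transform <- function(m, features = NULL, eps = 1) {
  stopifnot(inherits(m, "umi_matrix"))
  if (eps <= 0) stop("eps must be positive")
  genes <- feature_ids(features, m)
  log2(eps + as.matrix(m$counts[genes, , drop = FALSE]))
}

feature_ids <- function(features, m) {
  if (is.null(features)) return(m$gene_ids)
  ids <- if (inherits(features, "feature_set")) features$gene_ids else features
  missing <- setdiff(ids, m$gene_ids)
  if (length(missing))
    stop("feature genes absent from matrix: ", paste(utils::head(missing, 3),
                                                     collapse = ", "))
  ids
}

#' Raw cell-cell similarity matrix
#'
#' Pearson correlations between cells over the log-transformed feature
#' counts. Optionally the matrix is first down-sampled to the minimum cell
#' depth, so that deeper profiles do not look artificially more similar to
#' each other; with highly variable depth distributions this is usually
#' skipped and the sampling bias handled by the rank transform instead.
#'
#' @param m a [umi_matrix].
#' @param features feature genes (see [umi_log_transform()]).
#' @param eps log regularizer.
#' @param downsample down-sample all cells to `min(cell_totals)` first?
#' @param rng_seed seed for the optional down-sampling.
#' @return a symmetric cells x cells correlation matrix with unit
#'   diagonal. Cells with zero variance across the features get
#'   similarity 0 to every other cell (with a warning).
#' @export
raw_similarity <- function(m, features = NULL, eps = 1, downsample = FALSE,
                           rng_seed = 1) {
  if (downsample) m <- downsample_cells(m, rng_seed = rng_seed)
  x <- umi_log_transform(m, features, eps)
  if (nrow(x) < 2)
    stop("similarity needs at least 2 feature genes")
  sds <- apply(x, 2, stats::sd)
  flat <- is.na(sds) | sds == 0
  r <- suppressWarnings(stats::cor(x))
  if (any(flat)) {
    warning(sum(flat), " cell(s) with zero variance across features; ",
            "their similarities are set to 0")
    r[flat, ] <- 0; r[, flat] <- 0
  }
  diag(r) <- 1
  r
}

#' Rank-transform a similarity matrix
#'
#' Per row, the off-diagonal entries are ranked by descending similarity:
#' rank 1 is the most similar neighbor. Ties are broken toward the lower
#' cell index. The diagonal is excluded and set to NA.
#'
#' @param r a symmetric similarity matrix.
#' @return an integer matrix of ranks; each row's off-diagonal entries are
#'   a permutation of `1..(n-1)`.
#' @export
rank_rows <- function(r) {
  n <- nrow(r)
  if (n != ncol(r)) stop("similarity matrix must be square")
  s <- matrix(NA_integer_, n, n, dimnames = dimnames(r))
  for (i in seq_len(n)) {
    v <- r[i, -i]
    s[i, -i] <- as.integer(rank(-v, ties.method = "first"))
  }
  s
}

# rank positive entries of v descending (rank 1 = largest), ties to the
# lower index; zeros and negatives get rank Inf (never kept)
.rank_positive_desc <- function(v) {
  out <- rep(Inf, length(v))
  pos <- which(v > 0)
  if (length(pos)) out[pos] <- rank(-v[pos], ties.method = "first")
  out
}

#' Balance a rank matrix into the directed K-nn cell graph
#'
#' Three-step balancing of the mutual rank structure:
#' 1. symmetrize by the rank product and clip:
#'    `s1_ij = max(alpha*K^2 - s_ij * s_ji, 0)` — only mutually
#'    well-ranked pairs survive;
#' 2. keep at most `beta*K` incoming edges per node:
#'    `s2_ij = max(beta*K - rank_i(s1_ij), 0)`, ranking each column's
#'    positive entries descending;
#' 3. keep at most `K` outgoing edges per node:
#'    `a_ij = max(K - rank_j(s2_ij), 0)`, ranking each row's positive
#'    entries descending.
#' Zero entries are deleted edges and are never ranked. Because ranks are
#' 1-based, the retained out-degree is at most `K - 1` strictly positive
#' edges. Nodes may end up with low or zero degree — that is how outlier
#' cells disconnect.
#'
#' @param s an integer rank matrix from [rank_rows()].
#' @param K target neighborhood size.
#' @param alpha rank-product clip factor (default 10).
#' @param beta incoming-degree factor (default 3).
#' @return an object of class `balanced_graph`: list with the sparse
#'   weighted adjacency `adj` (cells x cells, `adj[i, j]` = weight of edge
#'   i -> j), parameters, and the intermediate matrices `s1`, `s2` (sparse)
#'   for inspection.
#' @export
balance_graph <- function(s, K, alpha = 10, beta = 3) {
  n <- nrow(s)
  if (K < 2) stop("K must be >= 2")
  sp <- s * t(s)
  s1 <- pmax(alpha * K^2 - sp, 0)
  s1[is.na(s1)] <- 0          # diagonal
  # step 2: bound incoming degree (rank within columns)
  s2 <- apply(s1, 2, function(v) pmax(beta * K - .rank_positive_desc(v), 0))
  # step 3: bound outgoing degree (rank within rows)
  a <- t(apply(s2, 1, function(v) pmax(K - .rank_positive_desc(v), 0)))
  dimnames(a) <- dimnames(s1) <- dimnames(s2) <- dimnames(s)
  g <- list(adj = methods::as(Matrix::drop0(a), "CsparseMatrix"),
            K = K, alpha = alpha, beta = beta,
            s1 = methods::as(Matrix::drop0(s1), "CsparseMatrix"),
            s2 = methods::as(Matrix::drop0(s2), "CsparseMatrix"),
            cell_ids = rownames(s))
  class(g) <- "balanced_graph"
  g
}

#' @export
print.balanced_graph <- function(x, ...) {
  deg <- Matrix::rowSums(x$adj > 0)
  cat(sprintf("balanced_graph: %d cells, %d edges, out-degree <= %d (median %d)\n",
              nrow(x$adj), length(x$adj@x), x$K, as.integer(stats::median(deg))))
  invisible(x)
}

#' Build the balanced K-nn graph straight from a UMI matrix
#'
#' Convenience wrapper: [raw_similarity()] then [rank_rows()] then
#' [balance_graph()].
#'
#' @inheritParams raw_similarity
#' @inheritParams balance_graph
#' @return a `balanced_graph`.
#' @export
build_balanced_graph <- function(m, features = NULL, K = 100, alpha = 10,
                                 beta = 3, eps = 1, downsample = FALSE,
                                 rng_seed = 1) {
  r <- raw_similarity(m, features, eps = eps, downsample = downsample,
                      rng_seed = rng_seed)
  balance_graph(rank_rows(r), K = K, alpha = alpha, beta = beta)
}

#' Write a balanced graph as an edge-list TSV (source, target, weight)
#' @param g a `balanced_graph` (or any object with a sparse `adj`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edges <- function(g, path) {
  tm <- methods::as(g$adj, "TsparseMatrix")
  ids <- g$cell_ids
  utils::write.table(
    data.frame(source = ids[tm@i + 1L], target = ids[tm@j + 1L],
               weight = tm@x),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
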