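#' Metacell pool frequencies
#'
#' Sums the UMIs of each metacell's member cells into one pool and
#' normalizes: `p_gk = sum_i u_gi / sum_i u_i` over `i` in metacell `k`.
#' Columns each sum to 1.
#'
#' @param m a [umi_matrix].
#' @param assignment an `mc_assignment` or `metacell_cover` over the same
#'   cells.
#' @return a genes x metacells matrix of pooled frequencies.
#' @export
pool_frequencies <- function(m, assignment) {
  mc <- .match_mc(m, assignment)
  ks <- sort(unique(mc[!is.na(mc)]))
  if (!length(ks)) stop("assignment has no non-empty metacell")
  ind <- Matrix::sparseMatrix(i = which(!is.na(mc)),
                              j = match(mc[!is.na(mc)], ks), x = 1,
                              dims = c(length(mc), length(ks)))
  pooled <- as.matrix(m$counts %*% ind)
  tot <- colSums(pooled)
  if (any(tot == 0)) stop("metacell with zero total UMIs")
  p <- sweep(pooled, 2, tot, "/")
  dimnames(p) <- list(m$gene_ids, ks)
  p
}

.match_mc <- function(m, assignment) {
  if (!identical(assignment$cell_ids, m$cell_ids)) {
    idx <- match(m$cell_ids, assignment$cell_ids)
    if (anyNA(idx)) stop("assignment does not cover the matrix's cells")
    assignment$mc[idx]
  } else assignment$mc
}

#' Regularized observed/expected fold change per cell and gene
#'
#' `f_gi = log2((1 + u_gi) / (1 + u_i * p_g,mc(i)))` — how far a cell's
#' observed count deviates from the multinomial expectation under its
#' metacell's pool frequency. The +1 regularization caps attainable folds
#' for low-count genes, so only well-supported deviations can score high.
#'
#' @param m a [umi_matrix].
#' @param pfreq pool frequencies from [pool_frequencies()].
#' @param assignment the assignment `pfreq` was computed against.
#' @return a dense genes x cells matrix; columns of unassigned cells are
#'   NA.
#' @export
outlier_fold <- function(m, pfreq, assignment) {
  mc <- .match_mc(m, assignment)
  f <- matrix(NA_real_, nrow(m$counts), ncol(m$counts),
              dimnames = list(m$gene_ids, m$cell_ids))
  assigned <- which(!is.na(mc))
  col <- match(as.character(mc[assigned]), colnames(pfreq))
  expected <- sweep(pfreq[, col, drop = FALSE], 2,
                    m$cell_totals[assigned], "*")
  f[, assigned] <- log2((1 + as.matrix(m$counts[, assigned, drop = FALSE])) /
                        (1 + expected))
  f
}

#' Flag parametric outlier cells
#'
#' A single pass over the cover: pool frequencies are computed once, and
#' every cell showing at least one gene with fold deviation
#' `f_gi >= t_lfc` (inclusive, i.e. `2^t_lfc`-fold or more enrichment over
#' its metacell model) is moved from its metacell into the outlier set.
#' Frequencies are deliberately not re-pooled after removal.
#'
#' @param m a [umi_matrix].
#' @param assignment an `mc_assignment`.
#' @param t_lfc fold threshold (default 3, i.e. 8-fold).
#' @return a list: `assignment` (with flagged cells set to NA),
#'   `outliers` (cell ids), and `report` — a data.frame (cell, metacell,
#'   top offending gene, its f value) for every flagged cell.
#' @export
filter_outliers <- function(m, assignment, t_lfc = 3) {
  stopifnot(t_lfc > 0)
  pfreq <- pool_frequencies(m, assignment)
  f <- outlier_fold(m, pfreq, assignment)
  mc <- .match_mc(m, assignment)
  fmax <- suppressWarnings(apply(f, 2, max, na.rm = TRUE))
  fmax[!is.finite(fmax)] <- -Inf
  flagged <- which(!is.na(mc) & fmax >= t_lfc)
  top_gene <- if (length(flagged))
    m$gene_ids[apply(f[, flagged, drop = FALSE], 2, which.max)]
  else character(0)
  report <- data.frame(cell = m$cell_ids[flagged],
                       metacell = mc[flagged], top_gene = top_gene,
                       f = fmax[flagged], row.names = NULL,
                       stringsAsFactors = FALSE)
  new_mc <- mc
  new_mc[flagged] <- NA_integer_
  emptied <- setdiff(unique(mc[!is.na(mc)]), unique(new_mc[!is.na(new_mc)]))
  if (length(emptied))
    warning("outlier filtering emptied metacell(s): ",
            paste(emptied, collapse = ", "))
  list(assignment = .assignment(ifelse(is.na(new_mc), -1L, new_mc - 1L),
                                m$cell_ids),
       outliers = m$cell_ids[flagged], report = report)
}

# DBSCAN on a precomputed distance matrix. Core points have at least
# min_pts points (self included) within eps; clusters grow by BFS over
# core points; border points join the first core cluster that reaches
# them; label 0 = noise.
dbscan_dist <- function(d, eps, min_pts) {
  n <- nrow(d)
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, 1L) >= min_pts
  labels <- rep(0L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      for (j in nb[[q]]) {
        if (labels[j] == 0L) {
          labels[j] <- cl
          if (core[j]) queue <- c(queue, j)
        }
      }
    }
  }
  labels
}

#' Split heterogeneous metacells
#'
#' Screens every metacell for hidden substructure by clustering its cells
#' de novo: genes with high intra-metacell normalized variance/mean
#' (> `var_mean_min`, computed on depth-equalized counts) are selected,
#' correlation distances on the log-transformed counts restricted to those
#' genes are fed to DBSCAN, and when more than one cluster emerges the
#' metacell is split accordingly (noise points stay with the largest
#' cluster, so the cover is preserved). Metacells with fewer than
#' `dbscan_min_pts` cells, or without enough variable genes, are left
#' intact. In a sound cover splits should almost never fire; the step is
#' mostly a homogeneity validation.
#'
#' @param m a [umi_matrix].
#' @param assignment an `mc_assignment`.
#' @param var_mean_min variance/mean gate for intra-metacell variable
#'   genes (default 1.2).
#' @param dbscan_eps DBSCAN radius on correlation distance; `NULL`
#'   (default) uses the largest of the per-cell `min_pts`-th
#'   nearest-neighbor distances, so every cell is a core point and the
#'   metacell splits only when sub-populations are separated by more than
#'   any local neighborhood radius — robust to unbalanced mixtures while
#'   keeping homogeneous metacells whole.
#' @param dbscan_min_pts DBSCAN core size (default 4).
#' @param min_size optional minimum size for split-off pieces; smaller
#'   pieces become outliers (unassigned) instead of undersized metacells
#'   — they are exactly the rare distinct states too scarce to support a
#'   metacell of their own. The largest piece always keeps the original
#'   label. `NULL` keeps every piece.
#' @param rng_seed seed for the per-metacell down-sampling.
#' @return a list: `assignment` (relabeled, labels compacted) and
#'   `n_split` — how many metacells were split.
#' @export
split_heterogeneous <- function(m, assignment, var_mean_min = 1.2,
                                dbscan_eps = NULL, dbscan_min_pts = 4,
                                min_size = NULL, rng_seed = 1) {
  stopifnot(var_mean_min > 0)
  mc <- .match_mc(m, assignment)
  new_mc <- mc
  next_label <- max(mc, na.rm = TRUE)
  n_split <- 0L
  for (k in sort(unique(mc[!is.na(mc)]))) {
    cells <- which(!is.na(mc) & mc == k)
    if (length(cells) < dbscan_min_pts) next
    sub <- subset_umi(m, cells = cells)
    ds <- downsample_cells(sub, rng_seed = rng_seed + k)
    dcnt <- as.matrix(ds$counts)
    vm <- apply(dcnt, 1, stats::var) / pmax(rowMeans(dcnt), .Machine$double.eps)
    genes <- which(rowMeans(dcnt) > 0 & vm > var_mean_min)
    if (length(genes) < 2) next
    x <- log2(1 + dcnt[genes, , drop = FALSE])
    r <- suppressWarnings(stats::cor(x))
    r[is.na(r)] <- 0
    d <- 1 - r
    eps <- if (is.null(dbscan_eps)) {
      # largest min_pts-th nearest-neighbor distance: every cell is a core
      # point, so the metacell splits only when groups are separated by
      # more than any local neighborhood radius
      knn_d <- apply(d, 1, function(v) sort(v)[min(dbscan_min_pts + 1,
                                                   length(v))])
      max(knn_d)
    } else dbscan_eps
    labels <- dbscan_dist(d, eps, dbscan_min_pts)
    found <- setdiff(unique(labels), 0L)
    if (length(found) < 2) next
    # noise points go to the largest cluster; the largest cluster keeps k
    main <- found[which.max(tabulate(factor(labels, levels = found)))]
    labels[labels == 0L] <- main
    for (cl in setdiff(found, main)) {
      piece <- cells[labels == cl]
      if (!is.null(min_size) && length(piece) < min_size) {
        new_mc[piece] <- NA_integer_
      } else {
        next_label <- next_label + 1L
        new_mc[piece] <- next_label
      }
    }
    n_split <- n_split + 1L
  }
  out <- ifelse(is.na(new_mc), -1L, new_mc - 1L)
  list(assignment = .assignment(out, m$cell_ids), n_split = n_split)
}

#' Assemble a metacell cover
#'
#' Final container tying an assignment to its outlier provenance: every
#' cell is either in exactly one metacell or in the outlier set, flagged
#' as a `parametric` outlier (fold-deviation filter) or a
#' `small_component` outlier (left unassigned by the partitioner).
#'
#' @param assignment an `mc_assignment`.
#' @param parametric_outliers cell ids removed by [filter_outliers()].
#' @return an object of class `metacell_cover` with fields `cell_ids`,
#'   `mc` (NA for outliers), `outlier_type` (NA for assigned cells),
#'   `n_mcs`.
#' @export
metacell_cover <- function(assignment, parametric_outliers = character(0)) {
  mc <- assignment$mc
  otype <- rep(NA_character_, length(mc))
  out <- is.na(mc)
  otype[out] <- ifelse(assignment$cell_ids[out] %in% parametric_outliers,
                       "parametric", "small_component")
  structure(list(cell_ids = assignment$cell_ids, mc = mc,
                 outlier_type = otype,
                 n_mcs = length(unique(mc[!is.na(mc)]))),
            class = "metacell_cover")
}

#' @export
print.metacell_cover <- function(x, ...) {
  cat(sprintf("metacell_cover: %d cells in %d metacells; %d outliers (%d parametric)\n",
              sum(!is.na(x$mc)), x$n_mcs, sum(is.na(x$mc)),
              sum(x$outlier_type == "parametric", na.rm = TRUE)))
  invisible(x)
}

#' Drop metacells by id (manual curation, e.g. doublet metacells)
#'
#' @param cover a `metacell_cover`.
#' @param mc_ids integer labels to dissolve; their cells become parametric
#'   outliers.
#' @return a `metacell_cover` with compacted labels.
#' @export
drop_metacells <- function(cover, mc_ids) {
  hit <- !is.na(cover$mc) & cover$mc %in% mc_ids
  cover$mc[hit] <- NA_integer_
  cover$outlier_type[hit] <- "parametric"
  keep <- sort(unique(cover$mc[!is.na(cover$mc)]))
  cover$mc <- match(cover$mc, keep)
  cover$n_mcs <- length(keep)
  cover
}

#' Write the outlier report TSV (cell, metacell, top offending gene, f)
#' @param report the `report` element of [filter_outliers()]'s result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_outlier_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
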