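#' Graph closure of each metacell
#'
#' Fraction of a metacell's incident edges (positive-weight directed edges
#' of the balanced graph touching at least one member cell) that have both
#' endpoints inside the metacell. High closure means the metacell is
#' graph-isolated; low closure marks metacells embedded in a larger
#' connected neighborhood.
#'
#' @param g a `balanced_graph` (or sparse adjacency).
#' @param cover a `metacell_cover` or `mc_assignment`.
#' @return a named numeric vector, one value in `[0, 1]` per metacell; NA
#'   for metacells with no incident edge.
#' @export
mc_closure <- function(g, cover) {
  adj <- .as_adj(g)
  tm <- methods::as(adj, "TsparseMatrix")
  src <- cover$mc[tm@i + 1L]
  dst <- cover$mc[tm@j + 1L]
  ks <- sort(unique(cover$mc[!is.na(cover$mc)]))
  out <- vapply(ks, function(k) {
    ins <- sum(!is.na(src) & !is.na(dst) & src == k & dst == k)
    inc <- sum((!is.na(src) & src == k) | (!is.na(dst) & dst == k))
    if (inc == 0) NA_real_ else ins / inc
  }, numeric(1))
  names(out) <- ks
  out
}

# Null draws of per-cell counts for one gene, conditional on its total s
# within a metacell of n_cells cells down-sampled to T molecules each.
# Under multinomial sampling the conditional law is multivariate
# hypergeometric (s molecules spread over n_cells * T slots, T per cell);
# for sparse genes the with-replacement (multinomial) placement is an
# excellent and much cheaper approximation.
.null_placement <- function(s, n_cells, T, n_draws) {
  if (s / (n_cells * T) < 0.005)
    return(stats::rmultinom(n_draws, s, rep(1 / n_cells, n_cells)))
  C <- matrix(0L, n_cells, n_draws)
  s_rem <- rep(s, n_draws)
  slots_left <- n_cells * T
  for (i in seq_len(n_cells - 1)) {
    slots_left <- slots_left - T
    ci <- stats::rhyper(n_draws, T, slots_left, s_rem)
    C[i, ] <- ci
    s_rem <- s_rem - ci
  }
  C[n_cells, ] <- s_rem
  C
}

#' Multinomial adherence diagnostics per gene and metacell
#'
#' Quantifies how well each metacell behaves like repeated multinomial
#' sampling from one RNA pool. Within each metacell, cells are
#' down-sampled to uniform totals `T` and each gene is scored by the
#' binomial log-likelihood of its per-cell counts and by its
#' over-dispersion (observed / expected binomial variance, averaged over
#' `n_downsamples` independent down-samples). The empirical p-value is an
#' exact conditional test: given the gene's total `s` in the down-sampled
#' metacell, multinomial sampling makes the cells exchangeable and the
#' null placement of the `s` molecules over cells is multivariate
#' hypergeometric, independent of the unknown pool frequency — so the
#' observed likelihood is ranked among `n_null` such placements with no
#' plug-in bias. Ties are broken by a randomized p-value (uniform under
#' the null), floored at `1/(n_null + 1)`. Genes absent from the
#' down-sampled metacell get NA. The report also carries per-metacell
#' coefficient-of-variation and zero-fraction curves against their
#' Poisson expectations.
#'
#' @param m a [umi_matrix].
#' @param cover a `metacell_cover` or `mc_assignment`.
#' @param genes gene ids to score (typically features plus enriched
#'   genes); `NULL` scores all genes.
#' @param n_null number of null draws (default 999).
#' @param n_downsamples down-samples averaged for over-dispersion
#'   (default 10).
#' @param min_cells smallest metacell scored (default 3).
#' @param rng_seed integer seed.
#' @return an object of class `adherence_report`: list with `gene_mc`
#'   (data.frame: gene, mc, p_value, over_dispersion, mean_count) and
#'   `poisson` (data.frame: mc, gene, mean, cv_obs, cv_poisson, zero_obs,
#'   zero_poisson).
#' @export
binomial_adherence <- function(m, cover, genes = NULL, n_null = 999,
                               n_downsamples = 10, min_cells = 3,
                               rng_seed = 1) {
  mc <- .match_mc(m, cover)
  gids <- feature_ids(genes, m)
  ks <- sort(unique(mc[!is.na(mc)]))
  gene_mc <- list(); poisson <- list()
  for (k in ks) {
    cells <- which(!is.na(mc) & mc == k)
    if (length(cells) < min_cells) next
    sub <- subset_umi(m, genes = gids, cells = cells)
    T <- min(sub$cell_totals)
    n_c <- length(cells)
    if (T < 1) next
    phat_pool <- sub$gene_totals / sum(sub$gene_totals)

    # canonical down-sample scored for the p-value; further ones for the
    # over-dispersion average
    od_acc <- matrix(NA_real_, length(gids), n_downsamples)
    mean_ds <- rep(NA_real_, length(gids))
    cv_obs <- zero_obs <- rep(NA_real_, length(gids))
    dc1 <- NULL
    with_rng_seed(rng_seed + 7919L * k, {
      for (d in seq_len(n_downsamples)) {
        dc <- as.matrix(downsample_cells(sub, target = T,
                                         rng_seed = stats::runif(1, 1, 2^30))$counts)
        rs <- rowSums(dc)
        ph <- rs / (n_c * T)
        vv <- apply(dc, 1, stats::var)
        expv <- T * ph * (1 - ph)
        od_acc[, d] <- ifelse(expv > 0, vv / expv, NA_real_)
        if (d == 1) {
          dc1 <- dc
          mean_ds <- rs / n_c
          cv_obs <- ifelse(rs > 0, sqrt(vv) / (rs / n_c), NA_real_)
          zero_obs <- rowMeans(dc == 0)
        }
      }
      # exact conditional null: given a gene's total s in the down-sampled
      # metacell, cells are exchangeable and the binomial log-likelihood
      # reduces (up to a constant in s) to sum_i lchoose(T, c_i); the
      # observed value is ranked among n_null conditional placements.
      # Rounding to 1e-6 merges float noise so identical count multisets
      # tie exactly; ties are broken by a randomized p-value.
      pv <- rep(NA_real_, length(gids))
      s_all <- rowSums(dc1)
      lc <- lchoose(T, 0:min(T, max(s_all)))
      for (gi in which(s_all > 0)) {
        s <- s_all[gi]
        C <- .null_placement(s, n_c, T, n_null)
        stat_null <- round(colSums(matrix(lc[C + 1L], n_c, n_null)), 6)
        stat_obs <- round(sum(lc[dc1[gi, ] + 1L]), 6)
        r <- sum(stat_null < stat_obs); t <- sum(stat_null == stat_obs)
        pv[gi] <- min(1, max((r + stats::runif(1) * (1 + t)) / (n_null + 1),
                             1 / (n_null + 1)))
      }
    })
    od <- rowMeans(od_acc, na.rm = TRUE)
    od[is.nan(od)] <- NA_real_
    gene_mc[[length(gene_mc) + 1L]] <- data.frame(
      gene = gids, mc = k, p_value = pv, over_dispersion = od,
      mean_count = mean_ds, stringsAsFactors = FALSE)
    poisson[[length(poisson) + 1L]] <- data.frame(
      mc = k, gene = gids, mean = mean_ds, cv_obs = cv_obs,
      cv_poisson = ifelse(mean_ds > 0, 1 / sqrt(mean_ds), NA_real_),
      zero_obs = zero_obs, zero_poisson = exp(-mean_ds),
      stringsAsFactors = FALSE)
  }
  structure(list(gene_mc = do.call(rbind, gene_mc),
                 poisson = do.call(rbind, poisson),
                 n_null = n_null, n_downsamples = n_downsamples),
            class = "adherence_report")
}

#' @export
print.adherence_report <- function(x, ...) {
  gm <- x$gene_mc
  cat(sprintf("adherence_report: %d gene x metacell scores (%d metacells); median over-dispersion %.2f\n",
              nrow(gm), length(unique(gm$mc)),
              stats::median(gm$over_dispersion, na.rm = TRUE)))
  invisible(x)
}

#' Write the over-dispersion heatmap table (genes x metacells)
#' @param report an `adherence_report`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_adherence <- function(report, path) {
  gm <- report$gene_mc
  wide <- stats::reshape(gm[, c("gene", "mc", "over_dispersion")],
                         idvar = "gene", timevar = "mc", direction = "wide")
  utils::write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Within-metacell residual gene-gene correlations
#'
#' Averages gene-gene Pearson correlation matrices of log-transformed,
#' depth-equalized counts across metacells, and compares them with the
#' same computation after a seeded permutation of the metacell labels
#' (the global baseline). Genes with zero variance inside a metacell
#' contribute 0 to the average for their pairs. Residual structure above
#' the shuffled baseline indicates transcriptional variation the cover
#' did not absorb.
#'
#' @param m a [umi_matrix].
#' @param cover a `metacell_cover` or `mc_assignment`.
#' @param genes gene ids to correlate (`NULL` = all).
#' @param min_cells smallest metacell used (default 3).
#' @param rng_seed seed for the down-sampling and the label permutation.
#' @return a list with matrices `within` and `shuffled`.
#' @export
intra_mc_correlations <- function(m, cover, genes = NULL, min_cells = 3,
                                  rng_seed = 1) {
  mc <- .match_mc(m, cover)
  gids <- feature_ids(genes, m)
  avg_for <- function(labels, seed_off) {
    acc <- matrix(0, length(gids), length(gids))
    nmc <- 0L
    for (k in sort(unique(labels[!is.na(labels)]))) {
      cells <- which(!is.na(labels) & labels == k)
      if (length(cells) < min_cells) next
      sub <- subset_umi(m, genes = gids, cells = cells)
      ds <- downsample_cells(sub, rng_seed = rng_seed + seed_off + k)
      x <- log2(1 + as.matrix(ds$counts))
      r <- suppressWarnings(stats::cor(t(x)))
      r[is.na(r)] <- 0
      diag(r) <- 1
      acc <- acc + r
      nmc <- nmc + 1L
    }
    if (nmc == 0L) stop("no metacell with >= ", min_cells, " cells")
    acc / nmc
  }
  within <- avg_for(mc, 0L)
  shuffled_mc <- with_rng_seed(rng_seed, sample(mc))
  shuffled <- avg_for(shuffled_mc, 1000L)
  dimnames(within) <- dimnames(shuffled) <- list(gids, gids)
  list(within = within, shuffled = shuffled)
}

# regularized geometric-mean pool frequency of the prediction formula:
# (exp[weighted mean of log2(1 + mult * u)] - 1) / weighted mean depth
.pool_predict <- function(log_sums, depth_sums, n_pool) {
  pred <- (exp(log_sums / n_pool) - 1) / (depth_sums / n_pool)
  pred[!is.finite(pred)] <- NA_real_
  pred
}

#' Cross-validated expression prediction
#'
#' Measures how well a similarity structure captures local manifold
#' geometry: genes are split into `n_folds` folds; for each fold the raw
#' similarity matrix (and, for the metacell strategy, a fresh graph
#' partition) is rebuilt on the remaining genes only, and each held-out
#' gene's per-cell frequency is predicted from a pool around the cell —
#' its metacell (`mc_pool`) or its `n_neighbors` nearest raw-similarity
#' neighbors (`raw_knn_pool`). A cell is never part of its own pool. Pool
#' frequencies use the regularized geometric mean
#' `(exp[mean log2(1 + pool_multiplier * u)] - 1) / mean depth`. With
#' `cross_validate = FALSE` the similarities are built once on all genes
#' (the over-fitting regime). Per gene, the report gives the Pearson
#' correlation between predicted and observed (`u_gi / u_i`) frequencies
#' across cells.
#'
#' @param m a [umi_matrix].
#' @param n_folds gene folds (default 100).
#' @param n_neighbors pool size of the raw-knn strategy (default 50).
#' @param pool_multiplier the multiplier inside the log of the pool
#'   formula (default 7).
#' @param strategies subset of `c("mc_pool", "raw_knn_pool")`.
#' @param cross_validate rebuild similarities per fold (TRUE) or fit and
#'   predict on all genes (FALSE).
#' @param K,alpha,beta,size_min,stickiness,max_passes graph/partition
#'   parameters used to rebuild the metacell cover per fold (a direct
#'   seed + optimize partition of the balanced graph).
#' @param eps log-transform regularizer for the similarities.
#' @param rng_seed integer seed.
#' @return an object of class `cv_report`: data.frame with per-gene
#'   `mean_expr` (UMI per cell) and one correlation column per strategy.
#' @export
cv_predict <- function(m, n_folds = 100, n_neighbors = 50,
                       pool_multiplier = 7,
                       strategies = c("mc_pool", "raw_knn_pool"),
                       cross_validate = TRUE, K = 100, alpha = 10, beta = 3,
                       size_min = max(2, round(K / 4)), stickiness = 1.01,
                       max_passes = 50, eps = 1, rng_seed = 1) {
  strategies <- match.arg(strategies, several.ok = TRUE)
  ng <- length(m$gene_ids); n <- length(m$cell_ids)
  if (cross_validate && ng < n_folds)
    stop("need at least n_folds genes")
  obs_freq <- t(t(as.matrix(m$counts)) / m$cell_totals)
  fold_of <- if (cross_validate)
    with_rng_seed(rng_seed, sample(rep_len(seq_len(n_folds), ng)))
  else rep(1L, ng)
  n_folds_eff <- if (cross_validate) n_folds else 1L

  pred_mc <- pred_knn <- matrix(NA_real_, ng, n,
                                dimnames = dimnames(obs_freq))
  logc <- log2(1 + pool_multiplier * as.matrix(m$counts))
  depth <- m$cell_totals

  for (fold in seq_len(n_folds_eff)) {
    held <- if (cross_validate) which(fold_of == fold) else seq_len(ng)
    train_genes <- if (cross_validate) m$gene_ids[-held] else m$gene_ids
    if (length(train_genes) < 2) stop("fold leaves fewer than 2 genes")
    r <- raw_similarity(m, train_genes, eps = eps)
    if ("mc_pool" %in% strategies) {
      g <- balance_graph(rank_rows(r), K = K, alpha = alpha, beta = beta)
      a <- partition_graph(g, size_min = size_min, max_passes = max_passes,
                           stickiness = stickiness,
                           rng_seed = rng_seed + fold)
      mcv <- a$mc
      for (k in sort(unique(mcv[!is.na(mcv)]))) {
        cells <- which(!is.na(mcv) & mcv == k)
        nk <- length(cells)
        if (nk < 2) next
        ls <- rowSums(logc[held, cells, drop = FALSE])
        dsum <- sum(depth[cells])
        for (ci in seq_along(cells)) {
          i <- cells[ci]
          pred_mc[held, i] <- .pool_predict(ls - logc[held, i],
                                            dsum - depth[i], nk - 1)
        }
      }
    }
    if ("raw_knn_pool" %in% strategies) {
      diag(r) <- -Inf
      nb <- apply(r, 1, function(v) order(v, decreasing = TRUE)[seq_len(n_neighbors)])
      w <- Matrix::sparseMatrix(i = as.vector(nb),
                                j = rep(seq_len(n), each = n_neighbors),
                                x = 1, dims = c(n, n))
      ls <- logc[held, , drop = FALSE] %*% w
      dsum <- as.vector(depth %*% w)
      pred_knn[held, ] <- as.matrix(
        t(t(exp(as.matrix(ls) / n_neighbors) - 1) / (dsum / n_neighbors)))
    }
  }
  res <- data.frame(gene = m$gene_ids,
                    mean_expr = m$gene_totals / n,
                    stringsAsFactors = FALSE)
  safe_cor <- function(pred) {
    vapply(seq_len(ng), function(g) {
      ok <- !is.na(pred[g, ])
      if (sum(ok) < 3 || stats::sd(pred[g, ok]) == 0 ||
          stats::sd(obs_freq[g, ok]) == 0) return(NA_real_)
      stats::cor(pred[g, ok], obs_freq[g, ok])
    }, numeric(1))
  }
  if ("mc_pool" %in% strategies) res$cor_mc <- safe_cor(pred_mc)
  if ("raw_knn_pool" %in% strategies) res$cor_knn <- safe_cor(pred_knn)
  class(res) <- c("cv_report", "data.frame")
  res
}

#' Write a CV report TSV (gene, mean expression, correlation per strategy)
#' @param report a `cv_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
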