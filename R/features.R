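#' Per-gene statistics for feature-gene selection
#'
#' Computes, for every gene, the statistics the selection step thresholds
#' on:
#' \describe{
#'   \item{`total`}{total UMIs across all cells.}
#'   \item{`n_cells_at_min`}{number of cells with at least
#'     `min_umi_per_cell` UMIs of the gene.}
#'   \item{`size_corr`, `size_corr_norm`}{Pearson correlation of the
#'     gene's counts with the per-cell totals (depth); the normalized form
#'     subtracts the mean raw correlation of expression-matched genes
#'     (20 equal-occupancy bins by gene total), removing the trend that
#'     ties raw size correlation to mean expression.}
#'   \item{`niche`}{fraction of the gene's UMIs carried by its top 5%
#'     highest-count cells, minus the expectation of that fraction under
#'     multinomial sampling (deterministic Poisson order-statistic
#'     approximation at the gene's mean rate). High values mark genes
#'     concentrated in a small cell niche.}
#'   \item{`var_mean`}{variance/mean ratio of depth-equalized
#'     (down-sampled) counts; 0 for genes absent after down-sampling.}
#' }
#' All-zero genes get 0 for every statistic, never NaN.
#'
#' @param m a [umi_matrix].
#' @param min_umi_per_cell count threshold used for `n_cells_at_min`
#'   (default 3).
#' @param top_frac niche-cell fraction (default 0.05).
#' @param n_bins expression bins for size-correlation normalization.
#' @param ds_target depth for the var/mean down-sampling; defaults to the
#'   minimum cell total.
#' @param rng_seed seed for the down-sampling draw.
#' @return a data.frame with one row per gene.
#' @export
gene_stats <- function(m, min_umi_per_cell = 3, top_frac = 0.05, n_bins = 20,
                       ds_target = NULL, rng_seed = 1) {
  stopifnot(inherits(m, "umi_matrix"))
  n <- length(m$cell_ids)
  if (n < 2) stop("gene statistics need at least 2 cells")
  cnt <- as.matrix(m$counts)
  tot <- m$gene_totals
  nonzero <- tot > 0

  n_at_min <- rowSums(cnt >= min_umi_per_cell)

  # raw size correlation: cor of u_gi with cell depth u_i
  depth <- m$cell_totals
  sds <- apply(cnt, 1, stats::sd)
  size_corr <- rep(0, length(tot))
  ok <- nonzero & sds > 0 & stats::sd(depth) > 0
  if (any(ok))
    size_corr[ok] <- suppressWarnings(
      as.vector(stats::cor(t(cnt[ok, , drop = FALSE]), depth)))
  size_corr[is.na(size_corr)] <- 0

  # center against expression-matched genes: 20 equal-occupancy bins
  size_corr_norm <- size_corr
  if (sum(nonzero) >= 2) {
    nb <- min(n_bins, sum(nonzero))
    br <- unique(stats::quantile(tot[nonzero], probs = seq(0, 1, length.out = nb + 1)))
    bin <- findInterval(tot[nonzero], br, rightmost.closed = TRUE,
                        all.inside = TRUE)
    bin_mean <- tapply(size_corr[nonzero], bin, mean)
    size_corr_norm[nonzero] <- size_corr[nonzero] - bin_mean[as.character(bin)]
  }

  # niche score
  m_top <- max(1L, ceiling(top_frac * n))
  obs_frac <- rep(0, length(tot))
  if (any(nonzero)) {
    srt <- apply(cnt[nonzero, , drop = FALSE], 1, function(x)
      sum(sort.int(x, decreasing = TRUE)[seq_len(m_top)]))
    obs_frac[nonzero] <- srt / tot[nonzero]
  }
  exp_frac <- vapply(tot, .poisson_top_frac, numeric(1),
                     n_cells = n, m_top = m_top)
  niche <- ifelse(nonzero, obs_frac - exp_frac, 0)

  # var/mean on depth-equalized counts
  ds <- downsample_cells(m, target = ds_target, rng_seed = rng_seed)
  dcnt <- as.matrix(ds$counts)
  dmean <- rowMeans(dcnt)
  dvar <- apply(dcnt, 1, stats::var)
  var_mean <- ifelse(dmean > 0, dvar / dmean, 0)

  data.frame(gene = m$gene_ids, total = tot, n_cells_at_min = n_at_min,
             size_corr = size_corr, size_corr_norm = size_corr_norm,
             niche = niche, var_mean = var_mean,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Expected fraction of a gene's UMIs inside its m_top highest-count cells
# under multinomial sampling, approximating per-cell counts as iid
# Poisson(total/n). Threshold form of the expected sum of the m largest of
# n iid draws: choose t with n*P(X > t) <= m_top < n*P(X >= t); the top
# cells then take all mass above t plus the remainder at t.
.poisson_top_frac <- function(total, n_cells, m_top) {
  if (total <= 0) return(0)
  lam <- total / n_cells
  xmax <- max(10, stats::qpois(1 - 1e-12, lam))
  x <- 0:xmax
  px <- stats::dpois(x, lam)
  p_gt <- rev(cumsum(rev(px))) - px          # P(X > x)
  t <- x[which(n_cells * p_gt <= m_top)[1]]
  e_above <- n_cells * sum(x[x > t] * px[x > t])
  e_at_t <- (m_top - n_cells * p_gt[t + 1]) * t
  min(1, (e_above + e_at_t) / total)
}

#' Select feature genes
#'
#' A gene enters the feature set F iff all of:
#' 1. `size_corr_norm < size_corr_max` OR `niche > niche_score_min`
#'    (replaced by `var_mean >= var_mean_min` when that is given),
#' 2. `total >= min_total_umi`,
#' 3. at least `min_cells_at_min` cells carry `>= min_umi_per_cell` UMIs
#'    (as tabulated by [gene_stats()]),
#' 4. the gene is not blacklisted.
#'
#' @param stats the data.frame from [gene_stats()].
#' @param min_total_umi default 300.
#' @param min_cells_at_min default 3.
#' @param size_corr_max default -0.1.
#' @param niche_score_min default 0.1.
#' @param var_mean_min optional; when set, replaces criterion 1.
#' @param gene_blacklist gene ids never selected (e.g. ribosomal proteins).
#' @return an object of class `feature_set`: list with `gene_ids` and the
#'   per-gene `stats` table of the selected genes.
#' @export
select_features <- function(stats, min_total_umi = 300, min_cells_at_min = 3,
                            size_corr_max = -0.1, niche_score_min = 0.1,
                            var_mean_min = NULL, gene_blacklist = NULL) {
  crit1 <- if (is.null(var_mean_min))
    (stats$size_corr_norm < size_corr_max) | (stats$niche > niche_score_min)
  else stats$var_mean >= var_mean_min
  keep <- crit1 &
    stats$total >= min_total_umi &
    stats$n_cells_at_min >= min_cells_at_min &
    !(stats$gene %in% gene_blacklist)
  if (!any(keep))
    stop("no gene passed feature selection; relax the thresholds ",
         "(e.g. lower min_total_umi or niche_score_min)")
  out <- list(gene_ids = stats$gene[keep], stats = stats[keep, , drop = FALSE])
  class(out) <- "feature_set"
  out
}

#' Construct a feature set from explicit gene ids
#'
#' Useful when the feature genes are fixed by the study design (marker
#' panels, calibration runs on data without informative genes) rather
#' than selected from statistics.
#'
#' @param gene_ids character vector of gene identifiers.
#' @param stats optional per-gene statistics table.
#' @return a `feature_set`.
#' @export
feature_set <- function(gene_ids, stats = NULL) {
  stopifnot(is.character(gene_ids), length(gene_ids) > 0)
  structure(list(gene_ids = gene_ids,
                 stats = stats %||% data.frame(gene = gene_ids)),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("feature_set: %d genes\n", length(x$gene_ids)))
  invisible(x)
}

#' Write a feature set as a one-column gene list plus a statistics TSV
#' @param fs a `feature_set`.
#' @param path output path for the gene list; the statistics table is
#'   written alongside as `<path>.stats.tsv`.
#' @return `path`, invisibly.
#' @export
write_features <- function(fs, path) {
  writeLines(fs$gene_ids, path)
  utils::write.table(fs$stats, paste0(path, ".stats.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
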