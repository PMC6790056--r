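#' Metacell expression profiles (regularized geometric mean)
#'
#' The per-metacell gene intensity is the geometric mean of `1 + u_gi`
#' across member cells, minus 1, normalized by the metacell's mean depth:
#' `p_gk = (exp[mean_i log(1 + u_gi)] - 1) / mean_i(u_i)`.
#' Genes absent from a metacell map to exactly 0. The alternative reading
#' of the regularization (subtracting 1 inside the exponent, which only
#' rescales every value by `exp(-1)`) is available via
#' `regularization = "inside"`.
#'
#' @param m a [umi_matrix].
#' @param cover a `metacell_cover` or `mc_assignment`.
#' @param regularization `"outside"` (default) or `"inside"` — where the
#'   `- 1` of the regularized geometric mean is applied.
#' @return a genes x metacells matrix of regularized frequencies.
#' @export
geometric_profile <- function(m, cover, regularization = c("outside", "inside")) {
  regularization <- match.arg(regularization)
  mc <- .match_mc(m, cover)
  ks <- sort(unique(mc[!is.na(mc)]))
  if (!length(ks)) stop("cover has no non-empty metacell")
  logc <- log1p(as.matrix(m$counts))          # log(1 + u)
  p <- matrix(0, nrow(logc), length(ks),
              dimnames = list(m$gene_ids, ks))
  for (j in seq_along(ks)) {
    cells <- which(!is.na(mc) & mc == ks[j])
    gm <- rowMeans(logc[, cells, drop = FALSE])
    mean_depth <- mean(m$cell_totals[cells])
    p[, j] <- if (regularization == "outside") (exp(gm) - 1) / mean_depth
              else exp(gm - 1) / mean_depth
  }
  p
}

#' Log fold enrichment over the across-metacell median
#'
#' `lfp_gk = log2((p_gk + eps) / median_k'(p_gk' + eps))`. With an odd
#' number of metacells every gene's median lfp is exactly 0. Values are
#' comparable across metacells of one dataset but shift by an additive
#' constant when the metacell composition changes.
#'
#' @param p a genes x metacells profile matrix ([geometric_profile()]).
#' @param eps regularizer (default 1e-4); adapt to the typical metacell
#'   molecule total.
#' @return a genes x metacells matrix of log2 enrichments.
#' @export
lfp_table <- function(p, eps = 1e-4) {
  med <- apply(p + eps, 1, stats::median)
  log2((p + eps) / med)
}

#' Metacell profiles bundle
#'
#' Convenience wrapper computing both the regularized geometric-mean
#' frequencies and their log-fold enrichments.
#'
#' @inheritParams geometric_profile
#' @param eps_lfp regularizer for [lfp_table()].
#' @return an object of class `mc_profile`: list with `p_gk`, `lfp`,
#'   `eps_lfp`.
#' @export
mc_profiles <- function(m, cover, eps_lfp = 1e-4,
                        regularization = c("outside", "inside")) {
  p <- geometric_profile(m, cover, regularization)
  structure(list(p_gk = p, lfp = lfp_table(p, eps_lfp), eps_lfp = eps_lfp),
            class = "mc_profile")
}

#' @export
print.mc_profile <- function(x, ...) {
  cat(sprintf("mc_profile: %d genes x %d metacells (eps = %g)\n",
              nrow(x$p_gk), ncol(x$p_gk), x$eps_lfp))
  invisible(x)
}

#' Top enriched marker genes per metacell (heatmap ordering)
#' @param profile an `mc_profile`.
#' @param n_top genes per metacell (default 5).
#' @return a named list, one character vector of gene ids per metacell,
#'   ordered by decreasing lfp.
#' @export
top_markers <- function(profile, n_top = 5) {
  lfp <- profile$lfp
  out <- lapply(seq_len(ncol(lfp)), function(k)
    rownames(lfp)[order(-lfp[, k])[seq_len(min(n_top, nrow(lfp)))]])
  names(out) <- colnames(lfp)
  out
}

#' Write p_gk and lfp as genes x metacells TSVs
#' @param profile an `mc_profile`.
#' @param prefix output prefix; writes `<prefix>.p_gk.tsv` and
#'   `<prefix>.lfp.tsv`.
#' @return `prefix`, invisibly.
#' @export
write_profiles <- function(profile, prefix) {
  for (what in c("p_gk", "lfp")) {
    tab <- profile[[what]]
    utils::write.table(data.frame(gene = rownames(tab), tab,
                                  check.names = FALSE),
                       paste0(prefix, ".", what, ".tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(prefix)
}
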