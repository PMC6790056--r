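#' Bootstrap resampling of graph partitions
#'
#' Runs the seed + optimize partition on `n_boot` resamples of the
#' balanced graph, each obtained by keeping every cell independently with
#' probability `rho` and inducing the subgraph on the kept cells. Pairwise
#' tallies record how often two cells were co-sampled (`o`) and how often
#' they were co-assigned to one subgraph (`c`); their ratio `s_boot` is
#' the bootstrap co-occurrence frequency. Each resample consumes its own
#' RNG stream derived from `rng_seed`, so the tallies do not depend on
#' execution order.
#'
#' @param g a `balanced_graph` or sparse directed adjacency.
#' @param size_min minimum subgraph size for each resampled partition.
#' @param n_boot number of resamples (default 500).
#' @param rho cell inclusion probability (default 0.75).
#' @param max_passes,stickiness see [optimize_partition()].
#' @param rng_seed global integer seed.
#' @return an object of class `cooc_stats`: list with symmetric integer
#'   matrices `o`, `c`, the frequency matrix `s_boot` (0 where a pair was
#'   never co-sampled), `n_boot`, `n_skipped`, and `cell_ids`.
#' @export
resample_partitions <- function(g, size_min, n_boot = 500, rho = 0.75,
                                max_passes = 50, stickiness = 1.01,
                                rng_seed = 1) {
  stopifnot(n_boot >= 1, rho > 0, rho <= 1)
  adj <- .as_adj(g)
  n <- nrow(adj)
  o <- matrix(0L, n, n)
  cc <- matrix(0L, n, n)
  n_skipped <- 0L
  for (b in seq_len(n_boot)) {
    res <- with_rng_seed(rng_seed + b, {
      keep <- which(stats::runif(n) < rho)
      if (length(keep) < size_min) {
        NULL
      } else {
        sub <- adj[keep, keep, drop = FALSE]
        cs <- graph_csc(sub)
        part <- .cpp_partition(cs$out_p, cs$out_i, cs$out_w, cs$in_p,
                               cs$in_i, cs$in_w, cs$n,
                               as.integer(size_min), as.integer(max_passes),
                               stickiness, integer(0), TRUE, TRUE)
        list(keep = keep, mc = part$mc)
      }
    })
    if (is.null(res)) { n_skipped <- n_skipped + 1L; next }
    .cpp_tally_cooc(res$keep - 1L, res$mc, o, cc)
  }
  if (n_skipped > 0)
    warning(n_skipped, " resample(s) had fewer than size_min cells and were skipped")
  o <- o + t(o); diag(o) <- diag(o) %/% 2L
  cc <- cc + t(cc); diag(cc) <- diag(cc) %/% 2L
  s <- matrix(0, n, n)
  pos <- o > 0
  s[pos] <- cc[pos] / o[pos]
  dimnames(o) <- dimnames(cc) <- dimnames(s) <- dimnames(adj)
  structure(list(o = o, c = cc, s_boot = s, n_boot = n_boot,
                 n_skipped = n_skipped, cell_ids = rownames(adj)),
            class = "cooc_stats")
}

#' @export
print.cooc_stats <- function(x, ...) {
  cat(sprintf("cooc_stats: %d cells, %d resamples (%d skipped)\n",
              length(x$cell_ids), x$n_boot, x$n_skipped))
  invisible(x)
}

#' Threshold the co-occurrence matrix into the consensus graph
#'
#' For each cell `i`, `T_i` is its `k_core`-th largest co-occurrence
#' frequency (or its smallest positive one when the cell has fewer than
#' `k_core` positive co-occurrences). A pair keeps an edge iff
#' `s_boot_ij > max(T_i, T_j) * threshold_factor`. The result is handed
#' back as a symmetric 0/1 directed adjacency (each undirected edge
#' becomes two unit arcs) ready for the partitioner; node degrees are
#' deliberately not capped.
#'
#' @param stats a `cooc_stats`.
#' @param k_core neighbor count defining the per-cell critical value
#'   (default 30).
#' @param threshold_factor multiplier on the pairwise critical value
#'   (default 0.5).
#' @return a sparse symmetric 0/1 adjacency matrix (`dgCMatrix`).
#' @export
cooc_graph <- function(stats, k_core = 30, threshold_factor = 0.5) {
  stopifnot(inherits(stats, "cooc_stats"), k_core >= 1,
            threshold_factor > 0, threshold_factor <= 1)
  s <- stats$s_boot
  n <- nrow(s)
  ti <- numeric(n)
  for (i in seq_len(n)) {
    v <- s[i, -i]
    pos <- v[v > 0]
    ti[i] <- if (!length(pos)) Inf
             else if (length(pos) < k_core) min(pos)
             else sort.int(pos, decreasing = TRUE)[k_core]
  }
  thr <- outer(ti, ti, pmax) * threshold_factor
  keep <- s > thr
  diag(keep) <- FALSE
  adj <- methods::as(Matrix::drop0(keep * 1), "CsparseMatrix")
  dimnames(adj) <- dimnames(s)
  adj
}

#' Final consensus partition
#'
#' Re-applies the seed + optimize partition algorithm to the consensus
#' co-occurrence graph. Cells in components smaller than `size_min` end up
#' unassigned (outliers). With `enforce_min_size = TRUE` (default),
#' subgraphs that shrank below `size_min` during optimization are
#' dissolved and their members reassigned by further optimization sweeps,
#' so every reported metacell meets the minimum size; dissolved cells with
#' no remaining connection become outliers.
#'
#' @param g_boot adjacency from [cooc_graph()].
#' @param size_min minimum metacell size (default 30).
#' @param max_passes,stickiness,rng_seed see [partition_graph()].
#' @param enforce_min_size dissolve undersized metacells after
#'   optimization (default TRUE).
#' @return an `mc_assignment`.
#' @export
final_partition <- function(g_boot, size_min = 30, max_passes = 100,
                            stickiness = 1.01, rng_seed = 1,
                            enforce_min_size = TRUE) {
  if (!nrow(g_boot)) stop("empty consensus graph")
  a <- partition_graph(g_boot, size_min = size_min, max_passes = max_passes,
                       stickiness = stickiness, rng_seed = rng_seed)
  if (enforce_min_size) {
    for (iter in seq_len(20)) {
      sizes <- table(a$mc)
      small <- as.integer(names(sizes)[sizes < size_min])
      if (!length(small)) break
      a$mc[a$mc %in% small] <- NA_integer_
      if (all(is.na(a$mc))) break
      a <- suppressWarnings(
        optimize_partition(g_boot, a, max_passes = max_passes,
                           stickiness = stickiness,
                           rng_seed = rng_seed + iter))
    }
  }
  a
}

#' Persist co-occurrence tallies as a sparse triplet TSV (i, j, o, c) over
#' pairs with o > 0
#' @param stats a `cooc_stats`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cooc <- function(stats, path) {
  idx <- which(upper.tri(stats$o) & stats$o > 0, arr.ind = TRUE)
  utils::write.table(
    data.frame(i = stats$cell_ids[idx[, 1]], j = stats$cell_ids[idx[, 2]],
               o = stats$o[idx], c = stats$c[idx]),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
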