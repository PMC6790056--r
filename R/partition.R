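# CSC views of a directed weighted adjacency matrix: `out` columns hold
# each node's outgoing edges (CSC of t(adj)), `in` columns its incoming
# edges (CSC of adj itself).
graph_csc <- function(adj) {
  adj <- methods::as(adj, "CsparseMatrix")
  tad <- Matrix::t(adj)
  list(out_p = tad@p, out_i = tad@i, out_w = tad@x,
       in_p = adj@p, in_i = adj@i, in_w = adj@x, n = nrow(adj))
}

.as_adj <- function(g) {
  if (inherits(g, "balanced_graph")) return(g$adj)
  if (!inherits(g, "Matrix")) g <- Matrix::Matrix(g, sparse = TRUE)
  methods::as(methods::as(methods::as(g, "dMatrix"), "generalMatrix"),
              "CsparseMatrix")
}

.assignment <- function(mc0, cell_ids, converged = TRUE, passes = 0L,
                        edge_visits = 0, compact = TRUE) {
  mc <- ifelse(mc0 < 0, NA_integer_, mc0 + 1L)
  if (compact && any(!is.na(mc))) {
    keep <- sort(unique(mc[!is.na(mc)]))
    mc <- match(mc, keep)              # drop empty labels, renumber 1..k
  }
  structure(list(mc = mc, cell_ids = cell_ids,
                 n_mcs = length(unique(mc[!is.na(mc)])),
                 converged = converged, passes = passes,
                 edge_visits = edge_visits),
            class = "mc_assignment")
}

#' @export
print.mc_assignment <- function(x, ...) {
  cat(sprintf("mc_assignment: %d cells in %d subgraphs, %d unassigned%s\n",
              sum(!is.na(x$mc)), x$n_mcs, sum(is.na(x$mc)),
              if (isTRUE(x$converged)) "" else " [not converged]"))
  invisible(x)
}

#' Seed a graph partition by cover-free sampling
#'
#' Iteratively draws seed cells from the uncovered set with probability
#' proportional to the cube of the cover-free score
#' `f(i) = |N_out(i) - C|` (the number of a cell's outgoing neighbors not
#' yet covered), claiming each seed together with its uncovered
#' out-neighbors as a new subgraph, until no uncovered cell retains more
#' than `size_min` uncovered neighbors. Cells left uncovered stay
#' unassigned (`NA`).
#'
#' @param g a `balanced_graph` or a sparse directed adjacency matrix.
#' @param size_min minimum subgraph size (stop criterion), must be below
#'   the graph's K.
#' @param rng_seed integer seed.
#' @return an `mc_assignment`: list with `mc` (integer label per cell, NA
#'   = unassigned), `n_mcs`, and bookkeeping fields.
#' @export
seed_partition <- function(g, size_min, rng_seed = 1) {
  adj <- .as_adj(g)
  cs <- graph_csc(adj)
  res <- with_rng_seed(rng_seed,
    .cpp_partition(cs$out_p, cs$out_i, cs$out_w, cs$in_p, cs$in_i, cs$in_w,
                   cs$n, as.integer(size_min), 0L, 1.0, integer(0),
                   TRUE, FALSE))
  .assignment(res$mc, rownames(adj), compact = FALSE)
}

#' Optimize a seeded partition by association-score sweeps
#'
#' Visits cells in a reshuffled random order each pass and reassigns each
#' to the subgraph `k` maximizing `w_ik = wi_ik * wo_ik / |M_k|^2`, where
#' `wo_ik` / `wi_ik` sum the weights of the cell's outgoing / incoming
#' edges into `M_k`. The score of a cell's current subgraph is multiplied
#' by `stickiness^pass`, which enforces convergence. Ties go to the
#' current subgraph, then the lowest label. Cells whose component was too
#' small to seed remain unassigned and are the partition's outliers.
#'
#' @param g graph as in [seed_partition()].
#' @param assignment an `mc_assignment` (typically from [seed_partition()]).
#' @param max_passes sweep limit (default 50); if reached without a
#'   no-move pass the result carries `converged = FALSE`.
#' @param stickiness per-pass multiplier on the current subgraph's score
#'   (default 1.01, must be >= 1).
#' @param rng_seed integer seed for the sweep order.
#' @return an `mc_assignment` with empty labels compacted away.
#' @export
optimize_partition <- function(g, assignment, max_passes = 50,
                               stickiness = 1.01, rng_seed = 1) {
  stopifnot(inherits(assignment, "mc_assignment"), stickiness >= 1)
  adj <- .as_adj(g)
  cs <- graph_csc(adj)
  init <- ifelse(is.na(assignment$mc), -1L, as.integer(assignment$mc) - 1L)
  res <- with_rng_seed(rng_seed,
    .cpp_partition(cs$out_p, cs$out_i, cs$out_w, cs$in_p, cs$in_i, cs$in_w,
                   cs$n, 0L, as.integer(max_passes), stickiness, init,
                   FALSE, TRUE))
  if (!res$converged)
    warning("optimization did not converge within ", max_passes, " passes")
  .assignment(res$mc, rownames(adj), res$converged, res$passes,
              res$edge_visits)
}

#' Seed and optimize in one call
#'
#' @inheritParams seed_partition
#' @inheritParams optimize_partition
#' @return an `mc_assignment`.
#' @export
partition_graph <- function(g, size_min, max_passes = 50, stickiness = 1.01,
                            rng_seed = 1) {
  adj <- .as_adj(g)
  cs <- graph_csc(adj)
  res <- with_rng_seed(rng_seed,
    .cpp_partition(cs$out_p, cs$out_i, cs$out_w, cs$in_p, cs$in_i, cs$in_w,
                   cs$n, as.integer(size_min), as.integer(max_passes),
                   stickiness, integer(0), TRUE, TRUE))
  if (!res$converged)
    warning("optimization did not converge within ", max_passes, " passes")
  .assignment(res$mc, rownames(adj), res$converged, res$passes,
              res$edge_visits)
}

#' Write an assignment as a two-column TSV (cell id, metacell id; -1 for
#' outliers/unassigned cells)
#' @param a an `mc_assignment` or `metacell_cover`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_assignment <- function(a, path) {
  utils::write.table(
    data.frame(cell = a$cell_ids, metacell = ifelse(is.na(a$mc), -1L, a$mc)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
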