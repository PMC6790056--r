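#' Project balanced-graph edges onto metacell pairs
#'
#' Aggregates the single-cell graph into a metacell-level edge weight
#' matrix `b_ml = K^2 / (|M_m| * |M_l|) * sum_{i in M_m, j in M_l}
#' ceil(a_ij / C)` with `C = median metacell size`, then symmetrizes it as
#' `B' = row-normalized B + column-normalized B`.
#'
#' @param g a `balanced_graph`.
#' @param cover a `metacell_cover` or `mc_assignment`.
#' @return a list with matrices `B` and `Bprime` (metacells x metacells).
#' @export
mc_edge_matrix <- function(g, cover) {
  adj <- .as_adj(g)
  K <- if (inherits(g, "balanced_graph")) g$K else
    max(Matrix::rowSums(adj > 0))
  mc <- cover$mc
  ks <- sort(unique(mc[!is.na(mc)]))
  sizes <- vapply(ks, function(k) sum(mc == k, na.rm = TRUE), numeric(1))
  C <- stats::median(sizes)
  tm <- methods::as(adj, "TsparseMatrix")
  src <- match(mc[tm@i + 1L], ks); dst <- match(mc[tm@j + 1L], ks)
  keep <- !is.na(src) & !is.na(dst)
  B <- matrix(0, length(ks), length(ks), dimnames = list(ks, ks))
  if (any(keep)) {
    agg <- tapply(ceiling(tm@x[keep] / C),
                  list(factor(src[keep], seq_along(ks)),
                       factor(dst[keep], seq_along(ks))), sum)
    agg[is.na(agg)] <- 0
    B <- K^2 * agg / outer(sizes, sizes)
    dimnames(B) <- list(ks, ks)
  }
  rn <- B / pmax(rowSums(B), .Machine$double.eps)
  cn <- t(t(B) / pmax(colSums(B), .Machine$double.eps))
  list(B = B, Bprime = rn + cn)
}

#' Build the metacell graph for layout
#'
#' Candidate edges are off-diagonal pairs with `b' > t_edge`; each
#' metacell contributes its `d_max` best candidates (by `b'`), so the
#' final degree can exceed `d_max` only through edges added by partners.
#' The result may have several connected components.
#'
#' @param bprime the `Bprime` matrix from [mc_edge_matrix()].
#' @param t_edge candidate threshold (default 0.08).
#' @param d_max added edges per metacell (default 4).
#' @return an [igraph::graph] on the metacells (vertex names = labels).
#' @export
build_mc_graph <- function(bprime, t_edge = 0.08, d_max = 4) {
  stopifnot(nrow(bprime) == ncol(bprime), d_max >= 1)
  n <- nrow(bprime)
  edges <- matrix(integer(0), 0, 2)
  for (m in seq_len(n)) {
    cand <- setdiff(which(bprime[m, ] > t_edge), m)
    if (!length(cand)) next
    top <- cand[order(-bprime[m, cand])][seq_len(min(d_max, length(cand)))]
    edges <- rbind(edges, cbind(m, top))
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::V(g)$name <- rownames(bprime) %||% as.character(seq_len(n))
  if (nrow(edges)) {
    und <- unique(t(apply(edges, 1, sort)))
    g <- igraph::add_edges(g, t(und))
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Force-directed layout of the metacell graph
#'
#' Seeded Fruchterman-Reingold embedding; connected components are laid
#' out independently and packed on a grid. A single metacell sits at the
#' origin. Identical seeds give identical coordinates.
#'
#' @param g_m metacell graph from [build_mc_graph()].
#' @param iterations FR iterations (default 500).
#' @param rng_seed integer seed.
#' @return a data.frame with `mc`, `x`, `y`.
#' @export
layout_mcs <- function(g_m, iterations = 500, rng_seed = 1) {
  n <- igraph::vcount(g_m)
  coords <- with_rng_seed(rng_seed, {
    comp <- igraph::components(g_m)
    xy <- matrix(0, n, 2)
    ncomp <- comp$no
    grid <- ceiling(sqrt(ncomp))
    for (ci in seq_len(ncomp)) {
      vs <- which(comp$membership == ci)
      sub <- igraph::induced_subgraph(g_m, vs)
      sxy <- if (length(vs) == 1) matrix(0, 1, 2)
             else igraph::layout_with_fr(sub, niter = iterations)
      # unit-normalize and park the component on its grid slot
      rng <- max(apply(sxy, 2, function(v) diff(range(v))), 1e-9)
      sxy <- sweep(sxy, 2, colMeans(sxy)) / rng
      slot <- c((ci - 1) %% grid, (ci - 1) %/% grid)
      xy[vs, ] <- sweep(sxy * 0.8, 2, slot * 1.5, "+")
    }
    xy
  })
  data.frame(mc = igraph::V(g_m)$name, x = coords[, 1], y = coords[, 2],
             stringsAsFactors = FALSE)
}

#' Position single cells from metacell coordinates
#'
#' Each cell is placed at the unweighted average of the metacell
#' coordinates of its balanced-graph neighbors (either edge direction),
#' after dropping neighbors whose metacell is neither the cell's own nor
#' adjacent to it in the metacell graph. Cells with no surviving neighbor
#' sit exactly at their metacell's coordinates. Outlier cells are placed
#' at the metacell of their strongest neighbor, flagged `outlier`; those
#' with no assigned neighbor at all are omitted.
#'
#' @param g a `balanced_graph`.
#' @param cover a `metacell_cover` or `mc_assignment`.
#' @param g_m the metacell graph.
#' @param coords metacell coordinates from [layout_mcs()].
#' @return a data.frame with `cell`, `mc`, `x`, `y`, `kind` (`cell` or
#'   `outlier`).
#' @export
position_cells <- function(g, cover, g_m, coords) {
  adj <- .as_adj(g)
  n <- nrow(adj)
  mc <- cover$mc
  ks <- coords$mc
  mc_xy <- as.matrix(coords[, c("x", "y")])
  rownames(mc_xy) <- ks
  am <- igraph::as_adjacency_matrix(g_m, sparse = FALSE) > 0
  rownames(am) <- colnames(am) <- igraph::V(g_m)$name
  sym <- methods::as(adj + Matrix::t(adj), "CsparseMatrix")
  # symmetric, so column slots double as row neighborhoods
  nbr_of <- function(i) {
    if (sym@p[i + 1L] == sym@p[i]) integer(0)
    else sym@i[(sym@p[i] + 1L):sym@p[i + 1L]] + 1L
  }
  w_of <- function(i) {
    if (sym@p[i + 1L] == sym@p[i]) numeric(0)
    else sym@x[(sym@p[i] + 1L):sym@p[i + 1L]]
  }
  out <- data.frame(cell = character(0), mc = integer(0), x = numeric(0),
                    y = numeric(0), kind = character(0),
                    stringsAsFactors = FALSE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    nbr <- nbr_of(i)
    wts <- w_of(i)
    k <- mc[i]
    if (is.na(k)) {
      # outlier: adopt the metacell of the heaviest assigned neighbor
      keep <- !is.na(mc[nbr])
      nbr <- nbr[keep]; wts <- wts[keep]
      if (!length(nbr)) next
      kk <- mc[nbr[which.max(wts)]]
      rows[[i]] <- data.frame(cell = rownames(adj)[i], mc = NA_integer_,
                              x = mc_xy[as.character(kk), 1],
                              y = mc_xy[as.character(kk), 2],
                              kind = "outlier", stringsAsFactors = FALSE)
      next
    }
    kn <- mc[nbr]
    kn <- kn[!is.na(kn)]
    ok <- kn == k | am[as.character(k), as.character(kn)]
    xy <- if (any(ok)) colMeans(mc_xy[as.character(kn[ok]), , drop = FALSE])
          else mc_xy[as.character(k), ]
    rows[[i]] <- data.frame(cell = rownames(adj)[i], mc = k, x = xy[1],
                            y = xy[2], kind = "cell",
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, c(list(out), rows[!vapply(rows, is.null, TRUE)]))
}

#' Full 2D projection of a metacell cover
#'
#' Runs [mc_edge_matrix()], [build_mc_graph()], [layout_mcs()] and
#' [position_cells()] in sequence.
#'
#' @inheritParams mc_edge_matrix
#' @inheritParams build_mc_graph
#' @inheritParams layout_mcs
#' @return an object of class `mc_layout_2d`: list with `mc_coords`,
#'   `cell_coords`, `graph`, `Bprime`.
#' @export
mc_layout <- function(g, cover, t_edge = 0.08, d_max = 4, iterations = 500,
                      rng_seed = 1) {
  em <- mc_edge_matrix(g, cover)
  g_m <- build_mc_graph(em$Bprime, t_edge = t_edge, d_max = d_max)
  mc_coords <- layout_mcs(g_m, iterations = iterations, rng_seed = rng_seed)
  cell_coords <- position_cells(g, cover, g_m, mc_coords)
  structure(list(mc_coords = mc_coords, cell_coords = cell_coords,
                 graph = g_m, Bprime = em$Bprime),
            class = "mc_layout_2d")
}

#' Write layout coordinates as a TSV (id, x, y, kind)
#' @param layout an `mc_layout_2d`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_coords <- function(layout, path) {
  tab <- rbind(
    data.frame(id = layout$mc_coords$mc, x = layout$mc_coords$x,
               y = layout$mc_coords$y, kind = "mc",
               stringsAsFactors = FALSE),
    data.frame(id = layout$cell_coords$cell, x = layout$cell_coords$x,
               y = layout$cell_coords$y, kind = layout$cell_coords$kind,
               stringsAsFactors = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Scatter plot of a 2D projection (base graphics)
#'
#' @param x an `mc_layout_2d`.
#' @param color_by optional factor over cells (in `cell_coords` order).
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.mc_layout_2d <- function(x, color_by = NULL, ...) {
  cc <- x$cell_coords
  col <- if (is.null(color_by)) "grey60"
         else grDevices::rainbow(nlevels(factor(color_by)))[factor(color_by)]
  graphics::plot(cc$x, cc$y, pch = 16, cex = 0.4, col = col,
                 xlab = "x", ylab = "y", ...)
  graphics::points(x$mc_coords$x, x$mc_coords$y, pch = 21, bg = "white",
                   cex = 1.4)
  graphics::text(x$mc_coords$x, x$mc_coords$y, x$mc_coords$mc, cex = 0.6)
  invisible(x)
}
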