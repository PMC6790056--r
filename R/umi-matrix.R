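#' UMI count matrix
#'
#' Container for a genes x cells matrix of non-negative integer UMI counts,
#' with per-cell and per-gene molecule totals kept in sync. Counts are held
#' as a sparse `dgCMatrix` with gene ids as rownames and cell ids
#' (barcodes) as colnames. All of metacellr works on this orientation:
#' genes are rows, cells are columns.
#'
#' @param counts a matrix or sparse Matrix of non-negative integer counts,
#'   genes x cells, with unique dimnames.
#' @return an object of class `umi_matrix`: a list with elements `counts`
#'   (dgCMatrix), `gene_ids`, `cell_ids`, `gene_totals`, `cell_totals`.
#' @examples
#' m <- umi_matrix(matrix(c(2, 0, 0, 0, 0, 5), nrow = 3,
#'                 dimnames = list(paste0("g", 1:3), c("c1", "c2"))))
#' m$cell_totals
#' @export
umi_matrix <- function(counts) {
  if (!inherits(counts, "Matrix")) counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene rownames and cell colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicated gene ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))])[1], "..."))
  if (anyDuplicated(colnames(counts)))
    stop("duplicated cell ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))])[1], "..."))
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x))))
    stop("counts must be non-negative integers")
  obj <- list(
    counts      = counts,
    gene_ids    = rownames(counts),
    cell_ids    = colnames(counts),
    gene_totals = Matrix::rowSums(counts),
    cell_totals = Matrix::colSums(counts)
  )
  class(obj) <- "umi_matrix"
  obj
}

#' @export
print.umi_matrix <- function(x, ...) {
  cat(sprintf("umi_matrix: %d genes x %d cells, %d UMIs (median depth %d)\n",
              length(x$gene_ids), length(x$cell_ids),
              as.integer(sum(x$cell_totals)),
              as.integer(stats::median(x$cell_totals))))
  invisible(x)
}

#' @export
dim.umi_matrix <- function(x) dim(x$counts)

#' Subset a UMI matrix by gene and/or cell ids (or indices); totals are
#' recomputed.
#' @param m a [umi_matrix].
#' @param genes,cells character ids or integer/logical indices; `NULL` keeps
#'   all.
#' @return a [umi_matrix].
#' @export
subset_umi <- function(m, genes = NULL, cells = NULL) {
  stopifnot(inherits(m, "umi_matrix"))
  cnt <- m$counts
  if (!is.null(genes)) cnt <- cnt[genes, , drop = FALSE]
  if (!is.null(cells)) cnt <- cnt[, cells, drop = FALSE]
  umi_matrix(cnt)
}

.read_ids_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  # 10x v2 genes.tsv and v3 features.tsv carry the id in column 1
  as.character(tab[[1]])
}

#' Read a UMI count matrix
#'
#' Readers for the three supported on-disk layouts, all normalized to the
#' genes x cells orientation:
#' \describe{
#'   \item{`mtx_triplet`}{a 10x-style directory (or a `matrix.mtx` path)
#'     holding `matrix.mtx` plus gene ids in `genes.tsv` or `features.tsv`
#'     and cell barcodes in `barcodes.tsv`.}
#'   \item{`dense_tsv`}{a dense TSV with gene ids in the first column and
#'     cell ids in the header.}
#'   \item{`hdf5`}{an HDF5 group holding CSC arrays `data`, `indices`,
#'     `indptr`, `shape` plus `genes` and `barcodes` id vectors (requires
#'     the rhdf5 package).}
#' }
#'
#' @param path file or directory path.
#' @param format one of `"mtx_triplet"`, `"dense_tsv"`, `"hdf5"`.
#' @param hdf5_group group name inside an HDF5 file (default `"matrix"`).
#' @return a [umi_matrix].
#' @seealso [write_umi_matrix()] for the lossless inverse.
#' @export
load_umi_matrix <- function(path, format = c("mtx_triplet", "dense_tsv", "hdf5"),
                            hdf5_group = "matrix") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file or directory: ", path)
  switch(format,
    mtx_triplet = {
      dir <- if (dir.exists(path)) path else dirname(path)
      mtx <- file.path(dir, "matrix.mtx")
      if (!file.exists(mtx)) stop("matrix.mtx not found under ", dir)
      gf <- file.path(dir, c("genes.tsv", "features.tsv"))
      gf <- gf[file.exists(gf)][1]
      bf <- file.path(dir, "barcodes.tsv")
      if (is.na(gf)) stop("genes.tsv / features.tsv not found under ", dir)
      if (!file.exists(bf)) stop("barcodes.tsv not found under ", dir)
      cnt <- Matrix::readMM(mtx)
      gids <- .read_ids_tsv(gf); cids <- .read_ids_tsv(bf)
      if (nrow(cnt) != length(gids))
        stop("matrix.mtx declares ", nrow(cnt), " genes but ", basename(gf),
             " lists ", length(gids))
      if (ncol(cnt) != length(cids))
        stop("matrix.mtx declares ", ncol(cnt), " cells but barcodes.tsv lists ",
             length(cids))
      dimnames(cnt) <- list(gids, cids)
      umi_matrix(cnt)
    },
    dense_tsv = {
      tab <- utils::read.table(path, sep = "\t", header = TRUE,
                               row.names = 1, check.names = FALSE,
                               stringsAsFactors = FALSE, quote = "",
                               comment.char = "")
      umi_matrix(as.matrix(tab))
    },
    hdf5 = {
      if (!requireNamespace("rhdf5", quietly = TRUE))
        stop("reading hdf5 requires the rhdf5 package")
      g <- function(nm) rhdf5::h5read(path, file.path(hdf5_group, nm))
      shape <- as.integer(g("shape"))
      cnt <- Matrix::sparseMatrix(
        i = as.integer(g("indices")) + 1L, p = as.integer(g("indptr")),
        x = as.numeric(g("data")), dims = shape,
        dimnames = list(as.character(g("genes")), as.character(g("barcodes"))))
      umi_matrix(cnt)
    })
}

#' Write a UMI count matrix
#'
#' Inverse of [load_umi_matrix()]: `load(write(m)) == m` for every format.
#'
#' @param m a [umi_matrix].
#' @param path output directory (`mtx_triplet`) or file path.
#' @param format one of `"mtx_triplet"`, `"dense_tsv"`, `"hdf5"`.
#' @param hdf5_group group name for hdf5 output.
#' @return `path`, invisibly.
#' @export
write_umi_matrix <- function(m, path, format = c("mtx_triplet", "dense_tsv", "hdf5"),
                             hdf5_group = "matrix") {
  stopifnot(inherits(m, "umi_matrix"))
  format <- match.arg(format)
  switch(format,
    mtx_triplet = {
      dir.create(path, showWarnings = FALSE, recursive = TRUE)
      Matrix::writeMM(m$counts, file.path(path, "matrix.mtx"))
      writeLines(m$gene_ids, file.path(path, "genes.tsv"))
      writeLines(m$cell_ids, file.path(path, "barcodes.tsv"))
    },
    dense_tsv = {
      tab <- as.matrix(m$counts)
      utils::write.table(
        data.frame(gene = m$gene_ids, tab, check.names = FALSE),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    },
    hdf5 = {
      if (!requireNamespace("rhdf5", quietly = TRUE))
        stop("writing hdf5 requires the rhdf5 package")
      if (file.exists(path)) unlink(path)
      rhdf5::h5createFile(path)
      rhdf5::h5createGroup(path, hdf5_group)
      h <- function(obj, nm) rhdf5::h5write(obj, path, file.path(hdf5_group, nm))
      h(as.numeric(m$counts@x), "data")
      h(as.integer(m$counts@i), "indices")
      h(as.integer(m$counts@p), "indptr")
      h(dim(m$counts), "shape")
      h(m$gene_ids, "genes")
      h(m$cell_ids, "barcodes")
      rhdf5::h5closeAll()
    })
  invisible(path)
}

#' Filter cells and genes
#'
#' Removes blacklisted genes first, then recomputes cell totals and drops
#' cells whose total falls below `min_umi` or above `max_umi`. Thresholds
#' follow the "less than" convention: a cell with total exactly `min_umi`
#' (or `max_umi`) is retained.
#'
#' @param m a [umi_matrix].
#' @param min_umi minimum retained cell total (inclusive), default 0.
#' @param max_umi maximum retained cell total (inclusive), default `Inf`.
#' @param gene_blacklist character vector of gene ids to remove before
#'   totals are recomputed (e.g. mitochondrial genes), or `NULL`.
#' @return a filtered [umi_matrix].
#' @export
filter_cells_and_genes <- function(m, min_umi = 0, max_umi = Inf,
                                   gene_blacklist = NULL) {
  stopifnot(inherits(m, "umi_matrix"), min_umi >= 0)
  if (is.finite(max_umi) && max_umi <= min_umi)
    stop("max_umi must exceed min_umi")
  keep_g <- !(m$gene_ids %in% gene_blacklist)
  cnt <- m$counts[keep_g, , drop = FALSE]
  tot <- Matrix::colSums(cnt)
  keep_c <- tot >= min_umi & tot <= max_umi
  if (!any(keep_c))
    stop("cell filter removed every cell (min_umi = ", min_umi,
         ", max_umi = ", max_umi, ")")
  umi_matrix(cnt[, keep_c, drop = FALSE])
}

# Down-sample one sparse column to exactly `target` molecules without
# replacement: draw `target` distinct molecule indices from 1..total and
# bin them by the cumulative gene boundaries (multivariate hypergeometric).
.downsample_col <- function(x, target) {
  tot <- sum(x)
  if (tot <= target) return(x)
  picked <- sort.int(sample.int(tot, target))
  bounds <- cumsum(x)
  tabulate(findInterval(picked, bounds, left.open = TRUE) + 1L,
           nbins = length(x))
}

#' Down-sample cells to a fixed depth
#'
#' Draws exactly `target` molecules from each cell without replacement
#' (multivariate hypergeometric), equalizing sequencing depth. Cells whose
#' total is below `target` are dropped.
#'
#' @param m a [umi_matrix].
#' @param target number of molecules to keep per cell; defaults to the
#'   minimum cell total so that no cell is dropped.
#' @param rng_seed integer seed making the draw reproducible.
#' @return a [umi_matrix] in which every cell total equals `target`.
#' @export
downsample_cells <- function(m, target = NULL, rng_seed = 1) {
  stopifnot(inherits(m, "umi_matrix"))
  if (is.null(target)) target <- min(m$cell_totals)
  if (target <= 0) stop("target must be a positive integer")
  keep <- m$cell_totals >= target
  if (!any(keep)) stop("no cell reaches the down-sampling target ", target)
  cnt <- as.matrix(m$counts[, keep, drop = FALSE])
  with_rng_seed(rng_seed, {
    for (j in seq_len(ncol(cnt)))
      cnt[, j] <- .downsample_col(cnt[, j], target)
  })
  umi_matrix(cnt)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched.
with_rng_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}
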