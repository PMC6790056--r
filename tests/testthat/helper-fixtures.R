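# Shared fixtures and independent brute-force oracles. The oracles are
# straight-line transcriptions of the defining formulas (triple loops,
# no shared code with the implementation).

tiny_umi <- function(n_genes = 10, n_cells = 8, max_count = 6, seed = 1,
                     depth = NULL) {
  set.seed(seed)
  cnt <- if (is.null(depth)) {
    matrix(rpois(n_genes * n_cells, max_count / 2), n_genes, n_cells)
  } else {
    prof <- rgamma(n_genes, 1) + 0.05
    sapply(seq_len(n_cells), function(i) rmultinom(1, depth, prof)[, 1])
  }
  dimnames(cnt) <- list(sprintf("g%02d", seq_len(n_genes)),
                        sprintf("c%02d", seq_len(n_cells)))
  umi_matrix(cnt)
}

random_rank_matrix <- function(n, seed) {
  set.seed(seed)
  s <- matrix(NA_integer_, n, n)
  for (i in seq_len(n)) s[i, -i] <- sample(n - 1L)
  dimnames(s) <- list(paste0("c", 1:n), paste0("c", 1:n))
  s
}

# random sparse directed weighted graph as a dense matrix
random_graph <- function(n, seed, p_edge = 0.35, max_w = 5) {
  set.seed(seed)
  a <- matrix(ifelse(runif(n * n) < p_edge, sample(max_w, n * n, TRUE), 0), n, n)
  diag(a) <- 0
  dimnames(a) <- list(paste0("c", 1:n), paste0("c", 1:n))
  a
}

random_cover <- function(n, k, seed, p_outlier = 0.1) {
  set.seed(seed)
  mc <- sample(k, n, replace = TRUE)
  mc[runif(n) < p_outlier] <- NA_integer_
  structure(list(mc = mc, cell_ids = paste0("c", 1:n),
                 n_mcs = length(unique(mc[!is.na(mc)]))),
            class = "mc_assignment")
}

block_cover <- function(m, n_blocks) {
  n <- length(m$cell_ids)
  mc <- rep(seq_len(n_blocks), each = ceiling(n / n_blocks))[seq_len(n)]
  structure(list(mc = mc, cell_ids = m$cell_ids, n_mcs = n_blocks),
            class = "mc_assignment")
}

# --- oracles -------------------------------------------------------------

# three-step balancing, written as literal loops over the formulas
brute_balance <- function(s, K, alpha = 10, beta = 3) {
  n <- nrow(s)
  s1 <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) if (i != j)
    s1[i, j] <- max(alpha * K^2 - s[i, j] * s[j, i], 0)
  rank_desc <- function(v) {
    # rank positive entries descending, ties to lower index
    r <- rep(Inf, length(v))
    ord <- order(-v, seq_along(v))
    rr <- 0
    for (idx in ord) if (v[idx] > 0) { rr <- rr + 1; r[idx] <- rr }
    r
  }
  s2 <- matrix(0, n, n)
  for (j in 1:n) {
    r <- rank_desc(s1[, j])
    for (i in 1:n) if (s1[i, j] > 0) s2[i, j] <- max(beta * K - r[i], 0)
  }
  a <- matrix(0, n, n)
  for (i in 1:n) {
    r <- rank_desc(s2[i, ])
    for (j in 1:n) if (s2[i, j] > 0) a[i, j] <- max(K - r[j], 0)
  }
  dimnames(a) <- dimnames(s)
  a
}

# co-occurrence threshold rule, literal
brute_cooc_edges <- function(sboot, k_core, factor = 0.5) {
  n <- nrow(sboot)
  ti <- numeric(n)
  for (i in 1:n) {
    v <- sort(sboot[i, -i][sboot[i, -i] > 0], decreasing = TRUE)
    ti[i] <- if (!length(v)) Inf else if (length(v) < k_core) min(v)
             else v[k_core]
  }
  e <- matrix(FALSE, n, n)
  for (i in 1:n) for (j in 1:n) if (i != j)
    e[i, j] <- sboot[i, j] > max(ti[i], ti[j]) * factor
  e
}

# metacell edge projection b_ml, literal double loop
brute_mc_edge <- function(a, mc, K) {
  ks <- sort(unique(mc[!is.na(mc)]))
  sizes <- sapply(ks, function(k) sum(mc == k, na.rm = TRUE))
  C <- median(sizes)
  B <- matrix(0, length(ks), length(ks), dimnames = list(ks, ks))
  n <- nrow(a)
  for (m in seq_along(ks)) for (l in seq_along(ks)) {
    tot <- 0
    for (i in 1:n) for (j in 1:n)
      if (!is.na(mc[i]) && !is.na(mc[j]) && mc[i] == ks[m] &&
          mc[j] == ks[l] && a[i, j] > 0)
        tot <- tot + ceiling(a[i, j] / C)
    B[m, l] <- K^2 / (sizes[m] * sizes[l]) * tot
  }
  B
}

# closure = intra edges / incident edges, literal
brute_closure <- function(a, mc) {
  ks <- sort(unique(mc[!is.na(mc)]))
  out <- setNames(numeric(length(ks)), ks)
  n <- nrow(a)
  for (kk in seq_along(ks)) {
    k <- ks[kk]; ins <- 0; inc <- 0
    for (i in 1:n) for (j in 1:n) if (a[i, j] > 0) {
      mi <- !is.na(mc[i]) && mc[i] == k
      mj <- !is.na(mc[j]) && mc[j] == k
      if (mi && mj) ins <- ins + 1
      if (mi || mj) inc <- inc + 1
    }
    out[kk] <- if (inc == 0) NA_real_ else ins / inc
  }
  out
}

majority_label <- function(mc, truth) {
  out <- rep(NA_character_, length(mc))
  for (k in unique(mc[!is.na(mc)])) {
    i <- which(!is.na(mc) & mc == k)
    out[i] <- names(which.max(table(truth[i])))
  }
  out
}

# small 3-type mixture used by several integration tests
mini_mixture <- function(seed = 5, n_genes = 200, cells_per_type = 100,
                         depth = 400) {
  spec <- synthetic_spec(
    n_genes, metacellr:::.make_type_profiles(n_genes, 3, block = 30),
    cells_per_type, depth_model = list(kind = "fixed", depth = depth),
    rng_seed = seed)
  synth_generate(spec)
}
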