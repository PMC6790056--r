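# R transcription of the seeding pseudocode, consuming the RNG exactly
# like the shipped implementation (one uniform draw per seed, cumulative
# scan over uncovered cells in index order).
seed_trace <- function(a, size_min, rng_seed) {
  n <- nrow(a)
  out_nbr <- lapply(seq_len(n), function(i) which(a[i, ] > 0))
  in_nbr <- lapply(seq_len(n), function(j) which(a[, j] > 0))
  mc <- rep(-1L, n)
  covered <- rep(FALSE, n)
  f <- vapply(out_nbr, length, 1)
  k <- 0L
  set.seed(rng_seed)
  repeat {
    if (max(c(-1, f[!covered])) <= size_min) break
    w <- ifelse(covered, 0, f^3)
    tot <- sum(w)
    if (tot <= 0) break
    r <- runif(1) * tot
    j <- which(cumsum(w) >= r)[1]
    claimed <- c(j, setdiff(out_nbr[[j]], which(covered)))
    claimed <- unique(claimed)
    mc[claimed] <- k
    covered[claimed] <- TRUE
    for (u in claimed) f[in_nbr[[u]]] <- f[in_nbr[[u]]] - 1
    k <- k + 1L
  }
  ifelse(mc < 0, NA_integer_, mc + 1L)
}

clique_graph <- function(sizes, w = 1) {
  n <- sum(sizes)
  a <- matrix(0, n, n)
  off <- 0
  for (s in sizes) {
    a[off + 1:s, off + 1:s] <- w
    off <- off + s
  }
  diag(a) <- 0
  dimnames(a) <- list(paste0("c", 1:n), paste0("c", 1:n))
  a
}

test_that("a complete graph with size_min 1 is covered by a single seed", {
  a <- clique_graph(7)
  s <- seed_partition(a, size_min = 1, rng_seed = 3)
  expect_equal(s$n_mcs, 1L)
  expect_true(all(!is.na(s$mc)))
})

test_that("two disconnected cliques draw one seed each", {
  a <- clique_graph(c(5, 5))
  s <- seed_partition(a, size_min = 2, rng_seed = 1)
  expect_equal(s$n_mcs, 2L)
  expect_equal(length(unique(s$mc[1:5])), 1L)
  expect_equal(length(unique(s$mc[6:10])), 1L)
  expect_false(s$mc[1] == s$mc[6])
})

test_that("seeding matches a straight-line transcription of the pseudocode", {
  for (seed in c(2, 17, 91)) {
    a <- random_graph(18, seed = seed, p_edge = 0.3)
    got <- seed_partition(a, size_min = 2, rng_seed = seed + 5)
    ref <- seed_trace(a, size_min = 2, rng_seed = seed + 5)
    expect_identical(got$mc, ref, info = paste("seed", seed))
  }
})

test_that("optimizing two seeded cliques converges to the cliques", {
  a <- clique_graph(c(6, 6))
  s <- seed_partition(a, size_min = 2, rng_seed = 4)
  o <- optimize_partition(a, s, rng_seed = 4)
  expect_true(o$converged)
  expect_equal(length(unique(o$mc[1:6])), 1L)
  expect_equal(length(unique(o$mc[7:12])), 1L)
  expect_false(o$mc[1] == o$mc[7])
})

test_that("converged assignments are stable under the association score", {
  a <- random_graph(30, seed = 77, p_edge = 0.35)
  p <- partition_graph(a, size_min = 3, rng_seed = 9)
  expect_true(p$converged)
  stick <- 1.01^p$passes
  sizes <- table(factor(p$mc, levels = sort(unique(p$mc))))
  for (i in 1:30) {
    k_cur <- p$mc[i]
    if (is.na(k_cur)) next
    w <- sapply(sort(unique(p$mc)), function(k) {
      wo <- sum(a[i, which(p$mc == k)])
      wi <- sum(a[which(p$mc == k), i])
      wi * wo / sum(p$mc == k, na.rm = TRUE)^2
    })
    names(w) <- sort(unique(p$mc))
    expect_gte(w[as.character(k_cur)] * stick, max(w) * (1 - 1e-12))
  }
})

test_that("a one-directional cell is still absorbed by its component", {
  # cell 7 only points INTO a 6-clique (no incoming edges): its product
  # score is zero everywhere, yet it must not stay unassigned
  a <- clique_graph(6)
  a <- rbind(cbind(a, 0), 0)
  a[7, 1:3] <- 1
  dimnames(a) <- list(paste0("c", 1:7), paste0("c", 1:7))
  p <- partition_graph(a, size_min = 2, rng_seed = 2)
  expect_false(is.na(p$mc[7]))
  expect_equal(p$mc[7], p$mc[1])
})

test_that("cells in components below size_min become outliers", {
  a <- clique_graph(c(8, 2))   # the 2-component cannot reach size_min 4
  p <- partition_graph(a, size_min = 4, rng_seed = 1)
  expect_true(all(is.na(p$mc[9:10])))
  expect_true(all(!is.na(p$mc[1:8])))
})

test_that("one hundred random fixtures converge within 50 passes", {
  for (seed in 1:100) {
    n <- sample(10:25, 1)
    a <- random_graph(n, seed = 3000 + seed, p_edge = 0.4)
    p <- partition_graph(a, size_min = 2, max_passes = 50,
                         rng_seed = seed)
    expect_true(p$converged, info = paste("seed", seed))
  }
})

test_that("a fixed seed reproduces the assignment exactly", {
  a <- random_graph(40, seed = 5, p_edge = 0.25)
  p1 <- partition_graph(a, size_min = 3, rng_seed = 11)
  p2 <- partition_graph(a, size_min = 3, rng_seed = 11)
  expect_identical(p1$mc, p2$mc)
})

test_that("optimization work grows linearly with edge count", {
  visits <- sapply(c(30, 60, 120), function(n) {
    a <- random_graph(n, seed = n, p_edge = 0.2)
    p <- partition_graph(a, size_min = 3, rng_seed = 1)
    edges <- sum(a > 0)
    # each pass touches each directed edge at most twice (out + in scan)
    expect_lte(p$edge_visits, 2 * edges * p$passes)
    p$edge_visits / (edges * p$passes)
  })
  expect_true(all(visits <= 2))
})

test_that("assignments export with -1 for unassigned cells", {
  a <- clique_graph(c(8, 2))
  p <- partition_graph(a, size_min = 4, rng_seed = 1)
  f <- withr::local_tempfile()
  write_assignment(p, f)
  tab <- read.delim(f)
  expect_equal(sum(tab$metacell == -1), 2)
})
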