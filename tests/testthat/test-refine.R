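simple_assignment <- function(m, mc) {
  structure(list(mc = mc, cell_ids = m$cell_ids,
                 n_mcs = length(unique(mc[!is.na(mc)]))),
            class = "mc_assignment")
}

test_that("pool frequencies sum each metacell's molecules", {
  cnt <- cbind(a = c(2, 2), b = c(0, 4))
  rownames(cnt) <- c("g1", "g2")
  m <- umi_matrix(cnt)
  p <- pool_frequencies(m, simple_assignment(m, c(1L, 1L)))
  expect_equal(p["g1", "1"], 0.25)   # (2 + 0) / (4 + 4)
  expect_equal(colSums(p), c("1" = 1))

  m10 <- tiny_umi(12, 10, seed = 40)
  a10 <- simple_assignment(m10, rep(c(1L, 2L), each = 5))
  p10 <- pool_frequencies(m10, a10)
  for (k in 1:2) {
    cells <- which(a10$mc == k)
    expect_equal(unname(p10[, as.character(k)]),
                 unname(rowSums(as.matrix(m10$counts[, cells])) /
                        sum(m10$cell_totals[cells])))
  }
})

test_that("fold deviations follow the regularized formula", {
  # u_gi = 15, u_i = 100, p = 0.01 -> log2(16 / 2) = 3
  cnt <- rbind(g1 = c(15, 5), g2 = c(85, 95))
  colnames(cnt) <- c("a", "b")
  m <- umi_matrix(cnt)
  a <- simple_assignment(m, c(1L, 1L))
  pf <- matrix(c(0.01, 0.99), 2, 1, dimnames = list(c("g1", "g2"), "1"))
  f <- outlier_fold(m, pf, a)
  expect_equal(f["g1", "a"], 3)
  # zero counts can never be enriched
  m0 <- umi_matrix(rbind(g1 = c(0, 0), g2 = c(50, 60)) |>
                   `colnames<-`(c("a", "b")))
  f0 <- outlier_fold(m0, pool_frequencies(m0, a), a)
  expect_true(all(f0["g1", ] <= 0))
})

test_that("regularization bounds enrichment folds for low-count genes", {
  # exhaustive grid: a gene observed at u_gi <= 3 can never look more than
  # 4-fold (f = 2) enriched, whatever the expectation
  for (u in 0:3) for (depth in c(50, 200, 1000)) for (p in c(0, 1e-4, 1e-2)) {
    f <- log2((1 + u) / (1 + depth * p))
    expect_lte(f, 2)
  }
})

test_that("outlier filtering flags at the threshold inclusively, single pass", {
  fx <- mini_mixture(seed = 51)
  m <- fx$matrix
  a <- simple_assignment(m, rep(1:3, each = 100))
  pf <- pool_frequencies(m, a)
  f <- outlier_fold(m, pf, a)
  t_star <- sort(apply(f, 2, max), decreasing = TRUE)[3]  # 3rd highest cell
  fo <- filter_outliers(m, a, t_lfc = t_star)
  expect_true(m$cell_ids[which.max(apply(f, 2, max))] %in% fo$outliers)
  expect_equal(length(fo$outliers), 3L)  # >= is inclusive
  # single pass: rerunning on the unchanged assignment flags the same set
  fo2 <- filter_outliers(m, a, t_lfc = t_star)
  expect_identical(fo$outliers, fo2$outliers)
  expect_equal(nrow(fo$report), 3L)
  expect_true(all(fo$report$f >= t_star))
})

test_that("a pure multinomial population is almost never flagged", {
  spec <- synthetic_spec(300, metacellr:::.make_type_profiles(300, 1),
                         400, depth_model = list(kind = "fixed", depth = 1000),
                         rng_seed = 61)
  m <- synth_generate(spec)$matrix
  a <- simple_assignment(m, rep(1:2, each = 200))
  fo <- filter_outliers(m, a, t_lfc = 3)
  expect_lte(length(fo$outliers) / 400, 0.02)
})

test_that("spiked doublets inside parent metacells are recovered", {
  fx <- synth_generate(synthetic_spec(
    400, metacellr:::.make_type_profiles(400, 2, block = 50), 150,
    depth_model = list(kind = "fixed", depth = 600), doublet_rate = 0.02,
    rng_seed = 71))
  m <- fx$matrix; lab <- fx$labels
  mc <- ifelse(lab$type == "type1", 1L, 2L)
  mc[lab$is_doublet] <- rep(c(1L, 2L), length.out = sum(lab$is_doublet))
  fo <- filter_outliers(m, simple_assignment(m, mc), t_lfc = 3)
  flagged <- m$cell_ids %in% fo$outliers
  recall <- sum(flagged & lab$is_doublet) / sum(lab$is_doublet)
  precision <- sum(flagged & lab$is_doublet) / max(1, sum(flagged))
  expect_gte(recall, 0.7)
  expect_gte(precision, 0.5)
})

test_that("homogeneous metacells stay whole; planted mixtures split", {
  prof <- metacellr:::.make_type_profiles(300, 2, block = 40)
  mk <- function(plist, n_each, seed) {
    set.seed(seed)
    cnt <- sapply(rep(seq_along(plist), each = n_each),
                  function(k) rmultinom(1, 500, plist[[k]])[, 1])
    dimnames(cnt) <- list(sprintf("g%03d", 1:300),
                          sprintf("c%03d", seq_len(ncol(cnt))))
    umi_matrix(cnt)
  }
  for (seed in 1:3) {
    mh <- mk(prof[1], 80, seed)
    rh <- split_heterogeneous(mh, simple_assignment(mh, rep(1L, 80)),
                              rng_seed = seed)
    expect_equal(rh$n_split, 0L, info = paste("homog seed", seed))
    mx <- mk(prof, 40, seed + 50)
    rx <- split_heterogeneous(mx, simple_assignment(mx, rep(1L, 80)),
                              rng_seed = seed)
    expect_equal(rx$assignment$n_mcs, 2L, info = paste("mixed seed", seed))
    # splitting relabels but never changes the union of cells
    expect_equal(sum(!is.na(rx$assignment$mc)), 80)
  }
  # a 2-cell metacell is below min_pts and left untouched
  m2 <- mk(prof[1], 2, 9)
  r2 <- split_heterogeneous(m2, simple_assignment(m2, c(1L, 1L)))
  expect_equal(r2$n_split, 0L)
})

test_that("sub-minimum split pieces become outliers when min_size is set", {
  prof <- metacellr:::.make_type_profiles(300, 2, block = 40)
  set.seed(3)
  cnt <- sapply(rep(1:2, c(60, 5)),
                function(k) rmultinom(1, 500, prof[[k]])[, 1])
  dimnames(cnt) <- list(sprintf("g%03d", 1:300), sprintf("c%03d", 1:65))
  m <- umi_matrix(cnt)
  r <- split_heterogeneous(m, simple_assignment(m, rep(1L, 65)),
                           min_size = 20, rng_seed = 1)
  expect_equal(r$assignment$n_mcs, 1L)
  expect_equal(sum(is.na(r$assignment$mc)), 5L)
})

test_that("the cover law holds exactly through refinement", {
  fx <- mini_mixture(seed = 81)
  m <- fx$matrix
  a <- simple_assignment(m, rep(1:3, each = 100))
  fo <- filter_outliers(m, a, t_lfc = 2)
  sp <- split_heterogeneous(m, fo$assignment, rng_seed = 1)
  cover <- metacell_cover(sp$assignment, fo$outliers)
  expect_identical(cover$cell_ids, m$cell_ids)
  expect_equal(sum(!is.na(cover$mc)) + sum(is.na(cover$mc)), 300L)
  expect_true(all(is.na(cover$outlier_type) == !is.na(cover$mc)))
  expect_true(all(cover$outlier_type[cover$cell_ids %in% fo$outliers] ==
                  "parametric"))
})

test_that("manual metacell dropping sends cells to the outlier set", {
  fx <- mini_mixture(seed = 91)
  m <- fx$matrix
  cover <- metacell_cover(simple_assignment(m, rep(1:3, each = 100)))
  d <- drop_metacells(cover, 2L)
  expect_equal(d$n_mcs, 2L)
  expect_equal(sum(is.na(d$mc)), 100L)
  expect_true(all(d$outlier_type[is.na(d$mc)] == "parametric"))
})
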