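as_cover <- function(m, mc) {
  structure(list(mc = mc, cell_ids = m$cell_ids,
                 n_mcs = length(unique(mc[!is.na(mc)]))),
            class = "mc_assignment")
}

test_that("closure is 1 for isolated cliques and 0 for outward-only cells", {
  a <- matrix(0, 6, 6)
  a[1:3, 1:3] <- 1                       # clique metacell
  a[4, 5] <- 1; a[4, 6] <- 1             # cell 4 only points outward
  diag(a) <- 0
  dimnames(a) <- list(paste0("c", 1:6), paste0("c", 1:6))
  cov <- list(mc = c(1L, 1L, 1L, 2L, NA, NA), cell_ids = rownames(a))
  cl <- mc_closure(a, cov)
  expect_equal(cl[["1"]], 1)
  expect_equal(cl[["2"]], 0)
})

test_that("closure matches brute-force counting on random fixtures", {
  for (seed in 1:12) {
    n <- sample(8:18, 1)
    a <- random_graph(n, seed = 700 + seed, p_edge = 0.3)
    cov <- random_cover(n, 3, seed = seed)
    expect_equal(mc_closure(a, cov), brute_closure(a, cov$mc),
                 info = paste("seed", seed))
  }
})

test_that("single-metacell closure equals one minus the outlier-incident share", {
  a <- random_graph(15, seed = 9, p_edge = 0.35)
  mc <- c(rep(1L, 12), NA, NA, NA)
  cov <- list(mc = mc, cell_ids = rownames(a))
  edges <- which(a > 0, arr.ind = TRUE)
  both_in <- apply(edges, 1, function(e) all(!is.na(mc[e])))
  incident <- apply(edges, 1, function(e) any(!is.na(mc[e])))
  expect_equal(mc_closure(a, cov)[["1"]], sum(both_in) / sum(incident))
})

test_that("adherence p-values are calibrated on multinomial data", {
  spec <- synthetic_spec(120, metacellr:::.make_type_profiles(120, 1, block = 20),
                         240, depth_model = list(kind = "fixed", depth = 300),
                         rng_seed = 17)
  m <- synth_generate(spec)$matrix
  ad <- binomial_adherence(m, as_cover(m, rep(1:3, each = 80)), rng_seed = 5)
  pv <- ad$gene_mc$p_value
  pv <- pv[!is.na(pv)]
  expect_true(all(pv >= 1 / 1000 & pv <= 1))
  expect_gt(length(pv), 300)
  expect_gt(mean(pv < 0.05), 0.02)
  expect_lt(mean(pv < 0.05), 0.10)
  od <- ad$gene_mc$over_dispersion
  expect_gt(median(od, na.rm = TRUE), 0.7)
  expect_lt(median(od, na.rm = TRUE), 1.3)
})

test_that("planted over-dispersion is flagged", {
  spec <- synthetic_spec(100, metacellr:::.make_type_profiles(100, 1, block = 10),
                         120, depth_model = list(kind = "fixed", depth = 400),
                         rng_seed = 23)
  m <- synth_generate(spec)$matrix
  cnt <- as.matrix(m$counts)
  # gene 50: replace with a two-rate mixture (variance doubled and more)
  set.seed(1)
  lam <- ifelse(runif(120) < 0.5, 2, 14)
  cnt["g0050", ] <- rpois(120, lam)
  m2 <- umi_matrix(cnt)
  ad <- binomial_adherence(m2, as_cover(m2, rep(1L, 120)), rng_seed = 2)
  row <- ad$gene_mc[ad$gene_mc$gene == "g0050", ]
  expect_gt(row$over_dispersion, 1)
  expect_lt(row$p_value, 0.01)
})

test_that("a constant gene after down-sampling has zero over-dispersion", {
  set.seed(8)
  cnt <- rbind(g1 = rep(50L, 30), matrix(rpois(30 * 20, 3), 20, 30,
               dimnames = list(sprintf("g%02d", 2:21), NULL)))
  colnames(cnt) <- sprintf("c%02d", 1:30)
  # pad a filler gene so every cell total is equal: down-sampling is then
  # the identity and g1 stays exactly constant
  cnt <- rbind(cnt, g_fill = max(colSums(cnt)) - colSums(cnt))
  m <- umi_matrix(cnt)
  expect_equal(length(unique(m$cell_totals)), 1L)
  ad <- binomial_adherence(m, as_cover(m, rep(1L, 30)), n_downsamples = 2,
                           rng_seed = 3)
  g1 <- ad$gene_mc[ad$gene_mc$gene == "g1", ]
  expect_equal(g1$over_dispersion, 0)
  poi <- ad$poisson[ad$poisson$gene == "g1", ]
  expect_equal(poi$zero_obs, 0)
})

test_that("residual correlations: planted module beats the shuffled baseline", {
  spec <- synthetic_spec(80, metacellr:::.make_type_profiles(80, 1, block = 10),
                         150, depth_model = list(kind = "fixed", depth = 300),
                         rng_seed = 31)
  m <- synth_generate(spec)$matrix
  cnt <- as.matrix(m$counts)
  # a module co-varying inside metacell 1, while the two genes' mean
  # levels move in opposite directions across the metacells: permuting
  # labels mixes the two groups and the between-group anti-correlation
  # masks the residual within-metacell signal
  set.seed(4)
  boost <- ifelse(runif(75) < 0.5, 0L, 12L)
  cnt["g0030", 1:75] <- cnt["g0030", 1:75] + boost
  cnt["g0031", 1:75] <- cnt["g0031", 1:75] + boost
  cnt["g0030", 76:150] <- cnt["g0030", 76:150] + 40L
  cnt["g0031", 76:150] <- 0L
  m2 <- umi_matrix(cnt)
  ic <- intra_mc_correlations(m2, as_cover(m2, rep(1:2, each = 75)),
                              rng_seed = 6)
  expect_gt(ic$within["g0030", "g0031"],
            ic$shuffled["g0030", "g0031"] + 0.2)
  # null genes stay near the baseline
  null_pairs <- abs(ic$within[1:20, 1:20] - ic$shuffled[1:20, 1:20])
  expect_lt(median(null_pairs[upper.tri(null_pairs)]), 0.15)
})

test_that("a single-metacell cover equals the label-free computation", {
  m <- mini_mixture(seed = 41, cells_per_type = 30)$matrix
  ic <- intra_mc_correlations(m, as_cover(m, rep(1L, 90)), rng_seed = 2)
  ds <- downsample_cells(m, rng_seed = 2 + 0 + 1)  # matching internal seed
  x <- log2(1 + as.matrix(ds$counts))
  r <- suppressWarnings(cor(t(x))); r[is.na(r)] <- 0; diag(r) <- 1
  expect_equal(unname(ic$within), unname(r))
})

test_that("prediction accuracy grows with expression and degrades without CV", {
  fx <- mini_mixture(seed = 55, n_genes = 150, cells_per_type = 80)
  m <- fx$matrix
  cv <- cv_predict(m, n_folds = 6, n_neighbors = 20, K = 25, size_min = 6,
                   rng_seed = 3)
  nocv <- cv_predict(m, n_folds = 6, n_neighbors = 20, K = 25, size_min = 6,
                     cross_validate = FALSE, rng_seed = 3)
  expect_true(all(cv$cor_mc >= -1 & cv$cor_mc <= 1, na.rm = TRUE))
  bins <- cut(rank(cv$mean_expr, ties.method = "first"), 3)
  med <- tapply(cv$cor_mc, bins, median, na.rm = TRUE)
  expect_true(!is.unsorted(med))
  expect_gt(median(cv$cor_mc[cv$mean_expr > 1], na.rm = TRUE), 0.7)
  gap_knn <- mean(nocv$cor_knn - cv$cor_knn, na.rm = TRUE)
  gap_mc <- mean(nocv$cor_mc - cv$cor_mc, na.rm = TRUE)
  expect_gt(gap_knn, gap_mc)
  expect_error(cv_predict(m, n_folds = 151), "n_folds")
})
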