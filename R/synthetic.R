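#' Specification for a ground-truthed synthetic UMI data set
#'
#' Describes a multinomial mixture of cell types from which
#' [synth_generate()] draws a UMI count matrix with known labels. Each cell
#' type is a gene-frequency profile (summing to 1); cells are multinomial
#' draws of their depth from their (possibly mixed) profile. Optional
#' extras emulate the main artefacts of droplet scRNA-seq data:
#' continuous gradients between two anchor types, doublets (two lysates in
#' one droplet, drawn from the average of two distinct type profiles at
#' double depth), and a rare outlier population.
#'
#' @param n_genes number of genes.
#' @param type_profiles list (or matrix, genes x types) of frequency
#'   vectors, each summing to 1.
#' @param cells_per_type integer, recycled across types.
#' @param depth_model either `list(kind = "fixed", depth = d)` or
#'   `list(kind = "lognormal", meanlog = log(800), sdlog = 0.4)`.
#' @param gradient_pairs optional data.frame with columns `type_a`,
#'   `type_b`, `n_cells`; each gradient cell mixes the two anchor profiles
#'   as `lambda * p_a + (1 - lambda) * p_b`, `lambda ~ Uniform(0, 1)`.
#' @param doublet_rate fraction of extra cells generated as doublets.
#' @param outlier_profile optional frequency vector for a rare distinct
#'   population.
#' @param n_outliers number of cells drawn from `outlier_profile`.
#' @param rng_seed integer seed.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes, type_profiles, cells_per_type,
                           depth_model = list(kind = "lognormal",
                                              meanlog = log(800), sdlog = 0.4),
                           gradient_pairs = NULL, doublet_rate = 0,
                           outlier_profile = NULL, n_outliers = 0,
                           rng_seed = 1) {
  if (is.matrix(type_profiles))
    type_profiles <- lapply(seq_len(ncol(type_profiles)),
                            function(k) type_profiles[, k])
  if (!length(type_profiles)) stop("at least one type profile is required")
  for (p in type_profiles) {
    if (length(p) != n_genes) stop("profile length != n_genes")
    if (any(p < 0) || abs(sum(p) - 1) > 1e-12)
      stop("profiles must be non-negative and sum to 1")
  }
  if (!is.null(outlier_profile) &&
      (length(outlier_profile) != n_genes ||
       abs(sum(outlier_profile) - 1) > 1e-12))
    stop("outlier_profile must be a frequency vector over n_genes")
  if (doublet_rate < 0 || doublet_rate > 1) stop("doublet_rate must be in [0,1]")
  if (length(type_profiles) < 2 && doublet_rate > 0)
    stop("doublets require at least two types")
  obj <- list(n_genes = n_genes, type_profiles = type_profiles,
              cells_per_type = rep_len(cells_per_type, length(type_profiles)),
              depth_model = depth_model, gradient_pairs = gradient_pairs,
              doublet_rate = doublet_rate, outlier_profile = outlier_profile,
              n_outliers = n_outliers, rng_seed = rng_seed)
  class(obj) <- "synthetic_spec"
  obj
}

.draw_depths <- function(n, model) {
  if (model$kind == "fixed") return(rep(model$depth, n))
  pmax(20L, round(stats::rlnorm(n, model$meanlog, model$sdlog)))
}

#' Generate a synthetic UMI matrix with ground-truth labels
#'
#' @param spec a [synthetic_spec()].
#' @return a list with elements `matrix` (a [umi_matrix]) and `labels`
#'   (data.frame: `cell_id`, `type`, `lambda` (gradient mixing coefficient,
#'   NA for non-gradient cells), `is_doublet`, `is_outlier`).
#' @export
synth_generate <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ntype <- length(spec$type_profiles)
  prof <- list(); type <- character(); lambda <- numeric()
  is_dbl <- logical(); is_out <- logical(); depth_mult <- numeric()

  with_rng_seed(spec$rng_seed, {
    for (k in seq_len(ntype)) {
      n <- spec$cells_per_type[k]
      prof <- c(prof, rep(list(spec$type_profiles[[k]]), n))
      type <- c(type, rep(paste0("type", k), n))
      lambda <- c(lambda, rep(NA_real_, n))
      is_dbl <- c(is_dbl, rep(FALSE, n)); is_out <- c(is_out, rep(FALSE, n))
      depth_mult <- c(depth_mult, rep(1, n))
    }
    if (!is.null(spec$gradient_pairs)) {
      for (r in seq_len(nrow(spec$gradient_pairs))) {
        gp <- spec$gradient_pairs[r, ]
        lam <- stats::runif(gp$n_cells)
        pa <- spec$type_profiles[[gp$type_a]]
        pb <- spec$type_profiles[[gp$type_b]]
        prof <- c(prof, lapply(lam, function(l) l * pa + (1 - l) * pb))
        type <- c(type, rep(sprintf("grad%d_%d", gp$type_a, gp$type_b),
                            gp$n_cells))
        lambda <- c(lambda, lam)
        is_dbl <- c(is_dbl, rep(FALSE, gp$n_cells))
        is_out <- c(is_out, rep(FALSE, gp$n_cells))
        depth_mult <- c(depth_mult, rep(1, gp$n_cells))
      }
    }
    n_dbl <- round(spec$doublet_rate * length(prof))
    if (n_dbl > 0) {
      for (d in seq_len(n_dbl)) {
        ab <- sample.int(ntype, 2)
        prof <- c(prof, list((spec$type_profiles[[ab[1]]] +
                              spec$type_profiles[[ab[2]]]) / 2))
        type <- c(type, sprintf("doublet%d_%d", ab[1], ab[2]))
      }
      lambda <- c(lambda, rep(NA_real_, n_dbl))
      is_dbl <- c(is_dbl, rep(TRUE, n_dbl))
      is_out <- c(is_out, rep(FALSE, n_dbl))
      depth_mult <- c(depth_mult, rep(2, n_dbl))  # two lysates
    }
    if (spec$n_outliers > 0) {
      if (is.null(spec$outlier_profile)) stop("n_outliers > 0 needs a profile")
      prof <- c(prof, rep(list(spec$outlier_profile), spec$n_outliers))
      type <- c(type, rep("outlier", spec$n_outliers))
      lambda <- c(lambda, rep(NA_real_, spec$n_outliers))
      is_dbl <- c(is_dbl, rep(FALSE, spec$n_outliers))
      is_out <- c(is_out, rep(TRUE, spec$n_outliers))
      depth_mult <- c(depth_mult, rep(1, spec$n_outliers))
    }
    n_cells <- length(prof)
    depths <- round(.draw_depths(n_cells, spec$depth_model) * depth_mult)
    cnt <- matrix(0L, spec$n_genes, n_cells)
    for (i in seq_len(n_cells))
      cnt[, i] <- stats::rmultinom(1, depths[i], prof[[i]])[, 1]
  })
  dimnames(cnt) <- list(sprintf("g%04d", seq_len(spec$n_genes)),
                        sprintf("c%05d", seq_len(ncol(cnt))))
  list(matrix = umi_matrix(cnt),
       labels = data.frame(cell_id = colnames(cnt), type = type,
                           lambda = lambda, is_doublet = is_dbl,
                           is_outlier = is_out, stringsAsFactors = FALSE))
}

# Deterministic construction of `ntype` well-separated frequency profiles:
# a shared power-law backbone plus disjoint blocks of strongly boosted
# type-private genes. Pairwise total-variation distance is checked >= 0.4.
.make_type_profiles <- function(n_genes, ntype, block = 60, boost = 12,
                                min_tv = 0.4) {
  base <- 1 / (seq_len(n_genes) + 10)     # power-law-ish expression backbone
  base <- base / sum(base)
  prof <- vector("list", ntype)
  for (k in seq_len(ntype)) {
    p <- base
    idx <- ((k - 1) * block + 1):(k * block)
    p[idx] <- p[idx] * boost
    # each type also silences the private blocks of the other types
    other <- setdiff(seq_len(ntype * block), idx)
    p[other] <- p[other] * 0.05
    prof[[k]] <- p / sum(p)
  }
  for (a in seq_len(ntype - 1)) for (b in (a + 1):ntype) {
    tv <- sum(abs(prof[[a]] - prof[[b]])) / 2
    if (tv < min_tv)
      stop(sprintf("profiles %d/%d separated by TV %.2f < %.2f", a, b, tv, min_tv))
  }
  prof
}

#' Fixed synthetic presets used throughout the test and acceptance suites
#'
#' Versioned, documented study conditions:
#' \describe{
#'   \item{`five_types`}{5 well-separated profiles (pairwise total
#'     variation >= 0.4), 300 cells each (1500 cells), 600 genes, depth
#'     lognormal around 800.}
#'   \item{`gradient`}{two anchor types (150 cells each) plus 600 cells
#'     drawn from uniform mixtures of the anchors.}
#'   \item{`doublet_spike`}{two distant types (490 cells each) plus 2%
#'     doublets at double depth.}
#'   \item{`null_multinomial`}{a single type, 600 genes, 1000 cells,
#'     fixed depth 800 — pure multinomial sampling noise.}
#' }
#'
#' @param name preset name.
#' @param rng_seed seed stored in the spec (the preset's structure itself
#'   is deterministic).
#' @return a [synthetic_spec()].
#' @export
make_preset <- function(name = c("five_types", "gradient", "doublet_spike",
                                 "null_multinomial"),
                        rng_seed = 20190726) {
  name <- match.arg(name)
  lognorm <- list(kind = "lognormal", meanlog = log(800), sdlog = 0.4)
  switch(name,
    five_types = synthetic_spec(
      n_genes = 600, type_profiles = .make_type_profiles(600, 5),
      cells_per_type = 300, depth_model = lognorm, rng_seed = rng_seed),
    gradient = {
      prof <- .make_type_profiles(600, 2)
      synthetic_spec(
        n_genes = 600, type_profiles = prof, cells_per_type = 150,
        depth_model = lognorm,
        gradient_pairs = data.frame(type_a = 1, type_b = 2, n_cells = 600),
        rng_seed = rng_seed)
    },
    doublet_spike = synthetic_spec(
      n_genes = 600, type_profiles = .make_type_profiles(600, 2),
      cells_per_type = 490, depth_model = lognorm, doublet_rate = 0.02,
      rng_seed = rng_seed),
    null_multinomial = synthetic_spec(
      n_genes = 600, type_profiles = .make_type_profiles(600, 1),
      cells_per_type = 1000,
      depth_model = list(kind = "fixed", depth = 800), rng_seed = rng_seed))
}
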