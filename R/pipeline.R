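#' Pipeline configuration
#'
#' One flat configuration object covering every stage, with named presets
#' mirroring published parameter sets:
#' \describe{
#'   \item{`pbmc`}{K = 100, 500 resamples of rho = 0.75, alpha = 10,
#'     beta = 3, consensus K_core = 30, t_lfc = 3 (8-fold), eps_lfp =
#'     1e-4, cell filter >= 800 UMIs.}
#'   \item{`worm`}{cell filter 100..8000 UMIs, K = 150 with 1000
#'     resamples, consensus K = 30 / size_min = 30 / alpha = 2,
#'     t_lfc = 4.}
#'   \item{`planaria`}{cell filter 500..18000 UMIs, K = 150, consensus as
#'     worm, t_lfc = 4.5, niche threshold 0.05.}
#' }
#' Any field can be overridden through `...`.
#'
#' @param preset `"pbmc"` (default), `"worm"`, or `"planaria"`.
#' @param ... named overrides of any config field.
#' @return an object of class `mc_config` (a named list).
#' @export
mc_config <- function(preset = c("pbmc", "worm", "planaria"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    # cell/gene filtering
    min_umi = 800, max_umi = Inf, gene_blacklist = character(0),
    # feature selection
    min_total_umi = 300, min_cells_at_min = 3, min_umi_per_cell = 3,
    size_corr_max = -0.1, niche_score_min = 0.1, var_mean_min = NULL,
    # similarity graph
    K = 100, alpha = 10, beta = 3, log_eps = 1, downsample_before_corr = FALSE,
    # partition
    size_min = NULL, max_passes = 100, stickiness = 1.01,
    # consensus
    n_boot = 500, rho = 0.75, k_core = 30, threshold_factor = 0.5,
    consensus_K = 30, consensus_size_min = 30, consensus_alpha = 2,
    # refinement
    t_lfc = 3, var_mean_split = 1.2, dbscan_eps = NULL, dbscan_min_pts = 4,
    # profiles
    eps_lfp = 1e-4, profile_regularization = "outside",
    # layout
    t_edge = 0.08, d_max = 4, layout_iterations = 500,
    # global
    rng_seed = 1
  )
  cfg <- switch(preset,
    pbmc = cfg,
    worm = utils::modifyList(cfg, list(
      min_umi = 100, max_umi = 8000, K = 150, n_boot = 1000, t_lfc = 4)),
    planaria = utils::modifyList(cfg, list(
      min_umi = 500, max_umi = 18000, K = 150, n_boot = 1000, t_lfc = 4.5,
      niche_score_min = 0.05)))
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(cfg, over, keep.null = TRUE)
  if (is.null(cfg$size_min)) cfg$size_min <- max(2, round(cfg$K / 4))
  if (cfg$size_min >= cfg$K) stop("size_min must be below K")
  if (cfg$k_core > cfg$consensus_K * cfg$beta)
    stop("k_core must not exceed consensus_K * beta")
  class(cfg) <- "mc_config"
  cfg
}

#' @export
print.mc_config <- function(x, ...) {
  cat(sprintf("mc_config: K=%d alpha=%g beta=%g | n_boot=%d rho=%g | consensus K=%d size_min=%d | t_lfc=%g | seed=%d\n",
              x$K, x$alpha, x$beta, x$n_boot, x$rho, x$consensus_K,
              x$consensus_size_min, x$t_lfc, x$rng_seed))
  invisible(x)
}

.stage_log <- function(quiet, stage, fmt, ...) {
  if (!quiet)
    message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                    sprintf(fmt, ...)))
}

#' Run the full metacell pipeline
#'
#' Executes load/filter, feature selection, balanced-graph construction,
#' bootstrap consensus partitioning, parametric outlier filtering,
#' homogeneity splitting, profile computation, adherence diagnostics and
#' the 2D projection, in that order. Every stage is a pure function of
#' (input, config, seed); reruns with the same triple are bit-identical.
#'
#' @param m a [umi_matrix] (already loaded).
#' @param config an [mc_config()].
#' @param features optional precomputed `feature_set` or character vector
#'   of gene ids (skips selection).
#' @param out_dir optional directory; when given, every intermediate is
#'   persisted there as plain-text tables plus a JSON-free run manifest.
#' @param diagnostics run [binomial_adherence()] (slowest stage;
#'   default TRUE).
#' @param quiet suppress stage logging.
#' @return an object of class `mc_pipeline`: list with `cover`,
#'   `profiles`, `layout`, `graph`, `features`, `assignment_raw`,
#'   `adherence` (or NULL), `outlier_report`, `config`, `manifest`.
#' @export
run_pipeline <- function(m, config = mc_config(), features = NULL,
                         out_dir = NULL, diagnostics = TRUE, quiet = FALSE) {
  stopifnot(inherits(m, "umi_matrix"), inherits(config, "mc_config"))
  seed <- config$rng_seed
  t0 <- Sys.time()

  .stage_log(quiet, "filter", "input %d genes x %d cells",
             length(m$gene_ids), length(m$cell_ids))
  mf <- filter_cells_and_genes(m, config$min_umi, config$max_umi,
                               config$gene_blacklist)
  .stage_log(quiet, "filter", "%d cells retained", length(mf$cell_ids))

  if (is.character(features)) features <- feature_set(features)
  if (is.null(features)) {
    st <- gene_stats(mf, min_umi_per_cell = config$min_umi_per_cell,
                     rng_seed = seed)
    features <- select_features(st,
      min_total_umi = config$min_total_umi,
      min_cells_at_min = config$min_cells_at_min,
      size_corr_max = config$size_corr_max,
      niche_score_min = config$niche_score_min,
      var_mean_min = config$var_mean_min,
      gene_blacklist = config$gene_blacklist)
  }
  .stage_log(quiet, "features", "%d feature genes", length(features$gene_ids))

  g <- build_balanced_graph(mf, features, K = config$K, alpha = config$alpha,
                            beta = config$beta, eps = config$log_eps,
                            downsample = config$downsample_before_corr,
                            rng_seed = seed)
  .stage_log(quiet, "graph", "%d edges", length(g$adj@x))

  cooc <- resample_partitions(g, size_min = config$size_min,
                              n_boot = config$n_boot, rho = config$rho,
                              max_passes = config$max_passes,
                              stickiness = config$stickiness,
                              rng_seed = seed)
  gb <- cooc_graph(cooc, k_core = config$k_core,
                   threshold_factor = config$threshold_factor)
  assignment <- final_partition(gb, size_min = config$consensus_size_min,
                                max_passes = config$max_passes,
                                stickiness = config$stickiness,
                                rng_seed = seed)
  .stage_log(quiet, "consensus", "%d metacells, %d unassigned",
             assignment$n_mcs, sum(is.na(assignment$mc)))

  filt <- filter_outliers(mf, assignment, t_lfc = config$t_lfc)
  .stage_log(quiet, "outliers", "%d parametric outliers", length(filt$outliers))
  spl <- split_heterogeneous(mf, filt$assignment,
                             var_mean_min = config$var_mean_split,
                             dbscan_eps = config$dbscan_eps,
                             dbscan_min_pts = config$dbscan_min_pts,
                             min_size = config$consensus_size_min,
                             rng_seed = seed)
  if (spl$n_split > 0)
    .stage_log(quiet, "split", "%d metacells split", spl$n_split)
  cover <- metacell_cover(spl$assignment, filt$outliers)

  profiles <- mc_profiles(mf, cover, eps_lfp = config$eps_lfp,
                          regularization = config$profile_regularization)

  adherence <- NULL
  if (diagnostics) {
    enriched <- rownames(profiles$lfp)[apply(profiles$lfp, 1, max) >= 1]
    diag_genes <- union(features$gene_ids, enriched)
    adherence <- binomial_adherence(mf, cover, genes = diag_genes,
                                    rng_seed = seed)
    .stage_log(quiet, "adherence", "median over-dispersion %.2f",
               stats::median(adherence$gene_mc$over_dispersion, na.rm = TRUE))
  }

  layout <- mc_layout(g, cover, t_edge = config$t_edge, d_max = config$d_max,
                      iterations = config$layout_iterations, rng_seed = seed)

  manifest <- list(
    package_version = as.character(utils::packageVersion("metacellr")),
    n_genes_in = length(m$gene_ids), n_cells_in = length(m$cell_ids),
    n_cells_filtered = length(mf$cell_ids),
    n_features = length(features$gene_ids), n_mcs = cover$n_mcs,
    n_outliers = sum(is.na(cover$mc)), rng_seed = seed,
    config_hash = config_hash(config),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  res <- structure(list(cover = cover, profiles = profiles, layout = layout,
                        graph = g, features = features, cooc = cooc,
                        assignment_raw = assignment, adherence = adherence,
                        outlier_report = filt$report, config = config,
                        matrix_filtered = mf, manifest = manifest),
                   class = "mc_pipeline")
  if (!is.null(out_dir)) persist_pipeline(res, out_dir)
  res
}

#' @export
print.mc_pipeline <- function(x, ...) {
  cat("metacell pipeline result\n")
  print(x$cover)
  cat(sprintf("  features: %d | config hash: %s | %.1f s\n",
              x$manifest$n_features, x$manifest$config_hash,
              x$manifest$elapsed_s))
  invisible(x)
}

#' Stable hash of a configuration (md5 of its canonical serialization)
#' @param config an `mc_config`.
#' @return a character md5 digest.
#' @export
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(config[order(names(unclass(config)))], file = tmp)
  unname(tools::md5sum(tmp))
}

#' Persist all pipeline intermediates as plain-text tables
#' @param res an `mc_pipeline` result.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
persist_pipeline <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(out_dir, x)
  write_features(res$features, fp("features.txt"))
  write_edges(res$graph, fp("balanced_graph.tsv"))
  write_cooc(res$cooc, fp("cooc.tsv"))
  write_assignment(res$cover, fp("metacells.tsv"))
  write_outlier_report(res$outlier_report, fp("outliers.tsv"))
  write_profiles(res$profiles, fp("profiles"))
  write_coords(res$layout, fp("coords.tsv"))
  if (!is.null(res$adherence))
    write_adherence(res$adherence, fp("over_dispersion.tsv"))
  manifest <- res$manifest
  writeLines(paste(names(manifest), vapply(manifest, format, ""), sep = "\t"),
             fp("manifest.tsv"))
  invisible(out_dir)
}
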