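#' Default pipeline configuration
#'
#' Nested list of every stage's parameters, suitable for writing as YAML and
#' editing. All method parameters (bootstrap sample size 100, 400 bootstraps
#' per condition, 10 principal components, UMAP n_neighbors 50 / min_dist 1.0
#' / spread 3.0, manhattan metric and Leiden clustering in the trajectory
#' stage) live here, never hard-coded in stage code.
#'
#' @param seed global seed; per-stage seeds are derived from it.
#' @param n_cells cells per synthetic condition (default 120).
#' @return nested list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1L, n_cells = 120L) {
  structure(list(
    seed = as.integer(seed),
    cohort = list(conditions = default_conditions(n_cells)),
    morphology = unclass(morpho_gen_params()),
    tmd = list(resolution = 100L, bandwidth = NULL, bounds_pad = 1.05,
               filtration = "radial"),
    bootstrap = list(sample_size = 100L, n_bootstraps = 400L,
                     replacement = TRUE),
    embed = list(n_pcs = 10L, umap_n_neighbors = 50L, umap_min_dist = 1.0,
                 umap_spread = 3.0, metric = "euclidean"),
    trajectory = list(num_dim = 10L, umap_metric = "manhattan",
                      umap_min_dist = 1.0, umap_n_neighbors = 50L,
                      umap_spread = 3.0, leiden_resolution = 1.0,
                      knn_k = 20L, use_partition = FALSE, close_loop = FALSE,
                      root_condition = "normotensive"),
    quant = list(min_size = 30L, threshold_method = "otsu",
                 watershed_tolerance = 1),
    images = unclass(image_gen_params())
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Missing keys fall back to [default_config()] values; unknown keys are an
#' error (typo guard).
#'
#' @param path YAML file path.
#' @return `pipeline_config` list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_config()
  merge_cfg <- function(base, user, prefix = "") {
    for (k in names(user)) {
      if (!k %in% names(base)) stop("unknown config key: ", prefix, k)
      if (is.list(base[[k]]) && is.list(user[[k]]) &&
          !is.null(names(base[[k]])) && k != "conditions") {
        base[[k]] <- merge_cfg(base[[k]], user[[k]], paste0(prefix, k, "."))
      } else {
        base[[k]] <- user[[k]]
      }
    }
    base
  }
  out <- merge_cfg(unclass(base), user)
  out$cohort$conditions <- as.data.frame(out$cohort$conditions)
  structure(out, class = "pipeline_config")
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  conds <- cfg$cohort$conditions
  if (!cfg$trajectory$root_condition %in% conds$name) {
    stop("trajectory root_condition '", cfg$trajectory$root_condition,
         "' is not one of the cohort conditions (",
         paste(conds$name, collapse = ", "), ")")
  }
  if (cfg$tmd$resolution < 2) stop("tmd resolution must be >= 2")
  invisible(cfg)
}

#' Run the analysis pipeline end to end
#'
#' Stages, in dependency order: `simulate` (synthetic cohort + marker
#' images), `features` (14-feature panel + group tests), `tmd` (barcodes and
#' persistence images), `embed` (bootstrap + PCA + UMAP + separation),
#' `trajectory` (Leiden + principal graph + pseudotime), `quant` (particle
#' counts + colocalization). Intermediate objects are cached under
#' `outdir/cache/` so a downstream stage can be re-run from cached upstream
#' outputs; all outputs are TSV plus a JSON run manifest with seeds and
#' checksums. A failing stage leaves a `<stage>.failed` marker and raises.
#'
#' @param config a `pipeline_config` (or path to a YAML config).
#' @param outdir output directory.
#' @param stages character vector of stages to run, or "all".
#' @param overwrite allow writing into an existing non-empty directory.
#' @return the run manifest (list), invisibly; also written as
#'   `outdir/run_manifest.json`.
#' @export
run_pipeline <- function(config = default_config(), outdir,
                         stages = "all", overwrite = FALSE) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  all_stages <- c("simulate", "features", "tmd", "embed", "trajectory",
                  "quant")
  if (identical(stages, "all")) stages <- all_stages
  stopifnot(all(stages %in% all_stages))
  if (dir.exists(outdir) && length(list.files(outdir)) && !overwrite &&
      "simulate" %in% stages) {
    stop("output directory exists and is not empty: ", outdir,
         " (use overwrite = TRUE)")
  }
  cache_dir <- file.path(outdir, "cache")
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(config$seed, 6L)
  names(seeds) <- all_stages
  manifest <- list(seed = config$seed, stage_seeds = as.list(seeds),
                   stages = list(), outputs = list())

  cache <- function(name) file.path(cache_dir, paste0(name, ".rds"))
  run_stage <- function(name, fun) {
    marker <- file.path(outdir, paste0(name, ".failed"))
    if (file.exists(marker)) unlink(marker)
    res <- tryCatch(fun(), error = function(e) {
      writeLines(conditionMessage(e), marker)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages[[name]] <<- "ok"
    res
  }

  if ("simulate" %in% stages) {
    run_stage("simulate", function() {
      spec <- cohort_spec(config$cohort$conditions, seed = seeds[["simulate"]],
                          gen_params = do.call(morpho_gen_params,
                                               config$morphology))
      man <- generate_cohort(spec, file.path(outdir, "cohort"),
                             overwrite = overwrite)
      img_par <- do.call(image_gen_params,
                         c(config$images[setdiff(names(config$images),
                                                 "seed")],
                           list(seed = seeds[["simulate"]] + 1L)))
      img <- generate_marker_image(img_par)
      dir.create(file.path(outdir, "images"), showWarnings = FALSE)
      write_marker_tiff(img, file.path(outdir, "images", "markers.tif"))
      utils::write.table(img$truth,
                         file.path(outdir, "images", "markers_truth.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      saveRDS(man, cache("manifest"))
      saveRDS(img, cache("image"))
      TRUE
    })
  }

  load_cohort <- function() {
    if (!file.exists(cache("cells"))) {
      cohort <- read_cohort(file.path(outdir, "cohort", "manifest.tsv"))
      saveRDS(cohort, cache("cells"))
    }
    readRDS(cache("cells"))
  }

  if ("features" %in% stages) {
    run_stage("features", function() {
      cohort <- load_cohort()
      ft <- feature_table(cohort$cells)
      write_feature_table(ft, file.path(outdir, "features.tsv"))
      if (!is.null(ft$tests)) {
        utils::write.table(ft$tests, file.path(outdir, "feature_tests.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      saveRDS(ft, cache("features"))
      TRUE
    })
  }

  if ("tmd" %in% stages) {
    run_stage("tmd", function() {
      cohort <- load_cohort()
      cpi <- cohort_persistence_images(
        cohort$cells, R = config$tmd$resolution,
        bandwidth = config$tmd$bandwidth,
        filtration = config$tmd$filtration)
      write_barcodes(cpi$barcodes, file.path(outdir, "barcodes.tsv"))
      saveRDS(cpi, cache("tmd"))
      TRUE
    })
  }

  if ("embed" %in% stages) {
    run_stage("embed", function() {
      cpi <- readRDS(cache("tmd"))
      cohort <- load_cohort()
      bs <- bootstrap_images(cpi$pixels, cohort$manifest$condition,
                             bootstrap_config(
                               sample_size = config$bootstrap$sample_size,
                               n_bootstraps = config$bootstrap$n_bootstraps,
                               replacement = config$bootstrap$replacement,
                               seed = seeds[["embed"]]))
      emb <- embed_samples(bs, embed_config(
        n_pcs = config$embed$n_pcs,
        umap_n_neighbors = config$embed$umap_n_neighbors,
        umap_min_dist = config$embed$umap_min_dist,
        umap_spread = config$embed$umap_spread,
        metric = config$embed$metric, seed = seeds[["embed"]]))
      write_embedding(emb, file.path(outdir, "embedding.tsv"))
      sep <- cluster_separation(emb)
      utils::write.table(sep, file.path(outdir, "separation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      saveRDS(bs, cache("bootstrap"))
      TRUE
    })
  }

  if ("trajectory" %in% stages) {
    run_stage("trajectory", function() {
      bs <- readRDS(cache("bootstrap"))
      tcfg <- trajectory_config(
        num_dim = config$trajectory$num_dim,
        umap_metric = config$trajectory$umap_metric,
        umap_min_dist = config$trajectory$umap_min_dist,
        umap_n_neighbors = config$trajectory$umap_n_neighbors,
        umap_spread = config$trajectory$umap_spread,
        leiden_resolution = config$trajectory$leiden_resolution,
        knn_k = config$trajectory$knn_k,
        root_condition = config$trajectory$root_condition,
        seed = seeds[["trajectory"]])
      tr <- fit_trajectory(bs, tcfg)
      write_trajectory(tr, file.path(outdir, "trajectory.tsv"))
      utils::write.table(pseudotime_by_condition(tr),
                         file.path(outdir, "pseudotime_by_condition.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      saveRDS(tr, cache("trajectory"))
      TRUE
    })
  }

  if ("quant" %in% stages) {
    run_stage("quant", function() {
      img <- readRDS(cache("image"))
      q <- count_particles(img$channels$ch1,
                           min_size = config$quant$min_size,
                           threshold_method = config$quant$threshold_method,
                           watershed_tolerance = config$quant$watershed_tolerance,
                           intensity_channels = list(ch2 = img$channels$ch2))
      utils::write.table(q$particles, file.path(outdir, "particles.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (q$particle_count >= 4) {
        ce <- correlate_expression(q$particles$mean_intensity,
                                   q$particles$mean_ch2)
        utils::write.table(
          data.frame(r = ce$r, n = ce$n, p_value = ce$p_value,
                     ci_lo = ce$ci[1], ci_hi = ce$ci[2]),
          file.path(outdir, "marker_correlation.tsv"),
          sep = "\t", quote = FALSE, row.names = FALSE)
      }
      TRUE
    })
  }

  tsvs <- list.files(outdir, pattern = "\\.tsv$", recursive = TRUE,
                     full.names = TRUE)
  manifest$outputs <- as.list(tools::md5sum(tsvs))
  names(manifest$outputs) <- substring(tsvs, nchar(outdir) + 2)
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
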