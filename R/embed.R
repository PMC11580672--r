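#' Bootstrap configuration
#'
#' Defaults follow the study design for morphological phenotyping: each
#' pseudo-sample averages the persistence images of 100 cells drawn with
#' replacement from one condition, and 400 pseudo-samples are collected per
#' condition.
#'
#' @param sample_size cells per bootstrap pseudo-sample (default 100).
#' @param n_bootstraps pseudo-samples per condition (default 400).
#' @param replacement draw with replacement (default TRUE).
#' @param seed integer seed.
#' @return list of class `bootstrap_config`.
#' @export
bootstrap_config <- function(sample_size = 100L, n_bootstraps = 400L,
                             replacement = TRUE, seed = 1L) {
  stopifnot(sample_size >= 1, n_bootstraps >= 1)
  structure(list(sample_size = as.integer(sample_size),
                 n_bootstraps = as.integer(n_bootstraps),
                 replacement = isTRUE(replacement), seed = seed),
            class = "bootstrap_config")
}

#' Bootstrap-aggregate per-cell persistence images into pseudo-samples
#'
#' For each condition, draws `n_bootstraps` resamples of `sample_size` cells
#' (with replacement by default) and takes the pixel-wise mean persistence
#' image of each resample. Each pseudo-sample's 10,000-pixel vector plays the
#' role of a gene-expression profile in the downstream embedding and
#' trajectory stages.
#'
#' @param pixels n_cells x n_pixels matrix (rows: cells), e.g. the `pixels`
#'   element of [cohort_persistence_images()].
#' @param conditions length-n_cells condition labels.
#' @param cfg a [bootstrap_config()].
#' @return list of class `bootstrap_samples`: `samples` data.frame
#'   (`sample_id`, `condition`), `pixels` (n_samples x n_pixels matrix),
#'   `members` (list of integer vectors of member row indices, each of length
#'   `sample_size`).
#' @export
bootstrap_images <- function(pixels, conditions, cfg = bootstrap_config()) {
  stopifnot(is.matrix(pixels), nrow(pixels) == length(conditions),
            inherits(cfg, "bootstrap_config"))
  conds <- unique(conditions)
  if (any(is.na(conds))) stop("conditions must be non-missing")
  with_seed(cfg$seed, {
    out_px <- vector("list", length(conds))
    out_members <- list()
    ids <- character(0); labs <- character(0)
    for (ci in seq_along(conds)) {
      rows <- which(conditions == conds[ci])
      if (!length(rows)) stop("condition with 0 cells: ", conds[ci])
      if (!cfg$replacement && cfg$sample_size > length(rows)) {
        stop("sample_size (", cfg$sample_size, ") exceeds population (",
             length(rows), ") for condition ", conds[ci],
             " without replacement")
      }
      draws <- replicate(cfg$n_bootstraps,
                         sample(rows, cfg$sample_size,
                                replace = cfg$replacement),
                         simplify = FALSE)
      # counts matrix (n_bootstraps x n_cells_in_cond) -> mean via matmul
      C <- matrix(0, cfg$n_bootstraps, length(rows))
      for (b in seq_along(draws)) {
        tb <- tabulate(match(draws[[b]], rows), nbins = length(rows))
        C[b, ] <- tb / cfg$sample_size
      }
      out_px[[ci]] <- C %*% pixels[rows, , drop = FALSE]
      out_members <- c(out_members, draws)
      ids <- c(ids, sprintf("%s_bs%04d", conds[ci],
                            seq_len(cfg$n_bootstraps)))
      labs <- c(labs, rep(as.character(conds[ci]), cfg$n_bootstraps))
    }
    px <- do.call(rbind, out_px)
    rownames(px) <- ids
    structure(list(samples = data.frame(sample_id = ids, condition = labs),
                   pixels = px, members = out_members),
              class = "bootstrap_samples")
  })
}

#' @export
print.bootstrap_samples <- function(x, ...) {
  cat(sprintf("<bootstrap_samples> %d pseudo-samples x %d pixels (%s)\n",
              nrow(x$pixels), ncol(x$pixels),
              paste(unique(x$samples$condition), collapse = ", ")))
  invisible(x)
}

#' Embedding configuration
#'
#' Defaults follow the phenotyping stage's printed parameters: the first ten
#' principal components feed UMAP with n_neighbors = 50, min_dist = 1.0 and
#' spread = 3.0 (euclidean metric).
#'
#' @param n_pcs principal components retained (default 10).
#' @param umap_n_neighbors,umap_min_dist,umap_spread,metric UMAP parameters.
#' @param seed integer seed (UMAP runs single-threaded for reproducibility).
#' @return list of class `embed_config`.
#' @export
embed_config <- function(n_pcs = 10L, umap_n_neighbors = 50L,
                         umap_min_dist = 1.0, umap_spread = 3.0,
                         metric = "euclidean", seed = 1L) {
  stopifnot(n_pcs >= 2, umap_n_neighbors >= 2, umap_min_dist > 0,
            umap_spread >= umap_min_dist)
  structure(list(n_pcs = as.integer(n_pcs),
                 umap_n_neighbors = as.integer(umap_n_neighbors),
                 umap_min_dist = umap_min_dist, umap_spread = umap_spread,
                 metric = metric, seed = seed),
            class = "embed_config")
}

# Exact PCA scores via the n x n Gram matrix when pixels outnumber samples
# (equivalent to SVD of the centred matrix). Returns scores, sdev and the
# number of components actually available.
pca_scores <- function(X, k, tol = 1e-10) {
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  if (ncol(X) >= n) {
    K <- tcrossprod(Xc)
    e <- eigen(K, symmetric = TRUE)
    pos <- e$values > tol * max(e$values, 0)
    k_av <- sum(pos)
    if (k_av < k) {
      warning("rank-deficient input: retaining ", max(k_av, 1L), " of ", k,
              " requested components")
      k <- max(k_av, 1L)   # keep one (possibly zero) column for degenerate input
    }
    d <- sqrt(pmax(e$values[seq_len(k)], 0))
    scores <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(d, k)
    sdev <- sqrt(pmax(e$values, 0) / (n - 1))
  } else {
    s <- svd(Xc, nu = min(n, ncol(X)), nv = 0)
    pos <- s$d > tol * max(s$d, 0)
    k_av <- sum(pos)
    if (k_av < k) {
      warning("rank-deficient input: retaining ", max(k_av, 1L), " of ", k,
              " requested components")
      k <- max(k_av, 1L)
    }
    scores <- s$u[, seq_len(k), drop = FALSE] %*% diag(s$d[seq_len(k)], k)
    sdev <- s$d / sqrt(n - 1)
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = scores, sdev = sdev, k = k)
}

# Seeded, single-threaded UMAP. Exact-duplicate rows are collapsed before
# embedding and mapped back, so identical inputs get identical coordinates.
# `key` identifies duplicates; it defaults to the rows of X but callers pass
# the upstream (pre-PCA) rows so that duplicate inputs stay duplicates even
# when the decomposition introduces float-level jitter.
run_umap <- function(X, n_neighbors, min_dist, spread, metric, seed,
                     key = NULL) {
  if (is.null(key)) key <- apply(X, 1, paste, collapse = "\r")
  uniq <- !duplicated(key)
  Xu <- X[uniq, , drop = FALSE]
  if (nrow(Xu) < 3) {
    # all points coincide (or nearly): a flat layout is the only meaningful one
    coords_u <- matrix(0, nrow(Xu), 2)
  } else {
    nn <- min(n_neighbors, nrow(Xu) - 1)
    coords_u <- with_seed(seed, {
      uwot::umap(Xu, n_neighbors = nn, min_dist = min_dist, spread = spread,
                 metric = metric, n_threads = 1, n_sgd_threads = 0,
                 batch = FALSE)
    })
  }
  coords_u[match(key, key[uniq]), , drop = FALSE]
}

# Duplicate-detection key over the rows of a numeric matrix. Pasting whole
# rows is O(n*p) string work; two fixed projections are enough to identify
# exact duplicates (distinct rows collide only if both weighted sums agree to
# full double precision, in which case they are treated as duplicates — the
# harmless direction).
row_key <- function(X) {
  p <- ncol(X)
  v1 <- sin(seq_len(p)); v2 <- cos(seq_len(p))
  # row-wise sums (not one BLAS multiply): blocked BLAS kernels may add in a
  # position-dependent order, giving float-different results for identical
  # rows, which is exactly what this key must not do
  vapply(seq_len(nrow(X)), function(i) {
    xi <- X[i, ]
    paste(format(sum(xi * v1), digits = 17), format(sum(xi * v2), digits = 17))
  }, character(1))
}

#' Embed bootstrap pseudo-samples by PCA then UMAP
#'
#' PCA is fitted jointly on the pooled pseudo-samples of all conditions (a
#' shared basis is required for cross-condition geometry); UMAP embeds the
#' retained PC scores. Runs are deterministic for a fixed seed (UMAP is
#' seeded and single-threaded; exact-duplicate rows receive identical
#' coordinates).
#'
#' @param samples a [bootstrap_samples()] object, or a plain pixel matrix.
#' @param cfg an [embed_config()].
#' @param conditions condition labels (taken from `samples` when omitted).
#' @return data.frame of class `embedding_result`: `sample_id`, `condition`,
#'   `PC1..PCk`, `UMAP1`, `UMAP2`.
#' @export
embed_samples <- function(samples, cfg = embed_config(), conditions = NULL) {
  if (inherits(samples, "bootstrap_samples")) {
    px <- samples$pixels
    conditions <- conditions %||% samples$samples$condition
    ids <- samples$samples$sample_id
  } else {
    px <- samples
    ids <- rownames(px) %||% sprintf("s%05d", seq_len(nrow(px)))
  }
  stopifnot(nrow(px) >= cfg$n_pcs + 1)
  p <- pca_scores(px, cfg$n_pcs)
  um <- run_umap(p$scores, cfg$umap_n_neighbors, cfg$umap_min_dist,
                 cfg$umap_spread, cfg$metric, cfg$seed, key = row_key(px))
  out <- data.frame(sample_id = ids,
                    condition = conditions %||% NA_character_,
                    p$scores, UMAP1 = um[, 1], UMAP2 = um[, 2])
  class(out) <- c("embedding_result", class(out))
  out
}

#' Quantify condition separation in an embedding
#'
#' For every pair of conditions, the mean silhouette width of the two
#' condition labels over UMAP coordinates, and the distance between the two
#' condition centroids — the quantitative counterpart of conditions
#' "clustering together" vs "clustering separately" in the UMAP plots.
#'
#' @param result an `embedding_result` from [embed_samples()] (or any
#'   data.frame with `condition`, `UMAP1`, `UMAP2`).
#' @return data.frame: `cond_a`, `cond_b`, `silhouette`, `centroid_dist`.
#' @export
cluster_separation <- function(result) {
  conds <- unique(result$condition)
  if (length(conds) < 2L) stop("need >= 2 conditions")
  xy <- as.matrix(result[, c("UMAP1", "UMAP2")])
  pairs <- utils::combn(conds, 2)
  out <- data.frame(cond_a = pairs[1, ], cond_b = pairs[2, ],
                    silhouette = NA_real_, centroid_dist = NA_real_)
  for (i in seq_len(ncol(pairs))) {
    sel <- result$condition %in% pairs[, i]
    lab <- as.integer(factor(result$condition[sel], levels = pairs[, i]))
    sil <- cluster::silhouette(lab, stats::dist(xy[sel, , drop = FALSE]))
    out$silhouette[i] <- mean(sil[, "sil_width"])
    ca <- colMeans(xy[result$condition == pairs[1, i], , drop = FALSE])
    cb <- colMeans(xy[result$condition == pairs[2, i], , drop = FALSE])
    out$centroid_dist[i] <- sqrt(sum((ca - cb)^2))
  }
  out
}

#' Write an embedding result as TSV
#'
#' @param result an `embedding_result`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
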