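#' Trajectory configuration
#'
#' Defaults follow the trajectory stage's printed parameters for treating
#' persistence-image pixels as genes: 10 principal components, UMAP with the
#' manhattan metric, min_dist = 1.0 and n_neighbors = 50, Leiden clustering,
#' a single partition and no loop closure (the principal graph is a tree).
#'
#' @param num_dim principal components retained (default 10).
#' @param umap_metric UMAP metric (default "manhattan").
#' @param umap_min_dist,umap_n_neighbors,umap_spread UMAP parameters
#'   (`umap_spread` defaults to 3.0 for consistency with the embedding
#'   stage).
#' @param cluster_method only "leiden" is implemented.
#' @param leiden_resolution Leiden resolution parameter (default 1.0).
#' @param knn_k neighbours of the kNN graph fed to Leiden (default 20).
#' @param use_partition,close_loop kept for interface fidelity; must be FALSE
#'   (single partition, acyclic principal graph).
#' @param root_condition condition anchoring pseudotime 0 (the homeostatic /
#'   control population).
#' @param seed integer seed.
#' @return list of class `trajectory_config`.
#' @export
trajectory_config <- function(num_dim = 10L, umap_metric = "manhattan",
                              umap_min_dist = 1.0, umap_n_neighbors = 50L,
                              umap_spread = 3.0,
                              cluster_method = "leiden",
                              leiden_resolution = 1.0, knn_k = 20L,
                              use_partition = FALSE, close_loop = FALSE,
                              root_condition = "normotensive", seed = 1L) {
  stopifnot(num_dim >= 2, umap_n_neighbors >= 2, knn_k >= 1,
            identical(cluster_method, "leiden"),
            !isTRUE(use_partition), !isTRUE(close_loop))
  structure(list(num_dim = as.integer(num_dim), umap_metric = umap_metric,
                 umap_min_dist = umap_min_dist,
                 umap_n_neighbors = as.integer(umap_n_neighbors),
                 umap_spread = umap_spread, cluster_method = cluster_method,
                 leiden_resolution = leiden_resolution,
                 knn_k = as.integer(knn_k),
                 use_partition = FALSE, close_loop = FALSE,
                 root_condition = root_condition, seed = seed),
            class = "trajectory_config")
}

# symmetric kNN graph (igraph) from a coordinate matrix
knn_graph <- function(xy, k) {
  n <- nrow(xy)
  k <- min(k, n - 1L)
  d <- as.matrix(stats::dist(xy))
  nn <- apply(d, 1, function(r) order(r)[2:(k + 1L)])
  el <- cbind(rep(seq_len(n), each = k), as.vector(nn))
  el <- unique(t(apply(el, 1, sort)))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::simplify(g)
}

#' Fit a pseudotime trajectory over bootstrap pseudo-samples
#'
#' Treats each pseudo-sample's persistence-image pixels as a gene-expression
#' profile and runs: PCA (`num_dim` components), then kNN graph and Leiden
#' community detection on the PC scores, then a principal graph as the
#' minimum spanning tree over cluster centroids (a transparent surrogate for
#' reversed-graph-embedding tree learning; the contract of an acyclic,
#' single-partition principal graph is preserved). Each pseudo-sample is
#' projected to the nearest point on the nearest tree edge, and pseudotime
#' is the geodesic arc length along the tree from the root (the centroid
#' node nearest the `root_condition` samples), shifted so the minimum over
#' samples is exactly 0.
#'
#' The backbone is clustered and learned in the retained PC space, where
#' distances between pseudo-sample populations are faithful; a UMAP of the
#' PC scores (manhattan metric by default) provides the 2D display layout
#' carried in the output. Learning the backbone on display coordinates is
#' unreliable when condition populations are compact and well separated:
#' their mutual placement in a 2D UMAP is then largely arbitrary, whereas
#' PC-space geometry is not.
#'
#' @param samples a [bootstrap_samples()] object, or an n x p pixel matrix.
#' @param cfg a [trajectory_config()]; `cfg$root_condition` must occur in the
#'   condition labels.
#' @param conditions condition labels (taken from `samples` when omitted).
#' @return object of class `trajectory_result`: `samples` data.frame
#'   (`sample_id`, `condition`, `cluster`, `pseudotime`, `UMAP1`, `UMAP2`,
#'   `edge_a`, `edge_b`, `t_along` for projection bookkeeping), `graph`
#'   (list: `nodes` centroid data.frame in PC space, `nodes_umap` display
#'   centroids, `edges` data.frame with `from`, `to`, `length`), `root_node`,
#'   `offset` (raw-geodesic value subtracted so `min(pseudotime) == 0`) and
#'   `node_dist` (geodesic node-to-node distance matrix).
#' @export
fit_trajectory <- function(samples, cfg = trajectory_config(),
                           conditions = NULL) {
  if (inherits(samples, "bootstrap_samples")) {
    px <- samples$pixels
    conditions <- conditions %||% samples$samples$condition
    ids <- samples$samples$sample_id
  } else {
    px <- as.matrix(samples)
    ids <- rownames(px) %||% sprintf("s%05d", seq_len(nrow(px)))
  }
  stopifnot(inherits(cfg, "trajectory_config"), nrow(px) >= 3)
  if (is.null(conditions)) stop("condition labels are required")
  if (!cfg$root_condition %in% conditions) {
    stop("root_condition '", cfg$root_condition,
         "' absent from condition labels")
  }

  p <- pca_scores(px, min(cfg$num_dim, nrow(px) - 1L))
  X <- p$scores
  um <- run_umap(X, cfg$umap_n_neighbors, cfg$umap_min_dist,
                 cfg$umap_spread, cfg$umap_metric, cfg$seed,
                 key = row_key(px))

  g <- knn_graph(X, cfg$knn_k)
  memb <- with_seed(cfg$seed, {
    cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = cfg$leiden_resolution,
                                 n_iterations = 10)
    igraph::membership(cl)
  })
  cl_ids <- sort(unique(memb))
  centroids <- t(vapply(cl_ids, function(cid) {
    colMeans(X[memb == cid, , drop = FALSE])
  }, numeric(ncol(X))))
  centroids_umap <- t(vapply(cl_ids, function(cid) {
    colMeans(um[memb == cid, , drop = FALSE])
  }, numeric(2)))

  n_cl <- nrow(centroids)
  if (n_cl == 1L) {
    warning("single cluster: principal graph is one node; pseudotime is ",
            "distance to the centroid")
    d0 <- sqrt(rowSums(sweep(X, 2, centroids[1, ])^2))
    res_samples <- data.frame(sample_id = ids, condition = conditions,
                              cluster = as.integer(memb),
                              pseudotime = d0 - min(d0),
                              UMAP1 = um[, 1], UMAP2 = um[, 2],
                              edge_a = 1L, edge_b = 1L, t_along = 0)
    return(structure(
      list(samples = res_samples,
           graph = list(nodes = as.data.frame(centroids),
                        nodes_umap = as.data.frame(centroids_umap),
                        edges = data.frame(from = integer(0), to = integer(0),
                                           length = numeric(0))),
           root_node = 1L, offset = min(d0), node_dist = matrix(0, 1, 1)),
      class = "trajectory_result"))
  }

  cd <- as.matrix(stats::dist(centroids))
  full <- igraph::graph_from_adjacency_matrix(cd, mode = "undirected",
                                              weighted = TRUE)
  tree <- igraph::mst(full, weights = igraph::E(full)$weight)
  el <- igraph::as_edgelist(tree, names = FALSE)
  elen <- igraph::E(tree)$weight
  node_dist <- igraph::distances(tree, weights = elen)

  root_centroid <- colMeans(X[conditions == cfg$root_condition, ,
                              drop = FALSE])
  root_node <- which.min(sqrt(rowSums(sweep(centroids, 2,
                                            root_centroid)^2)))

  proj <- project_to_tree(X, centroids, el)
  raw_pt <- pmin(node_dist[root_node, proj$a] + proj$t * proj$len,
                 node_dist[root_node, proj$b] + (1 - proj$t) * proj$len)
  offset <- min(raw_pt)

  res_samples <- data.frame(sample_id = ids, condition = conditions,
                            cluster = as.integer(memb),
                            pseudotime = raw_pt - offset,
                            UMAP1 = um[, 1], UMAP2 = um[, 2],
                            edge_a = proj$a, edge_b = proj$b,
                            t_along = proj$t)
  structure(list(samples = res_samples,
                 graph = list(nodes = as.data.frame(centroids),
                              nodes_umap = as.data.frame(centroids_umap),
                              edges = data.frame(from = el[, 1], to = el[, 2],
                                                 length = elen)),
                 root_node = root_node, offset = offset,
                 node_dist = node_dist),
            class = "trajectory_result")
}

# Project points onto the nearest point of the nearest segment among tree
# edges. Returns edge endpoints (a, b), fractional position t in [0,1],
# edge length, and projection distance.
project_to_tree <- function(pts, centroids, edgelist) {
  n <- nrow(pts)
  best <- list(a = integer(n), b = integer(n), t = numeric(n),
               len = numeric(n), d = rep(Inf, n))
  for (e in seq_len(nrow(edgelist))) {
    a <- edgelist[e, 1]; b <- edgelist[e, 2]
    pa <- centroids[a, ]; ab <- centroids[b, ] - pa
    len2 <- sum(ab^2)
    t <- as.vector(pmin(1, pmax(0, (sweep(pts, 2, pa) %*% ab) / len2)))
    proj <- matrix(pa, n, length(pa), byrow = TRUE) + t %o% ab
    d <- sqrt(rowSums((pts - proj)^2))
    upd <- d < best$d
    best$a[upd] <- a; best$b[upd] <- b; best$t[upd] <- t[upd]
    best$len[upd] <- sqrt(len2); best$d[upd] <- d[upd]
  }
  best
}

#' @export
print.trajectory_result <- function(x, ...) {
  cat(sprintf(
    "<trajectory_result> %d samples, %d clusters, root node %d, max pseudotime %.2f\n",
    nrow(x$samples), nrow(x$graph$nodes), x$root_node,
    max(x$samples$pseudotime)))
  invisible(x)
}

#' Recovery of the latent reactivity axis by pseudotime
#'
#' Correlates each pseudo-sample's ground-truth mean reactivity (mean phi of
#' its member cells) with its fitted pseudotime: Spearman rho plus a
#' permutation p-value (pseudotime permuted across pseudo-samples).
#'
#' @param sample_phi per-pseudo-sample mean generator reactivity.
#' @param pseudotime per-pseudo-sample pseudotime (same order).
#' @param n_perm permutations for the p-value (default 10000).
#' @param seed permutation seed.
#' @return list: `rho`, `p_value`, `n`, `flag` ("ok", "constant_pseudotime",
#'   or "underdetermined" when fewer than 3 distinct phi values are present,
#'   where rank correlation is trivially +/-1).
#' @export
pseudotime_recovery <- function(sample_phi, pseudotime, n_perm = 10000L,
                                seed = 1L) {
  stopifnot(length(sample_phi) == length(pseudotime))
  if (stats::sd(pseudotime) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = length(sample_phi),
                flag = "constant_pseudotime"))
  }
  rho <- stats::cor(sample_phi, pseudotime, method = "spearman")
  rp <- rank(sample_phi); rt <- rank(pseudotime)
  obs <- abs(stats::cor(rp, rt))
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      abs(stats::cor(rp, sample(rt))) >= obs - 1e-12
    }, logical(1)))
  })
  flag <- if (length(unique(round(sample_phi, 10))) < 3) "underdetermined"
          else "ok"
  list(rho = rho, p_value = (exceed + 1) / (n_perm + 1),
       n = length(sample_phi), flag = flag)
}

#' Per-condition pseudotime summary (median ordering along the trajectory)
#'
#' @param result a [fit_trajectory()] result.
#' @return data.frame: `condition`, `median_pseudotime`, `mean_pseudotime`,
#'   `n`, ordered by median pseudotime.
#' @export
pseudotime_by_condition <- function(result) {
  s <- result$samples
  agg <- do.call(rbind, lapply(split(s, s$condition), function(d) {
    data.frame(condition = d$condition[1],
               median_pseudotime = stats::median(d$pseudotime),
               mean_pseudotime = mean(d$pseudotime), n = nrow(d))
  }))
  agg <- agg[order(agg$median_pseudotime), ]
  rownames(agg) <- NULL
  agg
}

#' Write a trajectory result as TSVs
#'
#' @param result a [fit_trajectory()] result.
#' @param path sample-level TSV path; the principal-graph edge list is
#'   written next to it with suffix `_graph.tsv`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(result, path) {
  utils::write.table(result$samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gpath <- sub("\\.tsv$", "", path)
  utils::write.table(result$graph$edges, paste0(gpath, "_graph.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
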