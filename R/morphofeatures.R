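#' The 14-feature morphometric panel
#'
#' Names of the fixed per-cell feature panel computed by
#' [extract_features()]: skeleton counts and lengths, frustum-based surface
#' and volume, shape factors, and a graph-centrality summary.
#'
#' @return character vector of length 14.
#' @export
feature_names <- function() {
  c("n_nodes", "n_branch_points", "n_tips", "total_branch_length",
    "mean_branch_length", "max_branch_order", "mean_radial_distance",
    "cell_volume", "cell_surface_area", "soma_volume", "sphericity",
    "circularity", "ramification_index", "mean_node_betweenness")
}

#' Extract the morphometric feature panel from one morphology
#'
#' Computes 14 per-cell features from the SWC tree model:
#' \describe{
#'   \item{n_nodes}{skeleton node count.}
#'   \item{n_branch_points}{non-root nodes with >= 2 children.}
#'   \item{n_tips}{nodes with no children (0 for a soma-only cell).}
#'   \item{total_branch_length}{sum of Euclidean segment lengths, um.}
#'   \item{mean_branch_length}{total length / number of branches, where a
#'     branch is a maximal path between soma/branch-point/tip endpoints.}
#'   \item{max_branch_order}{maximum centrifugal branch order (primary
#'     processes have order 1; order increments after each branch point).}
#'   \item{mean_radial_distance}{mean Euclidean distance of non-root nodes
#'     from the soma, um.}
#'   \item{cell_volume}{soma sphere plus per-segment conical frusta
#'     (radius-annotated), um^3.}
#'   \item{cell_surface_area}{soma sphere area plus frustum lateral areas,
#'     um^2.}
#'   \item{soma_volume}{4/3 pi r^3 of the soma node, um^3.}
#'   \item{sphericity}{pi^(1/3) (6V)^(2/3) / A with V = cell_volume,
#'     A = cell_surface_area; 1 for a sphere (soma-only cell), decreasing
#'     with ramification.}
#'   \item{circularity}{4 pi Area / Perimeter^2 of the convex hull of the
#'     xy-projection of the nodes (imaging-plane shape factor); defined as 1
#'     for a soma-only cell and 0 for a degenerate (collinear) projection.}
#'   \item{ramification_index}{tips per primary process.}
#'   \item{mean_node_betweenness}{mean normalized shortest-path betweenness
#'     centrality over tree nodes.}
#' }
#'
#' @param m a [morphology()].
#' @return one-row data.frame: `cell_id`, `condition`, then the 14 features.
#' @export
extract_features <- function(m) {
  stopifnot(inherits(m, "morphology"))
  nd <- m$nodes
  n <- nrow(nd)
  ridx <- root_index(m)
  pidx <- parent_index(m)
  kids <- children_index(m)
  n_children <- lengths(kids)

  tips <- which(n_children == 0L & seq_len(n) != ridx)
  branch_pts <- which(n_children >= 2L & seq_len(n) != ridx)
  n_primary <- n_children[ridx]

  seg_len <- segment_lengths(m)
  total_len <- sum(seg_len)
  radial <- radial_distance(m)

  # branches: maximal paths whose endpoints are root / branch point / tip.
  # Walk up from every branch endpoint (tip or branch point) to the previous
  # endpoint; count and accumulate branch order along the way.
  endpoint <- rep(FALSE, n)
  endpoint[c(tips, branch_pts, ridx)] <- TRUE
  n_branches <- sum(endpoint) - 1L  # every endpoint except the root tops one branch
  # centrifugal branch order per branch endpoint
  order_of <- integer(n)           # order of the branch ending at this endpoint
  max_order <- 0L
  if (n > 1L) {
    topo <- seq_len(n)             # nodes are parents-first
    branch_order <- integer(n)     # order of the branch each node lies on
    for (v in topo) {
      if (v == ridx) { branch_order[v] <- 0L; next }
      p <- pidx[v]
      branch_order[v] <- if (p == ridx || n_children[p] >= 2L)
        branch_order[p] + 1L else branch_order[p]
    }
    max_order <- max(branch_order)
  }

  soma_r <- nd$radius[ridx]
  soma_vol <- 4 / 3 * pi * soma_r^3
  soma_area <- 4 * pi * soma_r^2
  frustum_vol <- frustum_lat <- 0
  if (n > 1L) {
    nr <- seq_len(n)[-ridx]
    r1 <- nd$radius[pidx[nr]]
    # the soma sphere is accounted for separately; segments leaving the soma
    # use the process radius at both ends
    r1[pidx[nr] == ridx] <- nd$radius[nr][pidx[nr] == ridx]
    r2 <- nd$radius[nr]
    L <- seg_len[nr]
    frustum_vol <- sum(pi * L / 3 * (r1^2 + r1 * r2 + r2^2))
    frustum_lat <- sum(pi * (r1 + r2) * sqrt(L^2 + (r1 - r2)^2))
  }
  V <- soma_vol + frustum_vol
  A <- soma_area + frustum_lat
  sphericity <- pi^(1 / 3) * (6 * V)^(2 / 3) / A

  circularity <- xy_hull_circularity(nd$x, nd$y)

  mean_btw <- 0
  if (n > 2L) {
    g <- igraph::graph_from_edgelist(
      cbind(pidx[-ridx], seq_len(n)[-ridx]), directed = FALSE)
    mean_btw <- mean(igraph::betweenness(g, directed = FALSE,
                                         normalized = TRUE))
  }

  data.frame(
    cell_id = m$cell_id, condition = m$condition,
    n_nodes = n,
    n_branch_points = length(branch_pts),
    n_tips = length(tips),
    total_branch_length = total_len,
    mean_branch_length = if (n_branches >= 1L) total_len / n_branches else 0,
    max_branch_order = max_order,
    mean_radial_distance = if (n > 1L) mean(radial[-ridx]) else 0,
    cell_volume = V,
    cell_surface_area = A,
    soma_volume = soma_vol,
    sphericity = sphericity,
    circularity = circularity,
    ramification_index = if (n_primary >= 1L) length(tips) / n_primary else 0,
    mean_node_betweenness = mean_btw,
    stringsAsFactors = FALSE
  )
}

# 4 pi A / P^2 of the convex hull of the xy point cloud; 1 for a single
# point (soma disk), 0 for a degenerate hull.
xy_hull_circularity <- function(x, y) {
  pts <- unique(cbind(x, y))
  if (nrow(pts) == 1L) return(1)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  if (length(h) < 3L) return(0)
  hx <- pts[h, 1]; hy <- pts[h, 2]
  area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  per <- sum(sqrt(diff(c(hx, hx[1]))^2 + diff(c(hy, hy[1]))^2))
  if (per <= 0 || area <= 0) return(0)
  4 * pi * area / per^2
}

#' Per-cohort feature table, condition summaries and group tests
#'
#' Applies [extract_features()] to every cell, summarizes each feature per
#' condition (mean +/- SEM), and, when >= 2 conditions with >= 3 cells each
#' are present, tests each feature across conditions: Welch t-test for two
#' groups, one-way ANOVA with Tukey HSD post-hoc for three or more (via
#' [compare_groups()]). Reports the fraction of testable features with
#' p < alpha per comparison — the fraction-of-features-changed readout.
#' Zero-variance features (identical in all groups) are skipped and flagged.
#'
#' @param cells list of [morphology()], or the result of [read_cohort()].
#' @param conditions optional condition labels overriding the per-cell ones.
#' @param alpha significance level for the fraction-significant readout.
#' @param features feature subset to analyze (default all 14).
#' @return list with `features` (per-cell data.frame), `summary`
#'   (condition x feature mean/sem/n), `tests` (per-feature omnibus p and,
#'   for >= 3 groups, Tukey pairwise adjusted p), `fraction_significant`
#'   (named numeric, one entry per comparison), `skipped` (zero-variance
#'   features).
#' @export
feature_table <- function(cells, conditions = NULL, alpha = 0.05,
                          features = feature_names()) {
  if (!is.null(cells$cells)) cells <- cells$cells
  stopifnot(length(cells) >= 1, all(features %in% feature_names()))
  feats <- do.call(rbind, lapply(cells, extract_features))
  rownames(feats) <- NULL
  if (!is.null(conditions)) feats$condition <- conditions
  groups <- unique(feats$condition)
  groups <- groups[!is.na(groups)]

  summ <- do.call(rbind, lapply(groups, function(g) {
    sub <- feats[feats$condition %in% g, features, drop = FALSE]
    data.frame(condition = g, feature = features,
               mean = vapply(sub, mean, numeric(1)),
               sem = vapply(sub, function(v) {
                 if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
               }, numeric(1)),
               n = nrow(sub), row.names = NULL)
  }))

  out <- list(features = feats, summary = summ, tests = NULL,
              fraction_significant = NULL, skipped = character(0))
  if (length(groups) < 2L) return(out)
  sizes <- table(factor(feats$condition, levels = groups))
  if (any(sizes < 3L)) {
    warning("need >= 3 cells per condition for group tests; skipping tests")
    return(out)
  }

  tests <- list(); tukey <- list(); skipped <- character(0)
  for (f in features) {
    v <- feats[[f]]
    grp <- factor(feats$condition, levels = groups)
    if (stats::sd(v) == 0) { skipped <- c(skipped, f); next }
    cmp <- compare_groups(v, grp)
    tests[[f]] <- data.frame(feature = f, statistic = cmp$statistic,
                             p_value = cmp$p_value, row.names = NULL)
    if (!is.null(cmp$posthoc)) {
      tk <- cmp$posthoc
      tk$feature <- f
      tukey[[f]] <- tk
    }
  }
  tests_df <- do.call(rbind, tests)
  rownames(tests_df) <- NULL
  frac <- c(omnibus = mean(tests_df$p_value < alpha))
  if (length(tukey)) {
    tk_all <- do.call(rbind, tukey)
    rownames(tk_all) <- NULL
    per_pair <- tapply(tk_all$p_adj < alpha, tk_all$pair, mean)
    frac <- c(frac, per_pair)
    out$tukey <- tk_all
  }
  out$tests <- tests_df
  out$fraction_significant <- frac
  out$skipped <- skipped
  out
}

#' Write a per-cell feature table as TSV
#'
#' @param ft result of [feature_table()] (or its `features` element).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  df <- if (is.data.frame(ft)) ft else ft$features
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
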