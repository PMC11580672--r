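# Shared fixtures and independent oracles, built in code at test time.

# quick morphology constructor from a compact node spec
make_tree <- function(...) {
  rows <- list(...)
  nodes <- do.call(rbind, lapply(rows, function(r) {
    data.frame(id = r[1], struct_type = r[2], x = r[3], y = r[4], z = r[5],
               radius = r[6], parent_id = r[7])
  }))
  morphology(nodes, cell_id = "fixture")
}

# the Y-shaped test cell: root -> branch point at z=5 -> two tips
y_tree <- function() {
  make_tree(c(1, 1, 0, 0, 0, 1, -1),
            c(2, 3, 0, 0, 5, 1, 1),
            c(3, 3, 0, 0, 10, 1, 2),
            c(4, 3, 0, 3, 9, 1, 2))
}

# random rooted tree with strictly increasing radial distance along every
# root-to-leaf path (outward growth), n_tips tips, distinct node distances
random_monotone_tree <- function(n_tips, seed) {
  set.seed(seed)
  nodes <- data.frame(id = 1L, struct_type = 1L, x = 0, y = 0, z = 0,
                      radius = 3, parent_id = -1L)
  open <- 1L  # node ids that may still receive children
  next_id <- 2L
  while (sum(nodes$parent_id != -1L & !nodes$id %in% nodes$parent_id) <
         n_tips || next_id <= 2L) {
    par_id <- if (length(open) == 1L) open else sample(open, 1)
    pr <- nodes[nodes$id == par_id, ]
    r0 <- sqrt(pr$x^2 + pr$y^2 + pr$z^2)
    # a point strictly farther from the origin than the parent
    repeat {
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      pos <- c(pr$x, pr$y, pr$z) + runif(1, 1, 8) * dir
      if (sqrt(sum(pos^2)) > r0 + 1e-6) break
    }
    nodes <- rbind(nodes, data.frame(id = next_id, struct_type = 3L,
                                     x = pos[1], y = pos[2], z = pos[3],
                                     radius = runif(1, 0.3, 1.5),
                                     parent_id = par_id))
    # keep at most 2 children per node
    if (sum(nodes$parent_id == par_id) >= 2) open <- setdiff(open, par_id)
    open <- c(open, next_id)
    next_id <- next_id + 1L
    n_leaves <- sum(!nodes$id %in% nodes$parent_id)
    if (n_leaves >= n_tips) break
  }
  morphology(nodes, cell_id = paste0("rand", seed))
}

# Independent TMD oracle: simulate the descending (superlevel-set) filtration
# with union-find over nodes sorted by decreasing radial distance. Components
# carry (birth, carrying tip id); merges at an activating node kill the
# younger components at that node's filtration value.
oracle_barcode_unionfind <- function(m) {
  nd <- m$nodes
  n <- nrow(nd)
  ridx <- which(nd$parent_id == -1L)
  f <- sqrt((nd$x - nd$x[ridx])^2 + (nd$y - nd$y[ridx])^2 +
            (nd$z - nd$z[ridx])^2)
  pidx <- match(nd$parent_id, nd$id)
  adj <- vector("list", n)
  for (v in seq_len(n)) {
    if (v == ridx) next
    adj[[v]] <- c(adj[[v]], pidx[v])
    adj[[pidx[v]]] <- c(adj[[pidx[v]]], v)
  }
  parent <- seq_len(n)            # union-find
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  birth <- rep(NA_real_, n); tip <- rep(NA_integer_, n)  # per root-of-set
  active <- rep(FALSE, n)
  bars <- NULL
  is_leaf <- !(seq_len(n) %in% pidx)
  for (v in order(-f)) {
    active[v] <- TRUE
    birth[v] <- f[v]
    tip[v] <- if (is_leaf[v]) nd$id[v] else NA_integer_
    comps <- unique(vapply(adj[[v]][active[adj[[v]]]],
                           function(u) find(u), integer(1)))
    for (cr in comps) {
      rv <- find(v)
      # elder rule: larger birth survives; ties by smaller tip id
      a <- rv; b <- cr
      keep_a <- (birth[a] > birth[b]) ||
        (birth[a] == birth[b] && !is.na(tip[a]) &&
           (is.na(tip[b]) || tip[a] < tip[b]))
      surv <- if (keep_a) a else b
      dead <- if (keep_a) b else a
      if (!is.na(tip[dead])) {
        bars <- rbind(bars, data.frame(birth = birth[dead], death = f[v],
                                       tip_id = tip[dead]))
      }
      parent[dead] <- surv
    }
  }
  last <- find(ridx)
  bars <- rbind(bars, data.frame(birth = birth[last], death = f[ridx],
                                 tip_id = tip[last]))
  bars[order(-bars$birth, bars$tip_id), ]
}

# O(n^3) betweenness oracle: for every pair, walk the unique tree path and
# credit interior nodes; normalized mean over nodes.
oracle_mean_betweenness <- function(m) {
  nd <- m$nodes
  n <- nrow(nd)
  if (n <= 2) return(0)
  pidx <- match(nd$parent_id, nd$id)
  ancestors <- function(v) {
    path <- v
    while (!is.na(pidx[path[length(path)]])) path <- c(path, pidx[path[length(path)]])
    path
  }
  btw <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    as <- ancestors(s); at <- ancestors(t)
    lca <- intersect(as, at)[1]
    path <- c(as[seq_len(which(as == lca))],
              rev(at[seq_len(which(at == lca) - 1)]))
    interior <- setdiff(path, c(s, t))
    btw[interior] <- btw[interior] + 1
  }
  mean(btw / ((n - 1) * (n - 2) / 2))
}

# Tukey HSD oracle: explicit studentized-range evaluation
oracle_tukey <- function(values, group) {
  group <- factor(group)
  k <- nlevels(group)
  ns <- tapply(values, group, length)
  ms <- tapply(values, group, mean)
  N <- length(values)
  mse <- sum((values - ms[group])^2) / (N - k)
  pairs <- utils::combn(levels(group), 2)
  data.frame(
    pair = paste0(pairs[2, ], "-", pairs[1, ]),
    p_adj = vapply(seq_len(ncol(pairs)), function(i) {
      a <- pairs[1, i]; b <- pairs[2, i]
      se <- sqrt(mse / 2 * (1 / ns[a] + 1 / ns[b]))
      q <- abs(ms[a] - ms[b]) / se
      stats::ptukey(q, nmeans = k, df = N - k, lower.tail = FALSE)
    }, numeric(1))
  )
}

# random rigid motion: proper rotation (QR-based) plus translation
apply_rigid_motion <- function(m, seed, about_z_only = FALSE) {
  set.seed(seed)
  if (about_z_only) {
    th <- runif(1, 0, 2 * pi)
    R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  } else {
    qr_ <- qr(matrix(rnorm(9), 3))
    R <- qr.Q(qr_)
    if (det(R) < 0) R[, 1] <- -R[, 1]
  }
  tr <- runif(3, -50, 50)
  xyz <- as.matrix(m$nodes[, c("x", "y", "z")]) %*% t(R)
  m$nodes$x <- xyz[, 1] + tr[1]
  m$nodes$y <- xyz[, 2] + tr[2]
  m$nodes$z <- xyz[, 3] + tr[3]
  m
}

# Insert a collinear midpoint node into every segment. The midpoint radius is
# the mean of the two process radii; a soma-adjacent segment is modelled as a
# cylinder of the child's process radius (the soma sphere is accounted for
# separately), so there the midpoint takes the child's radius.
subdivide_segments <- function(m) {
  nd <- m$nodes
  pidx <- match(nd$parent_id, nd$id)
  root <- which(nd$parent_id == -1L)
  new_id <- max(nd$id)
  extra <- NULL
  for (v in seq_len(nrow(nd))) {
    if (is.na(pidx[v])) next
    p <- pidx[v]
    r_mid <- if (p == root) nd$radius[v] else (nd$radius[v] + nd$radius[p]) / 2
    new_id <- new_id + 1L
    extra <- rbind(extra, data.frame(
      id = new_id, struct_type = nd$struct_type[v],
      x = (nd$x[v] + nd$x[p]) / 2, y = (nd$y[v] + nd$y[p]) / 2,
      z = (nd$z[v] + nd$z[p]) / 2,
      radius = r_mid,
      parent_id = nd$parent_id[v]))
    nd$parent_id[v] <- new_id
  }
  morphology(rbind(nd, extra), cell_id = m$cell_id,
             condition = m$condition)
}

# small synthetic cohort helper used by embedding/trajectory tests
small_cohort <- function(phi_means, n_cells = 40, seed = 1,
                         concentration = 30) {
  conds <- data.frame(name = paste0("g", seq_along(phi_means)),
                      phi_mean = phi_means,
                      phi_concentration = concentration,
                      n_cells = n_cells)
  generate_cohort_cells(cohort_spec(conds, seed = seed))
}
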