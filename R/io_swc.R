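#' Construct a morphology object
#'
#' A `morphology` is the canonical per-cell data model used by all downstream
#' stages: a rooted 3D tree with a per-node radius, following SWC semantics.
#' The node table has columns `id`, `struct_type`, `x`, `y`, `z`, `radius`,
#' `parent_id`; coordinates and radii are in micrometres. The soma is the
#' single root node (`parent_id == -1`, conventionally `struct_type == 1`);
#' every other node is a process point attached to exactly one parent.
#'
#' @param nodes data.frame with columns id, struct_type, x, y, z, radius,
#'   parent_id. Node ids must be unique positive integers; exactly one node
#'   must have parent_id -1.
#' @param cell_id character scalar identifying the cell.
#' @param condition optional character label (experimental group).
#' @param source one of "traced" or "synthetic".
#' @param validate if TRUE (default) the tree invariants are checked and node
#'   order is normalized so parents precede children.
#' @return An object of class `morphology`: a list with elements `nodes`
#'   (validated node data.frame), `cell_id`, `condition`, `source`.
#' @export
morphology <- function(nodes, cell_id, condition = NA_character_,
                       source = c("synthetic", "traced"), validate = TRUE) {
  source <- match.arg(source)
  required <- c("id", "struct_type", "x", "y", "z", "radius", "parent_id")
  if (!all(required %in% names(nodes))) {
    stop("nodes must have columns: ", paste(required, collapse = ", "))
  }
  nodes <- as.data.frame(nodes)[, required]
  nodes$id <- as.integer(nodes$id)
  nodes$struct_type <- as.integer(nodes$struct_type)
  nodes$parent_id <- as.integer(nodes$parent_id)
  if (validate) nodes <- validate_swc_nodes(nodes)
  structure(
    list(nodes = nodes, cell_id = as.character(cell_id),
         condition = as.character(condition), source = source),
    class = "morphology"
  )
}

#' @export
print.morphology <- function(x, ...) {
  cat(sprintf("<morphology> %s (%s)\n", x$cell_id,
              ifelse(is.na(x$condition), "no condition", x$condition)))
  cat(sprintf("  %d nodes, root id %d, source: %s\n",
              nrow(x$nodes), x$nodes$id[x$nodes$parent_id == -1L], x$source))
  invisible(x)
}

# Validate SWC node-table invariants and return nodes re-ordered so that
# parents precede children (children keep their relative order).
validate_swc_nodes <- function(nodes) {
  if (nrow(nodes) < 1L) stop("morphology must have at least one node")
  if (anyDuplicated(nodes$id)) {
    stop("duplicate node id: ", nodes$id[duplicated(nodes$id)][1])
  }
  if (any(nodes$id <= 0L)) stop("node ids must be positive integers")
  bad_r <- nodes$id[!is.finite(nodes$radius) | nodes$radius <= 0]
  if (length(bad_r)) {
    stop("non-positive radius at node id ", bad_r[1])
  }
  roots <- nodes$id[nodes$parent_id == -1L]
  if (length(roots) == 0L) stop("no root node (parent_id == -1) found")
  if (length(roots) > 1L) {
    stop("multiple roots: ids ", paste(roots, collapse = ", "))
  }
  idx <- match(nodes$parent_id, nodes$id)
  missing_parent <- nodes$parent_id != -1L & is.na(idx)
  if (any(missing_parent)) {
    off <- which(missing_parent)[1]
    stop(sprintf("node %d references missing parent %d",
                 nodes$id[off], nodes$parent_id[off]))
  }
  if (any(nodes$parent_id == nodes$id)) {
    stop("node ", nodes$id[which(nodes$parent_id == nodes$id)[1]],
         " is its own parent")
  }
  # topological order by BFS from the root; leftovers indicate a cycle
  # (a node set unreachable from the root in a graph where every node has
  # exactly one parent must contain a cycle)
  n <- nrow(nodes)
  children <- split(seq_len(n), factor(idx, levels = seq_len(n)))
  order_out <- integer(n)
  queue <- which(nodes$parent_id == -1L)
  k <- 0L
  while (length(queue)) {
    order_out[(k + 1L):(k + length(queue))] <- queue
    k <- k + length(queue)
    queue <- unlist(children[as.character(queue)], use.names = FALSE)
  }
  if (k < n) {
    unreachable <- setdiff(seq_len(n), order_out[seq_len(k)])
    stop("cycle or disconnected subtree involving node id ",
         nodes$id[unreachable[1]])
  }
  out <- nodes[order_out, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a single-cell morphology from an SWC file
#'
#' Parses the standard whitespace-delimited 7-column SWC format
#' (id, type, x, y, z, radius, parent). `#` comment lines are allowed and the
#' header comments `# cell_id: ...` and `# condition: ...` (as written by
#' [write_swc()]) are honoured. Multi-point somas, which some tracing tools
#' export, are collapsed onto the root: extra `struct_type == 1` nodes are
#' removed and their children reattached to the root, preserving the root's
#' coordinates (the radial-distance filtration requires a single soma point).
#' Unknown struct_type codes are accepted and treated as process nodes.
#'
#' @param path path to an SWC file.
#' @param cell_id,condition overrides for the values read from the header
#'   (defaults: header value, else file basename / NA).
#' @return A validated [morphology()] with nodes ordered parents-first.
#' @export
read_swc <- function(path, cell_id = NULL, condition = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(trimws(lines), "#")]
  get_hdr <- function(key) {
    m <- regmatches(hdr, regexec(paste0("#\\s*", key, ":\\s*(.+)$"), hdr))
    hits <- vapply(m, function(g) if (length(g) == 2) g[2] else NA_character_,
                   character(1))
    hits <- trimws(hits[!is.na(hits)])
    if (length(hits)) hits[1] else NA_character_
  }
  if (is.null(cell_id)) {
    cell_id <- get_hdr("cell_id")
    if (is.na(cell_id)) cell_id <- sub("\\.swc$", "", basename(path))
  }
  if (is.null(condition)) condition <- get_hdr("condition")
  source <- get_hdr("source")
  if (is.na(source) || !source %in% c("traced", "synthetic")) source <- "traced"

  body <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (!length(body)) stop("no SWC records in ", path)
  fields <- strsplit(trimws(body), "\\s+")
  if (any(lengths(fields) != 7L)) {
    stop("malformed SWC record (expected 7 columns) at line: ",
         body[which(lengths(fields) != 7L)[1]])
  }
  m <- matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE)
  nodes <- data.frame(
    id = as.integer(m[, 1]), struct_type = as.integer(m[, 2]),
    x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
    parent_id = as.integer(m[, 7])
  )
  nodes <- collapse_multisoma(nodes)
  morphology(nodes, cell_id = cell_id, condition = condition, source = source)
}

# Collapse extra type-1 (soma) nodes onto the root soma node: children of a
# removed soma node are re-parented to the root. Root keeps its coordinates.
collapse_multisoma <- function(nodes) {
  soma <- which(nodes$struct_type == 1L)
  if (length(soma) <= 1L) return(nodes)
  root_row <- which(nodes$parent_id == -1L)
  if (length(root_row) != 1L) return(nodes)  # validation will report it
  extra <- setdiff(soma, root_row)
  if (!length(extra)) return(nodes)
  drop_ids <- nodes$id[extra]
  root_id <- nodes$id[root_row]
  # iterate: a soma chain must fully re-route to the root
  repeat {
    hit <- nodes$parent_id %in% drop_ids
    if (!any(hit)) break
    nodes$parent_id[hit] <- root_id
  }
  nodes[!nodes$id %in% drop_ids, , drop = FALSE]
}

#' Write a morphology to an SWC file
#'
#' Emits standard 7-column SWC with parents before children and a comment
#' header recording `cell_id`, `condition` and `source` so that
#' [read_swc()] round-trips them.
#'
#' @param m a [morphology()].
#' @param path output file path.
#' @param digits significant digits for coordinates/radii (default 9,
#'   round-trips doubles to well below 1e-6 um on cell-scale coordinates).
#' @return `path`, invisibly.
#' @export
write_swc <- function(m, path, digits = 9) {
  stopifnot(inherits(m, "morphology"))
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open for writing: ", path)
  })
  on.exit(close(con))
  writeLines(c(
    paste0("# cell_id: ", m$cell_id),
    paste0("# condition: ", m$condition),
    paste0("# source: ", m$source),
    "# id type x y z radius parent"
  ), con)
  nd <- m$nodes
  writeLines(sprintf("%d %d %s %s %s %s %d",
                     nd$id, nd$struct_type,
                     formatC(nd$x, digits = digits, format = "g"),
                     formatC(nd$y, digits = digits, format = "g"),
                     formatC(nd$z, digits = digits, format = "g"),
                     formatC(nd$radius, digits = digits, format = "g"),
                     nd$parent_id), con)
  invisible(path)
}

#' Read a cohort manifest and its morphologies
#'
#' A cohort is a directory of SWC files indexed by a TSV manifest with
#' columns `cell_id`, `path`, `condition` (paths relative to the manifest's
#' directory or absolute). Extra columns (e.g. the generator's ground-truth
#' `phi`) are carried through.
#'
#' @param manifest_path path to the manifest TSV.
#' @return list with `manifest` (data.frame) and `cells` (named list of
#'   [morphology()] objects, in manifest order).
#' @export
read_cohort <- function(manifest_path) {
  man <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  need <- c("cell_id", "path", "condition")
  if (!all(need %in% names(man))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  base <- dirname(manifest_path)
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", man$path), man$path,
                  file.path(base, man$path))
  cells <- mapply(function(p, id, cond) read_swc(p, cell_id = id, condition = cond),
                  paths, man$cell_id, man$condition, SIMPLIFY = FALSE)
  names(cells) <- man$cell_id
  list(manifest = man, cells = cells)
}

#' Prune short terminal branches
#'
#' Tracing tools occasionally emit short spurious filaments that cannot be
#' removed by hand. This optional cleanup removes terminal branches (tip back
#' to the nearest branch point or the soma) whose path length is below
#' `min_length`, repeating until no such branch remains. It is **off by
#' default** throughout the pipeline: no principled threshold exists, and
#' bootstrap aggregation plus PCA already damp small artifacts.
#'
#' @param m a [morphology()].
#' @param min_length minimum terminal-branch path length to keep, um.
#' @return a pruned, re-validated [morphology()] (at least the soma remains).
#' @export
prune_short_branches <- function(m, min_length) {
  stopifnot(inherits(m, "morphology"), min_length >= 0)
  repeat {
    nd <- m$nodes
    n <- nrow(nd)
    if (n == 1L) break
    pidx <- parent_index(m)
    seg <- segment_lengths(m)
    n_children <- tabulate(pidx[!is.na(pidx)], nbins = n)
    ridx <- root_index(m)
    tips <- which(n_children == 0L & seq_len(n) != ridx)
    drop <- integer(0)
    for (tp in tips) {
      path <- tp
      v <- tp
      # walk up through pass-through nodes to the branch point / soma
      while (n_children[pidx[v]] == 1L && pidx[v] != ridx) {
        v <- pidx[v]
        path <- c(path, v)
      }
      if (sum(seg[path]) < min_length) drop <- c(drop, path)
    }
    drop <- unique(drop)
    if (!length(drop)) break
    m <- morphology(nd[-drop, , drop = FALSE], cell_id = m$cell_id,
                    condition = m$condition, source = m$source)
  }
  m
}

# --- small internal tree accessors shared by downstream modules ------------

# index (row) of the root node
root_index <- function(m) which(m$nodes$parent_id == -1L)

# row index of each node's parent (NA for the root)
parent_index <- function(m) match(m$nodes$parent_id, m$nodes$id)

# list: for each row, integer vector of child row indices
children_index <- function(m) {
  pidx <- parent_index(m)
  n <- nrow(m$nodes)
  unname(split(seq_len(n), factor(pidx, levels = seq_len(n))))
}

# Euclidean distance of every node from the soma (root)
radial_distance <- function(m) {
  r <- root_index(m)
  nd <- m$nodes
  sqrt((nd$x - nd$x[r])^2 + (nd$y - nd$y[r])^2 + (nd$z - nd$z[r])^2)
}

# length of the segment joining each node to its parent (0 for root)
segment_lengths <- function(m) {
  pidx <- parent_index(m)
  nd <- m$nodes
  len <- numeric(nrow(nd))
  ok <- !is.na(pidx)
  len[ok] <- sqrt((nd$x[ok] - nd$x[pidx[ok]])^2 +
                  (nd$y[ok] - nd$y[pidx[ok]])^2 +
                  (nd$z[ok] - nd$z[pidx[ok]])^2)
  len
}
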