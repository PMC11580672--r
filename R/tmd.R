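#' Topological morphology descriptor (TMD) persistence barcode
#'
#' Computes the persistence barcode of a rooted tree under a descending
#' filtration by distance from the soma: each process (leaf) starts a
#' component at its filtration value, and when components merge at a branch
#' point the elder rule applies — the component with the larger birth
#' survives while every other child component emits a bar
#' `(its birth, f(branch point))`. The component that survives to the soma
#' emits the maximal bar `(max tip distance, 0)`. Bars therefore record where
#' each process starts and ends as its distance from the soma, and the number
#' of bars equals the number of tips. Ties in birth are broken in favour of
#' the smaller carrying-tip node id.
#'
#' Note that with several primary processes the last merges happen at the
#' soma itself (filtration value 0), so a tree with k primaries has k bars
#' with death 0, the maximal bar among them.
#'
#' @param m a [morphology()].
#' @param filtration `"radial"` (Euclidean distance from the soma; default)
#'   or `"path"` (path length along the tree from the soma).
#' @return object of class `persistence_barcode`: list with `cell_id` and
#'   `bars`, a data.frame `(birth, death, tip_id)` with `birth >= death`
#'   for outward-growing trees. A soma-only cell yields the single bar (0,0).
#' @export
tmd_barcode <- function(m, filtration = c("radial", "path")) {
  stopifnot(inherits(m, "morphology"))
  filtration <- match.arg(filtration)
  nd <- m$nodes
  n <- nrow(nd)
  ridx <- root_index(m)
  f <- if (filtration == "radial") {
    radial_distance(m)
  } else {
    pl <- numeric(n); seg <- segment_lengths(m); pidx <- parent_index(m)
    for (v in seq_len(n)) if (v != ridx) pl[v] <- pl[pidx[v]] + seg[v]
    pl
  }
  if (n == 1L) {
    return(structure(list(cell_id = m$cell_id,
                          bars = data.frame(birth = 0, death = 0,
                                            tip_id = nd$id[1])),
                     class = "persistence_barcode"))
  }
  kids <- children_index(m)
  birth <- numeric(n)    # birth carried by the surviving component at node v
  tipid <- integer(n)    # id of the tip carrying that birth
  bars_b <- bars_d <- numeric(0); bars_t <- integer(0)
  for (v in rev(seq_len(n))) {      # children before parents (rows are topo)
    ch <- kids[[v]]
    if (!length(ch)) { birth[v] <- f[v]; tipid[v] <- nd$id[v]; next }
    b <- birth[ch]; t_id <- tipid[ch]
    # elder rule: largest birth survives; ties -> smaller tip id
    surv <- order(-b, t_id)[1]
    for (j in seq_along(ch)) {
      if (j == surv) next
      bars_b <- c(bars_b, b[j]); bars_d <- c(bars_d, f[v])
      bars_t <- c(bars_t, t_id[j])
    }
    birth[v] <- b[surv]; tipid[v] <- t_id[surv]
  }
  bars_b <- c(bars_b, birth[ridx]); bars_d <- c(bars_d, f[ridx])
  bars_t <- c(bars_t, tipid[ridx])
  ord <- order(-bars_b, bars_t)
  structure(list(cell_id = m$cell_id,
                 bars = data.frame(birth = bars_b[ord], death = bars_d[ord],
                                   tip_id = bars_t[ord])),
            class = "persistence_barcode")
}

#' @export
print.persistence_barcode <- function(x, ...) {
  cat(sprintf("<persistence_barcode> %s: %d bars, max birth %.2f um\n",
              x$cell_id, nrow(x$bars), max(x$bars$birth)))
  invisible(x)
}

#' Cohort-global persistence-image bounds
#'
#' All cells of a cohort must share one pixel grid so that persistence images
#' can be averaged pixel-wise. Bounds are `(0, pad * max birth)` over all
#' barcodes.
#'
#' @param barcodes list of [tmd_barcode()] results.
#' @param pad multiplicative head-room (default 1.05).
#' @return numeric length-2 vector `(0, L_max)`.
#' @export
cohort_bounds <- function(barcodes, pad = 1.05) {
  mx <- max(vapply(barcodes, function(b) max(b$bars$birth), numeric(1)))
  c(0, pad * max(mx, .Machine$double.eps))
}

#' Persistence image of a barcode
#'
#' Sum of isotropic Gaussians, one per bar, centred at (birth, death) and
#' evaluated at the centres of an R x R pixel grid over `bounds` in both
#' axes (birth on x, death on y), then normalized to sum 1. Bars are
#' unweighted by default; `weighting = "persistence"` weights each bar by
#' its length `birth - death` before normalization.
#'
#' @param b a [tmd_barcode()] result.
#' @param bounds `(lo, hi)` covering all bar endpoints — use the
#'   cohort-global [cohort_bounds()] so all cells share one grid.
#' @param R grid resolution per axis; the default 100 yields the 10,000-pixel
#'   vector treated downstream as a pseudo-sample's expression profile.
#' @param bandwidth Gaussian sigma in um; default `diff(bounds) / 20`
#'   (scale-relative smoothing keeps images comparable across cohorts).
#' @param weighting `"none"` (default) or `"persistence"`.
#' @return object of class `persistence_image`: list with `cell_id`,
#'   `pixels` (length R^2 vector, row-major with birth on x and death on y),
#'   `R`, `bounds`, `bandwidth`.
#' @export
persistence_image <- function(b, bounds = NULL, R = 100L, bandwidth = NULL,
                              weighting = c("none", "persistence")) {
  stopifnot(inherits(b, "persistence_barcode"), R >= 2)
  weighting <- match.arg(weighting)
  bars <- b$bars
  if (is.null(bounds)) bounds <- c(0, 1.05 * max(bars$birth,
                                                 .Machine$double.eps))
  out_of <- bars$birth < bounds[1] | bars$birth > bounds[2] |
    bars$death < bounds[1] | bars$death > bounds[2]
  if (any(out_of)) {
    i <- which(out_of)[1]
    stop(sprintf(
      "bar (%.3f, %.3f) lies outside bounds [%.3f, %.3f]; use cohort-global bounds",
      bars$birth[i], bars$death[i], bounds[1], bounds[2]))
  }
  if (is.null(bandwidth)) bandwidth <- diff(bounds) / 20
  stopifnot(bandwidth > 0)
  h <- diff(bounds) / R
  centers <- bounds[1] + (seq_len(R) - 0.5) * h
  w <- switch(weighting,
              none = rep(1, nrow(bars)),
              persistence = pmax(bars$birth - bars$death, 0))
  # separable Gaussians: image = sum_i w_i * gy(death_i) %o% gx(birth_i)
  img <- matrix(0, R, R)  # rows = death (y), cols = birth (x)
  for (i in seq_len(nrow(bars))) {
    gx <- exp(-(centers - bars$birth[i])^2 / (2 * bandwidth^2))
    gy <- exp(-(centers - bars$death[i])^2 / (2 * bandwidth^2))
    img <- img + w[i] * (gy %o% gx)
  }
  s <- sum(img)
  if (s > 0) img <- img / s
  structure(list(cell_id = b$cell_id, pixels = as.vector(t(img)),
                 R = as.integer(R), bounds = bounds, bandwidth = bandwidth),
            class = "persistence_image")
}

#' Barcodes and shared-grid persistence images for a whole cohort
#'
#' @param cells list of [morphology()].
#' @param R grid resolution (default 100, i.e. 10,000 pixels).
#' @param bandwidth Gaussian sigma; default `L_max / 20` with cohort-global
#'   `L_max`.
#' @param bounds optional fixed bounds; default [cohort_bounds()].
#' @param filtration passed to [tmd_barcode()].
#' @return list with `barcodes` (list), `pixels` (n_cells x R^2 matrix, one
#'   row per cell), `bounds`, `bandwidth`, `R`.
#' @export
cohort_persistence_images <- function(cells, R = 100L, bandwidth = NULL,
                                      bounds = NULL,
                                      filtration = "radial") {
  barcodes <- lapply(cells, tmd_barcode, filtration = filtration)
  if (is.null(bounds)) bounds <- cohort_bounds(barcodes)
  if (is.null(bandwidth)) bandwidth <- diff(bounds) / 20
  px <- t(vapply(barcodes,
                 function(b) persistence_image(b, bounds = bounds, R = R,
                                               bandwidth = bandwidth)$pixels,
                 numeric(R * R)))
  rownames(px) <- vapply(barcodes, `[[`, character(1), "cell_id")
  list(barcodes = barcodes, pixels = px, bounds = bounds,
       bandwidth = bandwidth, R = as.integer(R))
}

#' Write cohort barcodes as a long TSV (cell_id, birth, death)
#'
#' @param barcodes list of [tmd_barcode()] results.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_barcodes <- function(barcodes, path) {
  df <- do.call(rbind, lapply(barcodes, function(b) {
    data.frame(cell_id = b$cell_id, birth = b$bars$birth,
               death = b$bars$death)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
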