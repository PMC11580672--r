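#' Parameters for the synthetic microglia morphology generator
#'
#' Microglia morphology varies continuously between a highly ramified
#' homeostatic phenotype and a de-ramified amoeboid reactive phenotype. The
#' generator summarizes this continuum with a single reactivity scalar
#' `phi` in \[0, 1\] (0 = homeostatic, 1 = amoeboid): every structural
#' parameter is given as a (homeostatic, reactive) pair and linearly
#' interpolated by `phi`, so expected tip count, total process length, branch
#' order and territory all decrease monotonically as `phi` grows while the
#' soma stays fixed.
#'
#' Defaults produce trees whose homeostatic extreme has ~5-7 primary
#' processes ramifying to order ~6 over a 50-100 um territory and whose
#' reactive extreme has 2-4 stubby, rarely branching processes — the
#' classic ramified-to-amoeboid spectrum. The soma radius default of 6 um
#' corresponds to the 12 um maximum soma diameter criterion used when
#' seeding tracing.
#'
#' @param phi reactivity in \[0,1\].
#' @param n_primary_range (homeostatic, reactive) mean number of primary
#'   processes; the realized count is Poisson (minimum 1).
#' @param seg_len_mean (homeostatic, reactive) mean segment length, um;
#'   segment lengths are Gamma(shape 4) with this mean.
#' @param branch_prob (homeostatic, reactive) probability that a segment ends
#'   in a bifurcation rather than a tip, applied up to `max_order`.
#' @param max_order (homeostatic, reactive) maximum centrifugal branch order.
#' @param angle_sd angular noise (radians) added to the parent direction for
#'   each child segment.
#' @param soma_radius soma radius, um.
#' @param seed integer seed; NULL uses (and advances) the current RNG stream.
#' @return list of class `morpho_gen_params`.
#' @export
morpho_gen_params <- function(phi = 0,
                              n_primary_range = c(6, 3),
                              seg_len_mean = c(14, 7),
                              branch_prob = c(0.9, 0.25),
                              max_order = c(6, 2),
                              angle_sd = 0.4,
                              soma_radius = 6,
                              seed = NULL) {
  stopifnot(phi >= 0, phi <= 1,
            all(n_primary_range > 0), all(seg_len_mean > 0),
            all(branch_prob > 0), all(branch_prob <= 1),
            all(max_order >= 1), angle_sd > 0, soma_radius > 0)
  structure(list(phi = phi, n_primary_range = n_primary_range,
                 seg_len_mean = seg_len_mean, branch_prob = branch_prob,
                 max_order = max_order, angle_sd = angle_sd,
                 soma_radius = soma_radius, seed = seed),
            class = "morpho_gen_params")
}

# random unit vector in 3D
runif_sphere <- function() {
  z <- stats::rnorm(3)
  z / sqrt(sum(z^2))
}

# child direction = parent direction plus Gaussian noise, resampled (bounded)
# so that the segment endpoint is strictly farther from the soma than `from`:
# processes radiate outward, which keeps the radial filtration monotone.
outward_direction <- function(dir, from, len, angle_sd, max_try = 25L) {
  r0 <- sqrt(sum(from^2))
  for (i in seq_len(max_try)) {
    d <- dir + stats::rnorm(3, 0, angle_sd)
    d <- d / sqrt(sum(d^2))
    if (sqrt(sum((from + len * d)^2)) > r0) return(d)
  }
  from / max(r0, 1e-12)  # fall back to the pure radial direction
}

#' Generate one synthetic microglia morphology
#'
#' Grows a rooted 3D tree outward from a spherical soma. The number of
#' primary processes is Poisson with the phi-interpolated mean (redrawn,
#' bounded, until at least one primary); segment lengths are Gamma
#' distributed; each segment ends in a bifurcation with the phi-interpolated
#' branch probability while below the maximum branch order, otherwise in a
#' tip; child directions are the parent direction plus isotropic Gaussian
#' angular noise, constrained to point away from the soma. Process radii
#' taper geometrically with branch order.
#'
#' @param p a [morpho_gen_params()].
#' @param cell_id id for the generated cell (default derived from the seed).
#' @param condition optional condition label.
#' @return a valid [morphology()] (writable by [write_swc()]).
#' @export
generate_morphology <- function(p = morpho_gen_params(), cell_id = NULL,
                                condition = NA_character_) {
  stopifnot(inherits(p, "morpho_gen_params"))
  if (is.null(cell_id)) {
    cell_id <- sprintf("synth_phi%03.0f_%s", 100 * p$phi,
                       p$seed %||% "live")
  }
  with_seed(p$seed, {
    lambda_primary <- interp_pair(p$n_primary_range, p$phi)
    seg_mu <- interp_pair(p$seg_len_mean, p$phi)
    pbranch <- interp_pair(p$branch_prob, p$phi)
    kmax <- max(1L, round(interp_pair(p$max_order, p$phi)))

    n_primary <- 0L
    for (i in 1:100) {
      n_primary <- stats::rpois(1, lambda_primary)
      if (n_primary >= 1L) break
    }
    if (n_primary < 1L) {
      stop("could not draw a positive number of primary processes; ",
           "n_primary_range too small")
    }

    ids <- integer(0); types <- integer(0); par <- integer(0)
    xyz <- matrix(numeric(0), ncol = 3); rad <- numeric(0)
    add_node <- function(type, pos, r, parent) {
      ids[[length(ids) + 1L]] <<- length(ids) + 1L
      types[[length(types) + 1L]] <<- type
      xyz <<- rbind(xyz, pos)
      rad[[length(rad) + 1L]] <<- r
      par[[length(par) + 1L]] <<- parent
      length(ids)
    }
    add_node(1L, c(0, 0, 0), p$soma_radius, -1L)

    # iterative DFS over growing segments: (parent node, direction, order)
    stack <- lapply(seq_len(n_primary), function(i) {
      list(parent = 1L, dir = runif_sphere(), order = 1L, first = TRUE)
    })
    while (length(stack)) {
      s <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      from <- xyz[s$parent, ]
      len <- stats::rgamma(1, shape = 4, scale = seg_mu / 4)
      d <- outward_direction(s$dir, from, len, p$angle_sd)
      # primary segments start at the soma surface
      pos <- from + d * (len + if (isTRUE(s$first)) p$soma_radius else 0)
      r <- max(0.25, 1.2 * 0.85^(s$order - 1))
      node <- add_node(3L, pos, r, s$parent)
      if (s$order < kmax && stats::runif(1) < pbranch) {
        for (k in 1:2) {
          stack[[length(stack) + 1L]] <-
            list(parent = node, dir = d, order = s$order + 1L, first = FALSE)
        }
      }
    }
    nodes <- data.frame(id = ids, struct_type = types,
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                        radius = rad, parent_id = par)
    morphology(nodes, cell_id = cell_id, condition = condition,
               source = "synthetic")
  })
}

#' Specify a synthetic cohort of condition-labelled morphologies
#'
#' Each condition draws per-cell reactivity `phi ~ Beta(mean, concentration)`
#' (shape1 = mean * concentration, shape2 = (1 - mean) * concentration), so
#' `phi_mean` sets the condition's position on the homeostatic-to-reactive
#' axis and `phi_concentration` its within-condition homogeneity
#' (concentration -> Inf degenerates to a fixed phi).
#'
#' The default conditions mimic an ocular-hypertension time course plus a
#' lipoxin-B4-treated arm: normotensive 0.10, 2 wk 0.35, 4 wk 0.85
#' (peak reactivity), 6 wk 0.40 (partial reversal), treated 0.25.
#'
#' @param conditions data.frame with columns `name`, `phi_mean` (in (0,1)),
#'   `phi_concentration` (> 0), `n_cells` (>= 1).
#' @param seed integer seed for the whole cohort.
#' @param gen_params baseline [morpho_gen_params()] whose `phi`/`seed` are
#'   overridden per cell.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(conditions = default_conditions(),
                        seed = 1L,
                        gen_params = morpho_gen_params()) {
  conditions <- as.data.frame(conditions)
  stopifnot(all(c("name", "phi_mean", "phi_concentration", "n_cells")
                %in% names(conditions)),
            all(conditions$n_cells >= 1),
            all(conditions$phi_mean > 0), all(conditions$phi_mean < 1),
            all(conditions$phi_concentration > 0),
            !anyDuplicated(conditions$name))
  structure(list(conditions = conditions, seed = seed,
                 gen_params = gen_params),
            class = "cohort_spec")
}

#' Default condition presets for the synthetic cohort
#'
#' @param n_cells cells per condition (default 120).
#' @return data.frame usable as the `conditions` argument of [cohort_spec()].
#' @export
default_conditions <- function(n_cells = 120L) {
  data.frame(
    name = c("normotensive", "OHT_2wk", "OHT_4wk", "OHT_6wk", "OHT_LXB4"),
    phi_mean = c(0.10, 0.35, 0.85, 0.40, 0.25),
    phi_concentration = 30,
    n_cells = as.integer(n_cells)
  )
}

#' Generate a cohort of synthetic morphologies in memory
#'
#' @param spec a [cohort_spec()].
#' @return list with `cells` (list of [morphology()]), and `info`
#'   (data.frame: cell_id, condition, phi, seed).
#' @export
generate_cohort_cells <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  conds <- spec$conditions
  n_total <- sum(conds$n_cells)
  seeds <- derive_seeds(spec$seed, n_total + 1L)
  phis <- with_seed(seeds[n_total + 1L], {
    unlist(lapply(seq_len(nrow(conds)), function(i) {
      a <- conds$phi_mean[i] * conds$phi_concentration[i]
      b <- (1 - conds$phi_mean[i]) * conds$phi_concentration[i]
      stats::rbeta(conds$n_cells[i], a, b)
    }))
  })
  condition <- rep(conds$name, conds$n_cells)
  cell_id <- sprintf("%s_c%03d", condition,
                     unlist(lapply(conds$n_cells, seq_len)))
  cells <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    p <- spec$gen_params
    p$phi <- phis[i]
    p$seed <- seeds[i]
    cells[[i]] <- generate_morphology(p, cell_id = cell_id[i],
                                      condition = condition[i])
  }
  names(cells) <- cell_id
  list(cells = cells,
       info = data.frame(cell_id = cell_id, condition = condition,
                         phi = phis, seed = seeds[seq_len(n_total)]))
}

#' Generate a cohort on disk: SWC files plus a TSV manifest
#'
#' Writes one SWC per cell under `outdir/swc/` and a manifest TSV
#' (`cell_id`, `path`, `condition`, plus the ground-truth `phi`) at
#' `outdir/manifest.tsv`.
#'
#' @param spec a [cohort_spec()].
#' @param outdir output directory (created if needed).
#' @param overwrite allow writing into an existing non-empty directory.
#' @return the manifest data.frame, invisibly (its `path` column is relative
#'   to `outdir`).
#' @export
generate_cohort <- function(spec, outdir, overwrite = FALSE) {
  if (dir.exists(outdir) && length(list.files(outdir)) && !overwrite) {
    stop("output directory exists and is not empty: ", outdir,
         " (use overwrite = TRUE)")
  }
  dir.create(file.path(outdir, "swc"), recursive = TRUE, showWarnings = FALSE)
  gen <- generate_cohort_cells(spec)
  rel <- file.path("swc", paste0(gen$info$cell_id, ".swc"))
  for (i in seq_along(gen$cells)) {
    write_swc(gen$cells[[i]], file.path(outdir, rel[i]))
  }
  man <- data.frame(cell_id = gen$info$cell_id, path = rel,
                    condition = gen$info$condition, phi = gen$info$phi)
  utils::write.table(man, file.path(outdir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(man)
}
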