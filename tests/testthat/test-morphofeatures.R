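test_that("a soma-only cell is a perfect sphere with zeroed branch features", {
  m <- make_tree(c(1, 1, 2, -3, 4, 4, -1))
  f <- extract_features(m)
  expect_equal(f$sphericity, 1.0)
  expect_equal(f$circularity, 1.0)
  expect_equal(f$n_tips, 0)
  expect_equal(f$n_branch_points, 0)
  expect_equal(f$total_branch_length, 0)
  expect_equal(f$mean_branch_length, 0)
  expect_equal(f$soma_volume, 4 / 3 * pi * 64)
  expect_equal(f$cell_volume, f$soma_volume)
  expect_equal(f$mean_node_betweenness, 0)
})

test_that("the Y-tree features match hand arithmetic", {
  f <- extract_features(y_tree())
  expect_equal(f$n_nodes, 4)
  expect_equal(f$n_tips, 2)
  expect_equal(f$n_branch_points, 1)
  # segments: 5 (root->bp), 5 (bp->tip1), sqrt(3^2+4^2)=5 (bp->tip2)
  expect_equal(f$total_branch_length, 15)
  expect_equal(f$mean_branch_length, 5)   # 3 maximal branches
  expect_equal(f$max_branch_order, 2)
  expect_equal(f$ramification_index, 2)   # 2 tips / 1 primary
})

test_that("mean betweenness equals a brute-force all-pairs path oracle", {
  for (seed in 1:10) {
    m <- random_monotone_tree(6, seed)   # ~11-12 nodes
    expect_equal(extract_features(m)$mean_node_betweenness,
                 oracle_mean_betweenness(m), tolerance = 1e-12,
                 info = paste("seed", seed))
  }
})

test_that("features are invariant under rigid motions", {
  invariant_3d <- setdiff(feature_names(), "circularity")
  for (seed in 1:10) {
    m <- generate_morphology(morpho_gen_params(phi = runif(1), seed = seed))
    f0 <- extract_features(m)
    f3 <- extract_features(apply_rigid_motion(m, seed + 50))
    for (feat in invariant_3d) {
      expect_equal(f3[[feat]], f0[[feat]], tolerance = 1e-6,
                   info = paste(feat, "3D, seed", seed))
    }
    # circularity is an imaging-plane (xy) shape factor: invariant under
    # in-plane rigid motions only
    fz <- extract_features(apply_rigid_motion(m, seed + 80,
                                              about_z_only = TRUE))
    for (feat in feature_names()) {
      expect_equal(fz[[feat]], f0[[feat]], tolerance = 1e-6,
                   info = paste(feat, "z-rotation, seed", seed))
    }
  }
})

test_that("collinear node subdivision preserves geometry-level features", {
  kept <- c("n_tips", "n_branch_points", "total_branch_length",
            "mean_branch_length", "max_branch_order", "cell_volume",
            "cell_surface_area", "soma_volume", "sphericity", "circularity",
            "ramification_index")
  for (seed in 1:10) {
    m <- generate_morphology(morpho_gen_params(phi = runif(1), seed = seed))
    f0 <- extract_features(m)
    f1 <- extract_features(subdivide_segments(m))
    expect_equal(f1$n_nodes, 2 * f0$n_nodes - 1)
    for (feat in kept) {
      expect_equal(f1[[feat]], f0[[feat]], tolerance = 1e-6,
                   info = paste(feat, "seed", seed))
    }
  }
})

test_that("amoeboid cells are more spherical than ramified cells", {
  sph <- function(phi) mean(vapply(1:30, function(s) {
    extract_features(generate_morphology(morpho_gen_params(phi = phi,
                                                           seed = s)))$sphericity
  }, numeric(1)))
  expect_gt(sph(1), sph(0))
})

test_that("identical condition distributions yield a near-null significance fraction", {
  fracs <- vapply(1:10, function(run) {
    conds <- data.frame(name = c("a", "b"), phi_mean = 0.4,
                        phi_concentration = 30, n_cells = 40)
    gen <- generate_cohort_cells(cohort_spec(conds, seed = 1000 + run))
    ft <- feature_table(gen$cells)
    ft$fraction_significant[["omnibus"]]
  }, numeric(1))
  expect_lte(mean(fracs), 0.15)
})

test_that("strongly separated cohorts flag most features as changed", {
  for (seed in 1:3) {
    conds <- data.frame(name = c("lo", "hi"), phi_mean = c(0.1, 0.9),
                        phi_concentration = 30, n_cells = 120)
    gen <- generate_cohort_cells(cohort_spec(conds, seed = seed))
    ft <- feature_table(gen$cells)
    n_feat <- nrow(ft$tests) + length(ft$skipped)
    expect_equal(n_feat, 14)
    expect_gte(sum(ft$tests$p_value < 0.05), 10)
  }
})

test_that("a single condition yields summaries but no tests", {
  conds <- data.frame(name = "only", phi_mean = 0.5, phi_concentration = 30,
                      n_cells = 5)
  gen <- generate_cohort_cells(cohort_spec(conds, seed = 1))
  ft <- feature_table(gen$cells)
  expect_null(ft$tests)
  expect_equal(unique(ft$summary$condition), "only")
  expect_equal(nrow(ft$summary), 14)
})

test_that("three or more conditions use ANOVA with Tukey pairs", {
  gen <- small_cohort(c(0.1, 0.5, 0.9), n_cells = 25, seed = 2)
  ft <- feature_table(gen$cells)
  expect_true(all(c("omnibus", "g2-g1", "g3-g1", "g3-g2") %in%
                  names(ft$fraction_significant)))
  expect_true(all(ft$tukey$p_adj >= 0 & ft$tukey$p_adj <= 1))
})
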