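test_that("a straight unbranched neurite gives the single bar (L, 0)", {
  m <- make_tree(c(1, 1, 0, 0, 0, 3, -1),
                 c(2, 3, 0, 0, 4, 1, 1),
                 c(3, 3, 0, 0, 10, 1, 2))
  b <- tmd_barcode(m)
  expect_equal(nrow(b$bars), 1)
  expect_equal(b$bars$birth, 10)
  expect_equal(b$bars$death, 0)
})

test_that("the Y-tree barcode matches the hand-executed elder rule", {
  b <- tmd_barcode(y_tree())
  # tips at radial distances 10 and sqrt(0+9+81)=sqrt(90)~9.49; merge at 5
  expect_equal(nrow(b$bars), 2)
  expect_equal(b$bars$birth[1], 10)
  expect_equal(b$bars$death[1], 0)
  expect_equal(b$bars$birth[2], sqrt(90))
  expect_equal(b$bars$death[2], 5)
})

test_that("a soma-only cell yields the degenerate bar (0, 0)", {
  b <- tmd_barcode(make_tree(c(1, 1, 0, 0, 0, 5, -1)))
  expect_equal(b$bars$birth, 0)
  expect_equal(b$bars$death, 0)
})

test_that("barcode equals the union-find filtration oracle on random trees", {
  for (seed in 1:50) {
    m <- random_monotone_tree(sample(2:15, 1), seed)
    b <- tmd_barcode(m)
    o <- oracle_barcode_unionfind(m)
    expect_equal(nrow(b$bars), sum(!m$nodes$id %in% m$nodes$parent_id),
                 info = paste("bar count == tip count, seed", seed))
    expect_equal(b$bars$birth, o$birth, tolerance = 1e-12,
                 info = paste("births, seed", seed))
    expect_equal(b$bars$death, o$death, tolerance = 1e-12,
                 info = paste("deaths, seed", seed))
    expect_equal(b$bars$tip_id, o$tip_id, info = paste("tips, seed", seed))
  }
})

test_that("barcodes satisfy their structural invariants on generator output", {
  for (seed in 1:10) {
    m <- generate_morphology(morpho_gen_params(phi = runif(1), seed = seed))
    b <- tmd_barcode(m)
    f <- extract_features(m)
    expect_equal(nrow(b$bars), f$n_tips)
    expect_true(all(b$bars$birth >= b$bars$death - 1e-9))
    # maximal bar reaches the soma; death-0 bars == primaries
    expect_equal(b$bars$death[which.max(b$bars$birth)], 0)
    n_primary <- sum(m$nodes$parent_id == m$nodes$id[m$nodes$parent_id == -1])
    expect_equal(sum(b$bars$death == 0), n_primary)
    # total persistence bounded by total path length
    expect_lte(sum(b$bars$birth - b$bars$death),
               f$total_branch_length + 1e-9)
  }
})

test_that("barcode is invariant under rigid motion and node subdivision", {
  for (seed in 1:10) {
    m <- generate_morphology(morpho_gen_params(phi = runif(1), seed = seed))
    b0 <- tmd_barcode(m)$bars
    b1 <- tmd_barcode(apply_rigid_motion(m, seed + 7))$bars
    b2 <- tmd_barcode(subdivide_segments(m))$bars
    expect_equal(b1$birth, b0$birth, tolerance = 1e-6)
    expect_equal(b1$death, b0$death, tolerance = 1e-6)
    expect_equal(b2$birth, b0$birth, tolerance = 1e-9)
    expect_equal(b2$death, b0$death, tolerance = 1e-9)
  }
})

test_that("persistence image has unit mass and peaks at a central bar", {
  b <- structure(list(cell_id = "x",
                      bars = data.frame(birth = 5, death = 5, tip_id = 1L)),
                 class = "persistence_barcode")
  img <- persistence_image(b, bounds = c(0, 10), R = 101, bandwidth = 0.3)
  expect_equal(sum(img$pixels), 1, tolerance = 1e-9)
  expect_length(img$pixels, 101^2)
  # center pixel of a 101x101 grid over (0,10) sits exactly at (5,5)
  expect_equal(which.max(img$pixels), (101^2 + 1) / 2)
})

test_that("default resolution yields the 10,000-pixel vector", {
  m <- generate_morphology(morpho_gen_params(phi = 0.3, seed = 2))
  img <- persistence_image(tmd_barcode(m))
  expect_length(img$pixels, 10000)
})

test_that("duplicating every bar leaves the normalized image unchanged", {
  m <- generate_morphology(morpho_gen_params(phi = 0.3, seed = 3))
  b <- tmd_barcode(m)
  b2 <- b; b2$bars <- rbind(b$bars, b$bars)
  bounds <- c(0, 1.05 * max(b$bars$birth))
  expect_equal(persistence_image(b2, bounds = bounds)$pixels,
               persistence_image(b, bounds = bounds)$pixels,
               tolerance = 1e-12)
})

test_that("bars outside the bounds are reported by value", {
  b <- structure(list(cell_id = "x",
                      bars = data.frame(birth = 12, death = 0, tip_id = 1L)),
                 class = "persistence_barcode")
  expect_error(persistence_image(b, bounds = c(0, 10)), "outside bounds")
})

test_that("the image responds linearly to small bar perturbations", {
  m <- generate_morphology(morpho_gen_params(phi = 0.2, seed = 4))
  b <- tmd_barcode(m)
  L <- 1.2 * max(b$bars$birth)
  bounds <- c(0, L)
  base <- persistence_image(b, bounds = bounds)$pixels
  l1 <- function(eps) {
    bp <- b
    bp$bars$birth <- bp$bars$birth + eps
    bp$bars$death <- bp$bars$death + eps
    sum(abs(persistence_image(bp, bounds = bounds)$pixels - base))
  }
  e <- 0.01 * L
  expect_lt(l1(e), 0.5)                 # small perturbation, small L1 change
  expect_equal(l1(e) / l1(e / 2), 2, tolerance = 0.25)  # ~linear in eps
})

test_that("cohort images share one grid and normalize per cell", {
  gen <- small_cohort(c(0.2, 0.8), n_cells = 6, seed = 5)
  cpi <- cohort_persistence_images(gen$cells)
  expect_equal(dim(cpi$pixels), c(12, 10000))
  expect_equal(unname(rowSums(cpi$pixels)), rep(1, 12), tolerance = 1e-9)
  expect_equal(cpi$bounds[1], 0)
})
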