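test_that("degenerate single-cell condition reproduces that cell's image", {
  gen <- small_cohort(0.5, n_cells = 1, seed = 1)
  cpi <- cohort_persistence_images(gen$cells)
  bs <- bootstrap_images(cpi$pixels, gen$info$condition,
                         bootstrap_config(sample_size = 100,
                                          n_bootstraps = 5, seed = 1))
  for (i in 1:5) {
    expect_equal(unname(bs$pixels[i, ]), unname(cpi$pixels[1, ]),
                 tolerance = 1e-12)
  }
})

test_that("bootstrap bookkeeping: counts, membership and pixel means agree", {
  gen <- small_cohort(c(0.2, 0.5, 0.8), n_cells = 10, seed = 2)
  cpi <- cohort_persistence_images(gen$cells)
  cfg <- bootstrap_config(sample_size = 7, n_bootstraps = 20, seed = 2)
  bs <- bootstrap_images(cpi$pixels, gen$info$condition, cfg)
  expect_equal(nrow(bs$pixels), 60)                    # 3 x 20
  expect_true(all(lengths(bs$members) == 7))
  expect_equal(unname(rowSums(bs$pixels)), rep(1, 60), tolerance = 1e-9)
  for (i in c(1, 25, 60)) {
    expect_equal(unname(bs$pixels[i, ]),
                 unname(colMeans(cpi$pixels[bs$members[[i]], , drop = FALSE])),
                 tolerance = 1e-12)
    # members come from the pseudo-sample's own condition
    expect_equal(unique(gen$info$condition[bs$members[[i]]]),
                 bs$samples$condition[i])
  }
})

test_that("sampling without replacement requires a large enough population", {
  gen <- small_cohort(0.5, n_cells = 5, seed = 3)
  cpi <- cohort_persistence_images(gen$cells)
  expect_error(
    bootstrap_images(cpi$pixels, gen$info$condition,
                     bootstrap_config(sample_size = 10, n_bootstraps = 2,
                                      replacement = FALSE, seed = 1)),
    "exceeds population")
})

test_that("bootstrap grand mean converges to the population mean with size", {
  gen <- small_cohort(0.5, n_cells = 60, seed = 4)
  cpi <- cohort_persistence_images(gen$cells)
  pop <- colMeans(cpi$pixels)
  l1 <- function(ssize, seed) {
    bs <- bootstrap_images(cpi$pixels, gen$info$condition,
                           bootstrap_config(sample_size = ssize,
                                            n_bootstraps = 100, seed = seed))
    sum(abs(colMeans(bs$pixels) - pop))
  }
  err_small <- mean(vapply(1:3, function(s) l1(10, s), numeric(1)))
  err_big <- mean(vapply(1:3, function(s) l1(40, s), numeric(1)))
  expect_lt(err_big, err_small)
})

test_that("PCA matches a dense SVD oracle on a toy matrix", {
  set.seed(9)
  X <- matrix(rnorm(50 * 30), 50, 30) %*% diag(seq(3, 0.1, length.out = 30))
  p <- gliamorph:::pca_scores(X, 10)
  s <- svd(scale(X, center = TRUE, scale = FALSE))
  oracle_scores <- s$u[, 1:10] %*% diag(s$d[1:10])
  # same variance captured ...
  expect_gte(sum(p$sdev[1:10]^2), 0.99 * sum(s$d[1:10]^2) / 49)
  # ... and same scores up to sign
  for (k in 1:10) {
    expect_equal(abs(cor(p$scores[, k], oracle_scores[, k])), 1,
                 tolerance = 1e-8)
  }
})

test_that("rank-deficient input retains the available components with a warning", {
  X <- matrix(rnorm(20 * 3), 20, 3) %*% matrix(rnorm(3 * 50), 3, 50)
  expect_warning(p <- gliamorph:::pca_scores(X, 10), "rank-deficient")
  expect_lte(p$k, 3)
})

test_that("duplicated pseudo-samples receive identical UMAP coordinates", {
  set.seed(5)
  X <- matrix(rnorm(80 * 40), 80, 40)
  X <- rbind(X, X[1:10, ])   # exact duplicates
  emb <- embed_samples(X, embed_config(n_pcs = 5, umap_n_neighbors = 10,
                                       seed = 3),
                       conditions = rep("a", 90))
  for (i in 1:10) {
    expect_identical(emb$UMAP1[80 + i], emb$UMAP1[i])
    expect_identical(emb$UMAP2[80 + i], emb$UMAP2[i])
  }
})

test_that("embedding is bitwise reproducible for a fixed seed", {
  gen <- small_cohort(c(0.2, 0.8), n_cells = 15, seed = 6)
  cpi <- cohort_persistence_images(gen$cells)
  bs <- bootstrap_images(cpi$pixels, gen$info$condition,
                         bootstrap_config(sample_size = 10, n_bootstraps = 40,
                                          seed = 6))
  e1 <- embed_samples(bs, embed_config(umap_n_neighbors = 15, seed = 6))
  e2 <- embed_samples(bs, embed_config(umap_n_neighbors = 15, seed = 6))
  expect_identical(e1, e2)
})

test_that("separation grows with the reactivity gap and vanishes under permutation", {
  sil_for_gap <- function(phi_b, seed) {
    gen <- small_cohort(c(0.1, phi_b), n_cells = 60, seed = seed)
    cpi <- cohort_persistence_images(gen$cells)
    bs <- bootstrap_images(cpi$pixels, gen$info$condition,
                           bootstrap_config(sample_size = 30,
                                            n_bootstraps = 60, seed = seed))
    emb <- embed_samples(bs, embed_config(umap_n_neighbors = 20, seed = seed))
    list(emb = emb, sil = cluster_separation(emb)$silhouette)
  }
  sils <- sapply(c(0.3, 0.6, 0.9), function(b) {
    mean(vapply(1:3, function(s) sil_for_gap(b, s)$sil, numeric(1)))
  })
  expect_true(all(diff(sils) >= -0.05))  # non-decreasing in the gap
  expect_gt(sils[3], 0.5)

  # label permutation null
  r <- sil_for_gap(0.9, 1)
  emb <- r$emb
  set.seed(1)
  emb$condition <- sample(emb$condition)
  expect_lte(abs(cluster_separation(emb)$silhouette), 0.05)
})

test_that("cluster_separation requires at least two conditions", {
  df <- data.frame(condition = "a", UMAP1 = rnorm(10), UMAP2 = rnorm(10))
  expect_error(cluster_separation(df), ">= 2 conditions")
})
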