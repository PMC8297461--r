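test_that("PCA reconstructs profiles and centres scores", {
  run <- fullSyntheticRun()
  pca <- fitPCA(run$x)
  scores <- pca$scores
  recon <- reconstructPCA(pca$model, scores)
  expect_lt(max(abs(recon - t(erMatrix(run$x)))), 1e-8)
  expect_lt(max(abs(colMeans(scores))), 1e-8)
  # loadings orthonormal, variances match score variances, non-increasing
  g <- crossprod(pcaLoadings(pca$model))
  expect_lt(max(abs(g - diag(20))), 1e-8)
  expect_equal(apply(scores, 2, var), explainedVariance(pca$model),
               ignore_attr = TRUE)
  expect_false(is.unsorted(rev(explainedVariance(pca$model))))
  # the mean profile projects to the zero score vector
  center <- matrix(pcaCenter(pca$model), 1)
  expect_lt(max(abs(projectPCA(pca$model, center))), 1e-8)
  expect_error(fitPCA(t(erMatrix(run$x))[1:10, ]), "at least")
})

test_that("PC1 tracks mean ER on a magnitude-dominant landscape", {
  run <- fullSyntheticRun()
  r2 <- cor(pcScores(run$model)[, 1], meanER(run$x))^2
  expect_gt(r2, 0.9)
})

test_that("UMAP is deterministic, shaped and locality-preserving", {
  set.seed(99)
  X <- matrix(rnorm(120 * 20), 120)
  X[120, ] <- X[1, ]                      # a duplicated point
  u1 <- fitUMAP(X, seed = 5L)
  u2 <- fitUMAP(X, seed = 5L)
  expect_identical(u1$embedding, u2$embedding)
  expect_equal(dim(u1$embedding), c(120, 2))
  expect_true(all(is.finite(u1$embedding)))
  D <- as.matrix(dist(u1$embedding))
  expect_lte(D[1, 120], quantile(D[upper.tri(D)], 0.01))
  expect_error(fitUMAP(X[1:10, ], nNeighbors = 15L), "n_neighbors")
})

test_that("UMAP separates planted archetypes in the embedding", {
  run <- fullSyntheticRun()
  emb <- umapEmbedding(run$model)
  cls <- paste(run$truth$wt_aa, run$truth$archetype)
  keep <- run$truth$archetype != "permissive"
  emb <- emb[keep, ]; cls <- cls[keep]
  D <- as.matrix(dist(emb))
  same <- outer(cls, cls, `==`)
  ut <- upper.tri(D)
  expect_lt(mean(D[ut & same]), mean(D[ut & !same]))
})

test_that("mean ER summaries follow their definitions", {
  expect_equal(meanER(rep(0, 20)), 0)
  expect_equal(meanER(rep(-1, 20)), -1)
  expect_equal(meanER(c(rep(-1, 10), rep(0, 10))), -0.5)

  # two A-positions with A->C of -1 and 0: cell (A, C) mean is -0.5
  er <- matrix(0, 20, 2, dimnames = list(aminoAcids(), NULL))
  er["C", ] <- c(-1, 0)
  x <- MutationalLandscape(er, positionData = data.frame(
    study = "s", gene = "g", position = 1:2, wt_aa = "A"))
  stm <- substitutionTypeMeans(x)
  expect_equal(stm["A", "C"], -0.5)
  expect_true(all(is.na(stm["W", ])))       # no tryptophan positions

  # mean away excludes the synonymous entry
  er2 <- matrix(-1, 20, 1, dimnames = list(aminoAcids(), NULL))
  er2["A", 1] <- 0
  x2 <- MutationalLandscape(er2, positionData = data.frame(
    study = "s", gene = "g", position = 1, wt_aa = "A"))
  away <- meanERAway(x2)
  expect_equal(away[["A"]], -1)
  expect_true(is.na(away[["C"]]))
})

test_that("identical profiles broadcast through substitution-type means", {
  prof <- seq(-1, 0.9, length.out = 20)
  er <- matrix(prof, 20, 6, dimnames = list(aminoAcids(), NULL))
  x <- MutationalLandscape(er, positionData = data.frame(
    study = "s", gene = "g", position = 1:6,
    wt_aa = c("A", "A", "C", "C", "D", "D")))
  stm <- substitutionTypeMeans(x)
  for (a in c("A", "C", "D"))
    expect_equal(stm[a, ], setNames(prof, aminoAcids()))
})

test_that("per-substitution annotations average per position", {
  ann <- data.frame(gene = "g", position = c(1, 1, 2),
                    mut_aa = c("C", "D", "C"), term = "ddG",
                    value = c(1.0, 3.0, 2.0), stringsAsFactors = FALSE)
  agg <- aggregatePositionAnnotations(ann)
  expect_equal(agg$mean_value[agg$position == 1], 2.0)
  expect_equal(agg$mean_value[agg$position == 2], 2.0)
  empty <- aggregatePositionAnnotations(ann[0, ])
  expect_equal(nrow(empty), 0)
  expect_error(
    aggregatePositionAnnotations(ann[, setdiff(names(ann), "value")]),
    "value")
})
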