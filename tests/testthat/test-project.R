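test_that("projection reproduces stored PC scores for reference positions", {
  run <- fullSyntheticRun()
  bundle <- buildReferenceBundle(run$x, run$model, run$assignments,
                                 run$medians)
  proj <- projectPositions(run$x, bundle)
  expect_lt(max(abs(proj$pcScores - pcScores(run$model))), 1e-6)
  expect_equal(dim(proj$embedding), c(ncol(run$x), 2))
  # the reference mean profile projects to the zero score vector
  center <- MutationalLandscape(matrix(pcaCenter(run$model@pca), 20),
                                positionData = data.frame(
                                  study = "q", gene = "q", position = 1,
                                  wt_aa = "A"))
  expect_lt(max(abs(projectPositions(center, bundle)$pcScores)), 1e-8)
})

test_that("subtype assignment follows permissive, centroid and radius rules", {
  run <- fullSyntheticRun()
  bundle <- buildReferenceBundle(run$x, run$model, run$assignments,
                                 run$medians)
  # a near-zero profile is permissive regardless of amino acid
  er <- matrix(0.1, 20, 1, dimnames = list(aminoAcids(), NULL))
  quiet <- MutationalLandscape(er, positionData = data.frame(
    study = "q", gene = "q", position = 1, wt_aa = "L"))
  expect_equal(assignSubtype(quiet, bundle), "LP")
  # labels always carry the query's wild type
  labels <- assignSubtype(run$x, bundle)
  expect_equal(substr(labels, 1, 1), positionData(run$x)$wt_aa)
})

test_that("reference positions are re-assigned their own subtype", {
  run <- fullSyntheticRun()
  bundle <- buildReferenceBundle(run$x, run$model, run$assignments,
                                 run$medians)
  labels <- assignSubtype(run$x, bundle)
  orig <- run$assignments$label
  nonOutlier <- !grepl("O$", orig)
  expect_gt(mean(labels[nonOutlier] == orig[nonOutlier]), 0.95)
})

test_that("bundles survive the JSON/TSV round trip", {
  run <- fullSyntheticRun()
  bundle <- buildReferenceBundle(run$x, run$model, run$assignments,
                                 run$medians)
  prefix <- file.path(tempdir(), "refbundle")
  writeReferenceBundle(bundle, prefix)
  back <- readReferenceBundle(prefix)
  expect_equal(back@pca@center, bundle@pca@center, tolerance = 1e-12)
  expect_equal(back@pca@loadings, bundle@pca@loadings, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back@centroids, bundle@centroids, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back@radii, bundle@radii, tolerance = 1e-12)
  expect_equal(back@permissiveThreshold, bundle@permissiveThreshold)
  # assignments through the reloaded bundle are unchanged
  labels <- assignSubtype(run$x, back)
  expect_equal(labels, assignSubtype(run$x, bundle))
  # and the reloaded transformer projects finite coordinates
  proj <- projectPositions(run$x[, 1:5], back)
  expect_true(all(is.finite(proj$embedding)))
})

test_that("new-study gaps are imputed from the bundle's stored medians", {
  run <- fullSyntheticRun()
  bundle <- buildReferenceBundle(run$x, run$model, run$assignments,
                                 run$medians)
  tab <- data.frame(study = "new", gene = "g", position = 1, wt_aa = "A",
                    mut_aa = setdiff(c(aminoAcids(), "*"), c("A", "C")),
                    er = -0.8, measured = TRUE, stringsAsFactors = FALSE)
  x <- imputeMissing(tab, medians = bundle)
  med <- bundle@imputationMedians
  want <- med$median[med$wt_aa == "A" & med$mut_aa == "C"]
  expect_equal(erMatrix(x)["C", 1], want)
  # an amino acid the bundle has never seen cannot be assigned
  er <- matrix(-1, 20, 1, dimnames = list(aminoAcids(), NULL))
  odd <- MutationalLandscape(er, positionData = data.frame(
    study = "q", gene = "q", position = 1, wt_aa = "W"))
  fake <- bundle
  keep <- substr(rownames(bundle@centroids), 1, 1) != "W"
  fake@centroids <- bundle@centroids[keep, , drop = FALSE]
  fake@radii <- bundle@radii[keep]
  fake@assignments <- bundle@assignments[
    substr(bundle@assignments, 1, 1) != "W"]
  expect_error(assignSubtype(odd, fake), "absent")
})
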