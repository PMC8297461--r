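# Shared fixtures, built in code.  The expensive default-scale synthetic
# run is memoised so several test files can reuse it.

.fixtures <- new.env(parent = emptyenv())

# default-scale synthetic landscape (4 studies x 500 positions), processed
# end to end, with truth aligned to the landscape columns
fullSyntheticRun <- function() {
  if (!is.null(.fixtures$full)) return(.fixtures$full)
  spec <- syntheticSpec(seed = 7L)
  sim <- generateLandscape(spec)
  tabs <- lapply(names(sim$studies), function(id)
    processStudy(sim$studies[[id]], sim$configs[[id]]))
  x <- buildLandscape(tabs)
  model <- fitLandscape(x, seed = 11L)
  assignments <- suppressWarnings(assignSubtypes(x, model))
  truth <- sim$truth
  key <- paste(truth$study, truth$gene, truth$position, sep = ":")
  truth <- truth[match(colnames(erMatrix(x)), key), ]
  medians <- substitutionTypeMedians(do.call(rbind, tabs))
  .fixtures$full <- list(spec = spec, sim = sim, tables = tabs, x = x,
                         model = model, assignments = assignments,
                         truth = truth, medians = medians)
  .fixtures$full
}

# small noiseless study table: every archetype recoverable exactly
noiselessStudy <- function(seed = 3L, nPositions = 60L) {
  spec <- syntheticSpec(nStudies = 1L, nPositions = nPositions,
                        noiseSd = 0, replicateCount = 1L,
                        replicateNoiseSd = 0, studyScale = 1,
                        missingRate = 0, seed = seed)
  generateLandscape(spec)
}

# a tiny hand-checkable record table on the log2-ER scale
tinyRecords <- function() {
  data.frame(
    study = "s1", gene = "g1",
    substitutions = c("A1C", "A1C", "A1D", "A2=", "A1*"),
    score = c(-1.0, -2.0, -0.7, 0.0, -3.0),
    replicate = c("r1", "r2", "r1", "r1", "r1"),
    condition = "c1", stringsAsFactors = FALSE)
}

# random planted clustering instance in cosine geometry: k well-separated
# direction classes (pairwise cosine distance of centres >= 0.6, noise far
# below the separation), n <= 200
plantedCosineInstance <- function(seed) {
  set.seed(seed)
  k <- sample(2:4, 1)
  sizes <- sample(25:45, k, replace = TRUE)
  repeat {
    centers <- matrix(rnorm(k * 10), k)
    centers <- centers / sqrt(rowSums(centers^2))
    if (k < 2) break
    cd <- as.matrix(cosineDist(centers))
    if (min(cd[upper.tri(cd)]) >= 0.6) break
  }
  X <- do.call(rbind, lapply(seq_len(k), function(i)
    sweep(matrix(rnorm(sizes[i] * 10, 0, 0.07), sizes[i]), 2,
          centers[i, ], `+`)))
  list(X = X, truth = rep(seq_len(k), sizes))
}

# planted distinct selective (non-permissive) classes under the default
# generator mixtures: the saturation plateau reference
plantedSelectiveClassCount <- function() {
  mixtures <- dmslandscape:::defaultMixtures()
  sum(vapply(mixtures, function(w)
    sum(names(w) != "permissive"), integer(1)))
}
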