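# Projection of new studies onto a stored reference landscape.

#' Build a reference bundle from a fitted landscape
#'
#' Freezes everything a new study needs to be mapped onto this landscape:
#' the PCA model, the UMAP transformer (with its parameters and seed), the
#' per-subtype centroids in the clustering PC range with an outlier radius
#' each (the `radiusQuantile` quantile of member-to-centroid cosine
#' distance), the pooled imputation medians, and the permissive threshold.
#'
#' @param x The reference [MutationalLandscape-class].
#' @param model The [LandscapeModel-class] fitted on `x`.
#' @param assignments Subtype assignments from [assignSubtypes()].
#' @param medians Pooled [substitutionTypeMedians()] of the normalised
#'   tables that built `x`.
#' @param params The [ClusteringParams-class] used for the assignments.
#' @param radiusQuantile Quantile defining the outlier radius (default
#'   0.95).
#' @return A [ReferenceBundle-class].
#' @export
buildReferenceBundle <- function(x, model, assignments, medians,
                                 params = clusteringParams(),
                                 radiusQuantile = 0.95) {
  pcr <- seq(params@pcRange[1], params@pcRange[2])
  pcs <- pcScores(model)[, pcr, drop = FALSE]
  numbered <- sort(unique(assignments$label[grepl("^[A-Y][0-9]+$",
                                                  assignments$label)]))
  centroids <- matrix(NA_real_, length(numbered), length(pcr),
                      dimnames = list(numbered, colnames(pcs)))
  radii <- setNames(numeric(length(numbered)), numbered)
  for (lb in numbered) {
    members <- which(assignments$label == lb)
    centroids[lb, ] <- colMeans(pcs[members, , drop = FALSE])
    dists <- vapply(members, function(i)
      cosineDistVec(pcs[i, ], centroids[lb, ]), numeric(1))
    # inverted-ECDF quantile: the smallest member distance covering at
    # least radiusQuantile of members, so the radius truly contains them
    radii[lb] <- quantile(dists, radiusQuantile, names = FALSE, type = 1)
  }
  new("ReferenceBundle", pca = model@pca, umapParams = model@umapParams,
      umapModel = model@umapModel, referenceER = erMatrix(x),
      positions = positionData(x),
      assignments = setNames(assignments$label, colnames(erMatrix(x))),
      centroids = centroids, radii = radii,
      imputationMedians = medians,
      permissiveThreshold = params@permissiveThreshold,
      pcRange = params@pcRange)
}

cosineDistVec <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine distance undefined for zero vector")
  1 - sum(u * v) / (nu * nv)
}

#' Project new positions onto a reference landscape
#'
#' Computes PC scores through the bundle's stored center and loadings and
#' 2-D coordinates through the stored UMAP transformer.  The new study must
#' already be normalised by the ingest pipeline, with gaps imputed from the
#' bundle's stored medians (pass `bundle@imputationMedians`, or the bundle
#' itself, to [imputeMissing()]).
#'
#' @param x A [MutationalLandscape-class] of new positions.
#' @param bundle A [ReferenceBundle-class].
#' @return List with `pcScores` (N x 20) and `embedding` (N x 2).
#' @export
projectPositions <- function(x, bundle) {
  profiles <- t(erMatrix(x))
  scores <- sweep(profiles, 2, bundle@pca@center) %*% bundle@pca@loadings
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  if (is.null(bundle@umapModel))
    stop("bundle has no live UMAP transformer; load it with ",
         "readReferenceBundle()")
  emb <- uwot::umap_transform(profiles, bundle@umapModel)
  dimnames(emb) <- list(rownames(profiles), c("umap1", "umap2"))
  list(pcScores = scores, embedding = emb)
}

#' Assign subtypes to new positions via a reference bundle
#'
#' The nearest-centroid rule mirroring the clustering geometry: a position
#' whose every ER entry is below the permissive threshold in magnitude is
#' `XP`; otherwise it is assigned the nearest same-amino-acid numbered
#' subtype centroid by cosine distance in the clustering PC range, or `XO`
#' when that distance exceeds the subtype's outlier radius.
#'
#' @param x A [MutationalLandscape-class] of new, normalised and imputed
#'   positions.
#' @param bundle A [ReferenceBundle-class].
#' @return Character vector of labels, one per position.
#' @export
assignSubtype <- function(x, bundle) {
  er <- erMatrix(x)
  wt <- positionData(x)$wt_aa
  pcr <- seq(bundle@pcRange[1], bundle@pcRange[2])
  scores <- sweep(t(er), 2, bundle@pca@center) %*% bundle@pca@loadings
  centroidAA <- substr(rownames(bundle@centroids), 1, 1)
  refAAs <- unique(c(centroidAA, substr(bundle@assignments, 1, 1)))
  labels <- character(ncol(er))
  for (j in seq_len(ncol(er))) {
    a <- wt[j]
    if (!a %in% refAAs)
      stop("amino acid '", a, "' is absent from the reference bundle")
    if (max(abs(er[, j])) < bundle@permissiveThreshold) {
      labels[j] <- paste0(a, "P")
      next
    }
    mine <- which(centroidAA == a)
    if (length(mine) == 0) { labels[j] <- paste0(a, "O"); next }
    v <- scores[j, pcr]
    dists <- vapply(mine, function(k)
      cosineDistVec(v, bundle@centroids[k, ]), numeric(1))
    k <- mine[which.min(dists)]
    labels[j] <- if (min(dists) <= bundle@radii[k])
      rownames(bundle@centroids)[k] else paste0(a, "O")
  }
  labels
}

#' Serialise / load a reference bundle
#'
#' `writeReferenceBundle` writes a JSON file (`<prefix>.json`: PCA model,
#' UMAP parameters, centroids, radii, imputation medians, thresholds) and a
#' TSV sidecar (`<prefix>_reference.tsv`: reference profiles with labels).
#' `readReferenceBundle` reads them back and rebuilds the UMAP transformer
#' deterministically by refitting on the stored reference profiles with the
#' stored seed.
#'
#' @param bundle A [ReferenceBundle-class].
#' @param prefix Path prefix for the two files.
#' @return `writeReferenceBundle` returns the file paths invisibly;
#'   `readReferenceBundle` returns the [ReferenceBundle-class].
#' @export
writeReferenceBundle <- function(bundle, prefix) {
  jsonPath <- paste0(prefix, ".json")
  tsvPath <- paste0(prefix, "_reference.tsv")
  payload <- list(
    pca = list(center = bundle@pca@center,
               loadings = as.vector(t(bundle@pca@loadings)),
               explained_variance = bundle@pca@explainedVariance),
    umap_params = bundle@umapParams,
    centroids = list(labels = rownames(bundle@centroids),
                     values = as.vector(t(bundle@centroids))),
    radii = as.list(bundle@radii),
    imputation_medians = bundle@imputationMedians,
    permissive_threshold = bundle@permissiveThreshold,
    pc_range = bundle@pcRange)
  # 17 significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(payload, jsonPath, auto_unbox = TRUE,
                       digits = I(17))
  ref <- data.frame(key = colnames(bundle@referenceER),
                    bundle@positions,
                    label = unname(bundle@assignments),
                    t(bundle@referenceER), check.names = FALSE)
  writeTsv(ref, tsvPath)
  invisible(c(jsonPath, tsvPath))
}

#' @rdname writeReferenceBundle
#' @export
readReferenceBundle <- function(prefix) {
  payload <- jsonlite::read_json(paste0(prefix, ".json"),
                                 simplifyVector = TRUE)
  ref <- readTsv(paste0(prefix, "_reference.tsv"))
  er <- t(as.matrix(ref[, AA_ALPHABET]))
  colnames(er) <- ref$key
  p <- length(payload$pca$center)
  pcNames <- paste0("PC", seq_len(p))
  center <- setNames(payload$pca$center, AA_ALPHABET[seq_len(p)])
  loadings <- matrix(payload$pca$loadings, p, p, byrow = TRUE,
                     dimnames = list(AA_ALPHABET[seq_len(p)], pcNames))
  pca <- new("PCAModel", center = center, loadings = loadings,
             explainedVariance = payload$pca$explained_variance)
  pcr <- as.integer(payload$pc_range)
  labs <- as.character(unlist(payload$centroids$labels))
  pcCols <- paste0("PC", seq(pcr[1], pcr[2]))
  centroids <- matrix(as.numeric(unlist(payload$centroids$values)),
                      nrow = length(labs), ncol = length(pcCols),
                      byrow = TRUE, dimnames = list(labs, pcCols))
  up <- payload$umap_params
  um <- fitUMAP(t(er), nNeighbors = up$n_neighbors, minDist = up$min_dist,
                seed = up$seed)
  posCols <- setdiff(colnames(ref), c("key", "label", AA_ALPHABET))
  new("ReferenceBundle", pca = pca,
      umapParams = list(n_neighbors = as.integer(up$n_neighbors),
                        min_dist = up$min_dist, seed = as.integer(up$seed)),
      umapModel = um$model, referenceER = er,
      positions = ref[, posCols, drop = FALSE],
      assignments = setNames(ref$label, ref$key),
      centroids = centroids,
      radii = setNames(as.numeric(unlist(payload$radii))[seq_along(labs)],
                       labs),
      imputationMedians = as.data.frame(payload$imputation_medians),
      permissiveThreshold = payload$permissive_threshold,
      pcRange = as.integer(payload$pc_range))
}
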