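# Amino acid subtypes: permissive split, per-amino-acid clustering in
# PC2-PC20 cosine space, frequency-ordered labelling and characterisation.

#' Split off permissive positions
#'
#' A position is permissive when every one of its 20 ER entries has
#' magnitude below the threshold: it tolerates everything, and its profile
#' direction — all that cosine distance sees — is noise.
#'
#' @param x A [MutationalLandscape-class].
#' @param threshold Strict |ER| bound (default 0.4).
#' @return Logical vector, `TRUE` for permissive positions.
#' @export
splitPermissive <- function(x, threshold = 0.4) {
  apply(abs(erMatrix(x)), 2, max) < threshold
}

#' Cluster the positions of one amino acid
#'
#' Average-linkage hierarchical clustering with cosine distance on the
#' clustering PC range (PC2-PC20 by default), cut with
#' [dynamicHybridCut()].  With fewer than two positions nothing can be
#' clustered and all points are returned as outliers with a warning.
#'
#' @param pcs N x k matrix: the clustering-range PC scores of the
#'   clusterable positions of one amino acid.
#' @param deepSplit,minClusterSize See [dynamicHybridCut()].
#' @return Integer cluster ids (0 = outlier), one per row of `pcs`.
#' @export
clusterAminoAcid <- function(pcs, deepSplit = 0, minClusterSize = 20L) {
  pcs <- as.matrix(pcs)
  if (nrow(pcs) < 2) {
    warning("fewer than 2 clusterable positions; all returned as outliers")
    return(rep(0L, nrow(pcs)))
  }
  d <- cosineDist(pcs)
  hc <- hclust(d, method = "average")
  dynamicHybridCut(hc, d, deepSplit = deepSplit,
                   minClusterSize = minClusterSize)
}

#' Assign every position to an amino acid subtype
#'
#' The three-step subtype procedure, applied independently to the positions
#' of each wild-type amino acid X: (1) split off permissive positions
#' (label `XP`); (2) cluster the rest by average-linkage cosine distance on
#' their PC2-PC20 scores; (3) cut the dendrogram with the hybrid dynamic
#' tree cut.  Detected clusters are renumbered `X1, X2, ...` from most to
#' least frequent (ties broken by smaller mean intra-cluster cosine
#' distance, then by lowest member index); unassigned positions are
#' outliers, `XO`.
#'
#' @param x A [MutationalLandscape-class].
#' @param model A [LandscapeModel-class] fitted on `x` (the PCA basis is
#'   fit on the whole landscape, permissive positions included).
#' @param params A [ClusteringParams-class].
#' @return data.frame `study`, `gene`, `position`, `wt_aa`, `label`, in
#'   landscape column order.
#' @export
assignSubtypes <- function(x, model, params = clusteringParams()) {
  pd <- positionData(x)
  n <- ncol(x)
  perm <- splitPermissive(x, params@permissiveThreshold)
  pcr <- seq(params@pcRange[1], params@pcRange[2])
  pcs <- pcScores(model)[, pcr, drop = FALSE]

  labels <- character(n)
  labels[perm] <- paste0(pd$wt_aa[perm], "P")
  for (a in unique(pd$wt_aa)) {
    idx <- which(pd$wt_aa == a & !perm)
    if (length(idx) == 0) next
    ids <- if (length(idx) < 2) {
      warning("fewer than 2 clusterable positions for amino acid ", a,
              "; all returned as outliers")
      rep(0L, length(idx))
    } else {
      clusterAminoAcid(pcs[idx, , drop = FALSE],
                       deepSplit = params@deepSplit[[a]],
                       minClusterSize = params@minClusterSize)
    }
    labels[idx] <- labelSubtypes(ids, a, pcs[idx, , drop = FALSE])
  }
  data.frame(study = pd$study, gene = pd$gene, position = pd$position,
             wt_aa = pd$wt_aa, label = labels, stringsAsFactors = FALSE)
}

#' Frequency-ordered subtype labels for one amino acid
#'
#' Renumbers raw cluster ids by decreasing size: the most frequent cluster
#' becomes `X1`, and so on; id 0 becomes the outlier label `XO`.  Equal-size
#' clusters are ordered by smaller mean intra-cluster cosine distance, then
#' by lowest member index, so labelling is deterministic and invariant to
#' input order.
#'
#' @param ids Integer cluster ids from [clusterAminoAcid()] (0 = outlier).
#' @param aa Single-letter wild-type amino acid.
#' @param pcs The PC-score rows the ids refer to (used only for the
#'   tie-break).
#' @return Character vector of labels.
#' @export
labelSubtypes <- function(ids, aa, pcs = NULL) {
  labels <- character(length(ids))
  labels[ids == 0L] <- paste0(aa, "O")
  ks <- sort(unique(ids[ids > 0L]))
  if (length(ks)) {
    size <- vapply(ks, function(k) sum(ids == k), integer(1))
    tight <- vapply(ks, function(k) {
      members <- which(ids == k)
      if (is.null(pcs) || length(members) < 2) return(0)
      mean(as.matrix(cosineDist(pcs[members, , drop = FALSE])))
    }, numeric(1))
    firstIdx <- vapply(ks, function(k) min(which(ids == k)), integer(1))
    ord <- order(-size, tight, firstIdx)
    for (r in seq_along(ord))
      labels[ids == ks[ord[r]]] <- paste0(aa, r)
  }
  labels
}

#' Mean profiles, sizes and frequencies of subtypes
#'
#' One row per label with the member count, the frequency among all
#' positions of that amino acid, and the entry-wise mean ER profile.
#'
#' @param assignments data.frame from [assignSubtypes()].
#' @param x The [MutationalLandscape-class] the assignments refer to.
#' @return data.frame `label`, `wt_aa`, `size`, `frequency`, `mean_ER`
#'   (mean of the mean profile) and 20 columns `mean_A` ... `mean_Y`.
#' @export
subtypeProfiles <- function(assignments, x) {
  er <- erMatrix(x)
  wt <- positionData(x)$wt_aa
  stopifnot(nrow(assignments) == ncol(er))
  aaTotals <- table(wt)
  labs <- sort(unique(assignments$label))
  rows <- lapply(labs, function(lb) {
    members <- which(assignments$label == lb)
    prof <- rowMeans(er[, members, drop = FALSE])
    a <- substr(lb, 1, 1)
    cbind(data.frame(label = lb, wt_aa = a, size = length(members),
                     frequency = length(members) / as.integer(aaTotals[[a]]),
                     mean_ER = mean(prof), stringsAsFactors = FALSE),
          as.data.frame(t(setNames(prof, paste0("mean_", AA_ALPHABET)))))
  })
  out <- do.call(rbind, rows)
  # most frequent first within each amino acid, P and O after the numbered
  num <- suppressWarnings(as.integer(sub("^[A-Y]", "", out$label)))
  rank <- ifelse(!is.na(num), num,
                 ifelse(grepl("P$", out$label), 1000L, 1001L))
  out <- out[order(out$wt_aa, rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Correlate subtype mean profiles
#'
#' Pearson correlation between the mean profiles of all subtypes, plus an
#' average-linkage grouping on the distance `1 - r`, used to organise
#' subtypes into recurring classes (e.g. "not proline"-like patterns shared
#' across amino acids).
#'
#' @param profiles data.frame from [subtypeProfiles()].
#' @return List with `correlation` (matrix), `hclust` and `order` (labels
#'   in dendrogram order).
#' @export
correlateSubtypes <- function(profiles) {
  if (nrow(profiles) < 2) stop("need at least 2 subtypes to correlate")
  m <- as.matrix(profiles[, paste0("mean_", AA_ALPHABET)])
  rownames(m) <- profiles$label
  sds <- apply(m, 1, sd)
  if (any(sds == 0))
    stop("constant mean profile(s); correlation undefined for: ",
         paste(profiles$label[sds == 0], collapse = ", "))
  r <- cor(t(m))
  hc <- hclust(as.dist(1 - r), method = "average")
  list(correlation = r, hclust = hc, order = rownames(m)[hc$order])
}

#' The most selective subtype of each amino acid
#'
#' For each amino acid with at least one numbered subtype, returns the
#' subtype whose mean profile mean is lowest (most negative: tolerating
#' least).  `direction = "highest"` flips the rule to the literal
#' highest-mean reading.
#'
#' @param profiles data.frame from [subtypeProfiles()].
#' @param direction `"lowest"` (default, most intolerant) or `"highest"`.
#' @return Named character vector, one label per amino acid present
#'   (`NA` when an amino acid has only permissive/outlier labels).
#' @export
mostSelectiveSubtype <- function(profiles, direction = c("lowest",
                                                         "highest")) {
  direction <- match.arg(direction)
  numbered <- profiles[grepl("^[A-Y][0-9]+$", profiles$label), ,
                       drop = FALSE]
  aas <- sort(unique(profiles$wt_aa))
  out <- setNames(rep(NA_character_, length(aas)), aas)
  for (a in intersect(aas, unique(numbered$wt_aa))) {
    sub <- numbered[numbered$wt_aa == a, , drop = FALSE]
    pick <- if (direction == "lowest") which.min(sub$mean_ER)
            else which.max(sub$mean_ER)
    out[a] <- sub$label[pick]
  }
  out
}

#' Subtype saturation analysis
#'
#' Repeatedly re-runs the full subtype pipeline (PCA refit included) on
#' nested random subsets of positions and counts the numbered subtypes
#' found, to ask whether the catalogue is saturating as data accumulate.
#'
#' @param x A [MutationalLandscape-class].
#' @param start First subset size (default 1000).
#' @param step Size increment (default 200).
#' @param nShuffles Number of random position orders (default 100).
#' @param seed Integer seed; results are reproducible for a fixed seed.
#' @param params A [ClusteringParams-class].
#' @param nNeighbors,minDist UMAP settings are not needed here; the PCA
#'   basis is refit per subset.
#' @return data.frame `shuffle`, `size`, `n_subtypes` (numbered subtypes
#'   only, permissive and outlier labels excluded).
#' @export
saturationAnalysis <- function(x, start = 1000L, step = 200L,
                               nShuffles = 100L, seed = 1L,
                               params = clusteringParams()) {
  n <- ncol(x)
  if (start > n) stop("start (", start, ") exceeds available positions (",
                      n, ")")
  sizes <- seq(as.integer(start), n, by = as.integer(step))
  if (sizes[length(sizes)] != n) sizes <- c(sizes, n)
  set.seed(seed)
  perms <- lapply(seq_len(nShuffles), function(i) sample.int(n))
  rows <- list()
  for (s in seq_len(nShuffles)) {
    for (sz in sizes) {
      sub <- x[, sort(perms[[s]][seq_len(sz)])]
      sub <- methods::as(sub, "MutationalLandscape")
      pca <- fitPCA(sub)
      fakeModel <- new("LandscapeModel", pca = pca$model,
                       pcScores = pca$scores,
                       embedding = matrix(0, ncol(sub), 2),
                       umapParams = list(n_neighbors = 15L, min_dist = 0.1,
                                         seed = 0L),
                       umapModel = NULL,
                       positions = colnames(erMatrix(sub)))
      asg <- assignSubtypes(sub, fakeModel, params)
      cnt <- length(unique(asg$label[grepl("^[A-Y][0-9]+$", asg$label)]))
      rows[[length(rows) + 1]] <- data.frame(shuffle = s, size = sz,
                                             n_subtypes = cnt)
    }
  }
  do.call(rbind, rows)
}
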