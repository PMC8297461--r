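# The combined landscape: PCA and UMAP views plus per-position summary
# statistics.

#' Fit a PCA model of the mutational landscape
#'
#' Principal components of the 20-dimensional normalised profiles (full
#' rank, no scaling).  Column signs are fixed so that each loading's
#' largest-magnitude element is positive, making serialised models stable.
#' On landscapes whose dominant variation is overall profile magnitude, PC1
#' tracks mean ER almost perfectly.
#'
#' @param x A [MutationalLandscape-class] or an N x 20 matrix of profiles.
#' @return A list with `model` (a [PCAModel-class]) and `scores`
#'   (N x 20 matrix of PC scores).
#' @export
fitPCA <- function(x) {
  profiles <- profileMatrix(x)
  n <- nrow(profiles)
  if (n < ncol(profiles) + 1)
    stop("need at least ", ncol(profiles) + 1, " profiles to fit a ",
         "full-rank PCA; got ", n)
  pc <- prcomp(profiles, center = TRUE, scale. = FALSE)
  load <- pc$rotation
  flip <- apply(load, 2, function(v) v[which.max(abs(v))] < 0)
  load[, flip] <- -load[, flip]
  scores <- pc$x
  scores[, flip] <- -scores[, flip]
  model <- new("PCAModel", center = pc$center, loadings = load,
               explainedVariance = pc$sdev^2)
  dimnames(scores) <- list(rownames(profiles),
                           paste0("PC", seq_len(ncol(scores))))
  list(model = model, scores = scores)
}

profileMatrix <- function(x) {
  if (is(x, "MutationalLandscape")) t(erMatrix(x)) else as.matrix(x)
}

#' Project profiles with a fitted PCA model
#'
#' @param model A [PCAModel-class].
#' @param x Profiles (landscape or N x 20 matrix).
#' @return N x 20 matrix of PC scores.
#' @export
projectPCA <- function(model, x) {
  profiles <- profileMatrix(x)
  scores <- sweep(profiles, 2, model@center) %*% model@loadings
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  scores
}

#' Reconstruct profiles from PC scores
#'
#' @param model A [PCAModel-class].
#' @param scores N x 20 matrix of PC scores.
#' @return N x 20 matrix of reconstructed profiles.
#' @export
reconstructPCA <- function(model, scores) {
  sweep(scores %*% t(model@loadings), 2, model@center, `+`)
}

#' Fit a 2-D UMAP embedding
#'
#' Uniform manifold approximation of the 20-dimensional profiles (Euclidean
#' metric).  The run is single-threaded and seeded, so identical inputs,
#' parameters and seed give identical embeddings, and the returned
#' transformer supports out-of-sample projection via [projectPositions()].
#'
#' @param x Landscape or N x d matrix.
#' @param nNeighbors,minDist UMAP hyper-parameters (defaults 15, 0.1).
#' @param seed Integer seed.
#' @return List with `embedding` (N x 2) and `model` (uwot transformer).
#' @export
fitUMAP <- function(x, nNeighbors = 15L, minDist = 0.1, seed = 42L) {
  m <- profileMatrix(x)
  if (nrow(m) < nNeighbors + 1)
    stop("need more than n_neighbors = ", nNeighbors, " points; got ",
         nrow(m))
  set.seed(seed)
  fit <- uwot::umap(m, n_neighbors = nNeighbors, min_dist = minDist,
                    metric = "euclidean", n_threads = 1, n_sgd_threads = 0,
                    ret_model = TRUE)
  emb <- fit$embedding
  dimnames(emb) <- list(rownames(m), c("umap1", "umap2"))
  list(embedding = emb, model = fit)
}

#' Fit the full landscape model (PCA + UMAP)
#'
#' @param x A [MutationalLandscape-class].
#' @param nNeighbors,minDist,seed UMAP settings (see [fitUMAP()]).
#' @return A [LandscapeModel-class].
#' @export
fitLandscape <- function(x, nNeighbors = 15L, minDist = 0.1, seed = 42L) {
  pca <- fitPCA(x)
  um <- fitUMAP(x, nNeighbors, minDist, seed)
  new("LandscapeModel", pca = pca$model, pcScores = pca$scores,
      embedding = um$embedding,
      umapParams = list(n_neighbors = as.integer(nNeighbors),
                        min_dist = minDist, seed = as.integer(seed)),
      umapModel = um$model, positions = colnames(erMatrix(x)))
}

#' Mean normalised ER per position
#'
#' Arithmetic mean of the 20 profile entries; the landscape's strongest
#' single descriptor of a position's overall mutational tolerance.
#'
#' @param x A [MutationalLandscape-class], a profile matrix (N x 20) or a
#'   single 20-vector.
#' @return Numeric vector of per-position means (a scalar for a single
#'   profile).
#' @export
meanER <- function(x) {
  if (is(x, "MutationalLandscape")) return(colMeans(erMatrix(x)))
  if (is.matrix(x)) return(rowMeans(x))
  mean(x)
}

#' Mean ER per substitution type
#'
#' Cell (a, b) is the mean normalised ER of substitutions a -> b over all
#' positions with wild type a; the diagonal holds the synonymous mean.
#' Types never observed are `NA`.  Comparable to log-odds substitution
#' matrices such as BLOSUM62.
#'
#' @param x A [MutationalLandscape-class].
#' @return 20 x 20 numeric matrix (rows = wild type, columns = target).
#' @export
substitutionTypeMeans <- function(x) {
  er <- erMatrix(x)
  wt <- positionData(x)$wt_aa
  out <- matrix(NA_real_, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  for (a in AA_ALPHABET) {
    cols <- wt == a
    if (any(cols))
      out[a, ] <- rowMeans(er[, cols, drop = FALSE])
  }
  out
}

#' Mean ER away from each wild-type amino acid
#'
#' Entry a is the mean over all positions with wild type a of the 19
#' missense entries (the synonymous entry is excluded); an estimate of the
#' average cost of mutating away from that amino acid.
#'
#' @param x A [MutationalLandscape-class].
#' @return Named numeric 20-vector (`NA` for absent wild types).
#' @export
meanERAway <- function(x) {
  er <- erMatrix(x)
  wt <- positionData(x)$wt_aa
  out <- setNames(rep(NA_real_, 20), AA_ALPHABET)
  for (a in AA_ALPHABET) {
    cols <- which(wt == a)
    if (length(cols)) {
      sub <- er[setdiff(AA_ALPHABET, a), cols, drop = FALSE]
      out[a] <- mean(sub)
    }
  }
  out
}

#' Aggregate per-substitution annotations to positions
#'
#' Averages externally supplied per-substitution annotation values (for
#' example per-substitution stability-change terms) over the available
#' substitutions at each position, one mean per (gene, position, term).
#'
#' @param annotations data.frame with columns `gene`, `position`, `term`,
#'   `value` and optionally `mut_aa`.
#' @return data.frame `gene`, `position`, `term`, `mean_value`.
#' @export
aggregatePositionAnnotations <- function(annotations) {
  annotations <- as.data.frame(annotations)
  need <- c("gene", "position", "term", "value")
  miss <- setdiff(need, colnames(annotations))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  if (nrow(annotations) == 0)
    return(data.frame(gene = character(0), position = integer(0),
                      term = character(0), mean_value = numeric(0)))
  agg <- aggregate(value ~ gene + position + term, data = annotations,
                   FUN = mean)
  names(agg)[names(agg) == "value"] <- "mean_value"
  agg[order(agg$gene, agg$position, agg$term), , drop = FALSE]
}

#' Correlation of substitution-type means with BLOSUM62
#'
#' Convenience comparison of the landscape's mean missense ER per
#' substitution type against the BLOSUM62 log-odds matrix, an evolutionary
#' yardstick: combined landscapes built from function-related selections
#' correlate positively with it.
#'
#' @param x A [MutationalLandscape-class].
#' @return List with `r` (Pearson correlation over observed missense types)
#'   and `n` (number of types compared).
#' @export
blosumComparison <- function(x) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("Biostrings is required for the BLOSUM62 comparison")
  data("BLOSUM62", package = "Biostrings", envir = environment())
  blosum <- get("BLOSUM62", envir = environment())[AA_ALPHABET, AA_ALPHABET]
  stm <- substitutionTypeMeans(x)
  off <- row(stm) != col(stm) & !is.na(stm)
  list(r = cor(stm[off], blosum[off]), n = sum(off))
}
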