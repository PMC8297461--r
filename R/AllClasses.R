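#' @import methods
#' @importFrom stats median prcomp var cor sd quantile cutree hclust as.dist
#'   as.dendrogram aggregate setNames rnorm runif complete.cases
#' @importFrom utils read.csv read.delim write.table packageVersion head tail
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
NULL

# ---------------------------------------------------------------------------
# StudyConfig ----------------------------------------------------------------

#' StudyConfig: recipe for standardising one DMS study
#'
#' Declarative description of how a single published deep mutational
#' scanning study is converted to the common log2 enrichment-ratio (ER)
#' scale: the score transform, the treatment of experimental conditions, and
#' the multi-mutant averaging cap.
#'
#' @slot studyId,gene Identifiers.
#' @slot transform One of `"identity"`, `"log2_ratio"`, `"negate"`,
#'   `"affine"`.
#' @slot transformParams Numeric `(a, b)` for the affine transform
#'   `a * score + b`; ignored otherwise.
#' @slot conditionPolicy Named character vector mapping condition ids to
#'   `"average"`, `"prefer"` or `"drop"`.  Conditions not named follow
#'   `"average"`.
#' @slot multimutantCap Maximum number of substitutions a multi-mutant
#'   sequence may carry to contribute to single-substitution averaging.
#' @slot wtAAMap Optional named character vector (names = positions) giving
#'   the declared wild-type amino acid, used for validation.
#' @export
setClass("StudyConfig",
         slots = c(studyId = "character", gene = "character",
                   transform = "character", transformParams = "numeric",
                   conditionPolicy = "character", multimutantCap = "integer",
                   wtAAMap = "character"))

#' Construct a StudyConfig
#'
#' @param studyId,gene Identifiers.
#' @param transform Score transform onto the log2-ER scale.
#' @param transformParams Numeric `(a, b)` for `transform = "affine"`.
#' @param conditionPolicy Named character vector of per-condition policies
#'   (`"average"`, `"prefer"`, `"drop"`).
#' @param multimutantCap Positive integer cap on multi-mutant order.
#' @param wtAAMap Optional named character vector of declared wild types.
#' @return A [StudyConfig-class] object.
#' @examples
#' studyConfig("S1", "geneA", transform = "log2_ratio")
#' @export
studyConfig <- function(studyId, gene = NA_character_,
                        transform = c("identity", "log2_ratio", "negate",
                                      "affine"),
                        transformParams = c(1, 0),
                        conditionPolicy = character(0),
                        multimutantCap = 3L,
                        wtAAMap = character(0)) {
  transform <- match.arg(transform)
  multimutantCap <- as.integer(multimutantCap)
  if (is.na(multimutantCap) || multimutantCap < 1L)
    stop("multimutantCap must be a positive integer")
  if (length(conditionPolicy) &&
      !all(conditionPolicy %in% c("average", "prefer", "drop")))
    stop("conditionPolicy values must be 'average', 'prefer' or 'drop'")
  new("StudyConfig", studyId = as.character(studyId),
      gene = as.character(gene), transform = transform,
      transformParams = as.numeric(transformParams),
      conditionPolicy = conditionPolicy,
      multimutantCap = multimutantCap, wtAAMap = wtAAMap)
}

setMethod("show", "StudyConfig", function(object) {
  cat("StudyConfig for study '", object@studyId, "' (gene ",
      object@gene, ")\n", sep = "")
  cat("  transform: ", object@transform, "\n", sep = "")
  if (length(object@conditionPolicy))
    cat("  conditions: ",
        paste(names(object@conditionPolicy), object@conditionPolicy,
              sep = "=", collapse = ", "), "\n", sep = "")
  cat("  multi-mutant cap: ", object@multimutantCap, "\n", sep = "")
})

# ---------------------------------------------------------------------------
# MutationalLandscape --------------------------------------------------------

#' MutationalLandscape: combined per-position mutational profiles
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding the
#' combined mutational landscape.  Columns are protein positions (one per
#' study x gene x position), rows are the 20 target amino acids in the order
#' of [aminoAcids()].  Assay `"er"` holds normalised enrichment-ratio
#' scores (the entry at the wild-type amino acid is the synonymous score);
#' assay `"imputed"` is a logical mask marking entries that were filled by
#' imputation rather than measured.  `colData` carries `study`, `gene`,
#' `position`, `wt_aa`, `nonsense_er`, `nonsense_imputed` and
#' `n_nonsyn_measured`.
#'
#' @export
setClass("MutationalLandscape", contains = "SummarizedExperiment")

setValidity("MutationalLandscape", function(object) {
  msg <- character(0)
  if (!all(c("er", "imputed") %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assays 'er' and 'imputed' are required")
  if (!identical(rownames(object), AA_ALPHABET))
    msg <- c(msg, "rows must be the 20 amino acids in canonical order")
  need <- c("study", "gene", "position", "wt_aa", "nonsense_er",
            "nonsense_imputed", "n_nonsyn_measured")
  miss <- setdiff(need, colnames(SummarizedExperiment::colData(object)))
  if (length(miss))
    msg <- c(msg, paste("missing colData columns:",
                        paste(miss, collapse = ", ")))
  if (length(msg) == 0) {
    er <- SummarizedExperiment::assay(object, "er")
    if (any(!is.finite(er)))
      msg <- c(msg, "assay 'er' must be finite after imputation")
    wt <- object$wt_aa
    if (!all(wt %in% AA_ALPHABET))
      msg <- c(msg, "wt_aa must be standard amino acids")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MutationalLandscape
#'
#' @param er 20 x N numeric matrix of normalised ER scores (rows in
#'   [aminoAcids()] order).
#' @param imputed 20 x N logical matrix marking imputed entries; defaults to
#'   all-`FALSE`.
#' @param positionData data.frame with one row per column of `er` and at
#'   least `study`, `gene`, `position`, `wt_aa`; optional `nonsense_er`,
#'   `nonsense_imputed`, `n_nonsyn_measured` are filled with defaults.
#' @return A [MutationalLandscape-class].
#' @export
MutationalLandscape <- function(er, imputed = NULL, positionData) {
  er <- as.matrix(er)
  rownames(er) <- AA_ALPHABET
  if (is.null(imputed))
    imputed <- matrix(FALSE, nrow(er), ncol(er))
  imputed <- as.matrix(imputed)
  rownames(imputed) <- AA_ALPHABET
  positionData <- as.data.frame(positionData)
  if (is.null(positionData$nonsense_er))
    positionData$nonsense_er <- NA_real_
  if (is.null(positionData$nonsense_imputed))
    positionData$nonsense_imputed <- FALSE
  if (is.null(positionData$n_nonsyn_measured))
    positionData$n_nonsyn_measured <- colSums(!imputed) -
      as.integer(!imputed[cbind(match(positionData$wt_aa, AA_ALPHABET),
                                seq_len(ncol(er)))]) +
      as.integer(!positionData$nonsense_imputed & !is.na(positionData$nonsense_er))
  keys <- positionKey(positionData)
  colnames(er) <- keys
  colnames(imputed) <- keys
  rownames(positionData) <- keys
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(er = er, imputed = imputed),
    colData = S4Vectors::DataFrame(positionData))
  new("MutationalLandscape", se)
}

positionKey <- function(df) {
  paste(df$study, df$gene, df$position, sep = ":")
}

setMethod("show", "MutationalLandscape", function(object) {
  cat("MutationalLandscape with", ncol(object), "positions from",
      length(unique(object$study)), "study/studies,",
      length(unique(paste(object$study, object$gene))), "gene(s)\n")
  imp <- SummarizedExperiment::assay(object, "imputed")
  cat(sprintf("  measured missense/synonymous entries: %.2f%%\n",
              100 * mean(!imp)))
  cat("  wild-type amino acids:",
      paste(sort(unique(object$wt_aa)), collapse = ""), "\n")
})

#' Accessors for MutationalLandscape
#'
#' `erMatrix` returns the 20 x N normalised ER matrix, `imputedMask` the
#' logical imputation mask, `positionData` the per-position metadata and
#' `nonsenseER` the per-position nonsense ER scores.
#'
#' @param x A [MutationalLandscape-class].
#' @return See individual descriptions.
#' @name landscape-accessors
NULL

#' @rdname landscape-accessors
#' @export
erMatrix <- function(x) SummarizedExperiment::assay(x, "er")

#' @rdname landscape-accessors
#' @export
imputedMask <- function(x) SummarizedExperiment::assay(x, "imputed")

#' @rdname landscape-accessors
#' @export
positionData <- function(x)
  as.data.frame(SummarizedExperiment::colData(x))

#' @rdname landscape-accessors
#' @export
nonsenseER <- function(x) x$nonsense_er

# ---------------------------------------------------------------------------
# PCAModel / LandscapeModel --------------------------------------------------

#' PCAModel: principal components of the mutational landscape
#'
#' @slot center Numeric 20-vector, the mean profile.
#' @slot loadings 20 x 20 orthonormal matrix; columns are PC1..PC20 with the
#'   sign convention that each column's largest-magnitude element is
#'   positive.
#' @slot explainedVariance Non-increasing numeric 20-vector; entry k is the
#'   variance of the scores on PC k.
#' @export
setClass("PCAModel",
         slots = c(center = "numeric", loadings = "matrix",
                   explainedVariance = "numeric"))

setValidity("PCAModel", function(object) {
  msg <- character(0)
  p <- length(object@center)
  if (!all(dim(object@loadings) == c(p, p)))
    msg <- c(msg, "loadings must be square and match center length")
  g <- crossprod(object@loadings)
  if (max(abs(g - diag(p))) > 1e-8)
    msg <- c(msg, "loadings columns must be orthonormal (tol 1e-8)")
  ev <- object@explainedVariance
  if (is.unsorted(rev(ev)))
    msg <- c(msg, "explainedVariance must be non-increasing")
  if (any(ev < -1e-12))
    msg <- c(msg, "explainedVariance must be non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PCAModel", function(object) {
  ev <- object@explainedVariance
  cat("PCAModel on", length(object@center), "dimensions\n")
  cat(sprintf("  PC1 explains %.1f%% of variance\n", 100 * ev[1] / sum(ev)))
})

#' @rdname fitPCA
#' @export
pcaCenter <- function(model) model@center

#' @rdname fitPCA
#' @export
pcaLoadings <- function(model) model@loadings

#' @rdname fitPCA
#' @export
explainedVariance <- function(model) model@explainedVariance

#' LandscapeModel: fitted landscape (PCA + UMAP)
#'
#' Bundles the PCA model, per-position PC scores, the 2-D UMAP embedding,
#' the UMAP hyper-parameters/seed and the in-memory UMAP transformer used
#' for out-of-sample projection.
#'
#' @slot pca A [PCAModel-class].
#' @slot pcScores N x 20 matrix of PC scores.
#' @slot embedding N x 2 UMAP coordinates.
#' @slot umapParams List with `n_neighbors`, `min_dist`, `seed`.
#' @slot umapModel The `uwot` model object (session-local; rebuild with
#'   [fitLandscape()] or [readReferenceBundle()] after deserialisation).
#' @slot positions Character vector of position keys shared by `pcScores`
#'   and `embedding` rows.
#' @export
setClass("LandscapeModel",
         slots = c(pca = "PCAModel", pcScores = "matrix",
                   embedding = "matrix", umapParams = "list",
                   umapModel = "ANY", positions = "character"))

setValidity("LandscapeModel", function(object) {
  msg <- character(0)
  n <- length(object@positions)
  if (nrow(object@pcScores) != n)
    msg <- c(msg, "pcScores rows must match positions")
  if (nrow(object@embedding) != n || ncol(object@embedding) != 2)
    msg <- c(msg, "embedding must be n x 2 and match positions")
  if (length(msg)) msg else TRUE
})

setMethod("show", "LandscapeModel", function(object) {
  cat("LandscapeModel:", length(object@positions), "positions\n")
  ev <- explainedVariance(object@pca)
  cat(sprintf("  PCA: PC1 %.1f%%, PC2 %.1f%% of variance\n",
              100 * ev[1] / sum(ev), 100 * ev[2] / sum(ev)))
  cat(sprintf("  UMAP: n_neighbors=%d, min_dist=%g, seed=%d\n",
              object@umapParams$n_neighbors, object@umapParams$min_dist,
              object@umapParams$seed))
})

#' @rdname fitLandscape
#' @export
pcScores <- function(model) model@pcScores

#' @rdname fitLandscape
#' @export
umapEmbedding <- function(model) model@embedding

# ---------------------------------------------------------------------------
# ClusteringParams ------------------------------------------------------------

#' ClusteringParams: settings for subtype identification
#'
#' @slot permissiveThreshold Positions with `|ER| <` this value for every
#'   substitution are split off as permissive before clustering (default
#'   0.4).
#' @slot pcRange Integer pair, the inclusive range of principal components
#'   used for clustering (default `c(2L, 20L)`; PC1 is excluded because it
#'   tracks mean ER).
#' @slot deepSplit Named numeric vector (one entry per amino acid, values 0
#'   or 1) controlling dendrogram split sensitivity; default all 0.
#' @slot minClusterSize Minimum subtype size (default 20).
#' @export
setClass("ClusteringParams",
         slots = c(permissiveThreshold = "numeric", pcRange = "integer",
                   deepSplit = "numeric", minClusterSize = "integer"))

#' Construct clustering parameters
#'
#' @param permissiveThreshold Permissive |ER| threshold (> 0).
#' @param pcRange Integer pair `(lo, hi)`, `1 <= lo <= hi <= 20`.
#' @param deepSplit Either a single value (0 or 1) applied to every amino
#'   acid or a named vector keyed by amino acid.
#' @param minClusterSize Positive integer.
#' @return A [ClusteringParams-class].
#' @examples
#' clusteringParams(deepSplit = c(C = 1))
#' @export
clusteringParams <- function(permissiveThreshold = 0.4,
                             pcRange = c(2L, 20L),
                             deepSplit = 0,
                             minClusterSize = 20L) {
  if (permissiveThreshold <= 0) stop("permissiveThreshold must be > 0")
  pcRange <- as.integer(pcRange)
  if (length(pcRange) != 2 || pcRange[1] < 1 || pcRange[1] > pcRange[2] ||
      pcRange[2] > 20)
    stop("pcRange must satisfy 1 <= lo <= hi <= 20")
  ds <- setNames(rep(0, 20), AA_ALPHABET)
  if (!is.null(names(deepSplit))) {
    bad <- setdiff(names(deepSplit), AA_ALPHABET)
    if (length(bad)) stop("unknown amino acids in deepSplit: ",
                          paste(bad, collapse = ", "))
    ds[names(deepSplit)] <- deepSplit
  } else if (length(deepSplit) == 1) {
    ds[] <- deepSplit
  } else stop("deepSplit must be scalar or named by amino acid")
  if (!all(ds %in% c(0, 1)))
    stop("deepSplit values must be 0 or 1")
  minClusterSize <- as.integer(minClusterSize)
  if (minClusterSize < 1L) stop("minClusterSize must be >= 1")
  new("ClusteringParams", permissiveThreshold = permissiveThreshold,
      pcRange = pcRange, deepSplit = ds, minClusterSize = minClusterSize)
}

setMethod("show", "ClusteringParams", function(object) {
  cat("ClusteringParams: permissive |ER| <", object@permissiveThreshold,
      "; PCs", object@pcRange[1], "-", object@pcRange[2],
      "; min cluster size", object@minClusterSize, "\n")
  ds <- object@deepSplit
  if (any(ds != 0))
    cat("  deepSplit = 1 for:", paste(names(ds)[ds == 1], collapse = ""),
        "\n")
})

# ---------------------------------------------------------------------------
# ReferenceBundle -------------------------------------------------------------

#' ReferenceBundle: frozen landscape for projecting new studies
#'
#' Everything needed to map positions of a new, independently normalised DMS
#' study onto a stored reference landscape: the PCA model, UMAP parameters
#' plus transformer, the per-subtype centroids (in the clustering PC range)
#' with outlier radii, the pooled imputation medians and the permissive
#' threshold.
#'
#' @slot pca A [PCAModel-class].
#' @slot umapParams List with `n_neighbors`, `min_dist`, `seed`.
#' @slot umapModel `uwot` transformer (rebuilt deterministically on load).
#' @slot referenceER 20 x N reference ER matrix (needed to rebuild the
#'   transformer and for self-consistency checks).
#' @slot positions Reference position metadata (data.frame).
#' @slot assignments Named character vector of subtype labels per reference
#'   position key.
#' @slot centroids Numbered-subtype centroids in the clustering PC range
#'   (rows named by label).
#' @slot radii Per-subtype outlier radius: the 95th percentile (by default)
#'   of member-to-centroid cosine distance.
#' @slot imputationMedians data.frame `wt_aa`, `mut_aa`, `median` of pooled
#'   substitution-type medians.
#' @slot permissiveThreshold,pcRange As in [ClusteringParams-class].
#' @export
setClass("ReferenceBundle",
         slots = c(pca = "PCAModel", umapParams = "list", umapModel = "ANY",
                   referenceER = "matrix", positions = "data.frame",
                   assignments = "character", centroids = "matrix",
                   radii = "numeric", imputationMedians = "data.frame",
                   permissiveThreshold = "numeric", pcRange = "integer"))

setValidity("ReferenceBundle", function(object) {
  msg <- character(0)
  labs <- rownames(object@centroids)
  if (is.null(labs)) labs <- character(0)
  if (!all(grepl("^[A-Y][0-9]+$", labs)))
    msg <- c(msg, "centroid rows must be numbered subtype labels")
  rn <- names(object@radii)
  if (is.null(rn)) rn <- character(0)
  if (!identical(labs, rn))
    msg <- c(msg, "every numbered subtype needs a centroid and a radius")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ReferenceBundle", function(object) {
  cat("ReferenceBundle:", ncol(object@referenceER), "reference positions,",
      nrow(object@centroids), "numbered subtypes\n")
  cat("  permissive threshold:", object@permissiveThreshold,
      "; clustering PCs", object@pcRange[1], "-", object@pcRange[2], "\n")
})
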