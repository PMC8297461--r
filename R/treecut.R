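# Dynamic Hybrid tree cut: adaptive, shape-based cluster detection on a
# dendrogram followed by nearest-cluster assignment of stragglers.

#' Cosine distance matrix
#'
#' Pairwise cosine distance `1 - u.v / (|u||v|)` between the rows of a
#' matrix; values lie in [0, 2] (2 = antiparallel).  The metric measures the
#' angle between profiles, discarding overall magnitude — which is why
#' near-zero (permissive) profiles must be split off before clustering:
#' their direction is noise and the distance is undefined for an exact zero
#' vector.
#'
#' @param m Numeric matrix, one observation per row.
#' @return A [stats::dist] object.
#' @export
cosineDist <- function(m) {
  m <- as.matrix(m)
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0))
    stop("cosine distance undefined for zero vector(s) at row(s): ",
         paste(which(nrm == 0), collapse = ", "))
  sims <- tcrossprod(m / nrm)
  d <- 1 - sims
  d[d < 0] <- 0          # numerical guard: identical rows
  as.dist(d)
}

# size of the "core" of a branch: the earliest-attaching members used to
# judge how tight the branch is
coreSize <- function(branchSize, minClusterSize) {
  base <- minClusterSize / 2 + 1
  if (base < branchSize) as.integer(base + sqrt(branchSize - base))
  else as.integer(branchSize)
}

#' Hybrid dynamic tree cut
#'
#' Adaptive cluster detection on an average-linkage dendrogram in two
#' stages.  Stage 1 walks the merge tree bottom-up and recognises a branch
#' as a cluster when it (i) has at least `minClusterSize` members, (ii) has
#' a tight core — the mean attachment height of its core members is at most
#' `maxCoreScatter` of the dendrogram height range — and (iii) is separated
#' from its merge partner by a gap of at least `minGap` of the height range.
#' Stage 2 attaches each remaining unlabelled point to the nearest detected
#' cluster (by mean distance to members) when that distance is within the
#' cluster's assignment radius; points beyond every radius stay unassigned
#' (id 0).  `deepSplit` selects the published sensitivity presets:
#' 0 -> (maxCoreScatter 0.64, minGap 0.27), 1 -> (0.73, 0.2025).
#'
#' @param hc An [stats::hclust] object built from `d`.
#' @param d Distance matrix (`dist` or square symmetric matrix) used to
#'   build `hc`.
#' @param deepSplit 0 (conservative) or 1 (more splitting).
#' @param minClusterSize Minimum cluster size (default 20).
#' @param cutHeight Static cut height; defaults to 99% of the maximum merge
#'   height.
#' @return Integer vector of cluster ids, in input-row order; ids >= 1 are
#'   clusters (in no particular order), 0 marks unassigned points.
#' @export
dynamicHybridCut <- function(hc, d, deepSplit = 0, minClusterSize = 20L,
                             cutHeight = NULL) {
  if (!inherits(hc, "hclust")) stop("hc must be an hclust object")
  dm <- as.matrix(d)
  if (nrow(dm) != ncol(dm) || max(abs(dm - t(dm))) > 1e-10)
    stop("distance matrix must be square and symmetric")
  n <- length(hc$order)
  if (nrow(dm) != n) stop("distance matrix does not match the dendrogram")
  if (!deepSplit %in% c(0, 1)) stop("deepSplit must be 0 or 1")
  minClusterSize <- as.integer(minClusterSize)

  heights <- hc$height
  maxH <- max(heights)
  if (is.null(cutHeight)) cutHeight <- 0.99 * maxH
  # a dendrogram whose first merge already exceeds the cut height has no
  # height structure to cut: treat the whole tree as one branch
  if (cutHeight <= heights[1]) cutHeight <- maxH * (1 + 1e-8)

  if (maxH <= 0) {
    # degenerate: all points coincide
    labels <- rep(if (n >= minClusterSize) 1L else 0L, n)
    return(labels)
  }

  preset <- if (deepSplit == 0) c(0.64, 0.27) else c(0.73, 0.2025)
  nMerge <- length(heights)
  refHeight <- heights[max(1L, round(0.05 * nMerge))]
  maxAbsCoreScatter <- refHeight + preset[1] * (cutHeight - refHeight)
  minAbsGap <- preset[2] * (cutHeight - refHeight)

  # --- stage 1: tree-based branch detection -------------------------------
  # branch bookkeeping: members + the height at which each member attached
  branches <- list()
  final <- list()                     # finalised clusters (member vectors)
  branchOf <- integer(n)              # leaf -> active branch id (0 = none)
  mergeBranch <- integer(nMerge)      # merge i -> resulting branch id
  composite <- logical(0)             # branch id -> contains final clusters?
  floaters <- list()                  # per composite branch: loose members

  newBranch <- function(members, attach) {
    branches[[length(branches) + 1]] <<- list(members = members,
                                              attach = attach,
                                              top = max(attach))
    composite[length(branches)] <<- FALSE
    floaters[[length(branches)]] <<- integer(0)
    length(branches)
  }

  # a branch qualifies as a cluster at the height it is merged away when it
  # is big enough, its core is tight, and the merge height stands clear of
  # the core (core-based, so late-attaching stragglers cannot mask a gap)
  qualifies <- function(b, mergeHeight) {
    size <- length(b$members)
    if (size < minClusterSize) return(FALSE)
    cs <- coreSize(size, minClusterSize)
    coreScatter <- mean(sort(b$attach)[seq_len(cs)])
    if (coreScatter > maxAbsCoreScatter) return(FALSE)
    (mergeHeight - coreScatter) >= minAbsGap
  }

  finalize <- function(b) {
    final[[length(final) + 1]] <<- b$members
  }

  sideInfo <- function(idx) {
    # idx < 0: leaf; idx > 0: branch created by merge idx
    if (idx < 0) list(type = "leaf", leaf = -idx)
    else list(type = "branch", id = mergeBranch[idx])
  }

  for (i in seq_len(nMerge)) {
    h <- heights[i]
    a <- sideInfo(hc$merge[i, 1])
    b <- sideInfo(hc$merge[i, 2])

    if (h > cutHeight) {
      # sides stay separate; close out each side
      for (s in list(a, b)) {
        if (s$type == "branch" && s$id > 0L && !composite[s$id]) {
          br <- branches[[s$id]]
          if (length(br$members) >= minClusterSize) {
            cs <- coreSize(length(br$members), minClusterSize)
            core <- sort(br$attach)[seq_len(cs)]
            if (mean(core) <= maxAbsCoreScatter) finalize(br)
          }
          branches[s$id] <- list(NULL)
        }
      }
      mergeBranch[i] <- 0L
      next
    }

    if (a$type == "leaf" && b$type == "leaf") {
      id <- newBranch(c(a$leaf, b$leaf), c(h, h))
      branchOf[c(a$leaf, b$leaf)] <- id
      mergeBranch[i] <- id
      next
    }

    if (xor(a$type == "leaf", b$type == "leaf")) {
      leaf <- if (a$type == "leaf") a$leaf else b$leaf
      id <- if (a$type == "leaf") b$id else a$id
      if (id == 0L) { # partner was closed above cutHeight (cannot happen: heights sorted)
        id <- newBranch(leaf, h)
        branchOf[leaf] <- id
      } else if (composite[id]) {
        floaters[[id]] <- c(floaters[[id]], leaf)
      } else {
        br <- branches[[id]]
        br$members <- c(br$members, leaf)
        br$attach <- c(br$attach, h)
        br$top <- h
        branches[[id]] <- br
        branchOf[leaf] <- id
      }
      mergeBranch[i] <- id
      next
    }

    # branch + branch
    ia <- a$id; ib <- b$id
    if (ia == 0L || ib == 0L) { mergeBranch[i] <- max(ia, ib); next }
    compA <- composite[ia]; compB <- composite[ib]
    if (compA || compB) {
      # absorb into (or create) a composite branch
      for (id in c(ia, ib)) {
        if (!composite[id]) {
          br <- branches[[id]]
          if (qualifies(br, h)) finalize(br)
          else floaters[[if (compA) ia else ib]] <-
              c(floaters[[if (compA) ia else ib]], br$members)
        }
      }
      keep <- if (compA) ia else ib
      other <- if (compA) ib else ia
      if (compA && compB) {
        floaters[[keep]] <- c(floaters[[keep]], floaters[[other]])
      }
      mergeBranch[i] <- keep
      next
    }

    brA <- branches[[ia]]; brB <- branches[[ib]]
    qa <- qualifies(brA, h); qb <- qualifies(brB, h)
    if (qa && qb) {
      finalize(brA); finalize(brB)
      composite[ia] <- TRUE
      branches[[ia]] <- list(members = integer(0), attach = numeric(0),
                             top = h)
      mergeBranch[i] <- ia
    } else {
      # merge into one continuing simple branch (absorb the other side)
      merged <- list(members = c(brA$members, brB$members),
                     attach = c(brA$attach, brB$attach),
                     top = h)
      branches[[ia]] <- merged
      branchOf[brB$members] <- ia
      branches[ib] <- list(NULL)
      mergeBranch[i] <- ia
    }
  }

  # close out whatever is left at the root
  rootId <- mergeBranch[nMerge]
  if (rootId > 0L && !composite[rootId]) {
    br <- branches[[rootId]]
    if (!is.null(br) && length(br$members) >= minClusterSize) {
      cs <- coreSize(length(br$members), minClusterSize)
      core <- sort(br$attach)[seq_len(cs)]
      if (mean(core) <= maxAbsCoreScatter) finalize(br)
    }
  }

  labels <- integer(n)
  for (k in seq_along(final)) labels[final[[k]]] <- k

  # --- stage 2: nearest-cluster assignment of stragglers ------------------
  if (length(final) && any(labels == 0L)) {
    radii <- vapply(final, function(members) {
      if (length(members) < 2) return(0)
      sub <- dm[members, members, drop = FALSE]
      max(rowSums(sub) / (length(members) - 1))
    }, numeric(1))
    un <- which(labels == 0L)
    for (p in un) {
      dmean <- vapply(final, function(members) mean(dm[p, members]),
                      numeric(1))
      k <- which.min(dmean)
      if (dmean[k] <= radii[k]) labels[p] <- k
    }
  }
  labels
}
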