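# Synthetic DMS studies with planted position archetypes: ground truth for
# testing every pipeline stage without external data.

#' Default position archetype library
#'
#' Idealised 20-entry ER templates emulating recurring position classes
#' seen in combined DMS landscapes: fully intolerant positions, positions
#' that only reject proline, positions requiring a chemical class
#' (hydrophobic, small, aromatic, negative, positive) and permissive
#' positions.  Entries are 0 (tolerated) or -1 (deleterious); the
#' synonymous slot is forced to 0 when a template is planted at a concrete
#' wild type.
#'
#' @return Named list of archetypes, each a list with `template` (named
#'   20-vector) and `nonsense` (nonsense ER, -1 except for permissive).
#' @examples
#' names(defaultArchetypes())
#' @export
defaultArchetypes <- function() {
  tmpl <- function(tolerated) {
    v <- setNames(rep(-1, 20), AA_ALPHABET)
    v[tolerated] <- 0
    v
  }
  list(
    permissive = list(template = tmpl(AA_ALPHABET), nonsense = -1),
    intolerant = list(template = tmpl(character(0)), nonsense = -1),
    not_proline = list(template = tmpl(setdiff(AA_ALPHABET, "P")),
                       nonsense = -1),
    hydrophobic = list(template = tmpl(c("A", "C", "F", "I", "L", "M",
                                         "V", "W", "Y")), nonsense = -1),
    small = list(template = tmpl(c("A", "C", "G", "S", "T")),
                 nonsense = -1),
    aromatic = list(template = tmpl(c("F", "H", "W", "Y")), nonsense = -1),
    negative = list(template = tmpl(c("D", "E")), nonsense = -1),
    positive = list(template = tmpl(c("H", "K", "R")), nonsense = -1))
}

# Default per-amino-acid archetype mixtures.  Each wild type gets two
# selective classes with near-disjoint tolerated sets (so their profile
# directions are distinguishable after the mean-ER component is removed), a
# not-proline class and a permissive class.  The fully intolerant class is
# planted only at hydrophobic wild types, where no narrow chemical class
# shadows it; at narrow-class wild types (e.g. D, E) "intolerant" and
# "requires that class" differ in too few coordinates to be distinct
# position types.  Proline swaps not_proline (degenerate at wt P) for a
# second chemical class.
defaultMixtures <- function() {
  menu <- list(
    hydro = c("intolerant", "hydrophobic"),    # A C I L M V
    arom = c("aromatic", "small"),             # F W Y
    pos = c("positive", "hydrophobic"),        # H K R
    neg = c("negative", "hydrophobic"),        # D E
    polar = c("small", "hydrophobic"))         # G N Q S T
  cls <- c(A = "hydro", C = "hydro", I = "hydro", L = "hydro",
           M = "hydro", V = "hydro", F = "arom", W = "arom", Y = "arom",
           H = "pos", K = "pos", R = "pos", D = "neg", E = "neg",
           G = "polar", N = "polar", Q = "polar", S = "polar",
           T = "polar", P = "polar")
  out <- lapply(AA_ALPHABET, function(a) {
    if (a == "P")
      c(small = 0.4, hydrophobic = 0.4, permissive = 0.2)
    else
      setNames(c(0.3, 0.3, 0.2, 0.2),
               c(menu[[cls[[a]]]], "not_proline", "permissive"))
  })
  setNames(out, AA_ALPHABET)
}

#' Specification of a synthetic DMS landscape
#'
#' Defines the study conditions the generator emulates: planted archetype
#' mixtures per wild-type amino acid, per-entry Gaussian noise, replicate
#' structure, multiplicative per-study scale factors (removed by
#' normalisation), missingness, optional multi-mutant sequences and the
#' seed.
#'
#' @param nStudies Number of studies/genes (default 4).
#' @param nPositions Positions per gene (default 500).
#' @param archetypes Archetype library (default [defaultArchetypes()]).
#' @param mixtures Per-amino-acid named weight vectors over archetypes;
#'   each must sum to 1 (default `defaultMixtures()`).
#' @param noiseSd Per-entry Gaussian SD on the true position effect
#'   (default 0.08).
#' @param replicateCount Replicates per study (default 3).
#' @param replicateNoiseSd Additional per-replicate Gaussian SD (default
#'   0.12).
#' @param studyScale Positive multiplicative scale per study; recycled
#'   (default `c(1, 2, 5, 0.5)`).
#' @param missingRate Probability that a substitution is unmeasured
#'   (default 0.02, leaving about 98% of entries measured); rates leaving fewer than 15 of 20 nonsynonymous
#'   entries in expectation trigger a warning.
#' @param multimutant `NULL` (default) or a list with `nSequences`,
#'   `order` (substitutions per sequence) and `epistasisSd`.
#' @param seed Integer seed (default 1).
#' @return A classed list (`syntheticSpec`).
#' @export
syntheticSpec <- function(nStudies = 4L, nPositions = 500L,
                          archetypes = defaultArchetypes(),
                          mixtures = defaultMixtures(),
                          noiseSd = 0.08, replicateCount = 3L,
                          replicateNoiseSd = 0.12,
                          studyScale = c(1, 2, 5, 0.5),
                          missingRate = 0.02, multimutant = NULL,
                          seed = 1L) {
  for (a in names(mixtures)) {
    w <- mixtures[[a]]
    if (abs(sum(w) - 1) > 1e-8)
      stop("archetype weights for amino acid ", a, " must sum to 1")
    bad <- setdiff(names(w), names(archetypes))
    if (length(bad))
      stop("unknown archetype(s) for amino acid ", a, ": ",
           paste(bad, collapse = ", "))
  }
  if (missingRate < 0 || missingRate >= 1)
    stop("missingRate must be in [0, 1)")
  if (20 * (1 - missingRate) < 15)
    warning("missingRate ", missingRate, " leaves fewer than 15 of 20 ",
            "nonsynonymous entries in expectation; most positions will be ",
            "filtered")
  if (any(studyScale <= 0)) stop("studyScale must be positive")
  structure(list(nStudies = as.integer(nStudies),
                 nPositions = as.integer(nPositions),
                 archetypes = archetypes, mixtures = mixtures,
                 noiseSd = noiseSd,
                 replicateCount = as.integer(replicateCount),
                 replicateNoiseSd = replicateNoiseSd,
                 studyScale = rep_len(studyScale, nStudies),
                 missingRate = missingRate, multimutant = multimutant,
                 seed = as.integer(seed)),
            class = "syntheticSpec")
}

#' Generate a synthetic DMS landscape with planted archetypes
#'
#' For each study: draws wild types uniformly, assigns each position an
#' archetype from its amino acid's mixture, then emits raw variant records
#' `scale * (template + position noise + replicate noise)` for every
#' substitution (missense, nonsense and synonymous), deleting substitutions
#' at the missing rate.  The accompanying truth table maps every position
#' to its planted archetype.  Fully reproducible for a fixed spec seed.
#'
#' @param spec A [syntheticSpec()].
#' @return List with `studies` (named list of raw record data.frames in the
#'   ingest dialect), `configs` (named list of [StudyConfig-class], all
#'   identity transforms) and `truth` (data.frame `study`, `gene`,
#'   `position`, `wt_aa`, `archetype`).
#' @export
generateLandscape <- function(spec) {
  stopifnot(inherits(spec, "syntheticSpec"))
  set.seed(spec$seed)
  studies <- list(); configs <- list(); truths <- list()
  for (s in seq_len(spec$nStudies)) {
    studyId <- sprintf("synth%02d", s)
    gene <- sprintf("gene%02d", s)
    scale <- spec$studyScale[s]
    wt <- sample(AA_ALPHABET, spec$nPositions, replace = TRUE)
    arch <- vapply(wt, function(a) {
      w <- spec$mixtures[[a]]
      sample(names(w), 1L, prob = w)
    }, character(1))

    rows <- vector("list", spec$nPositions)
    for (p in seq_len(spec$nPositions)) {
      at <- spec$archetypes[[arch[p]]]
      template <- at$template
      template[wt[p]] <- 0                        # synonymous slot
      targets <- c(AA_ALPHABET, "*")
      mu <- c(template, at$nonsense)
      mu <- mu + rnorm(21, 0, spec$noiseSd)
      mu[match(wt[p], targets)] <- template[wt[p]] +
        rnorm(1, 0, spec$noiseSd / 2)             # synonymous: tight at 0
      keep <- runif(21) >= spec$missingRate
      if (!any(keep)) next
      tok <- ifelse(targets == wt[p], paste0(wt[p], p, "="),
                    paste0(wt[p], p, targets))
      reps <- seq_len(spec$replicateCount)
      idx <- which(keep)
      rows[[p]] <- data.frame(
        study = studyId, gene = gene,
        substitutions = rep(tok[idx], each = spec$replicateCount),
        score = scale * (rep(mu[idx], each = spec$replicateCount) +
                           rnorm(length(idx) * spec$replicateCount, 0,
                                 spec$replicateNoiseSd)),
        replicate = rep(paste0("r", reps), length(idx)),
        condition = "c1", stringsAsFactors = FALSE)
    }
    studies[[studyId]] <- do.call(rbind, rows)
    configs[[studyId]] <- studyConfig(studyId, gene,
                                      transform = "identity")
    truths[[studyId]] <- data.frame(study = studyId, gene = gene,
                                    position = seq_len(spec$nPositions),
                                    wt_aa = wt, archetype = arch,
                                    stringsAsFactors = FALSE)
  }
  list(studies = studies, configs = configs,
       truth = do.call(rbind, c(truths, list(make.row.names = FALSE))))
}

#' Generate multi-mutant sequences with approximately additive effects
#'
#' Samples sequences of `order` distinct single substitutions from a table
#' of single effects; each sequence's score is the sum of its members'
#' effects plus Gaussian epistasis noise.  Used to exercise
#' [collapseMultimutants()] recovery.
#'
#' @param singles data.frame `study`, `gene`, `position`, `wt_aa`,
#'   `mut_aa`, `score` of single-substitution effects.
#' @param nSequences Number of multi-mutant sequences.
#' @param order Substitutions per sequence (default 2).
#' @param epistasisSd Gaussian SD of the epistatic deviation (default 0).
#' @param seed Integer seed.
#' @return data.frame of multi-mutant records in the ingest dialect.
#' @export
generateMultimutants <- function(singles, nSequences, order = 2L,
                                 epistasisSd = 0, seed = 1L) {
  set.seed(seed)
  singles <- as.data.frame(singles)
  n <- nrow(singles)
  if (n < order) stop("not enough single effects to sample from")
  rows <- vector("list", nSequences)
  for (i in seq_len(nSequences)) {
    repeat {
      pick <- sample.int(n, order)
      if (!anyDuplicated(singles$position[pick])) break
    }
    pick <- pick[base::order(singles$position[pick])]
    tok <- paste(ifelse(singles$mut_aa[pick] == singles$wt_aa[pick],
                        paste0(singles$wt_aa[pick], singles$position[pick],
                               "="),
                        paste0(singles$wt_aa[pick], singles$position[pick],
                               singles$mut_aa[pick])),
                 collapse = ";")
    rows[[i]] <- data.frame(study = singles$study[1],
                            gene = singles$gene[1], substitutions = tok,
                            score = sum(singles$score[pick]) +
                              rnorm(1, 0, epistasisSd),
                            replicate = "r1", condition = "c1",
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
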