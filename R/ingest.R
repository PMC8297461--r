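# Study-level standardisation: raw variant scores -> normalised ER profiles.
# Pipeline order is fixed: transform -> average replicates/conditions ->
# collapse multi-mutants -> normalise -> filter positions -> impute.

#' Transform raw study scores onto the common log2-ER scale
#'
#' Applies the study's declared transform so that 0 means
#' wild-type-equivalent, negative deleterious and positive advantageous.
#' All supported transforms are monotone increasing (`negate` relative to a
#' deleteriousness score), so score order within a study is preserved.
#'
#' @param records data.frame of variant records with columns `study`,
#'   `gene`, `substitutions`, `score` and optional `replicate`, `condition`.
#' @param config A [StudyConfig-class].
#' @return The records with `score` replaced by its log2-ER transform.
#' @examples
#' rec <- data.frame(study = "s", gene = "g", substitutions = "A1C",
#'                   score = 0.5)
#' transformScores(rec, studyConfig("s", "g", transform = "log2_ratio"))
#' @export
transformScores <- function(records, config) {
  records <- checkRecordColumns(records)
  s <- records$score
  records$score <- switch(config@transform,
    identity = s,
    log2_ratio = {
      bad <- which(s <= 0)
      if (length(bad))
        stop("log2_ratio transform requires positive ratios; offending ",
             "record(s): ",
             paste(records$substitutions[head(bad, 5)], collapse = ", "))
      log2(s)
    },
    negate = -s,
    affine = config@transformParams[1] * s + config@transformParams[2],
    stop("unknown transform '", config@transform, "'"))
  records
}

checkRecordColumns <- function(records) {
  records <- as.data.frame(records)
  need <- c("study", "gene", "substitutions", "score")
  miss <- setdiff(need, colnames(records))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  if (is.null(records$replicate))
    records$replicate <- rep("", nrow(records))
  if (is.null(records$condition))
    records$condition <- rep("", nrow(records))
  records$replicate[is.na(records$replicate)] <- ""
  records$condition[is.na(records$condition)] <- ""
  records
}

#' Average replicates and comparable conditions
#'
#' Collapses a study's records to one score per (gene, substitution set):
#' the arithmetic mean over replicates and over conditions whose policy is
#' `"average"`.  Conditions marked `"drop"` are excluded; if any condition
#' is marked `"prefer"`, only preferred conditions are kept.  Conditions not
#' named in the policy default to `"average"`.
#'
#' @inheritParams transformScores
#' @return data.frame with one row per (study, gene, substitutions) and the
#'   averaged `score`.
#' @export
averageReplicates <- function(records, config) {
  records <- checkRecordColumns(records)
  pol <- config@conditionPolicy
  conds <- unique(records$condition)
  eff <- setNames(rep("average", length(conds)), conds)
  known <- intersect(conds, names(pol))
  eff[known] <- pol[known]
  keep <- if (any(eff == "prefer")) names(eff)[eff == "prefer"]
          else names(eff)[eff == "average"]
  if (length(keep) == 0)
    stop("condition policy retains zero conditions for study '",
         config@studyId, "'")
  records <- records[records$condition %in% keep, , drop = FALSE]
  agg <- aggregate(score ~ study + gene + substitutions, data = records,
                   FUN = mean)
  agg[order(agg$gene, agg$substitutions), , drop = FALSE]
}

#' Collapse multi-mutant sequences to single-substitution scores
#'
#' Substitutions measured directly as single variants keep their score
#' verbatim.  A substitution only observed inside multi-mutant sequences is
#' scored as the mean over all sequences that contain it and carry at most
#' `cap` substitutions; substitutions seen only in sequences above the cap
#' are absent from the output.
#'
#' @param records Replicate-averaged records (see [averageReplicates()]).
#' @param cap Positive integer: maximum multi-mutant order to average over.
#' @return data.frame with columns `study`, `gene`, `position`, `wt_aa`,
#'   `mut_aa`, `score` — one row per single substitution.
#' @export
collapseMultimutants <- function(records, cap = 3L) {
  cap <- as.integer(cap)
  if (is.na(cap) || cap < 1L) stop("cap must be a positive integer")
  records <- checkRecordColumns(records)
  flat <- parseSubstitutionsFlat(records$substitutions)
  ord <- tabulate(flat$record, nbins = nrow(records))
  flat$study <- records$study[flat$record]
  flat$gene <- records$gene[flat$record]
  flat$score <- records$score[flat$record]
  flat$ord <- ord[flat$record]

  out <- flat[flat$ord == 1L,
              c("study", "gene", "position", "wt_aa", "mut_aa", "score"),
              drop = FALSE]
  dupKey <- paste(out$study, out$gene, out$position, out$mut_aa)
  if (anyDuplicated(dupKey))
    stop("duplicate single-substitution records after averaging")

  multi <- flat[flat$ord > 1L & flat$ord <= cap, , drop = FALSE]
  if (nrow(multi)) {
    multiKey <- paste(multi$study, multi$gene, multi$position,
                      multi$mut_aa)
    multi <- multi[!(multiKey %in% dupKey), , drop = FALSE]
    if (nrow(multi)) {
      agg <- aggregate(score ~ study + gene + position + wt_aa + mut_aa,
                       data = multi, FUN = mean)
      out <- rbind(out, agg[, colnames(out)])
    }
  }
  rownames(out) <- NULL
  out[order(out$gene, out$position, out$mut_aa), , drop = FALSE]
}

#' Normalise a study against its deleterious tail
#'
#' Divides every score by the magnitude of the median of the study's lowest
#' 10% of nonsynonymous scores (the `ceiling(0.1 * n)` smallest values),
#' anchoring complete loss of function at -1 across studies: nonsense
#' mutations and other fully deleterious variants typically populate this
#' tail.  Synonymous scores are excluded from the tail pool but are rescaled
#' along with everything else.  Signs are preserved, and the result is
#' invariant to positive rescaling of the input.
#'
#' @param scores Single-substitution table from [collapseMultimutants()]
#'   (one study).
#' @return The table with an additional `er` column of normalised scores
#'   and `measured = TRUE`.
#' @export
normalizeStudy <- function(scores) {
  scores <- as.data.frame(scores)
  if (length(unique(scores$study)) > 1)
    stop("normalizeStudy expects a single study; got ",
         length(unique(scores$study)))
  pool <- scores$score[scores$mut_aa != "="]
  n <- length(pool)
  if (n < 10)
    stop("study has ", n, " nonsynonymous scores; >= 10 required")
  k <- ceiling(0.1 * n)
  m <- median(sort(pool)[seq_len(k)])
  if (m == 0)
    stop("degenerate study: no deleterious tail (bottom-decile median is 0)")
  scores$er <- scores$score / abs(m)
  scores$measured <- TRUE
  scores
}

#' Drop positions with sparse coverage
#'
#' Retains exactly the positions with measurements for at least 15 of the 20
#' nonsynonymous substitutions (19 missense + nonsense); synonymous
#' measurements do not count towards the 20.  Scores are never altered.
#'
#' @param table Normalised study table(s) with columns `study`, `gene`,
#'   `position`, `wt_aa`, `mut_aa`, `er`, `measured`.
#' @param minMeasured Minimum nonsynonymous measurements (default 15).
#' @return The table restricted to retained positions.
#' @export
filterPositions <- function(table, minMeasured = 15L) {
  table <- as.data.frame(table)
  if (nrow(table) == 0) return(table)
  nonsyn <- table[table$mut_aa != "=" & table$measured, , drop = FALSE]
  key <- paste(nonsyn$study, nonsyn$gene, nonsyn$position, sep = ":")
  counts <- table(key)
  keepKeys <- names(counts)[counts >= minMeasured]
  allKey <- paste(table$study, table$gene, table$position, sep = ":")
  out <- table[allKey %in% keepKeys, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pooled substitution-type medians
#'
#' Median normalised ER of each measured substitution type
#' (wild type -> target, including nonsense) pooled across all supplied
#' tables; the imputation reference.
#'
#' @param table Combined normalised table.
#' @return data.frame `wt_aa`, `mut_aa`, `median`.
#' @export
substitutionTypeMedians <- function(table) {
  table <- as.data.frame(table)
  nonsyn <- table[table$mut_aa != "=" & table$measured, , drop = FALSE]
  agg <- aggregate(er ~ wt_aa + mut_aa, data = nonsyn, FUN = median)
  names(agg)[names(agg) == "er"] <- "median"
  agg
}

#' Impute missing entries and assemble complete mutational profiles
#'
#' Fills each missing missense or nonsense entry with the median normalised
#' score of that substitution type (e.g. A->C) pooled across all studies,
#' and each missing synonymous entry with 0, then assembles one complete
#' 20-entry profile per position.  The imputation mask records exactly the
#' filled entries.
#'
#' @param tables A normalised, filtered table or list of tables (rows
#'   `study`, `gene`, `position`, `wt_aa`, `mut_aa`, `er`, `measured`).
#' @param medians Optional precomputed [substitutionTypeMedians()] table;
#'   when projecting a new study onto a reference landscape, pass the
#'   bundle's stored medians so imputation matches the reference.
#' @return A [MutationalLandscape-class].
#' @export
imputeMissing <- function(tables, medians = NULL) {
  if (is.data.frame(tables)) tables <- list(tables)
  combined <- do.call(rbind, lapply(tables, as.data.frame))
  if (nrow(combined) == 0) stop("no rows to impute")
  if (is(medians, "ReferenceBundle")) medians <- medians@imputationMedians
  if (is.null(medians)) medians <- substitutionTypeMedians(combined)
  medKey <- paste(medians$wt_aa, medians$mut_aa)
  medVal <- setNames(medians$median, medKey)

  combined$mut_eff <- ifelse(combined$mut_aa == "=", combined$wt_aa,
                             combined$mut_aa)
  key <- paste(combined$study, combined$gene, combined$position, sep = ":")
  split_idx <- split(seq_len(nrow(combined)), key)
  # preserve first-appearance order of positions
  split_idx <- split_idx[unique(key)]

  n <- length(split_idx)
  er <- matrix(NA_real_, 20, n, dimnames = list(AA_ALPHABET, NULL))
  imputed <- matrix(FALSE, 20, n)
  pd <- data.frame(study = character(n), gene = character(n),
                   position = integer(n), wt_aa = character(n),
                   nonsense_er = NA_real_, nonsense_imputed = FALSE,
                   n_nonsyn_measured = 0L, stringsAsFactors = FALSE)
  missingTypes <- character(0)

  for (j in seq_len(n)) {
    rows <- combined[split_idx[[j]], , drop = FALSE]
    wt <- rows$wt_aa[1]
    pd$study[j] <- rows$study[1]; pd$gene[j] <- rows$gene[1]
    pd$position[j] <- rows$position[1]; pd$wt_aa[j] <- wt

    ms <- rows[rows$mut_eff %in% AA_ALPHABET & rows$measured, , drop = FALSE]
    er[ms$mut_eff, j] <- ms$er
    nmis <- sum(ms$mut_eff != wt)

    non <- rows[rows$mut_aa == "*" & rows$measured, , drop = FALSE]
    if (nrow(non)) {
      pd$nonsense_er[j] <- non$er[1]
    } else {
      mk <- paste(wt, "*")
      if (is.na(medVal[mk])) {
        missingTypes <- c(missingTypes, mk)
      } else {
        pd$nonsense_er[j] <- medVal[[mk]]
        pd$nonsense_imputed[j] <- TRUE
      }
    }
    pd$n_nonsyn_measured[j] <- nmis + as.integer(nrow(non) > 0)

    gaps <- AA_ALPHABET[is.na(er[, j])]
    for (a in gaps) {
      if (a == wt) {
        er[a, j] <- 0               # synonymous imputed to 0
      } else {
        mk <- paste(wt, a)
        if (is.na(medVal[mk])) {
          missingTypes <- c(missingTypes, mk)
          next
        }
        er[a, j] <- medVal[[mk]]
      }
      imputed[match(a, AA_ALPHABET), j] <- TRUE
    }
  }
  if (length(missingTypes))
    stop("no measured instances anywhere for substitution type(s): ",
         paste(unique(sub(" ", "->", missingTypes)), collapse = ", "))
  MutationalLandscape(er, imputed, pd)
}

#' Run the per-study standardisation pipeline
#'
#' Convenience wrapper applying, in order: [transformScores()],
#' [averageReplicates()], [collapseMultimutants()] (with the config's cap)
#' and [normalizeStudy()].
#'
#' @inheritParams transformScores
#' @return Normalised single-substitution table for the study.
#' @export
processStudy <- function(records, config) {
  records <- transformScores(records, config)
  records <- averageReplicates(records, config)
  singles <- collapseMultimutants(records, cap = config@multimutantCap)
  validateWildTypes(singles, config)
  normalizeStudy(singles)
}

validateWildTypes <- function(singles, config) {
  wtmap <- config@wtAAMap
  if (length(wtmap) == 0) return(invisible(TRUE))
  pos <- as.character(singles$position)
  known <- pos %in% names(wtmap)
  bad <- known & singles$wt_aa != wtmap[pos]
  if (any(bad))
    warning("wild-type mismatch with declared map at position(s) ",
            paste(unique(singles$position[bad]), collapse = ", "),
            " in study '", config@studyId, "'; keeping study's declaration")
  invisible(TRUE)
}

#' Combine normalised studies into a complete landscape
#'
#' Binds normalised per-study tables, applies the coverage filter and
#' imputes remaining gaps.  The same (gene, position) assayed by several
#' studies yields several independent profiles keyed by study.
#'
#' @param tables List of normalised study tables (or one combined table).
#' @param minMeasured Coverage threshold passed to [filterPositions()].
#' @return A [MutationalLandscape-class].
#' @export
buildLandscape <- function(tables, minMeasured = 15L) {
  if (is.data.frame(tables)) tables <- list(tables)
  combined <- do.call(rbind, lapply(tables, as.data.frame))
  warnWildTypeConflicts(combined)
  filtered <- filterPositions(combined, minMeasured)
  if (nrow(filtered) == 0) stop("no positions pass the coverage filter")
  imputeMissing(filtered)
}

warnWildTypeConflicts <- function(combined) {
  key <- paste(combined$gene, combined$position, sep = ":")
  wt <- tapply(combined$wt_aa, key, function(x) length(unique(x)))
  conf <- names(wt)[wt > 1]
  if (length(conf))
    warning("studies disagree on the wild type at ",
            length(conf), " gene position(s) (e.g. ", conf[1],
            "); keeping each study's declaration")
  invisible(TRUE)
}
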