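# File dialects: per-study CSV/TSV variant tables, YAML study configs,
# combined TSV output, JSON run manifests.  Coordinates are 1-based protein
# residue numbering; nonsense is '*', synonymous '='.

#' Read a per-study variant score table
#'
#' CSV or TSV (by extension) with required columns `study`, `gene`,
#' `substitutions`, `score` and optional `replicate`, `condition`.
#' Substitution tokens may be compact or HGVS protein strings, semicolon
#' joined for multi-mutant sequences; they are validated on read.
#'
#' @param path File path.
#' @return data.frame of variant records.
#' @export
readStudyCsv <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE)
  need <- c("study", "gene", "substitutions", "score")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("file '", path, "' is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(df)) {
    flat <- tryCatch(parseSubstitutionsFlat(df$substitutions),
                     error = function(e)
                       stop("in file '", path, "': ", conditionMessage(e),
                            call. = FALSE))
    # normalise every token to the compact dialect
    tok <- formatSubstitution(flat$position, flat$wt_aa, flat$mut_aa)
    df$substitutions <- vapply(split(tok, flat$record), paste,
                               character(1), collapse = ";")
  }
  checkRecordColumns(df)
}

#' Read a study configuration from YAML
#'
#' One YAML document per study with keys `study`, `gene`, `transform`,
#' `transform_params`, `condition_policy`, `multimutant_cap`, `wt_aa_map`
#' and `include`; unknown keys are an error (strict schema).
#'
#' @param path YAML file path.
#' @return A [StudyConfig-class].  Studies with `include: false` return
#'   `NULL`.
#' @export
readStudyConfig <- function(path) {
  y <- yaml::read_yaml(path)
  allowed <- c("study", "gene", "transform", "transform_params",
               "condition_policy", "multimutant_cap", "wt_aa_map",
               "include")
  bad <- setdiff(names(y), allowed)
  if (length(bad))
    stop("unknown key(s) in config '", path, "': ",
         paste(bad, collapse = ", "))
  if (is.null(y$study)) stop("config '", path, "' must name a study")
  if (isFALSE(y$include)) return(NULL)
  studyConfig(
    studyId = y$study,
    gene = if (is.null(y$gene)) NA_character_ else y$gene,
    transform = if (is.null(y$transform)) "identity" else y$transform,
    transformParams = if (is.null(y$transform_params)) c(1, 0)
                      else as.numeric(y$transform_params),
    conditionPolicy = if (is.null(y$condition_policy)) character(0)
                      else unlist(y$condition_policy),
    multimutantCap = if (is.null(y$multimutant_cap)) 3L
                     else y$multimutant_cap,
    wtAAMap = if (is.null(y$wt_aa_map)) character(0)
              else unlist(lapply(y$wt_aa_map, as.character)))
}

# internal TSV writer/reader: floats keep >= 15 significant digits so that
# write-then-read is the identity on doubles
writeTsv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]]))
      out[[j]] <- formatC(out[[j]], digits = 17, format = "g")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Write / read a combined normalised table
#'
#' TSV with one row per (study, gene, position, mut_aa); floating values
#' are serialised with full precision so the round trip is exact.
#'
#' @param table Combined normalised table (columns `study`, `gene`,
#'   `position`, `wt_aa`, `mut_aa`, `er`, `measured`).
#' @param path File path.
#' @return `writeCombinedTsv` returns the path invisibly;
#'   `readCombinedTsv` the table.
#' @export
writeCombinedTsv <- function(table, path) {
  need <- c("study", "gene", "position", "wt_aa", "mut_aa", "er",
            "measured")
  miss <- setdiff(need, colnames(table))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  writeTsv(as.data.frame(table)[, need], path)
}

#' @rdname writeCombinedTsv
#' @export
readCombinedTsv <- function(path) {
  df <- readTsv(path)
  need <- c("study", "gene", "position", "wt_aa", "mut_aa", "er",
            "measured")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("file '", path, "' is missing required column(s): ",
         paste(miss, collapse = ", "))
  df$measured <- as.logical(df$measured)
  df
}

#' Write a run manifest
#'
#' JSON record of a pipeline run: the command, input-file MD5 hashes, the
#' seed(s), the package version and a timestamp.  Every command-line run
#' emits exactly one manifest, making outputs attributable and
#' reproducible.
#'
#' @param command Character; the (sub)command executed.
#' @param inputs Character vector of input file paths (hashed).
#' @param seed Integer seed(s) used.
#' @param path Output JSON path.
#' @return The manifest list, invisibly.
#' @export
writeRunManifest <- function(command, inputs, seed, path) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(command = command, input_md5 = hashes, seed = seed,
                   package = "dmslandscape",
                   version = as.character(packageVersion("dmslandscape")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Export a fitted landscape as TSV
#'
#' One row per position: key columns, mean ER, PC1..PC20 scores and the
#' two UMAP coordinates.
#'
#' @param x A [MutationalLandscape-class].
#' @param model The matching [LandscapeModel-class].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
writeLandscapeTsv <- function(x, model, path) {
  pd <- positionData(x)
  df <- data.frame(key = colnames(erMatrix(x)),
                   pd[, c("study", "gene", "position", "wt_aa")],
                   mean_er = meanER(x), pcScores(model),
                   umapEmbedding(model), check.names = FALSE)
  writeTsv(df, path)
}
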