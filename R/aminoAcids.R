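#' Canonical amino-acid alphabet
#'
#' The 20 standard amino acids in the single-letter alphabetical order used
#' throughout the package for profile vectors and matrix rows.
#'
#' @return Character vector of length 20.
#' @examples
#' aminoAcids()
#' @export
aminoAcids <- function() AA_ALPHABET

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# three-letter -> one-letter map for HGVS protein tokens
AA_THREE <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
              Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
              Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
              Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V",
              Ter = "*")

#' Parse a protein substitution token
#'
#' Accepts the compact dialect (`"A123C"`, `"Q45*"`, `"K9="`) and HGVS
#' protein notation (`"p.Ala123Cys"`, `"p.Gln45Ter"`, `"p.Lys9="`) and
#' normalises both to a canonical 1-based tuple.  Nonsense is `"*"` and a
#' synonymous substitution is `"="`.
#'
#' @param token Character vector of substitution tokens.
#' @return A data.frame with columns `position` (integer), `wt_aa` and
#'   `mut_aa` (single-letter codes, `"*"` for nonsense, `"="` for
#'   synonymous), one row per token.
#' @examples
#' parseSubstitutionToken(c("A123C", "p.Gln45Ter", "K9="))
#' @export
parseSubstitutionToken <- function(token) {
  token <- as.character(token)
  n <- length(token)
  pos <- integer(n); wt <- character(n); mut <- character(n)
  compact <- "^([A-Z])([0-9]+)([A-Z*=])$"
  hgvs <- "^p\\.([A-Z][a-z]{2})([0-9]+)([A-Z][a-z]{2}|=)$"
  isC <- grepl(compact, token)
  isH <- !isC & grepl(hgvs, token)
  bad <- which(!(isC | isH))
  if (length(bad))
    stop("malformed substitution token '", token[bad[1]], "'")
  if (any(isC)) {
    wt[isC] <- sub(compact, "\\1", token[isC])
    pos[isC] <- as.integer(sub(compact, "\\2", token[isC]))
    mut[isC] <- sub(compact, "\\3", token[isC])
  }
  if (any(isH)) {
    wt3 <- sub(hgvs, "\\1", token[isH])
    mut3 <- sub(hgvs, "\\3", token[isH])
    badAA <- !(wt3 %in% names(AA_THREE)) |
      !(mut3 %in% c(names(AA_THREE), "="))
    if (any(badAA))
      stop("malformed substitution token '", token[isH][badAA][1],
           "': unknown amino acid code")
    wt[isH] <- AA_THREE[wt3]
    pos[isH] <- as.integer(sub(hgvs, "\\2", token[isH]))
    mut[isH] <- ifelse(mut3 == "=", "=", AA_THREE[mut3])
  }
  bad <- which(!wt %in% AA_ALPHABET)
  if (length(bad))
    stop("malformed substitution token '", token[bad[1]],
         "': invalid wild-type amino acid '", wt[bad[1]], "'")
  bad <- which(!mut %in% c(AA_ALPHABET, "*", "="))
  if (length(bad))
    stop("malformed substitution token '", token[bad[1]],
         "': invalid target amino acid '", mut[bad[1]], "'")
  bad <- which(pos < 1L)
  if (length(bad))
    stop("malformed substitution token '", token[bad[1]],
         "': position must be >= 1")
  bad <- which(mut == wt)
  if (length(bad))
    stop("malformed substitution token '", token[bad[1]],
         "': wild type equals target; use '", wt[bad[1]], pos[bad[1]],
         "=' for synonymous")
  data.frame(position = pos, wt_aa = wt, mut_aa = mut,
             stringsAsFactors = FALSE)
}

#' Parse a semicolon-joined substitution list
#'
#' @param x Character vector; each element joins one or more substitution
#'   tokens with `";"` (a multi-mutant sequence).
#' @return A list of data.frames as returned by [parseSubstitutionToken()].
#' @keywords internal
parseSubstitutions <- function(x) {
  flat <- parseSubstitutionsFlat(x)
  unname(lapply(split(seq_len(nrow(flat)), flat$record),
                function(i) flat[i, c("position", "wt_aa", "mut_aa")]))
}

# flat variant: one row per token with the originating record index
parseSubstitutionsFlat <- function(x) {
  parts <- strsplit(as.character(x), ";", fixed = TRUE)
  flat <- parseSubstitutionToken(unlist(parts, use.names = FALSE))
  flat$record <- rep(seq_along(x), lengths(parts))
  flat
}

# canonical compact token(s) for parsed substitutions
formatSubstitution <- function(position, wt_aa, mut_aa) {
  ifelse(mut_aa == "=", paste0(wt_aa, position, "="),
         paste0(wt_aa, position, mut_aa))
}
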