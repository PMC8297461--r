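test_that("score transforms land on the log2-ER scale", {
  rec <- data.frame(study = "s", gene = "g",
                    substitutions = c("A1C", "A2C", "A3C"),
                    score = c(1.0, 0.5, 2.0), stringsAsFactors = FALSE)
  out <- transformScores(rec, studyConfig("s", "g",
                                          transform = "log2_ratio"))
  expect_equal(out$score, c(0, -1, 1))

  idcfg <- studyConfig("s", "g", transform = "identity")
  expect_equal(transformScores(rec, idcfg)$score, rec$score)

  neg <- transformScores(rec, studyConfig("s", "g", transform = "negate"))
  expect_equal(neg$score, -rec$score)

  aff <- transformScores(rec, studyConfig("s", "g", transform = "affine",
                                          transformParams = c(2, 1)))
  expect_equal(aff$score, 2 * rec$score + 1)

  rec$score[2] <- -0.5
  expect_error(transformScores(rec, studyConfig("s", "g",
                                                transform = "log2_ratio")),
               "A2C")
})

test_that("replicates and conditions average according to policy", {
  cfg <- studyConfig("s1", "g1")
  out <- averageReplicates(tinyRecords(), cfg)
  expect_equal(out$score[out$substitutions == "A1C"], -1.5)
  expect_equal(out$score[out$substitutions == "A1D"], -0.7)

  rec <- data.frame(study = "s", gene = "g", substitutions = "A1C",
                    score = c(-1, 5), replicate = "r1",
                    condition = c("c1", "c2"), stringsAsFactors = FALSE)
  dropped <- averageReplicates(rec, studyConfig("s", "g",
    conditionPolicy = c(c1 = "average", c2 = "drop")))
  expect_equal(dropped$score, -1)

  preferred <- averageReplicates(rec, studyConfig("s", "g",
    conditionPolicy = c(c2 = "prefer")))
  expect_equal(preferred$score, 5)

  expect_error(averageReplicates(rec, studyConfig("s", "g",
    conditionPolicy = c(c1 = "drop", c2 = "drop"))), "zero conditions")
})

test_that("multi-mutant collapse keeps direct scores and averages the rest", {
  rec <- data.frame(
    study = "s", gene = "g",
    substitutions = c("A1C;D2E", "A1C;F3G", "D2E", "F3G"),
    score = c(-1.0, -0.4, -0.2, -0.1), stringsAsFactors = FALSE)
  out <- collapseMultimutants(rec, cap = 2L)
  expect_equal(out$score[out$position == 1], -0.7)     # mean(-1, -0.4)
  expect_equal(out$score[out$position == 2], -0.2)     # direct wins
  expect_equal(out$score[out$position == 3], -0.1)

  # direct measurement wins over multi-mutant evidence
  rec2 <- rbind(rec, data.frame(study = "s", gene = "g",
                                substitutions = "A1C", score = -0.3))
  out2 <- collapseMultimutants(rec2, cap = 2L)
  expect_equal(out2$score[out2$position == 1], -0.3)

  # substitutions only seen above the cap are absent
  rec3 <- data.frame(study = "s", gene = "g",
                     substitutions = c("A1C;D2E;F3G", "D2E", "F3G"),
                     score = c(-2, -0.2, -0.1), stringsAsFactors = FALSE)
  out3 <- collapseMultimutants(rec3, cap = 2L)
  expect_false(1 %in% out3$position)
  expect_error(collapseMultimutants(rec, cap = 0L), "positive")
})

test_that("normalisation anchors the bottom-decile median at -1", {
  # 20 scores whose two smallest are -10 and -9: divisor |median| = 9.5
  scores <- data.frame(study = "s", gene = "g", position = 1:20,
                       wt_aa = "A", mut_aa = "C",
                       score = c(-10, -9, seq(-2, 2, length.out = 18)),
                       stringsAsFactors = FALSE)
  out <- normalizeStudy(scores)
  expect_equal(out$er, scores$score / 9.5)
  expect_equal(out$er[1], -10 / 9.5)

  allneg <- scores
  allneg$score <- rep(-1, 20)
  expect_equal(normalizeStudy(allneg)$er, rep(-1, 20))

  # positive rescaling leaves the output unchanged
  scaled <- scores
  scaled$score <- scores$score * 7.3
  expect_equal(normalizeStudy(scaled)$er, out$er)

  degen <- scores
  degen$score <- abs(degen$score)
  degen$score[1:2] <- 0
  expect_error(normalizeStudy(degen), "no deleterious tail")
  expect_error(normalizeStudy(scores[1:5, ]), ">= 10 required")
})

test_that("synonymous scores are rescaled but stay out of the tail pool", {
  scores <- data.frame(study = "s", gene = "g",
                       position = c(1:10, 1),
                       wt_aa = "A",
                       mut_aa = c(rep("C", 10), "="),
                       score = c(-2, -2, seq(-1, 1, length.out = 8), -50),
                       stringsAsFactors = FALSE)
  out <- normalizeStudy(scores)
  # ceil(0.1 * 10) = 1 smallest nonsynonymous score is -2, so the divisor
  # is 2, not 50
  expect_equal(out$er[1], -1)
  expect_equal(out$er[11], -25)
})

test_that("the coverage filter keeps >= 15 nonsynonymous measurements", {
  mkpos <- function(pos, n) {
    muts <- c(setdiff(aminoAcids(), "A")[seq_len(min(n, 19))],
              if (n >= 20) "*")
    data.frame(study = "s", gene = "g", position = pos, wt_aa = "A",
               mut_aa = muts, er = -1, measured = TRUE,
               stringsAsFactors = FALSE)
  }
  tab <- rbind(mkpos(1, 14), mkpos(2, 15), mkpos(3, 20),
               # synonymous rows never count towards the 20
               data.frame(study = "s", gene = "g", position = 1,
                          wt_aa = "A", mut_aa = "=", er = 0,
                          measured = TRUE, stringsAsFactors = FALSE))
  out <- filterPositions(tab)
  expect_setequal(unique(out$position), c(2, 3))
  # scores are never altered
  expect_equal(out$er, tab$er[tab$position %in% c(2, 3)])
  expect_equal(nrow(filterPositions(tab[0, ])), 0)
})

test_that("imputation fills gaps with pooled substitution-type medians", {
  full <- function(pos, wt = "A", skip = character(0), erAC = -1) {
    muts <- setdiff(c(aminoAcids(), "*"), c(wt, skip))
    er <- rep(-0.2, length(muts))
    er[muts == "C"] <- erAC
    data.frame(study = "s", gene = "g", position = pos, wt_aa = wt,
               mut_aa = muts, er = er, measured = TRUE,
               stringsAsFactors = FALSE)
  }
  tab <- rbind(full(1, erAC = -1.0), full(2, erAC = -0.5),
               full(3, erAC = 0.1), full(4, skip = c("C", "D", "E", "F")))
  x <- imputeMissing(tab)
  er <- erMatrix(x)
  mask <- imputedMask(x)
  expect_equal(er["C", 4], -0.5)         # median of -1, -0.5, 0.1
  expect_equal(er["D", 4], -0.2)
  expect_true(all(mask[c("C", "D", "E", "F"), 4]))
  # missing synonymous entries become 0 and are masked
  expect_equal(er["A", 4], 0)
  expect_true(mask["A", 4])
  # fully measured positions (bar synonymous) keep their values unmasked
  expect_equal(er["C", 1], -1.0)
  expect_false(any(mask[setdiff(aminoAcids(), "A"), 1]))
  expect_true(all(is.finite(er)))
  # measured nonsynonymous count: positions 1-3 have 19 missense + nonsense
  expect_equal(positionData(x)$n_nonsyn_measured, c(20, 20, 20, 16))

  # a type never measured anywhere is an error naming the type
  lonely <- full(1, wt = "W", skip = "C")[1:10, ]
  expect_error(imputeMissing(lonely), "W->C")
})

test_that("the pipeline normalises before filtering", {
  # the sparse position carries the deleterious tail; under the stated
  # order it sets the divisor even though it is later filtered out
  dense <- data.frame(study = "s", gene = "g", position = 1,
                      wt_aa = "A",
                      mut_aa = setdiff(c(aminoAcids(), "*"), "A"),
                      score = seq(-1, 0.9, length.out = 20),
                      stringsAsFactors = FALSE)
  sparse <- data.frame(study = "s", gene = "g", position = 2,
                       wt_aa = "A", mut_aa = c("C", "D"),
                       score = c(-40, -40), stringsAsFactors = FALSE)
  study <- rbind(dense, sparse)
  normalised <- normalizeStudy(study)      # divisor from bottom 10% = |-40|
  filtered <- filterPositions(normalised)
  expect_setequal(unique(filtered$position), 1)
  expect_equal(filtered$er, dense$score / 40)
  # the reversed order would normalise by 1 instead - a different table
  wrongOrder <- normalizeStudy(filterPositions(
    transform(study, er = score, measured = TRUE)))
  expect_false(isTRUE(all.equal(filtered$er, wrongOrder$er)))
})

test_that("wild-type disagreements between studies warn but keep both", {
  t1 <- data.frame(study = "s1", gene = "g", position = 1, wt_aa = "A",
                   mut_aa = setdiff(c(aminoAcids(), "*"), "A"), er = -1,
                   measured = TRUE, stringsAsFactors = FALSE)
  t2 <- t1
  t2$study <- "s2"
  t2$wt_aa <- "C"
  t2$mut_aa <- setdiff(c(aminoAcids(), "*"), "C")
  expect_warning(x <- buildLandscape(list(t1, t2)), "disagree")
  expect_equal(ncol(x), 2)
  expect_setequal(positionData(x)$wt_aa, c("A", "C"))
})
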