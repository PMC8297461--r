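test_that("the permissive split is strict and exhaustive", {
  er <- matrix(0, 20, 3, dimnames = list(aminoAcids(), NULL))
  er[, 1] <- c(rep(0.39, 10), rep(-0.39, 10))   # all below threshold
  er["C", 2] <- -0.4                             # exactly at: clusterable
  x <- MutationalLandscape(er, positionData = data.frame(
    study = "s", gene = "g", position = 1:3, wt_aa = "A"))
  perm <- splitPermissive(x, 0.4)
  expect_equal(perm, c(TRUE, FALSE, TRUE), ignore_attr = TRUE)
})

test_that("subtype labels renumber clusters by size with stable ties", {
  ids <- c(rep(2L, 5), rep(7L, 8), 0L, 0L)
  labels <- labelSubtypes(ids, "C")
  expect_equal(labels[ids == 7L], rep("C1", 8))   # largest first
  expect_equal(labels[ids == 2L], rep("C2", 5))
  expect_equal(labels[ids == 0L], rep("CO", 2))

  # equal sizes: the tighter cluster takes the lower number
  set.seed(2)
  tight <- matrix(rep(c(1, 0, 0), each = 10), 10) +
    matrix(rnorm(30, 0, 0.01), 10)
  loose <- matrix(rep(c(0, 1, 0), each = 10), 10) +
    matrix(rnorm(30, 0, 0.3), 10)
  pcs <- rbind(tight, loose)
  ids2 <- rep(c(1L, 2L), each = 10)
  labels2 <- labelSubtypes(ids2, "A", pcs)
  expect_equal(unique(labels2[1:10]), "A1")
  expect_equal(unique(labels2[11:20]), "A2")
  # swapping the raw ids does not change the outcome
  labels3 <- labelSubtypes(c(rep(2L, 10), rep(1L, 10)), "A", pcs)
  expect_equal(labels3, labels2)
})

test_that("assignments partition all positions with lawful labels", {
  run <- fullSyntheticRun()
  asg <- run$assignments
  expect_equal(nrow(asg), ncol(run$x))
  expect_true(all(grepl("^[A-Y](P|O|[1-9][0-9]*)$", asg$label)))
  expect_equal(substr(asg$label, 1, 1), asg$wt_aa)
  # per amino acid: |P| + |O| + sum |Xi| equals the total
  for (a in unique(asg$wt_aa)) {
    sub <- asg$label[asg$wt_aa == a]
    expect_equal(sum(grepl("P$", sub)) + sum(grepl("O$", sub)) +
                   sum(grepl("[0-9]$", sub)), length(sub))
  }
  # permissive positions never enter the distance matrix
  perm <- splitPermissive(run$x)
  expect_true(all(grepl("P$", asg$label[perm])))
  expect_true(!any(grepl("P$", asg$label[!perm])))
})

test_that("subtype sizes are non-increasing in their index", {
  run <- fullSyntheticRun()
  prof <- subtypeProfiles(run$assignments, run$x)
  numbered <- prof[grepl("^[A-Y][0-9]+$", prof$label), ]
  for (a in unique(numbered$wt_aa)) {
    sizes <- numbered$size[numbered$wt_aa == a]
    idx <- as.integer(sub("^[A-Y]", "", numbered$label[numbered$wt_aa == a]))
    expect_false(is.unsorted(rev(sizes[order(idx)])))
  }
  # frequencies over one amino acid sum to 1
  freqSum <- tapply(prof$frequency, prof$wt_aa, sum)
  expect_equal(as.vector(freqSum), rep(1, length(freqSum)),
               tolerance = 1e-12)
})

test_that("subtype mean profiles average their members", {
  er <- matrix(0, 20, 3, dimnames = list(aminoAcids(), NULL))
  er[, 2] <- -1
  er[, 3] <- -1
  x <- MutationalLandscape(er, positionData = data.frame(
    study = "s", gene = "g", position = 1:3, wt_aa = "A"))
  asg <- data.frame(study = "s", gene = "g", position = 1:3, wt_aa = "A",
                    label = c("A1", "A1", "A2"), stringsAsFactors = FALSE)
  prof <- subtypeProfiles(asg, x)
  expect_equal(unlist(prof[prof$label == "A1",
                           paste0("mean_", aminoAcids())]),
               setNames(rep(-0.5, 20), paste0("mean_", aminoAcids())))
  expect_equal(prof$size, c(2L, 1L))
  expect_equal(prof$frequency, c(2 / 3, 1 / 3))
})

test_that("subtype correlation matches the direct formula", {
  base <- seq(-1, 0.9, length.out = 20)
  profs <- data.frame(label = c("A1", "A2", "C1"), wt_aa = c("A", "A", "C"),
                      size = c(3L, 2L, 4L), frequency = c(0.6, 0.4, 1),
                      mean_ER = 0)
  m <- rbind(base, -base, base + rnorm(20, 0, 0.1))
  colnames(m) <- paste0("mean_", aminoAcids())
  profs <- cbind(profs[, 1:5], m)
  out <- correlateSubtypes(profs)
  expect_equal(out$correlation["A1", "A2"], -1)
  expect_equal(out$correlation["A1", "C1"], cor(base, m[3, ]),
               ignore_attr = TRUE)
  expect_setequal(out$order, profs$label)

  flat <- profs
  flat[1, paste0("mean_", aminoAcids())] <- 0
  expect_error(correlateSubtypes(flat), "A1")
})

test_that("the most selective subtype is the lowest-mean one by default", {
  profs <- data.frame(label = c("A1", "A2", "C1", "DP"),
                      wt_aa = c("A", "A", "C", "D"),
                      size = c(5L, 5L, 5L, 5L), frequency = 1,
                      mean_ER = c(-0.2, -0.9, -0.5, 0))
  expect_equal(mostSelectiveSubtype(profs)[["A"]], "A2")
  expect_equal(mostSelectiveSubtype(profs)[["C"]], "C1")
  expect_true(is.na(mostSelectiveSubtype(profs)[["D"]]))
  expect_equal(mostSelectiveSubtype(profs,
                                    direction = "highest")[["A"]], "A1")
})

test_that("clustering warns and marks outliers when too few positions", {
  expect_warning(ids <- clusterAminoAcid(matrix(1, 1, 19)), "fewer than 2")
  expect_equal(ids, 0L)
})
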