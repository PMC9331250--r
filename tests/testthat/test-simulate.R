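test_that("the default design produces the expected shapes and metadata", {
  st <- simulateStudy(nSource = 5, nTarget = 4, nBackground = 6,
                      edgesPerTarget = 1, seed = 1)
  # 4 timepoints x (6 chow + 15 HFD) samples per tissue
  expect_identical(ncol(liverData(st)), 4L * (6L + 15L))
  expect_identical(nrow(liverData(st)), 5L + 6L)
  expect_identical(nrow(aortaData(st)), 4L + 6L)
  cd <- as.data.frame(SummarizedExperiment::colData(liverData(st)))
  tab <- table(cd$diet, cd$time_weeks)
  expect_true(all(tab["chow", ] == 6) && all(tab["HFD", ] == 15))
  expect_identical(sum(adjacency(studyTruth(st))), 4)
  expect_identical(nrow(studyPhenotype(st)), 4L * 21L)
})

test_that("the same seed reproduces the study exactly; seeds differ otherwise", {
  a <- simulateStudy(nSource = 4, nTarget = 3, nBackground = 2,
                     edgesPerTarget = 2, seed = 5)
  b <- simulateStudy(nSource = 4, nTarget = 3, nBackground = 2,
                     edgesPerTarget = 2, seed = 5)
  c <- simulateStudy(nSource = 4, nTarget = 3, nBackground = 2,
                     edgesPerTarget = 2, seed = 6)
  expect_identical(SummarizedExperiment::assay(liverData(a)),
                   SummarizedExperiment::assay(liverData(b)))
  expect_identical(studyPhenotype(a), studyPhenotype(b))
  expect_false(identical(SummarizedExperiment::assay(liverData(a)),
                         SummarizedExperiment::assay(liverData(c))))
})

test_that("the noise-free limit reproduces exp(latent) per cell", {
  st <- simulateStudy(nSource = 5, nTarget = 5, nBackground = 0,
                      edgesPerTarget = 1, dispersion = 0, latentSd = 0,
                      animalSd = 0, seed = 2)
  m <- SummarizedExperiment::assay(liverData(st), "counts")
  cd <- as.data.frame(SummarizedExperiment::colData(liverData(st)))
  for (tw in c(6, 24)) for (diet in c("chow", "HFD")) {
    sel <- cd$diet == diet & cd$time_weeks == tw
    cell <- m[, sel, drop = FALSE]
    # replicates are identical in the deterministic limit, and within
    # rounding of the latent mean
    expect_true(all(cell == cell[, 1]))
    expect_true(all(abs(cell - round(cell)) == 0))
  }
})

test_that("NB replicate averages converge to exp(latent) at large n", {
  tr <- studyTruth(simulateStudy(nSource = 6, nTarget = 3,
                                 nBackground = 0, edgesPerTarget = 2,
                                 seed = 4))
  # same truth + seed: identical latent trajectories, different noise
  st <- simulateStudy(truth = tr, nBackground = 0, nChow = 300,
                      nHFD = 300, latentSd = 0, animalSd = 0,
                      dispersion = 0.1, seed = 4)
  det <- simulateStudy(truth = tr, nBackground = 0, nChow = 2, nHFD = 2,
                       latentSd = 0, animalSd = 0, dispersion = 0,
                       seed = 4)
  m <- SummarizedExperiment::assay(liverData(st))
  cd <- as.data.frame(SummarizedExperiment::colData(liverData(st)))
  mDet <- SummarizedExperiment::assay(liverData(det))
  cdDet <- as.data.frame(SummarizedExperiment::colData(liverData(det)))
  sel <- cd$diet == "chow" & cd$time_weeks == 6
  selDet <- cdDet$diet == "chow" & cdDet$time_weeks == 6
  mu <- mDet[, selDet][, 1]
  avg <- rowMeans(m[, sel])
  expect_true(all(abs(avg - mu) / mu < 3.5 * sqrt(0.1 + 1 / mu) /
                    sqrt(sum(sel))))
})

test_that("with no planted edges, targets are source-independent and recovery is chance", {
  base <- simulateStudy(nSource = 10, nTarget = 5, nBackground = 0,
                        edgesPerTarget = 1, seed = 9)
  tr <- studyTruth(base)
  # zero out the network but keep gene sets/dimensions
  empty <- new("SimulationTruth", sourceGenes = tr@sourceGenes,
               targetGenes = tr@targetGenes,
               adjacency = tr@adjacency * 0, effectSign = tr@effectSign * 0,
               effectWeight = tr@effectWeight * 0,
               decayAlpha = tr@decayAlpha, dietEffect = tr@dietEffect,
               seed = tr@seed)
  st <- simulateStudy(truth = empty, seed = 9)
  a <- SummarizedExperiment::assay(aortaData(st), "counts")
  # zero drive: targets sit at the zero log-equilibrium (mean count 1)
  expect_lt(mean(a[tr@targetGenes, ]), 3)
  expect_gt(mean(a[tr@targetGenes, ]), 0.3)
  expect_error(scoreRecovery(matrix(1, 10, 5,
                 dimnames = list(tr@sourceGenes, tr@targetGenes)), empty),
               class = "crossGRN_no_edges")
})

test_that("recovery scoring matches hand-enumerated concordance on a 3x3 toy", {
  src <- paste0("s", 1:3); tgt <- paste0("t", 1:3)
  adj <- matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 0), 3,
                dimnames = list(src, tgt))
  sgn <- adj; wt <- adj
  truth <- new("SimulationTruth", sourceGenes = src, targetGenes = tgt,
               adjacency = adj, effectSign = sgn, effectWeight = wt,
               decayAlpha = setNames(rep(0.1, 3), tgt),
               dietEffect = setNames(rep(1, 3), src), seed = 1L)
  vim <- matrix(c(0.9, 0.1, 0.2,
                  0.3, 0.8, 0.1,
                  0.5, 0.2, 0.4), 3, byrow = FALSE,
                dimnames = list(src, tgt))
  # brute force: count concordant (positive, negative) pairs
  scores <- as.vector(vim); labels <- as.vector(adj) == 1
  conc <- 0; total <- 0
  for (p in which(labels)) for (n in which(!labels)) {
    total <- total + 1
    conc <- conc + (scores[p] > scores[n]) + 0.5 * (scores[p] == scores[n])
  }
  r <- scoreRecovery(vim, truth)
  expect_equal(r$auroc, conc / total)
})

test_that("degenerate rankings score their documented AUROC values", {
  src <- paste0("s", 1:2); tgt <- paste0("t", 1:2)
  adj <- matrix(c(1, 0, 0, 1), 2, dimnames = list(src, tgt))
  truth <- new("SimulationTruth", sourceGenes = src, targetGenes = tgt,
               adjacency = adj, effectSign = adj, effectWeight = adj,
               decayAlpha = setNames(rep(0.1, 2), tgt),
               dietEffect = setNames(rep(1, 2), src), seed = 1L)
  expect_equal(scoreRecovery(adj, truth)$auroc, 1)        # vim == adjacency
  flat <- adj * 0 + 0.5
  expect_equal(scoreRecovery(flat, truth)$auroc, 0.5)     # constant: mid-rank
  expect_equal(scoreRecovery(flat, truth)$aupr, 0.5)      # prevalence
})

test_that("simulation errors on infeasible designs", {
  expect_error(simulateStudy(nChow = 1, seed = 1),
               class = "crossGRN_bad_design")
  expect_error(simulateStudy(timepoints = c(6, 12), seed = 1),
               class = "crossGRN_bad_design")
  expect_error(simulateStudy(dispersion = -0.1, seed = 1),
               class = "crossGRN_bad_dispersion")
  expect_error(simulateStudy(nSource = 3, edgesPerTarget = 5, seed = 1),
               class = "crossGRN_bad_design")
})
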