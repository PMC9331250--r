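mkTraj <- function(vals, tissue = "liver", diet = "chow",
                   times = c(6, 12, 18, 24)) {
  new("Trajectory", tissue = tissue, diet = diet,
      geneIds = rownames(vals), times = times, values = vals)
}

test_that("trajectories transform then average, per diet", {
  st <- tinyStudy()
  se <- liverData(st)
  trajs <- buildTrajectories(se, collapse = "mean")
  expect_named(trajs, c("chow", "HFD"))
  # contract: mean of transformed values, not transform of means
  m <- SummarizedExperiment::assay(se, "counts")
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  sf <- computeSizeFactors(m)
  sel <- cd$diet == "chow" & cd$time_weeks == 6
  g <- rownames(m)[1]
  expect_equal(trajs$chow@values[g, "6"],
               mean(log1p(m[g, sel] / sf[sel])))
  # constant counts give a constant trajectory
  flat <- matrix(7L, 2, ncol(m), dimnames = list(c("a", "b"), colnames(m)))
  seFlat <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = flat),
    colData = SummarizedExperiment::colData(se))
  tf <- buildTrajectories(seFlat, collapse = "mean")
  expect_equal(max(tf$HFD@values) - min(tf$HFD@values), 0)
})

test_that("replicate mode yields one series per animal rank with shared animals", {
  st <- tinyStudy()
  lTr <- buildTrajectories(liverData(st))
  aTr <- buildTrajectories(aortaData(st))
  expect_length(lTr, 6 + 15)
  expect_identical(sort(names(lTr)), sort(names(aTr)))
  expect_true(all(vapply(lTr, function(t) length(t@times) == 4, logical(1))))
})

test_that("decay rate estimation recovers a pure exponential and floors flat genes", {
  vals <- rbind(decayer = exp(-0.5 * c(0, 2, 4)), flat = rep(2, 3))
  traj <- mkTraj(vals, times = c(0, 2, 4))
  expect_equal(estimateAlpha(traj, "decayer"), 0.5)
  expect_equal(estimateAlpha(traj, "flat"), 1e-2)
  expect_equal(estimateAlpha(traj, "decayer", mode = "fixed:1.0"), 1.0)
  expect_error(estimateAlpha(traj, "nope"), class = "crossGRN_gene_mismatch")
  # expression-scale option back-transforms log1p storage
  logTraj <- mkTraj(rbind(g = log1p(exp(-0.5 * c(0, 2, 4)) * 100)),
                    times = c(0, 2, 4))
  expect_equal(estimateAlpha(logTraj, "g", scale = "expression"), 0.5,
               tolerance = 1e-6)
})

test_that("a single linear driver attains the top importance over iid decoys", {
  for (seed in c(1, 2, 3)) {
    set.seed(seed)
    mkSeries <- function() {
      s <- rbind(s1 = cumsum(rnorm(4)) + 5, s2 = rnorm(4, 5),
                 s3 = rnorm(4, 5), s4 = rnorm(4, 5))
      x <- numeric(4); alpha <- 0.1; w <- 0.2
      x[1] <- w * s[1, 1] / alpha
      for (k in 1:3) x[k + 1] <- x[k] + 6 * (-alpha * x[k] + w * s[1, k])
      list(s = s, t = rbind(tg = x))
    }
    A <- mkSeries(); B <- mkSeries()
    sTr <- list(chow = mkTraj(A$s, "liver", "chow"),
                HFD = mkTraj(B$s, "liver", "HFD"))
    tTr <- list(chow = mkTraj(A$t, "aorta", "chow"),
                HFD = mkTraj(B$t, "aorta", "HFD"))
    v <- suppressWarnings(
      inferVim(sTr, tTr, alphas = c(tg = 0.1), nTrees = 500, seed = seed))
    expect_identical(names(which.max(vimValues(v)[, "tg"])), "s1")
  }
})

test_that("the top-ranked regulator is preserved under source permutation", {
  set.seed(4)
  s <- rbind(s1 = cumsum(rnorm(4)) + 5, s2 = rnorm(4, 5), s3 = rnorm(4, 5),
             s4 = rnorm(4, 5))
  x <- numeric(4); x[1] <- 10
  for (k in 1:3) x[k + 1] <- x[k] + 6 * (-0.1 * x[k] + 0.2 * s[1, k])
  tTr <- list(chow = mkTraj(rbind(tg = x), "aorta", "chow"),
              HFD = mkTraj(rbind(tg = x + 0.01), "aorta", "HFD"))
  sTrA <- list(chow = mkTraj(s, "liver", "chow"),
               HFD = mkTraj(s, "liver", "HFD"))
  perm <- c(3, 1, 4, 2)
  sTrB <- list(chow = mkTraj(s[perm, ], "liver", "chow"),
               HFD = mkTraj(s[perm, ], "liver", "HFD"))
  vA <- suppressWarnings(inferVim(sTrA, tTr, c(tg = 0.1), 500, seed = 4))
  vB <- suppressWarnings(inferVim(sTrB, tTr, c(tg = 0.1), 500, seed = 4))
  expect_identical(names(which.max(vimValues(vA)[, "tg"])),
                   names(which.max(vimValues(vB)[, "tg"])))
})

test_that("VIM columns are normalized, deterministic under a fixed seed, and balanced-checked", {
  st <- tinyStudy()
  tr <- studyTruth(st)
  sTr <- buildTrajectories(liverData(st), genes = tr@sourceGenes)
  tTr <- buildTrajectories(aortaData(st), genes = tr@targetGenes)
  al <- estimateDecayRates(buildTrajectories(aortaData(st),
        genes = tr@targetGenes, collapse = "mean"), scale = "expression")
  v1 <- inferVim(sTr, tTr, al, nTrees = 200, seed = 11)
  v2 <- inferVim(sTr, tTr, al, nTrees = 200, seed = 11)
  expect_identical(vimValues(v1), vimValues(v2))
  sums <- colSums(vimValues(v1))
  expect_true(all(abs(sums[sums > 0] - 1) < 1e-6))
  expect_true(all(vimValues(v1) >= 0))
  # unbalanced source/target counts warn (5 sources vs 1 target)
  oneTgt <- tr@targetGenes[1]
  tOne <- buildTrajectories(aortaData(st), genes = oneTgt)
  expect_warning(inferVim(sTr, tOne, al[oneTgt], nTrees = 50, seed = 1),
                 "unbalanced")
  expect_error(suppressWarnings(
    inferVim(sTr, tTr, al[-1], nTrees = 50, seed = 1)),
    class = "crossGRN_missing_alpha")
})

test_that("shuffling targets against sources destroys recovery (permutation null)", {
  st <- simulateStudy(nSource = 20, nTarget = 8, nBackground = 0,
                      edgesPerTarget = 3, seed = 21)
  tr <- studyTruth(st)
  sTr <- buildTrajectories(liverData(st), genes = tr@sourceGenes)
  tTr <- buildTrajectories(aortaData(st), genes = tr@targetGenes)
  al <- estimateDecayRates(buildTrajectories(aortaData(st),
        genes = tr@targetGenes, collapse = "mean"), scale = "expression")
  set.seed(21)
  # break the animal pairing between tissues
  shuf <- sample(names(tTr))
  tShuf <- tTr[shuf]
  names(tShuf) <- names(tTr)
  v <- suppressWarnings(inferVim(sTr, tShuf, al, nTrees = 300, seed = 21))
  r <- scoreRecovery(v, tr)
  expect_lt(abs(r$auroc - 0.5), 0.15)
})
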