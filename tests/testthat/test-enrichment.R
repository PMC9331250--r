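test_that("Fisher enrichment equals the closed-form hypergeometric tail", {
  # fully overlapping draw: p = 1 / C(10, 5)
  u <- paste0("g", 1:10)
  fe <- fisherEnrich(u[1:5], u[1:5], u)
  expect_equal(fe$p_fisher, 1 / choose(10, 5))
  # zero overlap: P(X >= 0) = 1
  expect_equal(fisherEnrich(u[6:10], u[1:5], u)$p_fisher, 1)
})

test_that("Fisher enrichment agrees with enumeration for every N <= 20", {
  for (N in c(5, 9, 14, 20)) {
    u <- paste0("g", seq_len(N))
    for (K in 1:(N - 1)) for (n in 1:(N - 1)) {
      k <- max(0, K + n - N):min(K, n)
      k <- k[length(k)]  # the most extreme realizable overlap
      deg <- c(u[seq_len(k)], setdiff(u[(K + 1):N], u)[0],
               setdiff(u, u[seq_len(K)])[seq_len(n - k)])
      fe <- fisherEnrich(deg, u[seq_len(K)], u)
      expect_equal(fe$p_fisher, enumHyperP(fe$k, K, n, N),
                   tolerance = 1e-12,
                   info = sprintf("N=%d K=%d n=%d", N, K, n))
    }
  }
})

test_that("Fisher enrichment matches fisher.test as an independent check", {
  set.seed(11)
  u <- paste0("g", 1:50)
  for (i in 1:10) {
    set <- sample(u, sample(5:20, 1))
    deg <- sample(u, sample(5:20, 1))
    fe <- fisherEnrich(deg, set, u)
    ft <- fisher.test(matrix(c(fe$k, fe$K - fe$k, fe$n - fe$k,
                               fe$N - fe$K - fe$n + fe$k), 2),
                      alternative = "greater")$p.value
    expect_equal(fe$p_fisher, ft, tolerance = 1e-9)
  }
})

test_that("activation z-score follows the sign-consistency formula", {
  mkSet <- function(dirn) list(name = "s", category = "other",
                               genes = names(dirn), direction = dirn)
  deg4 <- data.frame(gene = paste0("g", 1:4), log2fc = c(1, 2, 0.5, 3))
  expect_equal(activationZ(deg4, mkSet(setNames(rep(1, 4), deg4$gene))), 2)
  mixed <- setNames(c(1, 1, -1, -1), deg4$gene)
  expect_equal(activationZ(deg4, mkSet(mixed)), 0)
  deg9 <- data.frame(gene = paste0("g", 1:9), log2fc = rep(-2, 9))
  z9 <- activationZ(deg9, mkSet(setNames(rep(-1, 9), deg9$gene)))
  expect_equal(z9, 3)
  expect_gt(z9, 2)  # classified activated
  # no directional overlap: absent, not an error
  expect_true(is.na(activationZ(deg4, list(name = "s", category = "other",
                                           genes = "zz",
                                           direction = numeric(0)))))
})

test_that("activation z changes sign when expected directions flip", {
  set.seed(5)
  deg <- data.frame(gene = paste0("g", 1:7),
                    log2fc = rnorm(7))
  dirn <- setNames(sample(c(-1, 1), 7, replace = TRUE), deg$gene)
  s1 <- list(name = "s", category = "other", genes = deg$gene,
             direction = dirn)
  s2 <- s1; s2$direction <- -dirn
  expect_equal(activationZ(deg, s1), -activationZ(deg, s2))
})

test_that("DEP overlap counts shared pathways at a timepoint", {
  rec <- function(sets, tissue) data.frame(
    set_name = sets, tissue = tissue, time_weeks = 24, dep = TRUE)
  out <- depOverlap(rec(c("A", "B", "C"), "liver"),
                    rec(c("B", "C", "D"), "aorta"), 24)
  expect_equal(out$n_shared, 2)
  expect_equal(out$aorta_shared_fraction, 2 / 3)
  expect_equal(depOverlap(rec(c("A", "B"), "liver"),
                          rec(c("A", "B"), "aorta"),
                          24)$aorta_shared_fraction, 1)
  expect_equal(depOverlap(rec("A", "liver"), rec("B", "aorta"),
                          24)$aorta_shared_fraction, 0)
})

test_that("process dynamics shares are counts of passing pathways", {
  rec <- data.frame(
    set_name = paste0("s", 1:5), category = c(rep("lipid", 3),
                                              "fibrosis", "inflammation"),
    tissue = "liver", time_weeks = 6,
    neg_log10_p = c(6, 7, 8, 9, 2))  # inflammation fails the cutoff
  dyn <- processDynamics(rec, topCutoff = 5)
  shares <- setNames(dyn$share, dyn$category)
  expect_equal(shares[["lipid"]], 0.75)
  expect_equal(shares[["fibrosis"]], 0.25)
  expect_equal(shares[["inflammation"]], 0)
  expect_equal(sum(dyn$share), 1)
  # nothing passes: all zero
  dyn0 <- processDynamics(transform(rec, neg_log10_p = 1), topCutoff = 5)
  expect_equal(sum(dyn0$share), 0)
})

test_that("end-to-end enrichment flags the planted liver pathways as DEPs", {
  # needs a universe where planted sets are a small fraction, otherwise
  # the hypergeometric tail cannot get small
  st <- simulateStudy(nSource = 24, nTarget = 10, nBackground = 75,
                      edgesPerTarget = 3, seed = 7)
  deg <- degAll(st)
  enr <- enrichAll(deg, studyGeneSets(st))
  liverLate <- enr[enr$tissue == "liver" & enr$time_weeks == 24 &
                     grepl("^liver_", enr$set_name), ]
  expect_true(any(liverLate$dep))
  # DEP counts are monotone non-increasing as enrich_p decreases
  loose <- enrichAll(deg, studyGeneSets(st), enrichP = 0.05)
  strict <- enrichAll(deg, studyGeneSets(st), enrichP = 0.001)
  for (tw in unique(enr$time_weeks))
    expect_lte(sum(strict$dep & strict$time_weeks == tw),
               sum(loose$dep & loose$time_weeks == tw))
  # invariants of every record
  expect_true(all(enr$k <= pmin(enr$K, enr$n)))
  expect_equal(enr$neg_log10_p, -log10(enr$p_fisher))
  expect_equal(enr$dep, enr$p_fisher < 0.01)
})

test_that("plot helpers draw without error on a null device", {
  dyn <- data.frame(tissue = rep(c("liver", "aorta"), each = 16),
                    time_weeks = rep(rep(c(6, 12, 18, 24), each = 4), 2),
                    category = rep(c("lipid", "inflammation", "fibrosis",
                                     "other"), 8),
                    share = rep(c(0.5, 0.3, 0.2, 0), 8))
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_invisible(plotProcessDynamics(dyn))
  rep <- concordance(data.frame(gene = c("A", "B"),
                                direction = c("up", "down")),
                     data.frame(gene = c("A", "B"),
                                log2fc = c(1, -0.9)))
  expect_invisible(plotConcordance(rep))
})
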