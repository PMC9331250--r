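# Shared fixtures, generated in code.

# tiny study reused across tests (cheap: 5 src, 4 tgt, 6 bg per tissue)
tinyStudy <- local({
  cache <- NULL
  function(seed = 1, ...) {
    if (is.null(cache) || length(list(...)) || seed != 1)
      return(simulateStudy(nSource = 5, nTarget = 4, nBackground = 6,
                           edgesPerTarget = 2, seed = seed, ...))
    cache
  }
})

writeTempCounts <- function(m, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "counts.tsv")
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

toySheet <- function(samples, tissue = "liver", diet = "chow",
                     time_weeks = 6) {
  data.frame(sample_id = samples,
             animal_id = paste0("an_", seq_along(samples)),
             tissue = tissue, diet = diet, time_weeks = time_weeks,
             stringsAsFactors = FALSE)
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
# (tie-free data); mirrors the doubled-smaller-tail convention
enumMannWhitneyP <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  r <- rank(pooled)
  uObs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  idx <- utils::combn(n, na)
  uAll <- apply(idx, 2, function(i) sum(r[i]) - na * (na + 1) / 2)
  mu <- na * (n - na) / 2
  min(1, 2 * min(mean(uAll <= uObs), mean(uAll >= uObs)))
}

# hypergeometric upper tail by explicit summation over all tables
enumHyperP <- function(k, K, n, N) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}
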