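#' One-sided Fisher enrichment p-value for a gene set
#'
#' Hypergeometric upper-tail probability of observing at least the actual
#' overlap between the differentially expressed genes and the gene set,
#' both intersected with the expression universe:
#' `P(X >= k)` with `X ~ Hypergeom(N, K, n)` where `N` is the universe
#' size, `K` the set size in the universe, `n` the number of DEGs and `k`
#' the overlap.
#'
#' @param degGenes character, differentially expressed genes.
#' @param geneSet character, the set's member genes.
#' @param universe character, all testable genes (non-empty).
#' @return list with `k`, `K`, `n`, `N`, `p_fisher`, `neg_log10_p`.
#' @export
fisherEnrich <- function(degGenes, geneSet, universe) {
  if (!length(universe)) .err("empty_universe", "universe is empty")
  universe <- unique(universe)
  set <- intersect(unique(geneSet), universe)
  deg <- intersect(unique(degGenes), universe)
  k <- length(intersect(deg, set))
  K <- length(set); n <- length(deg); N <- length(universe)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(k = k, K = K, n = n, N = N, p_fisher = p,
       neg_log10_p = -log10(p))
}

#' Activation z-score of a gene set from DEG directions
#'
#' Sign-consistency statistic between observed fold-change directions and
#' the set's expected per-gene regulation directions:
#' `z = sum_g sign(log2fc_g) * dir_g / sqrt(m)` over the `m` overlapping
#' directional DEGs. `z > 2` predicts activation, `z < -2` predicts
#' inhibition. Returns `NA` when no overlapping DEG carries an expected
#' direction (absent is a value, not an error).
#'
#' @param degSub data.frame with columns `gene` and `log2fc` (the
#'   significant genes of one tissue/timepoint).
#' @param set one gene-set record (element of [geneSets()]), carrying a
#'   `direction` map.
#' @return numeric z, or `NA_real_`.
#' @export
activationZ <- function(degSub, set) {
  dirn <- set$direction
  if (!length(dirn)) return(NA_real_)
  hit <- degSub[degSub$gene %in% names(dirn), , drop = FALSE]
  if (!nrow(hit)) return(NA_real_)
  sum(sign(hit$log2fc) * dirn[hit$gene]) / sqrt(nrow(hit))
}

#' Gene-set enrichment per tissue and timepoint
#'
#' For every gene set and every (tissue, timepoint) cell of the DEG table:
#' Fisher-exact enrichment of the significant genes against the tissue's
#' expression universe, the activation z-score where expected directions
#' exist, and the differentially-expressed-pathway (DEP) flag at
#' `p_fisher < enrichP`.
#'
#' @param deg DEG table from [degAll()].
#' @param sets [GeneSetCollection-class].
#' @param universes named list mapping tissue to its universe (character
#'   of testable genes); defaults to all genes present in `deg` for that
#'   tissue.
#' @param enrichP DEP significance cutoff on the Fisher p (default 0.01).
#' @return data.frame of enrichment records: `set_name`, `category`,
#'   `tissue`, `time_weeks`, `k`, `K`, `n`, `N`, `p_fisher`,
#'   `neg_log10_p`, `z`, `dep`.
#' @export
enrichAll <- function(deg, sets, universes = NULL, enrichP = 0.01) {
  out <- list()
  for (tissue in unique(deg$tissue)) {
    dT <- deg[deg$tissue == tissue, , drop = FALSE]
    universe <- if (!is.null(universes[[tissue]])) universes[[tissue]]
                else unique(dT$gene)
    for (tw in sort(unique(dT$time_weeks))) {
      cell <- dT[dT$time_weeks == tw, , drop = FALSE]
      sig <- cell[cell$significant, , drop = FALSE]
      for (s in geneSets(sets)) {
        if (!length(intersect(s$genes, universe))) next
        fe <- fisherEnrich(sig$gene, s$genes, universe)
        out[[length(out) + 1L]] <- data.frame(
          set_name = s$name, category = s$category, tissue = tissue,
          time_weeks = tw, k = fe$k, K = fe$K, n = fe$n, N = fe$N,
          p_fisher = fe$p_fisher, neg_log10_p = fe$neg_log10_p,
          z = activationZ(sig, s), dep = fe$p_fisher < enrichP,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Overlap of differentially expressed pathways between tissues
#'
#' At one timepoint, counts the DEPs (records with `dep = TRUE`) of each
#' tissue and the pathways shared between them, and reports the shared
#' fraction of the aorta's DEPs.
#'
#' @param liver,aorta enrichment record data.frames (see [enrichAll()]).
#' @param timeWeeks the timepoint to compare at.
#' @return list with `n_liver`, `n_aorta`, `n_shared`,
#'   `aorta_shared_fraction` (`NA` when the aorta has no DEPs).
#' @export
depOverlap <- function(liver, aorta, timeWeeks) {
  depSets <- function(df) unique(
    df$set_name[df$dep & df$time_weeks == timeWeeks])
  l <- depSets(liver); a <- depSets(aorta)
  sh <- length(intersect(l, a))
  list(n_liver = length(l), n_aorta = length(a), n_shared = sh,
       aorta_shared_fraction = if (length(a)) sh / length(a) else NA_real_)
}

#' Time-resolved process-category dynamics of top pathways
#'
#' Restricts the enrichment records of each (tissue, timepoint) cell to
#' the top pathways (`neg_log10_p > topCutoff`) and reports each process
#' category's share of that top set by pathway count. Shares across
#' categories sum to 1 where any pathway passes, and are all 0 otherwise.
#'
#' @param records enrichment records from [enrichAll()].
#' @param topCutoff `-log10(p)` threshold defining the top pathways
#'   (default 5).
#' @return data.frame with `tissue`, `time_weeks`, `category`, `share`.
#' @export
processDynamics <- function(records, topCutoff = 5) {
  out <- list()
  for (tissue in unique(records$tissue)) {
    for (tw in sort(unique(records$time_weeks[records$tissue == tissue]))) {
      cell <- records[records$tissue == tissue & records$time_weeks == tw &
                        records$neg_log10_p > topCutoff, , drop = FALSE]
      tot <- nrow(cell)
      share <- vapply(.validCategories, function(cc)
        if (tot == 0) 0 else sum(cell$category == cc) / tot, numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        tissue = tissue, time_weeks = tw, category = .validCategories,
        share = unname(share), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Plot time-resolved process-category dynamics
#'
#' Stacked-area view of each process category's share of the top
#' pathways over time, one panel per tissue. Draws on the current
#' graphics device.
#'
#' @param dynamics result of [processDynamics()].
#' @return invisibly, `dynamics`.
#' @export
plotProcessDynamics <- function(dynamics) {
  tissues <- unique(dynamics$tissue)
  cats <- .validCategories
  cols <- c(lipid = "#E6B33C", inflammation = "#C0392B",
            fibrosis = "#2471A3", other = "grey70")
  old <- graphics::par(mfrow = c(1, length(tissues)),
                       mar = c(4, 4, 3, 1))
  on.exit(graphics::par(old))
  for (ti in tissues) {
    d <- dynamics[dynamics$tissue == ti, ]
    tw <- sort(unique(d$time_weeks))
    shares <- sapply(tw, function(t2)
      vapply(cats, function(cc)
        d$share[d$time_weeks == t2 & d$category == cc][1], numeric(1)))
    cum <- apply(shares, 2, cumsum)
    graphics::plot(range(tw), c(0, 1), type = "n",
                   xlab = "weeks", ylab = "share of top pathways",
                   main = ti)
    lower <- rep(0, length(tw))
    for (i in seq_along(cats)) {
      graphics::polygon(c(tw, rev(tw)), c(cum[i, ], rev(lower)),
                        col = cols[[cats[i]]], border = NA)
      lower <- cum[i, ]
    }
    graphics::legend("topright", legend = cats, fill = cols[cats],
                     cex = 0.7, bg = "white")
  }
  invisible(dynamics)
}
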