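#' Select edges above a VIM percentile
#'
#' Computes the empirical percentile threshold over all source x target
#' importance entries (linear-interpolation quantile definition) and
#' retains the edges whose importance is strictly greater. Entries exactly
#' equal to the threshold are dropped — the tie rule is deterministic, and
#' a constant matrix yields no edges. Each retained edge also reports its
#' mid-rank empirical percentile among all entries.
#'
#' @param vim [VimMatrix-class] or a source x target matrix.
#' @param percentile cutoff in \[0, 100) (default 99).
#' @return data.frame with columns `source`, `target`, `vim`,
#'   `percentile_rank`, sorted by decreasing importance.
#' @export
selectEdges <- function(vim, percentile = 99) {
  if (percentile < 0 || percentile >= 100)
    .err("bad_percentile", "percentile must be in [0, 100)")
  m <- if (is(vim, "VimMatrix")) vimValues(vim) else as.matrix(vim)
  if (!length(m)) .err("bad_input", "empty VIM matrix")
  v <- as.vector(m)
  thr <- stats::quantile(v, percentile / 100, type = 7, names = FALSE)
  keep <- which(m > thr, arr.ind = TRUE)
  r <- rank(v, ties.method = "average")
  pr <- 100 * (r - 0.5) / length(v)
  idx <- (keep[, 2] - 1) * nrow(m) + keep[, 1]
  out <- data.frame(source = rownames(m)[keep[, 1]],
                    target = colnames(m)[keep[, 2]],
                    vim = m[keep], percentile_rank = pr[idx],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$vim, out$source, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble the annotated bipartite cross-tissue network
#'
#' Builds a [CrossTissueNetwork-class] from selected edges: every edge
#' must run from a liver source gene to an aorta target gene (a gene
#' appearing on both sides violates the bipartite contract and errors),
#' and every node is annotated with all gene sets containing it
#' (`"unassigned"` when none do).
#'
#' @param edges edge data.frame from [selectEdges()].
#' @param sets [GeneSetCollection-class] used for annotation.
#' @param label analysis label, `"lipid_fibrosis"` or `"inflammation"`.
#' @return [CrossTissueNetwork-class]
#' @export
assembleNetwork <- function(edges, sets, label = "lipid_fibrosis") {
  if (nrow(edges) && length(intersect(edges$source, edges$target)))
    .err("not_bipartite",
         "gene(s) appear as both source and target: %s",
         paste(intersect(edges$source, edges$target), collapse = ", "))
  annotate <- function(genes, tissue) {
    if (!length(genes))
      return(data.frame(gene = character(0), tissue = character(0),
                        pathways = character(0), stringsAsFactors = FALSE))
    pw <- vapply(genes, function(g) {
      hits <- names(Filter(function(s) g %in% s$genes, geneSets(sets)))
      if (length(hits)) paste(hits, collapse = ";") else "unassigned"
    }, character(1))
    data.frame(gene = genes, tissue = tissue, pathways = unname(pw),
               stringsAsFactors = FALSE)
  }
  nodes <- rbind(annotate(unique(edges$source), "liver"),
                 annotate(unique(edges$target), "aorta"))
  new("CrossTissueNetwork", edges = edges, nodes = nodes, label = label)
}

#' Cross-study directional concordance of key regulators
#'
#' Calls each regulator's direction in a second study from its log2 fold
#' change with the strict `+/-fcCutoff` rule (`up` iff `log2fc >
#' fcCutoff`, `down` iff `log2fc < -fcCutoff`, else `not_de`) and compares
#' it with the first study's direction. Regulators absent from the second
#' study's DEG table are reported `not_de` with concordance `NA`.
#'
#' @param regulators data.frame with columns `gene` and `direction`
#'   (`"up"`/`"down"`, the first study's call); duplicate genes error.
#' @param deg2 second-study DEG table with columns `gene` and `log2fc`
#'   (at most one record per gene).
#' @param fcCutoff absolute log2 fold-change call threshold (default 0.4).
#' @return list with `table` (per-regulator data.frame: `gene`,
#'   `direction_study1`, `log2fc_study2`, `called_study2`, `concordant`)
#'   and `summary` (`n_concordant`, `n_discordant`, `n_not_de`).
#' @export
concordance <- function(regulators, deg2, fcCutoff = 0.4) {
  if (anyDuplicated(regulators$gene))
    .err("duplicate_regulators", "duplicate regulator entries")
  if (anyDuplicated(deg2$gene))
    .err("duplicate_regulators", "deg2 has duplicate gene records")
  idx <- match(regulators$gene, deg2$gene)
  lfc <- deg2$log2fc[idx]
  called <- ifelse(is.na(lfc), "not_de",
            ifelse(lfc > fcCutoff, "up",
            ifelse(lfc < -fcCutoff, "down", "not_de")))
  conc <- ifelse(called == "not_de", NA, called == regulators$direction)
  tab <- data.frame(gene = regulators$gene,
                    direction_study1 = regulators$direction,
                    log2fc_study2 = lfc, called_study2 = called,
                    concordant = conc, stringsAsFactors = FALSE)
  list(table = tab,
       summary = list(n_concordant = sum(conc %in% TRUE),
                      n_discordant = sum(conc %in% FALSE),
                      n_not_de = sum(called == "not_de")))
}

#' Reference list of hepatic key regulators
#'
#' The hepatic key regulators identified in the source time-course study,
#' with their HFD-vs-chow regulation direction in that study, shipped for
#' real-data validation runs. `APCS` has no stated direction and is
#' returned with `NA`.
#'
#' @return data.frame with columns `gene`, `direction`, `category`.
#' @export
hepaticKeyRegulators <- function() {
  data.frame(
    gene = c("LCAT", "ACAT2", "SC5D", "HMGCR", "SQLE", "MVK",
             "APOA2", "APOC4", "IL1A", "VCAM1", "NFKB2", "SELP",
             "C1R", "APCS", "PDGFD", "COL3A1", "FGG"),
    direction = c("down", "down", "down", "down", "down", "down",
                  "down", "down", "up", "up", "up", "up",
                  "down", NA, "up", "up", "down"),
    category = c(rep("lipid", 8), rep("inflammation", 6),
                 rep("fibrosis", 3)),
    stringsAsFactors = FALSE)
}

#' Plot a cross-study concordance heatmap
#'
#' One row per regulator, colored by the second study's log2 fold change
#' (blue = down, red = up), with the first study's direction in the row
#' labels. Draws on the current graphics device.
#'
#' @param report result of [concordance()].
#' @param main plot title.
#' @return invisibly, the matrix drawn.
#' @export
plotConcordance <- function(report, main = "Cross-study concordance") {
  tab <- report$table
  lfc <- tab$log2fc_study2
  lfc[is.na(lfc)] <- 0
  lim <- max(abs(lfc), 0.5)
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(101)
  idx <- round(100 * (lfc + lim) / (2 * lim)) + 1
  old <- graphics::par(mar = c(4, 8, 3, 1))
  on.exit(graphics::par(old))
  graphics::image(x = 1, y = seq_len(nrow(tab)),
                  z = matrix(seq_len(nrow(tab)), 1), col = pal[idx],
                  axes = FALSE, xlab = "log2FC study 2", ylab = "",
                  main = main)
  graphics::axis(2, at = seq_len(nrow(tab)), las = 2, cex.axis = 0.8,
                 labels = sprintf("%s (%s)", tab$gene,
                                  tab$direction_study1))
  graphics::box()
  invisible(matrix(lfc, ncol = 1, dimnames = list(tab$gene, "log2fc")))
}
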