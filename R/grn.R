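#' Build expression trajectories from a cross-sectional time course
#'
#' Counts are normalized by median-of-ratios size factors and transformed
#' to `log(1 + x)`; transform-then-average/order is the contract. Two
#' replicate handling modes exist:
#'
#' * `collapse = "replicate"` (default): every replicate rank within a
#'   diet becomes its own short time series — the animal at rank `r` of
#'   each timepoint's cohort (animals sorted by id) supplies that series'
#'   value. Because both tissues are profiled from the same animals, the
#'   rank-`r` liver and aorta series cover the same mice at every
#'   timepoint. This keeps all animals as training material for the
#'   dynamical inference.
#' * `collapse = "mean"`: replicates are averaged per timepoint, giving
#'   one low-noise series per diet (used for decay-rate estimation).
#'
#' Chow and HFD always remain separate series.
#'
#' @param se single-tissue [SummarizedExperiment] with a `counts` assay.
#' @param genes optional character, subset of genes (default all).
#' @param collapse `"replicate"` or `"mean"` (see above).
#' @return named list of [Trajectory-class] objects (`"chow"`, `"HFD"`
#'   for `"mean"`; `"chow.1"`, ..., `"HFD.1"`, ... for `"replicate"`).
#' @export
buildTrajectories <- function(se, genes = NULL,
                              collapse = c("replicate", "mean")) {
  collapse <- match.arg(collapse)
  m <- assay(se, "counts")
  cd <- as.data.frame(colData(se))
  tissue <- unique(cd$tissue)
  if (length(tissue) != 1L)
    .err("bad_input", "buildTrajectories expects a single-tissue experiment")
  if (is.null(genes)) genes <- rownames(m)
  absent <- setdiff(genes, rownames(m))
  if (length(absent))
    .err("gene_mismatch", "genes not in count matrix: %s",
         paste(absent, collapse = ", "))
  sf <- computeSizeFactors(m)
  logExpr <- log1p(sweep(m[genes, , drop = FALSE], 2, sf, "/"))
  times <- sort(unique(cd$time_weeks))
  trajs <- list()
  for (diet in c("chow", "HFD")) {
    cells <- lapply(times, function(tw) {
      sel <- which(cd$diet == diet & cd$time_weeks == tw)
      if (!length(sel))
        .err("missing_cell", "no %s samples at week %s in %s",
             diet, tw, tissue)
      sel[order(cd$animal_id[sel])]
    })
    if (collapse == "mean") {
      vals <- vapply(cells, function(sel)
        rowMeans(logExpr[, sel, drop = FALSE]), numeric(length(genes)))
      vals <- matrix(vals, nrow = length(genes),
                     dimnames = list(genes, times))
      trajs[[diet]] <- new("Trajectory", tissue = tissue, diet = diet,
                           geneIds = genes, times = as.numeric(times),
                           values = vals)
    } else {
      nRep <- min(lengths(cells))
      for (r in seq_len(nRep)) {
        vals <- vapply(cells, function(sel) logExpr[, sel[r]],
                       numeric(length(genes)))
        vals <- matrix(vals, nrow = length(genes),
                       dimnames = list(genes, times))
        trajs[[paste(diet, r, sep = ".")]] <-
          new("Trajectory", tissue = tissue, diet = diet,
              geneIds = genes, times = as.numeric(times), values = vals)
      }
    }
  }
  trajs
}

#' Estimate a gene's first-order decay rate from its trajectory
#'
#' In `"from_data"` mode the decay rate is
#' `ln(max / min) / |t_at_max - t_at_min|` on the gene's trajectory
#' (shifted to be positive first when any value is <= 0), the max/min
#' log-ratio convention of the dynamical network-inference family; a flat
#' trajectory falls back to the floor. `mode = "fixed:<value>"` returns
#' the given value for every gene.
#'
#' Decay acts on transcript abundance, so when the trajectory stores
#' log-transformed expression the estimator should be applied on the
#' expression scale: `scale = "expression"` back-transforms `log(1 + x)`
#' values with `expm1()` first. `scale = "asis"` (default) uses the
#' stored values directly.
#'
#' @param traj [Trajectory-class].
#' @param gene gene id present in the trajectory.
#' @param mode `"from_data"` or `"fixed:<value>"`.
#' @param floor lower bound for the estimate (default 1e-2 per week).
#' @param scale `"asis"` or `"expression"` (see above).
#' @return positive scalar decay rate (per week).
#' @export
estimateAlpha <- function(traj, gene, mode = "from_data", floor = 1e-2,
                          scale = c("asis", "expression")) {
  scale <- match.arg(scale)
  if (!gene %in% traj@geneIds)
    .err("gene_mismatch", "gene '%s' not in trajectory", gene)
  if (grepl("^fixed:", mode)) {
    val <- as.numeric(sub("^fixed:", "", mode))
    if (is.na(val) || val <= 0)
      .err("bad_input", "fixed alpha must be a positive number")
    return(val)
  }
  if (!identical(mode, "from_data"))
    .err("bad_input", "mode must be 'from_data' or 'fixed:<value>'")
  x <- traj@values[match(gene, traj@geneIds), ]
  if (scale == "expression") x <- expm1(x)
  if (min(x) <= 0) x <- x - min(x) + 1  # shift to a positive scale
  iMax <- which.max(x); iMin <- which.min(x)
  if (x[iMax] == x[iMin]) return(floor)  # flat gene
  max(log(x[iMax] / x[iMin]) / abs(traj@times[iMax] - traj@times[iMin]),
      floor)
}

#' Decay rates for a set of target genes over several diet series
#'
#' Applies [estimateAlpha()] per series and averages across series, so
#' both diet trajectories inform each target's decay rate.
#'
#' @param trajs list of [Trajectory-class] (the target tissue's series).
#' @param genes character, target genes (default: genes of the first
#'   series).
#' @param mode,floor,scale passed to [estimateAlpha()]; the pipeline uses
#'   `scale = "expression"` on log-stored trajectories.
#' @return named positive numeric vector.
#' @export
estimateDecayRates <- function(trajs, genes = NULL, mode = "from_data",
                               floor = 1e-2,
                               scale = c("asis", "expression")) {
  scale <- match.arg(scale)
  if (is.null(genes)) genes <- trajs[[1]]@geneIds
  vapply(genes, function(g)
    mean(vapply(trajs, estimateAlpha, numeric(1), gene = g, mode = mode,
                floor = floor, scale = scale)), numeric(1))
}

#' Infer the source-to-target variable-importance matrix
#'
#' The dynamical network-inference core. For each target gene `j`,
#' training rows are built from consecutive-timepoint pairs pooled over
#' all series: the inputs are the source-gene expressions at `t_k` and
#' the response is the decay-compensated temporal derivative
#' `y_k = (x_j(t_{k+1}) - x_j(t_k)) / (t_{k+1} - t_k) + alpha_j x_j(t_k)`.
#' In a cross-sectional design no animal is observed twice, so the
#' information lives on two scales and the training rows are pooled from
#' both:
#'
#' * cohort rows — one per (diet, transition): cell-mean source
#'   expression as inputs and the full decay-compensated derivative of
#'   the cell-mean target trajectory as response. These carry the
#'   temporal dynamics.
#' * animal rows — one per (replicate series, timepoint) whenever a diet
#'   has more than one series: within-cell deviations of source
#'   expression as inputs and `alpha_j` times the within-cell deviation
#'   of the target as response. The slope has no animal-level component
#'   (consecutive timepoints are different animals), so only the decay
#'   term remains; it is where each animal's regulator state leaves its
#'   imprint on its own target tissue. Because this relation is
#'   timepoint-local, every timepoint contributes rows, including the
#'   last. These rows carry the inter-individual covariation and are
#'   what make the replicate animals informative.
#'
#' With one series per diet the animal rows vanish and the construction
#' reduces to the plain per-series derivative regression.
#'
#' A seeded random forest (`ranger`, impurity importance, fully grown
#' trees, `mtry = sqrt(n_source)` by default, single-threaded for
#' determinism) is fit per target and the per-source importances are
#' normalized to sum to 1 over sources whenever any split occurred.
#'
#' A warning is emitted when the source/target gene counts are unbalanced
#' (ratio outside \[0.5, 2\]), since strongly unbalanced input/output sets
#' bias the importance ranking.
#'
#' @param sourceTrajs,targetTrajs named lists of [Trajectory-class], one
#'   per diet, sharing diets and time grids.
#' @param alphas named per-target decay rates (see
#'   [estimateDecayRates()]).
#' @param nTrees ensemble size (default 1000).
#' @param seed integer seed; per-target streams are derived from it so
#'   results do not depend on evaluation order.
#' @param mtry candidate features per split (default
#'   `max(1, floor(sqrt(n_source)))`).
#' @param importance `"impurity"` (default) or `"permutation"`.
#' @param alphaMode label recorded in the result's metadata describing how
#'   `alphas` were obtained (default `"from_data"`).
#' @return [VimMatrix-class]
#' @export
inferVim <- function(sourceTrajs, targetTrajs, alphas, nTrees = 1000,
                     seed = 1, mtry = NULL, importance = "impurity",
                     alphaMode = "from_data") {
  diets <- names(sourceTrajs)
  if (!identical(sort(diets), sort(names(targetTrajs))))
    .err("bad_input", "source and target trajectories must share series")
  targetTrajs <- targetTrajs[diets]  # align series by name
  for (d in diets)
    if (!isTRUE(all.equal(sourceTrajs[[d]]@times, targetTrajs[[d]]@times)))
      .err("bad_input", "source and target time grids differ for %s", d)
  srcGenes <- sourceTrajs[[1]]@geneIds
  tgtGenes <- targetTrajs[[1]]@geneIds
  missingAlpha <- setdiff(tgtGenes, names(alphas))
  if (length(missingAlpha))
    .err("missing_alpha", "no decay rate for: %s",
         paste(missingAlpha, collapse = ", "))
  ratio <- length(srcGenes) / length(tgtGenes)
  if (ratio < 0.5 || ratio > 2)
    warning(sprintf(paste("unbalanced analysis: %d source vs %d target",
                          "genes; importance rankings may be biased"),
                    length(srcGenes), length(tgtGenes)))
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(length(srcGenes))))

  ## two-scale training design (see Details)
  dietOf <- vapply(targetTrajs, function(tt) tt@diet, character(1))
  K <- length(targetTrajs[[1]]@times)
  dt <- diff(targetTrajs[[1]]@times)
  dietMean <- function(trajs, sel)
    Reduce(`+`, lapply(trajs[sel], function(tt) tt@values)) / sum(sel)

  Xcohort <- NULL; Xanimal <- NULL
  yPartsC <- list(); yPartsA <- list()  # per-block response ingredients
  for (d in unique(dietOf)) {
    sel <- dietOf == d
    sBar <- dietMean(sourceTrajs, sel)   # source cell means
    tBar <- dietMean(targetTrajs, sel)   # target cell means
    Xcohort <- rbind(Xcohort, t(sBar[, -K, drop = FALSE]))
    yPartsC[[d]] <- list(
      xNow = tBar[, -K, drop = FALSE],
      slope = (tBar[, -1, drop = FALSE] - tBar[, -K, drop = FALSE]) /
        matrix(dt, nrow(tBar), K - 1, byrow = TRUE))
    if (sum(sel) > 1) {
      for (r in which(sel)) {
        Xanimal <- rbind(Xanimal, t(sourceTrajs[[r]]@values - sBar))
        yPartsA[[length(yPartsA) + 1L]] <-
          targetTrajs[[r]]@values - tBar
      }
    }
  }
  if (nrow(Xcohort) < 2)
    .err("bad_input", "fewer than 2 training rows per target")
  colnames(Xcohort) <- srcGenes
  if (!is.null(Xanimal)) colnames(Xanimal) <- srcGenes

  fitImportance <- function(Xblk, y, treeSeed) {
    df <- data.frame(..y = y, Xblk, check.names = FALSE)
    fit <- ranger::ranger(
      dependent.variable.name = "..y", data = df,
      num.trees = nTrees, mtry = mtry, min.node.size = 1,
      importance = importance, num.threads = 1, seed = treeSeed)
    imp <- fit$variable.importance[srcGenes]
    imp[is.na(imp)] <- 0
    imp <- pmax(imp, 0)
    tot <- sum(imp)
    if (tot > 0) imp / tot else rep(0, length(srcGenes))
  }

  vim <- matrix(0, length(srcGenes), length(tgtGenes),
                dimnames = list(srcGenes, tgtGenes))
  baseSeed <- .stageSeed(seed, "grn")
  for (j in seq_along(tgtGenes)) {
    aj <- alphas[[tgtGenes[j]]]
    yC <- unlist(lapply(yPartsC, function(p)
      p$slope[j, ] + aj * p$xNow[j, ]), use.names = FALSE)
    impC <- fitImportance(Xcohort, yC, baseSeed + j)
    if (is.null(Xanimal)) {
      vim[, j] <- impC
    } else {
      yA <- unlist(lapply(yPartsA, function(dev) aj * dev[j, ]),
                   use.names = FALSE)
      impA <- fitImportance(Xanimal, yA, baseSeed + 500000L + j)
      # blocks weighted by the rows they contribute
      wC <- nrow(Xcohort); wA <- nrow(Xanimal)
      vim[, j] <- (wC * impC + wA * impA) / (wC + wA)
    }
  }
  new("VimMatrix", vim = vim, nTrees = as.integer(nTrees),
      seed = as.integer(seed), alphaMode = alphaMode)
}
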