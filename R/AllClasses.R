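#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Gene set collection with process categories and expected directions
#'
#' Container for GMT-style gene sets. Each set carries a process-category
#' label (`lipid`, `inflammation`, `fibrosis` or `other`) and, optionally,
#' an expected regulation direction (+1/-1) per member gene, used by the
#' activation z-score.
#'
#' @slot sets named list; each element is a list with elements `name`,
#'   `category`, `genes` (character) and `direction` (named numeric in
#'   \{-1, +1\}, possibly empty).
#'
#' @seealso [readGmt()], [activationZ()]
#' @export
setClass("GeneSetCollection", representation(sets = "list"))

.validCategories <- c("lipid", "inflammation", "fibrosis", "other")

setValidity("GeneSetCollection", function(object) {
  s <- object@sets
  if (length(s) == 0L) return("collection contains no gene sets")
  nm <- unname(vapply(s, function(x) x$name, character(1)))
  if (anyDuplicated(nm)) return("gene set names must be unique")
  if (!identical(names(s), nm)) return("list names must match set names")
  for (x in s) {
    if (length(x$genes) == 0L) return(sprintf("set '%s' is empty", x$name))
    if (!x$category %in% .validCategories)
      return(sprintf("set '%s' has unknown category '%s'", x$name, x$category))
    if (length(x$direction) &&
        (!all(names(x$direction) %in% x$genes) ||
         !all(x$direction %in% c(-1, 1))))
      return(sprintf("set '%s': directions must map member genes to +/-1",
                     x$name))
  }
  TRUE
})

#' Ground truth of a simulated two-tissue study
#'
#' Planted liver-source to aorta-target regulatory structure: adjacency,
#' effect signs and weights, per-target decay rates, per-source diet effects
#' and the seed used, so that edge recovery can be scored exactly.
#'
#' @slot sourceGenes,targetGenes character vectors of gene ids.
#' @slot adjacency source x target 0/1 matrix.
#' @slot effectSign source x target matrix in \{-1, 0, +1\}; nonzero exactly
#'   where `adjacency` is 1.
#' @slot effectWeight source x target non-negative matrix; positive exactly
#'   where `adjacency` is 1.
#' @slot decayAlpha named numeric, per-target first-order decay rate (>0,
#'   per week).
#' @slot dietEffect named numeric, per-source log-scale shift reached on
#'   high-fat diet at the final timepoint.
#' @slot seed integer seed the study was generated from.
#'
#' @seealso [simulateStudy()], [scoreRecovery()]
#' @export
setClass("SimulationTruth", representation(
  sourceGenes = "character", targetGenes = "character",
  adjacency = "matrix", effectSign = "matrix", effectWeight = "matrix",
  decayAlpha = "numeric", dietEffect = "numeric", seed = "integer"))

setValidity("SimulationTruth", function(object) {
  ns <- length(object@sourceGenes); nt <- length(object@targetGenes)
  dims <- list(object@adjacency, object@effectSign, object@effectWeight)
  if (!all(vapply(dims, function(m) identical(dim(m), c(ns, nt)), logical(1))))
    return("adjacency/sign/weight matrices must be source x target")
  if (!all(object@adjacency %in% c(0, 1))) return("adjacency must be 0/1")
  if (!all((object@effectSign != 0) == (object@adjacency == 1)))
    return("effect sign must be nonzero exactly on planted edges")
  if (!all((object@effectWeight > 0) == (object@adjacency == 1)))
    return("effect weight must be positive exactly on planted edges")
  if (length(object@decayAlpha) != nt || any(object@decayAlpha <= 0))
    return("decayAlpha must be positive, one per target gene")
  if (length(object@dietEffect) != ns)
    return("dietEffect must have one entry per source gene")
  TRUE
})

#' A simulated two-tissue time-course study
#'
#' Liver and aorta count data (as [SummarizedExperiment] objects sharing
#' animal ids), a per-animal phenotype table, the gene sets the generator
#' assigned, and the planted [SimulationTruth].
#'
#' @slot liver,aorta [SummarizedExperiment] with a `counts` assay and
#'   sample-sheet columns (`sample_id`, `animal_id`, `tissue`, `diet`,
#'   `time_weeks`) in `colData`.
#' @slot phenotype data.frame, one row per animal.
#' @slot geneSets [GeneSetCollection] covering planted genes.
#' @slot truth [SimulationTruth].
#'
#' @seealso [simulateStudy()]
#' @export
setClass("SimulatedStudy", representation(
  liver = "SummarizedExperiment", aorta = "SummarizedExperiment",
  phenotype = "data.frame", geneSets = "GeneSetCollection",
  truth = "SimulationTruth"))

setValidity("SimulatedStudy", function(object) {
  cl <- colData(object@liver); ca <- colData(object@aorta)
  need <- c("sample_id", "animal_id", "tissue", "diet", "time_weeks")
  if (!all(need %in% colnames(cl)) || !all(need %in% colnames(ca)))
    return("colData must carry the sample-sheet columns")
  if (!setequal(cl$animal_id, ca$animal_id))
    return("liver and aorta must share animal ids")
  TRUE
})

#' Replicate-summarized expression trajectory of one tissue/diet series
#'
#' Log-scale expression (genes x timepoints) after normalization, transform
#' and replicate averaging; the unit the dynamical network inference
#' consumes.
#'
#' @slot tissue,diet single character labels.
#' @slot geneIds character.
#' @slot times strictly increasing numeric (weeks), length >= 3.
#' @slot values genes x times numeric matrix.
#'
#' @seealso [buildTrajectories()], [inferVim()]
#' @export
setClass("Trajectory", representation(
  tissue = "character", diet = "character", geneIds = "character",
  times = "numeric", values = "matrix"))

setValidity("Trajectory", function(object) {
  if (length(object@times) < 3L) return("a trajectory needs >= 3 timepoints")
  if (any(diff(object@times) <= 0)) return("times must be strictly increasing")
  if (!identical(dim(object@values),
                 c(length(object@geneIds), length(object@times))))
    return("values must be genes x times")
  if (anyNA(object@values)) return("trajectory has missing cells")
  TRUE
})

#' Variable-importance matrix of candidate source-to-target edges
#'
#' Source x target matrix of random-forest importances from the dynamical
#' network inference; importances are normalized to sum to one per target
#' whenever any split occurred.
#'
#' @slot vim source x target non-negative numeric matrix.
#' @slot nTrees,seed integers recording how the ensemble was fit.
#' @slot alphaMode character, decay-rate mode used (`"from_data"` or
#'   `"fixed:<value>"`).
#'
#' @seealso [inferVim()], [selectEdges()], [scoreRecovery()]
#' @export
setClass("VimMatrix", representation(
  vim = "matrix", nTrees = "integer", seed = "integer",
  alphaMode = "character"))

setValidity("VimMatrix", function(object) {
  if (any(object@vim < 0)) return("importances must be non-negative")
  cs <- colSums(object@vim)
  if (any(cs > 1 + 1e-6)) return("per-target importances must sum to <= 1")
  if (is.null(rownames(object@vim)) || is.null(colnames(object@vim)))
    return("vim must carry source/target gene names")
  TRUE
})

#' Bipartite cross-tissue regulator-target network
#'
#' Percentile- and direction-filtered edges from liver source genes to aorta
#' target genes, with per-node tissue and pathway annotation.
#'
#' @slot edges data.frame with columns `source`, `target`, `vim`,
#'   `percentile_rank`.
#' @slot nodes data.frame with columns `gene`, `tissue`, `pathways`
#'   (semicolon-joined set names, `"unassigned"` when in no set).
#' @slot label analysis label (`"lipid_fibrosis"` or `"inflammation"`).
#'
#' @seealso [assembleNetwork()]
#' @export
setClass("CrossTissueNetwork", representation(
  edges = "data.frame", nodes = "data.frame", label = "character"))

setValidity("CrossTissueNetwork", function(object) {
  e <- object@edges
  if (nrow(e) &&
      length(intersect(unique(e$source), unique(e$target))) > 0)
    return("network must be bipartite: a gene cannot be source and target")
  n <- object@nodes
  if (nrow(n) && !all(c("gene", "tissue", "pathways") %in% colnames(n)))
    return("nodes must carry gene/tissue/pathways columns")
  if (!object@label %in% c("lipid_fibrosis", "inflammation"))
    return("label must be 'lipid_fibrosis' or 'inflammation'")
  TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "GeneSetCollection", function(object) {
  cats <- table(vapply(object@sets, function(x) x$category, character(1)))
  cat("GeneSetCollection with", length(object@sets), "sets\n")
  cat("  categories:",
      paste(sprintf("%s=%d", names(cats), cats), collapse = ", "), "\n")
})

setMethod("show", "SimulationTruth", function(object) {
  cat("SimulationTruth:", length(object@sourceGenes), "source x",
      length(object@targetGenes), "target genes,",
      sum(object@adjacency), "planted edges (seed", object@seed, ")\n")
})

setMethod("show", "SimulatedStudy", function(object) {
  cat("SimulatedStudy\n")
  cat("  liver:", nrow(object@liver), "genes x", ncol(object@liver),
      "samples\n")
  cat("  aorta:", nrow(object@aorta), "genes x", ncol(object@aorta),
      "samples\n")
  show(object@truth)
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory %s/%s: %d genes over weeks %s\n", object@tissue,
              object@diet, length(object@geneIds),
              paste(object@times, collapse = ",")))
})

setMethod("show", "VimMatrix", function(object) {
  cat("VimMatrix:", nrow(object@vim), "sources x", ncol(object@vim),
      "targets (nTrees =", object@nTrees, ", seed =", object@seed,
      ", alpha =", object@alphaMode, ")\n")
})

setMethod("show", "CrossTissueNetwork", function(object) {
  cat("CrossTissueNetwork [", object@label, "]: ", nrow(object@edges),
      " edges, ", nrow(object@nodes), " nodes\n", sep = "")
})

## ---- accessors ----------------------------------------------------------

#' @describeIn VimMatrix-class the raw source x target importance matrix
#' @param object a `VimMatrix`, `SimulationTruth`, `SimulatedStudy`,
#'   `CrossTissueNetwork` or `GeneSetCollection`.
#' @export
vimValues <- function(object) {
  stopifnot(is(object, "VimMatrix"))
  object@vim
}

#' @describeIn SimulationTruth-class planted 0/1 adjacency (source x target)
#' @export
adjacency <- function(object) {
  stopifnot(is(object, "SimulationTruth"))
  object@adjacency
}

#' @describeIn SimulationTruth-class per-target decay rates
#' @export
decayRates <- function(object) {
  stopifnot(is(object, "SimulationTruth"))
  object@decayAlpha
}

#' @describeIn SimulatedStudy-class planted ground truth
#' @export
studyTruth <- function(object) {
  stopifnot(is(object, "SimulatedStudy"))
  object@truth
}

#' @describeIn SimulatedStudy-class liver [SummarizedExperiment]
#' @export
liverData <- function(object) {
  stopifnot(is(object, "SimulatedStudy"))
  object@liver
}

#' @describeIn SimulatedStudy-class aorta [SummarizedExperiment]
#' @export
aortaData <- function(object) {
  stopifnot(is(object, "SimulatedStudy"))
  object@aorta
}

#' @describeIn SimulatedStudy-class generator-assigned gene sets
#' @export
studyGeneSets <- function(object) {
  stopifnot(is(object, "SimulatedStudy"))
  object@geneSets
}

#' @describeIn SimulatedStudy-class per-animal phenotype table
#' @export
studyPhenotype <- function(object) {
  stopifnot(is(object, "SimulatedStudy"))
  object@phenotype
}

#' @describeIn GeneSetCollection-class set names
#' @export
geneSetNames <- function(object) {
  stopifnot(is(object, "GeneSetCollection"))
  names(object@sets)
}

#' @describeIn GeneSetCollection-class list of per-set records
#' @export
geneSets <- function(object) {
  stopifnot(is(object, "GeneSetCollection"))
  object@sets
}

#' @describeIn CrossTissueNetwork-class edge table
#' @export
networkEdges <- function(object) {
  stopifnot(is(object, "CrossTissueNetwork"))
  object@edges
}

#' @describeIn CrossTissueNetwork-class node annotation table
#' @export
networkNodes <- function(object) {
  stopifnot(is(object, "CrossTissueNetwork"))
  object@nodes
}
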