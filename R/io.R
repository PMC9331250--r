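#' Read a sample sheet
#'
#' Reads the tab-separated sample sheet describing every sequenced sample:
#' columns `sample_id`, `animal_id`, `tissue` (`liver`/`aorta`), `diet`
#' (`chow`/`HFD`) and `time_weeks` (positive integer sacrifice week).
#'
#' @param path path to a TSV file.
#' @return data.frame with the five validated columns.
#' @export
readSampleSheet <- function(path) {
  df <- .readTsv(path)
  need <- c("sample_id", "animal_id", "tissue", "diet", "time_weeks")
  if (!all(need %in% colnames(df)))
    .err("malformed_sheet", "sample sheet must have columns: %s",
         paste(need, collapse = ", "))
  validateSampleSheet(df[, need])
}

#' Validate a sample sheet data.frame
#'
#' @param sheet data.frame with sample-sheet columns.
#' @return the validated sheet (invisibly unchanged).
#' @export
validateSampleSheet <- function(sheet) {
  if (anyDuplicated(sheet$sample_id))
    .err("duplicate_samples", "sample ids must be unique")
  if (!all(sheet$tissue %in% c("liver", "aorta")))
    .err("malformed_sheet", "tissue must be 'liver' or 'aorta'")
  if (!all(sheet$diet %in% c("chow", "HFD")))
    .err("malformed_sheet", "diet must be 'chow' or 'HFD'")
  tw <- sheet$time_weeks
  if (any(is.na(tw)) || any(tw <= 0) || any(tw != round(tw)))
    .err("malformed_sheet", "time_weeks must be positive integers")
  sheet$time_weeks <- as.integer(sheet$time_weeks)
  sheet
}

#' Read a gene-level count matrix against a sample sheet
#'
#' Reads a tab-separated counts file (first column gene ids, header row
#' sample ids, integer cells) and returns a validated
#' [SummarizedExperiment] whose `colData` is the matching rows of the
#' sample sheet. Samples absent from the sheet are an error, as are
#' negative, non-integer or duplicated-gene entries; each failure raises a
#' distinct condition class (`crossGRN_missing_file`,
#' `crossGRN_negative_counts`, `crossGRN_noninteger_counts`,
#' `crossGRN_duplicate_genes`, `crossGRN_sample_mismatch`).
#'
#' @param path path to the counts TSV.
#' @param sheet sample sheet data.frame (see [readSampleSheet()]).
#' @return [SummarizedExperiment] with assay `counts`.
#' @export
readCountMatrix <- function(path, sheet) {
  if (!file.exists(path)) .err("missing_file", "file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) .err("noninteger_counts", "counts contain non-numeric cells")
  if (any(m < 0)) .err("negative_counts", "counts contain negative entries")
  if (any(m != round(m)))
    .err("noninteger_counts", "counts contain non-integer entries")
  if (anyDuplicated(genes))
    .err("duplicate_genes", "duplicate gene ids: %s",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  missing <- setdiff(colnames(m), sheet$sample_id)
  if (length(missing))
    .err("sample_mismatch", "samples absent from sheet: %s",
         paste(missing, collapse = ", "))
  rownames(m) <- genes
  cd <- sheet[match(colnames(m), sheet$sample_id), , drop = FALSE]
  rownames(cd) <- cd$sample_id
  SummarizedExperiment(assays = list(counts = m),
                       colData = S4Vectors::DataFrame(cd))
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member genes. The description field may carry `category=<c>` (one
#' of lipid/inflammation/fibrosis/other; default `other`) and
#' `dir:<GENE>=<+1|-1>` tokens annotating each gene's expected regulation
#' direction, separated by spaces.
#'
#' @param path path to a `.gmt` file.
#' @return [GeneSetCollection-class].
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) .err("missing_file", "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) .err("empty_collection", "GMT file has no sets")
  sets <- lapply(lines, .parseGmtLine)
  names(sets) <- vapply(sets, function(x) x$name, character(1))
  new("GeneSetCollection", sets = sets)
}

.parseGmtLine <- function(line) {
  fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(fields) < 3L)
    .err("malformed_gmt", "GMT line with no genes: %s", substr(line, 1, 60))
  name <- fields[1]
  genes <- fields[-(1:2)]
  genes <- genes[nzchar(genes)]
  if (!length(genes))
    .err("malformed_gmt", "GMT set '%s' has zero genes", name)
  category <- "other"
  direction <- numeric(0)
  for (tok in strsplit(trimws(fields[2]), "\\s+")[[1]]) {
    if (grepl("^category=", tok)) {
      category <- sub("^category=", "", tok)
      if (!category %in% .validCategories)
        .err("malformed_gmt", "set '%s': unknown category '%s'",
             name, category)
    } else if (grepl("^dir:", tok)) {
      kv <- strsplit(sub("^dir:", "", tok), "=", fixed = TRUE)[[1]]
      if (length(kv) != 2L || !kv[2] %in% c("1", "+1", "-1"))
        .err("malformed_gmt", "set '%s': bad direction token '%s'", name, tok)
      direction[kv[1]] <- as.numeric(kv[2])
    }
  }
  if (length(direction) && !all(names(direction) %in% genes))
    .err("malformed_gmt", "set '%s': direction for non-member gene", name)
  list(name = name, category = category, genes = genes,
       direction = direction)
}

#' Write a gene set collection to GMT
#'
#' @param sets [GeneSetCollection-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeGmt <- function(sets, path) {
  lines <- vapply(geneSets(sets), function(x) {
    desc <- paste0("category=", x$category)
    if (length(x$direction))
      desc <- paste(c(desc, sprintf("dir:%s=%d", names(x$direction),
                                    as.integer(x$direction))),
                    collapse = " ")
    paste(c(x$name, desc, x$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-animal phenotype table
#'
#' Expects columns `animal_id`, `diet`, `time_weeks` plus measured
#' variables (body_weight, glucose, insulin, steatosis, inflammation,
#' fibrosis, lesion_area). Measured values must be non-negative and
#' percentage variables at most 100.
#'
#' @param path path to a TSV file.
#' @return validated data.frame.
#' @export
readPhenotypeTable <- function(path) {
  df <- .readTsv(path)
  need <- c("animal_id", "diet", "time_weeks")
  if (!all(need %in% colnames(df)))
    .err("malformed_phenotype", "phenotype table needs columns: %s",
         paste(need, collapse = ", "))
  vars <- setdiff(colnames(df), need)
  for (v in vars) {
    x <- df[[v]]
    if (is.numeric(x) && any(x < 0, na.rm = TRUE))
      .err("malformed_phenotype", "negative values in '%s'", v)
  }
  for (v in intersect(c("steatosis", "fibrosis"), vars))
    if (any(df[[v]] > 100, na.rm = TRUE))
      .err("malformed_phenotype", "'%s' is a percentage and must be <= 100", v)
  df
}

#' Write a simulated study to a directory of plain-text files
#'
#' Emits the same formats the readers consume: per-tissue counts TSVs, a
#' sample sheet, the phenotype table, the generator's GMT, and truth tables
#' (adjacency, signed weights, decay rates).
#'
#' @param study [SimulatedStudy-class].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(liver = file.path(dir, "liver_counts.tsv"),
         aorta = file.path(dir, "aorta_counts.tsv"),
         sheet = file.path(dir, "sample_sheet.tsv"),
         phenotype = file.path(dir, "phenotypes.tsv"),
         gmt = file.path(dir, "gene_sets.gmt"),
         adjacency = file.path(dir, "truth_adjacency.tsv"),
         alpha = file.path(dir, "truth_alpha.tsv"))
  .writeMatrixTsv(assay(liverData(study), "counts"), p[["liver"]])
  .writeMatrixTsv(assay(aortaData(study), "counts"), p[["aorta"]])
  sheet <- rbind(as.data.frame(colData(liverData(study))),
                 as.data.frame(colData(aortaData(study))))
  .writeTsv(sheet, p[["sheet"]])
  .writeTsv(studyPhenotype(study), p[["phenotype"]])
  writeGmt(studyGeneSets(study), p[["gmt"]])
  tr <- studyTruth(study)
  .writeMatrixTsv(tr@adjacency * tr@effectSign * tr@effectWeight,
                  p[["adjacency"]], id_col = "source_gene")
  .writeTsv(data.frame(target_gene = tr@targetGenes, alpha = tr@decayAlpha),
            p[["alpha"]])
  invisible(p)
}
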