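#' Read and validate a pipeline configuration
#'
#' YAML configuration with the analysis thresholds as explicit, overridable
#' values (defaults are the study's conventions): `deg_p` (0.01),
#' `enrich_p` (0.01), `top_cutoff` (5), `vim_percentile` (99), `fc_cutoff`
#' (0.4), `n_trees` (1000), `alpha_mode` (`"from_data"`), `seed`, `out_dir`,
#' and either a `simulate:` block (arguments of [simulateStudy()]) or an
#' `inputs:` block with file paths (`liver_counts`, `aorta_counts`,
#' `sample_sheet`, `gmt`, `phenotypes`, optionally `deg2_table`).
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @return validated configuration list with defaults filled in.
#' @export
readConfig <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  defaults <- list(deg_p = 0.01, enrich_p = 0.01, top_cutoff = 5,
                   vim_percentile = 99, fc_cutoff = 0.4, n_trees = 1000,
                   alpha_mode = "from_data", seed = 1,
                   out_dir = "crossgrn_out", simulate = list())
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  if (cfg$vim_percentile < 0 || cfg$vim_percentile >= 100)
    .err("bad_config", "vim_percentile must be in [0, 100)")
  for (k in c("deg_p", "enrich_p"))
    if (cfg[[k]] <= 0 || cfg[[k]] >= 1)
      .err("bad_config", "%s must be in (0, 1)", k)
  if (cfg$fc_cutoff < 0) .err("bad_config", "fc_cutoff must be >= 0")
  if (cfg$n_trees < 1) .err("bad_config", "n_trees must be >= 1")
  cfg
}

#' Run the cross-tissue analysis pipeline
#'
#' Chains the stages `simulate` (or load inputs), `deg`, `enrich`, `grn`,
#' `network`, `validate`, writing every artifact as TSV under
#' `cfg$out_dir` together with a plain-text run log recording all
#' thresholds and the seed. Any stage failure aborts with a stage-labelled
#' error. Two runs with the same configuration and seed produce
#' byte-identical artifacts.
#'
#' The `grn`/`network` stages run the two analyses of the study design —
#' liver lipid/fibrosis-pathway genes as sources, and liver
#' inflammation-pathway genes as sources — against the aorta target genes,
#' and overlay them at report time.
#'
#' @param config path to a YAML config or a list (see [readConfig()]).
#' @param stages which stages to run, in pipeline order; later stages pull
#'   in the earlier ones they depend on.
#' @return invisibly, a list with the in-memory artifacts (`study`,
#'   `deg`, `enrichment`, `dynamics`, `vim`, `networks`, `concordance`)
#'   and `files` (paths written).
#' @export
runPipeline <- function(config,
                        stages = c("simulate", "deg", "enrich", "grn",
                                   "network", "validate")) {
  cfg <- readConfig(config)
  order <- c("simulate", "deg", "enrich", "grn", "network", "validate")
  stages <- order[order %in% order[seq_len(max(match(stages, order)))]]
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  logLines <- c("crossGRN pipeline run",
                sprintf("seed: %s", cfg$seed),
                sprintf("deg_p: %s; enrich_p: %s; top_cutoff: %s",
                        cfg$deg_p, cfg$enrich_p, cfg$top_cutoff),
                sprintf("vim_percentile: %s; fc_cutoff: %s; n_trees: %s; alpha_mode: %s",
                        cfg$vim_percentile, cfg$fc_cutoff, cfg$n_trees,
                        cfg$alpha_mode),
                sprintf("stages: %s", paste(stages, collapse = ",")))
  res <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  ## ---- inputs ------------------------------------------------------------
  simulated <- is.null(cfg$inputs)
  res$study <- stage("simulate", {
    if (simulated) {
      do.call(simulateStudy, c(cfg$simulate, list(seed = cfg$seed)))
    } else {
      sheet <- readSampleSheet(cfg$inputs$sample_sheet)
      list(liver = readCountMatrix(cfg$inputs$liver_counts, sheet),
           aorta = readCountMatrix(cfg$inputs$aorta_counts, sheet),
           geneSets = readGmt(cfg$inputs$gmt),
           phenotype = readPhenotypeTable(cfg$inputs$phenotypes))
    }
  })
  liver <- if (simulated) liverData(res$study) else res$study$liver
  aorta <- if (simulated) aortaData(res$study) else res$study$aorta
  sets <- if (simulated) studyGeneSets(res$study) else res$study$geneSets
  pheno <- if (simulated) studyPhenotype(res$study) else res$study$phenotype
  if (simulated && "simulate" %in% stages)
    files <- c(files, writeStudy(res$study, file.path(cfg$out_dir, "study")))

  ## phenotype statistics always accompany the study; HOMA-IR is derived
  ## from insulin and glucose before testing
  if (all(c("insulin", "glucose") %in% colnames(pheno)))
    pheno$homa_ir <- homaIr(pheno$insulin, pheno$glucose)
  res$phenotype_stats <- phenotypeStats(pheno)
  f <- file.path(cfg$out_dir, "phenotype_stats.tsv")
  .writeTsv(res$phenotype_stats, f); files <- c(files, f)

  if (!any(c("deg", "enrich", "grn", "network", "validate") %in% stages)) {
    writeLines(logLines, file.path(cfg$out_dir, "run_log.txt"))
    return(invisible(c(res, list(files = files))))
  }

  ## ---- differential expression -------------------------------------------
  res$deg <- stage("deg", rbind(degAll(liver, cfg$deg_p),
                                degAll(aorta, cfg$deg_p)))
  f <- file.path(cfg$out_dir, "deg_table.tsv")
  .writeTsv(res$deg, f); files <- c(files, f)

  ## ---- enrichment --------------------------------------------------------
  if (any(c("enrich", "grn", "network", "validate") %in% stages)) {
    res$enrichment <- stage("enrich", enrichAll(res$deg, sets,
                                                enrichP = cfg$enrich_p))
    res$dynamics <- processDynamics(res$enrichment, cfg$top_cutoff)
    f1 <- file.path(cfg$out_dir, "enrichment.tsv")
    f2 <- file.path(cfg$out_dir, "process_dynamics.tsv")
    .writeTsv(res$enrichment, f1); .writeTsv(res$dynamics, f2)
    files <- c(files, f1, f2)
  }

  ## ---- network inference + selection -------------------------------------
  if (any(c("grn", "network", "validate") %in% stages)) {
    analyses <- list(lipid_fibrosis = c("lipid", "fibrosis"),
                     inflammation = "inflammation")
    liverTrajAll <- stage("grn", buildTrajectories(liver))
    aortaTrajAll <- stage("grn", buildTrajectories(aorta))
    aortaTrajMean <- stage("grn", buildTrajectories(aorta,
                                                    collapse = "mean"))
    degLiver <- res$deg[res$deg$tissue == "liver" & res$deg$significant, ]
    degAorta <- res$deg[res$deg$tissue == "aorta" & res$deg$significant, ]
    setsByCat <- function(cats) {
      unique(unlist(lapply(geneSets(sets), function(s)
        if (s$category %in% cats) s$genes else character(0))))
    }
    targets <- intersect(unique(degAorta$gene),
                         intersect(unlist(lapply(geneSets(sets),
                                                 `[[`, "genes")),
                                   rownames(aorta)))
    if (!length(targets)) targets <- unique(degAorta$gene)
    res$vim <- list(); res$networks <- list()
    edgeTables <- list()
    for (an in names(analyses)) {
      sources <- intersect(unique(degLiver$gene),
                           intersect(setsByCat(analyses[[an]]),
                                     rownames(liver)))
      if (length(sources) < 2 || length(targets) < 1) {
        logLines <- c(logLines, sprintf(
          "analysis %s skipped: %d source / %d target genes", an,
          length(sources), length(targets)))
        next
      }
      sTr <- lapply(liverTrajAll, .subsetTrajectory, genes = sources)
      tTr <- lapply(aortaTrajAll, .subsetTrajectory, genes = targets)
      # decay rates come from the low-noise replicate-mean trajectories
      alphas <- stage("grn", .alphasFromMode(
        lapply(aortaTrajMean, .subsetTrajectory, genes = targets),
        targets, cfg$alpha_mode))
      vim <- stage("grn", inferVim(sTr, tTr, alphas,
                                   nTrees = cfg$n_trees, seed = cfg$seed,
                                   alphaMode = cfg$alpha_mode))
      res$vim[[an]] <- vim
      f <- file.path(cfg$out_dir, sprintf("vim_%s.tsv", an))
      .writeMatrixTsv(vimValues(vim), f, id_col = "source_gene")
      fm <- file.path(cfg$out_dir, sprintf("vim_%s_meta.tsv", an))
      .writeTsv(data.frame(n_trees = vim@nTrees, seed = vim@seed,
                           alpha_mode = vim@alphaMode), fm)
      files <- c(files, f, fm)
      if (any(c("network", "validate") %in% stages)) {
        edges <- stage("network", selectEdges(vim, cfg$vim_percentile))
        net <- stage("network", assembleNetwork(edges, sets, an))
        # liver-to-aorta direction filter, guaranteed by construction
        stopifnot(all(edges$source %in% rownames(liver)),
                  all(edges$target %in% rownames(aorta)))
        res$networks[[an]] <- net
        edgeTables[[an]] <- cbind(analysis = an, edges)
        fe <- file.path(cfg$out_dir, sprintf("edges_%s.tsv", an))
        fn <- file.path(cfg$out_dir, sprintf("network_nodes_%s.tsv", an))
        .writeTsv(edges, fe); .writeTsv(networkNodes(net), fn)
        files <- c(files, fe, fn)
      }
    }
    if (length(edgeTables)) {
      f <- file.path(cfg$out_dir, "edges_all.tsv")
      .writeTsv(do.call(rbind, edgeTables), f); files <- c(files, f)
    }
  }

  ## ---- cross-study validation --------------------------------------------
  if ("validate" %in% stages && length(res$networks)) {
    res$concordance <- stage("validate", {
      regGenes <- unique(unlist(lapply(res$networks, function(n)
        networkEdges(n)$source)))
      lastWeek <- max(res$deg$time_weeks)
      d1 <- res$deg[res$deg$tissue == "liver" &
                      res$deg$time_weeks == lastWeek, ]
      regs <- data.frame(gene = regGenes,
                         direction = ifelse(
                           d1$log2fc[match(regGenes, d1$gene)] > 0,
                           "up", "down"),
                         stringsAsFactors = FALSE)
      deg2 <- if (simulated) {
        st2 <- simulateStudy(truth = studyTruth(res$study),
                             seed = .stageSeed(cfg$seed, "simulate2"))
        d2 <- degAll(liverData(st2), cfg$deg_p)
        d2[d2$time_weeks == max(d2$time_weeks), ]
      } else if (!is.null(cfg$inputs$deg2_table)) {
        .readTsv(cfg$inputs$deg2_table)
      } else {
        .err("missing_file",
             "validate stage needs inputs$deg2_table for real data")
      }
      concordance(regs, deg2, cfg$fc_cutoff)
    })
    f <- file.path(cfg$out_dir, "concordance.tsv")
    .writeTsv(res$concordance$table, f); files <- c(files, f)
    logLines <- c(logLines, sprintf(
      "concordance: %d concordant, %d discordant, %d not_de",
      res$concordance$summary$n_concordant,
      res$concordance$summary$n_discordant,
      res$concordance$summary$n_not_de))
  }

  writeLines(logLines, file.path(cfg$out_dir, "run_log.txt"))
  files <- c(files, file.path(cfg$out_dir, "run_log.txt"))
  invisible(c(res, list(files = files)))
}

.subsetTrajectory <- function(traj, genes) {
  new("Trajectory", tissue = traj@tissue, diet = traj@diet,
      geneIds = genes, times = traj@times,
      values = traj@values[genes, , drop = FALSE])
}

.alphasFromMode <- function(targetTrajs, genes, mode) {
  if (grepl("^fixed:", mode)) {
    val <- as.numeric(sub("^fixed:", "", mode))
    return(stats::setNames(rep(val, length(genes)), genes))
  }
  # trajectories store log1p expression; decay is read off the
  # expression scale
  estimateDecayRates(targetTrajs, genes, mode = mode,
                     scale = "expression")
}
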