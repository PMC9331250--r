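#' Simulate a two-tissue cross-sectional time-course study
#'
#' Generates liver (source) and aorta (target) count matrices over a set of
#' sacrifice timepoints with a planted bipartite liver-to-aorta regulatory
#' network, emulating a cross-sectional design in which a fresh group of
#' animals (default 6 chow, 15 high-fat diet) is sacrificed at every
#' timepoint and both tissues are profiled from the same animals.
#'
#' Source genes follow diet-dependent latent log-expression trajectories:
#' flat at a gene-specific baseline plus per-timepoint latent fluctuation
#' (`latentSd`) on chow, and additionally shifted on HFD by a
#' gene-specific, monotone ramp reaching `dietEffect` at the final
#' timepoint. The latent fluctuation models cohort-level biological
#' variation between sacrifice groups; because targets integrate the
#' actual source trajectories (fluctuation included) through the decay
#' model, it is also what renders regulator recovery identifiable from
#' few timepoints. Target genes obey the first-order decay model the
#' inference stage assumes, stepped on the trajectory grid:
#' \deqn{x_j(t_{k+1}) = x_j(t_k) + \Delta t\,(-\alpha_j x_j(t_k) +
#'   \sum_i w_{ij} s_{ij} x_i(t_k))}
#' with per-target decay rate \eqn{\alpha_j}, planted weights \eqn{w} and
#' signs \eqn{s}. Background genes in both tissues are flat and carry no
#' cross-tissue dependence.
#'
#' On top of the cohort trajectory, each animal carries its own
#' regulator-state deviation (`animalSd`): animal `a`'s liver source gene
#' `i` sits at `x_i(t) + delta_ia`, and because the two tissues come from
#' the same animal, its aorta targets reflect its own regulator deviations
#' through the quasi-static gain of the decay model,
#' `sum_i w_ij s_ij delta_ia / alpha_j`. This inter-individual biological
#' variation is what makes the replicate animals of a cross-sectional
#' design informative for cross-tissue network inference rather than
#' redundant draws.
#'
#' Per-animal counts are negative-binomial draws around `exp(latent)` with
#' variance \eqn{\mu + \phi\mu^2}; `dispersion = 0` gives the
#' deterministic noise-free limit (`round(exp(latent))`).
#'
#' @param nSource,nTarget numbers of planted liver source and aorta target
#'   genes.
#' @param nBackground independent background genes added to each tissue
#'   (default 120, keeping planted genes a minority of the panel so that
#'   median-of-ratios normalization retains its mostly-not-DE
#'   assumption).
#' @param edgesPerTarget planted regulators per target (<= `nSource`).
#' @param timepoints sacrifice weeks, strictly increasing, length >= 3.
#' @param nChow,nHFD animals per diet per timepoint (>= 2).
#' @param dispersion NB dispersion \eqn{\phi} (>= 0; 0 = noise-free limit).
#' @param latentSd sd (natural-log scale) of the per-(gene, diet,
#'   timepoint) latent fluctuation of source genes (default 0.45; 0 gives
#'   perfectly smooth source trajectories). Background genes never carry
#'   it, so they remain exact NB nulls.
#' @param animalSd sd (natural-log scale) of each animal's persistent
#'   regulator-state deviation, transmitted within the animal from liver
#'   sources to aorta targets (default 0.45; 0 makes replicate animals
#'   exchangeable NB draws). Background genes never carry it.
#' @param seed integer seed; the same seed reproduces the study exactly.
#' @param truth optional [SimulationTruth-class] to reuse (same planted
#'   structure, fresh noise) — used to emulate an independent validation
#'   study of the same biology.
#' @param saturating if `TRUE`, source effects enter through a saturating
#'   `8 * tanh(x/8)` transfer instead of linearly (model-mismatch option).
#' @param sharedAnimalSd sd of an optional per-animal log-scale offset
#'   shared by both tissues (default 0: tissues independent given the
#'   latent trajectory).
#'
#' @return [SimulatedStudy-class]
#' @examples
#' st <- simulateStudy(nSource = 5, nTarget = 4, nBackground = 6,
#'                     edgesPerTarget = 2, seed = 1)
#' st
#' @export
simulateStudy <- function(nSource = 50, nTarget = 20, nBackground = 120,
                          edgesPerTarget = 5,
                          timepoints = c(6L, 12L, 18L, 24L),
                          nChow = 6, nHFD = 15, dispersion = 0.1,
                          latentSd = 0.45, animalSd = 0.45, seed = 1,
                          truth = NULL, saturating = FALSE,
                          sharedAnimalSd = 0) {
  if (length(timepoints) < 3L)
    .err("bad_design", "need >= 3 timepoints")
  if (any(diff(timepoints) <= 0))
    .err("bad_design", "timepoints must be strictly increasing")
  if (nChow < 2 || nHFD < 2)
    .err("bad_design", "need >= 2 replicates per (diet, time) cell")
  if (dispersion < 0)
    .err("bad_dispersion", "dispersion must be non-negative")
  if (is.null(truth) && edgesPerTarget > nSource)
    .err("bad_design", "edgesPerTarget cannot exceed nSource")

  set.seed(.stageSeed(seed, "simulate"))
  K <- length(timepoints)

  if (is.null(truth)) {
    truth <- .plantTruth(nSource, nTarget, edgesPerTarget, seed)
  } else {
    stopifnot(is(truth, "SimulationTruth"))
    nSource <- length(truth@sourceGenes)
    nTarget <- length(truth@targetGenes)
  }
  src <- truth@sourceGenes
  tgt <- truth@targetGenes

  ## -- latent source trajectories (genes x times), per diet ----------------
  base <- stats::runif(nSource, 2.5, 5.5)
  # gene-specific monotone ramp: large first increment so the HFD response
  # is already well underway at the first sacrifice, then gene-specific
  # curvature; ramp hits 1 at the final timepoint
  inc <- cbind(stats::runif(nSource, 1.5, 2.5),
               matrix(stats::runif(nSource * (K - 1), 0, 1), nSource))
  ramp <- t(apply(inc, 1, cumsum)) / rowSums(inc)
  eta <- function() matrix(stats::rnorm(nSource * K, 0, latentSd),
                           nSource, K)
  xs_chow <- matrix(base, nSource, K) + eta()
  xs_hfd <- matrix(base, nSource, K) + truth@dietEffect * ramp + eta()
  rownames(xs_chow) <- rownames(xs_hfd) <- src

  ## -- latent target trajectories via the decay model ----------------------
  w <- truth@effectWeight * truth@effectSign
  sat <- function(x) if (saturating) 8 * tanh(x / 8) else x
  stepTargets <- function(xs) {
    xt <- matrix(0, nTarget, K, dimnames = list(tgt, NULL))
    drive <- crossprod(w, sat(xs))          # target x time
    xt[, 1] <- drive[, 1] / truth@decayAlpha # start at equilibrium
    for (k in seq_len(K - 1)) {
      dt <- timepoints[k + 1] - timepoints[k]
      xt[, k + 1] <- xt[, k] +
        dt * (-truth@decayAlpha * xt[, k] + drive[, k])
    }
    xt
  }
  xt_chow <- stepTargets(xs_chow)
  xt_hfd <- stepTargets(xs_hfd)

  ## -- background genes: flat, diet-independent ----------------------------
  bgLiver <- stats::runif(nBackground, 3.5, 6.5)
  bgAorta <- stats::runif(nBackground, 3.5, 6.5)
  bgl_id <- if (nBackground) sprintf("L_BG%03d", seq_len(nBackground)) else character(0)
  bga_id <- if (nBackground) sprintf("A_BG%03d", seq_len(nBackground)) else character(0)

  ## -- design / animals ----------------------------------------------------
  design <- expand.grid(rep = seq_len(nChow + nHFD), time_weeks = timepoints,
                        KEEP.OUT.ATTRS = FALSE)
  design$diet <- ifelse(design$rep <= nChow, "chow", "HFD")
  design$animal_id <- sprintf("%s_t%02d_%02d", design$diet,
                              design$time_weeks, design$rep)
  animalOffset <- stats::rnorm(nrow(design), 0, sharedAnimalSd)
  # per-animal regulator-state deviations and their within-animal
  # quasi-static imprint on that animal's targets
  deltaSrc <- matrix(stats::rnorm(nSource * nrow(design), 0, animalSd),
                     nSource, nrow(design))
  deltaTgt <- crossprod(w, deltaSrc) / truth@decayAlpha

  drawTissue <- function(tissue, latentPlanted_chow, latentPlanted_hfd,
                         bgBase, bgIds, delta) {
    genes <- c(rownames(latentPlanted_chow), bgIds)
    # numeric storage with integral values: extreme latents can exceed
    # the 32-bit integer range
    m <- matrix(0, length(genes), nrow(design),
                dimnames = list(genes, NULL))
    sampleIds <- sprintf("%s_%s", tissue, design$animal_id)
    colnames(m) <- sampleIds
    for (s in seq_len(nrow(design))) {
      k <- match(design$time_weeks[s], timepoints)
      lat <- if (design$diet[s] == "chow") latentPlanted_chow[, k]
             else latentPlanted_hfd[, k]
      lat <- c(lat + delta[, s], bgBase) + animalOffset[s]
      mu <- exp(lat)
      m[, s] <- if (dispersion == 0) round(mu)
                else stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    }
    cd <- S4Vectors::DataFrame(sample_id = sampleIds,
                               animal_id = design$animal_id,
                               tissue = tissue, diet = design$diet,
                               time_weeks = as.integer(design$time_weeks),
                               row.names = sampleIds)
    SummarizedExperiment(assays = list(counts = m), colData = cd)
  }
  liver <- drawTissue("liver", xs_chow, xs_hfd, bgLiver, bgl_id, deltaSrc)
  aorta <- drawTissue("aorta", xt_chow, xt_hfd, bgAorta, bga_id, deltaTgt)

  pheno <- .simulatePhenotypes(design)
  sets <- .simulatedGeneSets(truth, bgl_id, bga_id)

  new("SimulatedStudy", liver = liver, aorta = aorta, phenotype = pheno,
      geneSets = sets, truth = truth)
}

# Planted structure: adjacency with a fixed number of regulators per
# target, mostly-activating signed weights scaled by the target's decay
# rate (coupling gain 4 keeps the per-edge fluctuation signal above the
# count-noise floor while equilibria stay at expressed log levels), and
# diet-effect shifts of either sign for the sources.
.plantTruth <- function(nSource, nTarget, edgesPerTarget, seed) {
  src <- sprintf("L_SRC%03d", seq_len(nSource))
  tgt <- sprintf("A_TGT%03d", seq_len(nTarget))
  adj <- sgn <- wt <- matrix(0, nSource, nTarget,
                             dimnames = list(src, tgt))
  alpha <- stats::runif(nTarget, 0.1, 0.3)
  names(alpha) <- tgt
  for (j in seq_len(nTarget)) {
    reg <- sample.int(nSource, edgesPerTarget)
    adj[reg, j] <- 1
    sgn[reg, j] <- sample(c(1, -1), edgesPerTarget, replace = TRUE,
                          prob = c(0.75, 0.25))
    wt[reg, j] <- stats::runif(edgesPerTarget, 0.5, 1.5) *
      4 * alpha[j] / edgesPerTarget
  }
  dietEffect <- sample(c(1, -1), nSource, replace = TRUE) *
    stats::runif(nSource, 2.5, 3.5)
  names(dietEffect) <- src
  new("SimulationTruth", sourceGenes = src, targetGenes = tgt,
      adjacency = adj, effectSign = sgn, effectWeight = wt,
      decayAlpha = alpha, dietEffect = dietEffect,
      seed = as.integer(seed))
}

# Phenotypes drawn around published magnitudes for this disease model:
# obesity, hyperinsulinemia with stable glucose, early steatosis, late
# inflammation/fibrosis, and a lesion area that grows quadratically with
# steatosis.
.simulatePhenotypes <- function(design) {
  t <- design$time_weeks
  hfd <- design$diet == "HFD"
  n <- nrow(design)
  bw <- ifelse(hfd, 33 + 0.78 * t, 30 + 0.28 * t) + stats::rnorm(n, 0, 2.5)
  glucose <- pmax(stats::rnorm(n, ifelse(hfd, 6.9, 6.7), 0.7), 0.1)
  insulin <- pmax(ifelse(hfd, 2 + 0.78 * t, 2) *
                    exp(stats::rnorm(n, 0, 0.25)), 0.05)
  steat <- pmin(pmax(ifelse(hfd, 60 * sqrt(t / 24), 0.3) +
                       stats::rnorm(n, 0, ifelse(hfd, 8, 0.3)), 0), 100)
  inflam <- pmax(ifelse(hfd, 1.5 + 0.44 * t, 1.5) + stats::rnorm(n, 0, 1.5), 0)
  fibro <- pmin(pmax(ifelse(hfd, pmax(0.42 * (t - 12), 0), 0) +
                       stats::rnorm(n, 0, 1), 0), 100)
  lesion <- pmax(15 + 1.5 * steat + 0.045 * steat^2 +
                   stats::rnorm(n, 0, 25), 0)
  data.frame(animal_id = design$animal_id, diet = design$diet,
             time_weeks = as.integer(t), body_weight = bw,
             glucose = glucose, insulin = insulin, steatosis = steat,
             inflammation = inflam, fibrosis = fibro,
             lesion_area = lesion, stringsAsFactors = FALSE)
}

# Generator-assigned pathway membership: liver sources split round-robin
# over the three disease processes (with expected directions from the diet
# effect), aorta targets over inflammation/lipid sets; a slice of
# background genes is mixed into each set so enrichment has non-members.
.simulatedGeneSets <- function(truth, bgLiver, bgAorta) {
  src <- truth@sourceGenes
  tgt <- truth@targetGenes
  cat3 <- c("lipid", "inflammation", "fibrosis")
  sets <- list()
  for (i in 1:3) {
    members <- src[seq_along(src) %% 3 == (i - 1)]
    if (!length(members)) next
    bg <- bgLiver[seq_along(bgLiver) %% 3 == (i - 1)]
    bg <- bg[seq_len(min(3, length(bg)))]
    dirn <- sign(truth@dietEffect[members])
    sets[[paste0("liver_", cat3[i])]] <- list(
      name = paste0("liver_", cat3[i]), category = cat3[i],
      genes = c(members, bg), direction = dirn)
  }
  for (i in 1:2) {
    members <- tgt[seq_along(tgt) %% 2 == (i - 1)]
    if (!length(members)) next
    bg <- bgAorta[seq_along(bgAorta) %% 2 == (i - 1)]
    bg <- bg[seq_len(min(3, length(bg)))]
    nm <- paste0("aorta_", c("inflammation", "lipid")[i])
    sets[[nm]] <- list(name = nm,
                       category = c("inflammation", "lipid")[i],
                       genes = c(members, bg), direction = numeric(0))
  }
  new("GeneSetCollection", sets = sets)
}

#' Score recovery of the planted network from a VIM ranking
#'
#' Ranks all source-by-target pairs by importance and scores them against
#' the planted adjacency: AUROC from mid-rank tied ranks (a constant VIM
#' scores exactly 0.5) and AUPR as step-wise average precision with tied
#' scores processed as atomic groups.
#'
#' @param vim [VimMatrix-class] or a plain source x target matrix.
#' @param truth [SimulationTruth-class] over the same genes.
#' @return list with elements `auroc` and `aupr`, both in \[0, 1\].
#' @export
scoreRecovery <- function(vim, truth) {
  m <- if (is(vim, "VimMatrix")) vimValues(vim) else vim
  adj <- adjacency(truth)
  if (!setequal(rownames(m), rownames(adj)) ||
      !setequal(colnames(m), colnames(adj)))
    .err("gene_mismatch", "vim and truth must index the same genes")
  m <- m[rownames(adj), colnames(adj), drop = FALSE]
  scores <- as.vector(m)
  labels <- as.vector(adj) == 1
  nPos <- sum(labels); nNeg <- sum(!labels)
  if (nPos == 0) .err("no_edges", "truth contains no positive edges")
  r <- rank(scores, ties.method = "average")
  auroc <- (sum(r[labels]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  ## AUPR: descending score, tie groups atomic, step-wise precision
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]; sc <- scores[o]
  grp <- cumsum(!duplicated(sc))
  tpCum <- cumsum(lab)
  nCum <- seq_along(lab)
  ends <- which(!duplicated(grp, fromLast = TRUE))
  recall <- tpCum[ends] / nPos
  precision <- tpCum[ends] / nCum[ends]
  aupr <- sum(diff(c(0, recall)) * precision)
  list(auroc = auroc, aupr = aupr)
}
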