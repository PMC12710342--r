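#' Run the full analysis pipeline on a cohort
#'
#' Convenience end-to-end driver used by the worked examples and the
#' reproducibility script: relative abundance, rare-taxon filter, CLR,
#' prevalence/abundance taxa filter, technical-covariate residualisation,
#' alpha diversity with the Friedman test, beta diversity (Euclidean on
#' adjusted CLR) with the per-phase and self-vs-random procedures, the visit
#' model ladder, ICC, CST assignment with transitions, and the overall
#' hormone models.
#'
#' @param cohort a \code{\link{CycleCohort-class}}.
#' @param models ladder steps to fit (default \code{c(1, 2)}).
#' @param nPerm permutations for empirical p-values (default 0 = skip).
#' @param nRandom random replicates of the self-vs-random procedure.
#' @param seed master seed for all resampling.
#' @param centroids optional centroid matrix for CST assignment; defaults to
#'   the regime centroids of the generating config when present.
#' @param outDir optional directory; when given, every result table is also
#'   written as a TSV (deterministic byte-for-byte under a fixed seed).
#' @return list of result tables.
#' @export
runPipeline <- function(cohort, models = c(1, 2), nPerm = 0, nRandom = 10,
                        seed = 1L, centroids = NULL, outDir = NULL) {
  counts <- taxaCounts(cohort)
  design <- sampleData(cohort)
  counts <- rareTaxaFilter(counts)
  rel <- relativeAbundance(counts)
  clr <- clrTransform(rel)
  keptTaxa <- filterTaxa(rel)

  adjTech <- residualizeTaxa(clr, design, modelId = 2L)
  alpha <- alphaDiversity(counts)
  friedman <- friedmanAlpha(alpha$shannon, design)

  dEuc <- euclideanCLR(adjTech)
  phaseBeta <- perPhaseBeta(dEuc, design)
  svr <- selfVsRandom(dEuc, design, nRandom = nRandom, seed = seed)

  visitFits <- do.call(rbind, lapply(models, function(k) {
    adj <- residualizeTaxa(clr[, keptTaxa, drop = FALSE], design,
                           modelId = as.integer(k))
    fitVisitModels(adj, design, nPerm = nPerm,
                   seed = .substream(seed, "ladder", k))
  }))
  icc <- iccTaxa(adjTech[, keptTaxa, drop = FALSE], design)

  if (is.null(centroids)) {
    cfg <- S4Vectors::metadata(cohort)$config
    if (!is.null(cfg)) centroids <- generateCentroids(cfg)
  }
  cst <- NULL; transitions <- NULL
  if (!is.null(centroids)) {
    cst <- assignCST(rel, centroids)
    transitions <- cstTransitions(cst, design)
  }

  cleaned <- removeHormoneOutliers(hormoneLevels(cohort))
  overall <- fitOverallHormoneModels(
    cleaned$hormones, adjTech[, keptTaxa, drop = FALSE], design,
    nPerm = 0, seed = .substream(seed, "overall"))

  res <- list(alpha = alpha, friedman = friedman, phaseBeta = phaseBeta,
              selfVsRandom = svr, visitModels = visitFits, icc = icc,
              cst = cst, transitions = transitions, overall = overall,
              keptTaxa = keptTaxa)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(df, name) utils::write.table(
      df, file.path(outDir, name), sep = "\t", quote = FALSE,
      row.names = FALSE)
    wt(alpha, "alpha_diversity.tsv")
    wt(phaseBeta$tests, "beta_per_phase_tests.tsv")
    wt(svr$tests, "beta_self_vs_random_tests.tsv")
    wt(visitFits, "visit_models.tsv")
    wt(icc, "icc.tsv")
    if (!is.null(cst)) {
      wt(cst, "cst_assignments.tsv")
      wt(transitions$transitions, "cst_transitions.tsv")
    }
    wt(overall, "hormone_overall_models.tsv")
  }
  res
}
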