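#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

#' @rdname taxaCounts
#' @export
setGeneric("taxaCounts", function(x) standardGeneric("taxaCounts"))

#' @rdname sampleData
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' @rdname hormoneLevels
#' @export
setGeneric("hormoneLevels", function(x) standardGeneric("hormoneLevels"))

#' @rdname groundTruth
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

.HORMONES <- c("BES17", "LH", "FSH", "PROG", "PRL")
.CSTS <- c("CST-I", "CST-II", "CST-III", "CST-IV", "CST-V")

# Marker species whose dominance defines the Lactobacillus CSTs.
.CST_MARKERS <- c(
  "CST-I"   = "Lactobacillus_crispatus",
  "CST-II"  = "Lactobacillus_gasseri",
  "CST-III" = "Lactobacillus_iners",
  "CST-V"   = "Lactobacillus_jensenii"
)

#' Default taxa panel for the synthetic cohort
#'
#' Twenty-five vaginal taxa spanning the four Lactobacillus CST markers and
#' the anaerobes that define CST-IV, named with GTDB-style species labels.
#'
#' @return character vector of taxon names.
#' @export
defaultTaxaPanel <- function() {
  c("Lactobacillus_iners", "Lactobacillus_crispatus", "Lactobacillus_gasseri",
    "Lactobacillus_jensenii", "Bifidobacterium_vaginale",
    "Bifidobacterium_breve", "Prevotella_timonensis_A", "Prevotella_bivia",
    "Fannyhessea_vaginae", "Streptococcus_agalactiae",
    "Streptococcus_unclassified", "Finegoldia_magna", "Anaerococcus_tetradius",
    "Dialister_micraerophilus", "Sneathia_amnii", "Megasphaera_lornae",
    "Atopobium_spp", "Corynebacterium_spp", "Gemella_spp",
    "Mobiluncus_curtisii", "Peptoniphilus_spp", "Ureaplasma_parvum",
    "Aerococcus_christensenii", "Staphylococcus_epidermidis",
    "Veillonella_montpellierensis")
}

#' Default per-regime baseline log-abundances
#'
#' One row per community state type, one column per taxon in the panel.
#' The dominant marker of each Lactobacillus CST sits well above background so
#' that softmax of the latents yields the characteristic >60 percent dominance;
#' CST-IV spreads mass over several anaerobes with no single dominant.
#'
#' @param taxa character vector of taxon names (default \code{defaultTaxaPanel()}).
#' @return numeric matrix, regimes x taxa.
#' @export
defaultRegimeBaselines <- function(taxa = defaultTaxaPanel()) {
  b <- matrix(0, nrow = length(.CSTS), ncol = length(taxa),
              dimnames = list(.CSTS, taxa))
  set <- function(regime, taxon, value) {
    if (taxon %in% taxa) b[regime, taxon] <<- value
  }
  set("CST-I", "Lactobacillus_crispatus", 6.5)
  set("CST-I", "Lactobacillus_iners", 3.0)
  set("CST-II", "Lactobacillus_gasseri", 6.5)
  set("CST-II", "Lactobacillus_iners", 2.5)
  set("CST-III", "Lactobacillus_iners", 6.5)
  set("CST-III", "Lactobacillus_crispatus", 2.5)
  set("CST-V", "Lactobacillus_jensenii", 6.5)
  set("CST-V", "Lactobacillus_iners", 2.5)
  iv <- c(Bifidobacterium_vaginale = 4.2, Prevotella_timonensis_A = 3.8,
          Fannyhessea_vaginae = 3.4, Prevotella_bivia = 3.2,
          Finegoldia_magna = 3.0, Anaerococcus_tetradius = 2.8,
          Dialister_micraerophilus = 2.8, Sneathia_amnii = 2.6,
          Megasphaera_lornae = 2.4, Lactobacillus_iners = 2.5)
  for (t in names(iv)) set("CST-IV", t, iv[[t]])
  b
}

#' Default cyclic hormone profiles
#'
#' Per-visit population means, within-woman SD and between-woman SD for the
#' five serum hormones. 17-beta estradiol (BES17) and LH peak at the ovulatory
#' visit, progesterone peaks in the luteal visits, prolactin is flat. Units are
#' arbitrary but fixed per hormone (pg/mL-like for BES17, IU/L-like for
#' LH/FSH, ng/mL-like for PROG/PRL).
#'
#' @return named list, one element per hormone with fields \code{mean}
#'   (length 4, visits 1-4), \code{withinSD}, \code{womanSD}.
#' @export
defaultHormoneProfiles <- function() {
  list(
    BES17 = list(mean = c(60, 180, 120, 100), withinSD = 20, womanSD = 10),
    LH    = list(mean = c(8, 35, 12, 7),      withinSD = 4,  womanSD = 1.5),
    FSH   = list(mean = c(7, 9, 4, 3),        withinSD = 1.5, womanSD = 0.8),
    PROG  = list(mean = c(1.5, 2, 9, 7),      withinSD = 0.8, womanSD = 0.4),
    PRL   = list(mean = c(15, 17, 16, 15),    withinSD = 4,  womanSD = 3)
  )
}

#' Default CST regime frequencies
#'
#' Sample-level CST frequencies observed in healthy reproductive-age Italian
#' women (CST-III most common, CST-V rarest), renormalised to sum exactly to 1.
#'
#' @return named numeric vector over the five CSTs.
#' @export
defaultCstFrequencies <- function() {
  f <- c("CST-I" = 0.316, "CST-II" = 0.127, "CST-III" = 0.382,
         "CST-IV" = 0.141, "CST-V" = 0.033)
  f / sum(f)
}

#' Configuration of a synthetic menstrual-cycle cohort
#'
#' S4 container for every knob of the generator: cohort size, CST regime
#' frequencies, target intraclass correlation, library-size distribution,
#' missingness, injected visit and hormone effects, hormone trajectories and
#' the taxa panel with its per-regime baselines.
#'
#' @slot nWomen number of women followed.
#' @slot nVisits number of visits per woman (fixed at 4).
#' @slot seed master RNG seed; all substreams derive from it.
#' @slot cstFrequencies named probabilities of each CST regime (sum to 1).
#' @slot iccTarget target intraclass correlation of latent taxon abundance.
#' @slot residualSD residual SD of the latent log-abundance (sets the scale).
#' @slot librarySizeMean,librarySizeDispersion negative-binomial library sizes.
#' @slot missingRate overall expected fraction of missing (woman, visit) rows;
#'   visit 1 is never dropped.
#' @slot visitEffects data.frame (taxon, slope): linear visit-number effects on
#'   the latent (CLR-scale) abundance.
#' @slot hormoneEffects data.frame (hormone, taxon, coef): couplings between
#'   standardised hormone deviations and latent abundance.
#' @slot hormoneProfiles per-hormone visit means and SDs
#'   (see \code{\link{defaultHormoneProfiles}}).
#' @slot taxaPanel ordered taxon names.
#' @slot regimeBaselines regimes x taxa matrix of baseline log-abundances.
#' @export
setClass("CohortConfig",
  representation(
    nWomen = "integer", nVisits = "integer", seed = "integer",
    cstFrequencies = "numeric", iccTarget = "numeric", residualSD = "numeric",
    librarySizeMean = "numeric", librarySizeDispersion = "numeric",
    missingRate = "numeric", visitEffects = "data.frame",
    hormoneEffects = "data.frame", hormoneProfiles = "list",
    taxaPanel = "character", regimeBaselines = "matrix"
  )
)

setValidity("CohortConfig", function(object) {
  msgs <- character(0)
  if (length(object@nWomen) != 1 || is.na(object@nWomen) || object@nWomen < 1)
    msgs <- c(msgs, "nWomen must be a positive integer")
  if (object@nVisits != 4L)
    msgs <- c(msgs, "nVisits is fixed at 4 (one visit per cycle phase)")
  if (abs(sum(object@cstFrequencies) - 1) > 1e-9)
    msgs <- c(msgs, "cstFrequencies must sum to 1 (within 1e-9)")
  if (any(object@cstFrequencies < 0))
    msgs <- c(msgs, "cstFrequencies must be non-negative")
  if (length(object@taxaPanel) == 0)
    msgs <- c(msgs, "taxaPanel must not be empty")
  if (anyDuplicated(object@taxaPanel))
    msgs <- c(msgs, "taxaPanel has duplicated taxon names")
  if (object@iccTarget < 0 || object@iccTarget >= 1)
    msgs <- c(msgs, "iccTarget must be in [0, 1)")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msgs <- c(msgs, "missingRate must be in [0, 1)")
  if (object@librarySizeMean <= 0)
    msgs <- c(msgs, "librarySizeMean must be positive")
  bad <- setdiff(object@visitEffects$taxon, object@taxaPanel)
  if (length(bad))
    msgs <- c(msgs, paste("visitEffects name unknown taxa:",
                          paste(bad, collapse = ", ")))
  bad <- setdiff(object@hormoneEffects$taxon, object@taxaPanel)
  if (length(bad))
    msgs <- c(msgs, paste("hormoneEffects name unknown taxa:",
                          paste(bad, collapse = ", ")))
  bad <- setdiff(object@hormoneEffects$hormone, names(object@hormoneProfiles))
  if (length(bad))
    msgs <- c(msgs, paste("hormoneEffects name unknown hormones:",
                          paste(bad, collapse = ", ")))
  if (!setequal(names(object@cstFrequencies), rownames(object@regimeBaselines)))
    msgs <- c(msgs, "cstFrequencies and regimeBaselines regimes differ")
  if (!identical(colnames(object@regimeBaselines), object@taxaPanel))
    msgs <- c(msgs, "regimeBaselines columns must equal taxaPanel")
  if (length(msgs)) msgs else TRUE
})

#' Create a cohort configuration
#'
#' @param nWomen number of women (default 61).
#' @param seed master RNG seed.
#' @param cstFrequencies named CST regime probabilities summing to 1.
#' @param iccTarget target intraclass correlation of latent abundances in
#'   [0, 1); 0 makes samples exchangeable across women.
#' @param residualSD residual SD of the latent log-abundance.
#' @param librarySizeMean,librarySizeDispersion mean and dispersion (size) of
#'   the negative-binomial sequencing depth per sample.
#' @param missingRate overall expected fraction of missing (woman, visit) rows.
#' @param visitEffects data.frame with columns \code{taxon}, \code{slope}.
#' @param hormoneEffects data.frame with columns \code{hormone}, \code{taxon},
#'   \code{coef}.
#' @param hormoneProfiles see \code{\link{defaultHormoneProfiles}}.
#' @param taxaPanel character vector of taxon names.
#' @param regimeBaselines regimes x taxa baseline log-abundance matrix.
#' @return a validated \code{CohortConfig} object.
#' @examples
#' cfg <- cohortConfig(nWomen = 10, seed = 1)
#' cfg
#' @export
cohortConfig <- function(nWomen = 61L, seed = 1L,
                         cstFrequencies = defaultCstFrequencies(),
                         iccTarget = 0.75, residualSD = 1,
                         librarySizeMean = 1e5, librarySizeDispersion = 20,
                         missingRate = 0.13,
                         visitEffects = data.frame(taxon = character(0),
                                                   slope = numeric(0)),
                         hormoneEffects = data.frame(hormone = character(0),
                                                     taxon = character(0),
                                                     coef = numeric(0)),
                         hormoneProfiles = defaultHormoneProfiles(),
                         taxaPanel = defaultTaxaPanel(),
                         regimeBaselines = defaultRegimeBaselines(taxaPanel)) {
  new("CohortConfig",
      nWomen = as.integer(nWomen), nVisits = 4L, seed = as.integer(seed),
      cstFrequencies = cstFrequencies, iccTarget = iccTarget,
      residualSD = residualSD, librarySizeMean = librarySizeMean,
      librarySizeDispersion = librarySizeDispersion, missingRate = missingRate,
      visitEffects = visitEffects, hormoneEffects = hormoneEffects,
      hormoneProfiles = hormoneProfiles, taxaPanel = taxaPanel,
      regimeBaselines = regimeBaselines)
}

#' @describeIn CohortConfig-class compact display
#' @param object a \code{CohortConfig}.
#' @export
setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig:", object@nWomen, "women x", object@nVisits, "visits,",
      length(object@taxaPanel), "taxa\n")
  cat("  seed:", object@seed, " iccTarget:", object@iccTarget,
      " missingRate:", object@missingRate, "\n")
  cat("  injected effects:", nrow(object@visitEffects), "visit,",
      nrow(object@hormoneEffects), "hormone\n")
})

#' Longitudinal vaginal-microbiota cohort container
#'
#' Extends \code{SummarizedExperiment}: the \code{counts} assay holds the
#' taxa x samples read counts; \code{colData} carries the sample key
#' (woman, visit, phase), technical covariates (Qubit_DNA, Qubit_Library,
#' Total_counts), host covariates and the five serum hormones. For simulated
#' cohorts, \code{metadata()$groundTruth} records every quantity used in
#' generation.
#'
#' @export
setClass("CycleCohort", contains = "SummarizedExperiment")

setValidity("CycleCohort", function(object) {
  msgs <- character(0)
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'counts' is required")
  else {
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (any(cnt < 0)) msgs <- c(msgs, "counts must be non-negative")
    if (any(cnt != round(cnt))) msgs <- c(msgs, "counts must be integral")
  }
  cd <- colData(object)
  need <- c("woman", "visit")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msgs <- c(msgs, paste("colData lacks:", paste(miss, collapse = ", ")))
  if (all(c("woman", "visit") %in% colnames(cd)) &&
      anyDuplicated(paste(cd$woman, cd$visit)))
    msgs <- c(msgs, "(woman, visit) pairs must be unique")
  if (length(msgs)) msgs else TRUE
})

#' Taxa count matrix of a cohort
#'
#' @param x a \code{CycleCohort}.
#' @return integer matrix, samples x taxa (transposed from the internal
#'   taxa x samples assay for direct use by the analysis functions).
#' @name taxaCounts
#' @export
setMethod("taxaCounts", "CycleCohort", function(x) {
  t(SummarizedExperiment::assay(x, "counts"))
})

#' Sample-level metadata of a cohort
#'
#' @param x a \code{CycleCohort}.
#' @return data.frame with one row per sample: woman, visit, phase, technical
#'   and host covariates.
#' @name sampleData
#' @export
setMethod("sampleData", "CycleCohort", function(x) {
  df <- as.data.frame(colData(x))
  df[, setdiff(colnames(df), .HORMONES), drop = FALSE]
})

#' Hormone panel of a cohort
#'
#' @param x a \code{CycleCohort}.
#' @return numeric matrix, samples x 5 hormones (BES17, LH, FSH, PROG, PRL).
#' @name hormoneLevels
#' @export
setMethod("hormoneLevels", "CycleCohort", function(x) {
  as.matrix(as.data.frame(colData(x))[, .HORMONES, drop = FALSE])
})

#' Generation ground truth of a simulated cohort
#'
#' @param x a \code{CycleCohort}.
#' @return list recording the per-woman regimes, random intercepts, injected
#'   effects, true ICC and the latent CLR-scale abundances, or NULL for
#'   cohorts read from files.
#' @name groundTruth
#' @export
setMethod("groundTruth", "CycleCohort", function(x) {
  S4Vectors::metadata(x)$groundTruth
})

#' @describeIn CycleCohort-class compact display
#' @param object a \code{CycleCohort}.
#' @export
setMethod("show", "CycleCohort", function(object) {
  cd <- colData(object)
  cat("CycleCohort:", ncol(object), "samples,", nrow(object), "taxa,",
      length(unique(cd$woman)), "women\n")
  tab <- table(factor(cd$visit, levels = 1:4))
  cat("  samples per visit (F/O/EL/LL):", paste(tab, collapse = "/"), "\n")
  if (!is.null(S4Vectors::metadata(object)$groundTruth))
    cat("  simulated cohort with ground truth attached\n")
})
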