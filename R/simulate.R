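#' Simulate a longitudinal vaginal-microbiota cohort
#'
#' Generates a complete synthetic cohort with known ground truth. Each woman
#' is assigned a CST regime from the configured frequencies; her latent
#' CLR-scale taxon abundances are the regime baseline plus a per-(woman, taxon)
#' random intercept (variance set from \code{iccTarget}), any injected linear
#' visit effects, any injected couplings to standardised hormone deviations,
#' and residual Gaussian noise. Compositions arise by softmax of the latents
#' (logistic-normal), counts by a multinomial draw at a negative-binomial
#' library size. Hormones follow per-visit profile means plus woman-level
#' intercepts and within-woman noise. Visits 2-4 are dropped completely at
#' random so that the overall expected missingness equals \code{missingRate};
#' visit 1 (the anchor of the self-vs-random procedure) is never dropped.
#'
#' @param config a \code{\link{cohortConfig}} object.
#' @return a \code{\link{CycleCohort-class}} with ground truth in
#'   \code{groundTruth()}.
#' @examples
#' cohort <- simulateCohort(cohortConfig(nWomen = 8, seed = 42))
#' cohort
#' @export
simulateCohort <- function(config) {
  validObject(config)
  nW <- config@nWomen
  taxa <- config@taxaPanel
  nT <- length(taxa)
  women <- sprintf("W%03d", seq_len(nW))

  # variance components from the ICC target: icc = sb^2 / (sb^2 + se^2)
  se2 <- config@residualSD^2
  sb2 <- if (config@iccTarget > 0) config@iccTarget / (1 - config@iccTarget) * se2 else 0

  regimes <- .withSeed(.substream(config@seed, "regimes"),
    sample(names(config@cstFrequencies), nW, replace = TRUE,
           prob = config@cstFrequencies))
  names(regimes) <- women

  intercepts <- .withSeed(.substream(config@seed, "intercepts"),
    matrix(stats::rnorm(nW * nT, sd = sqrt(sb2)), nrow = nW,
           dimnames = list(women, taxa)))

  # full (woman, visit) grid; missingness applied at the end
  grid <- expand.grid(woman = women, visit = 1:4, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$woman, grid$visit), ]
  sampleId <- sprintf("%s_V%d", grid$woman, grid$visit)
  nS <- nrow(grid)

  # hormones: woman intercept + visit-profile mean + within-woman noise
  hseed <- .substream(config@seed, "hormones")
  hormones <- matrix(NA_real_, nS, length(.HORMONES),
                     dimnames = list(sampleId, .HORMONES))
  hz <- hormones  # standardised deviations from the visit mean
  for (h in .HORMONES) {
    prof <- config@hormoneProfiles[[h]]
    vals <- .withSeed(.substream(hseed, h), {
      wi <- stats::rnorm(nW, sd = prof$womanSD)
      names(wi) <- women
      prof$mean[grid$visit] + wi[grid$woman] +
        stats::rnorm(nS, sd = prof$withinSD)
    })
    hz[, h] <- (vals - prof$mean[grid$visit]) /
      sqrt(prof$withinSD^2 + prof$womanSD^2)
    hormones[, h] <- pmax(vals, 0.01)
  }

  # latent CLR-scale abundances
  latent <- config@regimeBaselines[regimes[grid$woman], , drop = FALSE] +
    intercepts[grid$woman, , drop = FALSE]
  dimnames(latent) <- list(sampleId, taxa)
  if (nrow(config@visitEffects)) {
    for (i in seq_len(nrow(config@visitEffects))) {
      tx <- config@visitEffects$taxon[i]
      latent[, tx] <- latent[, tx] + config@visitEffects$slope[i] * grid$visit
    }
  }
  if (nrow(config@hormoneEffects)) {
    for (i in seq_len(nrow(config@hormoneEffects))) {
      tx <- config@hormoneEffects$taxon[i]
      hh <- config@hormoneEffects$hormone[i]
      latent[, tx] <- latent[, tx] + config@hormoneEffects$coef[i] * hz[, hh]
    }
  }
  latent <- latent + .withSeed(.substream(config@seed, "noise"),
    matrix(stats::rnorm(nS * nT, sd = config@residualSD), nS, nT))

  # composition via softmax, counts via multinomial at NB library size
  comp <- exp(latent - apply(latent, 1, max))
  comp <- comp / rowSums(comp)
  counts <- .withSeed(.substream(config@seed, "counts"), {
    libs <- pmax(stats::rnbinom(nS, mu = config@librarySizeMean,
                                size = config@librarySizeDispersion), 1000L)
    out <- matrix(0L, nS, nT, dimnames = list(sampleId, taxa))
    for (s in seq_len(nS))
      out[s, ] <- as.integer(stats::rmultinom(1, libs[s], comp[s, ]))
    out
  })

  # technical and host covariates
  covar <- .withSeed(.substream(config@seed, "covariates"), {
    age <- round(stats::runif(nW, 18, 45)); names(age) <- women
    preg <- sample(c("never_pregnant", "at_least_one"), nW, replace = TRUE,
                   prob = c(0.6, 0.4)); names(preg) <- women
    pill <- sample(c("never", "past_use"), nW, replace = TRUE,
                   prob = c(0.5, 0.5)); names(pill) <- women
    whr <- sample(c("low", "mid", "high"), nW, replace = TRUE); names(whr) <- women
    smoke <- sample(c("no", "yes"), nW, replace = TRUE, prob = c(0.75, 0.25))
    names(smoke) <- women
    data.frame(
      Qubit_DNA = stats::rlnorm(nS, log(10), 0.4),
      Qubit_Library = stats::rlnorm(nS, log(20), 0.3),
      Age = age[grid$woman],
      sex_less_than_two_days = sample(c("no", "yes"), nS, replace = TRUE,
                                      prob = c(0.7, 0.3)),
      Pregnancy_category = preg[grid$woman],
      Pill_use = pill[grid$woman],
      Swab_after_feces = sample(c("no", "yes"), nS, replace = TRUE,
                                prob = c(0.8, 0.2)),
      Bristol_stool_scale = sample(1:7, nS, replace = TRUE),
      Swab_morning_or_not = sample(c("morning", "day"), nS, replace = TRUE),
      WHR_ranges = whr[grid$woman],
      smoking = smoke[grid$woman],
      stringsAsFactors = FALSE)
  })

  # missingness: visit 1 never dropped; visits 2-4 dropped at rate*4/3 so the
  # overall expected missing fraction equals missingRate
  keep <- .withSeed(.substream(config@seed, "missing"), {
    pDrop <- min(config@missingRate * 4 / 3, 1 - 1e-12)
    drop <- grid$visit > 1 & stats::runif(nS) < pDrop
    !drop
  })

  cd <- data.frame(
    sample_id = sampleId, woman = grid$woman, visit = grid$visit,
    phase = visitPhase(grid$visit),
    covar,
    Total_counts = rowSums(counts),
    as.data.frame(hormones),
    row.names = sampleId, stringsAsFactors = FALSE)

  truth <- list(
    regimes = regimes,
    interceptSD = sqrt(sb2),
    intercepts = intercepts,
    visitEffects = config@visitEffects,
    hormoneEffects = config@hormoneEffects,
    trueICC = stats::setNames(rep(sb2 / (sb2 + se2), nT), taxa),
    latent = latent[keep, , drop = FALSE],
    hormoneZ = hz[keep, , drop = FALSE],
    seed = config@seed)

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = t(counts[keep, , drop = FALSE])),
    colData = S4Vectors::DataFrame(cd[keep, , drop = FALSE]),
    metadata = list(groundTruth = truth, config = config))
  new("CycleCohort", se)
}

#' Regime centroid compositions
#'
#' Mean composition of each CST regime: the softmax of the configured baseline
#' log-abundances. Useful as a synthetic centroid table for the
#' nearest-centroid classifier.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @return matrix, regimes x taxa, rows summing to 1.
#' @export
generateCentroids <- function(config) {
  validObject(config)
  b <- exp(config@regimeBaselines)
  b / rowSums(b)
}

#' Synthetic per-sample read statistics
#'
#' Fixture generator for the sample-level QC rules: per-sample input and
#' post-trimming read counts across three batches, each with one negative
#' control. The draw is arranged to span both sides of every QC threshold
#' (at least one sample under 80,000 input reads, one under 60,000 survived
#' reads, and one contaminated negative control above 500 reads).
#'
#' @param config a \code{\link{cohortConfig}}.
#' @param seed RNG seed (default: the config seed).
#' @return data.frame with columns sample_id, input_reads, survived_reads,
#'   batch, is_negative_control.
#' @export
generateReadStats <- function(config, seed = config@seed) {
  validObject(config)
  nS <- config@nWomen * 4L
  ids <- sprintf("W%03d_V%d",
                 rep(seq_len(config@nWomen), each = 4), rep(1:4, config@nWomen))
  .withSeed(.substream(seed, "readstats"), {
    input <- round(stats::rlnorm(nS, log(150000), 0.25))
    survived <- round(input * stats::runif(nS, 0.80, 0.95))
    # force boundary cases
    input[1] <- 75000L; survived[1] <- 70000L
    input[2] <- 85000L; survived[2] <- 55000L
    batch <- rep_len(1:3, nS)
    stats <- data.frame(sample_id = ids, input_reads = input,
                        survived_reads = pmin(survived, input),
                        batch = batch, is_negative_control = FALSE,
                        stringsAsFactors = FALSE)
    neg <- data.frame(sample_id = sprintf("NEG_%d", 1:3),
                      input_reads = c(2000L, 1500L, 3000L),
                      survived_reads = c(120L, 80L, 650L),
                      batch = 1:3,
                      is_negative_control = TRUE, stringsAsFactors = FALSE)
    rbind(stats, neg)
  })
}
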