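test_that("configuration invariants are enforced", {
  expect_error(cohortConfig(nWomen = 0), "positive")
  expect_error(cohortConfig(cstFrequencies = c("CST-I" = 0.5, "CST-II" = 0.4),
                            regimeBaselines = defaultRegimeBaselines()[1:2, ]),
               "sum to 1")
  expect_error(cohortConfig(taxaPanel = character(0)), "empty|taxaPanel")
  expect_error(
    cohortConfig(visitEffects = data.frame(taxon = "NotATaxon", slope = 1)),
    "unknown taxa")
  expect_error(cohortConfig(missingRate = 1), "missingRate")
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- cohortConfig(nWomen = 12, seed = 99)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(taxaCounts(a), taxaCounts(b))
  expect_identical(as.data.frame(SummarizedExperiment::colData(a)),
                   as.data.frame(SummarizedExperiment::colData(b)))
  c2 <- simulateCohort(cohortConfig(nWomen = 12, seed = 100))
  expect_false(identical(taxaCounts(a), taxaCounts(c2)))
})

test_that("ground truth round-trips the generating quantities", {
  cfg <- cohortConfig(
    nWomen = 10, seed = 3,
    visitEffects = data.frame(taxon = "Lactobacillus_iners", slope = 0.4),
    hormoneEffects = data.frame(hormone = "PROG",
                                taxon = "Lactobacillus_crispatus",
                                coef = -0.5))
  gt <- groundTruth(simulateCohort(cfg))
  expect_identical(gt$visitEffects, cfg@visitEffects)
  expect_identical(gt$hormoneEffects, cfg@hormoneEffects)
  expect_setequal(unique(gt$regimes) , intersect(names(cfg@cstFrequencies),
                                                 unique(gt$regimes)))
  expect_equal(unname(gt$trueICC[1]), 0.75, tolerance = 1e-12)
})

test_that("every count row sums to its drawn library size and visit 1 is never missing", {
  co <- simulateCohort(cohortConfig(nWomen = 25, seed = 11))
  cnt <- taxaCounts(co)
  cd <- sampleData(co)
  expect_true(all(rowSums(cnt) == cd$Total_counts))
  expect_true(all(rowSums(cnt) >= 1000))
  expect_true(all(sprintf("W%03d", 1:25) %in% cd$woman[cd$visit == 1]))
})

test_that("default missingness emulates the observed QC yield", {
  co <- simulateCohort(cohortConfig(nWomen = 61, seed = 5))
  # E[retained] = 61 + 183 * (1 - 0.13 * 4/3) ~ 212; allow ~4 SD
  expect_gt(ncol(co), 192)
  expect_lt(ncol(co), 232)
})

test_that("regime frequencies converge to the configured probabilities", {
  cfg <- cohortConfig(nWomen = 2000, seed = 17, librarySizeMean = 2000,
                      missingRate = 0)
  gt <- groundTruth(simulateCohort(cfg))
  obs <- table(factor(gt$regimes, levels = names(cfg@cstFrequencies)))
  gof <- suppressWarnings(
    chisq.test(obs, p = cfg@cstFrequencies))
  expect_gt(gof$p.value, 0.01)
})

test_that("latent ICC matches the target under the ANOVA estimator", {
  cfg <- singleRegimeConfig(nWomen = 500, seed = 23, librarySizeMean = 2000,
                            missingRate = 0)
  co <- simulateCohort(cfg)
  gt <- groundTruth(co)
  woman <- sampleData(co)$woman
  icc <- vapply(colnames(gt$latent), function(tx)
    anovaICC(gt$latent[, tx], woman), numeric(1))
  expect_lt(abs(mean(icc) - 0.75), 0.05)

  cfg0 <- singleRegimeConfig(nWomen = 200, seed = 29, iccTarget = 0,
                             librarySizeMean = 2000, missingRate = 0)
  gt0 <- groundTruth(simulateCohort(cfg0))
  w0 <- sub("_V[0-9]$", "", rownames(gt0$latent))
  icc0 <- vapply(colnames(gt0$latent), function(tx)
    anovaICC(gt0$latent[, tx], w0), numeric(1))
  expect_lt(abs(mean(icc0)), 0.05)
})

test_that("per-visit hormone means follow the configured profiles", {
  cfg <- cohortConfig(nWomen = 400, seed = 31, librarySizeMean = 2000,
                      missingRate = 0)
  co <- simulateCohort(cfg)
  h <- hormoneLevels(co)
  visit <- sampleData(co)$visit
  for (nm in c("BES17", "PROG")) {
    prof <- defaultHormoneProfiles()[[nm]]
    obs <- tapply(h[, nm], visit, mean)
    se <- sqrt(prof$withinSD^2 + prof$womanSD^2) / sqrt(400)
    expect_true(all(abs(obs - prof$mean) < 5 * se + 0.05 * prof$mean))
  }
  # defaults encode the cycle: BES17 peaks at the ovulatory visit, PROG in
  # the luteal visits
  expect_equal(unname(which.max(tapply(h[, "BES17"], visit, mean))), 2)
  expect_true(which.max(tapply(h[, "PROG"], visit, mean)) %in% c(3, 4))
})

test_that("regime centroids are normalised and peak at their marker", {
  cfg <- cohortConfig(nWomen = 5, seed = 1)
  cent <- generateCentroids(cfg)
  expect_equal(nrow(cent), 5)
  expect_true(all(abs(rowSums(cent) - 1) < 1e-9))
  expect_identical(names(which.max(cent["CST-III", ])), "Lactobacillus_iners")
  expect_identical(names(which.max(cent["CST-I", ])),
                   "Lactobacillus_crispatus")
  # a noiseless regime sample has Yue-Clayton similarity 1 to its centroid
  expect_equal(yueClaytonSimilarity(cent["CST-I", ], cent["CST-I", ]), 1)
})

test_that("read statistics span the QC thresholds", {
  st <- generateReadStats(cohortConfig(nWomen = 30, seed = 2))
  expect_true(all(st$survived_reads <= st$input_reads))
  smp <- st[!st$is_negative_control, ]
  expect_true(any(smp$input_reads < 80000))
  expect_true(any(smp$survived_reads < 60000))
  expect_true(any(st$is_negative_control & st$survived_reads > 500))
})
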