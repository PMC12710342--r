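test_that("visit model recovers an injected slope and flags degeneracy", {
  cfg <- singleRegimeConfig(
    nWomen = 60, seed = 77, iccTarget = 0.8, residualSD = 0.5,
    missingRate = 0,
    visitEffects = data.frame(taxon = "Bifidobacterium_breve", slope = 0.5))
  co <- simulateCohort(cfg)
  design <- sampleData(co)
  clr <- clrTransform(relativeAbundance(taxaCounts(co)))
  fit <- fitVisitModels(clr[, c("Bifidobacterium_breve",
                                "Prevotella_bivia"), drop = FALSE], design)
  focal <- fit[fit$taxon == "Bifidobacterium_breve", ]
  expect_lt(abs(focal$beta - 0.5), 0.15)
  expect_lt(focal$p, 0.001)
  null <- fit[fit$taxon == "Prevotella_bivia", ]
  expect_true(null$ci_lo < 0 && null$ci_hi > 0)

  # taxon constant within every woman: slope exactly 0, flagged singular
  womanMeans <- rnorm(20)
  const <- matrix(rep(womanMeans, each = 4), ncol = 1,
                  dimnames = list(NULL, "const"))
  dsg <- data.frame(woman = rep(paste0("w", 1:20), each = 4),
                    visit = rep(1:4, 20))
  fc <- fitVisitModels(const, dsg)
  expect_equal(fc$beta, 0, tolerance = 1e-8)
  expect_true(fc$singular)
})

test_that("empirical p-value is the exact proportion of permuted p-values", {
  pPerm <- c(rep(0.009, 50), seq(0.02, 1, length.out = 950))
  expect_equal(empiricalP(0.01, pPerm), 0.05)
  expect_equal(empiricalP(1, pPerm), 1)      # all permuted p at or below
  expect_equal(empiricalP(0.001, pPerm), 0)  # zero attainable
})

test_that("permutation machinery yields calibrated empirical p for a null taxon", {
  cfg <- singleRegimeConfig(nWomen = 30, seed = 13, iccTarget = 0,
                            missingRate = 0, librarySizeMean = 5000)
  co <- simulateCohort(cfg)
  clr <- clrTransform(relativeAbundance(taxaCounts(co)))
  fit <- fitVisitModels(clr[, "Prevotella_bivia", drop = FALSE],
                        sampleData(co), nPerm = 99, seed = 5)
  expect_true(fit$p_empirical >= 0 && fit$p_empirical <= 1)
  # asymptotic and empirical p agree in order of magnitude on null data
  expect_gt(fit$p_empirical, 0.01 * fit$p)
  fit2 <- fitVisitModels(clr[, "Prevotella_bivia", drop = FALSE],
                         sampleData(co), nPerm = 99, seed = 5)
  expect_identical(fit$p_empirical, fit2$p_empirical)
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(fdrAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdrAdjust(0.37), 0.37)
  expect_equal(fdrAdjust(rep(1, 5)), rep(1, 5))
  expect_error(fdrAdjust(numeric(0)), "empty")
  # q >= p within the declared family
  set.seed(2)
  p <- runif(20)
  expect_true(all(fdrAdjust(p) >= p - 1e-12))
})

test_that("ICC estimates track the variance components", {
  # sigma_b^2 = 3, sigma_e^2 = 1 -> ICC 0.75
  set.seed(11)
  nW <- 200
  woman <- rep(sprintf("w%03d", 1:nW), each = 4)
  y <- rep(rnorm(nW, sd = sqrt(3)), each = 4) + rnorm(nW * 4, sd = 1)
  dsg <- data.frame(woman = woman, visit = rep(1:4, nW))
  res <- iccTaxa(matrix(y, ncol = 1, dimnames = list(NULL, "t")), dsg)
  expect_gt(res$icc, 0.70)
  expect_lt(res$icc, 0.80)
  # zero between-woman variance
  y0 <- rnorm(nW * 4)
  res0 <- iccTaxa(matrix(y0, ncol = 1, dimnames = list(NULL, "t")), dsg)
  expect_lt(res0$icc, 0.05)
  # zero residual variance
  y1 <- rep(rnorm(nW), each = 4)
  res1 <- iccTaxa(matrix(y1, ncol = 1, dimnames = list(NULL, "t")), dsg)
  expect_gt(res1$icc, 0.95)
  expect_true(res1$singular)
})

test_that("hormone outliers beyond 4 SD are removed, 3.9 SD kept", {
  set.seed(3)
  x <- rnorm(200)
  m <- mean(x); s <- sd(x)
  h <- matrix(c(x, m + 3.9 * s, m + 5 * s), ncol = 1,
              dimnames = list(NULL, "PROG"))
  # recompute against the full-vector mean/SD (single pass, as implemented)
  res <- removeHormoneOutliers(h)
  mm <- mean(h); ss <- sd(h)
  shouldGo <- abs(h[, 1] - mm) > 4 * ss
  expect_identical(which(is.na(res$hormones[, 1])), which(shouldGo))
  expect_false(is.na(res$hormones[201, 1]) && !shouldGo[201])
})

test_that("outlier removal rate matches the normal tail probability", {
  set.seed(9)
  h <- matrix(rnorm(10000), ncol = 1, dimnames = list(NULL, "BES17"))
  res <- removeHormoneOutliers(h)
  expected <- 2 * pnorm(-4) * 10000   # ~0.63
  expect_lte(nrow(res$removed), expected + 3)
})

test_that("consecutive differences skip gap pairs", {
  dsg <- data.frame(woman = c(rep("w1", 4), "w2", "w2", "w2"),
                    visit = c(1:4, 1, 3, 4))
  vals <- c(1, 3, 6, 10, 0, 5, 6)
  d <- consecutiveDifferences(vals, dsg)
  d1 <- d[d$woman == "w1", ]
  expect_equal(nrow(d1), 3)
  expect_equal(d1$value, c(2, 3, 4))
  d2 <- d[d$woman == "w2", ]
  expect_equal(nrow(d2), 1)                 # (1,3) gap skipped
  expect_identical(d2$transition, "EL->LL")
  expect_equal(d2$value, 1)
  const <- consecutiveDifferences(rep(2, 4), dsg[1:4, ])
  expect_true(all(const$value == 0))
})

test_that("ordernorm maps to normal quantiles and preserves order", {
  got <- orderNorm(c(10, 2, 30))
  expect_equal(got, qnorm(c(2, 1, 3) / 4), tolerance = 1e-10)
  expect_equal(sort(got), c(-0.6745, 0, 0.6745), tolerance = 1e-4)
  x <- rexp(100)
  y <- orderNorm(x)
  expect_identical(order(x), order(y))
  expect_gt(shapiro.test(y)$p.value, 0.05)
  withNA <- orderNorm(c(1, NA, 2, 3))
  expect_true(is.na(withNA[2]))
  expect_warning(z <- orderNorm(rep(1, 5)), "identical")
  expect_true(all(z == 0))
})

test_that("difference models flag degenerate input and recover couplings", {
  set.seed(21)
  n <- 60
  tr <- rep("EL->LL", n)
  dt <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "L_crispatus"))
  dh <- matrix(0.8 * dt[, 1] + rnorm(n, sd = 0.5), ncol = 1,
               dimnames = list(NULL, "PROG"))
  res <- fitDifferenceModels(dh, dt, tr, nPerm = 99, seed = 1)
  expect_gt(res$beta, 0)
  expect_lt(res$p, 0.05)
  expect_lte(res$p_empirical, 0.1)
  flat <- matrix(0, n, 1, dimnames = list(NULL, "zerovar"))
  res0 <- fitDifferenceModels(dh, flat, tr)
  expect_identical(res0$flag, "degenerate")
  expect_true(is.na(res0$beta))
  small <- fitDifferenceModels(dh[1:5, , drop = FALSE],
                               dt[1:5, , drop = FALSE], tr[1:5])
  expect_identical(small$flag, "low_n")
})

test_that("overall hormone model rejects constant predictors and finds couplings", {
  cfg <- cohortConfig(
    nWomen = 61, seed = 19, missingRate = 0,
    hormoneEffects = data.frame(hormone = "BES17",
                                taxon = "Prevotella_timonensis_A",
                                coef = -1.5))
  co <- simulateCohort(cfg)
  design <- sampleData(co)
  clr <- clrTransform(relativeAbundance(taxaCounts(co)))
  adj <- residualizeTaxa(clr, design, modelId = 2L)
  h <- hormoneLevels(co)
  fit <- fitOverallHormoneModel(h[, "BES17"],
                                adj[, "Prevotella_timonensis_A"], design)
  expect_lt(fit$beta, 0)
  expect_lt(fit$p, 0.05)
  expect_error(
    fitOverallHormoneModel(h[, "BES17"], rep(1, nrow(design)), design),
    "zero-variance")
})

test_that("visit model slope is invariant to shifting a taxon by a constant", {
  cfg <- singleRegimeConfig(nWomen = 20, seed = 33, missingRate = 0,
                            librarySizeMean = 5000)
  co <- simulateCohort(cfg)
  clr <- clrTransform(relativeAbundance(taxaCounts(co)))
  y <- clr[, "Finegoldia_magna", drop = FALSE]
  f1 <- fitVisitModels(y, sampleData(co))
  y2 <- y + 100
  f2 <- fitVisitModels(y2, sampleData(co))
  expect_equal(f1$beta, f2$beta, tolerance = 1e-6)
})
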