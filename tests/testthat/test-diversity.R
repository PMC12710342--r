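test_that("alpha diversity matches closed forms", {
  m <- rbind(single = c(100L, 0L, 0L, 0L),
             uniform = c(25L, 25L, 25L, 25L))
  colnames(m) <- paste0("t", 1:4)
  a <- alphaDiversity(m)
  expect_equal(a$shannon, c(0, log(4)), tolerance = 1e-10)
  expect_equal(a$simpson, c(0, 0.75), tolerance = 1e-10)
  p <- c(0.1, 0.3, 0.6)
  a2 <- alphaDiversity(matrix(c(10L, 30L, 60L), 1,
                              dimnames = list("s", paste0("t", 1:3))))
  expect_equal(a2$shannon, -sum(p * log(p)), tolerance = 1e-10)  # 0.8979
  expect_equal(a2$shannon, 0.8979457, tolerance = 1e-6)
})

test_that("Bray-Curtis matches the hand formula", {
  rel <- rbind(a = c(0.7, 0.3), b = c(0.3, 0.7), c = c(0.7, 0.3),
               d = c(1, 0), e = c(0, 1))
  d <- brayCurtis(rel)
  expect_equal(d["a", "b"], 0.4, tolerance = 1e-10)  # sum|x-y|/sum(x+y)
  expect_equal(d["a", "c"], 0)
  expect_equal(d["d", "e"], 1)                       # disjoint supports
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
})

test_that("distance construction is permutation-equivariant", {
  rel <- relativeAbundance(toyCounts())
  d1 <- brayCurtis(rel)
  perm <- c(3, 1, 4, 2)
  d2 <- brayCurtis(rel[perm, ])
  expect_equal(unname(d2), unname(d1[perm, perm]), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("PCoA recovers Euclidean configurations exactly", {
  set.seed(7)
  pts <- cbind(rnorm(12), rnorm(12))
  rownames(pts) <- paste0("s", 1:12)
  d <- as.matrix(dist(pts))
  ord <- pcoaOrdination(d, nAxes = 2)
  expect_equal(unname(as.matrix(dist(ord$scores))), unname(d),
               tolerance = 1e-8)
  expect_true(all(diff(ord$eigenvalues) <= 1e-8))  # decreasing order
  # duplicated sample gets identical scores
  d2 <- as.matrix(dist(pts[c(1, 1:12), ]))
  ord2 <- suppressWarnings(pcoaOrdination(d2, nAxes = 2))
  expect_equal(ord2$scores[1, ], ord2$scores[2, ], tolerance = 1e-8)
})

test_that("PCoA eigenvalues match a direct Gram eigendecomposition", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  J <- diag(3) - matrix(1 / 3, 3, 3)
  G <- -0.5 * J %*% (d^2) %*% J            # independent oracle
  expected <- sort(eigen(G, symmetric = TRUE)$values, decreasing = TRUE)
  ord <- suppressWarnings(pcoaOrdination(d, nAxes = 2))
  expect_equal(ord$eigenvalues[1:2], expected[1:2], tolerance = 1e-8)
})

test_that("per-visit Kruskal-Wallis screening behaves at the extremes", {
  n <- 60
  md <- data.frame(visit = rep(1, n),
                   flat = rep(c("x", "y"), n / 2),
                   sep = rep(c("x", "y"), each = n / 2),
                   const = "only")
  scores <- matrix(c(rep(0:1, n / 2) * 0 + 1,         # identical scores
                     c(rnorm(n / 2), rnorm(n / 2, 10))), n, 2,
                   dimnames = list(NULL, c("Axis1", "Axis2")))
  ord <- list(scores = scores)
  class(ord) <- "cyclevagPCoA"
  res <- screenCovariatesPerVisit(ord, md, c("flat", "sep", "const"))
  expect_gt(res$p[res$axis == "Axis1" & res$variable == "flat"], 0.9)
  expect_lt(res$p[res$axis == "Axis2" & res$variable == "sep"], 1e-6)
  expect_true(is.na(res$p[res$axis == "Axis1" & res$variable == "const"]))
})

test_that("axis adjustment residualises only significant covariates", {
  set.seed(1)
  n <- 50
  md <- data.frame(visit = rep(1:2, n / 2), Age = rnorm(n))
  scores <- cbind(Axis1 = 3 * md$Age + rnorm(n, sd = 0.1),
                  Axis2 = rnorm(n))
  ord <- structure(list(scores = scores), class = "cyclevagPCoA")
  sig <- data.frame(axis = "Axis1", variable = "Age")
  adj <- adjustAxes(ord, md, sig)
  expect_lt(abs(cor(adj$adjusted[, "Axis1"], md$Age)), 1e-6)
  expect_equal(adj$adjusted[, "Axis2"], scores[, "Axis2"] -
               mean(scores[, "Axis2"]), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(adj$adjustments$Axis1, "Age")
})

test_that("PERMANOVA pseudo-F matches brute force and p hits the floor", {
  rel <- rbind(a1 = c(1, 0), a2 = c(1, 0), a3 = c(0.99, 0.01),
               b1 = c(0, 1), b2 = c(0, 1), b3 = c(0.01, 0.99))
  d <- brayCurtis(rel)
  g <- rep(c("a", "b"), each = 3)
  res <- permanovaTest(d, g, nPerm = 99, seed = 1)
  expect_equal(res$F, permanovaF(d, g), tolerance = 1e-8)
  expect_identical(res, permanovaTest(d, g, nPerm = 99, seed = 1))
  expect_error(permanovaTest(d, rep("a", 6)), "2 levels")
  # two well-separated groups, large enough that a random permutation almost
  # surely never reproduces the split: p sits at the 1/(nPerm+1) floor
  set.seed(4)
  pts <- rbind(matrix(rnorm(10 * 3), 10, 3),
               matrix(rnorm(10 * 3, mean = 50), 10, 3))
  g2 <- rep(c("a", "b"), each = 10)
  res2 <- permanovaTest(as.matrix(dist(pts)), g2, nPerm = 99, seed = 2)
  expect_equal(res2$p, 1 / 100)
})

test_that("Friedman test on alpha diversity handles the extremes", {
  design <- data.frame(woman = rep(paste0("w", 1:20), each = 4),
                       visit = rep(1:4, 20))
  flat <- rep(1, 80)
  expect_equal(friedmanAlpha(flat, design)$p, 1)
  rising <- rep(1:4, 20) + rnorm(80, sd = 1e-3)
  expect_lt(friedmanAlpha(rising, design)$p, 1e-4)
  expect_error(friedmanAlpha(flat[1:4], design[1:4, ]), "at least 2 women")
})

test_that("per-phase beta comparison: degenerate and dispersed cases", {
  nW <- 60
  design <- data.frame(woman = rep(sprintf("w%02d", 1:nW), each = 4),
                       visit = rep(1:4, nW))
  # all samples identical
  same <- matrix(0, nW * 4, nW * 4)
  res0 <- perPhaseBeta(same, design)
  expect_true(all(res0$perSample$value == 0))
  expect_true(all(res0$tests$wilcoxon_p == 1 & res0$tests$t_p == 1))
  # follicular phase with doubled dispersion
  set.seed(5)
  pts <- matrix(rnorm(nW * 4 * 5), nW * 4, 5)
  pts[design$visit == 1, ] <- pts[design$visit == 1, ] * 2
  res <- perPhaseBeta(as.matrix(dist(pts)), design)
  means <- tapply(res$perSample$value, res$perSample$phase, mean)
  expect_identical(names(which.max(means)), "F")
  fo <- res$tests[res$tests$phase1 == "F" & res$tests$phase2 == "O", ]
  expect_lt(fo$wilcoxon_p, 0.05)
  # Bonferroni multiplication rule over the six phase pairs
  expect_true(all(res$tests$m == 6))
  expect_equal(res$tests$wilcoxon_p_bonferroni,
               pmin(1, res$tests$wilcoxon_p * 6))
})

test_that("self-vs-random separates individual signatures", {
  # each woman's 4 samples identical, women mutually distinct
  nW <- 10
  design <- data.frame(woman = rep(sprintf("w%02d", 1:nW), each = 4),
                       visit = rep(1:4, nW))
  pts <- matrix(rep(seq_len(nW) * 10, each = 4), ncol = 1)
  d <- as.matrix(dist(pts))
  rownames(d) <- colnames(d) <- sprintf("%s_V%d", design$woman, design$visit)
  res <- selfVsRandom(d, design, nRandom = 5, seed = 2)
  expect_true(all(res$self == 0))
  expect_true(all(res$random > 0, na.rm = TRUE))
  expect_true(all(res$tests$p < 1e-4))
  # Self summaries are seed-invariant; Random replicates are not
  res2 <- selfVsRandom(d, design, nRandom = 5, seed = 99)
  expect_identical(res$self, res2$self)
  expect_false(identical(res$random, res2$random))
})
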