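# Independent oracles and small fixtures used across the suite.

# One-way ANOVA ICC estimator (Fisher), independent of the lme4-based module.
anovaICC <- function(y, group) {
  g <- factor(group)
  a <- stats::anova(stats::lm(y ~ g))
  msb <- a$`Mean Sq`[1]
  msw <- a$`Mean Sq`[2]
  ns <- table(g)
  k0 <- (sum(ns) - sum(ns^2) / sum(ns)) / (length(ns) - 1)
  (msb - msw) / (msb + (k0 - 1) * msw)
}

# Brute-force PERMANOVA pseudo-F from the distance partition:
# SST = sum of squared distances over all pairs / N; SSW likewise per group.
permanovaF <- function(d, g) {
  d <- as.matrix(d)
  g <- factor(g)
  n <- nrow(d)
  sst <- sum(d[lower.tri(d)]^2) / n
  ssw <- 0
  for (lv in levels(g)) {
    ix <- which(g == lv)
    dd <- d[ix, ix]
    ssw <- ssw + sum(dd[lower.tri(dd)]^2) / length(ix)
  }
  ssb <- sst - ssw
  a <- nlevels(g)
  (ssb / (a - 1)) / (ssw / (n - a))
}

# Single-regime configuration: isolates the ICC variance components from
# between-regime composition differences.
singleRegimeConfig <- function(nWomen, seed, iccTarget = 0.75, ...) {
  taxa <- defaultTaxaPanel()
  base <- defaultRegimeBaselines(taxa)["CST-I", , drop = FALSE]
  cohortConfig(nWomen = nWomen, seed = seed, iccTarget = iccTarget,
               cstFrequencies = c("CST-I" = 1),
               regimeBaselines = base, ...)
}

# 12-sample read-stats fixture spanning every QC boundary:
#  - input exactly at / just below 80,000
#  - survived exactly at / just below 60,000
#  - negative controls exactly at / just above 500 reads
qcFixture <- function() {
  smp <- data.frame(
    sample_id = sprintf("S%02d", 1:12),
    input_reads = c(75000, 80000, 79999, 150000, 85000, 90000,
                    120000, 110000, 100000, 95000, 105000, 130000),
    survived_reads = c(70000, 78000, 75000, 140000, 55000, 59999,
                       60000, 100000, 90000, 80000, 95000, 120000),
    batch = c(1, 1, 1, 1, 1, 1, 2, 2, 2, 3, 3, 3),
    is_negative_control = FALSE, stringsAsFactors = FALSE)
  neg <- data.frame(
    sample_id = c("NEG1", "NEG2", "NEG3"),
    input_reads = c(2000, 2000, 2000),
    survived_reads = c(100, 500, 501),  # batch 3 contaminated (>500)
    batch = 1:3, is_negative_control = TRUE, stringsAsFactors = FALSE)
  rbind(smp, neg)
}

toyCounts <- function() {
  m <- matrix(c(10, 30, 60,
                5, 5, 90,
                0, 50, 50,
                25, 25, 50), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), c("A", "B", "C")))
  storage.mode(m) <- "integer"
  m
}
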