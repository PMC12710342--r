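#' Per-phase beta-diversity comparison
#'
#' For each sample, summarises (mean or median) its distances to all other
#' samples collected in the same cycle phase; the per-phase distributions are
#' then compared pairwise with a Wilcoxon test and a t-test, both paired by
#' woman over women observed in both phases, with Bonferroni correction over
#' the six phase pairs.
#'
#' @param dist square distance matrix over samples.
#' @param design data.frame with columns woman and visit (or phase), rows
#'   matching the distance matrix order.
#' @param summary "mean" or "median".
#' @return list with \code{perSample} (sample, woman, phase, value),
#'   \code{phaseSummary}, and \code{tests} (phase pair, raw and
#'   Bonferroni-corrected p for both tests, with the correction factor m).
#' @export
perPhaseBeta <- function(dist, design, summary = c("mean", "median")) {
  summary <- match.arg(summary)
  sfun <- if (summary == "mean") mean else stats::median
  d <- as.matrix(dist)
  stopifnot(nrow(design) == nrow(d))
  phase <- if ("phase" %in% colnames(design)) design$phase
           else visitPhase(design$visit)
  phase <- factor(phase, levels = .PHASES)
  if (any(table(phase) < 2)) stop("every phase needs at least 2 samples")

  value <- vapply(seq_len(nrow(d)), function(i) {
    same <- setdiff(which(phase == phase[i]), i)
    sfun(d[i, same])
  }, numeric(1))
  perSample <- data.frame(
    sample_id = rownames(d) %||% as.character(seq_len(nrow(d))),
    woman = design$woman, phase = phase, value = value,
    stringsAsFactors = FALSE)

  pairs <- utils::combn(.PHASES, 2)
  m <- ncol(pairs)
  tests <- lapply(seq_len(m), function(k) {
    p1 <- pairs[1, k]; p2 <- pairs[2, k]
    x1 <- perSample[perSample$phase == p1, ]
    x2 <- perSample[perSample$phase == p2, ]
    common <- intersect(x1$woman, x2$woman)
    v1 <- x1$value[match(common, x1$woman)]
    v2 <- x2$value[match(common, x2$woman)]
    if (length(common) >= 2 && all(v1 == v2)) {
      # all paired differences zero: no evidence of any phase difference
      wp <- 1; tp <- 1
    } else {
      wp <- tryCatch(suppressWarnings(
        stats::wilcox.test(v1, v2, paired = TRUE, exact = FALSE)$p.value),
        error = function(e) NA_real_)
      tp <- tryCatch(stats::t.test(v1, v2, paired = TRUE)$p.value,
                     error = function(e) NA_real_)
    }
    data.frame(phase1 = p1, phase2 = p2, n_pairs = length(common),
               wilcoxon_p = wp, t_p = tp,
               wilcoxon_p_bonferroni = pmin(1, wp * m),
               t_p_bonferroni = pmin(1, tp * m), m = m,
               stringsAsFactors = FALSE)
  })
  phaseSummary <- stats::aggregate(value ~ phase, perSample, function(v)
    c(mean = mean(v), median = stats::median(v)))
  list(perSample = perSample,
       phaseSummary = data.frame(phase = phaseSummary$phase,
                                 phaseSummary$value),
       tests = do.call(rbind, tests), summary = summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Self-versus-random beta-diversity comparison
#'
#' The Self distribution is, for each woman with at least two samples, the
#' summary (mean or median) of the pairwise distances among her own samples.
#' For each of \code{nRandom} replicates, a pseudo-woman is built for every
#' woman: her own visit-1 sample plus one sample per remaining phase, each
#' drawn uniformly from the other women (donor women distinct within a
#' pseudo-woman, the focal woman excluded), and summarised the same way.
#' Self is compared to each replicate with an unpaired Wilcoxon test,
#' Bonferroni-corrected over the replicates. The Self summaries do not depend
#' on the seed; only the Random replicates do.
#'
#' @param dist square distance matrix over samples.
#' @param design data.frame with columns woman and visit matching the
#'   distance rows.
#' @param nRandom number of random replicates (default 10).
#' @param seed RNG seed.
#' @param summary "mean" or "median".
#' @return list with \code{self} (named per-woman summaries), \code{random}
#'   (women x replicates matrix), and \code{tests} (replicate, p, Bonferroni
#'   p, m).
#' @export
selfVsRandom <- function(dist, design, nRandom = 10, seed = 1L,
                         summary = c("mean", "median")) {
  summary <- match.arg(summary)
  sfun <- if (summary == "mean") mean else stats::median
  d <- as.matrix(dist)
  stopifnot(nrow(design) == nrow(d), all(c("woman", "visit") %in%
                                         colnames(design)))
  women <- unique(design$woman)
  if (length(women) < 4) stop("need at least 4 women")

  idx <- split(seq_len(nrow(d)), design$woman)
  self <- vapply(idx, function(ix) {
    if (length(ix) < 2) return(NA_real_)
    sfun(d[ix, ix][lower.tri(matrix(0, length(ix), length(ix)))])
  }, numeric(1))
  self <- self[!is.na(self)]

  v1 <- stats::setNames(rownames(d)[design$visit == 1],
                        design$woman[design$visit == 1])
  byPhase <- lapply(2:4, function(v) which(design$visit == v))
  names(byPhase) <- as.character(2:4)

  random <- .withSeed(.substream(seed, "selfvsrandom"), {
    out <- matrix(NA_real_, length(women), nRandom,
                  dimnames = list(women, paste0("Random", seq_len(nRandom))))
    for (r in seq_len(nRandom)) {
      for (w in women) {
        if (!w %in% names(v1)) next
        rows <- match(v1[[w]], rownames(d))
        used <- w
        ok <- TRUE
        for (v in names(byPhase)) {
          cand <- byPhase[[v]]
          cand <- cand[!design$woman[cand] %in% used]
          if (!length(cand)) { ok <- FALSE; break }
          pick <- cand[sample.int(length(cand), 1)]
          used <- c(used, design$woman[pick])
          rows <- c(rows, pick)
        }
        if (!ok) next
        out[w, r] <- sfun(d[rows, rows][lower.tri(diag(length(rows)))])
      }
    }
    out
  })

  m <- nRandom
  tests <- do.call(rbind, lapply(seq_len(nRandom), function(r) {
    p <- stats::wilcox.test(self, random[, r], exact = FALSE)$p.value
    data.frame(replicate = r, p = p, p_bonferroni = min(1, p * m), m = m)
  }))
  list(self = self, random = random, tests = tests, summary = summary)
}
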