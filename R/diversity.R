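#' Alpha diversity indices
#'
#' Shannon-Weiner H = -sum p_i ln p_i and Simpson diversity reported as the
#' complement D = 1 - sum p_i^2 (the raw concentration sum p_i^2 is also
#' returned for completeness).
#'
#' @param counts samples x taxa matrix of counts (or relative abundances).
#' @return data.frame with columns sample_id, shannon, simpson,
#'   simpson_concentration.
#' @export
alphaDiversity <- function(counts) {
  counts <- .assertMatrixLike(counts, "counts")
  if (any(rowSums(counts) <= 0))
    stop("all-zero sample row(s): ",
         paste(rownames(counts)[rowSums(counts) <= 0], collapse = ", "))
  data.frame(
    sample_id = rownames(counts),
    shannon = vegan::diversity(counts, index = "shannon"),
    simpson = vegan::diversity(counts, index = "simpson"),
    simpson_concentration = 1 - vegan::diversity(counts, index = "simpson"),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity matrix
#'
#' BC(x, y) = sum|x_i - y_i| / sum(x_i + y_i) on relative abundances.
#'
#' @param rel samples x taxa relative-abundance matrix.
#' @return square symmetric matrix with attribute \code{metric =
#'   "bray_curtis"}; entries in [0, 1], zero diagonal.
#' @export
brayCurtis <- function(rel) {
  rel <- .assertMatrixLike(rel, "rel")
  if (nrow(rel) < 2) stop("need at least 2 samples")
  d <- as.matrix(vegan::vegdist(rel, method = "bray"))
  attr(d, "metric") <- "bray_curtis"
  d
}

#' Euclidean distance on (residualized) CLR coordinates
#'
#' @param adj samples x taxa matrix of CLR values or covariate-adjusted CLR
#'   residuals.
#' @return square symmetric matrix with attribute \code{metric =
#'   "euclidean_clr"}.
#' @export
euclideanCLR <- function(adj) {
  adj <- .assertMatrixLike(adj, "adj")
  if (nrow(adj) < 2) stop("need at least 2 samples")
  d <- as.matrix(stats::dist(adj))
  attr(d, "metric") <- "euclidean_clr"
  d
}

#' Principal coordinate analysis
#'
#' Classical metric MDS: eigendecomposition of the double-centered Gram
#' matrix. Axes are taken from positive eigenvalues only (warning if fewer
#' than requested); all eigenvalues, including negative ones, are reported.
#'
#' @param dist square distance matrix (or \code{dist}).
#' @param nAxes number of axes to return (default 5).
#' @return object of class \code{cyclevagPCoA}: list with \code{scores}
#'   (samples x axes), \code{eigenvalues}, \code{adjusted} (NULL until
#'   \code{\link{adjustAxes}}), \code{adjustments}.
#' @export
pcoaOrdination <- function(dist, nAxes = 5) {
  d <- stats::as.dist(dist)
  n <- attr(d, "Size")
  fit <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- fit$eig
  nPos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  k <- min(nAxes, nPos)
  if (k < nAxes)
    warning("only ", k, " positive eigenvalues; returning ", k, " axes")
  scores <- fit$points[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("Axis", seq_len(k))
  structure(list(scores = scores, eigenvalues = eig,
                 adjusted = NULL, adjustments = NULL),
            class = "cyclevagPCoA")
}

#' @export
print.cyclevagPCoA <- function(x, ...) {
  relEig <- x$eigenvalues[seq_len(ncol(x$scores))] /
    sum(x$eigenvalues[x$eigenvalues > 0])
  cat("PCoA:", nrow(x$scores), "samples,", ncol(x$scores), "axes (",
      paste(sprintf("%.1f%%", 100 * relEig), collapse = ", "), ")\n")
  if (!is.null(x$adjusted)) cat("  axes adjusted for covariates\n")
  invisible(x)
}

#' Bin a continuous variable into quantile groups
#' @noRd
.binContinuous <- function(x, bins = 3) {
  qs <- stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                        na.rm = TRUE)
  cut(x, breaks = unique(qs), include.lowest = TRUE)
}

#' Per-visit covariate screening of ordination axes
#'
#' Kruskal-Wallis independence tests of each PCoA axis against each variable,
#' run separately within each visit so the longitudinal measurements stay
#' independent. Continuous variables are binned into quantile groups
#' (tertiles by default). Levels observed fewer than twice within a visit are
#' dropped (noted in the output); a variable constant within a visit yields
#' \code{NA} with a reason.
#'
#' @param ordination a \code{cyclevagPCoA}.
#' @param metadata data.frame, rows matching the ordination scores.
#' @param variables character vector of metadata columns to screen.
#' @param bins number of quantile bins for continuous variables (default 3).
#' @return data.frame with columns axis, variable, visit, p, note.
#' @export
screenCovariatesPerVisit <- function(ordination, metadata, variables,
                                     bins = 3) {
  scores <- ordination$scores
  stopifnot(nrow(metadata) == nrow(scores), "visit" %in% colnames(metadata))
  out <- list()
  for (v in sort(unique(metadata$visit))) {
    ix <- which(metadata$visit == v)
    for (var in variables) {
      x <- metadata[[var]][ix]
      g <- if (is.numeric(x) && length(unique(x)) > 6)
        .binContinuous(x, bins) else factor(x)
      note <- ""
      keepLv <- names(table(g))[table(g) >= 2]
      if (length(keepLv) < length(levels(droplevels(g)))) {
        note <- "levels with <2 observations dropped"
        g[!g %in% keepLv] <- NA
      }
      g <- droplevels(factor(g))
      for (ax in colnames(scores)) {
        p <- if (nlevels(g) < 2) {
          note <- "variable constant within visit"
          NA_real_
        } else {
          ok <- !is.na(g)
          sc <- scores[ix, ax][ok]
          if (stats::var(sc) == 0) 1  # tied scores carry no signal
          else stats::kruskal.test(sc, g[ok])$p.value
        }
        out[[length(out) + 1]] <- data.frame(
          axis = ax, variable = var, visit = v, p = p, note = note,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Adjust ordination axes for their significant covariates
#'
#' Each axis is replaced by its OLS residuals on the covariates with which the
#' screening step found a significant association (at \code{alpha}, in any
#' visit); axes with no significant covariate are left unchanged (centered).
#'
#' @param ordination a \code{cyclevagPCoA}.
#' @param metadata data.frame matching the scores rows.
#' @param screen result of \code{\link{screenCovariatesPerVisit}}, or a
#'   data.frame with columns axis, variable (pre-selected pairs).
#' @param alpha significance level applied to \code{screen$p} when present
#'   (default 0.05).
#' @return the ordination with \code{adjusted} scores and the
#'   \code{adjustments} record filled in.
#' @export
adjustAxes <- function(ordination, metadata, screen, alpha = 0.05) {
  pairs <- if ("p" %in% colnames(screen))
    unique(screen[!is.na(screen$p) & screen$p < alpha, c("axis", "variable")])
  else unique(screen[, c("axis", "variable")])
  adj <- ordination$scores
  rec <- list()
  for (ax in colnames(adj)) {
    covs <- pairs$variable[pairs$axis == ax]
    rec[[ax]] <- covs
    if (length(covs)) {
      adj[, ax] <- residualizeTaxa(adj[, ax, drop = FALSE], metadata,
                                   modelId = covs)[, 1]
    } else {
      adj[, ax] <- adj[, ax] - mean(adj[, ax])
    }
  }
  ordination$adjusted <- adj
  ordination$adjustments <- rec
  ordination
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: pseudo-F from the
#' partitioned sums of squared distances, with the p-value computed as
#' (1 + #\{F_perm >= F_obs\}) / (1 + nPerm) over permutations of sample
#' labels.
#'
#' @param dist square distance matrix (or \code{dist}).
#' @param grouping factor-like vector, one entry per sample, with at least two
#'   levels each holding at least two samples.
#' @param nPerm number of permutations (default 999).
#' @param seed RNG seed.
#' @return list with \code{F}, \code{R2}, \code{p}, \code{nPerm}.
#' @export
permanovaTest <- function(dist, grouping, nPerm = 999, seed = 1L) {
  g <- factor(grouping)
  if (nlevels(g) < 2) stop("grouping must have at least 2 levels")
  if (any(table(g) < 2)) stop("each group needs at least 2 samples")
  d <- stats::as.dist(dist)
  df <- data.frame(g = g)
  fit <- .withSeed(seed,
    vegan::adonis2(d ~ g, data = df, permutations = nPerm))
  list(F = fit$F[1], R2 = fit$R2[1], p = fit$`Pr(>F)`[1], nPerm = nPerm)
}

#' Friedman test of alpha diversity across the four phases
#'
#' Uses only women observed at all four visits (complete cases).
#'
#' @param values numeric vector, one per sample.
#' @param design data.frame with columns woman and visit matching
#'   \code{values}.
#' @return list with \code{statistic}, \code{p}, \code{nWomen}.
#' @export
friedmanAlpha <- function(values, design) {
  stopifnot(length(values) == nrow(design))
  wide <- tapply(values, list(design$woman, design$visit), identity)
  complete <- wide[stats::complete.cases(wide), , drop = FALSE]
  if (nrow(complete) < 2)
    stop("need at least 2 women with complete visit series")
  ft <- suppressWarnings(stats::friedman.test(as.matrix(complete)))
  stat <- unname(ft$statistic)
  p <- ft$p.value
  if (!is.finite(stat)) { stat <- 0; p <- 1 }  # all-tied data carry no signal
  list(statistic = stat, p = p, nWomen = nrow(complete))
}
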