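#' Convert counts to relative abundances
#'
#' @param counts samples x taxa matrix with positive row sums.
#' @return samples x taxa matrix of fractions, rows summing to 1.
#' @export
relativeAbundance <- function(counts) {
  counts <- .assertMatrixLike(counts, "counts")
  rs <- rowSums(counts)
  if (any(rs <= 0))
    stop("all-zero sample row(s): ",
         paste(rownames(counts)[rs <= 0], collapse = ", "))
  counts / rs
}

#' Centered log-ratio transform
#'
#' Per row, \code{clr_i = ln(x_i + eps) - mean_j ln(x_j + eps)}, so every row
#' sums to zero. When zeros are present a positive pseudocount is required;
#' the default is half the smallest nonzero relative abundance of the table,
#' recorded in the \code{"pseudocount"} attribute of the result.
#'
#' @param rel samples x taxa relative-abundance matrix.
#' @param pseudocount additive constant; \code{NULL} (default) chooses
#'   min(nonzero)/2 if zeros are present, else 0.
#' @return samples x taxa matrix of CLR coordinates.
#' @export
clrTransform <- function(rel, pseudocount = NULL) {
  rel <- .assertMatrixLike(rel, "rel")
  hasZero <- any(rel == 0)
  if (is.null(pseudocount))
    pseudocount <- if (hasZero) min(rel[rel > 0]) / 2 else 0
  if (hasZero && pseudocount <= 0)
    stop("zeros present: a positive pseudocount is required")
  lg <- log(rel + pseudocount)
  out <- lg - rowMeans(lg)
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Filter taxa on prevalence and mean abundance
#'
#' A taxon is kept iff its prevalence (fraction of samples with abundance
#' strictly above zero) strictly exceeds \code{minPrevalence} AND its mean
#' relative abundance across all samples strictly exceeds
#' \code{minMeanAbund}. Both thresholds are strict.
#'
#' @param rel samples x taxa relative-abundance matrix.
#' @param minPrevalence prevalence threshold (default 0.20).
#' @param minMeanAbund mean-abundance threshold (default 0.001, i.e. 0.10%).
#' @return character vector of retained taxon names.
#' @export
filterTaxa <- function(rel, minPrevalence = 0.20, minMeanAbund = 0.001) {
  rel <- .assertMatrixLike(rel, "rel")
  prev <- colMeans(rel > 0)
  meanAb <- colMeans(rel)
  colnames(rel)[prev > minPrevalence & meanAb > minMeanAbund]
}

#' The stepwise covariate ladder
#'
#' Ten cumulative covariate sets used to adjust CLR-transformed taxa: model 1
#' uses no covariates (centering only), model 2 adds the technical covariates
#' (Qubit_DNA, Qubit_Library, Total_counts), and models 3-10 add, one at a
#' time: Age, sex_less_than_two_days, Pregnancy_category, Pill_use,
#' Swab_after_feces, Bristol_stool_scale, Swab_morning_or_not, WHR_ranges.
#'
#' @return list of 10 character vectors of covariate names.
#' @export
covariateLadder <- function() {
  steps <- list(
    character(0),
    c("Qubit_DNA", "Qubit_Library", "Total_counts"),
    "Age", "sex_less_than_two_days", "Pregnancy_category", "Pill_use",
    "Swab_after_feces", "Bristol_stool_scale", "Swab_morning_or_not",
    "WHR_ranges")
  out <- vector("list", 10)
  acc <- character(0)
  for (k in 1:10) {
    acc <- c(acc, steps[[k]])
    out[[k]] <- acc
  }
  out
}

#' Build an OLS design matrix from covariates
#'
#' Categorical covariates expand to treatment-coded indicators with the most
#' frequent level as reference. Returns the design without intercept column
#' (centering handles the intercept).
#' @noRd
.designMatrix <- function(metadata, covariates) {
  if (!length(covariates)) return(matrix(0, nrow(metadata), 0))
  miss <- setdiff(covariates, colnames(metadata))
  if (length(miss))
    stop("metadata lacks covariate(s): ", paste(miss, collapse = ", "))
  df <- metadata[, covariates, drop = FALSE]
  for (cv in covariates) {
    if (!is.numeric(df[[cv]])) {
      f <- factor(df[[cv]])
      ref <- names(sort(table(f), decreasing = TRUE))[1]
      df[[cv]] <- stats::relevel(f, ref = ref)
    }
  }
  X <- stats::model.matrix(~ ., data = df)
  X[, -1, drop = FALSE]
}

#' Residualize CLR taxa on a covariate-ladder step
#'
#' Per taxon, ordinary least-squares residuals of the CLR abundance on the
#' covariate design of ladder step \code{modelId} (model 1 = centering only).
#' Rows with missing covariate values are dropped listwise with a message.
#' Sample order is preserved.
#'
#' @param clr samples x taxa CLR matrix.
#' @param metadata data.frame of covariates, rows matching \code{clr} rows
#'   (by rownames when present).
#' @param modelId ladder step in 1..10, or a character vector of covariate
#'   names for a custom design.
#' @return samples x taxa residual matrix with attributes \code{modelId} and
#'   \code{covariates}.
#' @export
residualizeTaxa <- function(clr, metadata, modelId = 1L) {
  clr <- .assertMatrixLike(clr, "clr")
  if (is.numeric(modelId)) {
    stopifnot(modelId %in% 1:10)
    covariates <- covariateLadder()[[modelId]]
  } else {
    covariates <- modelId
    modelId <- NA_integer_
  }
  if (!is.null(rownames(clr)) && !is.null(rownames(metadata)))
    metadata <- metadata[rownames(clr), , drop = FALSE]
  if (nrow(metadata) != nrow(clr))
    stop("metadata rows do not match clr rows")
  complete <- if (length(covariates))
    stats::complete.cases(metadata[, covariates, drop = FALSE])
  else rep(TRUE, nrow(clr))
  if (any(!complete))
    message(sum(!complete), " sample(s) dropped for missing covariates")
  Y <- clr[complete, , drop = FALSE]
  X <- .designMatrix(metadata[complete, , drop = FALSE], covariates)
  Xc <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(Xc)
  if (qrX$rank < ncol(Xc)) {
    drop <- colnames(Xc)[qrX$pivot[(qrX$rank + 1):ncol(Xc)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(drop, collapse = ", "))
  }
  res <- as.matrix(stats::lm.fit(Xc, Y)$residuals)
  dimnames(res) <- dimnames(Y)
  attr(res, "modelId") <- modelId
  attr(res, "covariates") <- covariates
  res
}

#' Dominance summary per taxon
#'
#' A sample is dominated by a taxon when that taxon's relative abundance is
#' strictly above \code{threshold}; a woman counts as ever-dominated when any
#' of her samples is. Also reports prevalence and mean relative abundance per
#' cycle phase.
#'
#' @param rel samples x taxa relative-abundance matrix.
#' @param design data.frame with rows matching \code{rel} and columns
#'   \code{woman} and \code{visit} (or \code{phase}).
#' @param threshold dominance threshold (default 0.60, strict).
#' @return list with \code{dominance} (data.frame per taxon: fraction of
#'   samples dominated, fraction of women ever dominated) and \code{perPhase}
#'   (per taxon and phase: prevalence and mean abundance).
#' @export
dominanceSummary <- function(rel, design, threshold = 0.60) {
  rel <- .assertMatrixLike(rel, "rel")
  stopifnot(nrow(design) == nrow(rel), "woman" %in% colnames(design))
  phase <- if ("phase" %in% colnames(design)) design$phase
           else visitPhase(design$visit)
  dom <- rel > threshold
  womenOf <- split(seq_len(nrow(rel)), design$woman)
  fracWomen <- vapply(colnames(rel), function(tx) {
    mean(vapply(womenOf, function(ix) any(dom[ix, tx]), logical(1)))
  }, numeric(1))
  dominance <- data.frame(
    taxon = colnames(rel),
    frac_samples_dominated = colMeans(dom),
    frac_women_dominated = fracWomen,
    prevalence = colMeans(rel > 0),
    mean_abundance = colMeans(rel),
    row.names = NULL, stringsAsFactors = FALSE)
  ph <- factor(phase, levels = .PHASES)
  perPhase <- do.call(rbind, lapply(levels(ph), function(p) {
    ix <- which(ph == p)
    data.frame(taxon = colnames(rel), phase = p,
               prevalence = colMeans(rel[ix, , drop = FALSE] > 0),
               mean_abundance = colMeans(rel[ix, , drop = FALSE]),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  list(dominance = dominance, perPhase = perPhase, threshold = threshold)
}
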