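#' @importFrom lme4 lmer fixef VarCorr isSingular refit lmerControl
NULL

.lmerCtrl <- function() {
  lme4::lmerControl(check.conv.singular = "ignore", calc.derivs = FALSE)
}

#' Fit one Gaussian random-intercept visit model
#'
#' \code{y ~ visit_number + (1|woman)}, REML. The p-value for the visit slope
#' uses the normal approximation on t = beta/SE by default; with
#' \code{dfMethod = "satterthwaite"} (requires lmerTest) the Satterthwaite
#' degrees of freedom are used instead.
#' @noRd
.fitVisitOne <- function(y, design, dfMethod = "normal") {
  df <- data.frame(y = y, visit_number = design$visit, woman = design$woman)
  df <- df[stats::complete.cases(df), ]
  fit <- NULL
  singular <- FALSE
  converged <- TRUE
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(y ~ visit_number + (1 | woman), data = df, REML = TRUE,
                 control = .lmerCtrl()))),
    error = function(e) NULL)
  if (is.null(fit)) {
    # degenerate data (e.g. zero residual variance): fall back to OLS with
    # woman fixed effects so a slope is still reported
    lmfit <- stats::lm(y ~ visit_number + factor(woman), data = df)
    co <- summary(lmfit)$coefficients
    beta <- co["visit_number", 1]
    se <- co["visit_number", 2]
    if (!is.finite(se)) se <- 0
    p <- if (se > 0) 2 * stats::pnorm(-abs(beta / se)) else
      if (abs(beta) < 1e-12) 1 else 0
    return(list(beta = beta, se = se, p = p,
                varBetween = NA_real_, varResid = 0, singular = TRUE,
                converged = FALSE, n = nrow(df), fit = NULL))
  }
  beta <- lme4::fixef(fit)[["visit_number"]]
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))[["visit_number"]]
  p <- if (dfMethod == "satterthwaite" &&
           requireNamespace("lmerTest", quietly = TRUE)) {
    fitT <- suppressMessages(suppressWarnings(
      lmerTest::lmer(y ~ visit_number + (1 | woman), data = df, REML = TRUE)))
    stats::coef(summary(fitT))["visit_number", "Pr(>|t|)"]
  } else {
    2 * stats::pnorm(-abs(beta / se))
  }
  vc <- lme4::VarCorr(fit)
  vb <- as.numeric(vc$woman)
  vr <- stats::sigma(fit)^2
  # singular when either variance component collapses to the boundary
  singular <- lme4::isSingular(fit) || vr < 1e-6 * (vb + vr)
  list(beta = beta, se = se, p = p,
       varBetween = vb, varResid = vr,
       singular = singular, converged = converged, n = nrow(df), fit = fit)
}

#' Visit-trajectory models for every taxon
#'
#' Fits the Gaussian random-intercept model
#' \code{taxon_adj ~ visit_number + (1|woman)} per taxon, where
#' \code{taxon_adj} are covariate-ladder residuals (see
#' \code{\link{residualizeTaxa}}) and visit_number is numeric 1-4. Optionally
#' derives a permutation empirical p-value per taxon by permuting the taxon's
#' abundance column across all rows, refitting, and taking the proportion of
#' permutation p-values at or below the observed one (exact proportion; 0 is
#' attainable). Benjamini-Hochberg q-values are computed over the taxa family
#' from the asymptotic (not empirical) p-values.
#'
#' @param adj samples x taxa matrix of adjusted CLR abundances.
#' @param design data.frame with columns woman and visit matching the rows.
#' @param nPerm permutations for the empirical p-value (0 = skip).
#' @param seed master seed; per-taxon substreams are derived by hashing the
#'   taxon name, so adding a taxon never changes another taxon's permutations.
#' @param dfMethod "normal" (default) or "satterthwaite".
#' @return data.frame, one row per taxon: beta, se, ci_lo, ci_hi, p,
#'   p_empirical, q, n, singular, converged, model_id.
#' @export
fitVisitModels <- function(adj, design, nPerm = 0, seed = 1L,
                           dfMethod = c("normal", "satterthwaite")) {
  dfMethod <- match.arg(dfMethod)
  adj <- .assertMatrixLike(adj, "adj")
  stopifnot(nrow(design) == nrow(adj))
  modelId <- attr(adj, "modelId") %||% NA_integer_
  rows <- lapply(colnames(adj), function(tx) {
    f <- .fitVisitOne(adj[, tx], design, dfMethod)
    pEmp <- NA_real_
    flag <- ""
    if (nPerm > 0 && !is.null(f$fit)) {
      ep <- .empiricalPvalueRefit(f$fit, f$p, nPerm,
                                  .substream(seed, "visitperm", tx))
      pEmp <- ep$p_empirical
      if (ep$frac_failed > 0.2) flag <- "unreliable_permutations"
    }
    data.frame(taxon = tx, model_id = modelId, beta = f$beta, se = f$se,
               ci_lo = f$beta - 1.96 * f$se, ci_hi = f$beta + 1.96 * f$se,
               p = f$p, p_empirical = pEmp, n = f$n,
               singular = f$singular, converged = f$converged, flag = flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- fdrAdjust(out$p)
  out
}

#' Empirical p-value by response permutation with lme4::refit
#' @noRd
.empiricalPvalueRefit <- function(fit, pObs, nPerm, seed) {
  y <- stats::model.frame(fit)[[1]]
  pPerm <- .withSeed(seed, {
    vapply(seq_len(nPerm), function(i) {
      yp <- sample(y)
      tryCatch({
        rf <- suppressMessages(suppressWarnings(lme4::refit(fit, yp)))
        b <- lme4::fixef(rf)[["visit_number"]]
        s <- sqrt(diag(as.matrix(stats::vcov(rf))))[["visit_number"]]
        2 * stats::pnorm(-abs(b / s))
      }, error = function(e) NA_real_)
    }, numeric(1))
  })
  failed <- mean(is.na(pPerm))
  list(p_empirical = empiricalP(pObs, pPerm[!is.na(pPerm)]),
       frac_failed = failed)
}

#' Permutation empirical p-value
#'
#' The proportion of permutation p-values less than or equal to the observed
#' p-value, as an exact proportion over the permutations run (0 is
#' attainable; the minimum positive value is 1/nPerm).
#'
#' @param pObs observed p-value.
#' @param pPerm vector of permutation p-values.
#' @return empirical p in [0, 1].
#' @examples
#' empiricalP(0.01, c(rep(0.005, 50), runif(950, 0.02, 1)))  # 0.05
#' @export
empiricalP <- function(pObs, pPerm) {
  if (!length(pPerm)) return(NA_real_)
  sum(pPerm <= pObs) / length(pPerm)
}

#' Benjamini-Hochberg q-values
#'
#' @param p vector of p-values in [0, 1].
#' @return step-up BH adjusted q-values.
#' @export
fdrAdjust <- function(p) {
  if (!length(p)) stop("empty p-value vector")
  stats::p.adjust(p, method = "BH")
}

#' Intraclass correlation per taxon
#'
#' Variance decomposition of the random-intercept visit model: ICC =
#' between-woman variance / (between-woman + residual variance), quantifying
#' the stability of a taxon's abundance across time points within women.
#' Singular fits are reported at the boundary (0 or 1) with a flag.
#'
#' @param adj samples x taxa matrix of adjusted CLR abundances (typically the
#'   technical-covariate ladder step).
#' @param design data.frame with columns woman and visit.
#' @return data.frame per taxon: var_between, var_resid, icc, singular.
#' @export
iccTaxa <- function(adj, design) {
  adj <- .assertMatrixLike(adj, "adj")
  rows <- lapply(colnames(adj), function(tx) {
    f <- .fitVisitOne(adj[, tx], design)
    vb <- f$varBetween
    vr <- f$varResid
    icc <- if (is.na(vb)) 1 else if (vb + vr <= 0) 0 else vb / (vb + vr)
    data.frame(taxon = tx, var_between = vb, var_resid = vr, icc = icc,
               singular = f$singular, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Remove hormone outliers
#'
#' Per hormone, values more than \code{k} standard deviations from the mean
#' (mean and SD computed once over all non-missing samples, all visits
#' pooled) are set to missing.
#'
#' @param hormones samples x hormones numeric matrix.
#' @param k SD multiplier (default 4).
#' @return list with \code{hormones} (cleaned matrix) and \code{removed}
#'   (data.frame hormone, sample_id, value).
#' @export
removeHormoneOutliers <- function(hormones, k = 4) {
  hormones <- .assertMatrixLike(hormones, "hormones")
  log <- list()
  for (h in colnames(hormones)) {
    x <- hormones[, h]
    if (sum(!is.na(x)) < 3) stop("need at least 3 values for hormone ", h)
    m <- mean(x, na.rm = TRUE)
    s <- stats::sd(x, na.rm = TRUE)
    out <- !is.na(x) & abs(x - m) > k * s
    if (any(out)) {
      log[[h]] <- data.frame(
        hormone = h,
        sample_id = rownames(hormones)[out] %||% which(out),
        value = x[out], stringsAsFactors = FALSE)
      hormones[out, h] <- NA_real_
    }
  }
  list(hormones = hormones,
       removed = if (length(log)) do.call(rbind, c(log, make.row.names = FALSE))
                 else data.frame(hormone = character(0),
                                 sample_id = character(0),
                                 value = numeric(0)))
}

.TRANSITIONS <- c("F->O", "O->EL", "EL->LL")

#' Differences between consecutive cycle phases
#'
#' Computes value(t+1) - value(t) per woman for consecutive available visit
#' pairs only; pairs spanning a gap (e.g. visits 1 and 3 with visit 2
#' missing) are skipped.
#'
#' @param values samples x variables matrix (or a vector).
#' @param design data.frame with columns woman and visit matching the rows.
#' @return data.frame with columns woman, transition (F->O, O->EL, EL->LL),
#'   from_visit, to_visit, and one delta column per input variable.
#' @export
consecutiveDifferences <- function(values, design) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1,
                                             dimnames = list(NULL, "value"))
  values <- .assertMatrixLike(values, "values")
  stopifnot(nrow(design) == nrow(values))
  out <- list()
  for (w in unique(design$woman)) {
    ix <- which(design$woman == w)
    vs <- design$visit[ix]
    for (t in 1:3) {
      i1 <- ix[vs == t]; i2 <- ix[vs == t + 1]
      if (length(i1) == 1 && length(i2) == 1) {
        row <- data.frame(woman = w, transition = .TRANSITIONS[t],
                          from_visit = t, to_visit = t + 1,
                          stringsAsFactors = FALSE)
        out[[length(out) + 1]] <- cbind(row, t(values[i2, ] - values[i1, ]))
      }
    }
  }
  if (!length(out))
    return(data.frame(woman = character(0), transition = character(0),
                      from_visit = integer(0), to_visit = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rank-based inverse normal transform (ordered quantile normalisation)
#'
#' Maps values through normal quantiles: y_i = qnorm(rank_i / (n + 1)) with
#' mid-ranks for ties; missing values propagate. All-identical input returns
#' zeros with a warning.
#'
#' @param x numeric vector.
#' @return transformed vector of the same length.
#' @export
orderNorm <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 3) stop("need at least 3 non-missing values")
  out <- rep(NA_real_, length(x))
  if (length(unique(x[ok])) == 1) {
    warning("all values identical; returning zeros")
    out[ok] <- 0
    return(out)
  }
  r <- rank(x[ok], ties.method = "average")
  out[ok] <- stats::qnorm(r / (sum(ok) + 1))
  out
}

#' Hormone-change versus taxa-change models per transition
#'
#' For each (hormone, taxon, transition): Gaussian model of the ordernorm-
#' transformed hormone difference on the ordernorm-transformed adjusted-taxon
#' difference. With at most one observation per woman per transition the
#' random intercept is unidentifiable, so the fit is OLS within transition;
#' \code{clusterBy} switches to woman-clustered robust standard errors
#' (requires the sandwich package). Empirical p-values permute the taxa-
#' difference column within the transition. BH q-values are computed over the
#' whole (hormone x taxon x transition) family from asymptotic p-values.
#'
#' @param dHormones rows x hormones matrix of transformed hormone differences.
#' @param dTaxa rows x taxa matrix of transformed taxa differences.
#' @param transition character vector per row (values among F->O, O->EL,
#'   EL->LL).
#' @param nPerm permutations for empirical p (0 = skip).
#' @param seed master seed.
#' @param clusterBy optional vector of woman ids for clustered SEs.
#' @param minN below this many complete pairs the fit is flagged low_n
#'   (default 10).
#' @return tidy data.frame: hormone, taxon, transition, beta, se, p,
#'   p_empirical, q, n, flag.
#' @export
fitDifferenceModels <- function(dHormones, dTaxa, transition, nPerm = 0,
                                seed = 1L, clusterBy = NULL, minN = 10) {
  dHormones <- .assertMatrixLike(dHormones, "dHormones")
  dTaxa <- .assertMatrixLike(dTaxa, "dTaxa")
  stopifnot(nrow(dHormones) == nrow(dTaxa),
            length(transition) == nrow(dTaxa))
  rows <- list()
  for (tr in unique(transition)) {
    sel <- which(transition == tr)
    for (h in colnames(dHormones)) {
      for (tx in colnames(dTaxa)) {
        dh <- dHormones[sel, h]; dt <- dTaxa[sel, tx]
        ok <- stats::complete.cases(dh, dt)
        dh <- dh[ok]; dt <- dt[ok]
        flag <- if (length(dh) < minN) "low_n" else ""
        if (length(dh) < 3 || stats::sd(dt) == 0) {
          rows[[length(rows) + 1]] <- data.frame(
            hormone = h, taxon = tx, transition = tr, beta = NA_real_,
            se = NA_real_, p = NA_real_, p_empirical = NA_real_,
            n = length(dh), flag = "degenerate", stringsAsFactors = FALSE)
          next
        }
        fit <- stats::lm(dh ~ dt)
        co <- summary(fit)$coefficients
        beta <- co["dt", 1]; se <- co["dt", 2]; p <- co["dt", 4]
        if (!is.null(clusterBy)) {
          if (!requireNamespace("sandwich", quietly = TRUE))
            stop("clusterBy requires the sandwich package")
          vc <- sandwich::vcovCL(fit, cluster = clusterBy[sel][ok])
          se <- sqrt(vc["dt", "dt"])
          p <- 2 * stats::pnorm(-abs(beta / se))
        }
        pEmp <- NA_real_
        if (nPerm > 0) {
          pPerm <- .withSeed(.substream(seed, "diffperm", h, tx, tr), {
            vapply(seq_len(nPerm), function(i) {
              summary(stats::lm(dh ~ sample(dt)))$coefficients[2, 4]
            }, numeric(1))
          })
          pEmp <- empiricalP(p, pPerm)
        }
        rows[[length(rows) + 1]] <- data.frame(
          hormone = h, taxon = tx, transition = tr, beta = beta, se = se,
          p = p, p_empirical = pEmp, n = length(dh), flag = flag,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  if (any(ok)) out$q[ok] <- fdrAdjust(out$p[ok])
  out
}

#' Overall hormone-taxa association model
#'
#' \code{hormone ~ visit_number + taxon_adj + (1|woman) + Pregnancy_category},
#' Gaussian with a random intercept per woman; the focal coefficient is the
#' adjusted-taxon term. The empirical p-value permutes the taxa column (a
#' predictor) across all rows and refits the full model.
#'
#' @param hormone numeric vector per sample (outlier-cleaned).
#' @param taxonAdj numeric vector of adjusted CLR abundances per sample.
#' @param design data.frame with columns woman, visit, Pregnancy_category.
#' @param nPerm permutations for the empirical p (0 = skip).
#' @param seed RNG seed.
#' @return one-row data.frame: beta, se, ci_lo, ci_hi, p, p_empirical, n,
#'   singular, converged.
#' @export
fitOverallHormoneModel <- function(hormone, taxonAdj, design, nPerm = 0,
                                   seed = 1L) {
  stopifnot(length(hormone) == nrow(design),
            length(taxonAdj) == nrow(design))
  if (stats::sd(taxonAdj, na.rm = TRUE) == 0)
    stop("zero-variance predictor: taxa column is constant")
  df <- data.frame(h = hormone, y = taxonAdj, visit_number = design$visit,
                   woman = design$woman,
                   Pregnancy_category = factor(design$Pregnancy_category))
  df <- df[stats::complete.cases(df), ]
  fitOne <- function(d) {
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(h ~ visit_number + y + (1 | woman) + Pregnancy_category,
                 data = d, REML = TRUE, control = .lmerCtrl())))
    beta <- lme4::fixef(fit)[["y"]]
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))[["y"]]
    list(beta = beta, se = se, p = 2 * stats::pnorm(-abs(beta / se)),
         singular = lme4::isSingular(fit))
  }
  f <- fitOne(df)
  pEmp <- NA_real_
  if (nPerm > 0) {
    pPerm <- .withSeed(.substream(seed, "overallperm"), {
      vapply(seq_len(nPerm), function(i) {
        d <- df
        d$y <- sample(d$y)
        tryCatch(fitOne(d)$p, error = function(e) NA_real_)
      }, numeric(1))
    })
    pEmp <- empiricalP(f$p, pPerm[!is.na(pPerm)])
  }
  data.frame(beta = f$beta, se = f$se,
             ci_lo = f$beta - 1.96 * f$se, ci_hi = f$beta + 1.96 * f$se,
             p = f$p, p_empirical = pEmp, n = nrow(df),
             singular = f$singular, converged = TRUE,
             stringsAsFactors = FALSE)
}

#' Overall hormone-taxa associations for all pairs
#'
#' Runs \code{\link{fitOverallHormoneModel}} for every (hormone, taxon) pair
#' and adds BH q-values over the whole hormone x taxa family (declared
#' significance threshold 0.2, recorded in the \code{fdr_threshold}
#' attribute).
#'
#' @param hormones samples x hormones matrix (outlier-cleaned).
#' @param adj samples x taxa adjusted CLR matrix (taxa pre-filtered).
#' @param design data.frame with woman, visit, Pregnancy_category.
#' @param nPerm permutations for empirical p (0 = skip).
#' @param seed master seed; per-(hormone, taxon) substreams by hashing.
#' @param fdrThreshold declared FDR threshold (default 0.2).
#' @return tidy data.frame: hormone, taxon, beta, se, ci_lo, ci_hi, p,
#'   p_empirical, q, significant, n, singular.
#' @export
fitOverallHormoneModels <- function(hormones, adj, design, nPerm = 0,
                                    seed = 1L, fdrThreshold = 0.2) {
  hormones <- .assertMatrixLike(hormones, "hormones")
  adj <- .assertMatrixLike(adj, "adj")
  rows <- list()
  for (h in colnames(hormones)) {
    for (tx in colnames(adj)) {
      r <- tryCatch(
        fitOverallHormoneModel(hormones[, h], adj[, tx], design,
                               nPerm = nPerm,
                               seed = .substream(seed, "overall", h, tx)),
        error = function(e) NULL)
      if (is.null(r)) next
      rows[[length(rows) + 1]] <- cbind(
        data.frame(hormone = h, taxon = tx, stringsAsFactors = FALSE), r)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- fdrAdjust(out$p)
  out$significant <- out$q < fdrThreshold
  attr(out, "fdr_threshold") <- fdrThreshold
  out
}
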