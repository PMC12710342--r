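#' Read a centroid table
#'
#' TSV with first column the CST label and remaining columns the taxa
#' vocabulary; rows are reference compositions summing to 1.
#'
#' @param path file path.
#' @return matrix, centroids x taxa, rownames = CST labels.
#' @export
readCentroids <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  validateCentroids(m)
  m
}

#' Validate a centroid table
#' @param centroids centroids x taxa matrix.
#' @return the matrix invisibly if each row sums to 1 (within 1e-6) and
#'   labels are unique.
#' @export
validateCentroids <- function(centroids) {
  centroids <- .assertMatrixLike(centroids, "centroids")
  if (anyDuplicated(rownames(centroids))) stop("duplicate centroid labels")
  bad <- abs(rowSums(centroids) - 1) > 1e-6
  if (any(bad))
    stop("centroid row(s) not summing to 1: ",
         paste(rownames(centroids)[bad], collapse = ", "))
  invisible(centroids)
}

#' Harmonize sample compositions onto a centroid vocabulary
#'
#' Optionally renames taxa (old to new, colliding names summed), re-expresses
#' each composition on the centroid vocabulary and renormalises. Mass carried
#' by unmapped taxa is either dropped or pooled into an \code{"other"} bucket;
#' the dropped fraction is reported per sample, and samples losing more than
#' half their mass are flagged unclassifiable.
#'
#' @param rel samples x taxa relative-abundance matrix.
#' @param vocabulary character vector of centroid taxa.
#' @param renameMap optional named character vector (old name -> new name).
#' @param unmapped "drop" (default) or "other".
#' @return list with \code{composition} (samples x vocabulary, rows of
#'   classifiable samples summing to 1), \code{droppedMass} per sample, and
#'   \code{unclassifiable} logical vector.
#' @export
harmonizeTaxa <- function(rel, vocabulary, renameMap = NULL,
                          unmapped = c("drop", "other")) {
  unmapped <- match.arg(unmapped)
  rel <- .assertMatrixLike(rel, "rel")
  nm <- colnames(rel)
  if (!is.null(renameMap)) {
    hit <- match(nm, names(renameMap))
    nm[!is.na(hit)] <- unname(renameMap[hit[!is.na(hit)]])
  }
  merged <- t(rowsum(t(rel), group = nm, reorder = FALSE))
  vocab <- if (unmapped == "other") c(vocabulary, "other") else vocabulary
  out <- matrix(0, nrow(rel), length(vocab),
                dimnames = list(rownames(rel), vocab))
  known <- intersect(colnames(merged), vocabulary)
  out[, known] <- merged[, known, drop = FALSE]
  extra <- setdiff(colnames(merged), vocabulary)
  extraMass <- if (length(extra))
    rowSums(merged[, extra, drop = FALSE]) else rep(0, nrow(rel))
  if (unmapped == "other") out[, "other"] <- extraMass
  dropped <- if (unmapped == "drop") extraMass else rep(0, nrow(rel))
  unclassifiable <- dropped > 0.5
  tot <- rowSums(out)
  ok <- tot > 0
  out[ok, ] <- out[ok, , drop = FALSE] / tot[ok]
  list(composition = out, droppedMass = dropped,
       unclassifiable = unclassifiable | !ok)
}

#' Yue-Clayton similarity between two compositions
#'
#' theta = sum(x y) / (sum x^2 + sum y^2 - sum x y); 1 iff x = y, 0 for
#' disjoint supports.
#'
#' @param x,y compositions on the same vocabulary, each summing to 1.
#' @return similarity in [0, 1].
#' @export
yueClaytonSimilarity <- function(x, y) {
  if (length(x) != length(y)) stop("compositions on different vocabularies")
  if (sum(x) == 0 || sum(y) == 0) stop("zero composition vector")
  xy <- sum(x * y)
  xy / (sum(x^2) + sum(y^2) - xy)
}

#' Nearest-centroid CST assignment
#'
#' Assigns each sample the centroid with maximal Yue-Clayton similarity; ties
#' are broken lexicographically by label and flagged. Samples marked
#' unclassifiable (see \code{\link{harmonizeTaxa}}) carry an NA label.
#'
#' @param rel samples x taxa relative-abundance matrix, on the centroid
#'   vocabulary (use \code{\link{harmonizeTaxa}} first if needed).
#' @param centroids centroids x taxa matrix (rows sum to 1).
#' @param unclassifiable optional logical vector per sample.
#' @return data.frame: sample_id, cst, method, tie, plus one
#'   \code{theta_<label>} score column per centroid.
#' @export
assignCST <- function(rel, centroids, unclassifiable = NULL) {
  rel <- .assertMatrixLike(rel, "rel")
  validateCentroids(centroids)
  common <- intersect(colnames(rel), colnames(centroids))
  if (!length(common)) stop("no taxa shared with the centroid vocabulary")
  labs <- rownames(centroids)
  theta <- matrix(NA_real_, nrow(rel), length(labs),
                  dimnames = list(rownames(rel), paste0("theta_", labs)))
  for (s in seq_len(nrow(rel))) {
    for (k in seq_along(labs)) {
      theta[s, k] <- yueClaytonSimilarity(rel[s, common],
                                          centroids[labs[k], common])
    }
  }
  ord <- order(labs)  # lexicographic tie-break
  best <- apply(theta[, ord, drop = FALSE], 1, which.max)
  cst <- labs[ord][best]
  tie <- apply(theta, 1, function(v) sum(v == max(v)) > 1)
  if (!is.null(unclassifiable)) cst[unclassifiable] <- NA_character_
  data.frame(sample_id = rownames(rel) %||% as.character(seq_len(nrow(rel))),
             cst = cst, method = "centroid", tie = tie,
             theta, row.names = NULL, stringsAsFactors = FALSE)
}

#' Dominance-rule CST assignment
#'
#' Fallback heuristic: label I/II/III/V when the corresponding Lactobacillus
#' marker species strictly exceeds the dominance threshold, otherwise IV.
#'
#' @param rel samples x taxa relative-abundance matrix; taxa must include the
#'   four marker species.
#' @param threshold dominance threshold (default 0.60, strict).
#' @param markers named character vector CST label -> marker taxon.
#' @return data.frame: sample_id, cst, method.
#' @export
dominanceCST <- function(rel, threshold = 0.60, markers = .CST_MARKERS) {
  rel <- .assertMatrixLike(rel, "rel")
  miss <- setdiff(unname(markers), colnames(rel))
  if (length(miss))
    stop("marker taxa absent from table: ", paste(miss, collapse = ", "))
  cst <- rep("CST-IV", nrow(rel))
  for (lab in names(markers)) {
    cst[rel[, markers[[lab]]] > threshold] <- lab
  }
  data.frame(sample_id = rownames(rel) %||% as.character(seq_len(nrow(rel))),
             cst = cst, method = "dominance", stringsAsFactors = FALSE)
}

#' Longitudinal CST transitions
#'
#' Counts label changes between consecutive available visits per woman,
#' tabulates them by phase pair (F->O, O->EL, EL->LL), and classifies each
#' woman as CH (changed, complete data), CH+NA (changed, some visits
#' missing), NO CH, or NO CH+NA.
#'
#' @param assignments data.frame with a \code{cst} column, rows matching
#'   \code{design}.
#' @param design data.frame with columns woman and visit.
#' @return list with \code{transitions} (one row per consecutive pair),
#'   \code{pairCounts} (changes per phase pair), \code{womanClass}, and
#'   \code{nChangedWomen}.
#' @export
cstTransitions <- function(assignments, design) {
  stopifnot(nrow(assignments) == nrow(design))
  cst <- assignments$cst
  rows <- list()
  womanClass <- character(0)
  for (w in unique(design$woman)) {
    ix <- which(design$woman == w)
    vs <- design$visit[ix]
    changed <- FALSE
    for (t in 1:3) {
      i1 <- ix[vs == t]; i2 <- ix[vs == t + 1]
      if (length(i1) == 1 && length(i2) == 1 &&
          !is.na(cst[i1]) && !is.na(cst[i2])) {
        ch <- cst[i1] != cst[i2]
        changed <- changed || ch
        rows[[length(rows) + 1]] <- data.frame(
          woman = w, pair = .TRANSITIONS[t], from_visit = t, to_visit = t + 1,
          from = cst[i1], to = cst[i2], changed = ch,
          stringsAsFactors = FALSE)
      }
    }
    complete <- all(1:4 %in% vs) && !any(is.na(cst[ix]))
    womanClass[w] <- if (changed && complete) "CH"
      else if (changed) "CH+NA"
      else if (complete) "NO CH" else "NO CH+NA"
  }
  transitions <- if (length(rows)) do.call(rbind, rows) else
    data.frame(woman = character(0), pair = character(0),
               from_visit = integer(0), to_visit = integer(0),
               from = character(0), to = character(0), changed = logical(0))
  pairCounts <- vapply(.TRANSITIONS, function(p)
    sum(transitions$changed[transitions$pair == p]), numeric(1))
  list(transitions = transitions, pairCounts = pairCounts,
       womanClass = womanClass,
       nChangedWomen = sum(womanClass %in% c("CH", "CH+NA")))
}
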