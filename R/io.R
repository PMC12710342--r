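#' Read a taxa count table
#'
#' Reads a TSV with a header row and a first column \code{sample_id}; the
#' remaining columns are per-taxon non-negative integer counts. Validation
#' names the offending row/column on failure.
#'
#' @param path file path.
#' @return integer matrix, samples x taxa, rownames = sample ids.
#' @export
readCounts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("no taxa columns in ", path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  validateCounts(m)
  storage.mode(m) <- "integer"
  m
}

#' Validate a taxa count matrix
#'
#' @param counts samples x taxa matrix.
#' @return the matrix, invisibly, if valid; otherwise an error naming the
#'   first offending sample/taxon.
#' @export
validateCounts <- function(counts) {
  counts <- .assertMatrixLike(counts, "counts")
  if (ncol(counts) == 0) stop("no taxa columns")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate taxon names: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  bad <- which(counts < 0 | counts != round(counts) | is.na(counts),
               arr.ind = TRUE)
  if (nrow(bad))
    stop("invalid count at sample '", rownames(counts)[bad[1, 1]],
         "', taxon '", colnames(counts)[bad[1, 2]],
         "': counts must be non-negative integers")
  invisible(counts)
}

#' Write a taxa count table
#'
#' Inverse of \code{\link{readCounts}}: UTF-8, tab-separated, header row,
#' no quoting, first column \code{sample_id}.
#'
#' @param counts samples x taxa matrix.
#' @param path output file path.
#' @export
writeCounts <- function(counts, path) {
  counts <- validateCounts(counts)
  df <- data.frame(sample_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sample-level quality control
#'
#' Applies the three read-based QC rules: a sample is removed iff its input
#' reads are below \code{minInput}, its post-trimming reads are below
#' \code{minSurvived}, or the negative control of its batch shows
#' contamination (more than \code{negCtrlMax} reads). Each removal carries a
#' machine-readable reason code (\code{low_input}, \code{low_survived},
#' \code{contaminated_batch}); a sample failing several rules gets one row per
#' reason. Negative controls themselves are never returned among the kept
#' samples. A batch without a negative control raises a warning and skips the
#' contamination rule for that batch.
#'
#' @param stats data.frame with columns sample_id, input_reads,
#'   survived_reads, batch, is_negative_control.
#' @param minInput minimum input reads (default 80000).
#' @param minSurvived minimum post-trimming reads (default 60000).
#' @param negCtrlMax maximum reads tolerated in a negative control (default
#'   500, strict: removal when strictly above).
#' @return list with \code{kept} (character sample ids) and \code{removed}
#'   (data.frame sample_id, reason).
#' @export
qcFilterSamples <- function(stats, minInput = 80000, minSurvived = 60000,
                            negCtrlMax = 500) {
  need <- c("sample_id", "input_reads", "survived_reads", "batch",
            "is_negative_control")
  miss <- setdiff(need, colnames(stats))
  if (length(miss)) stop("stats lacks columns: ", paste(miss, collapse = ", "))
  if (any(stats$survived_reads > stats$input_reads))
    stop("survived_reads exceeds input_reads")

  ctrl <- stats[stats$is_negative_control, , drop = FALSE]
  smp <- stats[!stats$is_negative_control, , drop = FALSE]
  noCtrl <- setdiff(unique(smp$batch), unique(ctrl$batch))
  if (length(noCtrl))
    warning("batch(es) without negative control, contamination rule skipped: ",
            paste(noCtrl, collapse = ", "))
  contaminated <- unique(ctrl$batch[ctrl$survived_reads > negCtrlMax])

  rm1 <- smp$sample_id[smp$input_reads < minInput]
  rm2 <- smp$sample_id[smp$survived_reads < minSurvived]
  rm3 <- smp$sample_id[smp$batch %in% contaminated]
  removed <- data.frame(
    sample_id = c(rm1, rm2, rm3),
    reason = c(rep("low_input", length(rm1)),
               rep("low_survived", length(rm2)),
               rep("contaminated_batch", length(rm3))),
    stringsAsFactors = FALSE)
  list(kept = setdiff(smp$sample_id, removed$sample_id), removed = removed)
}

#' Rarefy count rows to a fixed depth
#'
#' Each sample whose total exceeds \code{depth} is replaced by a
#' without-replacement (multivariate hypergeometric) draw of exactly
#' \code{depth} reads from its count vector; samples at or below \code{depth}
#' are untouched. Deterministic under \code{seed}. This is the count-space
#' analogue of subsampling FASTQ reads.
#'
#' @param counts samples x taxa integer matrix.
#' @param depth target depth (reads per sample).
#' @param seed RNG seed.
#' @return integer matrix of the same shape.
#' @export
subsampleCounts <- function(counts, depth, seed = 1L) {
  counts <- validateCounts(counts)
  if (depth < 1) stop("depth must be a positive integer")
  over <- rowSums(counts) > depth
  if (any(over)) {
    sub <- .withSeed(.substream(seed, "subsample"),
      suppressWarnings(vegan::rrarefy(counts[over, , drop = FALSE], depth)))
    counts[over, ] <- sub
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Remove rare taxa
#'
#' A taxon is retained iff it has at least \code{minReads} reads in at least
#' \code{minSamples} samples (both thresholds inclusive).
#'
#' @param counts samples x taxa matrix.
#' @param minReads per-sample read threshold (default 5).
#' @param minSamples number of samples that must reach it (default 2).
#' @return the filtered count matrix.
#' @export
rareTaxaFilter <- function(counts, minReads = 5, minSamples = 2) {
  counts <- validateCounts(counts)
  keep <- colSums(counts >= minReads) >= minSamples
  counts[, keep, drop = FALSE]
}

#' Relabel (and merge) taxa columns
#'
#' Renames taxa via an old-name to new-name map; columns mapping to the same
#' new name (including collisions with existing unmapped columns) are summed.
#' Unmapped columns are unchanged. Total counts per sample are conserved
#' exactly.
#'
#' @param counts samples x taxa matrix.
#' @param mapping named character vector, names = old taxa, values = new taxa.
#' @param strict error on map keys absent from the table (default TRUE).
#' @param merge sum colliding columns (default TRUE); with \code{merge =
#'   FALSE} a collision is an error.
#' @return relabelled count matrix; column order follows first appearance.
#' @export
relabelTaxa <- function(counts, mapping, strict = TRUE, merge = TRUE) {
  counts <- validateCounts(counts)
  unknown <- setdiff(names(mapping), colnames(counts))
  if (length(unknown)) {
    if (strict)
      stop("mapping keys not present in table: ",
           paste(unknown, collapse = ", "))
    mapping <- mapping[setdiff(names(mapping), unknown)]
  }
  newNames <- colnames(counts)
  hit <- match(newNames, names(mapping))
  newNames[!is.na(hit)] <- unname(mapping[hit[!is.na(hit)]])
  if (anyDuplicated(newNames) && !merge)
    stop("relabelling produces duplicate taxa (set merge = TRUE to sum them): ",
         paste(unique(newNames[duplicated(newNames)]), collapse = ", "))
  out <- t(rowsum(t(counts), group = newNames, reorder = FALSE))
  storage.mode(out) <- "integer"
  validateCounts(out)
  out
}

#' Read a sample metadata table
#' @param path TSV path with header and a sample_id column.
#' @return data.frame with rownames = sample ids.
#' @export
readMetadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(df)) stop("metadata lacks a sample_id column")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in metadata")
  if ("visit" %in% colnames(df) && !all(df$visit %in% 1:4))
    stop("visit numbers must be in 1..4")
  rownames(df) <- df$sample_id
  df
}

#' Write a cohort to plain-text files
#'
#' Writes counts.tsv, hormones.tsv, metadata.tsv, read_stats.tsv,
#' centroids.tsv and truth.json (ground truth, if present) into a directory.
#'
#' @param cohort a \code{\link{CycleCohort-class}}.
#' @param dir output directory (created if needed).
#' @param config the generating \code{\link{cohortConfig}} used for the
#'   centroid and read-stats fixtures; defaults to the one stored in the
#'   cohort metadata.
#' @return the directory path, invisibly.
#' @export
writeCohort <- function(cohort, dir,
                        config = S4Vectors::metadata(cohort)$config) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeCounts(taxaCounts(cohort), file.path(dir, "counts.tsv"))
  md <- sampleData(cohort)
  utils::write.table(md, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  hm <- data.frame(sample_id = rownames(hormoneLevels(cohort)),
                   hormoneLevels(cohort), check.names = FALSE)
  utils::write.table(hm, file.path(dir, "hormones.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(config)) {
    cent <- generateCentroids(config)
    utils::write.table(
      data.frame(CST = rownames(cent), cent, check.names = FALSE),
      file.path(dir, "centroids.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(generateReadStats(config),
                       file.path(dir, "read_stats.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  gt <- groundTruth(cohort)
  if (!is.null(gt)) {
    gt$intercepts <- NULL; gt$latent <- NULL; gt$hormoneZ <- NULL
    jsonlite::write_json(gt, file.path(dir, "truth.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(dir)
}
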