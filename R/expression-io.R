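## Readers, normalisation and the filter chain for the intron/exon expression
## time courses.  Long-format tables are the native interchange format
## (feature_id, time, replicate, value); a wide reader is also provided.
## All readers tolerate gzip (R connections handle .gz transparently).

#' Read a long-format expression table into a TimeCourseMatrix
#'
#' Expects tab-separated columns \code{feature_id}, \code{time},
#' \code{replicate}, \code{value} (extra columns ignored).  Gzipped files are
#' read transparently.
#'
#' @param path file path (TSV, optionally .gz).
#' @return A \linkS4class{TimeCourseMatrix}.
#' @export
readTimeCourse <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("feature_id", "time", "replicate", "value")
  if (!all(need %in% colnames(df)))
    stop("long-format table needs columns: ", paste(need, collapse = ", "))
  feats <- unique(df$feature_id)
  key <- paste0("t", df$time, "_r", df$replicate)
  cols <- unique(df[, c("time", "replicate")])
  cols <- cols[order(cols$time, cols$replicate), ]
  ckey <- paste0("t", cols$time, "_r", cols$replicate)
  m <- matrix(NA_real_, length(feats), nrow(cols),
              dimnames = list(feats, ckey))
  m[cbind(match(df$feature_id, feats), match(key, ckey))] <- df$value
  if (anyNA(m)) stop("incomplete table: every feature needs every sample")
  TimeCourseMatrix(m, time = cols$time, replicate = cols$replicate)
}

#' Read a wide-format expression table
#'
#' First column \code{feature_id}; remaining columns named \code{t<time>_r<rep>}
#' (e.g. \code{t95_r1}).
#'
#' @param path file path (TSV, optionally .gz).
#' @return A \linkS4class{TimeCourseMatrix}.
#' @export
readTimeCourseWide <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(colnames(df)[1] == "feature_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$feature_id
  parts <- regmatches(colnames(m),
                      regexec("^t([0-9.]+)_r([0-9]+)$", colnames(m)))
  if (any(lengths(parts) != 3))
    stop("wide columns must be named t<time>_r<replicate>")
  TimeCourseMatrix(m,
                   time = as.numeric(vapply(parts, `[`, "", 2)),
                   replicate = as.integer(vapply(parts, `[`, "", 3)))
}

#' Write a TimeCourseMatrix as a long-format TSV
#'
#' @param x a \linkS4class{TimeCourseMatrix}.
#' @param path output path (".gz" suffix writes gzipped).
#' @return \code{path}, invisibly.
#' @export
writeTimeCourse <- function(x, path) {
  cd <- SummarizedExperiment::colData(x)
  v <- exprValues(x)
  df <- data.frame(
    feature_id = rep(rownames(v), times = ncol(v)),
    time = rep(cd$time, each = nrow(v)),
    replicate = rep(cd$replicate, each = nrow(v)),
    value = as.vector(v))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature annotation table
#'
#' TSV with columns \code{feature_id}, \code{gene_id} and any of
#' \code{total_intron_length}, \code{transcript_length}, \code{utr3_length}
#' (nt; NA where absent, e.g. intronless genes).
#'
#' @param path file path (TSV, optionally .gz).
#' @return data.frame keyed by \code{feature_id}.
#' @export
readFeatureAnnotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("feature_id", "gene_id") %in% colnames(df)))
    stop("annotation needs columns feature_id and gene_id")
  lenCols <- intersect(c("total_intron_length", "transcript_length",
                         "utr3_length"), colnames(df))
  for (cc in lenCols)
    if (any(df[[cc]] <= 0, na.rm = TRUE))
      stop("annotation lengths must be > 0 where present: ", cc)
  df
}

#' Modified RPKM normalisation
#'
#' Reads per kilobase per million mapped reads, where the total mapped reads
#' of each library normalises both the exon and the intron counts from that
#' sample: value = counts * 1e9 / (feature_length * library_total).
#'
#' @param counts integer/numeric matrix, features x samples.
#' @param featureLengths nt lengths, one per row; must be > 0.
#' @param libraryTotals total mapped reads per sample (column); must be > 0.
#' @param time,replicate per-column design, as in [TimeCourseMatrix()].
#' @return A \linkS4class{TimeCourseMatrix} of RPKM values.
#' @examples
#' rpkmModified(matrix(1000), 1000, 1e6,
#'              time = c(95, 105), replicate = c(1, 1))  # -> 1000
#' @export
rpkmModified <- function(counts, featureLengths, libraryTotals,
                         time, replicate) {
  counts <- as.matrix(counts)
  if (any(!is.finite(featureLengths)) || any(featureLengths <= 0))
    stop("feature lengths must be finite and > 0")
  if (any(!is.finite(libraryTotals)) || any(libraryTotals <= 0))
    stop("library totals must be finite and > 0")
  stopifnot(length(featureLengths) == nrow(counts),
            length(libraryTotals) == ncol(counts))
  v <- sweep(sweep(counts, 1, featureLengths, "/"), 2, libraryTotals, "/") * 1e9
  TimeCourseMatrix(v, time = time, replicate = replicate,
                   featureIDs = rownames(counts))
}

#' Normalise intronic reads by total intron length
#'
#' Divides each gene's intronic series by that gene's total intron length so
#' the production/splicing parameter S is comparable across genes.
#' Intronless genes (absent \code{total_intron_length}) are excluded with a
#' message.
#'
#' @param intronCounts a \linkS4class{TimeCourseMatrix} of gene-level
#'   intronic reads.
#' @param annotation data.frame from [readFeatureAnnotation()] with
#'   \code{feature_id} and \code{total_intron_length}.
#' @return A \linkS4class{TimeCourseMatrix} restricted to intron-bearing genes.
#' @export
normalizeIntronLengths <- function(intronCounts, annotation) {
  stopifnot(is(intronCounts, "TimeCourseMatrix"))
  len <- annotation$total_intron_length[
    match(rownames(intronCounts), annotation$feature_id)]
  drop <- is.na(len) | len <= 0
  if (any(drop))
    message(sum(drop), " intronless gene(s) excluded from intron-length ",
            "normalisation: ", paste(utils::head(rownames(intronCounts)[drop], 5),
                                     collapse = ", "),
            if (sum(drop) > 5) ", ..." else "")
  keep <- which(!drop)
  if (!length(keep)) stop("no intron-bearing genes left")
  v <- exprValues(intronCounts)[keep, , drop = FALSE] / len[keep]
  cd <- SummarizedExperiment::colData(intronCounts)
  TimeCourseMatrix(v, time = cd$time, replicate = cd$replicate)
}

#' Minimum-expression (TPM) filter
#'
#' Retains transcripts whose maximum over all samples reaches the threshold;
#' a transcript is removed only if it is below threshold at every sample of
#' the time course.
#'
#' @param x a \linkS4class{TimeCourseMatrix} on the TPM scale.
#' @param threshold minimum TPM (default 1).
#' @return filtered \linkS4class{TimeCourseMatrix}.
#' @export
filterMinTPM <- function(x, threshold = 1) {
  stopifnot(is(x, "TimeCourseMatrix"), threshold > 0)
  keep <- apply(exprValues(x), 1, max) >= threshold
  x[keep, ]
}

#' Zygotic-transcript filter
#'
#' Keeps transcripts whose replicate-mean expression at the first time point
#' (t = 95 min AEL) is below the threshold, i.e. transcripts that are not
#' maternally deposited.
#'
#' @param x a \linkS4class{TimeCourseMatrix} whose grid starts at
#'   \code{firstTime}.
#' @param threshold TPM cut at the first time point (default 0.5).
#' @param firstTime expected first time point (default 95); an error is
#'   raised if the grid does not start there.
#' @return filtered \linkS4class{TimeCourseMatrix}.
#' @export
filterZygotic <- function(x, threshold = 0.5, firstTime = 95) {
  stopifnot(is(x, "TimeCourseMatrix"))
  tt <- timePoints(x)
  if (tt[1] != firstTime)
    stop("first time point must be t = ", firstTime, " min")
  m0 <- meanByTime(x)[, 1]
  x[m0 < threshold, ]
}

#' Intron-signal filter
#'
#' Keeps genes that have introns (present in the annotation with a positive
#' total intron length) and at least one nonzero intronic count across the
#' time course.
#'
#' @param x a \linkS4class{TimeCourseMatrix} of gene-level intronic signal.
#' @param annotation optional data.frame with \code{feature_id} and
#'   \code{total_intron_length}; when supplied, intronless genes are dropped
#'   even if (spuriously) nonzero.
#' @return filtered \linkS4class{TimeCourseMatrix}.
#' @export
filterIntronSignal <- function(x, annotation = NULL) {
  stopifnot(is(x, "TimeCourseMatrix"))
  keep <- apply(exprValues(x), 1, function(r) any(r > 0))
  if (!is.null(annotation)) {
    len <- annotation$total_intron_length[
      match(rownames(x), annotation$feature_id)]
    keep <- keep & !is.na(len) & len > 0
  }
  x[keep, ]
}

#' Pre-mRNA / mRNA correlation filter
#'
#' Pearson correlation between the replicate-mean pre-mRNA and mature mRNA
#' series of each pair; pairs with correlation above \code{minR} are kept.
#' Zero-variance series cannot be correlated and are excluded with a message.
#'
#' @param pre,mature \linkS4class{TimeCourseMatrix} objects sharing a time
#'   grid.
#' @param pairs data.frame with columns \code{pre_id}, \code{mature_id}
#'   linking rows of \code{pre} to rows of \code{mature}; defaults to
#'   matching shared rownames.
#' @param minR correlation threshold (default 0.4, exclusive).
#' @return \code{pairs} restricted to the kept set, with a \code{correlation}
#'   column.
#' @export
filterCorrelation <- function(pre, mature, pairs = NULL, minR = 0.4) {
  stopifnot(is(pre, "TimeCourseMatrix"), is(mature, "TimeCourseMatrix"))
  if (!identical(timePoints(pre), timePoints(mature)))
    stop("pre and mature must share the time grid")
  if (is.null(pairs)) {
    ids <- intersect(rownames(pre), rownames(mature))
    pairs <- data.frame(pre_id = ids, mature_id = ids,
                        stringsAsFactors = FALSE)
  }
  mp <- meanByTime(pre); mm <- meanByTime(mature)
  r <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- mp[pairs$pre_id[i], ]; b <- mm[pairs$mature_id[i], ]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  if (anyNA(r))
    message(sum(is.na(r)), " pair(s) excluded: zero-variance series")
  pairs$correlation <- r
  pairs[!is.na(r) & r > minR, , drop = FALSE]
}
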