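## Codon stabilisation coefficients, codon-optimality scoring, and
## feature--half-life correlations.

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.senseCodons <- function() {
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  sort(setdiff(all64, .STOP_CODONS))
}

#' Per-transcript codon frequencies
#'
#' Counts in-frame codons of each CDS and returns proportions over the 61
#' sense codons (stop codons are counted separately and excluded from the
#' simplex).  Records with ambiguous bases or length not divisible by 3 are
#' skipped with a message.
#'
#' @param cds a \link[Biostrings]{DNAStringSet} or path to a FASTA file of
#'   CDS sequences beginning at the annotated start codon.
#' @return list with \code{frequencies} (transcripts x 61 proportions),
#'   \code{counts} (sense-codon counts), \code{stopCounts}, \code{skipped}
#'   (character vector of skipped record names).
#' @export
codonFrequencies <- function(cds) {
  if (is.character(cds)) cds <- Biostrings::readDNAStringSet(cds)
  stopifnot(is(cds, "DNAStringSet"))
  ok <- Biostrings::width(cds) %% 3 == 0 & Biostrings::width(cds) > 0
  lf <- Biostrings::letterFrequency(cds, letters = "ACGT", OR = 0)
  ok <- ok & rowSums(lf) == Biostrings::width(cds)
  skipped <- names(cds)[!ok]
  if (length(skipped))
    message(length(skipped), " CDS record(s) skipped (ambiguous bases or ",
            "length not divisible by 3)")
  cds <- cds[ok]
  if (!length(cds)) stop("no valid CDS records")
  cnt <- Biostrings::oligonucleotideFrequency(cds, width = 3, step = 3)
  sense <- .senseCodons()
  senseCnt <- cnt[, sense, drop = FALSE]
  stopCnt <- cnt[, .STOP_CODONS, drop = FALSE]
  tot <- rowSums(senseCnt)
  if (any(tot == 0)) stop("CDS with no sense codons")
  freq <- senseCnt / tot
  rownames(freq) <- rownames(senseCnt) <- rownames(stopCnt) <- names(cds)
  list(frequencies = freq, counts = senseCnt, stopCounts = stopCnt,
       skipped = skipped)
}

#' Codon stabilisation coefficients
#'
#' The CSC of a codon is the Pearson correlation, across transcripts, of the
#' codon's per-transcript frequency with transcript half-life.  Codons whose
#' frequency has zero variance (or constant half-lives) yield NA.
#'
#' @param frequencies transcripts x codons proportion matrix
#'   (\code{codonFrequencies(...)$frequencies}).
#' @param halfLives named numeric of half-lives (minutes); matched to
#'   rownames of \code{frequencies} when named.
#' @param logHalfLife correlate with log half-life instead (default FALSE;
#'   the raw half-life is the conventional correlate).
#' @param optimalSet optional character vector of optimal codons used to set
#'   the \code{optimal} flag.
#' @return data.frame with \code{codon}, \code{csc}, \code{optimal}, sorted
#'   by decreasing CSC.
#' @export
computeCSC <- function(frequencies, halfLives, logHalfLife = FALSE,
                       optimalSet = NULL) {
  if (!is.null(names(halfLives)))
    halfLives <- halfLives[rownames(frequencies)]
  stopifnot(length(halfLives) == nrow(frequencies))
  keep <- is.finite(halfLives)
  frequencies <- frequencies[keep, , drop = FALSE]
  halfLives <- halfLives[keep]
  if (nrow(frequencies) < 3)
    stop("need >= 3 transcripts with both codon usage and a half-life")
  h <- if (logHalfLife) log(halfLives) else halfLives
  if (stats::sd(h) == 0) {
    warning("constant half-lives: CSC undefined for every codon")
    csc <- rep(NA_real_, ncol(frequencies))
  } else {
    csc <- apply(frequencies, 2, function(f)
      if (stats::sd(f) == 0) NA_real_ else stats::cor(f, h))
  }
  out <- data.frame(codon = colnames(frequencies), csc = csc,
                    optimal = if (is.null(optimalSet)) NA else
                      colnames(frequencies) %in% optimalSet,
                    row.names = NULL)
  out[order(-out$csc, out$codon, na.last = TRUE), ]
}

#' Proportion of optimal codons per transcript
#'
#' @param counts transcripts x sense-codon count matrix
#'   (\code{codonFrequencies(...)$counts}).
#' @param optimalSet character vector of optimal codons (subset of the 61
#'   sense codons).
#' @return named numeric in [0, 1], one value per transcript.
#' @export
optimalityProportion <- function(counts, optimalSet) {
  stopifnot(all(optimalSet %in% .senseCodons()))
  tot <- rowSums(counts)
  if (any(tot == 0)) stop("empty CDS")
  rowSums(counts[, intersect(colnames(counts), optimalSet),
                 drop = FALSE]) / tot
}

#' Association tests between codon optimality, CSC sign and half-life class
#'
#' (i) A 2x2 chi-square test of association between codon optimality and CSC
#' sign (positive vs negative), and (ii) pairwise two-sample t tests of the
#' per-transcript optimal-codon proportion across half-life categories.
#'
#' @param cscTable data.frame from [computeCSC()] with non-NA \code{optimal}.
#' @param proportions named numeric from [optimalityProportion()].
#' @param categories factor of half-life categories aligned with
#'   \code{proportions} (levels short/medium/long used).
#' @return list with \code{chisq} (htest), \code{contingency},
#'   \code{tTests} (data.frame of pairwise comparisons), and
#'   \code{lowExpectedCells} warning flag.
#' @export
groupAssociationTests <- function(cscTable, proportions, categories) {
  tab <- cscTable[is.finite(cscTable$csc) & cscTable$csc != 0, ]
  sign <- factor(ifelse(tab$csc > 0, "positive", "negative"),
                 levels = c("positive", "negative"))
  if (!all(table(sign) > 0)) stop("both CSC sign groups must be non-empty")
  cont <- table(optimal = factor(tab$optimal, c(TRUE, FALSE)), csc = sign)
  chis <- suppressWarnings(stats::chisq.test(cont, correct = FALSE))
  lowExp <- any(chis$expected < 1)
  if (lowExp) warning("chi-square expected cell count < 1")
  categories <- droplevels(factor(categories))
  lev <- levels(categories)
  cmb <- utils::combn(lev, 2)
  tt <- lapply(seq_len(ncol(cmb)), function(i) {
    a <- proportions[categories == cmb[1, i]]
    b <- proportions[categories == cmb[2, i]]
    ht <- stats::t.test(a, b, var.equal = TRUE)
    data.frame(group1 = cmb[1, i], group2 = cmb[2, i],
               statistic = unname(ht$statistic), p_value = ht$p.value)
  })
  list(chisq = chis, contingency = cont, tTests = do.call(rbind, tt),
       lowExpectedCells = lowExp)
}

#' Correlate a per-transcript covariate with half-life
#'
#' Pearson correlation and two-sided p-value, as used for 3' UTR length,
#' transcript length and translation efficiency.
#'
#' @param values numeric covariate, aligned with \code{halfLives}.
#' @param halfLives numeric half-lives (minutes).
#' @return list with \code{r}, \code{p}, \code{n}.
#' @export
correlateFeature <- function(values, halfLives) {
  keep <- is.finite(values) & is.finite(halfLives)
  values <- values[keep]; halfLives <- halfLives[keep]
  if (length(values) < 3) stop("need >= 3 paired values")
  if (stats::sd(values) == 0 || stats::sd(halfLives) == 0)
    stop("zero-variance input")
  ht <- stats::cor.test(values, halfLives, method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value, n = length(values))
}

#' K-means clustering of codon usage
#'
#' Thin seeded wrapper around \code{\link[stats]{kmeans}} on the codon
#' frequency matrix, reporting mean half-life per cluster.
#'
#' @param frequencies transcripts x codons matrix.
#' @param k number of clusters.
#' @param halfLives optional aligned half-lives for per-cluster summaries.
#' @param seed integer seed for the initialisation.
#' @return list with \code{cluster} (assignments), \code{centers},
#'   \code{meanHalfLife} (per cluster, if half-lives given).
#' @export
codonUsageClusters <- function(frequencies, k, halfLives = NULL, seed = 1L) {
  set.seed(seed)
  km <- stats::kmeans(frequencies, centers = k, nstart = 10)
  out <- list(cluster = km$cluster, centers = km$centers)
  if (!is.null(halfLives))
    out$meanHalfLife <- tapply(halfLives, km$cluster, mean)
  out
}

#' Packaged optimal-codon set
#'
#' Reads a two-column TSV (\code{codon}, \code{optimal}) and returns the
#' codons flagged optimal.  The default file shipped with the package,
#' \code{optimal_codons_synthetic.tsv}, is a synthetic placeholder set (its
#' composition is arbitrary); analyses of real data should supply the
#' published species-specific optimal-codon classification instead.
#'
#' @param path TSV path; default is the packaged synthetic set.
#' @return character vector of optimal codons.
#' @export
optimalCodons <- function(path = system.file("extdata",
                                             "optimal_codons_synthetic.tsv",
                                             package = "DecayDynamics")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("codon", "optimal") %in% colnames(df)))
  df$codon[as.logical(df$optimal)]
}
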