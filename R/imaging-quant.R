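## Quantification of smFISH spot tables: optimal 5'/3' pairing, compaction,
## P-body colocalisation, lone-end enrichment, detection efficiency, and the
## mitotic-arrest exponential decay fit.  All distances are 3D Euclidean in
## physical nm; all thresholds use a strict "<".

#' Read an Airlocalize-style spot table
#'
#' CSV with columns \code{x}, \code{y}, \code{z} (and optionally
#' \code{intensity}), one file per channel.  Coordinates are multiplied by
#' the per-axis voxel size to obtain physical nm; tables already in nm use
#' the default \code{voxelSize = c(1, 1, 1)}.
#'
#' @param path CSV path (optionally gzipped).
#' @param voxelSize numeric(3), nm per voxel along x, y, z.
#' @param intensityQuantile optional upper intensity quantile (e.g. 0.99)
#'   above which spots are dropped, for removing residual transcription-site
#'   signals from pre-filtered tables.
#' @return numeric matrix with columns x, y, z (nm) and intensity if present.
#' @export
readSpotTable <- function(path, voxelSize = c(1, 1, 1),
                          intensityQuantile = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("x", "y", "z") %in% colnames(df)))
  m <- as.matrix(df[, intersect(c("x", "y", "z", "intensity"), colnames(df))])
  m[, 1:3] <- sweep(m[, 1:3, drop = FALSE], 2, voxelSize, "*")
  if (!is.null(intensityQuantile) && "intensity" %in% colnames(m)) {
    cut <- stats::quantile(m[, "intensity"], intensityQuantile)
    m <- m[m[, "intensity"] <= cut, , drop = FALSE]
  }
  m
}

.pairwiseDist <- function(a, b) {
  # rows of a x rows of b Euclidean distance in 3D
  a <- a[, 1:3, drop = FALSE]; b <- b[, 1:3, drop = FALSE]
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Optimal 5'/3' spot pairing
#'
#' Solves the rectangular assignment problem minimising the total Euclidean
#' distance over all pairings (shortest-augmenting-path solver), then
#' dissolves any assigned pair at or beyond \code{maxDist} into lone ends.
#' Leftover spots of the larger channel are lone by construction.
#'
#' @param spots5p,spots3p matrices with columns x, y, z in nm.
#' @param maxDist pairing threshold in nm (default 300, strict "<").
#' @return A \linkS4class{SpotMatching}.
#' @examples
#' m <- pairSpots(rbind(c(0, 0, 0)), rbind(c(100, 0, 0)))
#' matchedPairs(m)   # one pair at 100 nm
#' @export
pairSpots <- function(spots5p, spots3p, maxDist = 300) {
  s5 <- .spotMat(spots5p); s3 <- .spotMat(spots3p)
  n5 <- nrow(s5); n3 <- nrow(s3)
  empty <- function() new("SpotMatching",
    pairs = matrix(numeric(0), 0, 3,
                   dimnames = list(NULL, c("i5", "i3", "distance"))),
    lone5p = seq_len(n5), lone3p = seq_len(n3),
    threshold = as.numeric(maxDist))
  if (n5 == 0L || n3 == 0L) return(empty())
  D <- .pairwiseDist(s5, s3)
  if (n5 <= n3) {
    a <- .lapSolve(D)
    pairs <- cbind(i5 = seq_len(n5), i3 = a)
  } else {
    a <- .lapSolve(t(D))
    pairs <- cbind(i5 = a, i3 = seq_len(n3))
  }
  d <- D[pairs]
  keep <- d < maxDist
  pairs <- cbind(pairs[keep, , drop = FALSE], distance = d[keep])
  new("SpotMatching", pairs = pairs,
      lone5p = setdiff(seq_len(n5), pairs[, "i5"]),
      lone3p = setdiff(seq_len(n3), pairs[, "i3"]),
      threshold = as.numeric(maxDist))
}

#' End-to-end distance distribution of paired spots
#'
#' @param matching a \linkS4class{SpotMatching} with >= 1 pair.
#' @return list with \code{distances} (nm), \code{mean}, \code{median},
#'   \code{n}.
#' @export
endToEndDistances <- function(matching) {
  stopifnot(is(matching, "SpotMatching"))
  if (nrow(matching@pairs) == 0L) stop("no pairs in matching")
  d <- matching@pairs[, "distance"]
  list(distances = d, mean = mean(d), median = stats::median(d),
       n = length(d))
}

#' Assign spots to their nearest P-body
#'
#' A spot is colocalised when the distance to the nearest P-body centre is
#' strictly below \code{radius}.  Default 200 nm (a typical P-body radius)
#' for whole-mRNA analysis; 150 nm is the conservative end-specific choice.
#'
#' @param spots matrix with columns x, y, z (nm); may be empty.
#' @param pbodies matrix of P-body centres; if empty all flags are FALSE.
#' @param radius colocalisation radius in nm (default 200).
#' @return logical vector, one flag per spot.
#' @export
assignToPBodies <- function(spots, pbodies, radius = 200) {
  spots <- .spotMat(spots); pbodies <- .spotMat(pbodies)
  if (nrow(spots) == 0L) return(logical(0))
  if (nrow(pbodies) == 0L) return(rep(FALSE, nrow(spots)))
  dmin <- apply(.pairwiseDist(spots, pbodies), 1, min)
  dmin < radius
}

#' P-body colocalisation index
#'
#' C_P = m_coloc / (m_total * N_P): the colocalised fraction normalised by
#' the P-body count, making the index comparable across embryos with
#' different mRNA and P-body numbers.
#'
#' @param mColoc number of colocalised mRNAs.
#' @param mTotal total mRNA count (> 0).
#' @param nP P-body count (> 0).
#' @return numeric C_P in [0, 1/N_P].
#' @examples
#' colocalizationIndex(50, 200, 100)  # 0.0025
#' @export
colocalizationIndex <- function(mColoc, mTotal, nP) {
  stopifnot(mTotal > 0, nP > 0, mColoc >= 0, mColoc <= mTotal)
  mColoc / (mTotal * nP)
}

#' P-body enrichment of lone ends and intact mRNAs
#'
#' For each species (lone 5' end, lone 3' end, intact mRNA) the percentage
#' of members colocalised with a P-body, relative to the species total.
#' Intact mRNAs are located at the midpoint of their paired ends.
#'
#' @param matching a \linkS4class{SpotMatching}.
#' @param field the \linkS4class{SpotField} the matching was computed from.
#' @param radius colocalisation radius in nm (default 150, the conservative
#'   end-specific threshold).
#' @return data.frame with species, n_total, n_coloc, percent (NA and a
#'   flag when a species is empty).
#' @export
loneEndEnrichment <- function(matching, field, radius = 150) {
  stopifnot(is(matching, "SpotMatching"), is(field, "SpotField"))
  pb <- field@pbodies
  lone5 <- field@spots5p[matching@lone5p, , drop = FALSE]
  lone3 <- field@spots3p[matching@lone3p, , drop = FALSE]
  mid <- if (nrow(matching@pairs)) {
    (field@spots5p[matching@pairs[, "i5"], 1:3, drop = FALSE] +
     field@spots3p[matching@pairs[, "i3"], 1:3, drop = FALSE]) / 2
  } else matrix(numeric(0), 0, 3)
  one <- function(sp, name) {
    n <- nrow(sp)
    if (n == 0L)
      return(data.frame(species = name, n_total = 0L, n_coloc = 0L,
                        percent = NA_real_, empty = TRUE))
    cl <- sum(assignToPBodies(sp, pb, radius))
    data.frame(species = name, n_total = n, n_coloc = cl,
               percent = 100 * cl / n, empty = FALSE)
  }
  rbind(one(lone5, "lone_5p"), one(lone3, "lone_3p"), one(mid, "intact"))
}

#' Detection efficiency from an alternating-probe control
#'
#' In the alternating-probe design every mRNA should carry both channels, so
#' a lone spot in channel B marks a detection miss in channel A.  Efficiency
#' of channel A = pairs / (pairs + lone-B), and symmetrically for B.
#'
#' @param matching a \linkS4class{SpotMatching} from the control experiment.
#' @return named numeric: \code{efficiency5p}, \code{efficiency3p}
#'   (percent).
#' @examples
#' # 70 pairs + 30 lone 3' spots -> 5' channel efficiency 70%
#' @export
detectionEfficiency <- function(matching) {
  stopifnot(is(matching, "SpotMatching"))
  np <- nrow(matching@pairs)
  n5lone <- length(matching@lone5p); n3lone <- length(matching@lone3p)
  if (np + n5lone + n3lone == 0L) stop("no spots in matching")
  c(efficiency5p = 100 * np / (np + n3lone),
    efficiency3p = 100 * np / (np + n5lone))
}

#' Exponential decay fit of counts per cell
#'
#' Nonlinear least-squares fit of N(t) = N0 exp(-D t); the half-life is
#' ln(2)/D.  Non-decreasing data that drive D <= 0 are reported with an
#' infinite-half-life flag rather than an error.
#'
#' @param times time points (seconds or minutes; half-life is returned in
#'   the same unit as \code{times}).
#' @param counts counts per cell at each time.
#' @return list with \code{D}, \code{tHalf}, \code{N0}, \code{infinite}
#'   flag, \code{residualSD}.
#' @export
fitExponentialDecay <- function(times, counts) {
  stopifnot(length(times) == length(counts), length(unique(times)) >= 3,
            all(counts >= 0))
  slope <- stats::coef(stats::lm(log(pmax(counts, max(counts) * 1e-6)) ~
                                   times))[2]
  st <- list(N0 = max(counts), D = max(-slope, 1e-6))
  fit <- tryCatch(
    minpack.lm::nlsLM(counts ~ N0 * exp(-D * times), start = st,
                      lower = c(N0 = 0, D = 0)),
    error = function(e) NULL)
  if (is.null(fit)) {
    D <- unname(max(-slope, 0))
  } else {
    D <- unname(stats::coef(fit)["D"])
  }
  inf <- D <= 0
  list(D = D, tHalf = if (inf) Inf else log(2) / D,
       N0 = if (is.null(fit)) max(counts) else
         unname(stats::coef(fit)["N0"]),
       infinite = inf,
       residualSD = if (is.null(fit)) NA_real_ else
         stats::sigma(fit))
}

#' Signal-to-noise ratio of a counts-per-cell time course
#'
#' |mean(last) - mean(first)| divided by the average within-time-point
#' variance over time points with at least two replicates.  When every
#' within-time variance is zero but the change is nonzero the ratio is
#' capped (flagged) rather than returned as infinite.
#'
#' @param times time point per observation.
#' @param counts counts per cell per observation.
#' @param cap upper guard for a zero-variance denominator (default 1e6).
#' @return list with \code{snr}, \code{capped}.
#' @export
signalToNoise <- function(times, counts, cap = 1e6) {
  stopifnot(length(times) == length(counts))
  tt <- sort(unique(times))
  if (length(tt) < 2) stop("need >= 2 time points")
  reps <- vapply(tt, function(t0) sum(times == t0), integer(1))
  if (!any(reps >= 2)) stop("need at least one replicated time point")
  mFirst <- mean(counts[times == tt[1]])
  mLast <- mean(counts[times == tt[length(tt)]])
  vv <- vapply(tt[reps >= 2], function(t0)
    stats::var(counts[times == t0]), numeric(1))
  denom <- mean(vv)
  num <- abs(mLast - mFirst)
  if (denom == 0) {
    return(list(snr = if (num == 0) 0 else cap, capped = num != 0))
  }
  list(snr = num / denom, capped = FALSE)
}
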