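## Synthetic-data generators with recorded ground truth.  Ground-truth
## mature-mRNA trajectories come from adaptive numerical ODE integration
## (deSolve), deliberately independent of the model's closed-form kernel so
## that generator and inference engine can cross-validate each other.

.PAPER_GRID <- c(95, 105, 115, 125, 145, 160, 175, 190, 205, 220)

#' The experimental time grid
#'
#' Ten collection times, 95--220 minutes after egg lay, matching the embryo
#' staging design the package models.
#'
#' @return numeric(10) of minutes AEL.
#' @export
defaultTimeGrid <- function() .PAPER_GRID

# draw one smooth pre-mRNA trajectory on a fine grid and shift it
# non-negative (expression is physical; the fitted model does not itself
# enforce positivity)
.drawPreTrajectory <- function(fineGrid, lengthscale, variance) {
  K <- rbfKernel(fineGrid, fineGrid, lengthscale, variance)
  R <- .cholJitter(K)
  p <- as.vector(crossprod(R, stats::rnorm(length(fineGrid))))
  p + max(0, -min(p))
}

# ground-truth m(t): adaptive integration of dm/dt = S p - D m, m(t0) = 0
.integrateODE <- function(fineGrid, p, S, D, times) {
  pf <- stats::approxfun(fineGrid, p, rule = 2)
  sol <- deSolve::ode(y = c(m = 0), times = c(fineGrid[1], times),
                      func = function(t, y, parms)
                        list(S * pf(t) - D * y[1]),
                      parms = NULL, method = "lsoda",
                      rtol = 1e-8, atol = 1e-10)
  as.vector(sol[-1, "m"])
}

#' Simulate an expression cohort with known kinetics
#'
#' Per transcript: a smooth pre-mRNA trajectory p(t) is drawn from an RBF GP
#' on a fine grid (shifted non-negative), the mature trajectory m(t) is
#' obtained by adaptive numerical integration of dm/dt = S p - D m from
#' m(95) = 0, both are sampled on the experimental grid, and i.i.d. Gaussian
#' noise is added independently per replicate with standard deviation
#' \code{noiseLevels} times each trajectory's signal sd.
#'
#' @param nTranscripts number of transcripts.
#' @param D true degradation rates: either a vector of length
#'   \code{nTranscripts} or a range (length 2, default c(0.003, 0.05)) from
#'   which rates are drawn log-uniformly.
#' @param times observation grid (default [defaultTimeGrid()]).
#' @param nReps replicates per time point (default 3).
#' @param noiseLevels named numeric c(p = , m = ): noise sd as a fraction of
#'   each trajectory's sd (default 0.1 each).
#' @param lengthscale,variance,S GP and production parameters of the
#'   generating process (defaults 20 min, 1, 1).
#' @param onsetTime optional zygotic-activation onset (minutes AEL).  When
#'   given, the pre-mRNA trajectory is multiplied by a smooth activation
#'   ramp \code{pnorm((t - onsetTime) / onsetWidth)}, emulating genes that
#'   switch on during the window (pre-mRNA ~ 0 at the first time point).
#'   The default NULL keeps the stationary GP draw, which matches the
#'   inference model's own prior and is used for parameter recovery.
#' @param onsetWidth ramp width in minutes (default 12).
#' @param noiseModel \code{"constant"}: per-trajectory noise sd =
#'   noiseLevel x trajectory sd (the model's homoscedastic assumption);
#'   \code{"proportional"}: per-observation sd = noiseLevel x value plus a
#'   2\% floor, emulating depth-dependent measurement error in which
#'   near-zero expression is measured near zero.
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return list with \code{pre}, \code{mature}
#'   (\linkS4class{TimeCourseMatrix}; rows "txN"), \code{truth} (data.frame
#'   of per-transcript generating parameters incl. t_half), \code{seed},
#'   and \code{trajectories} (noise-free fine-grid p and m for oracle use).
#' @export
simulateExpressionCohort <- function(nTranscripts, D = c(0.003, 0.05),
                                     times = defaultTimeGrid(), nReps = 3,
                                     noiseLevels = c(p = 0.1, m = 0.1),
                                     lengthscale = 20, variance = 1, S = 1,
                                     onsetTime = NULL, onsetWidth = 12,
                                     noiseModel = c("constant",
                                                    "proportional"),
                                     seed = 1L) {
  stopifnot(nTranscripts >= 1)
  noiseModel <- match.arg(noiseModel)
  set.seed(seed)
  Dtrue <- if (length(D) == nTranscripts) D else
    exp(stats::runif(nTranscripts, log(min(D)), log(max(D))))
  fine <- seq(min(times), max(times), by = 0.5)
  ncol <- length(times) * nReps
  preM <- matrix(0, nTranscripts, ncol)
  matM <- matrix(0, nTranscripts, ncol)
  ids <- paste0("tx", seq_len(nTranscripts))
  trajP <- trajM <- matrix(0, nTranscripts, length(fine))
  sigP <- sigM <- numeric(nTranscripts)
  for (i in seq_len(nTranscripts)) {
    p <- .drawPreTrajectory(fine, lengthscale, variance)
    if (!is.null(onsetTime))
      p <- p * stats::pnorm((fine - onsetTime) / onsetWidth)
    m <- .integrateODE(fine, p, S, Dtrue[i], fine)
    trajP[i, ] <- p; trajM[i, ] <- m
    pObs <- p[match(times, fine)]
    mObs <- m[match(times, fine)]
    if (noiseModel == "constant") {
      sP <- rep(stats::sd(pObs) * noiseLevels[["p"]], ncol)
      sM <- rep(stats::sd(mObs) * noiseLevels[["m"]], ncol)
    } else {
      sP <- noiseLevels[["p"]] *
        (rep(pObs, each = nReps) + 0.02 * max(pObs))
      sM <- noiseLevels[["m"]] *
        (rep(mObs, each = nReps) + 0.02 * max(mObs))
    }
    sigP[i] <- mean(sP); sigM[i] <- mean(sM)
    preM[i, ] <- pmax(rep(pObs, each = nReps) + stats::rnorm(ncol, 0, sP), 0)
    matM[i, ] <- pmax(rep(mObs, each = nReps) + stats::rnorm(ncol, 0, sM), 0)
  }
  tcol <- rep(times, each = nReps)
  rcol <- rep(seq_len(nReps), length(times))
  truth <- data.frame(transcript_id = ids, D = Dtrue,
                      t_half = log(2) / Dtrue, S = S,
                      lengthscale = lengthscale, variance = variance,
                      noise_sd_p = sigP, noise_sd_m = sigM)
  list(pre = TimeCourseMatrix(preM, tcol, rcol, featureIDs = ids),
       mature = TimeCourseMatrix(matM, tcol, rcol, featureIDs = ids),
       truth = truth, seed = seed,
       trajectories = list(grid = fine, p = trajP, m = trajM))
}

.runifVolume <- function(n, volume) {
  cbind(x = stats::runif(n, volume[1, 1], volume[2, 1]),
        y = stats::runif(n, volume[1, 2], volume[2, 2]),
        z = stats::runif(n, volume[1, 3], volume[2, 3]))
}

# random point in/near a sphere of radius r around centre (uniform in ball)
.inSphere <- function(centres, r) {
  n <- nrow(centres)
  dir <- matrix(stats::rnorm(3 * n), n, 3)
  dir <- dir / sqrt(rowSums(dir^2))
  rad <- r * stats::runif(n)^(1 / 3)
  centres + dir * rad
}

#' Simulate a 3D smFISH spot field with known ground truth
#'
#' Intact mRNAs are placed uniformly in the volume with their 3' end offset
#' from the 5' end by a random direction at a distance drawn from
#' N(compactionMean, compactionSd) (truncated at 0).  Lone 5' and lone 3'
#' ends are added as specified fractions of the mRNA count.  P-bodies are
#' spherical (radius \code{pbodyRadius}); each species member is placed
#' inside a random P-body with its species' colocalisation probability
#' (intact mRNAs via their midpoint).  A density guard rejects parameter
#' sets whose expected nearest-neighbour spacing is too close to the pairing
#' threshold.
#'
#' @param nMrna number of intact mRNAs.
#' @param loneFraction5p,loneFraction3p lone ends to add, as fractions of
#'   \code{nMrna} (default 0.2 each).
#' @param compactionMean,compactionSd end-to-end distance distribution, nm
#'   (defaults 150, 30).
#' @param nPbodies number of P-bodies (default 50).
#' @param colocProbs named numeric c(intact = , lone5 = , lone3 = ):
#'   probability of placement inside a P-body (default all 0).
#' @param volume 2x3 bounds matrix in nm (default a 20 x 20 x 4 um slab).
#' @param pbodyRadius nm (default 100, so members sit well inside the
#'   150-200 nm colocalisation thresholds).
#' @param minSpacing density guard: 0.55 (V/n)^(1/3), the expected
#'   nearest-neighbour distance, must exceed this (default 900 nm = 3x the
#'   pairing threshold).
#' @param seed integer seed.
#' @return list with \code{field} (\linkS4class{SpotField}) and \code{truth}
#'   (generating parameters and per-species colocalisation labels).
#' @export
simulateSpotField <- function(nMrna, loneFraction5p = 0.2,
                              loneFraction3p = 0.2,
                              compactionMean = 150, compactionSd = 30,
                              nPbodies = 50,
                              colocProbs = c(intact = 0, lone5 = 0, lone3 = 0),
                              volume = rbind(c(0, 0, 0),
                                             c(20000, 20000, 4000)),
                              pbodyRadius = 100, minSpacing = 900,
                              seed = 1L) {
  set.seed(seed)
  volume <- as.matrix(volume)
  n5lone <- round(nMrna * loneFraction5p)
  n3lone <- round(nMrna * loneFraction3p)
  nTotal <- nMrna + n5lone + n3lone
  vol <- prod(volume[2, ] - volume[1, ])
  if (0.55 * (vol / max(nTotal, 1))^(1 / 3) <= minSpacing)
    stop("spot density too high: expected nearest-neighbour distance must ",
         "exceed ", minSpacing, " nm")
  pb <- .runifVolume(nPbodies, volume)
  place <- function(n, prob) {
    # returns position matrix + logical coloc label
    inPB <- stats::runif(n) < prob
    pos <- .runifVolume(n, volume)
    if (any(inPB) && nPbodies > 0) {
      ctr <- pb[sample.int(nPbodies, sum(inPB), replace = TRUE), ,
                drop = FALSE]
      pos[inPB, ] <- .inSphere(ctr, pbodyRadius)
    }
    list(pos = pos, coloc = inPB)
  }
  intact <- place(nMrna, colocProbs[["intact"]])
  d <- pmax(stats::rnorm(nMrna, compactionMean, compactionSd), 0)
  dir <- matrix(stats::rnorm(3 * nMrna), nMrna, 3)
  dir <- dir / sqrt(rowSums(dir^2))
  s5 <- intact$pos - dir * d / 2
  s3 <- intact$pos + dir * d / 2
  l5 <- place(n5lone, colocProbs[["lone5"]])
  l3 <- place(n3lone, colocProbs[["lone3"]])
  clamp <- function(m) {
    for (j in 1:3) m[, j] <- pmin(pmax(m[, j], volume[1, j]), volume[2, j])
    m
  }
  field <- SpotField(spots5p = clamp(rbind(s5, l5$pos)),
                     spots3p = clamp(rbind(s3, l3$pos)),
                     pbodies = pb, volume = volume)
  truth <- list(nMrna = nMrna, n5lone = n5lone, n3lone = n3lone,
                compactionMean = compactionMean, compactionSd = compactionSd,
                endToEnd = d, colocProbs = colocProbs,
                colocIntact = intact$coloc, colocLone5 = l5$coloc,
                colocLone3 = l3$coloc, pbodyRadius = pbodyRadius,
                seed = seed)
  list(field = field, truth = truth)
}

#' Simulate a codon-usage cohort with planted CSC effects
#'
#' Half-lives are drawn log-normally; per-transcript codon frequencies are
#' an exponential tilt of a common baseline where each codon's tilt combines
#' transcript-level noise with a term proportional to the standardised
#' half-life, sized so the frequency--half-life Pearson correlation is
#' approximately the planted CSC.  Sequences are emitted as valid CDS
#' (leading ATG drawn from the codon budget, trailing TAA stop, no internal
#' stops by construction).
#'
#' @param nTranscripts number of transcripts.
#' @param plantedCSC named numeric of target per-codon correlations in
#'   (-1, 1); unnamed codons get 0.
#' @param cdsLength CDS length in codons excluding the stop (default 300).
#' @param halfLifeMeanlog,halfLifeSdlog log-normal half-life distribution
#'   (defaults log(20), 0.6).
#' @param noiseSd transcript-level log-frequency jitter (default 0.15).
#' @param seed integer seed.
#' @return list with \code{cds} (\link[Biostrings]{DNAStringSet}),
#'   \code{halfLives} (named), \code{truth} (planted effects and seed).
#' @export
simulateCodonCohort <- function(nTranscripts, plantedCSC = numeric(0),
                                cdsLength = 300,
                                halfLifeMeanlog = log(20),
                                halfLifeSdlog = 0.6,
                                noiseSd = 0.15, seed = 1L) {
  stopifnot(all(abs(plantedCSC) < 1))
  sense <- .senseCodons()
  stopifnot(all(names(plantedCSC) %in% sense))
  set.seed(seed)
  hl <- stats::rlnorm(nTranscripts, halfLifeMeanlog, halfLifeSdlog)
  z <- as.vector(scale(hl))
  beta <- stats::setNames(rep(0, length(sense)), sense)
  r <- plantedCSC
  beta[names(r)] <- r / sqrt(1 - r^2) * noiseSd
  ids <- paste0("tx", seq_len(nTranscripts))
  seqs <- character(nTranscripts)
  for (i in seq_len(nTranscripts)) {
    tilt <- stats::rnorm(length(sense), 0, noiseSd) + beta * z[i]
    pr <- exp(tilt); pr <- pr / sum(pr)
    cnt <- floor(pr * cdsLength)
    # largest-remainder rounding to hit cdsLength exactly
    rem <- cdsLength - sum(cnt)
    if (rem > 0) {
      o <- order(pr * cdsLength - cnt, decreasing = TRUE)
      cnt[o[seq_len(rem)]] <- cnt[o[seq_len(rem)]] + 1
    }
    if (cnt[match("ATG", sense)] == 0) {
      j <- which.max(cnt)
      cnt[j] <- cnt[j] - 1
      cnt[match("ATG", sense)] <- cnt[match("ATG", sense)] + 1
    }
    body <- rep(sense, cnt)
    body <- c("ATG", sample(rep(body, 1)[-match("ATG", body)]))
    seqs[i] <- paste0(paste(body, collapse = ""), "TAA")
  }
  cds <- Biostrings::DNAStringSet(stats::setNames(seqs, ids))
  list(cds = cds, halfLives = stats::setNames(hl, ids),
       truth = list(plantedCSC = plantedCSC, beta = beta, seed = seed,
                    cdsLength = cdsLength))
}
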