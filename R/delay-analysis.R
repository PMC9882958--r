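## Peak-time delay between pre-mRNA and mature mRNA, estimated by posterior
## sampling of independent RBF GPs fitted to each series.  The delay of one
## posterior draw pair is argmax(mature draw) - argmax(pre draw); draws are
## paired by index.

#' Estimate the pre-mRNA to mRNA peak delay
#'
#' Fits an RBF + noise GP to each series, draws \code{nSamples} posterior
#' functions on a dense grid (1-minute resolution by default) and computes
#' the peak-time delay of each paired draw.  The point estimate is the median
#' of the sampled delays.
#'
#' @param timesP,valuesP pre-mRNA observations.
#' @param timesM,valuesM mature mRNA observations.
#' @param nSamples posterior draws per GP (default 100).
#' @param grid evaluation grid for peak finding (default 1-min steps over
#'   the observed range).
#' @param seed integer seed; the estimate is reproducible given the seed.
#' @param transcriptID identifier carried into the result.
#' @return list with \code{transcriptID}, \code{delaySamples} (minutes),
#'   \code{pointDelay} (median), \code{maturePeak} (argmax of the posterior
#'   mean of the mature series), \code{gridStep}.  NULL (with a message) if
#'   either GP fit fails.
#' @export
estimateDelay <- function(timesP, valuesP, timesM, valuesM, nSamples = 100L,
                          grid = NULL, seed = 1L,
                          transcriptID = NA_character_) {
  if (is.null(grid))
    grid <- seq(min(c(timesP, timesM)), max(c(timesP, timesM)), by = 1)
  fp <- fitSeriesGP(timesP, valuesP, "rbf_plus_noise", seed = seed)
  fm <- fitSeriesGP(timesM, valuesM, "rbf_plus_noise", seed = seed + 1L)
  if (!fp$converged || !fm$converged) {
    message("GP fit failed for ", transcriptID, "; transcript skipped")
    return(NULL)
  }
  pp <- gpPosterior(fp, grid, nDraws = nSamples, seed = seed + 2L)
  pm <- gpPosterior(fm, grid, nDraws = nSamples, seed = seed + 3L)
  peakP <- grid[apply(pp$draws, 2, which.max)]
  peakM <- grid[apply(pm$draws, 2, which.max)]
  delays <- peakM - peakP
  list(transcriptID = transcriptID,
       delaySamples = delays,
       pointDelay = stats::median(delays),
       maturePeak = grid[which.max(pm$mean)],
       gridStep = grid[2] - grid[1],
       finalTime = max(grid))
}

#' Remove uninformative delay estimates
#'
#' Drops transcripts whose point delay is non-positive or whose mature
#' profile peaks at the final time point (still rising, so the true peak is
#' unobserved).
#'
#' @param estimates list of results from [estimateDelay()].
#' @param finalTime final grid time (default 220 min AEL).
#' @return filtered list.
#' @export
filterDelays <- function(estimates, finalTime = 220) {
  keep <- vapply(estimates, function(e)
    !is.null(e) && e$pointDelay > 0 && e$maturePeak < finalTime, logical(1))
  estimates[keep]
}

#' Categorise delays into short/medium/long
#'
#' Boundaries are the 33% and 66% quantiles (linear interpolation) of the
#' point delays.  A transcript is assigned a category outright when at least
#' \code{certainty} of its delay samples fall in one interval; otherwise it
#' receives the interval of its median delay with an uncertain flag.
#'
#' @param estimates list from [estimateDelay()]/[filterDelays()], length >= 3.
#' @param certainty classification probability (default 0.9).
#' @return list with \code{boundaries} (named numeric) and \code{table}, a
#'   data.frame of transcript_id, point_delay, category, certain.
#' @export
categorizeDelays <- function(estimates, certainty = 0.9) {
  stopifnot(length(estimates) >= 3)
  pd <- vapply(estimates, `[[`, numeric(1), "pointDelay")
  b <- stats::quantile(pd, c(0.33, 0.66), names = FALSE, type = 7)
  lab <- function(x) ifelse(x < b[1], "short",
                     ifelse(x <= b[2], "medium", "long"))
  rows <- lapply(estimates, function(e) {
    f <- table(factor(lab(e$delaySamples),
                      levels = c("short", "medium", "long"))) /
      length(e$delaySamples)
    if (max(f) >= certainty) {
      data.frame(transcript_id = e$transcriptID, point_delay = e$pointDelay,
                 category = names(which.max(f)), certain = TRUE)
    } else {
      data.frame(transcript_id = e$transcriptID, point_delay = e$pointDelay,
                 category = lab(stats::median(e$delaySamples)),
                 certain = FALSE)
    }
  })
  tab <- do.call(rbind, rows)
  tab$category <- factor(tab$category, levels = c("short", "medium", "long"))
  list(boundaries = c(q33 = b[1], q66 = b[2]), table = tab)
}

#' Delay vs half-life confusion matrix
#'
#' Row-normalised 3x3 matrix of delay category (rows) against half-life
#' category (columns), plus the Pearson correlation of point delay with
#' half-life.
#'
#' @param delayTable data.frame from [categorizeDelays()]\code{$table}.
#' @param halfLifeTable data.frame with \code{transcript_id}, \code{t_half},
#'   \code{category} (short/medium/long).
#' @return list with \code{confusion} (rows sum to 1), \code{counts},
#'   \code{pearsonR}, \code{n}.
#' @export
delayHalfLifeConfusion <- function(delayTable, halfLifeTable) {
  m <- merge(delayTable, halfLifeTable, by = "transcript_id",
             suffixes = c("_delay", "_halflife"))
  if (!nrow(m)) stop("no transcripts shared between delay and half-life sets")
  lev <- c("short", "medium", "long")
  counts <- table(factor(m$category_delay, lev),
                  factor(m$category_halflife, lev))
  conf <- counts / pmax(rowSums(counts), 1)
  r <- stats::cor(m$point_delay, m$t_half)
  list(confusion = as.matrix(conf), counts = as.matrix(counts),
       pearsonR = r, n = nrow(m))
}
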