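## GP log-likelihood ratio test for dynamic vs flat expression series.
## The noise-only model is nested in the RBF + noise model (zero signal
## variance), so the LLR is non-negative at the global optimum.

#' GP likelihood-ratio test for a dynamic series
#'
#' Fits a dynamic GP (RBF + white noise) and a pure-noise GP to one series
#' and returns the log-likelihood ratio in nats.  The series is z-scored
#' before fitting (numerical stability only; the decision is
#' scale-invariant).
#'
#' @param times observation times (replicates = repeated times).
#' @param values observed expression.
#' @param threshold LLR above which the series is called dynamic (default 3
#'   nats, a chi-square(1)-style cutoff; the boundary null makes this
#'   conservative).
#' @param nRestarts,seed passed to [fitSeriesGP()].
#' @return list with \code{llr} (nats), \code{isDynamic}, \code{fitDynamic},
#'   \code{fitNoise}, \code{converged}.
#' @export
llrDynamicTest <- function(times, values, threshold = 3,
                           nRestarts = 5L, seed = 1L) {
  stopifnot(length(times) == length(values))
  s <- stats::sd(values)
  z <- if (is.finite(s) && s > 0) (values - mean(values)) / s else
    values - mean(values)
  fd <- fitSeriesGP(times, z, "rbf_plus_noise", nRestarts = nRestarts,
                    seed = seed)
  fn <- fitSeriesGP(times, z, "noise_only")
  if (!fd$converged)
    return(list(llr = NA_real_, isDynamic = NA, fitDynamic = fd,
                fitNoise = fn, converged = FALSE))
  llr <- fd$logLik - fn$logLik
  list(llr = llr, isDynamic = llr > threshold, fitDynamic = fd,
       fitNoise = fn, converged = TRUE)
}

#' Dynamic filter over a full time course
#'
#' Applies [llrDynamicTest()] to every feature of a
#' \linkS4class{TimeCourseMatrix}.
#'
#' @param x a \linkS4class{TimeCourseMatrix}.
#' @param threshold LLR threshold in nats (default 3).
#' @param nRestarts,seed per-series fitting settings; the seed is offset per
#'   feature for reproducibility.
#' @return \link[S4Vectors]{DataFrame} with \code{feature_id}, \code{llr},
#'   \code{is_dynamic} (NA where the fit failed).
#' @export
dynamicFilter <- function(x, threshold = 3, nRestarts = 5L, seed = 1L) {
  stopifnot(is(x, "TimeCourseMatrix"))
  tm <- SummarizedExperiment::colData(x)$time
  v <- exprValues(x)
  res <- lapply(seq_len(nrow(v)), function(i)
    llrDynamicTest(tm, v[i, ], threshold = threshold,
                   nRestarts = nRestarts, seed = seed + i))
  DataFrame(feature_id = rownames(v),
            llr = vapply(res, `[[`, numeric(1), "llr"),
            is_dynamic = vapply(res, `[[`, logical(1), "isDynamic"))
}

#' Write a dynamic-filter result table
#'
#' @param result \code{DataFrame} from [dynamicFilter()].
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeDynamicFilter <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
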