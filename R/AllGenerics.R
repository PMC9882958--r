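#' Accessors for TimeCourseMatrix and imaging classes
#'
#' @param x a \linkS4class{TimeCourseMatrix} (or other package class).
#' @name accessors
NULL

#' @describeIn accessors unique, sorted time grid (minutes AEL).
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))

#' @describeIn accessors replicate index per sample column.
#' @export
setGeneric("replicates", function(x) standardGeneric("replicates"))

#' @describeIn accessors expression values (features x samples).
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @describeIn accessors replicate-mean expression, features x time points.
#' @export
setGeneric("meanByTime", function(x) standardGeneric("meanByTime"))

#' @export
setMethod("timePoints", "TimeCourseMatrix", function(x)
  sort(unique(SummarizedExperiment::colData(x)$time)))

#' @export
setMethod("replicates", "TimeCourseMatrix", function(x)
  SummarizedExperiment::colData(x)$replicate)

#' @export
setMethod("exprValues", "TimeCourseMatrix", function(x)
  SummarizedExperiment::assay(x, "expression"))

#' @export
setMethod("meanByTime", "TimeCourseMatrix", function(x) {
  tm <- SummarizedExperiment::colData(x)$time
  tt <- sort(unique(tm))
  v <- SummarizedExperiment::assay(x, "expression")
  out <- vapply(tt, function(t0) rowMeans(v[, tm == t0, drop = FALSE]),
                numeric(nrow(v)))
  out <- matrix(out, nrow = nrow(v), dimnames = list(rownames(v), paste0("t", tt)))
  out
})

#' @export
setMethod("show", "TimeCourseMatrix", function(object) {
  tt <- timePoints(object)
  cat("TimeCourseMatrix:", nrow(object), "features,",
      length(tt), "time points x",
      ncol(object) / length(tt), "replicates\n")
  cat("  time grid (min AEL):", paste(tt, collapse = ", "), "\n")
})

#' @export
setMethod("show", "ODEModelParams", function(object) {
  cat("ODEModelParams (joint GP-ODE model)\n")
  cat(sprintf("  lengthscale = %.4g min, variance = %.4g\n",
              object@lengthscale, object@variance))
  cat(sprintf("  S = %.4g /min, D = %.4g /min (t1/2 = %.1f min)\n",
              object@S, object@D, log(2) / object@D))
  cat(sprintf("  noiseVarP = %.4g, noiseVarM = %.4g\n",
              object@noiseVarP, object@noiseVarM))
})

#' @export
setMethod("show", "PosteriorSamples", function(object) {
  cat("PosteriorSamples:", nrow(object@draws), "MALA draws (post burn-in)\n")
  cat(sprintf("  acceptance rate %.2f, step size %.3g, seed %d\n",
              object@acceptanceRate, object@stepSize, object@seed))
  th <- log(2) / object@draws[, "D"]
  cat(sprintf("  t1/2 posterior median %.1f min [%.1f, %.1f] (95%% equal-tailed)\n",
              stats::median(th), stats::quantile(th, 0.025),
              stats::quantile(th, 0.975)))
})

#' @export
setMethod("show", "SpotField", function(object) {
  cat("SpotField:", nrow(object@spots5p), "5' spots,",
      nrow(object@spots3p), "3' spots,", nrow(object@pbodies), "P-bodies\n")
  v <- object@volume
  cat(sprintf("  volume: [%g, %g] x [%g, %g] x [%g, %g] nm\n",
              v[1, 1], v[2, 1], v[1, 2], v[2, 2], v[1, 3], v[2, 3]))
})

#' @export
setMethod("show", "SpotMatching", function(object) {
  cat("SpotMatching:", nrow(object@pairs), "pairs (<",
      object@threshold, "nm),", length(object@lone5p), "lone 5',",
      length(object@lone3p), "lone 3'\n")
})

#' Extract the MALA draws matrix
#' @param x a \linkS4class{PosteriorSamples}.
#' @return numeric matrix of draws (natural parameter scale).
#' @export
posteriorDraws <- function(x) x@draws

#' Pairs / lone-end accessors for a SpotMatching
#' @param x a \linkS4class{SpotMatching}.
#' @return \code{matchedPairs}: matrix (i5, i3, distance); \code{loneEnds}:
#'   list with integer vectors \code{lone5p} and \code{lone3p}.
#' @export
matchedPairs <- function(x) x@pairs

#' @rdname matchedPairs
#' @export
loneEnds <- function(x) list(lone5p = x@lone5p, lone3p = x@lone3p)
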