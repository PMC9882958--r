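#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' TimeCourseMatrix: expression time course with replicate structure
#'
#' A \linkS4class{SummarizedExperiment} holding one assay (\code{"expression"})
#' of non-negative expression values for features (rows) across time-point x
#' replicate samples (columns).  Column metadata must contain \code{time}
#' (minutes after egg lay) and \code{replicate} (integer).  The default
#' experimental grid is ten time points, 95--220 min AEL, three replicates,
#' matching the embryo collection design the package models.
#'
#' @slot ... inherited from \code{SummarizedExperiment}.
#' @seealso [TimeCourseMatrix()] for the constructor, [timePoints()],
#'   [meanByTime()].
#' @export
setClass("TimeCourseMatrix", contains = "SummarizedExperiment")

.validTimeCourseMatrix <- function(object) {
  msg <- NULL
  if (!("expression" %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assay 'expression' is required")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("time", "replicate") %in% colnames(cd))) {
    msg <- c(msg, "colData must contain 'time' and 'replicate'")
    return(msg)
  }
  tt <- sort(unique(cd$time))
  if (length(tt) < 2L || any(diff(tt) <= 0))
    msg <- c(msg, "time grid must contain >= 2 strictly increasing time points")
  reps <- table(cd$time)
  if (length(unique(as.integer(reps))) != 1L)
    msg <- c(msg, "replicate count must be identical at every time point")
  v <- SummarizedExperiment::assay(object, "expression")
  if (any(!is.finite(v)) || any(v < 0))
    msg <- c(msg, "expression values must be finite and >= 0")
  if (is.null(msg)) TRUE else msg
}
setValidity("TimeCourseMatrix", .validTimeCourseMatrix)

#' Construct a TimeCourseMatrix
#'
#' @param values numeric matrix, features x samples, non-negative.
#' @param time numeric vector of time points (minutes AEL), one per column.
#' @param replicate integer vector of replicate indices, one per column.
#' @param featureIDs optional character vector of row names.
#' @return A \linkS4class{TimeCourseMatrix}.
#' @examples
#' tc <- TimeCourseMatrix(matrix(1:20, 2, 10),
#'                        time = rep(c(95, 105, 115, 125, 145), each = 2),
#'                        replicate = rep(1:2, 5))
#' timePoints(tc)
#' @export
TimeCourseMatrix <- function(values, time, replicate, featureIDs = rownames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(featureIDs)) rownames(values) <- featureIDs
  ord <- order(time, replicate)
  values <- values[, ord, drop = FALSE]
  cd <- DataFrame(time = as.numeric(time)[ord],
                  replicate = as.integer(replicate)[ord])
  rownames(cd) <- colnames(values) <-
    paste0("t", cd$time, "_r", cd$replicate)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expression = values), colData = cd)
  new("TimeCourseMatrix", se)
}

#' Parameters of the joint GP-ODE transcription/degradation model
#'
#' The six parameters of the joint Gaussian-process model of pre-mRNA p(t)
#' and mature mRNA m(t) linked by dm/dt = S p(t) - D m(t): RBF kernel
#' lengthscale (minutes) and signal variance for p(t), production/splicing
#' scale S and degradation rate D (both per minute), and the two observation
#' noise variances.  All strictly positive.
#'
#' @slot lengthscale numeric(1), RBF lengthscale in minutes.
#' @slot variance numeric(1), RBF signal variance.
#' @slot S numeric(1), production/splicing rate scale (per minute).
#' @slot D numeric(1), first-order degradation rate (per minute).
#' @slot noiseVarP numeric(1), pre-mRNA measurement noise variance.
#' @slot noiseVarM numeric(1), mature mRNA measurement noise variance.
#' @export
setClass("ODEModelParams",
  representation(lengthscale = "numeric", variance = "numeric",
                 S = "numeric", D = "numeric",
                 noiseVarP = "numeric", noiseVarM = "numeric"))

setValidity("ODEModelParams", function(object) {
  v <- c(object@lengthscale, object@variance, object@S, object@D,
         object@noiseVarP, object@noiseVarM)
  if (length(v) != 6L) return("all six parameter slots must have length 1")
  if (any(!is.finite(v)) || any(v <= 0))
    return("all parameters must be finite and strictly positive")
  TRUE
})

#' Construct ODEModelParams
#'
#' @param lengthscale,variance RBF kernel hyperparameters of the pre-mRNA GP.
#' @param S,D production/splicing scale and degradation rate (per minute).
#' @param noiseVarP,noiseVarM observation noise variances.
#' @return An \linkS4class{ODEModelParams}.
#' @examples
#' ODEModelParams(20, 1, 1, 0.02, 0.01, 0.01)
#' @export
ODEModelParams <- function(lengthscale, variance, S, D, noiseVarP, noiseVarM) {
  new("ODEModelParams", lengthscale = as.numeric(lengthscale),
      variance = as.numeric(variance), S = as.numeric(S), D = as.numeric(D),
      noiseVarP = as.numeric(noiseVarP), noiseVarM = as.numeric(noiseVarM))
}

#' MALA posterior draws over the six ODE model parameters
#'
#' @slot draws numeric matrix of post-burn-in draws (rows) over the six
#'   parameters (natural scale), columns named as in
#'   \linkS4class{ODEModelParams}.
#' @slot acceptanceRate numeric(1), post-burn-in Metropolis acceptance rate.
#' @slot seed integer(1) RNG seed used for the chain.
#' @slot chainLength integer(1), total chain length including burn-in.
#' @slot burnIn integer(1), discarded initial iterations.
#' @slot stepSize numeric(1), final (adapted) MALA step size.
#' @export
setClass("PosteriorSamples",
  representation(draws = "matrix", acceptanceRate = "numeric",
                 seed = "integer", chainLength = "integer",
                 burnIn = "integer", stepSize = "numeric"))

setValidity("PosteriorSamples", function(object) {
  if (ncol(object@draws) != 6L) return("draws must have 6 columns")
  if (any(object@draws <= 0)) return("all draws must be strictly positive")
  a <- object@acceptanceRate
  if (length(a) != 1L || a <= 0 || a >= 1)
    return("acceptance rate must lie in (0, 1)")
  TRUE
})

#' A 3D single-molecule spot field
#'
#' Physical-coordinate (nm) point sets for 5' probe-set spots, 3' probe-set
#' spots and P-body centres detected in one image volume, as produced by a
#' 3D Gaussian-mask spot detector after voxel-to-nm scaling.
#'
#' @slot spots5p,spots3p,pbodies numeric matrices with columns
#'   \code{x}, \code{y}, \code{z} (nm) and optionally \code{intensity}.
#' @slot volume numeric 2x3 matrix: lower/upper bounds of the image volume
#'   in nm (rows) for x, y, z (columns).
#' @export
setClass("SpotField",
  representation(spots5p = "matrix", spots3p = "matrix",
                 pbodies = "matrix", volume = "matrix"))

.inVolume <- function(m, vol) {
  if (nrow(m) == 0L) return(TRUE)
  all(sweep(m[, 1:3, drop = FALSE], 2, vol[1, ], ">=")) &&
    all(sweep(m[, 1:3, drop = FALSE], 2, vol[2, ], "<="))
}

setValidity("SpotField", function(object) {
  msg <- NULL
  for (nm in c("spots5p", "spots3p", "pbodies")) {
    m <- slot(object, nm)
    if (ncol(m) < 3L) msg <- c(msg, paste0(nm, " needs columns x, y, z"))
  }
  if (!identical(dim(object@volume), c(2L, 3L)))
    msg <- c(msg, "volume must be a 2x3 matrix of bounds")
  else if (!all(object@volume[2, ] > object@volume[1, ]))
    msg <- c(msg, "volume upper bounds must exceed lower bounds")
  else if (!.inVolume(object@spots5p, object@volume) ||
           !.inVolume(object@spots3p, object@volume) ||
           !.inVolume(object@pbodies, object@volume))
    msg <- c(msg, "all coordinates must lie within the volume")
  if (is.null(msg)) TRUE else msg
})

.spotMat <- function(m) {
  if (is.null(m) || length(m) == 0L)
    return(matrix(numeric(0), 0, 3, dimnames = list(NULL, c("x", "y", "z"))))
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (is.null(colnames(m))) colnames(m) <- c("x", "y", "z", "intensity")[seq_len(ncol(m))]
  m
}

#' Construct a SpotField
#'
#' @param spots5p,spots3p,pbodies matrices (or data frames) with columns
#'   x, y, z in nm (plus optional intensity).  Any may be empty.
#' @param volume 2x3 matrix of lower/upper nm bounds; computed from the data
#'   extent when omitted.
#' @return A \linkS4class{SpotField}.
#' @export
SpotField <- function(spots5p = NULL, spots3p = NULL, pbodies = NULL,
                      volume = NULL) {
  s5 <- .spotMat(spots5p); s3 <- .spotMat(spots3p); pb <- .spotMat(pbodies)
  if (is.null(volume)) {
    xyz <- rbind(s5[, 1:3, drop = FALSE], s3[, 1:3, drop = FALSE],
                 pb[, 1:3, drop = FALSE])
    if (nrow(xyz) == 0L) xyz <- rbind(c(0, 0, 0), c(1, 1, 1))
    volume <- rbind(apply(xyz, 2, min), apply(xyz, 2, max))
    if (any(volume[2, ] == volume[1, ]))
      volume[2, ] <- volume[2, ] + 1
  }
  volume <- as.matrix(volume)
  dimnames(volume) <- list(c("lower", "upper"), c("x", "y", "z"))
  new("SpotField", spots5p = s5, spots3p = s3, pbodies = pb, volume = volume)
}

#' Optimal 5'/3' spot pairing
#'
#' Result of the globally optimal assignment between 5' and 3' spots with
#' pairs at or beyond the distance threshold dissolved into lone ends.
#' Pairs and lone sets partition the input spots.
#'
#' @slot pairs numeric matrix with columns \code{i5}, \code{i3},
#'   \code{distance} (nm); each spot appears in at most one pair and every
#'   pair distance is strictly below \code{threshold}.
#' @slot lone5p,lone3p integer vectors of unpaired spot indices.
#' @slot threshold numeric(1) pairing distance threshold in nm.
#' @export
setClass("SpotMatching",
  representation(pairs = "matrix", lone5p = "integer", lone3p = "integer",
                 threshold = "numeric"))

setValidity("SpotMatching", function(object) {
  p <- object@pairs
  if (ncol(p) != 3L) return("pairs must have columns i5, i3, distance")
  if (nrow(p)) {
    if (anyDuplicated(p[, 1]) || anyDuplicated(p[, 2]))
      return("a spot may appear in at most one pair")
    if (any(p[, 3] >= object@threshold))
      return("all pair distances must be strictly below the threshold")
    if (any(p[, 1] %in% object@lone5p) || any(p[, 2] %in% object@lone3p))
      return("paired spots cannot also be lone")
  }
  TRUE
})
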