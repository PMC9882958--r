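## MAP and MALA inference for the joint GP-ODE model.  All inference runs in
## log-parameter space: the six parameters are strictly positive and the
## posterior is much closer to Gaussian on the log scale.  Priors are
## independent normals on the log parameters (i.e. log-normal on the natural
## scale), weakly informative and overridable.

.PAR_NAMES <- c("lengthscale", "variance", "S", "D", "noiseVarP", "noiseVarM")

#' Default log-normal priors for the six ODE model parameters
#'
#' Independent normal priors on the log parameters.  Defaults: lengthscale
#' centred on 25 min (dynamics unfold over a 125-min window), unit-scale
#' signal variance for sd-scaled data, production scale and degradation rate
#' centred on 0.05 and 0.02 per minute, and noise variances centred on 0.02
#' (a few percent of a unit-variance signal).  Standard deviations are wide
#' (0.75--1.5 on the log scale) so the data dominate.
#'
#' @return data.frame with columns \code{meanlog}, \code{sdlog}, one row per
#'   parameter.
#' @export
defaultPriors <- function() {
  data.frame(
    row.names = .PAR_NAMES,
    meanlog = c(log(25), 0, log(0.05), log(0.02), log(0.02), log(0.02)),
    sdlog   = c(0.75, 1, 1.5, 1.5, 1.5, 1.5))
}

.PAR_LOWER <- log(c(2, 1e-4, 1e-4, 1e-4, 1e-6, 1e-6))
.PAR_UPPER <- log(c(500, 1e3, 1e3, 1, 10, 10))

.paramsFromLog <- function(lp) {
  p <- exp(lp)
  ODEModelParams(p[1], p[2], p[3], p[4], p[5], p[6])
}

#' Assemble observation data for the joint model
#'
#' @param timesP,valuesP pre-mRNA observation times (min AEL) and values
#'   (replicates appear as repeated times).
#' @param timesM,valuesM mature mRNA observation times and values.
#' @param t0 model start time (default 95); m(t0) = 0 is assumed, which the
#'   zygotic filter justifies.
#' @param scale if TRUE (default), each series is divided by its standard
#'   deviation (not centred: zygotic series genuinely start near zero and the
#'   model pins m(t0) = 0).  Half-life is invariant to this scaling; S is
#'   reported on the scaled scale.
#' @return list used by [logPosterior()], [fitMAP()], [samplePosteriorMALA()].
#' @export
jointData <- function(timesP, valuesP, timesM, valuesM, t0 = 95, scale = TRUE) {
  stopifnot(length(timesP) == length(valuesP),
            length(timesM) == length(valuesM),
            length(valuesP) > 0, length(valuesM) > 0,
            all(is.finite(valuesP)), all(is.finite(valuesM)))
  scaleP <- if (scale) stats::sd(valuesP) else 1
  scaleM <- if (scale) stats::sd(valuesM) else 1
  if (!is.finite(scaleP) || scaleP == 0) scaleP <- 1
  if (!is.finite(scaleM) || scaleM == 0) scaleM <- 1
  op <- order(timesP); om <- order(timesM)
  up <- sort(unique(timesP)); um <- sort(unique(timesM))
  list(timesP = timesP[op], yP = valuesP[op] / scaleP,
       timesM = timesM[om], yM = valuesM[om] / scaleM,
       t0 = t0, scaleP = scaleP, scaleM = scaleM,
       uP = up, uM = um,
       iP = match(timesP[op], up), iM = match(timesM[om], um))
}

# Joint covariance over the observation vector (p obs then m obs), built on
# the distinct-time grids and expanded to replicates by indexing.
.obsCovariance <- function(par, data) {
  l <- par[1]; v <- par[2]; S <- par[3]; D <- par[4]
  tp <- data$uP - data$t0
  tm <- data$uM - data$t0
  np <- length(tp)
  Kpp <- rbfKernel(tp, tp, l, v)
  Kpm <- .kernelPM(tp, tm, l, v, S, D)
  Kmm <- .kernelMM(tm, tm, l, v, S, D)
  Kmm <- (Kmm + t(Kmm)) / 2
  K <- rbind(cbind(Kpp, Kpm), cbind(t(Kpm), Kmm))
  idx <- c(data$iP, np + data$iM)
  K[idx, idx, drop = FALSE]
}

#' Log posterior of the joint GP-ODE model
#'
#' Gaussian marginal log likelihood of the stacked observation vector
#' (pre-mRNA then mature) under [jointOdeKernel()] plus the observation-noise
#' diagonal, plus the log prior.  Parameter points whose covariance is not
#' positive definite after the jitter ladder score \code{-Inf}.
#'
#' @param logPar numeric(6): log of (lengthscale, variance, S, D, noiseVarP,
#'   noiseVarM).
#' @param data a list from [jointData()].
#' @param priors data.frame as [defaultPriors()].
#' @return scalar log posterior density (nats, up to a constant).
#' @export
logPosterior <- function(logPar, data, priors = defaultPriors()) {
  if (any(!is.finite(logPar))) return(-Inf)
  par <- exp(logPar)
  K <- .obsCovariance(par, data)
  nP <- length(data$yP); nM <- length(data$yM)
  noise <- c(rep(par[5], nP), rep(par[6], nM))
  diag(K) <- diag(K) + noise
  R <- .cholJitter(K)
  if (is.null(R)) return(-Inf)
  y <- c(data$yP, data$yM)
  alpha <- backsolve(R, forwardsolve(t(R), y))
  ll <- -0.5 * sum(y * alpha) - sum(log(diag(R))) -
    0.5 * length(y) * log(2 * pi)
  lp <- sum(stats::dnorm(logPar, priors$meanlog, priors$sdlog, log = TRUE))
  ll + lp
}

# forward finite-difference gradient of the log posterior; f0 can be
# supplied to reuse an already-computed value at logPar.  (The Metropolis
# correction keeps the MALA chain exactly invariant for any deterministic
# gradient approximation.)
.gradLogPosterior <- function(logPar, data, priors, h = 1e-6, f0 = NULL) {
  if (is.null(f0)) f0 <- logPosterior(logPar, data, priors)
  g <- numeric(6)
  for (i in seq_len(6)) {
    e <- numeric(6); e[i] <- h
    g[i] <- (logPosterior(logPar + e, data, priors) - f0) / h
  }
  g
}

#' Maximum a posteriori fit by multi-restart bounded quasi-Newton
#'
#' Optimises the log posterior over the six log parameters with L-BFGS-B from
#' several seeded, jittered initialisations (the GP marginal likelihood is
#' multi-modal) and returns the best converged run.
#'
#' @param data list from [jointData()].
#' @param priors data.frame as [defaultPriors()].
#' @param seed integer seed; the fit is deterministic given the seed.
#' @param nRestarts number of optimisation restarts (default 5).
#' @return list with \code{params} (\linkS4class{ODEModelParams}),
#'   \code{logPar}, \code{logPosterior}, \code{convergence} (0 = clean),
#'   \code{nRestartsOK}.
#' @export
fitMAP <- function(data, priors = defaultPriors(), seed = 1L, nRestarts = 5L) {
  set.seed(seed)
  starts <- vector("list", nRestarts)
  starts[[1]] <- priors$meanlog
  if (nRestarts > 1)
    for (i in 2:nRestarts)
      starts[[i]] <- priors$meanlog + stats::rnorm(6, 0, 0.6 * priors$sdlog)
  negf <- function(lp) {
    v <- logPosterior(lp, data, priors)
    if (!is.finite(v)) 1e10 else -v
  }
  best <- NULL; nok <- 0L
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, negf, method = "L-BFGS-B",
                   lower = .PAR_LOWER, upper = .PAR_UPPER,
                   control = list(maxit = 300)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e10) next
    nok <- nok + 1L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("all MAP restarts failed: transcript cannot be fit")
  list(params = .paramsFromLog(best$par), logPar = best$par,
       logPosterior = -best$value, convergence = best$convergence,
       nRestartsOK = nok)
}

#' Posterior sampling with the Metropolis-adjusted Langevin algorithm
#'
#' MALA in log-parameter space with Metropolis correction: proposals
#' x' = x + (eps^2/2) grad + eps xi use the gradient of the log posterior
#' (central finite differences), giving much better exploration than a
#' random-walk chain.  The step size adapts towards a 0.574 acceptance rate
#' during burn-in only, then stays fixed so the post-burn-in chain is a
#' valid MCMC sample.
#'
#' @param data list from [jointData()].
#' @param priors data.frame as [defaultPriors()].
#' @param nSamples post-burn-in draws to keep (default 4000).
#' @param burnIn discarded adaptation iterations (default 1000).
#' @param stepSize initial MALA step size on the preconditioned scale
#'   (default 1, the natural scale once the mass matrix absorbs the local
#'   curvature; adapted during burn-in).
#' @param seed integer seed; the chain is reproducible given the seed.
#' @param init optional numeric(6) log-parameter start, typically
#'   \code{fitMAP(...)$logPar}.
#' @return a \linkS4class{PosteriorSamples}.  A warning is emitted if the
#'   post-burn-in acceptance rate leaves (0.05, 0.95) or the chain shows no
#'   effective movement.
#' @export
samplePosteriorMALA <- function(data, priors = defaultPriors(),
                                nSamples = 4000L, burnIn = 1000L,
                                stepSize = 1.0, seed = 1L, init = NULL) {
  set.seed(seed)
  x0 <- if (is.null(init)) priors$meanlog else init
  # precondition with the inverse curvature at the start point so the chain
  # explores all six log parameters (and their ridges) on native scales
  H <- .hessLogPosterior(x0, data, priors)
  mass <- .massFromHessian(H, max(priors$sdlog)^2)
  res <- .runMALA(logTarget = function(x) logPosterior(x, data, priors),
                  gradTarget = function(x, fx = NULL)
                    .gradLogPosterior(x, data, priors, f0 = fx),
                  init = x0, nSamples = nSamples, burnIn = burnIn,
                  stepSize = stepSize, massMatrix = mass)
  draws <- exp(res$draws)
  colnames(draws) <- .PAR_NAMES
  rate <- res$acceptanceRate
  if (rate < 0.05 || rate > 0.95)
    warning(sprintf("MALA acceptance rate %.2f outside (0.05, 0.95); ",
                    rate), "inspect chain diagnostics")
  if (all(apply(draws, 2, stats::sd) == 0))
    warning("MALA chain shows zero effective movement")
  rate <- min(max(rate, 1 / (nSamples + 1)), nSamples / (nSamples + 1))
  new("PosteriorSamples", draws = draws, acceptanceRate = rate,
      seed = as.integer(seed), chainLength = as.integer(burnIn + nSamples),
      burnIn = as.integer(burnIn), stepSize = res$stepSize)
}

# Generic MALA chain over an arbitrary log target.  Proposal
# x' = x + (eps^2/2) M grad + eps chol(M)' xi with Metropolis-Hastings
# correction, where M is an optional SPD preconditioner (mass matrix)
# matching the target's local covariance (e.g. the inverse Hessian at the
# MAP), which decorrelates ridge-shaped posteriors such as the S-D ridge of
# the ODE model; the step size adapts towards ~0.574 acceptance during
# burn-in only.  Uses the current RNG stream (caller sets the seed).
.runMALA <- function(logTarget, gradTarget, init, nSamples, burnIn,
                     stepSize, massMatrix = NULL, adaptTarget = 0.574) {
  x <- init
  d <- length(x)
  if (is.null(massMatrix)) massMatrix <- diag(d)
  Rm <- chol(massMatrix)          # M = Rm' Rm
  Minv <- chol2inv(Rm)
  fx <- logTarget(x)
  if (!is.finite(fx)) stop("initial point has zero target density")
  gx <- gradTarget(x, fx)
  eps <- stepSize
  draws <- matrix(NA_real_, nSamples, d)
  accWin <- 0L; winLen <- 25L; accPost <- 0L
  qdist <- function(a, b) drop(t(a - b) %*% Minv %*% (a - b))
  for (it in seq_len(burnIn + nSamples)) {
    xi <- stats::rnorm(d)
    mu <- x + 0.5 * eps^2 * drop(massMatrix %*% gx)
    xp <- mu + eps * drop(crossprod(Rm, xi))
    fp <- logTarget(xp)
    if (is.finite(fp)) {
      gp <- gradTarget(xp, fp)
      mup <- xp + 0.5 * eps^2 * drop(massMatrix %*% gp)
      lqFwd <- -qdist(xp, mu) / (2 * eps^2)
      lqRev <- -qdist(x, mup) / (2 * eps^2)
      la <- fp + lqRev - fx - lqFwd
      if (is.finite(la) && log(stats::runif(1)) < la) {
        x <- xp; fx <- fp; gx <- gp
        accWin <- accWin + 1L
        if (it > burnIn) accPost <- accPost + 1L
      }
    }
    if (it <= burnIn && it %% winLen == 0L) {
      eps <- eps * exp(accWin / winLen - adaptTarget)
      accWin <- 0L
    }
    if (it > burnIn) draws[it - burnIn, ] <- x
  }
  list(draws = draws, acceptanceRate = accPost / nSamples, stepSize = eps)
}

# full finite-difference Hessian of the log posterior at a point; the MALA
# mass matrix is its negated inverse, eigenvalue-clamped to SPD with scales
# bounded by the prior variances
.hessLogPosterior <- function(logPar, data, priors, h = 1e-3) {
  d <- length(logPar)
  H <- matrix(0, d, d)
  f0 <- logPosterior(logPar, data, priors)
  fp <- fm <- numeric(d)
  for (i in seq_len(d)) {
    e <- numeric(d); e[i] <- h
    fp[i] <- logPosterior(logPar + e, data, priors)
    fm[i] <- logPosterior(logPar - e, data, priors)
    H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h^2
  }
  for (i in seq_len(d - 1)) for (j in (i + 1):d) {
    ei <- numeric(d); ei[i] <- h
    ej <- numeric(d); ej[j] <- h
    fpp <- logPosterior(logPar + ei + ej, data, priors)
    H[i, j] <- H[j, i] <-
      (fpp - fp[i] - fp[j] + f0) / h^2
  }
  H
}

.massFromHessian <- function(H, priorVar) {
  ev <- eigen(-(H + t(H)) / 2, symmetric = TRUE)
  lam <- pmin(pmax(ev$values, 1 / priorVar), 1e6)  # curvature bounds
  M <- ev$vectors %*% diag(1 / lam) %*% t(ev$vectors)
  (M + t(M)) / 2
}

#' Half-life from a first-order degradation rate
#'
#' t1/2 = ln(2) / D for exponential decay at rate D per minute.
#'
#' @param D degradation rate(s), per minute; must be > 0.
#' @return half-life in minutes.
#' @examples
#' halfLifeFromD(0.003)   # 231.0 min
#' halfLifeFromD(0.05)    # 13.9 min
#' @export
halfLifeFromD <- function(D) {
  if (any(!is.finite(D)) || any(D <= 0))
    stop("degradation rate D must be finite and > 0")
  log(2) / D
}

#' Assign half-life stability categories
#'
#' Boundaries at 15 and 25 minutes; half-lives above 250 minutes are excluded
#' from the reported set.
#'
#' @param tHalf half-life/-lives in minutes (> 0).
#' @param boundaries numeric(2) category boundaries (default c(15, 25)).
#' @param exclusionLimit half-lives above this are "excluded" (default 250).
#' @return factor with levels short, medium, long, excluded.
#' @examples
#' categorizeHalfLife(c(9, 16, 28, 260))
#' @export
categorizeHalfLife <- function(tHalf, boundaries = c(15, 25),
                               exclusionLimit = 250) {
  stopifnot(all(tHalf > 0), length(boundaries) == 2,
            boundaries[1] < boundaries[2], exclusionLimit > boundaries[2])
  out <- ifelse(tHalf > exclusionLimit, "excluded",
         ifelse(tHalf < boundaries[1], "short",
         ifelse(tHalf <= boundaries[2], "medium", "long")))
  factor(out, levels = c("short", "medium", "long", "excluded"))
}

#' Equal-tailed credible interval for the half-life
#'
#' Quantile interval of ln(2)/D over the post-burn-in MALA draws.
#'
#' @param samples a \linkS4class{PosteriorSamples} with >= 200 draws.
#' @param level credible level (default 0.95).
#' @return named numeric: \code{lower}, \code{median}, \code{upper} (minutes).
#' @export
credibleInterval <- function(samples, level = 0.95) {
  stopifnot(is(samples, "PosteriorSamples"))
  if (nrow(samples@draws) < 200L)
    stop("need at least 200 post-burn-in draws for a credible interval")
  th <- log(2) / samples@draws[, "D"]
  a <- (1 - level) / 2
  q <- stats::quantile(th, c(a, 0.5, 1 - a), names = FALSE)
  c(lower = q[1], median = q[2], upper = q[3])
}

#' Fit the half-life of one transcript
#'
#' End-to-end per-transcript inference: scale the series, find the MAP point,
#' run a MALA chain started at the MAP, and report D, t1/2 = ln(2)/D, the 95%
#' credible interval and the stability category.
#'
#' @param timesP,valuesP,timesM,valuesM observations as in [jointData()].
#' @param transcriptID identifier carried into the result.
#' @param priors data.frame as [defaultPriors()].
#' @param nSamples,burnIn,stepSize MALA settings (see
#'   [samplePosteriorMALA()]).
#' @param nRestarts MAP optimisation restarts (see [fitMAP()]).
#' @param seed integer seed governing both MAP restarts and the chain.
#' @param t0 model start time (default 95 min AEL).
#' @param posterior keep the \linkS4class{PosteriorSamples} object in the
#'   result (default TRUE).
#' @return list with \code{transcriptID}, \code{map} (ODEModelParams),
#'   \code{DMap}, \code{tHalf}, \code{ci} (lower/median/upper minutes),
#'   \code{category}, \code{acceptanceRate}, \code{nonIdentifiable} flag
#'   (credible interval on D nearly as wide as the prior's central 90%
#'   interval), and optionally \code{posterior}.
#' @export
fitHalfLife <- function(timesP, valuesP, timesM, valuesM,
                        transcriptID = NA_character_,
                        priors = defaultPriors(),
                        nSamples = 4000L, burnIn = 1000L, stepSize = 0.1,
                        nRestarts = 5L, seed = 1L, t0 = 95, posterior = TRUE) {
  data <- jointData(timesP, valuesP, timesM, valuesM, t0 = t0)
  map <- fitMAP(data, priors, seed = seed, nRestarts = nRestarts)
  post <- samplePosteriorMALA(data, priors, nSamples = nSamples,
                              burnIn = burnIn, stepSize = stepSize,
                              seed = seed + 1L, init = map$logPar)
  ci <- credibleInterval(post)
  DMap <- map$params@D
  tHalf <- halfLifeFromD(DMap)
  # posterior spread of log D close to the prior's spread means the data
  # did not constrain the degradation rate
  nonIdent <- stats::sd(log(post@draws[, "D"])) > 0.5 * priors["D", "sdlog"]
  out <- list(transcriptID = transcriptID, map = map$params,
              DMap = DMap, tHalf = tHalf, ci = ci,
              category = categorizeHalfLife(tHalf),
              acceptanceRate = post@acceptanceRate,
              nonIdentifiable = nonIdent,
              logPosterior = map$logPosterior)
  if (posterior) out$posterior <- post
  out
}
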