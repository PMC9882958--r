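## Single-series GP regression with an RBF + white-noise kernel, used by the
## dynamic (LLR) filter and by the peak-delay analysis.  Replicates enter as
## repeated observations at the same time.

# negative log marginal likelihood of y ~ N(0, K_rbf + sn2 I)
.nlmlRBF <- function(logTheta, t, y) {
  l <- exp(logTheta[1]); v <- exp(logTheta[2]); sn2 <- exp(logTheta[3])
  K <- rbfKernel(t, t, l, v)
  diag(K) <- diag(K) + sn2
  R <- .cholJitter(K)
  if (is.null(R)) return(1e10)
  alpha <- backsolve(R, forwardsolve(t(R), y))
  0.5 * sum(y * alpha) + sum(log(diag(R))) + 0.5 * length(y) * log(2 * pi)
}

#' Fit a GP to one expression series
#'
#' Maximum-marginal-likelihood fit of either a dynamic model (RBF kernel plus
#' white noise) or a pure-noise model.  The series is centred internally
#' (zero-mean GP); the noise-only model then has the closed-form optimum
#' sigma2_hat = mean(y^2), while the RBF model is optimised by multi-restart
#' L-BFGS-B over log hyperparameters with seeded jittered initialisations
#' (the marginal likelihood is multi-modal).
#'
#' @param times observation times (replicates = repeated times).
#' @param values observed expression, same length as \code{times}.
#' @param kernel \code{"rbf_plus_noise"} or \code{"noise_only"}.
#' @param nRestarts optimisation restarts for the RBF model (default 5).
#' @param seed integer seed for the restart jitter.
#' @return list with \code{kernel}, \code{hyperparameters} (lengthscale,
#'   variance, noiseVar as applicable), \code{logLik} (maximised log marginal
#'   likelihood, nats), \code{converged}, and the centred data (\code{times},
#'   \code{values}, \code{offset}) for downstream prediction.
#' @export
fitSeriesGP <- function(times, values,
                        kernel = c("rbf_plus_noise", "noise_only"),
                        nRestarts = 5L, seed = 1L) {
  kernel <- match.arg(kernel)
  stopifnot(length(times) == length(values), length(unique(times)) >= 2,
            all(is.finite(values)))
  mu <- mean(values)
  y <- values - mu
  n <- length(y)
  if (kernel == "noise_only") {
    s2 <- mean(y^2)
    if (s2 == 0) s2 <- .Machine$double.eps
    ll <- -0.5 * n * log(2 * pi * s2) - 0.5 * n
    return(list(kernel = kernel, hyperparameters = c(noiseVar = s2),
                logLik = ll, converged = TRUE,
                times = times, values = y, offset = mu))
  }
  sdy <- stats::sd(y); if (sdy == 0) sdy <- 1
  span <- diff(range(times))
  set.seed(seed)
  base <- c(log(span / 4), log(sdy^2), log(0.1 * sdy^2))
  lower <- c(log(span / 50), log(1e-8 * sdy^2), log(1e-8 * sdy^2))
  upper <- c(log(span * 10), log(1e3 * sdy^2), log(1e3 * sdy^2))
  best <- NULL
  for (i in seq_len(nRestarts)) {
    st <- if (i == 1) base else base + stats::rnorm(3, 0, 1)
    st <- pmin(pmax(st, lower), upper)
    fit <- tryCatch(
      stats::optim(st, .nlmlRBF, t = times, y = y, method = "L-BFGS-B",
                   lower = lower, upper = upper, control = list(maxit = 200)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e10) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    return(list(kernel = kernel, hyperparameters = NULL, logLik = NA_real_,
                converged = FALSE, times = times, values = y, offset = mu))
  hp <- exp(best$par)
  names(hp) <- c("lengthscale", "variance", "noiseVar")
  list(kernel = kernel, hyperparameters = hp, logLik = -best$value,
       converged = TRUE,
       times = times, values = y, offset = mu)
}

#' GP posterior mean and draws on a prediction grid
#'
#' Standard GP conditional for the RBF + noise model fitted by
#' [fitSeriesGP()]: posterior over the noise-free latent function on
#' \code{grid}, optionally with joint posterior draws.
#'
#' @param fit an RBF fit from [fitSeriesGP()].
#' @param grid prediction times.
#' @param nDraws number of posterior function draws (0 = mean/cov only).
#' @param seed integer seed for the draws.
#' @return list with \code{mean} (length(grid)), \code{cov}, and if
#'   \code{nDraws > 0} a matrix \code{draws} (grid x nDraws).  Values include
#'   the series offset (original scale).
#' @export
gpPosterior <- function(fit, grid, nDraws = 0L, seed = 1L) {
  stopifnot(fit$kernel == "rbf_plus_noise", !is.null(fit$hyperparameters))
  hp <- fit$hyperparameters
  t <- fit$times; y <- fit$values
  K <- rbfKernel(t, t, hp["lengthscale"], hp["variance"])
  diag(K) <- diag(K) + hp["noiseVar"]
  R <- .cholJitter(K)
  if (is.null(R)) stop("posterior covariance factorisation failed")
  Ks <- rbfKernel(grid, t, hp["lengthscale"], hp["variance"])
  Kss <- rbfKernel(grid, grid, hp["lengthscale"], hp["variance"])
  alpha <- backsolve(R, forwardsolve(t(R), y))
  mu <- as.vector(Ks %*% alpha) + fit$offset
  V <- forwardsolve(t(R), t(Ks))
  S <- Kss - crossprod(V)
  S <- (S + t(S)) / 2
  out <- list(mean = mu, cov = S)
  if (nDraws > 0) {
    set.seed(seed)
    Rs <- .cholJitter(S)
    if (is.null(Rs)) stop("posterior covariance factorisation failed")
    Z <- matrix(stats::rnorm(length(grid) * nDraws), length(grid), nDraws)
    out$draws <- mu + crossprod(Rs, Z)
  }
  out
}
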