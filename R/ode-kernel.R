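## Closed-form joint covariance of (p, m) where p(t) ~ GP(0, RBF) and
## m(t) = S * int_{t0}^t exp(-D (t-u)) p(u) du  (i.e. dm/dt = S p - D m,
## m(t0) = 0).  All cross terms reduce to differences of erfc values; each
## term is computed as exp(E + log erfc(x)) so that the exp(gamma^2)-type
## prefactors never overflow and opposing erf tails never cancel
## catastrophically.

# log erfc(x), stable for large |x|; erfc(x) = 2 * pnorm(-x * sqrt(2))
.logErfc <- function(x) log(2) + stats::pnorm(-x * sqrt(2), log.p = TRUE)

# exp(e) * erfc(x), computed in log space
.expErfc <- function(e, x) exp(e + .logErfc(x))

#' RBF kernel matrix
#'
#' @param t1,t2 numeric time vectors.
#' @param lengthscale,variance kernel hyperparameters;
#'   k(t, t') = variance * exp(-(t - t')^2 / (2 lengthscale^2)).
#' @return length(t1) x length(t2) covariance matrix.
#' @export
rbfKernel <- function(t1, t2, lengthscale, variance) {
  variance * exp(-outer(t1, t2, "-")^2 / (2 * lengthscale^2))
}

# Cov(p(tp), m(tm)); tp, tm are vectors of times relative to the model
# start (tau = t - t0), so m(0) = 0.
.kernelPM <- function(tp, tm, lengthscale, variance, S, D) {
  l <- lengthscale
  s <- sqrt(2) * l
  g <- D * l / sqrt(2)
  A <- S * variance * l * sqrt(pi / 2)
  Dl <- outer(tp, tm, function(a, b) b - a)  # tm - tp
  TP <- matrix(tp, length(tp), length(tm))
  A * (.expErfc(g^2 - D * Dl, g - Dl / s) -
       .expErfc(g^2 - D * Dl, g + TP / s))
}

# Cov(m(t), m(t')) for times relative to the model start
.kernelMM <- function(tm1, tm2, lengthscale, variance, S, D) {
  l <- lengthscale
  s <- sqrt(2) * l
  g <- D * l / sqrt(2)
  B <- S^2 * variance * l * sqrt(pi / 2) / (2 * D)
  T1 <- matrix(tm1, length(tm1), length(tm2))
  T2 <- t(matrix(tm2, length(tm2), length(tm1)))
  Dl <- T1 - T2
  term1 <- .expErfc(g^2 + D * Dl,  Dl / s + g) - .expErfc(g^2 + D * Dl, T1 / s + g)
  term2 <- .expErfc(g^2 - D * Dl, -Dl / s + g) - .expErfc(g^2 - D * Dl, T2 / s + g)
  term3 <- .expErfc(g^2 - D * (T1 + T2), g - T1 / s) -
           .expErfc(g^2 - D * (T1 + T2), g)
  term4 <- .expErfc(g^2 - D * (T1 + T2), g - T2 / s) -
           .expErfc(g^2 - D * (T1 + T2), g)
  B * (term1 + term2 - term3 - term4)
}

#' Joint GP-ODE covariance over pre-mRNA and mature mRNA
#'
#' Builds the block covariance matrix of the joint Gaussian process
#' (p(times_p), m(times_m)) implied by an RBF prior on the pre-mRNA p(t) and
#' the degradation ODE dm/dt = S p(t) - D m(t) with initial condition
#' m(t0) = 0 (zygotic transcripts carry no mature mRNA at the start of the
#' window).  The blocks are K_pp (RBF), K_pm and K_mm, the latter two in
#' closed form via erf integrals of the exponential-decay convolution.
#'
#' @param params an \linkS4class{ODEModelParams} (noise variances unused here).
#' @param timesP,timesM times (minutes) at which p and m are evaluated.
#' @param t0 model start time; default 95 min AEL.
#' @return (length(timesP) + length(timesM)) square symmetric covariance
#'   matrix, p-block first.
#' @examples
#' par <- ODEModelParams(20, 1, 1, 0.02, 0.01, 0.01)
#' K <- jointOdeKernel(par, timesP = c(95, 145, 220), timesM = c(95, 145, 220))
#' isSymmetric(K)
#' @export
jointOdeKernel <- function(params, timesP, timesM, t0 = 95) {
  stopifnot(is(params, "ODEModelParams"))
  tp <- timesP - t0
  tm <- timesM - t0
  l <- params@lengthscale; v <- params@variance
  Kpp <- rbfKernel(tp, tp, l, v)
  Kpm <- .kernelPM(tp, tm, l, v, params@S, params@D)
  Kmm <- .kernelMM(tm, tm, l, v, params@S, params@D)
  Kmm <- (Kmm + t(Kmm)) / 2   # enforce exact symmetry
  rbind(cbind(Kpp, Kpm), cbind(t(Kpm), Kmm))
}

# Cholesky with a jitter ladder on the diagonal; NULL if the matrix is not
# numerically PSD even at the maximum jitter.
.cholJitter <- function(K, jitters = 10^seq(-8, -4, by = 1)) {
  sc <- mean(diag(K))
  if (!is.finite(sc) || sc <= 0) sc <- 1
  for (j in c(0, jitters)) {
    R <- tryCatch(chol(K + diag(j * sc, nrow(K))), error = function(e) NULL)
    if (!is.null(R)) return(R)
  }
  NULL
}
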