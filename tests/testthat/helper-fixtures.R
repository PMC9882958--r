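# Shared fixtures and independent oracles, built in code at test time.

PAPER_GRID <- c(95, 105, 115, 125, 145, 160, 175, 190, 205, 220)

# small TimeCourseMatrix with nFeat features on the full grid x 3 reps
makeTCM <- function(values, nReps = 3, times = PAPER_GRID) {
  values <- as.matrix(values)
  TimeCourseMatrix(values, time = rep(times, each = nReps),
                   replicate = rep(seq_len(nReps), length(times)),
                   featureIDs = rownames(values))
}

# brute-force minimum-cost rectangular assignment by exhaustive enumeration
# (rows <= cols; returns min total cost). Independent of the package solver.
bruteForceAssignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m, n <= 7)
  best <- Inf
  rec <- function(row, used, acc) {
    if (acc >= best) return()
    if (row > n) { best <<- acc; return() }
    for (j in seq_len(m)) if (!used[j]) {
      used[j] <- TRUE
      rec(row + 1, used, acc + cost[row, j])
      used[j] <- FALSE
    }
  }
  rec(1, rep(FALSE, m), 0)
  best
}

# Monte-Carlo oracle for the joint (p, m) covariance: draw p paths from the
# RBF GP on a fine grid and push each through an exponential-trapezoidal
# numerical integrator of dm/dt = S p - D m, m(t0) = 0.  Independent of the
# package's closed-form kernel.  Returns empirical covariance of the stacked
# vector (p(times), m(times)) and its per-entry Monte-Carlo SE.
mcJointCov <- function(lengthscale, variance, S, D, times, t0 = 95,
                       nPaths = 50000, h = 0.25, chunk = 10000, seed = 1) {
  set.seed(seed)
  fine <- seq(t0, max(times), by = h)
  nf <- length(fine)
  obs <- match(times, fine)
  stopifnot(!anyNA(obs))
  K <- rbfKernel(fine, fine, lengthscale, variance) + diag(1e-9, nf)
  L <- t(chol(K))
  ed <- exp(-D * h)
  dim2 <- 2 * length(times)
  S1 <- matrix(0, dim2, dim2); S2 <- matrix(0, dim2, dim2)
  done <- 0
  while (done < nPaths) {
    nc <- min(chunk, nPaths - done)
    P <- L %*% matrix(rnorm(nf * nc), nf, nc)
    M <- matrix(0, nf, nc)
    for (i in 2:nf)
      M[i, ] <- M[i - 1, ] * ed + S * h / 2 * (P[i - 1, ] * ed + P[i, ])
    X <- rbind(P[obs, , drop = FALSE], M[obs, , drop = FALSE])
    S1 <- S1 + tcrossprod(X)
    X2 <- X * X
    S2 <- S2 + tcrossprod(X2)
    done <- done + nc
  }
  emp <- S1 / nPaths
  se <- sqrt(pmax(S2 / nPaths - emp^2, 0) / nPaths)
  list(cov = emp, se = se, n = nPaths)
}

# analytic joint covariance at the observation times for comparison
analyticJointCov <- function(lengthscale, variance, S, D, times, t0 = 95) {
  jointOdeKernel(ODEModelParams(lengthscale, variance, S, D, 1e-12, 1e-12),
                 timesP = times, timesM = times, t0 = t0)
}
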