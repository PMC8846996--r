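#' Tensor-product Gauss-Hermite grid
#'
#' Builds the Cartesian product of one-dimensional Gauss-Hermite abscissas
#' and weights (physicists' convention, weight function \eqn{e^{-|c|^2}},
#' so the weights sum to \eqn{\pi^{q/2}}).
#'
#' @param nq number of quadrature points per dimension.
#' @param q dimension of the random effects vector.
#' @return object of class `ghGrid` with `C` (the `nq^q` by `q` matrix of
#'   abscissas \eqn{c_t}), `logw` (log product weights \eqn{\log\pi_t}) and
#'   `c2` (\eqn{|c_t|^2}, the compensation factor folded into log-space
#'   accumulation).
#' @export
ghGrid <- function(nq, q) {
  stopifnot(nq >= 1, q >= 1)
  if (nq == 1L) {
    gh <- list(x = 0, w = sqrt(pi))
  } else {
    gh <- pracma::gaussHermite(nq)
  }
  grids <- rep(list(seq_len(nq)), q)
  comb <- as.matrix(expand.grid(grids))
  C <- matrix(gh$x[comb], ncol = q)
  logw <- rowSums(matrix(log(gh$w)[comb], ncol = q))
  structure(list(nq = as.integer(nq), q = as.integer(q),
                 C = unname(C), logw = logw, c2 = rowSums(C^2)),
            class = "ghGrid")
}

#' Rescaled abscissas for the standard quadrature rule
#'
#' Maps the raw grid to \eqn{\tilde b_t = \sqrt{2}\,\Sigma^{1/2} c_t}
#' (symmetric eigendecomposition square root).  These points depend on the
#' current \eqn{\Sigma^{(m)}} and are recomputed at every EM iteration.
#'
#' @param grid a [ghGrid()].
#' @param Sigma current random-effects covariance (PSD).
#' @return matrix of points (rows \eqn{\tilde b_t}) with attribute
#'   `logJacobian`, the log change-of-variable factor
#'   \eqn{(q/2)\log 2 + \tfrac12\log|\Sigma|}.
#' @export
standardAbscissas <- function(grid, Sigma) {
  Sigma <- as.matrix(Sigma)
  e <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-10) stop("Sigma must be positive semi-definite")
  ev <- pmax(e$values, 0)
  root <- e$vectors %*% (sqrt(ev) * t(e$vectors))
  pts <- sqrt(2) * grid$C %*% root
  attr(pts, "logJacobian") <- (grid$q / 2) * log(2) +
    0.5 * sum(log(pmax(ev, 1e-300)))
  pts
}

#' Pseudo-adaptive abscissas for one subject
#'
#' Maps the raw grid to \eqn{\tilde r_t = \tilde b_i + \sqrt{2}\,
#' \tilde H_i^{-1/2} c_t}, centred and scaled by the subject's empirical
#' Bayes estimate from the preliminary mixed-model fit.  These points are
#' computed once before the EM loop and never updated.
#'
#' @param grid a [ghGrid()].
#' @param eb an [ebMoments()] object.
#' @param i subject index (in the descending-time ordering).
#' @return matrix of points with attribute `logJacobian`.
#' @export
pseudoAdaptiveAbscissas <- function(grid, eb, i) {
  root <- .symSqrt(eb$H_inv[[i]])
  pts <- sqrt(2) * grid$C %*% root
  pts <- sweep(pts, 2L, eb$b_tilde[i, ], "+")
  attr(pts, "logJacobian") <- (grid$q / 2) * log(2) + 0.5 * attr(root, "logdet")
  pts
}

# Evaluate the fitted step cumulative baseline hazards at every subject's
# observed time, and the jump at each event subject's own time.
# Returns Lambda (n x K) and logdL (n; log jump for subjects with
# cause = k > 0, NA for censored).  Errors if an event subject's time
# carries no positive jump (inconsistent baseline).
.baselineAt <- function(data, params) {
  n <- data$n
  Lambda <- matrix(0, n, data$K)
  logdL <- rep(NA_real_, n)
  for (k in seq_len(data$K)) {
    bl <- params$baseline[[k]]
    ei <- data$events[[k]]
    if (length(bl$times) != ei$q_k || (ei$q_k && any(bl$times != ei$times)))
      stop("baseline jump times do not match the event-time index for risk ", k)
    Lambda[, k] <- stepLookup(bl$cum, ei$times, data$time)
    ev <- which(data$cause == k)
    if (length(ev)) {
      j <- ei$jump[ev]
      if (any(!is.finite(bl$jumps[j])) || any(bl$jumps[j] <= 0))
        stop("event subject with zero baseline jump at its event time (risk ", k, ")")
      logdL[ev] <- log(bl$jumps[j])
    }
  }
  list(Lambda = Lambda, logdL = logdL)
}

#' Per-subject complete-data log density
#'
#' Evaluates \eqn{\log f(Y_i, C_i \mid b, \Psi)} at a single random-effects
#' value `b`: the Gaussian log density of the subject's responses, plus for
#' an observed cause \eqn{k = D_i > 0} the term \eqn{\log\Delta\Lambda_{0k}
#' (T_i) + X_i^{(2)T}\gamma_k + \nu_k^T b}, minus the cumulative hazard
#' \eqn{\sum_k \Lambda_{0k}(T_i)\exp(X_i^{(2)T}\gamma_k + \nu_k^T b)}.
#' Entirely on the log scale.
#'
#' @param data a [jointData()] object.
#' @param i subject index (descending-time ordering).
#' @param b numeric q-vector.
#' @param params a parameter set as carried by [jmFit()] objects (elements
#'   `beta`, `sigma2`, `Sigma`, `gamma`, `nu`, `baseline`).
#' @param haz optional precomputed baseline evaluation (internal reuse).
#' @export
logJointDensity <- function(data, i, b, params, haz = NULL) {
  if (is.null(haz)) haz <- .baselineAt(data, params)
  rows <- which(data$subj == i)
  ll <- 0
  if (length(rows)) {
    res <- data$y[rows] - data$X[rows, , drop = FALSE] %*% params$beta -
      data$Z[rows, , drop = FALSE] %*% b
    ll <- -0.5 * length(rows) * log(2 * pi * params$sigma2) -
      sum(res^2) / (2 * params$sigma2)
  }
  for (k in seq_len(data$K)) {
    eta <- sum(data$X2[i, ] * params$gamma[[k]]) + sum(params$nu[[k]] * b)
    if (data$cause[i] == k) ll <- ll + haz$logdL[i] + eta
    ll <- ll - haz$Lambda[i, k] * exp(eta)
  }
  ll
}

#' Posterior moments of the random effects for one subject
#'
#' Reference (per-subject) implementation of the self-normalizing
#' quadrature ratio estimator: posterior expectations of \eqn{b_i},
#' \eqn{b_i b_i^T} and, for each risk, \eqn{\exp(\nu_k^T b_i)},
#' \eqn{b_i\exp(\nu_k^T b_i)}, \eqn{b_i b_i^T\exp(\nu_k^T b_i)} given the
#' subject's longitudinal and survival data.  Weights are handled by
#' log-sum-exp: the maximal log integrand is subtracted before
#' exponentiating.  [eStep()] computes the same quantities vectorized over
#' subjects.
#'
#' @inheritParams logJointDensity
#' @param points rescaled abscissas for this subject, from
#'   [standardAbscissas()] or [pseudoAdaptiveAbscissas()].
#' @param grid the [ghGrid()] the points were built from.
#' @return list with `Eb`, `Ebb`, `Eexp`, `Ebexp`, `Ebbexp`, `logNorm` (the
#'   log normalizing constant, i.e. the subject's observed-data
#'   log-likelihood contribution) and the normalized node `weights`.
#' @export
posteriorMoments <- function(data, i, params, points, grid, haz = NULL) {
  if (is.null(haz)) haz <- .baselineAt(data, params)
  q <- grid$q; Tn <- nrow(points)
  SigInv <- chol2inv(chol(params$Sigma))
  logdet <- determinant(params$Sigma, logarithm = TRUE)$modulus
  logint <- numeric(Tn)
  for (t in seq_len(Tn)) {
    b <- points[t, ]
    logint[t] <- grid$logw[t] + grid$c2[t] + attr(points, "logJacobian") +
      logJointDensity(data, i, b, params, haz) -
      0.5 * q * log(2 * pi) - 0.5 * as.numeric(logdet) -
      0.5 * sum(b * (SigInv %*% b))
  }
  m <- max(logint)
  if (!is.finite(m)) stop("all quadrature integrand values underflowed for subject ", i)
  w <- exp(logint - m)
  den <- sum(w)
  w <- w / den
  Eb <- colSums(w * points)
  Ebb <- crossprod(points, w * points)
  Eexp <- numeric(data$K); Ebexp <- vector("list", data$K); Ebbexp <- vector("list", data$K)
  for (k in seq_len(data$K)) {
    e <- exp(points %*% params$nu[[k]])[, 1]
    Eexp[k] <- sum(w * e)
    Ebexp[[k]] <- colSums(w * e * points)
    Ebbexp[[k]] <- crossprod(points, (w * e) * points)
  }
  list(Eb = Eb, Ebb = Ebb, Eexp = Eexp, Ebexp = Ebexp, Ebbexp = Ebbexp,
       logNorm = m + log(den), weights = w)
}
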