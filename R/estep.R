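# Quadrature point containers used by the EM loop.
#
# For the pseudo-adaptive rule the points are per subject and fixed for the
# whole fit; they are flattened into one n x (T*q) matrix (columns: node t
# of coordinate j at column (j-1)*T + t) plus a per-subject log Jacobian.
# For the standard rule a single T x q matrix is rebuilt from the current
# Sigma at every iteration.
.pseudoPoints <- function(data, grid, eb) {
  n <- data$n; q <- grid$q; Tn <- nrow(grid$C)
  flat <- matrix(0, n, Tn * q)
  logJac <- numeric(n)
  sq2C <- sqrt(2) * grid$C
  for (i in seq_len(n)) {
    root <- .symSqrt(eb$H_inv[[i]])
    pts <- sq2C %*% root
    pts <- sweep(pts, 2L, eb$b_tilde[i, ], "+")
    flat[i, ] <- as.vector(pts)
    logJac[i] <- (q / 2) * log(2) + 0.5 * attr(root, "logdet")
  }
  list(mode = "pseudo-adaptive", flat = flat, logJac = logJac,
       Tn = Tn, q = q)
}

.standardPoints <- function(grid, Sigma) {
  pts <- standardAbscissas(grid, Sigma)
  list(mode = "standard", points = pts,
       logJac = attr(pts, "logJacobian"), Tn = nrow(pts), q = ncol(pts))
}

# node t as an n x q matrix
.nodeMatrix <- function(qp, t, n) {
  if (qp$mode == "pseudo-adaptive") {
    qp$flat[, t + (seq_len(qp$q) - 1L) * qp$Tn, drop = FALSE]
  } else {
    matrix(qp$points[t, ], n, qp$q, byrow = TRUE)
  }
}

#' E-step: posterior moments for all subjects
#'
#' Vectorized evaluation of the per-subject joint density over the
#' quadrature grid and of all posterior expectations needed by the M-step
#' and the score computation: \eqn{E(b_i)}, \eqn{E(b_i b_i^T)} and, for
#' each risk \eqn{k}, \eqn{E\{\exp(\nu_k^T b_i)\}},
#' \eqn{E\{b_i\exp(\nu_k^T b_i)\}}, \eqn{E\{b_i b_i^T\exp(\nu_k^T b_i)\}}.
#' All moment families are accumulated in one pass over the grid so the
#' density is evaluated once per node, and baseline hazards are looked up
#' with the merged linear scan, for a total cost of \eqn{O(n\,n_q^{\,q})}
#' per call.  Log-sum-exp is used throughout.
#'
#' @param data a [jointData()] object.
#' @param params parameter set (elements `beta`, `sigma2`, `Sigma`,
#'   `gamma`, `nu`, `baseline`).
#' @param qp quadrature points, from the internal containers built by
#'   [jmFit()]; pass `NULL` to build standard-rule points from
#'   `params$Sigma`.
#' @param grid the [ghGrid()] in use.
#' @param want_moments if `FALSE`, only the log normalizing constants
#'   (observed-data log-likelihood contributions) are returned.
#' @return object of class `posteriorMomentSet`: `Eb` (n x q), `Ebb`
#'   (n x q^2, column-major), `Eexp` (n x K), `Ebexp`/`Ebbexp` (lists over
#'   risks), `logNorm` (n), and the normalized node weights (n x T).
#' @export
eStep <- function(data, params, qp = NULL, grid = ghGrid(6L, data$q),
                  want_moments = TRUE) {
  if (is.null(qp)) qp <- .standardPoints(grid, params$Sigma)
  n <- data$n; q <- data$q; K <- data$K; Tn <- qp$Tn
  subj <- data$subj
  haz <- .baselineAt(data, params)

  rfix <- data$y - as.vector(data$X %*% params$beta)
  eta <- vapply(seq_len(K), function(k) as.vector(data$X2 %*% params$gamma[[k]]),
                numeric(n))
  evind <- vapply(seq_len(K), function(k) as.numeric(data$cause == k), numeric(n))
  cev <- rowSums(evind * eta) + ifelse(is.na(haz$logdL), 0, haz$logdL)

  SigInv <- chol2inv(chol(params$Sigma))
  logdetS <- as.numeric(determinant(params$Sigma, logarithm = TRUE)$modulus)
  const <- -0.5 * data$nobs * log(2 * pi * params$sigma2) -
    0.5 * q * log(2 * pi) - 0.5 * logdetS + qp$logJac + cev

  L <- matrix(0, n, Tn)
  for (t in seq_len(Tn)) {
    B <- .nodeMatrix(qp, t, n)
    zb <- rowSums(data$Z * B[subj, , drop = FALSE])
    ss <- rowsum((rfix - zb)^2, subj)[, 1L]
    lt <- const - ss / (2 * params$sigma2) -
      0.5 * rowSums((B %*% SigInv) * B) + grid$logw[t] + grid$c2[t]
    for (k in seq_len(K)) {
      nb <- as.vector(B %*% params$nu[[k]])
      lt <- lt + evind[, k] * nb - haz$Lambda[, k] * exp(eta[, k] + nb)
    }
    L[, t] <- lt
  }
  m <- do.call(pmax, as.data.frame(L))
  if (any(!is.finite(m)))
    stop("quadrature integrand underflowed for subject(s) ",
         paste(utils::head(which(!is.finite(m)), 5L), collapse = ", "))
  W <- exp(L - m)
  den <- rowSums(W)
  logNorm <- m + log(den)
  if (!want_moments)
    return(structure(list(logNorm = logNorm), class = "posteriorMomentSet"))
  W <- W / den

  Eb <- matrix(0, n, q)
  Ebb <- matrix(0, n, q * q)
  Eexp <- matrix(0, n, K)
  Ebexp <- rep(list(matrix(0, n, q)), K)
  Ebbexp <- rep(list(matrix(0, n, q * q)), K)
  for (t in seq_len(Tn)) {
    B <- .nodeMatrix(qp, t, n)
    wt <- W[, t]
    BB <- B[, rep(seq_len(q), times = q), drop = FALSE] *
      B[, rep(seq_len(q), each = q), drop = FALSE]
    Eb <- Eb + wt * B
    Ebb <- Ebb + wt * BB
    for (k in seq_len(K)) {
      e <- wt * exp(as.vector(B %*% params$nu[[k]]))
      Eexp[, k] <- Eexp[, k] + e
      Ebexp[[k]] <- Ebexp[[k]] + e * B
      Ebbexp[[k]] <- Ebbexp[[k]] + e * BB
    }
  }
  structure(list(Eb = Eb, Ebb = Ebb, Eexp = Eexp, Ebexp = Ebexp,
                 Ebbexp = Ebbexp, logNorm = logNorm, weights = W, qp = qp),
            class = "posteriorMomentSet")
}

#' Observed-data log-likelihood
#'
#' \eqn{\sum_i \log \int f(Y_i \mid b)\, f(C_i \mid b)\, f(b)\, db},
#' each integral approximated on the quadrature grid on the log scale.
#'
#' @inheritParams eStep
#' @export
observedLoglik <- function(data, params, qp = NULL, grid = ghGrid(6L, data$q)) {
  if (data$n == 0L) return(0)
  sum(eStep(data, params, qp, grid, want_moments = FALSE)$logNorm)
}

# E^{(m)}[ complete-data log-likelihood ] as a function of candidate
# parameters, using the stored node weights of `moments`; `parts` selects
# the longitudinal+prior term, the survival term of one risk, or all.
# Used for step-halving in the survival update and by the gradient-zero
# certification of the closed-form M-step.
.expectedCompleteLoglik <- function(data, moments, params,
                                    parts = c("all", "gaussian", "survival"),
                                    risk = NULL) {
  parts <- match.arg(parts)
  qp <- moments$qp
  n <- data$n; q <- data$q; Tn <- qp$Tn
  subj <- data$subj
  W <- moments$weights
  total <- 0
  if (parts %in% c("all", "gaussian")) {
    rfix <- data$y - as.vector(data$X %*% params$beta)
    SigInv <- chol2inv(chol(params$Sigma))
    logdetS <- as.numeric(determinant(params$Sigma, logarithm = TRUE)$modulus)
    acc <- numeric(n)
    for (t in seq_len(Tn)) {
      B <- .nodeMatrix(qp, t, n)
      zb <- rowSums(data$Z * B[subj, , drop = FALSE])
      ss <- rowsum((rfix - zb)^2, subj)[, 1L]
      acc <- acc + W[, t] *
        (-ss / (2 * params$sigma2) - 0.5 * rowSums((B %*% SigInv) * B))
    }
    total <- total + sum(acc) -
      0.5 * sum(data$nobs) * log(2 * pi * params$sigma2) -
      0.5 * n * (q * log(2 * pi) + logdetS)
  }
  if (parts %in% c("all", "survival")) {
    haz <- .baselineAt(data, params)
    risks <- if (is.null(risk)) seq_len(data$K) else risk
    for (k in risks) {
      eta <- as.vector(data$X2 %*% params$gamma[[k]])
      ev <- data$cause == k
      Eexp_nu <- numeric(n)
      Ebnu <- numeric(n)
      for (t in seq_len(Tn)) {
        B <- .nodeMatrix(qp, t, n)
        nb <- as.vector(B %*% params$nu[[k]])
        Eexp_nu <- Eexp_nu + W[, t] * exp(nb)
        Ebnu <- Ebnu + W[, t] * nb
      }
      total <- total + sum(ifelse(ev, haz$logdL, 0) + ev * (eta + Ebnu)) -
        sum(haz$Lambda[, k] * exp(eta) * Eexp_nu)
    }
  }
  total
}
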