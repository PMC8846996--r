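#' Per-subject profiled-likelihood scores
#'
#' Computes the `n x dim(Omega)` matrix of per-subject score vectors of the
#' profiled log-likelihood at the fitted parameters, where
#' \eqn{\Omega = (\beta, \mathrm{vech}\,\Sigma, \sigma^2, \gamma_1, \nu_1,
#' \dots, \gamma_K, \nu_K)} and the nonparametric baseline hazards are
#' profiled out through the Breslow map (posterior expectations held fixed
#' at their fitted values, the approximation underlying the empirical
#' Fisher information).  The \eqn{\gamma_k}/\eqn{\nu_k} blocks combine (i)
#' event terms in the subject's own covariates and moments, (ii) risk-set
#' ratio terms at the subject's event time, and (iii) the event-prefix sums
#' \eqn{B(T_i)} computed with [eventPrefixMap()], so the whole matrix costs
#' \eqn{O(n\,\mathrm{dim}\,\Omega)}.
#'
#' Column order: `beta` block, `vech(Sigma)` (lower triangle by column,
#' off-diagonals scored as free parameters of the symmetric matrix),
#' `sigma2`, then `gamma_k`, `nu_k` for each risk.
#'
#' @param data a [jointData()] object.
#' @param fit a converged [jmFit()] object.
#' @param force compute even for a non-converged fit.
#' @return score matrix with named columns (class `scoreMatrix`).
#' @export
subjectScores <- function(data, fit, force = FALSE) {
  if (!fit$converged && !force)
    stop("fit did not converge; scores at a non-stationary point are not meaningful ",
         "(use force = TRUE to override)")
  params <- fit$params
  moments <- fit$moments
  n <- data$n; p <- data$p; q <- data$q; K <- data$K; p2 <- data$p2
  subj <- data$subj

  # Gaussian blocks
  zEb <- rowSums(data$Z * moments$Eb[subj, , drop = FALSE])
  res <- data$y - as.vector(data$X %*% params$beta)
  sc_beta <- rowsum(data$X * (res - zEb), subj) / params$sigma2

  ZZ <- data$Z[, rep(seq_len(q), times = q), drop = FALSE] *
    data$Z[, rep(seq_len(q), each = q), drop = FALSE]
  quad <- rowSums(ZZ * moments$Ebb[subj, , drop = FALSE])
  s_i <- rowsum(res^2 - 2 * res * zEb + quad, subj)[, 1L]
  sc_sigma2 <- -data$nobs / (2 * params$sigma2) + s_i / (2 * params$sigma2^2)

  P <- chol2inv(chol(params$Sigma))
  kronPP <- kronecker(P, P)
  Mmat <- 0.5 * (moments$Ebb %*% kronPP -
                   matrix(as.vector(P), n, q * q, byrow = TRUE))
  vi <- which(lower.tri(matrix(0, q, q), diag = TRUE))
  mult <- ifelse(as.vector(diag(q))[vi] == 1, 1, 2)
  idxmap <- matrix(seq_len(q * q), q, q)
  sc_Sigma <- Mmat[, idxmap[lower.tri(idxmap, diag = TRUE)], drop = FALSE] *
    rep(mult, each = n)

  sc_surv <- vector("list", K)
  haz <- .baselineAt(data, params)
  for (k in seq_len(K)) {
    ei <- data$events[[k]]
    eta <- as.vector(data$X2 %*% params$gamma[[k]])
    w <- exp(eta) * moments$Eexp[, k]
    eB <- exp(eta) * moments$Ebexp[[k]]
    if (ei$q_k == 0L) {
      sc_surv[[k]] <- matrix(0, n, p2 + q)
      next
    }
    sums <- risksetSuffixSums(cbind(w, w * data$X2, eB), ei$times, data$time)
    S <- sums[, 1L]
    U <- sums[, 1L + seq_len(p2), drop = FALSE]
    Vb <- sums[, 1L + p2 + seq_len(q), drop = FALSE]
    Wg <- U / S; Wn <- Vb / S
    Bg <- eventPrefixMap(ei$d * U / S^2, ei$times, data$time)
    Bn <- eventPrefixMap(ei$d * Vb / S^2, ei$times, data$time)
    ev <- data$cause == k
    Lam <- haz$Lambda[, k]
    g <- -Lam * w * data$X2 + w * Bg
    nu_part <- -Lam * eB + w * Bn
    g[ev, ] <- g[ev, , drop = FALSE] + data$X2[ev, , drop = FALSE] -
      Wg[ei$jump[ev], , drop = FALSE]
    nu_part[ev, ] <- nu_part[ev, , drop = FALSE] +
      moments$Eb[ev, , drop = FALSE] - Wn[ei$jump[ev], , drop = FALSE]
    sc_surv[[k]] <- cbind(g, nu_part)
  }
  out <- cbind(sc_beta, sc_Sigma, sc_sigma2, do.call(cbind, sc_surv))
  colnames(out) <- .parametricNames(data)
  structure(out, class = c("scoreMatrix", class(out)))
}

#' Approximate empirical Fisher information
#'
#' \eqn{\sum_i s_i s_i^T}, the sum of outer products of the per-subject
#' profiled-likelihood scores; symmetric positive semi-definite by
#' construction.
#'
#' @param scores a [subjectScores()] matrix.
#' @export
empiricalFisher <- function(scores) {
  crossprod(unclass(scores))
}

.fisherInverse <- function(fisher) {
  inv <- tryCatch(chol2inv(chol(fisher)), error = function(e) NULL)
  if (is.null(inv)) {
    warning("empirical Fisher information numerically singular; adding ridge 1e-8")
    inv <- tryCatch(chol2inv(chol(fisher + diag(1e-8, nrow(fisher)))),
                    error = function(e)
                      stop("empirical Fisher information singular even after ridge"))
  }
  dimnames(inv) <- dimnames(fisher)
  inv
}

#' Standard errors from the empirical Fisher information
#'
#' Square roots of the diagonal of the inverse information; a ridge of
#' `1e-8` is added with a warning if the matrix is numerically singular.
#'
#' @param fisher matrix from [empiricalFisher()].
#' @export
standardErrors <- function(fisher) {
  inv <- .fisherInverse(fisher)
  se <- sqrt(pmax(diag(inv), 0))
  names(se) <- colnames(fisher)
  se
}

.unpackParametric <- function(omega, data, template) {
  p <- data$p; q <- data$q; K <- data$K; p2 <- data$p2
  params <- template
  pos <- 0L
  params$beta <- omega[pos + seq_len(p)]; pos <- pos + p
  S <- matrix(0, q, q)
  S[lower.tri(S, diag = TRUE)] <- omega[pos + seq_len(q * (q + 1) / 2)]
  S <- S + t(S) - diag(diag(S))
  params$Sigma <- S; pos <- pos + q * (q + 1) / 2
  params$sigma2 <- omega[pos + 1L]; pos <- pos + 1L
  for (k in seq_len(K)) {
    params$gamma[[k]] <- omega[pos + seq_len(p2)]; pos <- pos + p2
    params$nu[[k]] <- omega[pos + seq_len(q)]; pos <- pos + q
  }
  params
}

#' Per-subject profiled log-likelihood (certification oracle)
#'
#' Evaluates, at an arbitrary parametric component \eqn{\Omega}, the
#' per-subject observed log-likelihood with the baseline hazards
#' re-profiled through the Breslow map in which the posterior measure is
#' held fixed at the fitted one: the risk-set denominators use
#' \eqn{\exp(X_r^{(2)T}\gamma_k)\,\hat E_r\{\exp(\nu_k^T b_r)\}} where
#' \eqn{\hat E_r} averages over the stored quadrature weights of the fit.
#' [subjectScores()] is the exact gradient of this function at the fitted
#' \eqn{\Omega}; central differences of `profiledLoglik` are therefore the
#' numerical-differentiation oracle used to certify the analytic scores.
#'
#' @param data a [jointData()] object.
#' @param fit a [jmFit()] object supplying the frozen posterior weights and
#'   quadrature points.
#' @param omega parameter vector in the [subjectScores()] column order;
#'   defaults to the fitted values.
#' @return vector of n per-subject profiled log-likelihood contributions.
#' @export
profiledLoglik <- function(data, fit, omega = .packParametric(fit$params)) {
  params <- .unpackParametric(omega, data, fit$params)
  W <- fit$moments$weights
  qp <- fit$qp
  for (k in seq_len(data$K)) {
    ei <- data$events[[k]]
    if (ei$q_k == 0L) {
      params$baseline[[k]] <- list(times = numeric(0), jumps = numeric(0),
                                   cum = numeric(0))
      next
    }
    g <- numeric(data$n)
    for (t in seq_len(qp$Tn)) {
      B <- .nodeMatrix(qp, t, data$n)
      g <- g + W[, t] * exp(as.vector(B %*% params$nu[[k]]))
    }
    S <- risksetSuffixSums(exp(as.vector(data$X2 %*% params$gamma[[k]])) * g,
                           ei$times, data$time)
    jumps <- ei$d / S
    params$baseline[[k]] <- list(times = ei$times, jumps = jumps,
                                 cum = rev(cumsum(rev(jumps))))
  }
  eStep(data, params, qp, fit$grid, want_moments = FALSE)$logNorm
}
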