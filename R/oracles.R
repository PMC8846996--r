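# Deliberately naive reference implementations of every scan, risk-set sum,
# Hessian and score aggregate.  They repeat a global search or double loop
# per subject / event time -- O(n q_k), O(n^2) or worse -- and exist solely
# to certify the linear algorithms (in the test suite and behind the CLI
# --validate flag).  Performance is a non-goal here.

#' Naive step-function lookup (global search per subject)
#'
#' Same contract as [stepLookup()], implemented by scanning all event times
#' for every subject: \eqn{O(n\,q_k)} comparisons.
#' @inheritParams stepLookup
#' @export
naiveStepLookup <- function(values, event_times, sorted_times,
                            instrument = FALSE) {
  qk <- length(event_times)
  ncomp <- 0L
  out <- vapply(sorted_times, function(Ti) {
    ncomp <<- ncomp + qk
    hit <- which(event_times <= Ti)
    if (length(hit)) values[hit[1L]] else 0
  }, numeric(1))
  if (instrument) attr(out, "comparisons") <- ncomp
  out
}

#' Naive risk-set sums (full scan per event time)
#'
#' Same contract as [risksetSuffixSums()]: for each event time the whole
#' subject vector is scanned to rebuild the risk set, \eqn{O(n\,q_k)}.
#' @inheritParams risksetSuffixSums
#' @export
naiveRisksetSums <- function(a, event_times, sorted_times, instrument = FALSE) {
  vec <- is.null(dim(a))
  a <- as.matrix(a)
  n <- length(sorted_times)
  out <- matrix(0, length(event_times), ncol(a))
  for (j in seq_along(event_times))
    out[j, ] <- colSums(a[sorted_times >= event_times[j], , drop = FALSE])
  if (vec) out <- out[, 1L]
  if (instrument) attr(out, "comparisons") <- n * length(event_times)
  out
}

#' Naive event-prefix sums (double loop)
#'
#' Same contract as [eventPrefixMap()]: \eqn{B(T_i)} rebuilt from scratch
#' for every subject.
#' @inheritParams eventPrefixMap
#' @export
naiveEventPrefix <- function(b, event_times, sorted_times, instrument = FALSE) {
  vec <- is.null(dim(b))
  b <- as.matrix(b)
  out <- matrix(0, length(sorted_times), ncol(b))
  for (i in seq_along(sorted_times)) {
    sel <- event_times <= sorted_times[i]
    if (any(sel)) out[i, ] <- colSums(b[sel, , drop = FALSE])
  }
  if (vec) out <- out[, 1L]
  if (instrument)
    attr(out, "comparisons") <- length(sorted_times) * length(event_times)
  out
}

#' Naive survival Hessian and score (double loop over risk sets)
#'
#' Recomputes the expected complete-data score and Hessian for
#' \eqn{(\gamma_k, \nu_k)} by explicitly rebuilding each risk set,
#' \eqn{O(n\,q_k)}; the contract of the fast suffix-sum version used inside
#' [mStepSurvival()].
#'
#' @inheritParams mStepSurvival
#' @param gamma,nu coefficient vectors for risk `k`.
#' @param dL baseline jumps at the descending event times.
#' @export
naiveSurvivalHessian <- function(data, moments, gamma, nu, k, dL) {
  ei <- data$events[[k]]
  p2 <- data$p2; q <- data$q
  eta <- as.vector(data$X2 %*% gamma)
  w <- exp(eta) * moments$Eexp[, k]
  eB <- exp(eta) * moments$Ebexp[[k]]
  eBB <- exp(eta) * moments$Ebbexp[[k]]
  score <- numeric(p2 + q)
  H <- matrix(0, p2 + q, p2 + q)
  ev <- data$cause == k
  score[seq_len(p2)] <- colSums(data$X2[ev, , drop = FALSE])
  score[p2 + seq_len(q)] <- colSums(moments$Eb[ev, , drop = FALSE])
  for (j in seq_len(ei$q_k)) {
    R <- which(data$time >= ei$times[j])
    for (r in R) {
      xr <- data$X2[r, ]
      score[seq_len(p2)] <- score[seq_len(p2)] - dL[j] * w[r] * xr
      score[p2 + seq_len(q)] <- score[p2 + seq_len(q)] - dL[j] * eB[r, ]
      H[seq_len(p2), seq_len(p2)] <- H[seq_len(p2), seq_len(p2)] +
        dL[j] * w[r] * tcrossprod(xr)
      H[seq_len(p2), p2 + seq_len(q)] <- H[seq_len(p2), p2 + seq_len(q)] +
        dL[j] * tcrossprod(xr, eB[r, ])
      H[p2 + seq_len(q), p2 + seq_len(q)] <- H[p2 + seq_len(q), p2 + seq_len(q)] +
        dL[j] * matrix(eBB[r, ], q, q)
    }
  }
  H[p2 + seq_len(q), seq_len(p2)] <- t(H[seq_len(p2), p2 + seq_len(q)])
  list(score = score, hessian = (H + t(H)) / 2)
}

#' Naive profiled-score survival blocks (double loops)
#'
#' Recomputes the \eqn{\gamma_k} and \eqn{\nu_k} blocks of the per-subject
#' profiled scores with explicit risk-set and event-prefix double loops
#' (\eqn{O(n^2)} per risk), the contract of the linearized computation in
#' [subjectScores()].
#'
#' @inheritParams subjectScores
#' @param k risk index.
#' @export
naiveScoreBlocks <- function(data, fit, k) {
  params <- fit$params; moments <- fit$moments
  n <- data$n; p2 <- data$p2; q <- data$q
  ei <- data$events[[k]]
  eta <- as.vector(data$X2 %*% params$gamma[[k]])
  w <- exp(eta) * moments$Eexp[, k]
  eB <- exp(eta) * moments$Ebexp[[k]]
  haz <- .baselineAt(data, params)
  out <- matrix(0, n, p2 + q)
  for (i in seq_len(n)) {
    gsc <- numeric(p2); nsc <- numeric(q)
    if (data$cause[i] == k) {
      R <- which(data$time >= data$time[i])
      S <- sum(w[R])
      gsc <- data$X2[i, ] - colSums(w[R] * data$X2[R, , drop = FALSE]) / S
      nsc <- moments$Eb[i, ] - colSums(eB[R, , drop = FALSE]) / S
    }
    gsc <- gsc - haz$Lambda[i, k] * w[i] * data$X2[i, ]
    nsc <- nsc - haz$Lambda[i, k] * eB[i, ]
    for (j in seq_len(ei$q_k)) {
      if (ei$times[j] <= data$time[i]) {
        R <- which(data$time >= ei$times[j])
        S <- sum(w[R])
        gsc <- gsc + w[i] * ei$d[j] * colSums(w[R] * data$X2[R, , drop = FALSE]) / S^2
        nsc <- nsc + w[i] * ei$d[j] * colSums(eB[R, , drop = FALSE]) / S^2
      }
    }
    out[i, ] <- c(gsc, nsc)
  }
  out
}

#' Naive empirical Bayes computation (no caching)
#'
#' Same contract as [ebMoments()], but the shared \eqn{p \times p} sum
#' \eqn{\sum_i X_i^{(1)} V_i^{-1} X_i^{(1)T}} is recomputed inside the
#' subject loop, giving the \eqn{O(n^2)} cost the cached version avoids.
#'
#' @inheritParams ebMoments
#' @export
naiveEBMoments <- function(data, beta, sigma2, Sigma) {
  n <- data$n
  perSubject <- function(i) {
    rows <- which(data$subj == i)
    Zi <- data$Z[rows, , drop = FALSE]
    Xi <- data$X[rows, , drop = FALSE]
    Vi <- Zi %*% Sigma %*% t(Zi) + diag(sigma2, length(rows))
    ViInv <- chol2inv(chol(Vi))
    list(Zi = Zi, Xi = Xi, ViInv = ViInv,
         ri = data$y[rows] - Xi %*% beta)
  }
  b_tilde <- matrix(0, n, data$q)
  H_inv <- vector("list", n)
  for (i in seq_len(n)) {
    # recompute the full sum for every subject (the point of this oracle)
    A <- matrix(0, data$p, data$p)
    for (l in seq_len(n)) {
      sl <- perSubject(l)
      A <- A + crossprod(sl$Xi, sl$ViInv %*% sl$Xi)
    }
    si <- perSubject(i)
    b_tilde[i, ] <- Sigma %*% crossprod(si$Zi, si$ViInv %*% si$ri)
    M <- crossprod(si$Zi, si$ViInv %*% si$Zi)
    G <- crossprod(si$Zi, si$ViInv %*% si$Xi)
    H_inv[[i]] <- Sigma - Sigma %*% (M - G %*% solve(A) %*% t(G)) %*% Sigma
  }
  structure(list(b_tilde = b_tilde, H_inv = H_inv, V_inv_cache = NULL,
                 beta = beta, sigma2 = sigma2, Sigma = Sigma),
            class = "ebEstimates")
}

#' Cross-check the fast scans against their naive twins
#'
#' Runs [stepLookup()], [risksetSuffixSums()] and [eventPrefixMap()] against
#' the naive implementations on the dataset's own event structure with
#' random per-subject values, and reports the maximal absolute discrepancy.
#' Exposed on the command line as `fit --validate`.
#'
#' @param data a [jointData()] object.
#' @param seed RNG seed for the random per-subject values.
#' @return named vector of maximal absolute differences per primitive.
#' @export
validateScans <- function(data, seed = 1L) {
  set.seed(seed)
  out <- c(step_lookup = 0, riskset_sums = 0, event_prefix = 0)
  for (k in seq_len(data$K)) {
    ei <- data$events[[k]]
    vals <- cumsum(stats::rexp(ei$q_k))
    vals <- rev(vals)  # nondecreasing in time, like a cumulative hazard
    a <- stats::rnorm(data$n)
    b <- stats::rnorm(ei$q_k)
    out["step_lookup"] <- max(out["step_lookup"],
      abs(stepLookup(vals, ei$times, data$time) -
            naiveStepLookup(vals, ei$times, data$time)))
    out["riskset_sums"] <- max(out["riskset_sums"],
      abs(risksetSuffixSums(a, ei$times, data$time) -
            naiveRisksetSums(a, ei$times, data$time)))
    out["event_prefix"] <- max(out["event_prefix"],
      abs(eventPrefixMap(b, ei$times, data$time) -
            naiveEventPrefix(b, ei$times, data$time)))
  }
  out
}
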