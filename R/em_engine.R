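#' Closed-form M-step updates for the Gaussian components
#'
#' Updates \eqn{\beta}, \eqn{\sigma^2} and \eqn{\Sigma} by their
#' closed-form maximizers of the expected complete-data log-likelihood:
#' \deqn{\beta = \left(\sum_{ij} x_{ij}x_{ij}^T\right)^{-1}
#'   \sum_{ij} x_{ij}\{Y_{ij} - \tilde x_{ij}^T E(b_i)\},}
#' \eqn{\sigma^2} the averaged expected squared residual (with the
#' second-moment correction), and \eqn{\Sigma = n^{-1}\sum_i E(b_i b_i^T)}.
#'
#' @param data a [jointData()] object.
#' @param moments an [eStep()] result.
#' @param cache optional precomputed list (Cholesky of the normal matrix and
#'   the elementwise products of random-design columns) as built by
#'   [jmFit()]; recomputed if omitted.
#' @return list with `beta`, `sigma2`, `Sigma`.
#' @export
mStepGaussian <- function(data, moments, cache = NULL) {
  if (is.null(cache)) cache <- .gaussianCache(data)
  subj <- data$subj
  zEb <- rowSums(data$Z * moments$Eb[subj, , drop = FALSE])
  beta <- backsolve(cache$RX, backsolve(cache$RX, crossprod(data$X, data$y - zEb),
                                        transpose = TRUE))
  beta <- as.vector(beta)
  res <- data$y - as.vector(data$X %*% beta)
  quad <- rowSums(cache$ZZ * moments$Ebb[subj, , drop = FALSE])
  sigma2 <- mean(res^2 - 2 * res * zEb + quad)
  Sigma <- matrix(colMeans(moments$Ebb), data$q, data$q)
  Sigma <- (Sigma + t(Sigma)) / 2
  list(beta = beta, sigma2 = sigma2, Sigma = Sigma)
}

.gaussianCache <- function(data) {
  q <- data$q
  RX <- tryCatch(chol(crossprod(data$X)),
                 error = function(e) stop("singular fixed-effects normal equations"))
  ZZ <- data$Z[, rep(seq_len(q), times = q), drop = FALSE] *
    data$Z[, rep(seq_len(q), each = q), drop = FALSE]
  list(RX = RX, ZZ = ZZ)
}

#' Breslow-type baseline hazard update
#'
#' Closed-form M-step update of the cumulative baseline hazard for risk
#' `k`: jumps
#' \deqn{\Delta\Lambda_{0k}(t_{kj}) = d_{kj} \Big/ \sum_{r \in R(t_{kj})}
#'   \exp(X_r^{(2)T}\gamma_k)\, E\{\exp(\nu_k^T b_r)\},}
#' with all risk-set denominators produced by the suffix-sum recursion
#' ([risksetSuffixSums()]) in \eqn{O(n + q_k)}.
#'
#' @inheritParams mStepGaussian
#' @param gamma,nu current coefficient vectors for risk `k`.
#' @param k risk index.
#' @return list (step cumulative hazard): `times` (descending), `jumps`,
#'   `cum` (cumulative values at the jump times, right-continuous).
#' @export
mStepBaseline <- function(data, moments, gamma, nu, k) {
  ei <- data$events[[k]]
  if (ei$q_k == 0L)
    return(list(times = numeric(0), jumps = numeric(0), cum = numeric(0)))
  w <- exp(as.vector(data$X2 %*% gamma)) * moments$Eexp[, k]
  S <- risksetSuffixSums(w, ei$times, data$time)
  if (any(S <= 0)) stop("zero risk-set denominator in baseline update for risk ", k)
  jumps <- ei$d / S
  list(times = ei$times, jumps = jumps, cum = rev(cumsum(rev(jumps))))
}

# Score and (negative) Hessian of the expected complete-data log-likelihood
# term for (gamma_k, nu_k), with the baseline jumps dL fixed.  All risk-set
# aggregates come from one suffix-sum pass with a matrix-valued sequence.
.survivalScoreHessian <- function(data, moments, gamma, nu, k, dL) {
  ei <- data$events[[k]]
  p2 <- data$p2; q <- data$q
  eta <- as.vector(data$X2 %*% gamma)
  w <- exp(eta) * moments$Eexp[, k]            # exp(X2'g) E{exp(nu'b)}
  eB <- exp(eta) * moments$Ebexp[[k]]          # exp(X2'g) E{b exp(nu'b)}
  eBB <- exp(eta) * moments$Ebbexp[[k]]        # exp(X2'g) E{bb' exp(nu'b)}
  X2 <- data$X2
  wX <- w * X2
  wXX <- w * (X2[, rep(seq_len(p2), times = p2), drop = FALSE] *
                X2[, rep(seq_len(p2), each = p2), drop = FALSE])
  XeB <- X2[, rep(seq_len(p2), times = q), drop = FALSE] *
    eB[, rep(seq_len(q), each = p2), drop = FALSE]
  Acols <- cbind(wX, eB, wXX, XeB, eBB)
  S <- risksetSuffixSums(Acols, ei$times, data$time)
  dLS <- dL * S
  agg <- colSums(dLS)                          # sum_j dL_j * (risk-set sums)
  ev <- data$cause == k
  score <- unname(c(colSums(X2[ev, , drop = FALSE]) - agg[seq_len(p2)],
                    colSums(moments$Eb[ev, , drop = FALSE]) - agg[p2 + seq_len(q)]))
  o <- p2 + q
  H <- matrix(0, p2 + q, p2 + q)
  H[seq_len(p2), seq_len(p2)] <- matrix(agg[o + seq_len(p2 * p2)], p2, p2)
  Hgn <- matrix(agg[o + p2 * p2 + seq_len(p2 * q)], p2, q)
  H[seq_len(p2), p2 + seq_len(q)] <- Hgn
  H[p2 + seq_len(q), seq_len(p2)] <- t(Hgn)
  H[p2 + seq_len(q), p2 + seq_len(q)] <- matrix(agg[o + p2 * p2 + p2 * q +
                                                      seq_len(q * q)], q, q)
  H <- (H + t(H)) / 2
  list(score = score, hessian = H)
}

#' One-step Newton-Raphson update of the survival coefficients
#'
#' Performs a single Newton-Raphson step on the stacked
#' \eqn{(\gamma_k, \nu_k)} for the expected complete-data log-likelihood
#' term of risk `k`, holding the freshly updated baseline jumps fixed.  The
#' Hessian block for \eqn{\gamma_k} is
#' \deqn{I_{\gamma_k} = \sum_j \Delta\Lambda_{0k}(t_{kj})
#'   \sum_{r\in R(t_{kj})} \exp(X_r^{(2)T}\gamma_k)
#'   E\{\exp(\nu_k^T b_r)\} X_r^{(2)}X_r^{(2)T},}
#' and analogously for the \eqn{\nu_k} and cross blocks with the
#' \eqn{E\{b\exp\}} and \eqn{E\{bb^T\exp\}} moments; every risk-set
#' aggregate is produced by one [risksetSuffixSums()] pass, so the update
#' costs \eqn{O(n)}.  Step-halving (up to 10 times) is applied if the
#' expected complete-data log-likelihood term decreases.
#'
#' @inheritParams mStepGaussian
#' @param params current parameter set.
#' @param k risk index.
#' @param baseline fresh baseline for risk `k` from [mStepBaseline()].
#' @param fix_nu if `TRUE`, hold \eqn{\nu_k} at its current value and update
#'   only \eqn{\gamma_k}.
#' @return list with updated `gamma`, `nu`, and the `score`/`hessian` used.
#' @export
mStepSurvival <- function(data, moments, params, k, baseline,
                          fix_nu = FALSE) {
  gamma <- params$gamma[[k]]; nu <- params$nu[[k]]
  p2 <- data$p2; q <- data$q
  if (data$events[[k]]$q_k == 0L)
    return(list(gamma = gamma, nu = nu, score = rep(0, p2 + q), hessian = NULL))
  sh <- .survivalScoreHessian(data, moments, gamma, nu, k, baseline$jumps)
  sel <- if (fix_nu) seq_len(p2) else seq_len(p2 + q)
  H <- sh$hessian[sel, sel, drop = FALSE]
  step <- tryCatch(solve(H, sh$score[sel]),
                   error = function(e) {
                     Hr <- H + diag(1e-8, nrow(H))
                     tryCatch(solve(Hr, sh$score[sel]),
                              error = function(e2)
                                stop("singular Hessian in survival update for risk ", k))
                   })
  theta <- c(gamma, nu)
  cand <- params
  cand$baseline[[k]] <- baseline
  qOld <- .survivalQk(data, moments, cand, k, gamma, nu)
  fac <- 1
  for (h in 0:10) {
    thNew <- theta
    thNew[sel] <- theta[sel] + fac * step
    gN <- thNew[seq_len(p2)]; nN <- thNew[p2 + seq_len(q)]
    qNew <- .survivalQk(data, moments, cand, k, gN, nN)
    if (is.finite(qNew) && qNew >= qOld - 1e-10 * (abs(qOld) + 1)) break
    fac <- fac / 2
  }
  list(gamma = gN, nu = nN, score = sh$score, hessian = sh$hessian)
}

# survival part of E^{(m)}[log complete-data L] for risk k at candidate
# (gamma, nu), baseline fixed; E{exp(nu'b)} at the candidate nu is
# reconstructed from the stored node weights
.survivalQk <- function(data, moments, params, k, gamma, nu) {
  pk <- params
  pk$gamma[[k]] <- gamma
  pk$nu[[k]] <- nu
  .expectedCompleteLoglik(data, moments, pk, parts = "survival", risk = k)
}

# cause-specific Cox fit (no frailty): Newton-Raphson with the risk-set
# suffix-sum machinery and nu = 0, iterated to stationarity; used for
# initializing gamma_k
.coxInitGamma <- function(data, k, maxit = 100L, tol = 1e-9) {
  p2 <- data$p2
  gamma <- rep(0, p2)
  ei <- data$events[[k]]
  if (ei$q_k == 0L) return(gamma)
  mom0 <- list(Eexp = matrix(1, data$n, data$K),
               Ebexp = rep(list(matrix(0, data$n, data$q)), data$K),
               Ebbexp = rep(list(matrix(0, data$n, data$q * data$q)), data$K),
               Eb = matrix(0, data$n, data$q))
  for (it in seq_len(maxit)) {
    w <- exp(as.vector(data$X2 %*% gamma))
    S <- risksetSuffixSums(w, ei$times, data$time)
    dL <- ei$d / S
    sh <- .survivalScoreHessian(data, mom0, gamma, rep(0, data$q), k, dL)
    sc <- sh$score[seq_len(p2)]
    if (max(abs(sc)) < tol) break
    H <- sh$hessian[seq_len(p2), seq_len(p2), drop = FALSE]
    step <- solve(H + diag(1e-10, p2), sc)
    # guard against overshoot on extreme data
    if (max(abs(step)) > 2) step <- step * 2 / max(abs(step))
    gamma <- gamma + step
  }
  gamma
}

#' Fit the semiparametric joint model by EM
#'
#' Full estimation loop for the shared random effects joint model: initial
#' values from the longitudinal-only mixed model ([fitLMM()]) and
#' cause-specific Cox fits with \eqn{\nu_k = 0}; E-step posterior moments by
#' Gauss-Hermite quadrature ([eStep()]); M-step closed forms for
#' \eqn{\beta, \sigma^2, \Sigma} and the baseline hazards plus one
#' Newton-Raphson step per iteration for each \eqn{(\gamma_k, \nu_k)};
#' convergence monitored on both the parameter change and the observed-data
#' log-likelihood.  With the pseudo-adaptive rule the abscissas are built
#' once from the empirical Bayes estimates and reused throughout, and all
#' per-iteration computations are \eqn{O(n)} in the number of subjects.
#'
#' @param data a [jointData()] object.
#' @param quadrature `"pseudo-adaptive"` (default) or `"standard"`.
#' @param nq quadrature points per dimension; defaults to 6 for the
#'   pseudo-adaptive and 20 for the standard rule.
#' @param tol_param relative parameter-change tolerance
#'   (\eqn{\max_j |\theta_j^{(m+1)}-\theta_j^{(m)}| / (|\theta_j^{(m)}| +
#'   10^{-4})}).
#' @param tol_loglik relative observed log-likelihood change tolerance;
#'   either criterion stops the loop.
#' @param max_iter maximum EM iterations.
#' @param fix_nu hold all association parameters at zero (the no-frailty
#'   reduction; the survival submodel then collapses to cause-specific Cox
#'   regression).
#' @param se compute standard errors from the empirical Fisher information
#'   of the profiled likelihood ([subjectScores()]).
#' @param init optional list with starting `beta`, `sigma2`, `Sigma`
#'   (skips the internal mixed-model fit; the empirical Bayes abscissas are
#'   still built from these values).
#' @return object of class `jmFit`.
#' @export
jmFit <- function(data,
                  quadrature = c("pseudo-adaptive", "standard"),
                  nq = NULL,
                  tol_param = 1e-4, tol_loglik = 1e-8, max_iter = 500L,
                  fix_nu = FALSE, se = TRUE, init = NULL) {
  stopifnot(inherits(data, "jointData"))
  quadrature <- match.arg(quadrature)
  if (is.null(nq)) nq <- if (quadrature == "pseudo-adaptive") 6L else 20L
  grid <- ghGrid(nq, data$q)

  if (is.null(init)) {
    lmm <- fitLMM(data)
  } else {
    lmm <- list(beta = init$beta, sigma2 = init$sigma2, Sigma = init$Sigma)
  }
  Sigma0 <- lmm$Sigma
  if (min(eigen(Sigma0, symmetric = TRUE, only.values = TRUE)$values) < 1e-8)
    Sigma0 <- Sigma0 + diag(1e-6, data$q)   # lift boundary LMM fits off Sigma = 0

  qp <- if (quadrature == "pseudo-adaptive") {
    eb <- ebMoments(data, lmm$beta, lmm$sigma2, Sigma0)
    .pseudoPoints(data, grid, eb)
  } else NULL

  params <- list(beta = lmm$beta, sigma2 = lmm$sigma2, Sigma = Sigma0,
                 gamma = lapply(seq_len(data$K), function(k) .coxInitGamma(data, k)),
                 nu = rep(list(rep(0, data$q)), data$K),
                 baseline = vector("list", data$K))
  mom0 <- list(Eexp = matrix(1, data$n, data$K))
  for (k in seq_len(data$K))
    params$baseline[[k]] <- mStepBaseline(data, mom0, params$gamma[[k]],
                                          params$nu[[k]], k)
  cache <- .gaussianCache(data)

  trace <- numeric(0)
  converged <- FALSE
  iter_time <- numeric(0)
  for (m in seq_len(max_iter)) {
    t0 <- proc.time()[["elapsed"]]
    qpm <- if (quadrature == "standard") .standardPoints(grid, params$Sigma) else qp
    moments <- eStep(data, params, qpm, grid)
    trace <- c(trace, sum(moments$logNorm))

    new <- params
    for (k in seq_len(data$K)) {
      bl <- mStepBaseline(data, moments, params$gamma[[k]], params$nu[[k]], k)
      up <- mStepSurvival(data, moments, params, k, bl, fix_nu = fix_nu)
      new$baseline[[k]] <- bl
      new$gamma[[k]] <- up$gamma
      new$nu[[k]] <- up$nu
    }
    g <- mStepGaussian(data, moments, cache)
    new$beta <- g$beta; new$sigma2 <- g$sigma2; new$Sigma <- g$Sigma

    thOld <- .packParametric(params)
    thNew <- .packParametric(new)
    delta <- max(abs(thNew - thOld) / (abs(thOld) + 1e-4))
    dll <- if (m > 1L) abs(trace[m] - trace[m - 1L]) / (abs(trace[m - 1L]) + 1e-10) else Inf
    params <- new
    iter_time <- c(iter_time, proc.time()[["elapsed"]] - t0)
    if (delta < tol_param || dll < tol_loglik) { converged <- TRUE; break }
  }

  qpm <- if (quadrature == "standard") .standardPoints(grid, params$Sigma) else qp
  moments <- eStep(data, params, qpm, grid)
  trace <- c(trace, sum(moments$logNorm))
  for (k in seq_len(data$K))
    params$baseline[[k]] <- mStepBaseline(data, moments, params$gamma[[k]],
                                          params$nu[[k]], k)

  fit <- structure(list(
    params = params, loglik = trace[length(trace)], loglik_trace = trace,
    n_iter = length(iter_time), converged = converged,
    settings = list(quadrature = quadrature, nq = nq, tol_param = tol_param,
                    tol_loglik = tol_loglik, max_iter = max_iter,
                    fix_nu = fix_nu),
    moments = moments, qp = qpm, grid = grid,
    lmm_init = lmm[c("beta", "sigma2", "Sigma")],
    iter_time = iter_time, data = data
  ), class = "jmFit")
  if (se) {
    sc <- subjectScores(data, fit)
    fi <- empiricalFisher(sc)
    fit$scores <- sc
    fit$vcov <- .fisherInverse(fi)
    fit$se <- sqrt(pmax(diag(fit$vcov), 0))
    names(fit$se) <- colnames(sc)
  }
  fit
}

# parametric component Omega as a flat vector (baselines excluded);
# order: beta, vech(Sigma) lower-triangular by column, sigma2, then per
# risk gamma_k, nu_k
.packParametric <- function(params) {
  q <- nrow(params$Sigma)
  low <- which(lower.tri(params$Sigma, diag = TRUE))
  c(params$beta, params$Sigma[low], params$sigma2,
    unlist(lapply(seq_along(params$gamma),
                  function(k) c(params$gamma[[k]], params$nu[[k]]))))
}

.parametricNames <- function(data) {
  q <- data$q
  sn <- outer(seq_len(q), seq_len(q), function(i, j) sprintf("Sigma[%d,%d]", i, j))
  sn <- sn[lower.tri(sn, diag = TRUE)]
  fn <- data$columns$fixed
  cn <- data$columns$covariates
  c(paste0("beta.", fn), sn, "sigma2",
    unlist(lapply(seq_len(data$K), function(k)
      c(paste0("gamma", k, ".", cn), paste0("nu", k, ".", seq_len(q))))))
}

#' @export
print.jmFit <- function(x, ...) {
  cat("Semiparametric joint model (EM,", x$settings$quadrature,
      "Gauss-Hermite, nq =", x$settings$nq, ")\n")
  cat(sprintf("  n = %d subjects, %s after %d iterations, log-likelihood %.4f\n",
              x$data$n, if (x$converged) "converged" else "NOT converged",
              x$n_iter, x$loglik))
  est <- .packParametric(x$params)
  names(est) <- .parametricNames(x$data)
  tab <- data.frame(Estimate = est)
  if (!is.null(x$se)) {
    tab$SE <- x$se
    tab$z <- tab$Estimate / tab$SE
  }
  print(round(tab, 4))
  invisible(x)
}

#' Extract the parametric estimates of a joint model fit
#' @param object a [jmFit()] object.
#' @param ... unused.
#' @export
coef.jmFit <- function(object, ...) {
  est <- .packParametric(object$params)
  names(est) <- .parametricNames(object$data)
  est
}

#' @export
logLik.jmFit <- function(object, ...) {
  structure(object$loglik, df = length(.packParametric(object$params)),
            class = "logLik")
}

#' Fitted cumulative baseline hazard
#'
#' Evaluates the fitted step cumulative baseline hazard
#' \eqn{\hat\Lambda_{0k}(t)} of one risk at arbitrary times.
#'
#' @param fit a [jmFit()] object.
#' @param k risk index.
#' @param times evaluation times.
#' @export
cumBaseHazard <- function(fit, k, times) {
  bl <- fit$params$baseline[[k]]
  ord <- order(-times)
  out <- numeric(length(times))
  out[ord] <- stepLookup(bl$cum, bl$times, times[ord])
  out
}
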