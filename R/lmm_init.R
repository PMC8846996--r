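#' Fit the longitudinal submodel alone
#'
#' Maximum-likelihood fit of the linear mixed model
#' \eqn{Y_{ij} = X_{ij}^{(1)T}\beta + \tilde X_{ij}^{(1)T} b_i +
#' \varepsilon_{ij}} ignoring the survival outcome.  Used for starting
#' values of the joint EM algorithm and for the empirical Bayes quantities
#' that define the pseudo-adaptive quadrature rule.  ML (not REML) is used
#' because the joint EM targets the maximum-likelihood estimate.
#'
#' @param data a [jointData()] object.
#' @return list with `beta`, `sigma2`, `Sigma`, `loglik` (the marginal
#'   log-likelihood at the optimum) and the underlying `lme4` fit.
#' @export
fitLMM <- function(data) {
  stopifnot(inherits(data, "jointData"))
  p <- data$p; q <- data$q
  if (length(data$y) <= p + q * (q + 1) / 2 + 1)
    stop("too few longitudinal observations to fit the mixed model")
  df <- data.frame(.y = data$y, .id = factor(data$subj))
  fn <- paste0(".f", seq_len(p)); zn <- paste0(".z", seq_len(q))
  for (j in seq_len(p)) df[[fn[j]]] <- data$X[, j]
  for (j in seq_len(q)) df[[zn[j]]] <- data$Z[, j]
  form <- stats::as.formula(paste0(
    ".y ~ 0 + ", paste(fn, collapse = " + "),
    " + (0 + ", paste(zn, collapse = " + "), " | .id)"))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(form, data = df, REML = FALSE,
               control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                           check.nobs.vs.nRE = "ignore",
                                           calc.derivs = FALSE))))
  beta <- unname(lme4::fixef(fit))
  vc <- lme4::VarCorr(fit)
  Sigma <- unname(as.matrix(vc$.id)[seq_len(q), seq_len(q), drop = FALSE])
  attr(Sigma, "stddev") <- NULL; attr(Sigma, "correlation") <- NULL
  sigma2 <- stats::sigma(fit)^2
  list(beta = beta, sigma2 = sigma2, Sigma = Sigma,
       loglik = as.numeric(stats::logLik(fit)), fit = fit)
}

#' Marginal Gaussian log-likelihood of the mixed model
#'
#' Direct evaluation of \eqn{\sum_i \log N(Y_i; X_i\beta,\ Z_i \Sigma Z_i^T
#' + \sigma^2 I)}, independent of any particular optimizer.
#'
#' @param data a [jointData()] object.
#' @param beta,sigma2,Sigma mixed-model parameters.
#' @export
lmmMarginalLoglik <- function(data, beta, sigma2, Sigma) {
  ll <- 0
  for (i in seq_len(data$n)) {
    rows <- which(data$subj == i)
    Zi <- data$Z[rows, , drop = FALSE]
    Vi <- Zi %*% Sigma %*% t(Zi) + diag(sigma2, length(rows))
    ri <- data$y[rows] - data$X[rows, , drop = FALSE] %*% beta
    ch <- chol(Vi)
    ll <- ll - 0.5 * (length(rows) * log(2 * pi) + 2 * sum(log(diag(ch))) +
                        sum(backsolve(ch, ri, transpose = TRUE)^2))
  }
  ll
}

#' Empirical Bayes estimates and their conditional variances
#'
#' Computes, for every subject, the empirical Bayes estimate
#' \eqn{\tilde b_i = \hat\Sigma \tilde X_i^{(1)} \hat V_i^{-1}(Y_i -
#' X_i^{(1)T}\hat\beta)} and the conditional variance of
#' \eqn{\tilde b_i - b_i},
#' \deqn{\tilde H_i^{-1} = \hat\Sigma - \hat\Sigma \tilde X_i^{(1)}
#'   \left[\hat V_i^{-1} - \hat V_i^{-1} X_i^{(1)T}
#'   \left(\sum_i X_i^{(1)} \hat V_i^{-1} X_i^{(1)T}\right)^{-1}
#'   X_i^{(1)} \hat V_i^{-1}\right] \tilde X_i^{(1)T} \hat\Sigma,}
#' with \eqn{\hat V_i = \tilde X_i^{(1)T}\hat\Sigma\tilde X_i^{(1)} +
#' \hat\sigma^2 I}.  The shared \eqn{p \times p} sum is computed once and
#' cached, so the whole pass costs \eqn{O(n)} (per-subject work depends only
#' on \eqn{n_i}, \eqn{p}, \eqn{q}), rather than the \eqn{O(n^2)} of
#' recomputing the sum inside the subject loop.
#'
#' @param data a [jointData()] object.
#' @param beta,sigma2,Sigma mixed-model parameters, typically from
#'   [fitLMM()].
#' @return object of class `ebEstimates`: `b_tilde` (n x q), `H_inv` (list
#'   of q x q matrices), `V_inv_cache` (the cached p x p sum) and the
#'   parameters used.
#' @export
ebMoments <- function(data, beta, sigma2, Sigma) {
  n <- data$n; p <- data$p; q <- data$q
  u <- matrix(0, n, q)         # Z_i' V_i^{-1} r_i
  M <- vector("list", n)       # Z_i' V_i^{-1} Z_i
  G <- vector("list", n)       # Z_i' V_i^{-1} X_i
  A <- matrix(0, p, p)         # cached sum_i X_i' V_i^{-1} X_i
  idx <- split(seq_along(data$subj), data$subj)
  for (i in seq_len(n)) {
    rows <- idx[[i]]
    Zi <- data$Z[rows, , drop = FALSE]
    Xi <- data$X[rows, , drop = FALSE]
    Vi <- Zi %*% Sigma %*% t(Zi) + diag(sigma2, length(rows))
    ViInv <- chol2inv(chol(Vi))
    ri <- data$y[rows] - Xi %*% beta
    u[i, ] <- crossprod(Zi, ViInv %*% ri)
    M[[i]] <- crossprod(Zi, ViInv %*% Zi)
    G[[i]] <- crossprod(Zi, ViInv %*% Xi)
    A <- A + crossprod(Xi, ViInv %*% Xi)
  }
  Ainv <- chol2inv(chol(A))
  b_tilde <- u %*% Sigma       # rows Sigma %*% u_i (Sigma symmetric)
  H_inv <- lapply(seq_len(n), function(i) {
    Sigma - Sigma %*% (M[[i]] - G[[i]] %*% Ainv %*% t(G[[i]])) %*% Sigma
  })
  structure(list(b_tilde = b_tilde, H_inv = H_inv, V_inv_cache = A,
                 beta = beta, sigma2 = sigma2, Sigma = Sigma),
            class = "ebEstimates")
}

# symmetric eigendecomposition matrix square root with the documented
# jitter rule for near-singular conditional variances
.symSqrt <- function(S, jitter_tol = 1e-10, jitter = 1e-8) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  if (any(e$values < jitter_tol)) {
    warning("near-singular conditional variance; adding diagonal jitter")
    e <- eigen((S + t(S)) / 2 + diag(jitter, nrow(S)), symmetric = TRUE)
  }
  root <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  attr(root, "logdet") <- sum(log(pmax(e$values, jitter_tol)))
  root
}
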