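#' Generating truth for the joint-model simulator
#'
#' Bundles the parameters of the simulation design used throughout the
#' package: a random intercept-and-slope Gaussian longitudinal model
#' \deqn{Y_{ij} = \beta_0 + \beta_1 t_{ij} + \beta_2 X_{2i} + b_{0i} +
#'   b_{1i} t_{ij} + \varepsilon_{ij}}
#' linked to two competing risks with constant baseline hazards
#' \deqn{\lambda_k(t) = \lambda_{0k}\exp(\gamma_{k1}X_{1i} +
#'   \gamma_{k2}X_{2i} + \nu_k^T b_i), \quad k = 1, 2,}
#' where \eqn{X_{1i} \sim N(2,1)}, \eqn{X_{2i} \sim \mathrm{Bernoulli}(0.5)},
#' \eqn{b_i \sim N_2(0,\Sigma)}, and censoring is exponential.
#'
#' @param n number of subjects.
#' @param beta fixed effects \eqn{(\beta_0,\beta_1,\beta_2)}.
#' @param Sigma 2x2 random-effects covariance (default
#'   \eqn{\Sigma_{11}=0.5,\ \Sigma_{22}=0.25,\ \Sigma_{12}=0}).
#' @param sigma2 measurement-error variance (default 0.5).
#' @param gamma1,gamma2 cause-specific covariate effects (length 2).
#' @param nu1,nu2 association parameters multiplying the shared random
#'   effects in the two log-hazards (length 2).
#' @param lambda01,lambda02 constant baseline hazards (defaults 0.05, 0.1).
#' @param censor_mean mean of the exponential censoring time (default 20).
#' @param miss_rate probability that a scheduled post-baseline visit is
#'   skipped (default 0, i.e. the full visit grid).
#' @param seed RNG seed.
#' @return object of class `simTruth`.
#' @export
simTruth <- function(n = 1000L,
                     beta = c(2, -0.5, 1),
                     Sigma = diag(c(0.5, 0.25)),
                     sigma2 = 0.5,
                     gamma1 = c(0.5, -0.5),
                     gamma2 = c(-0.5, 0.5),
                     nu1 = c(0.5, 0.5),
                     nu2 = c(-0.5, -0.5),
                     lambda01 = 0.05,
                     lambda02 = 0.1,
                     censor_mean = 20,
                     miss_rate = 0,
                     seed = 1L) {
  Sigma <- as.matrix(Sigma)
  stopifnot(length(beta) == 3L, nrow(Sigma) == 2L, ncol(Sigma) == 2L,
            sigma2 > 0, lambda01 > 0, lambda02 > 0, censor_mean > 0,
            miss_rate >= 0, miss_rate < 1,
            length(gamma1) == 2L, length(gamma2) == 2L,
            length(nu1) == 2L, length(nu2) == 2L)
  if (max(abs(Sigma - t(Sigma))) > 1e-12) stop("Sigma must be symmetric")
  if (min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values) < -1e-12)
    stop("Sigma must be positive semi-definite")
  structure(list(n = as.integer(n), beta = beta, Sigma = Sigma, sigma2 = sigma2,
                 gamma1 = gamma1, gamma2 = gamma2, nu1 = nu1, nu2 = nu2,
                 lambda01 = lambda01, lambda02 = lambda02,
                 censor_mean = censor_mean, miss_rate = miss_rate,
                 seed = as.integer(seed)),
            class = "simTruth")
}

#' Simulate a joint longitudinal / competing-risks dataset
#'
#' Draws, per subject, covariates, shared random effects, two latent
#' cause-specific event times from constant hazards (inverse-CDF of an
#' exponential with subject-specific rate), and an independent exponential
#' censoring time; the observed time is the minimum of the three.
#' Longitudinal responses are emitted on the scheduled visit grid
#' \eqn{t_{ij} = 0, 1, 2, \dots} restricted to \eqn{t_{ij} \le T_i}
#' (measurements after the terminal time are missing by design; the baseline
#' visit is always kept).
#'
#' @param truth a [simTruth()] object.
#' @return a validated [jointData()] object with attributes `truth` and
#'   `latent` (the generated random effects and covariates, handy for
#'   simulation diagnostics).
#' @export
simulateJoint <- function(truth = simTruth()) {
  stopifnot(inherits(truth, "simTruth"))
  set.seed(truth$seed)
  n <- truth$n
  X1 <- stats::rnorm(n, 2, 1)
  X2 <- stats::rbinom(n, 1L, 0.5)
  e <- eigen(truth$Sigma, symmetric = TRUE)
  L <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  b <- matrix(stats::rnorm(2L * n), n, 2L) %*% L   # rows b_i ~ N(0, Sigma)

  rate1 <- truth$lambda01 * exp(truth$gamma1[1] * X1 + truth$gamma1[2] * X2 +
                                b %*% truth$nu1)
  rate2 <- truth$lambda02 * exp(truth$gamma2[1] * X1 + truth$gamma2[2] * X2 +
                                b %*% truth$nu2)
  T1 <- stats::rexp(n, rate = as.vector(rate1))
  T2 <- stats::rexp(n, rate = as.vector(rate2))
  V <- stats::rexp(n, rate = 1 / truth$censor_mean)
  Ti <- pmin(T1, T2, V)
  Di <- ifelse(Ti == T1, 1L, ifelse(Ti == T2, 2L, 0L))

  nvis <- floor(Ti) + 1
  long <- lapply(seq_len(n), function(i) {
    tij <- seq.int(0L, nvis[i] - 1L)
    if (truth$miss_rate > 0 && length(tij) > 1L) {
      keep <- c(TRUE, stats::runif(length(tij) - 1L) >= truth$miss_rate)
      tij <- tij[keep]
    }
    data.frame(id = i, time = tij,
               y = truth$beta[1] + truth$beta[2] * tij + truth$beta[3] * X2[i] +
                 b[i, 1] + b[i, 2] * tij +
                 stats::rnorm(length(tij), 0, sqrt(truth$sigma2)),
               x2 = X2[i])
  })
  long <- do.call(rbind, long)
  long$intercept <- 1
  long$slope <- long$time

  surv <- data.frame(id = seq_len(n), survtime = Ti, cause = Di,
                     x1 = X1, x2 = X2)

  dat <- jointData(long, surv,
                   fixed = c("intercept", "time", "x2"),
                   random = c("intercept", "slope"),
                   covariates = c("x1", "x2"),
                   K = 2L)
  attr(dat, "truth") <- truth
  attr(dat, "latent") <- list(b = b, X1 = X1, X2 = X2)
  dat
}

#' Simulate independent replicate datasets
#'
#' @param truth a [simTruth()] object; replicate `r` uses seed
#'   `truth$seed + r - 1`, so a fixed base seed is reproducible bit-for-bit.
#' @param R number of replicates.
#' @return list of [jointData()] objects.
#' @export
simulateReplicates <- function(truth, R) {
  stopifnot(R >= 1)
  lapply(seq_len(R), function(r) {
    tr <- truth
    tr$seed <- truth$seed + r - 1L
    simulateJoint(tr)
  })
}
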