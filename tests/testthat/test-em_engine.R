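test_that("Gaussian M-step reduces to OLS when the random effects vanish", {
  dat <- toyData(n = 50, seed = 3)
  mom <- list(Eb = matrix(0, dat$n, 2), Ebb = matrix(0, dat$n, 4))
  up <- mStepGaussian(dat, mom)
  fitlm <- lm.fit(dat$X, dat$y)
  expect_equal(up$beta, unname(fitlm$coefficients), tolerance = 1e-10)
  expect_equal(up$sigma2, mean(fitlm$residuals^2), tolerance = 1e-10)
  expect_equal(up$Sigma, matrix(0, 2, 2))
})

test_that("Sigma update averages the posterior second moments", {
  dat <- toyData(n = 20, seed = 3)
  M <- matrix(c(0.6, 0.1, 0.1, 0.3), 2)
  mom <- list(Eb = matrix(0, dat$n, 2),
              Ebb = matrix(as.vector(M), dat$n, 4, byrow = TRUE))
  expect_equal(mStepGaussian(dat, mom)$Sigma, M)
})

test_that("closed-form updates zero the gradient of the expected complete-data loglik", {
  dat <- toyData(n = 40, seed = 26)
  fit <- jmFit(dat, se = FALSE, max_iter = 4, tol_param = 0, tol_loglik = 0)
  mom <- eStep(dat, fit$params, fit$qp, fit$grid)
  up <- mStepGaussian(dat, mom)
  pars <- fit$params
  pars$beta <- up$beta; pars$sigma2 <- up$sigma2; pars$Sigma <- up$Sigma
  Q <- function(beta, sigma2, Sigma) {
    p <- pars; p$beta <- beta; p$sigma2 <- sigma2; p$Sigma <- Sigma
    jmscan:::.expectedCompleteLoglik(dat, mom, p, parts = "gaussian")
  }
  h <- 1e-5
  for (j in 1:3) {
    bp <- bm <- up$beta; bp[j] <- bp[j] + h; bm[j] <- bm[j] - h
    expect_lt(abs((Q(bp, up$sigma2, up$Sigma) - Q(bm, up$sigma2, up$Sigma)) / (2 * h)),
              1e-5)
  }
  expect_lt(abs((Q(up$beta, up$sigma2 + h, up$Sigma) -
                   Q(up$beta, up$sigma2 - h, up$Sigma)) / (2 * h)), 1e-5)
  for (el in list(c(1, 1), c(2, 1), c(2, 2))) {
    Sp <- Sm <- up$Sigma
    Sp[el[1], el[2]] <- Sp[el[1], el[2]] + h; Sp[el[2], el[1]] <- Sp[el[1], el[2]]
    Sm[el[1], el[2]] <- Sm[el[1], el[2]] - h; Sm[el[2], el[1]] <- Sm[el[1], el[2]]
    expect_lt(abs((Q(up$beta, up$sigma2, Sp) - Q(up$beta, up$sigma2, Sm)) / (2 * h)),
              1e-5)
  }
})

test_that("baseline update reduces to Nelson-Aalen without covariate or frailty effects", {
  dat <- toyData(n = 80, seed = 7)
  mom <- list(Eexp = matrix(1, dat$n, 2))
  for (k in 1:2) {
    bl <- mStepBaseline(dat, mom, c(0, 0), c(0, 0), k)
    ei <- eventIndex(dat, k)
    sizes <- risksetSuffixSums(rep(1, dat$n), ei$times, dat$time)
    expect_equal(bl$jumps, ei$d / sizes, tolerance = 1e-14)
    expect_true(all(diff(rev(bl$cum)) >= 0))  # nondecreasing in time
  }
  # singleton with an event
  long <- data.frame(id = 1, time = 0, y = 0, one = 1, z = 0)
  surv <- data.frame(id = 1, survtime = 2, cause = 1L, x = 0.4)
  d1 <- jointData(long, surv, fixed = "one", random = "z", covariates = "x")
  mom1 <- list(Eexp = matrix(1.5, 1, 1))
  bl1 <- mStepBaseline(d1, mom1, 0.7, 0, 1)
  expect_equal(bl1$jumps, 1 / (exp(0.7 * 0.4) * 1.5), tolerance = 1e-14)
})

test_that("baseline and survival Hessian match naive quadratic-time recomputation", {
  dat <- toyData(n = 150, seed = 29)
  fit <- jmFit(dat, se = FALSE, max_iter = 4, tol_param = 0, tol_loglik = 0)
  mom <- eStep(dat, fit$params, fit$qp, fit$grid)
  for (k in 1:2) {
    gamma <- fit$params$gamma[[k]]; nu <- fit$params$nu[[k]]
    bl <- mStepBaseline(dat, mom, gamma, nu, k)
    ei <- eventIndex(dat, k)
    w <- exp(as.vector(dat$X2 %*% gamma)) * mom$Eexp[, k]
    naiveS <- naiveRisksetSums(w, ei$times, dat$time)
    expect_equal(bl$jumps, ei$d / naiveS, tolerance = 1e-12)
    fast <- jmscan:::.survivalScoreHessian(dat, mom, gamma, nu, k, bl$jumps)
    slow <- naiveSurvivalHessian(dat, mom, gamma, nu, k, bl$jumps)
    expect_equal(fast$score, slow$score, tolerance = 1e-10)
    expect_equal(fast$hessian, slow$hessian, tolerance = 1e-10)
  }
})

test_that("the survival score vanishes at a tightly converged fit", {
  dat <- toyData(n = 100, seed = 33)
  fit <- jmFit(dat, se = FALSE, tol_param = 1e-9, tol_loglik = 0,
               max_iter = 3000)
  mom <- fit$moments
  for (k in 1:2) {
    bl <- fit$params$baseline[[k]]
    sh <- jmscan:::.survivalScoreHessian(dat, mom, fit$params$gamma[[k]],
                                         fit$params$nu[[k]], k, bl$jumps)
    expect_lt(max(abs(sh$score)), 1e-5)
  }
})

test_that("observed log-likelihood separates when the association is zero", {
  # short follow-up keeps every subject inside the quadrature accuracy
  # regime, so the integral itself (not only moment ratios) is sharp
  dat <- toyData(n = 60, seed = 35, lambda01 = 0.5, lambda02 = 1,
                 censor_mean = 5)
  par <- truthParams(dat)
  par$nu <- list(c(0, 0), c(0, 0))
  mom0 <- list(Eexp = matrix(1, dat$n, 2))
  for (k in 1:2)
    par$baseline[[k]] <- mStepBaseline(dat, mom0, par$gamma[[k]], par$nu[[k]], k)
  g <- ghGrid(9, 2)
  qp <- jmscan:::.pseudoPoints(dat, g,
                               ebMoments(dat, par$beta, par$sigma2, par$Sigma))
  ll <- observedLoglik(dat, par, qp, g)
  llY <- lmmMarginalLoglik(dat, par$beta, par$sigma2, par$Sigma)
  haz <- jmscan:::.baselineAt(dat, par)
  llC <- 0
  for (k in 1:2) {
    eta <- as.vector(dat$X2 %*% par$gamma[[k]])
    ev <- dat$cause == k
    llC <- llC + sum(haz$logdL[ev] + eta[ev]) - sum(haz$Lambda[, k] * exp(eta))
  }
  expect_equal(ll, llY + llC, tolerance = 1e-6)
})

test_that("E-step moments converge to a dense-grid quadrature reference", {
  # short follow-up: the empirical Bayes scaling then matches the joint
  # posterior and the tensor rule converges at its nominal exponential rate
  dat <- toyData(n = 50, seed = 37, lambda01 = 0.5, lambda02 = 1,
                 censor_mean = 5)
  fit <- jmFit(dat, nq = 6, se = FALSE, max_iter = 8, tol_param = 0,
               tol_loglik = 0)
  S0 <- fit$lmm_init$Sigma
  if (min(eigen(S0, symmetric = TRUE, only.values = TRUE)$values) < 1e-8)
    S0 <- S0 + diag(1e-6, 2)
  eb <- ebMoments(dat, fit$lmm_init$beta, fit$lmm_init$sigma2, S0)
  dense <- ghGrid(30, 2)
  ref <- eStep(dat, fit$params, jmscan:::.pseudoPoints(dat, dense, eb), dense)
  errAt <- function(nq) {
    g <- ghGrid(nq, 2)
    mom <- eStep(dat, fit$params, jmscan:::.pseudoPoints(dat, g, eb), g)
    c(Eb = max(abs(mom$Eb - ref$Eb)),
      Eexp = max(abs(mom$Eexp - ref$Eexp)),
      logNorm = max(abs(mom$logNorm - ref$logNorm)))
  }
  e6 <- errAt(6); e12 <- errAt(12)
  expect_lt(max(e12[c("Eb", "Eexp")]), 1e-5)
  expect_lt(e12[["logNorm"]], 1e-4)
  expect_lt(max(e6), 5e-2)        # default-resolution sanity bound
  expect_true(all(e12 < e6))      # error decreases with resolution
})

test_that("EM ascends the observed log-likelihood and is deterministic", {
  for (s in c(41, 43)) {
    dat <- toyData(n = 120, seed = s)
    fit <- jmFit(dat, se = FALSE, max_iter = 40)
    tr <- fit$loglik_trace
    expect_true(all(diff(tr) >= -1e-6 * abs(tr[-1])))
  }
  dat <- toyData(n = 60, seed = 45)
  f1 <- jmFit(dat, se = FALSE, max_iter = 15)
  f2 <- jmFit(dat, se = FALSE, max_iter = 15)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$loglik_trace, f2$loglik_trace)
})

test_that("the EM recovers the generating variance components at moderate n", {
  dat <- toyData(n = 1000, seed = 2)
  fit <- jmFit(dat, se = FALSE)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$Sigma[1, 1] - 0.5), 3 * 0.5 * sqrt(2 / 1000))
  expect_lt(abs(fit$params$sigma2 - 0.5), 3 * 0.5 * sqrt(2 / length(dat$y)))
})

test_that("an empty risk leaves the fit well-defined", {
  tr <- simTruth(n = 60, seed = 51, lambda02 = 1e-9)
  dat <- simulateJoint(tr)
  expect_equal(eventIndex(dat, 2)$q_k, 0L)
  fit <- jmFit(dat, se = FALSE, max_iter = 30)
  expect_length(fit$params$baseline[[2]]$jumps, 0L)
  expect_true(all(is.finite(coef(fit))))
})
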