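test_that("tensor grids satisfy the Gauss-Hermite identities", {
  g11 <- ghGrid(1, 1)
  expect_equal(as.vector(g11$C), 0)
  expect_equal(exp(g11$logw), sqrt(pi))
  for (spec in list(c(2, 1), c(6, 2), c(4, 3))) {
    g <- ghGrid(spec[1], spec[2])
    expect_equal(sum(exp(g$logw)), pi^(spec[2] / 2), tolerance = 1e-12)
    # symmetry under c -> -c
    expect_equal(sort(as.vector(g$C)), sort(-as.vector(g$C)))
  }
  # exactness for degree-3 polynomials at two points
  g <- ghGrid(2, 1)
  expect_equal(sum(exp(g$logw) * g$C[, 1]^2), sqrt(pi) / 2, tolerance = 1e-12)
})

test_that("standard abscissas rescale by sqrt(2) Sigma^(1/2)", {
  g <- ghGrid(5, 1)
  expect_equal(as.vector(standardAbscissas(g, matrix(1))),
               sqrt(2) * g$C[, 1], tolerance = 1e-14)
  expect_true(all(standardAbscissas(g, matrix(0)) == 0))
  g2 <- ghGrid(4, 2)
  pts <- standardAbscissas(g2, diag(c(0.5, 0.25)))
  expect_equal(pts, sqrt(2) * g2$C %*% diag(sqrt(c(0.5, 0.25))),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("pseudo-adaptive abscissas recentre on the empirical Bayes estimate", {
  g <- ghGrid(4, 2)
  eb0 <- structure(list(b_tilde = matrix(0, 1, 2), H_inv = list(diag(2))),
                   class = "ebEstimates")
  expect_equal(pseudoAdaptiveAbscissas(g, eb0, 1), sqrt(2) * g$C,
               tolerance = 1e-12, ignore_attr = TRUE)
  # a centre node maps to b_tilde itself
  g3 <- ghGrid(3, 2)   # odd rule contains the node c = (0, 0)
  H <- matrix(c(0.3, 0.1, 0.1, 0.2), 2)
  eb <- structure(list(b_tilde = matrix(c(0.7, -0.4), 1), H_inv = list(H)),
                  class = "ebEstimates")
  pts <- pseudoAdaptiveAbscissas(g3, eb, 1)
  centre <- which.min(rowSums(g3$C^2))
  expect_equal(pts[centre, ], c(0.7, -0.4), tolerance = 1e-8)
  # matrix-root oracle
  e <- eigen(H, symmetric = TRUE)
  root <- e$vectors %*% diag(sqrt(e$values)) %*% t(e$vectors)
  expect_equal(pts, sweep(sqrt(2) * g3$C %*% root, 2, c(0.7, -0.4), "+"),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("an event-free subject with no longitudinal rows has zero log density", {
  d <- emptySubjectData()
  p <- emptySubjectParams()
  expect_equal(logJointDensity(d, 1, c(0.3, -0.2), p), 0)
})

test_that("posterior equals prior for an uninformative subject", {
  d <- emptySubjectData()
  p <- emptySubjectParams()
  g <- ghGrid(4, 2)
  pts <- standardAbscissas(g, p$Sigma)
  pm <- posteriorMoments(d, 1, p, pts, g)
  expect_equal(pm$Eb, c(0, 0), tolerance = 1e-12)
  expect_equal(pm$Ebb, p$Sigma, tolerance = 1e-12)
  expect_equal(sum(pm$weights), 1, tolerance = 1e-12)
})

test_that("with nu = 0 the posterior mean equals the conjugate mixed-model solution", {
  dat <- toyData(n = 25, seed = 6, nu1 = c(0, 0), nu2 = c(0, 0))
  par <- truthParams(dat)
  g <- ghGrid(9, 2)
  eb <- ebMoments(dat, par$beta, par$sigma2, par$Sigma)
  haz <- jmscan:::.baselineAt(dat, par)
  for (i in c(2, 11, 20)) {
    pts <- pseudoAdaptiveAbscissas(g, eb, i)
    pm <- posteriorMoments(dat, i, par, pts, g, haz)
    # survival factor is constant in b, so the posterior is the Gaussian
    # mixed-model posterior with mean b_tilde
    expect_equal(pm$Eb, eb$b_tilde[i, ], tolerance = 1e-6)
  }
})

test_that("moment families are internally consistent (Jensen, nu -> 0 limit)", {
  dat <- toyData(n = 40, seed = 19)
  fit <- jmFit(dat, se = FALSE, max_iter = 5, tol_param = 0, tol_loglik = 0)
  mom <- fit$moments
  for (k in 1:2) {
    nu <- fit$params$nu[[k]]
    expect_true(all(mom$Eexp[, k] > 0))
    expect_true(all(mom$Eexp[, k] >= exp(mom$Eb %*% nu) - 1e-10))
  }
  # PSD posterior covariance
  for (i in c(1, 17, 40)) {
    V <- matrix(mom$Ebb[i, ], 2) - tcrossprod(mom$Eb[i, ])
    expect_gte(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  }
  # as nu -> 0, E{exp(nu b)} -> 1 and E{b exp(nu b)} -> E(b)
  par <- fit$params
  par$nu <- list(c(1e-8, -1e-8), c(0, 0))
  mom0 <- eStep(dat, par, fit$qp, fit$grid)
  expect_equal(mom0$Eexp[, 1], rep(1, dat$n), tolerance = 1e-6)
  expect_equal(mom0$Ebexp[[1]], mom0$Eb, tolerance = 1e-6)
})

test_that("the vectorized E-step matches the per-subject reference implementation", {
  dat <- toyData(n = 30, seed = 23)
  for (mode in c("pseudo-adaptive", "standard")) {
    fit <- jmFit(dat, quadrature = mode, nq = 5, se = FALSE, max_iter = 4,
                 tol_param = 0, tol_loglik = 0)
    par <- fit$params
    mom <- eStep(dat, par, fit$qp, fit$grid)
    haz <- jmscan:::.baselineAt(dat, par)
    for (i in c(1, 9, 30)) {
      pts <- if (mode == "standard") {
        standardAbscissas(fit$grid, par$Sigma)
      } else {
        S0 <- fit$lmm_init$Sigma
        if (min(eigen(S0, symmetric = TRUE, only.values = TRUE)$values) < 1e-8)
          S0 <- S0 + diag(1e-6, 2)
        pseudoAdaptiveAbscissas(fit$grid,
                                ebMoments(dat, fit$lmm_init$beta,
                                          fit$lmm_init$sigma2, S0), i)
      }
      pm <- posteriorMoments(dat, i, par, pts, fit$grid, haz)
      expect_equal(pm$Eb, mom$Eb[i, ], tolerance = 1e-10)
      expect_equal(as.vector(pm$Ebb), mom$Ebb[i, ], tolerance = 1e-10)
      expect_equal(pm$Eexp, mom$Eexp[i, ], tolerance = 1e-10)
      for (k in 1:2)
        expect_equal(pm$Ebexp[[k]], mom$Ebexp[[k]][i, ], tolerance = 1e-10)
      expect_equal(pm$logNorm, mom$logNorm[i], tolerance = 1e-10)
    }
  }
})
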