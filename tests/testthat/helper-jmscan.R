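# Shared fixtures: everything is generated in code at test time.

# small simulated joint dataset under the default design
toyData <- function(n = 60, seed = 2, ...) {
  simulateJoint(simTruth(n = n, seed = seed, ...))
}

# a random scan instance: descending subject times (with ties), a strict
# descending subset of "event" times, and per-subject values
scanInstance <- function(n, qk, seed, integer_values = FALSE, d = 1L) {
  set.seed(seed)
  Tv <- sort(round(stats::rexp(n, 0.2), 1), decreasing = TRUE)  # ties likely
  et <- sort(unique(sample(c(Tv, round(stats::rexp(max(qk, 1), 0.2), 1)))),
             decreasing = TRUE)
  qk <- min(qk, length(et))
  et <- if (qk > 0) sort(sample(et, qk), decreasing = TRUE) else numeric(0)
  a <- if (integer_values) matrix(sample(-5:5, n * d, replace = TRUE), n, d)
       else matrix(stats::rnorm(n * d), n, d)
  b <- if (integer_values) matrix(sample(-5:5, qk * d, replace = TRUE), qk, d)
       else matrix(stats::rnorm(qk * d), qk, d)
  list(T = Tv, et = et, a = if (d == 1L) a[, 1L] else a,
       b = if (d == 1L) b[, 1L] else b, n = n, qk = qk)
}

# parameter set at the generating truth of a simulated dataset, with
# Breslow baselines computed at nu = 0 moments (for density-level tests)
truthParams <- function(dat) {
  tr <- attr(dat, "truth")
  params <- list(beta = tr$beta, sigma2 = tr$sigma2, Sigma = tr$Sigma,
                 gamma = list(tr$gamma1, tr$gamma2),
                 nu = list(tr$nu1, tr$nu2),
                 baseline = vector("list", 2L))
  mom0 <- list(Eexp = matrix(1, dat$n, dat$K))
  for (k in 1:2)
    params$baseline[[k]] <- mStepBaseline(dat, mom0, params$gamma[[k]],
                                          params$nu[[k]], k)
  params
}

# hand-built minimal dataset object with a subject that has no
# longitudinal rows (the validated constructor forbids this; the density
# and moment code must still handle the empty-likelihood limit)
emptySubjectData <- function(Sigma = diag(c(0.5, 0.25))) {
  structure(list(
    id = c("a", "b"), time = c(2, 1), cause = c(0L, 0L),
    X2 = matrix(0, 2, 1), y = 0.5, X = matrix(1, 1, 1),
    Z = matrix(c(1, 0), 1, 2), subj = 2L, visit = 0, nobs = c(0L, 1L),
    n = 2L, p = 1L, q = 2L, K = 1L, p2 = 1L, desc_order = 1:2,
    columns = list(fixed = "x", random = c("z1", "z2"), covariates = "w"),
    events = list(structure(list(k = 1L, times = numeric(0), d = integer(0),
                                 q_k = 0L, jump = rep(NA_integer_, 2)),
                            class = "eventTimeIndex"))
  ), class = "jointData")
}

emptySubjectParams <- function(Sigma = diag(c(0.5, 0.25)), nu = c(0, 0)) {
  list(beta = 0, sigma2 = 0.5, Sigma = Sigma, gamma = list(0), nu = list(nu),
       baseline = list(list(times = numeric(0), jumps = numeric(0),
                            cum = numeric(0))))
}
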