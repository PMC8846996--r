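test_that("degenerate step-function lookups follow the boundary conventions", {
  # no events at all: everything is zero
  expect_equal(stepLookup(numeric(0), numeric(0), c(5, 3, 1)), c(0, 0, 0))
  # all subject times at or above the largest event time: top value,
  # including exact ties (right-continuity, closed risk sets)
  out <- stepLookup(c(0.9, 0.4), c(3, 1), c(7, 3, 3))
  expect_equal(out, c(0.9, 0.9, 0.9))
  # below the smallest event time: zero
  expect_equal(stepLookup(c(0.9, 0.4), c(3, 1), c(2, 0.5)), c(0.4, 0))
})

test_that("risk-set suffix sums count and sum correctly in the trivial cases", {
  Tv <- c(9, 7, 7, 4, 1)
  et <- c(7, 4)
  expect_equal(risksetSuffixSums(rep(1, 5), et, Tv), c(3, 4))
  # single event time at the minimum: the full sum
  a <- c(2, -1, 3, 0.5, 1)
  expect_equal(risksetSuffixSums(a, 1, Tv), sum(a))
  # matrix-valued sequences aggregate per column
  A <- cbind(a, 2 * a)
  expect_equal(risksetSuffixSums(A, et, Tv)[, 2], 2 * risksetSuffixSums(a, et, Tv))
})

test_that("event-prefix mapping handles the single-step and zero cases", {
  Tv <- c(6, 3, 2, 0.5)
  expect_equal(eventPrefixMap(5, 2, Tv), c(5, 5, 5, 0))
  expect_equal(eventPrefixMap(c(0, 0), c(4, 1), Tv), rep(0, 4))
})

test_that("fast scans agree with naive oracles over randomized instances", {
  cases <- expand.grid(n = c(1, 2, 10, 200), qfrac = c(0, 0.1, 0.5),
                       integer = c(TRUE, FALSE))
  for (r in seq_len(nrow(cases))) {
    n <- cases$n[r]
    qk <- ceiling(cases$qfrac[r] * n)
    for (s in 1:8) {
      inst <- scanInstance(n, qk, seed = 1000 * r + s,
                           integer_values = cases$integer[r])
      vals <- rev(cumsum(rev(abs(inst$b))))  # a nondecreasing step function
      f1 <- stepLookup(vals, inst$et, inst$T)
      n1 <- naiveStepLookup(vals, inst$et, inst$T)
      f2 <- risksetSuffixSums(inst$a, inst$et, inst$T)
      n2 <- naiveRisksetSums(inst$a, inst$et, inst$T)
      f3 <- eventPrefixMap(inst$b, inst$et, inst$T)
      n3 <- naiveEventPrefix(inst$b, inst$et, inst$T)
      if (cases$integer[r]) {
        expect_identical(as.numeric(f1), as.numeric(n1))
        expect_equal(f2, n2, tolerance = 1e-12)
        expect_equal(f3, n3, tolerance = 1e-12)
      } else {
        expect_equal(f1, n1, tolerance = 1e-10)
        expect_equal(f2, n2, tolerance = 1e-10)
        expect_equal(f3, n3, tolerance = 1e-10)
      }
      # cumulative-hazard style monotonicity is preserved by the lookup
      expect_true(all(diff(f1) <= 1e-12))
    }
  }
})

test_that("instrumented comparison counts are linear in n + q_k", {
  for (n in c(10, 500, 5000)) {
    inst <- scanInstance(n, ceiling(n / 3), seed = n)
    vals <- seq_along(inst$et)
    c1 <- attr(stepLookup(rev(vals), inst$et, inst$T, instrument = TRUE),
               "comparisons")
    c2 <- attr(risksetSuffixSums(inst$a, inst$et, inst$T, instrument = TRUE),
               "comparisons")
    c3 <- attr(eventPrefixMap(inst$b, inst$et, inst$T, instrument = TRUE),
               "comparisons")
    bound <- n + length(inst$et)
    expect_lte(c1, bound)
    expect_lte(c2, bound)
    expect_lte(c3, bound)
    # while the naive versions are ~ n * q_k
    cn <- attr(naiveStepLookup(rev(vals), inst$et, inst$T, instrument = TRUE),
               "comparisons")
    expect_equal(cn, n * length(inst$et))
  }
  # naive / fast comparison ratio grows linearly with n
  ratio <- sapply(c(100, 200, 400), function(n) {
    inst <- scanInstance(n, ceiling(n / 2), seed = n + 7)
    fast <- attr(risksetSuffixSums(inst$a, inst$et, inst$T, instrument = TRUE),
                 "comparisons")
    naive <- attr(naiveRisksetSums(inst$a, inst$et, inst$T, instrument = TRUE),
                  "comparisons")
    naive / fast
  })
  expect_true(all(diff(ratio) > 0))
  expect_gt(ratio[3] / ratio[1], 2)
})

test_that("unsorted inputs are rejected", {
  expect_error(stepLookup(1, 1, c(1, 5)), "not descending")
  expect_error(risksetSuffixSums(c(1, 1), c(1, 2), c(5, 1)), "not strictly")
})
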