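#' Merged-scan interval index for a descending step function
#'
#' For subject times \eqn{T_{(1)} \ge \dots \ge T_{(n)}} (descending) and
#' distinct event times \eqn{t_1 > \dots > t_{q_k}} (descending), returns
#' for each subject the index of the governing event time: `1` if
#' \eqn{T_i \ge t_1}, `j+1` if \eqn{T_i \in [t_{j+1}, t_j)}, and `0` if
#' \eqn{T_i} is below the smallest event time.  Both sequences are scanned
#' forward once, so the total number of comparisons is at most
#' \eqn{n + q_k}.  The step function is right-continuous: a subject time
#' exactly equal to an event time takes the value at that event time.
#'
#' @param sorted_times subject times, descending.
#' @param event_times distinct event times, descending.
#' @param instrument if `TRUE`, attach the comparison count as attribute
#'   `"comparisons"`.
#' @return integer vector of indices in `0..q_k`.
#' @export
stepIndex <- function(sorted_times, event_times, instrument = FALSE) {
  n <- length(sorted_times); qk <- length(event_times)
  if (n > 1L && is.unsorted(rev(sorted_times))) stop("subject times not descending")
  if (qk > 1L && any(diff(event_times) >= 0)) stop("event times not strictly descending")
  idx <- integer(n)
  j <- 1L; ncomp <- 0L
  for (i in seq_len(n)) {
    while (j <= qk) {
      ncomp <- ncomp + 1L
      if (event_times[j] > sorted_times[i]) j <- j + 1L else break
    }
    idx[i] <- if (j <= qk) j else 0L
  }
  if (instrument) attr(idx, "comparisons") <- ncomp
  idx
}

#' Step-function lookup at all subject times
#'
#' Evaluates a right-continuous nonincreasing-support step function, given
#' by its values at the descending event times, at every subject time in a
#' single merged forward pass (at most \eqn{n + q_k} comparisons).  Value
#' is 0 below the smallest event time.  Used to obtain
#' \eqn{\Lambda_{0k}(T_i)} for all subjects from the \eqn{q_k} values at
#' the event times.
#'
#' @param values values of the step function at the event times (value at
#'   `event_times[j]` governs \eqn{[t_{j}, t_{j-1})}).
#' @inheritParams stepIndex
#' @export
stepLookup <- function(values, event_times, sorted_times, instrument = FALSE) {
  stopifnot(length(values) == length(event_times))
  idx <- stepIndex(sorted_times, event_times, instrument = instrument)
  out <- ifelse(idx == 0L, 0, values[pmax(idx, 1L)])
  if (instrument) attr(out, "comparisons") <- attr(idx, "comparisons")
  out
}

#' Risk-set sums at all event times by the suffix-sum recursion
#'
#' Computes \eqn{\sum_{r \in R(t_{kj})} a_r} for \eqn{j = 1, \dots, q_k}
#' with \eqn{R(t) = \{r : T_r \ge t\}} (closed at `t`), using the
#' decomposition \eqn{R(t_{k(j+1)}) = R(t_{kj}) \cup \{r : T_r \in
#' [t_{k(j+1)}, t_{kj})\}}: every subject is accumulated exactly once, so
#' the cost is \eqn{O(n + q_k)} regardless of how many risk sets it
#' belongs to.
#'
#' @param a per-subject values aligned to the descending-time ordering;
#'   a vector or an `n x d` matrix (each column aggregated independently).
#' @inheritParams stepIndex
#' @return a `q_k x d` matrix (a `q_k`-vector if `a` is a vector).
#' @export
risksetSuffixSums <- function(a, event_times, sorted_times, instrument = FALSE) {
  vec <- is.null(dim(a))
  a <- as.matrix(a)
  n <- length(sorted_times); qk <- length(event_times)
  if (nrow(a) != n) stop("length of a must match the number of subjects")
  if (n > 1L && is.unsorted(rev(sorted_times))) stop("subject times not descending")
  if (qk > 1L && any(diff(event_times) >= 0)) stop("event times not strictly descending")
  out <- matrix(0, qk, ncol(a))
  acc <- numeric(ncol(a))
  i <- 1L; ncomp <- 0L
  for (j in seq_len(qk)) {
    i0 <- i
    while (i <= n) {
      ncomp <- ncomp + 1L
      if (sorted_times[i] >= event_times[j]) i <- i + 1L else break
    }
    if (i > i0) acc <- acc + colSums(a[i0:(i - 1L), , drop = FALSE])
    out[j, ] <- acc
  }
  if (vec) out <- out[, 1L]
  if (instrument) attr(out, "comparisons") <- ncomp
  out
}

#' Event-prefix sums mapped to all subject times
#'
#' Given per-event-time values \eqn{b_{kj}} (aligned to the descending
#' event times), computes \eqn{B(T_i) = \sum_{j : t_{kj} \le T_i} b_{kj}}
#' for every subject: first accumulate \eqn{B} at the event times by the
#' backward-in-time recursion, then map to subject times by the same merged
#' scan as [stepLookup()], for a total of \eqn{O(n + q_k)} operations.
#' These are the prefix-sum terms of the profiled-likelihood scores.
#'
#' @param b per-event-time values; vector of length `q_k` or a `q_k x d`
#'   matrix.
#' @inheritParams stepIndex
#' @return an `n x d` matrix (an `n`-vector if `b` is a vector).
#' @export
eventPrefixMap <- function(b, event_times, sorted_times, instrument = FALSE) {
  vec <- is.null(dim(b))
  b <- as.matrix(b)
  qk <- length(event_times)
  if (nrow(b) != qk) stop("b must have one row per event time")
  # B at the event times: suffix accumulation along descending times
  B <- if (qk) apply(b, 2L, function(col) rev(cumsum(rev(col)))) else b
  if (qk == 1L) B <- matrix(B, 1L)
  idx <- stepIndex(sorted_times, event_times, instrument = instrument)
  out <- matrix(0, length(sorted_times), ncol(b))
  hit <- idx > 0L
  out[hit, ] <- B[idx[hit], , drop = FALSE]
  if (vec) out <- out[, 1L]
  if (instrument) attr(out, "comparisons") <- attr(idx, "comparisons")
  out
}
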