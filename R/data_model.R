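#' Assemble a joint longitudinal / competing-risks dataset
#'
#' Validates and aligns a long-format table of repeated measurements with a
#' one-row-per-subject survival table, and stores everything in the global
#' descending-time subject ordering on which all linear scan algorithms in
#' this package rely.
#'
#' @param longitudinal data frame with one row per visit, containing the
#'   subject identifier, the visit time, the response, and the fixed- and
#'   random-effects design columns.
#' @param survival data frame with exactly one row per subject: identifier,
#'   observed time (event or censoring), cause (`0` = censored, `1..K` =
#'   failure type), and baseline covariate columns.
#' @param fixed,random character vectors naming the fixed-effect and
#'   random-effect design columns of `longitudinal` (include an explicit
#'   intercept column if one is wanted).
#' @param covariates character vector naming the survival covariate columns.
#' @param id,time,y names of the identifier, visit-time and response columns
#'   of `longitudinal`.
#' @param survtime,cause names of the observed-time and cause columns of
#'   `survival`.
#' @param K number of competing risks; defaults to the largest cause observed.
#'
#' @details Subjects are permuted so that observed times are in descending
#'   order \eqn{T_{(1)} \ge \dots \ge T_{(n)}}, ties broken by subject
#'   identifier for determinism.  Visits are sorted by time within subject.
#'   Visits recorded after the subject's observed time are rejected: the
#'   model treats the longitudinal outcome as unobservable after the
#'   terminal event.  The risk set convention is closed at the event time,
#'   \eqn{R(t) = \{r : T_r \ge t\}}, so a subject censored exactly at an
#'   event time is still at risk there.  Tied event times are collapsed to a
#'   single jump with multiplicity (Breslow handling of ties); tie detection
#'   uses exact equality since times are recorded, not computed.
#'
#' @return An object of class `jointData`; see [eventIndex()] for the
#'   per-risk event-time index it carries.
#' @export
jointData <- function(longitudinal, survival,
                      fixed, random, covariates,
                      id = "id", time = "time", y = "y",
                      survtime = "survtime", cause = "cause",
                      K = NULL) {
  longitudinal <- as.data.frame(longitudinal)
  survival <- as.data.frame(survival)
  need_long <- c(id, time, y, fixed, random)
  need_surv <- c(id, survtime, cause, covariates)
  miss <- setdiff(need_long, names(longitudinal))
  if (length(miss)) stop("longitudinal table lacks column(s): ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(need_surv, names(survival))
  if (length(miss)) stop("survival table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (anyNA(longitudinal[need_long])) stop("missing values in longitudinal table")
  if (anyNA(survival[need_surv])) stop("missing values in survival table")

  sid <- as.character(survival[[id]])
  if (anyDuplicated(sid)) stop("survival table must have exactly one row per subject")
  lid <- as.character(longitudinal[[id]])
  only_l <- setdiff(unique(lid), sid)
  only_s <- setdiff(sid, unique(lid))
  if (length(only_l)) stop("subject(s) in longitudinal but not survival table: ",
                           paste(utils::head(only_l, 5L), collapse = ", "))
  if (length(only_s)) stop("subject(s) in survival but not longitudinal table: ",
                           paste(utils::head(only_s, 5L), collapse = ", "))

  Ti <- as.numeric(survival[[survtime]])
  Di <- as.integer(survival[[cause]])
  if (any(!is.finite(Ti)) || any(Ti < 0)) stop("observed times must be finite and nonnegative")
  if (is.null(K)) K <- max(Di, 1L)
  K <- as.integer(K)
  if (K < 1L) stop("K must be at least 1")
  if (any(Di < 0L | Di > K)) stop("cause must lie in 0..K")

  # global descending-time subject order, ties broken by id
  ord <- order(-Ti, sid)
  sid <- sid[ord]; Ti <- Ti[ord]; Di <- Di[ord]
  X2 <- as.matrix(survival[ord, covariates, drop = FALSE])
  storage.mode(X2) <- "double"

  pos <- match(lid, sid)
  vt <- as.numeric(longitudinal[[time]])
  if (any(vt < 0)) stop("negative visit times")
  bad <- vt > Ti[pos] + 1e-12
  if (any(bad)) stop("visit after the observed survival time for subject(s): ",
                     paste(utils::head(unique(lid[bad]), 5L), collapse = ", "))
  lord <- order(pos, vt)
  subj <- pos[lord]
  visit <- vt[lord]
  yv <- as.numeric(longitudinal[[y]])[lord]
  X <- as.matrix(longitudinal[lord, fixed, drop = FALSE]); storage.mode(X) <- "double"
  Z <- as.matrix(longitudinal[lord, random, drop = FALSE]); storage.mode(Z) <- "double"
  if (!all(is.finite(X)) || !all(is.finite(Z)) || !all(is.finite(yv)))
    stop("non-finite values in longitudinal design or response")
  if (!all(is.finite(X2))) stop("non-finite survival covariates")

  n <- length(sid)
  nobs <- tabulate(subj, nbins = n)
  if (any(nobs == 0L)) stop("every subject needs at least one longitudinal record")

  dat <- structure(list(
    id = sid, time = Ti, cause = Di, X2 = X2,
    y = yv, X = X, Z = Z, subj = subj, visit = visit, nobs = nobs,
    n = n, p = ncol(X), q = ncol(Z), K = K, p2 = ncol(X2),
    desc_order = ord,
    columns = list(fixed = fixed, random = random, covariates = covariates)
  ), class = "jointData")
  dat$events <- lapply(seq_len(K), function(k) .buildEventIndex(dat, k))
  dat
}

# distinct descending type-k event times, multiplicities, and each type-k
# event subject's jump index
.buildEventIndex <- function(data, k) {
  ev <- which(data$cause == k)
  tev <- data$time[ev]
  ut <- sort(unique(tev), decreasing = TRUE)
  d <- if (length(ut)) as.integer(tabulate(match(tev, ut), nbins = length(ut))) else integer(0)
  jump <- rep(NA_integer_, data$n)
  jump[ev] <- match(tev, ut)
  structure(list(k = k, times = ut, d = d, q_k = length(ut), jump = jump),
            class = "eventTimeIndex")
}

#' Event-time index for one competing risk
#'
#' Returns the distinct observed type-`k` event times in descending order,
#' their multiplicities \eqn{d_{kj}}, and for each subject that failed from
#' cause `k` the index of its jump time.
#'
#' @param data a [jointData()] object.
#' @param k risk in `1..K`.
#' @return list with elements `times` (descending), `d`, `q_k`, `jump`.
#' @export
eventIndex <- function(data, k) {
  stopifnot(inherits(data, "jointData"), k >= 1L, k <= data$K)
  data$events[[k]]
}

#' @export
print.jointData <- function(x, ...) {
  cat("Joint longitudinal / competing-risks dataset\n")
  cat(sprintf("  subjects: %d   longitudinal records: %d\n", x$n, length(x$y)))
  cat(sprintf("  fixed effects p = %d, random effects q = %d, survival covariates p2 = %d\n",
              x$p, x$q, x$p2))
  for (k in seq_len(x$K))
    cat(sprintf("  risk %d: %d events at %d distinct times\n",
                k, sum(x$cause == k), x$events[[k]]$q_k))
  cat(sprintf("  censored: %d\n", sum(x$cause == 0L)))
  invisible(x)
}

#' Number of subjects in a joint dataset
#' @param data a [jointData()] object.
#' @export
nSubjects <- function(data) data$n
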