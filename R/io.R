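#' Read a model configuration file
#'
#' YAML configuration mapping the CSV columns to model roles, plus
#' quadrature and convergence settings.  Recognized fields: `id`, `time`,
#' `y`, `fixed`, `random`, `survtime`, `cause`, `covariates`, `K`,
#' `quadrature`, `nq`, `tol_param`, `tol_loglik`, `max_iter`.
#'
#' @param path YAML file.
#' @return list of settings with defaults filled in.
#' @export
readModelConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(id = "id", time = "time", y = "y",
                   survtime = "survtime", cause = "cause",
                   K = NULL, quadrature = "pseudo-adaptive", nq = NULL,
                   tol_param = 1e-4, tol_loglik = 1e-8, max_iter = 500L)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  for (nm in c("fixed", "random", "covariates"))
    if (is.null(cfg[[nm]]))
      stop("config must name the '", nm, "' columns")
  cfg
}

#' Read longitudinal and survival CSV files into a joint dataset
#'
#' @param long_path,surv_path paths to the longitudinal and survival CSV
#'   files (UTF-8, header row required).
#' @param config configuration list from [readModelConfig()] (or an
#'   equivalent list).
#' @return a validated [jointData()] object.
#' @export
readJointData <- function(long_path, surv_path, config) {
  long <- utils::read.csv(long_path, stringsAsFactors = FALSE)
  surv <- utils::read.csv(surv_path, stringsAsFactors = FALSE)
  jointData(long, surv,
            fixed = config$fixed, random = config$random,
            covariates = config$covariates,
            id = config$id, time = config$time, y = config$y,
            survtime = config$survtime, cause = config$cause,
            K = config$K)
}

#' Write a joint dataset to a pair of CSV files
#'
#' Writes `<prefix>_long.csv` and `<prefix>_surv.csv` in the formats read
#' back by [readJointData()].
#'
#' @param data a [jointData()] object.
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
writeJointData <- function(data, prefix) {
  cols <- data$columns
  dfl <- data.frame(id = data$id[data$subj], time = data$visit, y = data$y)
  for (nm in cols$fixed) dfl[[nm]] <- data$X[, nm]
  for (nm in cols$random) if (!nm %in% names(dfl)) dfl[[nm]] <- data$Z[, nm]
  dfs <- data.frame(id = data$id, survtime = data$time, cause = data$cause)
  for (nm in cols$covariates) dfs[[nm]] <- data$X2[, nm]
  pl <- paste0(prefix, "_long.csv"); ps <- paste0(prefix, "_surv.csv")
  utils::write.csv(dfl, pl, row.names = FALSE)
  utils::write.csv(dfs, ps, row.names = FALSE)
  invisible(c(pl, ps))
}

#' Write fit results to JSON and the baseline hazards to CSV
#'
#' The JSON file carries the parametric estimates, standard errors, the
#' full covariance matrix of \eqn{\hat\Omega}, the log-likelihood trace and
#' the settings; numbers are serialized at full precision so a read-back
#' reproduces the estimates bit-exactly.  The CSV lists one row per
#' baseline jump: `risk, time, jump, cumulative` (ascending time within
#' risk, so the cumulative column is nondecreasing).
#'
#' @param fit a [jmFit()] object.
#' @param path_json,path_csv output paths.
#' @return invisibly, the JSON path.
#' @export
writeResults <- function(fit, path_json, path_csv = NULL) {
  est <- coef(fit)
  out <- list(
    estimates = as.list(est),
    se = if (!is.null(fit$se)) as.list(fit$se) else NULL,
    vcov = fit$vcov,
    loglik = fit$loglik,
    loglik_trace = fit$loglik_trace,
    n_iter = fit$n_iter,
    converged = fit$converged,
    settings = fit$settings
  )
  jsonlite::write_json(out, path_json, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  if (!is.null(path_csv)) {
    rows <- do.call(rbind, lapply(seq_along(fit$params$baseline), function(k) {
      bl <- fit$params$baseline[[k]]
      if (!length(bl$times))
        return(data.frame(risk = integer(0), time = numeric(0),
                          jump = numeric(0), cumulative = numeric(0)))
      ord <- order(bl$times)
      data.frame(risk = k, time = bl$times[ord], jump = bl$jumps[ord],
                 cumulative = cumsum(bl$jumps[ord]))
    }))
    utils::write.csv(rows, path_csv, row.names = FALSE)
  }
  invisible(path_json)
}

#' Read back a JSON results file
#' @param path JSON file written by [writeResults()].
#' @export
readResults <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
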