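#' Run configuration
#'
#' A run is reproducible from its configuration plus seed alone. The
#' configuration is a YAML file with keys:
#' \describe{
#'   \item{model}{built-in model name (`"viral"`, `"nsclc"`, `"linear"`).}
#'   \item{model_args}{optional list passed to the model constructor
#'     (e.g. initial conditions, carrying capacity).}
#'   \item{parameters}{a list mapping parameter name to
#'     `value`/`lower`/`upper`.}
#'   \item{objective}{objective kind, see [objectiveSpec()].}
#'   \item{fd}{optional [fdConfig()] fields.}
#'   \item{seed}{integer seed.}
#' }
#'
#' @param path YAML file path.
#' @return `readRunConfig` returns a `run_config` list; `writeRunConfig`
#'   invisibly returns `path`.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$model)) stop("run config must name a model")
  if (is.null(cfg$parameters)) stop("run config must define parameters")
  if (is.null(cfg$objective)) cfg$objective <- "weighted_sum_of_squares"
  if (is.null(cfg$seed)) cfg$seed <- 1L
  structure(cfg, class = "run_config")
}

#' @rdname readRunConfig
#' @param cfg a `run_config` list.
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname readRunConfig
#' @export
configModel <- function(cfg) {
  args <- cfg$model_args
  if (is.null(args)) args <- list()
  if (!is.null(args$init)) args$init <- unlist(args$init)
  do.call(getModel, c(list(name = cfg$model), args))
}

#' @rdname readRunConfig
#' @export
configParams <- function(cfg) {
  ps <- cfg$parameters
  vals <- vapply(ps, function(x) as.numeric(x$value), numeric(1))
  lo <- vapply(ps, function(x) {
    if (is.null(x$lower)) -Inf else as.numeric(x$lower)
  }, numeric(1))
  hi <- vapply(ps, function(x) {
    if (is.null(x$upper)) Inf else as.numeric(x$upper)
  }, numeric(1))
  paramVector(vals, lo, hi, names = base::names(ps))
}

#' @rdname readRunConfig
#' @export
configFD <- function(cfg) {
  if (is.null(cfg$fd)) return(fdConfig())
  do.call(fdConfig, cfg$fd)
}

#' Write a data-space Jacobian as a labelled CSV matrix
#'
#' Rows are parameters, columns are data rows labelled `time@condition`.
#'
#' @param dpsi `p x d` matrix or a `continuation_state`.
#' @param path output path.
#' @export
writeDPsiCSV <- function(dpsi, path) {
  utils::write.csv(as.data.frame(asDPsiMatrix(dpsi)), path,
                   row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Write a continuation path as CSV
#'
#' One row per step: the parameter components of the predicted (and, when
#' available, corrected) estimate, the objective values, and the
#' cumulative evaluation counts.
#'
#' @param steps result of [continuationPath()].
#' @param path output path.
#' @export
writePathCSV <- function(steps, path) {
  rows <- lapply(seq_along(steps), function(j) {
    s <- steps[[j]]
    row <- data.frame(step = j, objective_predicted = s$objective_predicted)
    pv <- s$predicted$values
    for (nm in base::names(pv)) row[[paste0("pred_", nm)]] <- pv[[nm]]
    if (!is.null(s$theta)) {
      row$objective <- s$objective
      tv <- s$theta$values
      for (nm in base::names(tv)) row[[paste0("fit_", nm)]] <- tv[[nm]]
      row$n_obj_correct <- s$n_obj_correct
    }
    row$n_sim_cum <- s$n_sim
    row$n_obj_cum <- s$n_obj
    row
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
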