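#' Bounded parameter vector
#'
#' Container for a named model parameter vector together with the box
#' constraints that define the admissible region of parameter space. All
#' fitting and finite-difference machinery in the package respects these
#' bounds.
#'
#' @param values named numeric vector of parameter values.
#' @param lower,upper numeric vectors of box bounds, recycled to the length of
#'   `values`. Defaults are unbounded.
#' @param names optional character vector of parameter names; overrides
#'   `names(values)`.
#'
#' @return An object of class `param_vector`: a list with elements `values`,
#'   `lower` and `upper` (all named numeric vectors of equal length).
#' @examples
#' paramVector(c(beta = 2e-5, d = 0.15), lower = 0)
#' @export
paramVector <- function(values, lower = -Inf, upper = Inf, names = NULL) {
  values <- as.numeric2(values, names)
  p <- length(values)
  if (p < 1L) stop("parameter vector must have length >= 1")
  if (is.null(base::names(values))) {
    base::names(values) <- paste0("theta", seq_len(p))
  }
  lower <- rep_len(as.numeric(lower), p)
  upper <- rep_len(as.numeric(upper), p)
  base::names(lower) <- base::names(upper) <- base::names(values)
  pv <- structure(
    list(values = values, lower = lower, upper = upper),
    class = "param_vector"
  )
  validateParamVector(pv)
  pv
}

as.numeric2 <- function(x, nm = NULL) {
  out <- as.numeric(x)
  base::names(out) <- if (!is.null(nm)) nm else base::names(x)
  out
}

validateParamVector <- function(pv) {
  stopifnot(inherits(pv, "param_vector"))
  p <- length(pv$values)
  if (length(pv$lower) != p || length(pv$upper) != p) {
    stop("bounds must have the same length as the parameter vector")
  }
  if (anyNA(pv$values)) stop("parameter values must be finite")
  if (any(pv$lower > pv$upper)) stop("lower bound exceeds upper bound")
  bad <- pv$values < pv$lower - 1e-12 | pv$values > pv$upper + 1e-12
  if (any(bad)) {
    stop(
      "parameter(s) outside bounds: ",
      paste(base::names(pv$values)[bad], collapse = ", ")
    )
  }
  invisible(pv)
}

#' @export
print.param_vector <- function(x, ...) {
  cat("<param_vector> p =", length(x$values), "\n")
  print(data.frame(
    value = x$values, lower = x$lower, upper = x$upper,
    row.names = base::names(x$values)
  ))
  invisible(x)
}

#' @rdname paramVector
#' @param pv a `param_vector`.
#' @param values_new numeric vector of replacement values (same length).
#' @export
setParamValues <- function(pv, values_new) {
  stopifnot(inherits(pv, "param_vector"))
  values_new <- as.numeric(values_new)
  stopifnot(length(values_new) == length(pv$values))
  base::names(values_new) <- base::names(pv$values)
  pv$values <- values_new
  validateParamVector(pv)
  pv
}

## Clip a raw numeric vector into the admissible box; returns list(values, clipped)
clipToBounds <- function(pv, values_new) {
  clipped <- pmin(pmax(values_new, pv$lower), pv$upper)
  list(values = clipped, any_clipped = any(clipped != values_new))
}
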