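#' @useDynLib nichediverge, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats plogis qlogis rnorm runif rbinom quantile cor sd var
#'   median glm binomial coef predict prcomp t.test pt setNames aggregate
#'   complete.cases logLik as.formula
#' @importFrom utils read.csv write.csv head
NULL

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the current RNG state, seeds it, evaluates `expr`, and restores the
#' previous state so callers' random streams are unaffected.
#'
#' @param seed integer seed, or `NULL` to leave the RNG untouched.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible child seed from a master seed and string labels
#'
#' Stable polynomial string hash folded with the master seed, reduced modulo
#' 2^31 - 2. Adding a new label never perturbs the seeds derived for other
#' labels, so per-species and per-stage random streams are independent of the
#' set of species processed.
#'
#' @param master integer master seed.
#' @param ... character or numeric labels identifying the consumer
#'   (e.g. stage name, species id, replicate number).
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
spawn_seed <- function(master, ...) {
  labels <- paste(vapply(list(...), as.character, ""), collapse = "/")
  h <- as.double(master %% 2147483647L)
  for (code in utf8ToInt(labels)) {
    h <- (h * 31 + code) %% 2147483629
  }
  as.integer(h %% 2147483645) + 1L
}

#' Nearest-rank empirical percentile
#'
#' The k-th smallest value with `k = ceiling(p * n)`; the convention used for
#' all empirical null-distribution bounds in the package.
#'
#' @param x numeric vector.
#' @param p probability in (0, 1].
#' @return the nearest-rank percentile of `x`.
#' @keywords internal
nearest_rank <- function(x, p) {
  stopifnot(length(x) > 0, p > 0, p <= 1)
  xs <- sort(x)
  xs[max(1L, ceiling(p * length(xs)))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize longitudes to [-180, 180)
#' @param lon numeric vector of longitudes in degrees.
#' @return normalized longitudes.
#' @keywords internal
normalize_lon <- function(lon) {
  ((lon + 180) %% 360) - 180
}
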