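# Component niche models. All three algorithms are presence-background
# logistic fits on different feature expansions, solved by one compiled
# penalized-IRLS routine:
#   * "maxent"  — ridge-penalized logistic on standardized linear+quadratic
#                 features (regularisation multiplier x unit ridge), the
#                 penalized-GLM re-expression of MaxEnt restricted to
#                 linear/quadratic transformations;
#   * "glm"     — plain logistic regression on linear terms, no interactions;
#   * "gam"     — natural cubic spline basis per variable with a light ridge
#                 penalty, basis dimension 4 so each variable's effective
#                 degrees of freedom cannot exceed 4.

component_algorithms <- function() c("maxent", "glm", "gam")

# natural-spline knot placement that survives heavily tied covariates
# (e.g. a bathymetry plateau): quantile knots over the unique values, or a
# plain linear term when too few distinct values remain.
ns_knots <- function(x, df = 4) {
  ux <- sort(unique(x))
  if (length(ux) < df + 2) return(NULL)
  kn <- quantile(x, probs = seq_len(df - 1) / df, names = FALSE, type = 7)
  bnd <- range(x)
  if (anyDuplicated(kn) || any(kn <= bnd[1]) || any(kn >= bnd[2]))
    kn <- quantile(ux, probs = seq_len(df - 1) / df, names = FALSE, type = 7)
  if (anyDuplicated(kn) || any(kn <= bnd[1]) || any(kn >= bnd[2]))
    return(NULL)
  list(knots = kn, boundary = bnd)
}

# basis matrix for one variable given ns_knots() output (NULL -> linear)
ns_basis <- function(x, b) {
  if (is.null(b)) return(matrix(x, ncol = 1))
  unclass(splines::ns(x, knots = b$knots, Boundary.knots = b$boundary))
}

build_features <- function(algorithm, x, spec = NULL) {
  x <- as.matrix(x)
  if (algorithm %in% c("glm", "maxent")) {
    if (is.null(spec)) {
      ctr <- colMeans(x)
      scl <- apply(x, 2, sd)
      scl[scl == 0] <- 1
      spec <- list(algorithm = algorithm, vars = colnames(x),
                   center = ctr, scale = scl)
    }
    # standardization is an affine reparameterization: identical fit for
    # the plain GLM, and the scale on which the maxent ridge applies
    z <- sweep(sweep(x, 2, spec$center), 2, spec$scale, "/")
    list(X = if (algorithm == "glm") cbind(1, z) else cbind(1, z, z^2),
         spec = spec)
  } else if (algorithm == "gam") {
    if (is.null(spec)) {
      bases <- lapply(seq_len(ncol(x)), function(j) ns_knots(x[, j]))
      names(bases) <- colnames(x)
      spec <- list(algorithm = "gam", vars = colnames(x), bases = bases)
    }
    mats <- lapply(colnames(x), function(v) ns_basis(x[, v], spec$bases[[v]]))
    list(X = cbind(1, do.call(cbind, mats)), spec = spec)
  } else stop("unknown algorithm: ", algorithm)
}

component_penalty <- function(algorithm, n_features, reg_mult = 1) {
  # the 1e-6 on the GLM is numerical stabilization only (ties / constant
  # columns within a CV fold), not regularization
  base <- switch(algorithm,
                 glm = 1e-6,
                 maxent = 1 * reg_mult,
                 gam = 0.5)
  c(0, rep(base, n_features - 1))
}

#' Fit a single component niche model
#'
#' Fits one of the three ensemble algorithms as a (penalized) logistic
#' regression of presence (1) vs background (0) on the screened variables.
#' A fit that fails to converge or runs away (separable data) is refitted
#' with a small ridge penalty and flagged.
#'
#' @param algorithm `"maxent"`, `"glm"`, or `"gam"` (see file header for the
#'   feature expansions these denote).
#' @param x numeric matrix of covariates (rows = presences then background).
#' @param y 0/1 response (1 = presence).
#' @param reg_mult regularisation multiplier for the maxent-like ridge
#'   (default 1).
#' @return class `component_model`: coefficients, feature spec, effective
#'   degrees of freedom, convergence flag.
#' @export
fit_component <- function(algorithm, x, y, reg_mult = 1) {
  algorithm <- match.arg(algorithm, component_algorithms())
  if (sum(y == 1) < 10) stop("need at least 10 presences to fit a component")
  f <- build_features(algorithm, x)
  pen <- component_penalty(algorithm, ncol(f$X), reg_mult)
  fit <- irls_logistic(f$X, as.numeric(y), pen)
  flagged <- FALSE
  if (!fit$converged || max(abs(fit$coefficients)) > 30) {
    # separation / non-convergence: penalty fallback
    pen2 <- pen + c(0, rep(0.1, ncol(f$X) - 1))
    fit <- irls_logistic(f$X, as.numeric(y), pen2)
    flagged <- TRUE
  }
  structure(list(algorithm = algorithm, coefficients = drop(fit$coefficients),
                 spec = f$spec, edf = fit$edf, converged = fit$converged,
                 flagged = flagged),
            class = "component_model")
}

#' Predict presence probability from a component model
#' @param object a `component_model`.
#' @param newx covariate matrix with the model's variables as columns.
#' @param ... unused.
#' @return vector of probabilities in `[0, 1]`.
#' @export
predict.component_model <- function(object, newx, ...) {
  newx <- as.matrix(newx)[, object$spec$vars, drop = FALSE]
  f <- build_features(object$algorithm, newx, spec = object$spec)
  plogis(pmin(30, pmax(-30, drop(f$X %*% object$coefficients))))
}
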