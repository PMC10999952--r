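#' Build a covariate basis (linear or 2-df B-spline)
#'
#' Covariates are optionally `log1p`-transformed (the convention for
#' zero-inflated prey and competitor densities), then z-scored for
#' optimizer conditioning, then expanded:
#' \itemize{
#'   \item `linear`: a single centered column (the z-scored values);
#'   \item `spline2df`: a degree-2 B-spline with no interior knot and
#'     boundary knots at the observed minimum and maximum (two basis
#'     columns after the intercept column is dropped), so together with
#'     the model intercept the basis spans all quadratics on the observed
#'     range.
#' }
#' Centering/scaling constants and boundary knots are stored so the basis
#' is reproducible bit-for-bit on new data.
#'
#' @param values Covariate values at the sampling locations.
#' @param form `"linear"` or `"spline2df"`.
#' @param transform `"identity"` or `"log1p"`.
#' @param name Covariate name carried through outputs.
#' @return A `covariate_basis` with elements `columns` (n x df matrix),
#'   `name`, `form`, `transform`, `center`, `scale`, `boundary` (z-scale),
#'   `range_raw` (observed raw range).
#' @export
build_basis <- function(values, form = c("linear", "spline2df"),
                        transform = c("identity", "log1p"),
                        name = "covariate") {
  form <- match.arg(form)
  transform <- match.arg(transform)
  ok <- !is.na(values)
  if (!all(ok)) stop("covariate '", name, "' has ", sum(!ok),
                     " missing values; fill them first")
  x <- apply_transform(values, transform)
  if (any(!is.finite(x))) stop("non-finite transformed covariate '",
                               name, "'")
  if (sd(x) == 0) stop("constant covariate '", name,
                       "' gives a rank-deficient basis")
  center <- mean(x)
  scale <- sd(x)
  z <- (x - center) / scale
  boundary <- range(z)
  b <- structure(list(name = name, form = form, transform = transform,
                      center = center, scale = scale, boundary = boundary,
                      range_raw = range(values)),
                 class = "covariate_basis")
  b$columns <- basis_columns(b, z)
  b
}

apply_transform <- function(x, transform) {
  switch(transform, identity = x, log1p = log1p(x))
}

# evaluate basis columns at z-scored values (internal)
basis_columns <- function(basis, z) {
  if (basis$form == "linear") {
    m <- matrix(z, ncol = 1)
    colnames(m) <- basis$name
  } else {
    m <- splines::bs(z, degree = 2, df = 2,
                     Boundary.knots = basis$boundary)
    m <- unname(m[, , drop = FALSE])
    colnames(m) <- paste0(basis$name, "_bs", seq_len(ncol(m)))
  }
  m
}

#' Evaluate a stored basis on new covariate values
#'
#' Values outside the training boundary knots are clipped to the boundary
#' with a warning; `NA` inputs propagate to `NA` rows.
#'
#' @param object A `covariate_basis`.
#' @param newvalues Raw covariate values.
#' @param ... Unused.
#' @return Matrix of basis columns.
#' @export
predict.covariate_basis <- function(object, newvalues, ...) {
  z <- rep(NA_real_, length(newvalues))
  ok <- !is.na(newvalues)
  z[ok] <- (apply_transform(newvalues[ok], object$transform) -
              object$center) / object$scale
  out <- matrix(NA_real_, length(z),
                if (object$form == "linear") 1L else 2L)
  if (any(ok)) {
    zo <- z[ok]
    n_clip <- sum(zo < object$boundary[1] | zo > object$boundary[2])
    if (n_clip > 0 && object$form == "spline2df") {
      warning(n_clip, " value(s) outside the training range of '",
              object$name, "' clipped to the boundary knots")
      zo <- pmin(pmax(zo, object$boundary[1]), object$boundary[2])
    }
    out[ok, ] <- basis_columns(object, zo)
  }
  colnames(out) <- colnames(basis_columns(object, object$boundary))
  out
}

#' @export
print.covariate_basis <- function(x, ...) {
  cat("covariate_basis '", x$name, "': ", x$form, " (", x$transform,
      "), raw range [", format(x$range_raw[1]), ", ",
      format(x$range_raw[2]), "]\n", sep = "")
  invisible(x)
}
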