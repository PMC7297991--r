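#' Orthonormal polynomial age basis
#'
#' Builds scaled-and-centred orthogonal polynomial columns of gestational
#' week (the standard R parameterisation for polynomial growth modelling).
#' Columns are mutually orthogonal with unit norm over the reference weeks,
#' and the basis can be evaluated reproducibly at new weeks, in particular
#' at the 27-week reporting age.
#'
#' @param weeks Numeric vector of gestational weeks the basis is built on.
#' @param degree Polynomial degree, 1 to 4.
#' @return A `poly_basis` object.
#' @export
#' @examples
#' b <- build_poly_basis(c(18, 22, 27, 31, 36), degree = 2)
#' eval_basis(b, 27)
build_poly_basis <- function(weeks, degree) {
  if (!degree %in% 1:4) stop("`degree` must be in 1..4.", call. = FALSE)
  if (length(unique(weeks)) < degree + 1) {
    stop("need at least degree + 1 distinct weeks (",
         length(unique(weeks)), " given for degree ", degree, ").",
         call. = FALSE)
  }
  p <- poly(weeks, degree)
  structure(list(weeks = weeks, degree = degree, poly = p,
                 columns = unclass(p)[, , drop = FALSE]),
            class = "poly_basis")
}

#' @rdname build_poly_basis
#' @param basis A `poly_basis`.
#' @param new_weeks Weeks at which to evaluate the basis columns.
#' @return `eval_basis()` returns a matrix with one column per degree.
#' @export
eval_basis <- function(basis, new_weeks) {
  stopifnot(inherits(basis, "poly_basis"))
  m <- predict(basis$poly, new_weeks)
  matrix(m, nrow = length(new_weeks), ncol = basis$degree,
         dimnames = list(NULL, paste0("w", seq_len(basis$degree))))
}

# Attach basis columns w1..wk (built from the table's own weeks unless a
# basis is supplied) to a per-scan data frame.
add_basis_columns <- function(data, basis) {
  cols <- eval_basis(basis, data$gest_week)
  for (j in seq_len(ncol(cols))) data[[colnames(cols)[j]]] <- cols[, j]
  data
}

#' @export
print.poly_basis <- function(x, ...) {
  cat("<poly_basis> degree", x$degree, "on", length(x$weeks), "weeks in [",
      round(min(x$weeks), 2), ",", round(max(x$weeks), 2), "]\n")
  invisible(x)
}
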