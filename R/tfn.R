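#' Triangular fuzzy numbers
#'
#' A triangular fuzzy number (TFN) is the triple `(a, m, b)` with
#' `a <= m <= b`: membership rises linearly from 0 at `a` to 1 at the modal
#' value `m` and falls back to 0 at `b`. Shoulder TFNs with `a == m` or
#' `m == b` are permitted so that edge terms of a linguistic scale saturate
#' at the domain boundary. TFNs are the currency of all fuzzy arithmetic in
#' the package: pairwise-comparison entries, synthetic extents and aggregated
#' expert judgments are all TFNs.
#'
#' @param a Lower support bound.
#' @param m Modal value.
#' @param b Upper support bound.
#'
#' @return An object of class `"tfn"`: a named numeric vector `c(a, m, b)`.
#' @examples
#' tfn(0.2, 0.4, 0.6)
#' tfn_add(tfn(1, 2, 3), tfn(2, 3, 4))
#' @export
tfn <- function(a, m, b) {
  stopifnot(is.numeric(a), is.numeric(m), is.numeric(b),
            length(a) == 1, length(m) == 1, length(b) == 1)
  if (is.na(a) || is.na(m) || is.na(b)) {
    stop("TFN components must not be NA", call. = FALSE)
  }
  if (a > m + 1e-12 || m > b + 1e-12) {
    stop(sprintf("invalid TFN (%g, %g, %g): requires a <= m <= b", a, m, b),
         call. = FALSE)
  }
  structure(c(a = unname(a), m = unname(m), b = unname(b)), class = "tfn")
}

#' @rdname tfn
#' @param x Object to test or format.
#' @export
is_tfn <- function(x) inherits(x, "tfn")

#' @export
format.tfn <- function(x, ...) {
  sprintf("(%s, %s, %s)", format(x[["a"]], ...), format(x[["m"]], ...),
          format(x[["b"]], ...))
}

#' @export
print.tfn <- function(x, ...) {
  cat("<tfn> ", format(x, digits = 6), "\n", sep = "")
  invisible(x)
}

as_tfn <- function(x) {
  if (is_tfn(x)) return(x)
  if (is.numeric(x) && length(x) == 3) return(tfn(x[[1]], x[[2]], x[[3]]))
  if (is.numeric(x) && length(x) == 1) return(tfn(x, x, x))
  stop("cannot interpret object as a TFN", call. = FALSE)
}

#' TFN arithmetic
#'
#' Componentwise operations on triangular fuzzy numbers: extension-principle
#' addition, scaling by a nonnegative crisp constant, and the fuzzy
#' reciprocal. The reciprocal reverses the bounds, `1/x = (1/b, 1/m, 1/a)`,
#' and requires strictly positive support (comparison intensities are always
#' positive).
#'
#' @param x,y TFNs (see [tfn()]).
#' @param k Nonnegative scalar.
#'
#' @return A TFN.
#' @examples
#' tfn_scale(tfn(1, 2, 3), 2)
#' tfn_invert(tfn(2, 3, 4))
#' @export
tfn_add <- function(x, y) {
  x <- as_tfn(x); y <- as_tfn(y)
  tfn(x[["a"]] + y[["a"]], x[["m"]] + y[["m"]], x[["b"]] + y[["b"]])
}

#' @rdname tfn_add
#' @export
tfn_scale <- function(x, k) {
  x <- as_tfn(x)
  stopifnot(is.numeric(k), length(k) == 1)
  if (k < 0) stop("tfn_scale() requires k >= 0", call. = FALSE)
  tfn(k * x[["a"]], k * x[["m"]], k * x[["b"]])
}

#' @rdname tfn_add
#' @export
tfn_invert <- function(x) {
  x <- as_tfn(x)
  if (x[["a"]] <= 0) {
    stop(sprintf("cannot invert TFN %s: support must be strictly positive",
                 format(x)), call. = FALSE)
  }
  tfn(1 / x[["b"]], 1 / x[["m"]], 1 / x[["a"]])
}

#' Triangular membership function
#'
#' Evaluates the piecewise-linear membership of crisp values `v` in a TFN:
#' 0 outside the support, rising on `(a, m]`, falling on `(m, b)`. For a
#' left-shoulder TFN (`a == m`) membership is 1 at `v == a`; symmetrically
#' for a right shoulder.
#'
#' @param x A TFN.
#' @param v Numeric vector of crisp values.
#'
#' @return Numeric vector of degrees in `[0, 1]`, one per element of `v`.
#' @examples
#' tfn_membership(tfn(0.2, 0.4, 0.6), 0.36120376)
#' @export
tfn_membership <- function(x, v) {
  x <- as_tfn(x)
  stopifnot(is.numeric(v))
  a <- x[["a"]]; m <- x[["m"]]; b <- x[["b"]]
  out <- numeric(length(v))
  left <- if (m > a) (v - a) / (m - a) else as.numeric(v == a)
  right <- if (b > m) (b - v) / (b - m) else as.numeric(v == b)
  out <- ifelse(v <= m, left, right)
  out[v < a | v > b] <- 0
  out[v == m] <- 1
  pmin(1, pmax(0, out))
}

# centroid of a triangle: the alternative defuzzifier offered alongside the
# modal value
tfn_centroid <- function(x) {
  x <- as_tfn(x)
  (x[["a"]] + x[["m"]] + x[["b"]]) / 3
}
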