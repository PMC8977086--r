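#' Fuzzy pairwise-comparison matrices
#'
#' One expert's (or an aggregated panel's) reciprocal matrix of triangular
#' fuzzy comparison intensities over `n >= 2` sibling criteria. Internally
#' three `n x n` numeric matrices hold the lower, modal and upper components;
#' the diagonal is crisp (1, 1, 1) and the lower triangle is the fuzzy
#' reciprocal of the upper.
#'
#' `fuzzy_pairwise_matrix()` builds a matrix from a long tibble of
#' upper-triangle comparisons with columns `row`, `col` and either `label`
#' (a term of `scale`, or an `"a;m;b"` triple) or numeric columns
#' `a`, `m`, `b`. Missing upper-triangle pairs are an error; entries given
#' for both triangle halves must agree with reciprocity.
#'
#' @param comparisons Long tibble of pairwise comparisons.
#' @param labels Character vector of criterion names fixing the order; by
#'   default the order of first appearance in `comparisons`.
#' @param scale Comparison scale used to resolve linguistic labels.
#'
#' @return An object of class `"fpm"`.
#' @examples
#' fuzzy_pairwise_matrix(
#'   tibble::tibble(row = "price", col = "quality", label = "moderate"),
#'   labels = c("price", "quality")
#' )
#' @export
fuzzy_pairwise_matrix <- function(comparisons, labels = NULL,
                                  scale = comparison_scale()) {
  stopifnot(is.data.frame(comparisons),
            all(c("row", "col") %in% names(comparisons)))
  comparisons$row <- normalize_label(comparisons$row)
  comparisons$col <- normalize_label(comparisons$col)
  if (is.null(labels)) {
    labels <- unique(c(rbind(comparisons$row, comparisons$col)))
  } else {
    labels <- normalize_label(labels)
  }
  n <- length(labels)
  if (n < 2) stop("a pairwise matrix needs at least 2 criteria", call. = FALSE)
  unknown <- setdiff(unique(c(comparisons$row, comparisons$col)), labels)
  if (length(unknown)) {
    stop("comparison labels not in criterion set: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  A <- M <- B <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  diag(A) <- diag(M) <- diag(B) <- 1
  for (r in seq_len(nrow(comparisons))) {
    i <- match(comparisons$row[r], labels)
    j <- match(comparisons$col[r], labels)
    if (i == j) {
      stop(sprintf("row %d: diagonal comparison '%s' vs itself not allowed",
                   r, labels[i]), call. = FALSE)
    }
    x <- resolve_entry(comparisons, r, scale)
    if (!is.na(M[i, j]) && !tfn_close(c(A[i, j], M[i, j], B[i, j]), x, 1e-6)) {
      stop(sprintf("row %d: duplicate entry for (%s, %s) disagrees", r,
                   labels[i], labels[j]), call. = FALSE)
    }
    A[i, j] <- x[["a"]]; M[i, j] <- x[["m"]]; B[i, j] <- x[["b"]]
  }
  # fill reciprocals; check any explicitly supplied lower-triangle cells
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    up <- !is.na(M[i, j]); lo <- !is.na(M[j, i])
    if (!up && !lo) {
      stop(sprintf("missing comparison for pair (%s, %s)", labels[i], labels[j]),
           call. = FALSE)
    }
    if (up && lo) {
      inv <- tfn_invert(tfn(A[i, j], M[i, j], B[i, j]))
      if (!tfn_close(c(A[j, i], M[j, i], B[j, i]), inv, 1e-6)) {
        stop(sprintf("reciprocity violated for pair (%s, %s)",
                     labels[i], labels[j]), call. = FALSE)
      }
    } else if (up) {
      inv <- tfn_invert(tfn(A[i, j], M[i, j], B[i, j]))
      A[j, i] <- inv[["a"]]; M[j, i] <- inv[["m"]]; B[j, i] <- inv[["b"]]
    } else {
      inv <- tfn_invert(tfn(A[j, i], M[j, i], B[j, i]))
      A[i, j] <- inv[["a"]]; M[i, j] <- inv[["m"]]; B[i, j] <- inv[["b"]]
    }
  }
  new_fpm(labels, A, M, B)
}

resolve_entry <- function(comparisons, r, scale) {
  if (all(c("a", "m", "b") %in% names(comparisons)) &&
      !is.na(comparisons$m[r])) {
    return(tfn(comparisons$a[r], comparisons$m[r], comparisons$b[r]))
  }
  if (!"label" %in% names(comparisons)) {
    stop(sprintf("row %d: no label and no a/m/b triple", r), call. = FALSE)
  }
  lab <- as.character(comparisons$label[r])
  if (grepl(";", lab, fixed = TRUE)) {
    parts <- suppressWarnings(as.numeric(strsplit(lab, ";", fixed = TRUE)[[1]]))
    if (length(parts) != 3 || anyNA(parts)) {
      stop(sprintf("row %d: malformed triple '%s' (expected 'a;m;b')", r, lab),
           call. = FALSE)
    }
    return(tfn(parts[1], parts[2], parts[3]))
  }
  term_to_tfn(lab, scale)
}

tfn_close <- function(x, y, tol) {
  x <- as.numeric(x); y <- as.numeric(y)
  all(abs(x - y) <= tol * pmax(1, abs(y)))
}

new_fpm <- function(labels, A, M, B) {
  x <- structure(list(labels = labels, a = A, m = M, b = B), class = "fpm")
  validate_fpm(x)
  x
}

validate_fpm <- function(x) {
  n <- length(x$labels)
  if (n < 2) stop("pairwise matrix must have n >= 2", call. = FALSE)
  if (any(x$a <= 0)) stop("pairwise entries must have strictly positive support",
                          call. = FALSE)
  if (any(x$a > x$m + 1e-12) || any(x$m > x$b + 1e-12)) {
    stop("pairwise entries must satisfy a <= m <= b", call. = FALSE)
  }
  if (any(abs(diag(x$a) - 1) > 1e-12) || any(abs(diag(x$m) - 1) > 1e-12) ||
      any(abs(diag(x$b) - 1) > 1e-12)) {
    stop("diagonal entries must be (1, 1, 1)", call. = FALSE)
  }
  # reciprocity: entries[j, i] == 1 / entries[i, j] with bounds swapped
  rel <- function(p, q) abs(p - q) / pmax(1, abs(q))
  bad <- rel(t(x$a), 1 / x$b) > 1e-9 | rel(t(x$m), 1 / x$m) > 1e-9 |
    rel(t(x$b), 1 / x$a) > 1e-9
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("reciprocity violated at (%s, %s)",
                 x$labels[ij[2]], x$labels[ij[1]]), call. = FALSE)
  }
  invisible(x)
}

# direct constructor from component matrices (used by the simulator and the
# aggregator, which guarantee reciprocity by construction)
fpm_from_components <- function(labels, A, M, B) {
  dimnames(A) <- dimnames(M) <- dimnames(B) <- list(labels, labels)
  new_fpm(labels, A, M, B)
}

#' @export
print.fpm <- function(x, ...) {
  cat(sprintf("<fuzzy pairwise matrix> %d criteria: %s\n",
              length(x$labels), paste(x$labels, collapse = ", ")))
  print(tibble::as_tibble(x))
  invisible(x)
}

#' Long-format view of a fuzzy pairwise matrix
#'
#' @param x An `"fpm"`.
#' @param ... Unused.
#'
#' @return A tibble with columns `row`, `col`, `a`, `m`, `b` covering every
#'   cell, lower triangle and diagonal included.
#' @method as_tibble fpm
#' @export
as_tibble.fpm <- function(x, ...) {
  n <- length(x$labels)
  idx <- expand.grid(i = seq_len(n), j = seq_len(n))
  tibble::tibble(
    row = x$labels[idx$i],
    col = x$labels[idx$j],
    a = x$a[cbind(idx$i, idx$j)],
    m = x$m[cbind(idx$i, idx$j)],
    b = x$b[cbind(idx$i, idx$j)]
  )
}

#' Fuzzy synthetic extents
#'
#' The first stage of extent analysis: each criterion's fuzzy row sum is
#' normalized by the fuzzy grand total of the matrix,
#' `S_i = rowsum_i (x) (grand total)^(-1)`, the product taken with the fuzzy
#' reciprocal so that `S_i = (rowsum_i.a / total.b, rowsum_i.m / total.m,
#' rowsum_i.b / total.a)`.
#'
#' @param x An `"fpm"` (see [fuzzy_pairwise_matrix()]).
#'
#' @return A tibble with columns `criterion`, `a`, `m`, `b`.
#' @export
synthetic_extents <- function(x) {
  stopifnot(inherits(x, "fpm"))
  validate_fpm(x)
  ra <- unname(rowSums(x$a)); rm_ <- unname(rowSums(x$m)); rb <- unname(rowSums(x$b))
  tot <- c(sum(ra), sum(rm_), sum(rb))
  tibble::tibble(
    criterion = x$labels,
    a = ra / tot[3],
    m = rm_ / tot[2],
    b = rb / tot[1]
  )
}

#' Degree of possibility that one TFN exceeds another
#'
#' `possibility_degree(s2, s1)` is `V(s2 >= s1)`: 1 when `s2`'s mode is at
#' least `s1`'s, 0 when the supports are ordered the other way
#' (`s1.a >= s2.b`), and otherwise the height of the intersection of the
#' falling edge of `s2` with the rising edge of `s1`,
#' `(s1.a - s2.b) / ((s2.m - s2.b) - (s1.m - s1.a))`.
#'
#' @param s2,s1 TFNs.
#'
#' @return A degree in `[0, 1]`.
#' @examples
#' possibility_degree(tfn(1, 2, 3), tfn(2, 3, 4))
#' @export
possibility_degree <- function(s2, s1) {
  s2 <- as_tfn(s2); s1 <- as_tfn(s1)
  if (s2[["m"]] >= s1[["m"]]) return(1)
  if (s1[["a"]] >= s2[["b"]]) return(0)
  (s1[["a"]] - s2[["b"]]) / ((s2[["m"]] - s2[["b"]]) - (s1[["m"]] - s1[["a"]]))
}

#' Extent-analysis criterion weights
#'
#' Derives crisp criterion weights from a fuzzy pairwise matrix: synthetic
#' extents `S_i` ([synthetic_extents()]), the full matrix of possibility
#' degrees `V(S_i >= S_k)`, the minimum degree `d'(A_i) = min_{k != i}
#' V(S_i >= S_k)`, and the normalized weight vector `w = d' / sum(d')`. All
#' intermediates are retained for audit.
#'
#' Extent analysis is known to assign exact zero weight to criteria whose
#' extents lie entirely below another's support; when that happens a warning
#' is raised. `zero_floor = TRUE` instead substitutes a floor of 1e-6 on the
#' minimum degrees before normalization.
#'
#' @param x An `"fpm"`.
#' @param zero_floor Replace zero minimum degrees by 1e-6 before normalizing.
#'
#' @return An object of class `"extent_analysis"` with elements `labels`,
#'   `extents` (tibble), `possibility` (matrix), `min_degree`, `weights`.
#' @examples
#' m <- fuzzy_pairwise_matrix(
#'   tibble::tibble(row = "x", col = "y", label = "1;2;3"),
#'   labels = c("x", "y")
#' )
#' extent_weights(m)
#' @export
extent_weights <- function(x, zero_floor = FALSE) {
  stopifnot(inherits(x, "fpm"))
  ext <- synthetic_extents(x)
  n <- nrow(ext)
  S <- lapply(seq_len(n), function(i) tfn(ext$a[i], ext$m[i], ext$b[i]))
  V <- matrix(1, n, n, dimnames = list(ext$criterion, ext$criterion))
  for (i in seq_len(n)) for (k in seq_len(n)) {
    if (i != k) V[i, k] <- possibility_degree(S[[i]], S[[k]])
  }
  d <- vapply(seq_len(n), function(i) min(V[i, -i]), numeric(1))
  if (zero_floor) d <- pmax(d, 1e-6)
  if (all(d == 0)) {
    stop("degenerate panel: every minimum possibility degree is 0; cannot normalize",
         call. = FALSE)
  }
  if (any(d == 0)) {
    warning(sprintf(
      "extent analysis assigned zero weight to: %s (known pathology of the method)",
      paste(ext$criterion[d == 0], collapse = ", ")), call. = FALSE)
  }
  structure(list(labels = ext$criterion, extents = ext, possibility = V,
                 min_degree = stats::setNames(d, ext$criterion),
                 weights = stats::setNames(d / sum(d), ext$criterion)),
            class = "extent_analysis")
}

#' @export
print.extent_analysis <- function(x, ...) {
  cat("<extent analysis>\n")
  print(tidy(x))
  invisible(x)
}

#' @method tidy extent_analysis
#' @export
tidy.extent_analysis <- function(x, ...) {
  tibble::tibble(criterion = x$labels,
                 min_degree = unname(x$min_degree),
                 weight = unname(x$weights))
}

#' @method glance extent_analysis
#' @export
glance.extent_analysis <- function(x, ...) {
  tibble::tibble(n_criteria = length(x$labels),
                 n_zero_weights = sum(x$weights == 0))
}

# Saaty random consistency index by matrix order
saaty_ri <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49, 1.51,
              1.48, 1.56, 1.57, 1.59)

# principal eigenvalue of a positive matrix by power iteration
lambda_max_power <- function(C, tol = 1e-12, max_iter = 100000L) {
  n <- nrow(C)
  v <- rep(1 / n, n)
  lam <- 0
  for (it in seq_len(max_iter)) {
    w <- as.numeric(C %*% v)
    lam_new <- sum(w) / sum(v)
    w <- w / sum(w)
    if (abs(lam_new - lam) <= tol * max(1, abs(lam_new)) &&
        max(abs(w - v)) <= tol) {
      return(lam_new)
    }
    v <- w
    lam <- lam_new
  }
  lam
}

#' Consistency ratio on modal values
#'
#' Projects the fuzzy matrix to the crisp matrix of modal values, computes
#' the principal eigenvalue `lambda_max` by power iteration, the consistency
#' index `CI = (lambda_max - n) / (n - 1)` and the consistency ratio
#' `CR = CI / RI(n)` against the Saaty random-index table. Judgments are
#' consistent when `CR < 0.1`. For `n <= 2` a reciprocal matrix is always
#' consistent and `CR = 0` by convention.
#'
#' @param x An `"fpm"`.
#'
#' @return An object of class `"consistency_report"` with fields
#'   `n`, `lambda_max`, `consistency_index`, `random_index`,
#'   `consistency_ratio`, `consistent`.
#' @export
consistency_ratio <- function(x) {
  stopifnot(inherits(x, "fpm"))
  validate_fpm(x)
  n <- length(x$labels)
  if (n > length(saaty_ri)) {
    stop(sprintf("no random index available for n = %d (max %d)", n,
                 length(saaty_ri)), call. = FALSE)
  }
  if (n <= 2) {
    lam <- as.numeric(n)
    ci <- 0; cr <- 0; ri <- saaty_ri[n]
  } else {
    lam <- lambda_max_power(x$m)
    ci <- (lam - n) / (n - 1)
    ri <- saaty_ri[n]
    cr <- ci / ri
  }
  structure(list(n = n, lambda_max = lam, consistency_index = ci,
                 random_index = ri, consistency_ratio = cr,
                 consistent = cr < 0.1),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf(
    "<consistency report> n = %d, lambda_max = %.6f, CI = %.6f, RI = %.2f, CR = %.6f (%s)\n",
    x$n, x$lambda_max, x$consistency_index, x$random_index,
    x$consistency_ratio, if (x$consistent) "consistent" else "inconsistent"))
  invisible(x)
}

#' @method glance consistency_report
#' @export
glance.consistency_report <- function(x, ...) {
  tibble::tibble(n = x$n, lambda_max = x$lambda_max,
                 consistency_index = x$consistency_index,
                 random_index = x$random_index,
                 consistency_ratio = x$consistency_ratio,
                 consistent = x$consistent)
}

#' Aggregate an expert panel's pairwise matrices
#'
#' Geometric-mean consensus: each TFN component `(a, m, b)` of each cell is
#' the geometric mean of that component across experts. Componentwise
#' geometric means preserve reciprocity exactly (the geometric mean of
#' reciprocals is the reciprocal of the geometric mean), which is re-checked
#' on construction.
#'
#' @param matrices List of `"fpm"` objects with identical criterion labels
#'   in identical order.
#'
#' @return A single `"fpm"`.
#' @export
aggregate_matrices <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 1)
  lapply(matrices, function(m) stopifnot(inherits(m, "fpm")))
  labs <- matrices[[1]]$labels
  for (m in matrices[-1]) {
    if (!identical(m$labels, labs)) {
      extra <- setdiff(m$labels, labs); missing <- setdiff(labs, m$labels)
      stop(sprintf(
        "matrices disagree on criteria (extra: %s; missing: %s) or their order",
        paste(extra, collapse = ", "), paste(missing, collapse = ", ")),
        call. = FALSE)
    }
  }
  k <- length(matrices)
  gm <- function(comp) {
    acc <- Reduce(`+`, lapply(matrices, function(m) log(m[[comp]])))
    exp(acc / k)
  }
  fpm_from_components(labs, gm("a"), gm("m"), gm("b"))
}
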