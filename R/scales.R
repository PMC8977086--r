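#' Linguistic scales
#'
#' A linguistic scale maps an ordered set of verbal terms to triangular fuzzy
#' numbers on a common domain. Scales are plain tibbles with columns `term`,
#' `a`, `m`, `b` (one TFN per row, ordered by strictly increasing modal
#' value) plus a `domain` attribute, so they print, filter and join like any
#' other data frame.
#'
#' `linguistic_scale()` validates and constructs a scale from a data frame.
#' Validation checks: non-empty unique labels, valid TFNs, strictly
#' increasing modal values, and coverage (every point of the domain has
#' positive membership in at least one term).
#'
#' @param terms Data frame with columns `term`, `a`, `m`, `b`.
#' @param domain Length-2 numeric, the closed interval the scale covers.
#'
#' @return A tibble of class `"lingscale"`.
#' @seealso [case_scale()], [comparison_scale()]
#' @export
linguistic_scale <- function(terms, domain = c(min(terms$a), max(terms$b))) {
  stopifnot(is.data.frame(terms),
            all(c("term", "a", "m", "b") %in% names(terms)))
  terms <- tibble::as_tibble(terms)[, c("term", "a", "m", "b")]
  terms$term <- normalize_label(terms$term)
  if (any(!nzchar(terms$term))) stop("scale labels must be nonempty", call. = FALSE)
  if (anyDuplicated(terms$term)) {
    stop("scale labels must be unique: ",
         paste(unique(terms$term[duplicated(terms$term)]), collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(terms))) tfn(terms$a[i], terms$m[i], terms$b[i])
  if (nrow(terms) > 1 && any(diff(terms$m) <= 0)) {
    stop("scale terms must have strictly increasing modal values", call. = FALSE)
  }
  stopifnot(is.numeric(domain), length(domain) == 2, domain[1] < domain[2])
  grid <- seq(domain[1], domain[2], length.out = 201)
  covered <- Reduce(`+`, lapply(seq_len(nrow(terms)), function(i) {
    tfn_membership(tfn(terms$a[i], terms$m[i], terms$b[i]), grid)
  }))
  if (any(covered <= 0)) {
    stop("scale does not cover its domain: zero membership at e.g. x = ",
         format(grid[which(covered <= 0)[1]]), call. = FALSE)
  }
  structure(terms, domain = as.numeric(domain),
            class = c("lingscale", class(terms)))
}

normalize_label <- function(x) tolower(trimws(as.character(x)))

#' Default case-judgment scale
#'
#' The six-term scale on `[0, 1]` used for per-factor case judgments and for
#' classifying the model-based diagnosis: none (0, 0, 0.2), low (0, 0.2,
#' 0.4), medium (0.2, 0.4, 0.6), high (0.4, 0.6, 0.8), very_high (0.6, 0.8,
#' 1) and extreme (0.8, 1, 1). It is the evenly spaced triangular Ruspini
#' partition with modal points at multiples of 0.2: memberships of adjacent
#' terms sum to one everywhere on the open unit interval, so fuzzification
#' is an exact linear interpolation between neighbouring terms. The term set
#' is a reconstruction (the study's published scale table is not machine
#' readable); any replacement scale can be passed wherever a scale argument
#' appears.
#'
#' @return A `"lingscale"` tibble with six rows.
#' @examples
#' case_scale()
#' fuzzify(0.36120376, case_scale())
#' @export
case_scale <- function() {
  linguistic_scale(tibble::tibble(
    term = c("none", "low", "medium", "high", "very_high", "extreme"),
    a = c(0, 0, 0.2, 0.4, 0.6, 0.8),
    m = c(0, 0.2, 0.4, 0.6, 0.8, 1),
    b = c(0.2, 0.4, 0.6, 0.8, 1, 1)
  ), domain = c(0, 1))
}

#' Default pairwise-comparison scale
#'
#' Saaty-style fuzzy intensities for pairwise criterion comparisons:
#' intensity `i` in 1..9 maps to the TFN `(max(1, i - 1), i, min(9, i + 1))`,
#' with "equal" = (1, 1, 1) kept crisp as the diagonal convention requires.
#' Reciprocal entries (the lower triangle of a comparison matrix) are the
#' fuzzy reciprocals of these and are not scale terms themselves. Numeric
#' labels "1".."9" are accepted as aliases for the verbal terms.
#'
#' @return A `"lingscale"` tibble with nine rows.
#' @examples
#' comparison_scale()
#' term_to_tfn("equal", comparison_scale())
#' @export
comparison_scale <- function() {
  i <- 1:9
  linguistic_scale(tibble::tibble(
    term = c("equal", "weak_plus", "moderate", "moderate_plus", "strong",
             "strong_plus", "very_strong", "very_very_strong", "extreme"),
    # "equal" stays crisp (1, 1, 1): the AHP diagonal convention
    a = c(1, pmax(1, i[-1] - 1)),
    m = as.numeric(i),
    b = c(1, pmin(9, i[-1] + 1))
  ), domain = c(1, 9))
}

#' Look up a term's TFN
#'
#' Label matching is case-insensitive and whitespace-trimmed (judgment CSVs
#' are hand-entered). On the comparison scale, numeric strings "1".."9" are
#' accepted as intensity aliases.
#'
#' @param label Term label.
#' @param scale A `"lingscale"` (see [linguistic_scale()]).
#'
#' @return A [tfn()].
#' @export
term_to_tfn <- function(label, scale) {
  stopifnot(inherits(scale, "lingscale"), length(label) == 1)
  lab <- normalize_label(label)
  idx <- match(lab, scale$term)
  if (is.na(idx) && grepl("^[1-9]$", lab)) idx <- match(as.integer(lab), round(scale$m))
  if (is.na(idx)) {
    stop(sprintf("unknown term '%s'; scale has: %s", label,
                 paste(scale$term, collapse = ", ")), call. = FALSE)
  }
  tfn(scale$a[idx], scale$m[idx], scale$b[idx])
}

# modal value of each of a vector of labels; the scalar judgment value used
# throughout aggregation and scoring
term_modal <- function(labels, scale) {
  stopifnot(inherits(scale, "lingscale"))
  lab <- normalize_label(labels)
  idx <- match(lab, scale$term)
  if (anyNA(idx)) {
    bad <- unique(labels[is.na(idx)])
    stop(sprintf("unknown term(s): %s; scale has: %s",
                 paste(bad, collapse = ", "),
                 paste(scale$term, collapse = ", ")), call. = FALSE)
  }
  scale$m[idx]
}

#' Fuzzify a crisp value over a linguistic scale
#'
#' Evaluates the membership of `v` in every term of the scale. For a Ruspini
#' partition the degrees sum to one at every interior point of the domain,
#' so the result reads as a soft assignment of the crisp score to the
#' linguistic terms.
#'
#' @param v Crisp value inside the scale domain.
#' @param scale A `"lingscale"`.
#'
#' @return A tibble with columns `term` and `degree`, one row per scale term.
#' @examples
#' fuzzify(0.36120376, case_scale())
#' @export
fuzzify <- function(v, scale) {
  stopifnot(inherits(scale, "lingscale"), is.numeric(v), length(v) == 1)
  dom <- attr(scale, "domain")
  if (v < dom[1] - 1e-12 || v > dom[2] + 1e-12) {
    stop(sprintf("value %g outside scale domain [%g, %g]", v, dom[1], dom[2]),
         call. = FALSE)
  }
  v <- min(max(v, dom[1]), dom[2])
  tibble::tibble(
    term = scale$term,
    degree = vapply(seq_len(nrow(scale)), function(i) {
      tfn_membership(tfn(scale$a[i], scale$m[i], scale$b[i]), v)
    }, numeric(1))
  )
}

#' Plot the membership functions of a linguistic scale
#'
#' @param object A `"lingscale"`.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @method autoplot lingscale
#' @export
autoplot.lingscale <- function(object, ...) {
  dom <- attr(object, "domain")
  grid <- seq(dom[1], dom[2], length.out = 401)
  df <- purrr::map_dfr(seq_len(nrow(object)), function(i) {
    tibble::tibble(
      term = factor(object$term[i], levels = object$term),
      x = grid,
      membership = tfn_membership(tfn(object$a[i], object$m[i], object$b[i]), grid)
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$membership, colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "value", y = "membership", colour = "term") +
    ggplot2::theme_minimal()
}
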