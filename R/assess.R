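#' Aggregate a panel's case judgments
#'
#' For each case and factor, the experts' linguistic labels are mapped to
#' scalar judgment values (the label's modal value on `scale`) and combined
#' into the consensus TFN `e_agg = (min, geometric mean, max)`: the lower
#' bound is the most lenient judgment, the upper bound the most severe, and
#' the mode the panel's geometric-mean consensus. The defuzzified `degree`
#' that enters the risk score is `e_agg`'s mode by default, or its centroid
#' when `defuzz = "centroid"`.
#'
#' A "none" judgment has modal value 0 and would annihilate the geometric
#' mean of an otherwise non-zero panel; zero values are clamped to 1e-6 with
#' a warning.
#'
#' @param judgments Tibble with columns `case_id`, `expert_id`, `factor`,
#'   `label` (one row per expert and factor).
#' @param scale Case judgment scale (default [case_scale()]).
#' @param defuzz `"modal"` (default) or `"centroid"`.
#'
#' @return A tibble with columns `case_id`, `factor`, `a`, `m`, `b`,
#'   `degree`.
#' @examples
#' judgments <- tibble::tibble(
#'   case_id = "w1", expert_id = c("e1", "e2", "e3"),
#'   factor = "smoking", label = c("low", "medium", "very_high")
#' )
#' aggregate_case(judgments)
#' @export
aggregate_case <- function(judgments, scale = case_scale(),
                           defuzz = c("modal", "centroid")) {
  defuzz <- match.arg(defuzz)
  stopifnot(is.data.frame(judgments),
            all(c("case_id", "expert_id", "factor", "label") %in%
                  names(judgments)))
  if (nrow(judgments) == 0) stop("no judgments supplied", call. = FALSE)
  j <- tibble::as_tibble(judgments)
  j$case_id <- as.character(j$case_id)
  j$expert_id <- as.character(j$expert_id)
  j$factor <- normalize_label(j$factor)
  j$value <- term_modal(j$label, scale)
  if (any(j$value == 0)) {
    warning(
      "zero judgment values ('none') clamped to 1e-6 to keep the geometric mean finite",
      call. = FALSE)
    j$value <- pmax(j$value, 1e-6)
  }
  dup <- dplyr::count(j, .data$case_id, .data$expert_id, .data$factor)
  if (any(dup$n > 1)) {
    d <- dup[dup$n > 1, ][1, ]
    stop(sprintf("expert '%s' judged factor '%s' of case '%s' more than once",
                 d$expert_id, d$factor, d$case_id), call. = FALSE)
  }
  out <- dplyr::summarise(
    dplyr::group_by(j, .data$case_id, .data$factor),
    a = min(.data$value),
    m = exp(mean(log(.data$value))),
    b = max(.data$value),
    .groups = "drop"
  )
  out$degree <- if (defuzz == "modal") out$m else (out$a + out$m + out$b) / 3
  out
}

#' Model-based diagnosis score
#'
#' The MBD for one case is the doubly weighted sum of the per-factor
#' judgment degrees over the hierarchy,
#' `MBD = sum_j w_j * sum_i w_ij * degree_ij`,
#' where `w_j` is the dimension weight and `w_ij` the factor's local weight
#' — equivalently the sum of `global_weight * degree` over factors. With
#' normalized weights and degrees in `[0, 1]` the score is a convex
#' combination of the degrees, hence itself in `[0, 1]`.
#'
#' @param hierarchy A `"risk_hierarchy"`.
#' @param degrees Tibble with columns `factor` and `degree`, covering every
#'   factor of the hierarchy exactly once (extra factors are an error).
#'
#' @return A single number in `[0, 1]`.
#' @examples
#' h <- preterm_hierarchy()
#' mbd_score(h, tibble::tibble(factor = h$factor, degree = 0.4))
#' @export
mbd_score <- function(hierarchy, degrees) {
  stopifnot(inherits(hierarchy, "risk_hierarchy"), is.data.frame(degrees),
            all(c("factor", "degree") %in% names(degrees)))
  d <- tibble::as_tibble(degrees)
  d$factor <- normalize_label(d$factor)
  if (anyDuplicated(d$factor)) {
    stop("duplicate degree for factor(s): ",
         paste(unique(d$factor[duplicated(d$factor)]), collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(hierarchy$factor, d$factor)
  if (length(missing)) {
    stop("missing degree for factor(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(d$factor, hierarchy$factor)
  if (length(extra)) {
    stop("degrees supplied for unknown factor(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  if (any(d$degree < -1e-12 | d$degree > 1 + 1e-12)) {
    stop("degrees must lie in [0, 1]", call. = FALSE)
  }
  idx <- match(hierarchy$factor, d$factor)
  sum(hierarchy$global_weight * d$degree[idx])
}

#' Classify a diagnosis score linguistically
#'
#' Fuzzifies the crisp MBD over the case scale and reports the term with
#' maximal membership as the diagnosis. Ties are broken toward the
#' higher-risk (later) term — the clinically conservative choice.
#'
#' @param mbd Score in `[0, 1]`.
#' @param scale Case scale.
#'
#' @return A list with `fuzzified` (tibble `term`, `degree`) and `diagnosis`
#'   (character).
#' @examples
#' classify_mbd(0.36120376)
#' @export
classify_mbd <- function(mbd, scale = case_scale()) {
  stopifnot(is.numeric(mbd), length(mbd) == 1, mbd >= -1e-12, mbd <= 1 + 1e-12)
  fz <- fuzzify(mbd, scale)
  best <- max(fz$degree)
  diagnosis <- fz$term[max(which(fz$degree == best))]
  list(fuzzified = fz, diagnosis = diagnosis)
}

#' Assess cases end to end
#'
#' Composes [aggregate_case()], [mbd_score()] and [classify_mbd()] for every
#' case in a judgment table: per-factor geometric-mean consensus, the
#' weighted MBD score, its fuzzified membership profile and the linguistic
#' diagnosis. Per-factor aggregated judgments are retained in the
#' `"aggregates"` attribute for audit.
#'
#' @inheritParams aggregate_case
#' @param hierarchy A `"risk_hierarchy"`; judgments must cover exactly its
#'   factors for every case.
#'
#' @return A tibble of class `"case_assessments"`: one row per case with
#'   columns `case_id`, `mbd`, `diagnosis`, then one degree column per scale
#'   term.
#' @examples
#' h <- preterm_hierarchy()
#' j <- tidyr::expand_grid(case_id = "w1", expert_id = "e1",
#'                         factor = h$factor)
#' j$label <- "medium"
#' assess_cases(j, h)
#' @export
assess_cases <- function(judgments, hierarchy, scale = case_scale(),
                         defuzz = c("modal", "centroid")) {
  defuzz <- match.arg(defuzz)
  agg <- aggregate_case(judgments, scale = scale, defuzz = defuzz)
  per_case <- split(agg, agg$case_id)
  rows <- purrr::map_dfr(per_case, function(g) {
    score <- mbd_score(hierarchy, g[, c("factor", "degree")])
    cls <- classify_mbd(score, scale)
    deg <- stats::setNames(as.list(cls$fuzzified$degree), cls$fuzzified$term)
    tibble::tibble(case_id = g$case_id[1], mbd = score,
                   diagnosis = cls$diagnosis, !!!deg)
  })
  # keep the input's case order (split() sorts)
  rows <- rows[match(unique(normalize_id(judgments$case_id)), rows$case_id), ]
  structure(rows, aggregates = agg,
            class = c("case_assessments", class(rows)))
}

normalize_id <- function(x) as.character(x)

#' Rank assessed cases by risk
#'
#' Orders assessments by decreasing MBD; ties keep their input order, so the
#' ranking is stable.
#'
#' @param assessments Tibble with columns `case_id` and `mbd`, e.g. from
#'   [assess_cases()].
#'
#' @return The same tibble reordered, with a `rank` column prepended
#'   (ties share the smallest applicable rank).
#' @export
rank_cases <- function(assessments) {
  stopifnot(is.data.frame(assessments),
            all(c("case_id", "mbd") %in% names(assessments)))
  if (nrow(assessments) == 0) stop("no assessments to rank", call. = FALSE)
  ord <- order(-assessments$mbd)  # stable in R
  out <- tibble::as_tibble(assessments)[ord, ]
  out <- dplyr::bind_cols(
    tibble::tibble(rank = as.integer(rank(-out$mbd, ties.method = "min"))),
    out)
  out
}

#' Plot assessed cases
#'
#' Histogram of MBD scores coloured by linguistic diagnosis.
#'
#' @param object A `"case_assessments"` tibble.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @method autoplot case_assessments
#' @export
autoplot.case_assessments <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$mbd, fill = .data$diagnosis)) +
    ggplot2::geom_histogram(binwidth = 0.025, boundary = 0) +
    ggplot2::labs(x = "model-based diagnosis score", y = "cases",
                  fill = "diagnosis") +
    ggplot2::theme_minimal()
}
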