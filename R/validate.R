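#' Aggregated expert reference score for each case
#'
#' From a judgment table containing a distinguished overall-diagnosis factor
#' (default label `"overall"`), aggregates each case's overall judgments
#' with the same `(min, geometric mean, max)` consensus used for factor
#' judgments and returns the modal (geometric-mean) value as the expert
#' reference score.
#'
#' @param judgments Tibble with columns `case_id`, `expert_id`, `factor`,
#'   `label`, containing rows with `factor == overall` for every case.
#' @param scale Case judgment scale.
#' @param overall Name of the overall-diagnosis factor.
#'
#' @return A tibble with columns `case_id`, `expert_score`, `expert_label`
#'   (the scale term with modal value nearest the score, ties toward the
#'   higher-risk term).
#' @export
expert_reference_score <- function(judgments, scale = case_scale(),
                                   overall = "overall") {
  stopifnot(is.data.frame(judgments))
  j <- tibble::as_tibble(judgments)
  j$factor <- normalize_label(j$factor)
  j <- j[j$factor == normalize_label(overall), ]
  if (nrow(j) == 0) {
    stop(sprintf("no '%s' judgments found; the validation protocol needs per-case overall diagnoses",
                 overall), call. = FALSE)
  }
  agg <- aggregate_case(j, scale = scale)
  lab <- vapply(agg$degree, function(v) {
    d <- abs(scale$m - v)
    scale$term[max(which(d == min(d)))]
  }, character(1))
  tibble::tibble(case_id = agg$case_id, expert_score = agg$degree,
                 expert_label = lab)
}

# paired t statistic with the degenerate branches spelled out; the happy
# path delegates to stats::t.test
paired_t <- function(expert, model) {
  if (length(expert) != length(model)) {
    stop(sprintf("score lists differ in length (%d vs %d)",
                 length(expert), length(model)), call. = FALSE)
  }
  n <- length(expert)
  if (n < 2) stop("paired t-test needs at least 2 cases", call. = FALSE)
  d <- expert - model
  # sd on a numerically constant vector can be a rounding-noise positive
  if (stats::sd(d) <= 1e-12 * max(1, abs(mean(d)))) {
    if (abs(mean(d)) <= 1e-12) {
      return(list(t = 0, df = n - 1L, p = 1))
    }
    # constant nonzero difference: the statistic diverges
    return(list(t = sign(mean(d)) * Inf, df = n - 1L, p = 0))
  }
  tt <- stats::t.test(expert, model, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Paired t-test between expert and model scores
#'
#' Two-sided paired Student t-test on per-case score differences
#' `d_i = expert_i - model_i`: `t = mean(d) / (sd(d) / sqrt(n))` with the
#' sample standard deviation (`n - 1` denominator) and `n - 1` degrees of
#' freedom. Degenerate branches: identically zero differences give `t = 0`,
#' `p = 1`; a constant nonzero difference gives a divergent statistic,
#' reported as `p = 0` (discordant). Concordance is declared when
#' `p >= alpha`.
#'
#' @param expert_scores,model_scores Equal-length numeric score vectors.
#' @param alpha Significance level for the concordance call.
#'
#' @return A `"validation_report"` (score-level fields only; label fields
#'   are `NA` since no linguistic judgments are involved).
#' @examples
#' paired_t_test(c(0.4, 0.5, 0.6), c(0.38, 0.55, 0.58))
#' @export
paired_t_test <- function(expert_scores, model_scores, alpha = 0.05) {
  stopifnot(is.numeric(expert_scores), is.numeric(model_scores))
  tt <- paired_t(expert_scores, model_scores)
  structure(list(
    per_case = tibble::tibble(
      case_id = as.character(seq_along(expert_scores)),
      expert_score = expert_scores, model_score = model_scores,
      expert_label = NA_character_, model_label = NA_character_,
      labels_agree = NA),
    n_cases = length(expert_scores),
    mean_difference = mean(expert_scores - model_scores),
    t_statistic = tt$t,
    degrees_of_freedom = tt$df,
    p_value = tt$p,
    concordant = tt$p >= alpha,
    label_agreement = NA_real_
  ), class = "validation_report")
}

#' Validate model scores against aggregated expert diagnoses
#'
#' The three-step validation protocol: (1) aggregate the experts' overall
#' diagnoses per case into a reference score ([expert_reference_score()]);
#' (2) score the same cases with the fuzzy model ([assess_cases()] on the
#' per-factor judgments); (3) run a two-sided paired t-test on the per-case
#' differences. The model is declared concordant with the panel when
#' `p >= 0.05` — i.e. no statistically significant difference between
#' expert and model scores at the 5% level. Label-level agreement (model
#' diagnosis term vs the term nearest the expert score) is reported
#' alongside, since a score-level test can mask categorical disagreement.
#'
#' @param judgments Tibble with columns `case_id`, `expert_id`, `factor`,
#'   `label`, containing both the hierarchy's factors and an
#'   overall-diagnosis factor for every case.
#' @param hierarchy A `"risk_hierarchy"`.
#' @param scale Case judgment scale.
#' @param overall Name of the overall-diagnosis factor.
#' @param alpha Significance level for the concordance call.
#'
#' @return An object of class `"validation_report"`: list with `per_case`
#'   (tibble: `case_id`, `expert_score`, `model_score`, `expert_label`,
#'   `model_label`, `labels_agree`), `n_cases`, `mean_difference`,
#'   `t_statistic`, `degrees_of_freedom`, `p_value`, `concordant`,
#'   `label_agreement`.
#' @examples
#' h <- preterm_hierarchy()
#' j <- simulate_cases(20, h, n_experts = 7, seed = 42)
#' validate_model(j, h)
#' @export
validate_model <- function(judgments, hierarchy, scale = case_scale(),
                           overall = "overall", alpha = 0.05) {
  stopifnot(inherits(hierarchy, "risk_hierarchy"))
  j <- tibble::as_tibble(judgments)
  j$factor <- normalize_label(j$factor)
  ref <- expert_reference_score(j, scale = scale, overall = overall)
  asm <- assess_cases(j[j$factor != normalize_label(overall), ], hierarchy,
                      scale = scale)
  per_case <- dplyr::inner_join(
    ref,
    tibble::tibble(case_id = asm$case_id, model_score = asm$mbd,
                   model_label = asm$diagnosis),
    by = "case_id")
  if (nrow(per_case) < nrow(ref) || nrow(per_case) < nrow(asm)) {
    stop("cases with overall judgments and cases with factor judgments do not match",
         call. = FALSE)
  }
  per_case$labels_agree <- per_case$expert_label == per_case$model_label
  tt <- paired_t(per_case$expert_score, per_case$model_score)
  structure(list(
    per_case = per_case[, c("case_id", "expert_score", "model_score",
                            "expert_label", "model_label", "labels_agree")],
    n_cases = nrow(per_case),
    mean_difference = mean(per_case$expert_score - per_case$model_score),
    t_statistic = tt$t,
    degrees_of_freedom = tt$df,
    p_value = tt$p,
    concordant = tt$p >= alpha,
    label_agreement = mean(per_case$labels_agree)
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation report> %d cases: mean diff = %.6g, t(%d) = %.4g, p = %.4g -> %s; label agreement %.1f%%\n",
    x$n_cases, x$mean_difference, x$degrees_of_freedom, x$t_statistic,
    x$p_value, if (x$concordant) "concordant" else "discordant",
    if (is.na(x$label_agreement)) NA_real_ else 100 * x$label_agreement))
  invisible(x)
}

#' @method tidy validation_report
#' @export
tidy.validation_report <- function(x, ...) x$per_case

#' @method glance validation_report
#' @export
glance.validation_report <- function(x, ...) {
  tibble::tibble(n_cases = x$n_cases, mean_difference = x$mean_difference,
                 t_statistic = x$t_statistic,
                 degrees_of_freedom = x$degrees_of_freedom,
                 p_value = x$p_value, concordant = x$concordant,
                 label_agreement = x$label_agreement)
}

#' Plot expert versus model scores
#'
#' @param object A `"validation_report"`.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @method autoplot validation_report
#' @export
autoplot.validation_report <- function(object, ...) {
  ggplot2::ggplot(object$per_case,
                  ggplot2::aes(.data$expert_score, .data$model_score,
                               colour = .data$labels_agree)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "expert aggregated score", y = "model-based diagnosis",
                  colour = "labels agree") +
    ggplot2::theme_minimal()
}
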