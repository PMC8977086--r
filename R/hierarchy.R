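#' Risk hierarchies
#'
#' A risk hierarchy is goal -> risk dimensions -> risk factors, with a
#' weight at each level: `dim_weight` is the dimension's weight with respect
#' to the goal, `local_weight` the factor's weight within its dimension, and
#' `global_weight = dim_weight * local_weight` the factor's share of the
#' final score. A hierarchy is stored as a tidy tibble with one row per
#' factor and a `goal` attribute.
#'
#' `risk_hierarchy()` validates a tibble of weights directly (fixture mode);
#' [build_hierarchy()] derives the weights from fuzzy pairwise matrices
#' (panel mode). Dimension weights must sum to 1 within `tol` and factor
#' local weights must sum to 1 within `tol` inside every dimension; the
#' default `tol = 0.01` accommodates published rounding of weight tables.
#'
#' @param factors Tibble with columns `dimension`, `dim_weight`, `factor`,
#'   `local_weight`.
#' @param goal Short description of the decision goal.
#' @param tol Tolerance on each level's weight sums.
#'
#' @return A tibble of class `"risk_hierarchy"` with the columns above plus
#'   `global_weight`.
#' @examples
#' preterm_hierarchy()
#' @export
risk_hierarchy <- function(factors, goal = "risk", tol = 0.01) {
  stopifnot(is.data.frame(factors),
            all(c("dimension", "dim_weight", "factor", "local_weight") %in%
                  names(factors)))
  h <- tibble::as_tibble(factors)
  h$dimension <- normalize_label(h$dimension)
  h$factor <- normalize_label(h$factor)
  if (anyDuplicated(h$factor)) {
    stop("factor names must be unique across the hierarchy: ",
         paste(unique(h$factor[duplicated(h$factor)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(h$dim_weight < 0) || any(h$local_weight < 0)) {
    stop("weights must be nonnegative", call. = FALSE)
  }
  dims <- dplyr::distinct(h, .data$dimension, .data$dim_weight)
  if (anyDuplicated(dims$dimension)) {
    stop("a dimension appears with two different weights", call. = FALSE)
  }
  s <- sum(dims$dim_weight)
  if (abs(s - 1) > tol) {
    stop(sprintf("dimension weights sum to %.6f, not 1 (tolerance %.3g)", s, tol),
         call. = FALSE)
  }
  loc <- dplyr::summarise(dplyr::group_by(h, .data$dimension),
                          s = sum(.data$local_weight), .groups = "drop")
  bad <- loc[abs(loc$s - 1) > tol, ]
  if (nrow(bad)) {
    stop(sprintf("local weights in dimension '%s' sum to %.6f, not 1",
                 bad$dimension[1], bad$s[1]), call. = FALSE)
  }
  h$global_weight <- h$dim_weight * h$local_weight
  structure(h[, c("dimension", "dim_weight", "factor", "local_weight",
                  "global_weight")],
            goal = goal, class = c("risk_hierarchy", class(h)))
}

#' Derive a hierarchy from expert pairwise matrices
#'
#' Runs [extent_weights()] on the dimension-level matrix and on each
#' dimension's factor matrix, after checking every matrix for judgment
#' consistency ([consistency_ratio()], `CR < 0.1`). Inconsistent matrices
#' are an error unless `force = TRUE`. All extent-analysis intermediates and
#' consistency reports are attached for audit.
#'
#' @param dimension_matrix `"fpm"` comparing the risk dimensions.
#' @param factor_matrices Named list of `"fpm"`s, one per dimension label.
#' @param goal Decision goal description.
#' @param force Proceed despite `CR >= 0.1`.
#' @param zero_floor Passed to [extent_weights()].
#'
#' @return A `"risk_hierarchy"` tibble with attributes `extent` (named list
#'   of `"extent_analysis"` objects, `"goal"` plus one per dimension) and
#'   `consistency` (named list of `"consistency_report"`s).
#' @export
build_hierarchy <- function(dimension_matrix, factor_matrices,
                            goal = "preterm birth risk", force = FALSE,
                            zero_floor = FALSE) {
  stopifnot(inherits(dimension_matrix, "fpm"), is.list(factor_matrices))
  dims <- dimension_matrix$labels
  names(factor_matrices) <- normalize_label(names(factor_matrices))
  missing <- setdiff(dims, names(factor_matrices))
  if (length(missing)) {
    stop("missing factor matrix for dimension(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(factor_matrices), dims)
  if (length(extra)) {
    stop("factor matrices supplied for unknown dimension(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  }

  mats <- c(list(goal = dimension_matrix), factor_matrices[dims])
  reports <- lapply(mats, consistency_ratio)
  bad <- names(reports)[!vapply(reports, `[[`, logical(1), "consistent")]
  if (length(bad) && !force) {
    stop(sprintf(
      "pairwise matrix for %s has CR >= 0.1; judgments are consistent only if CR < 0.1 (use force = TRUE to override)",
      paste(bad, collapse = ", ")), call. = FALSE)
  }

  extents <- lapply(mats, extent_weights, zero_floor = zero_floor)
  dw <- extents$goal$weights
  h <- purrr::map_dfr(dims, function(d) {
    ew <- extents[[d]]
    tibble::tibble(dimension = d, dim_weight = unname(dw[d]),
                   factor = ew$labels, local_weight = unname(ew$weights))
  })
  out <- risk_hierarchy(h, goal = goal)
  attr(out, "extent") <- extents
  attr(out, "consistency") <- reports
  out
}

#' The published preterm-birth hierarchy fixture
#'
#' The six risk dimensions of the preterm-birth evaluation model with their
#' reported FAHP weights: information during pregnancy (IDP, 0.339), medical
#' history of previous pregnancies (MHPP, 0.306), clinical medical history
#' (CMH, 0.166), gynecological and obstetric history (GOH, 0.1342),
#' behavioural / mother's lifestyle (BML, 0.042) and socio/personal/economic
#' (SPE, 0.0115). The printed weights sum to 0.9987; they are kept as
#' printed rather than renormalized.
#'
#' Factor names are those attested in the study narrative (e.g. early
#' rupture of the amniotic sac, fetal fibronectin, early gestational age,
#' stillbirth, diabetes, chronic blood pressure, cardiovascular disease,
#' substance use, alcohol, smoking, late booking, maternal age, education
#' level, marital status). Per-factor weights were not published in
#' machine-readable form, so the fixture ships *reconstructed uniform* local
#' weights within each dimension; supply your own `local_weight` column (or
#' pairwise matrices via [build_hierarchy()]) to replace them.
#'
#' @return A `"risk_hierarchy"` tibble (17 factors across 6 dimensions).
#' @examples
#' preterm_hierarchy() |> dplyr::distinct(dimension, dim_weight)
#' @export
preterm_hierarchy <- function() {
  dims <- tibble::tibble(
    dimension = c("idp", "mhpp", "cmh", "goh", "bml", "spe"),
    dim_weight = c(0.339, 0.306, 0.166, 0.1342, 0.042, 0.0115)
  )
  facs <- list(
    idp  = c("early_rupture_of_amniotic_sac", "fetal_fibronectin"),
    mhpp = c("early_gestational_age", "stillbirth"),
    cmh  = c("type_1_2_diabetes", "chronic_blood_pressure",
             "cardiovascular_disease"),
    goh  = c("gynecological_obstetric_1", "gynecological_obstetric_2",
             "gynecological_obstetric_3"),
    bml  = c("substance_use", "alcohol", "smoking"),
    spe  = c("late_booking", "maternal_age", "education_level",
             "marital_status")
  )
  h <- purrr::map_dfr(seq_len(nrow(dims)), function(i) {
    f <- facs[[dims$dimension[i]]]
    tibble::tibble(dimension = dims$dimension[i],
                   dim_weight = dims$dim_weight[i],
                   factor = f,
                   local_weight = 1 / length(f))
  })
  risk_hierarchy(h, goal = "preterm birth risk")
}

#' @method tidy risk_hierarchy
#' @export
tidy.risk_hierarchy <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("dimension", "dim_weight", "factor",
                                 "local_weight", "global_weight")])
}

#' @method glance risk_hierarchy
#' @export
glance.risk_hierarchy <- function(x, ...) {
  tibble::tibble(
    goal = attr(x, "goal"),
    n_dimensions = dplyr::n_distinct(x$dimension),
    n_factors = nrow(x),
    dim_weight_sum = sum(dplyr::distinct(
      tibble::as_tibble(x), .data$dimension, .data$dim_weight)$dim_weight),
    global_weight_sum = sum(x$global_weight)
  )
}

#' Plot hierarchy weights
#'
#' Bar chart of global factor weights grouped by dimension.
#'
#' @param object A `"risk_hierarchy"`.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @method autoplot risk_hierarchy
#' @export
autoplot.risk_hierarchy <- function(object, ...) {
  df <- tidy(object)
  df$factor <- stats::reorder(df$factor, df$global_weight)
  ggplot2::ggplot(df, ggplot2::aes(.data$global_weight, .data$factor,
                                   fill = .data$dimension)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "global weight", y = NULL, fill = "dimension",
                  title = attr(object, "goal")) +
    ggplot2::theme_minimal()
}
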