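#' Read and write pairwise-comparison matrix CSVs
#'
#' Long-format CSV with header `row_label,col_label,term_or_triple`: one row
#' per comparison, the cell either a linguistic label of the comparison
#' scale or an explicit `a;m;b` triple. The upper triangle is required; the
#' lower triangle is derived by fuzzy reciprocity, and supplying both halves
#' triggers a reciprocity check. Malformed rows are reported with their row
#' number.
#'
#' @param path CSV file path.
#' @param scale Comparison scale for resolving labels.
#' @param labels Optional criterion order (defaults to order of appearance).
#'
#' @return An `"fpm"` (reader) / `path`, invisibly (writer).
#' @export
read_matrix_csv <- function(path, scale = comparison_scale(), labels = NULL) {
  df <- read_checked_csv(path, c("row_label", "col_label", "term_or_triple"))
  fuzzy_pairwise_matrix(
    tibble::tibble(row = df$row_label, col = df$col_label,
                   label = df$term_or_triple),
    labels = labels, scale = scale)
}

#' @rdname read_matrix_csv
#' @param x An `"fpm"` to serialize (upper triangle, explicit triples at
#'   full precision).
#' @export
write_matrix_csv <- function(x, path) {
  stopifnot(inherits(x, "fpm"))
  n <- length(x$labels)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  df <- tibble::tibble(
    row_label = x$labels[ij[, 1]],
    col_label = x$labels[ij[, 2]],
    term_or_triple = sprintf("%.17g;%.17g;%.17g",
                             x$a[ij], x$m[ij], x$b[ij])
  )
  readr::write_csv(df, path)
  invisible(path)
}

#' Read and write case-judgment CSVs
#'
#' Header `case_id,expert_id,factor,label`, one row per expert, case and
#' factor. Labels are validated against `scale` lazily by the consumers
#' ([aggregate_case()] etc.); the reader checks structure and non-emptiness.
#'
#' @param path CSV file path.
#'
#' @return A tibble (reader) / `path`, invisibly (writer).
#' @export
read_cases_csv <- function(path) {
  df <- read_checked_csv(path, c("case_id", "expert_id", "factor", "label"))
  tibble::as_tibble(df)
}

#' @rdname read_cases_csv
#' @param judgments Judgment tibble to serialize.
#' @export
write_cases_csv <- function(judgments, path) {
  stopifnot(is.data.frame(judgments),
            all(c("case_id", "expert_id", "factor", "label") %in%
                  names(judgments)))
  readr::write_csv(
    tibble::as_tibble(judgments)[, c("case_id", "expert_id", "factor", "label")],
    path)
  invisible(path)
}

read_checked_csv <- function(path, cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0) stop(path, ": no data rows", call. = FALSE)
  incomplete <- which(!stats::complete.cases(df[, cols]))
  if (length(incomplete)) {
    stop(sprintf("%s: malformed row %d (empty field)", path, incomplete[1]),
         call. = FALSE)
  }
  df
}

#' Read and write hierarchy configuration files
#'
#' JSON configuration with the decision goal, the linguistic scales and the
#' dimension/factor tree. Weights may be given directly (fixture mode) or
#' omitted when they are to be derived from pairwise matrices. The reader
#' validates the schema and the weight sums and reports the offending field
#' on failure; write-then-read round-trips any valid hierarchy.
#'
#' @param path JSON file path.
#'
#' @return `read_hierarchy_json()`: a list with elements `hierarchy` (a
#'   `"risk_hierarchy"`, or `NULL` when the config carries no weights),
#'   `tree` (tibble `dimension`/`factor`), and `scales` (named list of
#'   `"lingscale"`). `write_hierarchy_json()`: `path`, invisibly.
#' @export
read_hierarchy_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (field in c("goal", "dimensions")) {
    if (is.null(cfg[[field]])) {
      stop(sprintf("%s: missing required field '%s'", path, field),
           call. = FALSE)
    }
  }
  dims <- cfg$dimensions
  if (!is.data.frame(dims) || !all(c("name", "factors") %in% names(dims))) {
    stop(path, ": 'dimensions' must be an array of {name, weight?, factors}",
         call. = FALSE)
  }
  rows <- purrr::map_dfr(seq_len(nrow(dims)), function(i) {
    f <- dims$factors[[i]]
    if (!is.data.frame(f) || !"name" %in% names(f)) {
      stop(sprintf("%s: dimension '%s': 'factors' must be an array of {name, weight?}",
                   path, dims$name[i]), call. = FALSE)
    }
    tibble::tibble(
      dimension = dims$name[i],
      dim_weight = if ("weight" %in% names(dims)) dims$weight[i] else NA_real_,
      factor = f$name,
      local_weight = if ("weight" %in% names(f)) f$weight else NA_real_
    )
  })
  scales <- lapply(cfg$scales, function(s) {
    linguistic_scale(tibble::as_tibble(s[c("label", "a", "m", "b")]) |>
                       dplyr::rename(term = "label"),
                     domain = if (!is.null(attr(s, "domain"))) attr(s, "domain")
                              else c(min(s$a), max(s$b)))
  })
  hierarchy <- NULL
  if (!anyNA(rows$dim_weight) && !anyNA(rows$local_weight)) {
    hierarchy <- risk_hierarchy(rows, goal = cfg$goal)
  }
  list(hierarchy = hierarchy,
       tree = rows[, c("dimension", "factor")],
       scales = scales)
}

#' @rdname read_hierarchy_json
#' @param hierarchy A `"risk_hierarchy"`.
#' @param scales Named list of `"lingscale"` objects to embed.
#' @export
write_hierarchy_json <- function(hierarchy, path,
                                 scales = list(case = case_scale(),
                                               comparison = comparison_scale())) {
  stopifnot(inherits(hierarchy, "risk_hierarchy"))
  h <- tidy(hierarchy)
  dims <- dplyr::distinct(h, .data$dimension, .data$dim_weight)
  cfg <- list(
    goal = attr(hierarchy, "goal"),
    scales = lapply(scales, function(s) {
      tibble::tibble(label = s$term, a = s$a, m = s$m, b = s$b)
    }),
    dimensions = lapply(seq_len(nrow(dims)), function(i) {
      f <- h[h$dimension == dims$dimension[i], ]
      list(name = dims$dimension[i], weight = dims$dim_weight[i],
           factors = lapply(seq_len(nrow(f)), function(r) {
             list(name = f$factor[r], weight = f$local_weight[r])
           }))
    })
  )
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
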