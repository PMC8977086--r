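all_equal_fpm_named <- function(labs) {
  rows <- expand.grid(i = seq_along(labs), j = seq_along(labs))
  rows <- rows[rows$i < rows$j, ]
  fuzzy_pairwise_matrix(
    tibble::tibble(row = labs[rows$i], col = labs[rows$j], label = "equal"),
    labels = labs)
}

test_that("hierarchy validation enforces weight sums and uniqueness", {
  ok <- tibble::tibble(
    dimension = rep(c("d1", "d2"), each = 2),
    dim_weight = rep(c(0.6, 0.4), each = 2),
    factor = c("f1", "f2", "f3", "f4"),
    local_weight = c(0.5, 0.5, 0.3, 0.7))
  h <- risk_hierarchy(ok)
  expect_equal(h$global_weight, c(0.3, 0.3, 0.12, 0.28))

  bad_dims <- ok
  bad_dims$dim_weight <- rep(c(0.3, 0.2), each = 2)
  expect_error(risk_hierarchy(bad_dims), "dimension weights sum to 0.5")
  bad_loc <- ok
  bad_loc$local_weight <- c(0.5, 0.4, 0.3, 0.7)
  expect_error(risk_hierarchy(bad_loc), "local weights in dimension 'd1'")
  dup <- ok
  dup$factor <- c("f1", "f1", "f3", "f4")
  expect_error(risk_hierarchy(dup), "unique")
})

test_that("build_hierarchy composes extent weights over both levels", {
  dims <- paste0("d", 1:6)
  dm <- all_equal_fpm_named(dims)
  fms <- stats::setNames(
    lapply(dims, function(d) all_equal_fpm_named(paste0(d, "_f", 1:3))),
    dims)
  h <- build_hierarchy(dm, fms)
  expect_equal(unique(h$dim_weight), 1 / 6, tolerance = 1e-12)
  expect_equal(unique(h$local_weight), 1 / 3, tolerance = 1e-12)
  expect_equal(unique(h$global_weight), 1 / 18, tolerance = 1e-12)
  expect_length(attr(h, "consistency"), 7)

  expect_error(build_hierarchy(dm, fms[-1]), "missing factor matrix")
})

test_that("build_hierarchy rejects inconsistent judgments unless forced", {
  # a hard 3-cycle: a > b, b > c, and c > a, all strongly
  cyc <- fuzzy_pairwise_matrix(tibble::tibble(
    row = c("a", "a", "b"), col = c("b", "c", "c"),
    label = c("9;9;9", sprintf("%.17g;%.17g;%.17g", 1/9, 1/9, 1/9), "9;9;9")),
    labels = c("a", "b", "c"))
  expect_gte(consistency_ratio(cyc)$consistency_ratio, 0.1)
  fms <- list(a = all_equal_fpm_named(c("a1", "a2")),
              b = all_equal_fpm_named(c("b1", "b2")),
              c = all_equal_fpm_named(c("c1", "c2")))
  expect_error(build_hierarchy(cyc, fms), "CR < 0.1")
  h <- build_hierarchy(cyc, fms, force = TRUE)
  expect_s3_class(h, "risk_hierarchy")
})

test_that("the packaged fixture carries the published dimension weights", {
  h <- preterm_hierarchy()
  dims <- dplyr::distinct(tibble::as_tibble(h), dimension, dim_weight)
  expect_equal(dims$dimension, c("idp", "mhpp", "cmh", "goh", "bml", "spe"))
  expect_equal(dims$dim_weight, c(0.339, 0.306, 0.166, 0.1342, 0.042, 0.0115))
  expect_true(all(diff(dims$dim_weight) < 0))
  expect_equal(sum(dims$dim_weight), 0.9987, tolerance = 1e-9)
  # local weights are a uniform reconstruction summing to one per dimension
  loc <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(h), dimension),
                          s = sum(local_weight))
  expect_equal(loc$s, rep(1, 6), tolerance = 1e-12)
})

test_that("planted panels recover the planted dimension ranking", {
  planted <- c(0.35, 0.3, 0.15, 0.13, 0.05, 0.02)
  labs <- paste0("d", 1:6)
  panel <- simulate_panel(35, planted, labs, noise_sigma = 0.05, seed = 42)
  ew <- suppressWarnings(extent_weights(aggregate_matrices(panel)))
  expect_equal(order(-unname(ew$weights)), order(-planted))
})
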