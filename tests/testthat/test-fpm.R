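fpm_2x2 <- function(triple) {
  fuzzy_pairwise_matrix(
    tibble::tibble(row = "x", col = "y",
                   label = sprintf("%g;%g;%g", triple[1], triple[2], triple[3])),
    labels = c("x", "y"))
}

all_equal_fpm <- function(n) {
  labs <- paste0("c", seq_len(n))
  rows <- expand.grid(i = seq_len(n), j = seq_len(n))
  rows <- rows[rows$i < rows$j, ]
  fuzzy_pairwise_matrix(
    tibble::tibble(row = labs[rows$i], col = labs[rows$j], label = "equal"),
    labels = labs)
}

test_that("matrix construction derives reciprocals and validates input", {
  m <- fpm_2x2(c(1, 2, 3))
  expect_tfn_equal(c(m$a[2, 1], m$m[2, 1], m$b[2, 1]), c(1 / 3, 0.5, 1))
  expect_tfn_equal(c(m$a[1, 1], m$m[1, 1], m$b[1, 1]), c(1, 1, 1))

  # both triangle halves supplied and inconsistent
  expect_error(fuzzy_pairwise_matrix(
    tibble::tibble(row = c("x", "y"), col = c("y", "x"),
                   label = c("1;2;3", "1;1;1")), labels = c("x", "y")),
    "reciprocity")
  # both halves consistent is accepted
  m2 <- fuzzy_pairwise_matrix(
    tibble::tibble(row = c("x", "y"), col = c("y", "x"),
                   label = c("1;2;3", sprintf("%.17g;%.17g;%.17g", 1/3, 0.5, 1))),
    labels = c("x", "y"))
  expect_tfn_equal(c(m2$a[1, 2], m2$m[1, 2], m2$b[1, 2]), c(1, 2, 3))

  expect_error(fuzzy_pairwise_matrix(
    tibble::tibble(row = "x", col = "y", label = "0;1;2"),
    labels = c("x", "y")), "positive")
  expect_error(fuzzy_pairwise_matrix(
    tibble::tibble(row = "x", col = "y", label = "1;2"),
    labels = c("x", "y")), "malformed")
  expect_error(fuzzy_pairwise_matrix(
    tibble::tibble(row = "x", col = "z", label = "equal"),
    labels = c("x", "y")), "not in criterion set")
  expect_error(fuzzy_pairwise_matrix(
    tibble::tibble(row = "x", col = "y", label = "equal")[0, ],
    labels = c("x", "y", "z")), "missing comparison")
})

test_that("synthetic extents match hand-computed and oracle values", {
  m3 <- all_equal_fpm(3)
  ext <- synthetic_extents(m3)
  expect_equal(ext$a, rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(ext$m, rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(ext$b, rep(1 / 3, 3), tolerance = 1e-12)

  # row sums (2,3,4), (4/3,3/2,2); total (10/3, 9/2, 6)
  ext1 <- synthetic_extents(fpm_2x2(c(1, 2, 3)))
  expect_equal(ext1$a, c(2 / 6, (4 / 3) / 6), tolerance = 1e-9)
  expect_equal(ext1$m, c(3 / 4.5, 1.5 / 4.5), tolerance = 1e-9)
  expect_equal(ext1$b, c(4 / (10 / 3), 2 / (10 / 3)), tolerance = 1e-9)
  expect_equal(round(as.numeric(ext1[1, -1]), 4), c(0.3333, 0.6667, 1.2))
  expect_equal(round(as.numeric(ext1[2, -1]), 4), c(0.2222, 0.3333, 0.6))

  ext2 <- synthetic_extents(fpm_2x2(c(2, 3, 4)))
  expect_equal(round(as.numeric(ext2[1, -1]), 4), c(0.4615, 0.75, 1.1765))
  expect_equal(round(as.numeric(ext2[2, -1]), 4), c(0.1923, 0.25, 0.3529))
})

test_that("possibility degree matches closed-form and sup-min grid oracles", {
  expect_equal(possibility_degree(tfn(1, 2, 3), tfn(1, 2, 3)), 1)
  expect_equal(possibility_degree(tfn(0, 1, 2), tfn(3, 4, 5)), 0)
  expect_equal(possibility_degree(tfn(1, 2, 3), tfn(2, 3, 4)), 0.5)
  expect_equal(oracle_possibility_grid(c(1, 2, 3), c(2, 3, 4)), 0.5,
               tolerance = 1e-5)

  set.seed(21)
  for (rep in 1:30) {
    s2 <- sort(runif(3, 0, 3)); s1 <- sort(runif(3, 0, 3))
    v <- possibility_degree(tfn(s2[1], s2[2], s2[3]), tfn(s1[1], s1[2], s1[3]))
    expect_equal(v, oracle_possibility(s2, s1), tolerance = 1e-12)
    expect_gte(v, 0); expect_lte(v, 1)
    # at least one direction is fully possible
    v_rev <- possibility_degree(tfn(s1[1], s1[2], s1[3]),
                                tfn(s2[1], s2[2], s2[3]))
    expect_true(v == 1 || v_rev == 1)
  }
})

test_that("extent weights reproduce worked examples and expose the zero pathology", {
  ew <- extent_weights(all_equal_fpm(4))
  expect_equal(unname(ew$weights), rep(0.25, 4), tolerance = 1e-12)
  expect_equal(unname(diag(ew$possibility)), rep(1, 4))

  ew1 <- extent_weights(fpm_2x2(c(1, 2, 3)))
  expect_equal(unname(ew1$min_degree), c(1, 4 / 9), tolerance = 1e-9)
  expect_equal(round(unname(ew1$weights), 4), c(0.6923, 0.3077))

  # disjoint extents: V(S_2 >= S_1) = 0 -> zero weight with a warning
  expect_warning(ew2 <- extent_weights(fpm_2x2(c(2, 3, 4))), "zero weight")
  expect_equal(unname(ew2$weights), c(1, 0))
  # the floor option keeps the weight positive
  ew2f <- extent_weights(fpm_2x2(c(2, 3, 4)), zero_floor = TRUE)
  expect_gt(unname(ew2f$weights)[2], 0)

  # min_degrees are the row minima of the possibility matrix
  m <- random_fpm(5, seed = 99)
  ew5 <- suppressWarnings(extent_weights(m))
  for (i in 1:5) {
    expect_equal(unname(ew5$min_degree[i]), min(ew5$possibility[i, -i]))
  }
})

test_that("extent weights are equivariant under criterion permutation", {
  set.seed(31)
  for (rep in 1:5) {
    m <- random_fpm(4, seed = 310 + rep)
    ew <- suppressWarnings(extent_weights(m))
    perm <- sample(4)
    mp <- pretermrisk:::fpm_from_components(
      m$labels[perm], m$a[perm, perm], m$m[perm, perm], m$b[perm, perm])
    ewp <- suppressWarnings(extent_weights(mp))
    expect_equal(unname(ewp$weights), unname(ew$weights[perm]),
                 tolerance = 1e-12)
  }
})

test_that("crisp consistent matrices rank criteria as the generating weights", {
  w <- c(4, 2, 1) / 7
  m <- consistent_fpm(w)
  ew <- suppressWarnings(extent_weights(m))
  expect_equal(order(-unname(ew$weights)), order(-w))
})

test_that("consistency ratio is zero for consistent matrices and matches the eigen oracle", {
  r <- consistency_ratio(all_equal_fpm(3))
  expect_equal(r$lambda_max, 3, tolerance = 1e-9)
  expect_equal(r$consistency_ratio, 0, tolerance = 1e-9)
  expect_true(r$consistent)

  # rank-one modal matrix w ~ (4, 2, 1)
  m <- consistent_fpm(c(4, 2, 1) / 7)
  r2 <- consistency_ratio(m)
  expect_equal(r2$lambda_max, 3, tolerance = 1e-9)
  expect_equal(r2$consistency_ratio, 0, tolerance = 1e-9)

  # perturbed 6x6: agree with the dense eigensolver to 1e-8
  mp <- perturbed_fpm(c(0.3, 0.25, 0.2, 0.12, 0.08, 0.05), 0.3, seed = 7)
  rp <- consistency_ratio(mp)
  expect_gte(rp$lambda_max, 6)
  expect_lt(abs(rp$consistency_ratio - oracle_cr(mp$m)), 1e-8)

  # CR is invariant under permutation
  perm <- c(3, 1, 6, 2, 5, 4)
  mpp <- pretermrisk:::fpm_from_components(
    mp$labels[perm], mp$a[perm, perm], mp$m[perm, perm], mp$b[perm, perm])
  expect_equal(consistency_ratio(mpp)$consistency_ratio,
               rp$consistency_ratio, tolerance = 1e-9)

  # n = 2 is consistent by convention
  expect_equal(consistency_ratio(fpm_2x2(c(2, 3, 4)))$consistency_ratio, 0)
})

test_that("matrix aggregation is the componentwise geometric mean and keeps reciprocity", {
  m1 <- fpm_2x2(c(1, 2, 3))
  m2 <- fpm_2x2(c(2, 3, 4))
  agg <- aggregate_matrices(list(m1, m2))
  expect_tfn_equal(c(agg$a[1, 2], agg$m[1, 2], agg$b[1, 2]),
                   c(sqrt(2), sqrt(6), sqrt(12)))
  expect_tfn_equal(c(agg$a[2, 1], agg$m[2, 1], agg$b[2, 1]),
                   as.numeric(tfn_invert(tfn(sqrt(2), sqrt(6), sqrt(12)))))

  # identity and idempotence
  expect_equal(aggregate_matrices(list(m1))$m, m1$m)
  many <- aggregate_matrices(rep(list(m2), 35))
  expect_equal(many$m, m2$m, tolerance = 1e-12)

  # aggregated random panels satisfy reciprocity (validated on construction)
  panel <- lapply(1:5, function(s) random_fpm(4, seed = 400 + s))
  expect_s3_class(aggregate_matrices(panel), "fpm")

  expect_error(aggregate_matrices(list(m1, all_equal_fpm(3))), "disagree")
})
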