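uniform_hierarchy <- function(nd = 6, nf = 3) {
  risk_hierarchy(tibble::tibble(
    dimension = rep(paste0("d", seq_len(nd)), each = nf),
    dim_weight = 1 / nd,
    factor = paste0("d", rep(seq_len(nd), each = nf), "_f",
                    rep(seq_len(nf), nd)),
    local_weight = 1 / nf))
}

judged <- function(h, label, experts = "e1", case = "w1") {
  tidyr::expand_grid(case_id = case, expert_id = experts,
                     factor = h$factor) |>
    dplyr::mutate(label = label)
}

test_that("case aggregation is (min, geometric mean, max) of modal values", {
  one <- aggregate_case(tibble::tibble(
    case_id = "w", expert_id = "e1", factor = "f", label = "medium"))
  expect_equal(as.numeric(one[1, c("a", "m", "b")]), c(0.4, 0.4, 0.4))
  expect_equal(one$degree, 0.4)

  three <- aggregate_case(tibble::tibble(
    case_id = "w", expert_id = c("e1", "e2", "e3"), factor = "f",
    label = c("low", "medium", "very_high")))
  expect_equal(as.numeric(three[1, c("a", "m", "b")]), c(0.2, 0.4, 0.8),
               tolerance = 1e-12)

  many <- aggregate_case(tibble::tibble(
    case_id = "w", expert_id = paste0("e", 1:35), factor = "f",
    label = "high"))
  expect_equal(as.numeric(many[1, c("a", "m", "b")]), c(0.6, 0.6, 0.6),
               tolerance = 1e-12)

  # zero judgment values are clamped with a warning
  expect_warning(
    z <- aggregate_case(tibble::tibble(
      case_id = "w", expert_id = c("e1", "e2"), factor = "f",
      label = c("none", "medium"))),
    "clamped")
  expect_equal(z$a, 1e-6)
  expect_equal(z$m, sqrt(1e-6 * 0.4), tolerance = 1e-12)

  expect_error(aggregate_case(tibble::tibble(
    case_id = "w", expert_id = c("e1", "e1"), factor = "f",
    label = c("low", "high"))), "more than once")

  # centroid defuzzification is available behind the switch
  cen <- aggregate_case(tibble::tibble(
    case_id = "w", expert_id = c("e1", "e2", "e3"), factor = "f",
    label = c("low", "medium", "very_high")), defuzz = "centroid")
  expect_equal(cen$degree, (0.2 + 0.4 + 0.8) / 3, tolerance = 1e-12)
})

test_that("the MBD score is the weighted double sum with its bounds", {
  h <- uniform_hierarchy()
  deg <- tibble::tibble(factor = h$factor, degree = 1)
  expect_equal(mbd_score(h, deg), 1, tolerance = 1e-9)
  deg$degree <- 0
  expect_equal(mbd_score(h, deg), 0)
  deg$degree <- 0.4
  expect_equal(mbd_score(h, deg), 0.4, tolerance = 1e-12)

  expect_error(mbd_score(h, deg[-1, ]), "missing degree")
  deg2 <- deg; deg2$degree[1] <- 1.5
  expect_error(mbd_score(h, deg2), "\\[0, 1\\]")
  extra <- dplyr::bind_rows(deg, tibble::tibble(factor = "zzz", degree = 0.5))
  expect_error(mbd_score(h, extra), "unknown factor")
})

test_that("MBD is a convex combination, monotone and permutation invariant", {
  for (rep in 1:200) {
    h <- random_hierarchy(seed = 7000 + rep)
    set.seed(8000 + rep)
    deg <- tibble::tibble(factor = h$factor,
                          degree = runif(nrow(h)))
    s <- mbd_score(h, deg)
    expect_gte(s, min(deg$degree) - 1e-12)
    expect_lte(s, max(deg$degree) + 1e-12)
    # monotonicity: bumping one degree never lowers the score
    i <- sample(nrow(deg), 1)
    bump <- deg
    bump$degree[i] <- min(1, bump$degree[i] + runif(1, 0, 1 - bump$degree[i]))
    expect_gte(mbd_score(h, bump), s - 1e-12)
    # permutation invariance: factor order is irrelevant
    expect_equal(mbd_score(h, deg[sample(nrow(deg)), ]), s, tolerance = 1e-12)
  }
})

test_that("classification reproduces the worked example and breaks ties upward", {
  cls <- classify_mbd(0.36120376)
  expect_equal(cls$diagnosis, "medium")
  expect_equal(round(cls$fuzzified$degree[cls$fuzzified$term == "low"], 2), 0.19)
  expect_equal(round(cls$fuzzified$degree[cls$fuzzified$term == "medium"], 2), 0.81)

  cls4 <- classify_mbd(0.4)
  expect_equal(cls4$diagnosis, "medium")
  expect_equal(max(cls4$fuzzified$degree), 1)

  # exact tie between medium and high resolves to the riskier term
  cls5 <- classify_mbd(0.5)
  expect_equal(sort(cls5$fuzzified$degree, decreasing = TRUE)[1:2], c(0.5, 0.5))
  expect_equal(cls5$diagnosis, "high")
})

test_that("assess_cases composes aggregation, scoring and classification", {
  h <- uniform_hierarchy()
  suppressWarnings(a_none <- assess_cases(judged(h, "none"), h))
  expect_lt(a_none$mbd, 1e-5)
  expect_equal(a_none$diagnosis, "none")

  a_med <- assess_cases(judged(h, "medium"), h)
  expect_equal(a_med$mbd, 0.4, tolerance = 1e-12)
  expect_equal(a_med$diagnosis, "medium")
  expect_equal(a_med$medium, 1)

  # a mixed 35-expert panel concentrated on low/medium stays within the
  # bounds of the degrees present
  set.seed(99)
  j <- tidyr::expand_grid(case_id = "w1",
                          expert_id = paste0("e", 1:35),
                          factor = preterm_hierarchy()$factor)
  j$label <- sample(c("low", "medium"), nrow(j), replace = TRUE)
  a_mix <- assess_cases(j, preterm_hierarchy())
  expect_gte(a_mix$mbd, 0.2 * 0.9987 - 1e-9)
  expect_lte(a_mix$mbd, 0.6)
})

test_that("ranking is descending by score and stable under ties", {
  asm <- tibble::tibble(case_id = c("a", "b", "c"), mbd = c(0.2, 0.8, 0.5))
  expect_equal(rank_cases(asm)$case_id, c("b", "c", "a"))
  ties <- tibble::tibble(case_id = c("a", "b", "c"), mbd = 0.4)
  r <- rank_cases(ties)
  expect_equal(r$case_id, c("a", "b", "c"))
  expect_equal(r$rank, c(1L, 1L, 1L))

  # oracle equivalence on a large synthetic population
  set.seed(123)
  pop <- tibble::tibble(case_id = paste0("w", 1:153), mbd = runif(153))
  r2 <- rank_cases(pop)
  expect_equal(r2$case_id, pop$case_id[order(-pop$mbd)])
})
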