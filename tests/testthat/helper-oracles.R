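# Independent oracles, kept deliberately separate from the package's code
# paths: different formulations of the same quantities, used to cross-check
# the implementation.

# height of the sup-min intersection of two triangular membership functions,
# solved as the crossing of the falling edge of s2 with the rising edge of
# s1 (linear-equation route, not the closed-form ratio the package uses)
oracle_possibility <- function(s2, s1) {
  a1 <- s1[1]; m1 <- s1[2]; b1 <- s1[3]
  a2 <- s2[1]; m2 <- s2[2]; b2 <- s2[3]
  if (m2 >= m1) return(1)
  if (a1 >= b2) return(0)
  # rising edge of s1: mu = (x - a1) / (m1 - a1); falling edge of s2:
  # mu = (b2 - x) / (b2 - m2); solve for the crossing point
  x <- (a1 * (b2 - m2) + b2 * (m1 - a1)) / ((m1 - a1) + (b2 - m2))
  (x - a1) / (m1 - a1)
}

# sup-min on a fine grid, a second fully independent route
oracle_possibility_grid <- function(s2, s1, n = 200001) {
  lo <- min(s1, s2); hi <- max(s1, s2)
  x <- seq(lo, hi, length.out = n)
  mu <- function(s, x) {
    out <- numeric(length(x))
    ris <- x >= s[1] & x <= s[2]
    fal <- x > s[2] & x <= s[3]
    out[ris] <- if (s[2] > s[1]) (x[ris] - s[1]) / (s[2] - s[1]) else 1
    out[fal] <- if (s[3] > s[2]) (s[3] - x[fal]) / (s[3] - s[2]) else 1
    out
  }
  max(pmin(mu(s2, x), mu(s1, x)))
}

# extent analysis from the raw component matrices by explicit loops
oracle_extent <- function(A, M, B) {
  n <- nrow(A)
  ra <- numeric(n); rm_ <- numeric(n); rb <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ra[i] <- ra[i] + A[i, j]; rm_[i] <- rm_[i] + M[i, j]; rb[i] <- rb[i] + B[i, j]
  }
  S <- cbind(ra / sum(rb), rm_ / sum(rm_), rb / sum(ra))
  V <- matrix(1, n, n)
  for (i in seq_len(n)) for (k in seq_len(n)) {
    if (i != k) V[i, k] <- oracle_possibility(S[i, ], S[k, ])
  }
  d <- vapply(seq_len(n), function(i) min(V[i, -i]), numeric(1))
  list(S = S, V = V, d = d, w = if (sum(d) > 0) d / sum(d) else d * NA)
}

# principal eigenvalue via the dense eigensolver (the package uses power
# iteration)
oracle_lambda_max <- function(C) {
  ev <- eigen(C, only.values = TRUE)$values
  max(Re(ev[abs(Im(ev)) < 1e-8]))
}

oracle_cr <- function(C) {
  ri <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49, 1.51, 1.48,
          1.56, 1.57, 1.59)
  n <- nrow(C)
  if (n <= 2) return(0)
  (oracle_lambda_max(C) - n) / (n - 1) / ri[n]
}

# textbook paired t-test
oracle_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  p <- 2 * pt(-abs(t), df = n - 1)
  list(t = t, df = n - 1, p = p)
}

# random valid fuzzy pairwise matrix: random 1..9 intensities on the upper
# triangle with random orientation, TFNs from the default comparison scale
random_fpm <- function(n, seed) {
  set.seed(seed)
  rows <- list()
  labs <- paste0("c", seq_len(n))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    intensity <- sample(1:9, 1)
    flip <- runif(1) < 0.5
    t <- c(max(1, intensity - 1), intensity, min(9, intensity + 1))
    if (flip && intensity > 1) t <- rev(1 / t)
    rows[[length(rows) + 1]] <- tibble::tibble(
      row = labs[i], col = labs[j],
      label = sprintf("%.17g;%.17g;%.17g", t[1], t[2], t[3]))
  }
  fuzzy_pairwise_matrix(dplyr::bind_rows(rows), labels = labs)
}

# crisp perfectly consistent matrix from a weight vector, as an fpm
consistent_fpm <- function(w) {
  n <- length(w)
  labs <- paste0("c", seq_len(n))
  rows <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- w[i] / w[j]
    rows[[length(rows) + 1]] <- tibble::tibble(
      row = labs[i], col = labs[j],
      label = sprintf("%.17g;%.17g;%.17g", r, r, r))
  }
  fuzzy_pairwise_matrix(dplyr::bind_rows(rows), labels = labs)
}

# multiplicative lognormal perturbation of a consistent crisp matrix,
# returned as an fpm (crisp entries)
perturbed_fpm <- function(w, sigma, seed) {
  set.seed(seed)
  n <- length(w)
  labs <- paste0("c", seq_len(n))
  rows <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- (w[i] / w[j]) * exp(sigma * rnorm(1))
    rows[[length(rows) + 1]] <- tibble::tibble(
      row = labs[i], col = labs[j],
      label = sprintf("%.17g;%.17g;%.17g", r, r, r))
  }
  fuzzy_pairwise_matrix(dplyr::bind_rows(rows), labels = labs)
}

# random hierarchy for property tests
random_hierarchy <- function(seed, renormalize = TRUE) {
  set.seed(seed)
  nd <- sample(2:6, 1)
  h <- purrr::map_dfr(seq_len(nd), function(d) {
    nf <- sample(2:4, 1)
    lw <- rgamma(nf, 1) + 0.05
    tibble::tibble(dimension = paste0("d", d), dim_weight = NA_real_,
                   factor = paste0("d", d, "_f", seq_len(nf)),
                   local_weight = lw / sum(lw))
  })
  dw <- rgamma(nd, 1) + 0.05
  dw <- dw / sum(dw)
  h$dim_weight <- dw[match(h$dimension, paste0("d", seq_len(nd)))]
  risk_hierarchy(h)
}

expect_tfn_equal <- function(x, y, tol = 1e-9) {
  expect_equal(as.numeric(x), as.numeric(y), tolerance = tol)
}
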