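# derive a per-unit substream seed from the root seed (kept below 2^31)
substream_seed <- function(seed, i) {
  (as.numeric(seed) * 48271 + i) %% 2147483647
}

# snap a crisp ratio to the nearest 1..9 comparison intensity and return its
# TFN; ratios below 1 snap on the reciprocal side
snap_ratio_tfn <- function(r, scale) {
  stopifnot(r > 0)
  if (r >= 1) {
    intensities <- round(scale$m)
    i <- intensities[which.min(abs(intensities - r))]
    term_to_tfn(as.character(i), scale)
  } else {
    tfn_invert(snap_ratio_tfn(1 / r, scale))
  }
}

#' Simulate an expert panel of pairwise matrices
#'
#' Generates one fuzzy pairwise-comparison matrix per expert from a planted
#' ground-truth weight vector. For each upper-triangle pair the expert's
#' crisp ratio is `(w_i / w_j) * exp(sigma * z)` with `z` standard normal
#' (multiplicative lognormal judgment noise, the standard AHP simulation
#' model); the ratio is snapped to the nearest 1..9 intensity of the
#' comparison scale, emulating questionnaire discretization, and replaced by
#' that intensity's TFN. Reciprocal cells are derived, so every generated
#' matrix satisfies reciprocity by construction. Each expert draws from an
#' independent substream of the root seed; output is deterministic for a
#' fixed seed.
#'
#' @param n_experts Number of experts (default 35, the study's panel size).
#' @param true_weights Positive weights summing to 1, one per criterion.
#' @param labels Criterion names, same length as `true_weights`.
#' @param noise_sigma Lognormal standard deviation of the judgment noise.
#' @param seed Integer root seed.
#' @param scale Comparison scale whose intensities are snapped to.
#'
#' @return A list of `n_experts` objects of class `"fpm"`.
#' @examples
#' panel <- simulate_panel(5, c(0.6, 0.3, 0.1), c("a", "b", "c"),
#'                         noise_sigma = 0.05, seed = 1)
#' extent_weights(aggregate_matrices(panel))
#' @export
simulate_panel <- function(n_experts = 35, true_weights, labels,
                           noise_sigma = 0.05, seed = 1,
                           scale = comparison_scale()) {
  stopifnot(n_experts >= 1, length(labels) == length(true_weights),
            all(true_weights > 0), noise_sigma >= 0)
  if (abs(sum(true_weights) - 1) > 1e-8) {
    stop("true_weights must sum to 1", call. = FALSE)
  }
  labels <- normalize_label(labels)
  n <- length(labels)
  lapply(seq_len(n_experts), function(e) {
    set.seed(substream_seed(seed, e))
    A <- M <- B <- diag(n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      z <- stats::rnorm(1)
      r <- (true_weights[i] / true_weights[j]) * exp(noise_sigma * z)
      x <- snap_ratio_tfn(r, scale)
      A[i, j] <- x[["a"]]; M[i, j] <- x[["m"]]; B[i, j] <- x[["b"]]
      inv <- tfn_invert(x)
      A[j, i] <- inv[["a"]]; M[j, i] <- inv[["m"]]; B[j, i] <- inv[["b"]]
    }
    fpm_from_components(labels, A, M, B)
  })
}

#' Simulate a case population with expert judgments
#'
#' Generates a long judgment table for `n_cases` synthetic pregnant-woman
#' cases assessed by `n_experts` experts. Each case draws a latent
#' linguistic label per hierarchy factor from `risk_mix`; each expert
#' reports the latent label with probability `concordance` and otherwise an
#' adjacent term of the scale (uniform over the available neighbours —
#' experts rarely mislabel by more than one severity step).
#'
#' When `include_overall = TRUE` the table also carries a distinguished
#' `"overall"` row per case and expert: the case's latent overall diagnosis
#' is *sampled* from the fuzzified membership degrees of the latent MBD
#' (the MBD of the latent labels' modal values under `hierarchy`). Under the
#' Ruspini case scale those membership degrees are the linear-interpolation
#' weights between the two neighbouring terms, so the sampled term's modal
#' value is unbiased for the latent score — deterministic nearest-term
#' rounding would bias the simulated expert diagnoses whenever the
#' population-mean MBD falls between modal points. Experts then report the
#' latent overall term with the same concordance/adjacent-error model.
#'
#' The default `risk_mix` places mass on medium through extreme. The floor
#' terms (none, low) are supported but excluded from the default mix: a
#' single "none" report (modal value 0) collapses the geometric-mean
#' consensus of a factor (see [aggregate_case()]), so populations
#' concentrated at the scale floor are not score-concordant by construction;
#' see the package vignette.
#'
#' @param n_cases Number of cases (the study validated on 153).
#' @param hierarchy `"risk_hierarchy"` whose factors are judged.
#' @param n_experts Panel size per case (default 35).
#' @param risk_mix Named numeric: probability of each latent scale term;
#'   must sum to 1 and name only terms of `scale`.
#' @param concordance Probability in `[0, 1]` that an expert echoes the
#'   latent label.
#' @param seed Integer root seed; each case has its own substream.
#' @param scale Case judgment scale.
#' @param include_overall Also emit `"overall"` diagnosis rows.
#'
#' @return A tibble with columns `case_id`, `expert_id`, `factor`, `label`,
#'   plus attribute `"latent"` (tibble `case_id`, `factor`, `label` of the
#'   ground-truth labels, with overall rows when requested).
#' @examples
#' j <- simulate_cases(3, preterm_hierarchy(), n_experts = 5, seed = 1)
#' dplyr::count(j, case_id)
#' @export
simulate_cases <- function(n_cases, hierarchy, n_experts = 35,
                           risk_mix = c(medium = 0.45, high = 0.30,
                                        very_high = 0.15, extreme = 0.10),
                           concordance = 0.9, seed = 1,
                           scale = case_scale(), include_overall = TRUE) {
  stopifnot(n_cases >= 1, n_experts >= 1,
            inherits(hierarchy, "risk_hierarchy"),
            concordance >= 0, concordance <= 1)
  mix_terms <- normalize_label(names(risk_mix))
  if (!all(mix_terms %in% scale$term)) {
    stop("risk_mix names must be terms of the case scale", call. = FALSE)
  }
  if (abs(sum(risk_mix) - 1) > 1e-8 || any(risk_mix < 0)) {
    stop("risk_mix proportions must be nonnegative and sum to 1", call. = FALSE)
  }
  factors <- hierarchy$factor
  nf <- length(factors)
  nterm <- nrow(scale)
  mix_idx <- match(mix_terms, scale$term)
  width <- function(d) max(1, nchar(as.character(d)))

  res <- vector("list", n_cases)
  lat <- vector("list", n_cases)
  for (k in seq_len(n_cases)) {
    set.seed(substream_seed(seed, k))
    cid <- sprintf("case_%0*d", width(n_cases), k)
    latent <- mix_idx[sample.int(length(mix_idx), nf, replace = TRUE,
                                 prob = risk_mix)]
    # experts: echo latent with prob concordance, else an adjacent term
    rep_idx <- matrix(rep(latent, n_experts), nf, n_experts)
    err <- matrix(stats::runif(nf * n_experts) > concordance, nf, n_experts)
    if (any(err)) {
      cur <- rep_idx[err]
      step <- ifelse(stats::runif(sum(err)) < 0.5, -1L, 1L)
      prop <- cur + step
      # at the scale boundary only one neighbour exists
      prop[prop < 1L] <- 2L
      prop[prop > nterm] <- nterm - 1L
      rep_idx[err] <- prop
    }
    lat_rows <- tibble::tibble(case_id = cid, factor = factors,
                               label = scale$term[latent])
    rows <- tibble::tibble(
      case_id = cid,
      expert_id = sprintf("expert_%0*d", width(n_experts),
                          rep(seq_len(n_experts), each = nf)),
      factor = rep(factors, n_experts),
      label = scale$term[as.vector(rep_idx)]
    )
    if (include_overall) {
      lat_mbd <- sum(hierarchy$global_weight * scale$m[latent])
      fz <- fuzzify(lat_mbd, scale)
      ov_lat <- sample.int(nterm, 1, prob = fz$degree)
      ov_idx <- rep(ov_lat, n_experts)
      oerr <- stats::runif(n_experts) > concordance
      if (any(oerr)) {
        step <- ifelse(stats::runif(sum(oerr)) < 0.5, -1L, 1L)
        prop <- ov_idx[oerr] + step
        prop[prop < 1L] <- 2L
        prop[prop > nterm] <- nterm - 1L
        ov_idx[oerr] <- prop
      }
      rows <- dplyr::bind_rows(rows, tibble::tibble(
        case_id = cid,
        expert_id = sprintf("expert_%0*d", width(n_experts),
                            seq_len(n_experts)),
        factor = "overall",
        label = scale$term[ov_idx]
      ))
      lat_rows <- dplyr::bind_rows(
        lat_rows, tibble::tibble(case_id = cid, factor = "overall",
                                 label = scale$term[ov_lat]))
    }
    res[[k]] <- rows
    lat[[k]] <- lat_rows
  }
  out <- dplyr::bind_rows(res)
  attr(out, "latent") <- dplyr::bind_rows(lat)
  out
}
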