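#' Savage-Dickey Bayes factor for the full model
#'
#' The null model fixes `beta2 = beta3 = 1`, decoupling trait variance from
#' the substitution process. Because the null is nested at
#' `(log beta2, log beta3) = (0, 0)` and the priors are common across
#' elements, the Bayes factor in favour of the full model is the ratio of
#' the prior density to the posterior density at the origin. The prior
#' density is exactly the product of two independent standard normals at
#' zero, `1/(2*pi)`; the posterior density is a bivariate Gaussian kernel
#' density estimate over the post-burn-in samples (product kernel, Scott's
#' bandwidth by default).
#'
#' @param samples Two-column matrix or data frame of post-burn-in
#'   `(log beta2, log beta3)` samples; at least 500 rows.
#' @param bandwidth Either `"scott"` (bandwidth `sd * n^(-1/6)` per
#'   coordinate) or a numeric length-2 vector of bandwidths.
#' @param log_beta_var Prior variance of `log beta2` and `log beta3`.
#' @return List with `bf`, `prior_density`, `posterior_density`.
#' @export
savage_dickey_bf <- function(samples, bandwidth = "scott",
                             log_beta_var = 1) {
  samples <- as.matrix(samples)
  if (ncol(samples) != 2) stop("'samples' must have two columns")
  n <- nrow(samples)
  if (n < 500)
    stop("need at least 500 samples for a stable density estimate; got ", n)
  sds <- apply(samples, 2, stats::sd)
  if (any(sds == 0) || any(!is.finite(sds)))
    stop("degenerate samples (zero variance); run longer chains")
  if (identical(bandwidth, "scott")) {
    h <- sds * n^(-1 / 6)
  } else {
    h <- rep_len(as.numeric(bandwidth), 2)
    if (any(h <= 0)) stop("bandwidths must be positive")
  }
  post <- mean(stats::dnorm(0, samples[, 1], h[1]) *
               stats::dnorm(0, samples[, 2], h[2]))
  prior <- stats::dnorm(0, 0, sqrt(log_beta_var))^2
  if (post <= 0)
    stop("posterior density at the origin underflowed; run longer chains")
  list(bf = prior / post, prior_density = prior, posterior_density = post)
}

#' Evidence category for a Bayes factor
#'
#' `BF >= 100` is labelled "overwhelming", `BF >= 30` "very strong"
#' (boundaries inclusive), anything smaller "weak/none".
#'
#' @param bf Positive Bayes factor (vectorized).
#' @return Character vector of labels.
#' @export
categorize_evidence <- function(bf) {
  stopifnot(all(bf > 0))
  ifelse(bf >= 100, "overwhelming",
         ifelse(bf >= 30, "very strong", "weak/none"))
}

#' Rank elements by Bayes factor
#'
#' Orders element summaries by descending Bayes factor (ties broken by
#' element id). Elements failing the convergence screen are excluded from
#' the main ranking by default and returned in a side table.
#'
#' @param summaries List of `element_summary` objects (or a data frame with
#'   the same columns).
#' @param include_nonconverged Keep non-converged elements in the main
#'   ranking instead of the side table.
#' @return List with `ranked` and `nonconverged` data frames (columns:
#'   `element_id`, `bf`, `label`, `median_log_beta_ratio`, `ci80_lo`,
#'   `ci80_hi`, `rhat_max`, `converged`).
#' @export
rank_elements <- function(summaries, include_nonconverged = FALSE) {
  if (!length(summaries)) stop("no summaries supplied")
  if (is.data.frame(summaries)) {
    tab <- summaries
  } else {
    tab <- do.call(rbind, lapply(summaries, function(s) data.frame(
      element_id = s$element_id, bf = s$bf,
      median_log_beta_ratio = s$median_log_beta_ratio,
      ci80_lo = s$ci80[1], ci80_hi = s$ci80[2],
      rhat_max = s$rhat_max, converged = s$converged,
      stringsAsFactors = FALSE)))
  }
  tab$label <- categorize_evidence(tab$bf)
  tab <- tab[order(-tab$bf, tab$element_id), , drop = FALSE]
  rownames(tab) <- NULL
  cols <- c("element_id", "bf", "label", "median_log_beta_ratio",
            "ci80_lo", "ci80_hi", "rhat_max", "converged")
  tab <- tab[, cols]
  if (include_nonconverged) {
    list(ranked = tab, nonconverged = tab[0, ])
  } else {
    list(ranked = tab[tab$converged, , drop = FALSE],
         nonconverged = tab[!tab$converged, , drop = FALSE])
  }
}
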