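#' MCMC run configuration
#'
#' @param n_iter Gibbs sweeps per chain (default 10,000).
#' @param n_chains Number of independent chains (default 3).
#' @param burn_in_fraction Fraction of sweeps discarded (default 0.5).
#' @param thin Record every `thin`-th sweep (default 1).
#' @param step1_inner Inner Metropolis iterations per sweep in the trait
#'   block (default 500).
#' @param step1_mix Probability that an inner iteration proposes a
#'   parameter move rather than a latent-trait move (default 0.6).
#' @param prop_sd_log_param Random-walk s.d. for `log sigma2`, `log beta2`,
#'   `log beta3` (default 0.3).
#' @param prop_sd_trait_factor Latent-trait walk scale factor: proposal
#'   s.d. is this times `sqrt(median branch length * sigma2)` (default 0.5).
#' @param prop_sd_log_rate Random-walk s.d. for `log r2`, `log r3`
#'   (default 0.3).
#' @param rhat_threshold Convergence screen on the classic Gelman-Rubin
#'   statistic (default 1.01).
#' @param record_z Record posterior per-node state frequencies.
#' @param seed Master seed; per-chain seeds are derived from it.
#' @return A `run_config` list.
#' @export
run_config <- function(n_iter = 10000, n_chains = 3, burn_in_fraction = 0.5,
                       thin = 1, step1_inner = 500, step1_mix = 0.6,
                       prop_sd_log_param = 0.3, prop_sd_trait_factor = 0.5,
                       prop_sd_log_rate = 0.3, rhat_threshold = 1.01,
                       record_z = FALSE, seed = 1) {
  stopifnot(n_iter >= 1, n_chains >= 1, burn_in_fraction >= 0,
            burn_in_fraction < 1, thin >= 1, step1_inner >= 0,
            step1_mix >= 0, step1_mix <= 1)
  structure(list(n_iter = as.integer(n_iter), n_chains = as.integer(n_chains),
                 burn_in_fraction = burn_in_fraction, thin = as.integer(thin),
                 step1_inner = as.integer(step1_inner), step1_mix = step1_mix,
                 prop_sd_log_param = prop_sd_log_param,
                 prop_sd_trait_factor = prop_sd_trait_factor,
                 prop_sd_log_rate = prop_sd_log_rate,
                 rhat_threshold = rhat_threshold, record_z = record_z,
                 seed = as.integer(seed)), class = "run_config")
}

.cpp_config <- function(config, zfreq_from = 0L) {
  list(n_iter = config$n_iter, thin = config$thin,
       step1_inner = config$step1_inner, step1_mix = config$step1_mix,
       prop_sd_log_param = config$prop_sd_log_param,
       prop_sd_trait_factor = config$prop_sd_trait_factor,
       prop_sd_log_rate = config$prop_sd_log_rate,
       zfreq_from = as.integer(zfreq_from))
}

.trace_names <- c("log_sigma2", "log_beta2", "log_beta3", "log_beta_ratio",
                  "r2", "r3", "a", "b", "c", "log_joint")

# Draw an initial chain state: parameters from independent prior draws
# (overdispersed starts), states simulated from the drawn transition
# matrix, latent nucleotides already initialized by load_element.
.init_state <- function(element, phylogeny, priors) {
  p <- .draw_prior_params(priors)
  z <- sim_z(phylogeny, build_phi(p$a, p$b, p$c), priors$root_state_prior)
  list(params = p, z = z, y = element$y, X = element$X)
}

#' One full Gibbs sweep
#'
#' Executes, in order: the trait Metropolis block (Step 1), pruning and
#' forward sampling of ancestral nucleotides (Step 2), backward messages
#' and root-to-tip state sampling (Step 3), Metropolis updates of the rate
#' multipliers (Step 4), and the conjugate Beta update of the transition
#' parameters (Step 5), then recomputes the log joint.
#'
#' @param state List with `params` (named list of `r2`, `r3`, `sigma2`,
#'   `beta2`, `beta3`, `a`, `b`, `c`), `z`, `y`, `X`.
#' @param element An `element_data` (supplies the observation masks).
#' @param phylogeny A `phylogeny`.
#' @param model A `neutral_model`.
#' @param config A [run_config()].
#' @param priors Output of [model_priors()].
#' @return The updated state, with `log_joint` attached.
#' @export
gibbs_sweep <- function(state, element, phylogeny, model,
                        config = run_config(), priors = model_priors()) {
  cfg <- .cpp_config(utils::modifyList(config, list(n_iter = 1L, thin = 1L)))
  res <- cpp_run_chain(.pack_tree(phylogeny), model$Q, model$pi,
                       state$X, .obs_int(element), as.numeric(state$y),
                       .obsy_int(element, phylogeny), as.integer(state$z),
                       .params_vector(state$params), priors, cfg)
  out <- list(params = as.list(res$final_params), z = res$final_z,
              y = res$final_y, X = res$final_X)
  out$log_joint <- res$trace[1, 10]
  out
}

#' Metropolis update of the substitution rate multipliers (Step 4)
#'
#' One log-scale Gaussian random-walk Metropolis step each for `r2` and
#' `r3`, scored against the sequence likelihood of the fully imputed
#' alignment under the current conservation states plus the Gamma priors.
#'
#' @param element An `element_data` (supplies the observation masks).
#' @param state List with `params`, `z`, `y`, `X` (see [gibbs_sweep()]).
#' @param phylogeny A `phylogeny`.
#' @param model A `neutral_model`.
#' @param priors Output of [model_priors()].
#' @param prop_sd_log_rate Random-walk s.d. on the log-rate scale.
#' @return List with updated `params` and acceptance counts.
#' @export
step4_update_rates <- function(element, state, phylogeny, model,
                               priors = model_priors(),
                               prop_sd_log_rate = 0.3) {
  res <- cpp_step4(.pack_tree(phylogeny), model$Q, model$pi, state$X,
                   .obs_int(element), as.numeric(state$y),
                   .obsy_int(element, phylogeny), as.integer(state$z),
                   .params_vector(state$params), priors, prop_sd_log_rate)
  list(params = as.list(res$params), accept = res$accept)
}

#' Log joint density of a fully populated chain state
#'
#' Sum of the sequence block (per-site, per-branch log transition
#' probabilities plus the root stationary term), the trait block
#' (per-branch Brownian densities plus the root trait prior), the state
#' block (per-branch transition probabilities plus the root state prior),
#' and the log prior densities of all parameters (log-scale densities for
#' `sigma2`, `beta2`, `beta3`).
#'
#' @inheritParams step4_update_rates
#' @return The log joint density (a single finite number for valid states).
#' @export
log_joint <- function(element, state, phylogeny, model,
                      priors = model_priors()) {
  cpp_log_joint(.pack_tree(phylogeny), model$Q, model$pi, state$X,
                .obs_int(element), as.numeric(state$y),
                .obsy_int(element, phylogeny), as.integer(state$z),
                .params_vector(state$params), priors)
}

#' Run multiple MCMC chains on one element
#'
#' Runs `n_chains` independent chains from overdispersed starts (parameters
#' drawn from their priors, states simulated from the drawn transition
#' matrix), records per-sweep scalars (`log sigma2`, `log beta2`,
#' `log beta3`, `log(beta3/beta2)`, `r2`, `r3`, `a`, `b`, `c`, log joint),
#' and computes split-chain Gelman-Rubin diagnostics (classic and
#' rank-normalized) on the post-burn-in samples.
#'
#' @param element An `element_data` from [load_element()].
#' @param phylogeny A `phylogeny`.
#' @param model A `neutral_model`.
#' @param config A [run_config()].
#' @param priors Output of [model_priors()].
#' @return An object of class `chain_run`: list with `traces` (list of
#'   per-chain matrices), `post` (pooled post-burn-in matrix), `rhat`,
#'   `rhat_rank`, `converged`, `acceptance`, `summary` (per-scalar median
#'   and 10/90 percentiles), `zfreq` (if recorded), and `config`.
#' @export
run_chains <- function(element, phylogeny, model, config = run_config(),
                       priors = model_priors()) {
  traces <- vector("list", config$n_chains)
  accepts <- vector("list", config$n_chains)
  zfreqs <- vector("list", config$n_chains)
  burn_iter <- floor(config$n_iter * config$burn_in_fraction)
  zfreq_from <- if (config$record_z) burn_iter + 1L else 0L
  for (chain in seq_len(config$n_chains)) {
    set.seed(as.integer((as.numeric(config$seed) * 1009 + chain * 7919) %%
                          2147483629))
    st <- .init_state(element, phylogeny, priors)
    res <- cpp_run_chain(.pack_tree(phylogeny), model$Q, model$pi,
                         st$X, .obs_int(element), as.numeric(st$y),
                         .obsy_int(element, phylogeny), as.integer(st$z),
                         .params_vector(st$params), priors,
                         .cpp_config(config, zfreq_from))
    colnames(res$trace) <- .trace_names
    traces[[chain]] <- res$trace
    accepts[[chain]] <- res$accept
    if (config$record_z) zfreqs[[chain]] <- res$zfreq
  }
  n_rec <- nrow(traces[[1]])
  burn_rec <- floor(n_rec * config$burn_in_fraction)
  keep <- if (burn_rec < n_rec) (burn_rec + 1L):n_rec else n_rec
  monitored <- setdiff(.trace_names, "log_joint")
  rhat <- rhat_rank <- stats::setNames(rep(NA_real_, length(monitored)),
                                       monitored)
  for (sc in monitored) {
    draws <- vapply(traces, function(tr) tr[keep, sc], numeric(length(keep)))
    rhat[sc] <- gelman_rubin(draws)
    rhat_rank[sc] <- gelman_rubin(draws, rank_normalize = TRUE)
  }
  post <- do.call(rbind, lapply(traces, function(tr) tr[keep, , drop = FALSE]))
  acc <- Reduce(`+`, accepts)
  acc_rates <- c(
    step1_param = unname(acc["step1_param_acc"] / max(acc["step1_param_prop"], 1)),
    step1_trait = unname(acc["step1_trait_acc"] / max(acc["step1_trait_prop"], 1)),
    r2 = unname(acc["r2_acc"] / max(acc["r2_prop"], 1)),
    r3 = unname(acc["r3_acc"] / max(acc["r3_prop"], 1)))
  summ <- t(apply(post, 2, stats::quantile, probs = c(0.1, 0.5, 0.9)))
  colnames(summ) <- c("q10", "median", "q90")
  structure(list(
    traces = traces, post = post, rhat = rhat, rhat_rank = rhat_rank,
    converged = all(is.finite(rhat)) && max(rhat) < config$rhat_threshold,
    acceptance = acc_rates, summary = summ,
    zfreq = if (config$record_z) Reduce(`+`, zfreqs) / config$n_chains,
    config = config), class = "chain_run")
}

#' @export
print.chain_run <- function(x, ...) {
  cat("chain_run: ", length(x$traces), " chains x ",
      nrow(x$traces[[1]]), " recorded sweeps; converged = ",
      x$converged, " (max Rhat = ", format(max(x$rhat), digits = 4), ")\n",
      sep = "")
  print(round(x$summary, 3))
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Split-chain version: each chain is halved, then the classic
#' between/within variance ratio is computed. With
#' `rank_normalize = TRUE` the draws are first replaced by normal scores of
#' their pooled ranks (the rank-normalized variant).
#'
#' @param draws Matrix of samples, one column per chain.
#' @param rank_normalize Use the rank-normalized variant.
#' @return The potential scale reduction factor.
#' @export
gelman_rubin <- function(draws, rank_normalize = FALSE) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  split <- cbind(draws[seq_len(half), , drop = FALSE],
                 draws[(n - half + 1):n, , drop = FALSE])
  if (rank_normalize) {
    r <- rank(split, ties.method = "average")
    split <- matrix(stats::qnorm((r - 3 / 8) / (length(split) + 1 / 4)),
                    nrow(split), ncol(split))
  }
  m <- ncol(split)
  n2 <- nrow(split)
  means <- colMeans(split)
  vars <- apply(split, 2, stats::var)
  W <- mean(vars)
  B <- n2 * stats::var(means)
  if (W <= 0) return(if (B <= 0) 1 else Inf)
  sqrt(((n2 - 1) / n2 * W + B / n2) / W)
}

#' Fit the model to one element and summarize it
#'
#' Runs [run_chains()] and condenses the result into the per-element record
#' used for ranking: the Savage-Dickey Bayes factor in favour of the full
#' model, the posterior median and 80% credible interval of
#' `log(beta3/beta2)`, and the convergence screen.
#'
#' @param element An `element_data`.
#' @param phylogeny A `phylogeny`.
#' @param model A `neutral_model`.
#' @param config A [run_config()].
#' @param priors Output of [model_priors()].
#' @param element_id Identifier carried into the summary.
#' @return An `element_summary`: list with `element_id`, `bf`,
#'   `median_log_beta_ratio`, `ci80`, `rhat_max`, `converged`, `n_samples`,
#'   plus the underlying `run`.
#' @export
fit_element <- function(element, phylogeny, model, config = run_config(),
                        priors = model_priors(), element_id = "element") {
  run <- run_chains(element, phylogeny, model, config, priors)
  lb <- run$post[, c("log_beta2", "log_beta3"), drop = FALSE]
  bf <- savage_dickey_bf(lb)
  qs <- stats::quantile(run$post[, "log_beta_ratio"], c(0.1, 0.5, 0.9))
  structure(list(element_id = element_id, bf = bf$bf,
                 median_log_beta_ratio = unname(qs[2]),
                 ci80 = unname(qs[c(1, 3)]),
                 rhat_max = max(run$rhat), converged = run$converged,
                 n_samples = nrow(run$post), run = run),
            class = "element_summary")
}

#' @export
print.element_summary <- function(x, ...) {
  cat("element ", x$element_id, ": BF = ", format(x$bf, digits = 4),
      " (", categorize_evidence(x$bf), "); median log(beta3/beta2) = ",
      format(x$median_log_beta_ratio, digits = 3), " [",
      format(x$ci80[1], digits = 3), ", ", format(x$ci80[2], digits = 3),
      "]; max Rhat = ", format(x$rhat_max, digits = 4),
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  invisible(x)
}
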