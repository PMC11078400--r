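#' Log density of one Brownian-motion branch displacement
#'
#' The trait displacement along a branch is Normal with mean zero and
#' variance `t * v_state`, where `v_state` is the per-state variance
#' multiplier (`sigma2`, `beta2 * sigma2`, or `beta3 * sigma2`).
#'
#' @param y_child,y_parent Trait values at the two ends of the branch.
#' @param t Positive branch length.
#' @param v_state Positive variance rate for the branch's state.
#' @return The log density.
#' @export
trait_branch_logdensity <- function(y_child, y_parent, t, v_state) {
  stopifnot(t > 0, v_state > 0)
  stats::dnorm(y_child, mean = y_parent, sd = sqrt(t * v_state), log = TRUE)
}

#' Per-state variance multipliers
#'
#' @param sigma2,beta2,beta3 Positive variance parameters.
#' @return Numeric triple `(sigma2, beta2*sigma2, beta3*sigma2)`.
#' @export
variance_multipliers <- function(sigma2, beta2, beta3) {
  stopifnot(sigma2 > 0, beta2 > 0, beta3 > 0)
  c(sigma2, beta2 * sigma2, beta3 * sigma2)
}

#' Joint log density of the full trait vector
#'
#' Sum of per-branch Brownian displacement densities plus the root trait
#' prior `Normal(0, root_trait_var)`.
#'
#' @param y Fully populated length-`N` trait vector (observed + latent).
#' @param z Per-node conservation states (1, 2, 3).
#' @param vp List with `sigma2`, `beta2`, `beta3`.
#' @param phylogeny A `phylogeny`.
#' @param priors Output of [model_priors()].
#' @return The log density.
#' @export
trait_log_joint <- function(y, z, vp, phylogeny, priors = model_priors()) {
  phy <- phylogeny
  stopifnot(length(y) == phy$N, all(is.finite(y)))
  .check_states(z, phy)
  v <- variance_multipliers(vp$sigma2, vp$beta2, vp$beta3)
  nonroot <- setdiff(seq_len(phy$N), phy$root)
  ll <- sum(stats::dnorm(y[nonroot], mean = y[phy$parent[nonroot]],
                         sd = sqrt(phy$branch_length[nonroot] * v[z[nonroot]]),
                         log = TRUE))
  ll + stats::dnorm(y[phy$root], 0, sqrt(priors$root_trait_var), log = TRUE)
}

#' Metropolis block for trait parameters and latent trait values (Step 1)
#'
#' Performs `n_inner` Metropolis iterations. With probability `mix` an
#' iteration proposes a Gaussian random-walk move on one of `log sigma2`,
#' `log beta2`, `log beta3` (chosen uniformly); otherwise it perturbs one
#' uniformly chosen latent trait entry (ancestral nodes and leaves with
#' unobserved traits). The trait proposal standard deviation is
#' `prop_sd_trait_factor * sqrt(median branch length * sigma2)`.
#'
#' @param element An `element_data` (its `y` supplies current values).
#' @param y Current full trait vector.
#' @param z Current conservation states.
#' @param params List with current `sigma2`, `beta2`, `beta3` (and the
#'   other model parameters; only the trait block is updated).
#' @param phylogeny A `phylogeny`.
#' @param priors Output of [model_priors()].
#' @param model A `neutral_model` (the trait block does not use it beyond
#'   state bookkeeping; defaults to Jukes-Cantor).
#' @param n_inner Number of inner Metropolis iterations (default 500).
#' @param mix Probability of a parameter move per iteration (default 0.6).
#' @param prop_sd_log_param Random-walk s.d. on the log-parameter scale.
#' @param prop_sd_trait_factor Scale factor of the latent-trait walk.
#' @return List with updated `params`, `y`, and acceptance counts.
#' @export
step1_update_trait <- function(element, y, z, params, phylogeny,
                               priors = model_priors(),
                               model = neutral_model_jc(), n_inner = 500,
                               mix = 0.6, prop_sd_log_param = 0.3,
                               prop_sd_trait_factor = 0.5) {
  phy <- phylogeny
  .check_states(z, phy)
  p <- .params_vector(utils::modifyList(
    list(r2 = 1, r3 = 1, a = 0.5, b = 0.5, c = 0.5), params))
  res <- cpp_step1(.pack_tree(phy), model$Q, model$pi,
                   element$X, .obs_int(element), as.numeric(y),
                   .obsy_int(element, phy), as.integer(z), p, priors,
                   as.integer(n_inner), mix, prop_sd_log_param,
                   prop_sd_trait_factor)
  list(params = as.list(res$params), y = res$y, accept = res$accept)
}
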