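# Internal plumbing between R-side objects and the C++ sampler kernels.

.pack_tree <- function(phy) {
  parent <- phy$parent
  parent[phy$root] <- 0L
  child1 <- phy$children[, 1]
  child2 <- phy$children[, 2]
  child1[is.na(child1)] <- 0L
  child2[is.na(child2)] <- 0L
  tlen <- phy$branch_length
  tlen[phy$root] <- 0
  list(L = phy$L, N = phy$N, parent = as.integer(parent),
       child1 = as.integer(child1), child2 = as.integer(child2),
       postorder = as.integer(phy$postorder), tlen = as.numeric(tlen))
}

.pack_priors <- function(priors = model_priors()) {
  priors
}

#' Prior specification for the model
#'
#' Defaults follow the model's standard prior: `r2 ~ Gamma(shape 5, scale
#' 0.04)` (mean 0.2), `r3 ~ Gamma(shape 10, scale 0.2)` (mean 2),
#' `log sigma2 ~ Normal(0, var 2)`, `log beta2, log beta3 ~ Normal(0, var
#' 1)`, root trait `~ Normal(0, 1)`, `a, b, c ~ Beta(1, 1)`, and root
#' conservation state prior `(0.5, 0.5, 0)` (no mass on accelerated at the
#' root, since candidate elements are ascertained as broadly conserved).
#' All Normal second parameters are variances.
#'
#' @param r2_shape,r2_scale,r3_shape,r3_scale Gamma prior (shape-scale) for
#'   the conserved and accelerated substitution rate multipliers.
#' @param log_sigma2_var,log_beta_var,root_trait_var Variances of the
#'   Normal priors on `log sigma2`, `log beta2` / `log beta3`, and the root
#'   trait value.
#' @param phi_alpha,phi_beta Beta pseudo-counts shared by `a`, `b`, `c`.
#' @param root_state_prior Probability triple for the root state.
#' @return A named list of prior hyper-parameters.
#' @export
model_priors <- function(r2_shape = 5, r2_scale = 0.04,
                         r3_shape = 10, r3_scale = 0.2,
                         log_sigma2_var = 2, log_beta_var = 1,
                         root_trait_var = 1,
                         phi_alpha = 1, phi_beta = 1,
                         root_state_prior = c(0.5, 0.5, 0)) {
  stopifnot(r2_shape > 0, r2_scale > 0, r3_shape > 0, r3_scale > 0,
            log_sigma2_var > 0, log_beta_var > 0, root_trait_var > 0,
            phi_alpha > 0, phi_beta > 0,
            length(root_state_prior) == 3, all(root_state_prior >= 0),
            abs(sum(root_state_prior) - 1) < 1e-12)
  list(r2_shape = r2_shape, r2_scale = r2_scale,
       r3_shape = r3_shape, r3_scale = r3_scale,
       log_sigma2_var = log_sigma2_var, log_beta_var = log_beta_var,
       root_trait_var = root_trait_var,
       phi_alpha = phi_alpha, phi_beta = phi_beta,
       root_state_prior = as.numeric(root_state_prior))
}

# Draw model parameters from their priors (used for overdispersed chain
# starts and by the simulator's prior-replicate mode).
.draw_prior_params <- function(priors = model_priors()) {
  list(a = stats::rbeta(1, priors$phi_alpha, priors$phi_beta),
       b = stats::rbeta(1, priors$phi_alpha, priors$phi_beta),
       c = stats::rbeta(1, priors$phi_alpha, priors$phi_beta),
       r2 = stats::rgamma(1, shape = priors$r2_shape, scale = priors$r2_scale),
       r3 = stats::rgamma(1, shape = priors$r3_shape, scale = priors$r3_scale),
       sigma2 = exp(stats::rnorm(1, 0, sqrt(priors$log_sigma2_var))),
       beta2 = exp(stats::rnorm(1, 0, sqrt(priors$log_beta_var))),
       beta3 = exp(stats::rnorm(1, 0, sqrt(priors$log_beta_var))))
}

.params_vector <- function(p) {
  c(r2 = p$r2, r3 = p$r3, sigma2 = p$sigma2, beta2 = p$beta2,
    beta3 = p$beta3, a = p$a, b = p$b, c = p$c)
}

# obs matrix as integer for C++
.obs_int <- function(element) {
  m <- element$obs_mask
  storage.mode(m) <- "integer"
  m
}

.obsy_int <- function(element, phy) {
  obsy <- integer(phy$N)
  obsy[seq_len(phy$L)][element$observed_trait] <- 1L
  obsy
}
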