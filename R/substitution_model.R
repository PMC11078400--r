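#' Branch transition matrix under a state-modulated neutral process
#'
#' Computes `expm(Q * rate * t)`: the nucleotide transition probabilities
#' along a branch of length `t` whose conservation state scales the neutral
#' rate matrix by `rate`. Rows are renormalized only if numerical drift
#' exceeds `1e-12`.
#'
#' @param model A `neutral_model`.
#' @param rate Positive rate multiplier (1 = background).
#' @param t Positive branch length in expected substitutions per site.
#' @return A 4x4 row-stochastic matrix over A, C, G, T.
#' @examples
#' m <- neutral_model_jc()
#' P <- branch_transition_matrix(m, 1, 0.3)
#' P[1, 1]  # 1/4 + 3/4 * exp(-(4/3) * 0.3)
#' @export
branch_transition_matrix <- function(model, rate, t) {
  stopifnot(inherits(model, "neutral_model"), rate > 0, t > 0)
  P <- cpp_branch_matrix(model$Q, model$pi, rate, t)
  if (any(!is.finite(P)))
    stop("numerical error: non-finite transition matrix at rate = ", rate,
         ", t = ", t)
  dimnames(P) <- dimnames(model$Q)
  P
}

#' Pruning pass: per-node partial likelihoods of the leaf data
#'
#' Runs the postorder pruning recursion over the alignment given fixed
#' conservation states and rate multipliers, with per-site log-scaling to
#' prevent underflow. For node `i` and site `s` the partial likelihood is
#' the probability of the observed leaf data below `i` conditional on each
#' of the four possible nucleotides at `i`; observed leaves contribute
#' indicator vectors and missing cells all-ones vectors.
#'
#' @param element An `element_data`.
#' @param z Integer vector of per-node conservation states (1, 2, 3); the
#'   root entry is ignored by the recursion.
#' @param rates List or vector with `r2`, `r3` (background rate is fixed
#'   at 1).
#' @param phylogeny A `phylogeny`.
#' @param model A `neutral_model`.
#' @return List with `log_partials` (4 x S x N array), `site_loglik`
#'   (length-S vector of root-summed log likelihoods), and `loglik`.
#' @export
prune_partials <- function(element, z, rates, phylogeny, model) {
  .check_states(z, phylogeny)
  res <- cpp_prune(.pack_tree(phylogeny), model$Q, model$pi, element$X,
                   .obs_int(element), as.integer(z),
                   rates[["r2"]], rates[["r3"]], model_priors())
  res
}

#' Forward-sample ancestral nucleotides
#'
#' Draws ancestral sequences (and missing leaf cells) from their exact
#' conditional distribution given the observed leaves, the conservation
#' states and the rate multipliers: root sites proportional to
#' `pi * partial`, then root-to-tips proportional to
#' `partial * P(parent -> x)`.
#'
#' @inheritParams prune_partials
#' @param ndraws Number of independent draws (the pruning pass is shared).
#' @return List with `counts` (4 x S x N array of per-nucleotide draw
#'   counts) and `last_X` (the final sampled `N x S` matrix).
#' @export
sample_ancestral_nucleotides <- function(element, z, rates, phylogeny, model,
                                         ndraws = 1) {
  .check_states(z, phylogeny)
  cpp_sample_ancestors(.pack_tree(phylogeny), model$Q, model$pi, element$X,
                       .obs_int(element), as.integer(z),
                       rates[["r2"]], rates[["r3"]], model_priors(),
                       as.integer(ndraws))
}

.check_states <- function(z, phylogeny) {
  if (length(z) != phylogeny$N || anyNA(z) || !all(z %in% 1:3))
    stop("contract violation: z must assign a state in {1,2,3} to every node")
  invisible(TRUE)
}
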