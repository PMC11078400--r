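#' Conservation-state transition matrix
#'
#' Builds the 3x3 root-to-tip Markov matrix over conservation states
#' (1 = background, 2 = conserved, 3 = accelerated):
#' rows `(1-c, c, 0)`, `(0, 1-a, a)`, `(0, b, 1-b)`. The structural zeros
#' forbid returning to background and jumping straight from background to
#' accelerated; because `b > 0`, bursts of acceleration on internal branches
#' can revert to conservation.
#'
#' @param a,b,c Transition probabilities, each strictly inside (0, 1):
#'   `a` conserved to accelerated, `b` accelerated to conserved,
#'   `c` background to conserved.
#' @return A 3x3 row-stochastic matrix.
#' @export
build_phi <- function(a, b, c) {
  for (p in list(a = a, b = b, c = c))
    if (!is.numeric(p) || length(p) != 1 || is.na(p) || p <= 0 || p >= 1)
      stop("a, b, c must each lie strictly inside (0, 1)")
  matrix(c(1 - c, c, 0,
           0, 1 - a, a,
           0, b, 1 - b), 3, 3, byrow = TRUE)
}

#' Backward messages for conservation-state sampling
#'
#' Tips-to-root recursion computing, for every non-root node `i` and
#' candidate state `k`, the log joint likelihood of the sequence and trait
#' emissions in the subtree at `i` given the parent's (current) nucleotides
#' and trait value: the per-site log transition probabilities of the branch
#' above `i` under rate `r_k`, plus the Brownian branch density under
#' variance `v_k`, plus the children's messages mixed through the state
#' transition matrix (log-sum-exp).
#'
#' @param element An `element_data` whose `X` rows must be fully populated
#'   (observed and currently imputed ancestral nucleotides).
#' @param y Fully populated trait vector.
#' @param params List with `r2`, `r3`, `sigma2`, `beta2`, `beta3`, `a`,
#'   `b`, `c`.
#' @param phylogeny A `phylogeny`.
#' @param model A `neutral_model`.
#' @param priors Output of [model_priors()].
#' @return An `N x 3` matrix of log messages (root row unused).
#' @export
backward_messages <- function(element, y, params, phylogeny, model,
                              priors = model_priors()) {
  phy <- phylogeny
  if (anyNA(element$X)) stop("contract violation: X has unpopulated entries")
  if (anyNA(y) || length(y) != phy$N)
    stop("contract violation: y must be fully populated")
  z0 <- rep(1L, phy$N)
  res <- cpp_messages(.pack_tree(phy), model$Q, model$pi, element$X,
                      .obs_int(element), as.numeric(y),
                      .obsy_int(element, phy), z0,
                      .params_vector(params), priors)
  res$messages
}

#' Sample conservation states root-to-tips (Step 3)
#'
#' Draws the per-branch conservation states from their exact joint
#' conditional given the messages: the root from the root-state prior
#' combined with its children's mixed messages, then each descendant
#' proportional to `exp(message) * Phi[parent state, ]`.
#'
#' @inheritParams backward_messages
#' @param ndraws Number of draws (messages computed once).
#' @return List with `counts` (`N x 3` draw counts) and `last_z`.
#' @export
sample_states <- function(element, y, params, phylogeny, model,
                          priors = model_priors(), ndraws = 1) {
  phy <- phylogeny
  z0 <- rep(1L, phy$N)
  cpp_sample_states(.pack_tree(phy), model$Q, model$pi, element$X,
                    .obs_int(element), as.numeric(y),
                    .obsy_int(element, phy), z0,
                    .params_vector(params), priors, as.integer(ndraws))
}

#' Conjugate Beta update of the transition parameters (Step 5)
#'
#' Counts parent-to-child state transitions over all edges and draws
#' `c ~ Beta(alpha + n12, beta + n11)`, `a ~ Beta(alpha + n23, beta + n22)`,
#' `b ~ Beta(alpha + n32, beta + n33)` with Beta(1, 1) pseudo-counts by
#' default.
#'
#' @param z Per-node conservation states (root included).
#' @param phylogeny A `phylogeny`.
#' @param priors Output of [model_priors()] (supplies the pseudo-counts).
#' @return List with sampled `a`, `b`, `c`, the transition `counts`
#'   (3x3 matrix), and the Beta `shapes` actually used.
#' @export
update_phi <- function(z, phylogeny, priors = model_priors()) {
  phy <- phylogeny
  .check_states(z, phy)
  nonroot <- setdiff(seq_len(phy$N), phy$root)
  counts <- matrix(0, 3, 3,
                   dimnames = list(paste0("from", 1:3), paste0("to", 1:3)))
  for (j in nonroot)
    counts[z[phy$parent[j]], z[j]] <- counts[z[phy$parent[j]], z[j]] + 1
  if (counts[2, 1] > 0 || counts[3, 1] > 0 || counts[1, 3] > 0)
    stop("internal-consistency error: observed transition with zero ",
         "probability under the state process")
  al <- priors$phi_alpha
  be <- priors$phi_beta
  shapes <- list(c = c(al + counts[1, 2], be + counts[1, 1]),
                 a = c(al + counts[2, 3], be + counts[2, 2]),
                 b = c(al + counts[3, 2], be + counts[3, 3]))
  list(c = stats::rbeta(1, shapes$c[1], shapes$c[2]),
       a = stats::rbeta(1, shapes$a[1], shapes$a[2]),
       b = stats::rbeta(1, shapes$b[1], shapes$b[2]),
       counts = counts, shapes = shapes)
}
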