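#' Simulate conservation states down a tree
#'
#' Draws the root state from `root_prior` (default puts no mass on the
#' accelerated state) and each child state from the row of `phi` indexed by
#' its parent's state, root to tips.
#'
#' @param phylogeny A `phylogeny`.
#' @param phi 3x3 state transition matrix from [build_phi()].
#' @param root_prior Probability triple for the root state.
#' @return Integer vector of per-node states (1, 2, 3), root included.
#' @export
sim_z <- function(phylogeny, phi, root_prior = c(0.5, 0.5, 0)) {
  phy <- phylogeny
  z <- integer(phy$N)
  z[phy$root] <- sample.int(3L, 1, prob = root_prior)
  for (node in rev(phy$postorder)) {
    if (node == phy$root) next
    z[node] <- sample.int(3L, 1, prob = phi[z[phy$parent[node]], ])
  }
  z
}

#' Simulate an alignment under state-modulated substitution
#'
#' Root sites are drawn i.i.d. from the stationary distribution; each child
#' site is drawn from the row of `expm(Q * r_z * t)` indexed by the parent's
#' nucleotide.
#'
#' @param phylogeny A `phylogeny`.
#' @param z Per-node conservation states.
#' @param rates Vector or list with `r2` and `r3` (background rate 1), or a
#'   length-`N` numeric vector of per-branch rate multipliers (used by the
#'   uniform-rate false-positive scenarios).
#' @param model A `neutral_model`.
#' @param S Number of sites.
#' @return List with `alignment` (named character vector of leaf
#'   sequences) and `X_full` (`N x S` integer matrix including ancestral
#'   truth).
#' @export
sim_X <- function(phylogeny, z, rates, model, S) {
  phy <- phylogeny
  stopifnot(S >= 1)
  if (is.numeric(rates) && length(rates) == phy$N) {
    branch_rate <- rates
  } else {
    r <- c(1, rates[["r2"]], rates[["r3"]])
    branch_rate <- r[z]
  }
  X <- matrix(NA_integer_, phy$N, S)
  X[phy$root, ] <- sample.int(4L, S, replace = TRUE, prob = model$pi)
  for (node in rev(phy$postorder)) {
    if (node == phy$root) next
    P <- branch_transition_matrix(model, branch_rate[node],
                                  phy$branch_length[node])
    xp <- X[phy$parent[node], ]
    for (b in 1:4) {
      idx <- which(xp == b)
      if (length(idx))
        X[node, idx] <- sample.int(4L, length(idx), replace = TRUE,
                                   prob = P[b, ])
    }
  }
  nt <- c("a", "c", "g", "t")
  alignment <- vapply(seq_len(phy$L),
                      function(i) paste(nt[X[i, ]], collapse = ""), "")
  names(alignment) <- phy$leaf_label
  list(alignment = alignment, X_full = X)
}

#' Simulate a continuous trait under state-modulated Brownian motion
#'
#' The root value is drawn from `Normal(root_mean, root_var)`; each child
#' value from `Normal(parent value, t * v_state)`.
#'
#' @param phylogeny A `phylogeny`.
#' @param z Per-node conservation states.
#' @param vp List with `sigma2`, `beta2`, `beta3`.
#' @param root_mean,root_var Root trait prior (defaults Normal(0, 1)).
#' @return List with `trait` (named observed leaf values) and `y_full`
#'   (length-`N` vector including ancestral truth).
#' @export
sim_y <- function(phylogeny, z, vp, root_mean = 0, root_var = 1) {
  phy <- phylogeny
  v <- variance_multipliers(vp$sigma2, vp$beta2, vp$beta3)
  y <- numeric(phy$N)
  y[phy$root] <- stats::rnorm(1, root_mean, sqrt(root_var))
  for (node in rev(phy$postorder)) {
    if (node == phy$root) next
    y[node] <- stats::rnorm(1, y[phy$parent[node]],
                            sqrt(phy$branch_length[node] * v[z[node]]))
  }
  trait <- y[seq_len(phy$L)]
  names(trait) <- phy$leaf_label
  list(trait = trait, y_full = y)
}

#' Simulation configuration
#'
#' @param S Number of alignment sites.
#' @param draw_from_prior If `TRUE`, all model parameters are drawn from
#'   their priors; fixed values below override individual draws.
#' @param a,b,c,r2,r3,sigma2,beta2,beta3 Optional fixed parameter values.
#' @param neutral_override Optional single rate multiplier applied to every
#'   branch (the uniform-rate false-positive scenarios); when set, no
#'   conservation states drive the sequence simulation and `beta2` and
#'   `beta3` are fixed at 1.
#' @param fixed_trait Optional named numeric vector of leaf trait values to
#'   use instead of simulating the trait.
#' @return A `sim_config` list.
#' @export
sim_config <- function(S = 80, draw_from_prior = TRUE, a = NULL, b = NULL,
                       c = NULL, r2 = NULL, r3 = NULL, sigma2 = NULL,
                       beta2 = NULL, beta3 = NULL, neutral_override = NULL,
                       fixed_trait = NULL) {
  fixed <- list(a = a, b = b, c = c, r2 = r2, r3 = r3, sigma2 = sigma2,
                beta2 = beta2, beta3 = beta3)
  for (nm in c("a", "b", "c")) {
    v <- fixed[[nm]]
    if (!is.null(v) && (v <= 0 || v >= 1))
      stop(nm, " must lie strictly inside (0, 1)")
  }
  for (nm in c("r2", "r3", "sigma2", "beta2", "beta3")) {
    v <- fixed[[nm]]
    if (!is.null(v) && v <= 0) stop(nm, " must be positive")
  }
  if (!is.null(neutral_override) && neutral_override <= 0)
    stop("neutral_override must be positive")
  structure(list(S = S, draw_from_prior = draw_from_prior, fixed = fixed,
                 neutral_override = neutral_override,
                 fixed_trait = fixed_trait), class = "sim_config")
}

#' Simulate one study replicate
#'
#' In prior mode, draws `(a, b, c)` from Beta(1, 1), `r2` from
#' Gamma(shape 5, scale 0.04), `r3` from Gamma(shape 10, scale 0.2),
#' `log sigma2` from Normal(0, variance 2) and `log beta2`, `log beta3`
#' from Normal(0, variance 1) (any value fixed in `config` overrides its
#' draw), simulates conservation states, then an alignment and a trait.
#' With `neutral_override` set, the state simulation is skipped for the
#' sequence: one rate multiplier applies to every branch, `beta2 = beta3 =
#' 1`, and the trait is either simulated under plain Brownian motion with
#' the drawn `sigma2` or fixed to `config$fixed_trait`.
#'
#' @param phylogeny A `phylogeny`.
#' @param model A `neutral_model`.
#' @param config A [sim_config()].
#' @param priors Output of [model_priors()].
#' @return List with `params` (true parameter values), `z` (true states),
#'   `alignment`, `trait`, `X_full`, `y_full`.
#' @export
sim_study_replicate <- function(phylogeny, model, config = sim_config(),
                                priors = model_priors()) {
  phy <- phylogeny
  p <- if (config$draw_from_prior) .draw_prior_params(priors)
       else list(a = 0.5, b = 0.5, c = 0.5, r2 = 0.2, r3 = 2,
                 sigma2 = 1, beta2 = 1, beta3 = 1)
  for (nm in names(config$fixed))
    if (!is.null(config$fixed[[nm]])) p[[nm]] <- config$fixed[[nm]]

  if (!is.null(config$neutral_override)) {
    p$beta2 <- 1
    p$beta3 <- 1
    z <- rep(1L, phy$N)
    branch_rate <- rep(config$neutral_override, phy$N)
    sx <- sim_X(phy, z, branch_rate, model, config$S)
  } else {
    z <- sim_z(phy, build_phi(p$a, p$b, p$c), priors$root_state_prior)
    sx <- sim_X(phy, z, p, model, config$S)
  }

  if (!is.null(config$fixed_trait)) {
    miss <- setdiff(phy$leaf_label, names(config$fixed_trait))
    if (length(miss))
      stop("fixed_trait lacks species: ", paste(miss, collapse = ", "))
    trait <- config$fixed_trait[phy$leaf_label]
    y_full <- NULL
  } else {
    sy <- sim_y(phy, z, p, root_mean = 0, root_var = priors$root_trait_var)
    trait <- sy$trait
    y_full <- sy$y_full
  }

  list(params = p, z = z, alignment = sx$alignment, trait = trait,
       X_full = sx$X_full, y_full = y_full)
}

#' Write a simulated replicate to disk
#'
#' Emits a FASTA alignment, a two-column tab-separated trait table, and a
#' tab-separated truth file holding the generating parameter values and the
#' per-node conservation states, so that simulated data round-trips through
#' the standard loaders.
#'
#' @param rep A replicate from [sim_study_replicate()].
#' @param prefix Output path prefix; files `<prefix>.fa`,
#'   `<prefix>.trait.tsv`, `<prefix>.truth.tsv` are written.
#' @return Invisibly, the three paths.
#' @export
write_replicate <- function(rep, prefix) {
  fa <- paste0(prefix, ".fa")
  tr <- paste0(prefix, ".trait.tsv")
  th <- paste0(prefix, ".truth.tsv")
  write_element(rep$alignment, rep$trait, fa, tr)
  pars <- rep$params
  truth <- data.frame(
    key = c(names(pars), paste0("z_node", seq_along(rep$z))),
    value = c(unlist(pars), rep$z))
  utils::write.table(truth, th, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(fa, tr, th))
}
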