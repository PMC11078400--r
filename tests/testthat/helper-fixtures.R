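# Shared fixtures and independent oracles. Oracles use Matrix::expm and
# explicit enumeration so they share no code path with the package kernels.

tree2 <- function() parse_newick("(A:0.1,B:0.2);")
tree3 <- function() parse_newick("((A:0.1,B:0.1):0.1,C:0.2);")
tree4 <- function()
  parse_newick("((A:0.1,B:0.25):0.15,(C:0.3,D:0.12):0.2);")

jc <- function() neutral_model_jc()
gtr <- function() neutral_model_gtr()

# build an element_data from in-memory sequences / traits
element_from <- function(phy, seqs, trait = NULL, model = jc(), seed = 42) {
  if (is.null(trait)) {
    trait <- stats::setNames(rep(0, phy$L), phy$leaf_label)
  }
  set.seed(seed)
  load_element(seqs,
               data.frame(species = names(trait), value = unname(trait)),
               phy, model)
}

default_params <- function(...) {
  utils::modifyList(list(r2 = 0.3, r3 = 2.5, sigma2 = 1, beta2 = 1,
                         beta3 = 1, a = 0.3, b = 0.4, c = 0.25), list(...))
}

# independent matrix exponential
oracle_pmat <- function(model, rate, t) {
  as.matrix(Matrix::expm(model$Q * rate * t))
}

# per-site sequence likelihood by enumeration over every latent nucleotide
# xsite: length-N vector of codes 1..4, NA where latent/missing
oracle_site_lik <- function(phy, model, xsite, z, r2, r3) {
  r <- c(1, r2, r3)
  P <- vector("list", phy$N)
  for (j in seq_len(phy$N))
    if (j != phy$root)
      P[[j]] <- oracle_pmat(model, r[z[j]], phy$branch_length[j])
  free <- which(is.na(xsite))
  if (!length(free)) {
    p <- model$pi[xsite[phy$root]]
    for (j in seq_len(phy$N))
      if (j != phy$root) p <- p * P[[j]][xsite[phy$parent[j]], xsite[j]]
    return(unname(p))
  }
  grid <- as.matrix(expand.grid(rep(list(1:4), length(free))))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    x <- xsite
    x[free] <- grid[g, ]
    p <- model$pi[x[phy$root]]
    for (j in seq_len(phy$N))
      if (j != phy$root) p <- p * P[[j]][x[phy$parent[j]], x[j]]
    tot <- tot + p
  }
  unname(tot)
}

# per-node posterior P(X_node = x | leaves) by enumeration, one site
oracle_anc_posterior <- function(phy, model, xsite, z, r2, r3) {
  r <- c(1, r2, r3)
  P <- vector("list", phy$N)
  for (j in seq_len(phy$N))
    if (j != phy$root)
      P[[j]] <- oracle_pmat(model, r[z[j]], phy$branch_length[j])
  free <- which(is.na(xsite))
  grid <- as.matrix(expand.grid(rep(list(1:4), length(free))))
  post <- matrix(0, phy$N, 4)
  for (g in seq_len(nrow(grid))) {
    x <- xsite
    x[free] <- grid[g, ]
    p <- model$pi[x[phy$root]]
    for (j in seq_len(phy$N))
      if (j != phy$root) p <- p * P[[j]][x[phy$parent[j]], x[j]]
    for (i in seq_len(phy$N)) post[i, x[i]] <- post[i, x[i]] + p
  }
  sweep(post, 1, rowSums(post), "/")
}

# joint posterior over conservation-state configurations by enumeration:
# conditions on fully imputed X (N x S) and y, exactly as the Gibbs step
oracle_z_posterior <- function(phy, model, X, y, params,
                               priors = model_priors()) {
  N <- phy$N
  phi <- build_phi(params$a, params$b, params$c)
  v <- variance_multipliers(params$sigma2, params$beta2, params$beta3)
  r <- c(1, params$r2, params$r3)
  Pk <- vector("list", 3 * N)
  for (j in seq_len(N))
    if (j != phy$root)
      for (k in 1:3)
        Pk[[(j - 1) * 3 + k]] <- oracle_pmat(model, r[k],
                                             phy$branch_length[j])
  grid <- as.matrix(expand.grid(rep(list(1:3), N)))
  w <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    z <- grid[g, ]
    p <- priors$root_state_prior[z[phy$root]]
    if (p == 0) { w[g] <- 0; next }
    for (j in seq_len(N)) {
      if (j == phy$root) next
      pa <- phy$parent[j]
      p <- p * phi[z[pa], z[j]]
      if (p == 0) break
      Pj <- Pk[[(j - 1) * 3 + z[j]]]
      for (s in seq_len(ncol(X))) p <- p * Pj[X[pa, s], X[j, s]]
      p <- p * stats::dnorm(y[j], y[pa],
                            sqrt(phy$branch_length[j] * v[z[j]]))
    }
    w[g] <- p
  }
  w <- w / sum(w)
  marg <- matrix(0, N, 3)
  for (g in seq_len(nrow(grid)))
    for (i in seq_len(N)) marg[i, grid[g, i]] <- marg[i, grid[g, i]] + w[g]
  list(config = grid, prob = w, marginal = marg)
}

# Kolmogorov-Smirnov p-value helper for prior-recovery checks
ks_p <- function(x, cdf, ...) {
  suppressWarnings(stats::ks.test(x, cdf, ...)$p.value)
}
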