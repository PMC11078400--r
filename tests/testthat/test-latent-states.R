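test_that("the state transition matrix has the documented structure", {
  phi <- build_phi(0.5, 0.5, 0.5)
  expect_equal(phi, matrix(c(0.5, 0.5, 0,
                             0, 0.5, 0.5,
                             0, 0.5, 0.5), 3, 3, byrow = TRUE))
  for (p in list(c(0.1, 0.9, 0.3), c(0.99, 0.01, 0.5))) {
    phi <- build_phi(p[1], p[2], p[3])
    expect_equal(rowSums(phi), rep(1, 3))
    expect_equal(phi[1, 3], 0)  # background cannot jump to accelerated
    expect_equal(phi[2, 1], 0)  # no return to background
    expect_equal(phi[3, 1], 0)
  }
  expect_error(build_phi(0, 0.5, 0.5), "strictly inside")
  expect_error(build_phi(0.5, 1, 0.5), "strictly inside")
  expect_error(build_phi(0.5, 0.5, 1.2), "strictly inside")
})

test_that("leaf messages are emission-only and match a direct computation", {
  phy <- tree3()
  g <- gtr()
  el <- element_from(phy, c(A = "AC", B = "CC", C = "GT"),
                     trait = c(A = 0.4, B = -0.1, C = 1))
  params <- default_params(sigma2 = 0.7, beta2 = 2, beta3 = 0.3)
  msg <- backward_messages(el, el$y, params, phy, gtr())
  v <- variance_multipliers(0.7, 2, 0.3)
  r <- c(1, params$r2, params$r3)
  for (leaf in 1:3) {
    pa <- phy$parent[leaf]
    for (k in 1:3) {
      P <- oracle_pmat(g, r[k], phy$branch_length[leaf])
      seq_em <- sum(log(P[cbind(el$X[pa, ], el$X[leaf, ])]))
      trait_em <- dnorm(el$y[leaf], el$y[pa],
                        sqrt(phy$branch_length[leaf] * v[k]), log = TRUE)
      expect_equal(msg[leaf, k], seq_em + trait_em, tolerance = 1e-9)
    }
  }
})

test_that("state sampling matches brute-force enumeration", {
  phy <- tree3()
  g <- gtr()
  el <- element_from(phy, c(A = "AC", B = "CC", C = "GT"),
                     trait = c(A = 0.4, B = -0.1, C = 1.4))
  params <- default_params(sigma2 = 0.7, beta2 = 2.5, beta3 = 0.3)
  oracle <- oracle_z_posterior(phy, g, el$X, el$y, params)
  ndraws <- 100000
  set.seed(17)
  res <- sample_states(el, el$y, params, phy, g, ndraws = ndraws)
  freq <- res$counts / ndraws
  for (i in seq_len(phy$N)) {
    se <- pmax(sqrt(oracle$marginal[i, ] * (1 - oracle$marginal[i, ]) /
                      ndraws), 1e-4)
    expect_true(all(abs(freq[i, ] - oracle$marginal[i, ]) <= 3.5 * se),
                info = paste("node", i))
  }
  # root is never accelerated and structural zeros hold on every path
  expect_equal(freq[phy$root, 3], 0)
})

test_that("messages collapse to state-independence when emissions are flat", {
  phy <- tree4()
  el <- element_from(phy, c(A = "ACGT", B = "ACGT", C = "ACGT", D = "ACGT"),
                     trait = c(A = 1, B = 0.5, C = 0, D = -0.5))
  params <- default_params(r2 = 1, r3 = 1, beta2 = 1, beta3 = 1)
  msg <- backward_messages(el, el$y, params, phy, jc())
  for (leaf in 1:4)
    expect_equal(msg[leaf, 1], msg[leaf, 3], tolerance = 1e-10)
})

test_that("c -> 0 with a background root freezes the whole tree in background", {
  phy <- tree4()
  el <- element_from(phy, c(A = "A", B = "A", C = "A", D = "A"),
                     trait = c(A = 0, B = 0, C = 0, D = 0))
  params <- default_params(r2 = 1, r3 = 1, beta2 = 1, beta3 = 1, c = 1e-12)
  set.seed(2)
  # force the root into background so the limit applies to the whole tree
  res <- sample_states(el, el$y, params, phy, jc(),
                       priors = model_priors(root_state_prior = c(1, 0, 0)),
                       ndraws = 5000)
  expect_equal(res$counts[, 1], rep(5000, phy$N))
})

test_that("transition-parameter update uses the exact conjugate Beta shapes", {
  phy <- parse_newick(
    "(((a:1,b:1):1,(c:1,d:1):1):1,((e:1,f:1):1,(g:1,h:1):1):1);")
  # hand-built states: root background; one 1->2 chain with a 2->3 burst
  z <- integer(phy$N)
  z[phy$root] <- 1L
  for (node in rev(phy$postorder)) {
    if (node == phy$root) next
    z[node] <- z[phy$parent[node]]
  }
  # flip specific edges: children of root stay background, one subtree conserved
  rc <- phy$children[phy$root, ]
  z[rc[1]] <- 2L
  for (node in rev(phy$postorder))
    if (node != phy$root && z[phy$parent[node]] == 2L) z[node] <- 2L
  acc_node <- phy$children[rc[1], 1]
  z[acc_node] <- 3L  # one 2->3 transition
  res <- update_phi(z, phy)
  n <- res$counts
  expect_equal(unname(res$shapes$c), c(1 + n[1, 2], 1 + n[1, 1]))
  expect_equal(unname(res$shapes$a), c(1 + n[2, 3], 1 + n[2, 2]))
  expect_equal(unname(res$shapes$b), c(1 + n[3, 2], 1 + n[3, 3]))
  expect_equal(n[1, 2] , 1)  # the single 1->2 edge we created
  expect_equal(n[2, 3], 1)
  expect_equal(sum(n), phy$E)

  # all-background states: a and b revert to their Beta(1,1) prior
  zbg <- rep(1L, phy$N)
  res2 <- update_phi(zbg, phy)
  expect_equal(unname(res2$shapes$a), c(1, 1))
  expect_equal(unname(res2$shapes$b), c(1, 1))
  expect_equal(unname(res2$shapes$c), c(1, 1 + phy$E))

  # forbidden transitions raise an internal-consistency error
  zbad <- zbg
  zbad[phy$root] <- 2L
  zbad[phy$children[phy$root, 1]] <- 1L
  expect_error(update_phi(zbad, phy), "zero")
})

test_that("repeated conjugate draws have the Beta posterior mean", {
  phy <- tree4()
  z <- c(2L, 2L, 1L, 1L, 2L, 1L, 1L)  # n12 = 1 (edge 5), n11 = 3
  res <- update_phi(z, phy)
  n12 <- res$counts[1, 2]; n11 <- res$counts[1, 1]
  set.seed(4)
  draws <- replicate(20000, update_phi(z, phy)$c)
  expect_equal(mean(draws), (1 + n12) / (2 + n12 + n11), tolerance = 0.01)
})

test_that("an MCMC run never produces forbidden state transitions", {
  phy <- tree4()
  set.seed(8)
  rep <- sim_study_replicate(phy, jc(), sim_config(S = 15))
  el <- element_from(phy, rep$alignment, rep$trait)
  st <- list(params = default_params(), z = sim_z(phy, build_phi(0.3, 0.4, 0.25)),
             y = el$y, X = el$X)
  for (i in 1:50) {
    st <- gibbs_sweep(st, el, phy, jc(), run_config(n_iter = 1, seed = 1))
    z <- st$z
    expect_true(z[phy$root] %in% 1:2)
    for (j in setdiff(seq_len(phy$N), phy$root)) {
      expect_false(z[phy$parent[j]] != 1 && z[j] == 1)
      expect_false(z[phy$parent[j]] == 1 && z[j] == 3)
    }
  }
})
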