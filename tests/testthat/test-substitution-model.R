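test_that("branch transition matrices match closed forms and expm", {
  m <- jc()
  # JC closed form at rate 1, t = 0.3
  P <- branch_transition_matrix(m, 1, 0.3)
  same <- 1 / 4 + 3 / 4 * exp(-(4 / 3) * 0.3)
  expect_equal(unname(diag(P)), rep(same, 4), tolerance = 1e-12)
  expect_equal(unname(P[1, 2]), (1 - same) / 3, tolerance = 1e-12)
  # scaling identity
  expect_equal(branch_transition_matrix(m, 2, 0.1),
               branch_transition_matrix(m, 1, 0.2), tolerance = 1e-12)
  # t -> 0 limit approaches identity
  P0 <- branch_transition_matrix(m, 1, 1e-9)
  expect_equal(unname(P0), diag(4), tolerance = 1e-6)
  # general model agrees with an independent matrix exponential
  g <- gtr()
  for (tt in c(0.05, 0.3, 1.7)) {
    expect_equal(unname(branch_transition_matrix(g, 0.7, tt)),
                 unname(oracle_pmat(g, 0.7, tt)), tolerance = 1e-9)
  }
  # rows are stochastic
  expect_equal(rowSums(branch_transition_matrix(g, 3, 0.4)),
               c(A = 1, C = 1, G = 1, T = 1), tolerance = 1e-10)
})

test_that("pruning matches brute-force enumeration over ancestral states", {
  phy <- tree4()
  g <- gtr()
  z <- c(1L, 2L, 3L, 1L, 2L, 1L, 1L)  # mixed states along the 7 nodes
  el <- element_from(phy, c(A = "ACT", B = "AC-", C = "GCT", D = "ANT"))
  res <- prune_partials(el, z, list(r2 = 0.3, r3 = 2.5), phy, g)
  for (s in 1:3) {
    xsite <- rep(NA_integer_, phy$N)
    xsite[1:4] <- ifelse(el$obs_mask[1:4, s], el$X[1:4, s], NA_integer_)
    expect_equal(res$site_loglik[s],
                 log(oracle_site_lik(phy, g, xsite, z, 0.3, 2.5)),
                 tolerance = 1e-10)
  }
  expect_equal(res$loglik, sum(res$site_loglik))
})

test_that("leaf partials are indicators and all-missing columns marginalize to 1", {
  phy <- tree3()
  el <- element_from(phy, c(A = "A-", B = "A-", C = "A-"))
  z <- rep(1L, phy$N)
  res <- prune_partials(el, z, list(r2 = 0.5, r3 = 2), phy, jc())
  # observed leaf 'A': indicator on the first nucleotide
  expect_equal(exp(res$log_partials[, 1, 1]), c(1, 0, 0, 0))
  # missing leaf cell: all ones
  expect_equal(exp(res$log_partials[, 2, 1]), rep(1, 4))
  # all-missing column has total likelihood exactly 1
  expect_equal(res$site_loglik[2], 0, tolerance = 1e-12)
})

test_that("ancestral sampling matches the enumerated posterior", {
  phy <- tree4()
  g <- gtr()
  z <- c(2L, 1L, 3L, 1L, 1L, 2L, 1L)
  el <- element_from(phy, c(A = "A", B = "C", C = "A", D = "-"))
  ndraws <- 100000
  set.seed(99)
  res <- sample_ancestral_nucleotides(el, z, list(r2 = 0.3, r3 = 2.5),
                                      phy, g, ndraws = ndraws)
  xsite <- rep(NA_integer_, phy$N)
  xsite[1:4] <- ifelse(el$obs_mask[1:4, 1], el$X[1:4, 1], NA_integer_)
  post <- oracle_anc_posterior(phy, g, xsite, z, 0.3, 2.5)
  for (node in c(4, 5, 6, 7)) {  # missing leaf + all ancestors
    freq <- res$counts[, 1, node] / ndraws
    se <- pmax(sqrt(post[node, ] * (1 - post[node, ]) / ndraws), 1e-4)
    expect_true(all(abs(freq - post[node, ]) <= 3 * se),
                info = paste("node", node))
  }
})

test_that("ancestral draws at an all-missing column follow the prior", {
  phy <- tree3()
  g <- gtr()
  el <- element_from(phy, c(A = "-", B = "-", C = "-"))
  set.seed(7)
  res <- sample_ancestral_nucleotides(el, rep(1L, phy$N),
                                      list(r2 = 0.3, r3 = 2), phy, g,
                                      ndraws = 50000)
  freq <- res$counts[, 1, phy$root] / 50000
  se <- sqrt(g$pi * (1 - g$pi) / 50000)
  expect_true(all(abs(freq - g$pi) <= 3.5 * se))
})

test_that("near-zero branches copy the parent state", {
  phy <- parse_newick("(A:1e-8,B:1e-8);")
  el <- element_from(phy, c(A = "A", B = "A"))
  set.seed(1)
  res <- sample_ancestral_nucleotides(el, rep(1L, 3), list(r2 = 1, r3 = 1),
                                      phy, jc(), ndraws = 2000)
  expect_gt(res$counts[1, 1, 3] / 2000, 0.999)
})

test_that("averaged ancestral indicators converge to exact marginals", {
  # marginal-consistency property on a 4-leaf tree with missing data
  phy <- tree4()
  z <- rep(1L, phy$N)
  el <- element_from(phy, c(A = "AG", B = "-G", C = "GT", D = "AT"))
  set.seed(123)
  res <- sample_ancestral_nucleotides(el, z, list(r2 = 0.5, r3 = 2),
                                      phy, jc(), ndraws = 60000)
  for (s in 1:2) {
    xsite <- rep(NA_integer_, phy$N)
    xsite[1:4] <- ifelse(el$obs_mask[1:4, s], el$X[1:4, s], NA_integer_)
    post <- oracle_anc_posterior(phy, jc(), xsite, z, 0.5, 2)
    for (node in 5:7) {
      freq <- res$counts[, s, node] / 60000
      se <- pmax(sqrt(post[node, ] * (1 - post[node, ]) / 60000), 1e-4)
      expect_true(all(abs(freq - post[node, ]) <= 3.5 * se))
    }
  }
})
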