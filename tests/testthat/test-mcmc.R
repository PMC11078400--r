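test_that("a Gibbs sweep preserves all parameter domains and state structure", {
  phy <- tree4()
  set.seed(20)
  rep <- sim_study_replicate(phy, gtr(), sim_config(S = 12))
  el <- element_from(phy, rep$alignment, rep$trait, model = gtr())
  st <- list(params = default_params(), z = rep$z, y = el$y, X = el$X)
  for (i in 1:10) {
    st <- gibbs_sweep(st, el, phy, gtr(), run_config(n_iter = 1))
    p <- st$params
    expect_true(all(unlist(p[c("r2", "r3", "sigma2", "beta2", "beta3")]) > 0))
    expect_true(p$a > 0 && p$a < 1 && p$b > 0 && p$b < 1 && p$c > 0 && p$c < 1)
    expect_true(all(st$z %in% 1:3))
    expect_true(st$z[phy$root] %in% 1:2)
    expect_true(is.finite(st$log_joint))
    expect_true(all(st$X %in% 1:4))
    # observed leaf entries never change
    expect_equal(st$X[el$obs_mask], el$X[el$obs_mask])
  }
})

test_that("fixed seeds reproduce the trajectory exactly", {
  phy <- tree4()
  set.seed(40)
  rep <- sim_study_replicate(phy, jc(), sim_config(S = 10))
  el <- element_from(phy, rep$alignment, rep$trait)
  cfg <- run_config(n_iter = 50, n_chains = 2, seed = 123)
  r1 <- run_chains(el, phy, jc(), cfg)
  r2 <- run_chains(el, phy, jc(), cfg)
  expect_identical(r1$traces, r2$traces)
  r3 <- run_chains(el, phy, jc(), run_config(n_iter = 50, n_chains = 2,
                                             seed = 124))
  expect_false(identical(r1$traces, r3$traces))
})

test_that("log joint decomposes into independently computed factors", {
  phy <- tree3()
  g <- gtr()
  el <- element_from(phy, c(A = "ACG", B = "ACT", C = "GCG"),
                     trait = c(A = 0.5, B = 0, C = -1), model = g)
  z <- c(2L, 2L, 1L, 2L, 1L)
  params <- default_params(sigma2 = 0.9, beta2 = 1.4, beta3 = 0.6)
  st <- list(params = params, z = z, y = el$y, X = el$X)
  lj <- log_joint(el, st, phy, g)

  r <- c(1, params$r2, params$r3)
  seq_block <- sum(log(g$pi[el$X[phy$root, ]]))
  for (j in setdiff(seq_len(phy$N), phy$root)) {
    P <- oracle_pmat(g, r[z[j]], phy$branch_length[j])
    seq_block <- seq_block +
      sum(log(P[cbind(el$X[phy$parent[j], ], el$X[j, ])]))
  }
  trait_block <- trait_log_joint(el$y, z, params, phy)
  phi <- build_phi(params$a, params$b, params$c)
  state_block <- log(0.5) +
    sum(log(phi[cbind(z[phy$parent[-phy$root]], z[-phy$root])]))
  prior_block <-
    dgamma(params$r2, 5, scale = 0.04, log = TRUE) +
    dgamma(params$r3, 10, scale = 0.2, log = TRUE) +
    dnorm(log(params$sigma2), 0, sqrt(2), log = TRUE) +
    dnorm(log(params$beta2), 0, 1, log = TRUE) +
    dnorm(log(params$beta3), 0, 1, log = TRUE) +
    dbeta(params$a, 1, 1, log = TRUE) +
    dbeta(params$b, 1, 1, log = TRUE) +
    dbeta(params$c, 1, 1, log = TRUE)
  expect_equal(lj, seq_block + trait_block + state_block + prior_block,
               tolerance = 1e-8)
})

test_that("rate updates recover their prior when no branch uses them", {
  # with z all-background, r2 and r3 only feel their Gamma priors
  phy <- tree4()
  el <- element_from(phy, c(A = "ACGT", B = "ACGT", C = "ACGT", D = "ACGT"))
  z <- rep(1L, phy$N)
  params <- default_params()
  set.seed(61)
  n <- 6000
  r2d <- r3d <- numeric(n)
  st <- list(params = params, z = z, y = el$y, X = el$X)
  for (i in 1:n) {
    res <- step4_update_rates(el, st, phy, jc(), prop_sd_log_rate = 0.6)
    st$params$r2 <- res$params$r2
    st$params$r3 <- res$params$r3
    r2d[i] <- st$params$r2
    r3d[i] <- st$params$r3
  }
  thin <- seq(200, n, by = 10)
  expect_gt(ks_p(r2d[thin], "pgamma", shape = 5, scale = 0.04), 0.01)
  expect_gt(ks_p(r3d[thin], "pgamma", shape = 10, scale = 0.2), 0.01)
})

test_that("acceptance rate falls as the rate-proposal scale grows", {
  phy <- make_full_binary_tree(4, 0.1)
  set.seed(13)
  rep <- sim_study_replicate(phy, gtr(),
                             sim_config(S = 60, r2 = 0.2, r3 = 2))
  el <- element_from(phy, rep$alignment, rep$trait, model = gtr())
  rates <- vapply(c(0.05, 2.5), function(sc) {
    run <- run_chains(el, phy, gtr(),
                      run_config(n_iter = 150, n_chains = 1, seed = 5,
                                 prop_sd_log_rate = sc))
    unname(run$acceptance["r2"])
  }, 0)
  expect_gt(rates[1], rates[2])
})

test_that("the Gelman-Rubin statistic separates mixed from unmixed chains", {
  set.seed(70)
  iid <- matrix(rnorm(5000 * 3), 5000, 3)
  expect_lt(gelman_rubin(iid), 1.01)
  expect_lt(abs(gelman_rubin(iid, rank_normalize = TRUE) - 1), 0.01)
  shifted <- iid
  shifted[, 2] <- shifted[, 2] + 3
  expect_gt(gelman_rubin(shifted), 1.5)
  # a within-chain trend is caught by the split
  trended <- matrix(rnorm(4000 * 2), 4000, 2) +
    seq(0, 4, length.out = 4000)
  expect_gt(gelman_rubin(trended), 1.2)
})

test_that("chain summaries expose medians, intervals and acceptance rates", {
  phy <- tree4()
  set.seed(91)
  rep <- sim_study_replicate(phy, jc(), sim_config(S = 20))
  el <- element_from(phy, rep$alignment, rep$trait)
  run <- run_chains(el, phy, jc(),
                    run_config(n_iter = 300, n_chains = 2, seed = 2,
                               record_z = TRUE))
  expect_setequal(rownames(run$summary),
                  c("log_sigma2", "log_beta2", "log_beta3", "log_beta_ratio",
                    "r2", "r3", "a", "b", "c", "log_joint"))
  expect_true(all(run$summary[, "q10"] <= run$summary[, "median"]))
  expect_true(all(run$summary[, "median"] <= run$summary[, "q90"]))
  expect_true(all(run$acceptance >= 0 & run$acceptance <= 1))
  expect_true(all(is.finite(run$post)))
  expect_equal(dim(run$zfreq), c(phy$N, 3))
  expect_equal(unname(rowSums(run$zfreq)), rep(1, phy$N), tolerance = 1e-9)
  expect_equal(run$zfreq[phy$root, 3], 0)
})
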