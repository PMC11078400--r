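test_that("simulated states follow the transition matrix", {
  phy <- tree4()
  phi <- build_phi(a = 0.3, b = 0.4, c = 0.25)
  set.seed(10)
  trans <- matrix(0, 3, 3)
  root_states <- integer(10000)
  for (i in 1:10000) {
    z <- sim_z(phy, phi)
    root_states[i] <- z[phy$root]
    for (j in setdiff(seq_len(phy$N), phy$root))
      trans[z[phy$parent[j]], z[j]] <- trans[z[phy$parent[j]], z[j]] + 1
  }
  expect_true(all(root_states %in% 1:2))
  expect_equal(mean(root_states == 1), 0.5, tolerance = 0.02)
  freq <- sweep(trans, 1, rowSums(trans), "/")
  expect_equal(freq, phi, tolerance = 0.02)
  expect_equal(trans[2, 1] + trans[3, 1] + trans[1, 3], 0)
})

test_that("a = c -> 0 propagates the root state to the whole tree", {
  phy <- tree4()
  set.seed(3)
  for (i in 1:20) {
    z <- sim_z(phy, build_phi(1e-12, 0.5, 1e-12))
    expect_true(all(z == z[phy$root]))
  }
})

test_that("two-leaf divergence matches the Jukes-Cantor closed form", {
  phy <- tree2()  # t1 + t2 = 0.3
  m <- jc()
  rate <- 0.4
  d <- rate * 0.3
  p_diff <- 3 / 4 * (1 - exp(-4 * d / 3))
  set.seed(21)
  S <- 20000
  sx <- sim_X(phy, rep(2L, 3), list(r2 = rate, r3 = 1), m, S)
  obs <- mean(sx$X_full[1, ] != sx$X_full[2, ])
  expect_lt(abs(obs - p_diff), 3.5 * sqrt(p_diff * (1 - p_diff) / S))
})

test_that("leaf base frequencies approach the stationary distribution", {
  phy <- parse_newick("(A:30,B:30);")
  g <- gtr()
  set.seed(12)
  sx <- sim_X(phy, rep(1L, 3), list(r2 = 1, r3 = 1), g, 5000)
  freq <- tabulate(sx$X_full[1, ], 4) / 5000
  expect_equal(freq, unname(g$pi), tolerance = 0.03)
})

test_that("trait simulation matches Brownian-motion moments", {
  phy <- tree3()  # A,B sisters sharing a 0.1 branch; depth 0.2
  vp <- list(sigma2 = 1.5, beta2 = 1, beta3 = 1)
  set.seed(33)
  n <- 50000
  ya <- yb <- yc <- numeric(n)
  for (i in 1:n) {
    sy <- sim_y(phy, rep(1L, phy$N), vp)
    ya[i] <- sy$trait["A"]; yb[i] <- sy$trait["B"]; yc[i] <- sy$trait["C"]
  }
  # Var(tip) = root_var + depth * sigma2; Cov(A,B) = root_var + shared path
  expect_equal(var(ya), 1 + 0.2 * 1.5, tolerance = 0.03)
  expect_equal(var(yc), 1 + 0.2 * 1.5, tolerance = 0.03)
  expect_equal(cov(ya, yb), 1 + 0.1 * 1.5, tolerance = 0.03)
  expect_equal(cov(ya, yc), 1, tolerance = 0.03)
})

test_that("accelerated branches show larger displacements per unit length", {
  phy <- tree2()
  vp <- list(sigma2 = 1, beta2 = 0.1, beta3 = 10)
  set.seed(14)
  z <- c(2L, 3L, 1L)  # A conserved, B accelerated
  d2 <- d3 <- numeric(3000)
  for (i in 1:3000) {
    sy <- sim_y(phy, z, vp)
    d2[i] <- (sy$trait["A"] - sy$y_full[3])^2 / phy$branch_length[1]
    d3[i] <- (sy$trait["B"] - sy$y_full[3])^2 / phy$branch_length[2]
  }
  expect_gt(mean(d3), 10 * mean(d2))
})

test_that("prior replicates have the documented prior moments", {
  phy <- tree2()
  set.seed(55)
  pars <- replicate(4000, sim_study_replicate(
    phy, jc(), sim_config(S = 1))$params, simplify = FALSE)
  r2 <- vapply(pars, `[[`, 0, "r2")
  r3 <- vapply(pars, `[[`, 0, "r3")
  lb <- vapply(pars, function(p) log(p$beta3) - log(p$beta2), 0)
  expect_lt(abs(mean(r2) - 5 * 0.04), 0.006)   # E[r2] = 0.2
  expect_lt(abs(mean(r3) - 10 * 0.2), 0.04)    # E[r3] = 2
  # log(beta3/beta2) ~ Normal(0, 2): difference of two standard normals
  expect_equal(mean(lb), 0, tolerance = 0.08)
  expect_equal(var(lb), 2, tolerance = 0.15)
})

test_that("uniform-rate scenarios bypass the state process", {
  phy <- tree4()
  set.seed(9)
  rep <- sim_study_replicate(phy, jc(),
                             sim_config(S = 30, neutral_override = 0.2))
  expect_equal(rep$params$beta2, 1)
  expect_equal(rep$params$beta3, 1)
  expect_true(all(rep$z == 1L))
  # fixed traits pass through unchanged
  tr <- c(A = 1, B = 2, C = 3, D = 4)
  rep2 <- sim_study_replicate(phy, jc(),
                              sim_config(S = 10, neutral_override = 1,
                                         fixed_trait = tr))
  expect_equal(rep2$trait, tr)
})

test_that("replicates are reproducible and round-trip through the loaders", {
  phy <- tree4()
  set.seed(77)
  r1 <- sim_study_replicate(phy, gtr(), sim_config(S = 25))
  set.seed(77)
  r2 <- sim_study_replicate(phy, gtr(), sim_config(S = 25))
  expect_identical(r1, r2)

  dir <- tempfile(); dir.create(dir)
  prefix <- file.path(dir, "rep1")
  paths <- write_replicate(r1, prefix)
  expect_true(all(file.exists(paths)))
  set.seed(1)
  el <- load_element(paths[1], paths[2], phy, gtr())
  expect_equal(el$S, 25)
  obs <- el$X[1:4, ]
  truth <- r1$X_full[1:4, ]
  expect_equal(unname(obs), unname(truth))
  expect_equal(el$y[1:4], unname(r1$trait[phy$leaf_label]))
})

test_that("cmd_simulate writes byte-identical files under a repeated seed", {
  phy <- tree3()
  d1 <- tempfile(); dir.create(d1)
  d2 <- tempfile(); dir.create(d2)
  suppressMessages({
    cmd_simulate(phy, jc(), sim_config(S = 12), file.path(d1, "x"), seed = 5)
    cmd_simulate(phy, jc(), sim_config(S = 12), file.path(d2, "x"), seed = 5)
  })
  for (f in c("x.fa", "x.trait.tsv", "x.truth.tsv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})
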