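test_that("rate-matrix construction honors model structure", {
  Qi <- build_rate_matrix("independent",
                          c(qA01 = 0.3, qA10 = 0.7, qB01 = 1.1, qB10 = 0.2))
  expect_equal(Qi[1, 3], 0.3)   # A gain on B=0
  expect_equal(Qi[1, 2], 1.1)   # B gain on A=0
  expect_equal(Qi[2, 4], 0.3)   # A gain on B=1 equals A gain on B=0
  expect_equal(Qi[3, 4], 1.1)
  expect_equal(Qi[1, 4], 0)     # dual transitions forbidden
  expect_equal(Qi[2, 3], 0)
  expect_equal(unname(rowSums(Qi)), rep(0, 4))

  # all-equal dependent collapses to the equal-rate independent model
  Qd <- build_rate_matrix("dependent", setNames(rep(0.5, 8),
        c("q12", "q13", "q21", "q24", "q31", "q34", "q42", "q43")))
  Qe <- build_rate_matrix("independent",
                          c(qA01 = .5, qA10 = .5, qB01 = .5, qB10 = .5))
  expect_equal(Qd, Qe)

  # constrained: q34 = q43 = q12 = q21 shared
  Qc <- build_rate_matrix("dependent_constrained",
        c(shared = 0.9, q13 = 1, q31 = 2, q24 = 3, q42 = 4))
  expect_equal(unname(c(Qc[3, 4], Qc[4, 3], Qc[1, 2], Qc[2, 1])),
               rep(0.9, 4))
  expect_equal(Qc[2, 4], 3)
  expect_error(build_rate_matrix("dependent", rep(0.5, 5)), "rates")
  expect_error(build_rate_matrix("independent", c(-1, 1, 1, 1)), ">= 0")
})

test_that("paired likelihood equals enumeration on small trees", {
  for (seed in 1:5) {
    n <- sample(3:5, 1)
    tr <- random_tree(n, seed = 300 + seed)
    set.seed(seed)
    a <- setNames(sample(0:1, n, TRUE), tr$tip.label)
    b <- setNames(sample(0:1, n, TRUE), tr$tip.label)
    if (seed >= 4) { a[1] <- NA; b[2] <- NA }   # marginalized components
    Q <- build_rate_matrix("dependent",
                           setNames(runif(8, 0.05, 3),
                                    pagel_names <- c("q12", "q13", "q21",
                                    "q24", "q31", "q34", "q42", "q43")))
    oracle <- enum_ctmc(tr, tip_partials_paired(a, b, tr), Q, rep(.25, 4))
    expect_equal(paired_loglik(tr, a, b, Q), oracle$loglik,
                 tolerance = 1e-10)
  }
})

test_that("all-zero rates put full mass on the root state", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  Q <- build_rate_matrix("dependent", setNames(rep(0, 8),
       c("q12", "q13", "q21", "q24", "q31", "q34", "q42", "q43")))
  a <- c(A = 0, B = 0, C = 0); b <- c(A = 0, B = 0, C = 0)
  expect_equal(paired_loglik(tr, a, b, Q), log(1 / 4))
})

test_that("independent-model likelihood factorizes over traits", {
  for (seed in 1:8) {
    dat <- sim_pair_data(30, "independent",
                         c(qA01 = .4, qA10 = .6, qB01 = 1, qB10 = .3),
                         seed = 400 + seed)
    set.seed(seed)
    r <- runif(4, 0.05, 2)
    Qi <- build_rate_matrix("independent",
                            c(qA01 = r[1], qA10 = r[2], qB01 = r[3],
                              qB10 = r[4]))
    lab <- names(dat$A)
    llA <- enum2_pruned(dat$tree, dat$A,
                        matrix(c(-r[1], r[1], r[2], -r[2]), 2, 2,
                               byrow = TRUE))
    llB <- enum2_pruned(dat$tree, dat$B,
                        matrix(c(-r[3], r[3], r[4], -r[4]), 2, 2,
                               byrow = TRUE))
    expect_equal(paired_loglik(dat$tree, dat$A, dat$B, Qi), llA + llB,
                 tolerance = 1e-9)
  }
})

test_that("likelihood is invariant to relabeling trait A with rate swap", {
  dat <- sim_pair_data(40, "dependent_constrained",
                       c(shared = .5, q13 = .4, q31 = 1.5, q24 = 4,
                         q42 = 1), seed = 17)
  Q <- build_rate_matrix("dependent_constrained",
                         c(shared = .5, q13 = .4, q31 = 1.5, q24 = 4,
                           q42 = 1))
  # swap A labels: states (1,2) <-> (3,4); permute Q accordingly
  perm <- c(3, 4, 1, 2)
  Qs <- Q[perm, perm]
  ll1 <- paired_loglik(dat$tree, dat$A, dat$B, Q)
  ll2 <- paired_loglik(dat$tree, 1 - dat$A, dat$B, Qs)
  expect_equal(ll1, ll2, tolerance = 1e-9)
})

test_that("ML fits respect nesting and flag monomorphic traits", {
  dat <- sim_pair_data(120, "dependent_constrained",
                       c(shared = 1, q13 = 1, q31 = 1.5, q24 = 17,
                         q42 = 2.7), seed = 23)
  fi <- ml_fit(dat$tree, dat$A, dat$B, "independent")
  fc <- ml_fit(dat$tree, dat$A, dat$B, "dependent_constrained")
  fd <- ml_fit(dat$tree, dat$A, dat$B, "dependent")
  expect_gte(fd$loglik, fc$loglik - 1e-6)
  expect_gte(fd$loglik, fi$loglik - 1e-6)
  mono <- setNames(rep(0L, length(dat$B)), names(dat$B))
  fm <- ml_fit(dat$tree, dat$A, mono, "independent")
  expect_true(any(fm$boundary))   # monomorphic trait drives a rate to 0
})

test_that("posterior sampling is seed-reproducible with sane acceptance", {
  dat <- sim_pair_data(60, "independent",
                       c(qA01 = .5, qA10 = .5, qB01 = .5, qB10 = .5),
                       seed = 29)
  m1 <- mcmc_sample(dat$tree, dat$A, dat$B, "independent", n_iter = 1500,
                    seed = 7)
  m2 <- mcmc_sample(dat$tree, dat$A, dat$B, "independent", n_iter = 1500,
                    seed = 7)
  expect_identical(m1$chain, m2$chain)
  expect_gt(m1$accept, 0.05)
  expect_lt(m1$accept, 0.9)
})

test_that("prior-only sampling recovers the prior mean", {
  # likelihood switched off (beta = 0 stone): chain samples the prior
  lp <- dendrocare:::log_prior_logscale(
    dendrocare:::rate_prior("exponential", mean = 10))
  set.seed(101)
  run <- dendrocare:::mh_power(function(x) 0, lp, x0 = log(5),
                               n_iter = 20000, beta = 0, prop_sd = 1.5)
  draws <- exp(run$samples)
  mc_se <- sd(draws) / sqrt(dendrocare:::ess_simple(as.vector(draws)))
  expect_lt(abs(mean(draws) - 10), 3 * mc_se + 0.5)
})

test_that("stepping-stone estimates are stable across seeds", {
  dat <- sim_pair_data(100, "dependent_constrained",
                       c(shared = 1, q13 = 1, q31 = 1.5, q24 = 17,
                         q42 = 2.7), seed = 37)
  for (mc in c("independent", "dependent_constrained")) {
    ests <- vapply(1:4, function(s)
      stepping_stone_ml(dat$tree, dat$A, dat$B, mc,
                        n_stones = 20, iters_per_stone = 3000,
                        seed = s)$lnml, 0)
    expect_lt(sd(ests), 0.5)
  }
})

test_that("stepping-stone rejects degenerate schedules", {
  expect_error(stepping_stone_evidence(function(x) 0,
                                       function(x) dnorm(x, log = TRUE),
                                       0, n_stones = 1,
                                       iters_per_stone = 100),
               "beta=0")
})

test_that("log Bayes factor arithmetic, bands and fingerprint guard", {
  mk <- function(lnml, fp = "x") list(lnml = lnml, fingerprint = fp,
                                      model_class = "m")
  expect_equal(log_bayes_factor(mk(-10), mk(-10))$logBF, 0)
  expect_equal(log_bayes_factor(mk(-10), mk(-10))$band, "weak")
  bf <- log_bayes_factor(mk(-100), mk(-125))
  expect_equal(bf$logBF, 50)
  expect_equal(bf$band, "very strong")
  expect_equal(log_bayes_factor(mk(-10), mk(-11.5))$band, "positive")
  expect_equal(log_bayes_factor(mk(-10), mk(-13.5))$band, "strong")
  expect_error(log_bayes_factor(mk(-1, "a"), mk(-2, "b")), "different data")
})

test_that("transition summaries report posterior tables and rate ratios", {
  chain <- cbind(q24 = rep(17, 50), q42 = rep(2, 50), q31 = rep(1.5, 50))
  s <- transition_summary(chain)
  expect_equal(s$table$mean[s$table$parameter == "q24"], 17)
  expect_equal(unname(s$ratios["q24/q42"]), 8.5)
  expect_equal(unname(s$ratios["q24/q31"]), 17 / 1.5)
})
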