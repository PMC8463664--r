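test_that("Yule simulation is ultrametric, seeded, and grows at rate b", {
  t2 <- simulate_yule_tree(2, 1, seed = 1)
  expect_equal(ape::Ntip(t2), 2)
  expect_true(is_ultrametric_tree(t2))
  expect_equal(length(unique(tip_depths(t2))), 1)

  a <- ape::write.tree(simulate_yule_tree(50, 1, seed = 9))
  b <- ape::write.tree(simulate_yule_tree(50, 1, seed = 9))
  expect_identical(a, b)

  # pooled lineage-through-time slope approximates the birth rate
  slopes <- vapply(1:60, function(s) {
    tr <- simulate_yule_tree(80, 1, seed = 900 + s)
    bt <- sort(max(tip_depths(tr)) - ape::branching.times(tr))
    unname(coef(lm(log(seq_along(bt) + 1) ~ bt))[2])
  }, 0)
  expect_lt(abs(mean(slopes) - 1), 0.1)
})

test_that("exact CTMC simulation matches its transition kernel", {
  tr <- read_newick("(A:1,B:1);")
  Q <- er_q(2, 0.6)
  # zero rates inherit the root state everywhere
  all0 <- simulate_ctmc(read_newick("((A:1,B:1):1,C:2);"), er_q(2, 0),
                        1, seed = 3)
  expect_true(all(all0 == 1))
  # tip-pattern frequencies match the expm-based distribution (chi-square)
  P <- expm_oracle(Q, 1)
  probs <- outer(P[1, ], P[1, ])        # independent tips given root = 1
  counts <- matrix(0, 2, 2)
  for (i in 1:4000) {
    st <- simulate_ctmc(tr, Q, 1, seed = 10000 + i)
    counts[st["A"], st["B"]] <- counts[st["A"], st["B"]] + 1
  }
  expect_gt(chisq.test(as.vector(counts),
                       p = as.vector(probs))$p.value, 0.001)
  # long branches approach the stationary distribution
  big <- simulate_yule_tree(2000, 1, seed = 11)
  big$edge.length <- big$edge.length * 50
  st <- simulate_ctmc(big, er_q(2, 1), 1, seed = 12)
  expect_lt(abs(mean(st == 1) - 0.5), 3 * 0.5 / sqrt(2000) + 0.05)
})

test_that("Brownian simulation has the covariance the tree implies", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  x0 <- simulate_brownian(tr, 0, 5, seed = 21)
  expect_equal(unname(x0), rep(5, 3))
  expect_identical(simulate_brownian(tr, 1, 0, seed = 22),
                   simulate_brownian(tr, 1, 0, seed = 22))
  sims <- t(vapply(1:3000, function(i)
    simulate_brownian(tr, 1.7, 0, seed = 30000 + i), numeric(3)))
  emp <- cov(sims)
  expect_lt(max(abs(emp - 1.7 * tree_vcv(tr)[colnames(sims),
                                             colnames(sims)]) /
                  max(1.7 * tree_vcv(tr))), 0.08)
})

test_that("logistic response simulation responds to its parameters", {
  tr <- simulate_yule_tree(2000, 1, seed = 41)
  X <- cbind(x = rep(0, 2000))
  rownames(X) <- tr$tip.label
  y0 <- simulate_logistic_response(tr, X, c(0, 0), 0, seed = 42)
  expect_lt(abs(mean(y0) - 0.5), 0.04)
  # strong slope: response rate increases across predictor bins
  tr2 <- simulate_yule_tree(1500, 1, seed = 43)
  xv <- rnorm(1500)
  X2 <- cbind(x = xv); rownames(X2) <- tr2$tip.label
  y <- simulate_logistic_response(tr2, X2, c(0, 3), 0, seed = 44)
  bins <- cut(xv, quantile(xv, 0:4 / 4), include.lowest = TRUE)
  rates <- tapply(y[tr2$tip.label], bins, mean)
  expect_true(all(diff(rates) > 0))
  # phylogenetic effect: sister tips agree more than random pairs
  tr3 <- simulate_yule_tree(600, 1, seed = 45)
  X3 <- cbind(x = rep(0, 600)); rownames(X3) <- tr3$tip.label
  y3 <- simulate_logistic_response(tr3, X3, c(0, 0), 8, seed = 46)
  is_tip <- tr3$edge[, 2] <= 600
  sisters <- split(tr3$edge[is_tip, 2], tr3$edge[is_tip, 1])
  sisters <- Filter(function(s) length(s) == 2, sisters)
  sis_conc <- mean(vapply(sisters, function(s)
    y3[s[1]] == y3[s[2]], TRUE))
  set.seed(47)
  rnd <- mean(replicate(2000, {
    p <- sample(600, 2); y3[p[1]] == y3[p[2]]
  }))
  expect_gt(sis_conc, rnd)
})

test_that("the dendrobatid-like fixture matches the dendrobatid data shape", {
  fx <- make_dendrobatid_like_fixture(seed = 1)
  expect_equal(ape::Ntip(fx$tree), 220)
  expect_true(is_ultrametric_tree(fx$tree, tol = 1e-6))
  cd <- code_traits(fx$traits, fx$tree)$coded
  n_consp <- sum(cd$conspicuous, na.rm = TRUE)
  n_phy <- sum(cd$phytotelm_breeder, na.rm = TRUE)
  expect_gte(n_consp, 65); expect_lte(n_consp, 89)
  expect_gte(n_phy, 44); expect_lte(n_phy, 60)
  # many fields unknown for a large share of species
  expect_gt(mean(is.na(fx$traits$egg_size)), 0.2)
  expect_gt(mean(is.na(fx$traits$cannibalism)), 0.3)
  # byte-identical regeneration from the same seed
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write.csv(make_dendrobatid_like_fixture(seed = 6)$traits, f1,
            row.names = FALSE)
  write.csv(make_dendrobatid_like_fixture(seed = 6)$traits, f2,
            row.names = FALSE)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("simulate-then-fit closes the loop as trees grow", {
  rates <- c(shared = 1, q13 = 1, q31 = 1.5, q24 = 8, q42 = 2)
  err_at <- function(n, seed) {
    dat <- sim_pair_data(n, "dependent_constrained", rates, seed = seed)
    fit <- ml_fit(dat$tree, dat$A, dat$B, "dependent_constrained")
    median(abs(fit$rates - rates) / rates)
  }
  e_small <- median(vapply(1:3, function(s) err_at(80, 500 + s), 0))
  e_large <- median(vapply(1:3, function(s) err_at(600, 510 + s), 0))
  expect_lt(e_large, e_small)
})
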