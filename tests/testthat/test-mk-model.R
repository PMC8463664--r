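test_that("Mk likelihood matches closed forms on tiny trees", {
  # no change possible at q = 0: likelihood is the root prior mass
  tr <- read_newick("((A:1,B:1):1,C:2);")
  expect_equal(mk_loglik(tr, c(A = 0, B = 0, C = 0), q = 0, k = 2),
               log(0.5))
  # two tips, one change: likelihood from the 2-state closed form
  t2 <- read_newick("(A:1,B:1);")
  q <- 0.37
  p_same <- (1 + exp(-2 * q)) / 2
  expect_equal(mk_loglik(t2, c(A = 0, B = 1), q, k = 2),
               log(2 * 0.5 * p_same * (1 - p_same)), tolerance = 1e-12)
  expect_error(mk_loglik(tr, c(A = 0, B = 0, C = 0), q = -1), "scalar")
  expect_error(mk_loglik(tr, c(A = NA, B = NA, C = NA), q = 1),
               "no observed")
})

test_that("pruning equals enumeration for k = 2 and k = 3 with missing data", {
  for (seed in 1:6) {
    n <- sample(3:6, 1)
    tr <- random_tree(n, seed = 100 + seed)
    k <- if (seed %% 2 == 0) 3L else 2L
    set.seed(seed)
    st <- setNames(sample(0:(k - 1), n, TRUE), tr$tip.label)
    if (seed > 3) st[1] <- NA                       # marginalized tip
    if (length(unique(st[!is.na(st)])) < 2) st[2] <- (st[3] + 1) %% k
    q <- runif(1, 0.05, 3)
    tp <- if (k == 2) tip_partials_2state(st, tr) else {
      m <- matrix(1, k, n)
      for (i in seq_len(n)) if (!is.na(st[tr$tip.label[i]])) {
        m[, i] <- 0; m[st[tr$tip.label[i]] + 1, i] <- 1
      }
      m
    }
    oracle <- enum_ctmc(tr, tp, er_q(k, q), rep(1 / k, k))
    expect_equal(mk_loglik(tr, st, q, k), oracle$loglik,
                 tolerance = 1e-10)
  }
})

test_that("marginal reconstruction equals enumeration conditionals", {
  for (seed in 1:4) {
    tr <- random_tree(4, seed = 200 + seed)
    set.seed(seed)
    st <- setNames(sample(0:1, 4, TRUE), tr$tip.label)
    if (length(unique(st)) < 2) st[1] <- 1 - st[2]
    q <- runif(1, 0.1, 2)
    asr <- marginal_asr(tr, st, k = 2, model = list(q = q))
    oracle <- enum_ctmc(tr, tip_partials_2state(st, tr), er_q(2, q),
                        c(0.5, 0.5))
    expect_lt(max(abs(asr$anc - oracle$marginals)), 1e-9)
    expect_equal(unname(rowSums(asr$anc)), rep(1, nrow(asr$anc)),
                 tolerance = 1e-9)
  }
})

test_that("marginals hit the expected limits", {
  tr <- read_newick("((A:1,B:1):1,(C:1.5,D:1.5):0.5);")
  # q -> 0 with uniform tips: ancestral state certain
  asr <- marginal_asr(tr, c(A = 0, B = 0, C = 0, D = 0), k = 2,
                      model = list(q = 1e-9))
  expect_true(all(asr$anc[, 1] > 1 - 1e-6))
  # symmetric two-tip conflict: root marginal is uniform
  t2 <- read_newick("(A:1,B:1);")
  asr2 <- marginal_asr(t2, c(A = 0, B = 1), k = 2, model = list(q = 0.5))
  expect_equal(unname(asr2$anc[1, ]), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("likelihood is invariant under re-rooting (reversible ER)", {
  tr <- ape::unroot(random_tree(6, seed = 42))
  set.seed(9)
  st <- setNames(sample(0:1, 6, TRUE), tr$tip.label)
  st[1] <- 1 - st[2]
  q <- 0.7
  lls <- vapply(1:4, function(node) {
    rt <- ape::root(tr, outgroup = tr$tip.label[node], resolve.root = TRUE)
    mk_loglik(rt, st, q, k = 2)
  }, 0)
  expect_lt(max(lls) - min(lls), 1e-9)
})

test_that("ER rate estimation recovers ordering and flags boundaries", {
  tr <- scale_tree_height(simulate_yule_tree(300, 1, seed = 55))
  slow <- simulate_ctmc(tr, er_q(2, 0.1), 1, seed = 56) - 1
  fast <- simulate_ctmc(tr, er_q(2, 5), 1, seed = 57) - 1
  f_slow <- fit_er(tr, slow, k = 2)
  f_fast <- fit_er(tr, fast, k = 2)
  expect_lt(f_slow$q, f_fast$q)
  mono <- setNames(rep(0L, 300), tr$tip.label)
  f_mono <- fit_er(tr, mono, k = 2)
  expect_true(f_mono$boundary)
})

test_that("ER rate estimate is consistent on simulated data", {
  # moderate-scale recovery: median relative error across replicates
  tr <- scale_tree_height(simulate_yule_tree(300, 1, seed = 60))
  true_q <- 0.8
  rel_err <- vapply(1:10, function(i) {
    st <- simulate_ctmc(tr, er_q(2, true_q), 1, seed = 600 + i) - 1
    if (length(unique(st)) < 2) return(NA_real_)
    abs(fit_er(tr, st, k = 2)$q - true_q) / true_q
  }, 0)
  expect_lt(median(rel_err, na.rm = TRUE), 0.5)
})
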