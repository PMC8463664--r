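# Independent oracles used across the suite. The enumeration oracle computes
# CTMC likelihoods by summing over every internal-node state assignment,
# with transition probabilities from Matrix::expm -- a code path fully
# disjoint from the package's pruning kernel.

expm_oracle <- function(Q, t) as.matrix(Matrix::expm(Q * t))

# full-enumeration likelihood and per-node marginals for arbitrary k
enum_ctmc <- function(tree, tip_partials, Q, root_prior) {
  pp <- ape::reorder.phylo(tree, "postorder")
  n <- ape::Ntip(pp)
  k <- nrow(Q)
  nn <- n + pp$Nnode
  P <- lapply(seq_len(nrow(pp$edge)),
              function(e) expm_oracle(Q, pp$edge.length[e]))
  internal <- (n + 1):nn
  grid <- expand.grid(rep(list(seq_len(k)), length(internal)))
  lik <- 0
  marg <- matrix(0, nn, k)
  for (g in seq_len(nrow(grid))) {
    asg <- integer(nn)
    asg[internal] <- as.integer(grid[g, ])
    p_int <- root_prior[asg[n + 1]]
    for (e in seq_len(nrow(pp$edge))) {
      par <- pp$edge[e, 1]; ch <- pp$edge[e, 2]
      if (ch <= n) {
        p_int <- p_int * sum(P[[e]][asg[par], ] * tip_partials[, ch])
      } else {
        p_int <- p_int * P[[e]][asg[par], asg[ch]]
      }
    }
    lik <- lik + p_int
    for (v in internal) marg[v, asg[v]] <- marg[v, asg[v]] + p_int
  }
  list(loglik = log(lik), marginals = marg[internal, , drop = FALSE] / lik)
}

tip_partials_2state <- function(states, tree) {
  st <- states[tree$tip.label]
  tp <- matrix(1, 2, length(st))
  obs <- which(!is.na(st))
  tp[, obs] <- 0
  tp[cbind(st[obs] + 1L, obs)] <- 1
  tp
}

tip_partials_paired <- function(a, b, tree) {
  a <- a[tree$tip.label]; b <- b[tree$tip.label]
  tp <- matrix(0, 4, length(a))
  for (i in seq_along(a)) {
    for (ai in (if (is.na(a[i])) 0:1 else a[i]))
      for (bi in (if (is.na(b[i])) 0:1 else b[i]))
        tp[1 + 2 * ai + bi, i] <- 1
  }
  tp
}

# random rooted binary tree with the given tips and uniform branch lengths
random_tree <- function(n_tips, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_tips, rooted = TRUE,
                   br = function(n) runif(n, 0.1, 1.5))
  tr$tip.label <- paste0("t", seq_len(n_tips))
  tr
}

er_q <- function(k, q) {
  Q <- matrix(q, k, k); diag(Q) <- -(k - 1) * q; Q
}

# reference 2-state pruning in plain R with Matrix::expm transition matrices
enum2_pruned <- function(tree, states, Q, prior = c(0.5, 0.5)) {
  pp <- ape::reorder.phylo(tree, "postorder")
  n <- ape::Ntip(pp)
  L <- matrix(1, 2, n + pp$Nnode)
  st <- states[pp$tip.label]
  for (i in seq_len(n)) if (!is.na(st[i])) {
    L[, i] <- 0; L[st[i] + 1, i] <- 1
  }
  sc <- 0
  for (e in seq_len(nrow(pp$edge))) {
    P <- expm_oracle(Q, pp$edge.length[e])
    v <- P %*% L[, pp$edge[e, 2]]
    s <- sum(v); sc <- sc + log(s)
    L[, pp$edge[e, 1]] <- L[, pp$edge[e, 1]] * as.vector(v / s)
  }
  log(sum(prior * L[, n + 1])) + sc
}

# small simulated paired dataset helper
sim_pair_data <- function(n_tips, model_class, rates, seed,
                          root_state = 1) {
  tr <- scale_tree_height(simulate_yule_tree(n_tips, 1, seed = seed))
  Q <- build_rate_matrix(model_class, rates)
  d <- simulate_paired_ctmc(tr, Q, root_state, seed = seed + 5000L)
  list(tree = tr, A = setNames(d$traitA, d$species),
       B = setNames(d$traitB, d$species))
}
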