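# Equal-rates Mk model: pruning likelihood, ML rate estimation, and marginal
# ancestral state reconstruction for single discrete characters.

# postorder edge representation shared by all pruning code
prep_pruning <- function(tree) {
  tree <- validate_tree(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  list(tree = po, edge = po$edge, elen = po$edge.length,
       n_tips = ape::Ntip(po), n_nodes = ape::Ntip(po) + po$Nnode,
       root = ape::Ntip(po) + 1L)
}

# k x n_tips partial-likelihood matrix; missing states marginalized (ones)
tip_partials_from_states <- function(states, tree, k) {
  if (is.null(names(states)))
    stop_dc("tip states must be named by species")
  names(states) <- normalize_taxon_names(names(states))
  missing_sp <- setdiff(tree$tip.label, names(states))
  if (length(missing_sp))
    stop_dc("no state entry for tips: ", paste(missing_sp, collapse = ", "))
  st <- states[tree$tip.label]
  bad <- !is.na(st) & !(st %in% 0:(k - 1))
  if (any(bad)) stop_dc("states must be in 0..k-1 or NA")
  tp <- matrix(1, nrow = k, ncol = length(st))
  obs <- which(!is.na(st))
  tp[, obs] <- 0
  tp[cbind(st[obs] + 1L, obs)] <- 1
  tp
}

mk_q_matrix <- function(k, q) {
  Q <- matrix(q, k, k)
  diag(Q) <- -(k - 1) * q
  Q
}

# transition probability matrix exp(Q t) (R-side, used by the ASR pass)
pmat_r <- function(Q, t) {
  P <- ape::matexpo(Q * t)
  P[P < 0] <- 0
  P
}

#' Log-likelihood of tip data under an equal-rates Mk model
#'
#' Felsenstein pruning on the tree for a k-state character evolving under a
#' continuous-time Markov chain with a single shared rate q for every
#' ordered state pair. Missing tip states are marginalized (all-ones partial
#' likelihood), keeping the tree common across characters. The root state is
#' weighted by \code{root_prior} (the ER stationary distribution is uniform,
#' the default).
#'
#' @param tree A \code{phylo} object.
#' @param states Named vector of tip states in 0..k-1, NA for missing.
#' @param q Transition rate (per unit branch length), >= 0.
#' @param k Number of states.
#' @param root_prior Probability vector over the k states.
#' @return Log-likelihood (scalar).
#' @export
mk_loglik <- function(tree, states, q, k = 2, root_prior = rep(1 / k, k)) {
  if (length(q) != 1 || is.na(q) || q < 0) stop_dc("q must be a scalar >= 0")
  if (abs(sum(root_prior) - 1) > 1e-9 || any(root_prior < 0))
    stop_dc("root_prior must be a probability vector")
  pp <- prep_pruning(tree)
  tp <- tip_partials_from_states(states, pp$tree, k)
  if (all(tp == 1)) stop_dc("no observed tip states")
  .ctmc_loglik_cpp(pp$edge, pp$elen, pp$n_tips, pp$n_nodes, tp,
                   mk_q_matrix(k, q), root_prior, pp$root)
}

#' Fit the equal-rates Mk model by maximum likelihood
#'
#' Bounded search for the shared transition rate on the log scale
#' (q in [1e-8, 1e3]), seeded from a coarse grid so that multiple basins
#' are covered. Monomorphic data drive the estimate to the lower bound;
#' this is flagged rather than hidden.
#'
#' @inheritParams mk_loglik
#' @return List with \code{q} (ML estimate), \code{loglik}, \code{k},
#'   \code{root_prior}, and \code{boundary} (TRUE when the estimate sits on
#'   a search bound).
#' @export
fit_er <- function(tree, states, k = 2, root_prior = rep(1 / k, k)) {
  lb <- log(1e-8); ub <- log(1e3)
  f <- function(lq) mk_loglik(tree, states, exp(lq), k, root_prior)
  grid <- seq(log(1e-6), log(100), length.out = 9)
  lls <- vapply(grid, f, 0)
  i <- which.max(lls)
  lo <- if (i == 1) lb else grid[i - 1]
  hi <- if (i == length(grid)) ub else grid[i + 1]
  opt <- stats::optimize(f, interval = c(lo, hi), maximum = TRUE,
                         tol = 1e-8)
  # refine against the bounds in case the bracket missed the edge
  if (opt$objective < max(lls)) opt <- list(maximum = grid[i],
                                            objective = lls[i])
  q_hat <- exp(opt$maximum)
  boundary <- opt$maximum <= lb + 1e-6 || opt$maximum >= ub - 1e-6 ||
    q_hat <= 2e-8
  st <- states[!is.na(states)]
  if (length(unique(st)) < 2) boundary <- TRUE
  list(q = q_hat, loglik = opt$objective, k = k, root_prior = root_prior,
       boundary = boundary)
}

#' Marginal ancestral state reconstruction
#'
#' Per-internal-node marginal posterior probabilities of each state given
#' all tip data, computed by an up-down pass (partial likelihoods toward the
#' root, then outside-subtree likelihoods back down), with per-node
#' normalization for underflow control.
#'
#' @inheritParams mk_loglik
#' @param model Optional list with \code{q} (and optionally
#'   \code{root_prior}) as returned by \code{\link{fit_er}}; fitted by ML
#'   when omitted.
#' @return List with \code{anc} (matrix, one row per internal node in ape
#'   numbering, one column per state, rows summing to 1), \code{q},
#'   \code{loglik}.
#' @export
marginal_asr <- function(tree, states, k = 2, model = NULL,
                         root_prior = rep(1 / k, k)) {
  if (is.null(model)) model <- fit_er(tree, states, k, root_prior)
  q <- model$q
  root_prior <- model$root_prior %||% root_prior
  pp <- prep_pruning(tree)
  tr <- pp$tree
  tp <- tip_partials_from_states(states, tr, k)
  Q <- mk_q_matrix(k, q)

  n_edge <- nrow(pp$edge)
  L <- matrix(1, k, pp$n_nodes)
  L[, seq_len(pp$n_tips)] <- tp
  P_list <- vector("list", n_edge)
  V_list <- vector("list", n_edge)  # normalized per-edge up contributions
  for (e in seq_len(n_edge)) {
    par <- pp$edge[e, 1]; ch <- pp$edge[e, 2]
    P <- pmat_r(Q, pp$elen[e])
    v <- as.vector(P %*% L[, ch])
    s <- sum(v)
    if (s <= 0) stop_dc("zero partial likelihood during ASR")
    P_list[[e]] <- P
    V_list[[e]] <- v / s
    L[, par] <- L[, par] * (v / s)
  }

  children_edges <- split(seq_len(n_edge), pp$edge[, 1])
  D <- matrix(0, k, pp$n_nodes)
  D[, pp$root] <- root_prior
  for (e in rev(seq_len(n_edge))) {     # preorder
    par <- pp$edge[e, 1]; ch <- pp$edge[e, 2]
    sibs <- setdiff(children_edges[[as.character(par)]], e)
    ex <- D[, par]
    for (s_e in sibs) ex <- ex * V_list[[s_e]]
    d <- as.vector(t(P_list[[e]]) %*% ex)
    D[, ch] <- d / sum(d)
  }

  internal <- (pp$n_tips + 1L):pp$n_nodes
  anc <- t(vapply(internal, function(v) {
    m <- L[, v] * D[, v]
    m / sum(m)
  }, numeric(k)))
  rownames(anc) <- internal
  colnames(anc) <- paste0("state_", 0:(k - 1))
  ll <- .ctmc_loglik_cpp(pp$edge, pp$elen, pp$n_tips, pp$n_nodes, tp, Q,
                         root_prior, pp$root)
  list(anc = anc, q = q, loglik = ll, k = k)
}
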