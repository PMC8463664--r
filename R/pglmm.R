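# Phylogenetic regressions: generalized least squares under Brownian
# covariance, pairwise trait regressions with FDR adjustment, and Bayesian
# phylogenetic logistic regression with a species-level random effect.

#' Phylogenetic generalized least squares (Brownian covariance)
#'
#' Regresses y on x with residual covariance proportional to the Brownian
#' covariance of the tree (shared-path-length matrix). The tree is rescaled
#' to unit height before inversion for numerical conditioning; estimates are
#' invariant to that scaling. Reduces exactly to ordinary least squares on a
#' star phylogeny.
#'
#' @param y,x Named numeric vectors (names are species in the tree). NAs are
#'   dropped pairwise.
#' @param tree A \code{phylo} object containing all complete-case species.
#' @return List with \code{coefficients} (intercept, slope), \code{beta}
#'   (slope), \code{se}, \code{t}, \code{p} (two-sided), \code{n},
#'   \code{residuals} (named, response scale), \code{sigma2}.
#' @export
pgls <- function(y, x, tree) {
  if (is.null(names(y)) || is.null(names(x)))
    stop_dc("y and x must be named by species")
  names(y) <- normalize_taxon_names(names(y))
  names(x) <- normalize_taxon_names(names(x))
  sp <- intersect(names(y)[!is.na(y)], names(x)[!is.na(x)])
  sp <- intersect(sp, normalize_taxon_names(tree$tip.label))
  if (length(sp) < 4) stop_dc("need >= 4 complete pairs in the tree")
  tr <- scale_tree_height(prune_to_taxa(tree, sp))
  C <- tree_vcv(tr)[sp, sp]
  X <- cbind(`(Intercept)` = 1, x = x[sp])
  if (qr(X)$rank < 2) stop_dc("singular design (x is constant)")
  U <- chol(C)
  Xw <- backsolve(U, X, transpose = TRUE)
  yw <- backsolve(U, y[sp], transpose = TRUE)
  fit <- stats::lm.fit(Xw, yw)
  b <- fit$coefficients
  n <- length(sp); df <- n - 2
  sigma2 <- sum(fit$residuals^2) / df
  XtX_inv <- chol2inv(qr.R(fit$qr))
  se <- sqrt(sigma2 * diag(XtX_inv))
  tval <- b / se
  pval <- 2 * pt(-abs(tval), df)
  resid <- as.vector(y[sp] - X %*% b)
  names(resid) <- sp
  list(coefficients = b, beta = unname(b[2]), se = unname(se[2]),
       t = unname(tval[2]), p = unname(pval[2]), n = n,
       residuals = resid, sigma2 = sigma2)
}

#' Pairwise phylogenetic regressions with FDR adjustment
#'
#' Fits a PGLS for every unordered pair of traits and applies
#' Benjamini-Hochberg adjustment over the full set of pairwise p-values.
#' The output mirrors a lower-triangular comparison table: slope with a
#' significance flag ("*" when adjusted p < alpha, "NS" otherwise).
#'
#' @param traits Named list of named numeric vectors, or a data.frame with a
#'   \code{species} column and one column per trait.
#' @param tree A \code{phylo} object.
#' @param alpha FDR level for flags (default 0.05).
#' @return List with \code{pairs} (data.frame: trait_y, trait_x, beta, p,
#'   p_adj, flag, n) and \code{beta_matrix} (lower-triangular slopes).
#' @export
pairwise_pgls_matrix <- function(traits, tree, alpha = 0.05) {
  if (is.data.frame(traits)) {
    sp <- normalize_taxon_names(traits$species)
    nm <- setdiff(names(traits), "species")
    traits <- lapply(traits[nm], function(v) setNames(as.numeric(v), sp))
  }
  nm <- names(traits)
  if (length(nm) < 2) stop_dc("need >= 2 traits")
  cmb <- utils::combn(nm, 2)
  rows <- lapply(seq_len(ncol(cmb)), function(j) {
    xn <- cmb[1, j]; yn <- cmb[2, j]
    fit <- tryCatch(pgls(traits[[yn]], traits[[xn]], tree),
                    error = function(e) NULL)
    if (is.null(fit))
      data.frame(trait_y = yn, trait_x = xn, beta = NA, p = NA, n = NA)
    else
      data.frame(trait_y = yn, trait_x = xn, beta = fit$beta, p = fit$p,
                 n = fit$n)
  })
  tab <- do.call(rbind, rows)
  tab$p_adj <- p.adjust(tab$p, method = "BH")
  tab$flag <- ifelse(is.na(tab$p_adj), NA,
                     ifelse(tab$p_adj < alpha, "*", "NS"))
  bm <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
  for (i in seq_len(nrow(tab)))
    if (!is.na(tab$beta[i])) bm[tab$trait_y[i], tab$trait_x[i]] <- tab$beta[i]
  list(pairs = tab, beta_matrix = bm)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Compares between-chain and within-chain variance for one parameter.
#' Values near 1 indicate convergence.
#'
#' @param chains A list of >= 2 equal-length numeric vectors, or a matrix
#'   with one column per chain.
#' @return R-hat (scalar).
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)),
                                          function(j) chains[, j])
  m <- length(chains)
  if (m < 2) stop_dc("need >= 2 chains")
  n <- unique(vapply(chains, length, 0L))
  if (length(n) != 1 || n < 10) stop_dc("chains must be equal length >= 10")
  means <- vapply(chains, mean, 0)
  vars <- vapply(chains, var, 0)
  W <- mean(vars)
  if (W == 0) stop_dc("zero within-chain variance in all chains")
  B_over_n <- var(means)
  var_plus <- (n - 1) / n * W + B_over_n
  sqrt(var_plus / W)
}

# effective sample size by the initial-positive-sequence rule
ess_simple <- function(x) {
  n <- length(x)
  if (var(x) == 0) return(0)
  a <- acf(x, lag.max = min(n - 1, 500), plot = FALSE)$acf[-1]
  neg <- which(a < 0)
  if (length(neg)) a <- a[seq_len(neg[1] - 1)]
  max(1, n / (1 + 2 * sum(a)))
}

#' Bayesian phylogenetic logistic regression
#'
#' Logistic regression of a binary trait on continuous predictors with a
#' species-level random effect whose covariance is sigma^2 times the
#' Brownian covariance of the tree (rescaled to unit height). Coefficients
#' live on the latent logit scale with residual variance fixed at 1 (the
#' usual categorical-response convention). Sampling combines
#' random-walk Metropolis for the fixed effects, conditional-prior
#' independence proposals for the species effects, and a conjugate
#' inverse-gamma Gibbs update for sigma^2; proposal scales adapt during
#' burn-in only, so runs are reproducible bit-for-bit given the seed.
#'
#' @param response Name of the binary response column.
#' @param predictors Character vector of predictor column names.
#' @param data Data frame with a \code{species} column plus the named
#'   columns; complete cases are used and matched to the tree.
#' @param tree A \code{phylo} object.
#' @param prior List with \code{shape} and \code{scale} of the
#'   inverse-gamma prior on the random-effect variance (default 0.001,
#'   0.001) and \code{beta_var}, the fixed-effect normal prior variance
#'   (default 1e8).
#' @param n_iter,burn_in,thin,n_chains MCMC settings. Defaults (4 chains x
#'   50000 iterations, burn-in 5000, thin 10) are a desk-scale compromise;
#'   \code{scale = "published"} presets 2e7 iterations, burn-in 1000, thin 500.
#' @param seed Integer seed; chain c uses seed + c - 1.
#' @param scale "desk" or "published" preset (overridden by explicit arguments).
#' @return List with \code{summary} (data.frame: mean, sd, CI, pMCMC,
#'   R-hat, ESS per coefficient), \code{sigma2} summary, \code{chains}
#'   (list of sample matrices), \code{n}, \code{separation} flag.
#' @export
pglmm_logistic <- function(response, predictors, data, tree,
                           prior = list(shape = 0.001, scale = 0.001,
                                        beta_var = 1e8),
                           n_iter = NULL, burn_in = NULL, thin = NULL,
                           n_chains = 4, seed = 1,
                           scale = c("desk", "published")) {
  scale <- match.arg(scale)
  defaults <- if (scale == "desk") c(50000, 5000, 10) else c(2e7, 1000, 500)
  n_iter <- n_iter %||% defaults[1]
  burn_in <- burn_in %||% defaults[2]
  thin <- thin %||% defaults[3]
  if (n_chains < 2) stop_dc("need >= 2 chains for convergence diagnostics")
  if (n_iter <= burn_in) stop_dc("n_iter must exceed burn_in")

  cols <- c(response, predictors)
  if (!all(cols %in% names(data)))
    stop_dc("missing columns: ", paste(setdiff(cols, names(data)),
                                       collapse = ", "))
  sp <- normalize_taxon_names(data$species)
  cc <- stats::complete.cases(data[, cols, drop = FALSE]) &
    sp %in% normalize_taxon_names(tree$tip.label)
  d <- data[cc, , drop = FALSE]
  sp <- sp[cc]
  y <- as.numeric(d[[response]])
  if (!all(y %in% c(0, 1))) stop_dc("response must be binary 0/1")
  if (length(unique(y)) < 2)
    stop_dc("response has a single class among complete cases")
  X <- cbind(`(Intercept)` = 1,
             as.matrix(sapply(predictors, function(p) as.numeric(d[[p]]))))
  colnames(X) <- c("(Intercept)", predictors)
  if (qr(X)$rank < ncol(X)) stop_dc("singular design matrix")

  tr <- scale_tree_height(prune_to_taxa(tree, sp))
  C <- tree_vcv(tr)[sp, sp]
  Cinv <- chol2inv(chol(C + diag(1e-10, nrow(C))))

  p <- ncol(X)
  chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(seed + ch - 1)
    beta0 <- rnorm(p, 0, 0.5)
    out <- .pglmm_mcmc_cpp(y, X, Cinv, as.integer(n_iter),
                           as.integer(burn_in), as.integer(thin),
                           prior$shape %||% 0.001, prior$scale %||% 0.001,
                           prior$beta_var %||% 1e8, beta0, rep(0.3, p))
    colnames(out$beta) <- colnames(X)
    chains[[ch]] <- out
  }
  all_beta <- do.call(rbind, lapply(chains, `[[`, "beta"))
  all_sig <- unlist(lapply(chains, `[[`, "sigma2"))
  pmcmc <- apply(all_beta, 2, function(b) {
    pr <- mean(b > 0)
    max(2 * min(pr, 1 - pr), 1 / length(b))
  })
  rhat <- vapply(seq_len(p), function(j) {
    gelman_rubin(lapply(chains, function(ch) ch$beta[, j]))
  }, 0)
  ess <- vapply(seq_len(p), function(j) ess_simple(all_beta[, j]), 0)
  smry <- data.frame(
    coefficient = colnames(X),
    mean = colMeans(all_beta),
    sd = apply(all_beta, 2, sd),
    q2.5 = apply(all_beta, 2, quantile, 0.025),
    q97.5 = apply(all_beta, 2, quantile, 0.975),
    pMCMC = pmcmc, rhat = rhat, ess = ess, row.names = NULL)
  separation <- any(abs(smry$mean) > 20)
  if (separation)
    warning("very large coefficient magnitudes; possible (quasi-)separation",
            call. = FALSE)
  list(summary = smry,
       sigma2 = c(mean = mean(all_sig), median = median(all_sig),
                  q2.5 = quantile(all_sig, 0.025, names = FALSE),
                  q97.5 = quantile(all_sig, 0.975, names = FALSE)),
       chains = chains, n = length(y), response = response,
       separation = separation,
       settings = list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                       n_chains = n_chains, seed = seed))
}
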