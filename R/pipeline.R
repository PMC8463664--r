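# End-to-end orchestration: code traits -> ancestral reconstruction ->
# pairwise PGLS -> phylogenetic logistic regressions -> correlated-evolution
# Bayes factors and transition-rate summaries.

#' Audit a tree/trait-table pair before analysis
#'
#' Reports (never repairs): species present in the tree but absent from the
#' table and vice versa, per-column missingness, and the usable sample size
#' of each regression analysis (complete cases over its response and
#' predictor set).
#'
#' @param tree A \code{phylo} object or Newick path.
#' @param traits Raw trait data.frame or CSV path (see
#'   \code{\link{code_traits}}).
#' @return List with \code{only_in_tree}, \code{only_in_table},
#'   \code{missingness} (named fractions) and \code{usable_n} (per
#'   regression response).
#' @export
validate_inputs <- function(tree, traits) {
  if (is.character(tree)) tree <- read_newick(tree)
  if (is.character(traits)) traits <- read.csv(traits,
                                               stringsAsFactors = FALSE)
  tree <- validate_tree(tree)
  sp <- normalize_taxon_names(traits$species)
  coded <- code_traits(traits, tree = NULL)$coded
  preds <- c("conspicuousness_score", "ssd", "log_n_tadpoles",
             "residual_tadpole_size")
  preds <- intersect(preds, names(coded))
  responses <- c("phytotelm_breeder", "cannibalism", "alkaloids_present",
                 "transporter", "conspicuous", "habitat_far", "caregiver")
  usable <- vapply(responses, function(r) {
    v <- coded[[r]]
    if (is.character(v)) v <- ifelse(is.na(v), NA, 1)
    sum(stats::complete.cases(cbind(v, coded[, preds])) &
          sp %in% tree$tip.label)
  }, 0L)
  list(only_in_tree = setdiff(tree$tip.label, sp),
       only_in_table = setdiff(sp, tree$tip.label),
       missingness = vapply(traits, function(v)
         mean(is.na(v) | trimws(as.character(v)) %in% c("", "NA")), 0),
       usable_n = usable)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop_dc("pipeline stage '", name, "' failed: ", conditionMessage(e)))
}

#' Run the full comparative analysis
#'
#' Executes every stage on a tree and raw trait table: trait coding (with an
#' exclusion audit), equal-rates marginal ancestral state reconstruction of
#' the binary characters, pairwise PGLS with FDR adjustment, phylogenetic
#' logistic regressions of each binary response on the continuous
#' predictors, and the correlated-evolution test (independent vs dependent
#' vs constrained-dependent models, stepping-stone marginal likelihoods,
#' log Bayes factors, posterior transition rates). All randomness flows from
#' \code{seed}; two runs with the same inputs and seed are identical.
#'
#' @param tree A \code{phylo} object or Newick path.
#' @param traits Raw trait data.frame or CSV path.
#' @param out_dir Output directory (created if needed); CSV/JSON artifacts
#'   are written there. \code{NULL} skips writing.
#' @param seed Integer master seed.
#' @param scale "desk" (default; minutes) or "published" (the full published-scale
#'   chain settings; hours).
#' @param overrides Optional list of stage settings: \code{ss_stones},
#'   \code{ss_iters}, \code{mcmc_iter}, \code{pglmm_iter},
#'   \code{pglmm_burn}, \code{pglmm_thin}, \code{pglmm_chains},
#'   \code{responses}, \code{pagel_traitA}.
#' @return List with every stage's results (\code{audit}, \code{coded},
#'   \code{exclusions}, \code{asr}, \code{pairwise}, \code{pglmm},
#'   \code{pagel}).
#' @export
run_all <- function(tree, traits, out_dir = NULL, seed = 1,
                    scale = c("desk", "published"), overrides = list()) {
  scale <- match.arg(scale)
  if (is.character(tree)) tree <- read_newick(tree)
  if (is.character(traits)) traits <- read.csv(traits,
                                               stringsAsFactors = FALSE)
  tree <- validate_tree(tree)
  if (!nrow(traits))
    stop_dc("pipeline stage 'coding' failed: empty trait table")
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  o <- function(nm, default) overrides[[nm]] %||% default
  ss_stones <- o("ss_stones", if (scale == "desk") 20 else 100)
  ss_iters <- o("ss_iters", if (scale == "desk") 3000 else 10000)
  mcmc_iter <- o("mcmc_iter", if (scale == "desk") 6000 else 40000)
  pglmm_iter <- o("pglmm_iter", if (scale == "desk") 20000 else 2e7)
  pglmm_burn <- o("pglmm_burn", if (scale == "desk") 2000 else 1000)
  pglmm_thin <- o("pglmm_thin", if (scale == "desk") 10 else 500)
  pglmm_chains <- o("pglmm_chains", 4)

  log_lines <- c(sprintf("dendrocare run: seed=%d scale=%s time=%s", seed,
                         scale, format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                 sprintf("R %s; tips=%d; species=%d", getRversion(),
                         ape::Ntip(tree), nrow(traits)))

  audit <- run_stage("validate", validate_inputs(tree, traits))
  coding <- run_stage("coding", code_traits(traits, tree))
  coded <- coding$coded
  rownames(coded) <- coded$species
  common <- intersect(tree$tip.label, coded$species)
  if (length(common) < 4)
    stop_dc("pipeline stage 'coding' failed: almost no species joinable")
  wtree <- prune_to_taxa(tree, common)

  named01 <- function(col) {
    v <- coded[common, col]
    if (is.character(v)) v <- match(v, c("male", "female")) - 1L
    setNames(as.integer(v), common)
  }

  # marginal ancestral state reconstruction for each binary character
  asr_traits <- c("conspicuous", "caregiver", "habitat_far", "transporter",
                  "phytotelm_breeder", "cannibalism")
  asr <- run_stage("asr", {
    out <- list()
    for (trn in asr_traits) {
      st <- named01(trn)
      if (length(unique(st[!is.na(st)])) < 2) next
      out[[trn]] <- marginal_asr(wtree, st, k = 2)
    }
    out
  })

  # pairwise phylogenetic regressions with FDR (comparison-table shape)
  cont <- c("conspicuousness_score", "ssd", "log_clutch_size",
            "log_egg_size", "log_tadpole_size", "log_n_tadpoles")
  pair_traits <- lapply(cont, function(cn)
    setNames(as.numeric(coded[common, cn]), common))
  names(pair_traits) <- cont
  pairwise <- run_stage("pairwise_pgls",
                        pairwise_pgls_matrix(pair_traits, wtree))

  # phylogenetic logistic regressions (one per binary response)
  preds <- c("conspicuousness_score", "ssd", "log_n_tadpoles",
             "residual_tadpole_size")
  responses <- o("responses",
                 c("phytotelm_breeder", "cannibalism", "alkaloids_present",
                   "transporter", "conspicuous", "habitat_far", "caregiver"))
  dreg <- coded[common, , drop = FALSE]
  dreg$transporter <- match(dreg$transporter, c("male", "female")) - 1L
  dreg$caregiver <- match(dreg$caregiver, c("male", "female")) - 1L
  pglmm_fits <- run_stage("pglmm", {
    out <- list()
    for (r in responses) {
      pr <- if (r == "conspicuous") setdiff(preds, "conspicuousness_score")
            else preds
      fit <- tryCatch(
        pglmm_logistic(r, pr, dreg, wtree, n_iter = pglmm_iter,
                       burn_in = pglmm_burn, thin = pglmm_thin,
                       n_chains = pglmm_chains, seed = seed + 100),
        error = function(e) list(error = conditionMessage(e)))
      out[[r]] <- fit
    }
    out
  })

  # correlated evolution of aposematism components with phytotelm-breeding
  pagel_traitA <- o("pagel_traitA", c("conspicuous", "alkaloids_present"))
  pagel <- run_stage("pagel", {
    out <- list()
    tB <- named01("phytotelm_breeder")
    for (ta in pagel_traitA) {
      tA <- named01(ta)
      if (length(unique(tA[!is.na(tA)])) < 2 ||
          length(unique(tB[!is.na(tB)])) < 2) next
      ss_i <- stepping_stone_ml(wtree, tA, tB, "independent",
                                n_stones = ss_stones,
                                iters_per_stone = ss_iters, seed = seed + 1)
      ss_d <- stepping_stone_ml(wtree, tA, tB, "dependent",
                                n_stones = ss_stones,
                                iters_per_stone = ss_iters, seed = seed + 2)
      ss_c <- stepping_stone_ml(wtree, tA, tB, "dependent_constrained",
                                n_stones = ss_stones,
                                iters_per_stone = ss_iters, seed = seed + 3)
      mc <- mcmc_sample(wtree, tA, tB, "dependent_constrained",
                        n_iter = mcmc_iter, seed = seed + 4)
      out[[ta]] <- list(
        lnml = c(independent = ss_i$lnml, dependent = ss_d$lnml,
                 constrained = ss_c$lnml),
        bf_dependent = log_bayes_factor(ss_d, ss_i),
        bf_constrained = log_bayes_factor(ss_c, ss_i),
        rates = transition_summary(mc))
      log_lines <- c(log_lines, sprintf(
        "pagel %s: logBF(dep)=%.2f band=%s", ta,
        out[[ta]]$bf_dependent$logBF, out[[ta]]$bf_dependent$band))
    }
    out
  })

  res <- list(audit = audit, coded = coded, exclusions = coding$exclusions,
              asr = asr, pairwise = pairwise, pglmm = pglmm_fits,
              pagel = pagel, seed = seed, scale = scale)
  if (!is.null(out_dir)) write_run_outputs(res, out_dir, log_lines)
  res
}

write_run_outputs <- function(res, out_dir, log_lines = character()) {
  wcsv <- function(x, f) write.csv(x, file.path(out_dir, f),
                                   row.names = FALSE)
  wcsv(res$coded, "coded_traits.csv")
  wcsv(res$exclusions, "exclusions.csv")
  for (trn in names(res$asr)) {
    a <- res$asr[[trn]]
    wcsv(cbind(node = rownames(a$anc), as.data.frame(a$anc)),
         paste0("asr_", trn, ".csv"))
  }
  wcsv(res$pairwise$pairs, "table3_like.csv")
  t4 <- do.call(rbind, lapply(names(res$pglmm), function(r) {
    f <- res$pglmm[[r]]
    if (!is.null(f$error)) return(NULL)
    s <- f$summary
    data.frame(response = r, n = f$n, coefficient = s$coefficient,
               beta = s$mean, pMCMC = s$pMCMC, rhat = s$rhat)
  }))
  if (!is.null(t4)) wcsv(t4, "table4_like.csv")
  bf <- lapply(res$pagel, function(p)
    list(lnml = as.list(p$lnml),
         logBF_dependent = p$bf_dependent$logBF,
         band_dependent = p$bf_dependent$band,
         logBF_constrained = p$bf_constrained$logBF,
         band_constrained = p$bf_constrained$band))
  jsonlite::write_json(bf, file.path(out_dir, "bayes_factors.json"),
                       auto_unbox = TRUE, digits = NA)
  tr <- do.call(rbind, lapply(names(res$pagel), function(ta)
    cbind(traitA = ta, res$pagel[[ta]]$rates$table)))
  if (!is.null(tr)) wcsv(tr, "transition_rates.csv")
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
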