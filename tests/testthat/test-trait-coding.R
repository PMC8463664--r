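test_that("conspicuousness scoring sums the 11 segment indicators", {
  expect_equal(conspicuousness_score(rep(1, 11)), 11L)
  expect_equal(conspicuousness_score(rep(0, 11)), 0L)
  expect_equal(conspicuousness_score(c(rep(1, 6), rep(0, 5))), 6L)
  expect_error(conspicuousness_score(rep(1, 10)), "11")
  expect_error(conspicuousness_score(c(rep(1, 10), 2)), "0 or 1")
})

test_that("binarization thresholds match the trait definitions", {
  expect_equal(binarize_conspicuous(c(6, 5, 11, 0)), c(1L, 0L, 1L, 0L))
  expect_error(binarize_conspicuous(12), "range")
  # alkaloid presence is strictly greater than 10 ug / 100 mg
  expect_equal(alkaloid_presence(c(0, 10, 10.001, 50)), c(0L, 0L, 1L, 1L))
  expect_error(alkaloid_presence(-1), "negative")
})

test_that("sexual size dimorphism is the female/male SVL ratio", {
  expect_equal(sexual_size_dimorphism(27.46, 24.55), 27.46 / 24.55)
  expect_equal(round(sexual_size_dimorphism(27.46, 24.55), 4), 1.1185)
  expect_equal(sexual_size_dimorphism(20, 20), 1)
  expect_equal(round(sexual_size_dimorphism(16, 14), 4), 1.1429)
  expect_true(is.na(sexual_size_dimorphism(NA, 20)))
  expect_error(sexual_size_dimorphism(-1, 20), "positive")
})

test_that("caregiver coding binarizes and excludes with reasons", {
  out <- code_caregiver(c("male", "female", "none", "both", "unknown", NA))
  expect_equal(out$value, c("male", "female", NA, NA, NA, NA))
  expect_equal(out$reason[3], "no_parental_care")
  expect_equal(out$reason[4], "ambiguous_biparental")
  expect_true(all(is.na(out$reason[c(1, 2, 5, 6)])))
})

test_that("transporter coding follows the observed majority, ties missing", {
  expect_equal(code_transporter(c("male", "female", "unknown")),
               c("male", "female", NA))
  expect_equal(code_transporter("both", male_obs = 5, female_obs = 1),
               "male")
  expect_equal(code_transporter("both", male_obs = 1, female_obs = 4),
               "female")
  expect_true(is.na(code_transporter("both", male_obs = 2, female_obs = 2)))
})

test_that("deposition coding groups ponds and streams as non-phytotelm", {
  expect_equal(code_deposition(c("pond", "stream", "multiple", "phytotelm",
                                 "unknown")),
               c(0L, 0L, 0L, 1L, NA))
})

test_that("range handling takes midpoints and parses lo-hi strings", {
  expect_equal(median_of_range(1, 40), 20.5)
  expect_equal(median_of_range(12, 12), 12)
  expect_equal(median_of_range(2, 5), 3.5)
  expect_error(median_of_range(5, 2), "lo > hi")
  expect_equal(parse_range(c("12.5", "1-40", "NA", "")),
               c(12.5, 20.5, NA, NA))
})

test_that("log transform is natural log, rejects non-positives by name", {
  expect_equal(log_transform(c(1, exp(1))), c(0, 1))
  expect_true(is.na(log_transform(NA_real_)))
  expect_error(log_transform(c(a = 2, b = 0)), "b")
})

test_that("size-controlled residuals behave under known structure", {
  tr <- simulate_yule_tree(100, 1, seed = 21)
  fs <- exp(simulate_brownian(tr, 0.05, log(25), seed = 22))
  # exactly proportional trait -> residuals numerically zero
  r <- size_controlled_residuals(3.1 * fs, fs, tr)
  expect_lt(max(abs(r)), 1e-8)
  # star tree -> PGLS equals OLS
  star <- read_newick(paste0("(", paste0("t", 1:30, ":1", collapse = ","),
                             ");"))
  set.seed(23)
  y <- setNames(rnorm(30), star$tip.label)
  x <- setNames(rnorm(30, 10), star$tip.label)
  r_p <- size_controlled_residuals(y, x, star, method = "pgls")
  r_o <- unname(residuals(lm(y ~ x)))
  expect_lt(max(abs(unname(r_p) - r_o)), 1e-8)
  # simulated allometry: slope recovered within 3 SE
  lf <- simulate_brownian(tr, 0.05, log(25), seed = 24)
  egg <- 0.7 * lf + simulate_brownian(tr, 0.01, 0, seed = 25)
  fit <- pgls(egg, lf, tr)
  expect_lt(abs(fit$beta - 0.7), 3 * fit$se)
  # missingness propagates in place
  yy <- setNames(c(NA, rnorm(99)), names(fs))
  rr <- size_controlled_residuals(yy, fs, tr)
  expect_true(is.na(rr[1]) && sum(is.na(rr)) == 1)
})

test_that("trait-table coding is deterministic and audits exclusions", {
  fx <- make_dendrobatid_like_fixture(seed = 4, n_species = 120)
  out1 <- code_traits(fx$traits, fx$tree)
  out2 <- code_traits(fx$traits, fx$tree)
  expect_identical(out1, out2)
  expect_true(all(out1$exclusions$reason %in%
                    c("no_parental_care", "ambiguous_biparental")))
  # every excluded species is NA in the coded caregiver column
  excl_sp <- out1$exclusions$species
  expect_true(all(is.na(out1$coded$caregiver[
    out1$coded$species %in% excl_sp])))
  expect_error(code_traits(fx$traits[0, ]), "empty")
})
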