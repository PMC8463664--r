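# Trait definitions: conspicuousness scoring and binarization, alkaloid
# presence, sexual size dimorphism, binarization/exclusion rules for care
# traits, range medians, log transforms and female-size-controlled residuals.

#' Conspicuousness score from skin-segment indicators
#'
#' The body is divided into 11 non-overlapping skin segments; each is scored
#' 1 when its coloration contrasts against a leaf-litter background and 0
#' otherwise. The species score is the sum, 0 (no contrast) to 11 (maximum
#' contrast).
#'
#' @param segments Numeric vector of 11 binary indicators, or a matrix with
#'   11 columns (one row per species).
#' @return Integer score(s) in 0..11.
#' @export
conspicuousness_score <- function(segments) {
  m <- if (is.matrix(segments)) segments else matrix(segments, nrow = 1)
  if (ncol(m) != 11)
    stop_dc("exactly 11 segment indicators required, got ", ncol(m))
  if (!all(m %in% c(0, 1)))
    stop_dc("segment indicators must be 0 or 1")
  s <- as.integer(rowSums(m))
  if (!is.matrix(segments)) s[1] else s
}

#' Binarize a conspicuousness score
#'
#' Scores of 6 or more are coded conspicuous (1); below 6, non-conspicuous
#' (0). The 6-point threshold reflects the observation that alkaloid-bearing
#' species all score at least 6.
#'
#' @param score Numeric score(s) in 0..11; NA propagates.
#' @return Integer 0/1 vector.
#' @export
binarize_conspicuous <- function(score) {
  ok <- is.na(score) | (score >= 0 & score <= 11)
  if (!all(ok)) stop_dc("score out of range 0..11: ", score[!ok][1])
  as.integer(ifelse(is.na(score), NA, score >= 6))
}

#' Alkaloid presence from quantity
#'
#' Skin alkaloids are coded present when the measured quantity exceeds
#' 10 ug per 100 mg of skin (strictly greater), absent otherwise.
#'
#' @param level Numeric quantity in ug alkaloids per 100 mg skin; NA
#'   propagates.
#' @return Integer 0/1 vector.
#' @export
alkaloid_presence <- function(level) {
  bad <- !is.na(level) & level < 0
  if (any(bad)) stop_dc("negative alkaloid level: ", level[bad][1])
  as.integer(ifelse(is.na(level), NA, level > 10))
}

#' Sexual size dimorphism
#'
#' Ratio of female to male snout-vent length (mm / mm, dimensionless).
#' Missing either sex yields NA, never zero.
#'
#' @param female_svl,male_svl Numeric SVL in mm.
#' @return Numeric ratio female/male.
#' @export
sexual_size_dimorphism <- function(female_svl, male_svl) {
  bad <- (!is.na(female_svl) & female_svl <= 0) |
         (!is.na(male_svl) & male_svl <= 0)
  if (any(bad)) stop_dc("SVL must be positive")
  ifelse(is.na(female_svl) | is.na(male_svl), NA_real_,
         female_svl / male_svl)
}

#' Code the main caregiver sex
#'
#' Known cases are binarized as male- or female-biased care. Species with no
#' parental care, or with biparental care and no dominant sex, are excluded
#' with a machine-readable reason; unknown is missing.
#'
#' @param caregiver_raw Character vector with values in
#'   \code{none, male, female, both, unknown} (NA treated as unknown).
#' @return A data.frame with columns \code{value} ("male"/"female"/NA) and
#'   \code{reason} (NA, "no_parental_care", or "ambiguous_biparental").
#' @export
code_caregiver <- function(caregiver_raw) {
  raw <- tolower(trimws(as.character(caregiver_raw)))
  raw[is.na(caregiver_raw) | raw %in% c("", "na", "unknown")] <- "unknown"
  ok <- raw %in% c("none", "male", "female", "both", "unknown")
  if (!all(ok)) stop_dc("unrecognized caregiver value: ", raw[!ok][1])
  value <- ifelse(raw %in% c("male", "female"), raw, NA_character_)
  reason <- rep(NA_character_, length(raw))
  reason[raw == "none"] <- "no_parental_care"
  reason[raw == "both"] <- "ambiguous_biparental"
  data.frame(value = value, reason = reason, stringsAsFactors = FALSE)
}

#' Code the tadpole-transporting sex
#'
#' Assigned by the sex most frequently observed carrying tadpoles. When
#' observation counts are given, the majority sex wins; an exact tie is
#' coded missing rather than assigned arbitrarily.
#'
#' @param transporter_raw Character vector (\code{male, female, both,
#'   unknown}); "both" requires counts to resolve.
#' @param male_obs,female_obs Optional observation counts per species.
#' @return Character vector "male"/"female"/NA.
#' @export
code_transporter <- function(transporter_raw, male_obs = NULL,
                             female_obs = NULL) {
  raw <- tolower(trimws(as.character(transporter_raw)))
  raw[is.na(transporter_raw) | raw %in% c("", "na", "unknown")] <- "unknown"
  out <- ifelse(raw %in% c("male", "female"), raw, NA_character_)
  if (!is.null(male_obs) && !is.null(female_obs)) {
    use <- raw == "both" & !is.na(male_obs) & !is.na(female_obs)
    out[use & male_obs > female_obs] <- "male"
    out[use & female_obs > male_obs] <- "female"
    # exact ties stay NA
  }
  out
}

#' Code the tadpole deposition site
#'
#' Deposition sites are binarized as phytotelmata (1) versus
#' non-phytotelmata (0). Streams, ponds, and species that use both ponds
#' and streams are non-phytotelm; unknown is missing.
#'
#' @param deposition_raw Character vector with values in
#'   \code{stream, pond, phytotelm, multiple, unknown}.
#' @return Integer 0/1 vector.
#' @export
code_deposition <- function(deposition_raw) {
  raw <- tolower(trimws(as.character(deposition_raw)))
  raw[is.na(deposition_raw) | raw %in% c("", "na", "unknown")] <- "unknown"
  ok <- raw %in% c("stream", "pond", "phytotelm", "phytotelmata",
                   "multiple", "stream+pond", "unknown")
  if (!all(ok)) stop_dc("unrecognized deposition value: ", raw[!ok][1])
  ifelse(raw == "unknown", NA_integer_,
         as.integer(raw %in% c("phytotelm", "phytotelmata")))
}

#' Median of a reported range
#'
#' When only a min-max range is reported for a count or size, the analysis
#' value is the midpoint (lo + hi) / 2.
#'
#' @param lo,hi Numeric range endpoints, lo <= hi.
#' @return Numeric midpoint.
#' @export
median_of_range <- function(lo, hi) {
  bad <- !is.na(lo) & !is.na(hi) & lo > hi
  if (any(bad)) stop_dc("range with lo > hi")
  (lo + hi) / 2
}

#' Parse numeric-or-range strings
#'
#' Accepts plain numbers ("12.5") or "lo-hi" ranges ("1-40"), reducing
#' ranges to their median. "NA" and "" are missing.
#'
#' @param x Character vector.
#' @return Numeric vector.
#' @export
parse_range <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA_real_, length(x))
  plain <- grepl("^-?[0-9.]+$", x)
  out[plain] <- as.numeric(x[plain])
  rng <- grepl("^[0-9.]+\\s*-\\s*[0-9.]+$", x)
  if (any(rng)) {
    parts <- strsplit(x[rng], "\\s*-\\s*")
    lo <- vapply(parts, function(p) as.numeric(p[1]), 0)
    hi <- vapply(parts, function(p) as.numeric(p[2]), 0)
    out[rng] <- median_of_range(lo, hi)
  }
  out
}

#' Natural-log transform with named rejection of non-positive values
#'
#' @param values Numeric vector; NA propagates.
#' @param labels Optional names used in error messages.
#' @return log(values).
#' @export
log_transform <- function(values, labels = names(values)) {
  bad <- !is.na(values) & values <= 0
  if (any(bad)) {
    who <- if (!is.null(labels)) paste(labels[bad], collapse = ", ")
           else paste(which(bad), collapse = ", ")
    stop_dc("log transform requires positive values; offenders: ", who)
  }
  log(values)
}

#' Residuals of a trait controlled by female body size
#'
#' Regresses the trait on female SVL and returns residuals, so downstream
#' models see size-corrected values. The regression is phylogenetic GLS
#' under Brownian covariance by default; ordinary least squares is available
#' for sensitivity checks. Missing values propagate; species order is
#' preserved.
#'
#' @param trait Named numeric vector (names are species).
#' @param female_svl Named numeric vector aligned with \code{trait}.
#' @param tree A \code{phylo} object covering the complete-case species
#'   (required for \code{method = "pgls"}).
#' @param method "pgls" (default) or "ols".
#' @return Numeric vector of residuals, same length/order as \code{trait}.
#' @export
size_controlled_residuals <- function(trait, female_svl, tree = NULL,
                                      method = c("pgls", "ols")) {
  method <- match.arg(method)
  if (length(trait) != length(female_svl))
    stop_dc("trait and female_svl lengths differ")
  cc <- which(!is.na(trait) & !is.na(female_svl))
  if (length(cc) < 3) stop_dc("need >= 3 complete pairs")
  res <- rep(NA_real_, length(trait))
  if (method == "ols" || is.null(tree)) {
    if (method == "pgls" && is.null(tree)) stop_dc("pgls requires a tree")
    fit <- stats::lm(trait[cc] ~ female_svl[cc])
    res[cc] <- stats::residuals(fit)
  } else {
    sp <- names(trait)[cc]
    if (is.null(sp)) stop_dc("trait must be named by species for pgls")
    fit <- pgls(y = setNames(trait[cc], sp),
                x = setNames(female_svl[cc], sp), tree = tree)
    res[cc] <- fit$residuals
  }
  res
}

#' Code a raw species trait table
#'
#' Applies every coding rule to a raw table (one row per species): the 0-11
#' conspicuousness score and its binarization, alkaloid presence, SSD,
#' caregiver/transporter/deposition/habitat/cannibalism coding, range
#' medians and natural-log transforms of the continuous traits, and (when a
#' tree is supplied) female-size-controlled residuals of egg size, clutch
#' size and tadpole size. Deterministic: the same table always yields the
#' same coded table.
#'
#' @param records Data frame with columns named as in
#'   \code{\link{make_dendrobatid_like_fixture}}: \code{species},
#'   \code{caregiver_raw}, \code{transporter_raw} (optionally
#'   \code{transporter_male_obs}/\code{transporter_female_obs}),
#'   \code{habitat}, \code{deposition_raw}, \code{cannibalism},
#'   \code{male_svl}, \code{female_svl}, \code{clutch_size},
#'   \code{egg_size}, \code{tadpole_size}, \code{n_tadpoles_carried}, and
#'   either \code{segment_1}..\code{segment_11} or
#'   \code{conspicuousness_score}, plus \code{alkaloid_ug_per_100mg}.
#' @param tree Optional \code{phylo}; enables phylogenetic size-controlled
#'   residuals.
#' @return A list with \code{coded} (data.frame of coded traits) and
#'   \code{exclusions} (data.frame species/field/reason).
#' @export
code_traits <- function(records, tree = NULL) {
  if (!nrow(records)) stop_dc("empty trait table")
  if (!"species" %in% names(records)) stop_dc("missing 'species' column")
  sp <- normalize_taxon_names(records$species)

  seg_cols <- paste0("segment_", 1:11)
  score <- if (all(seg_cols %in% names(records))) {
    m <- as.matrix(records[, seg_cols])
    out <- rep(NA_integer_, nrow(m))
    full <- stats::complete.cases(m)
    if (any(full)) out[full] <- conspicuousness_score(m[full, , drop = FALSE])
    out
  } else if ("conspicuousness_score" %in% names(records)) {
    as.numeric(records$conspicuousness_score)
  } else rep(NA_real_, nrow(records))

  care <- code_caregiver(records$caregiver_raw %||% rep(NA, nrow(records)))
  dep <- code_deposition(records$deposition_raw %||% rep(NA, nrow(records)))
  transp <- code_transporter(
    records$transporter_raw %||% rep(NA, nrow(records)),
    records$transporter_male_obs %||% NULL,
    records$transporter_female_obs %||% NULL)

  habitat_raw <- tolower(trimws(as.character(
    records$habitat %||% rep(NA, nrow(records)))))
  habitat_far <- ifelse(habitat_raw %in% "far_stream", 1L,
                 ifelse(habitat_raw %in% "near_stream", 0L, NA_integer_))
  cann_raw <- tolower(trimws(as.character(
    records$cannibalism %||% rep(NA, nrow(records)))))
  cannibalism <- ifelse(cann_raw %in% "present", 1L,
                 ifelse(cann_raw %in% "absent", 0L, NA_integer_))

  num <- function(col) {
    v <- records[[col]] %||% rep(NA, nrow(records))
    if (is.character(v) || is.factor(v)) parse_range(v) else as.numeric(v)
  }
  clutch <- num("clutch_size"); egg <- num("egg_size")
  tad <- num("tadpole_size"); ntad <- num("n_tadpoles_carried")
  msvl <- num("male_svl"); fsvl <- num("female_svl")
  alk <- num("alkaloid_ug_per_100mg")

  coded <- data.frame(
    species = sp,
    conspicuousness_score = score,
    conspicuous = binarize_conspicuous(score),
    alkaloids_present = alkaloid_presence(alk),
    caregiver = care$value,
    transporter = transp,
    phytotelm_breeder = dep,
    habitat_far = habitat_far,
    cannibalism = cannibalism,
    ssd = sexual_size_dimorphism(fsvl, msvl),
    log_clutch_size = log_transform(clutch, sp),
    log_egg_size = log_transform(egg, sp),
    log_tadpole_size = log_transform(tad, sp),
    log_n_tadpoles = log_transform(ifelse(!is.na(ntad) & ntad == 0,
                                          NA, ntad), sp),
    stringsAsFactors = FALSE)

  # size-controlled residuals (phylogenetic when a tree is available)
  for (tr in c("egg_size", "clutch_size", "tadpole_size")) {
    v <- switch(tr, egg_size = egg, clutch_size = clutch, tadpole_size = tad)
    col <- paste0("residual_", tr)
    vals <- setNames(suppressWarnings(log(v)), sp)
    fs <- setNames(suppressWarnings(log(fsvl)), sp)
    n_cc <- sum(!is.na(vals) & !is.na(fs))
    if (n_cc >= 3) {
      if (!is.null(tree)) {
        keep <- intersect(sp[!is.na(vals) & !is.na(fs)], tree$tip.label)
        if (length(keep) >= 3) {
          sub <- prune_to_taxa(tree, keep)
          r <- size_controlled_residuals(vals[keep], fs[keep], sub, "pgls")
          coded[[col]] <- r[match(sp, keep)]
        } else coded[[col]] <- NA_real_
      } else {
        coded[[col]] <- size_controlled_residuals(vals, fs, method = "ols")
      }
    } else coded[[col]] <- NA_real_
  }

  excl <- data.frame(species = sp[!is.na(care$reason)],
                     field = "caregiver",
                     reason = care$reason[!is.na(care$reason)],
                     stringsAsFactors = FALSE)
  list(coded = coded, exclusions = excl)
}
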