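#' Default demographic strata for the synthetic population
#'
#' Gender-by-age-band cells with proportions and per-subscale latent means.
#' Proportions are the product of the published gender and age-band margins
#' of the 2016 Dutch sample; the latent mean of a cell is an additive
#' gender + age-band decomposition of the published subgroup mean T-scores,
#' mapped to the latent metric:
#' `mu_cell = (T_gender + T_ageband - T_total - 50) / 10`.
#' Stratum latent SDs default to 1 (the calibration-population scale).
#'
#' @return Data frame with one row per stratum: `gender`, `age_band`,
#'   `proportion`, `mu_gmh`, `mu_gph`, `sd_gmh`, `sd_gph`.
#' @export
default_strata <- function() {
  ref <- gh_reference_tscores()
  pick <- function(type, sub, scale, col = "mean_t")
    ref[[col]][ref$subgroup_type == type & ref$subgroup == sub &
               ref$subscale == scale]
  genders <- c("Male", "Female")
  bands <- c("18-34", "35-44", "45-54", "55-64", "65-74", "75+")
  n_total <- pick("total", "Total", "GMH", "n")
  grid <- expand.grid(gender = genders, age_band = bands,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$proportion <- vapply(seq_len(nrow(grid)), function(i) {
    (pick("gender", grid$gender[i], "GMH", "n") / n_total) *
      (pick("age", grid$age_band[i], "GMH", "n") / n_total)
  }, 0)
  grid$proportion <- grid$proportion / sum(grid$proportion)
  for (scale in c("GMH", "GPH")) {
    tot <- pick("total", "Total", scale)
    mu <- vapply(seq_len(nrow(grid)), function(i) {
      (pick("gender", grid$gender[i], scale) +
         pick("age", grid$age_band[i], scale) - tot - 50) / 10
    }, 0)
    grid[[paste0("mu_", tolower(scale))]] <- mu
  }
  grid$sd_gmh <- 1
  grid$sd_gph <- 1
  grid
}

#' Configuration for the synthetic survey population
#'
#' Defines the statistical structure of a generated population: demographic
#' strata (gender x age band) with cell proportions and per-cell bivariate
#' latent means for the mental and physical traits, the latent correlation,
#' graded-response item parameters for all 10 items (the 8 subscale items on
#' their own trait, the two standalone items on a standardized composite),
#' the composite weight of the anchor item, a completely-at-random
#' missingness rate, and margins for the remaining demographics.  The
#' defaults emulate the 2016 Dutch general-population study: n = 4370,
#' subgroup latent means about half an SD below the calibration centre, no
#' missing responses (the survey did not allow skipping), latent correlation
#' 0.6.
#'
#' @param n Number of respondents (default 4370).
#' @param seed Integer seed; every random draw of [generate_population()] is
#'   governed by it.
#' @param strata Stratum table as in [default_strata()].
#' @param rho Latent correlation between the mental and physical traits,
#'   in (-1, 1).
#' @param anchor_weight Weight `w` of the mental trait in the standardized
#'   composite `w theta_GMH + (1 - w) theta_GPH` driving the two standalone
#'   items (default 0.5).
#' @param missing_rate Per-item completely-at-random missingness rate in
#'   \[0, 1) (default 0).
#' @param params A `grm_parameters` list with a `trait` attribute assigning
#'   each item to `GMH`, `GPH` or `composite`.
#' @param demographic_margins Margins (variable/category/percent) used to
#'   draw education, region and ethnicity independently; default the 2016
#'   Dutch census margins.
#' @param age_weights Within-band age distributions; default
#'   [default_age_weights()].
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n = 4370, seed = 1, strata = default_strata(),
                             rho = 0.6, anchor_weight = 0.5,
                             missing_rate = 0,
                             params = default_item_parameters(),
                             demographic_margins = gh_census_margins(),
                             age_weights = default_age_weights()) {
  cfg <- structure(list(n = as.integer(n), seed = as.integer(seed),
                        strata = strata, rho = rho,
                        anchor_weight = anchor_weight,
                        missing_rate = missing_rate, params = params,
                        demographic_margins = demographic_margins,
                        age_weights = age_weights),
                   class = "synthetic_config")
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  if (cfg$n < 1L) fail("n must be positive")
  st <- cfg$strata
  need <- c("gender", "age_band", "proportion", "mu_gmh", "mu_gph",
            "sd_gmh", "sd_gph")
  if (!all(need %in% names(st)))
    fail("strata must have columns ", paste(need, collapse = ", "))
  if (abs(sum(st$proportion) - 1) > 1e-9)
    fail("stratum proportions must sum to 1")
  if (any(st$proportion < 0)) fail("negative stratum proportion")
  if (any(st$sd_gmh <= 0) || any(st$sd_gph <= 0)) fail("stratum SDs must be > 0")
  if (!(cfg$rho > -1 && cfg$rho < 1)) fail("rho must lie in (-1, 1)")
  if (cfg$anchor_weight < 0 || cfg$anchor_weight > 1)
    fail("anchor_weight must lie in [0, 1]")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    fail("missing_rate must lie in [0, 1)")
  trait <- attr(cfg$params, "trait")
  if (is.null(trait)) fail("item parameters must carry a trait attribute")
  if (!all(trait %in% c("GMH", "GPH", "composite")))
    fail("item traits must be GMH, GPH or composite")
  missing_bands <- setdiff(unique(st$age_band), names(cfg$age_weights))
  if (length(missing_bands))
    fail("age_weights lacks band(s): ", paste(missing_bands, collapse = ", "))
  for (b in names(cfg$age_weights)) {
    w <- cfg$age_weights[[b]]
    if (abs(sum(w$weight) - 1) > 1e-9 || any(w$weight < 0))
      fail("age weights for band ", b, " must be non-negative and sum to 1")
  }
  cfg
}

# draw one GRM category per respondent for one item, given trait values
draw_grm <- function(theta, item) {
  p <- grm_probability(theta, item)
  cum <- t(apply(p, 1L, cumsum))
  u <- stats::runif(length(theta))
  as.integer(rowSums(u > cum) + 1L)
}

# age band -> integer age range (75+ capped at the published sample maximum)
band_age_range <- function(band) {
  switch(band, "18-34" = c(18L, 34L), "35-44" = c(35L, 44L),
         "45-54" = c(45L, 54L), "55-64" = c(55L, 64L),
         "65-74" = c(65L, 74L), "75+" = c(75L, 93L),
         fail("unknown age band: ", band))
}

#' Default within-band age distributions
#'
#' The published tables pin down the age structure twice: fine reference
#' bands (18-34 ... 75+) with exact subgroup sizes, and the coarser census
#' bins (18-39, 40-65, > 65) of the sample margins.  A uniform age
#' distribution inside each fine band cannot satisfy both, so the default
#' within-band weights are calibrated from them: the 35-44 band is split at
#' 40 and the 65-74 band at 66 so that the implied coarse margins match the
#' published sample margins, and ages are uniform within each sub-segment
#' (and within every other band).
#'
#' @return Named list, one entry per reference age band, each a data frame
#'   with `age` and `weight` (weights sum to 1).
#' @export
default_age_weights <- function() {
  ref <- gh_reference_tscores()
  n_band <- stats::setNames(
    ref$n[ref$subgroup_type == "age" & ref$subscale == "GMH"],
    ref$subgroup[ref$subgroup_type == "age" & ref$subscale == "GMH"])
  sm <- gh_sample_margins()
  coarse <- stats::setNames(sm$percent[sm$variable == "age"],
                            sm$category[sm$variable == "age"])
  n_total <- sum(n_band)
  target_18_39 <- coarse[["18-39"]] / 100 * n_total
  target_40_65 <- coarse[["40-65"]] / 100 * n_total
  # share of the 35-44 band below age 40, then share of 65-74 at exactly 65
  s1 <- (target_18_39 - n_band[["18-34"]]) / n_band[["35-44"]]
  s2 <- (target_40_65 - n_band[["35-44"]] * (1 - s1) - n_band[["45-54"]] -
           n_band[["55-64"]]) / n_band[["65-74"]]
  s1 <- min(max(s1, 0), 1); s2 <- min(max(s2, 0), 1)
  uniform <- function(band) {
    r <- band_age_range(band)
    ages <- seq(r[1], r[2])
    data.frame(age = ages, weight = rep(1 / length(ages), length(ages)))
  }
  out <- lapply(names(n_band), uniform)
  names(out) <- names(n_band)
  out[["35-44"]]$weight <- c(rep(s1 / 5, 5), rep((1 - s1) / 5, 5))
  out[["65-74"]]$weight <- c(s2, rep((1 - s2) / 9, 9))
  out
}

#' Generate a synthetic survey population
#'
#' Draws, in a fixed order so identical seeds give identical output on any
#' platform: (1) a stratum per respondent from the configured proportions,
#' with age drawn from the within-band weights and education / region /
#' ethnicity from the demographic margins; (2) bivariate-normal latent
#' mental and physical traits with the stratum means, SDs and correlation
#' `rho`; (3) every item response from its graded-response category
#' probabilities at the respondent's trait (standalone items at the
#' standardized composite trait), written as *raw* response codes — the
#' reverse-coded items in their administration direction, and the pain item
#' banded back onto the 0-10 scale with a uniform draw inside the band;
#' (4) completely-at-random missingness masks.
#'
#' @param config A [synthetic_config()].
#' @return List of class `synthetic_population`: `records` (a respondent
#'   data frame in the package CSV dialect) and `truth` (`respondent_id`,
#'   `theta_gmh`, `theta_gph`, `theta_composite`, `stratum`) for recovery
#'   tests.
#' @examples
#' pop <- generate_population(synthetic_config(n = 100, seed = 7))
#' head(pop$records)
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  validate_synthetic_config(config)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  n <- config$n
  st <- config$strata
  instrument <- promis_gh_instrument()

  # (1) strata and demographics; ages drawn band by band in fixed band order
  cell <- sample.int(nrow(st), n, replace = TRUE, prob = st$proportion)
  band <- st$age_band[cell]
  age <- integer(n)
  for (b in names(config$age_weights)) {
    idx <- which(band == b)
    if (!length(idx)) next
    w <- config$age_weights[[b]]
    age[idx] <- sample(w$age, length(idx), replace = TRUE, prob = w$weight)
  }
  dm <- config$demographic_margins
  draw_margin <- function(variable) {
    m <- dm[dm$variable == variable & !is_unknown(dm$category) & dm$percent > 0, ]
    sample(m$category, n, replace = TRUE, prob = m$percent)
  }
  education <- draw_margin("education")
  region <- draw_margin("region")
  ethnicity <- draw_margin("ethnicity")

  # (2) correlated latent traits
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  theta_gmh <- st$mu_gmh[cell] + st$sd_gmh[cell] * z1
  theta_gph <- st$mu_gph[cell] +
    st$sd_gph[cell] * (config$rho * z1 + sqrt(1 - config$rho^2) * z2)
  w <- config$anchor_weight
  comp_sd <- sqrt(w^2 + (1 - w)^2 + 2 * w * (1 - w) * config$rho)
  theta_comp <- (w * theta_gmh + (1 - w) * theta_gph) / comp_sd

  # (3) item responses, instrument order, written as raw codes
  trait <- attr(config$params, "trait")
  raw <- matrix(NA_integer_, n, length(instrument$items),
                dimnames = list(NULL, names(instrument$items)))
  for (id in names(instrument$items)) {
    theta <- switch(trait[[id]], GMH = theta_gmh, GPH = theta_gph,
                    composite = theta_comp)
    k <- draw_grm(theta, config$params[[id]])
    item <- instrument$items[[id]]
    if (length(item$raw_scale) > 5L) {
      # invert the band map: uniform raw code within the scored band
      raw[, id] <- vapply(k, function(kk) {
        cand <- item$raw_scale[item$recode_map == kk]
        if (length(cand) == 1L) cand else sample(cand, 1L)
      }, 0L)
    } else if (item$reverse_coded) {
      raw[, id] <- 6L - k
    } else {
      raw[, id] <- k
    }
  }

  # (4) missingness masks
  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(length(raw)) < config$missing_rate,
                   nrow(raw), ncol(raw))
    raw[mask] <- NA_integer_
  }

  id_str <- sprintf("R%05d", seq_len(n))
  records <- data.frame(respondent_id = id_str, age = age,
                        gender = st$gender[cell], education = education,
                        region = region, ethnicity = ethnicity,
                        stringsAsFactors = FALSE)
  raw_df <- as.data.frame(raw)
  names(raw_df) <- item_column(colnames(raw))
  records <- cbind(records, raw_df)
  truth <- data.frame(respondent_id = id_str, theta_gmh = theta_gmh,
                      theta_gph = theta_gph, theta_composite = theta_comp,
                      stratum = paste(st$gender[cell], st$age_band[cell]),
                      stringsAsFactors = FALSE)
  structure(list(records = records, truth = truth, config = config),
            class = "synthetic_population")
}

#' @export
print.synthetic_population <- function(x, ...) {
  cat(sprintf("<synthetic_population> n = %d (seed %d)\n",
              nrow(x$records), x$config$seed))
  invisible(x)
}

#' Expected category frequencies implied by a trait distribution
#'
#' Closed-form check surface for the generator: integrates each item's
#' graded-response category probabilities over a normal trait distribution
#' by quadrature, giving the expected per-category percentages without
#' simulation.
#'
#' @param params A `grm_parameters` list.
#' @param mean,sd Trait distribution mean and SD.
#' @param grid A [quadrature_grid()] on the standard scale (nodes are mapped
#'   through `mean + sd * node`).
#' @return Matrix (items x categories) of percentages; rows sum to 100.
#' @export
implied_category_frequencies <- function(params, mean = 0, sd = 1,
                                         grid = quadrature_grid()) {
  if (sd <= 0) fail("sd must be > 0")
  theta <- mean + sd * grid$nodes
  out <- t(vapply(params, function(p) {
    freq <- colSums(grm_probability(theta, p) * grid$weights)
    c(100 * freq, rep(NA_real_, 5L - p$K))
  }, numeric(5L)))
  rownames(out) <- names(params)
  colnames(out) <- 1:5
  out
}
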