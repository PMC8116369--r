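#' Age bands used in the reference tables
#'
#' Closed integer bands 18-34, 35-44, 45-54, 55-64, 65-74 and an open-ended
#' 75+ band, the subgroup scheme of the published reference tables.  This is
#' deliberately distinct from the coarser census binning used by the
#' representativeness check ([bin_age_census()]).
#'
#' @param age Integer vector of ages in years (>= 18).
#' @return Factor with levels `18-34`, `35-44`, `45-54`, `55-64`, `65-74`,
#'   `75+`; `NA` age gives `NA`.
#' @export
age_band <- function(age) {
  if (any(!is.na(age) & age < 18))
    fail("reference tables are defined for adults (age >= 18); got age ",
         min(age, na.rm = TRUE))
  cut(age, breaks = c(18, 35, 45, 55, 65, 75, Inf), right = FALSE,
      labels = c("18-34", "35-44", "45-54", "55-64", "65-74", "75+"))
}

#' Distribution of responses per item
#'
#' Tabulates, per item, the percentage of respondents in each displayed
#' category, plus the mean and SD of the displayed codes.  Displayed
#' categories follow the published convention: recoded 1-5 codes (higher =
#' better health) for the five-point items, but the raw 0-10 codes for the
#' pain-intensity item, listed from worst to best health.  Missing responses
#' are excluded from that item's percentages.
#'
#' @param records Respondent data frame.
#' @param instrument A `promis_instrument`.
#' @return List of class `gh_distribution` with `cells` (`item_id`,
#'   `display_value`, `percent`) and `stats` (`item_id`, `n`, `mean`, `sd`).
#' @export
item_distribution_table <- function(records, instrument = promis_gh_instrument()) {
  if (!nrow(records)) fail("item_distribution_table needs a non-empty sample")
  scored <- recode_responses(records, instrument)
  cells <- list(); stats_rows <- list()
  for (id in names(instrument$items)) {
    item <- instrument$items[[id]]
    if (length(item$raw_scale) > 5L) {
      x <- records[[item_column(id)]]          # raw 0-10 codes
      # worst-to-best display: order raw codes by increasing recoded category
      vals <- item$raw_scale[order(item$recode_map, item$raw_scale)]
    } else {
      x <- scored[, id]
      vals <- 1:5
    }
    x <- x[!is.na(x)]
    if (!length(x)) fail(id, ": no observed responses to tabulate")
    pct <- 100 * tabulate(match(x, vals), length(vals)) / length(x)
    cells[[id]] <- data.frame(item_id = id, display_value = vals, percent = pct)
    stats_rows[[id]] <- data.frame(item_id = id, n = length(x),
                                   mean = mean(x), sd = stats::sd(x))
  }
  structure(list(cells = do.call(rbind, c(cells, make.row.names = FALSE)),
                 stats = do.call(rbind, c(stats_rows, make.row.names = FALSE))),
            class = "gh_distribution")
}

#' @export
print.gh_distribution <- function(x, ...) {
  cat("<gh_distribution>", nrow(x$stats), "items\n")
  df <- x$stats
  df$mean <- round_half_up(df$mean, 1); df$sd <- round_half_up(df$sd, 1)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Mean score implied by a printed category distribution
#'
#' Recomputes the "mean score" column of a response-distribution table from
#' its category percentages: `sum(value * percent / 100)`, reported to one
#' decimal (half-up).  Used to check printed tables for self-consistency.
#'
#' @param percentages Per-category percentages (should sum to 100 within
#'   printed rounding; a tolerance of 0.5 is enforced).
#' @param values Category values, same length and order as `percentages`.
#' @param digits Decimals to round to; `NULL` returns the unrounded mean.
#' @return The (rounded) weighted mean.
#' @examples
#' mean_from_distribution(c(20, 20, 20, 20, 20), 1:5)  # 3.0
#' @export
mean_from_distribution <- function(percentages, values, digits = 1) {
  if (length(percentages) != length(values))
    fail("percentages and values differ in length")
  if (any(percentages < 0)) fail("negative percentage")
  s <- sum(percentages)
  if (abs(s - 100) > 0.5)
    fail("percentages sum to ", format(s), ", not 100 (+- 0.5)")
  m <- sum(values * percentages / 100)
  if (is.null(digits)) m else round_half_up(m, digits)
}

#' Subgroup reference-value table
#'
#' Unweighted mean and SD of T-scores per subscale for the total sample, for
#' each gender, and for each reference age band — the layout of a published
#' normative table.  Respondents with missing gender or age are reported in
#' an `Unknown` subgroup (flagged) and are excluded from the gender/age
#' partitions but not from the total row.
#'
#' @param scores A `gh_scores` long data frame from [score_population()].
#' @param records The respondent data frame the scores came from (supplies
#'   `age` and `gender`).
#' @return Data frame of class `reference_table`: `subgroup_type`
#'   (`total`/`gender`/`age`), `subgroup`, `subscale`, `n`, `mean_t`, `sd_t`.
#'   Empty subgroups get `n = 0` and `NA` statistics.
#' @export
reference_table <- function(scores, records) {
  if (any(!is.na(records$age) & records$age < 18))
    fail("reference tables are defined for adults (age >= 18)")
  idx <- match(scores$respondent_id, records$respondent_id)
  if (anyNA(idx)) fail("scored respondent(s) missing from records")
  age <- records$age[idx]
  gender <- as.character(records$gender)[idx]
  band <- as.character(age_band(age))
  groups <- list(
    list(type = "total", label = "Total", sel = rep(TRUE, nrow(scores))),
    list(type = "gender", label = "Male", sel = !is.na(gender) & gender == "Male"),
    list(type = "gender", label = "Female", sel = !is.na(gender) & gender == "Female")
  )
  for (b in levels(age_band(18)))
    groups <- c(groups, list(list(type = "age", label = b,
                                  sel = !is.na(band) & band == b)))
  unknown <- is.na(gender) | !(gender %in% c("Male", "Female")) | is.na(band)
  if (any(unknown))
    groups <- c(groups, list(list(type = "unknown", label = "Unknown",
                                  sel = unknown)))
  subscales <- unique(scores$subscale)
  rows <- list()
  for (g in groups) for (s in subscales) {
    t <- scores$t_score[g$sel & scores$subscale == s]
    rows[[length(rows) + 1L]] <- data.frame(
      subgroup_type = g$type, subgroup = g$label, subscale = s,
      n = length(t),
      mean_t = if (length(t)) mean(t) else NA_real_,
      sd_t = if (length(t) > 1L) stats::sd(t) else NA_real_)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  class(out) <- c("reference_table", "data.frame")
  out
}

#' @export
print.reference_table <- function(x, ...) {
  df <- as.data.frame(x)
  df$mean_t <- round_half_up(df$mean_t, 1)
  df$sd_t <- round_half_up(df$sd_t, 1)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Compare a sample mean T-score to a fixed reference mean
#'
#' Difference between a subgroup's mean T-score and a fixed reference
#' constant (e.g. the calibration population's 50), with a one-sample normal
#' 95% confidence interval `difference +- 1.96 sd / sqrt(n)` for the sample
#' mean around it.
#'
#' @param mean,sd,n Sample mean T, SD and size (`n >= 2`, `sd > 0`).
#' @param reference_mean The fixed reference mean (default 50).
#' @param subgroup,subscale Optional labels carried into the result.
#' @return One-row data frame: `sample_mean`, `reference_mean`, `difference`,
#'   `ci_low`, `ci_high`.
#' @examples
#' compare_to_reference(44.7, 8.0, 4370)
#' @export
compare_to_reference <- function(mean, sd, n, reference_mean = 50,
                                 subgroup = NA_character_,
                                 subscale = NA_character_) {
  if (n < 2) fail("compare_to_reference needs n >= 2")
  if (sd <= 0) fail("compare_to_reference needs sd > 0")
  diff <- mean - reference_mean
  half <- 1.96 * sd / sqrt(n)
  data.frame(subgroup = subgroup, subscale = subscale, sample_mean = mean,
             reference_mean = reference_mean, difference = diff,
             ci_low = diff - half, ci_high = diff + half)
}

#' Gaps between a subscale and its short form
#'
#' Per-subgroup absolute difference between the mean T-scores of a long
#' subscale and its 2-item short form, plus the maximum over subgroups.  When
#' reproducing a printed table the published values are already rounded to
#' one decimal, so by default the gap is computed on 1-decimal-rounded means
#' (`rounded = FALSE` uses the unrounded means).
#'
#' @param table A [reference_table()] (or any data frame with
#'   `subgroup_type`, `subgroup`, `subscale`, `mean_t`).
#' @param pair Character vector of length 2: long and short subscale ids.
#' @param rounded Compute on 1-decimal rounded means (default `TRUE`).
#' @return Data frame (`subgroup_type`, `subgroup`, `mean_long`,
#'   `mean_short`, `gap`) with the maximum gap as attribute `max_gap`.
#' @export
subscale_gap_table <- function(table, pair = c("GMH", "GMH-2a"),
                               rounded = TRUE) {
  for (s in pair)
    if (!s %in% table$subscale) fail("subscale ", s, " not present in table")
  long <- table[table$subscale == pair[1] & table$subgroup_type != "unknown", ]
  short <- table[table$subscale == pair[2] & table$subgroup_type != "unknown", ]
  idx <- match(paste(long$subgroup_type, long$subgroup),
               paste(short$subgroup_type, short$subgroup))
  ml <- long$mean_t; ms <- short$mean_t[idx]
  if (rounded) { ml <- round_half_up(ml, 1); ms <- round_half_up(ms, 1) }
  out <- data.frame(subgroup_type = long$subgroup_type,
                    subgroup = long$subgroup,
                    mean_long = ml, mean_short = ms, gap = abs(ml - ms))
  attr(out, "max_gap") <- max(out$gap, na.rm = TRUE)
  out
}
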