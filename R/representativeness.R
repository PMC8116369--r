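#' Census age bins for the representativeness check
#'
#' The census margins use a coarser age binning (18-39, 40-65, > 65, with the
#' first two bands closed on both ends) than the reference tables.  Both
#' binnings are fixed configuration, not inferred from data.
#'
#' @param age Integer ages (>= 18).
#' @return Factor with levels `18-39`, `40-65`, `>65`.
#' @export
bin_age_census <- function(age) {
  cut(age, breaks = c(18, 40, 66, Inf), right = FALSE,
      labels = c("18-39", "40-65", ">65"))
}

read_margin_file <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("variable", "category", "percent")
  if (!all(need %in% names(df)))
    fail("margin file must have columns ", paste(need, collapse = ", "), ": ", path)
  validate_margins(df)
  df
}

validate_margins <- function(df) {
  if (any(df$percent < 0)) fail("negative census percentage")
  for (v in unique(df$variable)) {
    s <- sum(df$percent[df$variable == v & !is_unknown(df$category)])
    # printed margins are integer-rounded; with up to 4 categories the sum
    # can drift a full point or so from 100
    if (abs(s - 100) > 1.5)
      fail("margins for '", v, "' sum to ", format(s), ", not ~100")
  }
  invisible(df)
}

is_unknown <- function(category) tolower(category) %in% "unknown"

#' Census margins of the Dutch adult population (2016)
#'
#' Published marginal distributions (percentages) of age band, gender,
#' educational level, region of residence and ethnicity for the Dutch adult
#' population in 2016, the default yardstick for [margin_deviation_report()].
#'
#' @param path Optional path to a margins CSV (`variable,category,percent`);
#'   default loads the shipped 2016 Dutch census margins.
#' @return Data frame with columns `variable`, `category`, `percent`.
#' @export
gh_census_margins <- function(path = NULL) {
  path <- path %||% system.file("extdata", "census_margins_nl_2016.csv",
                                package = "promisref", mustWork = TRUE)
  read_margin_file(path)
}

# sample margins (same layout as a census margin table) from a respondent df
sample_margins <- function(records, variables) {
  rows <- list()
  for (v in variables) {
    x <- if (v == "age") bin_age_census(records$age)
         else records[[v]]
    if (is.null(x)) fail("margin variable absent from records: ", v)
    x <- as.character(x)
    x[is.na(x)] <- "Unknown"
    tab <- table(x)
    rows[[v]] <- data.frame(variable = v, category = names(tab),
                            percent = 100 * as.numeric(tab) / length(x))
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Representativeness of a sample against census margins
#'
#' Compares a sample's sociodemographic margins with census margins category
#' by category.  The deviation is the absolute difference of percentages
#' (percentage points); the sample passes when the maximum deviation over
#' all categories of all variables is strictly below the criterion
#' (default 2.5 points).  Categories labelled `Unknown` on either side are
#' reported but excluded from the deviations; a census category with no
#' sample respondents still enters with deviation equal to its census
#' percentage.
#'
#' @param records Respondent data frame, or `NULL` if `sample` is given
#'   directly.
#' @param margins Census margins data frame (see [gh_census_margins()]).
#' @param criterion Maximum allowable deviation in percentage points
#'   (default 2.5, strict comparison).
#' @param sample Optional pre-aggregated sample margins in the same layout as
#'   `margins` (used when only published percentages, not records, are
#'   available).
#' @return Data frame of class `rep_report` (`variable`, `category`,
#'   `sample_pct`, `census_pct`, `deviation`, `excluded`), with attributes
#'   `max_deviation`, `criterion` and `pass`.
#' @examples
#' rep <- margin_deviation_report(
#'   sample = read.csv(system.file("extdata", "sample_margins_2016.csv",
#'                                 package = "promisref")),
#'   margins = gh_census_margins())
#' attr(rep, "max_deviation")
#' @export
margin_deviation_report <- function(records = NULL,
                                    margins = gh_census_margins(),
                                    criterion = 2.5, sample = NULL) {
  validate_margins(margins)
  if (is.null(sample)) {
    if (is.null(records)) fail("supply records or pre-aggregated sample margins")
    sample <- sample_margins(records, unique(margins$variable))
  } else {
    validate_margins(sample)
  }
  rows <- list()
  for (v in unique(margins$variable)) {
    cm <- margins[margins$variable == v, ]
    sm <- sample[sample$variable == v, ]
    if (!nrow(sm)) fail("margin variable absent from sample: ", v)
    extra <- setdiff(sm$category[!is_unknown(sm$category)], cm$category)
    if (length(extra))
      fail("sample categor", if (length(extra) > 1) "ies" else "y", " for '",
           v, "' not in census margins: ", paste(extra, collapse = ", "),
           " (declare an Unknown bucket to exclude)")
    cats <- unique(c(cm$category, sm$category))
    spct <- sm$percent[match(cats, sm$category)]
    cpct <- cm$percent[match(cats, cm$category)]
    spct[is.na(spct)] <- 0; cpct[is.na(cpct)] <- 0
    excluded <- is_unknown(cats)
    rows[[v]] <- data.frame(variable = v, category = cats,
                            sample_pct = spct, census_pct = cpct,
                            deviation = abs(spct - cpct),
                            excluded = excluded)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  max_dev <- max(out$deviation[!out$excluded])
  attr(out, "max_deviation") <- max_dev
  attr(out, "criterion") <- criterion
  attr(out, "pass") <- max_dev < criterion
  class(out) <- c("rep_report", "data.frame")
  out
}

#' @export
print.rep_report <- function(x, ...) {
  df <- as.data.frame(x)
  df$sample_pct <- round_half_up(df$sample_pct, 1)
  df$deviation <- round_half_up(df$deviation, 1)
  print.data.frame(df, row.names = FALSE)
  cat(sprintf("max deviation %.1f %s criterion %.1f -> %s\n",
              attr(x, "max_deviation"),
              if (attr(x, "pass")) "<" else ">=", attr(x, "criterion"),
              if (attr(x, "pass")) "PASS" else "FAIL"))
  invisible(x)
}
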