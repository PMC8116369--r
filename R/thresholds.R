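#' Anchor response categories, worst to best health
#' @keywords internal
anchor_levels <- c("poor", "fair", "good", "very good", "excellent")

#' Mean T-score per anchor group
#'
#' Step one of the anchor-based threshold derivation: respondents are grouped
#' by their response to the general self-rated-health anchor item (poor /
#' fair / good / very good / excellent) and the unweighted mean subscale
#' T-score of each group is computed.  Category order is fixed by the label
#' scale, never by the sample.
#'
#' @param tscores Numeric vector of per-respondent T-scores for one subscale.
#' @param anchors Per-respondent anchor responses, aligned with `tscores`:
#'   scored categories 1..5 (1 = poor) or the labels themselves.  `NA`
#'   respondents are excluded.
#' @param subscale_id Optional label carried in the result.
#' @return Data frame of class `anchor_summary` (`category`, `n`, `mean_t`,
#'   `empty`), ordered poor to excellent; empty categories carry `NA` mean
#'   and `empty = TRUE`.
#' @export
anchor_group_means <- function(tscores, anchors, subscale_id = NULL) {
  if (length(tscores) != length(anchors))
    fail("tscores and anchors differ in length")
  if (is.numeric(anchors)) {
    bad <- !is.na(anchors) & !(anchors %in% 1:5)
    if (any(bad))
      fail("anchor value(s) outside the 5-category scale: ",
           paste(unique(anchors[bad]), collapse = ", "))
    anchors <- anchor_levels[anchors]
  } else {
    anchors <- tolower(as.character(anchors))
    bad <- !is.na(anchors) & !(anchors %in% anchor_levels)
    if (any(bad))
      fail("unknown anchor label(s): ", paste(unique(anchors[bad]), collapse = ", "))
  }
  keep <- !is.na(anchors) & !is.na(tscores)
  f <- factor(anchors[keep], levels = anchor_levels)
  n <- as.integer(table(f))
  mean_t <- as.numeric(tapply(tscores[keep], f, mean))
  out <- data.frame(category = anchor_levels, n = n, mean_t = mean_t,
                    empty = n == 0L)
  attr(out, "subscale_id") <- subscale_id
  class(out) <- c("anchor_summary", "data.frame")
  out
}

#' Midpoint between two adjacent anchor-group means
#'
#' The threshold between two adjacent health categories is the midpoint of
#' their mean T-scores, rounded to an integer half-up (e.g. means 60 and 54
#' give 57; means 54 and 47 give midpoint 50.5, hence threshold 51).
#'
#' @param mean_lower,mean_upper Mean T-scores of the two adjacent groups.
#' @return Integer threshold.
#' @export
anchor_midpoint <- function(mean_lower, mean_upper) {
  as.integer(round_half_up((mean_lower + mean_upper) / 2))
}

#' Derive the four interpretability thresholds
#'
#' Step two and three of the anchor-based procedure: for each of the four
#' adjacent category pairs (poor/fair, fair/good, good/very good, very
#' good/excellent) the midpoint of the two group means is taken and rounded
#' to an integer (half-up).  If the group means are not monotone in health
#' order the thresholds are still computed but flagged with a warning
#' (attribute `monotone = FALSE`); no isotonic correction is applied.
#'
#' @param summary An [anchor_group_means()] result with all five means
#'   defined.
#' @return Named integer vector of length 4 (`poor_fair`, `fair_good`,
#'   `good_verygood`, `verygood_excellent`).
#' @examples
#' s <- data.frame(category = c("poor", "fair", "good", "very good", "excellent"),
#'                 n = rep(10, 5), mean_t = c(30, 40, 47, 54, 60), empty = FALSE)
#' class(s) <- c("anchor_summary", "data.frame")
#' midpoint_thresholds(s)
#' @export
midpoint_thresholds <- function(summary) {
  stopifnot(inherits(summary, "anchor_summary"))
  m <- summary$mean_t[match(anchor_levels, summary$category)]
  if (anyNA(m))
    fail("anchor category without respondents: ",
         paste(anchor_levels[is.na(m)], collapse = ", "),
         " (all five group means must be defined)")
  monotone <- all(diff(m) > 0)
  if (!monotone)
    warning("anchor-group means are not strictly increasing in health order; ",
            "thresholds computed anyway", call. = FALSE)
  th <- vapply(1:4, function(i) anchor_midpoint(m[i], m[i + 1]), 0L)
  names(th) <- c("poor_fair", "fair_good", "good_verygood", "verygood_excellent")
  attr(th, "monotone") <- monotone
  th
}

#' Format thresholds as labelled health-category bands
#'
#' Turns four strictly increasing integer thresholds `t1 < t2 < t3 < t4` into
#' the five bands that tile the integer T-score axis: poor `< t1`, fair
#' `t1..t2-1`, good `t2..t3-1`, very good `t3..t4-1`, excellent `>= t4`.
#'
#' @param thresholds Integer vector of length 4, strictly increasing.
#' @param subscale_id Optional label.
#' @return Data frame of class `threshold_bands` (`band`, `lower`, `upper`,
#'   `label`), ordered poor to excellent.
#' @examples
#' format_bands(c(38, 43, 49, 56))
#' @export
format_bands <- function(thresholds, subscale_id = NULL) {
  t <- as.integer(thresholds)
  if (length(t) != 4L || anyNA(t) || any(diff(t) <= 0))
    fail("format_bands needs four strictly increasing integer thresholds")
  lower <- c(-Inf, t)
  upper <- c(t - 1L, Inf)
  label <- c(paste0("<", t[1]),
             paste0(t[1], "-", t[2] - 1L),
             paste0(t[2], "-", t[3] - 1L),
             paste0(t[3], "-", t[4] - 1L),
             paste0(">=", t[4]))
  out <- data.frame(band = anchor_levels, lower = lower, upper = upper,
                    label = label)
  attr(out, "thresholds") <- t
  attr(out, "subscale_id") <- subscale_id
  class(out) <- c("threshold_bands", "data.frame")
  out
}

#' @export
print.threshold_bands <- function(x, ...) {
  id <- attr(x, "subscale_id")
  cat("<threshold_bands>", if (!is.null(id)) id else "", "\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-10s %s\n", x$band[i], x$label[i]))
  invisible(x)
}

#' Classify a T-score into a health band
#'
#' Bands are defined on the integer T-score axis, so a non-integer score is
#' first rounded to an integer (half-up) and then looked up; every score
#' falls in exactly one band.
#'
#' @param t Numeric vector of T-scores.
#' @param bands A [format_bands()] object.
#' @return Character vector of band labels (`poor` ... `excellent`).
#' @examples
#' classify_tscore(37.9, format_bands(c(38, 43, 49, 56)))  # rounds to 38: fair
#' @export
classify_tscore <- function(t, bands) {
  stopifnot(inherits(bands, "threshold_bands"))
  r <- round_half_up(t)
  th <- attr(bands, "thresholds")
  idx <- findInterval(r, th) + 1L  # 0 thresholds passed -> band 1 (poor)
  bands$band[idx]
}

#' Published interpretability thresholds
#'
#' The integer thresholds separating poor/fair/good/very good/excellent
#' global mental and physical health, as published for the Dutch (2016) and
#' US reference populations, shipped for side-by-side comparison.
#'
#' @param population `"NL"` or `"US"`.
#' @param subscale `"GMH"` or `"GPH"`.
#' @return A [format_bands()] object.
#' @examples
#' reference_bands("NL", "GMH")
#' @export
reference_bands <- function(population = c("NL", "US"),
                            subscale = c("GMH", "GPH")) {
  population <- match.arg(population); subscale <- match.arg(subscale)
  df <- utils::read.csv(system.file("extdata", "threshold_reference.csv",
                                    package = "promisref", mustWork = TRUE))
  row <- df[df$population == population & df$subscale == subscale, ]
  format_bands(as.integer(row[, c("poor_fair", "fair_good", "good_verygood",
                                  "verygood_excellent")]),
               subscale_id = paste(population, subscale))
}
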