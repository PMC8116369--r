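#' Read a respondent CSV
#'
#' The respondent dialect is a CSV with header
#' `respondent_id,age,gender,education,region,ethnicity,global01,...,global10`;
#' item cells hold raw response codes and an empty cell means missing.
#' Validation is strict and reports every offending row by number: malformed
#' header, duplicate respondent ids, ages below 18, and raw codes outside an
#' item's scale all abort the read.
#'
#' @param path Path to the CSV.
#' @param instrument A `promis_instrument` defining the item columns and
#'   scales.
#' @return Validated respondent data frame (one row per respondent).
#' @export
read_responses <- function(path, instrument = promis_gh_instrument()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  validate_responses(df, instrument, source = path)
}

#' Validate a respondent table
#'
#' @param df Respondent data frame.
#' @param instrument A `promis_instrument`.
#' @param source Label used in error messages (e.g. the file name).
#' @return The validated data frame, invisibly usable downstream.
#' @export
validate_responses <- function(df, instrument = promis_gh_instrument(),
                               source = "responses") {
  required <- c("respondent_id", "age", "gender", "education", "region",
                "ethnicity", item_column(names(instrument$items)))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    fail(source, ": malformed header, missing column(s): ",
         paste(missing_cols, collapse = ", "))
  errors <- character()
  dup <- duplicated(df$respondent_id)
  if (any(dup))
    errors <- c(errors, paste0("row ", which(dup),
                               ": duplicate respondent_id ",
                               df$respondent_id[dup]))
  bad_age <- !is.na(df$age) & df$age < 18
  if (any(bad_age))
    errors <- c(errors, paste0("row ", which(bad_age), ": age below 18 (",
                               df$age[bad_age], ")"))
  for (id in names(instrument$items)) {
    item <- instrument$items[[id]]
    x <- df[[item_column(id)]]
    bad <- !is.na(x) & !(x %in% item$raw_scale)
    if (any(bad))
      errors <- c(errors, paste0("row ", which(bad), ": ", id, " value ",
                                 x[bad], " outside scale ",
                                 min(item$raw_scale), "-", max(item$raw_scale)))
  }
  if (length(errors))
    fail(source, ": ", length(errors), " validation error(s)\n  ",
         paste(utils::head(errors, 20L), collapse = "\n  "))
  df
}

#' Write a respondent CSV
#'
#' Inverse of [read_responses()]: missing responses become empty cells, so a
#' write/read round trip is the identity on all fields.
#'
#' @param records Respondent data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

# short digest of the effective configuration, for the run log
config_digest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}

#' Run the full reference-value pipeline
#'
#' One call from respondent data (or a simulated population) to the full
#' report bundle: scores every subscale, builds the subgroup reference
#' table, the item-distribution table, anchor-based thresholds for GMH and
#' GPH, and the representativeness report, and writes everything as CSV plus
#' a plain-text run log into `output_dir`.  Outputs are staged in a
#' temporary directory and only moved into place when every stage has
#' succeeded, so a failing run leaves no partial bundle behind.
#'
#' @param input Respondent data: a data frame, a path to a respondent CSV,
#'   or `NULL` to simulate a population from `sim_config`.
#' @param output_dir Directory for the bundle (created if needed).
#' @param params Item parameters (default the shipped synthetic set).
#' @param instrument A `promis_instrument`.
#' @param census Census margins for the representativeness check.
#' @param method Scoring method, `"pattern"` (default; handles missing
#'   items) or `"sum-table"` (complete responses only).
#' @param criterion Representativeness criterion in percentage points.
#' @param sim_config A [synthetic_config()] used when `input` is `NULL`.
#' @return Invisibly, a list with every computed object (`scores`,
#'   `reference_table`, `distribution`, `anchor_means`, `thresholds`,
#'   `bands`, `representativeness`, `log`).
#' @export
run_pipeline <- function(input = NULL, output_dir,
                         params = default_item_parameters(),
                         instrument = promis_gh_instrument(),
                         census = gh_census_margins(),
                         method = c("pattern", "sum-table"),
                         criterion = 2.5,
                         sim_config = synthetic_config()) {
  method <- match.arg(method)
  log <- c(sprintf("promisref %s", as.character(utils::packageVersion("promisref"))),
           sprintf("method: %s", method))
  if (is.null(input)) {
    pop <- generate_population(sim_config)
    records <- pop$records
    log <- c(log, sprintf("simulated population: n = %d, seed = %d",
                          sim_config$n, sim_config$seed))
  } else if (is.character(input)) {
    records <- read_responses(input, instrument)
    log <- c(log, sprintf("input: %s (%d records)", input, nrow(records)))
  } else {
    records <- validate_responses(input, instrument)
    log <- c(log, sprintf("input: data frame (%d records)", nrow(records)))
  }
  log <- c(log, sprintf("config digest: %s",
                        config_digest(list(method = method,
                                           criterion = criterion,
                                           params = params,
                                           n = nrow(records)))))

  scores <- score_population(records, params, instrument, method = method)
  n_flagged <- sum(scores$all_missing)
  if (n_flagged)
    log <- c(log, sprintf("flagged: %d subscale score(s) with no answered items",
                          n_flagged))
  ref <- reference_table(scores, records)
  dist <- item_distribution_table(records, instrument)
  anchor <- recode_responses(records, instrument)[, instrument$anchor_item]

  anchor_means <- list(); bands <- list(); thresholds <- list()
  for (s in c("GMH", "GPH")) {
    t <- scores$t_score[scores$subscale == s]
    am <- anchor_group_means(t, anchor, subscale_id = s)
    anchor_means[[s]] <- am
    if (any(am$empty)) {
      log <- c(log, sprintf("warning: empty anchor group(s) for %s: %s", s,
                            paste(am$category[am$empty], collapse = ", ")))
    } else {
      th <- withCallingHandlers(
        midpoint_thresholds(am),
        warning = function(w) {
          log <<- c(log, paste("warning:", conditionMessage(w)))
          invokeRestart("muffleWarning")
        })
      thresholds[[s]] <- th
      bands[[s]] <- format_bands(th, subscale_id = s)
    }
  }
  rep <- margin_deviation_report(records, census, criterion)
  log <- c(log, sprintf("representativeness: max deviation %.2f (criterion %.1f): %s",
                        attr(rep, "max_deviation"), criterion,
                        if (attr(rep, "pass")) "pass" else "FAIL"))

  # stage, then publish atomically
  stage <- file.path(tempfile("promisref_bundle"))
  dir.create(stage, recursive = TRUE)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  wr <- function(df, file) utils::write.csv(df, file.path(stage, file),
                                            row.names = FALSE, na = "")
  scores_out <- scores
  scores_out$t_score <- round_half_up(scores_out$t_score, 1)
  scores_out$se_t <- round_half_up(scores_out$se_t, 1)
  wr(scores_out[, c("respondent_id", "subscale", "t_score", "se_t",
                    "n_items_used", "all_missing")], "scores.csv")
  ref_out <- as.data.frame(ref)
  ref_out$mean_t <- round_half_up(ref_out$mean_t, 1)
  ref_out$sd_t <- round_half_up(ref_out$sd_t, 1)
  wr(ref_out, "reference_table.csv")
  dist_out <- dist$cells
  dist_out$percent <- round_half_up(dist_out$percent, 1)
  wr(dist_out, "item_distribution.csv")
  am_out <- do.call(rbind, lapply(names(anchor_means), function(s)
    cbind(subscale = s, as.data.frame(anchor_means[[s]]))))
  am_out$mean_t <- round_half_up(am_out$mean_t, 1)
  wr(am_out, "anchor_means.csv")
  if (length(bands)) {
    bands_out <- do.call(rbind, lapply(names(bands), function(s)
      cbind(subscale = s, as.data.frame(bands[[s]]))))
    wr(bands_out, "threshold_bands.csv")
  }
  rep_out <- as.data.frame(rep)
  rep_out$sample_pct <- round_half_up(rep_out$sample_pct, 2)
  rep_out$deviation <- round_half_up(rep_out$deviation, 2)
  wr(rep_out, "representativeness.csv")
  writeLines(log, file.path(stage, "run_log.txt"))

  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  for (f in list.files(stage))
    file.copy(file.path(stage, f), file.path(output_dir, f), overwrite = TRUE)

  invisible(list(scores = scores, reference_table = ref, distribution = dist,
                 anchor_means = anchor_means, thresholds = thresholds,
                 bands = bands, representativeness = rep, log = log))
}
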