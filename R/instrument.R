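#' @title The PROMIS Global Health instrument
#' @description
#' The instrument machinery encodes the 10 global-health items, their raw
#' response scales, the recode/reverse-code rules that map every raw response
#' onto a scored 1-5 category in which a higher category always means better
#' health, and the subscale membership:
#'
#' * GMH (global mental health): Global02, Global04, Global05, Global10
#' * GMH-2a (short form): Global04, Global05
#' * GPH (global physical health): Global03, Global06, Global07, Global08
#' * GPH-2a (short form): Global03, Global06
#'
#' Global01 (the general self-rated-health anchor) and Global09 belong to no
#' subscale.  Global08 and Global10 are administered in the "worse health =
#' higher raw code" direction and are reverse-coded at scoring time; Global07
#' (pain intensity) is administered on a 0-10 numeric rating scale and banded
#' onto the five scored categories.
#' @name promis_instrument
NULL

new_item_definition <- function(id, raw_scale, reverse_coded = FALSE,
                                recode_map = NULL, content = NULL) {
  if (is.null(recode_map)) {
    if (reverse_coded) {
      if (length(raw_scale) != 5L)
        fail(id, ": reverse coding without an explicit map needs a 5-point scale")
      recode_map <- stats::setNames(6L - raw_scale, raw_scale)
    } else {
      recode_map <- stats::setNames(as.integer(raw_scale), raw_scale)
    }
  }
  item <- structure(
    list(item_id = id, raw_scale = as.integer(raw_scale),
         reverse_coded = isTRUE(reverse_coded),
         recode_map = recode_map, content = content),
    class = "item_definition")
  validate_item_definition(item)
}

validate_item_definition <- function(item) {
  map <- item$recode_map
  if (!setequal(names(map), as.character(item$raw_scale)))
    fail(item$item_id, ": recode map must cover the raw scale exactly")
  map <- map[as.character(item$raw_scale)]  # raw-scale order
  if (!all(map %in% 1:5))
    fail(item$item_id, ": recoded categories must lie in 1..5")
  d <- diff(map)
  if (!(all(d >= 0) || all(d <= 0)))
    fail(item$item_id, ": recode map must be monotone over the raw scale")
  if (item$reverse_coded && !all(d <= 0))
    fail(item$item_id, ": reverse-coded item must have a non-increasing map")
  if (length(item$raw_scale) > 5L && !setequal(unique(map), 1:5))
    fail(item$item_id, ": banded recode must be surjective onto 1..5")
  item$recode_map <- map
  item
}

#' Load a PROMIS Global Health instrument definition
#'
#' Reads the versioned instrument configuration (items, raw scales,
#' recode/reverse rules, subscale membership, anchor item) from a YAML file.
#' The package ships the PROMIS-GH v1.2 definition as its default; other
#' PROMIS short forms can reuse the scoring machinery by supplying their own
#' configuration file in the same layout.
#'
#' @param path Path to an instrument YAML file; `NULL` (default) loads the
#'   shipped PROMIS-GH v1.2 definition.
#' @return An object of class `promis_instrument`: a list with `items` (named
#'   list of item definitions), `subscales` (named list of item-id vectors),
#'   `anchor_item`, `standalone_items` and `version`.
#' @examples
#' instr <- promis_gh_instrument()
#' names(instr$subscales)
#' @export
promis_gh_instrument <- function(path = NULL) {
  path <- path %||% system.file("extdata", "instrument_promis_gh.yaml",
                                package = "promisref", mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  items <- lapply(cfg$items, function(it) {
    recode <- NULL
    if (!is.null(it$recode)) {
      recode <- stats::setNames(as.integer(unlist(it$recode)), names(it$recode))
    }
    new_item_definition(it$id, seq(it$raw_min, it$raw_max),
                        reverse_coded = isTRUE(it$reverse),
                        recode_map = recode, content = it$content)
  })
  names(items) <- vapply(items, `[[`, "", "item_id")
  instr <- structure(
    list(version = cfg$version, name = cfg$instrument, items = items,
         subscales = lapply(cfg$subscales, unlist),
         anchor_item = cfg$anchor_item,
         standalone_items = unlist(cfg$standalone_items)),
    class = "promis_instrument")
  validate_instrument(instr)
}

validate_instrument <- function(instr) {
  ids <- names(instr$items)
  if (anyDuplicated(ids)) fail("duplicate item ids in instrument definition")
  members <- instr$subscales
  for (s in names(members)) {
    missing <- setdiff(members[[s]], ids)
    if (length(missing))
      fail("subscale ", s, " refers to unknown items: ",
           paste(missing, collapse = ", "))
  }
  if (all(c("GMH", "GMH-2a") %in% names(members)) &&
      !all(members[["GMH-2a"]] %in% members[["GMH"]]))
    fail("GMH-2a must be a subset of GMH")
  if (all(c("GPH", "GPH-2a") %in% names(members)) &&
      !all(members[["GPH-2a"]] %in% members[["GPH"]]))
    fail("GPH-2a must be a subset of GPH")
  if (all(c("GMH", "GPH") %in% names(members)) &&
      length(intersect(members[["GMH"]], members[["GPH"]])))
    fail("GMH and GPH must be disjoint")
  scored <- unique(unlist(members))
  standalone <- instr$standalone_items
  if (length(intersect(standalone, scored)))
    fail("standalone items must not belong to any subscale")
  if (!instr$anchor_item %in% standalone)
    fail("the anchor item must be a standalone item")
  n_rev <- sum(vapply(instr$items, `[[`, FALSE, "reverse_coded"))
  n_11 <- sum(vapply(instr$items, function(it) length(it$raw_scale), 0L) == 11L)
  if (identical(instr$name, "PROMIS-GH")) {
    if (n_rev != 2L) fail("PROMIS-GH must have exactly two reverse-coded items")
    if (n_11 != 1L) fail("PROMIS-GH must have exactly one 11-point item")
  }
  instr
}

#' @export
print.promis_instrument <- function(x, ...) {
  cat(sprintf("<%s v%s> %d items\n", x$name, x$version, length(x$items)))
  for (s in names(x$subscales))
    cat(sprintf("  %-7s: %s\n", s, paste(x$subscales[[s]], collapse = ", ")))
  cat("  anchor :", x$anchor_item, "\n")
  invisible(x)
}

#' Recode a raw item response onto the scored 1-5 scale
#'
#' Applies the item's recode map: identity for plain items, reversal for the
#' two reverse-coded items (fatigue, emotional problems), and the 0-10 to 1-5
#' banding for the pain-intensity item.  After recoding, a higher scored
#' category always means better health.
#'
#' @param item An `item_definition` from a [promis_gh_instrument()] object.
#' @param raw Vector of raw response codes; `NA` passes through as `NA`.
#' @return Integer vector of scored categories in 1..5.
#' @examples
#' instr <- promis_gh_instrument()
#' recode_response(instr$items$Global08, 1)   # "none" -> scored 5
#' recode_response(instr$items$Global07, c(0, 10))
#' @export
recode_response <- function(item, raw) {
  stopifnot(inherits(item, "item_definition"))
  out <- rep(NA_integer_, length(raw))
  ok <- !is.na(raw)
  bad <- ok & !(raw %in% item$raw_scale)
  if (any(bad))
    fail(item$item_id, ": raw value(s) ",
         paste(unique(raw[bad]), collapse = ", "), " outside scale ",
         min(item$raw_scale), "-", max(item$raw_scale))
  out[ok] <- item$recode_map[as.character(raw[ok])]
  out
}

# lower-case column name used in the respondent CSV dialect
item_column <- function(item_id) tolower(item_id)

#' Recode all item responses of a respondent table
#'
#' @param records A respondent data frame in the package's CSV dialect
#'   (columns `global01` ... `global10`, raw codes, `NA` = missing).
#' @param instrument A `promis_instrument`.
#' @return Integer matrix (respondents x 10 items, columns named by item id)
#'   of scored 1-5 categories; missing stays `NA`.
#' @export
recode_responses <- function(records, instrument = promis_gh_instrument()) {
  ids <- names(instrument$items)
  cols <- item_column(ids)
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols))
    fail("response table lacks item columns: ", paste(missing_cols, collapse = ", "))
  out <- matrix(NA_integer_, nrow(records), length(ids),
                dimnames = list(records$respondent_id, ids))
  for (i in seq_along(ids))
    out[, i] <- recode_response(instrument$items[[ids[i]]], records[[cols[i]]])
  out
}

#' Extract the recoded responses of one subscale
#'
#' Returns the scored (recoded) categories for exactly the member items of a
#' subscale, in the fixed instrument order.  Missing responses stay missing;
#' the number of columns always equals the subscale's item count.
#'
#' @param records Respondent data frame (see [read_responses()]).
#' @param instrument A `promis_instrument`.
#' @param subscale_id One of `"GMH"`, `"GMH-2a"`, `"GPH"`, `"GPH-2a"` (or any
#'   subscale declared in the instrument configuration).
#' @return Integer matrix (respondents x member items) of scored categories.
#' @examples
#' pop <- generate_population(synthetic_config(n = 5, seed = 1))
#' subscale_responses(pop$records, promis_gh_instrument(), "GPH-2a")
#' @export
subscale_responses <- function(records, instrument, subscale_id) {
  if (!subscale_id %in% names(instrument$subscales))
    fail("unknown subscale: ", subscale_id, " (have: ",
         paste(names(instrument$subscales), collapse = ", "), ")")
  ids <- instrument$subscales[[subscale_id]]
  scored <- recode_responses(records, instrument)
  scored[, ids, drop = FALSE]
}
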