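#' Published Dutch general-population summary tables (2016)
#'
#' Loaders for the published summary tables of the 2016 Dutch
#' general-population PROMIS-GH study, shipped as plain-text data:
#'
#' * `gh_reference_tscores()` — subgroup reference values (n, mean T, SD) for
#'   GMH, GMH-2a, GPH and GPH-2a by total / gender / age band, with the US
#'   reference-population columns alongside where published.
#' * `gh_item_distribution()` — per-item response-category percentages
#'   (total n = 4370), in the published display convention.
#' * `gh_item_summary()` — the published per-item mean (SD) of the displayed
#'   codes.
#' * `gh_sample_margins()` — the study sample's sociodemographic margins,
#'   for the representativeness check against [gh_census_margins()].
#'
#' These are inputs and regression anchors: the package recomputes derived
#' quantities (weighted means, reference-mean differences, short-form gaps,
#' margin deviations, threshold bands) from them.
#'
#' @return A data frame (layout described above).
#' @name reference_data
NULL

read_extdata <- function(file) {
  utils::read.csv(system.file("extdata", file, package = "promisref",
                              mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' @rdname reference_data
#' @export
gh_reference_tscores <- function() read_extdata("nl_reference_tscores_2016.csv")

#' @rdname reference_data
#' @export
gh_item_distribution <- function() read_extdata("nl_item_distribution_2016.csv")

#' @rdname reference_data
#' @export
gh_item_summary <- function() read_extdata("nl_item_summary_2016.csv")

#' @rdname reference_data
#' @export
gh_sample_margins <- function() read_extdata("sample_margins_2016.csv")
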