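#' Construct graded-response-model item parameters
#'
#' @param item_id Item identifier.
#' @param a Discrimination (slope), positive, on the logistic metric.
#' @param b Numeric vector of K-1 strictly increasing category thresholds
#'   (difficulty parameters) on the latent metric.
#' @return An object of class `item_parameters` with `K = length(b) + 1`
#'   response categories.
#' @examples
#' item_parameters("Global03", a = 3.2, b = c(-2.06, -0.72, 0.50, 1.56))
#' @export
item_parameters <- function(item_id, a, b) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    fail(item_id, ": discrimination must be a single positive number")
  if (length(b) < 1L || anyNA(b) || any(diff(b) <= 0))
    fail(item_id, ": thresholds must be strictly increasing and non-missing")
  structure(list(item_id = item_id, a = as.numeric(a), b = as.numeric(b),
                 K = length(b) + 1L),
            class = "item_parameters")
}

#' @export
print.item_parameters <- function(x, ...) {
  cat(sprintf("<item_parameters> %s: a = %.2f, b = (%s)\n", x$item_id, x$a,
              paste(sprintf("%.2f", x$b), collapse = ", ")))
  invisible(x)
}

#' Read item parameters from file
#'
#' The item-parameter file is a CSV with one record per item: `item_id`, the
#' discrimination `a`, and threshold columns `b1`, `b2`, ... (trailing `NA`
#' allowed for items with fewer categories).  An optional `trait` column
#' records which latent dimension the item loads on; it is kept as an
#' attribute and used by the synthetic-data generator.
#'
#' @param path Path to the parameter CSV.
#' @return A named list of [item_parameters()] objects (class
#'   `grm_parameters`), with a `trait` attribute if the file declares one.
#' @export
read_item_parameters <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("item_id", "a") %in% names(df)))
    fail("parameter file must have item_id and a columns: ", path)
  bcols <- grep("^b[0-9]+$", names(df), value = TRUE)
  bcols <- bcols[order(as.integer(sub("^b", "", bcols)))]
  if (!length(bcols)) fail("parameter file has no b1, b2, ... columns: ", path)
  params <- lapply(seq_len(nrow(df)), function(i) {
    b <- as.numeric(df[i, bcols])
    item_parameters(df$item_id[i], df$a[i], b[!is.na(b)])
  })
  names(params) <- df$item_id
  if (anyDuplicated(names(params))) fail("duplicate item ids in ", path)
  out <- structure(params, class = "grm_parameters")
  if ("trait" %in% names(df))
    attr(out, "trait") <- stats::setNames(df$trait, df$item_id)
  out
}

#' Write item parameters to file
#'
#' @param params A `grm_parameters` list.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_item_parameters <- function(params, path) {
  kmax <- max(vapply(params, `[[`, 0L, "K"))
  rows <- lapply(params, function(p) {
    b <- c(p$b, rep(NA_real_, kmax - p$K))
    c(list(item_id = p$item_id, a = p$a),
      stats::setNames(as.list(b), paste0("b", seq_len(kmax - 1L))))
  })
  df <- do.call(rbind, lapply(rows, as.data.frame))
  trait <- attr(params, "trait")
  if (!is.null(trait)) df <- cbind(df[1], trait = trait[df$item_id], df[-1])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default (synthetic) item parameters
#'
#' The official US calibration parameters of the PROMIS-GH items are
#' distributed through the HealthMeasures scoring channels and are not
#' redistributed here.  The package ships a clearly labelled *synthetic*
#' parameter set instead: discriminations between 1.7 and 3.2 and threshold
#' locations chosen so that, for latent trait levels typical of a
#' general-population sample (mean about half a standard deviation below the
#' calibration centre), the implied category frequencies resemble published
#' Dutch general-population response distributions.  Supply
#' [read_item_parameters()] with the official file to score against the real
#' calibration.
#'
#' @return A `grm_parameters` list for all 10 items with a `trait` attribute
#'   (`GMH`, `GPH`, or `composite`).
#' @export
default_item_parameters <- function() {
  read_item_parameters(system.file("extdata", "item_parameters_synthetic.csv",
                                   package = "promisref", mustWork = TRUE))
}

#' Quadrature grid for EAP scoring
#'
#' Equally spaced latent-trait nodes with normalized standard-normal prior
#' weights.  The default (161 nodes on \[-8, 8\]) is wide enough that the
#' truncated prior mass is negligible (< 1e-15) and dense enough that the
#' discretization error of posterior means is far below 1e-6 even for the
#' most extreme response patterns; see the package vignette for the
#' numerical argument.
#'
#' @param n_nodes Number of nodes (default 161).
#' @param range Length-2 numeric, grid end points (default `c(-8, 8)`).
#' @param prior_mean,prior_sd Prior location and scale (defaults 0 and 1, the
#'   calibration metric).
#' @return An object of class `quadrature_grid` with `nodes` and normalized
#'   `weights` (summing to 1).
#' @export
quadrature_grid <- function(n_nodes = 161L, range = c(-8, 8),
                            prior_mean = 0, prior_sd = 1) {
  if (n_nodes < 2L || range[2] <= range[1])
    fail("quadrature grid needs >= 2 nodes and an increasing range")
  nodes <- seq(range[1], range[2], length.out = n_nodes)
  w <- stats::dnorm(nodes, prior_mean, prior_sd)
  structure(list(nodes = nodes, weights = w / sum(w)),
            class = "quadrature_grid")
}
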