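#' Category response probabilities under the graded response model
#'
#' For an item with discrimination `a` and thresholds `b_1 < ... < b_{K-1}`,
#' the probability of responding in category `k` at trait level `theta` is
#' the difference of adjacent cumulative logistic curves:
#' `P(k | theta) = P*_k(theta) - P*_{k+1}(theta)` with
#' `P*_k(theta) = 1 / (1 + exp(-a (theta - b_{k-1})))`, `P*_1 = 1` and
#' `P*_{K+1} = 0`.
#'
#' @param theta Numeric vector of latent trait values.
#' @param item An [item_parameters()] object.
#' @param k Optional category (1..K); if supplied, returns the probability of
#'   that category only.
#' @return If `k` is `NULL`, a `length(theta) x K` matrix whose rows sum to 1;
#'   otherwise a numeric vector.
#' @examples
#' it <- item_parameters("x", a = 1.5, b = c(-2, -1, 0, 1))
#' rowSums(grm_probability(c(-1, 0, 1), it))
#' @export
grm_probability <- function(theta, item, k = NULL) {
  stopifnot(inherits(item, "item_parameters"))
  K <- item$K
  cum <- cbind(1, stats::plogis(item$a * outer(theta, item$b, "-")), 0)
  p <- cum[, 1:K, drop = FALSE] - cum[, 2:(K + 1), drop = FALSE]
  colnames(p) <- seq_len(K)
  if (is.null(k)) return(p)
  if (!(length(k) == 1L && k >= 1 && k <= K && k == as.integer(k)))
    fail(item$item_id, ": category k must be an integer in 1..", K)
  p[, k]
}

#' Map a latent trait value to the T-score metric
#'
#' The T metric has mean 50 and standard deviation 10 in the calibration
#' population: `T = 50 + 10 theta`.
#'
#' @param theta Numeric vector of latent trait values.
#' @return Numeric vector of T-scores.
#' @export
to_tscore <- function(theta) 50 + 10 * theta

# log category-probability table for one item: K x Q (categories x nodes)
log_prob_table <- function(item, grid) {
  p <- grm_probability(grid$nodes, item)
  t(log(pmax(p, .Machine$double.xmin)))
}

#' EAP response-pattern score for one respondent
#'
#' Expected-a-posteriori scoring from the full item-response pattern under a
#' standard-normal prior: the posterior over the quadrature nodes is
#' proportional to the prior weights times the likelihood, where the
#' likelihood is the product of graded-response category probabilities over
#' the *answered* items only.  Missing items simply contribute no factor, so
#' any subset of answered items — including none — yields a score; with no
#' answered items the posterior equals the prior (T = 50, SE = 10) and the
#' result is flagged rather than dropped.
#'
#' @param responses Integer vector of scored categories (1..K), `NA` = missing.
#' @param params List of [item_parameters()] aligned positionally with
#'   `responses`.
#' @param grid A [quadrature_grid()].
#' @return A list of class `tscore_result`: `theta_hat`, `se_theta`,
#'   `t_score = 50 + 10 theta_hat`, `se_t`, `n_items_used`, `all_missing`.
#' @examples
#' pars <- default_item_parameters()[c("Global03", "Global06")]
#' eap_score(c(3, NA), pars)
#' @export
eap_score <- function(responses, params, grid = quadrature_grid()) {
  res <- score_responses(matrix(as.integer(responses), nrow = 1L), params, grid)
  structure(as.list(res[1L, ]), class = "tscore_result")
}

#' @export
print.tscore_result <- function(x, ...) {
  cat(sprintf("T = %.1f (SE %.1f), theta = %.3f, %d item(s) used\n",
              round_half_up(x$t_score, 1), round_half_up(x$se_t, 1),
              x$theta_hat, x$n_items_used))
  invisible(x)
}

#' EAP-score a matrix of response patterns
#'
#' Vectorized response-pattern scoring: one row per respondent, one column
#' per item, scored categories with `NA` for missing.
#'
#' @param scored Integer matrix (respondents x items) of scored categories.
#' @param params List of [item_parameters()], one per column of `scored`.
#' @param grid A [quadrature_grid()].
#' @return Data frame with one row per respondent: `theta_hat`, `se_theta`,
#'   `t_score`, `se_t`, `n_items_used`, `all_missing`.
#' @export
score_responses <- function(scored, params, grid = quadrature_grid()) {
  scored <- as.matrix(scored)
  if (ncol(scored) != length(params))
    fail("response columns (", ncol(scored), ") do not match parameter list (",
         length(params), ")")
  n <- nrow(scored)
  Q <- length(grid$nodes)
  loglik <- matrix(0, n, Q)
  for (j in seq_along(params)) {
    K <- params[[j]]$K
    resp <- scored[, j]
    bad <- !is.na(resp) & (resp < 1L | resp > K)
    if (any(bad))
      fail(params[[j]]$item_id, ": response category outside 1..", K,
           " in row(s) ", paste(utils::head(which(bad), 5L), collapse = ", "))
    idx <- which(!is.na(resp))
    if (length(idx)) {
      lp <- log_prob_table(params[[j]], grid)       # K x Q
      loglik[idx, ] <- loglik[idx, ] + lp[resp[idx], , drop = FALSE]
    }
  }
  # normalize per row in log space, then apply prior weights
  shift <- apply(loglik, 1L, max)
  post <- exp(loglik - shift) * rep(grid$weights, each = n)
  post <- post / rowSums(post)
  theta <- as.vector(post %*% grid$nodes)
  m2 <- as.vector(post %*% grid$nodes^2)
  se <- sqrt(pmax(m2 - theta^2, 0))
  n_used <- rowSums(!is.na(scored))
  data.frame(theta_hat = theta, se_theta = se,
             t_score = to_tscore(theta), se_t = 10 * se,
             n_items_used = n_used, all_missing = n_used == 0L)
}

#' Summed-score to T-score conversion table
#'
#' Builds the scoring-manual-style conversion table mapping each attainable
#' raw sum of scored categories to a T-score.  The likelihood of each summed
#' score is accumulated with the Lord-Wingersky recursion over items (no
#' pattern enumeration), and each row's T-score is the EAP of the trait given
#' that summed-score likelihood under the prior.  The table applies only to
#' complete response patterns.
#'
#' @param params List of [item_parameters()] for the subscale's items.
#' @param grid A [quadrature_grid()].
#' @param subscale_id Optional label stored with the table.
#' @return Data frame of class `sum_score_table`: `sum_score` (from the sum
#'   of category minima to the sum of maxima), `theta_hat`, `se_theta`,
#'   `t_score` (non-decreasing in `sum_score`), `se_t`.
#' @examples
#' tab <- summed_score_table(default_item_parameters()[c("Global03", "Global06")])
#' tab$t_score
#' @export
summed_score_table <- function(params, grid = quadrature_grid(),
                               subscale_id = NULL) {
  if (!length(params)) fail("summed_score_table needs at least one item")
  Q <- length(grid$nodes)
  L <- matrix(1, 1L, Q)  # likelihood of the empty sum (offset 0)
  for (p in params) {
    prob <- grm_probability(grid$nodes, p)          # Q x K
    K <- p$K
    newL <- matrix(0, nrow(L) + K - 1L, Q)
    for (k in seq_len(K))
      newL[(k - 1L) + seq_len(nrow(L)), ] <-
        newL[(k - 1L) + seq_len(nrow(L)), , drop = FALSE] +
        L * rep(prob[, k], each = nrow(L))
    L <- newL
  }
  min_sum <- length(params)  # categories start at 1
  sums <- min_sum + seq_len(nrow(L)) - 1L
  post <- L * rep(grid$weights, each = nrow(L))
  post <- post / rowSums(post)
  theta <- as.vector(post %*% grid$nodes)
  m2 <- as.vector(post %*% grid$nodes^2)
  se <- sqrt(pmax(m2 - theta^2, 0))
  out <- data.frame(sum_score = sums, theta_hat = theta, se_theta = se,
                    t_score = to_tscore(theta), se_t = 10 * se)
  attr(out, "likelihood") <- L        # rows = sums, cols = grid nodes
  attr(out, "subscale_id") <- subscale_id
  class(out) <- c("sum_score_table", "data.frame")
  out
}

#' Export a conversion table as CSV
#'
#' Writes the raw-sum / T-score / SE columns in scoring-manual layout,
#' T-scores and standard errors rounded to one decimal (half-up).
#'
#' @param table A [summed_score_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conversion_table <- function(table, path) {
  out <- data.frame(raw_sum = table$sum_score,
                    t_score = round_half_up(table$t_score, 1),
                    se = round_half_up(table$se_t, 1))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Score a respondent population on the PROMIS-GH subscales
#'
#' Recodes raw responses, then scores every requested subscale for every
#' respondent, either by response-pattern EAP (`method = "pattern"`, the
#' accurate method, which handles missing items) or by summed-score table
#' lookup (`method = "sum-table"`, which requires complete responses on the
#' subscale and errors otherwise).
#'
#' @param records Respondent data frame (see [read_responses()]).
#' @param params A `grm_parameters` list covering the subscale items.
#' @param instrument A `promis_instrument`.
#' @param subscales Character vector of subscale ids to score.
#' @param method `"pattern"` or `"sum-table"`.
#' @param grid A [quadrature_grid()].
#' @return Long data frame of class `gh_scores`: `respondent_id`, `subscale`,
#'   `theta_hat`, `se_theta`, `t_score`, `se_t`, `n_items_used`,
#'   `all_missing`.
#' @export
score_population <- function(records, params = default_item_parameters(),
                             instrument = promis_gh_instrument(),
                             subscales = c("GMH", "GMH-2a", "GPH", "GPH-2a"),
                             method = c("pattern", "sum-table"),
                             grid = quadrature_grid()) {
  method <- match.arg(method)
  out <- lapply(subscales, function(s) {
    scored <- subscale_responses(records, instrument, s)
    pars <- params[colnames(scored)]
    if (any(vapply(pars, is.null, TRUE)))
      fail("missing item parameters for subscale ", s)
    if (method == "pattern") {
      res <- score_responses(scored, pars, grid)
    } else {
      if (anyNA(scored))
        fail("sum-table scoring requires complete responses on ", s,
             "; use method = \"pattern\" for records with missing items")
      tab <- summed_score_table(pars, grid, subscale_id = s)
      idx <- match(rowSums(scored), tab$sum_score)
      res <- data.frame(theta_hat = tab$theta_hat[idx],
                        se_theta = tab$se_theta[idx],
                        t_score = tab$t_score[idx], se_t = tab$se_t[idx],
                        n_items_used = ncol(scored),
                        all_missing = FALSE)
    }
    cbind(respondent_id = records$respondent_id, subscale = s, res)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("gh_scores", "data.frame")
  out
}
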