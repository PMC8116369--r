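# Shared fixtures, built in code.

the_instrument <- promis_gh_instrument()
the_params <- default_item_parameters()
the_grid <- quadrature_grid()

gmh_items <- the_instrument$subscales$GMH
gph_items <- the_instrument$subscales$GPH

# a minimal valid respondent row; override fields as needed
make_record <- function(id = "R1", age = 40, gender = "Female",
                        education = "Middle", region = "West",
                        ethnicity = "Native", responses = rep(3L, 10)) {
  names(responses) <- tolower(names(the_instrument$items))
  cbind(data.frame(respondent_id = id, age = age, gender = gender,
                   education = education, region = region,
                   ethnicity = ethnicity, stringsAsFactors = FALSE),
        as.data.frame(as.list(responses)))
}

make_records <- function(n, ...) {
  do.call(rbind, lapply(seq_len(n), function(i) make_record(id = paste0("R", i), ...)))
}

# all complete 4-item response patterns over 5 categories
all_patterns_4x5 <- as.matrix(expand.grid(1:5, 1:5, 1:5, 1:5,
                                          KEEP.OUT.ATTRS = FALSE))

# independent oracle: dense trapezoid integration of the posterior mean/SD
# over theta in [-8, 8] (10,001 points), sharing nothing with the package's
# quadrature path beyond the GRM curve itself
dense_eap_oracle <- function(responses, params, n_points = 10001L) {
  th <- seq(-8, 8, length.out = n_points)
  w <- stats::dnorm(th)
  w[c(1L, n_points)] <- w[c(1L, n_points)] / 2
  L <- rep(1, n_points)
  for (i in seq_along(params)) {
    if (is.na(responses[i])) next
    p <- params[[i]]
    k <- responses[i]
    upper <- if (k == 1) rep(1, n_points) else stats::plogis(p$a * (th - p$b[k - 1]))
    lower <- if (k == p$K) rep(0, n_points) else stats::plogis(p$a * (th - p$b[k]))
    L <- L * (upper - lower)
  }
  post <- w * L
  post <- post / sum(post)
  mu <- sum(th * post)
  list(theta = mu, se = sqrt(sum(th^2 * post) - mu^2))
}
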