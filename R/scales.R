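# Item keying. "yes" is coded 1 in the response matrices; key = 1 means the
# item scores a point on "yes", key = 0 means it scores on "no"
# (reverse-keyed). Order follows the published questionnaires.
gds15_key <- c(0, 1, 1, 1, 0, 1, 0, 1, 1, 1, 0, 1, 0, 1, 1)
names(gds15_key) <- c(
  "satisfied_with_life", "released_activities", "life_empty", "bored",
  "good_state_of_mind", "afraid_something_terrible", "joyful", "helpless",
  "prefer_stay_home", "memory_difficulties", "beautiful_to_be_alive",
  "valueless", "full_of_energy", "hopeless", "others_better_off")

# De Jong Gierveld 6-item scale: negatively worded items (emptiness, miss
# people, rejected) score on "yes" and form the emotional subscale; the
# positively worded items (rely on, trust, feel close) score on "no" and
# form the social subscale.
loneliness6_key <- c(1, 0, 0, 1, 0, 1)
names(loneliness6_key) <- c("emptiness", "rely_on", "trust_entirely",
                            "miss_people", "feel_close", "rejected")
loneliness6_emotional <- c(1L, 4L, 6L)
loneliness6_social <- c(2L, 3L, 5L)

# WHOQOL-BREF domain map (WHO item numbering, 26 items: 2 general + 24
# domain items) and the instrument's three negatively phrased items.
whoqol_domains <- list(
  physical      = c(3, 4, 10, 15, 16, 17, 18),
  psychological = c(5, 6, 7, 11, 19, 26),
  social        = c(20, 21, 22),
  environmental = c(8, 9, 12, 13, 14, 23, 24, 25)
)
whoqol_reverse <- c(3, 4, 26)

check_items <- function(responses, k, range, label) {
  responses <- as.matrix(responses)
  if (ncol(responses) == 1L && k > 1L) responses <- t(responses)
  if (ncol(responses) != k) {
    stopf("%s requires exactly %d items, got %d", label, k, ncol(responses))
  }
  bad <- !is.na(responses) & (responses < range[1] | responses > range[2])
  if (any(bad)) stopf("%s: response outside %d-%d", label, range[1], range[2])
  responses
}

# total with proration: score a keyed binary instrument, allowing up to 20%
# missing items (prorated to the full length), else NA
keyed_total <- function(responses, key) {
  pts <- sweep(responses, 2, key, function(r, k) ifelse(k == 1, r, 1 - r))
  n_miss <- rowSums(is.na(pts))
  k <- length(key)
  tot <- rowSums(pts, na.rm = TRUE) * k / (k - n_miss)
  tot[n_miss > 0.2 * k] <- NA_real_
  list(total = tot, points = pts, n_missing = n_miss)
}

#' Score the 15-item Geriatric Depression Scale
#'
#' Items are yes/no (1/0), in the questionnaire's order. Five items are
#' reverse-keyed (satisfaction with life, good state of mind, joyful,
#' beautiful to be alive, full of energy): they score a point on "no";
#' the other ten score on "yes". Totals above 5 are suggestive of
#' depression and 10 or more almost always indicative. Up to 20% missing
#' items are prorated; more invalidates the total.
#'
#' @param responses n x 15 matrix (or length-15 vector) of 1 = yes, 0 = no.
#' @return data.frame of class `scale_score` with `total` (0-15),
#'   `category` (`normal` <= 5, `suggestive` 6-9, `indicative` >= 10) and
#'   `n_missing`.
#' @export
#' @examples
#' score_gds15(c(1, 0, 0, 0, 1, 0, 1, 0, 0, 0, 1, 0, 1, 0, 0))  # total 0
score_gds15 <- function(responses) {
  r <- check_items(responses, 15L, c(0, 1), "GDS-15")
  s <- keyed_total(r, gds15_key)
  cat_lab <- cut(s$total, c(-Inf, 5, 9.5, Inf),
                 labels = c("normal", "suggestive", "indicative"))
  structure(data.frame(total = s$total, category = cat_lab,
                       n_missing = s$n_missing),
            instrument = "gds15", class = c("scale_score", "data.frame"))
}

#' Score the 6-item De Jong Gierveld loneliness scale
#'
#' Yes/no items; the three negatively worded items (emptiness, missing
#' people, feeling rejected) score on "yes" and sum to the emotional
#' subscale, the three positively worded items (people to rely on, people
#' to trust, people one feels close to) score on "no" and sum to the
#' social subscale. Higher totals mean more loneliness.
#'
#' @param responses n x 6 matrix (or length-6 vector) of 1 = yes, 0 = no.
#' @return data.frame of class `scale_score` with `total` (0-6),
#'   `emotional` (0-3), `social` (0-3), `n_missing`.
#' @export
#' @examples
#' score_loneliness6(c(1, 0, 0, 1, 0, 1))$total  # 6: every item keyed lonely
score_loneliness6 <- function(responses) {
  r <- check_items(responses, 6L, c(0, 1), "loneliness scale")
  s <- keyed_total(r, loneliness6_key)
  structure(data.frame(total = s$total,
                       emotional = rowSums(s$points[, loneliness6_emotional,
                                                    drop = FALSE]),
                       social = rowSums(s$points[, loneliness6_social,
                                                 drop = FALSE]),
                       n_missing = s$n_missing),
            instrument = "loneliness6", class = c("scale_score", "data.frame"))
}

#' Score the WHOQOL-BREF
#'
#' 26 items on a 1-5 scale: two general items plus 24 items in four
#' domains (physical 7, psychological 6, social 3, environmental 8). The
#' three negatively phrased items (pain, dependence on medication,
#' negative feelings) are reverse-coded as 6 - r. Domain scores per mode:
#' `raw_sum` is the item sum; `transformed_4_20` is 4 x the item mean
#' (range 4-20); `transformed_0_100` maps 4-20 linearly onto 0-100. A
#' domain with more than 20% of its items missing is invalid (NA); fewer
#' missing items are mean-substituted.
#'
#' @param responses n x 26 matrix (or length-26 vector), values 1-5.
#' @param mode `"raw_sum"`, `"transformed_4_20"` or `"transformed_0_100"`.
#' @return data.frame of class `scale_score` with one column per domain
#'   plus `n_missing`.
#' @export
#' @examples
#' score_whoqol_bref(rep(5, 26), mode = "transformed_0_100")
score_whoqol_bref <- function(responses,
                              mode = c("raw_sum", "transformed_4_20",
                                       "transformed_0_100")) {
  mode <- match.arg(mode)
  r <- check_items(responses, 26L, c(1, 5), "WHOQOL-BREF")
  r[, whoqol_reverse] <- 6 - r[, whoqol_reverse]
  dom <- vapply(whoqol_domains, function(items) {
    sub <- r[, items, drop = FALSE]
    k <- length(items)
    n_miss <- rowSums(is.na(sub))
    mu <- rowMeans(sub, na.rm = TRUE)          # mean substitution
    mu[n_miss > 0.2 * k] <- NA_real_
    switch(mode,
           raw_sum = mu * k,
           transformed_4_20 = 4 * mu,
           transformed_0_100 = (4 * mu - 4) * 100 / 16)
  }, numeric(nrow(r)))
  if (nrow(r) == 1L) dom <- matrix(dom, 1, dimnames = list(NULL, names(whoqol_domains)))
  structure(data.frame(dom, n_missing = rowSums(is.na(r))),
            instrument = "whoqol_bref", mode = mode,
            class = c("scale_score", "data.frame"))
}

#' Cronbach's alpha with a Feldt 95% confidence interval
#'
#' \deqn{\alpha = \frac{k}{k-1}\left(1 - \frac{\sum_j s_j^2}{s_T^2}\right)}
#' over complete cases, with the interval from Feldt's F approximation:
#' `1 - (1 - alpha) * F` at the 0.975 and 0.025 quantiles of
#' F(n - 1, (n - 1)(k - 1)).
#'
#' @param x respondents x items matrix (rows with any NA are dropped).
#' @return object of class `cronbach_alpha`: list with `alpha`, `ci`
#'   (length-2), `k`, `n`.
#' @export
#' @examples
#' r <- generate_item_responses(500, "loneliness6", seed = 2)
#' cronbach_alpha(r)
cronbach_alpha <- function(x) {
  x <- as.matrix(x)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  k <- ncol(x); n <- nrow(x)
  if (k < 2L) stopf("need at least 2 items")
  if (n < 3L) stopf("need at least 3 complete respondents")
  tot_var <- stats::var(rowSums(x))
  if (tot_var == 0) stopf("zero total-score variance: alpha undefined")
  a <- k / (k - 1) * (1 - sum(apply(x, 2, stats::var)) / tot_var)
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  ci <- c(1 - (1 - a) * stats::qf(0.975, df1, df2),
          1 - (1 - a) * stats::qf(0.025, df1, df2))
  structure(list(alpha = a, ci = ci, k = k, n = n), class = "cronbach_alpha")
}

#' @export
print.cronbach_alpha <- function(x, ...) {
  cat(sprintf("Cronbach alpha = %.3f (95%% CI %.3f-%.3f; %d items, n = %d)\n",
              x$alpha, x$ci[1], x$ci[2], x$k, x$n))
  invisible(x)
}
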