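#' Synthetic mortality schedule from a Gompertz hazard
#'
#' The force of mortality is `alpha * exp(beta * age)`; the central death
#' rate of each age group is the hazard at the group midpoint (the open
#' terminal group uses its start + 5 years). Deaths are `rate * exposure`;
#' with `count_mode = TRUE` they are rounded to integers and the rate
#' recomputed from the rounded counts. The operation is deterministic.
#'
#' @param profile a [cohort_profile()].
#' @param sex `"male"` or `"female"`.
#' @param age_grp age-group layout as from [age_groups()].
#' @param exposure person-years per group (scalar or vector; default 1e5).
#' @param count_mode round deaths to integer counts.
#' @return a [mortality_schedule()].
#' @export
#' @examples
#' p <- cohort_profile()
#' generate_mortality_schedule(p, "female", abridged_ages(95))
generate_mortality_schedule <- function(profile, sex, age_grp,
                                        exposure = 1e5, count_mode = FALSE) {
  sex <- match_sex(sex)
  check_age_groups(age_grp, "age groups")
  rate <- gompertz_hazard(profile, sex, age_midpoints(age_grp))
  if (any(rate > 1)) {
    warnf("hazard exceeds 1 per person-year in %d group(s); implausible but computed",
          sum(rate > 1))
  }
  exposure <- rep_len(exposure, nrow(age_grp))
  deaths <- rate * exposure
  if (count_mode) deaths <- round(deaths)
  mortality_schedule(age_grp, exposure, deaths, sex = sex)
}

#' Synthetic prevalence schedule from the profile's logistic model
#'
#' Proportion free of the condition per age group is
#' `1 - plogis(intercept + slope * midpoint + female_excess * is_female)`.
#'
#' @inheritParams generate_mortality_schedule
#' @param condition `"disability"` or `"morbidity"`.
#' @return a [prevalence_schedule()].
#' @export
generate_prevalence_schedule <- function(profile, sex, condition, age_grp) {
  sex <- match_sex(sex)
  condition <- match.arg(condition, c("disability", "morbidity"))
  check_age_groups(age_grp, "age groups")
  pf <- 1 - profile_prevalence(profile, condition, sex, age_midpoints(age_grp))
  prevalence_schedule(age_grp, pf, condition = condition, sex = sex)
}

# ---- latent-trait item model ---------------------------------------------

# model-implied Cronbach alpha of k binary items under a one-factor model
# P(yes | theta) = plogis(a * (theta - b_j)), theta ~ N(0,1), by
# Gauss-Legendre quadrature on the probit scale (deterministic).
implied_alpha_binary <- function(a, b) {
  k <- length(b)
  # 61-point rule on theta in [-8, 8] with normal weights
  gl <- seq(-8, 8, length.out = 201)
  w <- stats::dnorm(gl); w <- w / sum(w)
  P <- stats::plogis(a * outer(gl, b, "-"))       # nodes x items
  pbar <- colSums(P * w)
  EPP <- crossprod(P * sqrt(w))                   # E[p_j p_l]
  covm <- EPP - tcrossprod(pbar)
  diag(covm) <- pbar * (1 - pbar)                 # Bernoulli item variances
  tot <- sum(covm)
  k / (k - 1) * (1 - sum(diag(covm)) / tot)
}

# discrimination giving a target model-implied alpha for difficulties b
calibrate_discrimination <- function(target_alpha, b) {
  f <- function(a) implied_alpha_binary(a, b) - target_alpha
  stats::uniroot(f, c(0.05, 25), tol = 1e-7)$root
}

instrument_items <- c(gds15 = 15L, loneliness6 = 6L, whoqol_bref = 26L)

# per-instrument default difficulty spread
default_difficulties <- function(k) seq(-1, 1, length.out = k)

#' Synthetic item responses from a one-factor latent-trait model
#'
#' Binary instruments (GDS-15, 6-item loneliness) draw item j of respondent
#' i as Bernoulli with probability `plogis(a * (theta_i - b_j))`,
#' `theta_i ~ N(0, 1)`. The common discrimination a is calibrated
#' numerically so the model-implied Cronbach alpha equals the instrument's
#' `target_alpha` (0.89 for GDS-15 and 0.83 for the loneliness scale by
#' default). WHOQOL-BREF items are 1-5 ordinal: a congeneric continuous
#' response `loading * theta + sqrt(1 - loading^2) * e` cut at fixed normal
#' quantiles.
#'
#' @param n number of respondents (>= 2).
#' @param instrument `"gds15"`, `"loneliness6"` or `"whoqol_bref"`.
#' @param item_model list with `target_alpha` and optional `difficulty`
#'   (binary) or `loading` (ordinal); defaults as in [cohort_profile()].
#' @param seed integer seed.
#' @return matrix of class `item_response_matrix` (n x items), attribute
#'   `instrument`; binary 0/1 or ordinal 1-5.
#' @export
#' @examples
#' r <- generate_item_responses(200, "gds15", seed = 7)
#' cronbach_alpha(r)
generate_item_responses <- function(n, instrument, item_model = NULL, seed = 1L) {
  instrument <- match.arg(instrument, names(instrument_items))
  if (n < 2) stopf("need at least 2 respondents")
  k <- instrument_items[[instrument]]
  if (is.null(item_model)) {
    item_model <- cohort_profile(n_per_sex = 1)$item_model[[instrument]]
  }
  set.seed(derive_seed(seed, 11L))
  theta <- stats::rnorm(n)
  if (instrument == "whoqol_bref") {
    lam <- item_model$loading %||% 0.60
    cuts <- stats::qnorm(c(0.10, 0.35, 0.65, 0.90))
    y <- lam * matrix(theta, n, k) +
      sqrt(1 - lam^2) * matrix(stats::rnorm(n * k), n, k)
    resp <- matrix(findInterval(y, cuts) + 1L, n, k)
  } else {
    b <- item_model$difficulty %||% default_difficulties(k)
    a <- item_model$discrimination %||%
      calibrate_discrimination(item_model$target_alpha %||% 0.85, b)
    p <- stats::plogis(a * outer(theta, b, "-"))
    resp <- matrix(as.integer(stats::runif(n * k) < p), n, k)
  }
  colnames(resp) <- paste0(substr(instrument, 1, 3), "_", seq_len(k))
  structure(resp, instrument = instrument, class = "item_response_matrix")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# ---- survey cohort --------------------------------------------------------

#' Synthetic person-level survey cohort
#'
#' One row per person with sex, age, the six Washington-Group functional
#' limitation flags, a morbidity count, the categorical status flags, and
#' item responses for all three instruments. Ages are drawn with weights
#' declining exponentially over the cohort age range (rate 0.07/year), the
#' usual shape of an older-adult age pyramid. Each of the six disability
#' flags is Bernoulli with per-flag probability `1 - (1 - p_any)^(1/6)`,
#' independent given the person's age/sex risk, so the any-of-six union
#' matches the profile's logistic prevalence exactly. Morbidity counts are
#' Poisson with rate `-log(1 - p_any_morbidity)` (capped at 10), so the
#' any-morbidity marginal also matches its logistic target. Status flags are
#' Bernoulli at the profile's per-sex marginals.
#'
#' @param profile a [cohort_profile()].
#' @return data.frame with one row per person; columns `id`, `sex`, `age`,
#'   `dis_vision`, `dis_hearing`, `dis_walking`, `dis_remembering`,
#'   `dis_selfcare`, `dis_communicating`, `morbidity_count`, `adl_able`,
#'   `living_alone`, `employed`, `earning`, `healthcare`, and item columns
#'   `gds_1..15`, `lon_1..6`, `who_1..26`.
#' @export
#' @examples
#' coh <- generate_survey_cohort(cohort_profile(n_per_sex = 50, seed = 3))
#' table(coh$sex)
generate_survey_cohort <- function(profile) {
  stopifnot(inherits(profile, "cohort_profile"))
  n <- profile$n_per_sex
  ages_avail <- seq(profile$age_range[1], profile$age_range[2])
  wt <- exp(-0.07 * (ages_avail - ages_avail[1]))
  flags <- c("dis_vision", "dis_hearing", "dis_walking",
             "dis_remembering", "dis_selfcare", "dis_communicating")

  one_sex <- function(sex, off) {
    set.seed(derive_seed(profile$seed, off))
    age <- sample(ages_avail, n, replace = TRUE, prob = wt)
    p_any_dis <- profile_prevalence(profile, "disability", sex, age)
    p_flag <- 1 - (1 - p_any_dis)^(1 / 6)
    dis <- matrix(stats::runif(n * 6) < p_flag, n, 6)
    colnames(dis) <- flags
    lam <- -log(1 - profile_prevalence(profile, "morbidity", sex, age))
    morb <- pmin(stats::rpois(n, lam), 10L)
    st <- lapply(profile$status_marginals, function(p) {
      stats::runif(n) < p[[sex]]
    })
    cbind(data.frame(sex = sex, age = age),
          as.data.frame(dis * 1L),
          data.frame(morbidity_count = morb,
                     adl_able = st$adl_able * 1L,
                     living_alone = st$living_alone * 1L,
                     employed = st$employed * 1L,
                     earning = st$earning * 1L,
                     healthcare = st$healthcare * 1L))
  }
  out <- rbind(one_sex("male", 1L), one_sex("female", 2L))
  out <- cbind(id = seq_len(nrow(out)), out)
  gds <- generate_item_responses(nrow(out), "gds15",
                                 profile$item_model$gds15,
                                 seed = derive_seed(profile$seed, 3L))
  lon <- generate_item_responses(nrow(out), "loneliness6",
                                 profile$item_model$loneliness6,
                                 seed = derive_seed(profile$seed, 4L))
  who <- generate_item_responses(nrow(out), "whoqol_bref",
                                 profile$item_model$whoqol_bref,
                                 seed = derive_seed(profile$seed, 5L))
  colnames(gds) <- paste0("gds_", 1:15)
  colnames(lon) <- paste0("lon_", 1:6)
  colnames(who) <- paste0("who_", 1:26)
  cbind(out, as.data.frame(unclass(gds)), as.data.frame(unclass(lon)),
        as.data.frame(unclass(who)))
}
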