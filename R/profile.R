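#' Cohort profile: the parameters of the synthetic study population
#'
#' A `cohort_profile` bundles every parameter the synthetic-data generators
#' need: Gompertz mortality per sex, logistic age gradients of disability and
#' morbidity with a female excess on the logit scale, latent-trait item models
#' for the three psychometric instruments, and the marginal proportions of the
#' categorical status fields. The defaults describe an older-adult population
#' of a lower-middle-income country: higher female life expectancy, a female
#' excess in disability and morbidity, near-universal widowhood-driven living
#' alone among women, and very low female employment and earning.
#'
#' @param n_per_sex respondents per sex in a generated survey cohort.
#' @param age_range closed age interval (years) the survey cohort covers.
#' @param gompertz named list `list(male = c(alpha, beta), female = ...)`;
#'   the force of mortality at age x is `alpha * exp(beta * x)` per
#'   person-year. Defaults put the modal age at death near 72 (men) and
#'   77 (women) with slope 0.085/year.
#' @param disability,morbidity each a list with `intercept`, `slope` (per
#'   year of age) and `female_excess` (additive logit shift for women) for
#'   the any-condition prevalence `plogis(intercept + slope * age +
#'   female_excess * is_female)`. Defaults reproduce prevalences around
#'   55%/71% (any disability, men/women) and 63%/66% (any morbidity) at
#'   age 70.
#' @param item_model per-instrument latent-trait settings; each entry is a
#'   list with `target_alpha` (binary instruments, calibrated at generation
#'   time) or `loading` (WHOQOL ordinal items).
#' @param status_marginals named list of per-sex proportions for the
#'   categorical status fields (`living_alone`, `employed`, `earning`,
#'   `adl_able`, `healthcare`); each entry is `c(male = ..., female = ...)`.
#' @param seed integer base seed; all generator randomness derives from it.
#' @return an object of class `cohort_profile`.
#' @export
#' @examples
#' p <- cohort_profile(n_per_sex = 100, seed = 1)
#' p$status_marginals$living_alone
cohort_profile <- function(n_per_sex = 5000,
                           age_range = c(60, 100),
                           gompertz = list(
                             male   = c(alpha = 1.9e-4, beta = 0.085),
                             female = c(alpha = 1.2e-4, beta = 0.085)
                           ),
                           disability = list(intercept = -3.28, slope = 0.050,
                                             female_excess = 0.68),
                           morbidity  = list(intercept = -1.93, slope = 0.035,
                                             female_excess = 0.14),
                           item_model = list(
                             gds15       = list(target_alpha = 0.89),
                             loneliness6 = list(target_alpha = 0.83),
                             whoqol_bref = list(loading = 0.60)
                           ),
                           status_marginals = list(
                             living_alone = c(male = 0.089, female = 0.685),
                             employed     = c(male = 0.578, female = 0.030),
                             earning      = c(male = 0.598, female = 0.047),
                             adl_able     = c(male = 0.607, female = 0.529),
                             healthcare   = c(male = 0.614, female = 0.386)
                           ),
                           seed = 20260101L) {
  if (length(n_per_sex) != 1L || n_per_sex < 1) stopf("n_per_sex must be >= 1")
  if (length(age_range) != 2L || age_range[1] >= age_range[2]) {
    stopf("age_range must be an increasing pair of ages")
  }
  for (s in c("male", "female")) {
    g <- gompertz[[s]]
    if (is.null(g) || length(g) != 2L) stopf("gompertz$%s must be c(alpha, beta)", s)
    if (g[[1]] <= 0) stopf("gompertz$%s: alpha must be strictly positive", s)
  }
  for (cond in list(disability = disability, morbidity = morbidity)) {
    if (!all(is.finite(unlist(cond)))) stopf("logistic parameters must be finite")
  }
  for (fld in names(status_marginals)) {
    p <- status_marginals[[fld]]
    if (any(p < 0 | p > 1)) stopf("status_marginals$%s must lie in [0, 1]", fld)
  }
  structure(
    list(n_per_sex = as.integer(n_per_sex), age_range = age_range,
         gompertz = gompertz, disability = disability, morbidity = morbidity,
         item_model = item_model, status_marginals = status_marginals,
         seed = as.integer(seed)),
    class = "cohort_profile"
  )
}

#' @export
print.cohort_profile <- function(x, ...) {
  cat("Synthetic cohort profile\n")
  cat(sprintf("  n per sex: %d, ages %g-%g, seed %d\n",
              x$n_per_sex, x$age_range[1], x$age_range[2], x$seed))
  cat(sprintf("  Gompertz male alpha=%g beta=%g; female alpha=%g beta=%g\n",
              x$gompertz$male[[1]], x$gompertz$male[[2]],
              x$gompertz$female[[1]], x$gompertz$female[[2]]))
  cat(sprintf("  disability logit: %g + %g*age (+%g if female)\n",
              x$disability$intercept, x$disability$slope, x$disability$female_excess))
  cat(sprintf("  morbidity  logit: %g + %g*age (+%g if female)\n",
              x$morbidity$intercept, x$morbidity$slope, x$morbidity$female_excess))
  invisible(x)
}

# any-condition prevalence implied by the profile's logistic model
profile_prevalence <- function(profile, condition, sex, age) {
  par <- profile[[condition]]
  stats::plogis(par$intercept + par$slope * age +
                  par$female_excess * (sex == "female"))
}

gompertz_hazard <- function(profile, sex, age) {
  g <- profile$gompertz[[sex]]
  g[[1]] * exp(g[[2]] * age)
}

match_sex <- function(sex) match.arg(sex, c("male", "female"))
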