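#' Prevalence schedule: age-grouped proportion free of a condition
#'
#' @param age_grp age-group layout as from [age_groups()].
#' @param proportion_free fraction in \[0, 1\] per group.
#' @param condition `"disability"` or `"morbidity"` (free-form labels allowed).
#' @param sex,region optional stratum labels.
#' @return data.frame of class `prevalence_schedule`.
#' @export
prevalence_schedule <- function(age_grp, proportion_free, condition,
                                sex = NA_character_, region = NA_character_) {
  check_age_groups(age_grp, "prevalence schedule")
  proportion_free <- rep_len(proportion_free, nrow(age_grp))
  if (any(proportion_free < 0 | proportion_free > 1)) {
    stopf("proportion_free outside [0, 1] in group starting %g",
          age_grp$age_start[proportion_free < 0 | proportion_free > 1][1L])
  }
  structure(data.frame(age_start = age_grp$age_start, n = age_grp$n,
                       proportion_free = proportion_free),
            condition = condition, sex = sex, region = region,
            class = c("prevalence_schedule", "data.frame"))
}

#' Classify disability from the six Washington-Group flags
#'
#' A person reporting any of the six functional limitations (vision,
#' hearing, walking/climbing, remembering/concentrating, self-care,
#' communicating) counts as disabled; one limitation is a single
#' disability, two or more are multiple.
#'
#' @param flags logical (or 0/1) vector or matrix with exactly six
#'   flags per person (matrix rows are persons).
#' @return factor with levels `none`, `single`, `multiple`.
#' @export
#' @examples
#' classify_disability(c(0, 0, 0, 0, 0, 0))  # none
#' classify_disability(c(1, 0, 0, 0, 0, 0))  # single
classify_disability <- function(flags) {
  if (is.null(dim(flags))) flags <- matrix(flags, nrow = 1)
  if (ncol(flags) != 6L) {
    stopf("exactly six functional-domain flags are required, got %d", ncol(flags))
  }
  k <- rowSums(flags != 0)
  factor(ifelse(k == 0, "none", ifelse(k == 1, "single", "multiple")),
         levels = c("none", "single", "multiple"))
}

#' Classify morbidity burden from a condition count
#'
#' The categories are nested: any count >= 1 is morbidity, >= 2 is also
#' comorbidity, and > 2 is also multimorbidity. The most specific label is
#' returned; the membership predicates for the nested definitions are
#' available via [has_morbidity()], [has_comorbidity()] and
#' [has_multimorbidity()].
#'
#' @param count non-negative integer vector of concurrent conditions.
#' @return factor with levels `none`, `morbidity`, `comorbidity`,
#'   `multimorbidity`.
#' @export
#' @examples
#' classify_morbidity(0:3)
classify_morbidity <- function(count) {
  if (any(count < 0)) stopf("morbidity count must be non-negative")
  factor(ifelse(count == 0, "none",
         ifelse(count == 1, "morbidity",
         ifelse(count == 2, "comorbidity", "multimorbidity"))),
         levels = c("none", "morbidity", "comorbidity", "multimorbidity"))
}

#' @rdname classify_morbidity
#' @export
has_morbidity <- function(count) count >= 1
#' @rdname classify_morbidity
#' @export
has_comorbidity <- function(count) count >= 2
#' @rdname classify_morbidity
#' @export
has_multimorbidity <- function(count) count > 2

#' Age-specific prevalence from a person-level cohort
#'
#' @param cohort person-level data.frame as from [generate_survey_cohort()]
#'   (needs `age` plus the condition's fields).
#' @param condition `"disability"` (any of the six flags) or `"morbidity"`
#'   (count >= 1).
#' @param age_grp age-group layout the result should align with.
#' @return a [prevalence_schedule()] of the proportion free per group;
#'   an empty age group is an error.
#' @export
age_specific_prevalence <- function(cohort, condition, age_grp) {
  condition <- match.arg(condition, c("disability", "morbidity"))
  check_age_groups(age_grp, "age groups")
  affected <- if (condition == "disability") {
    classify_disability(as.matrix(cohort[, c("dis_vision", "dis_hearing",
                                             "dis_walking", "dis_remembering",
                                             "dis_selfcare", "dis_communicating")])) != "none"
  } else {
    has_morbidity(cohort$morbidity_count)
  }
  brk <- c(age_grp$age_start, Inf)
  grp <- findInterval(cohort$age, brk)
  grp[cohort$age < age_grp$age_start[1L]] <- NA
  cnt <- tabulate(grp, nbins = nrow(age_grp))
  if (any(cnt == 0)) {
    stopf("empty age group starting %g", age_grp$age_start[cnt == 0][1L])
  }
  aff <- vapply(seq_len(nrow(age_grp)),
                function(i) sum(affected[!is.na(grp) & grp == i]), 0)
  prevalence_schedule(age_grp, 1 - aff / cnt, condition = condition)
}

#' Sullivan health expectancy
#'
#' Partitions the life-table person-years by the prevalence of being free
#' of a condition:
#' \deqn{\mathrm{freeLE}_x = \frac{\sum_{i \ge x} L_i D_i}{l_x},}
#' where D is the proportion free in each age group. Total life expectancy
#' is taken from the same table, and the result carries the decomposition
#' `years_with_condition = LE - free_LE` and
#' `proportion_free = 100 free_LE / LE`.
#'
#' @param lt a [lifetable()].
#' @param prev a [prevalence_schedule()] whose groups align with the
#'   life-table rows at and above `reference_age`.
#' @param reference_age a boundary age of the table (e.g. 0, 60 or 65).
#' @return object of class `health_expectancy`: list with `reference_age`,
#'   `LE`, `free_LE`, `years_with_condition`, `proportion_free` (percent),
#'   and `condition`.
#' @export
#' @examples
#' g <- abridged_ages(85)
#' lt <- lifetable(mortality_schedule(g, 1e5, 1e5 * 0.01 * 1.4^seq_len(nrow(g))))
#' pv <- prevalence_schedule(g, 0.8, "disability")
#' sullivan_expectancy(lt, pv, 0)
sullivan_expectancy <- function(lt, prev, reference_age) {
  i0 <- match(reference_age, lt$age_start)
  if (is.na(i0)) stopf("reference age %g is not a life-table boundary", reference_age)
  rows <- seq(i0, nrow(lt))
  j <- match(lt$age_start[rows], prev$age_start)
  if (any(is.na(j))) {
    stopf("prevalence schedule lacks age group(s) starting %s",
          paste(lt$age_start[rows][is.na(j)], collapse = ", "))
  }
  if (any(abs(lt$n[rows] - prev$n[j]) > 1e-9, na.rm = TRUE)) {
    stopf("prevalence age groups misaligned with the life table")
  }
  free_LE <- sum(lt$L[rows] * prev$proportion_free[j]) / lt$l[i0]
  LE <- lt$e[i0]
  structure(list(reference_age = reference_age, LE = LE, free_LE = free_LE,
                 years_with_condition = LE - free_LE,
                 proportion_free = 100 * free_LE / LE,
                 condition = attr(prev, "condition"),
                 sex = attr(lt, "sex")),
            class = "health_expectancy")
}

#' @export
print.health_expectancy <- function(x, ...) {
  cat(sprintf("%s-free life expectancy at age %g%s\n",
              x$condition, x$reference_age,
              if (!is.null(x$sex) && !is.na(x$sex)) paste0(" (", x$sex, ")") else ""))
  cat(sprintf("  LE %.2f y, free %.2f y, with condition %.2f y (%.1f%% free)\n",
              x$LE, x$free_LE, x$years_with_condition,
              round_half_up(x$proportion_free, 1)))
  invisible(x)
}

#' Decompose a (LE, condition-free LE) pair
#'
#' The two derived report rows: years expected with the condition,
#' `LE - free_LE`, and the proportion of remaining life free of it,
#' `100 free_LE / LE`. Values rounded half-up to one decimal are attached
#' for report parity.
#'
#' @param LE total life expectancy (years), positive.
#' @param free_LE condition-free life expectancy, in \[0, LE\].
#' @return list with `years_with_condition`, `proportion_free_percent`,
#'   and their 1-decimal `rounded` counterparts.
#' @export
#' @examples
#' health_expectancy_summary(70.7, 58.1)  # 12.6 years, 82.2%
health_expectancy_summary <- function(LE, free_LE) {
  if (any(LE <= 0)) stopf("LE must be positive")
  if (any(free_LE < 0 | free_LE > LE)) stopf("free_LE must lie in [0, LE]")
  ywc <- LE - free_LE
  pct <- 100 * free_LE / LE
  list(years_with_condition = ywc, proportion_free_percent = pct,
       rounded = c(years_with_condition = round_half_up(ywc, 1),
                   proportion_free_percent = round_half_up(pct, 1)))
}

#' Per-sex status indicators of a survey cohort
#'
#' Percentages of living alone, employment, earning, ADL ability and
#' healthcare utilisation by sex, each with a binomial normal-approximation
#' 95% CI and the male - female difference.
#'
#' @param cohort person-level data.frame with `sex` and the status columns.
#' @return data.frame with one row per indicator: `male`, `male_lo`,
#'   `male_hi`, `female`, `female_lo`, `female_hi`, `difference`
#'   (percentage points, male - female).
#' @export
cohort_indicators <- function(cohort) {
  fields <- intersect(c("living_alone", "employed", "earning",
                        "adl_able", "healthcare"), names(cohort))
  for (s in c("male", "female")) {
    if (!any(cohort$sex == s)) stopf("empty stratum: no %s respondents", s)
  }
  one <- function(fld, s) {
    x <- cohort[[fld]][cohort$sex == s]
    n <- length(x); p <- mean(x)
    half <- stats::qnorm(0.975) * sqrt(p * (1 - p) / n)
    100 * c(p, max(0, p - half), min(1, p + half))
  }
  rows <- lapply(fields, function(fld) {
    m <- one(fld, "male"); f <- one(fld, "female")
    data.frame(indicator = fld, male = m[1], male_lo = m[2], male_hi = m[3],
               female = f[1], female_lo = f[2], female_hi = f[3],
               difference = m[1] - f[1])
  })
  do.call(rbind, rows)
}
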