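#' Read a mortality or prevalence schedule from CSV
#'
#' A mortality schedule has columns `age_start`, `age_width`, `population`
#' (or `exposure`), `deaths`, optional `sex`/`region`; a prevalence
#' schedule has `age_start`, `age_width`, `proportion_free`, optional
#' `condition`. The terminal row's `age_width` is empty (or `Inf`),
#' marking the open-ended group. Validation names the offending row or
#' column.
#'
#' @param path CSV file path (comma-separated, header row mandatory).
#' @return a [mortality_schedule()] or [prevalence_schedule()].
#' @export
read_schedule <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("age_start", "age_width") %in% names(df))) {
    stopf("%s: need columns age_start and age_width", path)
  }
  w <- suppressWarnings(as.numeric(df$age_width))
  w[is.na(w)] <- Inf
  g <- data.frame(age_start = df$age_start, n = w)
  check_age_groups(g, basename(path))
  first <- function(col, default) if (col %in% names(df)) df[[col]][1L] else default
  if ("proportion_free" %in% names(df)) {
    prevalence_schedule(g, df$proportion_free,
                        condition = first("condition", "disability"),
                        sex = first("sex", NA_character_),
                        region = first("region", NA_character_))
  } else {
    expo_col <- intersect(c("population", "exposure"), names(df))
    if (!length(expo_col) || !"deaths" %in% names(df)) {
      stopf("%s: need population/exposure and deaths, or proportion_free", path)
    }
    if (any(df$deaths < 0)) {
      stopf("%s: negative deaths at row %d", path, which(df$deaths < 0)[1L])
    }
    mortality_schedule(g, df[[expo_col[1L]]], df$deaths,
                       sex = first("sex", NA_character_),
                       region = first("region", NA_character_))
  }
}

#' Write a schedule to CSV
#'
#' Round-trips with [read_schedule()]: the open-ended terminal row is
#' written with an empty `age_width`.
#'
#' @param schedule a [mortality_schedule()] or [prevalence_schedule()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  df <- as.data.frame(schedule)
  out <- data.frame(age_start = df$age_start,
                    age_width = ifelse(is.finite(df$n), df$n, NA))
  if ("proportion_free" %in% names(df)) {
    out$proportion_free <- df$proportion_free
    out$condition <- attr(schedule, "condition")
  } else {
    out$population <- df$exposure
    out$deaths <- df$deaths
  }
  if (!is.na(attr(schedule, "sex") %||% NA)) out$sex <- attr(schedule, "sex")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

# proportions for the default WHO-scale indicator mapping; documented in
# the vignette as a demonstration mapping, overridable via who_positives
who_default_positives <- function(cohort, sex) {
  s <- cohort[cohort$sex == sex, ]
  dis_any <- classify_disability(as.matrix(
    s[, c("dis_vision", "dis_hearing", "dis_walking", "dis_remembering",
          "dis_selfcare", "dis_communicating")])) != "none"
  c(# health: three wellness + three physical-activity style indicators
    1 - mean(dis_any), mean(s$adl_able), 1 - mean(has_morbidity(s$morbidity_count)),
    1 - mean(has_comorbidity(s$morbidity_count)),
    1 - mean(has_multimorbidity(s$morbidity_count)), mean(s$healthcare),
    # participation
    mean(s$employed), mean(s$earning), 1 - mean(s$living_alone),
    # security: three financial + three physical
    mean(s$earning), mean(s$employed), mean(s$healthcare),
    mean(s$adl_able), 1 - mean(s$living_alone), 1 - mean(dis_any))
}

#' Run the full gender-stratified analysis on a synthetic cohort
#'
#' End to end: per-sex mortality schedules and abridged life tables,
#' model-based disability and morbidity prevalence schedules, Sullivan
#' health expectancies at the reference ages, a survey cohort with status
#' indicators, scale scoring with internal consistency, EU- and WHO-scale
#' Active Ageing Indices, and the male-female comparison tests (z for life
#' expectancy, Welch t for scale means, chi-square for living alone).
#'
#' @param profile a [cohort_profile()]; its seed drives all randomness.
#' @param reference_ages boundary ages for the Sullivan results.
#' @param ax_convention passed to [lifetable()].
#' @param radix life-table radix.
#' @param eu_indicators optional named list `list(male = ..., female = ...)`
#'   of EU indicator vectors; by default survey-style indicators are filled
#'   from the cohort marginals (employment rates from the employed flag,
#'   50 for fields the cohort does not carry) and the two capacity
#'   indicators are computed from the life table.
#' @param out_dir if non-NULL, the report bundle is written there as
#'   `report.json` plus per-sex life-table CSVs and a run log.
#' @return object of class `agewell_report` (a nested list; see the
#'   vignette for the layout).
#' @export
#' @examples
#' rep <- run_pipeline(cohort_profile(n_per_sex = 300, seed = 42))
#' rep$life_expectancy
run_pipeline <- function(profile = cohort_profile(),
                         reference_ages = c(0, 60, 65),
                         ax_convention = "literal", radix = 1e5,
                         eu_indicators = NULL, out_dir = NULL) {
  grid <- abridged_ages(95)
  cohort <- generate_survey_cohort(profile)
  sexes <- c("male", "female")

  lts <- lapply(stats::setNames(sexes, sexes), function(s) {
    lifetable(generate_mortality_schedule(profile, s, grid),
              radix = radix, ax_convention = ax_convention)
  })
  vars <- lapply(lts, le_variance)

  le <- do.call(rbind, lapply(sexes, function(s) {
    data.frame(sex = s, age = reference_ages,
               e = vapply(reference_ages, function(a) life_expectancy_at(lts[[s]], a), 0),
               var_e = vars[[s]]$var_e[match(reference_ages, vars[[s]]$age_start)])
  }))

  sullivan <- do.call(rbind, lapply(sexes, function(s) {
    do.call(rbind, lapply(c("disability", "morbidity"), function(cond) {
      prev <- generate_prevalence_schedule(profile, s, cond, grid)
      do.call(rbind, lapply(reference_ages, function(a) {
        h <- sullivan_expectancy(lts[[s]], prev, a)
        data.frame(sex = s, condition = cond, age = a, LE = h$LE,
                   free_LE = h$free_LE,
                   years_with_condition = h$years_with_condition,
                   proportion_free = h$proportion_free)
      }))
    }))
  }))

  indicators <- cohort_indicators(cohort)

  gds <- score_gds15(as.matrix(cohort[paste0("gds_", 1:15)]))
  lon <- score_loneliness6(as.matrix(cohort[paste0("lon_", 1:6)]))
  who <- score_whoqol_bref(as.matrix(cohort[paste0("who_", 1:26)]),
                           mode = "transformed_4_20")
  by_sex <- function(x) vapply(sexes, function(s) mean(x[cohort$sex == s]), 0)
  scales <- list(
    gds_mean = by_sex(gds$total),
    gds_depressed_pct = 100 * by_sex(gds$total > 5),
    loneliness_mean = by_sex(lon$total),
    whoqol_domain_means = sapply(names(whoqol_domains), function(d) by_sex(who[[d]])),
    alpha_gds15 = cronbach_alpha(cohort[paste0("gds_", 1:15)])$alpha,
    alpha_loneliness6 = cronbach_alpha(cohort[paste0("lon_", 1:6)])$alpha,
    alpha_whoqol = cronbach_alpha(cohort[paste0("who_", 1:26)])$alpha
  )

  # EU AAI: survey indicators from cohort marginals unless supplied
  cfg <- aai_eu_config()
  eu <- lapply(stats::setNames(sexes, sexes), function(s) {
    if (!is.null(eu_indicators)) {
      ind <- eu_indicators[[s]]
    } else {
      prev <- generate_prevalence_schedule(profile, s, "disability",
                                           age_groups(c(0, 1, seq(5, 95, 5))))
      cap <- aai_capacity_indicators(lts[[s]], prev)
      emp <- 100 * mean(cohort$employed[cohort$sex == s])
      nm <- unlist(lapply(cfg$domains, function(d) vapply(d$indicators, `[[`, "", "name")))
      ind <- stats::setNames(rep(50, length(nm)), nm)
      ind[grep("^employment_rate", nm)] <- emp
      ind[names(cap)] <- cap
    }
    aai_eu(ind, cfg)
  })
  who_aai <- lapply(stats::setNames(sexes, sexes), function(s) {
    aai_who(who_default_positives(cohort, s))
  })

  e0 <- function(s) le$e[le$sex == s & le$age == 0]
  v0 <- function(s) le$var_e[le$sex == s & le$age == 0]
  gds_by <- function(s) gds$total[cohort$sex == s]
  tests <- list(
    le_birth = le_difference_z_test(e0("female"), v0("female"), e0("male"), v0("male")),
    gds = welch_t_test(mean(gds_by("female")), stats::sd(gds_by("female")),
                       sum(cohort$sex == "female"),
                       mean(gds_by("male")), stats::sd(gds_by("male")),
                       sum(cohort$sex == "male")),
    living_alone = chi_square_test(as.matrix(table(cohort$sex, cohort$living_alone)))
  )

  report <- structure(
    list(profile_seed = profile$seed, ax_convention = ax_convention,
         radix = radix, n_per_sex = profile$n_per_sex,
         life_expectancy = le, sullivan = sullivan, indicators = indicators,
         scales = scales,
         aai = list(eu = eu, who = who_aai), tests = tests,
         lifetables = lts),
    class = "agewell_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    plain_df <- function(x) data.frame(lapply(x, identity))
    ser <- unclass(report)
    ser$lifetables <- lapply(lts, plain_df)
    ser$tests <- lapply(tests, unclass)
    ser$aai <- lapply(ser$aai, function(x) lapply(x, unclass))
    jsonlite::write_json(ser, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    for (s in sexes) {
      utils::write.csv(as.data.frame(lts[[s]]),
                       file.path(out_dir, paste0("lifetable_", s, ".csv")),
                       row.names = FALSE)
    }
    writeLines(c(sprintf("seed: %d", profile$seed),
                 sprintf("ax_convention: %s", ax_convention),
                 sprintf("radix: %g", radix),
                 sprintf("agewell version: %s",
                         as.character(utils::packageVersion("agewell"))),
                 sprintf("R version: %s", R.version.string)),
               file.path(out_dir, "run_log.txt"))
  }
  report
}

#' @export
print.agewell_report <- function(x, ...) {
  cat(sprintf("Gender-stratified ageing analysis (seed %d, n = %d per sex)\n\n",
              x$profile_seed, x$n_per_sex))
  cat("Life expectancy (years):\n")
  print(transform(x$life_expectancy, e = round_half_up(e, 1),
                  var_e = signif(var_e, 3)), row.names = FALSE)
  cat("\nSullivan health expectancies:\n")
  s <- x$sullivan
  s[c("LE", "free_LE", "years_with_condition", "proportion_free")] <-
    lapply(s[c("LE", "free_LE", "years_with_condition", "proportion_free")],
           round_half_up, 1)
  print(s, row.names = FALSE)
  cat(sprintf("\nAAI (EU): male %.1f, female %.1f;  AAI (WHO): male %.2f (%s), female %.2f (%s)\n",
              x$aai$eu$male$overall, x$aai$eu$female$overall,
              x$aai$who$male$overall, x$aai$who$male$level,
              x$aai$who$female$overall, x$aai$who$female$level))
  invisible(x)
}
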