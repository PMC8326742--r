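#' Mortality schedule: age-grouped exposures, deaths and central death rates
#'
#' @param age_grp age-group layout as from [age_groups()].
#' @param exposure person-count or person-years per group; must be positive.
#' @param deaths death count per group; non-negative.
#' @param sex,region optional stratum labels stored as attributes.
#' @return data.frame of class `mortality_schedule` with columns
#'   `age_start`, `n`, `exposure`, `deaths`, `m` (central death rate
#'   `deaths / exposure`, per person-year).
#' @export
mortality_schedule <- function(age_grp, exposure, deaths,
                               sex = NA_character_, region = NA_character_) {
  check_age_groups(age_grp, "mortality schedule")
  k <- nrow(age_grp)
  exposure <- rep_len(exposure, k)
  deaths <- rep_len(deaths, k)
  if (any(exposure <= 0)) {
    stopf("zero or negative exposure in age group starting %g",
          age_grp$age_start[exposure <= 0][1L])
  }
  if (any(deaths < 0)) stopf("negative death count")
  out <- data.frame(age_start = age_grp$age_start, n = age_grp$n,
                    exposure = exposure, deaths = deaths,
                    m = deaths / exposure)
  structure(out, sex = sex, region = region,
            class = c("mortality_schedule", "data.frame"))
}

#' Central death rates from population and death counts
#'
#' The central death rate of an age group is deaths per person-year of
#' exposure, `m = deaths / population`.
#'
#' @param population person-count (or person-years) per age group.
#' @param deaths death count per age group; same length.
#' @param age_grp age-group layout as from [age_groups()].
#' @inheritParams mortality_schedule
#' @return a [mortality_schedule()].
#' @export
#' @examples
#' g <- abridged_ages(85)
#' central_death_rates(rep(1000, nrow(g)), rep(10, nrow(g)), g)
central_death_rates <- function(population, deaths, age_grp,
                                sex = NA_character_, region = NA_character_) {
  if (length(population) != length(deaths)) {
    stopf("population and deaths have mismatched lengths (%d vs %d)",
          length(population), length(deaths))
  }
  if (length(population) != nrow(age_grp)) {
    stopf("counts do not match the age grouping (%d values, %d groups)",
          length(population), nrow(age_grp))
  }
  mortality_schedule(age_grp, population, deaths, sex = sex, region = region)
}

#' Probability of dying within an age interval
#'
#' Converts a central death rate m to the conditional probability of dying
#' in an interval of length n years,
#' \deqn{q = \frac{n\,m}{1 + (n - a)\,m},}
#' where a is the separation factor: the mean time lived in the interval by
#' those who die in it. The result is clamped to \[0, 1\] (with a warning)
#' for extreme rates.
#'
#' @param m central death rate (per person-year), non-negative.
#' @param n interval length in years, positive.
#' @param a separation factor in years; must not exceed `n`.
#' @return probability in \[0, 1\].
#' @export
#' @examples
#' probability_of_dying(0.05, n = 1, a = 0.3)  # 0.0483092
#' probability_of_dying(0.02, n = 5, a = 0.5)  # 0.0917431
probability_of_dying <- function(m, n, a) {
  if (any(m < 0)) stopf("central death rate must be non-negative")
  if (any(n <= 0)) stopf("interval length must be positive")
  if (any(a > n)) stopf("separation factor a = %g exceeds interval length n = %g",
                        max(a), max(n))
  q <- n * m / (1 + (n - a) * m)
  if (any(q > 1)) {
    warnf("probability of dying exceeded 1 for extreme rates; clamped")
    q <- pmin(q, 1)
  }
  pmax(q, 0)
}

# separation-factor schedule: 0.3 at age 0, 0.7 at age 1, 0.5 elsewhere.
# Under "literal" these are years; under "fraction" they are fractions of the
# interval (effective years a * n), which recovers the standard abridged
# midpoint a*n = n/2 at a = 0.5.
ax_values <- function(age_start) {
  ifelse(age_start == 0, 0.3, ifelse(age_start == 1, 0.7, 0.5))
}

#' Build an abridged (or single-year) life table
#'
#' Constructs the full life-table columns from a mortality schedule: the
#' m-to-q conversion of [probability_of_dying()] with separation factor 0.3
#' at age 0, 0.7 at age 1 and 0.5 at every other age, the survivorship
#' recursion l(x+n) = l(x)(1 - q), person-years L = n l(x+n) + a d, the
#' terminal open group closed with L = l/m, and life expectancy e = T/l.
#'
#' Two interpretations of the separation factor are supported.
#' `"literal"` (default) takes a in years exactly as given, so deaths in a
#' 5-year group are assumed to occur on average 0.5 years in. `"fraction"`
#' reads a as a fraction of the interval (effective separation a*n years),
#' which at a = 0.5 is the standard mid-interval convention for abridged
#' tables. The choice is recorded in the object.
#'
#' @param schedule a [mortality_schedule()].
#' @param radix size of the hypothetical birth cohort (default 100,000).
#' @param ax_convention `"literal"` or `"fraction"`; see Details.
#' @return data.frame of class `lifetable` with columns `age_start`, `n`,
#'   `m`, `a`, `q`, `l`, `d`, `L`, `T`, `e`; attributes `radix`,
#'   `ax_convention`, `sex`, `region`.
#' @export
#' @examples
#' g <- abridged_ages(85)
#' sched <- mortality_schedule(g, 1e5, 1e5 * 0.005 * (1.5^seq_len(nrow(g))))
#' lt <- lifetable(sched)
#' head(lt)
#' life_expectancy_at(lt, 0)
lifetable <- function(schedule, radix = 1e5,
                      ax_convention = c("literal", "fraction")) {
  ax_convention <- match.arg(ax_convention)
  if (!inherits(schedule, "mortality_schedule")) {
    schedule <- mortality_schedule(schedule[c("age_start", "n")],
                                   schedule$exposure, schedule$deaths)
  }
  k <- nrow(schedule)
  m <- schedule$m
  if (m[k] <= 0) stopf("terminal central death rate is zero: open group cannot be closed")

  a_frac <- ax_values(schedule$age_start)        # fraction-of-interval scale
  n_closed <- schedule$n[-k]
  a_years <- switch(ax_convention,
                    literal  = a_frac[-k],
                    fraction = a_frac[-k] * n_closed)

  q <- c(probability_of_dying(m[-k], n_closed, a_years), 1)
  l <- radix * cumprod(c(1, 1 - q[-k]))
  d <- l * q
  L <- c(schedule$n[-k] * l[-1L] + a_years * d[-k], l[k] / m[k])
  Tx <- rev(cumsum(rev(L)))
  e <- Tx / l

  out <- data.frame(age_start = schedule$age_start, n = schedule$n,
                    m = m, a = c(a_years, NA_real_), q = q, l = l, d = d,
                    L = L, T = Tx, e = e)
  structure(out, radix = radix, ax_convention = ax_convention,
            sex = attr(schedule, "sex"), region = attr(schedule, "region"),
            deaths_observed = schedule$deaths,
            class = c("lifetable", "data.frame"))
}

#' @export
print.lifetable <- function(x, digits = 4, ...) {
  cat(sprintf("Abridged life table (radix %s, ax convention '%s'%s)\n",
              format(attr(x, "radix"), big.mark = ","),
              attr(x, "ax_convention"),
              if (!is.na(attr(x, "sex"))) paste0(", ", attr(x, "sex")) else ""))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
summary.lifetable <- function(object, ...) {
  cat("Life table summary\n")
  for (age in intersect(c(0, 60, 65), object$age_start)) {
    cat(sprintf("  e(%d) = %.2f years\n", age, life_expectancy_at(object, age)))
  }
  cat(sprintf("  deaths column sums to the radix: %s\n",
              isTRUE(all.equal(sum(object$d), attr(object, "radix")))))
  invisible(object)
}

#' @export
plot.lifetable <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  graphics::plot(x$age_start, x$l / attr(x, "radix"), type = "s",
                 xlab = "age", ylab = "proportion surviving l(x)", ...)
  graphics::plot(x$age_start, x$e, type = "b", pch = 16,
                 xlab = "age", ylab = "life expectancy e(x)", ...)
  invisible(x)
}

#' Life expectancy at an exact table boundary
#'
#' @param lt a [lifetable()].
#' @param age a boundary age of the table; intermediate ages are an error
#'   (no interpolation is attempted).
#' @return life expectancy e(age) in years.
#' @export
life_expectancy_at <- function(lt, age) {
  i <- match(age, lt$age_start)
  if (is.na(i)) {
    stopf("age %g is not a boundary of this life table (boundaries: %s)",
          age, paste(lt$age_start, collapse = ", "))
  }
  lt$e[i]
}

#' Variance of life expectancy (Chiang-style)
#'
#' Binomial variance of each interval death probability,
#' var(q) = q^2 (1 - q) / D with D the observed deaths, propagated to the
#' life expectancies by the delta method:
#' \deqn{var(e_x) = \sum_{i \ge x} l_i^2 \left[(n_i - a_i) + e_{i+1}\right]^2
#'   var(q_i) / l_x^2.}
#' An interval with zero observed deaths contributes zero variance, as does
#' the terminal open group (its q is fixed at 1).
#'
#' @param lt a [lifetable()].
#' @param deaths_by_age observed death counts per interval; defaults to the
#'   deaths of the schedule the table was built from.
#' @return data.frame with `age_start`, `e`, `var_e`, `se_e`.
#' @export
le_variance <- function(lt, deaths_by_age = attr(lt, "deaths_observed")) {
  k <- nrow(lt)
  if (is.null(deaths_by_age)) stopf("observed death counts are required")
  deaths_by_age <- rep_len(deaths_by_age, k)
  var_q <- ifelse(deaths_by_age > 0,
                  lt$q^2 * (1 - lt$q) / deaths_by_age, 0)
  var_q[k] <- 0                     # terminal q fixed at 1
  e_next <- c(lt$e[-1L], 0)
  w <- lt$l^2 * ((lt$n - lt$a) + e_next)^2 * var_q
  w[k] <- 0
  var_e <- rev(cumsum(rev(w))) / lt$l^2
  data.frame(age_start = lt$age_start, e = lt$e,
             var_e = var_e, se_e = sqrt(var_e))
}
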