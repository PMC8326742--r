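# Independent oracles used across test files. These deliberately avoid the
# package's own code paths.

# Item keying copied verbatim from the published questionnaires: the value
# is the point awarded for a "yes" answer (reverse-keyed items award the
# point on "no").
table_gds_yes_points <- c(0, 1, 1, 1, 0, 1, 0, 1, 1, 1, 0, 1, 0, 1, 1)
table_lon_yes_points <- c(1, 0, 0, 1, 0, 1)

# brute-force scorer keyed directly from the questionnaire tables
brute_score <- function(responses, yes_points) {
  apply(responses, 1, function(r) {
    sum(ifelse(r == 1, yes_points, 1 - yes_points))
  })
}

# single-year mortality schedule with constant hazard
const_hazard_schedule <- function(m, max_age = 110) {
  g <- age_groups(0:max_age)
  mortality_schedule(g, exposure = 1e6, deaths = 1e6 * m)
}

# rebuild e(0) from a q vector by the plain life-table recursion; used as
# the target function for numeric delta-method differentiation
e0_from_q <- function(q, n_widths, a_years, m_term, radix = 1e5) {
  k <- length(q) + 1L
  l <- radix * cumprod(c(1, 1 - q))
  d <- l[-k] * q
  L <- n_widths * l[-1L] + a_years * d
  L_term <- l[k] / m_term
  (sum(L) + L_term) / radix
}

# piecewise-constant-hazard microsimulation: lifetimes, and state occupancy
# free of a condition with the given per-interval proportions free.
# Returns mean age at death and mean years lived free.
microsim_lifetimes <- function(m, widths, prop_free = NULL, n = 1e6, seed = 1) {
  set.seed(seed)
  k <- length(m)
  stopifnot(length(widths) == k, !is.finite(widths[k]))
  age_death <- numeric(n)
  free_years <- numeric(n)
  alive <- seq_len(n)
  start <- 0
  for (i in seq_len(k - 1L)) {
    tt <- stats::rexp(length(alive), m[i])
    died <- tt < widths[i]
    lived <- pmin(tt, widths[i])
    if (!is.null(prop_free)) {
      free_years[alive] <- free_years[alive] +
        lived * (stats::runif(length(alive)) < prop_free[i])
    }
    age_death[alive[died]] <- start + tt[died]
    alive <- alive[!died]
    start <- start + widths[i]
    if (!length(alive)) break
  }
  if (length(alive)) {
    tt <- stats::rexp(length(alive), m[k])
    if (!is.null(prop_free)) {
      free_years[alive] <- free_years[alive] +
        tt * (stats::runif(length(alive)) < prop_free[k])
    }
    age_death[alive] <- start + tt
  }
  list(mean_age = mean(age_death), mean_free = mean(free_years))
}

expect_within <- function(object, expected, tol) {
  expect_lt(abs(object - expected), tol)
}
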