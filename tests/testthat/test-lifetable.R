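test_that("the m-to-q conversion matches hand-evaluated values", {
  expect_equal(probability_of_dying(0, 5, 0.5), 0)
  expect_equal(probability_of_dying(0.05, 1, 0.3), 0.05 / (1 + 0.7 * 0.05),
               tolerance = 1e-12)                          # 0.0483092
  expect_equal(probability_of_dying(0.02, 5, 0.5), 0.1 / (1 + 4.5 * 0.02),
               tolerance = 1e-12)                          # 0.0917431
  expect_warning(q <- probability_of_dying(5, 5, 0.5), "clamped")
  expect_equal(q, 1)
  expect_error(probability_of_dying(0.1, 1, 1.5), "exceeds interval length")
  expect_error(probability_of_dying(-0.1, 5, 0.5), "non-negative")
})

test_that("central death rates are deaths over exposure with validation", {
  g <- abridged_ages(85)
  k <- nrow(g)
  s <- central_death_rates(rep(1000, k), rep(0, k), g)
  expect_true(all(s$m == 0))
  s2 <- central_death_rates(rep(1000, k), rep(10, k), g)
  expect_true(all(s2$m == 0.01))
  expect_error(central_death_rates(rep(1000, k - 1), rep(10, k - 1), g),
               "do not match")
  expect_error(central_death_rates(c(0, rep(1000, k - 1)), rep(1, k), g),
               "exposure")
  expect_error(central_death_rates(rep(1000, k), rep(10, k - 1), g),
               "mismatched")

  # round trip: rates from generated counts equal the generator hazards
  p <- cohort_profile()
  gen <- generate_mortality_schedule(p, "female", g, exposure = 1e6)
  back <- central_death_rates(gen$exposure, gen$deaths, g)
  expect_equal(back$m, gen$m, tolerance = 1e-12)
})

test_that("the survivorship recursion reproduces a hand-computed table", {
  # five single-year ages with q = 0.5 each, then an open group with m = 1;
  # the m values are inverted from q = n m / (1 + (n - a) m) per-row a
  a <- c(0.3, 0.7, 0.5, 0.5, 0.5)
  m <- 0.5 / (1 - (1 - a) * 0.5)
  g <- age_groups(0:5)
  lt <- lifetable(mortality_schedule(g, 1, c(m, 1)))
  expect_equal(lt$q[1:5], rep(0.5, 5), tolerance = 1e-12)
  expect_equal(lt$l, c(100000, 50000, 25000, 12500, 6250, 3125))
  expect_equal(sum(lt$d[1:5]), 96875)
  expect_equal(sum(lt$d), 100000)           # conservation including open group
  expect_equal(lt$e[6], 1)                  # closure: e = 1/m at the last boundary
})

test_that("life-table identities hold on a realistic schedule", {
  p <- cohort_profile()
  g <- abridged_ages(95)
  lt <- lifetable(generate_mortality_schedule(p, "male", g))
  expect_equal(sum(lt$d), attr(lt, "radix"), tolerance = 1e-9)
  expect_true(all(diff(lt$l) < 0))
  expect_true(all(diff(lt$T) < 0))
  expect_true(all(diff(lt$e) < 0))          # positive mortality at all ages
  expect_equal(lt$d, lt$l * lt$q)
  expect_equal(lt$e, lt$T / lt$l)

  # fraction convention: a = 0.5 becomes the standard mid-interval n/2
  # the heavy-mortality 90-94 group exceeds q = 1 under this convention
  # and is clamped, with a warning
  expect_warning(
    ltf <- lifetable(generate_mortality_schedule(p, "male", g),
                     ax_convention = "fraction"),
    "clamped")
  expect_equal(attr(ltf, "ax_convention"), "fraction")
  expect_equal(ltf$a[3], 0.5 * lt$n[3])     # 2.5 years in a 5-year group
  expect_gt(ltf$e[1], lt$e[1])              # later deaths, longer life
})

test_that("degenerate schedules close correctly", {
  # zero mortality in all closed intervals: certain survival to the open group
  g <- age_groups(c(0, 1, seq(5, 80, 5)))
  lt <- lifetable(mortality_schedule(g, 1000, c(rep(0, nrow(g) - 1), 100)))
  expect_equal(life_expectancy_at(lt, 0), 80 + 1 / 0.1, tolerance = 1e-9)

  # zero terminal rate is an explicit error
  expect_error(lifetable(mortality_schedule(g, 1000, 0)), "terminal")
})

test_that("a constant hazard gives exponential life expectancy", {
  lt <- suppressWarnings(lifetable(const_hazard_schedule(0.05, 110)))
  expect_within(life_expectancy_at(lt, 0), 1 / 0.05, 0.02 * (1 / 0.05))
})

test_that("life expectancy is read only at table boundaries", {
  p <- cohort_profile()
  lt <- lifetable(generate_mortality_schedule(p, "female", abridged_ages(95)))
  expect_equal(life_expectancy_at(lt, 0), lt$T[1] / attr(lt, "radix"))
  expect_equal(life_expectancy_at(lt, 95), 1 / lt$m[nrow(lt)])
  expect_error(life_expectancy_at(lt, 62), "not a boundary")
})

test_that("Chiang variance matches numeric delta-method propagation", {
  g <- age_groups(c(0, 1, 5, 10))
  deaths <- c(30, 12, 40, 200)
  sched <- mortality_schedule(g, c(1000, 900, 4000, 1500), deaths)
  lt <- lifetable(sched)

  h <- 1e-6
  q0 <- lt$q[1:3]
  f <- function(q) e0_from_q(q, n_widths = c(1, 4, 5),
                             a_years = c(0.3, 0.7, 0.5),
                             m_term = lt$m[4])
  grad <- vapply(1:3, function(i) {
    qp <- q0; qm <- q0
    qp[i] <- qp[i] + h; qm[i] <- qm[i] - h
    (f(qp) - f(qm)) / (2 * h)
  }, 0)
  var_q <- q0^2 * (1 - q0) / deaths[1:3]
  oracle <- sum(grad^2 * var_q)
  got <- le_variance(lt)$var_e[1]
  expect_equal(got, oracle, tolerance = 1e-5)
})

test_that("variance scales as binomial counts dictate", {
  g <- abridged_ages(85)
  p <- cohort_profile()
  s1 <- generate_mortality_schedule(p, "male", g, exposure = 1e4)
  s2 <- generate_mortality_schedule(p, "male", g, exposure = 2e4)
  v1 <- le_variance(lifetable(s1))
  v2 <- le_variance(lifetable(s2))
  expect_equal(v2$var_e, v1$var_e / 2, tolerance = 1e-9)  # rates unchanged

  # huge death counts: variance vanishes
  s3 <- generate_mortality_schedule(p, "male", g, exposure = 1e12)
  expect_true(all(le_variance(lifetable(s3))$var_e < 1e-8))

  # zero deaths in an interval contribute zero variance, no NaN
  sz <- mortality_schedule(g, 1000, c(0, rep(5, nrow(g) - 2), 100))
  vz <- le_variance(lifetable(sz))
  expect_true(all(is.finite(vz$var_e)))
})
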