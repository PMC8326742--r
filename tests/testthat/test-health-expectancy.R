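test_that("the any-of-six rule classifies disability", {
  expect_equal(as.character(classify_disability(rep(0, 6))), "none")
  expect_equal(as.character(classify_disability(c(1, 0, 0, 0, 0, 0))), "single")
  expect_equal(as.character(classify_disability(c(1, 1, 1, 0, 0, 0))), "multiple")
  m <- rbind(rep(0, 6), c(0, 1, 0, 0, 0, 0), rep(1, 6))
  expect_equal(as.character(classify_disability(m)), c("none", "single", "multiple"))
  expect_error(classify_disability(rep(1, 5)), "six")
})

test_that("morbidity categories nest as defined", {
  expect_equal(as.character(classify_morbidity(c(0, 1, 2, 3, 7))),
               c("none", "morbidity", "comorbidity", "multimorbidity",
                 "multimorbidity"))
  expect_error(classify_morbidity(-1), "non-negative")
  expect_equal(has_morbidity(0:3), c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(has_comorbidity(0:3), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(has_multimorbidity(0:3), c(FALSE, FALSE, FALSE, TRUE))
})

test_that("age-specific prevalence is a direct ratio per group", {
  coh <- data.frame(age = c(rep(62, 10), rep(67, 5)),
                    dis_vision = 0, dis_hearing = 0, dis_walking = 0,
                    dis_remembering = 0, dis_selfcare = 0,
                    dis_communicating = 0, morbidity_count = 0)
  g <- age_groups(c(60, 65))
  s <- age_specific_prevalence(coh, "disability", g)
  expect_equal(s$proportion_free, c(1, 1))

  coh$dis_vision[1:4] <- 1   # 4 of 10 disabled in the 60-64 group
  s2 <- age_specific_prevalence(coh, "disability", g)
  expect_equal(s2$proportion_free, c(0.6, 1))

  expect_error(age_specific_prevalence(coh[coh$age < 65, ], "disability", g),
               "empty age group")
})

test_that("cohort prevalence recovers the generator's logistic curve", {
  p <- cohort_profile(n_per_sex = 10000, seed = 21)
  coh <- generate_survey_cohort(p)
  g <- age_groups(seq(60, 90, 10))
  for (cond in c("disability", "morbidity")) {
    obs <- age_specific_prevalence(coh[coh$sex == "female", ], cond, g)
    for (i in seq_len(nrow(g))) {
      sub_age <- coh$age[coh$sex == "female"]
      in_grp <- sub_age >= g$age_start[i] &
        (is.infinite(g$n[i]) | sub_age < g$age_start[i] + g$n[i])
      par <- p[[cond]]
      pf_true <- mean(1 - plogis(par$intercept + par$slope * sub_age[in_grp] +
                                   par$female_excess))
      se <- sqrt(pf_true * (1 - pf_true) / sum(in_grp))
      expect_within(obs$proportion_free[i], pf_true, 3 * se + 1e-9)
    }
  }
})

test_that("Sullivan degeneracies and linearity hold", {
  p <- cohort_profile()
  g <- abridged_ages(95)
  lt <- lifetable(generate_mortality_schedule(p, "female", g))

  all_free <- prevalence_schedule(g, 1, "disability")
  h1 <- sullivan_expectancy(lt, all_free, 0)
  expect_equal(h1$free_LE, h1$LE, tolerance = 1e-12)

  none_free <- prevalence_schedule(g, 0, "disability")
  h0 <- sullivan_expectancy(lt, none_free, 60)
  expect_equal(h0$free_LE, 0)
  expect_equal(h0$years_with_condition, h0$LE)

  const <- prevalence_schedule(g, 0.73, "morbidity")
  hc <- sullivan_expectancy(lt, const, 65)
  expect_equal(hc$free_LE, 0.73 * hc$LE, tolerance = 1e-12)

  # pointwise-larger proportion free => larger free LE
  pv1 <- generate_prevalence_schedule(p, "female", "disability", g)
  pv2 <- prevalence_schedule(g, pmin(1, pv1$proportion_free + 0.05), "disability")
  expect_gt(sullivan_expectancy(lt, pv2, 0)$free_LE,
            sullivan_expectancy(lt, pv1, 0)$free_LE)

  # misalignment and bad reference ages are errors
  g2 <- age_groups(seq(0, 90, 10))
  expect_error(sullivan_expectancy(lt, prevalence_schedule(g2, 0.5, "x"), 0),
               "lacks age group|misaligned")
  expect_error(sullivan_expectancy(lt, pv1, 62), "not a life-table boundary")
})

test_that("the decomposition identities match the published report rows", {
  # women at birth
  w0 <- health_expectancy_summary(70.7, 58.1)
  expect_equal(unname(w0$rounded), c(12.6, 82.2))
  # men at birth
  m0 <- health_expectancy_summary(67.6, 58.5)
  expect_equal(unname(m0$rounded), c(9.1, 86.5))
  # women at older age
  w1 <- health_expectancy_summary(12.5, 5.9)
  expect_equal(unname(w1$rounded), c(6.6, 47.2))
  # identity holds unrounded
  expect_equal(w0$years_with_condition + 58.1, 70.7)
  expect_error(health_expectancy_summary(10, 11), "free_LE")
  expect_error(health_expectancy_summary(0, 0), "positive")
})

test_that("cohort status indicators come with CIs and differences", {
  coh <- data.frame(sex = rep(c("male", "female"), each = 200),
                    living_alone = 0, employed = 1, earning = 1,
                    adl_able = 1, healthcare = 0)
  ind <- cohort_indicators(coh)
  expect_equal(ind$male[ind$indicator == "living_alone"], 0)
  expect_equal(ind$female[ind$indicator == "living_alone"], 0)
  expect_equal(ind$difference[ind$indicator == "employed"], 0)

  p <- cohort_profile(n_per_sex = 10000, seed = 31)
  ind2 <- cohort_indicators(generate_survey_cohort(p))
  la <- ind2[ind2$indicator == "living_alone", ]
  expect_within(la$female, 68.5, 3 * sqrt(0.685 * 0.315 / 10000) * 100)
  expect_within(la$male, 8.9, 3 * sqrt(0.089 * 0.911 / 10000) * 100)

  # CI width shrinks like 1/sqrt(n)
  p_small <- cohort_profile(n_per_sex = 2500, seed = 31)
  ind3 <- cohort_indicators(generate_survey_cohort(p_small))
  w_small <- with(ind3[ind3$indicator == "living_alone", ], female_hi - female_lo)
  w_big <- with(la, female_hi - female_lo)
  expect_within(w_small / w_big, 2, 0.25)

  expect_error(cohort_indicators(coh[coh$sex == "male", ]), "empty stratum")
})
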