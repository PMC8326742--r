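test_that("GDS-15 scoring matches the questionnaire keying", {
  # all answers in the non-depressed direction: reverse items yes, rest no
  well <- ifelse(table_gds_yes_points == 0, 1, 0)
  s <- score_gds15(well)
  expect_equal(s$total, 0)
  expect_equal(as.character(s$category), "normal")

  # all answers in the depressed direction
  depressed <- table_gds_yes_points
  s2 <- score_gds15(depressed)
  expect_equal(s2$total, 15)
  expect_equal(as.character(s2$category), "indicative")

  expect_error(score_gds15(rep(1, 14)), "15 items")
  expect_error(score_gds15(c(rep(1, 14), 2)), "outside")
})

test_that("GDS categories follow the published cutpoints", {
  mk <- function(total) {
    r <- ifelse(table_gds_yes_points == 0, 1, 0)      # start at 0
    flip <- which(table_gds_yes_points == 1)[seq_len(total)]
    r[flip] <- 1
    r
  }
  expect_equal(as.character(score_gds15(mk(5))$category), "normal")
  expect_equal(as.character(score_gds15(mk(6))$category), "suggestive")
  expect_equal(as.character(score_gds15(mk(9))$category), "suggestive")
  expect_equal(as.character(score_gds15(mk(10))$category), "indicative")
})

test_that("random GDS patterns agree with a brute-force scorer", {
  set.seed(404)
  pats <- matrix(sample(0:1, 1000 * 15, replace = TRUE), 1000, 15)
  expect_equal(score_gds15(pats)$total, brute_score(pats, table_gds_yes_points))
})

test_that("all 64 loneliness patterns agree with a brute-force scorer", {
  pats <- as.matrix(expand.grid(rep(list(0:1), 6)))
  s <- score_loneliness6(pats)
  expect_equal(s$total, brute_score(pats, table_lon_yes_points))
  expect_equal(s$total, s$emotional + s$social)
  expect_true(all(s$emotional >= 0 & s$emotional <= 3))

  # the maximally lonely pattern keys every item
  expect_equal(score_loneliness6(c(1, 0, 0, 1, 0, 1))$total, 6)
  # plenty of people to rely on contributes nothing
  with_support <- score_loneliness6(c(1, 1, 0, 1, 0, 1))
  expect_equal(with_support$total, 5)
})

test_that("WHOQOL-BREF domain scores honour mode and reverse keying", {
  floor_case <- score_whoqol_bref(rep(5, 26), mode = "transformed_4_20")
  # items 3, 4 and 26 are reverse-coded, so all-5 is not the ceiling there
  expect_equal(floor_case$social, 20)
  expect_equal(floor_case$environmental, 20)

  no_rev <- rep(5, 26); no_rev[c(3, 4, 26)] <- 1   # recoded to 5 throughout
  expect_equal(unlist(score_whoqol_bref(no_rev, "transformed_4_20")[1, 1:4],
                      use.names = FALSE), rep(20, 4))
  expect_equal(unlist(score_whoqol_bref(no_rev, "transformed_0_100")[1, 1:4],
                      use.names = FALSE), rep(100, 4))

  all_low <- rep(1, 26); all_low[c(3, 4, 26)] <- 5
  expect_equal(unlist(score_whoqol_bref(all_low, "transformed_4_20")[1, 1:4],
                      use.names = FALSE), rep(4, 4))
  expect_equal(unlist(score_whoqol_bref(all_low, "raw_sum")[1, 1:4],
                      use.names = FALSE), c(7, 6, 3, 8))

  # hand-computed physical domain: reverse items raw 2 -> 4, giving
  # recoded (4, 4, 4, 3, 4, 5, 4), mean 4.0, transformed 16
  r <- rep(3, 26)
  r[c(3, 4)] <- 2
  r[c(10, 15, 16, 17, 18)] <- c(4, 3, 4, 5, 4)
  expect_equal(score_whoqol_bref(r, "transformed_4_20")$physical, 16)

  expect_error(score_whoqol_bref(rep(3, 25)), "26 items")
  expect_error(score_whoqol_bref(rep(6, 26)), "outside")
})

test_that("WHOQOL missing-item policy: mean substitution up to 20%", {
  r <- rep(4, 26)
  r[c(3, 4, 26)] <- 2               # reverse-keyed items recode back to 4
  r[10] <- NA                       # 1 of 7 physical items (14%)
  s <- score_whoqol_bref(r, "transformed_4_20")
  expect_equal(s$physical, 16)      # substituted with the domain mean
  r[20] <- NA                       # 1 of 3 social items (33%)
  s2 <- score_whoqol_bref(r, "transformed_4_20")
  expect_true(is.na(s2$social))
})

test_that("binary scale proration mirrors the 20% rule", {
  r <- table_gds_yes_points          # full depressed pattern, total 15
  r[1:3] <- NA                       # 20% missing: prorated
  expect_equal(score_gds15(r)$total, 12 * 15 / 12)
  r[4] <- NA                         # > 20%: invalid
  expect_true(is.na(score_gds15(r)$total))
})

test_that("Cronbach alpha matches closed-form oracles", {
  # identical items: perfect internal consistency
  x <- matrix(rep(rnorm(50), 4), ncol = 4)
  expect_equal(cronbach_alpha(x)$alpha, 1, tolerance = 1e-12)

  # two standardized items with exact sample correlation 0.5:
  # Spearman-Brown gives alpha = 2 * 0.5 / 1.5
  set.seed(1)
  a <- scale(rnorm(400))[, 1]
  b0 <- rnorm(400)
  b0 <- scale(resid(lm(b0 ~ a)))[, 1]         # exactly orthogonal to a
  y <- 0.5 * a + sqrt(0.75) * b0
  m <- cbind(a, y)
  expect_equal(cor(m)[1, 2], 0.5, tolerance = 1e-10)
  expect_equal(cronbach_alpha(m)$alpha, 2 * 0.5 / 1.5, tolerance = 1e-10)

  # independent items: alpha near zero
  set.seed(2)
  z <- matrix(rnorm(5000 * 6), ncol = 6)
  expect_within(cronbach_alpha(z)$alpha, 0, 0.06)

  expect_error(cronbach_alpha(matrix(1, 10, 3)), "zero total-score variance")
  expect_error(cronbach_alpha(matrix(rnorm(10), ncol = 1)), "2 items")
})

test_that("Feldt interval brackets the estimate and tightens with n", {
  r <- generate_item_responses(500, "gds15", seed = 3)
  ca <- cronbach_alpha(r)
  expect_true(ca$ci[1] < ca$alpha && ca$alpha < ca$ci[2])
  r2 <- generate_item_responses(4000, "gds15", seed = 3)
  ca2 <- cronbach_alpha(r2)
  expect_lt(diff(ca2$ci), diff(ca$ci))
})

test_that("generated responses recover the instrument's target alpha", {
  r <- generate_item_responses(5000, "loneliness6",
                               item_model = list(target_alpha = 0.83), seed = 12)
  expect_within(cronbach_alpha(r)$alpha, 0.83, 0.02)
})
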