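test_that("pearson_r matches the covariance formula and its limits", {
  x <- c(1, 2, 3, 4)
  expect_equal(as.numeric(pearson_r(x, 2 * x + 1)), 1)
  expect_equal(as.numeric(pearson_r(x, -x)), -1)

  y <- c(2, 1, 4, 3)
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(as.numeric(pearson_r(x, y)), hand)

  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_r(1:2, 2:3), "at least 3")
})

test_that("Lin's CCC penalises location shift that r ignores", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(lin_ccc(x, x)$coefficient, 1)

  expect_equal(lin_ccc(c(1, 2, 3), c(2, 3, 4))$coefficient, 4 / 7)

  shifted <- lin_ccc(x, x + 1000)
  expect_equal(as.numeric(pearson_r(x, x + 1000)), 1)
  expect_lt(shifted$coefficient, 0.01)
})

test_that("CCC never exceeds |r| (Lin's inequality)", {
  set.seed(42)
  for (i in 1:1000) {
    n <- sample(5:40, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 3))
    y <- runif(1, -2, 2) * x + rnorm(n, runif(1, -3, 3), runif(1, 0.5, 2))
    cc <- lin_ccc(x, y)$coefficient
    r <- abs(as.numeric(pearson_r(x, y)))
    expect_lte(cc, r + 1e-12)
  }
})

test_that("one-way ICC matches REML variance components on balanced data", {
  skip_if_not_installed("lme4")
  d <- simulate_repeated_measures(20, 3, var_subject = 50, var_error = 10,
                                  grand_mean = 70, seed = 9)
  ic <- icc_oneway(d$subject, d$value)
  fit <- lme4::lmer(value ~ 1 + (1 | subject), data = d, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))$vcov
  expect_equal(ic$var_subject, vc[1], tolerance = 1e-6)
  expect_equal(ic$var_error, vc[2], tolerance = 1e-6)
  expect_equal(ic$coefficient, vc[1] / sum(vc), tolerance = 1e-6)
  expect_lte(ic$ci_lower, ic$coefficient)
  expect_gte(ic$ci_upper, ic$coefficient)
})

test_that("ICC handles degenerate and unbalanced designs", {
  # identical within-subject values, distinct subjects: perfect reliability
  subj <- rep(letters[1:5], each = 3)
  vals <- rep(c(10, 20, 30, 40, 50), each = 3)
  expect_equal(icc_oneway(subj, vals)$coefficient, 1)

  # single-occasion data carries no reliability information
  expect_error(icc_oneway(letters[1:6], rnorm(6)),
               "insufficient replication")

  # unbalanced data (some subjects with 2, some 3 occasions) still works
  d <- simulate_repeated_measures(12, 3, 30, 10, 0, seed = 3)
  d <- d[-c(3, 6, 9), ]
  ic <- icc_oneway(d$subject, d$value)
  expect_true(ic$coefficient > 0 && ic$coefficient < 1)
  expect_gte(ic$var_subject, 0)
})

test_that("Bland-Altman summaries obey their arithmetic identities", {
  x <- c(3, 7, 1, 9)
  same <- bland_altman(x, x)
  expect_equal(same$d, 0)
  expect_equal(same$s, 0)
  expect_equal(unname(c(same$upper, same$lower)), c(0, 0))
  expect_true(is.na(same$cv))

  y <- c(2.5, 7.4, 0.3, 10)
  ab <- bland_altman(x, y)
  ba <- bland_altman(y, x)
  expect_equal(ba$d, -ab$d)
  expect_equal(unname(ba$upper), -unname(ab$lower))
  expect_equal(unname(ba$lower), -unname(ab$upper))
  expect_equal(ba$width, ab$width)
  expect_equal(unname(ab$width), 2 * 1.96 * ab$s)

  expect_equal(unname(limits_of_agreement(0, 1)),
               c(1.96, -1.96, 3.92))
  expect_equal(unname(limits_of_agreement(5, 0)), c(5, 5, 0))
  expect_error(limits_of_agreement(0, -1), "non-negative")
  expect_error(bland_altman(1, 2), "at least 2")
})

test_that("presentation rounding reproduces published-table conventions", {
  # width is differenced from the rounded limits, half away from zero
  nf <- format_agreement(list(d = -0.64, s = 1.68))
  expect_equal(unname(nf[c("upper", "lower", "width")]),
               c(2.65, -3.93, 6.58))
  expect_equal(round_half_away(c(0.005, -0.005, 2.675), 2),
               c(0.01, -0.01, 2.68))
})

test_that("Landis-Koch categories bracket the published interpretations", {
  expect_equal(landis_koch(0.86), "almost perfect")
  expect_equal(landis_koch(0.69), "substantial")
  expect_equal(landis_koch(1.0), "almost perfect")
  expect_equal(landis_koch(0.80), "substantial")
  expect_equal(landis_koch(0.0), "slight")
  expect_equal(landis_koch(-0.1), "poor")
  expect_error(landis_koch(1.2), "exceed 1")
})
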