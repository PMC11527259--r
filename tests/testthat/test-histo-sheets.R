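test_that("the schema holds exactly 16 parameters of the stated types", {
  schema <- histo_parameters()
  expect_identical(nrow(schema), 16L)
  expect_identical(sum(schema$type == "binary"), 8L)
  expect_identical(sum(schema$type == "ordinal"), 4L)
  expect_identical(sum(schema$in_kappa), 12L)
})

test_that("the validator enforces the 16-parameter contract", {
  co <- simulate_cohort(cohort_spec(1, seed = 1))
  pr <- simulate_score_sheets(co[[1]], 0, seed = 1)
  good <- pr$rater_a$values
  expect_s3_class(score_sheet("b", "A", good), "score_sheet")

  expect_error(score_sheet("b", "A", good[-1]), "16")
  extra <- c(good, list(parakeratosis = "yes"))
  expect_error(score_sheet("b", "A", extra), "16")
  bad <- good; bad$telangiectasia <- "maybe"
  expect_error(score_sheet("b", "A", bad), "telangiectasia")
  bad <- good; bad$matrix_he <- 7
  expect_error(score_sheet("b", "A", bad), "matrix_he")
  bad <- good; bad$pct_cd8_among_cd3 <- 140
  expect_error(score_sheet("b", "A", bad), "pct_cd8_among_cd3")
  bad <- good
  bad$perivascular_cd3_count <- 4; bad$perivascular_cd8_count <- 9
  expect_error(score_sheet("b", "A", bad), "CD8")
  expect_error(score_sheet("b", "A", good, assessment_round = 3),
               "assessment_round")
})

test_that("mean epidermal thickness is the mean of exactly five sites", {
  expect_equal(mean_epidermal_thickness(rep(62, 5)), 62)
  expect_equal(mean_epidermal_thickness(c(50, 60, 70, 80, 90)), 70)
  expect_error(mean_epidermal_thickness(c(50, 60, 70, 80)),
               "5 site measurements")
  expect_error(mean_epidermal_thickness(c(50, 60, 70, 80, -1)),
               "non-negative")
})

test_that("perfect agreement duplicates the truth sheet", {
  co <- simulate_cohort(cohort_spec(4, seed = 3))
  for (s in co) {
    pr <- simulate_score_sheets(s, 24, rater_agreement = 1, seed = 2)
    expect_identical(pr$rater_a$values, pr$rater_b$values)
    expect_identical(pr$rater_a$values, attr(pr, "truth")$values)
  }
})

test_that("degenerate severity-1 probabilities force every binary yes", {
  co <- simulate_cohort(cohort_spec(2, seed = 5), severity = 1)
  pr <- simulate_score_sheets(co[[1]], 0, rater_agreement = 1, seed = 4,
                              binary_p1 = 1)
  binary <- histo_parameters()$parameter[histo_parameters()$type ==
                                           "binary"]
  expect_true(all(unlist(pr$rater_a$values[binary]) == "yes"))
})

test_that("sheets are seed-deterministic, with round-stable truth", {
  co <- simulate_cohort(cohort_spec(2, seed = 8))
  s <- co[[1]]
  p1 <- simulate_score_sheets(s, 0, 0.8, seed = 6)
  p2 <- simulate_score_sheets(s, 0, 0.8, seed = 6)
  expect_identical(sheets_to_df(p1), sheets_to_df(p2))
  r2 <- simulate_score_sheets(s, 0, 0.8, seed = 6, assessment_round = 2)
  expect_identical(attr(p1, "truth")$values, attr(r2, "truth")$values)
  expect_false(identical(p1$rater_a$values, r2$rater_a$values) &&
                 identical(p1$rater_b$values, r2$rater_b$values))
  expect_error(simulate_score_sheets(s, 99, 0.8, seed = 1), "week 99")
})

test_that("realized copy rate matches the agreement parameter", {
  co <- simulate_cohort(cohort_spec(300, visit_weeks = 0L, seed = 12))
  for (a in c(0.6, 0.9)) {
    copied <- vapply(co, function(s)
      mean(attr(simulate_score_sheets(s, 0, a, seed = 17), "copied")),
      numeric(1))
    expect_lt(abs(mean(copied) - a), 0.03)
  }
})

test_that("fully disagreeing raters are independent (kappa near 0)", {
  co <- simulate_cohort(cohort_spec(500, visit_weeks = 0L, seed = 21))
  pairs <- lapply(co, simulate_score_sheets, week = 0,
                  rater_agreement = 0, seed = 9)
  rep <- agreement_report(pairs)
  kap <- rep$inter$kappa[rep$inter$type %in% c("binary", "ordinal")]
  expect_lt(abs(mean(kap, na.rm = TRUE)), 0.05)
})

test_that("binary kappa at 0.8 agreement sits in the oracle band", {
  # independent Monte-Carlo oracle over the generative model: truth is
  # Bernoulli(p(sev)) with logit-linear p, raters copy w.p. a else redraw
  # from the uniform-severity marginal
  p_of <- function(sev) plogis(qlogis(0.08) +
                                 (qlogis(0.92) - qlogis(0.08)) * sev)
  a <- 0.8
  set.seed(99)
  oracle_kappa <- replicate(60, {
    sev <- runif(400)
    truth <- rbinom(400, 1, p_of(sev))
    draw <- function() ifelse(runif(400) < a, truth,
                              rbinom(400, 1, p_of(runif(400))))
    k <- cohens_kappa(draw(), draw())
    k$kappa
  })
  band <- mean(oracle_kappa) + c(-4, 4) * sd(oracle_kappa)

  co <- simulate_cohort(cohort_spec(400, visit_weeks = 0L, seed = 31))
  pairs <- lapply(co, simulate_score_sheets, week = 0,
                  rater_agreement = a, seed = 13)
  rep <- agreement_report(pairs)
  kap <- rep$inter$kappa[rep$inter$type == "binary"]
  expect_gte(mean(kap), band[1])
  expect_lte(mean(kap), band[2])
})
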