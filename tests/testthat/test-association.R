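test_that("spearman handles the textbook permutation cases", {
  expect_equal(spearman_correlation(1:5, (1:5)^3)$rho, 1)
  expect_equal(spearman_correlation(1:5, -(1:5)^3)$rho, -1)
  # sum(d^2) = 6 -> rho = 1 - 36/120 = 0.7
  expect_equal(spearman_correlation(1:5, c(2, 3, 1, 4, 5))$rho, 0.7)
  expect_error(spearman_correlation(1:5, rep(2, 5)), "constant")
  expect_error(spearman_correlation(1:2, 1:2), "3 complete")
})

test_that("spearman matches the closed-form no-ties formula exactly", {
  set.seed(6)
  for (i in 1:25) {
    n <- sample(5:30, 1)
    x <- sample(n); y <- sample(n)
    expect_equal(spearman_correlation(x, y)$rho, spearman_noties(x, y))
  }
})

test_that("binary ordinal logistic reproduces the 2x2 cross-product OR", {
  outcome <- c(rep(0, 30), rep(1, 10), rep(0, 10), rep(1, 30))
  exposure <- c(rep(0, 40), rep(1, 40))
  res <- ordinal_logistic_or(outcome, exposure)
  expect_equal(res$odds_ratio, 9, tolerance = 1e-3)
  expect_lt(res$p, 0.001)
  expect_true(res$ci95[1] < 9 && 9 < res$ci95[2])
})

test_that("the binary path agrees with a Newton-oracle MLE to 1e-4", {
  # saturated 2x2 and a 2x3-style design
  tables <- list(
    list(y = c(rep(0, 30), rep(1, 10), rep(0, 10), rep(1, 30)),
         x = c(rep(0, 40), rep(1, 40))),
    list(y = c(rep(0, 20), rep(1, 5), rep(0, 12), rep(1, 13),
               rep(0, 4), rep(1, 21)),
         x = c(rep(0, 25), rep(1, 25), rep(2, 25))))
  for (tb in tables) {
    res <- ordinal_logistic_or(tb$y, tb$x)
    oracle <- logistic_mle_newton(tb$y, tb$x)
    expect_equal(log(res$odds_ratio), unname(oracle[2]), tolerance = 1e-4)
  }
})

test_that("a null exposure gives an OR near 1 at n = 1000", {
  set.seed(15)
  outcome <- sample(0:3, 1000, replace = TRUE,
                    prob = c(0.3, 0.3, 0.25, 0.15))
  exposure <- rnorm(1000, 20, 8)
  res <- ordinal_logistic_or(outcome, exposure)
  expect_gt(res$odds_ratio, 0.9)
  expect_lt(res$odds_ratio, 1.1)
})

test_that("proportional-odds simulation recovers the true OR", {
  set.seed(23)
  x <- rnorm(2000)
  y <- rpolr(x, beta = log(2), zeta = c(-1, 0.5, 2))
  res <- ordinal_logistic_or(y, x)
  expect_true(res$ci95[1] <= 2 && 2 <= res$ci95[2])
  expect_equal(res$odds_ratio, 2, tolerance = 0.15)
})

test_that("separation is flagged, not fatal", {
  y <- c(rep(0, 20), rep(1, 20))
  x <- c(rnorm(20, -5), rnorm(20, 5))
  expect_warning(res <- ordinal_logistic_or(y, x), "separation")
  expect_true(res$flagged)
  expect_identical(res$odds_ratio, Inf)
  expect_error(ordinal_logistic_or(rep(1, 30), rnorm(30)), "single-level")
})

make_assoc_inputs <- function(n = 200, seed = 33) {
  co <- simulate_cohort(cohort_spec(n, visit_weeks = 0L,
                                    noise_sd_mrss = 0, seed = seed))
  pairs <- lapply(co, simulate_score_sheets, week = 0,
                  rater_agreement = 0.9, seed = seed)
  sev <- vapply(co, function(s) unname(s$severity["0"]), numeric(1))
  ids <- vapply(pairs, function(p) p$rater_a$biopsy_id, "")
  clinical <- data.frame(biopsy_id = ids,
                         mrss_total = vapply(co, mrss_total, week = 0,
                                             numeric(1)))
  set.seed(seed)
  scores <- data.frame(biopsy_id = ids,
                       fibrosis_score = 51 * sev + rnorm(length(sev), 0, 2))
  list(pairs = pairs, clinical = clinical, scores = scores)
}

test_that("severity-linked parameters show ORs above 1 in the report", {
  d <- make_assoc_inputs()
  rep <- association_report(d$pairs, d$clinical, d$scores)
  binary <- histo_parameters()$parameter[histo_parameters()$type ==
                                           "binary"]
  sub <- rep$or_table[rep$or_table$parameter %in% binary &
                        rep$or_table$exposure == "mRSS" &
                        !rep$or_table$flagged, ]
  expect_gt(nrow(sub), 4)
  expect_true(all(sub$or > 1))
  expect_true(all(sub$ci_lo < sub$or & sub$or < sub$ci_hi))
  # correlation between the two scores is strong by construction
  expect_gt(rep$correlation$rho, 0.9)
  # no multiplicity correction, annotated
  expect_match(rep$multiplicity_correction, "none")
})

test_that("the report is deterministic and joins are checked", {
  d <- make_assoc_inputs(n = 40, seed = 44)
  r1 <- association_report(d$pairs, d$clinical, d$scores)
  r2 <- association_report(d$pairs, d$clinical, d$scores)
  expect_identical(r1$or_table, r2$or_table)
  expect_error(association_report(d$pairs, d$clinical[-1, ], d$scores),
               "join failure")
})

test_that("constant parameters are skipped with reasons", {
  vals <- list(epidermal_papilla_loss = "no", eccrine_entrapment = "no",
               eccrine_coil_loss = "no", telangiectasia = "no",
               hair_follicle_loss = "no", calcification = "no",
               subcut_fat_loss_or_widened_septa = "no",
               thickened_intima = "no", matrix_he = 1L,
               matrix_trichrome = 1L, cd34_stain = 1L, asma_stain = 1L,
               mean_epidermal_thickness_um = 60,
               perivascular_cd3_count = 5L, perivascular_cd8_count = 2L,
               pct_cd8_among_cd3 = 40)
  sheets <- unlist(lapply(1:6, function(i) lapply(c("A", "B"), function(r)
    score_sheet(sprintf("b%d", i), r, vals))), recursive = FALSE)
  clinical <- data.frame(biopsy_id = sprintf("b%d", 1:6),
                         mrss_total = seq(10, 35, 5))
  scores <- data.frame(biopsy_id = sprintf("b%d", 1:6),
                       fibrosis_score = seq(8, 33, 5))
  rep <- association_report(sheets, clinical, scores)
  expect_identical(nrow(rep$or_table), 0L)
  expect_identical(nrow(rep$skipped), 32L)
  expect_true(all(rep$skipped$reason == "single observed level"))
})
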