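# Ordinal-logistic odds ratios of histology per unit mRSS / Fibrosis
# Score, and the Spearman correlation between the two scores.

#' Spearman rank correlation
#'
#' Rank correlation with midrank ties and a two-sided p-value
#' (asymptotic t approximation, as appropriate with ties).
#'
#' @param x,y Equal-length numeric vectors (n >= 3).
#' @return A `correlation_result`: rho, p, n.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) abort_field("y", "length must match x")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) abort_field("x", "need at least 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("undefined correlation: constant input vector", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  structure(list(rho = unname(ct$estimate), p = ct$p.value,
                 n = length(x)), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f, p = %.3g, n = %d\n", x$rho, x$p, x$n))
  invisible(x)
}

#' Proportional-odds odds ratio for one histologic parameter
#'
#' Fits a proportional-odds (ordinal logistic) model of the parameter on a
#' single continuous exposure by maximum likelihood and reports the odds
#' ratio per 1-unit exposure change with a Wald 95% CI and p-value. A
#' two-level outcome reduces exactly to ordinary logistic regression.
#' Complete separation yields a flagged result with an infinite-OR
#' sentinel and a warning rather than an error.
#'
#' @param outcome Ordinal or binary vector (factor, character or numeric).
#' @param exposure Numeric vector (mRSS or Fibrosis Score).
#' @param parameter,exposure_name Labels carried into the result.
#' @param conf_level Confidence level for the Wald interval.
#' @return An `or_result`: parameter, exposure, odds_ratio, ci95, p, n,
#'   flagged.
#' @export
ordinal_logistic_or <- function(outcome, exposure,
                                parameter = NA_character_,
                                exposure_name = "exposure",
                                conf_level = 0.95) {
  if (length(outcome) != length(exposure))
    abort_field("exposure", "length must match outcome")
  keep <- !is.na(outcome) & !is.na(exposure)
  outcome <- outcome[keep]; exposure <- as.numeric(exposure[keep])
  lev <- if (is.factor(outcome)) levels(droplevels(factor(outcome)))
         else sort(unique(outcome))
  if (length(lev) < 2L)
    stop("single-level outcome: nothing to model", call. = FALSE)
  y <- ordered(outcome, levels = lev)

  sep <- FALSE
  if (length(lev) == 2L) {
    fit <- withCallingHandlers(
      stats::glm(I(as.integer(y) - 1L) ~ exposure,
                 family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w))) sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    beta <- stats::coef(fit)[["exposure"]]
    se <- sqrt(diag(stats::vcov(fit)))[["exposure"]]
  } else {
    fit <- tryCatch(
      suppressWarnings(MASS::polr(y ~ exposure, Hess = TRUE,
                                  method = "logistic",
                                  control = list(reltol = 1e-8))),
      error = function(e)
        stop("proportional-odds fit failed: ", conditionMessage(e),
             call. = FALSE))
    beta <- stats::coef(fit)[["exposure"]]
    se <- sqrt(diag(stats::vcov(fit)))[["exposure"]]
  }
  if (sep || abs(beta) > 15) {
    warning("complete separation for '", parameter,
            "': odds ratio unbounded", call. = FALSE)
    return(structure(list(parameter = parameter,
                          exposure = exposure_name,
                          odds_ratio = if (beta > 0) Inf else 0,
                          ci95 = c(NA_real_, NA_real_), p = NA_real_,
                          n = length(y), flagged = TRUE),
                     class = "or_result"))
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(parameter = parameter, exposure = exposure_name,
                 odds_ratio = exp(beta),
                 ci95 = exp(c(beta - z * se, beta + z * se)),
                 p = 2 * stats::pnorm(-abs(beta / se)),
                 n = length(y), flagged = FALSE),
            class = "or_result")
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("OR%s per 1-unit %s: %.3f (95%% CI %.3f-%.3f), p = %.3g, n = %d%s\n",
              if (is.na(x$parameter)) "" else paste0(" [", x$parameter, "]"),
              x$exposure, x$odds_ratio, x$ci95[1], x$ci95[2], x$p, x$n,
              if (x$flagged) " [flagged: separation]" else ""))
  invisible(x)
}

#' Rater-consensus values per biopsy and parameter
#'
#' Binary parameters: "yes" iff both raters scored yes (default), or the
#' rule named by `rule`; ordinal and continuous parameters: mean of the two
#' raters' values.
#'
#' @param sheets Score sheets (as in [agreement_report()]).
#' @param rule Discordant-binary rule: `"both_yes"` (default),
#'   `"either_yes"`, or `"rater_a"`.
#' @return Wide data frame: biopsy_id plus one numeric column per
#'   parameter (binary as 0/1).
#' @export
consensus_sheets <- function(sheets, rule = c("both_yes", "either_yes",
                                              "rater_a")) {
  rule <- match.arg(rule)
  df <- .sheet_long(sheets)
  df <- df[df$assessment_round == 1L & df$rater_id != "truth", ]
  raters <- sort(unique(df$rater_id))
  if (length(raters) != 2L)
    stop("consensus requires exactly two raters; found: ",
         paste(raters, collapse = ", "), call. = FALSE)
  schema <- histo_parameters()
  ids <- sort(unique(df$biopsy_id))
  out <- data.frame(biopsy_id = ids)
  for (i in seq_len(nrow(schema))) {
    p <- schema$parameter[i]
    a <- df$value[df$parameter == p & df$rater_id == raters[1]][
      match(ids, df$biopsy_id[df$parameter == p &
                                df$rater_id == raters[1]])]
    b <- df$value[df$parameter == p & df$rater_id == raters[2]][
      match(ids, df$biopsy_id[df$parameter == p &
                                df$rater_id == raters[2]])]
    out[[p]] <- if (schema$type[i] == "binary") {
      switch(rule,
             both_yes = as.numeric(a == "yes" & b == "yes"),
             either_yes = as.numeric(a == "yes" | b == "yes"),
             rater_a = as.numeric(a == "yes"))
    } else (as.numeric(a) + as.numeric(b)) / 2
  }
  out
}

.ordinalize <- function(v, type, max_levels = 12L) {
  u <- sort(unique(v[!is.na(v)]))
  if (length(u) <= max_levels) return(ordered(v, levels = u))
  br <- unique(stats::quantile(v, probs = seq(0, 1, 0.1), na.rm = TRUE))
  cut(v, breaks = br, include.lowest = TRUE, ordered_result = TRUE)
}

#' Histology association report against mRSS and Fibrosis Score
#'
#' For every schema parameter and both exposures, fits the
#' proportional-odds model of the rater-consensus parameter on the
#' exposure and tabulates the per-1-unit odds ratio. Continuous parameters
#' with many distinct values are binned into decile categories before the
#' ordinal fit. Single-level parameters are skipped and listed. No
#' multiple-testing correction is applied (exploratory analysis); the 0.05
#' significance threshold is annotated on the table.
#'
#' @param sheets Score sheets for all biopsies (two raters).
#' @param clinical Data frame biopsy_id, mrss_total.
#' @param scores Data frame biopsy_id, fibrosis_score (as returned by
#'   `predict()` on a list of QIF matrices).
#' @param rule Binary consensus rule, see [consensus_sheets()].
#' @param alpha Annotated significance threshold.
#' @return An `association_report`: `or_table`, `correlation`, `skipped`.
#' @export
association_report <- function(sheets, clinical, scores,
                               rule = "both_yes", alpha = 0.05) {
  cons <- consensus_sheets(sheets, rule = rule)
  for (nm in c("clinical", "scores")) {
    d <- get(nm)
    orphan <- setdiff(cons$biopsy_id, d$biopsy_id)
    if (length(orphan))
      stop("join failure: no ", nm, " record for biopsy_id ",
           paste(orphan, collapse = ", "), call. = FALSE)
  }
  cons$mRSS <- clinical$mrss_total[match(cons$biopsy_id,
                                         clinical$biopsy_id)]
  cons$FibrosisScore <- scores$fibrosis_score[match(cons$biopsy_id,
                                                    scores$biopsy_id)]
  schema <- histo_parameters()
  rows <- list(); skipped <- list()
  for (i in seq_len(nrow(schema))) {
    p <- schema$parameter[i]
    v <- cons[[p]]
    for (ex in c("mRSS", "FibrosisScore")) {
      n_lev <- length(unique(v[!is.na(v)]))
      if (n_lev < 2L) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(parameter = p, exposure = ex,
                     reason = "single observed level")
        next
      }
      res <- tryCatch(
        ordinal_logistic_or(.ordinalize(v, schema$type[i]), cons[[ex]],
                            parameter = p, exposure_name = ex),
        error = function(e) conditionMessage(e))
      if (is.character(res)) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(parameter = p, exposure = ex, reason = res)
        next
      }
      rows[[length(rows) + 1L]] <-
        data.frame(parameter = p, exposure = ex, or = res$odds_ratio,
                   ci_lo = res$ci95[1], ci_hi = res$ci95[2], p = res$p,
                   n = res$n,
                   flagged = res$flagged)
    }
  }
  or_table <- if (length(rows)) do.call(rbind, rows)
  else data.frame(parameter = character(), exposure = character(),
                  or = numeric(), ci_lo = numeric(), ci_hi = numeric(),
                  p = numeric(), n = integer(), flagged = logical())
  skipped <- if (length(skipped)) do.call(rbind, skipped)
  else data.frame(parameter = character(), exposure = character(),
                  reason = character())
  correlation <- spearman_correlation(cons$mRSS, cons$FibrosisScore)
  structure(list(or_table = or_table, correlation = correlation,
                 skipped = skipped, alpha = alpha,
                 multiplicity_correction = "none (exploratory)"),
            class = "association_report")
}

#' @export
print.association_report <- function(x, ...) {
  cat(sprintf("Histology association report (alpha = %.2f, %s)\n",
              x$alpha, x$multiplicity_correction))
  cat("mRSS vs Fibrosis Score: ")
  print(x$correlation)
  if (nrow(x$or_table)) {
    tab <- x$or_table
    tab$sig <- ifelse(!is.na(tab$p) & tab$p < x$alpha, "*", "")
    print(format(tab, digits = 3), row.names = FALSE)
  }
  if (nrow(x$skipped)) {
    cat("Skipped parameters:\n")
    print(format(x$skipped), row.names = FALSE)
  }
  invisible(x)
}
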