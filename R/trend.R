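# Per-parameter change per week: linear mixed model with random intercept
# and random slope per participant, independent (diagonal) random-effects
# covariance, fit by maximum likelihood.

#' Estimate change per week with a mixed-effects model
#'
#' Fits `value ~ week + (1 + week || subject_id)` by maximum likelihood
#' (uncorrelated random intercept and slope per participant) and returns
#' the fixed-effect week coefficient, its standard error and a Wald
#' p-value. Degenerate inputs with zero variance short-circuit to a zero
#' slope; if the mixed fit fails (for example, with too few repeated
#' measures per subject for the random slope), an ordinary least-squares
#' slope is returned with a note.
#'
#' @param long_scores Data frame with columns subject_id, week, value (and
#'   optionally rater_id; raters are pooled as repeated measures).
#' @return A `week_trend`: slope (per week), std_err, p, n_subjects,
#'   method.
#' @export
change_per_week <- function(long_scores) {
  stopifnot(is.data.frame(long_scores),
            all(c("subject_id", "week", "value") %in% names(long_scores)))
  d <- long_scores[!is.na(long_scores$value), ]
  d$value <- as.numeric(d$value)
  if (length(unique(d$week)) < 2L || length(unique(d$subject_id)) < 2L)
    stop("insufficient repeated measures: need >= 2 weeks and >= 2 ",
         "subjects (have ", length(unique(d$week)), " week(s), ",
         length(unique(d$subject_id)), " subject(s))", call. = FALSE)
  if (stats::var(d$value) == 0)
    return(structure(list(slope = 0, std_err = 0, p = NA_real_,
                          n_subjects = length(unique(d$subject_id)),
                          method = "constant"), class = "week_trend"))
  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      lme4::lmer(value ~ week + (1 + week || subject_id), data = d,
                 REML = FALSE,
                 control = lme4::lmerControl(
                   check.conv.singular = "ignore")))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    co <- summary(fit)$coefficients
    slope <- co["week", "Estimate"]; se <- co["week", "Std. Error"]
    method <- "lmm"
  } else {
    ols <- summary(stats::lm(value ~ week, data = d))$coefficients
    slope <- ols["week", "Estimate"]; se <- ols["week", "Std. Error"]
    method <- "ols_fallback"
  }
  p <- if (se > 0) 2 * stats::pnorm(-abs(slope / se)) else NA_real_
  structure(list(slope = slope, std_err = se, p = p,
                 n_subjects = length(unique(d$subject_id)),
                 method = method), class = "week_trend")
}

#' @export
print.week_trend <- function(x, ...) {
  cat(sprintf("change/week: %.4g (SE %.3g, p = %.3g, %d subjects, %s)\n",
              x$slope, x$std_err, x$p, x$n_subjects, x$method))
  invisible(x)
}

#' Change-per-week table over all numeric-codable parameters
#'
#' Binary parameters are coded yes = 1 / no = 0; ordinal and continuous
#' parameters enter on their scored scale. Each parameter is fit with
#' [change_per_week()] over all raters' round-1 values.
#'
#' @param sheets Score sheets (as in [agreement_report()]).
#' @param biopsy_map Data frame biopsy_id, subject_id, week.
#' @return Data frame: parameter, slope_per_week, se, p, n_subjects.
#' @export
parameter_trends <- function(sheets, biopsy_map) {
  df <- .sheet_long(sheets)
  df <- df[df$assessment_round == 1L & df$rater_id != "truth", ]
  df <- merge(df, biopsy_map, by = "biopsy_id")
  schema <- histo_parameters()
  do.call(rbind, lapply(seq_len(nrow(schema)), function(i) {
    p <- schema$parameter[i]
    sub <- df[df$parameter == p, ]
    val <- if (schema$type[i] == "binary")
      ifelse(sub$value == "yes", 1, 0) else as.numeric(sub$value)
    tr <- tryCatch(
      change_per_week(data.frame(subject_id = sub$subject_id,
                                 week = sub$week, value = val)),
      error = function(e) NULL)
    if (is.null(tr))
      data.frame(parameter = p, slope_per_week = NA_real_, se = NA_real_,
                 p = NA_real_, n_subjects = NA_integer_)
    else
      data.frame(parameter = p, slope_per_week = tr$slope, se = tr$std_err,
                 p = tr$p, n_subjects = tr$n_subjects)
  }))
}
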