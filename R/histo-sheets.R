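# The 16-parameter SSc dermatopathology schema, score-sheet validation,
# and the paired-rater score-sheet simulator.

#' The 16-parameter dermatopathology schema
#'
#' Eight binary (yes/no) parameters, four ordinal parameters scored against
#' a standard image set (default range 0-3; the range is a convention of
#' this package, configurable via `ordinal_max`), one continuous parameter
#' (mean epidermal thickness, the average of five site measurements in um)
#' and three perivascular lymphocyte parameters (CD3+ count, CD8+ count,
#' and %CD8+ among CD3+). Excluded historical parameters (parakeratosis,
#' pigment incontinence, epidermal pigmentation, lymphocyte exocytosis,
#' mucin) have no fields.
#'
#' @param ordinal_max Upper bound of the standard-image ordinal range.
#' @return Data frame: parameter, type, lo, hi, in_kappa.
#' @export
histo_parameters <- function(ordinal_max = 3L) {
  check_number(ordinal_max, "ordinal_max", lo = 1, integer = TRUE)
  binary <- c("epidermal_papilla_loss", "eccrine_entrapment",
              "eccrine_coil_loss", "telangiectasia", "hair_follicle_loss",
              "calcification", "subcut_fat_loss_or_widened_septa",
              "thickened_intima")
  ordinal <- c("matrix_he", "matrix_trichrome", "cd34_stain", "asma_stain")
  rbind(
    data.frame(parameter = binary, type = "binary", lo = 0, hi = 1,
               in_kappa = TRUE),
    data.frame(parameter = ordinal, type = "ordinal", lo = 0,
               hi = ordinal_max, in_kappa = TRUE),
    data.frame(parameter = "mean_epidermal_thickness_um",
               type = "continuous", lo = 0, hi = Inf, in_kappa = FALSE),
    data.frame(parameter = c("perivascular_cd3_count",
                             "perivascular_cd8_count"),
               type = "count", lo = 0, hi = Inf, in_kappa = FALSE),
    data.frame(parameter = "pct_cd8_among_cd3", type = "percent",
               lo = 0, hi = 100, in_kappa = FALSE))
}

#' Mean epidermal thickness from five site measurements
#'
#' Epidermal thickness is measured in micrometres at five randomly selected
#' sites on the biopsy and averaged.
#'
#' @param measurements Exactly five non-negative values (um).
#' @return Their arithmetic mean.
#' @export
mean_epidermal_thickness <- function(measurements) {
  if (length(measurements) != 5L)
    abort_field("measurements", "exactly 5 site measurements are required")
  if (!is.numeric(measurements) || any(!is.finite(measurements)) ||
      any(measurements < 0))
    abort_field("measurements", "must be non-negative numbers")
  mean(measurements)
}

#' Construct and validate a score sheet
#'
#' One rater's values for the 16 dermatopathology parameters on one biopsy
#' at one assessment round. Validation enforces: exactly the 16 schema
#' parameters, binary values in yes/no, ordinal values within the
#' standard-set range, percent in 0-100, and CD8+ count <= CD3+ count when
#' both are present.
#'
#' @param biopsy_id,rater_id Identifiers.
#' @param values Named list of the 16 parameter values (binary as
#'   "yes"/"no").
#' @param assessment_round 1 or 2 (intra-rater repeats).
#' @param ordinal_max Standard-image ordinal range upper bound.
#' @return A `score_sheet`.
#' @export
score_sheet <- function(biopsy_id, rater_id, values, assessment_round = 1L,
                        ordinal_max = 3L) {
  schema <- histo_parameters(ordinal_max)
  if (!setequal(names(values), schema$parameter) ||
      length(values) != nrow(schema))
    stop("score sheet must contain exactly the 16 schema parameters; got ",
         length(values), " (missing: ",
         paste(setdiff(schema$parameter, names(values)), collapse = ", "),
         "; extra: ",
         paste(setdiff(names(values), schema$parameter), collapse = ", "),
         ")", call. = FALSE)
  if (!assessment_round %in% 1:2)
    abort_field("assessment_round", "must be 1 or 2")
  for (i in seq_len(nrow(schema))) {
    p <- schema$parameter[i]; v <- values[[p]]
    if (is.null(v) || length(v) != 1L || (!is.na(v) && schema$type[i] ==
        "binary" && !v %in% c("yes", "no")))
      abort_field(p, "binary parameters must be 'yes' or 'no'")
    if (schema$type[i] != "binary" && !is.na(v)) {
      if (!is.numeric(v) || v < schema$lo[i] || v > schema$hi[i])
        abort_field(p, sprintf("must be numeric in [%s, %s]",
                               schema$lo[i], schema$hi[i]))
      if (schema$type[i] %in% c("ordinal", "count") && v != round(v))
        abort_field(p, "must be an integer")
    }
  }
  cd3 <- values$perivascular_cd3_count
  cd8 <- values$perivascular_cd8_count
  if (!is.na(cd3) && !is.na(cd8) && cd8 > cd3)
    abort_field("perivascular_cd8_count", "CD8+ count exceeds CD3+ count")
  structure(list(biopsy_id = biopsy_id, rater_id = rater_id,
                 assessment_round = as.integer(assessment_round),
                 values = values[schema$parameter],
                 ordinal_max = as.integer(ordinal_max)),
            class = "score_sheet")
}

#' @export
print.score_sheet <- function(x, ...) {
  cat(sprintf("score_sheet: biopsy %s, rater %s, round %d\n",
              x$biopsy_id, x$rater_id, x$assessment_round))
  v <- vapply(x$values, function(v) format(v), "")
  cat(paste0("  ", format(names(v)), " ", v, "\n"), sep = "")
  invisible(x)
}

# Generative ("truth") sheet values at a given severity. Binary parameters:
# P(yes) interpolates p0 -> p1 on the logit scale (linear in severity).
# Ordinal: thresholded severity plus noise. Thickness decreases with
# severity (epidermal atrophy); perivascular counts increase.
.truth_values <- function(severity, binary_p0, binary_p1, ordinal_max) {
  schema <- histo_parameters(ordinal_max)
  vals <- list()
  p_yes <- .binary_p(severity, binary_p0, binary_p1)
  for (p in schema$parameter[schema$type == "binary"])
    vals[[p]] <- if (stats::runif(1) < p_yes) "yes" else "no"
  for (p in schema$parameter[schema$type == "ordinal"])
    vals[[p]] <- as.integer(pmin(pmax(round(
      ordinal_max * severity + stats::rnorm(1, 0, 0.35)), 0), ordinal_max))
  vals$mean_epidermal_thickness_um <- mean_epidermal_thickness(
    pmax(75 - 25 * severity + stats::rnorm(5, 0, 4), 0))
  cd3 <- stats::rpois(1, 5 + 25 * severity)
  cd8 <- stats::rbinom(1, cd3, 0.2 + 0.4 * severity)
  vals$perivascular_cd3_count <- cd3
  vals$perivascular_cd8_count <- cd8
  vals$pct_cd8_among_cd3 <- if (cd3 > 0) 100 * cd8 / cd3 else 0
  vals
}

.binary_p <- function(severity, p0, p1) {
  if (p0 <= 0 || p1 >= 1) {
    # degenerate endpoints: linear interpolation keeps exact 0/1
    p0 + (p1 - p0) * severity
  } else stats::plogis(stats::qlogis(p0) +
                         (stats::qlogis(p1) - stats::qlogis(p0)) * severity)
}

#' Simulate a paired-rater score sheet for one biopsy
#'
#' A generative "truth" sheet is drawn at the subject's latent severity for
#' the requested week: binary parameter probabilities and ordinal /
#' continuous means are monotone in severity. Each of two blinded raters
#' then reproduces each truth value with probability `rater_agreement`, and
#' otherwise re-draws the parameter from its severity-free population
#' marginal (the parameter's distribution at a freshly drawn uniform
#' severity), so fully disagreeing raters are statistically independent.
#' Deterministic for a fixed seed.
#'
#' @param subject An `ssc_subject` from [simulate_cohort()].
#' @param week A week in `subject$visit_weeks`.
#' @param rater_agreement Copy probability in \[0, 1\].
#' @param seed Integer seed.
#' @param assessment_round 1 or 2.
#' @param binary_p0,binary_p1 P(yes) of every binary parameter at severity
#'   0 and 1.
#' @param ordinal_max Ordinal range upper bound.
#' @return A `score_sheet_pair`: list of two `score_sheet`s (raters "A" and
#'   "B"), with the truth sheet in `attr(, "truth")` and the realized copy
#'   indicators (16 x 2 logical matrix) in `attr(, "copied")`.
#' @export
simulate_score_sheets <- function(subject, week, rater_agreement = 0.8,
                                  seed = 1L, assessment_round = 1L,
                                  binary_p0 = 0.08, binary_p1 = 0.92,
                                  ordinal_max = 3L) {
  stopifnot(inherits(subject, "ssc_subject"))
  key <- as.character(week)
  if (!key %in% names(subject$severity))
    stop("week ", week, " not among visit weeks of ", subject$subject_id,
         call. = FALSE)
  check_number(rater_agreement, "rater_agreement", lo = 0, hi = 1)
  severity <- unname(subject$severity[key])
  biopsy_id <- sprintf("%s_w%02d", subject$subject_id, as.integer(week))
  schema <- histo_parameters(ordinal_max)

  # the truth is a property of the biopsy: identical across rounds, so
  # intra-rater repeats re-score the same slide
  truth <- with_seed(seed_stream(seed, subject$subject_id, week,
                                 "sheet_truth"),
                     .truth_values(severity, binary_p0, binary_p1,
                                   ordinal_max))
  out <- with_seed(seed_stream(seed, subject$subject_id, week,
                               "sheet_raters", assessment_round), {
    copied <- matrix(NA, nrow(schema), 2L,
                     dimnames = list(schema$parameter, c("A", "B")))
    raters <- lapply(1:2, function(r) {
      vals <- truth
      for (i in seq_len(nrow(schema))) {
        p <- schema$parameter[i]
        copy <- stats::runif(1) < rater_agreement
        copied[i, r] <<- copy
        if (!copy) {
          marg <- .truth_values(stats::runif(1), binary_p0, binary_p1,
                                ordinal_max)
          vals[[p]] <- marg[[p]]
        }
      }
      # keep each rater's sheet internally coherent
      if (vals$perivascular_cd8_count > vals$perivascular_cd3_count)
        vals$perivascular_cd8_count <- vals$perivascular_cd3_count
      vals
    })
    list(truth = truth, raters = raters, copied = copied)
  })
  pair <- list(
    rater_a = score_sheet(biopsy_id, "A", out$raters[[1]], assessment_round,
                          ordinal_max),
    rater_b = score_sheet(biopsy_id, "B", out$raters[[2]], assessment_round,
                          ordinal_max))
  structure(pair, class = "score_sheet_pair",
            truth = score_sheet(biopsy_id, "truth", out$truth,
                                assessment_round, ordinal_max),
            copied = out$copied, severity = severity)
}

#' Flatten score sheets to the long CSV schema
#'
#' @param sheets A `score_sheet`, `score_sheet_pair`, or list of either.
#' @return Data frame: biopsy_id, rater_id, assessment_round, parameter,
#'   value (character).
#' @export
sheets_to_df <- function(sheets) {
  flat <- list()
  collect <- function(s) {
    if (inherits(s, "score_sheet")) flat[[length(flat) + 1L]] <<- s
    else if (inherits(s, "score_sheet_pair")) {
      flat[[length(flat) + 1L]] <<- s$rater_a
      flat[[length(flat) + 1L]] <<- s$rater_b
    } else lapply(s, collect)
  }
  collect(sheets)
  do.call(rbind, lapply(flat, function(s)
    data.frame(biopsy_id = s$biopsy_id, rater_id = s$rater_id,
               assessment_round = s$assessment_round,
               parameter = names(s$values),
               value = vapply(s$values, function(v) as.character(v), ""),
               row.names = NULL)))
}
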