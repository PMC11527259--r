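# Synthetic trial cohorts: latent fibrosis severity driving the 17-site mRSS.

#' The 17 mRSS body sites
#'
#' Site labels for the modified Rodnan skin score: each site is scored
#' 0 (normal) to 3 (hidebound), so the total ranges 0-51.
#'
#' @return Character vector of length 17.
#' @export
mrss_sites <- function() {
  c("face", "anterior_chest", "abdomen",
    paste0(rep(c("fingers", "hands", "forearms", "upper_arms",
                 "thighs", "legs", "feet"), each = 2L),
           c("_r", "_l")))
}

# Severity window per site: site s becomes involved as latent severity
# crosses [(s-1)/17, s/17] (sites recruit sequentially). The windows tile
# [0, 1], so the noise-free expected total equals round(51 * severity) to
# within rounding, is monotone non-decreasing in severity, and hits exactly
# 0 at severity 0 and 51 at severity 1.
.site_scores <- function(severity, noise) {
  onset <- (seq_len(17L) - 1L) / 17
  frac <- pmin(pmax((severity - onset) * 17, 0), 1)
  pmin(pmax(round(3 * frac + noise), 0), 3)
}

#' Specify a synthetic SSc cohort
#'
#' Parameters of the generative model used throughout the package's tests:
#' a latent fibrosis severity in \[0, 1\] per subject per visit drives the
#' mRSS, the dermal image texture and the histology sheets jointly.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param visit_weeks Integer visit weeks; biopsy and mRSS visits coincide.
#' @param severity_drift_per_week Mean latent severity change per week
#'   (negative under effective therapy).
#' @param rater_agreement Probability in \[0, 1\] that a rater reproduces the
#'   generative score on any one histology parameter.
#' @param noise_sd_mrss Standard deviation of per-site latent noise added
#'   before thresholding into the 0-3 site score.
#' @param seed Master seed; every subject draws from its own sub-stream.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects,
                        visit_weeks = c(0L, 24L, 52L),
                        severity_drift_per_week = -0.001,
                        rater_agreement = 0.8,
                        noise_sd_mrss = 0.25,
                        seed = 1L) {
  check_number(n_subjects, "n_subjects", lo = 1, integer = TRUE)
  if (length(visit_weeks) < 1L || any(visit_weeks != round(visit_weeks)))
    abort_field("visit_weeks", "must be one or more integer weeks")
  check_number(severity_drift_per_week, "severity_drift_per_week")
  check_number(rater_agreement, "rater_agreement", lo = 0, hi = 1)
  check_number(noise_sd_mrss, "noise_sd_mrss", lo = 0)
  check_number(seed, "seed", integer = TRUE)
  structure(list(n_subjects = as.integer(n_subjects),
                 visit_weeks = as.integer(sort(visit_weeks)),
                 severity_drift_per_week = severity_drift_per_week,
                 rater_agreement = rater_agreement,
                 noise_sd_mrss = noise_sd_mrss,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a cohort of synthetic SSc subjects
#'
#' Each subject receives a baseline severity (uniform on 0.3-0.8, the
#' diffuse-cutaneous range), a linear severity trajectory
#' (`severity_drift_per_week` plus a subject-level random slope), and
#' per-visit 17-site mRSS scores obtained by thresholding site-specific
#' severity windows plus Gaussian noise into 0-3. Deterministic for a fixed
#' seed, and each subject draws from an independent sub-stream, so cohort
#' membership changes never perturb other subjects.
#'
#' @param spec A [cohort_spec()].
#' @param severity Optional fixed severity (single value or one per visit
#'   week) overriding the random trajectory for every subject; used to pin
#'   degenerate cases.
#' @return A list of `ssc_subject` objects, classed `ssc_cohort`.
#' @export
simulate_cohort <- function(spec, severity = NULL) {
  if (!inherits(spec, "cohort_spec"))
    abort_field("spec", "must be a cohort_spec")
  weeks <- spec$visit_weeks
  if (!is.null(severity)) {
    if (any(severity < 0 | severity > 1))
      abort_field("severity", "must lie in [0, 1]")
    severity <- rep_len(severity, length(weeks))
  }
  subjects <- lapply(seq_len(spec$n_subjects), function(i) {
    sid <- sprintf("S%03d", i)
    sev <- if (is.null(severity)) {
      with_seed(seed_stream(spec$seed, sid, "severity"), {
        sev0 <- stats::runif(1, 0.3, 0.8)
        slope <- spec$severity_drift_per_week + stats::rnorm(1, 0, 0.0015)
        pmin(pmax(sev0 + slope * weeks, 0), 1)
      })
    } else severity
    names(sev) <- weeks
    sites <- lapply(seq_along(weeks), function(k) {
      noise <- if (spec$noise_sd_mrss > 0) {
        with_seed(seed_stream(spec$seed, sid, weeks[k], "mrss"),
                  stats::rnorm(17L, 0, spec$noise_sd_mrss))
      } else rep(0, 17L)
      s <- .site_scores(sev[k], noise)
      names(s) <- mrss_sites()
      as.integer(s)
    })
    names(sites) <- weeks
    bseeds <- vapply(weeks, function(w)
      seed_stream(spec$seed, sid, w, "biopsy"), integer(1))
    names(bseeds) <- weeks
    structure(list(subject_id = sid, visit_weeks = weeks, severity = sev,
                   mrss_sites = sites, biopsy_seeds = bseeds),
              class = "ssc_subject")
  })
  structure(subjects, class = "ssc_cohort", spec = spec)
}

#' Total mRSS of a subject at one visit
#'
#' @param subject An `ssc_subject`.
#' @param week A week in `subject$visit_weeks`.
#' @return Integer total in 0-51.
#' @export
mrss_total <- function(subject, week) {
  key <- as.character(week)
  if (!key %in% names(subject$mrss_sites))
    stop("week ", week, " not among visit weeks of ", subject$subject_id,
         call. = FALSE)
  sum(subject$mrss_sites[[key]])
}

#' @export
print.ssc_cohort <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf("Synthetic SSc cohort: %d subjects, visits at weeks %s\n",
              length(x), paste(spec$visit_weeks, collapse = ", ")))
  totals <- vapply(x, function(s) mrss_total(s, s$visit_weeks[1]), numeric(1))
  cat(sprintf("Baseline mRSS: median %.0f (range %.0f-%.0f)\n",
              stats::median(totals), min(totals), max(totals)))
  invisible(x)
}

#' Flatten a cohort to a per-visit data frame
#'
#' @param cohort An `ssc_cohort`.
#' @return Data frame with subject_id, week, severity, mrss_total and one
#'   column per mRSS site.
#' @export
cohort_to_df <- function(cohort) {
  rows <- do.call(rbind, lapply(cohort, function(s) {
    do.call(rbind, lapply(as.character(s$visit_weeks), function(w) {
      sites <- as.list(s$mrss_sites[[w]])
      names(sites) <- paste0("site_", mrss_sites())
      cbind(data.frame(subject_id = s$subject_id, week = as.integer(w),
                       severity = unname(s$severity[w]),
                       mrss_total = sum(s$mrss_sites[[w]])),
            as.data.frame(sites))
    }))
  }))
  rownames(rows) <- NULL
  rows
}
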