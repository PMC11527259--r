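# Cohen's kappa with the published interpretation bands, and the
# inter-/intra-rater agreement report over score sheets.

#' Interpretation band of a kappa value
#'
#' Bands: <= 0 no agreement; 0.01-0.20 none-to-slight; 0.21-0.40 fair;
#' 0.41-0.60 moderate; 0.61-0.80 substantial; 0.81-1.00 almost perfect.
#' The printed bands are defined on two-decimal values, so kappa is rounded
#' to two decimals before banding (0.205 -> 0.21 -> "fair"), which makes
#' the mapping total.
#'
#' @param kappa A kappa value in \[-1, 1\].
#' @return The band label.
#' @export
kappa_category <- function(kappa) {
  check_number(kappa, "kappa", lo = -1, hi = 1)
  # half-up rounding to two decimals (0.205 -> 0.21), with a small epsilon
  # so values printed as x.xx5 are not pulled down by binary representation
  k <- floor(kappa * 100 + 0.5 + 1e-6) / 100
  if (k <= 0) "no agreement"
  else if (k <= 0.20) "none-to-slight"
  else if (k <= 0.40) "fair"
  else if (k <= 0.60) "moderate"
  else if (k <= 0.80) "substantial"
  else "almost perfect"
}

#' Cohen's kappa between two raters
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with the
#' expected agreement `p_e` computed from the two raters' marginal
#' frequencies over the shared category alphabet (the union of observed
#' categories). Pairs with a missing value in either vector are dropped.
#'
#' @param ratings_a,ratings_b Equal-length categorical vectors (>= 2
#'   complete pairs).
#' @param parameter Optional label carried into the result.
#' @return A `kappa_result`: parameter, kappa, category, n_items.
#' @export
cohens_kappa <- function(ratings_a, ratings_b, parameter = NA_character_) {
  if (length(ratings_a) != length(ratings_b))
    abort_field("ratings_b", "must have the same length as ratings_a")
  keep <- !is.na(ratings_a) & !is.na(ratings_b)
  a <- as.character(ratings_a[keep]); b <- as.character(ratings_b[keep])
  n <- length(a)
  if (n < 2L)
    stop("need at least 2 complete rating pairs", call. = FALSE)
  lev <- sort(unique(c(a, b)))
  tab <- table(factor(a, lev), factor(b, lev)) / n
  p_o <- sum(diag(tab))
  p_e <- sum(rowSums(tab) * colSums(tab))
  if (1 - p_e < .Machine$double.eps)
    stop("kappa undefined: expected agreement is 1 (all items in one ",
         "category)", call. = FALSE)
  k <- (p_o - p_e) / (1 - p_e)
  structure(list(parameter = parameter, kappa = k,
                 category = kappa_category(k), n_items = n),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa%s: %.3f (%s), n = %d\n",
              if (is.na(x$parameter)) "" else paste0(" [", x$parameter, "]"),
              x$kappa, x$category, x$n_items))
  invisible(x)
}

.sheet_long <- function(sheets) {
  df <- if (is.data.frame(sheets)) sheets else sheets_to_df(sheets)
  need <- c("biopsy_id", "rater_id", "assessment_round", "parameter",
            "value")
  stopifnot(all(need %in% names(df)))
  df
}

.kappa_or_na <- function(a, b, parameter) {
  tryCatch(cohens_kappa(a, b, parameter),
           error = function(e) list(parameter = parameter,
                                    kappa = NA_real_,
                                    category = "not assessable",
                                    n_items = sum(!is.na(a) & !is.na(b))))
}

#' Inter- and intra-rater agreement over score sheets
#'
#' Binary and ordinal parameters are compared with unweighted Cohen's kappa
#' and banded; continuous parameters (epidermal thickness, lymphocyte
#' counts, %CD8) are excluded from kappa and summarized by the mean
#' absolute difference between raters. Intra-rater agreement compares each
#' rater's two assessment rounds, where present. Parameters whose kappa is
#' undefined (a single observed category, or a missing rater) are marked
#' not assessable.
#'
#' @param sheets Score sheets (any mix of `score_sheet`,
#'   `score_sheet_pair`, lists of them, or an already-long data frame).
#' @return An `agreement_report`: `inter` and `intra` data frames.
#' @export
agreement_report <- function(sheets) {
  df <- .sheet_long(sheets)
  schema <- histo_parameters()
  raters <- setdiff(sort(unique(df$rater_id)), "truth")
  r1 <- df[df$assessment_round == 1L & df$rater_id %in% raters, ]

  inter <- do.call(rbind, lapply(seq_len(nrow(schema)), function(i) {
    p <- schema$parameter[i]
    sub <- r1[r1$parameter == p, ]
    wide <- tryCatch(
      stats::reshape(sub[, c("biopsy_id", "rater_id", "value")],
                     idvar = "biopsy_id", timevar = "rater_id",
                     direction = "wide"),
      error = function(e) NULL)
    cols <- paste0("value.", raters[1:2])
    if (length(raters) < 2L || is.null(wide) ||
        !all(cols %in% names(wide))) {
      return(data.frame(parameter = p, type = schema$type[i],
                        kappa = NA_real_, category = "not assessable",
                        mean_abs_diff = NA_real_, n = 0L))
    }
    a <- wide[[cols[1]]]; b <- wide[[cols[2]]]
    if (schema$in_kappa[i]) {
      k <- .kappa_or_na(a, b, p)
      data.frame(parameter = p, type = schema$type[i], kappa = k$kappa,
                 category = k$category, mean_abs_diff = NA_real_,
                 n = k$n_items)
    } else {
      av <- as.numeric(a); bv <- as.numeric(b)
      keep <- !is.na(av) & !is.na(bv)
      data.frame(parameter = p, type = schema$type[i], kappa = NA_real_,
                 category = "continuous (excluded from kappa)",
                 mean_abs_diff = mean(abs(av[keep] - bv[keep])),
                 n = sum(keep))
    }
  }))

  intra <- do.call(rbind, lapply(raters, function(r) {
    sub <- df[df$rater_id == r, ]
    if (length(unique(sub$assessment_round)) < 2L) return(NULL)
    do.call(rbind, lapply(schema$parameter[schema$in_kappa], function(p) {
      pp <- sub[sub$parameter == p, ]
      wide <- stats::reshape(pp[, c("biopsy_id", "assessment_round",
                                    "value")],
                             idvar = "biopsy_id",
                             timevar = "assessment_round",
                             direction = "wide")
      if (!all(c("value.1", "value.2") %in% names(wide))) return(NULL)
      k <- .kappa_or_na(wide$value.1, wide$value.2, p)
      data.frame(rater_id = r, parameter = p, kappa = k$kappa,
                 category = k$category, n = k$n_items)
    }))
  }))
  if (is.null(intra))
    intra <- data.frame(rater_id = character(), parameter = character(),
                        kappa = numeric(), category = character(),
                        n = integer())
  structure(list(inter = inter, intra = intra), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Inter-rater agreement (round 1):\n")
  print(format(x$inter, digits = 3), row.names = FALSE)
  if (nrow(x$intra)) {
    cat("\nIntra-rater agreement (round 1 vs 2):\n")
    print(format(x$intra, digits = 3), row.names = FALSE)
  } else cat("\nIntra-rater section empty (single assessment round).\n")
  invisible(x)
}
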