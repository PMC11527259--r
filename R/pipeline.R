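# One-config, one-seed orchestration of the full analysis:
# simulate -> sample -> extract -> fit -> score -> agree -> associate.
# Reruns with the same config produce byte-identical CSV/JSON artifacts.

#' Assemble and validate a pipeline run configuration
#'
#' All knobs of one reproducible run. Unknown arguments are rejected (the
#' formals are the schema), every field is validated here, before any
#' compute, and the configuration is serialized to JSON whose MD5 hash
#' stamps the run's manifest.
#'
#' @param outdir Output directory for all artifacts.
#' @param seed Master seed; every stage draws from derived sub-streams.
#' @param n_subjects,visit_weeks,severity_drift_per_week,rater_agreement,noise_sd_mrss
#'   Cohort parameters, see [cohort_spec()].
#' @param image_px,microns_per_pixel Rendered raster geometry.
#' @param n_patches,patch_area_mm2,min_dermis_fraction Patch sampling.
#' @param backend Feature backend name (`"texture"`).
#' @param n_features QIF width.
#' @param grid_n,grid_lo,grid_hi Penalty grid, see [make_lambda_grid()].
#' @param consensus_rule Binary consensus rule for associations.
#' @param alpha Annotated significance threshold.
#' @param write_images Also write rendered TIFFs (slower, larger).
#' @return A `run_config`.
#' @export
run_config <- function(outdir, seed = 1L, n_subjects = 10L,
                       visit_weeks = c(0L, 24L, 52L),
                       severity_drift_per_week = -0.001,
                       rater_agreement = 0.8, noise_sd_mrss = 0.25,
                       image_px = 1024L, microns_per_pixel = 2,
                       n_patches = 100L, patch_area_mm2 = 0.16,
                       min_dermis_fraction = 0.9, backend = "texture",
                       n_features = 256L, grid_n = 16L, grid_lo = 1e-5,
                       grid_hi = 1e3, consensus_rule = "both_yes",
                       alpha = 0.05, write_images = FALSE) {
  check_number(n_patches, "n_patches", lo = 1, integer = TRUE)
  check_number(image_px, "image_px", lo = 1, integer = TRUE)
  check_number(n_features, "n_features", lo = 1, integer = TRUE)
  check_number(patch_area_mm2, "patch_area_mm2", lo = .Machine$double.eps)
  check_number(min_dermis_fraction, "min_dermis_fraction", lo = 0, hi = 1)
  check_number(alpha, "alpha", lo = 0, hi = 1)
  if (!backend %in% "texture")
    abort_field("backend", "only the 'texture' backend is configurable ",
                "here")
  if (!consensus_rule %in% c("both_yes", "either_yes", "rater_a"))
    abort_field("consensus_rule", "unknown rule")
  # cohort parameters validated by cohort_spec
  spec <- cohort_spec(n_subjects, visit_weeks, severity_drift_per_week,
                      rater_agreement, noise_sd_mrss, seed)
  grid <- make_lambda_grid(grid_n, grid_lo, grid_hi)
  structure(list(outdir = outdir, seed = as.integer(seed),
                 cohort = spec, image_px = as.integer(image_px),
                 microns_per_pixel = microns_per_pixel,
                 n_patches = as.integer(n_patches),
                 patch_area_mm2 = patch_area_mm2,
                 min_dermis_fraction = min_dermis_fraction,
                 backend = backend, n_features = as.integer(n_features),
                 grid = grid, consensus_rule = consensus_rule,
                 alpha = alpha, write_images = isTRUE(write_images)),
            class = "run_config")
}

.write_artifact_csv <- function(df, path, config_hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", config_hash), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE)
  path
}

#' Read a pipeline CSV artifact
#'
#' @param path CSV path written by [run_pipeline()].
#' @return Data frame.
#' @export
read_artifact_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Run the full pipeline
#'
#' Executes every stage in dependency order under sub-streams of the master
#' seed and writes all artifacts into `config$outdir`: the serialized
#' config, cohort and biopsy tables, the patch manifest, the fitted model
#' (JSON), Fibrosis Scores, rater score sheets, agreement reports,
#' per-parameter weekly trends, the association table and the mRSS /
#' Fibrosis Score correlation, plus a manifest of artifact MD5 hashes. A
#' stage failure aborts with the stage name after persisting a partial
#' manifest.
#'
#' @param config A [run_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cfg_json <- file.path(out, "config.json")
  cfg <- config
  cfg$grid <- unclass(cfg$grid); cfg$cohort <- unclass(cfg$cohort)
  # the output location is ambient, not part of the scientific
  # configuration: identical configs in different directories must hash
  # identically
  cfg$outdir <- NULL
  jsonlite::write_json(unclass(cfg), cfg_json, auto_unbox = TRUE,
                       digits = NA)
  config_hash <- unname(tools::md5sum(cfg_json))

  artifacts <- c(config = "config.json")
  current_stage <- "init"
  persist_manifest <- function(status) {
    paths <- file.path(out, artifacts)
    jsonlite::write_json(
      list(status = status, config_hash = config_hash,
           artifacts = data.frame(
             name = names(artifacts), path = unname(artifacts),
             md5 = unname(tools::md5sum(paths)))),
      file.path(out, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  stage <- function(name, expr) {
    current_stage <<- name
    tryCatch(expr, error = function(e) {
      persist_manifest(sprintf("failed at stage '%s'", name))
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  emit <- function(name, filename, df) {
    .write_artifact_csv(df, file.path(out, filename), config_hash)
    artifacts[name] <<- filename
  }

  cohort <- stage("simulate", simulate_cohort(config$cohort))
  emit("cohort", "cohort.csv", cohort_to_df(cohort))

  weeks <- config$cohort$visit_weeks
  backend <- texture_backend(config$n_features, seed = config$seed)
  env <- new.env()
  stage("sample_extract", {
    env$qifs <- list(); env$manifests <- list(); env$biopsies <- list()
    for (s in cohort) {
      for (w in weeks) {
        bid <- sprintf("%s_w%02d", s$subject_id, w)
        bseed <- s$biopsy_seeds[[as.character(w)]]
        img <- render_biopsy(unname(s$severity[as.character(w)]),
                             config$microns_per_pixel, config$image_px,
                             config$image_px, seed = bseed)
        if (config$write_images) {
          dir.create(file.path(out, "images"), showWarnings = FALSE)
          write_biopsy_image(img, file.path(out, "images", bid))
        }
        ps <- sample_patches(img, n = config$n_patches,
                             patch_area_mm2 = config$patch_area_mm2,
                             seed = bseed,
                             min_dermis_fraction =
                               config$min_dermis_fraction,
                             biopsy_id = bid)
        env$manifests[[bid]] <- patch_manifest(ps)
        env$qifs[[bid]] <- extract_features(ps, backend)
        env$biopsies[[bid]] <- data.frame(
          biopsy_id = bid, subject_id = s$subject_id, week = w,
          severity = unname(s$severity[as.character(w)]),
          mrss_total = mrss_total(s, w))
      }
    }
  })
  biopsy_map <- do.call(rbind, env$biopsies)
  rownames(biopsy_map) <- NULL
  emit("biopsies", "biopsies.csv", biopsy_map)
  emit("patches", "patches.csv", do.call(rbind, env$manifests))

  model <- stage("fit", fit_fibrosis_model(
    env$qifs,
    stats::setNames(biopsy_map$mrss_total, biopsy_map$biopsy_id),
    stats::setNames(biopsy_map$subject_id, biopsy_map$biopsy_id),
    grid = config$grid, seed = config$seed))
  stage("fit", {
    write_fibrosis_model(model, file.path(out, "model.json"))
    artifacts["model"] <- "model.json"
  })

  scores <- stage("score", {
    sc <- predict(model, env$qifs)
    merge(biopsy_map[, c("biopsy_id", "subject_id", "week")], sc,
          by = "biopsy_id")
  })
  emit("scores", "scores.csv", scores)

  sheets <- stage("sheets", {
    pairs <- list()
    for (s in cohort) for (w in weeks) for (rnd in 1:2)
      pairs[[length(pairs) + 1L]] <- simulate_score_sheets(
        s, w, rater_agreement = config$cohort$rater_agreement,
        seed = config$seed, assessment_round = rnd)
    sheets_to_df(pairs)
  })
  emit("sheets", "sheets.csv", sheets)

  agree <- stage("agree", agreement_report(sheets))
  emit("agreement_inter", "agreement_inter.csv", agree$inter)
  emit("agreement_intra", "agreement_intra.csv", agree$intra)

  trends <- stage("trend", parameter_trends(sheets, biopsy_map))
  emit("trends", "trends.csv", trends)

  assoc <- stage("associate", association_report(
    sheets,
    clinical = biopsy_map[, c("biopsy_id", "mrss_total")],
    scores = scores, rule = config$consensus_rule,
    alpha = config$alpha))
  emit("associations", "associations.csv", assoc$or_table)
  emit("association_skips", "association_skips.csv", assoc$skipped)
  stage("associate", {
    jsonlite::write_json(
      list(rho = assoc$correlation$rho, p = assoc$correlation$p,
           n = assoc$correlation$n, config_hash = config_hash),
      file.path(out, "correlation.json"), auto_unbox = TRUE, digits = NA)
    artifacts["correlation"] <- "correlation.json"
  })

  persist_manifest("complete")
  invisible(jsonlite::read_json(file.path(out, "manifest.json"),
                                simplifyVector = TRUE))
}
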