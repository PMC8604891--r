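#' Evaluate and score a cohort of profiles on a phantom
#'
#' Paints each profile's dose, measures the 16 scheme metrics with the DVH
#' engine and scores them. The workhorse behind [run_challenge()] and the
#' calibration checks; returns everything in memory without touching disk.
#'
#' @param profiles list of `plan_profile`s.
#' @param phantom an [build_phantom()] result.
#' @param scheme a [load_scheme()] result.
#' @param keep_dose keep each painted `dose_grid` in the result (memory-heavy
#'   for large cohorts; default FALSE).
#' @return List with `metrics` (plans x 16 matrix of measured values),
#'   `scorecards` (list), `metadata` (data frame) and optionally `doses`.
#' @export
evaluate_cohort <- function(profiles, phantom, scheme = load_scheme(),
                            keep_dose = FALSE) {
  md <- cohort_metadata(profiles)
  metrics <- matrix(NA_real_, nrow = length(profiles),
                    ncol = length(scheme$metrics),
                    dimnames = list(md$plan_id, names(scheme$metrics)))
  scorecards <- vector("list", length(profiles))
  doses <- if (keep_dose) vector("list", length(profiles)) else NULL
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    dose <- paint_dose(phantom, p)
    vals <- evaluate_plan_metrics(dose, phantom, scheme)
    metrics[i, ] <- vals
    scorecards[[i]] <- score_plan(vals, c(list(plan_id = p$plan_id), p$delivery),
                                  scheme)
    if (keep_dose) doses[[i]] <- dose
  }
  out <- list(metrics = metrics, scorecards = scorecards, metadata = md)
  if (keep_dose) out$doses <- doses
  out
}

#' Run the full planning-challenge pipeline
#'
#' Chains the four stages into one reproducible run: generate (phantom +
#' calibrated cohort of painted dose distributions), evaluate (DVH metrics),
#' score (tiered PQM with gates) and cohort statistics (deviations from
#' ideal thresholds, Spearman correlation matrix, PTV-vs-OAR trade-off
#' fits). All outputs land in `out_dir` with provenance headers and a run
#' manifest listing file hashes; identical configuration and seed give
#' identical numeric outputs. Unacceptable plans are results, not errors.
#'
#' @param out_dir output directory (created if needed).
#' @param n_plans cohort size (default 14, the study's submission count).
#' @param seed integer root seed.
#' @param phantom_path,calibration_path,scheme_path configuration files;
#'   defaults are the shipped ones.
#' @param write_volumes write per-plan NIfTI dose volumes and the label
#'   volume (default TRUE).
#' @param min_stat_n smallest cohort for which the statistics stage runs
#'   (default 4); below it the stage is skipped with a message.
#' @return An object of class `planqm_run`: paths, cohort table, scorecards,
#'   statistics and the manifest, invisibly.
#' @export
run_challenge <- function(out_dir, n_plans = 14, seed = 1L,
                          phantom_path = system.file("extdata", "default_phantom.json", package = "planqm"),
                          calibration_path = system.file("extdata", "table1_calibration.json", package = "planqm"),
                          scheme_path = system.file("extdata", "default_scheme.json", package = "planqm"),
                          write_volumes = TRUE, min_stat_n = 4L) {
  for (p in c(phantom_path, calibration_path, scheme_path))
    if (!file.exists(p)) stop("missing configuration file: ", p, call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hashes <- tools::md5sum(c(phantom_path, calibration_path, scheme_path))
  names(hashes) <- c("phantom", "calibration", "scheme")

  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    message(sprintf("[planqm] %-12s %6.2f s", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    out
  }

  phantom <- stage("generate", {
    build_phantom(load_phantom_spec(phantom_path))
  })
  calibration <- load_calibration(calibration_path)
  scheme <- load_scheme(scheme_path)
  profiles <- sample_cohort_profiles(n_plans, calibration, seed)

  res <- stage("evaluate", {
    evaluate_cohort(profiles, phantom, scheme, keep_dose = write_volumes)
  })

  if (write_volumes) {
    vol_dir <- file.path(out_dir, "volumes")
    dir.create(vol_dir, showWarnings = FALSE)
    write_labels_nifti(phantom$masks, file.path(vol_dir, "structures.nii.gz"))
    for (i in seq_along(res$doses))
      write_dose_nifti(res$doses[[i]],
                       file.path(vol_dir, paste0(res$metadata$plan_id[i], "_dose.nii.gz")))
    res$doses <- NULL
  }

  metrics_df <- cbind(data.frame(plan_id = rownames(res$metrics),
                                 stringsAsFactors = FALSE),
                      as.data.frame(res$metrics))
  write_planqm_csv(metrics_df, file.path(out_dir, "metrics.csv"), seed, hashes)
  write_planqm_csv(res$metadata, file.path(out_dir, "cohort_metadata.csv"),
                   seed, hashes)
  cards_df <- scorecards_to_df(res$scorecards)
  write_planqm_csv(cards_df, file.path(out_dir, "scorecards.csv"), seed, hashes)

  cohort <- build_cohort_table(res$scorecards, res$metadata)
  stats <- NULL
  if (nrow(cohort) >= min_stat_n) {
    stats <- stage("cohort-stats", {
      dev <- deviation_analysis(cohort, scheme)
      cors <- spearman_matrix(cohort[setdiff(names(cohort), c("plan_id", "acceptable"))])
      ptv_ids <- names(scheme$metrics)[vapply(scheme$metrics, `[[`,
                                              character(1), "group") == "PTV"]
      fits <- lapply(ptv_ids, function(y) tradeoff_fit(cohort, "oar_points", y))
      names(fits) <- ptv_ids
      list(deviations = dev, correlations = cors, tradeoffs = fits)
    })
    write_planqm_csv(stats$deviations, file.path(out_dir, "deviations.csv"),
                     seed, hashes)
    write_planqm_csv(as.data.frame(stats$correlations),
                     file.path(out_dir, "correlations.csv"), seed, hashes)
    tr <- do.call(rbind, lapply(names(stats$tradeoffs), function(y)
      data.frame(y = y, x = "oar_points",
                 slope = stats$tradeoffs[[y]]$slope,
                 intercept = stats$tradeoffs[[y]]$intercept,
                 stringsAsFactors = FALSE)))
    write_planqm_csv(tr, file.path(out_dir, "tradeoff.csv"), seed, hashes)
  } else {
    message(sprintf("[planqm] cohort-stats skipped: %d plan(s) < %d",
                    nrow(cohort), min_stat_n))
  }

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    seed = seed, n_plans = n_plans,
    config = as.list(hashes),
    files = stats::setNames(as.list(unname(tools::md5sum(files))),
                            sub(paste0("^", out_dir, "/?"), "", files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(structure(
    list(out_dir = out_dir, cohort = cohort, scorecards = res$scorecards,
         metrics = res$metrics, statistics = stats, manifest = manifest,
         scheme = scheme, phantom = phantom),
    class = "planqm_run"
  ))
}

#' @export
print.planqm_run <- function(x, ...) {
  cat(sprintf("<planqm_run> %d plans -> %s\n", nrow(x$cohort), x$out_dir))
  cat(sprintf("  PQM median %.1f [%.1f-%.1f]; %d/%d acceptable\n",
              stats::median(x$cohort$pqm), min(x$cohort$pqm), max(x$cohort$pqm),
              sum(x$cohort$acceptable), nrow(x$cohort)))
  invisible(x)
}
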