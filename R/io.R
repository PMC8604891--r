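# Volume, table and config IO. Dose and label volumes are NIfTI (spacing in
# the header); label-integer -> structure-name maps live in a JSON sidecar.
# CSVs are UTF-8, comma-separated, '.' decimal, with units embedded in
# column names where applicable, and carry a provenance header as '#'
# comment lines.

#' Write a dose grid as NIfTI
#' @param dose a [dose_grid()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_dose_nifti <- function(dose, path) {
  img <- RNifti::asNifti(dose$values)
  RNifti::pixdim(img) <- dose$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a dose grid from NIfTI
#' @param path NIfTI file path.
#' @return A [dose_grid()].
#' @export
read_dose_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  dose_grid(array(as.numeric(img), dim = dim(img)),
            spacing_mm = RNifti::pixdim(img)[1:3])
}

#' Write structure masks as a NIfTI label volume plus name sidecar
#'
#' Structures are written as one integer label volume (1, 2, ...) with a
#' JSON sidecar mapping label integers to structure names. Overlapping
#' structures (the nested PTVs) are written innermost-last so that each
#' voxel carries the most specific label; use `one_per_structure = TRUE` to
#' write one binary NIfTI per structure instead (lossless for overlaps).
#'
#' @param masks named list of [structure_mask()]s.
#' @param path label volume path (or directory when `one_per_structure`).
#' @param names_path JSON sidecar path (default: `path` with `.json`).
#' @param one_per_structure write one binary volume per structure.
#' @return `path`, invisibly.
#' @export
write_labels_nifti <- function(masks, path,
                               names_path = sub("\\.nii(\\.gz)?$", ".json", path),
                               one_per_structure = FALSE) {
  if (one_per_structure) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (n in names(masks)) {
      img <- RNifti::asNifti(array(as.integer(masks[[n]]$voxels),
                                   dim = dim(masks[[n]]$voxels)))
      RNifti::pixdim(img) <- masks[[n]]$spacing_mm
      RNifti::writeNifti(img, file.path(path, paste0(n, ".nii.gz")))
    }
    return(invisible(path))
  }
  # paint larger structures first so nested/overlapping smaller ones win
  sizes <- vapply(masks, function(m) sum(m$voxels), numeric(1))
  ord <- names(sort(sizes, decreasing = TRUE))
  lab <- array(0L, dim = dim(masks[[1]]$voxels))
  ids <- seq_along(masks); names(ids) <- names(masks)
  for (n in ord) lab[masks[[n]]$voxels] <- ids[[n]]
  img <- RNifti::asNifti(lab)
  RNifti::pixdim(img) <- masks[[1]]$spacing_mm
  RNifti::writeNifti(img, path)
  jsonlite::write_json(as.list(ids), names_path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a label volume plus name sidecar into structure masks
#' @param path label NIfTI path.
#' @param names_path JSON sidecar mapping names to label integers.
#' @return Named list of [structure_mask()]s.
#' @export
read_labels_nifti <- function(path, names_path = sub("\\.nii(\\.gz)?$", ".json", path)) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  ids <- jsonlite::read_json(names_path, simplifyVector = TRUE)
  lab <- array(as.integer(img), dim = dim(img))
  out <- lapply(names(ids), function(n)
    structure_mask(n, lab == ids[[n]], sp))
  names(out) <- names(ids)
  out
}

provenance_header <- function(seed, config_hashes = character(0)) {
  c(sprintf("# planqm %s", as.character(utils::packageVersion("planqm"))),
    sprintf("# seed: %s", as.character(seed)),
    sprintf("# timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    if (length(config_hashes))
      sprintf("# input %s: %s", names(config_hashes), unname(config_hashes)))
}

#' Write a data frame as CSV with a provenance header
#'
#' '#'-prefixed header lines record the tool version, seed and input-config
#' hashes; [read_planqm_csv()] skips them. With the same configuration and
#' seed, all lines except the timestamp are identical across runs.
#'
#' @param df data frame.
#' @param path output path.
#' @param seed seed recorded in the header.
#' @param config_hashes named character vector of input-file md5 hashes.
#' @return `path`, invisibly.
#' @export
write_planqm_csv <- function(df, path, seed = NA, config_hashes = character(0)) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenance_header(seed, config_hashes), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_planqm_csv()]
#' @param path CSV path.
#' @return A data frame (provenance comment lines skipped).
#' @export
read_planqm_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Flatten scorecards to a data frame
#'
#' One row per plan: plan_id, the 16 metric values, the 16 per-metric
#' points (`<metric>_pts`), subtotals, PQM, acceptability and any gate
#' failures (semicolon-separated).
#'
#' @param scorecards list of `pqm_scorecard`s.
#' @return A data frame.
#' @export
scorecards_to_df <- function(scorecards) {
  do.call(rbind, lapply(scorecards, function(s) {
    gf <- if (nrow(s$gate_failures) == 0L) ""
    else paste(sprintf("%s(%.4g>%.4g)", s$gate_failures$gate,
                       s$gate_failures$observed, s$gate_failures$bound),
               collapse = ";")
    cbind(data.frame(plan_id = s$plan_id, stringsAsFactors = FALSE),
          as.data.frame(as.list(s$metric_values)),
          stats::setNames(as.data.frame(as.list(s$metric_points)),
                          paste0(names(s$metric_points), "_pts")),
          data.frame(ptv_points = s$ptv_points, oar_points = s$oar_points,
                     pqm = s$pqm, acceptable = s$acceptable,
                     gate_failures = gf, stringsAsFactors = FALSE))
  }))
}
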