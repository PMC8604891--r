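#' Dose grid
#'
#' A 3D scalar dose distribution in Gy on a regular voxel grid. Doses are
#' total physical dose (here: over 33 fractions); no EQD2/BED conversion is
#' applied anywhere in the package.
#'
#' @param values 3D numeric array of dose in Gy; finite and non-negative.
#' @param spacing_mm numeric length-3, voxel edge lengths in mm (> 0).
#' @param origin_mm numeric length-3, position of the first voxel centre in mm.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(values, spacing_mm, origin_mm = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  if (any(!is.finite(values)))
    stop("dose values must all be finite", call. = FALSE)
  if (any(values < 0))
    stop("dose values must be non-negative", call. = FALSE)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 strictly positive values", call. = FALSE)
  structure(
    list(values = values, spacing_mm = spacing_mm,
         origin_mm = as.numeric(origin_mm)),
    class = "dose_grid"
  )
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<dose_grid> %d x %d x %d voxels, %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]))
  cat(sprintf("  dose range: %.3f - %.3f Gy\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Structure mask
#'
#' A named binary volume aligned to a [dose_grid()]: a planning target volume
#' (PTV), organ at risk (OAR), or a derived ring (set difference).
#'
#' @param name structure name.
#' @param voxels 3D logical array.
#' @param spacing_mm voxel edge lengths in mm, shared with the dose grid.
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(name, voxels, spacing_mm) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array", call. = FALSE)
  storage.mode(voxels) <- "logical"
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 strictly positive values", call. = FALSE)
  structure(
    list(name = as.character(name), voxels = voxels, spacing_mm = spacing_mm),
    class = "structure_mask"
  )
}

#' Voxel volume in cc for a grid or mask
#' @param x a `dose_grid` or `structure_mask`.
#' @return Volume of one voxel in cubic centimetres.
#' @export
voxel_volume_cc <- function(x) prod(x$spacing_mm) / 1000

#' Structure volume in cc
#'
#' Volume is full-voxel: voxel count times voxel volume.
#'
#' @param mask a `structure_mask`.
#' @return Volume in cubic centimetres.
#' @export
structure_volume_cc <- function(mask) {
  sum(mask$voxels) * voxel_volume_cc(mask)
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask> '%s': %d voxels, %.3f cc\n",
              x$name, sum(x$voxels), structure_volume_cc(x)))
  invisible(x)
}

#' Ring (set-difference) structure
#'
#' Voxelwise `outer AND NOT inner`; the standard construction for shell
#' metrics such as the intermediate-dose spill between two nested PTVs.
#' An empty result is allowed here; metrics computed on it error downstream.
#'
#' @param outer,inner `structure_mask` objects on the same grid.
#' @return A `structure_mask` named `"<outer>-<inner>"`.
#' @export
ring <- function(outer, inner) {
  check_same_grid(outer, inner)
  structure_mask(paste0(outer$name, "-", inner$name),
                 outer$voxels & !inner$voxels, outer$spacing_mm)
}

check_same_grid <- function(a, b) {
  da <- dim(if (inherits(a, "dose_grid")) a$values else a$voxels)
  db <- dim(if (inherits(b, "dose_grid")) b$values else b$voxels)
  if (!identical(da, db))
    stop(sprintf("grid mismatch: %s vs %s",
                 paste(da, collapse = "x"), paste(db, collapse = "x")),
         call. = FALSE)
  invisible(TRUE)
}
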