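#' Cumulative dose-volume histogram
#'
#' Computes a cumulative DVH by full-voxel counting: each voxel contributes
#' its whole volume at its dose value (no partial-volume weighting; the
#' synthetic pipeline controls its own grids, and a supersampling hook is
#' deliberately not the default).
#'
#' @param dose a [dose_grid()].
#' @param mask a [structure_mask()] on the same grid, non-empty.
#' @param bin_width_gy histogram bin width in Gy (default 0.01 Gy, i.e. about
#'   0.1% of the highest prescription, below all scoring tier gaps).
#' @return An object of class `dvh_curve` with fields `dose_edges` (ascending
#'   bin edges in Gy, starting at 0), `cum_volume_fraction` (fraction of the
#'   structure volume receiving at least each edge dose; starts at 1, monotone
#'   non-increasing) and `structure_volume_cc`.
#' @export
compute_dvh <- function(dose, mask, bin_width_gy = 0.01) {
  check_same_grid(dose, mask)
  if (bin_width_gy <= 0) stop("`bin_width_gy` must be > 0", call. = FALSE)
  n <- sum(mask$voxels)
  if (n == 0L)
    stop(sprintf("structure '%s' is empty", mask$name), call. = FALSE)
  d <- dose$values[mask$voxels]
  bw <- bin_width_gy
  # edges 0, bw, 2bw, ..., covering max dose plus one extra bin
  n_edges <- floor(max(d) / bw) + 2L
  edges <- (seq_len(n_edges) - 1) * bw
  # voxel with dose d falls in bin floor(d/bw)+1; count(d >= edge_k) is then
  # the count of voxels with bin index >= k (doses exactly on an edge land in
  # the bin starting at that edge, so they count as receiving >= it)
  idx <- pmin(floor(d / bw) + 1L, n_edges)
  counts <- tabulate(idx, nbins = n_edges)
  cum <- rev(cumsum(rev(counts))) / n
  structure(
    list(dose_edges = edges, cum_volume_fraction = cum,
         structure_volume_cc = n * voxel_volume_cc(mask)),
    class = "dvh_curve"
  )
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve> %.3f cc, dose range to %.2f Gy (%d edges)\n",
              x$structure_volume_cc, max(x$dose_edges), length(x$dose_edges)))
  invisible(x)
}

check_dvh <- function(dvh) {
  if (!inherits(dvh, "dvh_curve")) stop("not a dvh_curve", call. = FALSE)
  invisible(TRUE)
}

# Greatest dose D such that at least `frac` of the volume receives >= D.
# The crossing is located on the binned inverse cumulative curve and the
# centre of the crossing bin is returned: every voxel contributing to that
# bin has a dose within half a bin width of the returned value, which is
# the engine's stated accuracy bound for inverse queries.
dvh_inverse <- function(dvh, frac) {
  f <- dvh$cum_volume_fraction
  e <- dvh$dose_edges
  if (frac <= f[length(f)]) return(e[length(e)])
  # small slack so that volume fractions equal to a count ratio up to
  # floating-point rounding select the correct bin
  k <- max(which(f >= frac - 1e-12))   # f[1] = 1 >= frac, so k exists
  if (k == length(f)) return(e[k])
  e[k] + (e[k + 1] - e[k]) / 2
}

#' Dose to the hottest x% of a structure (D_x%)
#'
#' The minimum dose received by the hottest `x_percent` of the structure
#' volume: the greatest dose D such that at least x% of the volume receives
#' at least D. This is the dominant clinical convention for coverage
#' reporting (e.g. D95%). The returned dose is accurate to half a DVH bin
#' width (0.005 Gy at the default binning).
#'
#' @param dvh a [compute_dvh()] result.
#' @param x_percent percentage of volume in (0, 100].
#' @return Dose in Gy.
#' @export
dose_at_volume_percent <- function(dvh, x_percent) {
  check_dvh(dvh)
  if (!is.finite(x_percent) || x_percent <= 0 || x_percent > 100)
    stop("`x_percent` must lie in (0, 100]", call. = FALSE)
  dvh_inverse(dvh, x_percent / 100)
}

#' Dose to the hottest v cc of a structure (D_xcc)
#'
#' Near-maximum dose surrogate (e.g. D0.1cc): greatest dose D such that at
#' least `v_cc` of the structure receives at least D.
#'
#' @param dvh a [compute_dvh()] result.
#' @param v_cc absolute volume in cc; must not exceed the structure volume.
#' @return Dose in Gy.
#' @export
dose_at_volume_cc <- function(dvh, v_cc) {
  check_dvh(dvh)
  if (!is.finite(v_cc) || v_cc <= 0)
    stop("`v_cc` must be > 0", call. = FALSE)
  if (v_cc > dvh$structure_volume_cc)
    stop(sprintf("requested volume %.4g cc exceeds structure volume %.4g cc",
                 v_cc, dvh$structure_volume_cc), call. = FALSE)
  dvh_inverse(dvh, v_cc / dvh$structure_volume_cc)
}

#' Mean structure dose (D_mean)
#'
#' Arithmetic mean of voxel doses inside the mask (all voxels have equal
#' volume on a regular grid).
#'
#' @param dose a [dose_grid()].
#' @param mask a non-empty [structure_mask()] on the same grid.
#' @return Dose in Gy.
#' @export
mean_dose <- function(dose, mask) {
  check_same_grid(dose, mask)
  if (!any(mask$voxels))
    stop(sprintf("structure '%s' is empty", mask$name), call. = FALSE)
  mean(dose$values[mask$voxels])
}

#' Volume receiving at least a dose (V_xGy), in percent
#'
#' @param dvh a [compute_dvh()] result.
#' @param d_gy dose threshold in Gy (>= 0).
#' @return Percentage of the structure volume receiving at least `d_gy`,
#'   linearly interpolated between DVH bin edges.
#' @export
volume_at_dose_percent <- function(dvh, d_gy) {
  check_dvh(dvh)
  if (!is.finite(d_gy) || d_gy < 0)
    stop("`d_gy` must be a non-negative dose", call. = FALSE)
  e <- dvh$dose_edges
  f <- dvh$cum_volume_fraction
  if (d_gy >= e[length(e)]) return(0)
  100 * stats::approx(e, f, xout = d_gy, rule = 2)$y
}

#' Conformation number
#'
#' CN = (TVRI/TV) x (TVRI/VRI), where TV is the target volume, VRI the
#' volume of the reference isodose (all voxels at or above the reference
#' dose) and TVRI the part of the target covered by the reference dose.
#' CN = 1 means the reference isodose exactly conforms to the target; the
#' first factor (coverage) penalizes under-coverage and the second
#' (selectivity) penalizes dose spill outside the target.
#'
#' @param dose a [dose_grid()].
#' @param target a non-empty [structure_mask()] (the low-risk PTV for the
#'   default scheme).
#' @param reference_dose_gy reference isodose level in Gy (> 0).
#' @return An object of class `conformity_components` with fields `tvri_cc`,
#'   `tv_cc`, `vri_cc`, `cn`, `coverage`, `selectivity` and `degenerate`
#'   (TRUE with a warning flag when no voxel reaches the reference dose, in
#'   which case CN = 0).
#' @export
conformation_number <- function(dose, target, reference_dose_gy) {
  check_same_grid(dose, target)
  if (!any(target$voxels))
    stop(sprintf("structure '%s' is empty", target$name), call. = FALSE)
  if (!is.finite(reference_dose_gy) || reference_dose_gy <= 0)
    stop("`reference_dose_gy` must be > 0", call. = FALSE)
  vv <- voxel_volume_cc(dose)
  ri <- dose$values >= reference_dose_gy
  vri <- sum(ri) * vv
  tv <- sum(target$voxels) * vv
  tvri <- sum(ri & target$voxels) * vv
  degenerate <- vri == 0
  cn <- if (degenerate) 0 else (tvri / tv) * (tvri / vri)
  structure(
    list(tvri_cc = tvri, tv_cc = tv, vri_cc = vri, cn = cn,
         coverage = tvri / tv,
         selectivity = if (degenerate) NA_real_ else tvri / vri,
         degenerate = degenerate),
    class = "conformity_components"
  )
}

#' @export
print.conformity_components <- function(x, ...) {
  cat(sprintf("<conformity> CN = %.4f (coverage %.4f x selectivity %s)\n",
              x$cn, x$coverage,
              if (x$degenerate) "NA [degenerate isodose]" else sprintf("%.4f", x$selectivity)))
  cat(sprintf("  TV %.2f cc, VRI %.2f cc, TVRI %.2f cc\n", x$tv_cc, x$vri_cc, x$tvri_cc))
  invisible(x)
}
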