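#' Extract all scheme metrics from a dose distribution
#'
#' Runs the DVH engine over a dose grid and returns the value of every
#' metric in the scheme: D_x% and D_xcc from the cumulative DVH inverse,
#' D_mean directly, V_xGy on (possibly ring) structures, and the
#' conformation number at the metric's reference dose. Structure names of
#' the form `"outer-inner"` are resolved as voxelwise set differences via
#' [ring()].
#'
#' @param dose a [dose_grid()].
#' @param phantom an [build_phantom()] result (or any named list of
#'   [structure_mask()]s under `$masks`).
#' @param scheme a [load_scheme()] result.
#' @param bin_width_gy DVH bin width in Gy (default 0.01).
#' @return Named numeric vector of metric values, one per scheme metric.
#' @export
evaluate_plan_metrics <- function(dose, phantom, scheme = load_scheme(),
                                  bin_width_gy = 0.01) {
  masks <- phantom$masks
  get_mask <- function(name) {
    if (!is.null(masks[[name]])) return(masks[[name]])
    if (grepl("-", name, fixed = TRUE)) {
      parts <- strsplit(name, "-", fixed = TRUE)[[1]]
      if (length(parts) == 2L && !is.null(masks[[parts[1]]]) &&
          !is.null(masks[[parts[2]]]))
        return(ring(masks[[parts[1]]], masks[[parts[2]]]))
    }
    stop(sprintf("unknown structure '%s' in scheme", name), call. = FALSE)
  }
  dvh_cache <- new.env(parent = emptyenv())
  get_dvh <- function(name) {
    if (!is.null(dvh_cache[[name]])) return(dvh_cache[[name]])
    dvh_cache[[name]] <- compute_dvh(dose, get_mask(name), bin_width_gy)
    dvh_cache[[name]]
  }
  out <- numeric(length(scheme$metrics))
  names(out) <- names(scheme$metrics)
  for (id in names(scheme$metrics)) {
    m <- scheme$metrics[[id]]
    out[id] <- switch(
      m$kind,
      D_percent = dose_at_volume_percent(get_dvh(m$structure), m$parameter),
      D_cc = dose_at_volume_cc(get_dvh(m$structure), m$parameter),
      D_mean = mean_dose(dose, get_mask(m$structure)),
      V_gy_percent = volume_at_dose_percent(get_dvh(m$structure), m$parameter),
      conformation = conformation_number(dose, get_mask(m$structure),
                                         m$parameter)$cn,
      stop(sprintf("unknown metric kind '%s'", m$kind), call. = FALSE)
    )
  }
  out
}
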