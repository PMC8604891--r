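# Dose painting: realise a profile's intended metric values as a 3D dose
# distribution on the phantom. Each painting region (PTV1, the PTV2 and PTV3
# rings, each OAR) receives doses through a monotone piecewise-linear
# quantile function d(u), u = fraction of the region volume receiving >= d,
# anchored so that the DVH engine measures each intended metric back within
# the painting tolerance (2% relative by contract; in practice much closer).
# Spatial assignment is rank-ordered: hotter doses go to voxels nearer the
# structure centre, so gradients are spatially coherent. Overlapping paints
# are resolved by voxelwise maximum. The background falls off smoothly and
# monotonically with (normalised radial) distance from PTV3. Painting is
# fully deterministic: no random numbers are drawn.

paint_infeasible <- function(metric_a, metric_b, why) {
  stop(sprintf("infeasible target combination (%s vs %s): %s",
               metric_a, metric_b, why), call. = FALSE)
}

# Evaluate a piecewise-linear quantile function at region ranks.
# u_anchor strictly increasing in [0, 1]; v_anchor non-increasing.
ramp_doses <- function(n, u_anchor, v_anchor) {
  u <- (seq_len(n) - 0.5) / n
  stats::approx(u_anchor, v_anchor, xout = u, rule = 2)$y
}

V567_REF_GY <- 56.7   # 105% of the 54 Gy elective prescription
CN_REF_GY <- 54       # conformation reference isodose = PTV3 prescription

#' Paint a dose distribution for one plan profile
#'
#' Constructs a [dose_grid()] on the phantom such that each of the 16 dose
#' submetrics, measured by the DVH engine on the painted grid, reproduces
#' the profile's intended value within the painting tolerance (2% relative).
#' Jointly infeasible targets (e.g. a PTV1 near-maximum below its D95%
#' coverage target) raise an infeasibility error naming the metric pair.
#'
#' @param phantom an [build_phantom()] result.
#' @param profile a `plan_profile` from [sample_cohort_profiles()].
#' @return A `dose_grid`.
#' @export
paint_dose <- function(phantom, profile) {
  t <- profile$metric_targets
  need <- default_metric_ids()
  if (!all(need %in% names(t)))
    stop("profile is missing metric targets: ",
         paste(setdiff(need, names(t)), collapse = ", "), call. = FALSE)
  gy_ids <- setdiff(need, c("ptv3_cn", "ptv3_ptv2_v56_7"))
  if (any(!is.finite(t[need])) || any(t[gy_ids] < 0) || any(t[gy_ids] > 80))
    stop("metric targets outside physical bounds (0-80 Gy)", call. = FALSE)
  if (t[["ptv3_cn"]] <= 0 || t[["ptv3_cn"]] > 1 ||
      t[["ptv3_ptv2_v56_7"]] < 0 || t[["ptv3_ptv2_v56_7"]] > 100)
    stop("conformation/volume targets outside their unit ranges", call. = FALSE)

  vv <- prod(phantom$spacing_mm) / 1000
  regions <- phantom$regions
  dose <- numeric(prod(phantom$grid_shape))

  ## background: exponential falloff with normalised radial distance to PTV3
  b <- t[["ptv3_d95"]] - 1
  dose[phantom$background_idx] <- b * exp(-3 * (phantom$background_radius - 1))

  ## PTV1: hot plateau (near-max D0.1cc) + coverage ramp through D95
  t95_1 <- t[["ptv1_d95"]]; t01_1 <- t[["ptv1_d0_1cc"]]
  if (t01_1 < t95_1 + 0.5)
    paint_infeasible("ptv1_d0_1cc", "ptv1_d95",
                     "hot spot cannot be colder than near-minimum coverage")
  n1 <- length(regions$ptv1)
  u01 <- (ceiling(0.1 / vv) + 2) / n1
  if (u01 >= 0.9)
    paint_infeasible("ptv1_d0_1cc", "ptv1_d95", "structure too small for hot spot")
  dose[regions$ptv1] <- ramp_doses(n1, c(0, u01, 0.95, 1),
                                   c(t01_1, t01_1, t95_1, t95_1 - 0.3))

  ## PTV2 ring: combined-rank anchor so that D95 over the whole of PTV2
  ## (hot PTV1 interior + ring) lands on the target
  t95_2 <- t[["ptv2_d95"]]
  f1 <- phantom$frac_ptv1_in_ptv2
  u_star <- (0.95 - f1) / (1 - f1)
  T2 <- min(t95_2 + 1.5, t95_1 - 0.4)
  if (T2 <= t95_2)
    paint_infeasible("ptv2_d95", "ptv1_d95",
                     "intermediate prescription target reaches the boost level")
  B2 <- T2 + (t95_2 - T2) / u_star
  n2 <- length(regions$ptv2_ring)
  dose[regions$ptv2_ring] <- ramp_doses(n2, c(0, u_star, 1), c(T2, t95_2, B2))

  ## OARs with a near-maximum target: small plateau of the hot volume, then
  ## a steep falloff (keeps any spill above the conformation reference tiny)
  hot_oars <- c(spinal_canal = 0.1, brainstem = 0.1, brachial_plexus = 0.5,
                brain = 0.1, esophagus = 0.1, mandible = 0.1)
  hot_ids <- c(spinal_canal = "spinal_canal_d0_1cc",
               brainstem = "brainstem_d0_1cc",
               brachial_plexus = "brachial_plexus_d0_5cc",
               brain = "brain_d0_1cc", esophagus = "esophagus_d0_1cc",
               mandible = "mandible_d0_1cc")
  for (s in names(hot_oars)) {
    tt <- t[[hot_ids[[s]]]]
    idx <- regions[[s]]
    n <- length(idx)
    u_hot <- (ceiling(hot_oars[[s]] / vv) + 2) / n
    if (u_hot >= 0.9)
      stop(sprintf("structure '%s' too small for its %.1f cc hot-spot target",
                   s, hot_oars[[s]]), call. = FALSE)
    ramp <- ramp_doses(n, c(0, u_hot, min(u_hot + 0.04, 0.95), 1),
                       c(tt, tt, tt - 6, max(tt - 15, 2)))
    dose[idx] <- pmax(dose[idx], ramp)
  }

  ## OARs with a mean-dose target: symmetric linear ramp, exact mean
  mean_ids <- c(parotid_left = "parotid_left_dmean",
                parotid_right = "parotid_right_dmean",
                glottis = "glottis_dmean", oral_cavity = "oral_cavity_dmean")
  for (s in names(mean_ids)) {
    tt <- t[[mean_ids[[s]]]]
    idx <- regions[[s]]
    ramp <- ramp_doses(length(idx), c(0, 1), c(tt + 2, max(tt - 2, 0)))
    dose[idx] <- pmax(dose[idx], ramp)
  }

  ## PTV3 ring: anchors for V56.7 (ring-local), conformation coverage at the
  ## 54 Gy reference (combined rank) and D95 (combined rank)
  t95_3 <- t[["ptv3_d95"]]; v567 <- t[["ptv3_ptv2_v56_7"]]; cn <- t[["ptv3_cn"]]
  f2 <- phantom$frac_ptv2_in_ptv3
  if (t95_3 >= CN_REF_GY)
    paint_infeasible("ptv3_d95", "ptv3_cn",
                     "D95 at or above the conformation reference dose")
  if (cn <= f2 + 0.02)
    paint_infeasible("ptv3_cn", "ptv2_d95",
                     "conformation coverage not above the PTV2 volume fraction")
  ## spill: volume outside PTV3 already painted at or above the reference
  ## dose (OAR hot spots); the coverage anchor is solved so that the
  ## measured CN = coverage x selectivity still lands on the target
  outside <- c(phantom$background_idx, unlist(regions[oar_names()],
                                              use.names = FALSE))
  spill_cc <- sum(dose[outside] >= CN_REF_GY) * vv
  tv_cc <- (length(regions$ptv1) + n2 + length(regions$ptv3_ring)) * vv
  cov_eff <- (cn + sqrt(cn^2 + 4 * cn * spill_cc / tv_cc)) / 2
  u_v <- v567 / 100
  u_cn <- (cov_eff - f2) / (1 - f2)
  u95 <- (0.95 - f2) / (1 - f2)
  if (u_cn <= u_v)
    paint_infeasible("ptv3_ptv2_v56_7", "ptv3_cn",
                     "V56.7 spill exceeds the conformation coverage fraction")
  if (u_cn >= u95)
    paint_infeasible("ptv3_cn", "ptv3_d95", "conformation coverage above 95%")
  T3 <- min(57.3, B2 - 0.05)
  if (T3 <= V567_REF_GY + 0.05)
    paint_infeasible("ptv2_d95", "ptv3_ptv2_v56_7",
                     "ring ceiling does not reach the V56.7 reference dose")
  n3 <- length(regions$ptv3_ring)
  dose[regions$ptv3_ring] <- ramp_doses(
    n3, c(0, u_v, u_cn, u95, 1),
    c(T3, V567_REF_GY, CN_REF_GY, t95_3, t95_3 - 1))

  dose_grid(array(dose, dim = phantom$grid_shape), phantom$spacing_mm)
}
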