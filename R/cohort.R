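# Truncated-normal helpers. Quantile function in closed form via the normal
# CDF; the location solver inverts "median of TN(mu, sd, lo, hi) = m", which
# is monotone increasing in mu.

# Quantile of TN(mean, sd, [lo, hi]) evaluated in whichever normal tail is
# numerically stable, so that locations far outside the support (which the
# median calibration can produce) do not saturate to the wrong bound.
qtruncnorm <- function(p, mean, sd, lo, hi) {
  alpha <- (lo - mean) / sd
  beta <- (hi - mean) / sd
  if (mean >= (lo + hi) / 2) {
    a <- stats::pnorm(alpha); b <- stats::pnorm(beta)
    z <- stats::qnorm((1 - p) * a + p * b)
  } else {
    qa <- stats::pnorm(alpha, lower.tail = FALSE)
    qb <- stats::pnorm(beta, lower.tail = FALSE)
    z <- stats::qnorm((1 - p) * qa + p * qb, lower.tail = FALSE)
  }
  pmin(pmax(mean + sd * z, lo), hi)
}

tn_median <- function(mean, sd, lo, hi) qtruncnorm(0.5, mean, sd, lo, hi)

# Location giving a requested median (monotone in the location; solved with
# an expanding bracket). The target is clamped slightly inside the support:
# a truncated normal's median is strictly interior, and printed medians can
# sit on a (rounded) range endpoint.
solve_tn_location <- function(median_target, sd, lo, hi) {
  eps <- 0.02 * (hi - lo)
  m <- min(max(median_target, lo + eps), hi - eps)
  f <- function(mu) tn_median(mu, sd, lo, hi) - m
  lower <- m - 2 * sd; upper <- m + 2 * sd
  for (i in 1:30) {
    if (f(lower) < 0) break
    lower <- lower - 2 * sd
  }
  for (i in 1:30) {
    if (f(upper) > 0) break
    upper <- upper + 2 * sd
  }
  stats::uniroot(f, lower = lower, upper = upper, tol = 1e-10)$root
}

#' Load a cohort calibration
#'
#' Reads a JSON calibration: one entry per metric/metadata field giving the
#' marginal summary (mean, SD, median, min, max) and a list of pairwise rank
#' correlations to impose. The shipped default
#' (`system.file("extdata", "table1_calibration.json", package = "planqm")`)
#' encodes the study cohort's descriptive statistics for the 16 dose
#' submetrics and 7 delivery-metadata fields, plus two standard-normal
#' latent plan-quality factors.
#'
#' Marginals are truncated normals on the printed range with scale equal to
#' the printed SD; the location is solved so that the marginal's *median*
#' equals the printed median (an asymmetrically truncated normal centred on
#' the printed mean would not reproduce it).
#'
#' @param path path to a calibration JSON file; default is the shipped one.
#' @return An object of class `cohort_calibration`.
#' @export
load_calibration <- function(path = system.file("extdata", "table1_calibration.json",
                                                package = "planqm")) {
  cal <- jsonlite::read_json(path, simplifyVector = TRUE)
  fields <- cal$fields
  if (is.null(fields$latent)) fields$latent <- FALSE
  fields$latent[is.na(fields$latent)] <- FALSE
  if (is.null(fields$integer)) fields$integer <- FALSE
  fields$integer[is.na(fields$integer)] <- FALSE
  needed <- c(default_metric_ids(),
              c("n_beams", "n_segments", "mu", "beam_on_min", "delivery_min",
                "experience_years", "viewray_years"))
  missing <- setdiff(needed, fields$id)
  if (length(missing))
    stop("calibration missing fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  loc <- rep(NA_real_, nrow(fields))
  for (i in seq_len(nrow(fields))) {
    if (fields$latent[i]) next
    loc[i] <- solve_tn_location(fields$median[i], fields$sd[i],
                                fields$min[i], fields$max[i])
  }
  fields$location <- loc
  structure(list(fields = fields, correlations = cal$correlations),
            class = "cohort_calibration")
}

default_metric_ids <- function() {
  c("ptv1_d95", "ptv1_d0_1cc", "ptv2_d95", "ptv3_d95", "ptv3_ptv2_v56_7",
    "ptv3_cn", "spinal_canal_d0_1cc", "parotid_left_dmean",
    "parotid_right_dmean", "brainstem_d0_1cc", "brachial_plexus_d0_5cc",
    "brain_d0_1cc", "esophagus_d0_1cc", "glottis_dmean", "mandible_d0_1cc",
    "oral_cavity_dmean")
}

# Rank-correlation matrix of the calibration, converted to the Pearson
# correlation of the underlying Gaussian copula (2 sin(pi rho / 6)) and
# repaired to the nearest positive semi-definite correlation matrix when the
# printed entries are jointly infeasible.
copula_correlation <- function(calibration) {
  ids <- calibration$fields$id
  k <- length(ids)
  S <- diag(k)
  dimnames(S) <- list(ids, ids)
  cors <- calibration$correlations
  if (!is.null(cors) && NROW(cors) > 0) {
    for (i in seq_len(NROW(cors))) {
      a <- cors$field_a[i]; b <- cors$field_b[i]; rho <- cors$rho[i]
      if (!(a %in% ids) || !(b %in% ids))
        stop(sprintf("correlation names unknown field: %s ~ %s", a, b),
             call. = FALSE)
      if (abs(rho) > 1) stop("correlation outside [-1, 1]", call. = FALSE)
      r <- 2 * sin(pi * rho / 6)
      S[a, b] <- r
      S[b, a] <- r
    }
  }
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    # the unprinted pairs pinned at 0 can make the printed set jointly
    # infeasible; repair to the nearest PSD correlation matrix, weighting
    # the latent proxy rows least so the adjustment lands there rather than
    # in the printed observable-pair entries
    # weighted Frobenius norm by congruence: positive definiteness is
    # invariant under D S D with D = diag(sqrt(w)), so repairing the scaled
    # matrix (diagonal kept) and scaling back yields a unit-diagonal PSD
    # matrix whose adjustments are concentrated in the low-weight rows
    w <- ifelse(calibration$fields$latent, 0.1, 1)
    D <- sqrt(w)
    rep <- Matrix::nearPD(S * tcrossprod(D), keepDiag = TRUE,
                          posd.tol = 1e-6)
    if (!rep$converged)
      stop("correlation matrix could not be repaired to PSD", call. = FALSE)
    S <- as.matrix(rep$mat) / tcrossprod(D)
    diag(S) <- 1
    dimnames(S) <- list(ids, ids)
  }
  S
}

#' Sample a cohort of plan quality profiles
#'
#' Draws `n_plans` per-plan profiles: intended values for the 16 dose
#' submetrics plus delivery metadata (beams, segments, MU, beam-on and total
#' delivery time, planner experience). Marginals are truncated normals from
#' the calibration; dependence is imposed through a Gaussian copula whose
#' off-diagonal entries are the calibrated rank correlations (0 where the
#' calibration states none). Sampling is deterministic given the seed; count
#' fields are rounded to integers.
#'
#' @param n_plans number of plans (>= 1).
#' @param calibration a [load_calibration()] result.
#' @param seed integer root seed; per-plan child seeds are derived by fixed
#'   arithmetic and recorded in each profile.
#' @return A list of `plan_profile` objects with attribute `"samples"` (the
#'   underlying numeric matrix, one row per plan).
#' @export
sample_cohort_profiles <- function(n_plans, calibration = load_calibration(),
                                   seed = 1L) {
  if (!is.numeric(n_plans) || n_plans < 1)
    stop("`n_plans` must be >= 1", call. = FALSE)
  n_plans <- as.integer(n_plans)
  fields <- calibration$fields
  ids <- fields$id
  S <- copula_correlation(calibration)
  R <- chol(S)
  set.seed(as.integer(seed))
  Z <- matrix(stats::rnorm(n_plans * length(ids)), nrow = n_plans) %*% R
  colnames(Z) <- ids
  X <- Z
  for (j in seq_along(ids)) {
    if (fields$latent[j]) next   # latent factors stay on the z scale
    u <- stats::pnorm(Z[, j])
    x <- qtruncnorm(u, fields$location[j], fields$sd[j],
                    fields$min[j], fields$max[j])
    if (fields$integer[j]) x <- round(x)
    X[, j] <- x
  }

  metric_ids <- default_metric_ids()
  lapply(seq_len(n_plans), function(i) {
    delivery <- list(
      n_beams = X[i, "n_beams"], n_segments = X[i, "n_segments"],
      mu = X[i, "mu"], beam_on_min = X[i, "beam_on_min"],
      delivery_min = X[i, "delivery_min"]
    )
    if (delivery$beam_on_min > delivery$delivery_min)
      delivery$beam_on_min <- delivery$delivery_min
    structure(
      list(plan_id = sprintf("plan_%03d", i),
           metric_targets = X[i, metric_ids],
           delivery = delivery,
           experience_years = X[i, "experience_years"],
           viewray_years = X[i, "viewray_years"],
           latent = c(pqm = unname(X[i, "pqm_latent"]),
                      ptv = unname(X[i, "ptv_latent"])),
           seed = (as.integer(seed) + 7919L * i) %% .Machine$integer.max),
      class = "plan_profile"
    )
  }) -> profiles
  attr(profiles, "samples") <- X
  profiles
}

#' @export
print.plan_profile <- function(x, ...) {
  cat(sprintf("<plan_profile> %s: %d beams, %d segments, %.0f MU, %.1f min delivery\n",
              x$plan_id, x$delivery$n_beams, x$delivery$n_segments,
              x$delivery$mu, x$delivery$delivery_min))
  print(round(x$metric_targets, 3))
  invisible(x)
}

#' Delivery metadata of a cohort as a data frame
#'
#' @param profiles list of `plan_profile`s from [sample_cohort_profiles()].
#' @return A data frame with one row per plan: plan_id, n_beams, n_segments,
#'   mu, beam_on_min, delivery_min, experience_years, viewray_years, seed.
#' @export
cohort_metadata <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p) {
    data.frame(plan_id = p$plan_id,
               n_beams = p$delivery$n_beams,
               n_segments = p$delivery$n_segments,
               mu = p$delivery$mu,
               beam_on_min = p$delivery$beam_on_min,
               delivery_min = p$delivery$delivery_min,
               experience_years = p$experience_years,
               viewray_years = p$viewray_years,
               seed = p$seed,
               stringsAsFactors = FALSE)
  }))
}
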