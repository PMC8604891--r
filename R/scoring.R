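#' Load a scoring scheme
#'
#' Reads a JSON scoring scheme: 16 metric specifications (structure, metric
#' kind, parameter, direction, group) each paired with a tier schedule, plus
#' the acceptability gates (maximum delivery time and hard dose constraints).
#' The shipped default (`system.file("extdata", "default_scheme.json",
#' package = "planqm")`) is a reconstructed scheme: 6 PTV metrics worth 78
#' points and 10 OAR metrics worth 72 points, for a 150-point plan quality
#' metric.
#'
#' @param path path to a scheme JSON file; default is the shipped scheme.
#' @param validate validate invariants after loading (default TRUE).
#' @return An object of class `pqm_scheme`.
#' @export
load_scheme <- function(path = system.file("extdata", "default_scheme.json",
                                           package = "planqm"),
                        validate = TRUE) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(raw$metrics) || is.null(raw$gates))
    stop("scheme file must contain 'metrics' and 'gates'", call. = FALSE)
  metrics <- lapply(raw$metrics, function(m) {
    for (f in c("metric_id", "structure", "kind", "direction", "group", "schedule"))
      if (is.null(m[[f]]))
        stop(sprintf("metric entry missing field '%s'", f), call. = FALSE)
    if (!m$kind %in% c("D_percent", "D_cc", "D_mean", "V_gy_percent", "conformation"))
      stop(sprintf("unknown metric kind '%s' for '%s'", m$kind, m$metric_id),
           call. = FALSE)
    if (!m$direction %in% c("higher_better", "lower_better"))
      stop(sprintf("unknown direction '%s'", m$direction), call. = FALSE)
    m$parameter <- if (is.null(m$parameter)) NA_real_ else as.numeric(m$parameter)
    m$schedule$boundaries <- as.numeric(unlist(m$schedule$boundaries))
    m$schedule$tier_points <- as.numeric(unlist(m$schedule$tier_points))
    m$schedule$max_points <- as.numeric(m$schedule$max_points)
    m
  })
  names(metrics) <- vapply(metrics, `[[`, character(1), "metric_id")
  gates <- raw$gates
  gates$max_delivery_min <- as.numeric(gates$max_delivery_min)
  scheme <- structure(
    list(name = raw$name, version = raw$version, provenance = raw$provenance,
         metrics = metrics, gates = gates),
    class = "pqm_scheme"
  )
  if (validate) {
    rep <- validate_scheme(scheme)
    if (!rep$valid)
      stop("invalid scoring scheme:\n  ",
           paste(rep$problems, collapse = "\n  "), call. = FALSE)
  }
  scheme
}

#' Validate a scoring scheme
#'
#' Checks every scheme invariant and returns a report listing all
#' violations: 16 unique metrics (6 PTV / 10 OAR), PTV maximum points
#' summing to 78 and OAR to 72 (total 150), tier boundaries strictly
#' monotone in the direction of improvement, tier points non-decreasing
#' from worst to best with 0 for the worst tier and the maximum for the
#' best, and a delivery-time gate.
#'
#' @param scheme a `pqm_scheme`.
#' @return A list with `valid` (logical) and `problems` (character vector).
#' @export
validate_scheme <- function(scheme) {
  p <- character(0)
  m <- scheme$metrics
  if (length(m) != 16L)
    p <- c(p, sprintf("scheme has %d metrics, expected 16", length(m)))
  ids <- vapply(m, `[[`, character(1), "metric_id")
  if (anyDuplicated(ids)) p <- c(p, "metric_ids are not unique")
  groups <- vapply(m, `[[`, character(1), "group")
  if (sum(groups == "PTV") != 6L)
    p <- c(p, sprintf("%d PTV metrics, expected 6", sum(groups == "PTV")))
  if (sum(groups == "OAR") != 10L)
    p <- c(p, sprintf("%d OAR metrics, expected 10", sum(groups == "OAR")))
  maxpts <- vapply(m, function(x) x$schedule$max_points, numeric(1))
  sp <- sum(maxpts[groups == "PTV"]); so <- sum(maxpts[groups == "OAR"])
  if (!isTRUE(all.equal(sp, 78)))
    p <- c(p, sprintf("PTV max points sum to %g, expected 78", sp))
  if (!isTRUE(all.equal(so, 72)))
    p <- c(p, sprintf("OAR max points sum to %g, expected 72", so))
  for (x in m) {
    s <- x$schedule
    b <- s$boundaries
    ord <- if (x$direction == "higher_better") diff(b) > 0 else diff(b) < 0
    if (length(b) > 1 && !all(ord))
      p <- c(p, sprintf("'%s': boundaries not strictly monotone towards improvement",
                        x$metric_id))
    if (length(s$tier_points) != length(b) + 1L)
      p <- c(p, sprintf("'%s': needs %d tier point values, has %d",
                        x$metric_id, length(b) + 1L, length(s$tier_points)))
    if (any(diff(s$tier_points) < 0))
      p <- c(p, sprintf("'%s': tier points decrease towards better tiers", x$metric_id))
    if (s$tier_points[1] != 0)
      p <- c(p, sprintf("'%s': worst tier must award 0 points", x$metric_id))
    if (!isTRUE(all.equal(s$tier_points[length(s$tier_points)], s$max_points)))
      p <- c(p, sprintf("'%s': best tier must award max_points", x$metric_id))
    if (!s$mode %in% c("tiered", "binary"))
      p <- c(p, sprintf("'%s': unknown schedule mode '%s'", x$metric_id, s$mode))
    if (s$mode == "binary" && length(b) != 1L)
      p <- c(p, sprintf("'%s': binary schedule needs exactly one boundary", x$metric_id))
  }
  if (is.null(scheme$gates$max_delivery_min) || !is.finite(scheme$gates$max_delivery_min))
    p <- c(p, "gates must include max_delivery_min")
  list(valid = length(p) == 0L, problems = p)
}

#' @export
print.pqm_scheme <- function(x, ...) {
  groups <- vapply(x$metrics, `[[`, character(1), "group")
  maxpts <- vapply(x$metrics, function(m) m$schedule$max_points, numeric(1))
  cat(sprintf("<pqm_scheme> '%s' (%s): %d metrics, PTV %g + OAR %g = %g points\n",
              x$name, x$provenance, length(x$metrics),
              sum(maxpts[groups == "PTV"]), sum(maxpts[groups == "OAR"]),
              sum(maxpts)))
  cat(sprintf("  delivery-time gate: %.4g min (inclusive); %d hard constraints\n",
              x$gates$max_delivery_min, length(x$gates$hard_constraints)))
  invisible(x)
}

tier_labels <- function(schedule) {
  if (schedule$mode == "binary") c("fail", "pass")
  else c("unacceptable", "marginal", "acceptable", "good", "ideal")
}

#' Score a single metric value against a tier schedule
#'
#' The tier is the position of the value among the schedule boundaries,
#' honouring the metric's direction of improvement. A value exactly on a
#' boundary takes the better tier (the inclusive rule, applied uniformly to
#' match the inclusive delivery-time limit).
#'
#' @param value metric value in its native unit; must be finite.
#' @param schedule a schedule list (`mode`, `boundaries`, `tier_points`,
#'   `max_points`) as found in `scheme$metrics[[i]]$schedule`.
#' @param direction `"higher_better"` or `"lower_better"`.
#' @return List with `tier` (label) and `points`.
#' @export
score_metric <- function(value, schedule, direction) {
  if (!is.finite(value))
    stop("cannot score a non-finite metric value", call. = FALSE)
  b <- schedule$boundaries
  k <- if (direction == "higher_better") sum(value >= b) else sum(value <= b)
  list(tier = tier_labels(schedule)[k + 1L],
       points = schedule$tier_points[k + 1L])
}

#' Apply acceptability gates
#'
#' A plan is unacceptable if its total delivery time exceeds the limit
#' (the limit itself is allowed: "20 min or less" is inclusive) or if any
#' hard dose constraint is violated. Gating never changes the numeric score,
#' only the acceptability flag.
#'
#' @param metric_values named numeric vector of the plan's metric values.
#' @param metadata list or one-row data frame with at least `delivery_min`.
#' @param scheme a `pqm_scheme`.
#' @return A data frame of gate failures (zero rows when acceptable) with
#'   columns `gate`, `bound`, `observed`.
#' @export
apply_gates <- function(metric_values, metadata, scheme) {
  if (is.null(metadata$delivery_min) || !is.finite(as.numeric(metadata$delivery_min)))
    stop("metadata must include a finite `delivery_min`", call. = FALSE)
  fails <- list()
  dt <- as.numeric(metadata$delivery_min)
  lim <- scheme$gates$max_delivery_min
  if (dt > lim)
    fails[[length(fails) + 1L]] <-
      data.frame(gate = "delivery_time", bound = lim, observed = dt)
  for (hc in scheme$gates$hard_constraints) {
    v <- metric_values[[hc$metric_id]]
    if (is.null(v) || !is.finite(v))
      stop(sprintf("hard constraint '%s' has no metric value", hc$metric_id),
           call. = FALSE)
    bad <- if (hc$direction == "lower_better") v > hc$bound else v < hc$bound
    if (bad)
      fails[[length(fails) + 1L]] <-
        data.frame(gate = hc$metric_id, bound = as.numeric(hc$bound), observed = v)
  }
  if (length(fails)) do.call(rbind, fails)
  else data.frame(gate = character(0), bound = numeric(0), observed = numeric(0))
}

#' Score a plan
#'
#' Scores all 16 metric values against the scheme, sums the PTV and OAR
#' subtotals into the plan quality metric (PQM, maximum 150), and applies
#' the acceptability gates.
#'
#' @param metric_values named numeric vector covering every scheme metric.
#' @param metadata list or one-row data frame of delivery metadata
#'   (at least `delivery_min`; `plan_id` is carried through if present).
#' @param scheme a `pqm_scheme`.
#' @return An object of class `pqm_scorecard`: `plan_id`, `metric_values`,
#'   `metric_points`, `metric_tiers`, `ptv_points`, `oar_points`, `pqm`,
#'   `acceptable`, `gate_failures`.
#' @export
score_plan <- function(metric_values, metadata, scheme) {
  ids <- names(scheme$metrics)
  missing <- setdiff(ids, names(metric_values))
  if (length(missing))
    stop("missing metric value(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  pts <- numeric(length(ids)); names(pts) <- ids
  tiers <- character(length(ids)); names(tiers) <- ids
  for (id in ids) {
    m <- scheme$metrics[[id]]
    sc <- score_metric(metric_values[[id]], m$schedule, m$direction)
    pts[id] <- sc$points
    tiers[id] <- sc$tier
  }
  groups <- vapply(scheme$metrics, `[[`, character(1), "group")
  ptv <- sum(pts[groups == "PTV"])
  oar <- sum(pts[groups == "OAR"])
  gf <- apply_gates(metric_values, metadata, scheme)
  structure(
    list(plan_id = if (!is.null(metadata$plan_id)) as.character(metadata$plan_id) else NA_character_,
         metric_values = metric_values[ids], metric_points = pts,
         metric_tiers = tiers, ptv_points = ptv, oar_points = oar,
         pqm = ptv + oar, acceptable = nrow(gf) == 0L, gate_failures = gf),
    class = "pqm_scorecard"
  )
}

#' @export
print.pqm_scorecard <- function(x, ...) {
  cat(sprintf("<pqm_scorecard> %s: PQM %.2f / 150 (PTV %.2f / 78, OAR %.2f / 72) - %s\n",
              x$plan_id, x$pqm, x$ptv_points, x$oar_points,
              if (x$acceptable) "acceptable" else "UNACCEPTABLE"))
  if (nrow(x$gate_failures)) {
    cat("  gate failures:\n")
    for (i in seq_len(nrow(x$gate_failures)))
      cat(sprintf("   - %s: observed %.4g vs bound %.4g\n",
                  x$gate_failures$gate[i], x$gate_failures$observed[i],
                  x$gate_failures$bound[i]))
  }
  invisible(x)
}

#' Ideal-score thresholds of a scheme
#'
#' The value at which each metric first earns its maximum points: the best
#' tier boundary for tiered schedules, the pass bound for binary ones. These
#' are the reference thresholds of the cohort deviation analysis.
#'
#' @param scheme a `pqm_scheme`.
#' @return Named numeric vector of thresholds in native metric units.
#' @export
ideal_thresholds <- function(scheme) {
  vapply(scheme$metrics, function(m) {
    b <- m$schedule$boundaries
    b[length(b)]
  }, numeric(1))
}

#' Metric directions of a scheme
#' @param scheme a `pqm_scheme`.
#' @return Named character vector (`"higher_better"`/`"lower_better"`).
#' @export
metric_directions <- function(scheme) {
  vapply(scheme$metrics, `[[`, character(1), "direction")
}
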