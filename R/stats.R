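#' Relative deviations from an ideal-score threshold
#'
#' Signed per-plan fractions `(value - threshold) / threshold` against the
#' threshold that earns maximum points. For a lower-is-better metric a
#' negative median deviation means the cohort's median performance is better
#' than the ideal threshold; for higher-is-better, a positive one.
#'
#' @param values numeric vector of per-plan metric values.
#' @param threshold ideal-score threshold in the metric's native unit
#'   (non-zero).
#' @param direction `"higher_better"` or `"lower_better"`.
#' @return List with `deviations` (raw signed fractions), `aligned`
#'   (direction-aligned: positive = better), and `median_better` (logical).
#' @export
relative_deviation <- function(values, threshold, direction = "higher_better") {
  if (!is.finite(threshold) || threshold == 0)
    stop("`threshold` must be finite and non-zero", call. = FALSE)
  if (length(values) < 1L) stop("no values supplied", call. = FALSE)
  dev <- (values - threshold) / threshold
  aligned <- if (direction == "lower_better") -dev else dev
  list(deviations = dev, aligned = aligned,
       median_better = stats::median(aligned) > 0)
}

# Distribution of the positive-rank sum over all 2^n sign assignments,
# by meet-in-the-middle subset sums (identical to full enumeration).
signed_rank_sums <- function(r) {
  half <- function(v) {
    s <- 0
    for (x in v) s <- c(s, s + x)
    s
  }
  n <- length(r)
  a <- half(r[seq_len(n %/% 2)])
  b <- half(r[seq.int(n %/% 2 + 1, n)])
  as.vector(outer(a, b, "+"))
}

#' Wilcoxon signed-rank test
#'
#' Two-sided one-sample signed-rank test (location zero). Zero differences
#' are dropped (classic Wilcoxon; set `zero_policy = "signed"` to keep them
#' with rank contributions split by sign convention of zero as positive
#' excluded — they then still contribute to the rank magnitudes). Ties get
#' average ranks. For n <= `exact_max` after zero handling, the two-sided p
#' is exact over all 2^n sign assignments (two times the smaller tail,
#' capped at 1); above that, a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param x numeric vector of differences (e.g. relative deviations).
#' @param exact_max largest n for exact enumeration (default 20; 2^20 sign
#'   vectors).
#' @param zero_policy `"drop"` (default) or `"signed"` (keep zeros in the
#'   ranking; they contribute half their rank to each side).
#' @return List with `statistic` (positive-rank sum V), `p_value`, `n_used`
#'   and `method` (`"exact"` or `"normal_approx"`).
#' @export
wilcoxon_signed_rank <- function(x, exact_max = 20L, zero_policy = c("drop", "signed")) {
  zero_policy <- match.arg(zero_policy)
  x <- x[is.finite(x)]
  if (zero_policy == "drop") x <- x[x != 0]
  if (length(x) < 3L || all(x == 0))
    stop("need at least 3 non-zero differences to test", call. = FALSE)
  r <- rank(abs(x))
  v <- sum(r[x > 0]) + if (zero_policy == "signed") sum(r[x == 0]) / 2 else 0
  n <- length(x)
  if (n <= exact_max) {
    sums <- signed_rank_sums(r)
    eps <- 1e-9
    p_lo <- mean(sums <= v + eps)
    p_hi <- mean(sums >= v - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)
    z <- (v - mu - sign(v - mu) * 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  list(statistic = v, p_value = p, n_used = n, method = method)
}

#' Cohort deviation analysis
#'
#' For every scheme metric: the per-plan relative deviations from the
#' ideal-score threshold, whether the cohort median outperforms the
#' threshold, and the two-sided signed-rank p-value for a shift away from
#' it. Significance stars: * p < 0.05, ** p < 0.01, *** p < 0.001; no
#' multiple-testing correction is applied.
#'
#' @param cohort a cohort table from [build_cohort_table()] (or any data
#'   frame with one column per metric).
#' @param scheme a `pqm_scheme` providing thresholds and directions.
#' @return A data frame of class `pqm_deviations`: metric_id, threshold,
#'   direction, median_value, median_deviation, median_deviation_aligned,
#'   median_better, p_value, stars.
#' @export
deviation_analysis <- function(cohort, scheme) {
  thr <- ideal_thresholds(scheme)
  dir <- metric_directions(scheme)
  rows <- lapply(names(scheme$metrics), function(id) {
    if (is.null(cohort[[id]]))
      stop(sprintf("cohort table lacks metric column '%s'", id), call. = FALSE)
    v <- cohort[[id]]
    if (any(!is.finite(v)))
      stop(sprintf("missing values in metric '%s'", id), call. = FALSE)
    rd <- relative_deviation(v, thr[[id]], dir[[id]])
    p <- tryCatch(wilcoxon_signed_rank(rd$deviations)$p_value,
                  error = function(e) NA_real_)
    data.frame(metric_id = id, threshold = thr[[id]], direction = dir[[id]],
               median_value = stats::median(v),
               median_deviation = stats::median(rd$deviations),
               median_deviation_aligned = stats::median(rd$aligned),
               median_better = rd$median_better,
               p_value = p, stars = p_stars(p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("pqm_deviations", class(out))
  out
}

p_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

#' Classify correlation strength
#'
#' Absolute-value thresholding with strict inequalities: |rho| > 0.7 strong,
#' 0.5 < |rho| <= 0.7 moderate, otherwise weak (|rho| = 0.5 is weak).
#'
#' @param rho correlation coefficient(s) in [-1, 1].
#' @return Character vector: `"strong"`, `"moderate"` or `"weak"`.
#' @export
classify_strength <- function(rho) {
  if (any(abs(rho[is.finite(rho)]) > 1))
    stop("`rho` must lie in [-1, 1]", call. = FALSE)
  ifelse(abs(rho) > 0.7, "strong", ifelse(abs(rho) > 0.5, "moderate", "weak"))
}

#' Spearman correlation matrix with significance
#'
#' All pairwise Spearman rank correlations (average ranks for ties) across
#' the cohort table's numeric columns, with p-values from the t
#' approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of
#' freedom (the approximation used by the usual rank-correlation routines),
#' strength classification, and a display flag reproducing the "only
#' moderate or stronger shown" matrix filter (|rho| > 0.5). Constant columns
#' yield undefined correlations, reported as `NA` (not 0) with
#' `computable = FALSE`.
#'
#' @param cohort data frame with >= 4 rows; non-numeric columns are ignored.
#' @return An object of class `pqm_correlations`: long data frame of pairs
#'   (field_a, field_b, rho, p_value, strength, displayed, computable, stars)
#'   with the full rho matrix as attribute `"rho_matrix"`.
#' @export
spearman_matrix <- function(cohort) {
  num <- cohort[vapply(cohort, is.numeric, logical(1))]
  if (nrow(num) < 4L) stop("need at least 4 plans for correlations", call. = FALSE)
  n <- nrow(num)
  const <- vapply(num, function(v) stats::sd(v) == 0, logical(1))
  rho <- suppressWarnings(stats::cor(num, method = "spearman"))
  rho[const, ] <- NA_real_
  rho[, const] <- NA_real_
  diag(rho) <- 1
  cols <- colnames(num)
  pairs <- utils::combn(cols, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    r <- rho[a, b]
    computable <- is.finite(r)
    p <- if (!computable) NA_real_
    else if (abs(r) >= 1) 0
    else {
      tt <- r * sqrt((n - 2) / (1 - r^2))
      2 * stats::pt(-abs(tt), df = n - 2)
    }
    data.frame(field_a = a, field_b = b, rho = r, p_value = p,
               strength = if (computable) classify_strength(r) else NA_character_,
               displayed = computable && abs(r) > 0.5,
               computable = computable, stars = p_stars(p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "rho_matrix") <- rho
  attr(out, "n") <- n
  class(out) <- c("pqm_correlations", class(out))
  out
}

#' PTV-vs-OAR trade-off fit
#'
#' Ordinary least-squares fit of one PTV metric against the OAR point
#' subtotal (or any two cohort columns), with the pointwise 95% confidence
#' band for the mean response: the descriptive trade-off summary between
#' target coverage and organ sparing.
#'
#' @param cohort cohort data frame (>= 3 rows).
#' @param x name of the predictor column (default `"oar_points"`).
#' @param y name of the response column (a PTV metric).
#' @param level confidence level for the band (default 0.95).
#' @return An object of class `pqm_tradeoff`: `slope`, `intercept`, `fit`
#'   (the `lm`), and `band(x0)`, a function returning fit/lwr/upr at new
#'   predictor values.
#' @export
tradeoff_fit <- function(cohort, x = "oar_points", y, level = 0.95) {
  if (is.null(cohort[[x]]) || is.null(cohort[[y]]))
    stop(sprintf("cohort table lacks column '%s' or '%s'", x, y), call. = FALSE)
  xv <- cohort[[x]]; yv <- cohort[[y]]
  if (length(xv) < 3L)
    stop("need at least 3 plans for a trade-off fit with a confidence band",
         call. = FALSE)
  if (stats::sd(xv) == 0)
    stop(sprintf("predictor '%s' is constant; fit undefined", x), call. = FALSE)
  df <- data.frame(.x = xv, .y = yv)
  fit <- stats::lm(.y ~ .x, data = df)
  band <- function(x0) {
    p <- stats::predict(fit, newdata = data.frame(.x = x0),
                        interval = "confidence", level = level)
    data.frame(x = x0, fit = p[, "fit"], lwr = p[, "lwr"], upr = p[, "upr"])
  }
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         x = x, y = y, level = level, fit = fit, band = band),
    class = "pqm_tradeoff"
  )
}

#' @export
print.pqm_tradeoff <- function(x, ...) {
  cat(sprintf("<pqm_tradeoff> %s ~ %s: slope %.4g, intercept %.4g (%d%% band)\n",
              x$y, x$x, x$slope, x$intercept, round(100 * x$level)))
  invisible(x)
}

#' Assemble the cohort table
#'
#' Binds per-plan scorecards and delivery metadata into the plans-by-metrics
#' table feeding the deviation and correlation analyses: 16 metric values,
#' the PTV/OAR subtotals and PQM, and the delivery metadata columns. Missing
#' cells are an error, never silently imputed.
#'
#' @param scorecards list of `pqm_scorecard`s.
#' @param metadata data frame from [cohort_metadata()].
#' @return A data frame with one row per plan.
#' @export
build_cohort_table <- function(scorecards, metadata) {
  vals <- do.call(rbind, lapply(scorecards, function(s)
    as.data.frame(as.list(s$metric_values))))
  extra <- data.frame(
    plan_id = vapply(scorecards, `[[`, character(1), "plan_id"),
    ptv_points = vapply(scorecards, `[[`, numeric(1), "ptv_points"),
    oar_points = vapply(scorecards, `[[`, numeric(1), "oar_points"),
    pqm = vapply(scorecards, `[[`, numeric(1), "pqm"),
    acceptable = vapply(scorecards, `[[`, logical(1), "acceptable"),
    stringsAsFactors = FALSE
  )
  tab <- cbind(extra["plan_id"], vals,
               extra[c("ptv_points", "oar_points", "pqm", "acceptable")])
  md <- metadata[setdiff(names(metadata), "seed")]
  tab <- merge(tab, md, by = "plan_id", sort = FALSE)
  num <- tab[vapply(tab, is.numeric, logical(1))]
  if (any(!vapply(num, function(v) all(is.finite(v)), logical(1))))
    stop("cohort table contains missing cells", call. = FALSE)
  tab
}
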