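test_that("the default scheme validates with the published point structure", {
  scheme <- load_scheme()
  expect_length(scheme$metrics, 16)
  groups <- vapply(scheme$metrics, `[[`, character(1), "group")
  expect_equal(sum(groups == "PTV"), 6)
  expect_equal(sum(groups == "OAR"), 10)
  maxpts <- vapply(scheme$metrics, function(m) m$schedule$max_points, numeric(1))
  expect_equal(sum(maxpts[groups == "PTV"]), 78)
  expect_equal(sum(maxpts[groups == "OAR"]), 72)
  expect_true(validate_scheme(scheme)$valid)
})

test_that("scheme validation reports every violation", {
  scheme <- load_scheme()
  s15 <- scheme; s15$metrics <- s15$metrics[-1]
  rep <- validate_scheme(s15)
  expect_false(rep$valid)
  expect_true(any(grepl("15 metrics", rep$problems)))
  sbad <- scheme
  sbad$metrics[["ptv1_d95"]]$schedule$max_points <- 15
  sbad$metrics[["ptv1_d95"]]$schedule$tier_points <- c(0, 3.75, 7.5, 11.25, 15)
  rep2 <- validate_scheme(sbad)
  expect_false(rep2$valid)
  expect_true(any(grepl("sum to 80", rep2$problems)))
  sbad2 <- scheme
  sbad2$metrics[["ptv1_d95"]]$schedule$boundaries <- c(63, 66.5, 65.5, 64.5)
  expect_false(validate_scheme(sbad2)$valid)
})

test_that("tier assignment honors direction and the inclusive boundary rule", {
  scheme <- load_scheme()
  cn_sched <- scheme$metrics[["ptv3_cn"]]$schedule
  expect_equal(score_metric(0.75, cn_sched, "higher_better")$tier, "good")
  expect_equal(score_metric(0.85, cn_sched, "higher_better")$tier, "ideal")
  expect_equal(score_metric(0.65, cn_sched, "higher_better")$tier, "acceptable")
  expect_equal(score_metric(0.4, cn_sched, "higher_better")$tier, "unacceptable")
  expect_equal(score_metric(0.4, cn_sched, "higher_better")$points, 0)
  # exact boundary takes the better tier, both directions
  expect_equal(score_metric(0.8, cn_sched, "higher_better")$tier, "ideal")
  sp_sched <- scheme$metrics[["spinal_canal_d0_1cc"]]$schedule
  expect_equal(score_metric(45.0, sp_sched, "lower_better")$tier, "ideal")
  expect_equal(score_metric(45.0001, sp_sched, "lower_better")$tier, "good")
  # binary: fail scores 0, pass scores max
  bp_sched <- scheme$metrics[["brachial_plexus_d0_5cc"]]$schedule
  expect_equal(score_metric(55, bp_sched, "lower_better")$points, 0)
  expect_equal(score_metric(55, bp_sched, "lower_better")$tier, "fail")
  expect_equal(score_metric(54, bp_sched, "lower_better")$points, 6)
  expect_error(score_metric(NaN, bp_sched, "lower_better"), "non-finite")
})

test_that("points step function is stable around every boundary (property)", {
  scheme <- load_scheme()
  for (m in scheme$metrics) {
    for (b in m$schedule$boundaries) {
      at <- score_metric(b, m$schedule, m$direction)$points
      eps <- 1e-9 * max(1, abs(b))
      better <- if (m$direction == "higher_better") b + eps else b - eps
      worse <- if (m$direction == "higher_better") b - eps else b + eps
      expect_equal(score_metric(better, m$schedule, m$direction)$points, at)
      expect_lte(score_metric(worse, m$schedule, m$direction)$points, at)
    }
  }
})

test_that("improving any single metric never lowers its points or the PQM", {
  scheme <- load_scheme()
  set.seed(60)
  ideal <- ideal_thresholds(scheme)
  dirs <- metric_directions(scheme)
  meta <- list(plan_id = "p", delivery_min = 18)
  for (rep in 1:10) {
    vals <- ideal * stats::runif(length(ideal), 0.7, 1.3)
    names(vals) <- names(ideal)
    vals["ptv3_cn"] <- stats::runif(1, 0, 1)
    base <- score_plan(vals, meta, scheme)
    expect_gte(base$pqm, 0); expect_lte(base$pqm, 150)
    expect_equal(base$pqm, base$ptv_points + base$oar_points)
    id <- sample(names(vals), 1)
    step <- if (id == "ptv3_cn") 0.05 else 0.8
    vals2 <- vals
    vals2[id] <- vals[id] + if (dirs[[id]] == "higher_better") step else -step
    improved <- score_plan(vals2, meta, scheme)
    expect_gte(improved$metric_points[[id]], base$metric_points[[id]])
    expect_gte(improved$pqm, base$pqm)
  }
})

test_that("gates flag delivery time and hard constraints without altering the score", {
  scheme <- load_scheme()
  ideal <- ideal_thresholds(scheme)
  ok <- score_plan(ideal, list(plan_id = "a", delivery_min = 20.0), scheme)
  expect_true(ok$acceptable)           # 20 min exactly is allowed
  late <- score_plan(ideal, list(plan_id = "b", delivery_min = 22.4), scheme)
  expect_false(late$acceptable)
  expect_equal(nrow(late$gate_failures), 1)
  expect_equal(late$gate_failures$gate, "delivery_time")
  expect_equal(late$pqm, ok$pqm)       # gating never changes the number
  # a violated hard constraint scores 0 on its binary metric and gates
  vals <- ideal; vals["brachial_plexus_d0_5cc"] <- 56
  gated <- score_plan(vals, list(plan_id = "c", delivery_min = 18), scheme)
  expect_false(gated$acceptable)
  expect_equal(gated$metric_points[["brachial_plexus_d0_5cc"]], 0)
  expect_error(apply_gates(ideal, list(), scheme), "delivery_min")
})

test_that("score_plan requires every scheme metric", {
  scheme <- load_scheme()
  vals <- ideal_thresholds(scheme)
  expect_error(score_plan(vals[-3], list(delivery_min = 18), scheme),
               names(vals)[3])
})
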