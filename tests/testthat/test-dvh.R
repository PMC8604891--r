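test_that("cumulative DVH matches voxel counting on simple structures", {
  u <- uniform_fixture(50)
  dvh <- compute_dvh(u$dose, u$mask)
  expect_equal(dvh$cum_volume_fraction[1], 1.0)
  expect_true(all(dvh$cum_volume_fraction[dvh$dose_edges <= 50] == 1.0))
  expect_true(all(dvh$cum_volume_fraction[dvh$dose_edges > 50] == 0.0))

  # two equal voxels at 40 and 60 Gy: 1.0 up to 40, 0.5 on (40, 60], 0 above
  sp <- c(2, 2, 2)
  d <- dose_grid(array(c(40, 60), c(2, 1, 1)), sp)
  m <- structure_mask("two", array(TRUE, c(2, 1, 1)), sp)
  dvh2 <- compute_dvh(d, m)
  f_at <- function(gy) dvh2$cum_volume_fraction[match(TRUE, abs(dvh2$dose_edges - gy) < 1e-9)]
  expect_equal(f_at(40), 1.0)
  expect_equal(f_at(40.01), 0.5)
  expect_equal(f_at(60), 0.5)
  expect_equal(dvh2$cum_volume_fraction[length(dvh2$cum_volume_fraction)], 0)
})

test_that("DVH rejects empty masks and misaligned grids", {
  u <- uniform_fixture(10)
  empty <- structure_mask("none", array(FALSE, dim(u$dose$values)), u$dose$spacing_mm)
  expect_error(compute_dvh(u$dose, empty), "empty")
  expect_error(mean_dose(u$dose, empty), "empty")
  other <- structure_mask("o", array(TRUE, c(3, 3, 3)), c(2, 2, 2))
  expect_error(compute_dvh(u$dose, other), "mismatch")
})

test_that("inverse DVH queries match the sorted-voxel oracle", {
  # 10 equal voxels with doses 1..10 Gy
  sp <- c(2, 2, 2)
  d <- dose_grid(array(1:10, c(10, 1, 1)), sp)
  m <- structure_mask("ten", array(TRUE, c(10, 1, 1)), sp)
  dvh <- compute_dvh(d, m)
  for (x in c(5, 25, 50, 95, 100)) {
    expect_lt(abs(dose_at_volume_percent(dvh, x) -
                  oracle_dose_at_fraction(1:10, x / 100)), 0.005 + 1e-9)
  }
  # x = 100 is the structure minimum
  d2 <- dose_grid(array(c(40, 60), c(2, 1, 1)), sp)
  m2 <- structure_mask("two", array(TRUE, c(2, 1, 1)), sp)
  expect_equal(dose_at_volume_percent(compute_dvh(d2, m2), 100), 40,
               tolerance = 0.005 / 40)

  # random grids: every metric vs the oracle, within half a bin width
  for (seed in 1:5) {
    fx <- random_grid_fixture(c(14, 11, 9), seed = seed)
    doses <- fx$dose$values[fx$mask$voxels]
    dvh <- compute_dvh(fx$dose, fx$mask)
    for (x in c(2, 30, 50, 80, 95, 98)) {
      expect_lt(abs(dose_at_volume_percent(dvh, x) -
                    oracle_dose_at_fraction(doses, x / 100)), 0.005 + 1e-9)
    }
    vv <- voxel_volume_cc(fx$mask)
    for (v_cc in c(vv, 3 * vv, 0.25 * structure_volume_cc(fx$mask))) {
      expect_lt(abs(dose_at_volume_cc(dvh, v_cc) -
                    oracle_dose_at_fraction(doses, v_cc / structure_volume_cc(fx$mask))),
                0.005 + 1e-9)
    }
    for (gy in c(0, 10, 35.5, 69, 200))
      expect_equal(volume_at_dose_percent(dvh, gy),
                   oracle_volume_at_dose(doses, gy), tolerance = 1e-3)
    expect_equal(mean_dose(fx$dose, fx$mask), mean(doses), tolerance = 1e-9)
  }
})

test_that("inverse DVH argument validation", {
  u <- uniform_fixture(42)
  dvh <- compute_dvh(u$dose, u$mask)
  # uniform dose: result within half a bin of the exact 42 Gy
  expect_lt(abs(dose_at_volume_percent(dvh, 95) - 42), 0.005 + 1e-9)
  expect_lt(abs(dose_at_volume_cc(dvh, 0.5) - 42), 0.005 + 1e-9)
  expect_error(dose_at_volume_percent(dvh, 0), "\\(0, 100\\]")
  expect_error(dose_at_volume_percent(dvh, 101), "\\(0, 100\\]")
  expect_error(dose_at_volume_cc(dvh, structure_volume_cc(u$mask) * 1.01),
               "exceeds structure volume")
  # the full structure volume returns the minimum dose
  expect_lt(abs(dose_at_volume_cc(dvh, structure_volume_cc(u$mask)) - 42),
            0.005 + 1e-9)
})

test_that("DVH cumulative fraction is monotone non-increasing (property)", {
  for (seed in 1:8) {
    fx <- random_grid_fixture(c(9, 9, 9), seed = 100 + seed)
    dvh <- compute_dvh(fx$dose, fx$mask)
    expect_true(all(diff(dvh$cum_volume_fraction) <= 0))
    expect_equal(dvh$cum_volume_fraction[1], 1.0)
    # D100 <= Dmean <= D at smallest queryable volume
    d100 <- dose_at_volume_percent(dvh, 100)
    dm <- mean_dose(fx$dose, fx$mask)
    dtop <- dose_at_volume_cc(dvh, voxel_volume_cc(fx$mask))
    expect_lte(d100, dm + 0.005)
    expect_lte(dm, dtop + 0.005)
    # dose_at_volume_percent non-increasing in x
    xs <- c(5, 20, 40, 60, 80, 95, 100)
    ds <- vapply(xs, function(x) dose_at_volume_percent(dvh, x), numeric(1))
    expect_true(all(diff(ds) <= 1e-9))
  }
})

test_that("halving the bin width moves inverse metrics by less than a bin", {
  fx <- random_grid_fixture(c(12, 12, 6), seed = 42)
  for (bw in c(0.08, 0.04, 0.02)) {
    a <- dose_at_volume_percent(compute_dvh(fx$dose, fx$mask, bw), 95)
    b <- dose_at_volume_percent(compute_dvh(fx$dose, fx$mask, bw / 2), 95)
    expect_lt(abs(a - b), bw)
  }
})

test_that("ring structures obey set identities", {
  sp <- c(2, 2, 2)
  a <- array(FALSE, c(6, 6, 6)); a[2:5, 2:5, 2:5] <- TRUE
  b <- array(FALSE, c(6, 6, 6)); b[3:4, 3:4, 3:4] <- TRUE
  outer_m <- structure_mask("outer", a, sp)
  inner_m <- structure_mask("inner", b, sp)
  r <- ring(outer_m, inner_m)
  expect_equal(structure_volume_cc(r),
               structure_volume_cc(outer_m) - structure_volume_cc(inner_m))
  expect_equal(r$name, "outer-inner")
  # inner == outer -> empty (allowed; metrics on it error)
  r2 <- ring(outer_m, outer_m)
  expect_equal(sum(r2$voxels), 0)
  expect_error(compute_dvh(dose_grid(array(1, c(6, 6, 6)), sp), r2), "empty")
  # disjoint inner -> ring == outer
  d <- array(FALSE, c(6, 6, 6)); d[1, 1, 1] <- TRUE
  r3 <- ring(outer_m, structure_mask("d", d, sp))
  expect_equal(r3$voxels, outer_m$voxels)
})

test_that("conformation number matches the voxel-count formula", {
  # reference isodose exactly equal to target -> CN = 1
  sp <- c(2, 2, 2)
  vals <- array(0, c(10, 10, 10)); tgt <- array(FALSE, c(10, 10, 10))
  tgt[3:7, 3:7, 3:7] <- TRUE; vals[tgt] <- 60
  cc <- conformation_number(dose_grid(vals, sp), structure_mask("t", tgt, sp), 54)
  expect_equal(cc$cn, 1.0)
  expect_false(cc$degenerate)

  # TV 1000, VRI 1200, overlap 900 -> CN = 900^2/(1000*1200) = 0.675
  n <- 20 * 20 * 10
  vals <- numeric(n); tgtv <- logical(n)
  tgtv[1:1000] <- TRUE
  vals[101:1300] <- 60          # 1200 voxels at reference; 900 inside target
  cc2 <- conformation_number(dose_grid(array(vals, c(20, 20, 10)), sp),
                             structure_mask("t", array(tgtv, c(20, 20, 10)), sp), 54)
  expect_equal(cc2$cn, 0.675)
  expect_equal(cc2$tvri_cc, 900 * 0.008)
  expect_equal(cc2$vri_cc, 1200 * 0.008)

  # no voxel at reference dose -> CN = 0 with degenerate flag, not an error
  cc3 <- conformation_number(dose_grid(array(10, c(4, 4, 4)), sp),
                             structure_mask("t", array(TRUE, c(4, 4, 4)), sp), 54)
  expect_equal(cc3$cn, 0)
  expect_true(cc3$degenerate)

  # random grids: formula equality and coverage x selectivity decomposition
  for (seed in 1:6) {
    fx <- random_grid_fixture(c(10, 10, 10), seed = 200 + seed)
    cc4 <- conformation_number(fx$dose, fx$mask, 40)
    expect_equal(cc4$cn, oracle_cn(fx$dose$values, fx$mask$voxels, 40),
                 tolerance = 1e-12)
    expect_gte(cc4$cn, 0); expect_lte(cc4$cn, 1)
    if (!cc4$degenerate)
      expect_equal(cc4$cn, cc4$coverage * cc4$selectivity, tolerance = 1e-12)
    expect_gte(cc4$coverage, 0); expect_lte(cc4$coverage, 1)
  }
})
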