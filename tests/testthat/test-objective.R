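test_that("prescription terms and specs validate their fields", {
  expect_error(prescription_term("dvh_max", "oar", 1, 10), "fraction")
  expect_error(prescription_term("target_lsq", "t", 1, 10, fraction = 0.5),
               "only applies")
  expect_error(prescription_term("target_lsq", "t", -1, 10), ">= 0")
  expect_error(objective_spec(list(
    prescription_term("oar_lsq", "o", 1, 5))), "target_lsq")
  expect_error(objective_spec(list(
    prescription_term("target_lsq", "t", 1, 8),
    prescription_term("dvh_min", "t", 1, 7, fraction = .9),
    prescription_term("dvh_min", "t", 1, 6, fraction = .9))), "at most one")
  spec <- objective_spec(list(
    prescription_term("target_lsq", "t", 1, 8),
    prescription_term("oar_lsq", "o", 1, 5),
    prescription_term("dvh_max", "o", 1, 5, fraction = .5)))
  expect_equal(spec$N1, 2)
  expect_equal(spec$N2, 1)
})

test_that("DVH active sets reproduce hand-worked examples", {
  fs <- flat_structures(8, target = 1:4, oar = 5:8)
  d <- numeric(8)
  d[5:8] <- c(9, 7, 3, 1)

  spec <- objective_spec(list(
    prescription_term("target_lsq", "target", 1, 8),
    prescription_term("dvh_max", "oar", 1, 5, fraction = 0.5)))
  sets <- identify_active_sets(d, spec, fs$structures)
  # descending OAR doses (9,7,3,1), k = 2, d'_2 = 7 >= 5:
  # active tail = ranks >= 2 with dose > 5 -> just the dose-7 voxel
  expect_equal(sets$sets[[2]]$indices, 6L)

  # all below the bound: empty set
  sets2 <- identify_active_sets(c(numeric(4), 4, 3, 2, 1), spec, fs$structures)
  expect_length(sets2$sets[[2]]$indices, 0)

  # DVH-min: target doses (10,9,2,1), p = .5, b3 = 8 -> d'_2 = 9 > 8, empty
  dmin <- c(10, 9, 2, 1, numeric(4))
  spec3 <- objective_spec(list(
    prescription_term("target_lsq", "target", 1, 8),
    prescription_term("dvh_min", "target", 1, 8, fraction = 0.5)))
  sets3 <- identify_active_sets(dmin, spec3, fs$structures)
  expect_length(sets3$sets[[2]]$indices, 0)

  # triggered DVH-min: b3 = 9.5 -> d'_2 = 9 <= 9.5, active = rank-2 voxel
  spec4 <- objective_spec(list(
    prescription_term("target_lsq", "target", 1, 8),
    prescription_term("dvh_min", "target", 1, 9.5, fraction = 0.5)))
  sets4 <- identify_active_sets(dmin, spec4, fs$structures)
  expect_equal(sets4$sets[[2]]$indices, 2L)

  # unknown structure
  spec5 <- objective_spec(list(prescription_term("target_lsq", "nope", 1, 8)))
  expect_error(identify_active_sets(d, spec5, fs$structures), "unknown structure")
})

test_that("active sets match an independent rank-based implementation", {
  fs <- flat_structures(40, target = 1:12, oar = 21:35)
  spec <- objective_spec(list(
    prescription_term("target_lsq", "target", 2, 8),
    prescription_term("oar_lsq", "oar", 1, 3),
    prescription_term("dvh_max", "oar", 1, 5, fraction = 0.4),
    prescription_term("dvh_min", "target", 1, 7.5, fraction = 0.9)))
  set.seed(42)
  for (trial in 1:200) {
    d <- round(stats::runif(40, 0, 10), 1)   # rounding forces ties
    sets <- identify_active_sets(d, spec, fs$structures)
    # independent route: rank() with ties.method = "first" on negated dose
    oar <- 21:35; tgt <- 1:12
    r_oar <- rank(-d[oar], ties.method = "first")
    k <- ceiling(0.4 * 15)
    exp_max <- if (sort(d[oar], decreasing = TRUE)[k] >= 5)
      oar[r_oar >= k & d[oar] > 5] else integer(0)
    expect_equal(sort(sets$sets[[3]]$indices), sort(exp_max))
    r_t <- rank(-d[tgt], ties.method = "first")
    kt <- ceiling(0.9 * 12)
    exp_min <- if (sort(d[tgt], decreasing = TRUE)[kt] <= 7.5)
      tgt[r_t <= kt & d[tgt] < 7.5] else integer(0)
    expect_equal(sort(sets$sets[[4]]$indices), sort(exp_min))
    expect_equal(sets$sets[[1]]$indices, tgt[d[tgt] != 8])
    expect_equal(sets$sets[[2]]$indices, oar[d[oar] > 3])
  }
})

test_that("objective evaluation matches hand arithmetic and scales in w", {
  fs <- flat_structures(4, target = 1:4)
  mk <- function(w) objective_spec(list(
    prescription_term("target_lsq", "target", w, 8)))
  d <- c(8, 8, 6, 8)
  s1 <- identify_active_sets(d, mk(1), fs$structures)
  expect_equal(evaluate_objective(d, mk(1), s1), (1 / 4) * (6 - 8)^2)
  s2 <- identify_active_sets(d, mk(2), fs$structures)
  expect_equal(evaluate_objective(d, mk(2), s2), 2 * 1.0)

  # perfect plan scores zero
  dperf <- c(8, 8, 8, 8)
  sp <- identify_active_sets(dperf, mk(1), fs$structures)
  expect_equal(evaluate_objective(dperf, mk(1), sp), 0)
})

test_that("per-voxel quadratic reproduces the objective, merging overlaps", {
  # body term overlaps the target: voxels belong to two terms
  fs <- flat_structures(30, target = 5:14, oar = 20:28)
  spec <- objective_spec(list(
    prescription_term("target_lsq", "target", 3, 8),
    prescription_term("oar_lsq", "body", 0.5, 1),
    prescription_term("oar_lsq", "oar", 2, 2),
    prescription_term("dvh_max", "oar", 1, 4, fraction = 0.5)))
  set.seed(99)
  for (trial in 1:50) {
    d <- stats::runif(30, 0, 10)
    sets <- identify_active_sets(d, spec, fs$structures)
    vq <- voxel_quadratic(spec, sets)
    direct <- evaluate_objective(d, spec, sets)
    viaq <- if (length(vq$voxel)) sum(vq$alpha * (d[vq$voxel] - vq$beta)^2) +
      vq$const else vq$const
    expect_lt(abs(direct - viaq), 1e-10 * max(1, direct))
    # quadratic must hold for arbitrary doses on the frozen sets
    d2 <- stats::runif(30, 0, 12)
    direct2 <- evaluate_objective(d2, spec, sets)
    viaq2 <- sum(vq$alpha * (d2[vq$voxel] - vq$beta)^2) + vq$const
    expect_lt(abs(direct2 - viaq2), 1e-10 * max(1, direct2))
  }

  # empty active sets: empty quadratic, f == 0
  spec0 <- objective_spec(list(prescription_term("target_lsq", "target", 1, 0)))
  sets0 <- identify_active_sets(numeric(30), spec0, fs$structures)
  vq0 <- voxel_quadratic(spec0, sets0)
  expect_length(vq0$voxel, 0)
  expect_equal(evaluate_objective(numeric(30), spec0, sets0), 0)
})
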