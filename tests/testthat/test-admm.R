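test_that("initialization is seeded-deterministic with the documented layout", {
  inst <- offset_instance()
  cfg <- qcbao_config(N_select = 2)
  a <- qcbao_init(inst, cfg, seed = 4)
  b <- qcbao_init(inst, cfg, seed = 4)
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)
  # consensus copies equal intensities, duals start at zero
  expect_identical(a$z, a$x)
  expect_true(all(vapply(a$lambda1, function(v) all(v == 0), TRUE)))
  expect_equal(a$lambda2, 0)
  # default start: every candidate on; subset mode: exactly N_select on
  expect_equal(sum(a$y), nrow(inst$candidates))
  s <- qcbao_init(inst, cfg, seed = 4, init_y = "subset")
  expect_equal(sum(s$y), 2)
})

test_that("x-update solves the per-beam normal equations", {
  # scalar case: one spot, one voxel, A = [2], alpha = 1, beta = 8, mu1 = 1,
  # consensus anchor 0  ->  x = (2*2*8) / (2*4 + 1) = 32/9
  inst1 <- one_voxel_instance(a = 2, b = 8, w = 1)
  cfg1 <- qcbao_config(N_select = 1, mu1 = 1, G = 0.01)
  st <- qcbao_init(inst1, cfg1, seed = 1)
  st$x[[1]] <- 1; st$z[[1]] <- 0; st$lambda1[[1]] <- 0; st$y <- 1
  st <- qcbao:::refresh_active_sets(st, inst1)
  st <- update_x(st, inst1)
  expect_equal(st$x[[1]], 32 / 9, tolerance = 1e-12)

  # deselected beams take the consensus-only minimum z + lambda1
  inst <- offset_instance()
  cfg <- qcbao_config(N_select = 1, G = 0.05)
  s2 <- qcbao_init(inst, cfg, seed = 2, init_y = "subset")
  for (i in seq_along(s2$lambda1))
    s2$lambda1[[i]] <- stats::rnorm(length(s2$lambda1[[i]]), sd = 0.1)
  s2 <- qcbao:::refresh_active_sets(s2, inst)
  s2 <- update_x(s2, inst)
  off <- which(s2$y < 0.5)
  for (i in off)
    expect_equal(s2$x[[i]], s2$z[[i]] + s2$lambda1[[i]])
})

test_that("x-update is stationary for its subproblem (finite differences)", {
  inst <- offset_instance()
  for (sd in 1:4) {
    cfg <- qcbao_config(N_select = 1)
    st <- qcbao_init(inst, cfg, seed = sd, init_y = "subset")
    st <- qcbao:::refresh_active_sets(st, inst)
    st <- update_x(st, inst)
    i <- which(st$y > 0.5)
    A <- inst$dose_influence[[i]]$matrix[st$vq$voxel, , drop = FALSE]
    h <- function(x) sum(st$vq$alpha * (as.numeric(A %*% x) - st$vq$beta)^2) +
      (st$mu1 / 2) * sum((x - st$z[[i]] - st$lambda1[[i]])^2)
    x0 <- st$x[[i]]
    eps <- 1e-5
    grad <- vapply(seq_along(x0), function(j) {
      e <- numeric(length(x0)); e[j] <- eps
      (h(x0 + e) - h(x0 - e)) / (2 * eps)
    }, 1.0)
    expect_lt(sqrt(sum(grad^2)), 1e-6)
  }
})

test_that("z-update implements the MMU proximal rule", {
  inst <- one_voxel_instance()
  cfg <- qcbao_config(N_select = 1, G = 2, mu1 = 1)
  st <- qcbao_init(inst, cfg, seed = 1)
  G <- 2
  v <- c(0, -1, G / 2, G / 2 - 1e-9, G, 1.5 * G, 10)
  st$x[[1]] <- v; st$lambda1[[1]] <- numeric(length(v))
  st$z[[1]] <- numeric(length(v))
  st <- update_z(st)
  expect_equal(st$z[[1]], c(0, 0, G, 0, G, 1.5 * G, 10))

  # dense grid-search oracle over {0} u [G, inf)
  set.seed(8)
  vv <- c(stats::runif(500, -2 * G, 4 * G), G / 2)
  st$x[[1]] <- vv; st$lambda1[[1]] <- numeric(length(vv))
  st$z[[1]] <- numeric(length(vv))
  st <- update_z(st)
  # ties (exactly v = G/2) resolve toward the deliverable piece, as printed
  grid <- seq(G, 5 * G, length.out = 40001)
  oracle <- vapply(vv, function(v) {
    zg <- grid[which.min((v - grid)^2)]
    if ((v - zg)^2 <= v^2) zg else 0
  }, 1.0)
  expect_lt(max(abs(st$z[[1]] - oracle)), 2e-4)
})

test_that("dual updates follow the printed ascent rules", {
  inst <- offset_instance()
  cfg <- qcbao_config(N_select = 2)
  st <- qcbao_init(inst, cfg, seed = 1, init_y = "subset")
  st$z <- lapply(st$x, function(v) v + 0.5)
  st0 <- st
  st <- update_duals(st, cfg)
  for (i in seq_along(st$x))
    expect_equal(st$lambda1[[i]], st0$lambda1[[i]] + st0$z[[i]] - st0$x[[i]])
  expect_equal(st$lambda2, sum(st0$y) - 2)

  # x == z leaves lambda1 unchanged; sum(y) == N leaves lambda2 unchanged
  st2 <- qcbao_init(inst, cfg, seed = 1, init_y = "subset")
  l0 <- st2$lambda1
  st2 <- update_duals(st2, cfg)
  for (i in seq_along(l0)) expect_equal(st2$lambda1[[i]], l0[[i]])
  expect_equal(st2$lambda2, 0)
})

test_that("y-update honors the cardinality penalty in degenerate cases", {
  inst <- offset_instance()
  B <- nrow(inst$candidates)
  cfg <- qcbao_config(N_select = 2, mu2 = 1e6, backend = "exact")
  st <- qcbao_init(inst, cfg, seed = 3)
  st <- qcbao:::refresh_active_sets(st, inst)

  # zero doses + huge mu2: y minimizes the penalty alone
  st$x <- lapply(st$x, function(v) numeric(length(v)))
  st$lambda2 <- 0
  st <- update_y(st, inst, cfg)
  expect_equal(sum(st$y), 2)

  # B == N_select with huge mu2: all beams on
  cfg_all <- qcbao_config(N_select = B, mu2 = 1e6, backend = "exact")
  st2 <- qcbao_init(inst, cfg_all, seed = 3)
  st2 <- qcbao:::refresh_active_sets(st2, inst)
  st2 <- update_y(st2, inst, cfg_all)
  expect_equal(st2$y, rep(1, B))
})

test_that("step 1 runs the documented iteration and keeps a full trace", {
  inst <- corridor_instance()
  cfg <- qcbao_config(N_select = 3, T_outer = 0)
  st0 <- qcbao_init(inst, cfg, seed = 1)
  expect_identical(run_step1(inst, cfg, seed = 1), st0)

  cfg5 <- qcbao_config(N_select = 3, T_outer = 5, backend = "sa")
  st <- run_step1(inst, cfg5, seed = 1)
  expect_length(st$trace, 5)
  expect_true(all(vapply(st$trace, function(t) is.finite(t$objective), TRUE)))
})

test_that("selection projection restores exact cardinality deterministically", {
  inst <- corridor_instance()
  cfg <- qcbao_config(N_select = 3, backend = "exact")
  st <- qcbao_init(inst, cfg, seed = 2)
  # scale intensities down so every contributing beam is needed (underdose)
  st$x <- lapply(st$x, function(v) 0.4 * v)
  st$z <- st$x
  st <- qcbao:::refresh_active_sets(st, inst)

  y_ok <- c(1, 1, 1, 0, 0, 0, 0, 0)
  expect_equal(project_selection(y_ok, st, inst, cfg), y_ok)

  # four beams on, one of them with zero dose contribution: it gets dropped
  st$x[[4]] <- numeric(length(st$x[[4]]))
  y4 <- c(1, 1, 1, 1, 0, 0, 0, 0)
  proj <- project_selection(y4, st, inst, cfg)
  expect_equal(sum(proj), 3)
  expect_equal(proj[4], 0)

  set.seed(10)
  for (trial in 1:10) {
    y <- as.numeric(stats::runif(8) < 0.5)
    p1 <- project_selection(y, st, inst, cfg)
    p2 <- project_selection(y, st, inst, cfg)
    expect_equal(sum(p1), 3)
    expect_identical(p1, p2)
  }
})

test_that("step 2 refines without raising the objective and respects the MMU", {
  inst <- corridor_instance()
  for (sd in 1:5) {
    cfg <- qcbao_config(N_select = 3, backend = "sa", normalize_d95 = FALSE)
    st <- run_step1(inst, cfg, seed = sd)
    st <- qcbao:::refresh_active_sets(st, inst)
    y <- project_selection(st$y, st, inst, cfg)
    st$y <- y
    d1 <- qcbao:::dose_from(inst, y, st$x)
    sets1 <- identify_active_sets(d1, st$spec, inst$structures)
    obj1 <- evaluate_objective(d1, st$spec, sets1)
    plan <- run_step2(inst, cfg, y, warm_state = st)
    expect_lte(plan$objective, obj1 + 1e-6)
    for (z in plan$intensities)
      expect_true(all(z == 0 | z >= plan$G - 1e-12))
  }

  # T_refine = 0 returns the warm plan's metrics
  cfg0 <- qcbao_config(N_select = 3, T_refine = 0, normalize_d95 = FALSE)
  st <- run_step1(inst, cfg0, seed = 1)
  st <- qcbao:::refresh_active_sets(st, inst)
  y <- project_selection(st$y, st, inst, cfg0)
  pl0 <- run_step2(inst, cfg0, y, warm_state = st)
  expect_length(pl0$step2_trace, 0)
  expect_equal(sort(pl0$selected_ids), sort(inst$candidates$id[y > 0.5]))
})

test_that("full pipeline returns exact-cardinality plans; forced selection works", {
  inst <- offset_instance()
  pl <- solve_qcbao(inst, qcbao_config(N_select = 2, T_refine = 80), seed = 1)
  expect_equal(nrow(pl$selected), 2)
  expect_equal(pl$mmu_violations, 0)

  # B == N_select: reduces to fluence optimization over the full set
  cfgB <- qcbao_config(N_select = 4, T_refine = 80)
  plB <- solve_qcbao(inst, cfgB, seed = 1)
  expect_equal(sort(plB$selected_ids), inst$candidates$id)
})

test_that("with fixed selection and no DVH terms step 2 matches projected gradient", {
  ph <- generate_phantom("offset-target-with-oar", size = 21, seed = 9)
  cand <- make_candidate_set(4, 0)
  spec <- objective_spec(list(
    prescription_term("target_lsq", "target", 10, ph$Dp),
    prescription_term("oar_lsq", "oar", 5, 0.2 * ph$Dp),
    prescription_term("oar_lsq", "body", 0.25, 0.1 * ph$Dp)))
  inst <- build_instance(ph, cand, objective = spec)
  cfg <- qcbao_config(N_select = 2, G = 0, T_refine = 2000, refine_tol = 1e-9,
                      normalize_d95 = FALSE)
  y <- c(1, 0, 1, 0)
  plan <- run_step2(inst, cfg, y, seed = 1)

  # independent FISTA solver on the joint nonneg least squares problem
  V <- cbind(inst$dose_influence[[1]]$matrix, inst$dose_influence[[3]]$matrix)
  st <- inst$structures
  tgt <- target_mask(st); oar <- st$masks$oar; body <- body_mask(st)
  fobj <- function(d) {
    (10 / length(tgt)) * sum((d[tgt] - ph$Dp)^2) +
      (5 / length(oar)) * sum(pmax(d[oar] - 0.2 * ph$Dp, 0)^2) +
      (0.25 / length(body)) * sum(pmax(d[body] - 0.1 * ph$Dp, 0)^2)
  }
  fgrad_d <- function(d) {
    g <- numeric(length(d))
    g[tgt] <- g[tgt] + (20 / length(tgt)) * (d[tgt] - ph$Dp)
    g[oar] <- g[oar] + (10 / length(oar)) * pmax(d[oar] - 0.2 * ph$Dp, 0)
    g[body] <- g[body] + (0.5 / length(body)) * pmax(d[body] - 0.1 * ph$Dp, 0)
    g
  }
  m <- ncol(V)
  # Lipschitz constant: 2 alpha_max lambda_max(V'V) via power iteration
  amax <- max(20 / length(tgt), 10 / length(oar), 0.5 / length(body))
  v0 <- rep(1, m)
  for (it in 1:50) {
    v0 <- as.numeric(Matrix::crossprod(V, V %*% v0))
    v0 <- v0 / sqrt(sum(v0^2))
  }
  lam <- sum(v0 * as.numeric(Matrix::crossprod(V, V %*% v0)))
  L <- 1.1 * amax * 2 * lam
  x <- numeric(m); xp <- x; tk <- 1
  for (it in 1:4000) {
    w <- x + ((tk - 1) / (tk + 2)) * (x - xp)
    d <- as.numeric(V %*% w)
    g <- as.numeric(Matrix::crossprod(V, fgrad_d(d)))
    xp <- x
    x <- pmax(w - g / L, 0)
    tk <- tk + 1
  }
  f_pg <- fobj(as.numeric(V %*% x))
  expect_lt(abs(plan$objective - f_pg) / max(1e-8, f_pg), 1e-4)
})

test_that("tuning protocol reduces to a single solve and summarizes runs", {
  inst <- offset_instance()
  cfg <- qcbao_config(N_select = 2, T_refine = 60, mu2_grid = 1, n_runs = 1)
  tuned <- qcbao_tune(inst, cfg, seed = 7)
  single_cfg <- cfg; single_cfg$mu2 <- 1
  single <- solve_qcbao(inst, single_cfg, seed = 7 + 1)
  expect_equal(tuned$best$objective, single$objective)
  expect_equal(tuned$best$selected_ids, single$selected_ids)
  expect_equal(nrow(tuned$summary), 1)

  cfg2 <- qcbao_config(N_select = 2, T_refine = 40, mu2_grid = c(0.1, 1, 10),
                       n_runs = 2)
  tuned2 <- qcbao_tune(inst, cfg2, seed = 1)
  expect_equal(nrow(tuned2$summary), 3)
  expect_equal(nrow(tuned2$runs), 6)
  expect_lte(tuned2$best$objective, min(tuned2$runs$objective) + 1e-12)
})
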