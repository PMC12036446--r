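#' Solver configuration
#'
#' Parameters of the two-step beam-angle optimization solver.  Step 1 runs
#' `T_outer` augmented-Lagrangian iterations alternating weighted
#' least-squares intensity updates, the minimum-monitor-unit (MMU) proximal
#' update, a QUBO beam-selection update and dual ascent; Step 2 refines the
#' intensities of the selected beams with the selection frozen.
#'
#' @param N_select number of beams to select.
#' @param G MMU threshold in intensity units: every delivered spot is
#'   either off or at least `G`.  `NULL` resolves at initialization to
#'   `G_frac` times the median intensity scale of the instance.
#' @param G_frac fraction used when `G` is `NULL`.
#' @param mu1 consensus (ADMM) penalty; `NULL` auto-scales to
#'   (initial objective) / (sum of squared initial intensities).
#' @param mu2 cardinality penalty weight on `(sum y - N)^2`.
#' @param T_outer Step-1 outer iterations (around 10 suffices in practice).
#' @param T_refine maximum Step-2 iterations; stops early when the relative
#'   objective change drops below `refine_tol`.
#' @param x_tol residual tolerance of the per-beam linear solves.
#' @param refine_tol Step-2 early-stop tolerance.
#' @param backend QUBO backend: `"sa"`, `"exact"` or `"ga"`.
#' @param backend_params list of extra arguments for the backend solver.
#' @param mu2_grid grid used by [qcbao_tune()].
#' @param n_runs independent runs per grid point in [qcbao_tune()].
#' @param normalize_d95 if `TRUE`, record the D95 normalization scale and
#'   compute plan-quality metrics on the normalized dose.  Reported
#'   intensities stay at their raw, MMU-feasible values; the scale is a
#'   separate field of the plan.
#' @export
qcbao_config <- function(N_select, G = NULL, G_frac = 0.05, mu1 = NULL,
                         mu2 = 1, T_outer = 10, T_refine = 500,
                         x_tol = 1e-8, refine_tol = 1e-6,
                         backend = c("sa", "exact", "ga"),
                         backend_params = list(),
                         mu2_grid = c(0.01, 0.1, 1, 10, 50), n_runs = 5,
                         normalize_d95 = TRUE) {
  backend <- match.arg(backend)
  if (!is_count(N_select) || N_select < 1)
    stop_bao("`N_select` must be a positive integer")
  if (!is.null(G) && G < 0) stop_bao("`G` must be >= 0")
  if (mu2 < 0) stop_bao("`mu2` must be >= 0")
  if (!is_count(T_outer) || T_outer < 0) stop_bao("`T_outer` must be >= 0")
  structure(list(N_select = as.integer(N_select), G = G, G_frac = G_frac,
                 mu1 = mu1, mu2 = mu2, T_outer = as.integer(T_outer),
                 T_refine = as.integer(T_refine), x_tol = x_tol,
                 refine_tol = refine_tol, backend = backend,
                 backend_params = backend_params, mu2_grid = mu2_grid,
                 n_runs = as.integer(n_runs),
                 normalize_d95 = isTRUE(normalize_d95)),
            class = "qcbao_config")
}

beam_matrix <- function(instance, i) instance$dose_influence[[i]]$matrix

# total dose of the currently selected beams
dose_from <- function(instance, y, x) {
  d <- numeric(n_voxels(instance$grid))
  for (i in which(y > 0.5))
    d <- d + as.numeric(beam_matrix(instance, i) %*% x[[i]])
  d
}

# per-beam dose vectors v_i = A_i x_i for every candidate
beam_doses <- function(instance, x) {
  lapply(seq_along(x), function(i)
    as.numeric(beam_matrix(instance, i) %*% x[[i]]))
}

#' Initialize the solver state
#'
#' Spot intensities start at delivery scale: beam i's spots are drawn near
#' `s_i / 2` (uniform within +/- 60%), where `s_i` is chosen so that
#' `N_select` beams at that scale jointly deliver about the prescription to
#' the target.  The selection vector starts with every candidate switched
#' on (`init_y = "full"`, the default): the first active-set refresh then
#' sees every beam's dose footprint, so organ-at-risk costs of all
#' candidates are visible to the first beam-selection subproblem, which
#' prunes the set under the cardinality penalty.  `init_y = "subset"`
#' instead starts from a uniformly random subset of exactly `N_select`
#' beams.  Consensus copies equal the intensities and all duals are zero.
#' Deterministic for a fixed seed.
#'
#' @param instance a `bao_instance`.
#' @param config a [qcbao_config()].
#' @param seed integer seed.
#' @param init_y `"full"` or `"subset"` (see above).
#' @return object of class `solver_state`.
#' @export
qcbao_init <- function(instance, config, seed = 1, init_y = c("full", "subset")) {
  validate_instance(instance)
  init_y <- match.arg(init_y)
  B <- nrow(instance$candidates)
  if (config$N_select > B)
    stop_bao("`N_select` exceeds the number of candidate beams")
  set.seed(as.integer(seed))
  tgt <- target_mask(instance$structures)
  xs <- numeric(B)
  x <- vector("list", B)
  for (i in seq_len(B)) {
    A <- beam_matrix(instance, i)
    u <- mean(as.numeric(A[tgt, , drop = FALSE] %*% rep(1, ncol(A))))
    xs[i] <- 2 * instance$Dp / (config$N_select * u)
    x[[i]] <- (xs[i] / 2) * stats::runif(ncol(A), 0.4, 1.6)
  }
  y <- if (init_y == "full") rep(1, B) else {
    yy <- numeric(B)
    yy[sample.int(B, config$N_select)] <- 1
    yy
  }
  spec <- instance$objective %||%
    default_objective(instance$structures, instance$Dp)
  G <- config$G %||% (config$G_frac * stats::median(xs))
  d0 <- dose_from(instance, y, x)
  sets0 <- identify_active_sets(d0, spec, instance$structures)
  vq0 <- voxel_quadratic(spec, sets0)
  # auto-scale the consensus penalty to the dose-term curvature (the mean
  # diagonal of the per-beam Hessians 2 A' D_alpha A).  Step 1 uses the
  # full scale so intensities adapt gradually while the selection settles;
  # Step 2 relaxes it for fast refinement of the frozen selection.
  mu1_base <- {
    aw <- numeric(n_voxels(instance$grid))
    aw[vq0$voxel] <- vq0$alpha
    hd <- unlist(lapply(seq_len(B), function(i) {
      A <- beam_matrix(instance, i)
      2 * Matrix::colSums(A * A * aw)
    }))
    max(mean(hd), 1e-8)
  }
  mu1_step1 <- config$mu1 %||% (1.0 * mu1_base)
  mu1_step2 <- config$mu1 %||% (0.1 * mu1_base)
  if (mu1_step1 <= 0) stop_bao("`mu1` must be > 0")
  structure(list(x = x, z = x, y = y,
                 lambda1 = lapply(x, function(v) numeric(length(v))),
                 lambda2 = 0, sets = NULL, vq = NULL,
                 mu1 = mu1_step1, mu1_step1 = mu1_step1,
                 mu1_step2 = mu1_step2,
                 G = G, x_scale = xs, spec = spec,
                 seed = as.integer(seed), iter = 0L, trace = list()),
            class = "solver_state")
}

# refresh active sets and the per-voxel quadratic from the current dose
refresh_active_sets <- function(state, instance) {
  d <- dose_from(instance, state$y, state$x)
  if (!all(is.finite(d)))
    stop_bao("non-finite dose encountered at iteration ", state$iter)
  state$sets <- identify_active_sets(d, state$spec, instance$structures)
  state$vq <- voxel_quadratic(state$spec, state$sets)
  state$objective <- evaluate_objective(d, state$spec, state$sets)
  state
}

#' Intensity (x) update
#'
#' Per-beam Gauss-Seidel pass.  A deselected beam's subproblem contains
#' only the consensus term, minimized at `z_i + lambda1_i`.  A selected
#' beam's subproblem is an unconstrained weighted least squares whose
#' first-order condition is the linear system
#' `(2 A_i' D_alpha A_i + mu1 I) x_i = 2 A_i' D_alpha r_i + mu1 (z_i + lambda1_i)`
#' with `r_i` the residual `beta` minus the dose of the other selected
#' beams on the active voxels.
#'
#' @param state a `solver_state` with current active sets.
#' @param instance the `bao_instance`.
#' @return the updated state.
#' @export
update_x <- function(state, instance) {
  if (is.null(state$vq)) stop_bao("active sets must be identified before update_x")
  if (state$mu1 <= 0)
    stop_bao("the intensity update requires mu1 > 0")
  act <- state$vq$voxel
  alpha <- state$vq$alpha
  beta <- state$vq$beta
  B <- length(state$x)
  if (length(act) == 0L) {
    for (i in seq_len(B)) state$x[[i]] <- state$z[[i]] + state$lambda1[[i]]
    return(state)
  }
  Aact <- vector("list", B)
  for (i in which(state$y > 0.5))
    Aact[[i]] <- beam_matrix(instance, i)[act, , drop = FALSE]
  s <- numeric(length(act))
  for (i in which(state$y > 0.5))
    s <- s + as.numeric(Aact[[i]] %*% state$x[[i]])
  # seeded random sweep order: a fixed order would let the first-updated
  # beams absorb most of the prescription sweep after sweep, biasing the
  # subsequent beam-selection step toward them
  for (i in sample.int(B)) {
    if (state$y[i] < 0.5) {
      state$x[[i]] <- state$z[[i]] + state$lambda1[[i]]
      next
    }
    Ai <- Aact[[i]]
    other <- s - as.numeric(Ai %*% state$x[[i]])
    AtD <- Matrix::crossprod(Ai, alpha * Ai)
    H <- 2 * as.matrix(AtD) + state$mu1 * diag(ncol(Ai))
    rhs <- 2 * as.numeric(Matrix::crossprod(Ai, alpha * (beta - other))) +
      state$mu1 * (state$z[[i]] + state$lambda1[[i]])
    xi <- solve(H, rhs)
    state$x[[i]] <- as.numeric(xi)
    s <- other + as.numeric(Ai %*% state$x[[i]])
  }
  state
}

#' MMU proximal (z) update
#'
#' Componentwise soft threshold onto the deliverable set `{0} u [G, inf)`:
#' with `v = x_i - lambda1_i`, `z_i = max(G, v)` when `v >= G/2` and 0
#' otherwise (the boundary `v = G/2` rounds up to `G`).
#'
#' @param state a `solver_state`.
#' @return the updated state.
#' @export
update_z <- function(state) {
  G <- state$G
  for (i in seq_along(state$z)) {
    v <- state$x[[i]] - state$lambda1[[i]]
    state$z[[i]] <- ifelse(v >= G / 2, pmax(G, v), 0)
  }
  state
}

solve_qubo_backend <- function(problem, config, seed) {
  switch(config$backend,
    exact = solve_qubo_exhaustive(problem),
    sa = do.call(solve_qubo_sa,
                 c(list(problem = problem, seed = seed),
                   config$backend_params)),
    ga = do.call(solve_qubo_ga,
                 c(list(problem = problem, seed = seed),
                   config$backend_params)))
}

#' Beam-selection (y) update
#'
#' Assembles the selection subproblem as a QUBO from the current per-beam
#' doses and solves it with the configured backend.
#'
#' @param state a `solver_state` with current active sets.
#' @param instance the `bao_instance`.
#' @param config a [qcbao_config()].
#' @return the updated state; `state$qubo_value` holds the attained value.
#' @export
update_y <- function(state, instance, config) {
  v <- beam_doses(instance, state$x)
  prob <- assemble_qubo(v, state$vq, config$mu2, config$N_select,
                        state$lambda2)
  sol <- tryCatch(
    solve_qubo_backend(prob, config, state$seed + 7919L * state$iter),
    error = function(e) stop_bao("QUBO backend failed at iteration ",
                                 state$iter, ": ", conditionMessage(e)))
  state$y <- as.numeric(sol$y > 0.5)
  state$qubo_value <- sol$value
  state
}

#' Dual updates
#'
#' `lambda1_i <- lambda1_i + z_i - x_i` per beam and
#' `lambda2 <- lambda2 + sum(y) - N`.
#'
#' @param state a `solver_state`.
#' @param config a [qcbao_config()].
#' @return the updated state.
#' @export
update_duals <- function(state, config) {
  for (i in seq_along(state$x))
    state$lambda1[[i]] <- state$lambda1[[i]] + state$z[[i]] - state$x[[i]]
  state$lambda2 <- state$lambda2 + sum(state$y) - config$N_select
  state
}

consensus_residual <- function(state) {
  sqrt(sum(vapply(seq_along(state$x), function(i)
    sum((state$x[[i]] - state$z[[i]])^2), 1.0)))
}

#' Step 1: joint beam selection and intensity optimization
#'
#' Runs `T_outer` outer iterations of active-set refresh followed by the
#' sequential x-, z-, y- and dual updates, retaining a full per-iteration
#' trace.
#'
#' @param instance a `bao_instance`.
#' @param config a [qcbao_config()].
#' @param seed integer seed.
#' @param state optional pre-built state (for resuming); default fresh
#'   initialization.
#' @return the final `solver_state`; `$trace` has one record per iteration
#'   with the objective at refresh time, the consensus residual, the
#'   selection cardinality, the attained QUBO value and the selection.
#' @export
run_step1 <- function(instance, config, seed = 1, state = NULL) {
  state <- state %||% qcbao_init(instance, config, seed)
  state$mu1 <- state$mu1_step1 %||% state$mu1
  if (config$T_outer == 0L) return(state)
  for (t in seq_len(config$T_outer)) {
    state$iter <- t
    state <- refresh_active_sets(state, instance)
    if (!is.finite(state$objective))
      stop_bao("objective became non-finite at Step-1 iteration ", t)
    state <- update_x(state, instance)
    state <- update_z(state)
    state <- update_y(state, instance, config)
    state <- update_duals(state, config)
    state$trace[[t]] <- list(iter = t, objective = state$objective,
                             consensus = consensus_residual(state),
                             cardinality = sum(state$y),
                             qubo_value = state$qubo_value,
                             y = state$y)
  }
  state
}

#' Project a selection onto the cardinality constraint
#'
#' The cardinality penalty is soft during Step 1; the final plan must pick
#' exactly `N_select` beams.  If the selection is infeasible, beams are
#' greedily toggled (added or dropped), each time choosing the toggle that
#' least increases the restricted augmented-Lagrangian objective, until the
#' count is exact.  Deterministic; ties resolve to the lowest beam index.
#'
#' @param y selection vector.
#' @param state a `solver_state` holding the current intensities, duals and
#'   active sets.
#' @param instance the `bao_instance`.
#' @param config a [qcbao_config()].
#' @return selection vector with exactly `N_select` ones.
#' @export
project_selection <- function(y, state, instance, config) {
  N <- config$N_select
  if (sum(y) == N) return(y)
  if (is.null(state$vq)) state <- refresh_active_sets(state, instance)
  v <- beam_doses(instance, state$x)
  prob <- assemble_qubo(v, state$vq, config$mu2, N, state$lambda2)
  while (sum(y) != N) {
    cand <- if (sum(y) > N) which(y > 0.5) else which(y < 0.5)
    trial <- matrix(rep(y, length(cand)), length(cand), length(y),
                    byrow = TRUE)
    trial[cbind(seq_along(cand), cand)] <- 1 - y[cand]
    vals <- qubo_value(prob, trial)
    y <- trial[which.min(vals), ]
  }
  y
}

#' Step 2: intensity refinement with frozen selection
#'
#' Re-solves the problem with the beam selection fixed: iterates active-set
#' refresh, x-update, z-update and dual update until `T_refine` iterations
#' or the relative objective change falls below `refine_tol`.
#' Final intensities are the consensus copies `z` of the selected beams,
#' MMU-feasible by construction of the proximal update.
#'
#' @param instance a `bao_instance`.
#' @param config a [qcbao_config()].
#' @param y_fixed selection vector with exactly `N_select` ones.
#' @param warm_state optional `solver_state` to warm-start from (typically
#'   the Step-1 result); a fresh deterministic state is built otherwise.
#' @param seed seed for the fresh state when no `warm_state` is given.
#' @return object of class `qcbao_plan`.
#' @export
run_step2 <- function(instance, config, y_fixed, warm_state = NULL,
                      seed = 1) {
  if (sum(y_fixed) != config$N_select)
    stop_bao("`y_fixed` must select exactly N_select beams")
  state <- warm_state %||% qcbao_init(instance, config, seed)
  state$y <- as.numeric(y_fixed > 0.5)
  state$mu1 <- state$mu1_step2 %||% state$mu1
  trace <- list()
  prev <- Inf
  for (t in seq_len(config$T_refine)) {
    state$iter <- t
    state <- refresh_active_sets(state, instance)
    if (!is.finite(state$objective))
      stop_bao("objective became non-finite at Step-2 iteration ", t)
    state <- update_x(state, instance)
    state <- update_z(state)
    state <- update_duals(state, config)
    trace[[t]] <- list(iter = t, objective = state$objective,
                       consensus = consensus_residual(state))
    if (is.finite(prev) &&
        abs(prev - state$objective) <= config$refine_tol * max(1, prev))
      break
    prev <- state$objective
  }
  finalize_plan(instance, config, state, step2_trace = trace)
}

finalize_plan <- function(instance, config, state, step2_trace = list(),
                          step1_trace = NULL, step1_objective = NA_real_) {
  sel <- which(state$y > 0.5)
  intensities <- state$z[sel]
  names(intensities) <- instance$candidates$id[sel]
  d <- numeric(n_voxels(instance$grid))
  for (k in seq_along(sel))
    d <- d + as.numeric(beam_matrix(instance, sel[k]) %*% intensities[[k]])
  sets <- identify_active_sets(d, state$spec, instance$structures)
  obj <- evaluate_objective(d, state$spec, sets)
  tm <- target_mask(instance$structures)
  scale <- 1
  scale_ok <- TRUE
  if (config$normalize_d95) {
    scale <- tryCatch(normalize_to_d95(d, tm, instance$Dp),
                      error = function(e) { scale_ok <<- FALSE; 1 })
  }
  mmu_viol <- sum(vapply(intensities, function(z)
    sum(z > 0 & z < state$G - 1e-12) + 0, 1.0))
  quality <- plan_quality(d * scale, instance$structures, instance$Dp)
  structure(list(
    selected_ids = instance$candidates$id[sel],
    selected = instance$candidates[sel, , drop = FALSE],
    intensities = intensities,
    dose = d,
    objective = obj,
    step1_objective = step1_objective,
    normalization_scale = if (config$normalize_d95 && scale_ok) scale else NA_real_,
    quality = quality,
    mmu_violations = mmu_viol,
    G = state$G, mu1 = state$mu1,
    seed = state$seed,
    config = config,
    step1_trace = step1_trace,
    step2_trace = step2_trace
  ), class = "qcbao_plan")
}

#' Solve a beam-angle optimization instance end to end
#'
#' Step 1 (joint selection + intensities), projection of the selection onto
#' the exact-cardinality constraint, then Step 2 refinement warm-started
#' from the Step-1 state.
#'
#' @param instance a `bao_instance`.
#' @param config a [qcbao_config()].
#' @param seed integer seed controlling initialization and the stochastic
#'   QUBO backends.
#' @return object of class `qcbao_plan`: selected angles, MMU-feasible
#'   intensities, dose, objective values, normalization scale, plan-quality
#'   metrics and full iteration traces.
#' @export
solve_qcbao <- function(instance, config, seed = 1) {
  state <- run_step1(instance, config, seed)
  if (is.null(state$vq)) state <- refresh_active_sets(state, instance)
  y <- project_selection(state$y, state, instance, config)
  state$y <- y
  s1_obj <- if (length(state$trace))
    state$trace[[length(state$trace)]]$objective else state$objective
  plan <- run_step2(instance, config, y, warm_state = state)
  plan$step1_objective <- s1_obj
  plan$step1_trace <- state$trace
  plan
}

#' Solve with a fixed set of beams (no selection step)
#'
#' The fixed-angle baseline: only spot-intensity optimization is performed
#' for a user-given beam set, as in clinical plans with manually chosen
#' angles.
#'
#' @param instance a `bao_instance`.
#' @param config a [qcbao_config()]; `N_select` is taken from the number of
#'   fixed beams.
#' @param beam_ids candidate `id`s to use.
#' @param seed integer seed.
#' @return a `qcbao_plan`.
#' @export
solve_fixed_angles <- function(instance, config, beam_ids, seed = 1) {
  pos <- match(beam_ids, instance$candidates$id)
  if (anyNA(pos)) stop_bao("unknown beam id(s): ",
                           paste(beam_ids[is.na(pos)], collapse = ", "))
  config$N_select <- length(pos)
  y <- numeric(nrow(instance$candidates))
  y[pos] <- 1
  run_step2(instance, config, y, seed = seed)
}

#' Tune the cardinality penalty and repeat runs
#'
#' For every `mu2` in the grid, performs `n_runs` independent seeded runs
#' of [solve_qcbao()], reports per-grid-point mean and standard deviation
#' of the final objective, and returns the single best run (lowest
#' objective) as the headline plan.
#'
#' @param instance a `bao_instance`.
#' @param config a [qcbao_config()] carrying `mu2_grid` and `n_runs`.
#' @param seed base seed; run `r` at grid point `g` uses
#'   `seed + 1000 * (g - 1) + r`.
#' @return list with `best` (a `qcbao_plan`), `summary` (one row per
#'   `mu2`: mean, sd, best objective) and `runs` (every run's seed,
#'   objective and CI).
#' @export
qcbao_tune <- function(instance, config, seed = 1) {
  if (config$n_runs < 1) stop_bao("`n_runs` must be >= 1")
  runs <- NULL
  best <- NULL
  for (g in seq_along(config$mu2_grid)) {
    mu2 <- config$mu2_grid[g]
    cfg <- config
    cfg$mu2 <- mu2
    for (r in seq_len(config$n_runs)) {
      run_seed <- as.integer(seed + 1000 * (g - 1) + r)
      plan <- solve_qcbao(instance, cfg, run_seed)
      runs <- rbind(runs, data.frame(
        mu2 = mu2, run = r, seed = run_seed, objective = plan$objective,
        CI = plan$quality$CI,
        selected = paste(plan$selected_ids, collapse = "+")))
      if (is.null(best) || plan$objective < best$objective) best <- plan
    }
  }
  summary <- do.call(rbind, lapply(split(runs, runs$mu2), function(df)
    data.frame(mu2 = df$mu2[1], mean_objective = mean(df$objective),
               sd_objective = stats::sd(df$objective),
               best_objective = min(df$objective), n_runs = nrow(df))))
  summary <- summary[order(summary$mu2), , drop = FALSE]
  rownames(summary) <- NULL
  list(best = best, summary = summary, runs = runs)
}

#' @export
print.qcbao_plan <- function(x, ...) {
  cat("QC-BAO plan: beams",
      paste(sprintf("(couch %g, gantry %g)", x$selected$couch_deg,
                    x$selected$gantry_deg), collapse = ", "), "\n")
  cat(sprintf("  objective %.6g (Step 1: %.6g), MMU G = %.4g, violations %d\n",
              x$objective, x$step1_objective, x$G, as.integer(x$mmu_violations)))
  if (!is.na(x$normalization_scale))
    cat(sprintf("  D95 normalization scale %.4f\n", x$normalization_scale))
  print(x$quality)
  invisible(x)
}
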