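# shared fixtures, built once per test run
.fx <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fx[[key]])) .fx[[key]] <- builder()
  .fx[[key]]
}

# 8-beam planted-corridor instance, the workhorse of solver tests
corridor_instance <- function(seed = 7, size = 31) {
  cached(paste0("corridor_", seed, "_", size), function() {
    ph <- generate_phantom("planted-corridor", size = size, seed = seed)
    build_instance(ph, make_candidate_set(8, 0))
  })
}

# small offset-target instance with 4 beams (fast unit-test instance)
offset_instance <- function(seed = 5) {
  cached(paste0("offset_", seed), function() {
    ph <- generate_phantom("offset-target-with-oar", size = 21, seed = seed)
    build_instance(ph, make_candidate_set(4, 0))
  })
}

# HN-style instance: 72 candidates (24 gantry x 3 couch)
hn_instance <- function() {
  cached("hn", function() {
    ph <- generate_phantom("offset-target-with-oar", size = 31, seed = 5)
    build_instance(ph, make_candidate_set(24, c(0, 30, 60)))
  })
}

# the 20 seeded HN-style plans shared by the cardinality and MMU checks
hn_plans <- function() {
  cached("hn_plans", function() {
    inst <- hn_instance()
    cfg <- qcbao_config(N_select = 4, backend = "sa", T_refine = 60)
    lapply(1:20, function(sd) solve_qcbao(inst, cfg, seed = sd))
  })
}

# hand-built one-voxel instance: single beam, single spot, A = [a]
one_voxel_instance <- function(a = 2, b = 8, w = 1) {
  grid <- voxel_grid(c(1, 1), spacing = 1)
  st <- structure_set(list(t = 1L, body = 1L),
                      c(t = "target", body = "body"), grid)
  A <- methods::as(Matrix::Matrix(a, 1, 1, sparse = TRUE), "CsparseMatrix")
  di <- structure(list(beam_id = 0L, matrix = A, spots = NULL),
                  class = "dose_influence")
  structure(list(grid = grid, structures = st,
                 candidates = make_candidate_set(1, 0),
                 dose_influence = list(di), Dp = b, spot_spec = spot_spec(),
                 objective = objective_spec(list(
                   prescription_term("target_lsq", "t", w, b)))),
            class = "bao_instance")
}

# random QUBO with controlled magnitudes
random_qubo <- function(B, seed, scale = 1) {
  set.seed(seed)
  Q <- matrix(stats::rnorm(B * B, sd = scale), B, B)
  Q <- (Q + t(Q)) / 2
  diag(Q) <- 0
  qubo_problem(Q, stats::rnorm(B, sd = scale), stats::rnorm(1))
}

# structure set over a flat grid with chosen masks (for objective tests)
flat_structures <- function(n, target, oar = NULL) {
  grid <- voxel_grid(c(1, n), spacing = 1)
  masks <- list(target = as.integer(target), body = seq_len(n))
  roles <- c(target = "target", body = "body")
  if (!is.null(oar)) {
    masks$oar <- as.integer(oar)
    roles <- c(roles, oar = "oar")
  }
  list(grid = grid, structures = structure_set(masks, roles, grid))
}
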