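#' Quadratic unconstrained binary optimization problem
#'
#' `value(y) = y' Q y + q' y + c` over `y` in `{0,1}^B`.  `Q` must be
#' symmetric; assemblies produced by [assemble_qubo()] use the zero-diagonal
#' convention with `y^2 = y` terms folded into `q`.
#'
#' @param Q symmetric B x B coefficient matrix.
#' @param q linear coefficients (length B).
#' @param c constant offset.
#' @export
qubo_problem <- function(Q, q, c = 0) {
  Q <- as.matrix(Q)
  q <- as.numeric(q)
  if (nrow(Q) != ncol(Q) || nrow(Q) != length(q))
    stop_bao("Q must be square with one row per entry of q",
             class = "qcbao_shape_error")
  if (!all(is.finite(Q)) || !all(is.finite(q)) || !is.finite(c))
    stop_bao("QUBO coefficients must be finite")
  if (max(abs(Q - t(Q))) > 1e-12 * max(1, max(abs(Q))))
    stop_bao("Q must be symmetric")
  structure(list(Q = Q, q = q, c = as.numeric(c), B = length(q)),
            class = "qubo_problem")
}

#' Evaluate a QUBO at one or many binary vectors
#'
#' @param problem a [qubo_problem()].
#' @param y binary vector of length B, or a matrix with one y per row.
#' @return numeric value(s).
#' @export
qubo_value <- function(problem, y) {
  if (is.matrix(y))
    return(rowSums((y %*% problem$Q) * y) + drop(y %*% problem$q) + problem$c)
  drop(crossprod(y, problem$Q %*% y)) + sum(problem$q * y) + problem$c
}

#' Assemble the binary beam-selection subproblem as a QUBO
#'
#' With intensities, consensus copies and duals frozen, the augmented
#' Lagrangian restricted to the selection vector `y` is
#' `sum_k alpha_k (sum_i y_i v_ik - beta_k)^2
#'  + (mu2/2) (sum_i y_i - N + lambda2)^2 + const`,
#' where `v_i = A_i x_i` is beam i's dose at current intensities.  This is
#' expanded exactly into QUBO form (using `y_i^2 = y_i` for the diagonal).
#'
#' @param beam_doses list of per-beam dose vectors `v_i` (full voxel
#'   length), one per candidate.
#' @param vq per-voxel quadratic coefficients from [voxel_quadratic()].
#' @param mu2 cardinality penalty weight (>= 0).
#' @param N number of beams to select.
#' @param lambda2 scalar dual of the cardinality constraint.
#' @return a [qubo_problem()] whose value at every `y` equals the restricted
#'   objective above (including its y-independent constants).
#' @export
assemble_qubo <- function(beam_doses, vq, mu2, N, lambda2 = 0) {
  B <- length(beam_doses)
  nv <- unique(vapply(beam_doses, length, 1L))
  if (length(nv) != 1L)
    stop_bao("beam dose vectors differ in length", class = "qcbao_shape_error")
  if (mu2 < 0) stop_bao("`mu2` must be >= 0")
  act <- vq$voxel
  V <- matrix(0, length(act), B)
  for (i in seq_len(B)) V[, i] <- as.numeric(beam_doses[[i]])[act]
  M <- crossprod(V, vq$alpha * V)            # M_ij = sum_k alpha v_i v_j
  g <- drop(crossprod(V, vq$alpha * vq$beta))
  a <- lambda2 - N
  Q <- M + mu2 / 2
  diag(Q) <- 0
  q <- diag(M) - 2 * g + mu2 / 2 + mu2 * a
  cst <- sum(vq$alpha * vq$beta^2) + vq$const + (mu2 / 2) * a^2
  qubo_problem(Q, q, cst)
}

binary_solution <- function(y, value, meta = list()) {
  structure(list(y = as.numeric(y), value = value, meta = meta),
            class = "qubo_solution")
}

# all binary vectors of length B in lexicographic order (y1 most significant)
enumerate_binary <- function(B, from = 0, to = 2^B - 1) {
  idx <- from:to
  Y <- matrix(0, length(idx), B)
  for (j in seq_len(B)) Y[, j] <- (idx %/% 2^(B - j)) %% 2
  Y
}

#' Exhaustive QUBO solver (ground-truth oracle)
#'
#' Enumerates all `2^B` binary vectors; refuses `B > 20`.  Ties are broken
#' toward the lexicographically smallest `y`.
#'
#' @param problem a [qubo_problem()].
#' @return a `qubo_solution`.
#' @export
solve_qubo_exhaustive <- function(problem) {
  B <- problem$B
  if (B > 20)
    stop_bao("exhaustive solver limited to B <= 20 (got ", B, ")",
             class = "qcbao_size_error")
  best_val <- Inf
  best_y <- NULL
  chunk <- 2^min(B, 14)
  for (start in seq(0, 2^B - 1, by = chunk)) {
    Y <- enumerate_binary(B, start, min(start + chunk - 1, 2^B - 1))
    v <- qubo_value(problem, Y)
    i <- which.min(v)            # first minimum = lexicographically smallest
    if (v[i] < best_val) {
      best_val <- v[i]
      best_y <- Y[i, ]
    }
  }
  binary_solution(best_y, best_val, list(solver = "exhaustive"))
}

default_beta_range <- function(problem) {
  mags <- abs(c(problem$Q[problem$Q != 0], problem$q[problem$q != 0]))
  if (length(mags) == 0L) return(c(0.1, 10))
  c(0.1 / mean(mags), 10 / max(min(mags), 1e-12 * max(mags)))
}

#' Simulated-annealing QUBO solver
#'
#' Best-of-reads single-flip Metropolis annealing on a geometric
#' inverse-temperature schedule; the classical stand-in for a quantum
#' annealing backend.  Deterministic for a fixed seed.
#'
#' @param problem a [qubo_problem()].
#' @param n_reads independent annealing restarts; the best read wins.
#' @param sweeps full single-flip sweeps per read.
#' @param beta_range inverse-temperature range `c(beta0, beta1)`; default
#'   scales with the coefficient magnitudes of the problem.
#' @param seed integer seed.
#' @return a `qubo_solution` whose `value` is recomputed from the returned
#'   `y`.
#' @export
solve_qubo_sa <- function(problem, n_reads = 32, sweeps = 1000,
                          beta_range = NULL, seed = 1) {
  stopifnot(n_reads >= 1, sweeps >= 1)
  beta_range <- beta_range %||% default_beta_range(problem)
  betas <- exp(seq(log(beta_range[1]), log(beta_range[2]),
                   length.out = sweeps))
  res <- .sa_anneal_cpp(problem$Q, problem$q, betas, as.integer(n_reads),
                        as.numeric(seed))
  y <- res$y
  binary_solution(y, qubo_value(problem, y),
                  list(solver = "sa", reads = n_reads, sweeps = sweeps,
                       beta_range = beta_range, seed = seed))
}

#' Genetic-algorithm QUBO solver
#'
#' Standard bitstring GA — tournament selection (size 2), uniform
#' crossover, per-bit mutation, elitism of one — mirroring a classical
#' mixed-integer baseline for the binary subproblem.  Deterministic for a
#' fixed seed.
#'
#' @param problem a [qubo_problem()].
#' @param population population size (>= 2).
#' @param generations number of generations.
#' @param p_mutate per-bit mutation probability; default `1/B`.
#' @param seed integer seed.
#' @return a `qubo_solution`.
#' @export
solve_qubo_ga <- function(problem, population = 40, generations = 80,
                          p_mutate = NULL, seed = 1) {
  if (population < 2) stop_bao("`population` must be >= 2")
  B <- problem$B
  p_mutate <- p_mutate %||% (1 / B)
  set.seed(as.integer(seed))
  pop <- matrix(as.numeric(stats::runif(population * B) < 0.5), population, B)
  fit <- qubo_value(problem, pop)
  for (gen in seq_len(generations)) {
    elite <- which.min(fit)
    # tournament selection of two parent pools
    i1 <- sample.int(population, population, replace = TRUE)
    i2 <- sample.int(population, population, replace = TRUE)
    pa <- ifelse(fit[i1] <= fit[i2], i1, i2)
    j1 <- sample.int(population, population, replace = TRUE)
    j2 <- sample.int(population, population, replace = TRUE)
    pb <- ifelse(fit[j1] <= fit[j2], j1, j2)
    mask <- matrix(stats::runif(population * B) < 0.5, population, B)
    child <- ifelse(mask, pop[pa, , drop = FALSE], pop[pb, , drop = FALSE])
    flip <- matrix(stats::runif(population * B) < p_mutate, population, B)
    child[flip] <- 1 - child[flip]
    child[1, ] <- pop[elite, ]               # elitism
    pop <- child
    fit <- qubo_value(problem, pop)
  }
  best <- which.min(fit)
  binary_solution(pop[best, ], fit[best],
                  list(solver = "ga", population = population,
                       generations = generations, p_mutate = p_mutate,
                       seed = seed))
}

#' @export
print.qubo_problem <- function(x, ...) {
  cat("QUBO problem: B =", x$B, "variables, constant =",
      format(x$c, digits = 6), "\n")
  invisible(x)
}

#' @export
print.qubo_solution <- function(x, ...) {
  cat("QUBO solution (", x$meta$solver %||% "?", "): value ",
      format(x$value, digits = 8), ", ", sum(x$y), " bits set of ",
      length(x$y), "\n", sep = "")
  invisible(x)
}

#' Write / read a QUBO as Matrix Market plus JSON sidecar
#'
#' @param problem a [qubo_problem()].
#' @param path base path; writes `<path>.mtx` (Q) and `<path>.json` (q, c).
#' @return `path`, invisibly.
#' @export
save_qubo <- function(problem, path) {
  Matrix::writeMM(methods::as(Matrix::Matrix(problem$Q, sparse = TRUE),
                              "CsparseMatrix"), paste0(path, ".mtx"))
  jsonlite::write_json(list(q = problem$q, c = problem$c),
                       paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' @rdname save_qubo
#' @export
load_qubo <- function(path) {
  Q <- as.matrix(Matrix::readMM(paste0(path, ".mtx")))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  qubo_problem(Q, side$q, side$c)
}
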