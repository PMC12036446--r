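#' Construct a candidate beam set
#'
#' Builds the candidate direction set for beam-angle optimization as the
#' Cartesian product of equally spaced gantry angles and a list of couch
#' angles.  The conventional non-coplanar candidate grid uses 24 gantry
#' angles (15 degree spacing) at couch angles 0, 30 and 60 degrees, giving
#' 72 candidates.
#'
#' @param n_gantry number of equally spaced gantry angles; spacing is
#'   `360 / n_gantry` starting at 0.
#' @param couch_list numeric vector of distinct couch angles in degrees,
#'   each in `[0, 360)`.
#' @return A data frame of class `beam_candidates` with columns `id`
#'   (0-based, unique), `couch_deg` and `gantry_deg`, ordered by
#'   (couch, gantry).
#' @examples
#' cand <- make_candidate_set(24, c(0, 30, 60))
#' nrow(cand)  # 72
#' @export
make_candidate_set <- function(n_gantry, couch_list = 0) {
  if (!is_count(n_gantry) || n_gantry < 1)
    stop_bao("`n_gantry` must be a positive integer")
  couch_list <- as.numeric(couch_list)
  if (length(couch_list) < 1 || anyNA(couch_list))
    stop_bao("`couch_list` must be a non-empty numeric vector")
  if (anyDuplicated(couch_list))
    stop_bao("couch angles must be distinct")
  if (any(couch_list < 0 | couch_list >= 360))
    stop_bao("couch angles must lie in [0, 360)")
  couch_list <- sort(couch_list)
  gantry <- (360 / n_gantry) * (seq_len(n_gantry) - 1)
  out <- data.frame(
    couch_deg  = rep(couch_list, each = n_gantry),
    gantry_deg = rep(gantry, times = length(couch_list))
  )
  out <- out[order(out$couch_deg, out$gantry_deg), , drop = FALSE]
  out <- cbind(id = seq_len(nrow(out)) - 1L, out)
  rownames(out) <- NULL
  class(out) <- c("beam_candidates", "data.frame")
  out
}

#' Regular voxel grid
#'
#' @param shape integer vector of grid dimensions (2D), `(nrow, ncol)`.
#' @param spacing edge length of a voxel in mm.
#' @return object of class `voxel_grid`.
#' @export
voxel_grid <- function(shape, spacing = 3) {
  shape <- as.integer(shape)
  if (length(shape) == 1L) shape <- c(shape, shape)
  if (length(shape) != 2L || any(shape < 1L))
    stop_bao("`shape` must give two positive dimensions")
  if (!is.numeric(spacing) || spacing <= 0)
    stop_bao("`spacing` must be > 0")
  structure(list(shape = shape, spacing = as.numeric(spacing)),
            class = "voxel_grid")
}

n_voxels <- function(grid) prod(grid$shape)

# voxel-center coordinates (mm), origin at grid center; linear indices are
# 1-based column-major over dim = shape (row r, column c).  x grows with the
# column index, y falls with the row index, so a beam at gantry 0 travels
# "up" the displayed image.
grid_coords <- function(grid) {
  nr <- grid$shape[1]; nc <- grid$shape[2]
  r <- rep(seq_len(nr), times = nc)
  c <- rep(seq_len(nc), each = nr)
  cbind(x = (c - (nc + 1) / 2) * grid$spacing,
        y = ((nr + 1) / 2 - r) * grid$spacing)
}

#' Named structure masks with roles
#'
#' A structure set holds one voxel-index set per anatomical structure
#' together with its role: exactly one `target`, exactly one `body`, and any
#' number of `oar` structures.  Indices are 1-based linear voxel indices.
#'
#' @param masks named list of integer voxel-index vectors.
#' @param roles named character vector (same names) with values
#'   `"target"`, `"oar"` or `"body"`.
#' @param grid the `voxel_grid` the indices refer to.
#' @return object of class `structure_set`.
#' @export
structure_set <- function(masks, roles, grid) {
  if (is.null(names(masks)) || anyDuplicated(names(masks)))
    stop_bao("`masks` must be a uniquely named list")
  if (!setequal(names(masks), names(roles)))
    stop_bao("`roles` must name the same structures as `masks`")
  roles <- roles[names(masks)]
  if (sum(roles == "target") != 1L) stop_bao("exactly one target structure required")
  if (sum(roles == "body") != 1L) stop_bao("exactly one body structure required")
  nv <- n_voxels(grid)
  masks <- lapply(masks, function(ix) {
    ix <- sort(unique(as.integer(ix)))
    if (length(ix) && (min(ix) < 1L || max(ix) > nv))
      stop_bao("structure index outside the grid")
    ix
  })
  tgt <- masks[[names(roles)[roles == "target"]]]
  body <- masks[[names(roles)[roles == "body"]]]
  if (length(tgt) == 0L) stop_bao("target mask is empty")
  if (!all(tgt %in% body)) stop_bao("target must be contained in body")
  structure(list(masks = masks, roles = roles), class = "structure_set")
}

#' Access structure masks by name or role
#'
#' @param structures a [structure_set()].
#' @param name structure name.
#' @return integer voxel indices.
#' @export
structure_mask <- function(structures, name) structures$masks[[name]]

#' @rdname structure_mask
#' @param role a role (`"target"`, `"oar"`, `"body"`).
#' @export
role_name <- function(structures, role) {
  names(structures$roles)[structures$roles == role]
}

#' @rdname structure_mask
#' @export
target_mask <- function(structures) {
  structures$masks[[role_name(structures, "target")]]
}

#' @rdname structure_mask
#' @export
body_mask <- function(structures) {
  structures$masks[[role_name(structures, "body")]]
}

disc_indices <- function(grid, center_xy, radius) {
  p <- grid_coords(grid)
  which((p[, 1] - center_xy[1])^2 + (p[, 2] - center_xy[2])^2 <= radius^2)
}

#' Generate a synthetic 2D phantom
#'
#' Deterministic (per seed) phantom generator used in place of clinical CT
#' data.  Three presets are available:
#' \describe{
#'   \item{`centered-target`}{circular target at the grid center inside a
#'     circular water body; no OAR.  Mirror-symmetric about the vertical
#'     axis, which makes it useful for geometric consistency checks.}
#'   \item{`offset-target-with-oar`}{target displaced from the center in a
#'     seeded direction with one circular OAR placed beside it.}
#'   \item{`planted-corridor`}{central target surrounded by an annular OAR
#'     with a seeded angular gap ("corridor"), so beams entering through the
#'     gap are geometrically preferable by construction.}
#' }
#'
#' @param preset one of `"centered-target"`, `"offset-target-with-oar"`,
#'   `"planted-corridor"`.
#' @param size grid dimension (scalar or length-2) in voxels.
#' @param seed integer seed controlling the seeded geometry choices.
#' @param spacing voxel edge (mm).
#' @param Dp prescription dose (Gy).
#' @param corridor_halfwidth_deg half-width of the planted angular gap
#'   (degrees), `planted-corridor` only.
#' @return list with elements `grid` (`voxel_grid`), `structures`
#'   (`structure_set`), `Dp`, and for the corridor preset
#'   `corridor_deg` (the gap center, entry-direction polar angle).
#' @export
generate_phantom <- function(preset, size = 31, seed = 1, spacing = 3,
                             Dp = 40, corridor_halfwidth_deg = 65) {
  preset <- match.arg(preset,
    c("centered-target", "offset-target-with-oar", "planted-corridor"))
  grid <- voxel_grid(size, spacing)
  ext <- min(grid$shape) * grid$spacing / 2   # half-extent, mm
  if (min(grid$shape) < 11L)
    stop_bao("grid too small to contain the phantom structures (need >= 11 voxels per side)")
  set.seed(as.integer(seed))
  body_r <- 0.92 * ext
  tgt_r <- 0.16 * ext
  body <- disc_indices(grid, c(0, 0), body_r)

  if (preset == "centered-target") {
    tgt <- disc_indices(grid, c(0, 0), tgt_r)
    masks <- list(target = tgt, body = body)
    roles <- c(target = "target", body = "body")
    extra <- NULL
  } else if (preset == "offset-target-with-oar") {
    phi <- stats::runif(1, 0, 2 * pi)
    ctr <- 0.35 * ext * c(cos(phi), sin(phi))
    tgt <- disc_indices(grid, ctr, tgt_r)
    # OAR beside the target, rotated a seeded quarter-ish turn away
    psi <- phi + stats::runif(1, pi / 3, 2 * pi / 3)
    oar_ctr <- ctr + 0.28 * ext * c(cos(psi), sin(psi))
    oar <- setdiff(disc_indices(grid, oar_ctr, 0.14 * ext), tgt)
    masks <- list(target = tgt, oar = oar, body = body)
    roles <- c(target = "target", oar = "oar", body = "body")
    extra <- NULL
  } else {
    tgt <- disc_indices(grid, c(0, 0), tgt_r)
    gap_deg <- stats::runif(1, 0, 360)
    p <- grid_coords(grid)
    rr <- sqrt(p[, 1]^2 + p[, 2]^2)
    ang <- (atan2(p[, 2], p[, 1]) * 180 / pi) %% 360
    dang <- pmin(abs(ang - gap_deg), 360 - abs(ang - gap_deg))
    ring <- which(rr >= 0.30 * ext & rr <= 0.62 * ext &
                  dang > corridor_halfwidth_deg)
    oar <- setdiff(intersect(ring, body), tgt)
    masks <- list(target = tgt, oar = oar, body = body)
    roles <- c(target = "target", oar = "oar", body = "body")
    extra <- gap_deg
  }
  out <- list(grid = grid, structures = structure_set(masks, roles, grid),
              Dp = as.numeric(Dp))
  if (!is.null(extra)) out$corridor_deg <- extra
  out
}

#' Pencil-beam spot model parameters
#'
#' @param lateral_spacing spot lattice spacing across the target's
#'   beam's-eye-view extent (mm).
#' @param n_layers number of range (energy) layers spanning the target's
#'   depth extent.
#' @param sigma0 lateral Gaussian sigma at the body surface (mm).
#' @param sigma_growth increase of lateral sigma per mm of depth
#'   (dimensionless).
#' @param floor_rel relative sparsity floor: matrix entries below
#'   `floor_rel * max(column)` are dropped.
#' @export
spot_spec <- function(lateral_spacing = 5, n_layers = 3, sigma0 = 3,
                      sigma_growth = 0.02, floor_rel = 1e-6) {
  stopifnot(lateral_spacing > 0, n_layers >= 1, sigma0 > 0,
            sigma_growth >= 0, floor_rel >= 0)
  structure(list(lateral_spacing = lateral_spacing,
                 n_layers = as.integer(n_layers), sigma0 = sigma0,
                 sigma_growth = sigma_growth, floor_rel = floor_rel),
            class = "spot_spec")
}

#' Analytic Bragg-like depth-dose curve
#'
#' Unit-peak pristine-peak model: an entrance plateau that rolls off
#' logistically at the range plus a Gaussian Bragg peak centered at the
#' range.  Dose is zero at negative depth (outside the body).
#'
#' @param depth depth along the beam axis from the body surface (mm); may be
#'   a vector.
#' @param range_mm depth of the Bragg peak (mm).
#' @return nonnegative dose per unit spot intensity.
#' @export
bragg_depth_dose <- function(depth, range_mm) {
  sig <- max(2.5, 0.035 * range_mm)
  plateau <- 0.35 / (1 + exp((depth - range_mm) / 2))
  peak <- exp(-(depth - range_mm)^2 / (2 * sig^2))
  ifelse(depth < 0, 0, plateau + peak)
}

#' Lateral spread of a spot at depth
#'
#' @param depth depth from surface (mm).
#' @param spec a [spot_spec()].
#' @return Gaussian sigma (mm).
#' @export
lateral_sigma <- function(depth, spec) {
  spec$sigma0 + spec$sigma_growth * pmax(depth, 0)
}

# unit direction of travel for a gantry angle: 0 deg -> +y, increasing
# counter-clockwise.  The couch angle is carried as a candidate label in 2D.
beam_direction <- function(gantry_deg) {
  th <- deg2rad(gantry_deg)
  c(-sin(th), cos(th))
}

#' Compute a per-beam dose-influence matrix
#'
#' Casts the beam through the phantom and builds the sparse dose-influence
#' matrix `A` whose column `j` is the dose (per unit intensity) of spot `j`.
#' Spots form a lattice of lateral offsets covering the target's
#' beam's-eye-view extent crossed with range layers spanning the target's
#' depth extent; each spot deposits an analytic Bragg depth-dose modulated
#' by a depth-growing Gaussian lateral kernel.  Dose is deposited only
#' inside the body.  Columns are ordered by (range layer, lateral offset).
#'
#' @param grid a [voxel_grid()].
#' @param structures a [structure_set()].
#' @param beam one row of a [make_candidate_set()] data frame (or any list
#'   with `gantry_deg`).
#' @param spec a [spot_spec()].
#' @return list of class `dose_influence` with `beam_id`, `matrix`
#'   (a `dgCMatrix`, voxels x spots), and `spots` (a data frame with the
#'   lateral offset and range of every column).
#' @export
compute_dose_influence <- function(grid, structures, beam, spec = spot_spec()) {
  u <- beam_direction(beam$gantry_deg)
  w <- c(u[2], -u[1])                      # beam's-eye-view lateral axis
  p <- grid_coords(grid)
  t_along <- p %*% u
  l_across <- p %*% w
  body <- body_mask(structures)
  tgt <- target_mask(structures)
  if (length(body) == 0L)
    stop_bao("beam misses the body entirely", class = "qcbao_empty_matrix")
  t_entry <- min(t_along[body])
  depth <- as.numeric(t_along) - t_entry

  # spot lattice from the target's BEV extent and depth extent
  lt <- l_across[tgt]
  lc <- (min(lt) + max(lt)) / 2
  k <- floor((max(lt) - lc) / spec$lateral_spacing)
  offsets <- lc + spec$lateral_spacing * seq(-k, k)
  dt <- depth[tgt]
  ranges <- if (spec$n_layers == 1L) (min(dt) + max(dt)) / 2 else
    seq(min(dt), max(dt), length.out = spec$n_layers)

  in_body <- logical(length(depth))
  in_body[body] <- TRUE
  cols <- vector("list", length(ranges) * length(offsets))
  meta <- data.frame(spot = integer(0), range_mm = numeric(0),
                     lateral_mm = numeric(0))
  s <- 0L
  for (R in ranges) {
    g <- bragg_depth_dose(depth, R)
    sig <- lateral_sigma(depth, spec)
    for (off in offsets) {
      s <- s + 1L
      dose <- g * exp(-(as.numeric(l_across) - off)^2 / (2 * sig^2))
      dose[!in_body] <- 0
      mx <- max(dose)
      if (mx > 0) dose[dose < spec$floor_rel * mx] <- 0
      cols[[s]] <- dose
      meta <- rbind(meta, data.frame(spot = s, range_mm = R, lateral_mm = off))
    }
  }
  A <- methods::as(Matrix::Matrix(do.call(cbind, cols), sparse = TRUE),
                   "CsparseMatrix")
  if (all(Matrix::colSums(A[tgt, , drop = FALSE]) == 0))
    stop_bao("no spot covers the target for this beam",
             class = "qcbao_empty_matrix")
  structure(list(beam_id = beam$id %||% NA_integer_, matrix = A, spots = meta),
            class = "dose_influence")
}

#' Assemble a BAO problem instance
#'
#' Computes the dose-influence matrix of every candidate beam and bundles
#' grid, structures, candidates, prescriptions and matrices into the
#' optimization input.
#'
#' @param phantom output of [generate_phantom()] (or a list with `grid`,
#'   `structures`, `Dp`).
#' @param candidates a [make_candidate_set()] data frame.
#' @param spec a [spot_spec()].
#' @param objective optional [objective_spec()] to attach.
#' @return object of class `bao_instance`.
#' @export
build_instance <- function(phantom, candidates, spec = spot_spec(),
                           objective = NULL) {
  di <- lapply(seq_len(nrow(candidates)), function(i)
    compute_dose_influence(phantom$grid, phantom$structures,
                           candidates[i, ], spec))
  inst <- structure(list(
    grid = phantom$grid, structures = phantom$structures,
    candidates = candidates, dose_influence = di,
    Dp = phantom$Dp, spot_spec = spec, objective = objective,
    corridor_deg = phantom$corridor_deg %||% NULL
  ), class = "bao_instance")
  validate_instance(inst)
  inst
}

validate_instance <- function(inst) {
  B <- nrow(inst$candidates)
  if (length(inst$dose_influence) != B)
    stop_bao("one dose-influence matrix per candidate required")
  nv <- n_voxels(inst$grid)
  for (di in inst$dose_influence) {
    A <- di$matrix
    if (nrow(A) != nv) stop_bao("dose-influence row count must equal voxel count")
    if (ncol(A) < 1L) stop_bao("each beam needs at least one spot")
    if (length(A@x) && min(A@x) < 0)
      stop_bao("dose-influence entries must be nonnegative")
  }
  invisible(inst)
}

#' @export
print.bao_instance <- function(x, ...) {
  cat("BAO instance:", nrow(x$candidates), "candidate beams,",
      n_voxels(x$grid), "voxels (", paste(x$grid$shape, collapse = "x"),
      "grid,", x$grid$spacing, "mm )\n")
  cat("  structures:", paste(sprintf("%s[%s]", names(x$structures$roles),
                                     x$structures$roles), collapse = ", "), "\n")
  cat("  prescription:", x$Dp, "Gy\n")
  m <- vapply(x$dose_influence, function(d) ncol(d$matrix), 1L)
  cat("  spots per beam:", min(m), "-", max(m), "\n")
  invisible(x)
}
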