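#' Save a BAO instance to a directory
#'
#' Writes one Matrix Market file per candidate beam, the structure masks as
#' a plain-text CSV of 1-based voxel indices, and a JSON manifest tying the
#' pieces together.  [load_instance()] reproduces the instance bit-exactly
#' (Matrix Market entries are written at full double precision).
#'
#' @param instance a `bao_instance`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
save_instance <- function(instance, dir) {
  validate_instance(instance)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  beams <- list()
  for (i in seq_len(nrow(instance$candidates))) {
    id <- instance$candidates$id[i]
    fn <- sprintf("beam_%03d.mtx", id)
    Matrix::writeMM(instance$dose_influence[[i]]$matrix, file.path(dir, fn))
    utils::write.csv(instance$dose_influence[[i]]$spots,
                     file.path(dir, sprintf("beam_%03d_spots.csv", id)),
                     row.names = FALSE)
    beams[[as.character(id)]] <- fn
  }
  st <- instance$structures
  sdf <- do.call(rbind, lapply(names(st$masks), function(nm)
    data.frame(structure = nm, role = unname(st$roles[nm]),
               index = st$masks[[nm]])))
  utils::write.csv(sdf, file.path(dir, "structures.csv"), row.names = FALSE)
  manifest <- list(
    format = "qcbao-instance-v1",
    grid = list(shape = instance$grid$shape, spacing = instance$grid$spacing),
    Dp = instance$Dp,
    candidates = instance$candidates[, c("id", "couch_deg", "gantry_deg")],
    structures_file = "structures.csv",
    beams = beams,
    spot_spec = unclass(instance$spot_spec),
    corridor_deg = instance$corridor_deg
  )
  if (!is.null(instance$objective))
    manifest$objective <- objective_spec_to_list(instance$objective)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(dir)
}

#' Load a BAO instance from a directory
#'
#' @param dir directory written by [save_instance()].
#' @return a `bao_instance`.
#' @export
load_instance <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop_bao("no manifest.json in ", dir,
                                 class = "qcbao_format_error")
  man <- jsonlite::read_json(mf, simplifyVector = TRUE)
  grid <- voxel_grid(man$grid$shape, man$grid$spacing)
  sdf <- utils::read.csv(file.path(dir, man$structures_file))
  lev <- unique(sdf$structure)   # preserve on-disk structure order
  fct <- factor(sdf$structure, levels = lev)
  masks <- split(as.integer(sdf$index), fct)
  roles <- vapply(split(sdf$role, fct), function(r) r[1], "")
  structures <- structure_set(masks, roles, grid)
  cand <- as.data.frame(man$candidates)
  cand$id <- as.integer(cand$id)
  class(cand) <- c("beam_candidates", "data.frame")
  nv <- n_voxels(grid)
  di <- lapply(seq_len(nrow(cand)), function(i) {
    id <- cand$id[i]
    fn <- man$beams[[as.character(id)]]
    if (is.null(fn) || !file.exists(file.path(dir, fn)))
      stop_bao("missing dose-influence file for beam id ", id,
               class = "qcbao_format_error")
    A <- tryCatch(Matrix::readMM(file.path(dir, fn)),
                  error = function(e) stop_bao(
                    "malformed Matrix Market file ", fn, ": ",
                    conditionMessage(e), class = "qcbao_format_error"))
    A <- methods::as(A, "CsparseMatrix")
    if (length(A@x) && min(A@x) < 0)
      stop_bao("negative dose-influence entry in ", fn,
               class = "qcbao_format_error")
    if (nrow(A) != nv)
      stop_bao("voxel count mismatch in ", fn, " (", nrow(A), " rows, grid has ",
               nv, " voxels)", class = "qcbao_format_error")
    sp_fn <- file.path(dir, sprintf("beam_%03d_spots.csv", id))
    spots <- if (file.exists(sp_fn)) utils::read.csv(sp_fn) else NULL
    structure(list(beam_id = id, matrix = A, spots = spots),
              class = "dose_influence")
  })
  spec <- if (!is.null(man$spot_spec))
    do.call(spot_spec, man$spot_spec) else spot_spec()
  obj <- if (!is.null(man$objective)) objective_spec_from_list(man$objective)
  inst <- structure(list(grid = grid, structures = structures,
                         candidates = cand, dose_influence = di,
                         Dp = man$Dp, spot_spec = spec, objective = obj,
                         corridor_deg = man$corridor_deg),
                    class = "bao_instance")
  validate_instance(inst)
  inst
}
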