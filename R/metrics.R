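#' Conformity index
#'
#' `CI = V100^2 / (V * V'100)` where `V100` is the number of target voxels
#' receiving at least the prescription dose, `V` the target size, and
#' `V'100` the number of voxels anywhere receiving at least the
#' prescription.  Bounded in `[0, 1]`; equals 1 when the prescription
#' isodose coincides exactly with the target.
#'
#' @param d dose vector (Gy).
#' @param target_mask integer voxel indices of the target.
#' @param Dp prescription dose (Gy), > 0.
#' @export
conformity_index <- function(d, target_mask, Dp) {
  if (length(target_mask) == 0L) stop_bao("empty target mask")
  if (Dp <= 0) stop_bao("`Dp` must be > 0")
  v100 <- sum(d[target_mask] >= Dp)
  vp100 <- sum(d >= Dp)
  if (vp100 == 0) return(0)
  v100^2 / (length(target_mask) * vp100)
}

#' Normalized maximum target dose
#'
#' Maximum dose over the target as a percentage of the prescription.
#'
#' @inheritParams conformity_index
#' @return percentage (100 means the hottest target voxel is exactly at
#'   prescription).
#' @export
normalized_dmax <- function(d, target_mask, Dp) {
  if (length(target_mask) == 0L) stop_bao("empty target mask")
  if (Dp <= 0) stop_bao("`Dp` must be > 0")
  100 * max(d[target_mask]) / Dp
}

#' Vx: percent volume at or above a dose threshold
#'
#' @param d dose vector (Gy).
#' @param mask structure voxel indices.
#' @param x_gy dose threshold (Gy); comparison is inclusive (`>=`).
#' @export
vx_percent <- function(d, mask, x_gy) {
  if (length(mask) == 0L) stop_bao("empty mask")
  100 * mean(d[mask] >= x_gy)
}

#' Mean structure dose
#'
#' @inheritParams vx_percent
#' @export
mean_dose <- function(d, mask) {
  if (length(mask) == 0L) stop_bao("empty mask")
  mean(d[mask])
}

#' Cumulative dose-volume histogram
#'
#' Volume fraction of the structure receiving at least each dose level, on
#' a uniform grid from 0 to the structure's maximum dose.
#'
#' @inheritParams vx_percent
#' @param n_bins number of bin edges (>= 2).
#' @return object of class `dvh_curve`: list with `dose` (bin edges, Gy)
#'   and `fraction` (non-increasing, starting at 1).
#' @export
compute_dvh <- function(d, mask, n_bins = 101) {
  if (length(mask) == 0L) stop_bao("empty mask")
  if (n_bins < 2) stop_bao("`n_bins` must be >= 2")
  dm <- d[mask]
  edges <- seq(0, max(dm), length.out = n_bins)
  frac <- vapply(edges, function(e) mean(dm >= e), 1.0)
  structure(list(dose = edges, fraction = frac), class = "dvh_curve")
}

#' D95 normalization scale
#'
#' Scale factor bringing the plan to the convention that 95% of the target
#' receives at least 100% of the prescription.  `D95` is the
#' `ceiling(0.95 V)`-th largest target dose; the returned scale is
#' `Dp / D95`, so after multiplying the dose (equivalently the intensities)
#' by it, `vx_percent(target, Dp) >= 95`.
#'
#' @inheritParams conformity_index
#' @return positive scale factor.
#' @export
normalize_to_d95 <- function(d, target_mask, Dp) {
  if (length(target_mask) == 0L) stop_bao("empty target mask")
  dt <- sort(d[target_mask], decreasing = TRUE)
  k <- ceiling(0.95 * length(dt))
  d95 <- dt[k]
  if (d95 <= 0) stop_bao("target dose is zero at the 95% level; cannot normalize")
  scale <- Dp / d95
  # guard the coverage postcondition against downward rounding of d95*scale
  if (d95 * scale < Dp) scale <- scale * (1 + 4 * .Machine$double.eps)
  scale
}

#' Plan-quality summary
#'
#' Conformity index and normalized target Dmax, plus per-structure mean
#' dose, max dose and optional Vx entries.
#'
#' @param d dose vector (Gy).
#' @param structures a `structure_set`.
#' @param Dp prescription dose (Gy).
#' @param vx_gy numeric vector of Vx thresholds (Gy) evaluated for every
#'   structure.
#' @return object of class `plan_quality`.
#' @export
plan_quality <- function(d, structures, Dp, vx_gy = numeric(0)) {
  tm <- target_mask(structures)
  per <- lapply(names(structures$masks), function(nm) {
    mask <- structures$masks[[nm]]
    vx_names <- if (length(vx_gy)) paste0("V", vx_gy) else character(0)
    if (length(mask) == 0L)
      return(list(role = unname(structures$roles[nm]), Dmean = NA_real_,
                  Dmax = NA_real_,
                  Vx = setNames(rep(NA_real_, length(vx_gy)), vx_names)))
    list(role = unname(structures$roles[nm]),
         Dmean = mean_dose(d, mask), Dmax = max(d[mask]),
         Vx = setNames(vapply(vx_gy, function(x) vx_percent(d, mask, x), 1.0),
                       vx_names))
  })
  names(per) <- names(structures$masks)
  structure(list(CI = conformity_index(d, tm, Dp),
                 Dmax_pct = normalized_dmax(d, tm, Dp),
                 structures = per, Dp = Dp),
            class = "plan_quality")
}

#' @export
print.plan_quality <- function(x, ...) {
  cat(sprintf("Plan quality (Dp = %g Gy): CI = %.3f, target Dmax = %.1f%%\n",
              x$Dp, x$CI, x$Dmax_pct))
  for (nm in names(x$structures)) {
    s <- x$structures[[nm]]
    cat(sprintf("  %-12s [%s]  Dmean %7.3f Gy  Dmax %7.3f Gy\n",
                nm, s$role, s$Dmean, s$Dmax))
  }
  invisible(x)
}

#' Write DVH curves for several structures as CSV
#'
#' @param d dose vector.
#' @param structures a `structure_set`.
#' @param path output CSV path.
#' @param n_bins bin edges per curve.
#' @export
write_dvh_csv <- function(d, structures, path, n_bins = 101) {
  rows <- do.call(rbind, lapply(names(structures$masks), function(nm) {
    if (length(structures$masks[[nm]]) == 0L) return(NULL)
    cv <- compute_dvh(d, structures$masks[[nm]], n_bins)
    data.frame(structure = nm, dose_gy = cv$dose, volume_fraction = cv$fraction)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
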