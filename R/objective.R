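#' A single prescription term of the plan objective
#'
#' The plan objective is a weighted sum of per-structure terms of four
#' kinds:
#' \describe{
#'   \item{`target_lsq`}{least squares pull of target dose toward the
#'     prescription level `b` (two-sided);}
#'   \item{`oar_lsq`}{least squares penalty on OAR dose above `b`
#'     (one-sided by default, see [objective_spec()]);}
#'   \item{`dvh_max`}{DVH-max constraint: at most a fraction `p` of the
#'     structure may exceed dose `b`; enforced by penalizing the violating
#'     voxels beyond rank `ceil(p * n)` of the descending dose sort;}
#'   \item{`dvh_min`}{DVH-min constraint on the target: at least a fraction
#'     `p` must reach dose `b`; penalizes cold voxels within the top
#'     `ceil(p * n)` ranks.}
#' }
#' Each term is normalized by its structure's voxel count.
#'
#' @param kind term kind (see above).
#' @param structure structure name the term applies to.
#' @param weight nonnegative weight.
#' @param dose dose level `b` in Gy.
#' @param fraction DVH volume fraction `p` in (0, 1]; DVH kinds only.
#' @export
prescription_term <- function(kind, structure, weight, dose, fraction = NULL) {
  kind <- match.arg(kind, c("target_lsq", "oar_lsq", "dvh_max", "dvh_min"))
  if (!is.numeric(weight) || weight < 0) stop_bao("`weight` must be >= 0")
  if (!is.numeric(dose) || dose < 0) stop_bao("`dose` must be >= 0")
  is_dvh <- kind %in% c("dvh_max", "dvh_min")
  if (is_dvh) {
    if (is.null(fraction) || fraction <= 0 || fraction > 1)
      stop_bao("DVH terms need `fraction` in (0, 1]")
  } else if (!is.null(fraction)) {
    stop_bao("`fraction` only applies to DVH terms")
  }
  structure(list(kind = kind, structure = structure,
                 weight = as.numeric(weight), dose = as.numeric(dose),
                 fraction = if (is_dvh) as.numeric(fraction) else NULL),
            class = "prescription_term")
}

#' Plan objective specification
#'
#' Ordered collection of [prescription_term()]s.
#'
#' @param terms list of `prescription_term`s.
#' @param oar_two_sided if `TRUE`, `oar_lsq` terms penalize any deviation
#'   from `b` (two-sided) instead of only doses above `b`.
#' @return object of class `objective_spec`; `N1` counts the least-squares
#'   terms and `N2` the DVH-max terms.
#' @export
objective_spec <- function(terms, oar_two_sided = FALSE) {
  if (inherits(terms, "prescription_term")) terms <- list(terms)
  stopifnot(all(vapply(terms, inherits, TRUE, "prescription_term")))
  kinds <- vapply(terms, function(t) t$kind, "")
  if (!any(kinds == "target_lsq"))
    stop_bao("objective needs at least one target_lsq term")
  if (sum(kinds == "dvh_min") > 1L)
    stop_bao("at most one dvh_min term is allowed")
  structure(list(terms = terms,
                 N1 = sum(kinds %in% c("target_lsq", "oar_lsq")),
                 N2 = sum(kinds == "dvh_max"),
                 oar_two_sided = isTRUE(oar_two_sided)),
            class = "objective_spec")
}

objective_spec_to_list <- function(spec) {
  list(oar_two_sided = spec$oar_two_sided,
       terms = lapply(spec$terms, function(t)
         list(kind = t$kind, structure = t$structure, weight = t$weight,
              dose = t$dose, fraction = t$fraction)))
}

objective_spec_from_list <- function(x) {
  terms <- x$terms
  if (is.data.frame(terms))
    terms <- lapply(seq_len(nrow(terms)), function(i) as.list(terms[i, ]))
  objective_spec(lapply(terms, function(t) {
    fr <- t$fraction
    if (!is.null(fr) && is.na(fr)) fr <- NULL
    prescription_term(t$kind, t$structure, t$weight, t$dose, fr)
  }), oar_two_sided = isTRUE(x$oar_two_sided))
}

#' Default objective for a synthetic phantom
#'
#' Target least squares at the prescription, a one-sided OAR least-squares
#' term plus a DVH-max term per OAR, and a DVH-min term keeping 95% of the
#' target at 95% of the prescription.
#'
#' @param structures a `structure_set`.
#' @param Dp prescription dose (Gy).
#' @export
default_objective <- function(structures, Dp) {
  terms <- list(prescription_term("target_lsq",
                                  role_name(structures, "target"),
                                  weight = 10, dose = Dp))
  for (nm in names(structures$roles)[structures$roles == "oar"]) {
    terms <- c(terms, list(
      prescription_term("oar_lsq", nm, weight = 10, dose = 0.2 * Dp),
      prescription_term("dvh_max", nm, weight = 10, dose = 0.4 * Dp,
                        fraction = 0.25)))
  }
  terms <- c(terms, list(
    # integral-dose sparing: penalize body dose above 10% of prescription,
    # the analogue of keeping the mean body dose low
    prescription_term("oar_lsq", role_name(structures, "body"),
                      weight = 0.25, dose = 0.1 * Dp),
    prescription_term("dvh_min", role_name(structures, "target"),
                      weight = 10, dose = 0.95 * Dp, fraction = 0.95)))
  objective_spec(terms)
}

# descending-sort ranks over a structure's doses; ties broken by stable
# order on voxel index
descending_ranks <- function(idx, d) order(-d[idx], seq_along(idx))

#' Identify the active voxel sets of each objective term
#'
#' Implements the iterative-convex-relaxation bookkeeping: least-squares
#' terms activate on voxels whose dose deviates from the level (two-sided
#' on the target, above-level only for OARs by default); a DVH-max term
#' activates on the violating tail of the descending dose sort when the
#' constraint is violated at rank `ceil(p * n)`; a DVH-min term activates on
#' cold voxels within the top `ceil(p * n)` ranks when the rank-`k` dose
#' falls below the level.
#'
#' @param d dose vector (Gy), one entry per voxel.
#' @param spec an [objective_spec()].
#' @param structures the `structure_set` naming the term structures.
#' @return object of class `active_sets`: per term a list with `indices`
#'   (voxel indices), the level `b`, weight `w` and normalizer `n`.
#' @export
identify_active_sets <- function(d, spec, structures) {
  sets <- lapply(spec$terms, function(t) {
    idx <- structures$masks[[t$structure]]
    if (is.null(idx))
      stop_bao("objective term references unknown structure '", t$structure,
               "'", class = "qcbao_config_error")
    n <- length(idx)
    ds <- d[idx]
    act <- switch(t$kind,
      target_lsq = idx[ds != t$dose],
      oar_lsq = if (spec$oar_two_sided) idx[ds != t$dose] else idx[ds > t$dose],
      dvh_max = {
        k <- ceiling(t$fraction * n)
        ord <- descending_ranks(idx, d)
        if (ds[ord[k]] >= t$dose) {
          tail_ix <- idx[ord[k:n]]
          tail_ix[d[tail_ix] > t$dose]
        } else integer(0)
      },
      dvh_min = {
        k <- ceiling(t$fraction * n)
        ord <- descending_ranks(idx, d)
        if (ds[ord[k]] <= t$dose) {
          top_ix <- idx[ord[1:k]]
          top_ix[d[top_ix] < t$dose]
        } else integer(0)
      })
    list(kind = t$kind, structure = t$structure, indices = as.integer(act),
         w = t$weight, b = t$dose, n = n)
  })
  structure(list(sets = sets), class = "active_sets")
}

#' Evaluate the plan objective on frozen active sets
#'
#' Sum over terms of `(w / n) * ||d[active] - b||^2`; empty active sets
#' contribute zero.
#'
#' @param d dose vector.
#' @param spec an [objective_spec()] (consistency check only).
#' @param sets an [identify_active_sets()] result.
#' @return nonnegative scalar.
#' @export
evaluate_objective <- function(d, spec, sets) {
  stopifnot(inherits(sets, "active_sets"))
  val <- 0
  for (s in sets$sets) {
    if (length(s$indices) == 0L) next
    val <- val + (s$w / s$n) * sum((d[s$indices] - s$b)^2)
  }
  val
}

#' Collapse the objective to per-voxel quadratic coefficients
#'
#' On frozen active sets the objective is a diagonal quadratic in dose:
#' `f(d) = sum_k alpha_k (d_k - beta_k)^2 + const` over active voxels,
#' where voxels active in several terms get summed coefficients, the
#' weighted-mean level, and a constant offset preserving the total.  This
#' shared kernel drives both the intensity update (weighted least squares)
#' and the assembly of the binary beam-selection subproblem.
#'
#' @param spec an [objective_spec()].
#' @param sets an [identify_active_sets()] result.
#' @return list with integer `voxel`, numeric `alpha`, `beta` (parallel
#'   vectors, sorted by voxel) and scalar `const`.
#' @export
voxel_quadratic <- function(spec, sets) {
  vox <- integer(0); al <- numeric(0); be <- numeric(0)
  for (s in sets$sets) {
    if (length(s$indices) == 0L) next
    vox <- c(vox, s$indices)
    al <- c(al, rep(s$w / s$n, length(s$indices)))
    be <- c(be, rep(s$b, length(s$indices)))
  }
  if (length(vox) == 0L)
    return(list(voxel = integer(0), alpha = numeric(0), beta = numeric(0),
                const = 0))
  o <- order(vox)
  vox <- vox[o]; al <- al[o]; be <- be[o]
  grp <- cumsum(!duplicated(vox))
  alpha <- as.numeric(rowsum(al, grp))
  ab <- as.numeric(rowsum(al * be, grp))
  ab2 <- as.numeric(rowsum(al * be^2, grp))
  beta <- ab / alpha
  const <- sum(ab2 - alpha * beta^2)
  list(voxel = vox[!duplicated(vox)], alpha = alpha, beta = beta,
       const = const)
}

# evaluate f from the quadratic form (cross-check / internal use)
eval_voxel_quadratic <- function(d, vq) {
  if (length(vq$voxel) == 0L) return(vq$const)
  sum(vq$alpha * (d[vq$voxel] - vq$beta)^2) + vq$const
}
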